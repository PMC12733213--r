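---
title: "Methods: meta-analysis of study-level cost-effectiveness evaluations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: meta-analysis of study-level cost-effectiveness evaluations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ceameta)
```

## The problem

Economic evaluations of a new therapy — here the siRNA lipid-lowering
agent inclisiran added to maximally tolerated statin-based standard of
care (SoC) — are published one health system at a time, each with its own
Markov or microsimulation model, price year, currency, risk population,
and willingness-to-pay (WTP) convention. A decision-maker who wants a
cross-country picture needs the study-level results harmonized onto one
monetary scale and synthesized with methods that respect how ratio
outcomes behave. `ceameta` implements that workflow for study-level data:
one row per modeled sub-scenario, carrying the incremental QALY gain
($\Delta E$), the incremental lifetime cost versus SoC ($\Delta C$), the
intervention arm's total lifetime cost, and the reported incremental
cost-effectiveness ratio (ICER).

The packaged dataset (`load_records("mastaleru2025")`) transcribes a
published 17-observation table of inclisiran evaluations from Singapore,
the USA, Switzerland, the UK, China and Australia (2020–2025). Modeled
sub-scenarios (age-at-intervention bands, risk strata) are retained as
separate observations, because they represent analytically distinct
populations. All monetary values in the fixture are already
purchasing-power-parity (PPP) adjusted US dollars at 2024 prices. Two
transcription decisions matter and are deliberate:

* In the source table the column labeled as an ICER in dollars actually
  holds the per-patient *incremental cost* — its minimum, median and
  maximum (8,739.16 / 51,287.21 / 3,422,471.51) are exactly the values
  the source summarizes as incremental cost — while the "per-QALY" column
  holds the reported ICER. The fixture maps `incremental_cost` and
  `icer_per_qaly` accordingly.
* The source uses both "UK" and "United Kingdom" for the same
  jurisdiction; `load_records()` canonicalizes to one label and keeps the
  original strings in an attribute.

Because reported ICERs, costs and QALY gains come from independently
rounded table columns, the package never *repairs* them: a consistency
check (`validate_table()`) flags records where the reported ICER and
$\Delta C/\Delta E$ disagree beyond a tolerance (default 1%), and those
flags delimit exactly where an ICER-based and an NMB-based
cost-effectiveness classification can diverge. Fourteen of the seventeen
fixture rows carry such a flag, which is typical of transcribed economic
tables and is reported, not rejected.

## Monetary harmonization

Costs are harmonized in two steps, each a pure multiplication: CPI
inflation within the original currency from the study's price year to
the target year (default 2024), then division by the country's PPP
conversion factor (local currency units per international dollar). The
identical composite factor is applied to the total cost, the incremental
cost and the ICER, so the internal relation ICER $= \Delta C/\Delta E$
survives harmonization whenever the raw record satisfied it, and QALY
fields are never touched. Records already labeled `PPP-USD` pass through
unchanged, making the operation idempotent; the packaged fixture is in
that state, so the harmonization module is exercised on synthetic and
user-supplied configuration tables (CSV; no network retrieval — the CPI
and PPP series are user inputs). Log-linear interpolation of missing CPI
years inside a covered range is available but off by default, since
silently bridging gaps in an official index series should be a visible
choice.

## Net monetary benefit and classification

At threshold $\lambda$ (USD/QALY), the net monetary benefit of a record
is

$$\mathrm{NMB}(\lambda) = \lambda \,\Delta E - C,$$

computed at full precision. The *cost basis* $C$ is an explicit
parameter. The health-economics standard is the incremental cost
(`basis = "incremental"`, the default), and the published classification
counts (3 of 17 cost-effective at $\lambda$ = 50,000; 8 of 17 at
150,000) reproduce under it. The published NMB summary table, however,
reproduces exactly only when $C$ is the intervention arm's *total*
lifetime cost (`basis = "total"`): for instance the minimum at
$\lambda$ = 50,000, $-881{,}984{,}657$ = $50{,}000 \times 0.19665 -
881{,}994{,}489.92$, is unambiguous about the basis used. Rather than
privileging either reading, both bases are first-class and every output
is labeled with the basis that produced it.

NMB is affine in $\lambda$ with slope $\Delta E$, so `nmb_shift()`
re-thresholds in closed form; tests hold this identity to machine
precision against direct recomputation, per record and in the mean.
Classification uses strictly positive NMB (ties at exactly zero are "not
cost-effective", the conservative reading), and is monotone
non-decreasing in $\lambda$ whenever all QALY gains are positive.
Country affordability compares each country's mean NMB at its own
threshold — explicit where published (Singapore 50,000; USA 150,000;
China and UK 30,000 in the shipped table), a 1–3$\times$ GDP-per-capita
multiple where only GDP is available (1$\times$ by default), and verdict
"unknown" otherwise.

One printed count is knowingly not reproduced: at $\lambda$ = 100,000
the per-study data give 6 cost-effective records under every reading we
can construct, while the published classification table prints 5. The
package reports the recomputed value.

## Descriptive conventions

Dispersion uses the sample SD ($n-1$ denominator) and normal 95%
intervals (mean $\pm 1.96\,$SE); quantiles use linear interpolation at
rank $(n-1)p$. These two conventions are the discriminating ones: on the
17 fixture ICERs they reproduce the published quartiles exactly
(53,149.66 / 83,717.19 / 524,740.92), and no other common quantile rule
reproduces both hinges. Groups of size one report a mean only — SD is
absent, not zero. Age-stratified summaries exclude records whose source
reports no usable age (`age_group == "unknown"`).

## Pooling

ICERs are ratios and are not pooled directly on the identity scale.
The inverse-variance machinery applies to QALY gains, incremental costs
and NMB; ICERs are pooled as $\log(\mathrm{ICER})$ and back-transformed,
a geometric-mean-type summary. The random-effects model uses the
DerSimonian–Laird moment estimator,

$$\hat\tau^2 = \max\!\left(0,\;
  \frac{Q - (k-1)}{\sum w_i - \sum w_i^2 / \sum w_i}\right),
  \qquad w_i = 1/\mathrm{SE}_i^2,$$

with re-weighted mean $\hat\mu = \sum w_i^* y_i / \sum w_i^*$,
$w_i^* = 1/(\mathrm{SE}_i^2 + \hat\tau^2)$, and
$I^2 = \max(0, (Q - df)/Q) \times 100$. The implementation is authored
in-package and is cross-checked in the test suite against both a
brute-force oracle and `metafor::rma(method = "DL")` to $10^{-10}$.

Study-level cost-effectiveness tables virtually never report a
within-study variance, so any inverse-variance synthesis of such data
rests on an imputation convention. `impute_se()` makes that convention
explicit and deterministic: a constant coefficient of variation
(default, cv = 0.2, with an SE floor of $10^{-6}$ of the column's mean
absolute value so near-zero estimates cannot take infinite weight), a
common fixed SE (under which the fixed-effect pooled estimate is the
unweighted mean — a useful degenerate check), or a user-supplied SE
column. Pooled outputs are labeled with the convention used. A
consequence worth noting: under *any* constant log-scale SE the DL
weights are equal and the back-transformed pooled log-ICER is exactly
the geometric mean of the ICERs — 211,596 USD/QALY on the fixture — so
that particular published value is convention-insensitive and is
asserted in the tests. The published pooled CIs, $I^2$ and $\tau^2$
values, by contrast, depend on the unstated variance source and are not
asserted anywhere; the estimators are validated by oracle equivalence
and parameter recovery instead (below). A REML alternative to
DerSimonian–Laird was considered and deliberately left out: with the
variance source already an imputation convention, a likelihood-based
refinement of $\tau^2$ would suggest a precision the data do not carry.

## Meta-regression

`fit_ols()` fits unweighted OLS of NMB (or ICER, or QALY gain) on
publication year and dummy-coded country and intervention, with
reference levels Australia and inclisiran monotherapy so each
coefficient is a contrast against that reference. Inference uses the t
distribution with $n - \mathrm{rank}$ degrees of freedom and no
heteroskedasticity correction. With 17 observations and three
categorical factors, perfect collinearity is expected, not exceptional:
every Singapore and USA row is the combination-with-SoC label and the
single Swiss row is the only "Other", so those two indicators are exact
linear combinations of country dummies. Collinear columns are dropped
deterministically — last entered, first dropped, with rank decisions at
relative tolerance $10^{-10}$ — and reported in `dropped_terms`, never
silently absorbed. Added-variable data (`partial_regression()`) are
residual-on-residual pairs whose OLS slope equals the full-model
coefficient (the Frisch–Waugh–Lovell identity, tested numerically for
every retained term).

On the fixture, the NMB-on-year-country-intervention model at
$\lambda$ = 50,000 under the total-cost basis reproduces the published
coefficient table to its printed precision (year $-196{,}046{,}100$;
China $+392{,}363{,}300$; Singapore $+196{,}419{,}900$; all p-values to
four decimals), which pins down both the basis and the threshold that
model used. Two published companion tables at higher thresholds do not
correspond to any model constructible from the printed per-study data
and are not asserted, nor are the published adjusted $R^2$ values, which
are inconsistent with each other in the source.

Simple trend regressions (`trend_slope()`) reproduce the published
slopes exactly: $-170{,}748$ USD/QALY per publication year for the ICER
(p = 0.56) and $+0.035$ QALYs per year for the QALY gain (p = 0.45).

## Publication bias and sensitivity

`egger_test()` regresses the standardized effect $y_i/\mathrm{SE}_i$ on
precision $1/\mathrm{SE}_i$ and t-tests the intercept (df = $k-2$),
solved in closed form from the normal equations; the test suite checks
it against `lm()` and verifies invariance under joint rescaling of
effects and SEs. On the fixture it runs only under a declared SE
imputation convention and its output is labeled with that convention,
so the published Egger p-values are not comparison targets.

`leave_one_out()` recomputes a summary $k$ times with one record
excluded; for the mean every row satisfies the exact identity
$\bar x_{-i} = (k\bar x - x_i)/(k-1)$, which the tests hold to machine
precision. The pooled-estimate variant re-estimates $\tau^2$ within
every leave-one-out replicate (a full re-fit, not a plug-in), because
removing an extreme study changes the heterogeneity it contributed to.

## The synthetic-data generator

`generate_studies()` emits study tables with known truth: true QALY
gains $\theta_i \sim N(\mu, \tau^2)$ truncated at zero (negative draws
are resampled with a bounded retry budget), observed gains
$y_i = \theta_i + N(0, \mathrm{SE}_i^2)$ with the SE drawn from a
configurable family, lognormal incremental costs scaled by per-country
multipliers, ICERs computed exactly as $\Delta C/\Delta E$ (generated
tables therefore raise zero consistency flags), and covariates assigned
deterministically. Defaults target the empirical regime of the fixture:
$\mu = 0.34$, $\tau = 0.27$, costs spanning roughly $10^4$–$10^6$ USD
with median far below mean.

Three design choices deserve explanation:

* **Covariate assignment.** Countries cycle fastest; the year advances
  one step per full country cycle; the intervention label has its own
  seeded stream. A plain shared round-robin was rejected because with
  six countries and six years it confounds year with the country cost
  multipliers perfectly, and a recovery experiment for a year effect
  then estimates the confounded contrast rather than the effect.
* **Truncation and recovery experiments.** At the empirical default
  regime ($\mu/\tau \approx 1.26$) the zero-truncation deflates the
  realized between-study variance by roughly a fifth — a real feature
  of nonnegative QALY gains, not an estimator fault. Validation
  experiments that target the *nominal* $\tau^2$ therefore place
  $\mu$ well away from the boundary (e.g. $\mu = 1$), where the
  generating law is the exact normal; at those settings, 500 replicates
  at $k=20$ give DL $\hat\tau^2$ bias below 10% of the truth and
  empirical 95% CI coverage for $\mu$ of about 93–96%. The Egger
  type-I-error experiment additionally sets $\tau = 0$, since the
  test's nominal level is only guaranteed without
  heterogeneity-induced heteroskedasticity.
* **Selection mechanism.** With `selection_strength` $s > 0$, a
  candidate is retained with probability $\exp(-s \max(0, u))$ where
  $u$ scales the shortfall of the observed effect below $\mu$ by the
  record's relative imprecision — suppression grows with both an
  unfavorable effect and a large SE, the classic small-study mechanism.
  At moderate strength this demonstrably shifts the expected Egger
  intercept upward and raises the rejection rate relative to
  no-selection baselines. It is *not* globally monotone in $s$: at
  extreme strength only precise, favorable studies survive and the
  asymmetry gradient saturates, so the tests assert the
  selection-versus-none contrast, not monotonicity over all strengths.

Problem sizes in the shipped validation experiments — 500 replicates at
$k = 20$ for pooling recovery, 200 at $k = 100$ for the year-effect
regression, 1,000 simulated meta-analyses at $k = 20$ for the Egger
level — were chosen to put Monte-Carlo error comfortably inside the
asserted bounds while keeping the whole suite a sub-minute run on one
core.

What passing these tests shows — and does not. The generator emulates
between-study heterogeneity, skewed costs, covariate effects and
small-study selection at the *study* level. It does not simulate
patient-level disease trajectories, correlated costs-and-effects within
a study, non-normal effect distributions, or reporting conventions of
real journals. Recovery on synthetic data validates the estimators under
the stated generating law; it cannot certify the published pooled values
whose within-study variance source is unstated.

## The pipeline

`run_pipeline()` executes the full sequence on a study table and writes
CSV mirrors of the harmonized data, the subgroup summaries, the ICER
distribution, the NMB threshold summaries, the classification and
affordability tables, the trend regressions, the convention-labeled
Egger result and the leave-one-out trace, plus a JSON manifest recording
every convention in force (cost basis, SE imputation, quantile rule,
$\tau^2$ estimator, target price year, seed). The fixture path is fully
deterministic: identical configurations produce byte-identical bundles,
which the tests check file by file. The package's surface is its R
functions; the pipeline, this vignette and `scripts/acceptance.R` are
the intended entry points, and no shell wrapper is shipped.

## Known limitations

* Monetary harmonization assumes the user supplies CPI/PPP series; no
  vintage resolution or source retrieval is attempted.
* Inverse-variance results on data without reported variances are only
  as meaningful as the declared imputation convention; they are labeled,
  but no label turns an assumption into data.
* With 17 observations and three categorical covariates the
  meta-regression is descriptive, not confirmatory; several published
  companion values (one classification count, one NMB median's sign,
  two coefficient tables, the adjusted $R^2$ values) are inconsistent
  with the published per-study data and are documented rather than
  matched.
* Quadrant handling for negative $\Delta E$ or $\Delta C$ is limited to
  tagging and exclusion from ICER-based classification; proper
  net-benefit analysis on all four quadrants is the recommended route
  for such data.
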
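test_that("OLS fit is exact on noiseless linear data", {
  tt <- tiny_table(6)
  tt$qaly_gain <- 2 * (tt$pub_year - 2020) + 1  # y = 2x + 1 in year units
  f <- fit_ols(design_spec("qaly_gain", covariates = "year"), tt)
  co <- f$coefficients
  expect_equal(co$estimate[co$term == "year"], 2)
  expect_equal(co$estimate[co$term == "(Intercept)"], 1 - 2 * 2020)
  expect_equal(f$r2, 1)
})

test_that("OLS solution matches the normal-equations oracle", {
  set.seed(43)
  for (r in 1:10) {
    n <- 20
    tt <- as.data.frame(tiny_table(3)[rep(1:3, length.out = n), ])
    tt$study_id <- sprintf("R%02d", 1:n)
    tt$pub_year <- sample(2018:2025, n, replace = TRUE)
    tt$country <- sample(c("Australia", "China", "UK"), n, replace = TRUE)
    tt$intervention <- sample(c("Inclisiran", "Other"), n, replace = TRUE)
    tt$qaly_gain <- rnorm(n)
    tt <- as_study_table(tt)
    f <- fit_ols(design_spec("qaly_gain"), tt)
    beta_oracle <- ols_oracle(f$X, f$y)
    expect_equal(unname(f$coefficients$estimate), beta_oracle,
                 tolerance = 1e-8)
    # residuals sum to zero with an intercept
    expect_equal(sum(f$residuals), 0, tolerance = 1e-8)
    expect_lte(f$adj_r2, f$r2)
  }
})

test_that("fixture NMB meta-regression reproduces the published model", {
  s <- fixture()
  f <- fit_ols(design_spec("nmb", lambda = 50000, basis = "total"), s)
  co <- setNames(f$coefficients$estimate, f$coefficients$term)
  pv <- setNames(f$coefficients$p, f$coefficients$term)
  # coefficients at the precision of the published table (nearest 100 USD)
  expect_equal(co[["year"]], -196046100, tolerance = 5e-7)
  expect_equal(co[["country:China"]], 392363300, tolerance = 5e-7)
  expect_equal(co[["country:Singapore"]], 196419900, tolerance = 5e-7)
  expect_equal(co[["country:Switzerland"]], -391816600, tolerance = 5e-7)
  expect_equal(co[["country:UK"]], -293711100, tolerance = 5e-7)
  expect_equal(co[["country:USA"]], -391851200, tolerance = 5e-7)
  # combination therapy carries a markedly lower NMB (about -588 million)
  expect_equal(co[["intervention:Inclisiran+statin"]], -587.9e6,
               tolerance = 1e-4)
  # p-values to the published 4 decimals
  expect_equal(round(pv[["year"]], 3), 0.025)
  expect_equal(round(pv[["country:China"]], 4), 0.1428)
  expect_equal(round(pv[["country:Singapore"]], 4), 0.372)
  expect_equal(round(pv[["intervention:Inclisiran+statin"]], 4), 0.0765)
  # sign pattern: China and Singapore above the Australian reference
  expect_gt(co[["country:China"]], 0)
  expect_gt(co[["country:Singapore"]], 0)
})

test_that("perfectly collinear indicators are dropped deterministically", {
  s <- fixture()
  f <- fit_ols(design_spec("nmb", lambda = 50000, basis = "total"), s)
  # every Singapore/USA row is combination-with-SoC and the single
  # Switzerland row is the only 'Other', so those indicators are exact
  # linear combinations of the country dummies entered before them
  expect_setequal(f$dropped_terms,
                  c("intervention:Inclisiran+SoC", "intervention:Other"))
  expect_false(any(f$dropped_terms %in% f$coefficients$term))
  expect_error(partial_regression(f, "intervention:Other"),
               "dropped-term")
  expect_error(fit_ols(design_spec("qaly_gain"), tiny_table(3)),
               "insufficient-data")
})

test_that("trend regressions reproduce the published slopes", {
  s <- fixture()
  ti <- trend_slope(s$icer_per_qaly, s$pub_year)
  expect_equal(ti$slope, -170748, tolerance = 5e-6)
  expect_equal(round(ti$p, 2), 0.56)
  tq <- trend_slope(s$qaly_gain, s$pub_year)
  expect_equal(tq$slope, 0.035, tolerance = 2e-2)
  expect_equal(round(tq$p, 2), 0.45)
  # degenerate inputs
  expect_equal(suppressWarnings(trend_slope(rep(5, 4), 2020:2023)$slope), 0)
  expect_error(trend_slope(1:4, rep(2020, 4)), "degenerate-design")
  expect_error(trend_slope(1:2, 2020:2021), "insufficient-data")
})

test_that("added-variable slopes equal full-model coefficients (FWL)", {
  s <- fixture()
  f <- fit_ols(design_spec("nmb", lambda = 100000, basis = "total"), s)
  for (term in setdiff(f$coefficients$term, "(Intercept)")) {
    pr <- partial_regression(f, term)
    expect_equal(attr(pr, "slope"),
                 f$coefficients$estimate[f$coefficients$term == term],
                 tolerance = 1e-8)
  }
  # single covariate: the partial plot is the centered raw data
  f1 <- fit_ols(design_spec("qaly_gain", covariates = "year"), s)
  pr1 <- partial_regression(f1, "year")
  expect_equal(pr1$x_resid, s$pub_year - mean(s$pub_year))
  expect_equal(pr1$y_resid, s$qaly_gain - mean(s$qaly_gain))
  # orthogonal covariates: partial residuals are the centered covariate
  n <- 8
  tt <- as.data.frame(tiny_table(3)[rep(1:3, length.out = n), ])
  tt$study_id <- sprintf("O%02d", 1:n)
  tt$pub_year <- rep(c(2020, 2021), each = 4)
  tt$country <- rep(rep(c("Australia", "China"), each = 2), 2)
  tt$qaly_gain <- rnorm(n)
  tt <- as_study_table(tt)
  f2 <- fit_ols(design_spec("qaly_gain", covariates = c("year", "country")),
                tt)
  pr2 <- partial_regression(f2, "year")
  expect_equal(pr2$x_resid, tt$pub_year - mean(tt$pub_year))
})
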
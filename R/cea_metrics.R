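#' Incremental cost-effectiveness ratio
#'
#' ICER = incremental cost / incremental QALYs. The cost-effectiveness
#' plane quadrant is attached as an attribute: `NE` (more costly, more
#' effective — the usual trade-off), `SE` (cheaper and more effective,
#' dominant), `NW` (more costly and less effective, dominated), `SW`
#' (cheaper, less effective). For negative incremental QALYs the ratio is
#' still returned, tagged with its quadrant, since its magnitude alone is
#' not decision-relevant.
#'
#' @param delta_cost incremental cost (vectorized).
#' @param delta_qaly incremental QALYs; must be nonzero.
#' @return numeric vector of ICERs with a `quadrant` attribute.
#' @examples
#' icer(10000, 0.5)
#' @export
icer <- function(delta_cost, delta_qaly) {
  if (any(delta_qaly == 0)) {
    stop("undefined-ratio error: delta_qaly = 0", call. = FALSE)
  }
  out <- delta_cost / delta_qaly
  quadrant <- ifelse(delta_qaly > 0,
                     ifelse(delta_cost >= 0, "NE", "SE"),
                     ifelse(delta_cost >= 0, "NW", "SW"))
  attr(out, "quadrant") <- quadrant
  out
}

#' Net monetary benefit at a willingness-to-pay threshold
#'
#' NMB = lambda * QALY gain − cost, computed per record at full precision.
#' The cost basis is explicit because published syntheses use both: the
#' health-economics standard is the incremental cost versus the comparator
#' (`basis = "incremental"`, the default); some summary tables instead
#' monetize against the intervention arm's total lifetime cost
#' (`basis = "total"`).
#'
#' @param table a `study_table` (or any data.frame with `study_id`,
#'   `qaly_gain` and the requested cost column).
#' @param lambda willingness-to-pay threshold in USD per QALY.
#' @param basis `"incremental"` or `"total"`.
#' @return data.frame with columns `study_id`, `lambda`, `cost_basis`,
#'   `nmb`.
#' @examples
#' studies <- load_records("mastaleru2025")
#' head(nmb(studies, 50000, basis = "total"))
#' @export
nmb <- function(table, lambda, basis = c("incremental", "total")) {
  basis <- match.arg(basis)
  cost_col <- if (basis == "incremental") "incremental_cost" else "total_cost"
  if (!cost_col %in% names(table) || anyNA(table[[cost_col]])) {
    stop("input error: missing cost field '", cost_col, "'", call. = FALSE)
  }
  data.frame(study_id = table$study_id,
             lambda = lambda,
             cost_basis = basis,
             nmb = lambda * table$qaly_gain - table[[cost_col]],
             stringsAsFactors = FALSE)
}

#' Re-threshold an NMB record in closed form
#'
#' NMB is affine in the threshold with slope equal to the QALY gain, so a
#' value computed at one threshold can be shifted to another without
#' touching the cost column: NMB(l2) = NMB(l1) + (l2 − l1) * QALY gain.
#' The result is bit-identical to direct recomputation.
#'
#' @param nmb_record data.frame as returned by [nmb()].
#' @param new_lambda target threshold, USD/QALY.
#' @param delta_qaly QALY gain(s) of the same record(s), same order.
#' @return data.frame in the same shape with `lambda` and `nmb` updated.
#' @export
nmb_shift <- function(nmb_record, new_lambda, delta_qaly) {
  nmb_record$nmb <- nmb_record$nmb +
    (new_lambda - nmb_record$lambda) * delta_qaly
  nmb_record$lambda <- new_lambda
  nmb_record
}

#' Classify records as cost-effective at a threshold
#'
#' Either by positive net monetary benefit (`nmb_positive`) or by reported
#' ICER below the threshold (`icer_below_lambda`). For consistent records
#' the two criteria coincide at `basis = "incremental"`; they diverge
#' exactly where [validate_table()] flags an ICER/cost/QALY inconsistency.
#' Records in the dominated/dominant quadrants (negative QALY gain) are
#' excluded from ICER-based classification with a warning.
#'
#' @param table a `study_table`.
#' @param lambda willingness-to-pay threshold, USD/QALY.
#' @param criterion `"nmb_positive"` or `"icer_below_lambda"`.
#' @param basis cost basis for the NMB criterion.
#' @return list with `flags` (named logical vector) and `count`.
#' @examples
#' studies <- load_records("mastaleru2025")
#' classify(studies, 50000)$count  # 3 of 17
#' @export
classify <- function(table, lambda,
                     criterion = c("nmb_positive", "icer_below_lambda"),
                     basis = c("incremental", "total")) {
  criterion <- match.arg(criterion)
  basis <- match.arg(basis)
  if (criterion == "nmb_positive") {
    flags <- nmb(table, lambda, basis)$nmb > 0
  } else {
    neg <- table$qaly_gain < 0
    if (any(neg)) {
      warning("excluding ", sum(neg),
              " record(s) with negative QALY gain from ICER classification")
    }
    flags <- !neg & table$icer_per_qaly < lambda
  }
  names(flags) <- table$study_id
  list(flags = flags, count = sum(flags), n = nrow(table),
       lambda = lambda, criterion = criterion, basis = basis)
}

#' Country-level affordability assessment
#'
#' Compares each country's mean study-level results against its
#' willingness-to-pay threshold: explicit thresholds where published,
#' otherwise a GDP-per-capita multiple (1x by default, up to 3x), otherwise
#' verdict `unknown`. The verdict is `yes` iff the country's mean NMB at
#' its threshold is strictly positive.
#'
#' @param table a `study_table`.
#' @param thresholds data.frame `country,lambda,source,gdp_multiple`
#'   (explicit rows carry `lambda`; `gdp_multiple` rows are resolved
#'   against `gdp`). The packaged defaults are at
#'   `system.file("extdata", "wtp_thresholds.csv", package = "ceameta")`.
#' @param gdp optional data.frame `country,gdp_per_capita` for
#'   GDP-multiple thresholds.
#' @param gdp_multiple multiple applied when a country has a GDP entry but
#'   no explicit threshold; conventionally in `[1, 3]`.
#' @param basis cost basis for NMB.
#' @return data.frame with one row per country: `country`, `mean_icer`,
#'   `threshold`, `mean_nmb`, `n_studies`, `n_cost_effective`, `verdict`.
#' @export
affordability <- function(table, thresholds, gdp = NULL, gdp_multiple = 1,
                          basis = c("incremental", "total")) {
  basis <- match.arg(basis)
  stopifnot(gdp_multiple >= 1, gdp_multiple <= 3)
  thresholds$country <- canonical_country(thresholds$country)
  countries <- unique(table$country)
  rows <- lapply(countries, function(cty) {
    sub <- table[table$country == cty, , drop = FALSE]
    lam <- NA_real_
    th <- thresholds[thresholds$country == cty, , drop = FALSE]
    if (nrow(th) >= 1L && !is.na(th$lambda[1L])) {
      lam <- th$lambda[1L]
    } else if (!is.null(gdp)) {
      g <- gdp$gdp_per_capita[canonical_country(gdp$country) == cty]
      if (length(g) == 1L) lam <- gdp_multiple * g
    }
    if (is.na(lam)) {
      return(data.frame(country = cty,
                        mean_icer = mean(sub$icer_per_qaly),
                        threshold = NA_real_, mean_nmb = NA_real_,
                        n_studies = nrow(sub), n_cost_effective = 0L,
                        verdict = "unknown", stringsAsFactors = FALSE))
    }
    nmbs <- nmb(sub, lam, basis)$nmb
    data.frame(country = cty,
               mean_icer = mean(sub$icer_per_qaly),
               threshold = lam,
               mean_nmb = mean(nmbs),
               n_studies = nrow(sub),
               n_cost_effective = sum(nmbs > 0),
               verdict = if (mean(nmbs) > 0) "yes" else "no",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
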
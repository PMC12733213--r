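#' Descriptive summary of a numeric vector
#'
#' Arithmetic mean, sample SD (n − 1 denominator), standard error,
#' normal-approximation 95% CI (mean ± 1.96 SE), and quantiles by linear
#' interpolation at rank (n − 1) * p (the convention of
#' [stats::quantile()] type 7). With a single value the dispersion fields
#' are absent (`NA`), not zero.
#'
#' @param values numeric vector, length >= 1, no NAs.
#' @return a `summary_stats` list: `n`, `mean`, `sd`, `se`, `ci95_low`,
#'   `ci95_high`, `min`, `q25`, `median`, `q75`, `max`, `quantile_rule`.
#' @examples
#' studies <- load_records("mastaleru2025")
#' summarize_values(studies$qaly_gain)$mean  # 0.34
#' @export
summarize_values <- function(values) {
  if (length(values) == 0L) {
    stop("empty-input error: no values to summarize", call. = FALSE)
  }
  stopifnot(!anyNA(values))
  n <- length(values)
  m <- mean(values)
  s <- if (n > 1L) sd(values) else NA_real_
  se <- if (n > 1L) s / sqrt(n) else NA_real_
  q <- unname(quantile(values, c(0, 0.25, 0.5, 0.75, 1), type = 7))
  structure(list(n = n, mean = m, sd = s, se = se,
                 ci95_low = if (n > 1L) m - 1.96 * se else NA_real_,
                 ci95_high = if (n > 1L) m + 1.96 * se else NA_real_,
                 min = q[1L], q25 = q[2L], median = q[3L], q75 = q[4L],
                 max = q[5L], quantile_rule = "linear_(n-1)p"),
            class = "summary_stats")
}

#' @export
print.summary_stats <- function(x, ...) {
  cat(sprintf("n = %d  mean = %g  sd = %s  se = %s\n", x$n, x$mean,
              format(x$sd), format(x$se)))
  cat(sprintf("95%% CI [%s, %s]\n", format(x$ci95_low), format(x$ci95_high)))
  cat(sprintf("min/q25/median/q75/max: %g / %g / %g / %g / %g\n",
              x$min, x$q25, x$median, x$q75, x$max))
  invisible(x)
}

#' Grouped summaries of QALY gain, incremental cost, and NMB
#'
#' One row of summaries per observed level of the grouping key, mirroring
#' subgroup syntheses by intervention type, region, or age group. Records
#' with `age_group == "unknown"` are excluded from age-stratified
#' summaries. Groups of size 1 report the mean only (SD absent).
#'
#' @param table a `study_table`.
#' @param group_key one of `"intervention"`, `"country"`, `"age_group"`.
#' @param lambdas numeric vector of WTP thresholds for NMB summaries.
#' @param basis cost basis for NMB.
#' @return data.frame with one row per group: `group`, `n`, `qaly_mean`,
#'   `qaly_sd`, `cost_mean`, `cost_sd`, then `nmb_mean_<lambda>` per
#'   threshold.
#' @export
group_summary <- function(table, group_key = c("intervention", "country",
                                               "age_group"),
                          lambdas = c(50000, 100000, 150000),
                          basis = c("incremental", "total")) {
  group_key <- match.arg(group_key)
  basis <- match.arg(basis)
  if (group_key == "age_group") {
    table <- table[table$age_group != "unknown", , drop = FALSE]
  }
  cost_col <- if (basis == "incremental") "incremental_cost" else "total_cost"
  levels_seen <- unique(table[[group_key]])
  rows <- lapply(levels_seen, function(g) {
    sub <- table[table[[group_key]] == g, , drop = FALSE]
    row <- data.frame(group = g, n = nrow(sub),
                      qaly_mean = mean(sub$qaly_gain),
                      qaly_sd = if (nrow(sub) > 1L) sd(sub$qaly_gain)
                                else NA_real_,
                      cost_mean = mean(sub[[cost_col]]),
                      cost_sd = if (nrow(sub) > 1L) sd(sub[[cost_col]])
                                else NA_real_,
                      stringsAsFactors = FALSE)
    for (lam in lambdas) {
      row[[paste0("nmb_mean_", format(lam, scientific = FALSE))]] <-
        mean(nmb(sub, lam, basis)$nmb)
    }
    row
  })
  out <- do.call(rbind, rows)
  attr(out, "group_key") <- group_key
  attr(out, "basis") <- basis
  out
}

#' Summary of per-study net monetary benefit at one threshold
#'
#' @param table a `study_table`.
#' @param lambda WTP threshold, USD/QALY.
#' @param basis cost basis.
#' @return a `summary_stats` object (see [summarize_values()]).
#' @examples
#' studies <- load_records("mastaleru2025")
#' nmb_summary(studies, 50000, basis = "total")$median
#' @export
nmb_summary <- function(table, lambda, basis = c("incremental", "total")) {
  basis <- match.arg(basis)
  summarize_values(nmb(table, lambda, basis)$nmb)
}
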
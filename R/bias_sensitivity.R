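#' Egger regression test for funnel-plot asymmetry
#'
#' Regresses the standardized effect y/SE on precision 1/SE and tests the
#' intercept against zero with a two-sided t-test (df = k − 2). A nonzero
#' intercept indicates small-study asymmetry: less precise studies report
#' systematically shifted effects. The regression is solved in closed form
#' from the normal equations. The intercept is invariant to rescaling all
#' SEs and effects by a common positive constant.
#'
#' @param yi per-study effect estimates.
#' @param sei per-study standard errors, all > 0; k >= 3.
#' @return an `egger_result`: `intercept`, `se_intercept`, `t`, `p`,
#'   `slope`, `k`.
#' @export
egger_test <- function(yi, sei) {
  .check_effect_inputs(yi, sei, min_k = 3L)
  z <- yi / sei        # standardized effect
  x <- 1 / sei         # precision
  k <- length(yi)
  # closed-form simple OLS
  xbar <- mean(x); zbar <- mean(z)
  sxx <- sum((x - xbar)^2)
  if (sxx == 0) {
    stop("degenerate-design error: all standard errors identical",
         call. = FALSE)
  }
  slope <- sum((x - xbar) * (z - zbar)) / sxx
  intercept <- zbar - slope * xbar
  res <- z - intercept - slope * x
  sigma2 <- sum(res^2) / (k - 2L)
  se_int <- sqrt(sigma2 * (1 / k + xbar^2 / sxx))
  tval <- intercept / se_int
  pval <- 2 * pt(-abs(tval), k - 2L)
  structure(list(intercept = intercept, se_intercept = se_int, t = tval,
                 p = pval, slope = slope, k = k),
            class = "egger_result")
}

#' @export
print.egger_result <- function(x, ...) {
  cat(sprintf(
    "Egger regression (k = %d): intercept %.4f (SE %.4f), t = %.3f, p = %.4f\n",
    x$k, x$intercept, x$se_intercept, x$t, x$p))
  invisible(x)
}

#' Leave-one-out sensitivity of a summary statistic
#'
#' Recomputes the statistic k times, excluding one record each time, to
#' expose single-study influence. For the mean every row satisfies the
#' exact exclusion identity mean(-i) = (k * mean − x_i) / (k − 1).
#'
#' @param values numeric vector, length >= 2.
#' @param statistic `"mean"` or `"median"`.
#' @param ids optional record labels (defaults to positions).
#' @return a `loo_result`: `rows` (data.frame `excluded_id`, `value`),
#'   `full_value`, `min_loo`, `max_loo`, `statistic`.
#' @examples
#' studies <- load_records("mastaleru2025")
#' leave_one_out(studies$icer_per_qaly, ids = studies$study_id)
#' @export
leave_one_out <- function(values, statistic = c("mean", "median"),
                          ids = NULL) {
  statistic <- match.arg(statistic)
  k <- length(values)
  if (k < 2L) {
    stop("insufficient-data error: need at least 2 values", call. = FALSE)
  }
  if (is.null(ids)) ids <- as.character(seq_len(k))
  stat_fun <- match.fun(statistic)
  loo <- vapply(seq_len(k), function(i) stat_fun(values[-i]), numeric(1))
  structure(list(rows = data.frame(excluded_id = ids, value = loo,
                                   stringsAsFactors = FALSE),
                 full_value = stat_fun(values),
                 min_loo = min(loo), max_loo = max(loo),
                 statistic = statistic),
            class = "loo_result")
}

#' @export
print.loo_result <- function(x, ...) {
  cat(sprintf("leave-one-out %s: full %.4f, range [%.4f, %.4f] over %d rows\n",
              x$statistic, x$full_value, x$min_loo, x$max_loo,
              nrow(x$rows)))
  invisible(x)
}

#' Leave-one-out sensitivity of the random-effects pooled estimate
#'
#' Full re-fit within each replicate: the between-study variance is
#' re-estimated on every leave-one-out subset (not plugged in from the
#' full fit).
#'
#' @param yi,sei effect estimates and standard errors (k >= 3 so every
#'   subset remains poolable).
#' @param ids optional record labels.
#' @return a `loo_result` whose `value` column holds the re-pooled
#'   DerSimonian-Laird estimates.
#' @export
leave_one_out_pooled <- function(yi, sei, ids = NULL) {
  .check_effect_inputs(yi, sei, min_k = 3L)
  k <- length(yi)
  if (is.null(ids)) ids <- as.character(seq_len(k))
  loo <- vapply(seq_len(k), function(i) {
    random_effects_dl(yi[-i], sei[-i])$pooled
  }, numeric(1))
  structure(list(rows = data.frame(excluded_id = ids, value = loo,
                                   stringsAsFactors = FALSE),
                 full_value = random_effects_dl(yi, sei)$pooled,
                 min_loo = min(loo), max_loo = max(loo),
                 statistic = "re_dl_pooled"),
            class = "loo_result")
}

#' Funnel-plot coordinates
#'
#' Plotting pairs (effect, SE) ordered by descending precision; values are
#' passed through untransformed.
#'
#' @param yi,sei effect estimates and standard errors.
#' @return data.frame with columns `effect`, `se`, ordered by descending
#'   precision (smallest SE first).
#' @export
funnel_coordinates <- function(yi, sei) {
  if (length(yi) == 0L) {
    return(data.frame(effect = numeric(0), se = numeric(0)))
  }
  o <- order(sei)
  data.frame(effect = yi[o], se = sei[o])
}
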
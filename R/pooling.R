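.check_effect_inputs <- function(yi, sei, min_k = 2L) {
  if (length(yi) != length(sei)) {
    stop("input error: yi and sei lengths differ", call. = FALSE)
  }
  if (length(yi) < min_k) {
    stop("insufficient-studies error: need at least ", min_k, " studies",
         call. = FALSE)
  }
  if (any(!is.finite(sei)) || any(sei <= 0)) {
    stop("input error: standard errors must be finite and > 0",
         call. = FALSE)
  }
  if (any(!is.finite(yi))) {
    stop("input error: estimates must be finite", call. = FALSE)
  }
  invisible(TRUE)
}

.new_pooled <- function(method, yi, sei, tau2, scale) {
  k <- length(yi)
  wi <- 1 / (sei^2 + tau2)
  pooled <- sum(wi * yi) / sum(wi)
  se_pooled <- sqrt(1 / sum(wi))
  # Q and I^2 are always computed from the fixed-effect weights
  wfe <- 1 / sei^2
  mu_fe <- sum(wfe * yi) / sum(wfe)
  Q <- sum(wfe * (yi - mu_fe)^2)
  df <- k - 1L
  i2 <- if (Q > df) 100 * (Q - df) / Q else 0
  out <- list(method = method, k = k, pooled = pooled,
              se_pooled = se_pooled,
              ci95_low = pooled - qnorm(0.975) * se_pooled,
              ci95_high = pooled + qnorm(0.975) * se_pooled,
              Q = Q, df = df, i2 = i2, tau2 = tau2, scale = scale,
              weights = wi)
  if (scale == "log") {
    out$back_transformed <- list(pooled = exp(pooled),
                                 ci95_low = exp(out$ci95_low),
                                 ci95_high = exp(out$ci95_high))
  }
  class(out) <- "pooled_estimate"
  out
}

#' Fixed-effect (inverse-variance) pooling
#'
#' Weighted mean with weights 1/SE^2; Cochran's Q heterogeneity statistic
#' and I^2 are reported alongside.
#'
#' @param yi per-study estimates (identity or log scale, homogeneous).
#' @param sei per-study standard errors, all > 0.
#' @param scale `"identity"` or `"log"`; on the log scale the pooled value
#'   and CI are also returned back-transformed.
#' @return a `pooled_estimate`: `method`, `k`, `pooled`, `se_pooled`,
#'   `ci95_low/high` (normal), `Q`, `df`, `i2` (percent), `tau2` (0 for
#'   FE), `weights`.
#' @examples
#' fixed_effect(c(1, 3), c(1, 1))$pooled  # 2
#' @export
fixed_effect <- function(yi, sei, scale = c("identity", "log")) {
  scale <- match.arg(scale)
  .check_effect_inputs(yi, sei)
  .new_pooled("FE", yi, sei, tau2 = 0, scale = scale)
}

#' Random-effects pooling with the DerSimonian-Laird estimator
#'
#' Between-study variance by the moment estimator
#' tau^2 = max(0, (Q − df) / (sum(w) − sum(w^2)/sum(w))) with fixed-effect
#' weights w = 1/SE^2, then an inverse-variance pooled mean with weights
#' 1/(SE^2 + tau^2). I^2 = max(0, (Q − df)/Q) * 100. When tau^2 = 0 the
#' result coincides with [fixed_effect()].
#'
#' @inheritParams fixed_effect
#' @return a `pooled_estimate` with `method = "RE_DL"`.
#' @examples
#' random_effects_dl(c(0.2, 0.4, 0.3), c(0.05, 0.05, 0.05))
#' @export
random_effects_dl <- function(yi, sei, scale = c("identity", "log")) {
  scale <- match.arg(scale)
  .check_effect_inputs(yi, sei)
  wi <- 1 / sei^2
  mu_fe <- sum(wi * yi) / sum(wi)
  Q <- sum(wi * (yi - mu_fe)^2)
  df <- length(yi) - 1L
  tau2 <- max(0, (Q - df) / (sum(wi) - sum(wi^2) / sum(wi)))
  .new_pooled("RE_DL", yi, sei, tau2 = tau2, scale = scale)
}

#' Pool ICERs on the log scale
#'
#' Ratio quantities are unsuitable for direct inverse-variance pooling, so
#' ICERs are pooled as log(ICER) under the random-effects model and
#' back-transformed, yielding a geometric-mean-type summary. Nonpositive
#' ICERs cannot be log-transformed and are excluded with a warning.
#'
#' @param icers positive ICER values, USD/QALY.
#' @param sei_log standard errors of log(ICER).
#' @return a `pooled_estimate` on the log scale with a `back_transformed`
#'   element (`exp` of the pooled value and CI bounds).
#' @export
pool_log_icer <- function(icers, sei_log) {
  keep <- icers > 0
  if (any(!keep)) {
    warning("excluding ", sum(!keep), " nonpositive ICER(s) from log pooling")
  }
  random_effects_dl(log(icers[keep]), sei_log[keep], scale = "log")
}

#' Impute within-study standard errors under a declared convention
#'
#' Published cost-effectiveness evaluations rarely report a within-study
#' variance for their point estimates, yet inverse-variance machinery
#' needs one. This helper makes the assumption explicit and deterministic:
#' `constant_cv` sets SE = cv * |estimate| (a constant coefficient of
#' variation, floored at 1e-6 of the column's mean absolute value so
#' near-zero estimates cannot receive infinite weight); `fixed_se` sets a
#' common SE (under which the FE pooled estimate is the unweighted mean);
#' `user_column` reads a per-record SE column. Every pooled result should
#' be reported together with the convention used.
#'
#' @param table a `study_table`.
#' @param quantity `"qaly_gain"`, `"incremental_cost"`, or `"nmb"`.
#' @param convention `"constant_cv"`, `"fixed_se"`, or `"user_column"`.
#' @param param cv (> 0) for `constant_cv`; the SE (> 0) for `fixed_se`;
#'   ignored for `user_column`.
#' @param lambda,basis NMB parameters, used when `quantity = "nmb"`.
#' @return data.frame with columns `study_id`, `estimate`, `se`, `scale`,
#'   and a `convention` attribute.
#' @export
impute_se <- function(table, quantity = c("qaly_gain", "incremental_cost",
                                          "nmb"),
                      convention = c("constant_cv", "fixed_se",
                                     "user_column"),
                      param = 0.2, lambda = 50000,
                      basis = c("incremental", "total")) {
  quantity <- match.arg(quantity)
  convention <- match.arg(convention)
  basis <- match.arg(basis)
  yi <- switch(quantity,
               qaly_gain = table$qaly_gain,
               incremental_cost = table$incremental_cost,
               nmb = nmb(table, lambda, basis)$nmb)
  se <- switch(convention,
    constant_cv = {
      stopifnot(param > 0)
      pmax(param * abs(yi), 1e-6 * mean(abs(yi)))
    },
    fixed_se = {
      stopifnot(param > 0)
      rep(param, length(yi))
    },
    user_column = {
      col <- paste0("se_", quantity)
      if (!col %in% names(table) || anyNA(table[[col]])) {
        stop("input error: user_column convention requires a complete '",
             col, "' column", call. = FALSE)
      }
      table[[col]]
    })
  out <- data.frame(study_id = table$study_id, estimate = yi, se = se,
                    scale = "identity", stringsAsFactors = FALSE)
  attr(out, "convention") <- sprintf("%s:%g", convention,
                                     if (convention == "user_column") NA
                                     else param)
  out
}

#' @export
print.pooled_estimate <- function(x, ...) {
  cat(sprintf("%s pooling of k = %d studies (%s scale)\n", x$method, x$k,
              x$scale))
  cat(sprintf("pooled = %g  SE = %g  95%% CI [%g, %g]\n", x$pooled,
              x$se_pooled, x$ci95_low, x$ci95_high))
  cat(sprintf("Q = %g (df = %d)  I2 = %.1f%%  tau2 = %g\n", x$Q, x$df,
              x$i2, x$tau2))
  if (!is.null(x$back_transformed)) {
    bt <- x$back_transformed
    cat(sprintf("back-transformed: %g [%g, %g]\n", bt$pooled, bt$ci95_low,
                bt$ci95_high))
  }
  invisible(x)
}
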
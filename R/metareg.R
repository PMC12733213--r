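#' Specify an OLS meta-regression design
#'
#' Response is per-study NMB (at a stated threshold and cost basis),
#' reported ICER, or QALY gain; covariates are publication year and/or
#' dummy-coded country and intervention, with explicit reference levels so
#' every dummy coefficient is a contrast against the reference.
#'
#' @param response `"nmb"`, `"icer_per_qaly"`, or `"qaly_gain"`.
#' @param lambda WTP threshold, required when `response = "nmb"`.
#' @param basis cost basis for NMB.
#' @param covariates ordered subset of `c("year", "country",
#'   "intervention")`; the order fixes which columns are dropped first
#'   under perfect collinearity (last entered, first dropped).
#' @param ref_country,ref_intervention reference levels for dummy coding.
#' @return a `design_spec` list.
#' @export
design_spec <- function(response = c("nmb", "icer_per_qaly", "qaly_gain"),
                        lambda = NULL,
                        basis = c("incremental", "total"),
                        covariates = c("year", "country", "intervention"),
                        ref_country = "Australia",
                        ref_intervention = "Inclisiran") {
  response <- match.arg(response)
  basis <- match.arg(basis)
  stopifnot(all(covariates %in% c("year", "country", "intervention")),
            length(covariates) >= 1L)
  if (response == "nmb" && is.null(lambda)) {
    stop("lambda is required when response = 'nmb'", call. = FALSE)
  }
  structure(list(response = response, lambda = lambda, basis = basis,
                 covariates = covariates, ref_country = ref_country,
                 ref_intervention = ref_intervention),
            class = "design_spec")
}

# dummy columns for one factor, reference level excluded, remaining levels
# in sorted order for determinism
.dummies <- function(x, ref, prefix) {
  lev <- sort(setdiff(unique(x), ref))
  if (!ref %in% x) {
    stop("reference level '", ref, "' not present in the data",
         call. = FALSE)
  }
  cols <- lapply(lev, function(l) as.numeric(x == l))
  m <- do.call(cbind, cols)
  colnames(m) <- paste0(prefix, lev)
  m
}

.build_design <- function(spec, table) {
  y <- switch(spec$response,
              nmb = nmb(table, spec$lambda, spec$basis)$nmb,
              icer_per_qaly = table$icer_per_qaly,
              qaly_gain = table$qaly_gain)
  X <- matrix(1, nrow = nrow(table), ncol = 1,
              dimnames = list(NULL, "(Intercept)"))
  for (cv in spec$covariates) {
    add <- switch(cv,
      year = matrix(table$pub_year, ncol = 1,
                    dimnames = list(NULL, "year")),
      country = .dummies(table$country, spec$ref_country, "country:"),
      intervention = .dummies(table$intervention, spec$ref_intervention,
                              "intervention:"))
    X <- cbind(X, add)
  }
  list(y = y, X = X)
}

# greedy rank filter in column-entry order: a column is dropped iff it is
# (numerically) in the span of the columns already kept, so collinear
# terms are removed last-entered first
.drop_collinear <- function(X, tol = 1e-10) {
  keep <- 1L
  for (j in seq_len(ncol(X))[-1L]) {
    qrk <- qr(X[, keep, drop = FALSE])
    res <- qr.resid(qrk, X[, j])
    ref <- max(sqrt(sum(X[, j]^2)), 1)
    if (sqrt(sum(res^2)) > tol * ref) keep <- c(keep, j)
  }
  keep
}

#' Fit an unweighted OLS meta-regression
#'
#' Ordinary least squares of the response on the design defined by
#' [design_spec()]. Perfectly collinear columns are removed
#' deterministically (last entered, first dropped; rank decisions at
#' relative tolerance 1e-10) and listed in `dropped_terms` — in small
#' study sets an intervention indicator can be an exact linear combination
#' of country dummies and then carries no estimable contrast of its own.
#' Inference uses the t distribution with n − rank degrees of freedom and
#' no heteroskedasticity correction.
#'
#' @param spec a [design_spec()].
#' @param table a `study_table`.
#' @return a `regression_result`: `coefficients` (data.frame with
#'   `estimate`, `se`, `t`, `p` per term), `r2`, `adj_r2`, `n`,
#'   `residuals`, `fitted`, `dropped_terms`, plus the retained design
#'   matrix and response for added-variable diagnostics.
#' @seealso [partial_regression()], [trend_slope()]
#' @export
fit_ols <- function(spec, table) {
  stopifnot(inherits(spec, "design_spec"))
  d <- .build_design(spec, table)
  keep <- .drop_collinear(d$X)
  dropped <- setdiff(colnames(d$X), colnames(d$X)[keep])
  X <- d$X[, keep, drop = FALSE]
  n <- nrow(X)
  p <- ncol(X)
  if (n <= p) {
    stop("insufficient-data error: n = ", n, " <= ", p,
         " estimable terms", call. = FALSE)
  }
  fit <- stats::lm.fit(X, d$y)
  beta <- fit$coefficients
  res <- fit$residuals
  df_res <- n - p
  sigma2 <- sum(res^2) / df_res
  XtX_inv <- chol2inv(chol(crossprod(X)))
  se <- sqrt(sigma2 * diag(XtX_inv))
  tval <- beta / se
  pval <- 2 * pt(-abs(tval), df_res)
  ss_tot <- sum((d$y - mean(d$y))^2)
  ss_res <- sum(res^2)
  r2 <- 1 - ss_res / ss_tot
  adj_r2 <- 1 - (1 - r2) * (n - 1) / df_res
  structure(list(
    coefficients = data.frame(term = colnames(X), estimate = unname(beta),
                              se = se, t = tval, p = pval,
                              row.names = NULL, stringsAsFactors = FALSE),
    r2 = r2, adj_r2 = adj_r2, n = n, df_residual = df_res,
    residuals = res, fitted = fit$fitted.values,
    dropped_terms = dropped, X = X, y = d$y, spec = spec),
    class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("OLS meta-regression (%s), n = %d\n", x$spec$response, x$n))
  print(x$coefficients, digits = 4)
  cat(sprintf("R2 = %.4f  adjusted R2 = %.4f\n", x$r2, x$adj_r2))
  if (length(x$dropped_terms) > 0L) {
    cat("dropped (collinear):", paste(x$dropped_terms, collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Simple temporal trend regression
#'
#' OLS of a study-level quantity on publication year, with the two-sided
#' t-test p-value for the slope.
#'
#' @param y response values.
#' @param years publication years (>= 2 distinct values, >= 3 points).
#' @return list with `slope` (per year), `se`, `p`, `intercept`.
#' @examples
#' studies <- load_records("mastaleru2025")
#' trend_slope(studies$icer_per_qaly, studies$pub_year)$slope
#' @export
trend_slope <- function(y, years) {
  if (length(y) < 3L) {
    stop("insufficient-data error: need at least 3 points", call. = FALSE)
  }
  if (length(unique(years)) < 2L) {
    stop("degenerate-design error: all years identical", call. = FALSE)
  }
  fit <- lm(y ~ years)
  s <- summary(fit)$coefficients
  list(slope = unname(s["years", "Estimate"]),
       se = unname(s["years", "Std. Error"]),
       p = unname(s["years", "Pr(>|t|)"]),
       intercept = unname(s["(Intercept)", "Estimate"]))
}

#' Added-variable (partial regression) data for one covariate
#'
#' Residualizes both the response and the chosen covariate on all other
#' retained columns of the fitted design. By the Frisch-Waugh-Lovell
#' theorem the OLS slope through the returned point pairs equals the
#' covariate's coefficient in the full model, so the plot shows what the
#' covariate adds after controlling for everything else.
#'
#' @param result a `regression_result` from [fit_ols()].
#' @param covariate name of a retained design column (e.g. `"year"`,
#'   `"country:China"`).
#' @return data.frame with columns `x_resid`, `y_resid` and a `slope`
#'   attribute.
#' @export
partial_regression <- function(result, covariate) {
  stopifnot(inherits(result, "regression_result"))
  if (covariate %in% result$dropped_terms) {
    stop("dropped-term error: '", covariate,
         "' was removed for perfect collinearity", call. = FALSE)
  }
  cols <- colnames(result$X)
  if (!covariate %in% cols) {
    stop("covariate '", covariate, "' is not among the fitted terms",
         call. = FALSE)
  }
  others <- result$X[, setdiff(cols, covariate), drop = FALSE]
  xj <- result$X[, covariate]
  if (ncol(others) == 0L) {
    x_res <- xj - mean(xj)
    y_res <- result$y - mean(result$y)
  } else {
    qro <- qr(others)
    x_res <- qr.resid(qro, xj)
    y_res <- qr.resid(qro, result$y)
  }
  out <- data.frame(x_resid = x_res, y_resid = y_res)
  attr(out, "slope") <- sum(x_res * y_res) / sum(x_res^2)
  out
}
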
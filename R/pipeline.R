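#' Configuration for the full analysis pipeline
#'
#' @param input path to a study-table CSV, or a packaged fixture name such
#'   as `"mastaleru2025"` (see [load_records()]).
#' @param wtp_list positive WTP thresholds, USD/QALY.
#' @param basis cost basis for NMB-based outputs.
#' @param se_convention SE imputation convention for pooling/Egger stages,
#'   as `"convention:param"` (e.g. `"constant_cv:0.2"`) or `"user_column"`.
#' @param price_year target price year for harmonization labeling.
#' @param thresholds_file CSV of country WTP thresholds (defaults to the
#'   packaged table).
#' @param cpi_file,ppp_file optional CPI / PPP tables; when both are given,
#'   non-harmonized records are harmonized before analysis.
#' @param out_dir output directory for the report bundle.
#' @param seed seed for any stochastic stage (the fixture path is fully
#'   deterministic; the seed is recorded in the manifest regardless).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(input = "mastaleru2025",
                            wtp_list = c(50000, 100000, 150000),
                            basis = c("incremental", "total"),
                            se_convention = "constant_cv:0.2",
                            price_year = 2024,
                            thresholds_file = NULL,
                            cpi_file = NULL, ppp_file = NULL,
                            out_dir = tempfile("ceameta_report_"),
                            seed = 1) {
  basis <- match.arg(basis)
  if (length(wtp_list) == 0L || any(wtp_list <= 0)) {
    stop("config error: wtp_list must be non-empty and positive",
         call. = FALSE)
  }
  if (is.null(thresholds_file)) {
    thresholds_file <- system.file("extdata", "wtp_thresholds.csv",
                                   package = "ceameta", mustWork = TRUE)
  }
  structure(as.list(environment()), class = "pipeline_config")
}

.parse_se_convention <- function(spec) {
  parts <- strsplit(spec, ":", fixed = TRUE)[[1]]
  list(convention = parts[1],
       param = if (length(parts) > 1L) as.numeric(parts[2]) else NA_real_)
}

.stats_row <- function(s) {
  data.frame(n = s$n, mean = s$mean, sd = s$sd, se = s$se,
             ci95_low = s$ci95_low, ci95_high = s$ci95_high, min = s$min,
             q25 = s$q25, median = s$median, q75 = s$q75, max = s$max)
}

#' Run the full cost-effectiveness meta-analysis pipeline
#'
#' Orchestrates load -> (optional) harmonization -> per-study NMB ->
#' descriptive, subgroup and distributional summaries -> classification
#' and affordability -> trend regressions -> SE imputation, pooling,
#' Egger test and leave-one-out -> report bundle. Every emitted number is
#' produced by exactly one package operation; the report layer only
#' formats. A JSON manifest records every convention in force (cost
#' basis, SE imputation, quantile rule, tau^2 estimator, price year,
#' seed), so a bundle is fully determined by its manifest and input.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with the computed objects and the paths of
#'   the written files.
#' @examples
#' \donttest{
#' res <- run_pipeline(pipeline_config(out_dir = tempfile()))
#' res$icer_summary$median
#' }
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  table <- load_records(config$input)
  if (!is.null(config$cpi_file) && !is.null(config$ppp_file)) {
    table <- harmonize_table(table, read_cpi(config$cpi_file),
                             read_ppp(config$ppp_file),
                             target_year = config$price_year)
  }
  flags <- validate_table(table)
  thresholds <- read.csv(config$thresholds_file, stringsAsFactors = FALSE)

  # subgroup and distributional summaries
  by_intervention <- group_summary(table, "intervention",
                                   config$wtp_list, config$basis)
  by_country <- group_summary(table, "country", config$wtp_list,
                              config$basis)
  by_age <- group_summary(table, "age_group", config$wtp_list,
                          config$basis)
  icer_summary <- summarize_values(table$icer_per_qaly)
  qaly_summary <- summarize_values(table$qaly_gain)
  cost_summary <- summarize_values(table$incremental_cost)
  nmb_tables <- lapply(config$wtp_list, function(lam) {
    cbind(lambda = lam, basis = config$basis,
          .stats_row(nmb_summary(table, lam, config$basis)))
  })
  nmb_tab <- do.call(rbind, nmb_tables)

  classification <- do.call(rbind, lapply(config$wtp_list, function(lam) {
    cl <- classify(table, lam, "nmb_positive", config$basis)
    data.frame(lambda = lam, cost_effective = cl$count, total = cl$n,
               proportion = cl$count / cl$n)
  }))
  afford <- affordability(table, thresholds, basis = config$basis)

  trend_icer <- trend_slope(table$icer_per_qaly, table$pub_year)
  trend_qaly <- trend_slope(table$qaly_gain, table$pub_year)

  conv <- .parse_se_convention(config$se_convention)
  eff <- impute_se(table, "qaly_gain", conv$convention, conv$param)
  pooled_qaly <- random_effects_dl(eff$estimate, eff$se)
  egger <- egger_test(eff$estimate, eff$se)
  loo <- leave_one_out(table$icer_per_qaly, "mean", ids = table$study_id)

  paths <- c(
    harmonized = file.path(config$out_dir, "harmonized_records.csv"),
    by_intervention = file.path(config$out_dir, "summary_by_intervention.csv"),
    by_country = file.path(config$out_dir, "summary_by_country.csv"),
    by_age = file.path(config$out_dir, "summary_by_age_group.csv"),
    icer_distribution = file.path(config$out_dir, "icer_distribution.csv"),
    nmb_summaries = file.path(config$out_dir, "nmb_summaries.csv"),
    classification = file.path(config$out_dir, "classification.csv"),
    affordability = file.path(config$out_dir, "affordability.csv"),
    trend = file.path(config$out_dir, "trend_regressions.csv"),
    egger = file.path(config$out_dir, "egger.csv"),
    loo = file.path(config$out_dir, "leave_one_out.csv"),
    flags = file.path(config$out_dir, "consistency_flags.csv"),
    manifest = file.path(config$out_dir, "manifest.json"))

  write_records(table, paths["harmonized"])
  write.csv(by_intervention, paths["by_intervention"], row.names = FALSE)
  write.csv(by_country, paths["by_country"], row.names = FALSE)
  write.csv(by_age, paths["by_age"], row.names = FALSE)
  write.csv(.stats_row(icer_summary), paths["icer_distribution"],
            row.names = FALSE)
  write.csv(nmb_tab, paths["nmb_summaries"], row.names = FALSE)
  write.csv(classification, paths["classification"], row.names = FALSE)
  write.csv(afford, paths["affordability"], row.names = FALSE)
  write.csv(data.frame(response = c("icer_per_qaly", "qaly_gain"),
                       slope = c(trend_icer$slope, trend_qaly$slope),
                       se = c(trend_icer$se, trend_qaly$se),
                       p = c(trend_icer$p, trend_qaly$p)),
            paths["trend"], row.names = FALSE)
  write.csv(data.frame(intercept = egger$intercept,
                       se_intercept = egger$se_intercept, t = egger$t,
                       p = egger$p, k = egger$k,
                       se_convention = config$se_convention),
            paths["egger"], row.names = FALSE)
  write.csv(loo$rows, paths["loo"], row.names = FALSE)
  write.csv(flags, paths["flags"], row.names = FALSE)

  manifest <- list(
    input = config$input, n_records = nrow(table),
    wtp_list = config$wtp_list, cost_basis = config$basis,
    se_convention = config$se_convention,
    quantile_rule = icer_summary$quantile_rule,
    tau2_estimator = "DerSimonian-Laird",
    price_year = config$price_year, seed = config$seed,
    n_consistency_flags = nrow(flags),
    files = as.list(basename(paths)))
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE,
                              digits = NA),
             paths["manifest"])

  invisible(list(table = table, flags = flags,
                 by_intervention = by_intervention,
                 by_country = by_country, by_age = by_age,
                 icer_summary = icer_summary, qaly_summary = qaly_summary,
                 cost_summary = cost_summary, nmb_summaries = nmb_tab,
                 classification = classification, affordability = afford,
                 trend_icer = trend_icer, trend_qaly = trend_qaly,
                 pooled_qaly = pooled_qaly, egger = egger, loo = loo,
                 paths = paths))
}
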
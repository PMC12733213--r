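#' @noRd
.schema_cols <- c("study_id", "authors_label", "pub_year", "country",
                  "intervention", "population_tag", "age_group", "model_type",
                  "qaly_gain", "total_qaly", "total_cost", "incremental_cost",
                  "icer_per_qaly", "currency_code", "price_year")

.numeric_cols <- c("pub_year", "qaly_gain", "total_qaly", "total_cost",
                   "incremental_cost", "icer_per_qaly", "price_year")

# optional within-study standard-error columns; empty in the shipped fixture
.optional_cols <- c("se_qaly_gain", "se_incremental_cost")

#' Canonicalize a country label
#'
#' The source tables use both "UK" and "United Kingdom" for the same
#' jurisdiction; one canonical label is required before grouping or dummy
#' coding. The pre-canonicalization string is kept by the caller
#' (see [load_records()]).
#'
#' @param x character vector of country labels.
#' @return character vector with aliases collapsed to the canonical label.
#' @export
canonical_country <- function(x) {
  x <- trimws(x)
  x[x %in% c("United Kingdom", "Great Britain")] <- "UK"
  x[x %in% c("United States", "United States of America", "US")] <- "USA"
  x
}

# strip thousands separators, currency junk and en-dash minus signs
.clean_numeric <- function(x) {
  x <- gsub(",", "", as.character(x), fixed = TRUE)
  x <- gsub("–|−", "-", x)
  x <- gsub("[$  ]", "", x)
  x[x == ""] <- NA_character_
  x
}

#' Construct a validated study table
#'
#' Core constructor behind [load_records()]: checks the schema, uniqueness
#' of `study_id`, and basic sanity of the numeric columns, then stamps the
#' `study_table` class.
#'
#' @param df a data.frame with the documented columns (see [load_records()]).
#' @param provenance free-text source tag stored as an attribute.
#' @return a `study_table` (a validated data.frame).
#' @export
as_study_table <- function(df, provenance = "user") {
  missing_cols <- setdiff(.schema_cols, names(df))
  if (length(missing_cols) > 0L) {
    stop("schema error: missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(df) == 0L) {
    stop("empty-input error: study table has no records", call. = FALSE)
  }
  for (col in intersect(c(.numeric_cols, .optional_cols), names(df))) {
    cleaned <- .clean_numeric(df[[col]])
    val <- suppressWarnings(as.numeric(cleaned))
    bad <- which(!is.na(cleaned) & is.na(val))
    if (length(bad) > 0L) {
      stop(sprintf("malformed numeric cell in column '%s', row %d: '%s'",
                   col, bad[1L], cleaned[bad[1L]]), call. = FALSE)
    }
    df[[col]] <- val
  }
  dup <- df$study_id[duplicated(df$study_id)]
  if (length(dup) > 0L) {
    stop("validation error: duplicate study_id: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  if (any(!is.na(df$total_qaly) & df$total_qaly <= 0)) {
    stop("validation error: total_qaly must be > 0", call. = FALSE)
  }
  original_country <- as.character(df$country)
  df$country <- canonical_country(original_country)
  df <- df[, c(.schema_cols, intersect(.optional_cols, names(df)))]
  attr(df, "provenance") <- provenance
  attr(df, "original_country") <- original_country
  class(df) <- c("study_table", "data.frame")
  df
}

#' Load a study-level table of economic evaluations
#'
#' Reads a UTF-8 CSV with the documented header (one row per modeled
#' sub-scenario) and returns a validated [as_study_table()] object.
#' Thousands separators and en-dash minus signs in numeric cells are
#' normalized; "United Kingdom" and "UK" are collapsed to one label (the
#' original strings are retained in the `original_country` attribute).
#'
#' The packaged 17-observation dataset of inclisiran economic evaluations
#' is available as `load_records("mastaleru2025")` (or
#' `"fixture:mastaleru2025"`). Its monetary columns are already
#' PPP-adjusted US dollars at 2024 prices. In the source tables the column
#' printed as "ICER USD" actually holds the per-patient incremental cost
#' (its distribution matches the incremental-cost summaries), while
#' "ICER/QALY USD" holds the reported ICER; the fixture maps
#' `incremental_cost` and `icer_per_qaly` accordingly.
#'
#' @param path_or_fixture path to a CSV file, or a packaged fixture name.
#' @return a `study_table`.
#' @seealso [write_records()], [validate_table()]
#' @examples
#' studies <- load_records("mastaleru2025")
#' nrow(studies)
#' @export
load_records <- function(path_or_fixture) {
  fixture <- sub("^fixture:", "", path_or_fixture)
  if (fixture %in% c("mastaleru2025")) {
    path <- system.file("extdata", paste0(fixture, ".csv"),
                        package = "ceameta", mustWork = TRUE)
    provenance <- paste0("fixture:", fixture)
  } else {
    path <- path_or_fixture
    if (!file.exists(path)) {
      stop("input file not found: ", path, call. = FALSE)
    }
    provenance <- path
  }
  df <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character",
                 fileEncoding = "UTF-8")
  if (nrow(df) == 0L) {
    stop("empty-input error: no data rows in ", path, call. = FALSE)
  }
  as_study_table(df, provenance = provenance)
}

#' Write a study table to CSV
#'
#' Inverse of [load_records()]: numeric columns are written at full
#' precision (up to 15 significant digits) so that a write/load round trip
#' is the identity.
#'
#' @param table a `study_table`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_records <- function(table, path) {
  stopifnot(inherits(table, "study_table"))
  out <- as.data.frame(table)
  for (col in intersect(c(.numeric_cols, .optional_cols), names(out))) {
    out[[col]] <- format(out[[col]], digits = 15, scientific = FALSE,
                         trim = TRUE)
    out[[col]][out[[col]] == "NA"] <- ""
  }
  write.csv(out, path, row.names = FALSE, quote = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Flag records whose reported ICER disagrees with incremental cost / QALY
#'
#' For each record compares the reported `icer_per_qaly` against the
#' implied ratio `incremental_cost / qaly_gain` and raises a consistency
#' flag (never a rejection) when the relative discrepancy exceeds `tol`.
#' Published tables mix cost bases and rounding conventions, so such
#' disagreements are informative rather than fatal; flagged records are
#' exactly those for which an ICER-based and an NMB-based cost-effectiveness
#' classification can diverge.
#'
#' @param table a `study_table`.
#' @param tol relative tolerance (fraction); `Inf` disables all flags.
#' @return data.frame with one row per flagged record: `study_id`,
#'   `icer_reported`, `icer_implied`, `rel_diff`. Zero rows when all
#'   records are consistent. The input is never modified.
#' @examples
#' flags <- validate_table(load_records("mastaleru2025"), tol = 0.01)
#' flags$study_id
#' @export
validate_table <- function(table, tol = 0.01) {
  stopifnot(inherits(table, "study_table"), tol >= 0)
  implied <- ifelse(table$qaly_gain != 0,
                    table$incremental_cost / table$qaly_gain, NA_real_)
  rel <- abs(table$icer_per_qaly - implied) / abs(table$icer_per_qaly)
  hit <- which(!is.na(rel) & rel > tol)
  data.frame(study_id = table$study_id[hit],
             icer_reported = table$icer_per_qaly[hit],
             icer_implied = implied[hit],
             rel_diff = rel[hit],
             stringsAsFactors = FALSE)
}

#' @export
print.study_table <- function(x, ...) {
  cat(sprintf("Study table: %d records (%s)\n", nrow(x),
              attr(x, "provenance")))
  print(as.data.frame(x), ...)
  invisible(x)
}
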
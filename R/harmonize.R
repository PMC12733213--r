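#' Read a consumer-price-index series table
#'
#' CSV schema: `country,year,index`. Index values are on an arbitrary base;
#' only ratios between years of the same country are ever used.
#'
#' @param path CSV path.
#' @return data.frame with columns country, year, index.
#' @export
read_cpi <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("country", "year", "index") %in% names(df)))
  if (any(df$index <= 0)) stop("CPI index values must be > 0", call. = FALSE)
  df$country <- canonical_country(df$country)
  df
}

#' Read a purchasing-power-parity conversion-factor table
#'
#' CSV schema: `country,year,lcu_per_intl_dollar` — local currency units
#' per international dollar.
#'
#' @param path CSV path.
#' @return data.frame with columns country, year, lcu_per_intl_dollar.
#' @export
read_ppp <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("country", "year", "lcu_per_intl_dollar") %in% names(df)))
  if (any(df$lcu_per_intl_dollar <= 0)) {
    stop("PPP factors must be > 0", call. = FALSE)
  }
  df$country <- canonical_country(df$country)
  df
}

.cpi_index <- function(cpi, country, year, interpolate = FALSE) {
  rows <- cpi[cpi$country == country, , drop = FALSE]
  hit <- rows$index[rows$year == year]
  if (length(hit) == 1L) return(hit)
  if (interpolate && nrow(rows) >= 2L &&
      year > min(rows$year) && year < max(rows$year)) {
    # log-linear interpolation inside the covered range
    o <- order(rows$year)
    return(exp(stats::approx(rows$year[o], log(rows$index[o]),
                             xout = year)$y))
  }
  stop(sprintf("coverage error: no CPI index for %s in %d", country, year),
       call. = FALSE)
}

#' Inflate a local-currency amount between price years
#'
#' Scales `amount` by the ratio of the country's CPI index at `to_year` to
#' its index at `from_year`, preserving the country's internal price
#' dynamics before any cross-country conversion.
#'
#' @param amount monetary amount in local currency units.
#' @param country canonical country name.
#' @param from_year,to_year price years; both must be covered by `cpi`.
#' @param cpi CPI table as from [read_cpi()].
#' @param interpolate log-linearly interpolate missing years inside the
#'   covered range (default off).
#' @return inflated amount in the same currency.
#' @examples
#' cpi <- data.frame(country = "X", year = c(2020, 2024), index = c(95, 114))
#' inflate(250, "X", 2020, 2024, cpi)  # 300
#' @export
inflate <- function(amount, country, from_year, to_year, cpi,
                    interpolate = FALSE) {
  if (from_year == to_year) return(amount)
  i_from <- .cpi_index(cpi, country, from_year, interpolate)
  i_to <- .cpi_index(cpi, country, to_year, interpolate)
  amount * i_to / i_from
}

#' Convert a local-currency amount to PPP-adjusted dollars
#'
#' Divides by the country's PPP conversion factor (local currency units per
#' international dollar), correcting for relative price levels without the
#' distortions of nominal exchange rates.
#'
#' @param amount monetary amount in local currency units.
#' @param country canonical country name.
#' @param year price year of the factor to use.
#' @param ppp PPP table as from [read_ppp()].
#' @return amount in PPP-adjusted international dollars.
#' @export
ppp_convert <- function(amount, country, year, ppp) {
  rows <- ppp[ppp$country == country & ppp$year == year, , drop = FALSE]
  if (nrow(rows) != 1L) {
    stop(sprintf("coverage error: no PPP factor for %s in %d", country, year),
         call. = FALSE)
  }
  amount / rows$lcu_per_intl_dollar
}

#' Harmonize a record's monetary fields to PPP dollars at a target year
#'
#' Two-step harmonization: CPI inflation of local-currency costs to
#' `target_year`, then PPP conversion to international dollars. The three
#' monetary fields (`total_cost`, `incremental_cost`, `icer_per_qaly`) are
#' scaled by the identical composite factor, so the internal relation
#' ICER = incremental cost / QALY gain is preserved whenever the raw record
#' satisfied it. QALY fields are never touched. Records already carrying
#' `currency_code == "PPP-USD"` pass through unchanged, making the
#' operation idempotent.
#'
#' @param record one-row slice of a `study_table` (or a list with the same
#'   fields).
#' @param cpi,ppp tables as from [read_cpi()] / [read_ppp()].
#' @param target_year target price year (default 2024).
#' @param interpolate passed to [inflate()].
#' @return the record with monetary fields harmonized, `currency_code`
#'   set to "PPP-USD", `price_year` set to `target_year`, and the original
#'   values retained in an `original_monetary` attribute.
#' @export
harmonize_record <- function(record, cpi, ppp, target_year = 2024,
                             interpolate = FALSE) {
  if (identical(record$currency_code, "PPP-USD")) {
    return(record)
  }
  money <- c("total_cost", "incremental_cost", "icer_per_qaly")
  orig <- as.list(record[money])
  inflated1 <- inflate(1, record$country, record$price_year, target_year,
                       cpi, interpolate)
  factor_total <- ppp_convert(inflated1, record$country, target_year, ppp)
  for (f in money) record[[f]] <- record[[f]] * factor_total
  record$currency_code <- "PPP-USD"
  record$price_year <- target_year
  attr(record, "original_monetary") <- orig
  record
}

#' Harmonize every record of a study table
#'
#' @param table a `study_table`.
#' @inheritParams harmonize_record
#' @return the harmonized `study_table`.
#' @export
harmonize_table <- function(table, cpi, ppp, target_year = 2024,
                            interpolate = FALSE) {
  stopifnot(inherits(table, "study_table"))
  for (i in seq_len(nrow(table))) {
    rec <- harmonize_record(table[i, , drop = FALSE], cpi, ppp,
                            target_year, interpolate)
    table[i, ] <- rec
  }
  attr(table, "target_price_year") <- target_year
  table
}
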
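#' Daily means from hourly monitor records
#'
#' Aggregates an hourly site-series table to daily means. A day is valid
#' iff at least `min_hour_fraction` of its 24 hours carry a usable value;
#' a valid day's mean is the mean of the hours present. Missing hours are
#' absent rows (or `NA` values); negative concentrations are instrument
#' noise and are treated as missing (counted in the `negative_log`
#' attribute).
#'
#' @param series Tibble (`site_id`, `timestamp` POSIXct/parseable,
#'   `value_ppb`).
#' @param min_hour_fraction Minimum fraction of the 24 hours required for a
#'   valid day (inclusive bound).
#' @return Tibble (`site_id`, `date`, `n_hours`, `mean_ppb`, `valid`).
#' @export
daily_means <- function(series, min_hour_fraction = 0.75) {
  stopifnot_cols(series, c("site_id", "timestamp", "value_ppb"), "series")
  if (nrow(series) == 0) abort("daily_means(): empty series")
  ts <- series$timestamp
  if (!inherits(ts, "POSIXct")) ts <- as.POSIXct(ts, tz = "UTC")
  v <- series$value_ppb
  n_neg <- sum(v < 0, na.rm = TRUE)
  v[!is.na(v) & v < 0] <- NA_real_
  out <- tibble(site_id = series$site_id,
                date = as.Date(ts, tz = "UTC"),
                value = v) |>
    filter(!is.na(.data$value)) |>
    group_by(.data$site_id, .data$date) |>
    summarise(n_hours = dplyr::n(), mean_ppb = mean(.data$value),
              .groups = "drop") |>
    mutate(valid = .data$n_hours >= min_hour_fraction * 24)
  attr(out, "negative_log") <- n_neg
  out
}

#' Annual means with day-completeness filtering
#'
#' Computes, per site, the mean over valid days of the target year, the
#' day-level completeness (valid days / days in the year; leap years use a
#' 366-day denominator), and the retention flag
#' `day_completeness >= min_day_fraction` (inclusive: "at least 75%" keeps
#' exactly 0.75 and drops 273/365 = 0.748). Sites with zero valid days get
#' `NA` means and are not retained.
#'
#' @param daily Output of [daily_means()].
#' @param year Target calendar year.
#' @param min_day_fraction Completeness threshold (inclusive).
#' @return Tibble (`site_id`, `year`, `mean_ppb`, `n_valid_days`,
#'   `day_completeness`, `retained`), one row per site present in `daily`.
#' @export
annual_mean <- function(daily, year, min_day_fraction = 0.75) {
  stopifnot_cols(daily, c("site_id", "date", "mean_ppb", "valid"), "daily")
  days_in_year <- as.integer(as.Date(sprintf("%d-01-01", year + 1)) -
                               as.Date(sprintf("%d-01-01", year)))
  daily |>
    filter(format(.data$date, "%Y") == as.character(year)) |>
    group_by(.data$site_id) |>
    summarise(
      year = as.integer(year),
      mean_ppb = if (any(.data$valid)) {
        mean(.data$mean_ppb[.data$valid])
      } else NA_real_,
      n_valid_days = sum(.data$valid),
      .groups = "drop"
    ) |>
    mutate(day_completeness = .data$n_valid_days / days_in_year,
           retained = .data$day_completeness >= min_day_fraction)
}

#' Validate site coordinates
#'
#' Flags sites with missing coordinates, and — when coordinates are given
#' as geographic lon/lat strings — coordinates reported to fewer than
#' `min_decimals` decimal places (precision is counted on the literal
#' string, e.g. `"38.48210"` has 5 and passes, `"38.48"` has 2 and fails).
#' Planar `x`/`y` coordinates are only checked for missingness.
#'
#' @param sites Tibble with either `x`,`y` (planar metres) or `lon`,`lat`
#'   (character or numeric degrees).
#' @param min_decimals Minimum decimal places for lon/lat.
#' @return `sites` with added `accepted` (logical) and `reject_reason`
#'   (`NA`, `"missing_coordinate"`, or `"insufficient_precision"`).
#' @export
validate_coordinates <- function(sites, min_decimals = 5L) {
  geo <- all(c("lon", "lat") %in% names(sites))
  if (!geo) stopifnot_cols(sites, c("x", "y"), "sites")
  cols <- if (geo) c("lon", "lat") else c("x", "y")
  a <- sites[[cols[1]]]; b <- sites[[cols[2]]]
  miss <- is.na(a) | is.na(b) |
    (is.character(a) & trimws(as.character(a)) == "") |
    (is.character(b) & trimws(as.character(b)) == "")
  reason <- ifelse(miss, "missing_coordinate", NA_character_)
  if (geo) {
    imprecise <- !miss &
      (decimal_places(a) < min_decimals | decimal_places(b) < min_decimals)
    reason[imprecise] <- "insufficient_precision"
  }
  sites |>
    mutate(accepted = is.na(reason), reject_reason = reason)
}

# Decimal places of the literal string; numerics use their shortest exact
# decimal representation (trailing zeros are unknowable once parsed).
decimal_places <- function(x) {
  s <- if (is.character(x)) trimws(x) else
    vapply(x, function(v) format(v, scientific = FALSE, trim = TRUE), "")
  vapply(s, function(v) {
    if (is.na(v) || !grepl("\\.", v)) 0L else nchar(sub("^[^.]*\\.", "", v))
  }, 0L, USE.NAMES = FALSE)
}

#' Hourly series to retained annual site means
#'
#' The full measurement QC chain: hourly records to daily means (hour rule)
#' to annual means (day-completeness rule), optionally preceded by
#' coordinate validation when a `sites` table is supplied.
#'
#' @inheritParams daily_means
#' @inheritParams annual_mean
#' @param sites Optional site table for [validate_coordinates()].
#' @return The [annual_mean()] tibble; sites failing coordinate validation
#'   are excluded and recorded in the `rejected_sites` attribute.
#' @export
qc_annual_means <- function(series, year, sites = NULL,
                            min_hour_fraction = 0.75,
                            min_day_fraction = 0.75) {
  rejected <- NULL
  if (!is.null(sites)) {
    checked <- validate_coordinates(sites)
    rejected <- filter(checked, !.data$accepted)
    series <- filter(series,
                     .data$site_id %in% checked$site_id[checked$accepted])
  }
  out <- annual_mean(daily_means(series, min_hour_fraction), year,
                     min_day_fraction)
  attr(out, "rejected_sites") <- rejected
  out
}
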
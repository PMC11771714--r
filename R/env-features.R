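#' Vapor pressure deficit from air temperature and relative humidity
#'
#' Saturation vapor pressure follows the Tetens form
#' `es = 0.6106 * exp(17.27 * Ta / (237.3 + Ta))` (kPa), actual vapor
#' pressure is `ea = RH * es / 100`, and `VPD = es - ea`.
#'
#' @param ta_c air temperature (degrees C, > -237.3).
#' @param rh_pct relative humidity (percent, in `[0, 100]`).
#' @return vapor pressure deficit (kPa, >= 0).
#' @examples
#' compute_vpd(25, 50)  # ~1.583 kPa
#' @export
compute_vpd <- function(ta_c, rh_pct) {
  if (any(rh_pct < 0 | rh_pct > 100, na.rm = TRUE)) {
    stop("rh_pct must lie in [0, 100]")
  }
  if (any(ta_c <= -237.3, na.rm = TRUE)) stop("ta_c out of range")
  es <- 0.6106 * exp(17.27 * ta_c / (237.3 + ta_c))
  es - rh_pct * es / 100
}

#' Fill gaps in a 30-minute weather series
#'
#' Re-grids the series onto its full 30-minute lattice and fills missing
#' values by linear interpolation within each variable (nearest-value
#' extension at the series boundaries). Filled records are flagged in the
#' `gap_filled` column; precipitation gaps are filled with 0 (events are
#' instantaneous accumulations, not a continuous field).
#'
#' @param weather a `weather_series` data frame, possibly with missing rows
#'   or `NA` values.
#' @param max_gap_fraction refuse to fill if more than this fraction of the
#'   lattice is missing (default 0.25).
#' @return a gap-free `weather_series` with `gap_filled` flags.
#' @export
gap_fill_weather <- function(weather, max_gap_fraction = 0.25) {
  ts_full <- seq(min(weather$timestamp), max(weather$timestamp), by = "30 min")
  idx <- match(ts_full, weather$timestamp)
  out <- data.frame(timestamp = ts_full)
  vars <- c("ta_c", "rh_pct", "fsd_wm2", "precip_mm")
  filled <- is.na(idx)
  for (v in vars) {
    x <- weather[[v]][idx]
    filled <- filled | is.na(x)
  }
  if (mean(filled) > max_gap_fraction) {
    stop("gap fraction ", round(mean(filled), 3), " exceeds ", max_gap_fraction)
  }
  for (v in vars) {
    x <- weather[[v]][idx]
    if (v == "precip_mm") {
      x[is.na(x)] <- 0
    } else if (anyNA(x)) {
      x <- stats::approx(seq_along(x)[!is.na(x)], x[!is.na(x)],
                         xout = seq_along(x), rule = 2)$y
    }
    out[[v]] <- x
  }
  out$gap_filled <- filled
  class(out) <- c("weather_series", "data.frame")
  out
}

#' Per-day environmental covariates
#'
#' Condenses a gap-free 30-minute weather series into the daily covariates
#' used by the statistical layer: the 10:00 ("morning") air temperature, VPD
#' and shortwave radiation, precipitation accumulated from midnight through
#' 10:00, and 3-day aggregates (means of the 30-min records of the 3
#' complete calendar days preceding the day -- or including it, see
#' `window`; precipitation as a 3-day sum). VPD is computed per 30-minute
#' record before any aggregation.
#'
#' @param weather a gap-free `weather_series`.
#' @param morning_hour local hour of the morning snapshot (default 10).
#' @param window `"exclude"` (default) uses the 3 calendar days before the
#'   day; `"include"` uses the day itself plus the 2 before it.
#' @return data frame keyed by `date` with columns `morning_Ta`,
#'   `morning_VPD`, `morning_Fsd`, `precip_to_10am`, `Ta_3day`, `VPD_3day`,
#'   `Fsd_3day`, `Precip_3day_sum`. 3-day fields are `NA` where fewer than 3
#'   qualifying days exist.
#' @export
daily_env_features <- function(weather, morning_hour = 10,
                               window = c("exclude", "include")) {
  window <- match.arg(window)
  w <- weather
  w$vpd <- compute_vpd(w$ta_c, w$rh_pct)
  w$date <- as.Date(w$timestamp, tz = "UTC")
  hour <- as.numeric(format(w$timestamp, "%H")) + as.numeric(format(w$timestamp, "%M")) / 60
  days <- sort(unique(w$date))

  morning <- w[hour == morning_hour, ]
  if (!all(days %in% morning$date)) {
    stop("missing ", morning_hour, ":00 record on ",
         paste(setdiff(format(days), format(morning$date)), collapse = ", "))
  }
  morning <- morning[match(days, morning$date), ]
  to10 <- vapply(days, function(d) sum(w$precip_mm[w$date == d & hour <= morning_hour]),
                 numeric(1))
  day_mean <- function(var) vapply(days, function(d) mean(w[[var]][w$date == d]), numeric(1))
  day_sum_precip <- vapply(days, function(d) sum(w$precip_mm[w$date == d]), numeric(1))
  mTa <- day_mean("ta_c"); mVPD <- day_mean("vpd"); mFsd <- day_mean("fsd_wm2")

  agg3 <- function(x, fun) {
    vapply(seq_along(days), function(i) {
      sel <- if (window == "exclude") (i - 3):(i - 1) else (i - 2):i
      if (any(sel < 1)) return(NA_real_)
      fun(x[sel])
    }, numeric(1))
  }
  data.frame(date = days,
             morning_Ta = morning$ta_c,
             morning_VPD = morning$vpd,
             morning_Fsd = morning$fsd_wm2,
             precip_to_10am = to10,
             Ta_3day = agg3(mTa, mean),
             VPD_3day = agg3(mVPD, mean),
             Fsd_3day = agg3(mFsd, mean),
             Precip_3day_sum = agg3(day_sum_precip, sum))
}

#' Read / write weather CSV
#'
#' The on-disk dialect is `timestamp` (ISO-8601), `ta_c`, `rh_pct`,
#' `fsd_wm2`, `precip_mm` and optionally `gap_filled`.
#'
#' @param path file path.
#' @return [read_weather()] returns a `weather_series`.
#' @export
read_weather <- function(path) {
  w <- utils::read.csv(path, stringsAsFactors = FALSE)
  w$timestamp <- as.POSIXct(w$timestamp, tz = "UTC",
                            tryFormats = c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S"))
  if (is.null(w$gap_filled)) w$gap_filled <- FALSE
  class(w) <- c("weather_series", "data.frame")
  w
}

#' @rdname read_weather
#' @param weather a `weather_series`.
#' @export
write_weather <- function(weather, path) {
  out <- weather
  out$timestamp <- format(out$timestamp, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
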
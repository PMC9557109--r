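#' Daily growing degree days
#'
#' Thermal time accumulated in a single day, computed from the daily
#' temperature extremes as `(tmax + tmin)/2 - tbase`, with negative values
#' clipped to zero. The default base temperature is the conventional 10 degC
#' for maize.
#'
#' @param tmax Daily maximum air temperature (degC). May be a vector.
#' @param tmin Daily minimum air temperature (degC). Same length as `tmax`.
#' @param tbase Base temperature (degC), default 10.
#' @return Numeric vector of daily GDD (degC d), each element >= 0.
#' @examples
#' daily_gdd(30, 20)        # 15
#' daily_gdd(12, 6)         # clipped to 0
#' @export
daily_gdd <- function(tmax, tmin, tbase = 10) {
  if (length(tmax) != length(tmin)) stop("tmax and tmin must have equal length")
  if (any(tmax < tmin)) {
    bad <- which(tmax < tmin)
    stop("tmax < tmin at position(s) ", paste(bad, collapse = ", "))
  }
  pmax(0, (tmax + tmin) / 2 - tbase)
}

#' Accumulate growing degree days over a date window
#'
#' Sums [daily_gdd()] over the days after `start` up to and including `end`
#' (start-exclusive, end-inclusive). Every calendar day in the window must be
#' present in the weather series; gaps are an error, not silently skipped.
#'
#' @param weather Data frame with columns `date` (Date), `tmax_c`, `tmin_c`.
#' @param start,end Dates delimiting the window; `start <= end`.
#' @param tbase Base temperature (degC), default 10.
#' @return Accumulated GDD (degC d), a single non-negative number. A zero
#'   length window (`start == end`) gives 0.
#' @export
accumulate_gdd <- function(weather, start, end, tbase = 10) {
  start <- as.Date(start); end <- as.Date(end)
  if (end < start) stop("end date precedes start date")
  if (start == end) return(0)
  wanted <- seq(start + 1, end, by = "day")
  idx <- match(wanted, as.Date(weather$date))
  if (anyNA(idx)) {
    stop("weather series has gaps in (", format(start), ", ", format(end),
         "]: missing ", paste(format(wanted[is.na(idx)]), collapse = ", "))
  }
  sum(daily_gdd(weather$tmax_c[idx], weather$tmin_c[idx], tbase))
}

#' Stage durations and thermal-time intervals for one year x hybrid
#'
#' Splits the growing season at silking (R1): calendar days and accumulated
#' GDD from sowing to R1 and from R1 to physiological maturity (R6), plus
#' their totals. Day counts are plain date differences
#' (start-exclusive/end-inclusive), so before + after = total by construction.
#'
#' @param rec One phenology record: a list or one-row data frame with `year`,
#'   `hybrid` and Date fields `sowing`, `r1`, `r6`.
#' @param weather Weather data frame covering sowing..R6 (see
#'   [accumulate_gdd()]).
#' @param tbase Base temperature (degC), default 10.
#' @return One-row data frame with columns `year`, `hybrid`,
#'   `days_before_silking`, `gdd_before_silking`, `days_after_silking`,
#'   `gdd_after_silking`, `total_days`, `total_gdd`.
#' @export
stage_durations <- function(rec, weather, tbase = 10) {
  sowing <- as.Date(rec$sowing); r1 <- as.Date(rec$r1); r6 <- as.Date(rec$r6)
  if (r1 < sowing || r6 < r1) stop("stage dates out of order: sowing <= R1 <= R6 required")
  d_before <- as.integer(r1 - sowing)
  d_after <- as.integer(r6 - r1)
  g_before <- accumulate_gdd(weather, sowing, r1, tbase)
  g_after <- accumulate_gdd(weather, r1, r6, tbase)
  data.frame(
    year = rec$year, hybrid = rec$hybrid,
    days_before_silking = d_before, gdd_before_silking = g_before,
    days_after_silking = d_after, gdd_after_silking = g_after,
    total_days = d_before + d_after, total_gdd = g_before + g_after,
    stringsAsFactors = FALSE
  )
}

#' Yield per unit thermal time
#'
#' Grain yield divided by accumulated GDD, a temperature resource-use
#' efficiency. The denominator is an explicit argument: reports compute it
#' both with post-silking GDD and with total GDD, since either accounting is
#' used in the trial literature.
#'
#' @param yield_kg_ha Grain yield (kg ha^-1).
#' @param gdd Accumulated GDD (degC d), > 0.
#' @return Yield per GDD (kg ha^-1 (degC d)^-1).
#' @export
yield_per_gdd <- function(yield_kg_ha, gdd) {
  if (any(gdd <= 0)) stop("gdd must be positive")
  yield_kg_ha / gdd
}
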
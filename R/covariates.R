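# Environmental covariates for the hourly models: diel phase from sun tables,
# tidal covariates from high/low water tables, pooled device temperature,
# hourly noise proxy and seasons.

#' Diel phase of timestamps
#'
#' Partitions each 24 h into morning, day, evening and night from a sun
#' table. Defaults: morning = `[civil_dawn, sunrise + 1 h)`, day =
#' `[sunrise + 1 h, sunset - 1 h)`, evening = `[sunset - 1 h, civil_dusk)`,
#' night = everything else (civil dusk to the next civil dawn). The 1 h
#' offsets around sunrise/sunset are configurable; published diel-phase
#' definitions vary and the defaults here are documented choices.
#'
#' @param t POSIXct vector (UTC).
#' @param sun sun table: data frame with `date`, `civil_dawn`, `sunrise`,
#'   `sunset`, `civil_dusk` (see [synthSunTable()], [readSunTable()]).
#' @param morning_offset_h hours after sunrise at which morning ends.
#' @param evening_offset_h hours before sunset at which evening starts.
#' @return factor with levels `morning`, `day`, `evening`, `night`.
#' @export
dielPeriod <- function(t, sun, morning_offset_h = 1, evening_offset_h = 1) {
  d <- utc_date(t)
  idx <- match(d, sun$date)
  if (anyNA(idx)) {
    stop("sun table has no entry for date(s): ",
         paste(unique(d[is.na(idx)]), collapse = ", "))
  }
  dawn <- sun$civil_dawn[idx]
  morning_end <- sun$sunrise[idx] + morning_offset_h * 3600
  evening_start <- sun$sunset[idx] - evening_offset_h * 3600
  dusk <- sun$civil_dusk[idx]
  phase <- rep("night", length(t))
  phase[t >= dawn & t < morning_end] <- "morning"
  phase[t >= morning_end & t < evening_start] <- "day"
  phase[t >= evening_start & t < dusk] <- "evening"
  factor(phase, levels = c("morning", "day", "evening", "night"))
}

#' Tidal covariates of timestamps
#'
#' For each timestamp: the signed time difference to the nearest high water
#' (hours; negative before, positive after), the tidal phase (`high` / `low`
#' within `phase_window_h` of the respective event, otherwise `flow` while
#' rising and `ebb` while falling) and the tidal range (m), the absolute
#' height difference between the nearest high water and its adjacent low
#' water on the side of `t` -- the spring/neap indicator.
#'
#' @param t POSIXct vector.
#' @param tide tide table: data frame with `time`, `type` (`"high"`/`"low"`),
#'   `height_m`, strictly increasing and alternating.
#' @param phase_window_h half-width of the slack-water window, hours.
#' @return data frame: `tide_diff_h`, `tidal_phase` (factor `ebb`, `flow`,
#'   `high`, `low`), `tidal_range_m`.
#' @export
tideCovariates <- function(t, tide, phase_window_h = 0.5) {
  validateTideTable(tide)
  tt <- as.numeric(tide$time)
  tn <- as.numeric(t)
  if (any(tn < tt[1] | tn > tt[length(tt)])) {
    stop("timestamp(s) outside the tide table span")
  }
  highs <- which(tide$type == "high")
  ht <- tt[highs]
  hi_near <- findInterval(tn, ht)        # last high at or before t (0 if none)
  pick_right <- hi_near == 0 |
    (hi_near < length(ht) & (tn - ht[pmax(hi_near, 1)]) >
       (ht[pmin(hi_near + 1, length(ht))] - tn))
  hi_idx <- ifelse(pick_right, pmin(hi_near + 1, length(ht)), pmax(hi_near, 1))
  diff_h <- (tn - ht[hi_idx]) / 3600

  # adjacent low on the side of t (events alternate, so neighbours are lows)
  full_hi <- highs[hi_idx]
  low_idx <- ifelse(diff_h < 0, full_hi - 1, full_hi + 1)
  low_idx[low_idx < 1] <- full_hi[low_idx < 1] + 1
  low_idx[low_idx > nrow(tide)] <- full_hi[low_idx > nrow(tide)] - 1
  range_m <- abs(tide$height_m[full_hi] - tide$height_m[low_idx])

  # phase: nearest event of any type within the slack window, else ebb/flow
  ev_near <- findInterval(tn, tt)
  ev_near[ev_near == 0] <- 1
  nxt <- pmin(ev_near + 1, length(tt))
  closer_next <- (tt[nxt] - tn) < (tn - tt[ev_near])
  nearest_ev <- ifelse(closer_next, nxt, ev_near)
  within <- abs(tn - tt[nearest_ev]) <= phase_window_h * 3600
  # between events the water rises towards a high and falls towards a low
  next_ev <- pmin(ev_near + 1, length(tt))
  rising <- tide$type[next_ev] == "high"
  phase <- ifelse(within, tide$type[nearest_ev], ifelse(rising, "flow", "ebb"))
  data.frame(
    tide_diff_h = diff_h,
    tidal_phase = factor(phase, levels = c("ebb", "flow", "high", "low")),
    tidal_range_m = range_m
  )
}

validateTideTable <- function(tide) {
  if (!all(c("time", "type", "height_m") %in% names(tide))) {
    stop("tide table needs columns time, type, height_m")
  }
  if (is.unsorted(as.numeric(tide$time), strictly = TRUE)) {
    stop("tide events must be strictly increasing in time")
  }
  if (nrow(tide) > 1 && any(tide$type[-1] == tide$type[-nrow(tide)])) {
    stop("tide events must alternate high/low")
  }
  invisible(tide)
}

#' Pooled hourly temperature from two co-deployed devices
#'
#' POD temperature sensors are relative, so the modeling covariate is the
#' mean of the two devices' hourly means; hours covered by only one device
#' use that device's value and are flagged.
#'
#' @param temp_a,temp_b data frames with `hour` (POSIXct) and
#'   `temperature_c`.
#' @return data frame: `hour`, `temperature_c`, `single_pod` (logical).
#' @export
pooledTemperature <- function(temp_a, temp_b) {
  m <- merge(temp_a, temp_b, by = "hour", all = TRUE,
             suffixes = c("_a", "_b"))
  both <- !is.na(m$temperature_c_a) & !is.na(m$temperature_c_b)
  pooled <- ifelse(both, (m$temperature_c_a + m$temperature_c_b) / 2,
                   ifelse(is.na(m$temperature_c_a), m$temperature_c_b,
                          m$temperature_c_a))
  data.frame(hour = m$hour, temperature_c = pooled, single_pod = !both)
}

#' Season of a month
#'
#' Meteorological seasons: spring = March--May, summer = June--August,
#' autumn = September--November, winter = December--February.
#'
#' @param month integer vector in 1..12, or POSIXct/Date (month extracted).
#' @return factor with levels `spring`, `summer`, `autumn`, `winter`.
#' @export
seasonOf <- function(month) {
  if (inherits(month, c("POSIXct", "POSIXt", "Date"))) {
    month <- as.integer(format(month, "%m"))
  }
  if (any(!month %in% 1:12)) stop("month must be in 1..12")
  s <- c("winter", "winter", "spring", "spring", "spring", "summer",
         "summer", "summer", "autumn", "autumn", "autumn", "winter")[month]
  factor(s, levels = c("spring", "summer", "autumn", "winter"))
}

#' Hourly noise proxy from per-minute Nall
#'
#' @param minutes data frame with `minute` (POSIXct) and `nall`.
#' @param stat aggregation statistic: `"mean"` (default), `"median"` or
#'   `"sum"`.
#' @return data frame: `hour`, `nall` (NA for hours with no monitored
#'   minute).
#' @export
hourlyNall <- function(minutes, stat = c("mean", "median", "sum")) {
  stat <- match.arg(stat)
  f <- switch(stat, mean = mean, median = stats::median, sum = sum)
  hr <- floor_hour(minutes$minute)
  agg <- tapply(minutes$nall, as.numeric(hr), f)
  data.frame(hour = .posix(as.numeric(names(agg))), nall = as.numeric(agg))
}

#' Assemble the hourly covariate table
#'
#' One row per hour of the effort period with every model covariate, or an
#' explicit missingness flag -- no silent gaps. Time-varying covariates are
#' evaluated at the bin centre (hour start + 30 min).
#'
#' @param hours POSIXct vector of hour starts (the effort period).
#' @param sun sun table (see [dielPeriod()]).
#' @param tide tide table (see [tideCovariates()]).
#' @param temperature pooled temperature table from [pooledTemperature()] (or
#'   any data frame with `hour`, `temperature_c`).
#' @param nall_hour hourly noise table from [hourlyNall()].
#' @param ... passed to [dielPeriod()] and [tideCovariates()].
#' @return data frame: `hour`, `month_frac`, `month`, `season`,
#'   `diel_period`, `temperature_c`, `nall`, `tide_diff_h`, `tidal_phase`,
#'   `tidal_range_m`, `complete` (logical).
#' @export
hourlyCovariates <- function(hours, sun, tide, temperature, nall_hour, ...) {
  centre <- hours + 1800
  tc <- tideCovariates(centre, tide, ...)
  out <- data.frame(
    hour = hours,
    month_frac = monthFraction(centre),
    month = as.integer(format(hours, "%m")),
    diel_period = dielPeriod(centre, sun, ...),
    tide_diff_h = tc$tide_diff_h,
    tidal_phase = tc$tidal_phase,
    tidal_range_m = tc$tidal_range_m
  )
  out$season <- seasonOf(out$month)
  out$temperature_c <- temperature$temperature_c[match(hours, temperature$hour)]
  out$nall <- nall_hour$nall[match(hours, nall_hour$hour)]
  out$complete <- stats::complete.cases(
    out[, c("temperature_c", "nall", "tide_diff_h", "tidal_range_m",
            "diel_period")])
  out
}
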
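# Synthetic environmental forcing for simulated deployments: sun and tide
# tables in the same layout as the delimited-text inputs accepted for real
# deployments, a shared lognormal-AR(1) ambient noise proxy (Nall) and a
# seasonal water-temperature series.

#' Synthetic sun table
#'
#' Builds a per-day table of civil dawn, sunrise, sunset and civil dusk with
#' a sinusoidal annual day-length cycle (defaults approximate a mid-latitude
#' NE Atlantic site, ~51 N). Labelled synthetic: a real deployment supplies
#' these times from published tables.
#'
#' @param start_date,end_date date range (inclusive).
#' @param mean_daylength,daylength_amplitude hours; day length is
#'   `mean + amplitude * cos(2*pi*(doy - 172)/365.25)` (peak at the June
#'   solstice).
#' @param twilight_minutes duration of civil twilight before sunrise / after
#'   sunset.
#' @return data frame: `date`, `civil_dawn`, `sunrise`, `sunset`,
#'   `civil_dusk` (POSIXct, UTC).
#' @export
synthSunTable <- function(start_date, end_date,
                          mean_daylength = 12.2, daylength_amplitude = 4.4,
                          twilight_minutes = 40) {
  dates <- seq(as.Date(start_date), as.Date(end_date), by = "day")
  doy <- as.integer(format(dates, "%j"))
  daylen <- mean_daylength + daylength_amplitude * cos(2 * pi * (doy - 172) / 365.25)
  midday <- .posix(as.POSIXct(dates, tz = "UTC")) + 12 * 3600
  sunrise <- midday - daylen / 2 * 3600
  sunset <- midday + daylen / 2 * 3600
  data.frame(
    date = dates,
    civil_dawn = sunrise - twilight_minutes * 60,
    sunrise = sunrise,
    sunset = sunset,
    civil_dusk = sunset + twilight_minutes * 60
  )
}

#' Synthetic tide table
#'
#' Alternating high/low water events on a semidiurnal (12.42 h) cycle with a
#' spring--neap (14.77 d) modulation of heights. Labelled synthetic: real
#' deployments supply tide tables as delimited text.
#'
#' @param start,end POSIXct window to cover (events extend half a cycle past
#'   both ends so every timestamp inside is bracketed).
#' @param high_mean,low_mean mean high/low water heights (m).
#' @param spring_amplitude half-range of the spring--neap height modulation (m).
#' @param first_high POSIXct time of a high water fixing the phase; default
#'   `start`.
#' @return data frame: `time` (POSIXct), `type` (`"high"`/`"low"`),
#'   `height_m`; events strictly alternate.
#' @export
synthTideTable <- function(start, end, high_mean = 3.1, low_mean = 0.9,
                           spring_amplitude = 0.6, first_high = NULL) {
  start <- .posix(start); end <- .posix(end)
  period <- 12.42 * 3600
  if (is.null(first_high)) first_high <- start
  t0 <- as.numeric(first_high) - period * ceiling((as.numeric(first_high) -
        as.numeric(start) + period) / period)
  highs <- seq(t0, as.numeric(end) + period, by = period)
  lows <- highs + period / 2
  sn <- function(tt) cos(2 * pi * tt / (14.77 * 86400))
  ev <- rbind(
    data.frame(time = highs, type = "high",
               height_m = high_mean + spring_amplitude * sn(highs)),
    data.frame(time = lows, type = "low",
               height_m = low_mean - spring_amplitude * 0.7 * sn(lows))
  )
  ev <- ev[order(ev$time), ]
  ev$time <- .posix(ev$time)
  rownames(ev) <- NULL
  ev
}

#' Simulate the per-minute ambient noise proxy (Nall)
#'
#' Lognormal AR(1) ambient component plus the true narrowband clicks emitted
#' in each minute, so `Nall >= clicks emitted` always holds. One series is
#' shared by both detectors of a co-deployment.
#'
#' @param minutes POSIXct vector of minute starts (consecutive).
#' @param params a [nallParams()] object.
#' @param true_clicks_per_minute integer vector aligned with `minutes`
#'   (0 if absent).
#' @param seed integer seed.
#' @return integer vector of Nall counts aligned with `minutes`.
#' @export
simulateNall <- function(minutes, params = nallParams(),
                         true_clicks_per_minute = 0, seed = 1) {
  n <- length(minutes)
  true_clicks_per_minute <- rep_len(true_clicks_per_minute, n)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  innov_sd <- params$sdlog * sqrt(1 - params$ar1^2)
  x <- numeric(n)
  x[1] <- rnorm(1, 0, params$sdlog)
  if (n > 1) {
    e <- rnorm(n - 1, 0, innov_sd)
    for (i in 2:n) x[i] <- params$ar1 * x[i - 1] + e[i - 1]
  }
  ambient <- round(exp(params$log_median + x))
  as.integer(ambient + true_clicks_per_minute)
}

#' Simulate hourly water temperature for one POD
#'
#' Seasonal sinusoid (late-summer peak) plus slow AR(1) weather noise and a
#' per-device offset: POD temperature sensors are relative, so each device
#' reports the shared water temperature with its own bias.
#'
#' @param hours POSIXct vector of hour starts.
#' @param mean_c,amplitude_c annual mean and amplitude, degrees C.
#' @param pod_offset additive device bias, degrees C.
#' @param noise_sd innovation sd of the AR(1) weather component.
#' @param seed integer seed (use the same seed for co-deployed devices so
#'   they share the weather component).
#' @return data frame: `hour` (POSIXct), `temperature_c`.
#' @export
simulateTemperature <- function(hours, mean_c = 12.5, amplitude_c = 3.5,
                                pod_offset = 0, noise_sd = 0.08, seed = 1) {
  n <- length(hours)
  doy <- as.integer(format(utc_date(hours), "%j"))
  seasonal <- mean_c + amplitude_c * cos(2 * pi * (doy - 228) / 365.25)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  ar <- 0.995
  w <- numeric(n)
  if (n > 0) w[1] <- rnorm(1, 0, noise_sd / sqrt(1 - ar^2))
  if (n > 1) {
    e <- rnorm(n - 1, 0, noise_sd)
    for (i in 2:n) w[i] <- ar * w[i - 1] + e[i - 1]
  }
  data.frame(hour = hours, temperature_c = seasonal + w + pod_offset)
}

# save/restore the global RNG state so simulators are pure given their seed
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}
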
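#' Occupancy process parameters
#'
#' Describes the encounter (porpoise presence) process: a Poisson process of
#' encounter starts whose instantaneous rate is modulated by a cyclic month
#' effect, a diel-period factor and a cyclic tidal effect, with exponentially
#' distributed encounter durations.
#'
#' The month modulation is `1 + month_amplitude * cos(2 * pi * (m - peak_month) / 12)`
#' with `m` the fractional month; the tidal modulation is
#' `1 + tide_amplitude * cos(2 * pi * h / 12.42)` with `h` the signed time to
#' the nearest high water in hours. Amplitudes must lie in `[0, 1]` so rates
#' stay non-negative.
#'
#' @param base_encounter_rate encounters per hour (> 0, or 0 for an empty
#'   process).
#' @param month_amplitude amplitude of the cyclic month multiplier, in `[0, 1]`.
#' @param peak_month fractional month (0--12) at which occupancy peaks;
#'   default 9.5 (October), matching the autumn peak typical of inshore
#'   porpoise monitoring sites.
#' @param diel_multipliers named numeric vector with entries `morning`, `day`,
#'   `evening`, `night`; all >= 0.
#' @param tide_amplitude amplitude of the cyclic tidal multiplier, in `[0, 1]`.
#' @param encounter_duration_mean mean encounter duration, minutes (> 0).
#' @param start_date,end_date deployment window (`Date` or coercible);
#'   `end_date` must be after `start_date`.
#' @return an object of class `occupancy_params`.
#' @export
occupancyParams <- function(base_encounter_rate = 0.2,
                            month_amplitude = 0.5,
                            peak_month = 9.5,
                            diel_multipliers = c(morning = 0.9, day = 1,
                                                 evening = 0.9, night = 0.7),
                            tide_amplitude = 0.3,
                            encounter_duration_mean = 12,
                            start_date = as.Date("2021-04-01"),
                            end_date = as.Date("2022-07-01")) {
  start_date <- as.Date(start_date)
  end_date <- as.Date(end_date)
  stopifnot(
    is.numeric(base_encounter_rate), length(base_encounter_rate) == 1,
    base_encounter_rate >= 0,
    month_amplitude >= 0, month_amplitude <= 1,
    peak_month >= 0, peak_month <= 12,
    tide_amplitude >= 0, tide_amplitude <= 1,
    encounter_duration_mean > 0
  )
  need <- c("morning", "day", "evening", "night")
  if (!all(need %in% names(diel_multipliers))) {
    stop("diel_multipliers must be named with: ", paste(need, collapse = ", "))
  }
  if (any(diel_multipliers < 0)) stop("diel multipliers must be >= 0")
  if (!(end_date > start_date)) stop("end_date must be after start_date")
  structure(
    list(base_encounter_rate = base_encounter_rate,
         month_amplitude = month_amplitude,
         peak_month = peak_month,
         diel_multipliers = diel_multipliers[need],
         tide_amplitude = tide_amplitude,
         encounter_duration_mean = encounter_duration_mean,
         start_date = start_date, end_date = end_date),
    class = "occupancy_params"
  )
}

#' Click-train structure parameters
#'
#' Within an encounter, click trains are separated by inter-train gaps; within
#' a train successive inter-click intervals (ICIs) come from either a regular
#' echolocation regime or a foraging-buzz regime (ICI < 10 ms). All interval
#' distributions are lognormal, parameterized on the log10-millisecond scale.
#'
#' @param regular_ici_log10_mean,regular_ici_log10_sd log10(ms) mean and sd of
#'   regular ICIs. Default mean `log10(60)` (~60 ms).
#' @param buzz_ici_log10_mean,buzz_ici_log10_sd log10(ms) mean and sd of buzz
#'   ICIs; the mean ICI must be below 10 ms. Default mean `log10(5)` (~5 ms).
#' @param intertrain_gap_log10_mean,intertrain_gap_log10_sd log10(ms) of gaps
#'   between trains. Default mean `log10(20000)` (~20 s).
#' @param buzz_train_probability probability that a train is a buzz train.
#' @param clicks_per_train either `list(fixed = n)` for exactly `n` clicks per
#'   train, or `list(mean = m, size = s)` for `2 + NegBin(mu = m - 2, size = s)`
#'   clicks (so every train has >= 2 clicks).
#' @return an object of class `train_params`.
#' @export
trainParams <- function(regular_ici_log10_mean = log10(60),
                        regular_ici_log10_sd = 0.15,
                        buzz_ici_log10_mean = log10(5),
                        buzz_ici_log10_sd = 0.1,
                        intertrain_gap_log10_mean = log10(20000),
                        intertrain_gap_log10_sd = 0.2,
                        buzz_train_probability = 0.2,
                        clicks_per_train = list(mean = 25, size = 6)) {
  if (!(10^buzz_ici_log10_mean < 10)) {
    stop("buzz ICI mean must be < 10 ms on the natural scale")
  }
  if (!(10 < 10^regular_ici_log10_mean)) {
    stop("regular ICI mean must be > 10 ms on the natural scale")
  }
  if (!(regular_ici_log10_mean < intertrain_gap_log10_mean)) {
    stop("inter-train gaps must be longer than regular ICIs")
  }
  stopifnot(
    buzz_train_probability >= 0, buzz_train_probability <= 1,
    regular_ici_log10_sd >= 0, buzz_ici_log10_sd >= 0,
    intertrain_gap_log10_sd >= 0
  )
  if (!is.list(clicks_per_train) ||
      !(("fixed" %in% names(clicks_per_train)) ||
        all(c("mean", "size") %in% names(clicks_per_train)))) {
    stop("clicks_per_train must be list(fixed=) or list(mean=, size=)")
  }
  if (!is.null(clicks_per_train$fixed) && clicks_per_train$fixed < 2) {
    stop("trains need at least 2 clicks")
  }
  if (!is.null(clicks_per_train$mean) && clicks_per_train$mean < 2) {
    stop("mean clicks per train must be >= 2")
  }
  structure(
    list(regular_ici_log10_mean = regular_ici_log10_mean,
         regular_ici_log10_sd = regular_ici_log10_sd,
         buzz_ici_log10_mean = buzz_ici_log10_mean,
         buzz_ici_log10_sd = buzz_ici_log10_sd,
         intertrain_gap_log10_mean = intertrain_gap_log10_mean,
         intertrain_gap_log10_sd = intertrain_gap_log10_sd,
         buzz_train_probability = buzz_train_probability,
         clicks_per_train = clicks_per_train),
    class = "train_params"
  )
}

#' Detector observation model
#'
#' The per-click observation model for one POD of a co-deployment. Each true
#' click is detected independently with probability
#' `plogis(qlogis(p_click) + noise_slope * z)` where `z` is the standardized
#' per-minute ambient-click count (Nall, the noise proxy). Detected clicks of
#' a true train register as a train when at least `min_clicks_train` survive;
#' the train quality class (Hi/Mod/Lo) is drawn from a categorical table
#' indexed by the completeness fraction (detected/true clicks). False-positive
#' trains are injected as a Poisson process.
#'
#' @param pod_label identifier, e.g. `"C"` or `"F"`.
#' @param p_click baseline per-click detection probability in `[0, 1]`.
#' @param noise_slope change in log-odds of click detection per unit of
#'   standardized Nall; <= 0 means detection degrades in noise.
#' @param quality_probs data frame with columns `completeness_min`, `Hi`,
#'   `Mod`, `Lo`: for a train with completeness `c`, the row with the largest
#'   `completeness_min <= c` gives the quality-class probabilities (each row
#'   must sum to 1).
#' @param false_train_rate false-positive trains per hour (>= 0).
#' @param false_quality_probs length-3 probability vector (Hi, Mod, Lo) for
#'   false-train quality; defaults heavily to Lo.
#' @param min_clicks_train minimum detected clicks to register a train (>= 2).
#' @return an object of class `detector_profile`.
#' @export
detectorProfile <- function(pod_label,
                            p_click,
                            noise_slope = 0,
                            quality_probs = defaultQualityProbs(),
                            false_train_rate = 0.01,
                            false_quality_probs = c(Hi = 0.05, Mod = 0.15, Lo = 0.8),
                            min_clicks_train = 5) {
  stopifnot(
    is.character(pod_label), length(pod_label) == 1,
    p_click >= 0, p_click <= 1,
    false_train_rate >= 0,
    min_clicks_train >= 2
  )
  qp <- as.data.frame(quality_probs)
  if (!all(c("completeness_min", "Hi", "Mod", "Lo") %in% names(qp))) {
    stop("quality_probs needs columns completeness_min, Hi, Mod, Lo")
  }
  rs <- rowSums(qp[, c("Hi", "Mod", "Lo")])
  if (any(abs(rs - 1) > 1e-8)) stop("quality_probs rows must sum to 1")
  if (is.unsorted(qp$completeness_min)) qp <- qp[order(qp$completeness_min), ]
  if (qp$completeness_min[1] > 0) stop("quality_probs must cover completeness 0")
  if (abs(sum(false_quality_probs) - 1) > 1e-8) {
    stop("false_quality_probs must sum to 1")
  }
  structure(
    list(pod_label = pod_label, p_click = p_click, noise_slope = noise_slope,
         quality_probs = qp, false_train_rate = false_train_rate,
         false_quality_probs = false_quality_probs,
         min_clicks_train = min_clicks_train),
    class = "detector_profile"
  )
}

#' @rdname detectorProfile
#' @export
defaultQualityProbs <- function() {
  data.frame(
    completeness_min = c(0, 0.3, 0.6, 0.85),
    Hi  = c(0.02, 0.10, 0.45, 0.80),
    Mod = c(0.28, 0.50, 0.45, 0.18),
    Lo  = c(0.70, 0.40, 0.10, 0.02)
  )
}

#' Default C-POD-like and F-POD-like detector profiles
#'
#' The F-like profile has substantially higher per-click sensitivity, a weak
#' noise response and few false trains; the C-like profile detects a small
#' fraction of clicks, degrades sharply in noise and produces more
#' false-positive trains. These emulate the qualitative contrast reported for
#' co-deployed C-POD/F-POD pairs (the successor detector records many more
#' clicks and detections, and is less noise-sensitive); the parametric form
#' and values are the package's own observation model, not manufacturer
#' specifications.
#'
#' @return a `detector_profile`.
#' @export
cPodProfile <- function() {
  detectorProfile(
    pod_label = "C", p_click = 0.15, noise_slope = -0.9,
    quality_probs = data.frame(
      completeness_min = c(0, 0.1, 0.25, 0.5),
      Hi  = c(0.01, 0.05, 0.25, 0.55),
      Mod = c(0.24, 0.45, 0.55, 0.38),
      Lo  = c(0.75, 0.50, 0.20, 0.07)
    ),
    false_train_rate = 0.015, min_clicks_train = 5
  )
}

#' @rdname cPodProfile
#' @export
fPodProfile <- function() {
  detectorProfile(
    pod_label = "F", p_click = 0.85, noise_slope = -0.15,
    quality_probs = defaultQualityProbs(),
    false_train_rate = 0.005, min_clicks_train = 5
  )
}

#' Ambient-noise (Nall) series parameters
#'
#' The per-minute count of unfiltered click-like events (Nall, 20--160 kHz
#' band) is simulated as a lognormal AR(1) series shared by both detectors of
#' a co-deployment (co-located devices hear the same soundscape), plus the
#' narrowband clicks actually emitted in that minute, so Nall always bounds
#' the true click count from below.
#'
#' @param log_median median of the ambient component (counts/minute).
#' @param sdlog marginal sd of the log ambient component.
#' @param ar1 lag-1 autocorrelation of the log ambient component, in `[0, 1)`.
#' @return an object of class `nall_params`.
#' @export
nallParams <- function(log_median = log(60), sdlog = 0.9, ar1 = 0.95) {
  stopifnot(sdlog >= 0, ar1 >= 0, ar1 < 1)
  structure(list(log_median = log_median, sdlog = sdlog, ar1 = ar1),
            class = "nall_params")
}
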
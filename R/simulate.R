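# Two-detector click-train simulator. Ground truth (encounters, clicks with
# behavior labels, per-minute presence and noise) is generated first; each
# detector profile is then applied as an independent per-click thinning with
# noise-dependent detection probability, train registration, quality
# labelling and false-positive injection.

#' Simulate porpoise encounter intervals
#'
#' Inhomogeneous Poisson process of encounter starts (rate = base rate x
#' month multiplier x diel multiplier x tide multiplier, simulated by
#' thinning) with exponential durations. Overlap is resolved by truncating an
#' encounter at the start of the next, so intervals are non-overlapping while
#' the start process keeps the specified instantaneous rate.
#'
#' @param params an [occupancyParams()] object.
#' @param seed integer seed; the output is deterministic given the seed.
#' @param sun,tide optional sun/tide tables; synthetic ones covering the
#'   deployment window are generated when omitted.
#' @return data frame (`encounter_id`, `start`, `end`) with attributes
#'   `sun`, `tide`, `window`.
#' @export
simulateOccupancy <- function(params, seed = 1, sun = NULL, tide = NULL) {
  stopifnot(inherits(params, "occupancy_params"))
  t0 <- .posix(as.POSIXct(params$start_date, tz = "UTC"))
  t1 <- .posix(as.POSIXct(params$end_date, tz = "UTC"))
  if (!(t1 > t0)) stop("degenerate date range")
  if (is.null(sun)) sun <- synthSunTable(params$start_date, params$end_date)
  if (is.null(tide)) tide <- synthTideTable(t0 - 86400, t1 + 86400)

  empty <- data.frame(encounter_id = integer(0),
                      start = .posix(numeric(0)), end = .posix(numeric(0)))
  attr(empty, "sun") <- sun; attr(empty, "tide") <- tide
  attr(empty, "window") <- c(t0, t1)
  if (params$base_encounter_rate == 0) return(empty)

  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)

  hours_total <- as.numeric(t1 - t0, units = "hours")
  lambda_max <- params$base_encounter_rate *
    (1 + params$month_amplitude) * max(params$diel_multipliers) *
    (1 + params$tide_amplitude)
  n_cand <- stats::rpois(1, lambda_max * hours_total)
  if (n_cand == 0) return(empty)
  cand <- sort(.posix(as.numeric(t0) +
                        stats::runif(n_cand) * as.numeric(t1 - t0, units = "secs")))

  month_mult <- 1 + params$month_amplitude *
    cos(2 * pi * (monthFraction(cand) - params$peak_month) / 12)
  diel_mult <- params$diel_multipliers[as.character(dielPeriod(cand, sun))]
  tide_mult <- 1 + params$tide_amplitude *
    cos(2 * pi * tideCovariates(cand, tide)$tide_diff_h / 12.42)
  rate <- params$base_encounter_rate * month_mult * diel_mult * tide_mult
  keep <- stats::runif(n_cand) < rate / lambda_max
  starts <- cand[keep]
  n <- length(starts)
  if (n == 0) return(empty)

  dur <- stats::rexp(n, rate = 1 / (params$encounter_duration_mean * 60))
  ends <- starts + dur
  if (n > 1) {
    nxt <- c(as.numeric(starts[-1]), Inf)
    ends <- .posix(pmin(as.numeric(ends), nxt))
  }
  ends <- .posix(pmin(as.numeric(ends), as.numeric(t1)))
  ok <- as.numeric(ends) > as.numeric(starts)
  out <- data.frame(encounter_id = seq_len(sum(ok)),
                    start = starts[ok], end = ends[ok])
  attr(out, "sun") <- sun; attr(out, "tide") <- tide
  attr(out, "window") <- c(t0, t1)
  out
}

#' Simulate labelled click trains within encounters
#'
#' Within each encounter, trains separated by lognormal inter-train gaps;
#' each train is a buzz train with probability `buzz_train_probability`, and
#' its successive ICIs are drawn from the corresponding lognormal regime.
#' Every click carries its behavior label (`"regular"` or `"buzz"`). Clicks
#' are truncated at the encounter end; trains left with fewer than 2 clicks
#' are dropped.
#'
#' @param encounters data frame from [simulateOccupancy()] (non-overlapping).
#' @param params a [trainParams()] object.
#' @param seed integer seed.
#' @return data frame: `encounter_id`, `train_id`, `time` (POSIXct, UTC,
#'   microsecond resolution), `label`.
#' @export
simulateClickTrains <- function(encounters, params, seed = 1) {
  stopifnot(inherits(params, "train_params"))
  if (nrow(encounters) > 1) {
    s <- order(encounters$start)
    e <- encounters[s, ]
    if (any(as.numeric(e$start[-1]) < as.numeric(e$end[-nrow(e)]))) {
      stop("encounters must be non-overlapping")
    }
  }
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)

  draw_n <- function() {
    cp <- params$clicks_per_train
    if (!is.null(cp$fixed)) return(cp$fixed)
    2 + stats::rnbinom(1, mu = cp$mean - 2, size = cp$size)
  }

  acc_time <- vector("list", nrow(encounters))
  acc_lab <- vector("list", nrow(encounters))
  acc_train <- vector("list", nrow(encounters))
  acc_enc <- vector("list", nrow(encounters))
  for (i in seq_len(nrow(encounters))) {
    e0 <- as.numeric(encounters$start[i])
    e1 <- as.numeric(encounters$end[i])
    t <- e0
    k <- 0L
    times <- list(); labs <- list(); tids <- list()
    while (t < e1) {
      is_buzz <- stats::runif(1) < params$buzz_train_probability
      n <- draw_n()
      if (is_buzz) {
        ici <- 10^stats::rnorm(n - 1, params$buzz_ici_log10_mean,
                               params$buzz_ici_log10_sd) / 1000
      } else {
        ici <- 10^stats::rnorm(n - 1, params$regular_ici_log10_mean,
                               params$regular_ici_log10_sd) / 1000
      }
      ct <- t + c(0, cumsum(ici))
      ct <- ct[ct < e1]
      gap_from <- if (length(ct)) ct[length(ct)] else t
      if (length(ct) >= 2) {
        k <- k + 1L
        times[[k]] <- ct
        labs[[k]] <- rep(if (is_buzz) "buzz" else "regular", length(ct))
        tids[[k]] <- rep(k, length(ct))
      }
      gap <- 10^stats::rnorm(1, params$intertrain_gap_log10_mean,
                             params$intertrain_gap_log10_sd) / 1000
      t <- gap_from + gap
    }
    if (k > 0) {
      acc_time[[i]] <- unlist(times)
      acc_lab[[i]] <- unlist(labs)
      acc_train[[i]] <- sprintf("e%06d_t%04d", encounters$encounter_id[i],
                                unlist(tids))
      acc_enc[[i]] <- rep(encounters$encounter_id[i], length(acc_time[[i]]))
    }
  }
  data.frame(
    encounter_id = as.integer(unlist(acc_enc)),
    train_id = as.character(unlist(acc_train)),
    time = round_us(.posix(as.numeric(unlist(acc_time)))),
    label = as.character(unlist(acc_lab)),
    stringsAsFactors = FALSE
  )
}

#' Assemble full ground truth for a deployment
#'
#' Runs the occupancy and click-train simulators, builds the per-minute grid
#' (true click counts, presence, shared Nall noise) and the shared hourly
#' water-temperature series. Sub-stage seeds are derived from `seed` by fixed
#' offsets so stages are individually reproducible.
#'
#' @param occupancy an [occupancyParams()] object.
#' @param trains a [trainParams()] object.
#' @param nall a [nallParams()] object.
#' @param seed integer master seed.
#' @param sun,tide optional environment tables (synthetic when omitted).
#' @return an object of class `pod_truth`: list with `encounters`, `clicks`,
#'   `minutes` (`minute`, `n_true_clicks`, `true_presence`, `nall`),
#'   `temperature` (`hour`, `temperature_c`), `window`, `sun`, `tide`.
#' @export
simulateTruth <- function(occupancy = occupancyParams(),
                          trains = trainParams(),
                          nall = nallParams(),
                          seed = 1, sun = NULL, tide = NULL) {
  enc <- simulateOccupancy(occupancy, seed = seed, sun = sun, tide = tide)
  sun <- attr(enc, "sun"); tide <- attr(enc, "tide")
  window <- attr(enc, "window")
  clicks <- simulateClickTrains(enc, trains, seed = seed + 1L)

  minute_grid <- .posix(seq(as.numeric(window[1]), as.numeric(window[2]) - 60,
                            by = 60))
  idx <- (floor(as.numeric(clicks$time) / 60) * 60 -
            as.numeric(window[1])) / 60 + 1
  counts <- tabulate(idx, nbins = length(minute_grid))
  nall_series <- simulateNall(minute_grid, nall, counts, seed = seed + 2L)
  hours <- .posix(seq(as.numeric(window[1]), as.numeric(window[2]) - 3600,
                      by = 3600))
  temp <- simulateTemperature(hours, seed = seed + 3L)

  structure(
    list(encounters = enc[, c("encounter_id", "start", "end")],
         clicks = clicks,
         minutes = data.frame(minute = minute_grid, n_true_clicks = counts,
                              true_presence = counts > 0, nall = nall_series),
         temperature = temp,
         window = window, sun = sun, tide = tide, seed = seed),
    class = "pod_truth"
  )
}

#' @export
print.pod_truth <- function(x, ...) {
  cat("Ground-truth deployment:",
      format(x$window[1], "%Y-%m-%d"), "to", format(x$window[2], "%Y-%m-%d"),
      "\n  encounters:", nrow(x$encounters),
      "\n  true clicks:", nrow(x$clicks),
      sprintf("(%.1f%% buzz)", 100 * mean(x$clicks$label == "buzz")),
      "\n  minutes with presence:", sum(x$minutes$true_presence), "of",
      nrow(x$minutes), "\n")
  invisible(x)
}

#' Apply a detector observation model to ground truth
#'
#' Each true click is detected independently with probability
#' `plogis(qlogis(p_click) + noise_slope * z)`, `z` the standardized Nall of
#' its minute. The detected clicks of a true train register as an observed
#' train when at least `min_clicks_train` survive; the quality class is drawn
#' from the completeness-indexed table. False-positive trains are injected at
#' `false_train_rate` per hour. Detection draws use a shared uniform stream
#' keyed only by the seed and the truth, so for the same seed a profile with
#' higher `p_click` detects a superset of clicks.
#'
#' @param truth a `pod_truth` object.
#' @param profile a [detectorProfile()] object.
#' @param seed integer seed.
#' @param temperature_offset additive device temperature bias, degrees C.
#' @return an object of class `pod_detections`: list with `trains` (one row
#'   per registered train: `pod`, `train_id`, `start_time`, `end_time`,
#'   `n_clicks`, `quality`, `species`, `truth_behavior`), `clicks` (`pod`,
#'   `train_id`, `time`, `ici_ms`, `truth_label`), `minutes` (`pod`,
#'   `minute`, `nall`, `temperature_c`), and `profile`.
#' @export
applyDetector <- function(truth, profile, seed = 1, temperature_offset = 0) {
  stopifnot(inherits(truth, "pod_truth"), inherits(profile, "detector_profile"))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)

  cl <- truth$clicks
  n <- nrow(cl)
  u <- stats::runif(n)  # shared stream: first draw, independent of profile

  z_all <- as.numeric(scale(truth$minutes$nall))
  if (all(is.na(z_all))) z_all <- rep(0, nrow(truth$minutes))
  midx <- (floor(as.numeric(cl$time) / 60) * 60 -
             as.numeric(truth$window[1])) / 60 + 1
  p <- stats::plogis(stats::qlogis(profile$p_click) +
                       profile$noise_slope * z_all[midx])
  detected <- u < p

  dcl <- cl[detected, , drop = FALSE]
  true_per_train <- table(cl$train_id)
  det_per_train <- table(factor(dcl$train_id, levels = names(true_per_train)))
  ndet <- as.integer(det_per_train)
  ntrue <- as.integer(true_per_train)
  registered_ids <- names(true_per_train)[ndet >= profile$min_clicks_train]

  reg <- dcl[dcl$train_id %in% registered_ids, , drop = FALSE]
  reg <- reg[order(reg$train_id, reg$time), ]

  # quality from completeness
  if (length(registered_ids)) {
    completeness <- (ndet / ntrue)[match(registered_ids, names(true_per_train))]
    qrow <- findInterval(completeness, profile$quality_probs$completeness_min)
    pm <- as.matrix(profile$quality_probs[, c("Hi", "Mod", "Lo")])[qrow, ,
                                                                   drop = FALSE]
    uq <- stats::runif(length(registered_ids))
    cum1 <- pm[, 1]; cum2 <- pm[, 1] + pm[, 2]
    quality <- c("Hi", "Mod", "Lo")[1 + (uq > cum1) + (uq > cum2)]
  } else {
    quality <- character(0)
  }

  if (nrow(reg)) {
    first <- !duplicated(reg$train_id)
    starts <- reg$time[first]
    ends <- rev(reg$time)[!duplicated(rev(reg$train_id))]
    ends <- rev(ends)
    counts <- as.integer(table(reg$train_id)[unique(reg$train_id)])
    behav <- reg$label[first]
    trains <- data.frame(
      pod = profile$pod_label,
      train_id = paste0(profile$pod_label, "_", unique(reg$train_id)),
      start_time = starts, end_time = ends, n_clicks = counts,
      quality = quality[match(unique(reg$train_id), registered_ids)],
      species = "NBHF", truth_behavior = behav, stringsAsFactors = FALSE)
    ici <- c(NA, diff(as.numeric(reg$time)) * 1000)
    ici[first] <- NA
    clicks_out <- data.frame(
      pod = profile$pod_label,
      train_id = paste0(profile$pod_label, "_", reg$train_id),
      time = reg$time, ici_ms = ici, truth_label = reg$label,
      stringsAsFactors = FALSE)
  } else {
    trains <- data.frame(pod = character(0), train_id = character(0),
                         start_time = .posix(numeric(0)),
                         end_time = .posix(numeric(0)), n_clicks = integer(0),
                         quality = character(0), species = character(0),
                         truth_behavior = character(0))
    clicks_out <- data.frame(pod = character(0), train_id = character(0),
                             time = .posix(numeric(0)), ici_ms = numeric(0),
                             truth_label = character(0))
  }

  # false-positive trains (mostly Lo quality, short)
  hours_total <- as.numeric(truth$window[2] - truth$window[1], units = "hours")
  nf <- stats::rpois(1, profile$false_train_rate * hours_total)
  if (nf > 0) {
    ft <- sort(as.numeric(truth$window[1]) +
                 stats::runif(nf) * (hours_total * 3600 - 60))
    fn <- 2L + stats::rpois(nf, 4)
    fq <- sample(c("Hi", "Mod", "Lo"), nf, replace = TRUE,
                 prob = profile$false_quality_probs)
    f_times <- lapply(seq_len(nf), function(j) {
      ft[j] + c(0, cumsum(10^stats::rnorm(fn[j] - 1, log10(80), 0.3) / 1000))
    })
    fid <- sprintf("%s_false_%05d", profile$pod_label, seq_len(nf))
    f_trains <- data.frame(
      pod = profile$pod_label, train_id = fid,
      start_time = round_us(.posix(ft)),
      end_time = round_us(.posix(vapply(f_times, max, 0))),
      n_clicks = fn, quality = fq, species = "NBHF",
      truth_behavior = "false", stringsAsFactors = FALSE)
    f_clicks <- data.frame(
      pod = profile$pod_label,
      train_id = rep(fid, fn),
      time = round_us(.posix(unlist(f_times))),
      ici_ms = unlist(lapply(f_times, function(t) c(NA, diff(t) * 1000))),
      truth_label = "false", stringsAsFactors = FALSE)
    trains <- rbind(trains, f_trains)
    clicks_out <- rbind(clicks_out, f_clicks)
  }
  trains <- trains[order(trains$start_time, trains$train_id), ]
  clicks_out <- clicks_out[order(clicks_out$time, clicks_out$train_id), ]
  rownames(trains) <- rownames(clicks_out) <- NULL

  temp_min <- truth$temperature$temperature_c[
    match(floor_hour(truth$minutes$minute), truth$temperature$hour)]
  minutes <- data.frame(pod = profile$pod_label,
                        minute = truth$minutes$minute,
                        nall = truth$minutes$nall,
                        temperature_c = round(temp_min + temperature_offset, 2))

  structure(list(trains = trains, clicks = clicks_out, minutes = minutes,
                 profile = profile, window = truth$window),
            class = "pod_detections")
}

#' @export
print.pod_detections <- function(x, ...) {
  cat("Detections for POD", x$profile$pod_label, "\n",
      " trains:", nrow(x$trains),
      sprintf("(Hi %d / Mod %d / Lo %d)",
              sum(x$trains$quality == "Hi"), sum(x$trains$quality == "Mod"),
              sum(x$trains$quality == "Lo")),
      "\n  clicks:", nrow(x$clicks), "\n")
  invisible(x)
}

#' Simulate a full two-detector co-deployment
#'
#' Shared ground truth observed by two (or more) detector profiles. Detection
#' draws for different pods use distinct sub-seeds and are conditionally
#' independent given the truth; noise and temperature are shared.
#'
#' @param occupancy,trains,nall parameter objects (defaults give a
#'   15-month deployment of a C-like/F-like pair).
#' @param profiles named list of [detectorProfile()] objects.
#' @param seed integer master seed.
#' @param sun,tide optional environment tables.
#' @param temperature_offsets numeric vector of per-device temperature
#'   biases, recycled over profiles.
#' @return an object of class `pod_codeployment`: list with `truth`, `pods`
#'   (named list of `pod_detections`), `sun`, `tide`, `seed`.
#' @export
simulateCodeployment <- function(occupancy = occupancyParams(),
                                 trains = trainParams(),
                                 nall = nallParams(),
                                 profiles = list(C = cPodProfile(),
                                                 F = fPodProfile()),
                                 seed = 1, sun = NULL, tide = NULL,
                                 temperature_offsets = c(-0.15, 0.15)) {
  truth <- simulateTruth(occupancy, trains, nall, seed = seed,
                         sun = sun, tide = tide)
  if (is.null(names(profiles))) {
    names(profiles) <- vapply(profiles, `[[`, "", "pod_label")
  }
  temperature_offsets <- rep_len(temperature_offsets, length(profiles))
  pods <- lapply(seq_along(profiles), function(k) {
    applyDetector(truth, profiles[[k]], seed = seed + 10L * k,
                  temperature_offset = temperature_offsets[k])
  })
  names(pods) <- names(profiles)
  structure(list(truth = truth, pods = pods, sun = truth$sun,
                 tide = truth$tide, seed = seed),
            class = "pod_codeployment")
}

#' @export
print.pod_codeployment <- function(x, ...) {
  print(x$truth)
  for (p in x$pods) print(p)
  invisible(x)
}
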
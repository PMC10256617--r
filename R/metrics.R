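# Detection metrics at minute/hour/day scales under train-quality filters,
# and the inter-detector comparison statistics (Kendall rank correlation,
# detection ratios, matched-bin proportions, validation subsampling).

#' Train-quality filter groupings
#'
#' The three nested groupings used to summarize detections: `Hi` (high
#' quality only), `HiMod` (high + moderate) and `HiModLo` (all classes).
#'
#' @param name one of `"Hi"`, `"HiMod"`, `"HiModLo"`.
#' @return character vector of included quality classes.
#' @export
filterGrouping <- function(name = c("HiModLo", "HiMod", "Hi")) {
  name <- match.arg(name)
  switch(name, Hi = "Hi", HiMod = c("Hi", "Mod"),
         HiModLo = c("Hi", "Mod", "Lo"))
}

# minutes spanned by each train (first to last click, inclusive), or just
# the start minute
train_minutes <- function(trains, span = c("train", "start")) {
  span <- match.arg(span)
  if (!nrow(trains)) return(.posix(numeric(0)))
  fs <- as.numeric(floor_minute(trains$start_time))
  if (span == "start") return(.posix(fs))
  fe <- as.numeric(floor_minute(trains$end_time))
  nmin <- (fe - fs) / 60 + 1
  .posix(rep(fs, nmin) + 60 * (sequence(nmin) - 1))
}

#' Aggregate detections into a detection series
#'
#' A minute is detection-positive iff at least one train of the grouping
#' overlaps it (by default a train occupies every minute between its first
#' and last click; `span = "start"` restricts to the start minute, for
#' comparison against exports that assign trains to their start minute).
#' Hour bins count positive minutes (DPM, 0--60), day bins count positive
#' hours (DPH, 0--24). Effort is explicit: only monitored minutes enter
#' denominators.
#'
#' @param x a `pod_detections` object, or a trains data frame (then supply
#'   `minutes`).
#' @param grouping filter grouping name (see [filterGrouping()]).
#' @param resolution `"minute"`, `"hour"` or `"day"`.
#' @param minutes effort table: data frame with a `minute` column listing the
#'   monitored minutes (taken from `x$minutes` when `x` is a
#'   `pod_detections`).
#' @param clicks optional clicks data frame; when supplied, NClx per bin is
#'   counted from click times of included trains, otherwise a train's clicks
#'   are assigned to its start minute.
#' @param span `"train"` (default) or `"start"`; see above.
#' @param clip drop train minutes outside the effort period instead of
#'   erroring.
#' @return a `detection_series` data frame: `bin` (POSIXct start), `detected`
#'   (0/1), `count` (positive sub-bins; NA at minute resolution), `nclx`,
#'   `effort` (monitored sub-bins; 1 at minute resolution); attributes `pod`,
#'   `grouping`, `resolution`, `span`.
#' @export
aggregateDetections <- function(x, grouping = "HiModLo",
                                resolution = c("minute", "hour", "day"),
                                minutes = NULL, clicks = NULL,
                                span = c("train", "start"), clip = FALSE) {
  resolution <- match.arg(resolution)
  span <- match.arg(span)
  if (inherits(x, "pod_detections")) {
    trains <- x$trains
    if (is.null(minutes)) minutes <- x$minutes
    if (is.null(clicks)) clicks <- x$clicks
  } else {
    trains <- x
  }
  if (is.null(minutes)) stop("an effort table of monitored minutes is required")
  classes <- filterGrouping(grouping)
  inc <- trains[trains$quality %in% classes, , drop = FALSE]
  pod <- if (nrow(trains)) trains$pod[1] else NA_character_

  effort_min <- sort(unique(as.numeric(floor_minute(minutes$minute))))
  pos_min <- unique(as.numeric(train_minutes(inc, span)))
  outside <- setdiff(pos_min, effort_min)
  if (length(outside)) {
    if (!clip) {
      stop("trains overlap ", length(outside),
           " minute(s) outside the effort period (set clip = TRUE to clip)")
    }
    pos_min <- setdiff(pos_min, outside)
  }

  nclx_min <- rep(0L, length(effort_min))
  if (!is.null(clicks) && nrow(clicks)) {
    inc_clicks <- clicks[clicks$train_id %in% inc$train_id, , drop = FALSE]
    cm <- as.numeric(floor_minute(inc_clicks$time))
    tab <- table(match(cm, effort_min))
    keep <- !is.na(as.integer(names(tab)))
    nclx_min[as.integer(names(tab))[keep]] <- as.integer(tab)[keep]
  } else if (nrow(inc)) {
    sm <- match(as.numeric(floor_minute(inc$start_time)), effort_min)
    ok <- !is.na(sm)
    agg <- tapply(inc$n_clicks[ok], sm[ok], sum)
    nclx_min[as.integer(names(agg))] <- as.integer(agg)
  }

  det <- as.integer(effort_min %in% pos_min)
  res <- data.frame(bin = .posix(effort_min), detected = det,
                    count = NA_integer_, nclx = nclx_min, effort = 1L)
  if (resolution != "minute") {
    key <- as.numeric(floor_hour(res$bin))
    res <- rollup_series(res, key, "detected")
    if (resolution == "day") {
      key <- as.numeric(floor_day(res$bin))
      res <- rollup_series(res, key, "detected")
    }
  }
  structure(res, pod = pod, grouping = grouping, resolution = resolution,
            span = span, class = c("detection_series", "data.frame"))
}

rollup_series <- function(res, key, positive_col) {
  split_idx <- match(key, unique(key))
  count <- as.integer(rowsum(res[[positive_col]], split_idx))
  nclx <- as.integer(rowsum(res$nclx, split_idx))
  effort <- as.integer(rowsum(rep(1L, nrow(res)), split_idx))
  data.frame(bin = .posix(unique(key)), detected = as.integer(count > 0),
             count = count, nclx = nclx, effort = effort)
}

#' @export
print.detection_series <- function(x, ...) {
  cat(sprintf("Detection series: pod %s, %s filter, %s resolution\n",
              attr(x, "pod"), attr(x, "grouping"), attr(x, "resolution")))
  cat(sprintf("  %d bins, %d positive (%.1f%%), NClx total %d\n",
              nrow(x), sum(x$detected), 100 * mean(x$detected),
              sum(x$nclx)))
  invisible(as.data.frame(x))
}

#' Effort-standardized detection rate
#'
#' `100 * positive bins / monitored bins` per period, so periods with unequal
#' recording effort are comparable. For a minute-resolution series this is
#' the DPM detection rate; hour and day series give DPH and DPD rates.
#'
#' @param series a `detection_series`.
#' @param period `"overall"`, `"season"` or `"month"`.
#' @return data frame: `period`, `positive`, `monitored`, `rate` (percent;
#'   NA where no bins were monitored).
#' @export
detectionRate <- function(series, period = c("overall", "season", "month")) {
  period <- match.arg(period)
  grp <- switch(period,
    overall = factor(rep("overall", nrow(series))),
    season = seasonOf(series$bin),
    month = factor(as.integer(format(series$bin, "%m")), levels = 1:12))
  pos <- tapply(series$detected, grp, sum)
  n <- tapply(series$detected, grp, length)
  n[is.na(n)] <- 0
  data.frame(period = names(pos), positive = as.integer(ifelse(is.na(pos), 0, pos)),
             monitored = as.integer(n),
             rate = ifelse(n > 0, 100 * as.numeric(pos) / as.numeric(n), NA),
             row.names = NULL)
}

#' Detection ratio between two detectors
#'
#' `CF = Det_F / Det_C`: the multiplicative excess of one detector's
#' detections over the other's for the same metric and period.
#'
#' @param det_f,det_c detection totals (counts).
#' @return `det_f / det_c`, or NA (with a warning) when `det_c` is 0.
#' @export
detectionRatio <- function(det_f, det_c) {
  out <- ifelse(det_c > 0, det_f / det_c, NA_real_)
  if (anyNA(out)) warning("detection ratio undefined where det_c = 0")
  out
}

#' Kendall rank correlation between paired detection series
#'
#' Tau-b with tie correction. The p-value uses the tie-corrected normal
#' approximation of the concordance statistic without continuity correction;
#' for n <= 8 an exact permutation enumeration is used instead.
#'
#' @param x,y paired numeric vectors, length >= 3.
#' @return list with `tau`, `p_value`, `n`, `method`. `tau` is NA when
#'   either input is constant.
#' @export
kendallTau <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 paired observations")
  if (length(unique(x)) == 1 || length(unique(y)) == 1) {
    return(list(tau = NA_real_, p_value = NA_real_, n = n,
                method = "undefined (constant input)"))
  }
  tau <- stats::cor(x, y, method = "kendall")
  if (n <= 8) {
    perms <- permutations_of(n)
    obs <- abs(tau)
    taus <- apply(perms, 1, function(p) stats::cor(x, y[p], method = "kendall"))
    p_value <- mean(abs(taus) >= obs - 1e-12)
    method <- "exact permutation"
  } else {
    # recover S from tau-b and tie counts, then tie-corrected normal variance
    tx <- table(x); ty <- table(y)
    D <- n * (n - 1) / 2
    Tx <- sum(tx * (tx - 1) / 2); Ty <- sum(ty * (ty - 1) / 2)
    S <- tau * sqrt((D - Tx) * (D - Ty))
    v0 <- n * (n - 1) * (2 * n + 5)
    vt <- sum(tx * (tx - 1) * (2 * tx + 5))
    vu <- sum(ty * (ty - 1) * (2 * ty + 5))
    v1 <- sum(tx * (tx - 1)) * sum(ty * (ty - 1)) / (2 * n * (n - 1))
    v2 <- sum(tx * (tx - 1) * (tx - 2)) * sum(ty * (ty - 1) * (ty - 2)) /
      (9 * n * (n - 1) * (n - 2))
    v <- (v0 - vt - vu) / 18 + v1 + v2
    z <- S / sqrt(v)
    p_value <- 2 * stats::pnorm(-abs(z))
    method <- "tie-corrected normal approximation"
  }
  list(tau = tau, p_value = min(p_value, 1), n = n, method = method)
}

permutations_of <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- permutations_of(n - 1)
  out <- matrix(0L, nrow(sub) * n, n)
  r <- 0L
  for (i in seq_len(n)) {
    rows <- (r + 1):(r + nrow(sub))
    out[rows, i] <- n
    out[rows, -i] <- sub
    r <- r + nrow(sub)
  }
  out
}

#' Matched and unmatched positive-bin proportions
#'
#' For each of two detection series sharing resolution, grouping and effort:
#' the fraction of its positive bins that the other detector did not mark
#' positive.
#'
#' @param series_a,series_b `detection_series` objects over the same bins.
#' @return data frame, one row per pod: `pod`, `positive`, `unmatched`,
#'   `prop_unmatched`.
#' @export
matchPositiveBins <- function(series_a, series_b) {
  for (at in c("resolution", "grouping")) {
    if (!identical(attr(series_a, at), attr(series_b, at))) {
      stop("series differ in ", at)
    }
  }
  if (!identical(as.numeric(series_a$bin), as.numeric(series_b$bin))) {
    stop("series cover different effort bins")
  }
  pa <- series_a$detected > 0
  pb <- series_b$detected > 0
  data.frame(
    pod = c(attr(series_a, "pod"), attr(series_b, "pod")),
    positive = c(sum(pa), sum(pb)),
    unmatched = c(sum(pa & !pb), sum(pb & !pa)),
    prop_unmatched = c(
      if (sum(pa)) sum(pa & !pb) / sum(pa) else NA_real_,
      if (sum(pb)) sum(pb & !pa) / sum(pb) else NA_real_)
  )
}

#' Draw a validation subsample of detection-positive minutes
#'
#' Visual-validation protocol: a fixed number of randomly chosen minutes
#' positive for Hi or Mod trains (all of them if fewer exist), plus every
#' minute positive for Lo trains, which are inspected exhaustively.
#'
#' @param trains trains data frame (quality-labelled).
#' @param minutes effort table of monitored minutes.
#' @param n_random number of Hi/Mod minutes to sample (>= 1).
#' @param seed integer seed; the sample is deterministic given the seed.
#' @param span passed to the minute expansion (see [aggregateDetections()]).
#' @return data frame: `minute`, `component` (`"HiMod_sample"` /
#'   `"Lo_census"`), sorted by time.
#' @export
validationSample <- function(trains, minutes, n_random = 100, seed = 1,
                             span = "train") {
  stopifnot(n_random >= 1)
  effort <- unique(as.numeric(floor_minute(minutes$minute)))
  himod <- intersect(unique(as.numeric(train_minutes(
    trains[trains$quality %in% c("Hi", "Mod"), , drop = FALSE], span))), effort)
  lo <- intersect(unique(as.numeric(train_minutes(
    trains[trains$quality == "Lo", , drop = FALSE], span))), effort)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  take <- if (length(himod) <= n_random) himod else sample(himod, n_random)
  out <- rbind(
    data.frame(minute = sort(take),
               component = rep("HiMod_sample", length(take))),
    data.frame(minute = sort(lo), component = rep("Lo_census", length(lo))))
  out$minute <- .posix(out$minute)
  out
}
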
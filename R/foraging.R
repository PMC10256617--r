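# Foraging-buzz classification from inter-click intervals: a univariate
# Gaussian mixture is fitted by EM to log10 ICIs (pooled with inter-train
# gaps so the pause component is identifiable); components whose mean ICI is
# below 10 ms are the buzz regime, the largest-mean component is the
# inter-train regime, the rest are regular echolocation.

BUZZ_THRESHOLD_LOG10 <- 1  # log10(10 ms)

#' Inter-click intervals from a click table
#'
#' One sample per successive within-train click pair (the sample carries the
#' time of the closing click); gaps from a train's last click to the next
#' train's first click are returned as candidate inter-train intervals.
#'
#' @param clicks data frame with `train_id`, `time`, and optionally `pod`.
#' @param include_intertrain include inter-train gaps (default TRUE; the
#'   mixture is fitted on the pooled set by default).
#' @return data frame: `pod`, `train_id`, `time`, `ici_ms`, `log10_ici`,
#'   `kind` (`"within"` / `"intertrain"`).
#' @export
computeICIs <- function(clicks, include_intertrain = TRUE) {
  if (!nrow(clicks)) {
    return(data.frame(pod = character(0), train_id = character(0),
                      time = .posix(numeric(0)), ici_ms = numeric(0),
                      log10_ici = numeric(0), kind = character(0)))
  }
  podv <- if ("pod" %in% names(clicks)) clicks$pod else rep("", nrow(clicks))
  ord <- order(podv, clicks$train_id, as.numeric(clicks$time))
  cl <- clicks[ord, , drop = FALSE]
  podv <- podv[ord]
  tnum <- as.numeric(cl$time)
  n <- nrow(cl)
  same_train <- c(FALSE, cl$train_id[-1] == cl$train_id[-n] &
                    podv[-1] == podv[-n])
  d <- c(NA, diff(tnum)) * 1000
  if (any(same_train & d <= 0, na.rm = TRUE)) {
    bad <- which(same_train & d <= 0)[1]
    stop("duplicate or non-increasing timestamps within train ",
         cl$train_id[bad])
  }
  within <- data.frame(
    pod = podv[same_train], train_id = cl$train_id[same_train],
    time = cl$time[same_train], ici_ms = d[same_train],
    kind = rep("within", sum(same_train)), stringsAsFactors = FALSE)
  out <- within
  if (include_intertrain && n > 1) {
    # last click of each train to first click of the next train (time order)
    key <- paste(podv, cl$train_id, sep = "\r")
    first <- !duplicated(key)
    tr <- data.frame(pod = podv[first], train_id = cl$train_id[first],
                     start = as.numeric(tapply(tnum, key, min)[key[first]]),
                     end = as.numeric(tapply(tnum, key, max)[key[first]]),
                     stringsAsFactors = FALSE)
    tr <- tr[order(tr$pod, tr$start), ]
    if (nrow(tr) > 1) {
      same_pod <- tr$pod[-1] == tr$pod[-nrow(tr)]
      gap_ms <- (tr$start[-1] - tr$end[-nrow(tr)]) * 1000
      keep <- same_pod & gap_ms > 0
      if (any(keep)) {
        inter <- data.frame(pod = tr$pod[-1][keep],
                            train_id = tr$train_id[-1][keep],
                            time = .posix(tr$start[-1][keep]),
                            ici_ms = gap_ms[keep],
                            kind = rep("intertrain", sum(keep)),
                            stringsAsFactors = FALSE)
        out <- rbind(within, inter)
      }
    }
  }
  out$log10_ici <- log10(out$ici_ms)
  out <- out[order(out$pod, as.numeric(out$time)), ]
  rownames(out) <- NULL
  out[, c("pod", "train_id", "time", "ici_ms", "log10_ici", "kind")]
}

# one EM run for a univariate K-component Gaussian mixture
em_once <- function(x, mu, sigma, w, max_iter, tol, min_sd = 1e-4) {
  n <- length(x)
  K <- length(mu)
  ll_trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    dens <- vapply(seq_len(K),
                   function(k) w[k] * stats::dnorm(x, mu[k], sigma[k]),
                   numeric(n))
    rowsum_d <- rowSums(dens)
    rowsum_d[rowsum_d < 1e-300] <- 1e-300
    ll <- sum(log(rowsum_d))
    ll_trace <- c(ll_trace, ll)
    r <- dens / rowsum_d
    nk <- colSums(r)
    if (any(nk < 1e-8)) return(list(degenerate = TRUE))
    w <- nk / n
    mu <- colSums(r * x) / nk
    sigma <- sqrt(colSums(r * (outer(x, mu, "-")^2)) / nk)
    if (any(sigma < min_sd)) return(list(degenerate = TRUE))
    if (ll - ll_old < tol && it > 1) { converged <- TRUE; break }
    ll_old <- ll
  }
  list(degenerate = FALSE, mu = mu, sigma = sigma, w = w,
       loglik = ll_trace[length(ll_trace)], ll_trace = ll_trace,
       n_iterations = length(ll_trace), converged = converged)
}

#' Fit a Gaussian mixture to log10 inter-click intervals
#'
#' EM with multiple starts per candidate component count K; the BIC-minimizing
#' fit is returned. EM iterates until the log-likelihood gain falls below
#' `tol` or `max_iter` iterations; degenerate runs (vanishing component or
#' sd) are restarted with jittered initial values. Component behavior labels:
#' every component with mean ICI < 10 ms is `buzz`; among the rest the
#' largest-mean component is `intertrain` (when inter-train gaps were
#' pooled); the remainder are `regular`.
#'
#' @param samples output of [computeICIs()], or a numeric vector of log10
#'   ICI values (ms).
#' @param k_candidates integer vector of component counts to try.
#' @param seed integer seed for the multi-start initialization.
#' @param n_starts EM starts per K (first start is quantile-based, the rest
#'   jittered).
#' @param max_iter,tol EM stopping rule.
#' @param max_samples parameter estimation uses a random subsample of at most
#'   this many values (the mixture has at most 11 free parameters, for which
#'   tens of thousands of samples are ample); classification via
#'   [classifyClicks()] still uses every sample.
#' @param within_only fit on within-train ICIs only (drops the pooled
#'   inter-train gaps; no component is then labelled `intertrain`).
#' @return an `ici_mixture_fit`: list with `K`, `weights`, `means`, `sds`
#'   (log10-ms scale), `labels`, `loglik`, `bic`, `bic_table`,
#'   `n_iterations`, `converged`, `ll_trace`, `n`.
#' @export
fitICIMixture <- function(samples, k_candidates = 2:4, seed = 1,
                          n_starts = 5, max_iter = 500, tol = 1e-8,
                          max_samples = 20000, within_only = FALSE) {
  if (is.data.frame(samples)) {
    if (within_only) samples <- samples[samples$kind == "within", , drop = FALSE]
    x <- samples$log10_ici
  } else {
    x <- as.numeric(samples)
  }
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 10 * max(k_candidates)) {
    stop("need at least 10 x max(k_candidates) = ", 10 * max(k_candidates),
         " samples, got ", n)
  }
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  if (n > max_samples) {
    x <- x[sort(sample.int(n, max_samples))]
    n <- max_samples
  }

  best <- NULL
  bic_table <- data.frame(K = integer(0), loglik = numeric(0), bic = numeric(0))
  for (K in sort(unique(k_candidates))) {
    best_k <- NULL
    for (s in seq_len(n_starts)) {
      qs <- stats::quantile(x, probs = (seq_len(K) - 0.5) / K, names = FALSE)
      mu0 <- if (s == 1) qs else qs + stats::rnorm(K, 0, stats::sd(x) / 4)
      sigma0 <- rep(stats::sd(x) / K, K)
      w0 <- rep(1 / K, K)
      fit <- em_once(x, mu0, sigma0, w0, max_iter, tol)
      tries <- 0
      while (isTRUE(fit$degenerate) && tries < 5) {
        tries <- tries + 1
        fit <- em_once(x, qs + stats::rnorm(K, 0, stats::sd(x) / 2),
                       rep(stats::sd(x) / 2, K), w0, max_iter, tol)
      }
      if (isTRUE(fit$degenerate)) next
      if (is.null(best_k) || fit$loglik > best_k$loglik) best_k <- fit
    }
    if (is.null(best_k)) next
    npar <- 3 * K - 1
    bic <- -2 * best_k$loglik + npar * log(n)
    bic_table <- rbind(bic_table,
                       data.frame(K = K, loglik = best_k$loglik, bic = bic))
    if (is.null(best) || bic < best$bic) {
      best <- c(best_k, list(K = K, bic = bic))
    }
  }
  if (is.null(best)) stop("all EM runs degenerated; too few distinct values?")

  ord <- order(best$mu)
  means <- best$mu[ord]; sds <- best$sigma[ord]; weights <- best$w[ord]
  labels <- rep("regular", best$K)
  labels[means < BUZZ_THRESHOLD_LOG10] <- "buzz"
  if (!within_only && any(means >= BUZZ_THRESHOLD_LOG10)) {
    labels[which.max(means)] <- "intertrain"
  }
  structure(
    list(K = best$K, weights = weights, means = means, sds = sds,
         labels = labels, loglik = best$loglik, bic = best$bic,
         bic_table = bic_table, n_iterations = best$n_iterations,
         converged = best$converged, ll_trace = best$ll_trace, n = n),
    class = "ici_mixture_fit")
}

#' @export
print.ici_mixture_fit <- function(x, ...) {
  cat(sprintf("Gaussian mixture on log10 ICI: K = %d (BIC %.1f, n = %d)%s\n",
              x$K, x$bic, x$n,
              if (!x$converged) " [NOT CONVERGED]" else ""))
  tab <- data.frame(component = seq_len(x$K), weight = round(x$weights, 3),
                    mean_log10_ms = round(x$means, 3),
                    mean_ms = round(10^x$means, 2), sd = round(x$sds, 3),
                    behavior = x$labels)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Classify ICI samples by maximum posterior component
#'
#' Each sample is assigned the behavior label of its maximum-posterior
#' mixture component; exact posterior ties go to the lower-mean component.
#'
#' @param fit an `ici_mixture_fit`.
#' @param samples output of [computeICIs()] or a numeric vector of log10 ICI
#'   values.
#' @return the samples with `behavior` and `posterior` columns (a data frame
#'   input), or a data frame with `log10_ici`, `behavior`, `posterior`.
#' @export
classifyClicks <- function(fit, samples) {
  stopifnot(inherits(fit, "ici_mixture_fit"))
  is_df <- is.data.frame(samples)
  x <- if (is_df) samples$log10_ici else as.numeric(samples)
  if (!length(x)) {
    if (is_df) {
      samples$behavior <- character(0); samples$posterior <- numeric(0)
      return(samples)
    }
    return(data.frame(log10_ici = numeric(0), behavior = character(0),
                      posterior = numeric(0)))
  }
  dens <- vapply(seq_len(fit$K),
                 function(k) fit$weights[k] * stats::dnorm(x, fit$means[k],
                                                           fit$sds[k]),
                 numeric(length(x)))
  dens <- matrix(dens, nrow = length(x))
  tot <- rowSums(dens)
  tot[tot < 1e-300] <- 1e-300
  post <- dens / tot
  # max.col with ties.method "first": components are mean-ordered, so ties
  # resolve to the lower-mean component
  pick <- max.col(post, ties.method = "first")
  behavior <- fit$labels[pick]
  pp <- post[cbind(seq_along(x), pick)]
  if (is_df) {
    samples$behavior <- behavior
    samples$posterior <- pp
    samples
  } else {
    data.frame(log10_ici = x, behavior = behavior, posterior = pp)
  }
}

#' Threshold-based buzz classification (cross-check mode)
#'
#' Labels every ICI below 10 ms as buzz, ignoring the mixture. Provided as a
#' fallback to cross-check the component-based assignment.
#'
#' @param samples output of [computeICIs()] or numeric log10 ICI values.
#' @return character vector of `"buzz"` / `"regular"`.
#' @export
thresholdBuzz <- function(samples) {
  x <- if (is.data.frame(samples)) samples$log10_ici else as.numeric(samples)
  ifelse(x < BUZZ_THRESHOLD_LOG10, "buzz", "regular")
}

#' Buzz series: BPM, BPH and buzz rate
#'
#' A minute is buzz-positive iff at least one buzz-labelled ICI sample falls
#' in it. Hourly BPM (0--60) is paired with the hourly DPM series of the same
#' grouping; the buzz rate is `100 * BPM / DPM`, missing (not zero) when
#' DPM = 0. Daily BPH counts hours with at least one buzz-positive minute.
#'
#' @param classified output of [classifyClicks()] on a [computeICIs()] data
#'   frame (needs `time` and `behavior`).
#' @param dpm_series hour-resolution `detection_series` from
#'   [aggregateDetections()].
#' @return list of class `buzz_series`: `hourly` (`hour`, `bpm`, `dpm`,
#'   `buzz_rate`), `daily` (`day`, `bph`), `grouping`.
#' @export
buzzSeries <- function(classified, dpm_series) {
  if (!identical(attr(dpm_series, "resolution"), "hour")) {
    stop("dpm_series must be an hour-resolution detection series")
  }
  buzz <- classified[classified$behavior == "buzz", , drop = FALSE]
  bmin <- unique(as.numeric(floor_minute(buzz$time)))
  bhour <- as.numeric(floor_hour(.posix(bmin)))
  bpm_tab <- table(bhour)
  hours <- as.numeric(dpm_series$bin)
  bpm <- as.integer(bpm_tab[match(hours, as.numeric(names(bpm_tab)))])
  bpm[is.na(bpm)] <- 0L
  stray <- setdiff(as.numeric(names(bpm_tab)), hours)
  if (length(stray)) {
    stop("buzz-positive minutes fall outside the DPM series effort period")
  }
  dpm <- dpm_series$count
  if (any(bpm > dpm)) {
    stop("internal inconsistency: BPM exceeds DPM in ", sum(bpm > dpm),
         " hour(s); are the clicks and the DPM series from the same grouping?")
  }
  hourly <- data.frame(hour = dpm_series$bin, bpm = bpm, dpm = dpm,
                       buzz_rate = ifelse(dpm > 0, 100 * bpm / dpm, NA_real_))
  day <- floor_day(hourly$hour)
  bph <- tapply(hourly$bpm > 0, as.numeric(day), sum)
  daily <- data.frame(day = .posix(as.numeric(names(bph))),
                      bph = as.integer(bph))
  structure(list(hourly = hourly, daily = daily,
                 grouping = attr(dpm_series, "grouping")),
            class = "buzz_series")
}

#' @export
print.buzz_series <- function(x, ...) {
  cat(sprintf("Buzz series (%s filter): %d hours, %d buzz-positive minutes\n",
              x$grouping, nrow(x$hourly), sum(x$hourly$bpm)))
  cat(sprintf("  mean buzz rate (DPM>0 hours): %.1f%%; mean BPH/day: %.2f\n",
              mean(x$hourly$buzz_rate, na.rm = TRUE), mean(x$daily$bph)))
  invisible(x)
}
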
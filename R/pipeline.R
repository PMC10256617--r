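# End-to-end orchestration: a reproducible staged pipeline over the
# simulator, metrics, foraging classifier, covariates and models, plus the
# two-detector comparison report.

#' Demo run configuration
#'
#' A compact co-deployment scenario (defaults: 120 days, C-like and F-like
#' profiles) suitable for a quick end-to-end run.
#'
#' @param output_dir directory for all artifacts.
#' @param seed master seed; per-stage seeds are derived as
#'   `seed + 100 * stage_index` so stages re-run in isolation reproduce
#'   identically.
#' @param days deployment length in days.
#' @param stages stages to run, in dependency order, a subset of
#'   `c("simulate", "metrics", "foraging", "covariates", "model", "compare")`.
#' @param fit_models fit the hourly additive models in the `model` stage
#'   (the slowest stage).
#' @return a `run_config` list.
#' @export
demoConfig <- function(output_dir = tempfile("podcompare_run_"), seed = 1,
                       days = 120,
                       stages = c("simulate", "metrics", "foraging",
                                  "covariates", "model", "compare"),
                       fit_models = TRUE) {
  start <- as.Date("2021-04-01")
  structure(
    list(output_dir = output_dir, seed = seed, stages = stages,
         fit_models = fit_models,
         occupancy = list(start_date = start, end_date = start + days),
         trains = list(), nall = list(),
         profiles = "CF"),
    class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Sections: `output_dir`, `seed`, `stages`, `occupancy`, `trains`, `nall`,
#' `fit_models`, and optionally `profiles` (a named list of
#' [detectorProfile()] argument lists, one per detector); unknown stage
#' names are an error.
#'
#' @param path YAML file.
#' @return a `run_config` list.
#' @export
readRunConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- demoConfig()
  for (nm in names(raw)) cfg[[nm]] <- raw[[nm]]
  if (!is.null(raw$occupancy)) {
    if (!is.null(raw$occupancy$start_date)) {
      cfg$occupancy$start_date <- as.Date(raw$occupancy$start_date)
    }
    if (!is.null(raw$occupancy$end_date)) {
      cfg$occupancy$end_date <- as.Date(raw$occupancy$end_date)
    }
  }
  cfg
}

ALL_STAGES <- c("simulate", "metrics", "foraging", "covariates", "model",
                "compare")

stage_seed <- function(seed, stage) seed + 100L * match(stage, ALL_STAGES)

#' Run the pipeline
#'
#' Executes the requested stages in dependency order and writes every
#' artifact plus a JSON manifest (inputs, outputs, seeds, timings) under the
#' configured output directory. Re-running with the same configuration
#' reproduces all numeric outputs exactly. A stage whose upstream artifacts
#' are missing stops with an error naming the stage to run first.
#'
#' @param config a `run_config` (see [demoConfig()], [readRunConfig()]).
#' @return the manifest, invisibly.
#' @export
runPipeline <- function(config) {
  stopifnot(!is.null(config$output_dir), !is.null(config$seed))
  unknown <- setdiff(config$stages, ALL_STAGES)
  if (length(unknown)) stop("unknown stage(s): ", paste(unknown, collapse = ", "))
  stages <- ALL_STAGES[ALL_STAGES %in% config$stages]
  out <- config$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(seed = config$seed,
                   package_version = as.character(utils::packageVersion("podcompare")),
                   stages = list())
  state <- new.env(parent = emptyenv())
  for (st in stages) {
    t0 <- Sys.time()
    do.call(paste0("stage_", st), list(config, state))
    manifest$stages[[st]] <- list(
      seed = stage_seed(config$seed, st),
      seconds = round(as.numeric(Sys.time() - t0, units = "secs"), 2),
      outputs = list.files(file.path(out, st), recursive = TRUE))
  }
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

require_stage <- function(config, stage, needed_by) {
  d <- file.path(config$output_dir, stage)
  if (!dir.exists(d)) {
    stop("stage '", needed_by, "' needs artifacts from stage '", stage,
         "'; run it first")
  }
  d
}

stage_simulate <- function(config, state) {
  d <- file.path(config$output_dir, "simulate")
  profiles <- if (is.list(config$profiles)) {
    lapply(config$profiles, function(p) do.call(detectorProfile, p))
  } else {
    list(C = cPodProfile(), F = fPodProfile())
  }
  co <- simulateCodeployment(
    occupancy = do.call(occupancyParams, config$occupancy),
    trains = do.call(trainParams, config$trains),
    nall = do.call(nallParams, config$nall),
    profiles = profiles,
    seed = stage_seed(config$seed, "simulate"))
  for (nm in names(co$pods)) {
    writePodExport(co$pods[[nm]], file.path(d, nm))
  }
  writeEnvironmentTables(co$sun, co$tide, file.path(d, "environment"))
  state$codeployment <- co
  invisible(d)
}

load_pods <- function(config, needed_by, state) {
  if (!is.null(state$codeployment)) return(state$codeployment$pods)
  d <- require_stage(config, "simulate", needed_by)
  pod_dirs <- setdiff(list.dirs(d, recursive = FALSE),
                      file.path(d, "environment"))
  pods <- lapply(pod_dirs, readPodExport)
  names(pods) <- basename(pod_dirs)
  pods
}

stage_metrics <- function(config, state) {
  pods <- load_pods(config, "metrics", state)
  d <- file.path(config$output_dir, "metrics")
  dir.create(d, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  for (nm in names(pods)) {
    for (grp in c("Hi", "HiMod", "HiModLo")) {
      for (res in c("minute", "hour", "day")) {
        s <- aggregateDetections(pods[[nm]], grouping = grp, resolution = res)
        rows[[length(rows) + 1]] <- data.frame(
          pod = nm, grouping = grp, resolution = res,
          bin = format_iso_us(s$bin), detected = s$detected, count = s$count,
          nclx = s$nclx, effort = s$effort)
      }
    }
  }
  utils::write.csv(do.call(rbind, rows), file.path(d, "metrics.csv"),
                   row.names = FALSE)
  invisible(d)
}

stage_foraging <- function(config, state) {
  pods <- load_pods(config, "foraging", state)
  d <- file.path(config$output_dir, "foraging")
  dir.create(d, showWarnings = FALSE, recursive = TRUE)
  sd <- stage_seed(config$seed, "foraging")
  for (nm in names(pods)) {
    ici <- computeICIs(pods[[nm]]$clicks)
    fit <- fitICIMixture(ici, seed = sd)
    cls <- classifyClicks(fit, ici)
    dpm_h <- aggregateDetections(pods[[nm]], grouping = "HiModLo",
                                 resolution = "hour")
    bz <- buzzSeries(cls, dpm_h)
    utils::write.csv(
      data.frame(pod = cls$pod, train_id = cls$train_id,
                 time = format_iso_us(cls$time), ici_ms = cls$ici_ms,
                 kind = cls$kind, behavior = cls$behavior,
                 posterior = cls$posterior),
      file.path(d, paste0(nm, "_labels.csv")), row.names = FALSE)
    jsonlite::write_json(
      list(K = fit$K, weights = fit$weights, means = fit$means,
           sds = fit$sds, labels = fit$labels, bic = fit$bic,
           loglik = fit$loglik, converged = fit$converged),
      file.path(d, paste0(nm, "_mixture.json")), auto_unbox = TRUE,
      digits = NA)
    utils::write.csv(
      data.frame(hour = format_iso_us(bz$hourly$hour), bpm = bz$hourly$bpm,
                 dpm = bz$hourly$dpm, buzz_rate = bz$hourly$buzz_rate),
      file.path(d, paste0(nm, "_buzz.csv")), row.names = FALSE)
    state$buzz[[nm]] <- bz
  }
  invisible(d)
}

stage_covariates <- function(config, state) {
  pods <- load_pods(config, "covariates", state)
  env_dir <- file.path(config$output_dir, "simulate", "environment")
  if (!is.null(state$codeployment)) {
    sun <- state$codeployment$sun; tide <- state$codeployment$tide
  } else {
    if (!dir.exists(env_dir)) require_stage(config, "simulate", "covariates")
    sun <- readSunTable(file.path(env_dir, "sun.csv"))
    tide <- readTideTable(file.path(env_dir, "tide.csv"))
  }
  d <- file.path(config$output_dir, "covariates")
  dir.create(d, showWarnings = FALSE, recursive = TRUE)
  temps <- lapply(pods, function(p) {
    agg <- tapply(p$minutes$temperature_c,
                  as.numeric(floor_hour(p$minutes$minute)), mean)
    data.frame(hour = .posix(as.numeric(names(agg))),
               temperature_c = as.numeric(agg))
  })
  pooled <- if (length(temps) >= 2) pooledTemperature(temps[[1]], temps[[2]])
            else temps[[1]]
  nall_h <- hourlyNall(pods[[1]]$minutes)
  hours <- nall_h$hour
  cov <- hourlyCovariates(hours, sun, tide, pooled, nall_h)
  utils::write.csv(
    cbind(data.frame(hour = format_iso_us(cov$hour)),
          cov[, setdiff(names(cov), "hour")]),
    file.path(d, "covariates.csv"), row.names = FALSE)
  state$covariates <- cov
  invisible(d)
}

stage_model <- function(config, state) {
  if (is.null(state$covariates)) stage_covariates(config, state)
  pods <- load_pods(config, "model", state)
  d <- file.path(config$output_dir, "model")
  dir.create(d, showWarnings = FALSE, recursive = TRUE)
  if (isFALSE(config$fit_models)) return(invisible(d))
  for (nm in names(pods)) {
    dpm_h <- aggregateDetections(pods[[nm]], grouping = "HiModLo",
                                 resolution = "hour")
    tab <- buildHourlyTable(dpm_h, state$covariates, state$buzz[[nm]])
    fit <- fitAdditiveModel(tab, modelSpec())
    utils::write.csv(fit$effects, file.path(d, paste0(nm, "_dpm_effects.csv")),
                     row.names = FALSE)
    utils::write.csv(smoothCurves(fit),
                     file.path(d, paste0(nm, "_dpm_smooths.csv")),
                     row.names = FALSE)
    jsonlite::write_json(
      list(pod = nm, response = "dpm_per_hour", theta = fit$theta,
           rho = fit$rho, aic = fit$aic,
           deviance_explained = fit$deviance_explained, auc = fit$auc,
           concurvity = as.list(fit$concurvity), n_used = fit$n_used,
           smoothing_criterion = "fREML with gamma penalty inflation",
           tide_sign_convention = "negative before high water"),
      file.path(d, paste0(nm, "_dpm_fit.json")), auto_unbox = TRUE, digits = NA)
    state$fits[[nm]] <- fit
  }
  invisible(d)
}

stage_compare <- function(config, state) {
  pods <- load_pods(config, "compare", state)
  d <- file.path(config$output_dir, "compare")
  rep <- compareReport(pods, seed = stage_seed(config$seed, "compare"))
  writeCompareReport(rep, d)
  invisible(d)
}

#' Two-detector comparison report
#'
#' Computes, for a processed co-deployment: detection totals and
#' effort-standardized rates per filter grouping and metric, Kendall
#' rank correlations between the detectors at every scale, the overall and
#' seasonal detection ratios (DPH, HiModLo), matched/unmatched positive-hour
#' proportions, and buzz summaries (mixture classification per pod, BPM/BPH
#' totals, buzz click fractions).
#'
#' @param pods a `pod_codeployment` or a named list of two `pod_detections`
#'   (the first pod is the ratio denominator, i.e. the C-like device).
#' @param groupings filter groupings to report.
#' @param seed seed for the mixture fits.
#' @return a `pod_comparison` list of data frames: `totals`, `rates`,
#'   `kendall`, `ratios`, `matched`, `buzz`.
#' @export
compareReport <- function(pods, groupings = c("Hi", "HiMod", "HiModLo"),
                          seed = 1) {
  if (inherits(pods, "pod_codeployment")) pods <- pods$pods
  if (length(pods) < 2) {
    warning("single-pod input: comparison statistics omitted")
  }
  series <- list()
  totals <- list(); rates <- list()
  for (nm in names(pods)) {
    for (grp in groupings) {
      for (res in c("minute", "hour", "day")) {
        s <- aggregateDetections(pods[[nm]], grouping = grp, resolution = res)
        series[[paste(nm, grp, res)]] <- s
        metric <- switch(res, minute = "DPM", hour = "DPH", day = "DPD")
        totals[[length(totals) + 1]] <- data.frame(
          pod = nm, grouping = grp, metric = metric,
          total = sum(s$detected), nclx = sum(s$nclx))
        r <- detectionRate(s, "season")
        rates[[length(rates) + 1]] <- cbind(
          data.frame(pod = nm, grouping = grp, metric = metric), r)
      }
    }
  }
  out <- list(totals = do.call(rbind, totals), rates = do.call(rbind, rates))

  if (length(pods) >= 2) {
    a <- names(pods)[1]; b <- names(pods)[2]
    kd <- list(); mt <- list()
    # correlate the paired series at each metric's native scale: hourly DPM
    # and NClx, daily DPH, daily DPD presence
    for (grp in groupings) {
      ha <- series[[paste(a, grp, "hour")]]; hb <- series[[paste(b, grp, "hour")]]
      da <- series[[paste(a, grp, "day")]]; db <- series[[paste(b, grp, "day")]]
      pairs <- list(DPM = list(ha$count, hb$count),
                    NClx = list(ha$nclx, hb$nclx),
                    DPH = list(da$count, db$count),
                    DPD = list(da$detected, db$detected))
      for (metric in names(pairs)) {
        kt <- kendallTau(pairs[[metric]][[1]], pairs[[metric]][[2]])
        kd[[length(kd) + 1]] <- data.frame(
          grouping = grp, metric = metric, tau = kt$tau,
          p_value = kt$p_value, n = kt$n)
      }
      mt[[length(mt) + 1]] <- cbind(data.frame(grouping = grp),
                                    matchPositiveBins(hb, ha))
    }
    out$kendall <- do.call(rbind, kd)
    out$matched <- do.call(rbind, mt)
    day_a <- series[[paste(a, "HiModLo", "day")]]
    day_b <- series[[paste(b, "HiModLo", "day")]]
    seas <- seasonOf(day_a$bin)
    present <- levels(seas)[levels(seas) %in% as.character(unique(seas))]
    dph_a <- tapply(day_a$count, seas, sum)[present]
    dph_b <- tapply(day_b$count, seas, sum)[present]
    out$ratios <- data.frame(
      period = c("overall", present),
      dph_first = c(sum(day_a$count), as.integer(dph_a)),
      dph_second = c(sum(day_b$count), as.integer(dph_b)),
      ratio = suppressWarnings(detectionRatio(
        c(sum(day_b$count), as.integer(dph_b)),
        c(sum(day_a$count), as.integer(dph_a)))))
  }

  bz <- list()
  for (nm in names(pods)) {
    ici <- computeICIs(pods[[nm]]$clicks)
    within_n <- sum(ici$kind == "within")
    if (within_n >= 50) {
      fit <- fitICIMixture(ici, seed = seed)
      cls <- classifyClicks(fit, ici)
      dpm_h <- aggregateDetections(pods[[nm]], grouping = "HiModLo",
                                   resolution = "hour")
      bs <- buzzSeries(cls, dpm_h)
      wi <- cls[cls$kind == "within", ]
      bz[[length(bz) + 1]] <- data.frame(
        pod = nm, n_ici = within_n, mixture_k = fit$K,
        buzz_click_pct = 100 * mean(wi$behavior == "buzz"),
        bpm_total = sum(bs$hourly$bpm), bph_total = sum(bs$daily$bph),
        mean_buzz_rate = mean(bs$hourly$buzz_rate, na.rm = TRUE))
    } else {
      bz[[length(bz) + 1]] <- data.frame(
        pod = nm, n_ici = within_n, mixture_k = NA_integer_,
        buzz_click_pct = if (within_n) 0 else NA_real_, bpm_total = 0L,
        bph_total = 0L, mean_buzz_rate = NA_real_)
    }
  }
  out$buzz <- do.call(rbind, bz)
  structure(out, class = c("pod_comparison", class(out)))
}

#' Write a comparison report to CSV files
#' @param report output of [compareReport()].
#' @param path directory.
#' @return `path`, invisibly.
#' @export
writeCompareReport <- function(report, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  for (nm in setdiff(names(report), "series")) {
    if (is.data.frame(report[[nm]])) {
      utils::write.csv(report[[nm]], file.path(path, paste0(nm, ".csv")),
                       row.names = FALSE)
    }
  }
  invisible(path)
}

#' @export
print.pod_comparison <- function(x, ...) {
  cat("Two-detector comparison\n\nTotals:\n")
  print(x$totals, row.names = FALSE)
  if (!is.null(x$ratios)) {
    cat("\nDetection ratios (DPH, HiModLo):\n")
    print(x$ratios, row.names = FALSE)
  }
  if (!is.null(x$buzz)) {
    cat("\nBuzz summary:\n")
    print(x$buzz, row.names = FALSE)
  }
  invisible(x)
}
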
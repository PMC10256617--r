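test_that("occupancy process honours rate structure and degenerate inputs", {
  p0 <- occupancyParams(base_encounter_rate = 0,
                        start_date = "2021-04-01", end_date = "2021-04-10")
  expect_identical(nrow(simulateOccupancy(p0, seed = 1)), 0L)

  expect_error(occupancyParams(start_date = "2021-04-10",
                               end_date = "2021-04-10"), "end_date")

  # night multiplier 0: no encounter starts at night
  pn <- occupancyParams(base_encounter_rate = 2, month_amplitude = 0,
                        diel_multipliers = c(morning = 1, day = 1,
                                             evening = 1, night = 0),
                        tide_amplitude = 0,
                        start_date = "2021-04-01", end_date = "2021-05-01")
  enc <- simulateOccupancy(pn, seed = 3)
  expect_gt(nrow(enc), 50)
  phases <- dielPeriod(enc$start, attr(enc, "sun"))
  expect_false(any(phases == "night"))

  # determinism
  enc2 <- simulateOccupancy(pn, seed = 3)
  expect_identical(enc, enc2)
})

test_that("homogeneous occupancy count matches the Poisson expectation", {
  p <- occupancyParams(base_encounter_rate = 0.5, month_amplitude = 0,
                       diel_multipliers = c(morning = 1, day = 1,
                                            evening = 1, night = 1),
                       tide_amplitude = 0, encounter_duration_mean = 10,
                       start_date = "2021-01-01", end_date = "2023-09-28")
  enc <- simulateOccupancy(p, seed = 1)
  expected <- 0.5 * 24 * 1000
  expect_lt(abs(nrow(enc) - expected), 3 * sqrt(expected))
  # intervals lie within the window and do not overlap
  expect_true(all(enc$start >= as.POSIXct("2021-01-01", tz = "UTC")))
  expect_true(all(enc$end <= as.POSIXct("2023-09-28", tz = "UTC")))
  expect_true(all(diff(as.numeric(enc$start)) >=
                    as.numeric(enc$end - enc$start)[-nrow(enc)] - 1e-9))
})

test_that("click trains follow the regime parameters", {
  enc1 <- data.frame(encounter_id = 1L,
                     start = as.POSIXct("2021-04-01 10:00:00", tz = "UTC"),
                     end = as.POSIXct("2021-04-01 10:20:00", tz = "UTC"))

  # buzz probability 0: no buzz labels
  cl <- simulateClickTrains(enc1, trainParams(buzz_train_probability = 0),
                            seed = 2)
  expect_gt(nrow(cl), 100)
  expect_false(any(cl$label == "buzz"))

  # all-buzz with tight sd: >99% of within-train ICIs under 10 ms
  clb <- simulateClickTrains(
    enc1, trainParams(buzz_train_probability = 1,
                      buzz_ici_log10_mean = log10(5),
                      buzz_ici_log10_sd = 0.05), seed = 2)
  ici <- computeICIs(clb, include_intertrain = FALSE)
  expect_gt(mean(ici$ici_ms < 10), 0.99)
  expect_true(all(clb$label == "buzz"))

  # deterministic layout: 3 trains of 10 clicks -> 27 within ICIs, 2 gaps
  tp <- trainParams(regular_ici_log10_sd = 0, intertrain_gap_log10_mean = 3,
                    intertrain_gap_log10_sd = 0,
                    buzz_train_probability = 0,
                    clicks_per_train = list(fixed = 10))
  enc_fit <- data.frame(encounter_id = 1L,
                        start = as.POSIXct("2021-04-01 10:00:00", tz = "UTC"),
                        end = as.POSIXct("2021-04-01 10:00:00", tz = "UTC") + 4.0)
  cl3 <- simulateClickTrains(enc_fit, tp, seed = 1)
  expect_identical(length(unique(cl3$train_id)), 3L)
  ici3 <- computeICIs(cl3)
  expect_identical(sum(ici3$kind == "within"), 27L)
  expect_identical(sum(ici3$kind == "intertrain"), 2L)

  # inconsistent ICI ordering rejected
  expect_error(trainParams(buzz_ici_log10_mean = log10(20)), "< 10 ms")
  expect_error(trainParams(regular_ici_log10_mean = log10(5)), "> 10 ms")
})

test_that("perfect and null detectors behave as contracts say", {
  truth <- simulateTruth(
    occupancyParams(base_encounter_rate = 1,
                    start_date = "2021-04-01", end_date = "2021-04-04"),
    seed = 5)
  perfect <- detectorProfile("P", p_click = 1, noise_slope = 0,
                             false_train_rate = 0, min_clicks_train = 2)
  det <- applyDetector(truth, perfect, seed = 6)
  expect_identical(nrow(det$clicks), nrow(truth$clicks))
  expect_identical(as.numeric(det$clicks$time),
                   sort(as.numeric(truth$clicks$time)))
  # label conservation
  key <- order(as.numeric(truth$clicks$time))
  expect_identical(det$clicks$truth_label, truth$clicks$label[key])

  null <- detectorProfile("N", p_click = 0, noise_slope = 0,
                          false_train_rate = 0.2, min_clicks_train = 2)
  det0 <- applyDetector(truth, null, seed = 6)
  expect_true(all(det0$trains$truth_behavior == "false"))
})

test_that("per-click thinning matches the binomial expectation", {
  truth <- simulateTruth(
    occupancyParams(base_encounter_rate = 1,
                    start_date = "2021-04-01", end_date = "2021-04-06"),
    seed = 7)
  n <- nrow(truth$clicks)
  expect_gt(n, 10000)
  half <- detectorProfile("H", p_click = 0.5, noise_slope = 0,
                          false_train_rate = 0, min_clicks_train = 2)
  det <- applyDetector(truth, half, seed = 7)
  expect_lt(abs(nrow(det$clicks) - 0.5 * n), 3 * sqrt(n * 0.25))
})

test_that("higher per-click sensitivity never reduces detections (coupling)", {
  truth <- simulateTruth(
    occupancyParams(base_encounter_rate = 0.8,
                    start_date = "2021-04-01", end_date = "2021-04-08"),
    seed = 11)
  set.seed(99)
  for (i in 1:20) {
    ps <- sort(runif(2, 0.05, 0.95))
    lo <- applyDetector(truth, detectorProfile("L", p_click = ps[1],
                                               false_train_rate = 0),
                        seed = 100 + i)
    hi <- applyDetector(truth, detectorProfile("H", p_click = ps[2],
                                               false_train_rate = 0),
                        seed = 100 + i)
    expect_gte(nrow(hi$clicks), nrow(lo$clicks))
    for (res in c("minute", "hour", "day")) {
      slo <- aggregateDetections(lo, "HiModLo", res)
      shi <- aggregateDetections(hi, "HiModLo", res)
      expect_gte(sum(shi$detected), sum(slo$detected))
    }
  }
})

test_that("negative noise slope suppresses detections in noisy minutes", {
  truth <- simulateTruth(
    occupancyParams(base_encounter_rate = 1.5, month_amplitude = 0,
                    tide_amplitude = 0,
                    start_date = "2021-04-01", end_date = "2021-04-15"),
    nall = nallParams(sdlog = 1.2, ar1 = 0.8),
    seed = 13)
  noisy <- detectorProfile("Z", p_click = 0.5, noise_slope = -1.5,
                           false_train_rate = 0, min_clicks_train = 2)
  det <- applyDetector(truth, noisy, seed = 14)
  # per-minute detected fraction vs ambient noise level
  mt <- truth$minutes[truth$minutes$n_true_clicks > 20, ]
  dcount <- as.integer(table(factor(
    as.numeric(podcompare:::floor_minute(det$clicks$time)),
    levels = as.numeric(mt$minute))))
  frac <- dcount / mt$n_true_clicks
  hi_noise <- mt$nall > median(mt$nall)
  wt <- wilcox.test(frac[hi_noise], frac[!hi_noise], alternative = "less")
  expect_lt(wt$p.value, 1e-6)
})

test_that("pod exports round-trip and are byte-stable", {
  co <- demo_codeployment()
  pod <- co$pods$C
  d1 <- file.path(tempdir(), "exp1"); d2 <- file.path(tempdir(), "exp2")
  writePodExport(pod, d1)
  writePodExport(pod, d2)
  for (f in c("trains.csv", "clicks.csv", "minutes.csv")) {
    expect_identical(readBin(file.path(d1, f), "raw", 5e6),
                     readBin(file.path(d2, f), "raw", 5e6))
  }
  back <- readPodExport(d1)
  expect_equal(as.numeric(back$trains$start_time),
               as.numeric(pod$trains$start_time), tolerance = 1e-6)
  expect_identical(back$trains$quality, pod$trains$quality)
  expect_identical(back$trains$n_clicks, pod$trains$n_clicks)
  expect_equal(as.numeric(back$clicks$time), as.numeric(pod$clicks$time),
               tolerance = 1e-6)
  expect_identical(back$clicks$truth_label, pod$clicks$truth_label)
  expect_equal(back$minutes$nall, pod$minutes$nall)

  # empty dataset: valid header-only files
  empty <- applyDetector(
    simulateTruth(occupancyParams(base_encounter_rate = 0,
                                  start_date = "2021-04-01",
                                  end_date = "2021-04-02"), seed = 1),
    detectorProfile("E", p_click = 1, false_train_rate = 0), seed = 1)
  d3 <- file.path(tempdir(), "exp3")
  writePodExport(empty, d3)
  back3 <- readPodExport(d3)
  expect_identical(nrow(back3$trains), 0L)
  expect_identical(nrow(back3$clicks), 0L)

  # out-of-order timestamps: error, or sorted under the documented flag
  scr <- pod
  scr$clicks <- scr$clicks[rev(seq_len(nrow(scr$clicks))), ]
  d4 <- file.path(tempdir(), "exp4")
  writePodExport(scr, d4)
  expect_error(readPodExport(d4), "out-of-order.*line", ignore.case = TRUE)
  sorted <- readPodExport(d4, sort = TRUE)
  expect_false(is.unsorted(as.numeric(sorted$clicks$time)))
})
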
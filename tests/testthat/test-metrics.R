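test_that("minute/hour/day aggregation counts positives correctly", {
  # two trains in minutes 0 and 5 of one hour: DPM = 2, DPH = 1, DPD = 1
  trains <- manual_trains(list(
    list(start = "2021-06-01 08:00:01", end = "2021-06-01 08:00:30",
         n = 2, quality = "Hi"),
    list(start = "2021-06-01 08:05:10", end = "2021-06-01 08:05:12",
         n = 5, quality = "Mod")))
  eff <- effort_minutes("2021-06-01", "2021-06-02")
  hr <- aggregateDetections(trains, "HiModLo", "hour", minutes = eff)
  expect_identical(hr$count[hr$bin == as.POSIXct("2021-06-01 08:00:00",
                                                 tz = "UTC")], 2L)
  expect_identical(sum(hr$detected), 1L)
  dy <- aggregateDetections(trains, "HiModLo", "day", minutes = eff)
  expect_identical(dy$count, 1L)
  expect_identical(dy$detected, 1L)
  expect_identical(dy$nclx, 7L)

  # a train spanning several minutes marks them all; start-only mode does not
  long <- manual_trains(list(
    list(start = "2021-06-01 09:00:30", end = "2021-06-01 09:02:30",
         n = 40, quality = "Hi")))
  mspan <- aggregateDetections(long, "Hi", "minute", minutes = eff)
  expect_identical(sum(mspan$detected), 3L)
  mstart <- aggregateDetections(long, "Hi", "minute", minutes = eff,
                                span = "start")
  expect_identical(sum(mstart$detected), 1L)

  # no trains: all zeros with effort intact
  none <- aggregateDetections(trains[0, ], "HiModLo", "hour", minutes = eff)
  expect_identical(sum(none$detected), 0L)
  expect_identical(nrow(none), 24L)
  expect_true(all(none$effort == 60L))

  # Hi filter on Lo-only trains: zeros at all scales
  lo_only <- manual_trains(list(
    list(start = "2021-06-01 10:00:00", end = "2021-06-01 10:00:05",
         n = 8, quality = "Lo")))
  expect_identical(sum(aggregateDetections(lo_only, "Hi", "day",
                                           minutes = eff)$count), 0L)

  # trains outside the effort period error unless clipped
  outside <- manual_trains(list(
    list(start = "2021-06-05 10:00:00", end = "2021-06-05 10:00:05",
         n = 4, quality = "Hi")))
  expect_error(aggregateDetections(outside, "Hi", "hour", minutes = eff),
               "effort")
  clipped <- aggregateDetections(outside, "Hi", "hour", minutes = eff,
                                 clip = TRUE)
  expect_identical(sum(clipped$detected), 0L)
})

test_that("detection rate standardizes by monitored effort", {
  trains <- manual_trains(lapply(0:143, function(i) {
    t0 <- as.POSIXct("2021-06-01", tz = "UTC") + i * 600
    list(start = format(t0), end = format(t0 + 5), n = 3, quality = "Hi")
  }))
  eff <- effort_minutes("2021-06-01", "2021-06-02")
  mn <- aggregateDetections(trains, "Hi", "minute", minutes = eff)
  r <- detectionRate(mn, "overall")
  expect_equal(r$rate, 10.0)
  expect_identical(r$monitored, 1440L)

  all_pos <- aggregateDetections(
    manual_trains(list(list(start = "2021-06-01 00:00:00",
                            end = "2021-06-01 23:59:30", n = 10000,
                            quality = "Hi"))),
    "Hi", "minute", minutes = eff)
  expect_equal(detectionRate(all_pos, "overall")$rate, 100)

  # equal underlying rate with unequal effort gives equal output
  eff2 <- effort_minutes("2021-07-01", "2021-07-03")
  trains2 <- manual_trains(lapply(0:287, function(i) {
    t0 <- as.POSIXct("2021-07-01", tz = "UTC") + i * 600
    list(start = format(t0), end = format(t0 + 5), n = 3, quality = "Hi")
  }))
  mn2 <- aggregateDetections(trains2, "Hi", "minute", minutes = eff2)
  expect_equal(detectionRate(mn2, "overall")$rate,
               detectionRate(mn, "overall")$rate)
})

test_that("detection ratio follows its contract", {
  expect_equal(detectionRatio(138, 100), 1.38)
  expect_equal(detectionRatio(57, 57), 1)
  expect_warning(r0 <- detectionRatio(10, 0), "undefined")
  expect_true(is.na(r0))
})

test_that("kendall tau equals the pair-counting oracle", {
  expect_equal(kendallTau(1:3, 1:3)$tau, 1)
  expect_equal(kendallTau(1:3, 3:1)$tau, -1)

  x <- c(1, 2, 2, 3); y <- c(1, 3, 2, 3)
  expect_equal(kendallTau(x, y)$tau, kendall_oracle(x, y))

  # randomized property: heavy-tie integer series up to n = 50
  set.seed(31)
  for (i in 1:30) {
    n <- sample(5:50, 1)
    x <- sample(0:6, n, replace = TRUE)
    y <- sample(0:6, n, replace = TRUE)
    if (length(unique(x)) == 1 || length(unique(y)) == 1) next
    expect_equal(kendallTau(x, y)$tau, kendall_oracle(x, y),
                 tolerance = 1e-12)
  }

  # constant input: undefined, reported missing
  const <- kendallTau(rep(2, 10), 1:10)
  expect_true(is.na(const$tau))

  # p-value sanity: agrees with cor.test's normal approximation with ties
  set.seed(8)
  x <- rpois(60, 3); y <- x + rpois(60, 2)
  ours <- kendallTau(x, y)
  ref <- suppressWarnings(cor.test(x, y, method = "kendall"))
  expect_equal(ours$p_value, ref$p.value, tolerance = 1e-8)
})

test_that("matched/unmatched bin proportions cover the set-logic cases", {
  eff <- effort_minutes("2021-06-01", "2021-06-02")
  mk <- function(starts, pod) {
    tr <- manual_trains(lapply(starts, function(s) {
      list(start = s, end = s, n = 3, quality = "Hi")
    }), pod = pod)
    aggregateDetections(tr, "Hi", "hour", minutes = eff)
  }
  a <- mk(c("2021-06-01 01:00:00", "2021-06-01 02:00:00"), "A")
  b <- mk(c("2021-06-01 01:00:00", "2021-06-01 02:00:00"), "B")
  m <- matchPositiveBins(a, b)
  expect_equal(m$prop_unmatched, c(0, 0))

  dis <- mk(c("2021-06-01 10:00:00", "2021-06-01 11:00:00"), "B")
  m2 <- matchPositiveBins(a, dis)
  expect_equal(m2$prop_unmatched, c(1, 1))

  sup <- mk(c("2021-06-01 01:00:00", "2021-06-01 02:00:00",
              "2021-06-01 03:00:00"), "B")
  m3 <- matchPositiveBins(a, sup)
  expect_equal(m3$prop_unmatched[1], 0)
  expect_gt(m3$prop_unmatched[2], 0)

  # mismatched effort errors
  eff2 <- effort_minutes("2021-06-01", "2021-06-03")
  c2 <- aggregateDetections(manual_trains(list(
    list(start = "2021-06-01 01:00:00", end = "2021-06-01 01:00:05",
         n = 3, quality = "Hi"))), "Hi", "hour", minutes = eff2)
  expect_error(matchPositiveBins(a, c2), "effort")
})

test_that("validation subsample follows the census-plus-sample protocol", {
  co <- demo_codeployment()
  pod <- co$pods$F
  vs <- validationSample(pod$trains, pod$minutes, n_random = 100, seed = 5)
  expect_identical(sum(vs$component == "HiMod_sample"), 100L)
  lo_minutes <- unique(as.numeric(podcompare:::floor_minute(
    podcompare:::train_minutes(
      pod$trains[pod$trains$quality == "Lo", ], "train"))))
  expect_identical(sum(vs$component == "Lo_census"), length(lo_minutes))
  # deterministic given the seed
  vs2 <- validationSample(pod$trains, pod$minutes, n_random = 100, seed = 5)
  expect_identical(vs, vs2)

  # fewer positives than requested: all returned
  few <- manual_trains(list(
    list(start = "2021-09-02 01:00:00", end = "2021-09-02 01:00:05",
         n = 3, quality = "Hi")))
  vsf <- validationSample(few, pod$minutes, n_random = 100, seed = 1)
  expect_identical(sum(vsf$component == "HiMod_sample"), 1L)
  expect_identical(sum(vsf$component == "Lo_census"), 0L)
})

test_that("metric hierarchy and filter monotonicity hold on simulated data", {
  co <- demo_codeployment()
  days_monitored <- length(unique(as.Date(co$pods$C$minutes$minute)))
  for (pod in co$pods) {
    prev <- NULL
    for (grp in c("Hi", "HiMod", "HiModLo")) {
      mn <- aggregateDetections(pod, grp, "minute")
      hr <- aggregateDetections(pod, grp, "hour")
      dy <- aggregateDetections(pod, grp, "day")
      dpm <- sum(mn$detected); dph <- sum(hr$detected); dpd <- sum(dy$detected)
      expect_lte(dpd, days_monitored)
      expect_lte(sum(dy$count), 24 * dpd)      # DPH <= 24 DPD
      expect_lte(sum(hr$count), 60 * dph)      # DPM <= 60 DPH
      expect_gte(sum(mn$nclx), dpm)            # NClx >= DPM
      # coarser bins positive whenever finer are
      expect_identical(dph, sum(hr$count > 0))
      expect_identical(dpd, sum(dy$count > 0))
      tot <- c(dpm = dpm, dph = dph, dpd = dpd, nclx = sum(mn$nclx))
      if (!is.null(prev)) expect_true(all(tot >= prev))
      prev <- tot
    }
  }
})
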
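test_that("rho estimation recovers AR coefficients and handles edge cases", {
  set.seed(5)
  white <- rnorm(10000)
  expect_lt(abs(estimateRho(white)), 0.03)
  ar <- as.numeric(arima.sim(list(ar = 0.5), 10000))
  expect_gt(estimateRho(ar), 0.47)
  expect_lt(estimateRho(ar), 0.53)
  expect_warning(r0 <- estimateRho(rnorm(50)), "fewer than 100")
  expect_identical(r0, 0)
  expect_warning(rc <- estimateRho(rep(1, 200)), "constant")
  expect_identical(rc, 0)

  # whitening an AR(1) series with its own coefficient leaves white noise
  w <- whitenResiduals(ar, 0.5)
  expect_lt(abs(estimateRho(w)), 0.03)
})

test_that("hourly table assembly enforces keys, effort and buzz contracts", {
  co <- demo_codeployment()
  nh <- hourlyNall(co$pods$C$minutes)
  cov <- hourlyCovariates(nh$hour, co$sun, co$tide,
                          data.frame(hour = nh$hour, temperature_c = 11), nh)
  two_days <- cov[cov$hour < as.POSIXct("2021-09-03", tz = "UTC"), ]
  dpm_h <- aggregateDetections(co$pods$F, "HiModLo", "hour")
  short <- dpm_h[dpm_h$bin < as.POSIXct("2021-09-03", tz = "UTC"), ]
  attributes(short)[c("pod", "grouping", "resolution", "span")] <-
    attributes(dpm_h)[c("pod", "grouping", "resolution", "span")]
  class(short) <- class(dpm_h)
  tab <- buildHourlyTable(short, two_days)
  expect_lte(nrow(tab), 48)
  expect_true(all(c("dpm", "month_frac", "diel_period", "ar_start") %in%
                    names(tab)))
  expect_identical(levels(tab$diel_period)[1], "day")

  dup <- rbind(short, short[1, ])
  attributes(dup)[c("pod", "grouping", "resolution", "span")] <-
    attributes(dpm_h)[c("pod", "grouping", "resolution", "span")]
  class(dup) <- class(dpm_h)
  expect_error(buildHourlyTable(dup, two_days), "duplicated hour")

  # buzz-rate response: DPM = 0 hours carry a missing rate into the table
  cls <- data.frame(time = short$bin[which(short$count > 0)[1]] + 30,
                    behavior = "buzz")
  bz <- buzzSeries(cls, short)
  tab2 <- buildHourlyTable(short, two_days, bz)
  expect_true(all(is.na(tab2$buzz_rate[tab2$dpm == 0])))
})

test_that("cyclic month smooth wraps and the factor reference is day", {
  tab <- simulateHourlyCounts(n_hours = 3000, seed = 2)
  fit <- fitAdditiveModel(tab, modelSpec(terms = c("diel_period", "month")))
  grid <- tab[rep(1, 2), ]
  grid$month_frac <- c(0, 12)
  pr <- predict(fit$model, newdata = grid, type = "terms")
  mcol <- grep("month_frac", colnames(pr))
  expect_equal(pr[1, mcol], pr[2, mcol], tolerance = 1e-8)
  # reference level absent from effect rows
  expect_false(any(grepl("diel_periodday", fit$effects$term)))
  expect_true(any(grepl("diel_periodnight", fit$effects$term)))

  # smooth-curve export covers the month smooth over its observed range
  sc <- smoothCurves(fit)
  expect_identical(unique(sc$covariate), "month_frac")
  expect_equal(range(sc$x), range(tab$month_frac))
})

test_that("shrinkage suppresses a null covariate and selection drops it", {
  # pure-noise covariate under a shrinkage basis: edf collapses
  set.seed(42)
  edfs <- vapply(1:10, function(i) {
    tab <- simulateHourlyCounts(n_hours = 2500, month_amplitude = 1,
                                noise_effect = 0, seed = 400 + i)
    fit <- fitAdditiveModel(tab, modelSpec(terms = c("month", "nall")))
    s <- summary(fit$model)
    s$s.table[grep("nall", rownames(s$s.table)), "edf"]
  }, 0)
  expect_gte(sum(edfs < 0.5), 9)

  # stepwise: the noise term goes first and informative terms survive
  drops <- vapply(1:5, function(i) {
    tab <- simulateHourlyCounts(n_hours = 1500, seed = 500 + i)
    sel <- stepwiseSelect(tab, modelSpec(terms = c("diel_period", "month",
                                                   "nall")))
    if (nrow(sel$trace)) sel$trace$dropped[1] else "none"
  }, "")
  expect_gte(sum(drops == "nall"), 4)

  # a fully informative model is left unchanged
  tab <- simulateHourlyCounts(n_hours = 2000, month_amplitude = 1.2,
                              diel_effects = c(morning = 0, evening = 0,
                                               night = -0.8), seed = 9)
  sel2 <- stepwiseSelect(tab, modelSpec(terms = c("diel_period", "month")))
  expect_identical(nrow(sel2$trace), 0L)
  expect_setequal(sel2$fit$spec$terms, c("diel_period", "month"))

  # nothing informative: intercept-only end state allowed
  tab0 <- simulateHourlyCounts(n_hours = 1200, month_amplitude = 0,
                               diel_effects = c(morning = 0, evening = 0,
                                                night = 0), seed = 10)
  sel0 <- stepwiseSelect(tab0, modelSpec(terms = c("nall")))
  expect_s3_class(sel0$fit, "pod_gam")
  if (nrow(sel0$trace)) expect_identical(length(sel0$fit$spec$terms), 0L)
})

test_that("AUC is a midrank statistic with NB presence scores", {
  # perfectly separated scores
  expect_equal(podcompare:::rankAUC(c(1, 2, 3, 10, 11), c(FALSE, FALSE, FALSE,
                                                          TRUE, TRUE)), 1)
  # label-independent scores: null AUC near 0.5
  set.seed(4)
  sc <- runif(10000); lab <- runif(10000) > 0.5
  a <- podcompare:::rankAUC(sc, lab)
  expect_gt(a, 0.48); expect_lt(a, 0.52)
  # single-class presence: undefined
  expect_true(is.na(podcompare:::rankAUC(sc, rep(TRUE, 10000))))
  # agrees with an independent implementation
  ref <- as.numeric(pROC::auc(pROC::roc(lab, sc, quiet = TRUE,
                                        direction = "<")))
  expect_equal(a, ref, tolerance = 1e-12)

  tab <- simulateHourlyCounts(n_hours = 2000, seed = 3)
  fit <- fitAdditiveModel(tab, modelSpec(terms = c("diel_period", "month")))
  expect_gt(fit$auc, 0.5)
  expect_lte(fit$auc, 1)
  expect_gte(fit$deviance_explained, 0)
})

test_that("concurvity is near 0 for independent and 1 for duplicated inputs", {
  set.seed(2)
  n <- 5000
  d <- data.frame(x1 = runif(n), x2 = runif(n), x3 = runif(n))
  d$y <- rpois(n, exp(0.5 + sin(2 * pi * d$x1) + d$x2))
  g <- mgcv::gam(y ~ s(x1) + s(x2) + s(x3), family = poisson, data = d)
  expect_true(all(concurvityTable(g) < 0.2))

  d$x4 <- d$x1
  g2 <- mgcv::gam(y ~ s(x1) + s(x4), family = poisson, data = d)
  expect_true(all(concurvityTable(g2) > 0.95))

  g1 <- mgcv::gam(y ~ s(x1), family = poisson, data = d)
  expect_identical(length(concurvityTable(g1)), 0L)
})

test_that("NB fit approaches a Poisson fit when dispersion vanishes", {
  tab <- simulateHourlyCounts(n_hours = 3000, theta = 1e5, seed = 6)
  spec <- modelSpec(terms = c("month"), theta = 1e5, rho = 0)
  fit <- fitAdditiveModel(tab, spec)
  pg <- mgcv::bam(dpm ~ s(month_frac, bs = "cc", k = 12), family = poisson,
                  knots = list(month_frac = c(0, 12)), data = tab,
                  method = "fREML", discrete = TRUE, gamma = 1.2)
  expect_lt(max(abs(fitted(fit$model) - fitted(pg)) / fitted(pg)), 0.01)
})

test_that("AIC prefers the true structure over an overfitted extra term", {
  # dispersion and autocorrelation are held fixed across candidate models,
  # as in the two-step fitting procedure, so AIC differences reflect terms
  wins <- 0
  for (i in 1:15) {
    tab <- simulateHourlyCounts(n_hours = 4000, seed = 700 + i)
    f_true <- fitAdditiveModel(tab, modelSpec(terms = c("diel_period",
                                                        "month"),
                                              theta = 2, rho = 0))
    f_over <- fitAdditiveModel(tab, modelSpec(terms = c("diel_period",
                                                        "month", "nall"),
                                              theta = 2, rho = 0))
    if (f_true$aic <= f_over$aic) wins <- wins + 1
  }
  expect_gte(wins, 12)
})
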
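# Shared fixtures and independent oracles. Heavy simulated objects are
# built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- builder()
  .fixtures[[key]]
}

# a 60-day co-deployment shared by metrics / foraging / pipeline tests
demo_codeployment <- function() {
  cached("codeployment", function() {
    simulateCodeployment(
      occupancyParams(start_date = "2021-09-01", end_date = "2021-10-31"),
      seed = 7)
  })
}

# brute-force O(n^2) tau-b oracle: explicit pair counting with tie correction
kendall_oracle <- function(x, y) {
  n <- length(x)
  C <- 0; D <- 0; Tx <- 0; Ty <- 0
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      dx <- sign(x[j] - x[i]); dy <- sign(y[j] - y[i])
      if (dx == 0 && dy == 0) { Tx <- Tx + 1; Ty <- Ty + 1 }
      else if (dx == 0) Tx <- Tx + 1
      else if (dy == 0) Ty <- Ty + 1
      else if (dx == dy) C <- C + 1
      else D <- D + 1
    }
  }
  n0 <- n * (n - 1) / 2
  (C - D) / sqrt((n0 - Tx) * (n0 - Ty))
}

# expected detection-positive hours under the per-click binomial observation
# model, computed from the ground truth by numerical summation: a train of m
# true clicks registers with probability P(Binom(m, p) >= min_clicks); an
# hour is positive unless every train in it fails to register. Holds for
# noise_slope = 0 and no false trains.
expected_dph <- function(truth, p_click, min_clicks) {
  cl <- truth$clicks
  first <- !duplicated(cl$train_id)
  m <- as.integer(table(cl$train_id)[cl$train_id[first]])
  hour <- floor(as.numeric(cl$time[first]) / 3600)
  p_reg <- 1 - pbinom(min_clicks - 1, m, p_click)
  log_fail <- tapply(log1p(-pmin(p_reg, 1 - 1e-15)), hour, sum)
  p_hour <- 1 - exp(as.numeric(log_fail))
  list(expected = sum(p_hour), variance = sum(p_hour * (1 - p_hour)))
}

# deterministic click/train tables for hand-computed metric examples
manual_trains <- function(specs, pod = "X") {
  do.call(rbind, lapply(seq_along(specs), function(i) {
    s <- specs[[i]]
    data.frame(pod = pod, train_id = sprintf("%s_t%02d", pod, i),
               start_time = as.POSIXct(s$start, tz = "UTC"),
               end_time = as.POSIXct(s$end, tz = "UTC"),
               n_clicks = s$n, quality = s$quality, species = "NBHF",
               truth_behavior = "regular", stringsAsFactors = FALSE)
  }))
}

effort_minutes <- function(from, to, pod = "X") {
  mins <- seq(as.POSIXct(from, tz = "UTC"), as.POSIXct(to, tz = "UTC") - 60,
              by = 60)
  data.frame(pod = pod, minute = mins, nall = 50, temperature_c = 12)
}
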
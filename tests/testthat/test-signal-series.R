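test_that("detrending annihilates a pure line and rejects degenerate input", {
  rec <- physio_record(list(ecg = c(1, 2, 3, 4, 5)), fs = 1)
  out <- detrend_and_clean(rec)
  expect_lt(max(abs(out$channels$ecg)), 1e-12)

  expect_error(detrend_and_clean(physio_record(list(ecg = rep(2, 10)),
                                               fs = 1)),
               "degenerate channel")
  expect_error(detrend_and_clean(physio_record(list(ecg = numeric(0)),
                                               fs = 1)),
               "empty channel")
})

test_that("a 10-SD spike is replaced and other samples are untouched", {
  set.seed(4)
  x <- rnorm(500)
  s <- sd(x)
  x[250] <- mean(x) + 10 * s
  rec <- physio_record(list(ecg = x), fs = 1)
  out <- detrend_and_clean(rec)$channels$ecg

  # reference: detrend by least squares, mask the >= 3 SD samples, and
  # interpolate across them
  t <- seq_along(x)
  resid <- stats::lm.fit(cbind(1, t), x)$residuals
  bad <- abs(resid - mean(resid)) >= 3 * sd(resid)
  ref <- resid
  ref[bad] <- approx(which(!bad), resid[!bad], xout = which(bad),
                     rule = 2)$y
  expect_true(bad[250])
  expect_equal(out, unname(ref), tolerance = 1e-10)
  expect_equal(length(out), length(x))
  expect_lt(max(abs(out[!bad] - resid[!bad])), 1e-10)
})

test_that("R-peak detection recovers synthetic beat rates", {
  p <- sim_group_defaults()
  p$bbi_sd <- 0; p$sbp_sd <- 0; p$sbp_noise <- 0; p$tt_sd <- 0

  p$bbi_mean <- 1000
  s60 <- simulate_subject(p, duration_s = 60, seed = 3, emit_raw = TRUE)
  rp <- detect_rpeaks(s60$record$channels$ecg, 250)
  expect_true(all(abs(diff(rp) * 1000 - 1000) <= 10))

  p$bbi_mean <- 750   # 80 bpm
  s80 <- simulate_subject(p, duration_s = 60, seed = 3, emit_raw = TRUE)
  rp80 <- detect_rpeaks(s80$record$channels$ecg, 250)
  expect_equal(length(rp80[rp80 < 60]) , 80, tolerance = 0.0125)

  expect_error(detect_rpeaks(rep(0, 1000), 250), "no QRS")
  expect_error(detect_rpeaks(rnorm(500), 50), "at least 100 Hz")
})

test_that("BBI extraction is direct differencing in milliseconds", {
  b <- extract_bbi(c(0, 1, 2.5))
  expect_equal(b$values, c(1000, 1500))
  expect_equal(b$timestamps, c(1, 2.5))
  expect_error(extract_bbi(c(0, 1)), "at least 3")
  u <- extract_bbi(seq(0, 8, by = 0.8))
  expect_true(all(abs(u$values - 800) < 1e-9))
})

test_that("per-beat pressure extrema match the waveform", {
  fs <- 250
  t <- (0:(2 * fs - 1)) / fs
  bp <- 100 + 20 * sin(2 * pi * t)   # one full cycle per second
  res <- extract_sbp_dbp(bp, fs, c(0, 1, 2))
  expect_equal(res$sbp$values, c(120, 120), tolerance = 0.02)
  expect_equal(res$dbp$values, c(80, 80), tolerance = 0.02)

  res2 <- extract_sbp_dbp(rep(90, fs), fs, c(0, 0.5))
  expect_equal(res2$sbp$values, 90)
  expect_equal(res2$dbp$values, 90)

  # beat window between samples -> skipped with a warning
  expect_warning(extract_sbp_dbp(rep(90, 10), 10, c(0, 0.52, 0.58, 0.9)),
                 "no BP samples")

  # SBP/DBP counts always agree (beat-window conservation)
  s <- quick_subject(seed = 21, duration_s = 60)
  raw <- simulate_subject(sim_group_defaults(), duration_s = 60, seed = 21,
                          emit_raw = TRUE)
  rp <- detect_rpeaks(raw$record$channels$ecg, 250)
  both <- extract_sbp_dbp(raw$record$channels$bp, 250, rp)
  expect_equal(length(both$sbp), length(both$dbp))
})

test_that("SBP series extracted from raw signals recovers injected values", {
  s <- simulate_subject(sim_group_defaults(), duration_s = 120, seed = 11,
                        emit_raw = TRUE)
  rp <- detect_rpeaks(s$record$channels$ecg, 250)
  both <- extract_sbp_dbp(s$record$channels$bp, 250, rp)
  expect_lt(abs(mean(both$sbp$values) - mean(s$truth$sbp)), 2)
  expect_lt(abs(mean(both$dbp$values) - mean(s$truth$dbp)), 2)
})

test_that("breath-cycle durations come from flow zero crossings", {
  fs <- 100
  t <- (0:(30 * fs - 1)) / fs
  tt <- extract_tt(sin(2 * pi * 0.25 * t), fs)
  expect_true(all(abs(tt$values - 4) < 0.02))
  expect_error(extract_tt(rep(1, 1000), fs), "breath onsets")

  s <- simulate_subject(sim_group_defaults(), duration_s = 120, seed = 11,
                        emit_raw = TRUE)
  ext <- extract_tt(s$record$channels$rf, 250)
  onsets <- s$truth$breath_onsets
  err <- vapply(seq_along(ext$timestamps), function(k) {
    j <- which.min(abs(onsets - ext$timestamps[k]))
    abs(ext$values[k] - (onsets[j] - onsets[j - 1]))
  }, numeric(1))
  # mean error below one raw sample period (1/250 s)
  expect_lt(mean(err), 1 / 250)
})

test_that("extracted BBI matches ground-truth beat times to sub-sample", {
  s <- simulate_subject(sim_group_defaults(), duration_s = 120, seed = 5,
                        emit_raw = TRUE)
  rp <- detect_rpeaks(s$record$channels$ecg, 250)
  bbi <- extract_bbi(rp)
  tb <- s$truth$beat_times
  err <- vapply(seq_along(bbi$timestamps), function(k) {
    j <- which.min(abs(tb - bbi$timestamps[k]))
    abs(bbi$values[k] - (tb[j] - tb[j - 1]) * 1000)
  }, numeric(1))
  expect_lt(mean(err), 1000 / 250)
})

test_that("resampling interpolates linearly and decimates by 4", {
  es <- event_series("SBP", c(10, 20), c(0, 2))
  r <- resample_series(es, 1.0)
  expect_equal(r$values, c(10, 15, 20))
  expect_equal(r$timestamps, c(0, 1, 2))
  expect_equal(r$grid_hz, 1)

  const <- event_series("SBP", rep(7, 10), 0:9)
  expect_true(all(abs(resample_series(const, 1.0)$values - 7) < 1e-9))

  long <- event_series("SBP", rnorm(600) + 100, 0:599)
  expect_equal(length(resample_series(long, 0.25)), 150)
  expect_error(resample_series(es, 2), "target_hz")
})

test_that("resampling a series already on the target grid is the identity", {
  es <- event_series("BBI", 800 + sin(0:99), 0:99, grid_hz = 1)
  r <- resample_series(es, 1.0)
  expect_lt(max(abs(r$values - es$values)), 1e-9)
  expect_equal(r$timestamps, es$timestamps)
})

test_that("synchronization clips to the common span and keeps positivity", {
  s <- quick_subject(seed = 8, duration_s = 200)
  g <- sync_series(s$series, 0.25)
  spans <- vapply(g, function(x) range(x$timestamps), numeric(2))
  expect_true(all(spans[1, ] == spans[1, 1]))
  expect_equal(length(unique(vapply(g, length, integer(1)))), 1L)
  expect_true(all(g$bbi$values > 0))
  expect_true(all(g$tt$values > 0))
})

test_that("event series validation enforces its invariants", {
  expect_error(event_series("BBI", c(800, -5), c(1, 2)), "positive")
  expect_error(event_series("SBP", c(1, 2), c(2, 1)), "increasing")
  expect_error(event_series("SBP", c(1, NA), c(1, 2)), "finite")
  expect_error(event_series("SBP", 1:3, c(0, 1, 2.5), grid_hz = 1),
               "uniform")
})
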
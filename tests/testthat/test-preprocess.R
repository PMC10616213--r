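test_that("median filter removes one-sample spikes and keeps boundaries", {
  g <- make_gaze(t = (0:2) / 240, x = c(5, 5, 5), y = c(5, 5, 5))
  expect_equal(median_filter(g, 3)$x, c(5, 5, 5))
  g2 <- make_gaze(t = (0:2) / 240, x = c(1, 100, 1), y = 0)
  expect_equal(median_filter(g2, 3)$x, c(1, 1, 1))
  expect_error(median_filter(g2, 4), "odd")
})

test_that("median filter equals the brute-force sort-and-pick median", {
  set.seed(42)
  n <- 500
  g <- make_gaze(t = (0:(n - 1)) / 240, x = rnorm(n, 0, 200), y = rnorm(n, 0, 80))
  for (k in c(3L, 5L)) {
    f <- median_filter(g, k)
    expect_equal(f$x, oracle_runmed(g$x, k))
    expect_equal(f$y, oracle_runmed(g$y, k))
    # timestamps, confidence and flags untouched
    expect_identical(f[c("t", "confidence", "on_screen", "valid")],
                     g[c("t", "confidence", "on_screen", "valid")])
  }
})

test_that("gap classification is strictly below threshold, plus off-screen", {
  g <- make_gaze(t = (0:3) / 240, x = 1, y = 1,
                 confidence = c(0.8, 0.95, 0.799, 0.2),
                 on_screen = c(TRUE, FALSE, TRUE, TRUE))
  cl <- classify_gaps(g, 0.8)
  expect_equal(cl$valid, c(TRUE, FALSE, FALSE, FALSE))
  expect_true(all(is.na(cl$x[!cl$valid])))
  set.seed(1)
  n <- 1000
  gr <- make_gaze(t = (0:(n - 1)) / 240, x = 0, y = 0,
                  confidence = runif(n), on_screen = runif(n) > 0.1)
  cl2 <- classify_gaps(gr, 0.8)
  expect_equal(mean(!cl2$valid),
               sum(gr$confidence < 0.8 | !gr$on_screen) / n)
})

test_that("gaps below 75 ms are linearly interpolated, longer gaps kept", {
  # 50 ms gap: flanking samples at 1.000 (x=0) and 1.050 (x=12), 11 missing
  t <- 1 + (0:12) / 240
  g <- make_gaze(t = t, x = c(0, rep(NA, 11), 12), y = 0,
                 valid = c(TRUE, rep(FALSE, 11), TRUE))
  out <- interpolate_short_gaps(g, 75)
  expect_true(all(out$valid))
  expect_equal(out$x[7], 6)  # x(1.025) midpoint of the linear fill
  expect_equal(out$x, seq(0, 12, by = 1), tolerance = 1e-9)

  # 100 ms gap stays; so does an exact 75 ms tie (strict <)
  for (gap_s in c(0.100, 0.075)) {
    n_int <- round(gap_s * 240) - 1
    t2 <- 1 + (0:(n_int + 1)) / 240
    g2 <- make_gaze(t = t2, x = c(0, rep(NA, n_int), 5), y = 0,
                    valid = c(TRUE, rep(FALSE, n_int), TRUE))
    expect_equal(interpolate_short_gaps(g2, 75)$valid, g2$valid)
  }
})

test_that("interpolation fills exactly the runs a run-length scan predicts", {
  set.seed(7)
  n <- 800
  t <- (0:(n - 1)) / 240
  valid <- runif(n) > 0.12
  g <- make_gaze(t = t, x = cumsum(rnorm(n)), y = 0, valid = valid)
  g$x[!valid] <- NA
  out <- interpolate_short_gaps(g, 75)
  # independent prediction of which samples become valid
  expected <- valid
  i <- 1
  while (i <= n) {
    if (!valid[i]) {
      j <- i
      while (j < n && !valid[j + 1]) j <- j + 1
      if (i > 1 && j < n && (t[j + 1] - t[i - 1]) * 1000 < 75) {
        expected[i:j] <- TRUE
      }
      i <- j + 1
    } else i <- i + 1
  }
  expect_equal(out$valid, expected)
  # filled values never leave the hull of the flanking valid coordinates
  filled <- which(out$valid & !valid)
  for (ix in filled) {
    lo <- max(which(valid[1:ix])); hi <- ix + min(which(valid[(ix + 1):n]))
    expect_gte(out$x[ix], min(g$x[lo], g$x[hi]) - 1e-9)
    expect_lte(out$x[ix], max(g$x[lo], g$x[hi]) + 1e-9)
  }
})

test_that("gap padding invalidates +/- 100 ms around remaining gaps, inclusive", {
  t <- seq(1.5, 2.7, by = 1 / 240)
  valid <- !(t >= 2.0 & t <= 2.2)
  g <- make_gaze(t = t, x = 1, y = 1, valid = valid)
  g$x[!valid] <- NA
  out <- extend_gaps(g, 100)
  expect_equal(out$valid, !(t >= 1.9 - 1e-12 & t <= 2.3 + 1e-12))

  clean <- make_gaze(t = t, x = 1, y = 1)
  expect_identical(extend_gaps(clean, 100), clean)

  # two gaps 150 ms apart: the pads overlap and the bridge is invalidated
  valid2 <- !((t >= 2.0 & t < 2.1) | (t >= 2.25 & t < 2.35))
  g2 <- make_gaze(t = t, x = 1, y = 1, valid = valid2)
  g2$x[!valid2] <- NA
  out2 <- extend_gaps(g2, 100)
  bridge <- t > 2.1 & t < 2.25
  expect_true(all(!out2$valid[bridge]))
})

test_that("resampling yields an exact uniform 240 Hz grid and reproduces linear data", {
  t_in <- sort(c((0:599) / 120, (0:599) / 120 + 1 / 240 + 1e-4))
  g <- make_gaze(t = t_in, x = 3 * t_in - 1, y = -2 * t_in + 5)
  out <- resample_uniform(g, 240)
  expect_lt(max(abs(diff(out$t) - 1 / 240)), 1e-6 / 1000)  # < 1 us deviation
  expect_equal(out$x, 3 * out$t - 1, tolerance = 1e-9)
  expect_equal(out$y, -2 * out$t + 5, tolerance = 1e-9)
})

test_that("monotone input stays monotone after Hermite resampling", {
  set.seed(5)
  t_in <- cumsum(runif(80, 0.002, 0.01))
  x_in <- cumsum(abs(rnorm(80)))
  g <- make_gaze(t = t_in, x = x_in, y = 0)
  out <- resample_uniform(g, 240)
  expect_true(all(diff(out$x[out$valid]) >= -1e-9))
  # cross-check against an independent monotone-cubic implementation; the
  # derivative estimators differ, so agreement is to a fraction of the range
  ref <- pracma::pchip(t_in, x_in, out$t[out$valid])
  expect_true(all(diff(ref) >= -1e-9))
  expect_lt(max(abs(out$x[out$valid] - ref)), 0.01 * diff(range(x_in)))
  # both stay inside the hull of the input (no overshoot anywhere)
  expect_true(all(out$x[out$valid] >= min(x_in) - 1e-9))
  expect_true(all(out$x[out$valid] <= max(x_in) + 1e-9))
})

test_that("resampling never bridges invalid spans", {
  t_in <- (0:480) / 240
  valid <- !(t_in > 0.8 & t_in < 1.2)
  g <- make_gaze(t = t_in, x = sin(t_in), y = cos(t_in), valid = valid)
  g$x[!valid] <- NA; g$y[!valid] <- NA
  out <- resample_uniform(g, 240)
  inside <- out$t > 0.8 & out$t < 1.2
  expect_true(all(!out$valid[inside]))
  expect_true(all(is.na(out$x[inside])))
  expect_true(all(out$valid[!inside]))
  # a segment with a single valid sample is emitted invalid
  v2 <- rep(FALSE, length(t_in)); v2[240] <- TRUE
  g2 <- make_gaze(t = t_in, x = 1, y = 1, valid = v2)
  g2$x[!v2] <- NA
  expect_true(all(!resample_uniform(g2, 240)$valid))
})

test_that("gap statistics count each preprocessing stage", {
  n <- 2400  # 10 s at 240 Hz
  t <- (0:(n - 1)) / 240
  clean <- make_gaze(t = t, x = 0, y = 0)
  st0 <- gap_stats(clean, clean, clean, clean)
  expect_equal(st0$pct_nan_before_interp, 0)
  expect_equal(st0$pct_nan_after_pad, 0)

  # one 200 ms blink: 2% missing after interp, 4% after the +/- 100 ms pad
  g <- make_gaze(t = t, x = 0, y = 0,
                 confidence = ifelse(t >= 4 & t < 4.2, 0.3, 0.99))
  cl <- classify_gaps(g, 0.8)
  ip <- interpolate_short_gaps(cl, 75)
  pd <- extend_gaps(ip, 100)
  st <- gap_stats(g, cl, ip, pd)
  expect_equal(st$pct_low_confidence, st$pct_nan_before_interp)
  expect_lt(abs(st$pct_nan_after_interp - 2.0), 100 / n + 1e-9)
  expect_lt(abs(st$pct_nan_after_pad - 4.0), 2 * 100 / n + 1e-9)
  expect_gte(st$pct_nan_after_pad, st$pct_nan_after_interp)
  expect_error(gap_stats(g, cl[-1, ], ip, pd), "length")
})

test_that("the composed pipeline is deterministic", {
  scn <- generate_scenario(scenario_script(duration_s = 3, noise_sigma_deg = 0.4,
                                           seed = 9))
  pooled <- pool_surfaces(scn$surfaces, scn$layout, scn$geom)
  a <- preprocess_gaze(pooled)
  b <- preprocess_gaze(pooled)
  expect_identical(a, b)
})
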
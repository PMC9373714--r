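# spike/burst detection, rates, peak statistics, filtering, regression

test_that("spike detection on a constructed trace", {
  fx <- generate_fixture("spiky_trace", spike_times = c(100, 300, 700),
                         peak = 32, fs = 50000)
  st <- detect_spikes(fx$values, dt = 1000 / fx$fs)
  expect_length(st, 3)
  expect_true(all(abs(st - fx$spike_times) < 1))
  # flat subthreshold trace: no detections
  expect_length(detect_spikes(rep(-70, 1000), 0.02), 0)
  # doubling the suprathreshold amplitude leaves the count unchanged
  v2 <- (fx$values + 70) * 2 - 70
  expect_length(detect_spikes(v2, 1000 / fx$fs), 3)
  # refractory lockout: a 1 ms double-peak counts once
  t <- seq(0, 20, by = 0.02)
  v <- -70 + 100 * (exp(-((t - 5) / 0.3)^2) + exp(-((t - 5.8) / 0.3)^2))
  expect_length(detect_spikes(v, 0.02, refractory = 2), 1)
})

test_that("burst rule on the constructed train and limiting cases", {
  b <- detect_bursts(c(0, 30, 60, 200, 230, 400))
  expect_equal(nrow(b), 2)
  expect_equal(b$start, c(1, 4))
  expect_equal(b$end, c(3, 5))
  expect_equal(b$n_spikes, c(3, 2))
  # all ISIs above the opening bound: no bursts
  expect_equal(nrow(detect_bursts(seq(0, 500, by = 50))), 0)
  # all ISIs at 30 ms: one burst containing every spike
  b2 <- detect_bursts(seq(0, 300, by = 30))
  expect_equal(nrow(b2), 1)
  expect_equal(b2$n_spikes, 11)
  # a 40-100 ms ISI continues but cannot open a burst
  b3 <- detect_bursts(c(0, 80, 160))
  expect_equal(nrow(b3), 0)
  b4 <- detect_bursts(c(0, 30, 90, 150, 400))
  expect_equal(nrow(b4), 1)
  expect_equal(b4$end, 4)
  # idempotent under time translation
  b5 <- detect_bursts(c(0, 30, 60, 200, 230, 400) + 1234.5)
  expect_equal(b5$start, b$start)
  expect_equal(b5$end, b$end)
  expect_equal(nrow(detect_bursts(numeric(0))), 0)
  expect_equal(nrow(detect_bursts(5)), 0)
})

test_that("firing rate windows correctly", {
  expect_equal(firing_rate(numeric(0)), 0)
  st <- seq(600, 3500, length.out = 30)
  expect_equal(firing_rate(st, c(500, 3500)), 10)
  # spikes outside the window are ignored
  expect_equal(firing_rate(c(100, st, 3900), c(500, 3500)), 10)
  expect_error(firing_rate(st, c(1000, 1000)), "range error")
})

test_that("mean membrane and mean peak potential", {
  expect_equal(mean_membrane_potential(rep(-70, 100)), -70)
  # duration-weighted concatenation
  a <- rnorm(300, -70); b <- rnorm(700, -60)
  expect_equal(mean_membrane_potential(c(a, b)),
               0.3 * mean(a) + 0.7 * mean(b))
  # streaming (one-pass) oracle vs the implementation on a long fixture
  set.seed(3)
  x <- rnorm(1e5, -65, 8)
  acc <- 0; for (chunk in split(x, rep(1:100, each = 1000)))
    acc <- acc + sum(chunk)
  expect_equal(mean_membrane_potential(x), acc / length(x))

  fx <- generate_fixture("spiky_trace", spike_times = c(100, 300, 700),
                         peak = 32, fs = 50000)
  st <- detect_spikes(fx$values, 1000 / fx$fs)
  expect_equal(mean_peak_potential(fx$values, st, 1000 / fx$fs), 32,
               tolerance = 1e-6)
  expect_true(is.na(mean_peak_potential(fx$values, numeric(0), 0.02)))
  # translation equivariance
  expect_equal(mean_peak_potential(fx$values + 5, st, 1000 / fx$fs),
               37, tolerance = 1e-6)
})

test_that("peak statistics of a current trace", {
  dt <- 0.02
  t <- seq(0, 1000 - dt, by = dt)
  spikes <- c(100, 250, 400, 600, 800)
  amps <- c(-2, -4, -6, -8, -10)
  cur <- numeric(length(t))
  for (i in seq_along(spikes))
    cur <- cur + amps[i] * exp(-((t - spikes[i]) / 0.5)^2)
  ps <- peak_stats(cur, spikes, dt)
  expect_equal(ps$peak_frequency, 5)       # 5 peaks over 1 s
  expect_equal(ps$peak_current, mean(abs(amps)), tolerance = 1e-6)
  # scaling the current doubles amplitude, preserves frequency
  ps2 <- peak_stats(2 * cur, spikes, dt)
  expect_equal(ps2$peak_frequency, 5)
  expect_equal(ps2$peak_current, 2 * ps$peak_current)
  # alignment audit: each search window contains exactly one extremum here
  z <- peak_stats(numeric(1000), numeric(0), dt)
  expect_equal(z$peak_frequency, 0)
  expect_true(is.na(z$peak_current))
})

test_that("IQR filter keeps the central half", {
  expect_equal(iqr_filter(1:8), 3:6)
  expect_equal(iqr_filter(rep(7, 10)), rep(7, 10))
  set.seed(9)
  x <- rnorm(41)
  kept <- iqr_filter(x)
  expect_true(all(kept %in% x))
  expect_equal(kept, x[x %in% kept])        # order-stable subset
  q <- quantile(x, c(.25, .75), type = 7, names = FALSE)
  expect_true(all(kept >= q[1] & kept <= q[2]))
  expect_error(iqr_filter(1:3), "size error")
})

test_that("rate-dopamine regression matches the normal-equations oracle", {
  # perfectly linear data
  fit <- rate_da_regression(c(0, 25, 50, 75, 100), 2 + 0.1 * c(0, 25, 50, 75, 100))
  expect_equal(fit$slope, 0.1)
  expect_equal(fit$intercept, 2)
  expect_equal(fit$r, 1)
  set.seed(11)
  x <- runif(40, 0, 100); y <- 1 + 0.05 * x + rnorm(40)
  fit <- rate_da_regression(x, y)
  # closed-form OLS via the normal equations
  xm <- cbind(1, x)
  beta <- solve(t(xm) %*% xm, t(xm) %*% y)
  expect_equal(fit$intercept, beta[1], tolerance = 1e-10)
  expect_equal(fit$slope, beta[2], tolerance = 1e-10)
  expect_equal(fit$r, cov(x, y) / (sd(x) * sd(y)), tolerance = 1e-12)
  # permutation invariance
  p <- sample(40)
  fit2 <- rate_da_regression(x[p], y[p])
  expect_equal(fit2$slope, fit$slope)
  expect_error(rate_da_regression(rep(50, 5), rnorm(5)), "singular")
})

test_that("current-voltage correlation and its degenerate cases", {
  set.seed(2)
  v <- rnorm(500)
  expect_equal(current_voltage_correlation(v, v), 1)
  expect_equal(current_voltage_correlation(-v, v), -1)
  i <- rnorm(500)
  # covariance-formula oracle
  r_oracle <- mean((i - mean(i)) * (v - mean(v))) /
    sqrt(mean((i - mean(i))^2) * mean((v - mean(v))^2))
  expect_equal(current_voltage_correlation(i, v), r_oracle, tolerance = 1e-12)
  expect_true(is.na(current_voltage_correlation(rep(1, 500), v)))
  expect_error(current_voltage_correlation(i[1:10], v), "alignment")
})
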
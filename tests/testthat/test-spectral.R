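# resampling, Welch PSD, STFT, dBm conversion, DiffRatio, delta-P, bands

test_that("resampling preserves in-band content and kills out-of-band", {
  fx <- generate_fixture("sinusoid", freq = 10, amp = 1, fs = 50000,
                         duration_s = 4)
  y <- resample_500hz(fx$values, 50000)
  expect_equal(length(y), 4 * 500)
  # amplitude preserved within 1% (compare RMS, ignoring filter edges)
  core <- y[200:1800]
  expect_equal(sqrt(mean(core^2)), 1 / sqrt(2), tolerance = 0.01)
  # 400 Hz component (above the 250 Hz output Nyquist) attenuated below 1%
  fx2 <- generate_fixture("sinusoid", freq = 400, amp = 1, fs = 50000,
                          duration_s = 4)
  y2 <- resample_500hz(fx2$values, 50000)
  expect_lt(sqrt(mean(y2[200:1800]^2)), 0.01)
  # DC passes exactly, and a non-integer factor errors
  expect_equal(resample_500hz(rep(3, 5000), 50000), rep(3, 50),
               tolerance = 1e-6)
  expect_error(resample_500hz(rnorm(100), 750), "rate error")
})

test_that("Welch PSD: grid geometry, peak location, Parseval audit", {
  fx <- generate_fixture("sinusoid", freq = 40, amp = 2, fs = 500,
                         duration_s = 30)
  psd <- compute_psd(fx$values)
  expect_length(psd$freq, 1024)
  expect_equal(psd$freq[1], 0)
  expect_lt(max(psd$freq), 250)
  expect_equal(psd$freq[2] - psd$freq[1], 500 / 2048)
  expect_equal(psd$freq[which.max(psd$power)], 40, tolerance = 0.25)
  # Parseval: integrated PSD matches the variance within 1 %
  set.seed(5)
  x <- rnorm(3e4)
  p <- compute_psd(x)
  df <- p$freq[2] - p$freq[1]
  expect_equal(sum(p$power) * df, var(x), tolerance = 0.01)
  # white noise is flat: band means agree across quarters within MC noise
  quarters <- split(p$power, cut(p$freq, 4))
  m <- vapply(quarters, mean, 0)
  expect_lt(max(m) / min(m), 1.15)
  expect_error(compute_psd(rnorm(100)), "length error")
})

test_that("pipeline linearity: scaling input scales PSD by c^2", {
  set.seed(6)
  x <- rnorm(5000)
  p1 <- compute_psd(x)
  p3 <- compute_psd(3 * x)
  expect_equal(p3$power, 9 * p1$power, tolerance = 1e-10)
  expect_equal(to_dbm(p3$power) - to_dbm(p1$power),
               rep(20 * log10(3), 1024), tolerance = 1e-9)
})

test_that("STFT window arithmetic and tone tracking", {
  fs <- 500
  x <- c(generate_fixture("sinusoid", freq = 20, fs = fs, duration_s = 2)$values,
         generate_fixture("sinusoid", freq = 80, fs = fs, duration_s = 2)$values)
  s <- stft(x, fs = fs)
  expect_equal(ncol(s$power), floor((length(x) - 50) / 25) + 1)
  expect_equal(nrow(s$power), 26)          # 0..250 Hz at 10 Hz spacing
  # dominant frequency switches at the junction (2000 ms) within one window
  peak_f <- s$freq[apply(s$power, 2, which.max)]
  before <- peak_f[s$t < 1900]
  after <- peak_f[s$t > 2100]
  expect_true(all(abs(before - 20) <= 10))
  expect_true(all(abs(after - 80) <= 10))
  # stationary tone: time-constant column profile
  s2 <- stft(generate_fixture("sinusoid", freq = 40, fs = fs,
                              duration_s = 3)$values, fs = fs)
  peaks <- apply(s2$power, 2, which.max)
  expect_equal(length(unique(peaks)), 1)
  expect_error(stft(rnorm(20), fs = fs), "length error")
})

test_that("dBm conversion", {
  expect_equal(to_dbm(1), 0)
  expect_equal(to_dbm(10), 10)
  expect_equal(to_dbm(0.5), 10 * log10(0.5))
  expect_equal(to_dbm(0.5), -3.0103, tolerance = 1e-4)
  expect_warning(out <- to_dbm(c(1, 0)), "floored")
  expect_equal(out[2], 10 * log10(.Machine$double.eps))
})

test_that("DiffRatio: self-comparison, strong separation, alpha monotonicity", {
  psds <- generate_fixture("white_noise_psds", n_trials = 4, seed = 2)
  # a group compared with itself: nothing significant
  self <- diff_ratio(psds, psds)
  expect_equal(self$diff_ratio, 0)
  expect_equal(self$n, 1024)
  # large mean offset, tiny variance: everything significant
  base <- do.call(rbind, lapply(psds, `[[`, "power"))
  sep <- diff_ratio(base, base * 1000)
  expect_gt(sep$diff_ratio, 0.99)
  # monotone nonincreasing in alpha
  a <- diff_ratio(psds[1:2], generate_fixture("white_noise_psds",
                                              n_trials = 2, seed = 3))
  for (al in c(0.2, 0.1, 0.05, 0.01)) {
    dr <- diff_ratio(psds[1:2], generate_fixture("white_noise_psds",
                                                 n_trials = 2, seed = 3),
                     alpha = al)$diff_ratio
    expect_lte(dr, diff_ratio(psds[1:2],
                              generate_fixture("white_noise_psds",
                                               n_trials = 2, seed = 3),
                              alpha = min(al * 2, 0.4))$diff_ratio)
  }
  expect_error(diff_ratio(base[, 1:100], base), "alignment")
})

test_that("per-frequency test is calibrated under the null", {
  # dBm values of independent Gaussian groups; empirical type-I error over
  # many repeats should sit near alpha = 0.1 (binomial CI check)
  set.seed(77)
  n_rep <- 40; nfreq <- 256; n1 <- n2 <- 5
  hits <- 0; total <- 0
  for (rep in seq_len(n_rep)) {
    a <- matrix(10^(rnorm(n1 * nfreq) / 10), n1, nfreq)
    b <- matrix(10^(rnorm(n2 * nfreq) / 10), n2, nfreq)
    dr <- diff_ratio(a, b, alpha = 0.1)
    hits <- hits + dr$n_diff; total <- total + dr$n
  }
  phat <- hits / total
  se <- sqrt(0.1 * 0.9 / total)
  # wide guard band: per-frequency p-values are not fully independent of
  # the Welch df correction, but calibration must hold to a few s.e.
  expect_gt(phat, 0.1 - 5 * se)
  expect_lt(phat, 0.1 + 5 * se)
})

test_that("delta-P difference maps", {
  psds <- generate_fixture("white_noise_psds", n_trials = 2, seed = 4)
  expect_equal(delta_p(psds[[1]], psds[[1]]), rep(0, 1024))
  p10 <- psds[[1]]; p10$power <- 10 * p10$power
  expect_equal(delta_p(p10, psds[[1]]), rep(10, 1024), tolerance = 1e-10)
  expect_equal(delta_p(psds[[1]], psds[[2]]),
               -delta_p(psds[[2]], psds[[1]]))
  expect_error(delta_p(psds[[1]]$power[1:10], psds[[1]]$power), "alignment")
})

test_that("band power over inclusive frequency bands", {
  psd <- compute_psd(generate_fixture("sinusoid", freq = 40, fs = 500,
                                      duration_s = 30)$values)
  expect_gt(band_power(psd, c(30, 50)), 50 * band_power(psd, c(50, 100)))
  flat <- psd; flat$power <- rep(2, 1024)
  expect_equal(band_power(flat, c(30, 100)), 2)
  expect_equal(band_power(flat, c(0, 250)), mean(flat$power))
  expect_error(band_power(psd, c(260, 270)), "range error")
})

test_that("LFP construction averages somata and resamples", {
  m <- generate_fixture("two_neuron_manifest")
  p <- simulation_protocol(duration = 600, da = dopamine_schedule("fixed", 50),
                           seed = 3)
  r <- run_trial(m, p)
  lfp <- make_lfp(r)
  expect_s3_class(lfp, "field_potential")
  expect_equal(lfp$fs, 500)
  # recording holds duration/dt + 1 samples, so the 500 Hz trace has
  # duration/2ms + 1 points
  expect_length(lfp$values, 301)
  # constant traces: mean of constants, unchanged by resampling
  r2 <- r
  r2$v[] <- -63
  lfp2 <- make_lfp(r2)
  expect_equal(mean(lfp2$values), -63, tolerance = 1e-6)
  expect_lt(diff(range(lfp2$values)), 1e-6)
  # permuting neuron order leaves the LFP unchanged
  r3 <- r
  r3$v <- r$v[, rev(seq_len(ncol(r$v)))]
  colnames(r3$v) <- rev(colnames(r$v))
  expect_equal(make_lfp(r3)$values, lfp$values)
})
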
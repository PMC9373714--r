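# Local field potential construction and spectral group statistics:
# resampling to 500 Hz, Welch power spectral densities on a 1024-point grid
# over 0-250 Hz, short-time Fourier transforms, dBm conversion, the
# per-frequency DiffRatio statistic, and dBm difference maps.

#' Construct the local field potential of one trial
#'
#' Mean of the somatic membrane potentials of all neurons in the recording,
#' resampled to 500 Hz.  The mean (rather than the sum) keeps values in mV
#' and makes the result invariant to the neuron count.
#'
#' @param recording a `recording` from [run_trial()], with all somatic
#'   voltages recorded at full rate.
#' @return object of class `field_potential`: list with `t` (ms), `values`
#'   (mV), and `fs` (500 Hz).
#' @export
make_lfp <- function(recording) {
  stopifnot(inherits(recording, "recording"))
  soma_cols <- grep("\\.soma$", colnames(recording$v))
  if (length(soma_cols) != nrow(recording$neurons))
    stop("completeness error: recording lacks somatic traces for all neurons")
  mean_v <- rowMeans(recording$v[, soma_cols, drop = FALSE])
  fs_in <- 1000 / recording$dt
  values <- resample_500hz(mean_v, fs_in)
  structure(list(t = seq_along(values) * 2 - 2, values = values, fs = 500),
            class = "field_potential")
}

#' Resample a trace to 500 Hz
#'
#' Anti-alias low-pass filtering followed by decimation, performed in
#' integer stages of at most 10.  Each stage applies an 8th-order
#' Butterworth low-pass (cutoff at 0.8 of the output Nyquist) forward and
#' backward (zero phase) over a reflection-padded copy of the signal, so a
#' constant trace passes through exactly and there are no start-up
#' transients.  The source rate must be an integer multiple of 500 Hz; the
#' default simulation step of 0.02 ms corresponds to 50 kHz and a total
#' factor of 100.
#'
#' @param x trace sampled at `fs_in`.
#' @param fs_in input sampling rate (Hz).
#' @return trace sampled at exactly 500 Hz.
#' @export
resample_500hz <- function(x, fs_in) {
  factor <- fs_in / 500
  if (abs(factor - round(factor)) > 1e-9)
    stop("rate error: source rate must be an integer multiple of 500 Hz")
  factor <- round(factor)
  if (factor == 1) return(x)
  remaining <- factor
  while (remaining > 1) {
    q <- if (remaining %% 10 == 0) 10
    else if (remaining %% 5 == 0) 5
    else if (remaining %% 2 == 0) 2
    else remaining
    bf <- signal::butter(4, 0.8 / q)          # filtfilt doubles the order
    n <- length(x)
    pad <- min(n - 1, 50 * q)
    left <- 2 * x[1] - x[(pad + 1):2]
    right <- 2 * x[n] - x[(n - 1):(n - pad)]
    xf <- signal::filtfilt(bf, c(left, x, right))
    x <- xf[pad + seq(1, n, by = q)]
    remaining <- remaining / q
  }
  x
}

#' Welch power spectral density on the 0-250 Hz grid
#'
#' The signal is demeaned, split into `nfft`-sample segments (default 2048)
#' with 50% overlap, Hann-windowed, and the squared transforms are averaged
#' with Parseval-consistent one-sided scaling.  At 500 Hz a 2048-point
#' transform yields exactly `N = 1024` one-sided grid points covering
#' 0-250 Hz.  A single-segment periodogram of the whole (zero-padded) trace
#' is available with `method = "periodogram"`.
#'
#' @param x signal at 500 Hz (a `field_potential` or numeric vector).
#' @param fs sampling rate (Hz).
#' @param nfft two-sided transform length.
#' @param method `"welch"` (default) or `"periodogram"`.
#' @param demean subtract the signal mean first (default `TRUE`).
#' @return object of class `psd_result`: list with `freq` (Hz, length
#'   `nfft/2`), `power` (W/Hz scale), `fs`, `nfft`.
#' @export
compute_psd <- function(x, fs = 500, nfft = 2048,
                        method = c("welch", "periodogram"), demean = TRUE) {
  if (inherits(x, "field_potential")) { fs <- x$fs; x <- x$values }
  method <- match.arg(method)
  n <- length(x)
  if (method == "welch" && n < nfft)
    stop("length error: signal shorter than one transform length (", nfft, ")")
  if (demean) x <- x - mean(x)
  win <- hann_window(nfft)
  u <- sum(win^2)
  if (method == "welch") {
    hop <- nfft / 2
    nseg <- floor((n - nfft) / hop) + 1
    acc <- numeric(nfft)
    for (s in seq_len(nseg)) {
      seg <- x[(s - 1) * hop + seq_len(nfft)] * win
      acc <- acc + Mod(stats::fft(seg))^2
    }
    pxx <- acc / (nseg * u * fs)
  } else {
    seg <- c(x, numeric(max(0, nfft - n)))
    if (length(seg) > nfft) seg <- seg[seq_len(nfft)]
    seg <- seg * win
    pxx <- Mod(stats::fft(seg))^2 / (u * fs)
  }
  half <- nfft / 2
  power <- pxx[seq_len(half)]
  power[-1] <- 2 * power[-1]  # one-sided doubling (not DC)
  structure(list(freq = (seq_len(half) - 1) * fs / nfft, power = power,
                 fs = fs, nfft = nfft),
            class = "psd_result")
}

hann_window <- function(n) 0.5 - 0.5 * cos(2 * pi * seq_len(n) / (n + 1))

#' Short-time Fourier transform
#'
#' 100 ms windows (50 samples at 500 Hz) with 50% overlap; each column is
#' the one-sided windowed periodogram of one segment, times are window
#' centers.  The number of windows is `floor((L - 50)/25) + 1`.
#'
#' @param x signal at 500 Hz (a `field_potential` or numeric vector).
#' @param fs sampling rate (Hz).
#' @param window_ms window length (ms).
#' @param overlap fractional overlap in `[0, 1)`.
#' @return list of class `stft_result`: `t` (ms, window centers), `freq`
#'   (Hz), `power` (freq x time matrix, W/Hz scale).
#' @export
stft <- function(x, fs = 500, window_ms = 100, overlap = 0.5) {
  if (inherits(x, "field_potential")) { fs <- x$fs; x <- x$values }
  nwin <- round(window_ms * fs / 1000)
  hop <- round(nwin * (1 - overlap))
  n <- length(x)
  if (n < nwin) stop("length error: signal shorter than one window")
  nseg <- floor((n - nwin) / hop) + 1
  win <- hann_window(nwin)
  u <- sum(win^2)
  half <- floor(nwin / 2) + 1
  out <- matrix(0, half, nseg)
  for (s in seq_len(nseg)) {
    seg <- x[(s - 1) * hop + seq_len(nwin)]
    seg <- (seg - mean(seg)) * win
    pxx <- Mod(stats::fft(seg))^2 / (u * fs)
    p <- pxx[seq_len(half)]
    p[2:(half - 1)] <- 2 * p[2:(half - 1)]
    out[, s] <- p
  }
  structure(list(t = ((seq_len(nseg) - 1) * hop + nwin / 2) * 1000 / fs,
                 freq = (seq_len(half) - 1) * fs / nwin, power = out),
            class = "stft_result")
}

#' Convert power to dBm/Hz
#'
#' \code{P_dBm = 10 log10(P_W)}, applied to the power spectral density value
#' as printed (no milliwatt reference rescaling).  Nonpositive values are
#' floored at machine epsilon with a warning.
#'
#' @param power_w power values (W/Hz scale).
#' @return dBm/Hz values.
#' @export
to_dbm <- function(power_w) {
  if (any(power_w <= 0)) {
    warning("nonpositive power floored to machine epsilon before log")
    power_w <- pmax(power_w, .Machine$double.eps)
  }
  10 * log10(power_w)
}

psd_group_matrix <- function(group) {
  if (inherits(group, "psd_result")) group <- list(group)
  if (is.list(group))
    group <- do.call(rbind, lapply(group, function(p) {
      stopifnot(inherits(p, "psd_result")); p$power
    }))
  group
}

#' Per-frequency group comparison and DiffRatio
#'
#' For each of the N frequency points, a two-sample t-test (Welch by
#' default) compares the dBm/Hz values of the two groups across trials;
#' frequencies with p below `alpha` (default 0.1) count as different, and
#' \code{DiffRatio = N_diff / N}.
#'
#' @param group_a,group_b lists of `psd_result`s (or trial x frequency
#'   matrices of power values) sharing one frequency grid.
#' @param alpha significance level.
#' @param var_equal use the pooled-variance test instead of Welch.
#' @return list of class `diff_summary`: `p` (per-frequency p-values),
#'   `n_diff`, `n`, `diff_ratio`, `alpha`.
#' @export
diff_ratio <- function(group_a, group_b, alpha = 0.1, var_equal = FALSE) {
  a <- psd_group_matrix(group_a); b <- psd_group_matrix(group_b)
  if (ncol(a) != ncol(b))
    stop("alignment error: groups are on different frequency grids")
  if (nrow(a) < 2L || nrow(b) < 2L)
    stop("need at least 2 spectra per group")
  da <- 10 * log10(pmax(a, .Machine$double.eps))
  db <- 10 * log10(pmax(b, .Machine$double.eps))
  n1 <- nrow(da); n2 <- nrow(db)
  m1 <- colMeans(da); m2 <- colMeans(db)
  v1 <- apply(da, 2, stats::var); v2 <- apply(db, 2, stats::var)
  if (var_equal) {
    sp <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se2 <- sp * (1 / n1 + 1 / n2)
    df <- rep(n1 + n2 - 2, length(se2))
  } else {
    se2 <- v1 / n1 + v2 / n2
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  tt <- (m1 - m2) / sqrt(se2)
  p <- 2 * stats::pt(-abs(tt), df)
  # identical groups give 0/0 -> NaN; no evidence of difference
  sig <- !is.na(p) & p < alpha
  structure(list(p = p, n_diff = sum(sig), n = ncol(a),
                 diff_ratio = sum(sig) / ncol(a), alpha = alpha),
            class = "diff_summary")
}

#' dBm/Hz difference map between two conditions
#'
#' \code{delta_P = P_dBm,DA - P_dBm,control = 10 log10(P_A / P_B)},
#' elementwise on aligned PSD vectors or STFT matrices.  Raw values are
#' returned; clipping to the conventional \[-20, 20\] display range is left
#' to plotting code.
#'
#' @param psd_a,psd_b `psd_result`s, `stft_result`s, or numeric
#'   arrays of power values on one grid.
#' @return difference in dBm/Hz, same shape as the inputs.
#' @export
delta_p <- function(psd_a, psd_b) {
  pa <- if (inherits(psd_a, "psd_result")) psd_a$power
        else if (inherits(psd_a, "stft_result")) psd_a$power else psd_a
  pb <- if (inherits(psd_b, "psd_result")) psd_b$power
        else if (inherits(psd_b, "stft_result")) psd_b$power else psd_b
  if (!identical(dim(pa), dim(pb)) || length(pa) != length(pb))
    stop("alignment error: power arrays differ in shape")
  10 * log10(pmax(pa, .Machine$double.eps) / pmax(pb, .Machine$double.eps))
}

#' Mean power in a frequency band
#'
#' Mean of the PSD values whose frequencies fall in `[lo, hi]` (inclusive);
#' the gamma band (30-100 Hz) and its 30-50 / 50-100 Hz sub-bands are the
#' conventional choices.
#'
#' @param psd a `psd_result`.
#' @param band `c(lo, hi)` in Hz.
#' @return mean power over the band.
#' @export
band_power <- function(psd, band) {
  stopifnot(inherits(psd, "psd_result"))
  sel <- psd$freq >= band[1] & psd$freq <= band[2]
  if (!any(sel)) stop("range error: band contains no grid points")
  mean(psd$power[sel])
}
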
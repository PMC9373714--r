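# Recording-level metrics: spike and burst detection, firing rates, mean
# membrane and peak potentials, peak-current statistics, IQR filtering,
# regression and current-voltage correlations.

#' Detect spikes in a voltage trace
#'
#' Upward threshold crossings with a refractory lockout.  The detection
#' threshold (default 0 mV) and 2 ms lockout are robust for Hodgkin-Huxley
#' spike shapes and are configuration-exposed.
#'
#' @param v uniformly sampled voltage trace (mV).
#' @param dt sample interval (ms).
#' @param threshold detection threshold (mV).
#' @param refractory lockout after each detection (ms).
#' @return increasing spike times (ms), with attribute `threshold`.
#' @export
detect_spikes <- function(v, dt, threshold = 0, refractory = 2) {
  up <- which(v[-1] > threshold & v[-length(v)] <= threshold)
  times <- up * dt   # first sample above threshold, 0-based time grid
  if (length(times) > 1L) {
    keep <- logical(length(times))
    last <- -Inf
    for (i in seq_along(times)) {
      if (times[i] - last >= refractory) { keep[i] <- TRUE; last <- times[i] }
    }
    times <- times[keep]
  }
  structure(times, threshold = threshold)
}

#' Detect bursts in a spike train
#'
#' A burst opens at spike i when the interspike interval to the next spike
#' is at most `open_isi` (40 ms); once open it extends while intervals stay
#' at or below `extend_isi` (100 ms) and closes at the first longer interval.
#' Single spikes never form a burst.
#'
#' @param times sorted spike times (ms).
#' @param open_isi maximal ISI that opens a burst (ms).
#' @param extend_isi maximal ISI that continues a burst (ms).
#' @return data.frame (class `burst_set`) with columns `start`, `end`
#'   (indices into `times`) and `n_spikes`; zero rows when no bursts.
#' @export
detect_bursts <- function(times, open_isi = 40, extend_isi = 100) {
  times <- as.numeric(times)
  n <- length(times)
  starts <- integer(0); ends <- integer(0)
  if (n >= 2L) {
    isi <- diff(times)
    i <- 1L
    while (i < n) {
      if (isi[i] <= open_isi) {
        j <- i + 1L
        while (j < n && isi[j] <= extend_isi) j <- j + 1L
        starts <- c(starts, i); ends <- c(ends, j)
        i <- j + 1L
      } else i <- i + 1L
    }
  }
  structure(data.frame(start = starts, end = ends,
                       n_spikes = ends - starts + 1L),
            class = c("burst_set", "data.frame"))
}

#' Firing rate over an analysis window
#'
#' @param times spike times (ms).
#' @param window `c(t0, t1)` in ms (default: the 500-3500 ms stimulus
#'   window).
#' @return rate in Hz.
#' @export
firing_rate <- function(times, window = c(500, 3500)) {
  if (diff(window) <= 0) stop("range error: window must have positive length")
  sum(times >= window[1] & times <= window[2]) / (diff(window) / 1000)
}

#' Mean membrane potential of a trace
#'
#' Arithmetic mean over the whole recorded period.
#'
#' @param v voltage trace (mV).
#' @return mean (mV).
#' @export
mean_membrane_potential <- function(v) mean(v)

#' Mean peak action potential
#'
#' For each spike, the local maximum of the voltage within +/- `half_window`
#' ms of the spike time; returns the mean over spikes, or `NA` for an empty
#' train.
#'
#' @param v voltage trace (mV).
#' @param times spike times (ms) detected on this trace.
#' @param dt sample interval (ms).
#' @param half_window search half-width (ms).
#' @return mean peak voltage (mV), or `NA_real_` when there are no spikes.
#' @export
mean_peak_potential <- function(v, times, dt, half_window = 2) {
  if (length(times) == 0L) return(NA_real_)
  n <- length(v)
  w <- round(half_window / dt)
  peaks <- vapply(times, function(tt) {
    i <- round(tt / dt) + 1L
    max(v[max(1L, i - w):min(n, i + w)])
  }, 0)
  mean(peaks)
}

#' Spike-aligned peak statistics of a current trace
#'
#' Each action potential is accompanied by a peak of the aligned current;
#' the per-spike extremum (largest absolute excursion within +/-
#' `half_window` ms) defines the peak, the count per second the peak
#' frequency, and the mean absolute extremum the peak current.
#'
#' @param current current trace aligned with the voltage trace.
#' @param times spike times (ms).
#' @param dt sample interval (ms).
#' @param duration duration over which to express the frequency (ms);
#'   defaults to the trace length.
#' @param half_window search half-width (ms).
#' @return list with `peak_frequency` (events/s) and `peak_current` (mean
#'   absolute peak amplitude; `NA` when there are no peaks).
#' @export
peak_stats <- function(current, times, dt, duration = length(current) * dt,
                       half_window = 2) {
  if (length(times) == 0L)
    return(list(peak_frequency = 0, peak_current = NA_real_))
  n <- length(current)
  w <- round(half_window / dt)
  peaks <- vapply(times, function(tt) {
    i <- round(tt / dt) + 1L
    seg <- current[max(1L, i - w):min(n, i + w)]
    seg[which.max(abs(seg))]
  }, 0)
  list(peak_frequency = length(peaks) / (duration / 1000),
       peak_current = mean(abs(peaks)))
}

#' Interquartile filter
#'
#' Keeps the values whose rank percentile lies in \[25%, 75%\] under the
#' linear-interpolation (type 7) percentile definition; order-stable.
#'
#' @param values numeric vector with at least 4 entries.
#' @return the retained values, in input order.
#' @export
iqr_filter <- function(values) {
  if (length(values) < 4L) stop("size error: need at least 4 values")
  q <- stats::quantile(values, c(0.25, 0.75), type = 7, names = FALSE)
  values[values >= q[1] & values <= q[2]]
}

#' Regression of firing rate on dopamine ratio
#'
#' Ordinary least squares of rate on the realised dopamine level, with the
#' Pearson correlation, as used after IQR-filtering the rates.
#'
#' @param da_ratio realised dopamine levels (percent).
#' @param rate firing rates (Hz), aligned with `da_ratio`.
#' @return list with `slope`, `intercept`, and `r`.
#' @export
rate_da_regression <- function(da_ratio, rate) {
  if (length(da_ratio) < 3L) stop("need at least 3 pairs")
  if (stats::var(da_ratio) == 0)
    stop("singular fit: dopamine ratios are degenerate")
  fit <- stats::lm(rate ~ da_ratio)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r = stats::cor(da_ratio, rate))
}

#' Correlation between a synaptic current and the membrane potential
#'
#' Pearson correlation over the analysis window; `NA` when either trace has
#' zero variance.
#'
#' @param current synaptic current trace.
#' @param v membrane potential trace, aligned with `current`.
#' @return Pearson r, or `NA_real_`.
#' @export
current_voltage_correlation <- function(current, v) {
  if (length(current) != length(v))
    stop("alignment error: traces differ in length")
  if (stats::sd(current) == 0 || stats::sd(v) == 0) return(NA_real_)
  stats::cor(current, v)
}
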
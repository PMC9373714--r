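# Deterministic fixture generation for tests and demos, and small helpers
# for building miniature network manifests in code.

#' Generate a deterministic test fixture
#'
#' Fixture kinds:
#' \describe{
#'   \item{`sinusoid`}{`list(t, values)`: sum of sinusoids sampled at `fs`;
#'     parameters `freq` (Hz, vector), `amp` (vector), `duration_s`, `fs`.}
#'   \item{`spike_train`}{the constructed burst-rule train
#'     `c(0, 30, 60, 200, 230, 400)` ms unless `times` is supplied.}
#'   \item{`spiky_trace`}{`list(t, values, spike_times)`: a subthreshold
#'     baseline with Gaussian spike transients of known peak at given times;
#'     parameters `spike_times`, `peak`, `baseline`, `fs`, `duration_s`.}
#'   \item{`white_noise_psds`}{list of `n_trials` `psd_result`s of Gaussian
#'     white noise (`sd`, `duration_s`, seeded), for null-calibration tests.}
#'   \item{`two_neuron_manifest`}{a miniature one-PYR + one-PV manifest with
#'     one glutamatergic and one GABAergic edge, for end-to-end tests.}
#' }
#'
#' @param kind fixture kind (see details).
#' @param seed integer seed; fixtures are fully deterministic under it.
#' @param ... kind-specific parameters overriding the defaults.
#' @return the fixture object.
#' @export
generate_fixture <- function(kind = c("sinusoid", "spike_train",
                                      "spiky_trace", "white_noise_psds",
                                      "two_neuron_manifest"),
                             seed = 1L, ...) {
  kind <- match.arg(kind)
  args <- list(...)
  switch(kind,
    sinusoid = {
      fs <- args$fs %||% 500
      dur <- args$duration_s %||% 10
      freq <- args$freq %||% 40
      amp <- args$amp %||% rep(1, length(freq))
      t <- seq(0, dur - 1 / fs, by = 1 / fs)
      values <- rowSums(mapply(function(f, a) a * sin(2 * pi * f * t),
                               freq, amp))
      list(t = t * 1000, values = values, fs = fs)
    },
    spike_train = args$times %||% c(0, 30, 60, 200, 230, 400),
    spiky_trace = {
      fs <- args$fs %||% 50000
      dur <- args$duration_s %||% 1
      baseline <- args$baseline %||% -70
      peak <- args$peak %||% 32
      st <- args$spike_times %||% c(100, 300, 700)
      t <- seq(0, dur * 1000 - 1000 / fs, by = 1000 / fs)
      v <- rep(baseline, length(t))
      for (s in st) v <- v + (peak - baseline) * exp(-((t - s) / 0.5)^2)
      list(t = t, values = v, spike_times = st, fs = fs)
    },
    white_noise_psds = {
      n_trials <- args$n_trials %||% 6
      dur <- args$duration_s %||% 20
      sd <- args$sd %||% 1
      with_seed(seed, lapply(seq_len(n_trials), function(i)
        compute_psd(stats::rnorm(dur * 500, sd = sd), fs = 500)))
    },
    two_neuron_manifest = {
      m <- list(
        populations = list(
          list(name = "pyr", region = "mPFC", kind = "PYR", count = 1L,
               stimulus = args$pyr_stim %||% c(1.0, 2.0)),
          list(name = "pv", region = "mPFC", kind = "PV", count = 1L,
               stimulus = args$pv_stim %||% c(0.2, 0.6))),
        edges = list(
          list(pre = "pyr", post = "pv", receptors = list("AMPA", "NMDA"),
               target = "soma"),
          list(pre = "pv", post = "pyr", receptors = list("GABAa"),
               target = "soma")),
        receptors = default_receptors(),
        stimulus_window = args$window %||% c(500, 3500))
      structure(m, class = "network_manifest")
    })
}

# Destexhe-type kinetic constants per receptor kind (single source for
# miniature manifests built in code; the shipped circuit manifest carries
# its own copy)
default_receptors <- function() {
  list(
    AMPA = list(g_max = 0.1, e_rev = 0, alpha = 1.1, beta = 0.19,
                t_max = 1, v_p = 2, k_p = 5),
    NMDA = list(g_max = 0.05, e_rev = 0, alpha = 0.072, beta = 0.0066,
                t_max = 1, v_p = 2, k_p = 5),
    GABAa = list(g_max = 0.2, e_rev = -80, alpha = 5, beta = 0.18,
                 t_max = 1, v_p = 2, k_p = 5))
}

#' Describe a neuron template as a table
#'
#' @param kind neuron kind (`"MSN"`, `"PYR"`, `"PV"`, `"CB"`).
#' @return data.frame with one row per compartment x channel.
#' @export
describe_template <- function(kind) {
  tpl <- build_template(kind)
  do.call(rbind, lapply(tpl$compartments, function(cc)
    data.frame(compartment = cc$name, length_um = cc$length,
               diameter_um = cc$diameter,
               channel = vapply(cc$channels, `[[`, "", "name"),
               mode = vapply(cc$channels, `[[`, "", "mode"),
               row.names = NULL)))
}
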
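# Fixed-step explicit Runge-Kutta 2(3) integration, trial orchestration
# with fully seeded randomness, and recording containers.

#' One fixed-size Bogacki-Shampine 2(3) step
#'
#' Advances `y` by `dt` with the explicit Runge-Kutta pair whose third-order
#' solution is propagated; the embedded second-order solution provides a
#' local error estimate returned as attribute `"err"`.  This is the same
#' tableau the compiled network core uses at fixed step.
#'
#' @param y state vector.
#' @param f derivative function `f(t, y)`.
#' @param dt step size.
#' @param t current time.
#' @return the state at `t + dt`, with attribute `err` (max-norm embedded
#'   error estimate).
#' @export
rk_step <- function(y, f, dt, t = 0) {
  k1 <- f(t, y)
  if (any(!is.finite(k1)))
    stop("numerical blowup: non-finite derivative in state ",
         which(!is.finite(k1))[1])
  k2 <- f(t + dt / 2, y + dt / 2 * k1)
  k3 <- f(t + 3 * dt / 4, y + 3 * dt / 4 * k2)
  ynew <- y + dt * (2 / 9 * k1 + 1 / 3 * k2 + 4 / 9 * k3)
  k4 <- f(t + dt, ynew)
  err <- dt * max(abs(-5 / 72 * k1 + 1 / 12 * k2 + 1 / 9 * k3 - 1 / 8 * k4))
  if (any(!is.finite(ynew)))
    stop("numerical blowup: non-finite state ", which(!is.finite(ynew))[1],
         " at t = ", t + dt)
  attr(ynew, "err") <- err
  ynew
}

#' Simulation protocol
#'
#' @param duration trial length (ms).
#' @param dt integration step (ms); the default 0.02 ms gives an effective
#'   50 kHz sampling of the membrane potential.
#' @param da a [dopamine_schedule()].
#' @param seed root integer seed; the per-trial (weights, stimulus, dopamine)
#'   seed tuple is derived from it so that a trial is fully reproducible.
#' @param record recording selection: list with `v` (`"somas"`, `"all"`, or
#'   compartment labels `"n3.soma"`), `channels` (channel labels
#'   `"n1.soma.KAs"`), and `synaptic` (data.frame with columns `comp` label
#'   and `type` in `exc`/`inh`).
#' @param record_stride store every n-th integration step (default 1 = full
#'   rate; spectral analysis requires full rate).
#' @param err_every compute the embedded error estimate every n-th step.
#' @return an object of class `simulation_protocol`.
#' @export
simulation_protocol <- function(duration = 4000, dt = 0.02,
                                da = dopamine_schedule("fixed", level = 100),
                                seed = 1L,
                                record = list(v = "somas"),
                                record_stride = 1L, err_every = 200L) {
  if (dt <= 0) stop("dt must be positive")
  nsteps <- duration / dt
  if (abs(nsteps - round(nsteps)) > 1e-8)
    stop("duration must be a whole number of steps")
  structure(list(duration = duration, dt = dt, da = da, seed = seed,
                 record = record, record_stride = as.integer(record_stride),
                 err_every = as.integer(err_every)),
            class = "simulation_protocol")
}

# derived, collision-free seed tuple per (condition, trial); kept < 2^31
trial_seeds <- function(root, condition = 1L, trial = 1L) {
  base <- (as.numeric(root) * 7919 + condition * 613 + trial * 17) %%
    2147480000
  list(weights = as.integer(base %% 2147480000) + 1L,
       stimulus = as.integer((base + 104729) %% 2147480000) + 1L,
       da = as.integer((base + 1299709) %% 2147480000) + 1L)
}

resolve_record <- function(cn, record) {
  v_sel <- record$v %||% "somas"
  rec_v <- if (identical(v_sel, "somas")) cn$soma_comp
  else if (identical(v_sel, "all")) seq_len(cn$ncomp) - 1L
  else {
    ix <- match(v_sel, cn$comp_names)
    if (anyNA(ix)) stop("unknown compartment label: ",
                        paste(v_sel[is.na(ix)], collapse = ", "))
    ix - 1L
  }
  rec_chan <- integer(0)
  if (!is.null(record$channels)) {
    ix <- match(record$channels, cn$c_label)
    if (anyNA(ix)) stop("unknown channel label: ",
                        paste(record$channels[is.na(ix)], collapse = ", "))
    rec_chan <- ix - 1L
  }
  rec_syn_comp <- integer(0); rec_syn_exc <- integer(0)
  if (!is.null(record$synaptic)) {
    ix <- match(record$synaptic$comp, cn$comp_names)
    if (anyNA(ix)) stop("unknown compartment label in synaptic record spec")
    rec_syn_comp <- ix - 1L
    rec_syn_exc <- as.integer(record$synaptic$type == "exc")
  }
  list(v = as.integer(rec_v), chan = as.integer(rec_chan),
       syn_comp = as.integer(rec_syn_comp), syn_exc = as.integer(rec_syn_exc),
       v_names = cn$comp_names[rec_v + 1L],
       chan_names = cn$c_label[rec_chan + 1L],
       syn_names = if (length(rec_syn_comp))
         paste0(cn$comp_names[rec_syn_comp + 1L], ".",
                ifelse(rec_syn_exc == 1L, "exc", "inh")) else character(0))
}

#' Run one simulation trial
#'
#' Rebuilds the connection weights under the trial's weight seed, samples the
#' dopamine level once from the protocol's schedule, applies the modulation
#' rules, compiles the network, and integrates it with the compiled
#' fixed-step Runge-Kutta 2(3) core.  The trial is bitwise reproducible from
#' `(protocol$seed, condition, trial)`.
#'
#' @param manifest a `network_manifest` (or a `da_network`, whose manifest is
#'   reused).
#' @param protocol a [simulation_protocol()].
#' @param trial trial index (enters the seed derivation).
#' @param condition condition index (enters the seed derivation).
#' @param rules dopamine modulation rules (default: shipped rules).
#' @return an object of class `recording`: time grid, voltage/current traces,
#'   spike times per neuron, and trial metadata.
#' @export
run_trial <- function(manifest = load_manifest(),
                      protocol = simulation_protocol(),
                      trial = 1L, condition = 1L,
                      rules = load_dopamine_rules()) {
  if (inherits(manifest, "da_network")) manifest <- manifest$manifest
  seeds <- trial_seeds(protocol$seed, condition, trial)
  net <- build_network(manifest, weight_seed = seeds$weights)
  k <- with_seed(seeds$da, sample_da_level(protocol$da))
  net <- apply_modulation(net, k, rules)
  cn <- compile_network(net)
  rec <- resolve_record(cn, protocol$record)
  out <- core_run(cn, protocol$duration, protocol$dt, seeds$stimulus,
                  protocol$record_stride, rec$v, rec$chan, rec$syn_comp,
                  rec$syn_exc, protocol$err_every)
  colnames(out$v) <- rec$v_names
  if (length(rec$chan_names)) colnames(out$channel) <- rec$chan_names
  if (length(rec$syn_names)) colnames(out$synaptic) <- rec$syn_names
  dt_rec <- protocol$dt * protocol$record_stride
  soma_cols <- match(cn$comp_names[cn$soma_comp + 1L], rec$v_names)
  spikes <- vector("list", cn$nneuron)
  for (i in seq_len(cn$nneuron)) {
    spikes[[i]] <- if (is.na(soma_cols[i])) numeric(0)
    else detect_spikes(out$v[, soma_cols[i]], dt_rec)
  }
  structure(list(t = out$t, v = out$v, channel = out$channel,
                 synaptic = out$synaptic, spikes = spikes,
                 dt = dt_rec, duration = protocol$duration,
                 da_level = k, seeds = seeds, trial = trial,
                 condition = condition, err_max = out$err_max,
                 neurons = net$neurons,
                 stim_window = c(cn$stim_on, cn$stim_off)),
            class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat("recording:", x$duration, "ms,", nrow(x$v), "samples,",
      ncol(x$v), "voltage traces, DA =", round(x$da_level, 2), "%\n")
  cat("spikes per neuron:", paste(vapply(x$spikes, length, 1L),
                                  collapse = " "), "\n")
  invisible(x)
}

#' Run a full experiment design
#'
#' `"quartiles"` runs the four random dopamine gradient ranges (0-25, 25-50,
#' 50-75, 75-100%) with 3 trials each; `"fixed5"` runs the five fixed levels
#' (MDD 0, low 25, medium 50, high 75, normal 100%) with 6 trials each.
#' Condition x trial cells get independent derived seed tuples; a failed
#' cell is recorded in the ledger without aborting the rest.
#'
#' @param design `"quartiles"` or `"fixed5"`, or a list of
#'   [dopamine_schedule()]s for a custom design.
#' @param manifest network manifest.
#' @param trials trials per condition (defaults: 3 for quartiles, 6 for
#'   fixed5).
#' @param seed root seed.
#' @param protocol base protocol; its `da` and `seed` fields are overridden
#'   per cell.
#' @return list with `recordings` (list of `recording` or `NULL` for failed
#'   cells) and `ledger` (data.frame of condition, trial, seeds, DA level,
#'   status).
#' @export
run_experiment <- function(design = c("quartiles", "fixed5"),
                           manifest = load_manifest(), trials = NULL,
                           seed = 1L, protocol = simulation_protocol()) {
  if (is.character(design)) {
    design <- match.arg(design)
    schedules <- switch(design,
      quartiles = lapply(list(c(0, 25), c(25, 50), c(50, 75), c(75, 100)),
                         function(rg) dopamine_schedule("uniform_range",
                                                        range = rg)),
      fixed5 = lapply(c(0, 25, 50, 75, 100),
                      function(l) dopamine_schedule("fixed", level = l)))
    if (is.null(trials)) trials <- if (design == "quartiles") 3L else 6L
  } else {
    schedules <- design
    if (is.null(trials)) trials <- 3L
  }
  recordings <- list(); ledger <- list()
  for (ci in seq_along(schedules)) for (ti in seq_len(trials)) {
    p <- protocol; p$da <- schedules[[ci]]; p$seed <- seed
    res <- tryCatch(run_trial(manifest, p, trial = ti, condition = ci),
                    error = function(e) e)
    ok <- inherits(res, "recording")
    recordings[[length(recordings) + 1L]] <- if (ok) res else NULL
    sd <- trial_seeds(seed, ci, ti)
    ledger[[length(ledger) + 1L]] <- data.frame(
      condition = ci, trial = ti, weight_seed = sd$weights,
      stimulus_seed = sd$stimulus, da_seed = sd$da,
      da_level = if (ok) res$da_level else NA_real_,
      status = if (ok) "ok" else conditionMessage(res))
  }
  list(recordings = recordings, ledger = do.call(rbind, ledger))
}
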
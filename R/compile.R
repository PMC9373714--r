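# Flattening of a da_network into the numeric arrays the compiled
# integration core consumes, plus a pure-R reference evaluation of the same
# full-network derivative (used to cross-check the core on small problems).

#' Compile a network into the integrator's flat representation
#'
#' Expands every neuron's template into per-compartment, per-gate,
#' per-channel and per-pool arrays, converts the Rall coupling conductances
#' to mS/cm^2, resolves synaptic edges to compartment indices, and computes
#' the initial state (voltages at `v_init`, gates at their steady state,
#' receptors closed, pools at their initial calcium).  Dopamine modulation
#' must be applied *before* compiling.  All cross-references are 0-based for
#' the compiled core; the state vector is laid out as
#' `[V | gates | receptors | calcium]`.
#'
#' @param network a `da_network`.
#' @return a list of flat arrays (class `compiled_network`); element
#'   `state0` is the initial state vector, `state_names` labels it.
#' @keywords internal
#' @export
compile_network <- function(network) {
  stopifnot(inherits(network, "da_network"))
  neurons <- network$neurons
  nn <- nrow(neurons)

  env <- new.env(parent = emptyenv())
  env$cm <- numeric(0); env$v0 <- numeric(0); env$comp_names <- character(0)
  env$neuron_of_comp <- integer(0); env$soma_comp <- integer(nn)
  env$cpl_a <- integer(0); env$cpl_b <- integer(0); env$cpl_g <- numeric(0)
  env$g_comp <- integer(0); env$g_kind <- integer(0); env$g_vh <- numeric(0)
  env$g_sl <- numeric(0); env$g_tau <- numeric(0); env$g_kd <- numeric(0)
  env$g_hill <- numeric(0); env$g_pool <- integer(0)
  env$g_bp_v <- numeric(0); env$g_bp_t <- numeric(0); env$g_off <- 0L
  env$gate0 <- numeric(0)
  env$c_comp <- integer(0); env$c_mode <- integer(0); env$c_g <- numeric(0)
  env$c_e <- numeric(0); env$c_a <- numeric(0); env$c_pmax <- numeric(0)
  env$c_act <- integer(0); env$c_inact <- integer(0)
  env$c_actp <- integer(0); env$c_inactp <- integer(0)
  env$c_pool <- integer(0); env$c_label <- character(0)
  env$p_comp <- integer(0); env$p_ca0 <- numeric(0); env$p_d <- numeric(0)
  env$p_kt <- numeric(0); env$p_kd <- numeric(0); env$p_taur <- numeric(0)
  env$p_k <- numeric(0); env$p_p <- numeric(0); env$p_rest <- numeric(0)

  add_gate <- function(gate, comp0, pool0, v_init, ca0) {
    env$g_comp <- c(env$g_comp, comp0)
    if (gate$kind == "ca") {
      if (pool0 < 0L) stop("ca-gated channel in a compartment without a pool")
      env$g_kind <- c(env$g_kind, 1L)
      env$g_vh <- c(env$g_vh, 0); env$g_sl <- c(env$g_sl, 1)
      env$g_kd <- c(env$g_kd, gate$kd); env$g_hill <- c(env$g_hill, gate$hill)
      env$g_pool <- c(env$g_pool, pool0)
      cah <- ca0^gate$hill
      env$gate0 <- c(env$gate0, cah / (cah + gate$kd^gate$hill))
    } else {
      env$g_kind <- c(env$g_kind, 0L)
      env$g_vh <- c(env$g_vh, gate$v_half); env$g_sl <- c(env$g_sl, gate$slope)
      env$g_kd <- c(env$g_kd, 0); env$g_hill <- c(env$g_hill, 0)
      env$g_pool <- c(env$g_pool, -1L)
      env$gate0 <- c(env$gate0, steady_state_gate(v_init, gate))
    }
    last_off <- env$g_off[length(env$g_off)]
    if (is.null(gate$tau_table)) {
      env$g_tau <- c(env$g_tau, gate$tau)
      env$g_off <- c(env$g_off, last_off)
    } else {
      env$g_tau <- c(env$g_tau, -1)
      env$g_bp_v <- c(env$g_bp_v, gate$tau_table[, 1L])
      env$g_bp_t <- c(env$g_bp_t, gate$tau_table[, 2L])
      env$g_off <- c(env$g_off, last_off + nrow(gate$tau_table))
    }
    length(env$g_comp) - 1L
  }

  comp_index <- vector("list", nn)
  for (ni in seq_len(nn)) {
    tpl <- network$templates[[neurons$kind[ni]]]
    base <- length(env$cm)
    idx <- stats::setNames(base + seq_along(tpl$compartments) - 1L,
                           vapply(tpl$compartments, `[[`, "", "name"))
    comp_index[[ni]] <- idx
    for (ci in seq_along(tpl$compartments)) {
      cc <- tpl$compartments[[ci]]
      comp0 <- base + ci - 1L
      env$cm <- c(env$cm, cc$c_m); env$v0 <- c(env$v0, cc$v_init)
      env$comp_names <- c(env$comp_names, paste0("n", ni, ".", cc$name))
      env$neuron_of_comp <- c(env$neuron_of_comp, ni - 1L)
      if (cc$name == "soma") env$soma_comp[ni] <- comp0
      pool0 <- -1L
      if (!is.null(cc$ca_pool)) {
        pool0 <- length(env$p_comp)
        pl <- cc$ca_pool
        env$p_comp <- c(env$p_comp, comp0); env$p_ca0 <- c(env$p_ca0, pl$ca_in)
        env$p_d <- c(env$p_d, pl$shell_depth); env$p_kt <- c(env$p_kt, pl$k_t)
        env$p_kd <- c(env$p_kd, pl$k_d); env$p_taur <- c(env$p_taur, pl$tau_r)
        env$p_k <- c(env$p_k, pl$scale_k); env$p_p <- c(env$p_p, pl$pump_p)
        env$p_rest <- c(env$p_rest, pl$ca_rest)
      }
      ca0 <- if (pool0 >= 0L) env$p_ca0[pool0 + 1L] else 0.001
      for (ch in cc$channels) {
        if (ch$mode == "ghk" && pool0 < 0L)
          stop("GHK channel '", ch$name, "' needs a calcium pool in ", cc$name)
        ai <- if (is.null(ch$activation)) -1L else
          add_gate(ch$activation, comp0, pool0, cc$v_init, ca0)
        hi <- if (is.null(ch$inactivation)) -1L else
          add_gate(ch$inactivation, comp0, pool0, cc$v_init, ca0)
        env$c_comp <- c(env$c_comp, comp0)
        env$c_mode <- c(env$c_mode,
                        match(ch$mode, c("ohmic", "partial", "ghk")) - 1L)
        env$c_g <- c(env$c_g,
                     if (is.null(ch$g_max) || !is.finite(ch$g_max)) 0
                     else ch$g_max)
        env$c_e <- c(env$c_e, if (is.finite(ch$e_rev)) ch$e_rev else 0)
        env$c_a <- c(env$c_a,
                     if (is.null(ch$partial_fraction)) 1 else ch$partial_fraction)
        env$c_pmax <- c(env$c_pmax, if (is.finite(ch$p_max)) ch$p_max else 0)
        env$c_act <- c(env$c_act, ai); env$c_inact <- c(env$c_inact, hi)
        env$c_actp <- c(env$c_actp,
                        if (is.null(ch$activation)) 0L else ch$activation$power)
        env$c_inactp <- c(env$c_inactp,
                          if (is.null(ch$inactivation)) 0L else
                            ch$inactivation$power)
        env$c_pool <- c(env$c_pool, pool0)
        env$c_label <- c(env$c_label, paste0("n", ni, ".", cc$name, ".",
                                             ch$name))
      }
    }
    adj <- tpl$adjacency
    if (nrow(adj)) for (ri in seq_len(nrow(adj))) {
      a <- tpl$compartments[[adj[ri, 1L]]]
      b <- tpl$compartments[[adj[ri, 2L]]]
      ia <- base + adj[ri, 1L] - 1L; ib <- base + adj[ri, 2L] - 1L
      env$cpl_a <- c(env$cpl_a, ia, ib); env$cpl_b <- c(env$cpl_b, ib, ia)
      env$cpl_g <- c(env$cpl_g,
                     COUPLING_UNIT * coupling_conductance(a, b),
                     COUPLING_UNIT * coupling_conductance(b, a))
    }
  }

  # synaptic edges -> compartment indices; "spine" targets are distributed
  # round-robin over the postsynaptic cell's spine compartments
  ed <- network$edges
  ne <- if (is.null(ed)) 0L else nrow(ed)
  e_pre_comp <- integer(ne); e_post_comp <- integer(ne); e_kind <- integer(ne)
  e_g <- numeric(ne); e_e <- numeric(ne); e_alpha <- numeric(ne)
  e_beta <- numeric(ne); e_tmax <- numeric(ne); e_vp <- numeric(ne)
  e_kp <- numeric(ne); e_w <- numeric(ne)
  spine_counter <- integer(nn)
  if (ne) for (i in seq_len(ne)) {
    pre <- ed$pre[i]; post <- ed$post[i]
    idx <- comp_index[[post]]
    tgt <- ed$target[i]
    if (tgt %in% names(idx)) {
      e_post_comp[i] <- idx[[tgt]]
    } else {
      cand <- grep(paste0("^", tgt, "(_[0-9]+)?$"), names(idx), value = TRUE)
      if (!length(cand))
        stop("configuration error: target compartment '", tgt,
             "' missing on neuron ", post)
      spine_counter[post] <- spine_counter[post] %% length(cand) + 1L
      e_post_comp[i] <- idx[[cand[spine_counter[post]]]]
    }
    e_pre_comp[i] <- env$soma_comp[pre]
    e_kind[i] <- match(ed$kind[i], c("AMPA", "NMDA", "GABAa")) - 1L
    e_g[i] <- ed$g_max[i]; e_e[i] <- ed$e_rev[i]
    e_alpha[i] <- ed$alpha[i]; e_beta[i] <- ed$beta[i]
    e_tmax[i] <- ed$t_max[i]; e_vp[i] <- ed$v_p[i]; e_kp[i] <- ed$k_p[i]
    e_w[i] <- ed$weight[i]
  }

  ncomp <- length(env$cm); ngate <- length(env$g_comp)
  npool <- length(env$p_comp)
  state_names <- c(paste0("V.", env$comp_names),
                   if (ngate) paste0("gate.", seq_len(ngate) - 1L),
                   if (ne) paste0("r.", seq_len(ne) - 1L),
                   if (npool) paste0("ca.", env$comp_names[env$p_comp + 1L]))
  stim <- network$stimulus[neurons$population]
  comp <- list(
    nneuron = nn, ncomp = ncomp, ngate = ngate, nedge = ne, npool = npool,
    cm = env$cm, neuron_of_comp = env$neuron_of_comp,
    soma_comp = env$soma_comp, comp_names = env$comp_names,
    cpl_a = env$cpl_a, cpl_b = env$cpl_b, cpl_g = env$cpl_g,
    g_comp = env$g_comp, g_kind = env$g_kind, g_vh = env$g_vh,
    g_sl = env$g_sl, g_tau = env$g_tau, g_off = env$g_off,
    g_bp_v = env$g_bp_v, g_bp_t = env$g_bp_t,
    g_kd = env$g_kd, g_hill = env$g_hill, g_pool = env$g_pool,
    c_comp = env$c_comp, c_mode = env$c_mode, c_g = env$c_g, c_e = env$c_e,
    c_a = env$c_a, c_pmax = env$c_pmax, c_act = env$c_act,
    c_inact = env$c_inact, c_actp = env$c_actp, c_inactp = env$c_inactp,
    c_pool = env$c_pool, c_label = env$c_label,
    p_comp = env$p_comp, p_d = env$p_d, p_kt = env$p_kt, p_kd = env$p_kd,
    p_taur = env$p_taur, p_k = env$p_k, p_p = env$p_p, p_rest = env$p_rest,
    ghk_z = 2, ghk_f = 96489, ghk_rt = 8.31 * 308.15, ghk_ca_out = 5,
    e_pre_comp = e_pre_comp, e_post_comp = e_post_comp, e_kind = e_kind,
    e_g = e_g, e_e = e_e, e_alpha = e_alpha, e_beta = e_beta,
    e_tmax = e_tmax, e_vp = e_vp, e_kp = e_kp, e_w = e_w,
    stim_min = vapply(stim, function(s) s$interval[1], 0),
    stim_max = vapply(stim, function(s) s$interval[2], 0),
    stim_on = if (nn) stim[[1]]$window[1] else 500,
    stim_off = if (nn) stim[[1]]$window[2] else 3500,
    state0 = c(env$v0, env$gate0, numeric(ne), env$p_ca0),
    state_names = state_names,
    neuron_kind = neurons$kind, neuron_region = neurons$region)
  class(comp) <- "compiled_network"
  comp
}

# gate tau lookup on the compiled arrays (vector over gates)
compiled_gate_tau <- function(cn, i, v) {
  if (cn$g_tau[i] > 0) return(cn$g_tau[i])
  lo <- cn$g_off[i] + 1L; hi <- cn$g_off[i + 1L]
  stats::approx(cn$g_bp_v[lo:hi], cn$g_bp_t[lo:hi], xout = v, rule = 2)$y
}

#' Reference full-network derivative in pure R
#'
#' Evaluates the complete coupled ODE right-hand side (voltages, gates,
#' receptors, calcium pools) on the compiled arrays using the package's
#' scalar operations.  Intended for validating the compiled core on small
#' networks; it is far too slow for production runs.
#'
#' @param cn a `compiled_network`.
#' @param state state vector (layout `[V | gates | r | ca]`).
#' @param stim per-neuron stimulus currents (uA/cm^2), applied at somas.
#' @return derivative vector of the same length.
#' @keywords internal
#' @export
network_derivative_r <- function(cn, state, stim) {
  nv <- cn$ncomp; ng <- cn$ngate; ne <- cn$nedge; np <- cn$npool
  v <- state[seq_len(nv)]
  gates <- state[nv + seq_len(ng)]
  r <- if (ne) state[nv + ng + seq_len(ne)] else numeric(0)
  ca <- if (np) state[nv + ng + ne + seq_len(np)] else numeric(0)
  i_ion <- numeric(nv); i_syn <- numeric(nv); i_cpl <- numeric(nv)
  i_ca_pool <- numeric(np)
  dgate <- numeric(ng)
  for (i in seq_len(ng)) {
    ci <- cn$g_comp[i] + 1L
    if (cn$g_kind[i] == 1L) {
      cah <- ca[cn$g_pool[i] + 1L]^cn$g_hill[i]
      minf <- cah / (cah + cn$g_kd[i]^cn$g_hill[i])
    } else {
      minf <- 1 / (1 + exp((v[ci] - cn$g_vh[i]) / cn$g_sl[i]))
    }
    dgate[i] <- (minf - gates[i]) / compiled_gate_tau(cn, i, v[ci])
  }
  ghk <- ghk_params()
  for (i in seq_along(cn$c_comp)) {
    ci <- cn$c_comp[i] + 1L
    m <- if (cn$c_act[i] >= 0L) gates[cn$c_act[i] + 1L] else 1
    h <- if (cn$c_inact[i] >= 0L) gates[cn$c_inact[i] + 1L] else 1
    mx <- m^cn$c_actp[i]; hy <- h^cn$c_inactp[i]
    cur <- if (cn$c_mode[i] == 0L) {
      cn$c_g[i] * mx * hy * (v[ci] - cn$c_e[i])
    } else if (cn$c_mode[i] == 1L) {
      a <- cn$c_a[i]
      cn$c_g[i] * mx * (a * h - (1 - a)) * (v[ci] - cn$c_e[i])
    } else {
      pi0 <- cn$c_pool[i] + 1L
      ghk_current(cn$c_pmax[i] * mx * hy, v[ci], ca[pi0], ghk)
    }
    i_ion[ci] <- i_ion[ci] + cur
    if (cn$c_mode[i] == 2L) {
      pi0 <- cn$c_pool[i] + 1L
      i_ca_pool[pi0] <- i_ca_pool[pi0] + cur
    }
  }
  dr <- numeric(ne)
  for (i in seq_len(ne)) {
    vpre <- v[cn$e_pre_comp[i] + 1L]; vpost <- v[cn$e_post_comp[i] + 1L]
    tt <- cn$e_tmax[i] / (1 + exp(-(vpre - cn$e_vp[i]) / cn$e_kp[i]))
    dr[i] <- cn$e_alpha[i] * tt * (1 - r[i]) - cn$e_beta[i] * r[i]
    cur <- cn$e_w[i] * cn$e_g[i] * r[i] * (vpost - cn$e_e[i])
    if (cn$e_kind[i] == 1L) cur <- cur * mg_block(vpost)
    pc <- cn$e_post_comp[i] + 1L
    i_syn[pc] <- i_syn[pc] + cur
  }
  for (i in seq_along(cn$cpl_a)) {
    a <- cn$cpl_a[i] + 1L; b <- cn$cpl_b[i] + 1L
    i_cpl[a] <- i_cpl[a] + cn$cpl_g[i] * (v[a] - v[b])
  }
  i_stim <- numeric(nv)
  i_stim[cn$soma_comp + 1L] <- stim
  dv <- (i_stim - i_ion - i_cpl - i_syn) / cn$cm
  dca <- numeric(np)
  for (i in seq_len(np)) {
    influx <- cn$p_k[i] * (-(i_ca_pool[i] * 1e-3)) /
      (2 * cn$ghk_f * cn$p_d[i])
    pump <- cn$p_p[i] * cn$p_kt[i] * ca[i] / (ca[i] + cn$p_kd[i])
    dca[i] <- influx - pump + (cn$p_rest[i] - ca[i]) / cn$p_taur[i]
  }
  c(dv, dgate, dr, dca)
}
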
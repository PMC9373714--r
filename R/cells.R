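# Neuron templates: compartment geometry, channel complements, Rall-type
# coupling between compartments, and the per-compartment membrane equation.

#' Define one compartment of a neuron template
#'
#' @param name compartment name (`"soma"`, `"proximal"`, `"distal"`,
#'   `"spine_1"`, ...).
#' @param length compartment length (um).
#' @param diameter compartment diameter (um).
#' @param c_m specific membrane capacitance (uF/cm^2).
#' @param r_l axial resistivity (Ohm cm).
#' @param channels list of [channel_spec()]s.
#' @param ca_pool a [calcium_pool()] or `NULL`.
#' @param v_init initial membrane voltage (mV).
#' @return an object of class `compartment_spec`.
#' @export
compartment_spec <- function(name, length, diameter, c_m = 1, r_l = 150,
                             channels = list(), ca_pool = NULL,
                             v_init = -70) {
  if (any(c(length, diameter, c_m, r_l) <= 0))
    stop("length, diameter, c_m and r_l must all be positive")
  structure(list(name = name, length = length, diameter = diameter,
                 c_m = c_m, r_l = r_l, channels = channels,
                 ca_pool = ca_pool, v_init = v_init),
            class = "compartment_spec")
}

#' Rall-type coupling conductance between two adjacent compartments
#'
#' Directional form
#' \deqn{g_{a \leftarrow b} = \frac{d_a d_b^2}
#'       {r_L l_a (d_a^2 l_b + d_b^2 l_a)}}
#' for compartment `a` receiving current from `b`; the coupling current into
#' `a` is \code{g (V_a - V_b)} (outward positive).  The value is returned in
#' the raw units of the formula; with d, l in um and `r_l` in Ohm cm,
#' multiplying by 1e7 yields mS/cm^2 of the receiving compartment's membrane
#' (the conversion the network compiler applies).  For identical compartments
#' this reduces to \code{d / (2 r_l l^2)}.
#'
#' @param a receiving [compartment_spec()].
#' @param b sending [compartment_spec()].
#' @param r_l axial resistivity (Ohm cm); defaults to the receiver's.
#' @return raw coupling conductance (see details).
#' @export
coupling_conductance <- function(a, b, r_l = a$r_l) {
  stopifnot(inherits(a, "compartment_spec"), inherits(b, "compartment_spec"))
  (a$diameter * b$diameter^2) /
    (r_l * a$length * (a$diameter^2 * b$length + b$diameter^2 * a$length))
}

# raw -> mS/cm^2 for lengths in um and r_l in Ohm*cm
COUPLING_UNIT <- 1e7

#' Membrane potential derivative of one compartment
#'
#' Current balance \code{C_m dV/dt + sum(I_ion) + sum(I_compartment) +
#' sum(I_synapse) = I_stimuli}, i.e.
#' \code{dV/dt = (I_stimuli - sum(I_ion) - sum(I_compartment) -
#' sum(I_synapse)) / C_m}.  All currents are densities (uA/cm^2, outward
#' positive except the stimulus, which depolarises when positive).
#'
#' @param c_m specific capacitance (uF/cm^2).
#' @param i_stimulus stimulus current (uA/cm^2).
#' @param i_ion summed ionic currents (uA/cm^2).
#' @param i_compartment summed coupling currents (uA/cm^2).
#' @param i_synapse summed synaptic currents (uA/cm^2).
#' @return dV/dt in mV/ms.
#' @export
membrane_derivative <- function(c_m, i_stimulus = 0, i_ion = 0,
                                i_compartment = 0, i_synapse = 0) {
  (i_stimulus - i_ion - i_compartment - i_synapse) / c_m
}

param_file <- function(name) {
  path <- system.file("extdata", "params", name, package = "dacircuit")
  if (!nzchar(path))
    stop("configuration error: parameter file '", name, "' not found")
  path
}

parse_gate <- function(g) {
  if (is.null(g)) return(NULL)
  tau <- g$tau
  if (is.list(tau)) tau <- cbind(unlist(tau$v), unlist(tau$tau))
  gate_spec(power = g$power,
            v_half = if (is.null(g$v_half)) NA_real_ else g$v_half,
            slope = if (is.null(g$slope)) NA_real_ else g$slope,
            tau = tau,
            role = if (is.null(g$role)) "activation" else g$role,
            kind = if (is.null(g$kind)) "v" else g$kind,
            kd = if (is.null(g$kd)) NA_real_ else g$kd,
            hill = if (is.null(g$hill)) 2 else g$hill)
}

# density entries in the YAML are either a scalar or a map keyed by
# compartment base name (spine_3 matches key "spine")
density_for <- function(entry, comp_name) {
  if (is.null(entry)) return(NULL)
  if (!is.list(entry)) return(entry)
  base <- sub("_[0-9]+$", "", comp_name)
  val <- entry[[base]]
  if (is.null(val)) val <- entry[[comp_name]]
  val
}

parse_channel <- function(name, def, comp_name) {
  mode <- if (is.null(def$mode)) "ohmic" else def$mode
  act <- parse_gate(def$activation)
  if (!is.null(act)) act$role <- "activation"
  inact <- parse_gate(def$inactivation)
  if (!is.null(inact)) inact$role <- "inactivation"
  if (mode == "ghk") {
    p <- density_for(def$p_max, comp_name)
    if (is.null(p)) return(NULL)
    channel_spec(name, mode = "ghk", activation = act, inactivation = inact,
                 ghk = ghk_params(), p_max = p)
  } else {
    g <- density_for(def$g_max, comp_name)
    if (is.null(g)) return(NULL)
    channel_spec(name, g_max = g, e_rev = def$e_rev, activation = act,
                 inactivation = inact,
                 partial_fraction = def$partial_fraction, mode = mode)
  }
}

#' Build a neuron template from its parameter file
#'
#' Loads the YAML parameter file for one neuron kind and instantiates its
#' compartments, channel complement, calcium pools and adjacency.  The
#' shipped templates are: MSN (1 soma + 10 identical dendritic spine
#' compartments in a star), PYR (soma-proximal-distal chain), and
#' single-compartment PV and CB interneurons, with 15/8/3/6 channel types
#' respectively.
#'
#' @param kind `"MSN"`, `"PYR"`, `"PV"`, or `"CB"`.
#' @param file optional path to an alternative parameter file.
#' @return an object of class `neuron_template` with elements `kind`,
#'   `compartments` (list of [compartment_spec()]), and `adjacency`
#'   (two-column matrix of compartment index pairs).
#' @export
build_template <- function(kind = c("MSN", "PYR", "PV", "CB"), file = NULL) {
  kind <- match.arg(kind)
  if (is.null(file)) file <- param_file(paste0(tolower(kind), ".yaml"))
  if (!file.exists(file))
    stop("configuration error: missing parameter file ", file)
  cfg <- yaml::read_yaml(file)
  comps <- list()
  for (cc in cfg$compartments) {
    n <- if (is.null(cc$count)) 1L else as.integer(cc$count)
    for (i in seq_len(n)) {
      nm <- if (n > 1L) paste0(cc$name, "_", i) else cc$name
      chans <- list()
      for (ch_name in cc$channels) {
        def <- cfg$channels[[ch_name]]
        if (is.null(def))
          stop("configuration error: channel '", ch_name,
               "' not defined in ", file)
        ch <- parse_channel(ch_name, def, nm)
        if (!is.null(ch)) chans[[length(chans) + 1L]] <- ch
      }
      pool <- if (isTRUE(cc$ca_pool)) calcium_pool() else NULL
      comps[[length(comps) + 1L]] <-
        compartment_spec(nm, length = cc$length, diameter = cc$diameter,
                         c_m = if (is.null(cfg$c_m)) 1 else cfg$c_m,
                         r_l = if (is.null(cfg$r_l)) 150 else cfg$r_l,
                         channels = chans, ca_pool = pool,
                         v_init = if (is.null(cfg$v_init)) -70 else cfg$v_init)
    }
  }
  adj <- switch(cfg$adjacency,
    star = cbind(1L, seq_along(comps)[-1L]),
    chain = if (length(comps) > 1L)
      cbind(seq_len(length(comps) - 1L), 2:length(comps))
    else matrix(integer(), 0, 2),
    none = matrix(integer(), 0, 2),
    stop("configuration error: unknown adjacency '", cfg$adjacency, "'"))
  tpl <- structure(list(kind = kind, compartments = comps, adjacency = adj),
                   class = "neuron_template")
  validate_template(tpl)
  tpl
}

#' Channel types present in a template
#' @param template a `neuron_template`.
#' @return sorted character vector of unique channel names.
#' @export
channel_types <- function(template) {
  sort(unique(unlist(lapply(template$compartments,
                            function(cc) vapply(cc$channels, `[[`, "", "name")))))
}

validate_template <- function(tpl) {
  n <- length(tpl$compartments)
  nm <- vapply(tpl$compartments, `[[`, "", "name")
  adj <- tpl$adjacency
  if (nrow(adj) && (max(adj) > n || min(adj) < 1L))
    stop("topology error: adjacency refers to a missing compartment")
  expected <- switch(tpl$kind,
    MSN = list(ncomp = 11L, nchan = 15L),
    PYR = list(ncomp = 3L, nchan = 8L),
    PV = list(ncomp = 1L, nchan = 3L),
    CB = list(ncomp = 1L, nchan = 6L))
  if (n != expected$ncomp)
    warning(tpl$kind, " template has ", n, " compartments (expected ",
            expected$ncomp, ")")
  nch <- length(channel_types(tpl))
  if (nch != expected$nchan)
    warning(tpl$kind, " template has ", nch, " channel types (expected ",
            expected$nchan, ")")
  invisible(tpl)
}

#' @export
print.neuron_template <- function(x, ...) {
  cat(x$kind, "template:", length(x$compartments), "compartments,",
      length(channel_types(x)), "channel types\n")
  for (cc in x$compartments) {
    cat(sprintf("  %-10s l=%g um d=%g um  channels: %s\n", cc$name,
                cc$length, cc$diameter,
                paste(vapply(cc$channels, `[[`, "", "name"), collapse = ", ")))
  }
  invisible(x)
}
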
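# shared miniature objects for the suite; everything built in code

simple_act_gate <- function(tau = 2)
  gate_spec(power = 1, v_half = -40, slope = -6, tau = tau)

simple_inact_gate <- function(tau = 10)
  gate_spec(power = 1, v_half = -60, slope = 6, tau = tau,
            role = "inactivation")

simple_ohmic <- function(g = 1, e = -90, x = 2, y = 0)
  channel_spec("K", g_max = g, e_rev = e,
               activation = gate_spec(x, -40, -6, 2),
               inactivation = if (y > 0) gate_spec(y, -60, 6, 10,
                                                   role = "inactivation"),
               mode = "ohmic")

simple_ampa <- function(g = 2, e = 0)
  receptor_spec("AMPA", g_max = g, e_rev = e, alpha = 1.1, beta = 0.19)

simple_nmda <- function(g = 2, e = 0)
  receptor_spec("NMDA", g_max = g, e_rev = e, alpha = 0.072, beta = 0.0066)

one_cell_manifest <- function(kind, stim = c(0, 5), window = c(500, 3500)) {
  m <- list(populations = list(list(name = "cell", region = "mPFC",
                                    kind = kind, count = 1L, stimulus = stim)),
            edges = list(), receptors = dacircuit:::default_receptors(),
            stimulus_window = window)
  structure(m, class = "network_manifest")
}

# the stimulus intervals the shipped circuit uses, for single-cell demos
manifest_stimulus <- function(kind, region = "mPFC") {
  m <- load_manifest()
  for (p in m$populations)
    if (p$kind == kind && p$region == region) return(unlist(p$stimulus))
  stop("no population of kind ", kind)
}
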
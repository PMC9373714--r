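# Kinetic two-state receptor models (Destexhe-type) for AMPA, NMDA and
# GABA-A currents, and the weighted summation of synaptic currents.

#' Define a kinetic receptor
#'
#' Two-state receptor with binding rate `alpha`, unbinding rate `beta`, and a
#' sigmoidal transmitter pulse driven by the presynaptic voltage.  NMDA
#' receptors additionally carry the voltage-dependent magnesium block
#' [mg_block()].
#'
#' @param kind `"AMPA"`, `"NMDA"`, or `"GABAa"`.
#' @param g_max maximal conductance (mS/cm^2 of postsynaptic membrane).
#' @param e_rev reversal potential (mV).
#' @param alpha binding rate (1/(mM ms)).
#' @param beta unbinding rate (1/ms).
#' @param t_max maximal transmitter concentration (mM).
#' @param v_p transmitter-release half-activation voltage (mV).
#' @param k_p transmitter-release slope (mV).
#' @return an object of class `receptor_spec`.
#' @export
receptor_spec <- function(kind = c("AMPA", "NMDA", "GABAa"), g_max, e_rev,
                          alpha, beta, t_max = 1, v_p = 2, k_p = 5) {
  kind <- match.arg(kind)
  if (any(c(alpha, beta, t_max, k_p) <= 0))
    stop("alpha, beta, t_max and k_p must be positive")
  structure(list(kind = kind, g_max = g_max, e_rev = e_rev, alpha = alpha,
                 beta = beta, t_max = t_max, v_p = v_p, k_p = k_p),
            class = "receptor_spec")
}

#' Transmitter concentration in the cleft
#'
#' \code{[T] = T_max / (1 + exp(-(V_pre - V_p)/K_p))}: a sigmoidal pulse of
#' transmitter released while the presynaptic terminal is depolarised.
#'
#' @param v_pre presynaptic somatic voltage (mV); vectorised.
#' @param spec a [receptor_spec()].
#' @return concentration in (0, t_max) mM.
#' @export
transmitter_concentration <- function(v_pre, spec) {
  spec$t_max / (1 + exp(-(v_pre - spec$v_p) / spec$k_p))
}

#' Rate of change of the open-receptor fraction
#'
#' \code{dr/dt = alpha [T] (1 - r) - beta r}.
#'
#' @param r open fraction in `[0, 1]`.
#' @param t_conc transmitter concentration (mM).
#' @param spec a [receptor_spec()].
#' @return rate in 1/ms.
#' @export
receptor_derivative <- function(r, t_conc, spec) {
  spec$alpha * t_conc * (1 - r) - spec$beta * r
}

#' AMPA / GABA-A synaptic current
#'
#' \code{I = g_max r (V_post - E)}.
#'
#' @param r open-receptor fraction.
#' @param v_post postsynaptic voltage (mV).
#' @param spec a [receptor_spec()] of kind AMPA or GABAa.
#' @return current density (uA/cm^2), outward positive.
#' @export
ampa_gaba_current <- function(r, v_post, spec) {
  if (spec$kind == "NMDA")
    stop("wrong kind: use nmda_current for NMDA receptors")
  spec$g_max * r * (v_post - spec$e_rev)
}

#' Voltage-dependent magnesium block of the NMDA receptor
#'
#' \code{B(V) = 1 / (1 + exp(-(V + 15)/16.3))}; strictly increasing in V,
#' 0.5 at -15 mV.
#'
#' @param v membrane voltage (mV); vectorised.
#' @return unblocked fraction in (0, 1).
#' @export
mg_block <- function(v) {
  1 / (1 + exp(-(v + 15) / 16.3))
}

#' NMDA synaptic current with magnesium block
#'
#' \code{I = g_max r B(V_post) (V_post - E)}.
#'
#' @inheritParams ampa_gaba_current
#' @param spec a [receptor_spec()] of kind NMDA.
#' @export
nmda_current <- function(r, v_post, spec) {
  if (spec$kind != "NMDA")
    stop("wrong kind: nmda_current needs an NMDA receptor")
  spec$g_max * r * mg_block(v_post) * (v_post - spec$e_rev)
}

#' Weighted sum of synaptic currents onto one target
#'
#' \code{I = sum_k w_k I_k} over the presynaptic partners; connection weights
#' are drawn uniformly from (0, 1) when the network is built.
#'
#' @param weights numeric vector of connection weights.
#' @param currents per-edge currents, aligned with `weights`.
#' @return summed current (0 for no edges).
#' @export
weighted_synaptic_sum <- function(weights, currents) {
  if (length(weights) != length(currents))
    stop("alignment error: weights and currents differ in length")
  if (length(weights) == 0L) return(0)
  sum(weights * currents)
}
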
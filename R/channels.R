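# Voltage-gated channel kinetics: Boltzmann gating, ohmic / partially
# inactivating currents, GHK calcium flux, and submembrane calcium pools.
#
# Unit conventions (declared once, used everywhere):
#   voltage mV, time ms, conductance density mS/cm^2, current density uA/cm^2,
#   capacitance uF/cm^2, concentration mM, GHK permeability cm/s,
#   lengths um, axial resistivity Ohm*cm.
#   Calcium pools take their current argument in mA/cm^2 (see ca_pool_derivative).

#' Define one gating variable of a voltage-gated channel
#'
#' A gate follows first-order kinetics \code{dm/dt = (m_inf(V) - m)/tau(V)} with
#' a Boltzmann steady state \code{m_inf(V) = 1/(1 + exp((V - v_half)/slope))}.
#' The slope is signed: activation gates carry a negative slope (open with
#' depolarisation), inactivation gates a positive slope.  \code{tau} is either
#' a single positive constant (ms) or a two-column table \code{cbind(v, tau)}
#' interpolated linearly in voltage and clamped at the table ends.
#'
#' A second gate kind, \code{kind = "ca"}, describes calcium-dependent
#' activation with a Hill steady state
#' \code{m_inf = ca^n / (ca^n + kd^n)} of the local shell calcium
#' concentration; it is used by the BK/SK-type potassium channels of the
#' shipped templates.
#'
#' @param power integer exponent applied to the gate state in the current law.
#' @param v_half half-activation voltage (mV); ignored for `kind = "ca"`.
#' @param slope signed Boltzmann slope (mV); ignored for `kind = "ca"`.
#' @param tau time constant: positive scalar (ms) or matrix/data.frame with
#'   columns voltage (mV) and tau (ms).
#' @param role `"activation"` or `"inactivation"`.
#' @param kind `"v"` (voltage Boltzmann, default) or `"ca"` (calcium Hill).
#' @param kd half-activation calcium concentration (mM), `kind = "ca"` only.
#' @param hill Hill coefficient, `kind = "ca"` only.
#' @return an object of class `gate_spec`.
#' @export
gate_spec <- function(power, v_half = NA_real_, slope = NA_real_, tau = 1,
                      role = c("activation", "inactivation"),
                      kind = c("v", "ca"), kd = NA_real_, hill = 2) {
  role <- match.arg(role)
  kind <- match.arg(kind)
  if (!is.numeric(power) || length(power) != 1L || power < 0)
    stop("gate power must be a single nonnegative number")
  if (kind == "v") {
    if (!is.finite(v_half)) stop("v_half must be finite for a voltage gate")
    if (!is.finite(slope) || slope == 0)
      stop("invalid parameter: gate slope must be finite and nonzero")
  } else {
    if (!is.finite(kd) || kd <= 0) stop("kd must be positive for a ca gate")
  }
  tau_tab <- NULL
  if (is.matrix(tau) || is.data.frame(tau)) {
    tau_tab <- as.matrix(tau)
    if (ncol(tau_tab) != 2L) stop("tabulated tau needs two columns (v, tau)")
    if (any(tau_tab[, 2L] <= 0)) stop("tau(V) must be strictly positive")
    tau_tab <- tau_tab[order(tau_tab[, 1L]), , drop = FALSE]
    tau <- NA_real_
  } else {
    if (!is.finite(tau) || tau <= 0) stop("constant tau must be positive")
  }
  structure(list(power = as.integer(power), v_half = v_half, slope = slope,
                 tau = tau, tau_table = tau_tab, role = role, kind = kind,
                 kd = kd, hill = hill),
            class = "gate_spec")
}

#' Boltzmann steady-state value of a gate
#'
#' @param v membrane voltage (mV); vectorised.
#' @param gate a [gate_spec()] of kind `"v"`.
#' @return steady-state open fraction in (0, 1).
#' @export
steady_state_gate <- function(v, gate) {
  stopifnot(inherits(gate, "gate_spec"))
  if (gate$kind != "v") stop("steady_state_gate applies to voltage gates")
  1 / (1 + exp((v - gate$v_half) / gate$slope))
}

#' Gate time constant at a voltage
#'
#' Constant gates return their scalar tau; tabulated gates are interpolated
#' linearly and clamped at the table ends.
#'
#' @inheritParams steady_state_gate
#' @return tau in ms (vectorised over `v`).
#' @export
gate_tau <- function(v, gate) {
  stopifnot(inherits(gate, "gate_spec"))
  if (is.null(gate$tau_table)) return(rep_len(gate$tau, length(v)))
  stats::approx(gate$tau_table[, 1L], gate$tau_table[, 2L], xout = v,
                rule = 2)$y
}

#' First-order relaxation rate of a gate state
#'
#' \code{dm/dt = (m_inf(V) - m) / tau(V)}.
#'
#' @param m current gate state in `[0, 1]`.
#' @param v membrane voltage (mV).
#' @param gate a [gate_spec()].
#' @param ca shell calcium (mM), required for `kind = "ca"` gates.
#' @return rate in 1/ms.
#' @export
gate_derivative <- function(m, v, gate, ca = NULL) {
  stopifnot(inherits(gate, "gate_spec"))
  if (gate$kind == "ca") {
    if (is.null(ca)) stop("ca gate needs the shell calcium concentration")
    cah <- ca^gate$hill
    minf <- cah / (cah + gate$kd^gate$hill)
  } else {
    minf <- steady_state_gate(v, gate)
  }
  (minf - m) / gate_tau(v, gate)
}

#' Define a voltage-gated conductance
#'
#' @param name channel identifier (e.g. `"NaP"`, `"KS"`, `"KAs"`, `"CaL1.2"`).
#' @param g_max maximum conductance density (mS/cm^2); ignored for GHK mode.
#' @param e_rev reversal potential (mV); must be `NA` for GHK mode.
#' @param activation,inactivation [gate_spec()]s or `NULL`.
#' @param partial_fraction partial-inactivation fraction `a` in `[0, 1]`
#'   (mode `"partial"` only): the current law becomes
#'   \code{g m^x (a h - (1 - a)) (V - E)}.
#' @param mode `"ohmic"`, `"partial"`, or `"ghk"`.
#' @param ghk a [ghk_params()] attachment (mode `"ghk"` only).
#' @param p_max maximum permeability (cm/s, mode `"ghk"` only).
#' @return an object of class `channel_spec`.
#' @export
channel_spec <- function(name, g_max = NA_real_, e_rev = NA_real_,
                         activation = NULL, inactivation = NULL,
                         partial_fraction = NULL,
                         mode = c("ohmic", "partial", "ghk"),
                         ghk = NULL, p_max = NA_real_) {
  mode <- match.arg(mode)
  if (mode == "partial") {
    if (is.null(partial_fraction) || !is.finite(partial_fraction) ||
        partial_fraction < 0 || partial_fraction > 1)
      stop("invalid parameter: partial_fraction must lie in [0, 1]")
    if (is.null(inactivation))
      stop("partial mode requires an inactivation gate")
  }
  if (mode == "ghk") {
    if (is.null(ghk) || !inherits(ghk, "ghk_params"))
      stop("ghk mode requires a ghk_params attachment")
    if (is.finite(e_rev))
      stop("ghk mode fixes the driving force; e_rev must be NA")
    if (!is.finite(p_max) || p_max <= 0)
      stop("ghk mode requires a positive p_max")
  } else {
    if (!is.finite(g_max) || g_max < 0) stop("g_max must be nonnegative")
    if (!is.finite(e_rev)) stop("e_rev must be finite")
  }
  structure(list(name = name, g_max = g_max, e_rev = e_rev,
                 activation = activation, inactivation = inactivation,
                 partial_fraction = partial_fraction, mode = mode,
                 ghk = ghk, p_max = p_max),
            class = "channel_spec")
}

#' Physical constants for the Goldman-Hodgkin-Katz calcium flux
#'
#' Defaults: valence 2, F = 96489 C/mol, R = 8.31 J/(K mol), T = 35 C
#' (308.15 K internally), extracellular calcium 5 mM.
#'
#' @param z ionic valence.
#' @param faraday Faraday constant (C/mol).
#' @param gas_const molar gas constant (J/(K mol)).
#' @param temperature_c temperature in degrees Celsius.
#' @param ca_out extracellular calcium (mM).
#' @return an object of class `ghk_params`.
#' @export
ghk_params <- function(z = 2, faraday = 96489, gas_const = 8.31,
                       temperature_c = 35, ca_out = 5) {
  vals <- c(z = z, faraday = faraday, gas_const = gas_const,
            temperature_k = temperature_c + 273.15, ca_out = ca_out)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all GHK constants must be strictly positive")
  structure(as.list(vals), class = "ghk_params")
}

#' Ohmic channel current
#'
#' \code{I = g_max m^x h^y (V - E)}; a channel without an inactivation gate
#' uses `y = 0`, i.e. the h-term is identically 1.
#'
#' @param spec a [channel_spec()] with `mode = "ohmic"`.
#' @param m activation gate state (1 if the channel has no activation gate).
#' @param h inactivation gate state (ignored when there is no inactivation gate).
#' @param v membrane voltage (mV).
#' @return current density (uA/cm^2), outward positive.
#' @export
ohmic_current <- function(spec, m, h, v) {
  stopifnot(inherits(spec, "channel_spec"))
  if (spec$mode != "ohmic") stop("wrong mode: ohmic_current needs an ohmic spec")
  mx <- if (is.null(spec$activation)) 1 else m^spec$activation$power
  hy <- if (is.null(spec$inactivation)) 1 else h^spec$inactivation$power
  spec$g_max * mx * hy * (v - spec$e_rev)
}

#' Partially inactivating channel current
#'
#' \code{I = g_max m^x (a h - (1 - a)) (V - E)} with the partial-inactivation
#' fraction `a` in `[0, 1]`; at `a = 1` this reduces to the ohmic law.
#'
#' @inheritParams ohmic_current
#' @export
partial_inactivation_current <- function(spec, m, h, v) {
  stopifnot(inherits(spec, "channel_spec"))
  if (spec$mode != "partial")
    stop("wrong mode: partial_inactivation_current needs a partial spec")
  a <- spec$partial_fraction
  mx <- if (is.null(spec$activation)) 1 else m^spec$activation$power
  spec$g_max * mx * (a * h - (1 - a)) * (v - spec$e_rev)
}

#' Goldman-Hodgkin-Katz calcium current
#'
#' Constant-field flux
#' \deqn{I = P z^2 F^2 V / (RT) \cdot
#'       \frac{[Ca]_{in} - [Ca]_{out} e^{-zFV/RT}}{1 - e^{-zFV/RT}}}
#' evaluated with V in volts and concentrations in mol/cm^3, returned in
#' uA/cm^2.  For \code{|zFV/RT| < 1e-4} the 0/0 form is replaced by the
#' two-term Taylor expansion
#' \code{I = P z F 1e6 (d + xi (ca_in + ca_out)/2)} (concentrations mol/cm^3,
#' d their difference), which makes the current continuous through V = 0 and
#' reproduces the L'Hopital limit \code{P z F ([Ca]_in - [Ca]_out)} exactly
#' at V = 0.
#'
#' @param p instantaneous permeability (cm/s), e.g. from [ca_permeability()].
#' @param v membrane voltage (mV); vectorised.
#' @param ca_in intracellular shell calcium (mM).
#' @param params a [ghk_params()].
#' @return current density (uA/cm^2); negative = inward.
#' @export
ghk_current <- function(p, v, ca_in, params = ghk_params()) {
  stopifnot(inherits(params, "ghk_params"))
  if (any(ca_in <= 0) || params$ca_out <= 0)
    stop("invalid state: calcium concentrations must be positive")
  z <- params$z; f <- params$faraday
  rt <- params$gas_const * params$temperature_k
  cin <- ca_in * 1e-6            # mM -> mol/cm^3
  cout <- params$ca_out * 1e-6
  xi <- z * f * (v / 1000) / rt  # dimensionless
  small <- abs(xi) < 1e-4
  out <- numeric(length(xi))
  if (any(!small)) {
    x <- xi[!small]
    em <- exp(-x)
    out[!small] <- p * z * f * 1e6 * x * (cin - cout * em) / (1 - em)
  }
  if (any(small)) {
    x <- xi[small]
    out[small] <- p * z * f * 1e6 * ((cin - cout) + x * (cin + cout) / 2)
  }
  out
}

#' Instantaneous calcium permeability from gate states
#'
#' \code{P = p_max m^x n^y}, bounded by `[0, p_max]` for gates in `[0, 1]`.
#'
#' @param p_max maximum permeability (cm/s).
#' @param m,n gate states in `[0, 1]`.
#' @param x,y integer gate exponents.
#' @export
ca_permeability <- function(p_max, m, x, n = 1, y = 0) {
  p_max * m^x * n^y
}

#' Submembrane calcium pool
#'
#' State and constants of the shell-calcium balance
#' \deqn{d[Ca]/dt = k (-I_{Ca})/(2 F d) - p K_t [Ca]/([Ca] + K_d)
#'       + ([Ca]_\infty - [Ca])/\tau_R}
#'
#' @param ca_in initial shell calcium (mM).
#' @param shell_depth shell depth d (um).
#' @param k_t pump rate constant (mM/ms).
#' @param k_d pump half-saturation (mM).
#' @param tau_r recovery time constant (ms).
#' @param scale_k flux scale factor k.
#' @param pump_p pump scale p.
#' @param ca_rest resting calcium \code{[Ca]_inf} (mM); the printed sources
#'   state only the initial value, so the default rest equals it.
#' @return an object of class `calcium_pool`.
#' @export
calcium_pool <- function(ca_in = 0.001, shell_depth = 0.1, k_t = 1e-4,
                         k_d = 1e-4, tau_r = 43, scale_k = 1000,
                         pump_p = 0.02, ca_rest = 0.001) {
  if (ca_in <= 0) stop("invalid state: ca_in must be positive")
  structure(list(ca_in = ca_in, shell_depth = shell_depth, k_t = k_t,
                 k_d = k_d, tau_r = tau_r, scale_k = scale_k,
                 pump_p = pump_p, ca_rest = ca_rest),
            class = "calcium_pool")
}

#' Rate of change of shell calcium
#'
#' Influx term \code{k (-i_ca)/(2 F d)}, saturable pump, and first-order
#' recovery toward `ca_rest`.  With d in um and k = 1000 the influx term is
#' dimensionally consistent for `i_ca` in mA/cm^2 (1 mA/cm^2 inward raises a
#' 0.1 um shell by ~0.052 mM/ms); the network core converts its uA/cm^2
#' channel currents accordingly before driving pools.
#'
#' @param pool a [calcium_pool()].
#' @param i_ca calcium current (mA/cm^2), negative = inward.
#' @param ca_in optional state override (mM); defaults to `pool$ca_in`.
#' @param faraday Faraday constant (C/mol).
#' @return d\[Ca\]/dt in mM/ms.
#' @export
ca_pool_derivative <- function(pool, i_ca, ca_in = pool$ca_in,
                               faraday = 96489) {
  stopifnot(inherits(pool, "calcium_pool"))
  if (any(ca_in <= 0)) stop("invalid state: ca_in must be positive")
  influx <- pool$scale_k * (-i_ca) / (2 * faraday * pool$shell_depth)
  pump <- pool$pump_p * pool$k_t * ca_in / (ca_in + pool$k_d)
  influx - pump + (pool$ca_rest - ca_in) / pool$tau_r
}

# channel current dispatcher used by the R reference derivative
channel_current <- function(spec, m, h, v, ca_in = NULL) {
  switch(spec$mode,
    ohmic = ohmic_current(spec, m, h, v),
    partial = partial_inactivation_current(spec, m, h, v),
    ghk = {
      x <- if (is.null(spec$activation)) 0 else spec$activation$power
      y <- if (is.null(spec$inactivation)) 0 else spec$inactivation$power
      p <- ca_permeability(spec$p_max, m, x, h, y)
      ghk_current(p, v, ca_in, spec$ghk)
    })
}
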
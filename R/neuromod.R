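# Dopamine as a direct scalar input: linear interpolation of modulated
# channel parameters between their 0% and 100% endpoint values, and the
# samplers for the fixed-level and quartile-range experiment designs.

#' Linear dopamine interpolation of a parameter
#'
#' A parameter with value `a` in the 0% (dopamine-depleted) condition and `b`
#' in the 100% (normal) condition takes the value \code{a + (b - a) k/100}
#' at dopamine level k%.
#'
#' @param a value at 0% dopamine.
#' @param b value at 100% dopamine.
#' @param k_percent dopamine level in `[0, 100]`.
#' @return interpolated value.
#' @export
interpolate_parameter <- function(a, b, k_percent) {
  if (any(k_percent < 0 | k_percent > 100))
    stop("range error: dopamine level must lie in [0, 100]")
  a + (b - a) * k_percent / 100
}

#' Dopamine schedule for an experiment condition
#'
#' Either a fixed level (the five-level design: MDD 0%, low 25%, medium 50%,
#' high 75%, normal 100%) or a uniform range (the quartile design: 0-25,
#' 25-50, 50-75, 75-100%), sampled once per neuron set per trial.
#'
#' @param mode `"fixed"` or `"uniform_range"`.
#' @param level fixed level in percent (`mode = "fixed"`).
#' @param range two-element `c(lo, hi)` in percent (`mode = "uniform_range"`).
#' @return an object of class `dopamine_schedule`.
#' @export
dopamine_schedule <- function(mode = c("fixed", "uniform_range"),
                              level = NULL, range = NULL) {
  mode <- match.arg(mode)
  if (mode == "fixed") {
    if (is.null(level) || level < 0 || level > 100)
      stop("fixed schedule needs a level in [0, 100]")
  } else {
    if (is.null(range) || length(range) != 2L || range[1] >= range[2] ||
        range[1] < 0 || range[2] > 100)
      stop("uniform_range schedule needs 0 <= lo < hi <= 100")
  }
  structure(list(mode = mode, level = level, range = range),
            class = "dopamine_schedule")
}

#' Sample a dopamine level from a schedule
#'
#' Fixed schedules return their level; uniform-range schedules draw one level
#' from U(lo, hi) using the current R random stream.
#'
#' @param schedule a [dopamine_schedule()].
#' @return dopamine level in percent.
#' @export
sample_da_level <- function(schedule) {
  stopifnot(inherits(schedule, "dopamine_schedule"))
  if (schedule$mode == "fixed") return(schedule$level)
  stats::runif(1, schedule$range[1], schedule$range[2])
}

#' Load the dopamine modulation rules
#'
#' Each rule names a neuron kind, compartment (base name; `spine` matches all
#' ten spines), channel, parameter path (`g_max`, `p_max`,
#' `activation.v_half`, ...), and the endpoint values at 0% and 100%
#' dopamine.  The shipped rules cover the Ca/CaN and KS conductances and the
#' NaP gating of pyramidal neurons, and the KAs and CaL1.2 parameters of
#' medium spiny neurons; synaptic receptor parameters are never touched.
#'
#' @param file optional path to an alternative rules file.
#' @return data.frame with columns `kind`, `compartment`, `channel`, `path`,
#'   `at0`, `at100`.
#' @export
load_dopamine_rules <- function(file = NULL) {
  if (is.null(file)) file <- param_file("dopamine_rules.yaml")
  raw <- yaml::read_yaml(file)$rules
  do.call(rbind, lapply(raw, function(r)
    data.frame(kind = r$kind, compartment = r$compartment,
               channel = r$channel, path = r$path,
               at0 = r$at0, at100 = r$at100)))
}

set_channel_param <- function(ch, path, value) {
  parts <- strsplit(path, ".", fixed = TRUE)[[1]]
  if (length(parts) == 1L) {
    if (is.null(ch[[parts]]) || !is.numeric(ch[[parts]]))
      stop("resolution error: channel '", ch$name,
           "' has no numeric parameter '", path, "'")
    ch[[parts]] <- value
  } else if (length(parts) == 2L) {
    g <- ch[[parts[1]]]
    if (is.null(g) || is.null(g[[parts[2]]]))
      stop("resolution error: cannot resolve '", path, "' on channel '",
           ch$name, "'")
    g[[parts[2]]] <- value
    ch[[parts[1]]] <- g
  } else stop("resolution error: parameter path too deep: ", path)
  ch
}

#' Apply dopamine modulation to a network
#'
#' Returns a copy of the network in which every rule's target parameter is
#' set to its interpolated value at `k_percent`; all other parameters are
#' untouched.  Rules always interpolate from their stored endpoints, so
#' applying the modulation twice at the same level is idempotent.
#'
#' @param network a `da_network` from [build_network()].
#' @param k_percent dopamine level in `[0, 100]`.
#' @param rules rules data.frame from [load_dopamine_rules()].
#' @return modulated `da_network` (with `$da_level` set).
#' @export
apply_modulation <- function(network, k_percent, rules = load_dopamine_rules()) {
  stopifnot(inherits(network, "da_network"))
  for (ri in seq_len(nrow(rules))) {
    r <- rules[ri, ]
    tpl <- network$templates[[r$kind]]
    if (is.null(tpl)) next  # kind absent from this (sub)circuit
    value <- interpolate_parameter(r$at0, r$at100, k_percent)
    hit <- FALSE
    for (ci in seq_along(tpl$compartments)) {
      cc <- tpl$compartments[[ci]]
      base <- sub("_[0-9]+$", "", cc$name)
      if (base != r$compartment && cc$name != r$compartment) next
      for (ki in seq_along(cc$channels)) {
        if (cc$channels[[ki]]$name != r$channel) next
        cc$channels[[ki]] <- set_channel_param(cc$channels[[ki]], r$path, value)
        hit <- TRUE
      }
      tpl$compartments[[ci]] <- cc
    }
    if (!hit)
      stop("resolution error: rule ", ri, " (", r$kind, " ", r$compartment,
           " ", r$channel, ") matched nothing")
    network$templates[[r$kind]] <- tpl
  }
  network$da_level <- k_percent
  network
}
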
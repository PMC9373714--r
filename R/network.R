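# Assembly of the 28-neuron NAc-mPFC circuit: populations, directed synapse
# groups by transmitter, random connection weights, and stimulus models.

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Random stimulus model
#'
#' Stimulus currents are uniformly distributed on `[min, max]` (uA/cm^2,
#' injected at the soma), redrawn every integration step, and zero outside
#' the stimulus window (default 500-3500 ms).
#'
#' @param interval `c(min, max)` current bounds (uA/cm^2).
#' @param window `c(t_on, t_off)` in ms.
#' @return an object of class `stimulus_model`.
#' @export
stimulus_model <- function(interval, window = c(500, 3500)) {
  if (interval[1] > interval[2]) stop("stimulus interval must have min <= max")
  if (window[1] >= window[2]) stop("stimulus window must have t_on < t_off")
  structure(list(interval = interval, window = window),
            class = "stimulus_model")
}

#' Sample stimulus currents at one time point
#'
#' Returns zero outside the stimulus window; inside it, `n` independent draws
#' from U(min, max) using the current R random stream.  (During compiled
#' simulation runs the same model is sampled by the core's own seeded stream,
#' redrawn every step.)
#'
#' @param model a [stimulus_model()].
#' @param t time (ms).
#' @param n number of neurons to draw for.
#' @return numeric vector of length `n` (uA/cm^2).
#' @export
sample_stimuli <- function(model, t, n = 1L) {
  stopifnot(inherits(model, "stimulus_model"))
  if (t < model$window[1] || t > model$window[2]) return(numeric(n))
  stats::runif(n, model$interval[1], model$interval[2])
}

#' Load and validate a network manifest
#'
#' The manifest lists populations (region, kind, count), directed edge groups
#' with their receptor kinds and conductances, per-population stimulus
#' intervals, and receptor rate constants.  Validation checks transmitter
#' consistency (glutamatergic edges originate from pyramidal cells,
#' GABAergic edges from interneurons or MSNs) and warns when the mPFC
#' pyramidal:interneuron ratio deviates from the 4:1 the circuit is built
#' around.
#'
#' @param file optional path to an alternative manifest.
#' @return manifest list (class `network_manifest`).
#' @export
load_manifest <- function(file = NULL) {
  if (is.null(file)) file <- param_file("network.yaml")
  if (!file.exists(file)) stop("configuration error: no manifest at ", file)
  m <- yaml::read_yaml(file)
  kinds <- vapply(m$populations, `[[`, "", "kind")
  if (any(!kinds %in% c("MSN", "PYR", "PV", "CB")))
    stop("configuration error: unknown population kind")
  counts <- vapply(m$populations, function(p) as.integer(p$count), 1L)
  regions <- vapply(m$populations, `[[`, "", "region")
  npyr <- sum(counts[kinds == "PYR" & regions == "mPFC"])
  nint <- sum(counts[kinds %in% c("PV", "CB") & regions == "mPFC"])
  if (nint > 0 && npyr != 4L * nint)
    warning("mPFC pyramidal:interneuron ratio is ", npyr, ":", nint,
            " (the circuit is specified around 4:1)")
  for (e in m$edges) {
    glut <- any(c("AMPA", "NMDA") %in% unlist(e$receptors))
    pre_kind <- kinds[match(e$pre, vapply(m$populations, `[[`, "", "name"))]
    if (glut && pre_kind != "PYR")
      stop("configuration error: glutamatergic edge from non-pyramidal '",
           e$pre, "'")
    if ("GABAa" %in% unlist(e$receptors) && pre_kind == "PYR")
      stop("configuration error: GABAergic edge from pyramidal '", e$pre, "'")
  }
  structure(m, class = "network_manifest")
}

#' Build the circuit from a manifest
#'
#' Instantiates one template per population member, draws one connection
#' weight per directed cell pair per receptor kind from U(0, 1) under
#' `weight_seed`, and attaches the stimulus models.  The VTA is represented
#' only by the dopamine schedule applied later via [apply_modulation()];
#' it has no spiking units, and MSN output targets nothing inside the
#' simulated circuit.
#'
#' @param manifest a manifest from [load_manifest()] (default: shipped 28-neuron
#'   circuit with 16 PYR + 2 PV + 2 CB in mPFC and 4 MSN + 2 PV + 2 CB in NAc).
#' @param weight_seed integer seed for the weight draws.
#' @return an object of class `da_network`.
#' @export
build_network <- function(manifest = load_manifest(), weight_seed = 1L) {
  stopifnot(inherits(manifest, "network_manifest"))
  pops <- manifest$populations
  pop_names <- vapply(pops, `[[`, "", "name")
  neurons <- do.call(rbind, lapply(pops, function(p)
    data.frame(population = p$name, region = p$region, kind = p$kind,
               stringsAsFactors = FALSE)[rep(1, p$count), , drop = FALSE]))
  neurons$id <- seq_len(nrow(neurons))
  rownames(neurons) <- NULL

  kinds_used <- unique(neurons$kind)
  templates <- stats::setNames(lapply(kinds_used, build_template), kinds_used)

  rec_cfg <- manifest$receptors
  edges <- with_seed(weight_seed, {
    rows <- list()
    for (e in manifest$edges) {
      pre_ids <- neurons$id[neurons$population == e$pre]
      post_ids <- neurons$id[neurons$population == e$post]
      target <- if (is.null(e$target)) "soma" else e$target
      for (rk in unlist(e$receptors)) {
        rc <- rec_cfg[[rk]]
        g <- if (is.null(e$g_max[[rk]])) rc$g_max else e$g_max[[rk]]
        for (pre in pre_ids) for (post in post_ids) {
          if (pre == post) next
          rows[[length(rows) + 1L]] <- data.frame(
            pre = pre, post = post, target = target, kind = rk,
            g_max = g, e_rev = rc$e_rev, alpha = rc$alpha, beta = rc$beta,
            t_max = rc$t_max, v_p = rc$v_p, k_p = rc$k_p,
            weight = stats::runif(1), stringsAsFactors = FALSE)
        }
      }
    }
    if (length(rows)) do.call(rbind, rows) else NULL
  })

  stim <- lapply(pops, function(p)
    stimulus_model(unlist(p$stimulus),
                   unlist(manifest$stimulus_window %||% c(500, 3500))))
  names(stim) <- pop_names

  structure(list(manifest = manifest, neurons = neurons,
                 templates = templates, edges = edges, stimulus = stim,
                 weight_seed = weight_seed, da_level = NULL),
            class = "da_network")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.da_network <- function(x, ...) {
  cat("da_network:", nrow(x$neurons), "neurons,",
      if (is.null(x$edges)) 0L else nrow(x$edges), "synaptic edges\n")
  print(table(x$neurons$region, x$neurons$kind))
  if (!is.null(x$da_level)) cat("dopamine level:", x$da_level, "%\n")
  invisible(x)
}

#' Connection weight matrix of a network
#'
#' @param network a `da_network`.
#' @param kind receptor kind to extract (`"AMPA"`, `"NMDA"`, `"GABAa"`).
#' @return dense pre x post matrix of weights (0 = no edge).
#' @export
weight_matrix <- function(network, kind = "AMPA") {
  n <- nrow(network$neurons)
  w <- matrix(0, n, n)
  e <- network$edges[network$edges$kind == kind, ]
  w[cbind(e$pre, e$post)] <- e$weight
  w
}
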
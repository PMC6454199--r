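#' Population and connectivity declarations
#'
#' A model is declared as a set of neuron populations plus probabilistic
#' connection rules between them. `population_spec()` describes one
#' population (its size, excitatory/inhibitory character and neuron
#' parameters); `connectivity_rule()` connects each ordered neuron pair
#' `(a, b)` with `a` in population `pre` and `b` in population `post`
#' independently with the given probability. Self-connections (autapses)
#' are never generated.
#'
#' @param name Population label (unique within a model).
#' @param size Number of neurons (non-negative integer).
#' @param excitatory Logical flag; inhibitory populations have their
#'   outgoing weights scaled by the model's `inhibitory_multiplier`.
#' @param params A [neuron_params()] object for the population.
#' @return `population_spec()` returns an `snn_population` list.
#' @export
population_spec <- function(name, size, excitatory = TRUE,
                            params = neuron_params()) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  check_number(size, "size", min = 0, integer = TRUE)
  check_flag(excitatory, "excitatory")
  stopifnot(inherits(params, "snn_neuron_params"))
  structure(list(name = name, size = as.integer(size),
                 excitatory = excitatory, params = params),
            class = "snn_population")
}

#' @rdname population_spec
#' @param pre,post Population labels; the wildcard `"*"` (valid only in
#'   inter-area rules) matches every population.
#' @param probability Per-pair connection probability in `[0, 1]`.
#' @param weight_dist,delay_dist Distribution specs (see [dist_constant()])
#'   for per-synapse weight magnitudes and delays. Delays are drawn on the
#'   step grid and are at least one step.
#' @return `connectivity_rule()` returns an `snn_rule` list.
#' @export
connectivity_rule <- function(pre, post, probability,
                              weight_dist = NULL, delay_dist = NULL) {
  stopifnot(is.character(pre), length(pre) == 1L,
            is.character(post), length(post) == 1L)
  if (!is.numeric(probability) || length(probability) != 1L ||
      is.na(probability) || probability < 0 || probability > 1) {
    stop("`probability` must be a single value in [0, 1]", call. = FALSE)
  }
  structure(list(pre = pre, post = post, probability = probability,
                 weight_dist = weight_dist, delay_dist = delay_dist),
            class = "snn_rule")
}

#' Assemble a model specification
#'
#' Bundles populations, connection rules and (for modular models) the
#' number of areas and inter-area rules into a single declarative object
#' consumed by [build_network()]. In a multi-area model every area is an
#' independent copy of the declared populations/rules, and each ordered
#' pair of distinct areas is additionally connected by the `inter_area_rules`
#' (fixed cell-to-cell probability between areas).
#'
#' @param populations List of [population_spec()] objects.
#' @param rules List of [connectivity_rule()] objects (applied within an
#'   area).
#' @param n_areas Number of modular areas (1 for a plain layered model).
#' @param inter_area_rules Rules applied between every ordered pair of
#'   distinct areas; `pre`/`post` may be `"*"`.
#' @param scale Global scaling factor in `(0, 1]`, applied to population
#'   sizes by [apply_scale()].
#' @param dt Simulation step (ms) defining the delay grid.
#' @param synapse A [synapse_params()] object (weight defaults,
#'   `tau_syn`, inhibitory multiplier).
#' @return An object of class `snn_model_spec`.
#' @seealso [cm_like_spec()], [multiarea_spec()], [build_network()]
#' @export
model_spec <- function(populations, rules, n_areas = 1L,
                       inter_area_rules = list(), scale = 1,
                       dt = 0.1, synapse = synapse_params()) {
  stopifnot(length(populations) > 0L,
            all(vapply(populations, inherits, TRUE, "snn_population")),
            all(vapply(rules, inherits, TRUE, "snn_rule")),
            all(vapply(inter_area_rules, inherits, TRUE, "snn_rule")),
            inherits(synapse, "snn_synapse_params"))
  check_number(n_areas, "n_areas", min = 1, integer = TRUE)
  check_number(scale, "scale", min = .Machine$double.xmin, max = 1)
  check_number(dt, "dt", min = .Machine$double.xmin)
  nms <- vapply(populations, `[[`, "", "name")
  if (anyDuplicated(nms)) stop("duplicate population names", call. = FALSE)
  for (r in rules) {
    if (!(r$pre %in% nms)) {
      stop("rule references unknown population: ", r$pre, call. = FALSE)
    }
    if (!(r$post %in% nms)) {
      stop("rule references unknown population: ", r$post, call. = FALSE)
    }
  }
  for (r in inter_area_rules) {
    if (r$pre != "*" && !(r$pre %in% nms)) {
      stop("inter-area rule references unknown population: ", r$pre,
           call. = FALSE)
    }
    if (r$post != "*" && !(r$post %in% nms)) {
      stop("inter-area rule references unknown population: ", r$post,
           call. = FALSE)
    }
  }
  structure(list(populations = populations, rules = rules,
                 n_areas = as.integer(n_areas),
                 inter_area_rules = inter_area_rules,
                 scale = scale, dt = dt, synapse = synapse),
            class = "snn_model_spec")
}

#' Rescale a model specification
#'
#' Multiplies every population size by `scale` (rounded to the nearest
#' integer) while leaving connection probabilities untouched, the standard
#' way of running a structurally faithful model at a fraction of its
#' original neuron count.
#'
#' @param spec An `snn_model_spec`.
#' @param scale Scaling fraction in `(0, 1]`.
#' @return The rescaled `snn_model_spec` (with `scale` recorded).
#' @examples
#' sp <- cm_like_spec(n_neurons = 1000)
#' sum(vapply(apply_scale(sp, 0.5)$populations, `[[`, 1L, "size"))
#' @export
apply_scale <- function(spec, scale) {
  stopifnot(inherits(spec, "snn_model_spec"))
  check_number(scale, "scale", min = .Machine$double.xmin, max = 1)
  spec$populations <- lapply(spec$populations, function(p) {
    p$size <- as.integer(round(p$size * scale))
    p
  })
  spec$scale <- scale
  spec
}

# Relative connection-strength matrix for the 8-population layered preset.
# Layers L2/3, L4, L5, L6, each split into an excitatory (e) and an
# inhibitory (i) population. Recurrent within-population connectivity is
# strongest, within-layer e<->i coupling next, a weak feedforward loop
# (L4->L2/3->L5->L6->L4) above baseline, everything else at baseline.
# The absolute scale is set by the requested mean in-degree; only the
# ratios are structural. The matrix is deliberately "CM-like" rather than
# a reprint of any published microcircuit table.
cm_relative_matrix <- function() {
  pops <- c("L2/3e", "L2/3i", "L4e", "L4i", "L5e", "L5i", "L6e", "L6i")
  layer <- rep(c("L2/3", "L4", "L5", "L6"), each = 2L)
  m <- matrix(1, 8L, 8L, dimnames = list(pops, pops))
  for (i in 1:8) for (j in 1:8) {
    if (i == j) m[i, j] <- 20
    else if (layer[i] == layer[j]) m[i, j] <- 10
  }
  ff <- rbind(c("L4e", "L2/3e"), c("L4e", "L2/3i"),
              c("L2/3e", "L5e"), c("L2/3e", "L5i"),
              c("L5e", "L6e"), c("L5e", "L6i"),
              c("L6e", "L4e"), c("L6e", "L4i"))
  m[ff] <- 3
  m
}

#' Layered cortical-microcircuit-style model preset
#'
#' Builds an 8-population layered network specification (L2/3, L4, L5, L6,
#' each with an excitatory and an inhibitory population at a 4:1 size
#' ratio). Within-population and within-layer connection probabilities
#' exceed cross-layer ones (ratio 20:10:1, with a weak feedforward loop at
#' 3), and the absolute probabilities are normalised so that the expected
#' mean in-degree equals `mean_in_degree`. Per-synapse delays are uniform
#' on `{1, ..., max_delay_steps} * dt`; their one-step minimum is what
#' forces a spike exchange at every simulation step.
#'
#' @param n_neurons Total neuron count (split 4:1 e:i across 4 equal
#'   layers).
#' @param mean_in_degree Target expected number of inputs per neuron.
#' @param weight Synaptic weight magnitude (constant per synapse).
#' @param max_delay_steps Upper bound of the uniform delay distribution,
#'   in steps.
#' @param dt Step size (ms).
#' @param neuron A [neuron_params()] object shared by all populations.
#' @param inhibitory_multiplier Scale factor for inhibitory weights.
#' @return An `snn_model_spec`.
#' @export
cm_like_spec <- function(n_neurons = 20000, mean_in_degree = 50,
                         weight = 0.02, max_delay_steps = 15, dt = 0.1,
                         neuron = neuron_params(),
                         inhibitory_multiplier = -4) {
  check_number(n_neurons, "n_neurons", min = 8, integer = TRUE)
  check_number(mean_in_degree, "mean_in_degree", min = 0)
  m <- cm_relative_matrix()
  pops <- rownames(m)
  per_layer <- n_neurons / 4
  sizes <- as.integer(round(rep(c(0.8, 0.2), 4L) * per_layer))
  names(sizes) <- pops
  # Normalise: expected mean in-degree over all neurons equals the target.
  tot <- 0
  for (i in seq_along(pops)) for (j in seq_along(pops)) {
    n_pairs <- sizes[i] * sizes[j] - (if (i == j) sizes[i] else 0)
    tot <- tot + m[i, j] * n_pairs
  }
  c_norm <- mean_in_degree * sum(sizes) / tot
  probs <- m * c_norm
  if (any(probs > 1)) {
    stop("requested mean in-degree is infeasible at this size ",
         "(a connection probability would exceed 1)", call. = FALSE)
  }
  populations <- lapply(pops, function(p) {
    population_spec(p, sizes[[p]], excitatory = grepl("e$", p),
                    params = neuron)
  })
  rules <- list()
  for (i in seq_along(pops)) for (j in seq_along(pops)) {
    if (probs[i, j] > 0 && sizes[i] > 0 && sizes[j] > 0) {
      rules[[length(rules) + 1L]] <- connectivity_rule(
        pops[i], pops[j], probs[i, j],
        weight_dist = dist_constant(weight),
        delay_dist = dist_uniform_steps(1, max_delay_steps))
    }
  }
  model_spec(populations, rules, dt = dt,
             synapse = synapse_params(
               weight = weight, inhibitory_multiplier = inhibitory_multiplier))
}

#' Modular multi-area model preset
#'
#' A 32-area (configurable) modular network in which every area is an
#' independent layered microcircuit ([cm_like_spec()]) and any two neurons
#' in distinct areas are connected with a single fixed probability,
#' independent of population. Intra-area connectivity dominates inter-area
#' connectivity by design, giving the modular structure that
#' connectivity-aware allocation exploits. The preset uses the stronger
#' inhibitory multiplier (-15) and weaker drive (0.38 mA) conventional for
#' the multi-area configuration.
#'
#' @param n_areas Number of areas (>= 2).
#' @param neurons_per_area Neurons in each area.
#' @param mean_in_degree_intra Target mean within-area in-degree.
#' @param inter_area_probability Fixed cell-to-cell probability between any
#'   two distinct areas.
#' @param weight,max_delay_steps,dt As in [cm_like_spec()].
#' @param i_ext Constant injected current (mA).
#' @param inhibitory_multiplier Scale factor for inhibitory weights.
#' @return An `snn_model_spec` with `n_areas` areas.
#' @export
multiarea_spec <- function(n_areas = 32, neurons_per_area = 1000,
                           mean_in_degree_intra = 45,
                           inter_area_probability = 1e-4,
                           weight = 0.02, max_delay_steps = 15, dt = 0.1,
                           i_ext = 0.38, inhibitory_multiplier = -15) {
  check_number(n_areas, "n_areas", min = 2, integer = TRUE)
  check_number(inter_area_probability, "inter_area_probability",
               min = 0, max = 1)
  base <- cm_like_spec(n_neurons = neurons_per_area,
                       mean_in_degree = mean_in_degree_intra,
                       weight = weight, max_delay_steps = max_delay_steps,
                       dt = dt, neuron = neuron_params(i_ext = i_ext),
                       inhibitory_multiplier = inhibitory_multiplier)
  inter <- list(connectivity_rule(
    "*", "*", inter_area_probability,
    weight_dist = dist_constant(weight),
    delay_dist = dist_uniform_steps(1, max_delay_steps)))
  model_spec(base$populations, base$rules, n_areas = n_areas,
             inter_area_rules = inter, dt = dt, synapse = base$synapse)
}

#' Read a model specification from a YAML or JSON file
#'
#' Structured-text interface to [model_spec()]. The file holds
#' `populations` (name, size, excitatory, optional neuron parameter
#' overrides), `rules` and optional `inter_area_rules` (pre, post,
#' probability, optional `weight`, optional `delay_steps` as
#' `[min, max]`), plus optional scalars `n_areas`, `scale`, `dt` and
#' synapse parameter overrides under `synapse`.
#'
#' @param path File path (`.yaml`/`.yml` or `.json`).
#' @return An `snn_model_spec`.
#' @export
read_model_spec <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(raw$populations) || is.null(raw$rules)) {
    stop("model file must declare `populations` and `rules`", call. = FALSE)
  }
  parse_pop <- function(p) {
    np <- do.call(neuron_params, p$neuron %||% list())
    population_spec(p$name, p$size, isTRUE(p$excitatory %||% TRUE), np)
  }
  parse_rule <- function(r) {
    wd <- if (!is.null(r$weight)) dist_constant(r$weight)
    dd <- if (!is.null(r$delay_steps)) {
      dist_uniform_steps(r$delay_steps[[1L]],
                         r$delay_steps[[length(r$delay_steps)]])
    }
    connectivity_rule(r$pre, r$post, r$probability,
                      weight_dist = wd, delay_dist = dd)
  }
  model_spec(
    populations = lapply(raw$populations, parse_pop),
    rules = lapply(raw$rules, parse_rule),
    n_areas = raw$n_areas %||% 1L,
    inter_area_rules = lapply(raw$inter_area_rules %||% list(), parse_rule),
    scale = raw$scale %||% 1,
    dt = raw$dt %||% 0.1,
    synapse = do.call(synapse_params, raw$synapse %||% list()))
}

#' @export
print.snn_model_spec <- function(x, ...) {
  sizes <- vapply(x$populations, `[[`, 1L, "size")
  cat(sprintf("SNN model spec: %d population(s), %d area(s), %s neurons%s\n",
              length(x$populations), x$n_areas,
              format(sum(sizes) * x$n_areas, big.mark = ","),
              if (x$scale < 1) sprintf(" (scale %.3g)", x$scale) else ""))
  cat(sprintf("  rules: %d intra-area, %d inter-area; dt = %g ms\n",
              length(x$rules), length(x$inter_area_rules), x$dt))
  invisible(x)
}
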
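#' Generate a network from a model specification
#'
#' Realises an `snn_model_spec` as a concrete synaptic network. Each
#' ordered neuron pair covered by a rule is connected independently with
#' the rule's probability (autapses excluded); weights and delays are drawn
#' from the rule's distributions. Neuron ids are 0-based and contiguous,
#' grouped by area and, within an area, by population in declaration
#' order, so in an equal-area model `area(id) == floor(id / area_size)`.
#'
#' Randomness is split into three named streams derived from `seed` --
#' structure, weights, delays -- so the synaptic wiring is unchanged when
#' only the weight or delay stream is reseeded. Identical `(spec, seed)`
#' always yields a bit-identical network.
#'
#' `build_layered_network()` and `build_multiarea_network()` are the
#' single-area and modular entry points; `build_network()` dispatches on
#' `spec$n_areas`.
#'
#' @param spec An `snn_model_spec` (see [model_spec()] and the presets
#'   [cm_like_spec()], [multiarea_spec()]). `spec$scale` is applied before
#'   generation.
#' @param seed Integer seed, or a list with elements `structure`,
#'   `weights`, `delays` for explicit stream control.
#' @return An object of class `snn_network`: neuron count, canonical edge
#'   table (`pre`, `post`, `weight`, `delay`, sorted by `pre` then `post`),
#'   per-neuron population/area labels and the parameter tables.
#' @examples
#' net <- build_network(cm_like_spec(n_neurons = 400, mean_in_degree = 10),
#'                      seed = 1)
#' network_summary(net)
#' @export
build_network <- function(spec, seed) {
  stopifnot(inherits(spec, "snn_model_spec"))
  if (spec$scale < 1) spec <- apply_scale(spec, spec$scale)
  seeds <- derive_seeds(seed)

  pops <- data.frame(
    name = vapply(spec$populations, `[[`, "", "name"),
    size = vapply(spec$populations, `[[`, 1L, "size"),
    excitatory = vapply(spec$populations, `[[`, TRUE, "excitatory"),
    stringsAsFactors = FALSE)
  pop_params <- lapply(spec$populations, `[[`, "params")
  names(pop_params) <- pops$name
  area_size <- sum(pops$size)
  n_areas <- spec$n_areas
  n <- area_size * n_areas
  pop_offset <- c(0L, cumsum(pops$size))  # within an area

  # Per-neuron labels.
  population <- rep.int(rep.int(seq_len(nrow(pops)), pops$size), n_areas)
  area <- if (n > 0) rep(seq_len(n_areas) - 1L, each = area_size) else integer()

  pop_range <- function(a, p) {  # 0-based [start, end) of population p in area a
    s <- (a - 1L) * area_size + pop_offset[p]
    c(s, s + pops$size[p])
  }

  # Enumerate rule instances in a fixed, documented order: all intra-area
  # blocks area by area, then inter-area blocks by ordered area pair.
  idx_of <- setNames(seq_len(nrow(pops)), pops$name)
  instances <- list()
  for (a in seq_len(n_areas)) {
    for (r in spec$rules) {
      i <- idx_of[[r$pre]]; j <- idx_of[[r$post]]
      instances[[length(instances) + 1L]] <- list(
        rule = r, pre = pop_range(a, i), post = pop_range(a, j),
        same = (i == j))
    }
  }
  if (n_areas >= 2L && length(spec$inter_area_rules) > 0L) {
    for (a in seq_len(n_areas)) for (b in seq_len(n_areas)) {
      if (a == b) next
      for (r in spec$inter_area_rules) {
        pre_rng <- if (r$pre == "*") {
          c((a - 1L) * area_size, a * area_size)
        } else pop_range(a, idx_of[[r$pre]])
        post_rng <- if (r$post == "*") {
          c((b - 1L) * area_size, b * area_size)
        } else pop_range(b, idx_of[[r$post]])
        instances[[length(instances) + 1L]] <- list(
          rule = r, pre = pre_rng, post = post_rng, same = FALSE)
      }
    }
  }

  # Pass 1 (structure stream): Bernoulli sampling of ordered pairs per block.
  blocks <- with_seed(seeds$structure, lapply(instances, function(inst) {
    sample_pair_block(inst$pre, inst$post, inst$rule$probability, inst$same)
  }))

  counts <- vapply(blocks, function(b) length(b$pre), 0L)

  # Pass 2 (weight stream): magnitudes per rule instance, aligned with the
  # sorted within-block edge order.
  weights <- with_seed(seeds$weights, lapply(seq_along(instances), function(k) {
    d <- instances[[k]]$rule$weight_dist %||% dist_constant(spec$synapse$weight)
    draw_dist(d, counts[k])
  }))

  # Pass 3 (delay stream).
  delays <- with_seed(seeds$delays, lapply(seq_along(instances), function(k) {
    d <- instances[[k]]$rule$delay_dist %||% dist_constant(spec$synapse$delay)
    draw_dist(d, counts[k], dt = spec$dt)
  }))

  pre <- unlist(lapply(blocks, `[[`, "pre"), use.names = FALSE) %||% integer()
  post <- unlist(lapply(blocks, `[[`, "post"), use.names = FALSE) %||% integer()
  w <- unlist(weights, use.names = FALSE) %||% numeric()
  dl <- unlist(delays, use.names = FALSE) %||% numeric()

  if (length(dl) && any(dl < spec$dt - 1e-9)) {
    stop("generated delays below one simulation step", call. = FALSE)
  }

  # Inhibitory presynaptic populations: scale weights once, globally.
  if (length(w)) {
    inhib <- !pops$excitatory[population[pre + 1L]]
    w[inhib] <- w[inhib] * spec$synapse$inhibitory_multiplier
  }

  o <- order(pre, post)
  edges <- data.frame(pre = pre[o], post = post[o],
                      weight = w[o], delay = dl[o])

  structure(list(
    n_neurons = as.integer(n), edges = edges,
    population = population, area = area,
    pops = pops, pop_params = pop_params,
    dt = spec$dt, synapse = spec$synapse, n_areas = n_areas,
    area_size = as.integer(area_size), seeds = seeds),
    class = "snn_network")
}

#' @rdname build_network
#' @export
build_layered_network <- function(spec, seed) {
  stopifnot(inherits(spec, "snn_model_spec"))
  if (spec$n_areas != 1L) {
    stop("build_layered_network() requires a single-area spec", call. = FALSE)
  }
  build_network(spec, seed)
}

#' @rdname build_network
#' @export
build_multiarea_network <- function(spec, seed) {
  stopifnot(inherits(spec, "snn_model_spec"))
  if (spec$n_areas < 2L) {
    stop("build_multiarea_network() requires n_areas >= 2", call. = FALSE)
  }
  build_network(spec, seed)
}

# Sample the ordered pairs of one connectivity block. `pre_rng`/`post_rng`
# are 0-based half-open id ranges; `same` marks a block whose pre and post
# ranges coincide, in which case the diagonal (autapses) is excluded from
# the sample space. Processes the block in row chunks to bound memory.
sample_pair_block <- function(pre_rng, post_rng, p, same) {
  n1 <- pre_rng[2L] - pre_rng[1L]
  n2 <- post_rng[2L] - post_rng[1L]
  if (n1 <= 0L || n2 <= 0L || p <= 0) {
    return(list(pre = integer(), post = integer()))
  }
  ncol_eff <- if (same) n2 - 1L else n2
  if (ncol_eff <= 0L) return(list(pre = integer(), post = integer()))
  chunk_rows <- max(1L, as.integer(2^26 %/% ncol_eff))
  pre_out <- list(); post_out <- list(); ci <- 0L
  r0 <- 0L
  while (r0 < n1) {
    rows <- min(chunk_rows, n1 - r0)
    cells <- rows * ncol_eff
    k <- rbinom(1L, cells, p)
    if (k > 0L) {
      idx <- sort.int(sample.int(cells, k)) - 1L
      r <- idx %/% ncol_eff          # row within chunk
      off <- idx %% ncol_eff
      cc <- if (same) off + (off >= (r + r0)) else off
      ci <- ci + 1L
      pre_out[[ci]] <- pre_rng[1L] + r0 + r
      post_out[[ci]] <- post_rng[1L] + cc
    }
    r0 <- r0 + rows
  }
  list(pre = unlist(pre_out, use.names = FALSE) %||% integer(),
       post = unlist(post_out, use.names = FALSE) %||% integer())
}

#' Summarise a generated network
#'
#' @param net An `snn_network`.
#' @return An `snn_network_summary` list: neuron and synapse counts,
#'   per-population and per-area neuron/synapse counts, and in/out-degree
#'   summaries.
#' @export
network_summary <- function(net) {
  stopifnot(inherits(net, "snn_network"))
  n <- net$n_neurons
  e <- net$edges
  in_deg <- tabulate(e$post + 1L, nbins = max(n, 1L))[seq_len(n)]
  out_deg <- tabulate(e$pre + 1L, nbins = max(n, 1L))[seq_len(n)]
  deg_sum <- function(d) {
    if (!length(d)) return(c(mean = 0, min = 0, max = 0))
    c(mean = mean(d), min = min(d), max = max(d))
  }
  per_pop <- if (n > 0) {
    data.frame(population = net$pops$name,
               neurons = as.integer(net$pops$size * net$n_areas),
               synapses_out = as.vector(
                 rowsum(out_deg, net$pops$name[net$population],
                        reorder = FALSE)[net$pops$name, 1L]))
  } else data.frame(population = character(), neurons = integer(),
                    synapses_out = integer())
  per_area <- if (n > 0) {
    data.frame(area = seq_len(net$n_areas) - 1L,
               neurons = as.integer(tabulate(net$area + 1L, net$n_areas)),
               synapses_out = as.vector(rowsum(
                 out_deg, factor(net$area, levels = seq_len(net$n_areas) - 1L))))
  } else data.frame(area = integer(), neurons = integer(),
                    synapses_out = integer())
  structure(list(
    n_neurons = n, n_synapses = nrow(e),
    per_population = per_pop, per_area = per_area,
    in_degree = deg_sum(in_deg), out_degree = deg_sum(out_deg)),
    class = "snn_network_summary")
}

#' @export
print.snn_network_summary <- function(x, ...) {
  cat(sprintf("Network: %s neurons, %s synapses\n",
              format(x$n_neurons, big.mark = ","),
              format(x$n_synapses, big.mark = ",")))
  cat(sprintf("  in-degree  mean %.2f (range %g-%g)\n",
              x$in_degree[["mean"]], x$in_degree[["min"]],
              x$in_degree[["max"]]))
  cat(sprintf("  out-degree mean %.2f (range %g-%g)\n",
              x$out_degree[["mean"]], x$out_degree[["min"]],
              x$out_degree[["max"]]))
  if (nrow(x$per_area) > 1L) {
    cat(sprintf("  %d areas of %s\n", nrow(x$per_area),
                paste(unique(x$per_area$neurons), collapse = "/")))
  }
  invisible(x)
}

#' @export
print.snn_network <- function(x, ...) {
  cat(sprintf(
    "snn_network: %s neurons, %s synapses, %d area(s), %d population(s)\n",
    format(x$n_neurons, big.mark = ","),
    format(nrow(x$edges), big.mark = ","), x$n_areas, nrow(x$pops)))
  invisible(x)
}
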
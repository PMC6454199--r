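#' Partitioner configuration
#'
#' Settings for [partition_hypergraph()]. `tolerance` is the maximum
#' allowed load imbalance (max part load over mean part load); the default
#' 1.001 presumes many vertices per part. When the weight granularity of a
#' (small) instance makes that infeasible -- a single vertex weight larger
#' than the permitted slack -- the partitioner relaxes stepwise through
#' `1.01, 1.05, 1.10` and reports the tolerance actually used.
#'
#' @param n_parts Number of processes `P >= 1`.
#' @param tolerance Maximum allowed imbalance (`>= 1`).
#' @param coarsening_stop Target coarse vertex count; default
#'   `max(10 * P, 150)`.
#' @param max_fm_passes Refinement pass cap per level (default 10; a level
#'   also stops at the first pass with zero gain).
#' @param seed Seed for the matching and refinement visit orders.
#' @return An `snn_partitioner_config` list.
#' @export
partitioner_config <- function(n_parts, tolerance = 1.001,
                               coarsening_stop = NULL,
                               max_fm_passes = 10, seed = 1) {
  check_number(n_parts, "n_parts", min = 1, integer = TRUE)
  check_number(tolerance, "tolerance", min = 1)
  check_number(max_fm_passes, "max_fm_passes", min = 1, integer = TRUE)
  coarsening_stop <- coarsening_stop %||% max(10L * n_parts, 150L)
  check_number(coarsening_stop, "coarsening_stop", min = 1, integer = TRUE)
  structure(list(n_parts = as.integer(n_parts), tolerance = tolerance,
                 coarsening_stop = as.integer(coarsening_stop),
                 max_fm_passes = as.integer(max_fm_passes),
                 seed = as.integer(seed)),
            class = "snn_partitioner_config")
}

#' Round-robin allocation
#'
#' Neuron `i` is hosted by process `i mod P` -- the standard static
#' load-balancing scheme of neuronal simulators, and the connectivity
#' worst case: it deliberately spreads the neurons most likely to be
#' interconnected (contiguous ids, same population/area) across all
#' processes.
#'
#' @param n_neurons Number of neurons.
#' @param P Number of processes.
#' @return An `snn_assignment`.
#' @examples
#' allocate_round_robin(6, 4)
#' @export
allocate_round_robin <- function(n_neurons, P) {
  check_number(n_neurons, "n_neurons", min = 0, integer = TRUE)
  check_number(P, "P", min = 1, integer = TRUE)
  a <- as_assignment((seq_len(n_neurons) - 1L) %% as.integer(P), P)
  attr(a, "method") <- "round_robin"
  a
}

#' Balanced random allocation
#'
#' A seeded random permutation of the vertices is assigned greedily, each
#' vertex to the currently lightest process by workload weight. This keeps
#' processes balanced (the final load gap never exceeds one vertex weight)
#' while remaining connectivity-blind, which makes it the reference
#' baseline for connectivity-aware partitioning.
#'
#' @param x An `snn_hypergraph` (weights are taken from it) or an
#'   `snn_network` (converted via [network_to_hypergraph()]).
#' @param P Number of processes.
#' @param seed Integer seed; identical `(x, P, seed)` yields an identical
#'   assignment.
#' @return An `snn_assignment`.
#' @export
allocate_random_balanced <- function(x, P, seed = 1) {
  if (inherits(x, "snn_network")) x <- network_to_hypergraph(x)
  stopifnot(inherits(x, "snn_hypergraph"))
  check_number(P, "P", min = 1, integer = TRUE)
  n <- x$n_vertices
  perm <- with_seed(seed, sample.int(n))
  part <- greedy_lightest(x$vertex_weights, perm, as.integer(P))
  a <- as_assignment(part, P)
  attr(a, "method") <- "random_balanced"
  attr(a, "imbalance") <- partition_imbalance(x, a)
  a
}

# Assign vertices (in the given visit order) to the currently lightest part.
greedy_lightest <- function(w, ord, P) {
  loads <- numeric(P)
  part <- integer(length(w))
  for (v in ord) {
    p <- which.min(loads)
    part[v] <- p - 1L
    loads[p] <- loads[p] + w[v]
  }
  part
}

#' Multilevel hypergraph partitioning
#'
#' Allocates vertices (neurons) to `P` processes by minimising the
#' connectivity-1 cut (see [partition_cost()]) subject to a load-imbalance
#' constraint, using the classic multilevel scheme: the hypergraph is
#' repeatedly *coarsened* by agglomerative inner-product matching
#' ([coarsen()]), the coarsest level is seeded with a balanced greedy
#' partition ([initial_partition()]), and the assignment is projected back
#' level by level with Fiduccia-Mattheyses refinement ([fm_refine()]) and
#' greedy rebalancing at every level (a V-cycle).
#'
#' If the requested tolerance is unattainable at the instance's weight
#' granularity the working tolerance is relaxed through `1.01, 1.05, 1.10`
#' and, on instances so small that even that leaves less than one vertex
#' weight of slack, floors at one vertex weight above the mean load (the
#' room any single-vertex move needs). The tolerance actually used is
#' always reported; if the final imbalance still exceeds it the function
#' fails rather than return an unbalanced assignment.
#'
#' @param hg A non-empty `snn_hypergraph`.
#' @param cfg An [partitioner_config()]; `cfg$n_parts` must not exceed the
#'   vertex count.
#' @return An `snn_assignment` with attributes `cut_cost`, `imbalance`,
#'   `tolerance_used`, `fm_moves`, `matching_ops` and `n_levels`. No part
#'   is ever empty.
#' @examples
#' hg <- hypergraph(list(c(0, 1), c(1, 2), c(3, 4), c(4, 5)), 6)
#' a <- partition_hypergraph(hg, partitioner_config(2, seed = 7))
#' attr(a, "cut_cost")
#' @export
partition_hypergraph <- function(hg, cfg) {
  stopifnot(inherits(hg, "snn_hypergraph"),
            inherits(cfg, "snn_partitioner_config"))
  n <- hg$n_vertices
  P <- cfg$n_parts
  if (n == 0L) stop("cannot partition an empty hypergraph", call. = FALSE)
  if (P > n) stop("n_parts exceeds the number of vertices", call. = FALSE)
  if (P == 1L) {
    a <- as_assignment(integer(n), 1L)
    attr(a, "method") <- "hypergraph"
    attr(a, "cut_cost") <- 0
    attr(a, "imbalance") <- 1
    attr(a, "tolerance_used") <- cfg$tolerance
    attr(a, "fm_moves") <- 0L
    attr(a, "matching_ops") <- 0
    attr(a, "n_levels") <- 0L
    return(a)
  }

  avg_load <- sum(hg$vertex_weights) / P
  work_tol <- working_tolerance(cfg$tolerance, max(hg$vertex_weights), avg_load)
  max_load <- work_tol * avg_load

  rng_seeds <- with_seed(cfg$seed, sample.int(.Machine$integer.max - 1L, 2048L))
  si <- 0L
  next_seed <- function() {
    si <<- si + 1L
    rng_seeds[[si]]
  }

  levels <- coarsen(hg, cfg, max_cluster_weight = max(
    max_load / 3, 2 * max(hg$vertex_weights)))
  matching_ops <- sum(vapply(levels, function(l) l$ops, 0))
  coarse_hg <- if (length(levels)) levels[[length(levels)]]$hg else hg

  a <- initial_partition(coarse_hg, cfg)
  part <- as.integer(a)
  fm_moves <- 0L

  refine_here <- function(g, part) {
    inc <- vertex_incidence(g)
    res <- rebalance_cpp(g$eptr, g$pins, inc$veptr, inc$vedges,
                         g$vertex_weights, part, P, max_load,
                         max_iter = 5L * g$n_vertices)
    part <- res$part
    for (pass in seq_len(cfg$max_fm_passes)) {
      ord <- with_seed(next_seed(), sample.int(g$n_vertices)) - 1L
      fm <- fm_pass_cpp(g$eptr, g$pins, inc$veptr, inc$vedges,
                        g$vertex_weights, part, P, max_load, ord)
      part <- fm$part
      fm_moves <<- fm_moves + fm$moves
      if (fm$gain <= 0) break
    }
    part
  }

  part <- refine_here(coarse_hg, part)
  # Uncoarsen: project through each level's vertex map, refine at each.
  for (li in rev(seq_along(levels))) {
    part <- part[levels[[li]]$group + 1L]
    g <- if (li > 1L) levels[[li - 1L]]$hg else hg
    part <- refine_here(g, part)
  }

  out <- as_assignment(part, P)
  imb <- partition_imbalance(hg, out)
  # Granularity escape hatch: relax the working tolerance and rebalance.
  while (imb > work_tol + 1e-12) {
    nxt <- next_tolerance(work_tol)
    if (is.null(nxt)) {
      stop(sprintf(
        "partition infeasible: imbalance %.4f exceeds the relaxation ladder",
        imb), call. = FALSE)
    }
    message(sprintf(
      "partition_hypergraph: tolerance %.4g infeasible at this granularity, relaxing to %.4g",
      work_tol, nxt))
    work_tol <- nxt
    max_load <- work_tol * avg_load
    part <- refine_here(hg, as.integer(out))
    out <- as_assignment(part, P)
    imb <- partition_imbalance(hg, out)
  }
  if (any(tabulate(as.integer(out) + 1L, P) == 0L)) {
    stop("internal error: empty part in partitioner output", call. = FALSE)
  }
  attr(out, "method") <- "hypergraph"
  attr(out, "cut_cost") <- partition_cost(hg, out)
  attr(out, "imbalance") <- imb
  attr(out, "tolerance_used") <- work_tol
  attr(out, "fm_moves") <- fm_moves
  attr(out, "matching_ops") <- matching_ops
  attr(out, "n_levels") <- length(levels)
  out
}

# The relaxation ladder for weight-granularity-infeasible tolerances. If
# even the last rung leaves less than one vertex weight of slack (tiny
# instances), the working tolerance floors at (avg + max weight) / avg:
# local search needs room for at least one vertex move, and an assignment
# within that load bound always exists (the LPT guarantee).
tolerance_ladder <- c(1.01, 1.05, 1.10)

working_tolerance <- function(tolerance, max_wt, avg_load) {
  for (tol in c(tolerance, tolerance_ladder[tolerance_ladder > tolerance])) {
    if (max_wt <= (tol - 1) * avg_load) return(tol)
  }
  max(1.10, (avg_load + max_wt) / avg_load)
}

next_tolerance <- function(tol) {
  nxt <- tolerance_ladder[tolerance_ladder > tol + 1e-12]
  if (length(nxt)) nxt[1L] else NULL
}

# Vertex -> incident hyperedge CSR view.
vertex_incidence <- function(hg) {
  m <- n_hyperedges(hg)
  eid <- rep.int(seq_len(m) - 1L, diff(hg$eptr))
  o <- order(hg$pins, eid)
  list(veptr = c(0L, cumsum(tabulate(hg$pins + 1L, nbins = hg$n_vertices))),
       vedges = eid[o])
}

#' Coarsening by agglomerative inner-product matching
#'
#' Produces the multilevel coarsening sequence. At each level vertices are
#' visited in a seeded random order and greedily matched in pairs: the
#' affinity of `u` and `v` is the sum over hyperedges containing both of
#' `1 / (|e| - 1)` (so small, tight edges attract most), ties breaking to
#' the smaller combined weight then the lower id. Matched pairs are merged
#' (weights add), hyperedges are reindexed with duplicate members
#' collapsed and single-vertex edges dropped. Coarsening stops at
#' `cfg$coarsening_stop` vertices or when a level shrinks the vertex count
#' by less than 5 percent. Vertices sharing no hyperedge are never matched
#' while positive-affinity partners remain.
#'
#' @inheritParams partition_hypergraph
#' @param max_cluster_weight Cap on a merged vertex's weight (defaults to
#'   a third of the allowed part load, so coarse vertices stay placeable).
#' @return A list of levels, each with `hg` (the coarse hypergraph),
#'   `group` (fine-vertex to coarse-vertex map, 0-based) and `ops`
#'   (matching score updates, a work counter).
#' @export
coarsen <- function(hg, cfg, max_cluster_weight = NULL) {
  stopifnot(inherits(hg, "snn_hypergraph"))
  if (hg$n_vertices == 0L) stop("empty hypergraph", call. = FALSE)
  max_cluster_weight <- max_cluster_weight %||%
    max(sum(hg$vertex_weights) / cfg$n_parts / 3,
        2 * max(hg$vertex_weights))
  seeds <- with_seed(cfg$seed, sample.int(.Machine$integer.max - 1L, 64L))
  levels <- list()
  g <- hg
  li <- 0L
  while (g$n_vertices > cfg$coarsening_stop && li < 60L) {
    li <- li + 1L
    ord <- with_seed(seeds[[li]], sample.int(g$n_vertices)) - 1L
    inc <- vertex_incidence(g)
    m <- ip_match_cpp(g$eptr, g$pins, inc$veptr, inc$vedges,
                      g$vertex_weights, ord, max_cluster_weight)
    if (m$n_groups >= g$n_vertices * 0.95) break  # < 5% reduction
    cg <- contract_hypergraph(g, m$group, m$n_groups)
    levels[[length(levels) + 1L]] <- list(hg = cg, group = m$group,
                                          ops = m$ops)
    g <- cg
  }
  levels
}

# Merge matched groups: coarse weight = sum of fine weights, pins relabeled
# with within-edge duplicates collapsed and singleton edges dropped.
contract_hypergraph <- function(hg, group, n_groups) {
  w <- as.vector(rowsum(hg$vertex_weights,
                        factor(group, levels = seq_len(n_groups) - 1L)))
  m <- n_hyperedges(hg)
  if (m == 0L) return(new_hypergraph(n_groups, 0L, integer(), w))
  eid <- rep.int(seq_len(m), diff(hg$eptr))
  cp <- group[hg$pins + 1L]
  o <- order(eid, cp)
  eid <- eid[o]; cp <- cp[o]
  keep <- c(TRUE, eid[-1L] != eid[-length(eid)] | cp[-1L] != cp[-length(cp)])
  eid <- eid[keep]; cp <- cp[keep]
  sizes <- tabulate(eid, nbins = m)
  big <- sizes >= 2L
  keep2 <- big[eid]
  eid <- eid[keep2]; cp <- cp[keep2]
  sizes <- sizes[big]
  new_hypergraph(n_groups, c(0L, cumsum(sizes)), cp, w)
}

#' Balanced seed partition of the coarsest level
#'
#' Longest-processing-time greedy: coarse vertices are taken in decreasing
#' weight order and placed on the currently lightest part, which bounds
#' the final load gap by one vertex weight and never produces an empty
#' part (P <= number of coarse vertices is required).
#'
#' @param coarse_hg The coarsest `snn_hypergraph`.
#' @param cfg An [partitioner_config()].
#' @return An `snn_assignment`.
#' @export
initial_partition <- function(coarse_hg, cfg) {
  stopifnot(inherits(coarse_hg, "snn_hypergraph"))
  n <- coarse_hg$n_vertices
  P <- cfg$n_parts
  if (n < P) stop("fewer coarse vertices than parts", call. = FALSE)
  ord <- order(coarse_hg$vertex_weights, decreasing = TRUE)
  part <- greedy_lightest(coarse_hg$vertex_weights, ord, P)
  as_assignment(part, P)
}

#' Fiduccia-Mattheyses refinement
#'
#' Pass-based local search on the connectivity-1 cut: each pass visits the
#' boundary vertices (members of hyperedges spanning more than one part)
#' in a seeded random order, tentatively moves each to its gain-maximal
#' admissible part and locks it, then rolls back to the best prefix of the
#' move sequence. A move is admissible if the target part's load stays
#' within the tolerance and the source part keeps at least one vertex;
#' the output cost is never worse than the input cost and accepted states
#' never violate the balance constraint. Passes stop at `max_fm_passes`
#' or at the first zero-gain pass.
#'
#' @param hg An `snn_hypergraph`.
#' @param a A valid `snn_assignment` to refine.
#' @param cfg An [partitioner_config()] (its `tolerance` defines the
#'   admissible max load; its `seed` the visit orders).
#' @return The refined `snn_assignment` with attribute `fm_moves`.
#' @export
fm_refine <- function(hg, a, cfg) {
  stopifnot(inherits(hg, "snn_hypergraph"),
            inherits(cfg, "snn_partitioner_config"))
  check_assignment(a, hg$n_vertices)
  P <- n_parts(a)
  max_load <- cfg$tolerance * sum(hg$vertex_weights) / P
  inc <- vertex_incidence(hg)
  part <- as.integer(a)
  seeds <- with_seed(cfg$seed, sample.int(.Machine$integer.max - 1L, 64L))
  moves <- 0L
  for (pass in seq_len(cfg$max_fm_passes)) {
    ord <- with_seed(seeds[[pass]], sample.int(hg$n_vertices)) - 1L
    fm <- fm_pass_cpp(hg$eptr, hg$pins, inc$veptr, inc$vedges,
                      hg$vertex_weights, part, P, max_load, ord)
    part <- fm$part
    moves <- moves + fm$moves
    if (fm$gain <= 0) break
  }
  out <- as_assignment(part, P)
  attr(out, "method") <- attr(a, "method")
  attr(out, "fm_moves") <- moves
  out
}

#' Allocate a network's neurons by strategy name
#'
#' Dispatches to [allocate_round_robin()], [allocate_random_balanced()] or
#' [partition_hypergraph()] and returns the assignment over the network's
#' neurons. All three strategies yield total assignments over the same
#' vertex set; simulated spike dynamics are identical across them (only
#' the communication accounting differs).
#'
#' @param net An `snn_network`.
#' @param strategy One of `"round_robin"`, `"random_balanced"`,
#'   `"hypergraph"`.
#' @param P Number of processes.
#' @param seed Seed for the randomised strategies.
#' @param hg Optional pre-built hypergraph (to avoid recomputation).
#' @param ... Further arguments to [partitioner_config()].
#' @return An `snn_assignment`.
#' @export
allocate <- function(net, strategy = c("round_robin", "random_balanced",
                                       "hypergraph"),
                     P, seed = 1, hg = NULL, ...) {
  strategy <- match.arg(strategy)
  stopifnot(inherits(net, "snn_network"))
  switch(strategy,
    round_robin = allocate_round_robin(net$n_neurons, P),
    random_balanced = allocate_random_balanced(
      hg %||% network_to_hypergraph(net), P, seed),
    hypergraph = partition_hypergraph(
      hg %||% network_to_hypergraph(net),
      partitioner_config(n_parts = P, seed = seed, ...)))
}

#' Write an assignment as a two-column CSV
#'
#' @param a An `snn_assignment`.
#' @param path Output path (columns `neuron_id`, `process_id`).
#' @export
write_assignment <- function(a, path) {
  stopifnot(inherits(a, "snn_assignment"))
  data.table::fwrite(data.table::data.table(
    neuron_id = seq_along(a) - 1L, process_id = as.integer(a)), path)
  invisible(path)
}
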
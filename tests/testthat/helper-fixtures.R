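# Test fixtures and independent brute-force oracles. The oracles evaluate
# definitions directly (loops over hyperedges, exhaustive enumeration) and
# never share code with the package's evaluation paths.

# Hand-built single-population network with an explicit edge list.
toy_network <- function(n, pre = integer(), post = integer(),
                        weight = 0.1, delay = 0.1,
                        params = neuron_params(), dt = 0.1,
                        synapse = synapse_params()) {
  stopifnot(length(pre) == length(post))
  w <- rep_len(weight, length(pre))
  d <- rep_len(delay, length(pre))
  o <- order(pre, post)
  structure(list(
    n_neurons = as.integer(n),
    edges = data.frame(pre = as.integer(pre)[o], post = as.integer(post)[o],
                       weight = w[o], delay = d[o]),
    population = rep(1L, n), area = rep(0L, n),
    pops = data.frame(name = "pop", size = as.integer(n), excitatory = TRUE,
                      stringsAsFactors = FALSE),
    pop_params = list(pop = params),
    dt = dt, synapse = synapse, n_areas = 1L, area_size = as.integer(n),
    seeds = list(structure = 1L, weights = 1L, delays = 1L)),
    class = "snn_network")
}

# Random small hypergraph for oracle comparisons.
rand_hypergraph <- function(n_vertices, n_edges, seed, max_size = 5,
                            unit_weights = FALSE) {
  set.seed(seed)
  edges <- lapply(seq_len(n_edges), function(i) {
    k <- sample(2:min(max_size, n_vertices), 1)
    sample.int(n_vertices, k) - 1L
  })
  w <- if (unit_weights) rep(1, n_vertices) else sample(1:5, n_vertices, TRUE)
  hypergraph(edges, n_vertices, w)
}

rand_assignment <- function(n, P, seed) {
  set.seed(seed)
  as_assignment(sample.int(P, n, replace = TRUE) - 1L, P)
}

# Brute-force connectivity-1 cut: per hyperedge, the set of parts of its
# members, summing (set size - 1).
bf_cut <- function(hg, a) {
  part <- as.integer(a)
  m <- length(hg$eptr) - 1L
  total <- 0
  for (e in seq_len(m)) {
    members <- hg$pins[(hg$eptr[e] + 1L):hg$eptr[e + 1L]]
    total <- total + length(unique(part[members + 1L])) - 1L
  }
  total
}

# Brute-force imbalance straight from the definition.
bf_imbalance <- function(hg, a) {
  P <- attr(a, "n_parts")
  loads <- numeric(P)
  for (v in seq_len(hg$n_vertices)) {
    p <- as.integer(a)[v] + 1L
    loads[p] <- loads[p] + hg$vertex_weights[v]
  }
  max(loads) / mean(loads)
}

# Exhaustive minimum cut over all P^n assignments (no balance constraint,
# so it lower-bounds any constrained partitioner).
bf_optimum <- function(hg, P) {
  n <- hg$n_vertices
  stopifnot(P^n <= 3^9 + 1)
  best <- Inf
  idx <- integer(n)
  for (code in 0:(P^n - 1)) {
    x <- code
    for (v in seq_len(n)) {
      idx[v] <- x %% P
      x <- x %/% P
    }
    best <- min(best, bf_cut(hg, as_assignment(idx, P)))
  }
  best
}

expect_same_raster <- function(a, b) {
  expect_identical(a$raster, b$raster)
}
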
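#' Hypergraphs for spike-communication modelling
#'
#' A hypergraph `H = (V, E)` is a vertex set plus a set of hyperedges,
#' each an arbitrary non-empty subset of `V`. Here the hypergraph is the
#' communication model of an SNN: one hyperedge per presynaptic neuron,
#' containing that neuron together with all of its postsynaptic targets --
#' the all-or-nothing unit of spike communication (when a neuron fires,
#' every target must be notified). Vertex weights model per-neuron
#' workload.
#'
#' `hypergraph()` builds the container from an explicit list of vertex
#' sets; [network_to_hypergraph()] derives it from a network. Internally
#' hyperedges are stored in compressed (CSR-style) form: a 0-based offset
#' vector `eptr` of length `m + 1` and a pin vector `pins` of 0-based
#' vertex ids.
#'
#' @param edges List of integer vectors of 0-based vertex ids (one per
#'   hyperedge, each non-empty; members are stored deduplicated and
#'   sorted).
#' @param n_vertices Vertex count.
#' @param vertex_weights Numeric workload weights, `>= 1` (default all 1).
#' @return An object of class `snn_hypergraph`.
#' @export
hypergraph <- function(edges, n_vertices, vertex_weights = NULL) {
  check_number(n_vertices, "n_vertices", min = 0, integer = TRUE)
  n_vertices <- as.integer(n_vertices)
  edges <- lapply(edges, function(e) {
    e <- sort.int(unique(as.integer(e)))
    if (length(e) == 0L) stop("empty hyperedge", call. = FALSE)
    if (any(e < 0L) || any(e >= n_vertices)) {
      stop("hyperedge member outside [0, n_vertices)", call. = FALSE)
    }
    e
  })
  vertex_weights <- vertex_weights %||% rep(1, n_vertices)
  if (length(vertex_weights) != n_vertices || any(vertex_weights < 1)) {
    stop("`vertex_weights` must have length n_vertices with all values >= 1",
         call. = FALSE)
  }
  sizes <- lengths(edges)
  new_hypergraph(
    n_vertices = n_vertices,
    eptr = c(0L, cumsum(sizes)),
    pins = unlist(edges, use.names = FALSE) %||% integer(),
    vertex_weights = as.numeric(vertex_weights))
}

new_hypergraph <- function(n_vertices, eptr, pins, vertex_weights) {
  structure(list(n_vertices = as.integer(n_vertices),
                 eptr = as.integer(eptr), pins = as.integer(pins),
                 vertex_weights = as.numeric(vertex_weights)),
            class = "snn_hypergraph")
}

n_hyperedges <- function(hg) length(hg$eptr) - 1L

# List-of-vectors view (0-based members), mostly for tests and export.
hyperedge_list <- function(hg) {
  m <- n_hyperedges(hg)
  if (m == 0L) return(list())
  unname(split(hg$pins, rep.int(seq_len(m), diff(hg$eptr))))
}

#' Derive the communication hypergraph of a network
#'
#' One hyperedge per presynaptic neuron with out-degree at least 1,
#' containing the neuron and all of its postsynaptic targets (each target
#' once, regardless of synapse multiplicity -- one spike message per
#' target). Neurons with no outgoing synapses produce no hyperedge: they
#' never initiate communication, but they still carry workload weight.
#' Vertex weights are `in-degree + 1` (see [vertex_weight()]).
#'
#' @param net An `snn_network`.
#' @return An `snn_hypergraph` with `n_vertices == net$n_neurons`.
#' @examples
#' net <- build_network(cm_like_spec(n_neurons = 200, mean_in_degree = 5), 1)
#' hg <- network_to_hypergraph(net)
#' sum(hg$vertex_weights) == nrow(net$edges) + net$n_neurons
#' @export
network_to_hypergraph <- function(net) {
  stopifnot(inherits(net, "snn_network"))
  n <- net$n_neurons
  e <- net$edges  # canonical: sorted by (pre, post)
  w <- tabulate(e$post + 1L, nbins = max(n, 1L))[seq_len(n)] + 1
  if (nrow(e) == 0L) {
    return(new_hypergraph(n, 0L, integer(), w))
  }
  # One pin per distinct (pre, post) pair: multiple synapses to the same
  # target still mean a single spike message.
  nr <- nrow(e)
  keep <- c(TRUE, !(e$pre[-1L] == e$pre[-nr] & e$post[-1L] == e$post[-nr]))
  e <- e[keep, , drop = FALSE]
  out_deg <- tabulate(e$pre + 1L, nbins = n)
  heads <- which(out_deg > 0L)            # presyn neurons, ascending
  sizes <- out_deg[heads] + 1L            # head pin + targets
  eptr <- c(0L, cumsum(sizes))
  pins <- integer(sum(sizes))
  head_pos <- eptr[-length(eptr)] + 1L
  pins[head_pos] <- heads - 1L
  pins[-head_pos] <- e$post
  new_hypergraph(n, eptr, pins, w)
}

#' Workload weight of a neuron
#'
#' The weight of a hypergraph vertex is the number of dendritic inputs of
#' the neuron plus one: synapse objects live on the postsynaptic side, so
#' incoming synapses dominate per-neuron computation, and the `+ 1`
#' accounts for the neuron update itself. Summed over the network,
#' `sum(weights) == n_synapses + n_neurons`.
#'
#' @param net An `snn_network`.
#' @param neuron 0-based neuron id(s).
#' @return Numeric weight(s), `in_degree + 1`.
#' @export
vertex_weight <- function(net, neuron) {
  stopifnot(inherits(net, "snn_network"))
  neuron <- as.integer(neuron)
  if (any(neuron < 0L) || any(neuron >= net$n_neurons)) {
    stop("neuron id out of range", call. = FALSE)
  }
  in_deg <- tabulate(net$edges$post + 1L, nbins = max(net$n_neurons, 1L))
  in_deg[neuron + 1L] + 1
}

#' Neuron-to-process assignments
#'
#' An assignment maps every vertex (neuron) to one of `n_parts` processes,
#' 0-based on both sides. [as_assignment()] validates and classes a plain
#' integer vector.
#'
#' @param part Integer vector of part ids in `[0, n_parts)`, one per
#'   vertex.
#' @param n_parts Number of processes `P >= 1`.
#' @return An `snn_assignment` (integer vector with an `n_parts`
#'   attribute).
#' @export
as_assignment <- function(part, n_parts) {
  check_number(n_parts, "n_parts", min = 1, integer = TRUE)
  part <- as.integer(part)
  if (anyNA(part)) stop("assignment must cover all vertices", call. = FALSE)
  if (length(part) && (min(part) < 0L || max(part) >= n_parts)) {
    stop("part ids must lie in [0, n_parts)", call. = FALSE)
  }
  structure(part, n_parts = as.integer(n_parts), class = "snn_assignment")
}

n_parts <- function(a) attr(a, "n_parts")

check_assignment <- function(a, n_vertices) {
  if (!inherits(a, "snn_assignment")) {
    stop("expected an `snn_assignment` (see as_assignment())", call. = FALSE)
  }
  if (length(a) != n_vertices) {
    stop(sprintf("assignment covers %d vertices but the object has %d",
                 length(a), n_vertices), call. = FALSE)
  }
  invisible(a)
}

#' Connectivity-1 cut cost of a partition
#'
#' For each hyperedge let `parts(e)` be the set of processes that host at
#' least one of its members. The hyperedge costs `|parts(e)| - 1` and the
#' partition costs the sum over all hyperedges. The cost is 0 exactly when
#' no hyperedge spans more than one process, i.e. when the simulation
#' needs no interprocess communication.
#'
#' @param hg An `snn_hypergraph`.
#' @param a An `snn_assignment` covering all vertices.
#' @return Non-negative cut cost (a count).
#' @examples
#' hg <- hypergraph(list(c(0, 1, 2), c(2, 3)), 4)
#' partition_cost(hg, as_assignment(c(0, 0, 0, 1), 2))  # 0 + 1
#' @export
partition_cost <- function(hg, a) {
  stopifnot(inherits(hg, "snn_hypergraph"))
  check_assignment(a, hg$n_vertices)
  cut_connectivity_cpp(hg$eptr, hg$pins, as.integer(a), n_parts(a))
}

#' Load imbalance of a partition
#'
#' The load `L(p)` of a process is the sum of the weights of its vertices;
#' the imbalance is the maximum load divided by the mean load over all
#' `P` processes. It is 1 for a perfectly balanced assignment and is the
#' quantity constrained (below a tolerance such as 1.001) during
#' partitioning. Empty parts are allowed by the metric and simply lower
#' the mean.
#'
#' @inheritParams partition_cost
#' @return Imbalance ratio `>= 1` (or 1 for an empty hypergraph).
#' @export
partition_imbalance <- function(hg, a) {
  stopifnot(inherits(hg, "snn_hypergraph"))
  check_assignment(a, hg$n_vertices)
  P <- n_parts(a)
  if (hg$n_vertices == 0L) return(1)
  loads <- part_loads(hg, a)
  max(loads) / (sum(loads) / P)
}

part_loads <- function(hg, a) {
  P <- n_parts(a)
  as.vector(rowsum(hg$vertex_weights,
                   factor(as.integer(a), levels = seq_len(P) - 1L)))
}

#' Partition quality metrics
#'
#' Convenience wrapper returning cut cost, per-part loads and imbalance in
#' one object.
#'
#' @inheritParams partition_cost
#' @return An `snn_partition_metrics` list with `cut_cost`, `part_loads`
#'   and `imbalance`.
#' @export
partition_metrics <- function(hg, a) {
  structure(list(cut_cost = partition_cost(hg, a),
                 part_loads = part_loads(hg, a),
                 imbalance = partition_imbalance(hg, a)),
            class = "snn_partition_metrics")
}

#' Process communication graph
#'
#' Collapses a network under an assignment into its process communication
#' graph (PCG): one node per process annotated with its hosted neuron
#' count, and a directed edge `a -> b` exactly when at least one synapse
#' has its presynaptic neuron on `a` and its postsynaptic neuron on
#' `b != a`. Edges carry the crossing synapse count and the connection
#' density `d_conn = crossing / (N_a * N_b)`. Processes joined by an edge
#' must synchronise during simulation.
#'
#' @param net An `snn_network`.
#' @param a An `snn_assignment` over the neurons.
#' @return An `snn_pcg`: `n_processes`, `neurons` (hosted counts), and an
#'   `edges` data frame (`from`, `to`, `synapses`, `density`).
#' @export
build_pcg <- function(net, a) {
  stopifnot(inherits(net, "snn_network"))
  check_assignment(a, net$n_neurons)
  P <- n_parts(a)
  part <- as.integer(a)
  hosted <- tabulate(part + 1L, nbins = P)
  pp <- part[net$edges$pre + 1L]
  qq <- part[net$edges$post + 1L]
  cross <- pp != qq
  if (any(cross)) {
    key <- pp[cross] * P + qq[cross]
    cnt <- tabulate(key + 1L, nbins = P * P)
    nz <- which(cnt > 0L) - 1L
    from <- nz %/% P
    to <- nz %% P
    edges <- data.frame(from = from, to = to, synapses = cnt[nz + 1L],
                        density = cnt[nz + 1L] /
                          (as.numeric(hosted[from + 1L]) * hosted[to + 1L]))
  } else {
    edges <- data.frame(from = integer(), to = integer(),
                        synapses = integer(), density = numeric())
  }
  structure(list(n_processes = P, neurons = hosted, edges = edges),
            class = "snn_pcg")
}

#' Export / import hypergraphs in hMETIS text format
#'
#' The standard hMETIS file: a header line `n_hyperedges n_vertices fmt`
#' (fmt 10 marks the presence of vertex weights), one line of 1-based
#' vertex ids per hyperedge, then one vertex weight per line.
#'
#' @param hg An `snn_hypergraph`.
#' @param path File path.
#' @return `write_hmetis()` returns `path` invisibly; `read_hmetis()` the
#'   parsed `snn_hypergraph`.
#' @export
write_hmetis <- function(hg, path) {
  stopifnot(inherits(hg, "snn_hypergraph"))
  m <- n_hyperedges(hg)
  lines <- c(
    sprintf("%d %d 10", m, hg$n_vertices),
    vapply(hyperedge_list(hg), function(e) paste(e + 1L, collapse = " "), ""),
    sprintf("%.17g", hg$vertex_weights))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_hmetis
#' @export
read_hmetis <- function(path) {
  lines <- readLines(path)
  hdr <- scan(text = lines[1L], quiet = TRUE)
  m <- as.integer(hdr[1L]); n <- as.integer(hdr[2L])
  fmt <- if (length(hdr) >= 3L) as.integer(hdr[3L]) else 0L
  edges <- lapply(seq_len(m), function(i) {
    as.integer(scan(text = lines[1L + i], quiet = TRUE)) - 1L
  })
  w <- if (fmt %in% c(10L, 11L)) {
    as.numeric(lines[(m + 2L):(m + 1L + n)])
  } else NULL
  hypergraph(edges, n, w)
}

#' @export
print.snn_hypergraph <- function(x, ...) {
  cat(sprintf("snn_hypergraph: %s vertices, %s hyperedges, %s pins\n",
              format(x$n_vertices, big.mark = ","),
              format(n_hyperedges(x), big.mark = ","),
              format(length(x$pins), big.mark = ",")))
  invisible(x)
}

#' @export
print.snn_assignment <- function(x, ...) {
  P <- n_parts(x)
  cat(sprintf("snn_assignment: %s vertices over %d process(es)\n",
              format(length(x), big.mark = ","), P))
  for (at in c("method", "cut_cost", "imbalance", "tolerance_used")) {
    if (!is.null(attr(x, at))) {
      cat(sprintf("  %s: %s\n", at, format(attr(x, at))))
    }
  }
  invisible(x)
}

#' @export
print.snn_partition_metrics <- function(x, ...) {
  cat(sprintf("cut cost %g, imbalance %.6f, loads [%s]\n", x$cut_cost,
              x$imbalance, paste(format(x$part_loads), collapse = ", ")))
  invisible(x)
}

#' @export
print.snn_pcg <- function(x, ...) {
  cat(sprintf("Process communication graph: %d processes, %d directed edges\n",
              x$n_processes, nrow(x$edges)))
  invisible(x)
}
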
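#' Per-step spike traffic
#'
#' The communication demand of one exchange step, before any pattern is
#' applied: one row per (source process, destination process, spiking
#' neuron id) triple, derived from the firing neurons and the target
#' lookup table. Destinations never equal sources and a neuron id appears
#' at most once per (src, dest) pair (one spike message per target process
#' regardless of synapse multiplicity).
#'
#' @param src,dest Integer process ids in `[0, P)`.
#' @param id Integer neuron ids (the address-event payload).
#' @param P Number of processes.
#' @return An `snn_step_traffic` list.
#' @export
step_traffic <- function(src, dest, id, P) {
  check_number(P, "P", min = 1, integer = TRUE)
  src <- as.integer(src); dest <- as.integer(dest); id <- as.integer(id)
  stopifnot(length(src) == length(dest), length(dest) == length(id))
  if (length(src)) {
    if (min(src, dest) < 0L || max(src, dest) >= P) {
      stop("process ids out of range", call. = FALSE)
    }
    if (any(src == dest)) {
      stop("traffic destinations must differ from sources", call. = FALSE)
    }
  }
  structure(list(P = as.integer(P), src = src, dest = dest, id = id),
            class = "snn_step_traffic")
}

#' Personalized exchange (PEX) census
#'
#' The two-phase census: (1) an explicit all-to-all handshake in which
#' *every* process sends one metadata unit to each of the other `P - 1`
#' processes -- even processes with nothing to send must announce that
#' nothing is coming -- for exactly `P * (P - 1)` units per exchange,
#' independent of activity; (2) payload messages only along the pairs
#' flagged in the metadata. The handshake volume grows quadratically in
#' `P` and becomes the dominant exchange cost at scale.
#'
#' @param traffic An [step_traffic()] object.
#' @return A list with `record` (an `snn_comm_record`: rounds, metadata
#'   and payload unit/byte counts, message counts, per-pair payload
#'   counts) and `delivered` (data frame `src`, `dest`, `id`, sorted by
#'   destination then source then id -- the exact multiset of delivered
#'   spike ids).
#' @examples
#' t0 <- step_traffic(src = c(0, 0), dest = c(1, 2), id = c(7, 7), P = 4)
#' pex_exchange(t0)$record$metadata_units  # 4 * 3
#' @export
pex_exchange <- function(traffic) {
  stopifnot(inherits(traffic, "snn_step_traffic"))
  P <- traffic$P
  base <- traffic_base(traffic)
  record <- structure(c(base, list(
    pattern = "pex", rounds = 2L,
    metadata_units = P * (P - 1L),
    metadata_bytes = 4 * P * (P - 1L),
    messages_total = P * (P - 1L) + base$messages_payload)),
    class = "snn_comm_record")
  list(record = record, delivered = delivered_frame(traffic))
}

#' Neighborhood exchange (NBX) census
#'
#' Dynamic sparse data exchange: payload messages go only to actual
#' targets and the explicit handshake is replaced by an asynchronous
#' barrier -- senders post non-blocking sends, probe for incoming
#' messages, and enter the barrier once their sends complete; the barrier
#' completing signals that all traffic is in flight or delivered. The
#' barrier token carries a payload of zero bytes (it is counted as one
#' message per process but contributes no metadata volume), so NBX
#' metadata volume is identically 0 and total volume scales with actual
#' traffic rather than with `P^2`.
#'
#' Delivered id multisets are identical to [pex_exchange()] on the same
#' traffic: the pattern can never change simulation dynamics.
#'
#' @inheritParams pex_exchange
#' @return As [pex_exchange()].
#' @export
nbx_exchange <- function(traffic) {
  stopifnot(inherits(traffic, "snn_step_traffic"))
  P <- traffic$P
  base <- traffic_base(traffic)
  record <- structure(c(base, list(
    pattern = "nbx", rounds = 1L,
    metadata_units = 0L,
    metadata_bytes = 0,
    messages_total = base$messages_payload + P)),  # + P barrier tokens
    class = "snn_comm_record")
  list(record = record, delivered = delivered_frame(traffic))
}

# Pattern-independent payload accounting: 4 bytes per neuron id, one
# payload message per communicating (src, dest) pair.
traffic_base <- function(traffic) {
  P <- traffic$P
  n <- length(traffic$id)
  if (n) {
    key <- traffic$src * P + traffic$dest
    pair_counts <- tabulate(key + 1L, nbins = P * P)
    nz <- which(pair_counts > 0L) - 1L
    pairs <- data.frame(src = nz %/% P, dest = nz %% P,
                        n_ids = pair_counts[nz + 1L])
    n_remote <- length(unique(traffic$id))
  } else {
    pairs <- data.frame(src = integer(), dest = integer(), n_ids = integer())
    n_remote <- 0L
  }
  list(P = P, pairs = pairs,
       payload_ids = n, payload_bytes = 4 * n,
       messages_payload = nrow(pairs),
       n_remote_spikes = n_remote)
}

delivered_frame <- function(traffic) {
  d <- data.frame(src = traffic$src, dest = traffic$dest, id = traffic$id)
  d <- d[order(d$dest, d$src, d$id), , drop = FALSE]
  rownames(d) <- NULL
  d
}

#' Aggregate communication statistics over a run
#'
#' Reduces a stream of per-exchange [pex_exchange()]/[nbx_exchange()]
#' records to the run-level metrics:
#'
#' * `arn` -- average runtime neighbors: the mean, over processes and
#'   exchange steps (silent steps included), of the number of distinct
#'   processes a process sends payload to; at most `P - 1`, and 0 when
#'   `P = 1`.
#' * `remote_spikes` -- firing events whose neuron has at least one
#'   remote target (counted once per firing event).
#' * `remote_spike_messages` -- per-(spike, target process) propagation
#'   events, i.e. total payload ids sent; the finer-grained companion of
#'   `remote_spikes`.
#' * `payload_bytes`, `metadata_bytes`, `messages_total` -- byte/message
#'   totals (4 bytes per id and per metadata unit; NBX metadata is 0).
#' * `pair_frequency` -- messages from `a` to `b` per simulated second.
#'
#' @param records List of `snn_comm_record`s from a completed run.
#' @param P Number of processes.
#' @param duration_ms Simulated time covered by the records (for
#'   `pair_frequency`).
#' @return An `snn_comm_stats` list. An empty record list yields
#'   zero-filled statistics.
#' @export
accumulate_stats <- function(records, P, duration_ms = NA_real_) {
  check_number(P, "P", min = 1, integer = TRUE)
  n_rec <- length(records)
  if (n_rec == 0L) {
    return(structure(list(
      P = as.integer(P), n_exchanges = 0L, arn = 0, remote_spikes = 0,
      remote_spike_messages = 0, payload_bytes = 0, metadata_bytes = 0,
      messages_total = 0, pair_frequency = data.frame(
        src = integer(), dest = integer(), per_second = numeric()),
      duration_ms = duration_ms), class = "snn_comm_stats"))
  }
  stopifnot(all(vapply(records, inherits, TRUE, "snn_comm_record")))
  pair_counts <- numeric(P * P)
  distinct_pairs <- 0
  for (r in records) {
    if (nrow(r$pairs)) {
      key <- r$pairs$src * P + r$pairs$dest
      pair_counts[key + 1L] <- pair_counts[key + 1L] + 1
      distinct_pairs <- distinct_pairs + nrow(r$pairs)
    }
  }
  nz <- which(pair_counts > 0) - 1L
  secs <- duration_ms / 1000
  structure(list(
    P = as.integer(P), n_exchanges = n_rec,
    arn = distinct_pairs / (P * n_rec),
    remote_spikes = sum(vapply(records, `[[`, 0, "n_remote_spikes")),
    remote_spike_messages = sum(vapply(records, `[[`, 0, "payload_ids")),
    payload_bytes = sum(vapply(records, `[[`, 0, "payload_bytes")),
    metadata_bytes = sum(vapply(records, `[[`, 0, "metadata_bytes")),
    messages_total = sum(vapply(records, `[[`, 0, "messages_total")),
    pair_frequency = data.frame(src = nz %/% P, dest = nz %% P,
                                per_second = pair_counts[nz + 1L] / secs),
    duration_ms = duration_ms), class = "snn_comm_stats")
}

#' Theoretical PEX volume curves
#'
#' Closed-form data volume of the two PEX phases on an artificial network
#' with constant spiking activity, per exchange step: the handshake always
#' costs `P * (P - 1)` metadata units (quadratic in `P`, independent of
#' activity), while the payload grows with the firing rate. Payload is
#' reported under two accountings: *per process* (each spike sends its id
#' to `mean_remote_targets` processes; the default `P - 1` is the dense /
#' random-allocation limit) and, when `synapses_per_neuron` is given,
#' *per synapse* (one id per remote synapse). The crossover process count
#' -- where handshake volume overtakes payload volume -- is attached per
#' rate.
#'
#' @param P_values Integer vector of process counts.
#' @param rates_hz Spike rates (spikes/s per neuron), e.g. 20/80/160 for
#'   low/medium/high activity.
#' @param neurons_per_process Neurons hosted per process (strong-scaling
#'   fixed-model convention: total neurons = `neurons_per_process * P` is
#'   not held fixed here; pass `total_neurons` to fix the model size).
#' @param total_neurons Optional fixed total model size (overrides
#'   `neurons_per_process`).
#' @param dt Step (ms); one exchange per step.
#' @param mean_remote_targets Mean distinct remote target processes per
#'   spike (default `P - 1`).
#' @param synapses_per_neuron Optional mean out-degree for the per-synapse
#'   accounting.
#' @param bytes_per_unit Bytes per id and per metadata unit (default 4,
#'   the 32-bit address-event convention).
#' @return A data frame with one row per `(P, rate)`; attribute
#'   `crossover` maps each rate to the smallest `P` whose handshake bytes
#'   exceed its payload bytes (NA if none).
#' @export
theoretical_pex_curves <- function(P_values, rates_hz, neurons_per_process,
                                   total_neurons = NULL, dt = 0.1,
                                   mean_remote_targets = NULL,
                                   synapses_per_neuron = NULL,
                                   bytes_per_unit = 4) {
  stopifnot(all(P_values >= 1), all(rates_hz >= 0))
  rows <- expand.grid(P = as.integer(P_values), rate_hz = rates_hz,
                      KEEP.OUT.ATTRS = FALSE)
  n_tot <- if (!is.null(total_neurons)) rep(total_neurons, nrow(rows))
           else neurons_per_process * rows$P
  spikes_per_exchange <- rows$rate_hz * n_tot * dt / 1000
  mrt <- mean_remote_targets %||% (rows$P - 1)
  rows$handshake_units <- rows$P * (rows$P - 1)
  rows$handshake_bytes <- bytes_per_unit * rows$handshake_units
  rows$payload_ids <- spikes_per_exchange * mrt
  rows$payload_bytes <- bytes_per_unit * rows$payload_ids
  rows$payload_ids_per_synapse <- if (!is.null(synapses_per_neuron)) {
    spikes_per_exchange * synapses_per_neuron
  } else NA_real_
  cross <- vapply(rates_hz, function(r) {
    sub <- rows[rows$rate_hz == r, ]
    sub <- sub[order(sub$P), ]
    hit <- which(sub$handshake_bytes > sub$payload_bytes)
    if (length(hit)) sub$P[hit[1L]] else NA_integer_
  }, 0L)
  attr(rows, "crossover") <- setNames(cross, rates_hz)
  rows
}

#' Write a per-exchange record stream as CSV
#'
#' One row per communicating (src, dest) pair per exchange step, with the
#' per-record metadata/payload totals repeated on each row (silent
#' exchanges produce a single row with NA src/dest).
#'
#' @param records List of `snn_comm_record`s (e.g. from a
#'   [run_simulation()] call with `keep_records = TRUE`).
#' @param path Output path.
#' @export
write_comm_records <- function(records, path) {
  rows <- lapply(seq_along(records), function(i) {
    r <- records[[i]]
    p <- if (nrow(r$pairs)) r$pairs else
      data.frame(src = NA_integer_, dest = NA_integer_, n_ids = 0L)
    data.frame(exchange = i, pattern = r$pattern, p,
               metadata_units = r$metadata_units,
               payload_bytes = r$payload_bytes,
               messages_total = r$messages_total)
  })
  data.table::fwrite(data.table::rbindlist(rows), path)
  invisible(path)
}

#' Abstract communication cost model
#'
#' A deliberately *non-physical* linear cost for qualitative PEX-vs-NBX
#' comparisons only: `alpha` per message, `beta` per byte, plus `alpha`
#' per sequential communication round per exchange (PEX pays two rounds,
#' NBX one). No units are implied and no wall-clock prediction is made --
#' real exchange timing depends on hardware, overlap and contention,
#' which this package does not model.
#'
#' @param sim An `snn_sim` result.
#' @param alpha Cost per message and per round (latency-like).
#' @param beta Cost per byte (bandwidth-like).
#' @return A single abstract cost value.
#' @export
abstract_comm_cost <- function(sim, alpha = 1, beta = 0.01) {
  stopifnot(inherits(sim, "snn_sim"))
  st <- sim$comm
  rounds <- switch(sim$comm_pattern, pex = 2, nbx = 1)
  alpha * (st$messages_total + rounds * st$n_exchanges) +
    beta * (st$payload_bytes + st$metadata_bytes)
}

#' @export
print.snn_comm_stats <- function(x, ...) {
  cat(sprintf("Communication statistics over %d exchange step(s), P = %d\n",
              x$n_exchanges, x$P))
  cat(sprintf("  ARN %.3f | remote spikes %g | spike messages %g\n",
              x$arn, x$remote_spikes, x$remote_spike_messages))
  cat(sprintf("  payload %s B | metadata %s B | messages %s\n",
              format(x$payload_bytes, big.mark = ","),
              format(x$metadata_bytes, big.mark = ","),
              format(x$messages_total, big.mark = ",")))
  invisible(x)
}
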
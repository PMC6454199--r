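#' Simulation configuration
#'
#' @param duration_ms Simulated time (ms).
#' @param dt Time step (ms, default 0.1); also the resolution of the
#'   synaptic delay grid.
#' @param comm_pattern Census exchange pattern for the communication
#'   accounting: `"pex"` or `"nbx"`. The pattern never affects dynamics.
#' @param exchange_every Steps between exchanges (default 1, the
#'   worst-case regime forced by random per-synapse delays with a one-step
#'   minimum; message packing across steps is deliberately not modelled).
#' @param seed Seed for the initial membrane potentials.
#' @param init Initial condition: `"uniform"` (default) draws each
#'   starting potential uniformly between reset and threshold, spreading
#'   firing phases the way an external noisy drive would; `"rest"` starts
#'   every neuron exactly at `v_rest` (with a suprathreshold resting
#'   potential this puts the whole network in phase lockstep -- useful for
#'   edge-case studies, degenerate as a communication benchmark).
#' @param keep_records Keep the per-exchange communication records on the
#'   result (they are always aggregated into `$comm`).
#' @return An `snn_sim_config` list.
#' @export
simulation_config <- function(duration_ms, dt = 0.1,
                              comm_pattern = c("pex", "nbx"),
                              exchange_every = 1, seed = 1,
                              init = c("uniform", "rest"),
                              keep_records = FALSE) {
  check_number(duration_ms, "duration_ms", min = 0)
  check_number(dt, "dt", min = .Machine$double.xmin)
  check_number(exchange_every, "exchange_every", min = 1, integer = TRUE)
  structure(list(duration_ms = duration_ms, dt = dt,
                 comm_pattern = match.arg(comm_pattern),
                 exchange_every = as.integer(exchange_every),
                 seed = seed, init = match.arg(init),
                 keep_records = isTRUE(keep_records)),
            class = "snn_sim_config")
}

#' One forward-Euler LIF update
#'
#' Vectorised leaky integrate-and-fire step with exponential synaptic
#' current. Per step: the synaptic current decays by
#' `exp(-dt / tau_syn)` and accumulates the newly arrived weights; then
#' non-refractory membranes integrate
#' `v <- v + dt / tau_m * (-(v - v_rest) + r_m * (i_ext + i_syn))`.
#' A neuron fires iff it is not refractory and `v >= v_thresh`; on firing
#' `v` is reset and the refractory counter set (the membrane is clamped at
#' `v_reset` while the counter runs down).
#'
#' @param state List with numeric vectors `v` (mV), `i_syn` and integer
#'   `refractory_steps_left` (one entry per neuron, or scalars).
#' @param params A [neuron_params()] object, or a list of equally shaped
#'   vectors for heterogeneous populations.
#' @param syn_input Summed synaptic weight arriving at each neuron this
#'   step.
#' @param dt Step (ms).
#' @param tau_syn Synaptic decay constant (ms), scalar or per neuron.
#' @return List with the updated `state` and a logical `fired` vector.
#' @examples
#' s <- list(v = -65, i_syn = 0, refractory_steps_left = 0L)
#' lif_step(s, neuron_params(v_rest = -65, i_ext = 0), 0, dt = 0.1)$fired
#' @export
lif_step <- function(state, params, syn_input, dt, tau_syn = 2) {
  check_number(dt, "dt", min = .Machine$double.xmin)
  v <- state$v
  i_syn <- state$i_syn * exp(-dt / tau_syn) + syn_input
  refr <- state$refractory_steps_left
  active <- refr <= 0L
  dv <- (dt / params$tau_m) *
    (-(v - params$v_rest) + params$r_m * (params$i_ext + i_syn))
  v <- ifelse(active, v + dv, v)
  refr <- ifelse(active, refr, refr - 1L)
  if (any(!is.finite(v))) {
    stop("non-finite membrane potential at neuron index ",
         which(!is.finite(v))[1L], call. = FALSE)
  }
  fired <- active & v >= params$v_thresh
  v[fired] <- rep_len(params$v_reset, length(v))[fired]
  refr[fired] <- rep_len(as.integer(round(params$t_ref / dt)),
                         length(refr))[fired]
  list(state = list(v = v, i_syn = i_syn, refractory_steps_left = refr),
       fired = fired)
}

#' Remote-target lookup table
#'
#' For each neuron, the sorted set of *remote* processes hosting at least
#' one of its postsynaptic targets (its own process is excluded). This is
#' the table each process consults when matching local spikes to outgoing
#' messages; it is populated once before simulation.
#'
#' @param net An `snn_network`.
#' @param a An `snn_assignment` over the neurons.
#' @return An `snn_target_lookup`: CSR offsets `lptr` (length
#'   `n_neurons + 1`) into `lproc` (0-based process ids).
#' @export
build_target_lookup <- function(net, a) {
  stopifnot(inherits(net, "snn_network"))
  check_assignment(a, net$n_neurons)
  P <- n_parts(a)
  part <- as.integer(a)
  n <- net$n_neurons
  pre <- net$edges$pre
  qq <- part[net$edges$post + 1L]
  keep <- qq != part[pre + 1L]
  pre <- pre[keep]; qq <- qq[keep]
  if (length(pre)) {
    key <- unique(as.numeric(pre) * P + qq)
    key <- sort(key)
    pre_u <- as.integer(key %/% P)
    proc <- as.integer(key %% P)
  } else {
    pre_u <- integer(); proc <- integer()
  }
  structure(list(P = P, n_neurons = n,
                 lptr = c(0L, cumsum(tabulate(pre_u + 1L, nbins = n))),
                 lproc = proc),
            class = "snn_target_lookup")
}

lookup_sets <- function(lookup) {
  n <- lookup$n_neurons
  sizes <- diff(lookup$lptr)
  out <- vector("list", n)
  nz <- which(sizes > 0L)
  if (length(nz)) {
    grp <- rep.int(nz, sizes[nz])
    out[nz] <- split(lookup$lproc, grp)
  }
  out[sizes == 0L] <- list(integer())
  out
}

#' Run a virtual-process distributed simulation
#'
#' Time-step-driven LIF simulation over `P` virtual processes. Each step
#' updates all neurons in ascending global id ([lif_step()]), collects the
#' spikes, delivers each spike to every postsynaptic synapse exactly
#' `delay / dt` steps later, and accounts the interprocess traffic of the
#' exchange through the configured census pattern ([pex_exchange()] /
#' [nbx_exchange()]).
#'
#' The engine executes sequentially but keeps an exact per-process
#' communication ledger; because the dynamics are computed globally in id
#' order, the spike raster is bit-identical for any allocation and either
#' communication pattern of the same network and config -- only the
#' communication statistics differ. Synapse objects live on the
#' postsynaptic side, so messages carry presynaptic neuron ids only.
#'
#' @param net An `snn_network` (all delays must sit on the `cfg$dt` grid
#'   and be at least one step).
#' @param a An `snn_assignment` covering all neurons.
#' @param cfg An [simulation_config()].
#' @return An `snn_sim` object: `raster` (data frame `step` (1-based),
#'   `neuron` (0-based), sorted by step then id), `comm` (an
#'   `snn_comm_stats`), per-process counters, the mean firing rate, and
#'   the run metadata.
#' @export
run_simulation <- function(net, a, cfg) {
  stopifnot(inherits(net, "snn_network"), inherits(cfg, "snn_sim_config"))
  check_assignment(a, net$n_neurons)
  n <- net$n_neurons
  P <- n_parts(a)
  part <- as.integer(a)
  dt <- cfg$dt
  n_steps <- as.integer(round(cfg$duration_ms / dt))

  e <- net$edges
  dsteps <- e$delay / dt
  if (nrow(e)) {
    if (any(abs(dsteps - round(dsteps)) > 1e-6)) {
      stop("synaptic delays must be multiples of dt", call. = FALSE)
    }
    dsteps <- as.integer(round(dsteps))
    if (any(dsteps < 1L)) {
      stop("synaptic delays must be at least one step", call. = FALSE)
    }
  } else dsteps <- integer()

  # CSR adjacency by presynaptic neuron (edges are pre-sorted).
  out_deg <- tabulate(e$pre + 1L, nbins = max(n, 1L))
  tptr <- c(0L, cumsum(out_deg))
  tgt <- e$post; wsyn <- e$weight

  # Per-neuron parameter vectors from the population tables.
  pp <- function(f) vapply(net$pop_params, `[[`, 0, f)[net$population]
  par <- list(v_rest = pp("v_rest"), v_thresh = pp("v_thresh"),
              v_reset = pp("v_reset"), tau_m = pp("tau_m"),
              r_m = pp("r_m"), t_ref = pp("t_ref"), i_ext = pp("i_ext"))
  tau_syn <- net$synapse$tau_syn

  v0 <- switch(cfg$init,
    rest = par$v_rest,
    uniform = with_seed(cfg$seed, {
      lo <- pmin(par$v_reset, par$v_thresh)
      lo + runif(n) * (par$v_thresh - lo)
    }))
  state <- list(v = v0, i_syn = numeric(n),
                refractory_steps_left = integer(n))

  lookup <- build_target_lookup(net, a)
  pattern_fn <- switch(cfg$comm_pattern, pex = pex_exchange,
                       nbx = nbx_exchange)

  D <- max(dsteps, 1L) + 1L          # delay ring buffer depth
  buf <- matrix(0, nrow = max(n, 1L), ncol = D)
  raster_steps <- vector("list", n_steps)
  records <- list()
  n_rec <- 0L
  events_by_proc <- numeric(P)
  events_total <- 0

  for (s in seq_len(n_steps)) {
    slot <- (s - 1L) %% D + 1L
    arrived <- buf[, slot]
    buf[, slot] <- 0

    up <- lif_step(state, par, arrived, dt, tau_syn)
    state <- up$state
    fidx <- which(up$fired)            # ascending global id order

    if (length(fidx)) {
      raster_steps[[s]] <- fidx - 1L
      # Deliver to all postsynaptic synapses, delay steps ahead.
      lens <- out_deg[fidx]
      nz <- lens > 0L
      if (any(nz)) {
        f2 <- fidx[nz]
        pos <- sequence(out_deg[f2]) + rep.int(tptr[f2], out_deg[f2])
        tg <- tgt[pos]
        arrive_slot <- (s - 1L + dsteps[pos]) %% D
        lin <- arrive_slot * n + tg + 1L
        add <- rowsum(wsyn[pos], lin)
        buf[as.numeric(rownames(add))] <- buf[as.numeric(rownames(add))] + add
        events_total <- events_total + length(pos)
        events_by_proc <- events_by_proc +
          tabulate(part[tg + 1L] + 1L, nbins = P)
      }
    }

    if (s %% cfg$exchange_every == 0L) {
      traffic <- if (length(fidx)) {
        f0 <- fidx - 1L
        ll <- lookup$lptr[fidx + 1L] - lookup$lptr[fidx]
        nz <- ll > 0L
        if (any(nz)) {
          fr <- f0[nz]; lr <- ll[nz]
          posl <- sequence(lr) + rep.int(lookup$lptr[fr + 1L], lr)
          step_traffic(src = rep.int(part[fr + 1L], lr),
                       dest = lookup$lproc[posl],
                       id = rep.int(fr, lr), P = P)
        } else step_traffic(integer(), integer(), integer(), P)
      } else step_traffic(integer(), integer(), integer(), P)
      n_rec <- n_rec + 1L
      records[[n_rec]] <- pattern_fn(traffic)$record
    }
  }

  spikes <- unlist(raster_steps, use.names = FALSE) %||% integer()
  steps_of <- rep.int(seq_len(n_steps),
                      vapply(raster_steps, length, 0L))
  raster <- data.frame(step = steps_of, neuron = spikes)

  comm <- accumulate_stats(records, P, duration_ms = cfg$duration_ms)
  duration_s <- cfg$duration_ms / 1000
  structure(list(
    raster = raster,
    n_neurons = n, n_steps = n_steps, dt = dt,
    duration_ms = cfg$duration_ms, P = P,
    comm_pattern = cfg$comm_pattern,
    comm = comm,
    counters = list(
      neuron_updates = as.numeric(n) * n_steps,
      neuron_updates_by_process = tabulate(part + 1L, nbins = P) *
        as.numeric(n_steps),
      synaptic_events = events_total,
      synaptic_events_by_process = events_by_proc),
    mean_rate_hz = if (duration_s > 0) nrow(raster) / (n * duration_s)
                   else NA_real_,
    records = if (cfg$keep_records) records else NULL,
    seed = cfg$seed),
    class = "snn_sim")
}

#' Mean network firing rate
#'
#' Total spike count divided by neuron count and simulated duration.
#'
#' @param result An `snn_sim`.
#' @return Rate in spikes/s.
#' @export
mean_firing_rate <- function(result) {
  stopifnot(inherits(result, "snn_sim"))
  if (result$duration_ms <= 0) {
    stop("duration must be positive to compute a rate", call. = FALSE)
  }
  nrow(result$raster) / (result$n_neurons * result$duration_ms / 1000)
}

#' Write per-process computation counters as CSV
#'
#' One row per virtual process: hosted neuron updates and synaptic events
#' processed over the run.
#'
#' @param result An `snn_sim`.
#' @param path Output path.
#' @export
write_counters <- function(result, path) {
  stopifnot(inherits(result, "snn_sim"))
  data.table::fwrite(data.table::data.table(
    process = seq_len(result$P) - 1L,
    neuron_updates = result$counters$neuron_updates_by_process,
    synaptic_events = result$counters$synaptic_events_by_process), path)
  invisible(path)
}

#' @export
print.snn_sim <- function(x, ...) {
  cat(sprintf(
    "snn_sim: %s neurons, %d steps of %g ms, P = %d, pattern = %s\n",
    format(x$n_neurons, big.mark = ","), x$n_steps, x$dt, x$P,
    toupper(x$comm_pattern)))
  cat(sprintf("  %s spikes (mean rate %.2f spikes/s)\n",
              format(nrow(x$raster), big.mark = ","), x$mean_rate_hz))
  cat(sprintf("  ARN %.3f, payload %s B, metadata %s B\n",
              x$comm$arn, format(x$comm$payload_bytes, big.mark = ","),
              format(x$comm$metadata_bytes, big.mark = ",")))
  invisible(x)
}
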
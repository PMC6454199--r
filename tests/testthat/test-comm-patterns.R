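# Build a random but invariant-respecting StepTraffic: each "firing"
# neuron is owned by a process and targets a random set of other
# processes, so (src, dest, id) triples are unique by construction.
rand_traffic <- function(P, n_spikes, seed, max_targets = P - 1L) {
  set.seed(seed)
  src <- integer(); dest <- integer(); id <- integer()
  if (n_spikes > 0) {
    for (k in seq_len(n_spikes)) {
      s <- sample.int(P, 1) - 1L
      nt <- sample.int(max(max_targets, 1L), 1)
      d <- sample(setdiff(0:(P - 1L), s), min(nt, P - 1L))
      src <- c(src, rep(s, length(d)))
      dest <- c(dest, d)
      id <- c(id, rep(1000L + k, length(d)))
    }
  }
  step_traffic(src, dest, id, P)
}

test_that("PEX handshake volume is exactly P(P-1), spikes or not", {
  silent <- step_traffic(integer(), integer(), integer(), 4)
  out <- pex_exchange(silent)
  expect_equal(out$record$metadata_units, 12L)
  expect_equal(out$record$payload_bytes, 0)
  expect_equal(out$record$rounds, 2L)
  expect_equal(pex_exchange(step_traffic(integer(), integer(), integer(),
                                         8))$record$metadata_units, 56L)
  # Quadratic growth: doubling P from 8 to 16 scales metadata by 240/56.
  m16 <- pex_exchange(step_traffic(integer(), integer(), integer(),
                                   16))$record$metadata_units
  expect_equal(m16 / 56, 240 / 56)
})

test_that("payload messages carry one id per (spike, target process)", {
  tr <- step_traffic(src = c(0, 0), dest = c(1, 2), id = c(7, 7), P = 4)
  out <- pex_exchange(tr)
  expect_equal(out$record$messages_payload, 2L)
  expect_equal(out$record$payload_ids, 2L)
  expect_equal(out$record$n_remote_spikes, 1L)
  expect_equal(out$delivered$id, c(7L, 7L))
})

test_that("NBX carries no metadata and delivers exactly what PEX delivers", {
  silent <- nbx_exchange(step_traffic(integer(), integer(), integer(), 6))
  expect_equal(silent$record$metadata_bytes, 0)
  expect_equal(silent$record$payload_bytes, 0)
  expect_equal(silent$record$rounds, 1L)
  for (seed in 1:25) {
    tr <- rand_traffic(P = 8, n_spikes = sample(0:12, 1), seed = seed)
    px <- pex_exchange(tr)
    nx <- nbx_exchange(tr)
    expect_identical(nx$delivered, px$delivered)
    expect_equal(nx$record$payload_bytes, px$record$payload_bytes)
    expect_equal(nx$record$metadata_bytes, 0)
  }
})

test_that("NBX total bytes undercut PEX whenever any pair is silent", {
  for (seed in 1:10) {
    tr <- rand_traffic(P = 6, n_spikes = 3, seed = seed, max_targets = 2)
    px <- pex_exchange(tr)$record
    nx <- nbx_exchange(tr)$record
    pairs_used <- nrow(px$pairs)
    if (pairs_used < 6 * 5) {
      expect_lt(nx$payload_bytes + nx$metadata_bytes,
                px$payload_bytes + px$metadata_bytes)
    }
  }
})

test_that("adding a spike never decreases payload bytes", {
  tr <- rand_traffic(P = 5, n_spikes = 4, seed = 2)
  before <- pex_exchange(tr)$record$payload_bytes
  tr2 <- step_traffic(c(tr$src, 0L), c(tr$dest, 3L), c(tr$id, 9999L), 5)
  expect_gte(pex_exchange(tr2)$record$payload_bytes, before)
  expect_gte(nbx_exchange(tr2)$record$payload_bytes, before)
})

test_that("aggregation implements the ARN definition", {
  expect_equal(accumulate_stats(list(), 4)$arn, 0)
  # Two processes; a neuron on p0 with one remote target fires every step:
  # |T_0| = 1, |T_1| = 0, so ARN = 0.5.
  recs <- lapply(1:20, function(s) {
    pex_exchange(step_traffic(0L, 1L, 5L, P = 2))$record
  })
  st <- accumulate_stats(recs, 2, duration_ms = 2)
  expect_equal(st$arn, 0.5)
  expect_equal(st$remote_spikes, 20)
  expect_equal(st$remote_spike_messages, 20)
  expect_equal(st$pair_frequency$per_second, 20 / 0.002)
  # Silent steps dilute the average.
  recs2 <- c(recs, lapply(1:20, function(s) {
    pex_exchange(step_traffic(integer(), integer(), integer(), 2))$record
  }))
  expect_equal(accumulate_stats(recs2, 2, 4)$arn, 0.25)
})

test_that("ARN is bounded by P - 1 and vanishes for a single process", {
  for (seed in 1:10) {
    P <- sample(2:7, 1)
    recs <- lapply(1:15, function(s) {
      pex_exchange(rand_traffic(P, sample(0:6, 1), seed * 100 + s))$record
    })
    expect_lte(accumulate_stats(recs, P)$arn, P - 1)
  }
  p <- neuron_params()
  net <- toy_network(3, pre = c(0, 1), post = c(1, 2), params = p)
  sim <- run_simulation(net, allocate_round_robin(3, 1),
                        simulation_config(5, seed = 1))
  expect_equal(sim$comm$arn, 0)
  expect_equal(sim$comm$remote_spikes, 0)
})

test_that("local-only targets leave remote spikes at zero despite activity", {
  net <- toy_network(4, pre = c(0, 1), post = c(1, 0), params = neuron_params())
  a <- as_assignment(c(0L, 0L, 1L, 1L), 2)   # the wired pair shares part 0
  sim <- run_simulation(net, a, simulation_config(10, seed = 1))
  expect_gt(nrow(sim$raster), 0)
  expect_equal(sim$comm$remote_spikes, 0)
  expect_equal(sim$comm$payload_bytes, 0)
  expect_equal(sim$comm$metadata_bytes, 4 * 2 * 1 * 100)  # PEX still pays
})

test_that("theoretical PEX curves: silent payload, quadratic handshake", {
  tab <- theoretical_pex_curves(P_values = c(8, 16, 32, 64),
                                rates_hz = c(0, 20),
                                neurons_per_process = 100)
  zero <- tab[tab$rate_hz == 0, ]
  expect_true(all(zero$payload_bytes == 0))
  expect_equal(zero$handshake_units, zero$P * (zero$P - 1))
  ratios <- zero$handshake_units[-1] / zero$handshake_units[-4]
  expect_true(all(ratios > 3.5 & ratios <= 4.5))  # -> 4 asymptotically
})

test_that("empirical PEX volume matches the closed form exactly", {
  # Two mutually wired neurons on different processes fire in lockstep
  # every 5 steps (t_ref 0.4 ms): rate 2000 spikes/s, 1 remote target each.
  p <- neuron_params(t_ref = 0.4, tau_m = 0.05)
  net <- toy_network(2, pre = c(0, 1), post = c(1, 0), weight = 0,
                     params = p)
  a <- as_assignment(c(0L, 1L), 2)
  sim <- run_simulation(net, a, simulation_config(50, seed = 1,
                                                  init = "rest"))
  expect_equal(mean_firing_rate(sim), 2000)
  tab <- theoretical_pex_curves(P_values = 2, rates_hz = 2000,
                                total_neurons = 2,
                                neurons_per_process = 1,
                                mean_remote_targets = 1)
  n_exchanges <- sim$n_steps
  expect_equal(sim$comm$payload_bytes, tab$payload_bytes * n_exchanges)
  expect_equal(sim$comm$metadata_bytes,
               tab$handshake_bytes * n_exchanges)
})

test_that("record streams, counters and the abstract cost model export", {
  net <- toy_network(4, pre = c(0, 1), post = c(2, 3),
                     params = neuron_params())
  a <- as_assignment(c(0L, 0L, 1L, 1L), 2)
  sims <- lapply(c("pex", "nbx"), function(pat) {
    run_simulation(net, a, simulation_config(5, comm_pattern = pat,
                                             seed = 1, keep_records = TRUE))
  })
  path <- tempfile(fileext = ".csv")
  write_comm_records(sims[[1]]$records, path)
  recs <- utils::read.csv(path)
  expect_equal(max(recs$exchange), 50)
  expect_true(all(recs$metadata_units == 2))
  cpath <- tempfile(fileext = ".csv")
  write_counters(sims[[1]], cpath)
  ctab <- utils::read.csv(cpath)
  expect_equal(sum(ctab$neuron_updates), 4 * 50)
  # Same traffic: the abstract model charges PEX its handshake and extra
  # round, so NBX can never cost more here.
  expect_lt(abstract_comm_cost(sims[[2]]), abstract_comm_cost(sims[[1]]))
})

test_that("traffic invariants are enforced at construction", {
  expect_error(step_traffic(0L, 0L, 1L, 4), "differ from sources")
  expect_error(step_traffic(0L, 9L, 1L, 4), "out of range")
})
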
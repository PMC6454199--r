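test_that("round robin is the mod map and spreads areas across parts", {
  a <- allocate_round_robin(6, 4)
  expect_equal(as.integer(a)[6], 1L)          # neuron 5 -> process 1
  expect_equal(as.integer(allocate_round_robin(5, 1)), rep(0L, 5))
  # Contiguous-area model: each area's share per part <= ceil(area/P).
  area_size <- 30; P <- 7
  a2 <- allocate_round_robin(4 * area_size, P)
  area <- (seq_len(4 * area_size) - 1L) %/% area_size
  share <- table(area, as.integer(a2))
  expect_lte(max(share), ceiling(area_size / P))
})

test_that("balanced random allocation balances by weight", {
  hg_u <- hypergraph(lapply(1:10, function(i) c(i - 1, i %% 100)), 100)
  a <- allocate_random_balanced(hg_u, 4, seed = 3)
  expect_equal(unname(tabulate(as.integer(a) + 1L, 4)), rep(25L, 4))

  one <- allocate_random_balanced(hg_u, 1, seed = 3)
  expect_equal(partition_imbalance(hg_u, one), 1)

  hg_w <- hypergraph(list(c(0, 1)), 5, vertex_weights = c(5, 4, 3, 3, 3))
  b <- allocate_random_balanced(hg_w, 2, seed = 1)
  loads <- c(sum(hg_w$vertex_weights[as.integer(b) == 0]),
             sum(hg_w$vertex_weights[as.integer(b) == 1]))
  expect_lte(abs(diff(loads)), max(hg_w$vertex_weights))

  expect_identical(allocate_random_balanced(hg_u, 4, seed = 9),
                   allocate_random_balanced(hg_u, 4, seed = 9))
})

test_that("LPT initial partition balances and never leaves empty parts", {
  w <- c(8, 7, 6, 5, 4)
  hg <- hypergraph(list(c(0, 1)), 5, vertex_weights = w)
  cfg <- partitioner_config(2)
  a <- initial_partition(hg, cfg)
  loads <- vapply(0:1, function(p) sum(w[as.integer(a) == p]), 0)
  # Brute force over all bipartitions: a perfect 15/15 split exists, and
  # greedy LPT is guaranteed to land within one (minimum) weight of it.
  all_gaps <- vapply(0:(2^5 - 1), function(code) {
    inb <- as.logical(intToBits(code))[1:5]
    abs(sum(w[inb]) - sum(w[!inb]))
  }, 0)
  expect_equal(min(all_gaps), 0)  # 15/15 reachable
  expect_lte(abs(diff(loads)), min(w))

  hg_eq <- hypergraph(list(c(0, 1)), 4)
  b <- initial_partition(hg_eq, partitioner_config(4))
  expect_equal(sort(unique(as.integer(b))), 0:3)
  expect_equal(partition_imbalance(hg_eq, b), 1)
  expect_error(initial_partition(hg_eq, partitioner_config(5)), "fewer")
})

test_that("coarsening conserves weight and preserves lifted costs", {
  for (seed in 1:8) {
    hg <- rand_hypergraph(40, 30, seed, max_size = 4)
    cfg <- partitioner_config(2, coarsening_stop = 5, seed = seed)
    levels <- coarsen(hg, cfg)
    expect_gt(length(levels), 0)
    for (li in seq_along(levels)) {
      expect_equal(sum(levels[[li]]$hg$vertex_weights),
                   sum(hg$vertex_weights))
    }
    # Any coarse assignment, lifted through the maps, has the same
    # connectivity-1 cost as evaluating the coarse instance directly.
    k <- length(levels)
    coarse <- levels[[k]]$hg
    ac <- rand_assignment(coarse$n_vertices, 3, seed + 7)
    fine_part <- as.integer(ac)
    for (li in rev(seq_len(k))) {
      fine_part <- fine_part[levels[[li]]$group + 1L]
    }
    expect_equal(partition_cost(hg, as_assignment(fine_part, 3)),
                 partition_cost(coarse, ac))
  }
})

test_that("matching only merges vertices that share a hyperedge", {
  hg <- hypergraph(list(c(0, 1), c(2, 3)), 6)  # vertices 4,5 isolated
  levels <- coarsen(hg, partitioner_config(2, coarsening_stop = 1, seed = 1))
  g <- levels[[1]]$group
  incident <- lapply(0:5, function(v) {
    which(vapply(seq_len(length(hg$eptr) - 1L), function(e) {
      v %in% hg$pins[(hg$eptr[e] + 1L):hg$eptr[e + 1L]]
    }, TRUE))
  })
  for (grp in unique(g)) {
    members <- which(g == grp) - 1L
    if (length(members) == 2L) {
      expect_gt(length(intersect(incident[[members[1] + 1L]],
                                 incident[[members[2] + 1L]])), 0)
    }
  }
  expect_true(all(tabulate(g[5:6] + 1L, max(g) + 1L) <= 1))
})

test_that("FM refinement never worsens the cut and fixes obvious splits", {
  # A split pair with balance slack refines into one part.
  hg <- hypergraph(list(c(0, 1)), 4)
  a <- as_assignment(c(0L, 1L, 0L, 1L), 2)
  cfg <- partitioner_config(2, tolerance = 1.5, seed = 2)
  r <- fm_refine(hg, a, cfg)
  expect_equal(partition_cost(hg, r), 0)

  for (seed in 1:40) {
    hg <- rand_hypergraph(12, 9, seed, unit_weights = TRUE)
    a <- rand_assignment(12, 3, seed + 99)
    r <- fm_refine(hg, a, partitioner_config(3, tolerance = 1.6, seed = seed))
    expect_lte(partition_cost(hg, r), partition_cost(hg, a))
  }
})

test_that("FM leaves an exhaustively optimal assignment at its optimum", {
  hg <- rand_hypergraph(8, 6, seed = 5, unit_weights = TRUE)
  # Constrained optimum by enumeration over the admissible states of the
  # refiner (unit weights, tolerance 1.34 => part sizes 3..5).
  opt <- Inf; best <- NULL
  for (code in 0:(2^8 - 1)) {
    part <- as.integer(intToBits(code))[1:8]
    if (sum(part) < 3 || sum(part) > 5) next
    a <- as_assignment(part, 2)
    cost <- bf_cut(hg, a)
    if (cost < opt) { opt <- cost; best <- a }
  }
  r <- fm_refine(hg, best, partitioner_config(2, tolerance = 1.34, seed = 3))
  expect_equal(partition_cost(hg, r), opt)
})

test_that("multilevel partitioning finds zero-cut component splits", {
  # Two weight-balanced connected components.
  edges <- c(lapply(0:5, function(i) c(i, (i + 1) %% 6)),
             lapply(6:11, function(i) c(i, 6 + (i + 1) %% 6)))
  hg <- hypergraph(edges, 12)
  a <- partition_hypergraph(hg, partitioner_config(2, seed = 4))
  expect_equal(partition_cost(hg, a), 0)
  expect_equal(partition_imbalance(hg, a), 1)
})

test_that("single-part and per-vertex edge cases hold", {
  hg <- rand_hypergraph(9, 5, seed = 1)
  a1 <- partition_hypergraph(hg, partitioner_config(1))
  expect_equal(as.integer(a1), rep(0L, 9))
  expect_equal(attr(a1, "cut_cost"), 0)
  expect_error(partition_hypergraph(hg, partitioner_config(10)),
               "exceeds")
})

test_that("partitioner is deterministic given its seed", {
  hg <- rand_hypergraph(60, 40, seed = 8, unit_weights = TRUE)
  cfg <- partitioner_config(4, coarsening_stop = 10, seed = 21)
  expect_identical(as.integer(partition_hypergraph(hg, cfg)),
                   as.integer(partition_hypergraph(hg, cfg)))
})

test_that("partitioner never beats the exhaustive optimum and beats random", {
  costs_ratio <- c()
  for (seed in 1:6) {
    hg <- rand_hypergraph(10, 8, seed + 200, unit_weights = TRUE)
    opt <- bf_optimum(hg, 2)
    a <- partition_hypergraph(hg, partitioner_config(2, seed = seed,
                                                     coarsening_stop = 4))
    cost <- partition_cost(hg, a)
    expect_gte(cost, opt)
    rnd <- vapply(1:20, function(s) {
      partition_cost(hg, allocate_random_balanced(hg, 2, seed = s))
    }, 0)
    expect_lte(cost, median(rnd))
    costs_ratio <- c(costs_ratio, if (opt > 0) cost / opt else 1)
  }
  expect_lte(median(costs_ratio), 1.5)
})

test_that("allocate() dispatches strategies over a network", {
  net <- build_network(cm_like_spec(n_neurons = 200, mean_in_degree = 6), 2)
  hg <- network_to_hypergraph(net)
  for (s in c("round_robin", "random_balanced", "hypergraph")) {
    a <- allocate(net, s, P = 4, seed = 3, hg = hg)
    expect_s3_class(a, "snn_assignment")
    expect_length(a, net$n_neurons)
    expect_equal(attr(a, "n_parts"), 4L)
  }
  path <- tempfile(fileext = ".csv")
  write_assignment(allocate_round_robin(5, 2), path)
  expect_equal(nrow(utils::read.csv(path)), 5L)
})
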
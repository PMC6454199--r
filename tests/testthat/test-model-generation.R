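one_pop_spec <- function(n, p, weight = 0.1, delay_steps = c(1, 1)) {
  model_spec(
    populations = list(population_spec("pop", n)),
    rules = list(connectivity_rule(
      "pop", "pop", p, weight_dist = dist_constant(weight),
      delay_dist = dist_uniform_steps(delay_steps[1], delay_steps[2]))))
}

test_that("probability-1 rule yields the complete digraph without autapses", {
  net <- build_layered_network(one_pop_spec(3, 1.0), seed = 1)
  expect_equal(nrow(net$edges), 6L)
  expect_true(all(net$edges$pre != net$edges$post))
})

test_that("probability 0 yields no synapses and zero-count summaries", {
  net <- build_layered_network(one_pop_spec(4, 0), seed = 1)
  expect_equal(nrow(net$edges), 0L)
  s <- network_summary(net)
  expect_equal(s$n_synapses, 0L)
  expect_equal(s$in_degree[["mean"]], 0)
})

test_that("synapse counts concentrate at the binomial expectation", {
  spec <- model_spec(
    populations = list(population_spec("a", 500), population_spec("b", 500)),
    rules = list(
      connectivity_rule("a", "b", 0.1, dist_constant(0.1),
                        dist_uniform_steps(1, 5)),
      connectivity_rule("b", "a", 0.1, dist_constant(0.1),
                        dist_uniform_steps(1, 5))))
  net <- build_layered_network(spec, seed = 42)
  n_trials <- 2 * 500 * 500
  mu <- n_trials * 0.1
  sigma <- sqrt(n_trials * 0.1 * 0.9)
  expect_lt(abs(nrow(net$edges) - mu), 4 * sigma)
})

test_that("generation is deterministic and streams are separable", {
  spec <- cm_like_spec(n_neurons = 800, mean_in_degree = 15)
  n1 <- build_network(spec, seed = 7)
  n2 <- build_network(spec, seed = 7)
  expect_identical(n1, n2)
  n3 <- build_network(spec, seed = 8)
  expect_false(identical(n1$edges, n3$edges))
  # Changing only the weight stream preserves the wiring.
  spec_u <- model_spec(
    populations = list(population_spec("p", 300)),
    rules = list(connectivity_rule("p", "p", 0.05,
                                   weight_dist = dist_uniform(0.01, 0.05),
                                   delay_dist = dist_uniform_steps(1, 5))))
  s1 <- list(structure = 11L, weights = 21L, delays = 31L)
  s2 <- list(structure = 11L, weights = 99L, delays = 31L)
  a <- build_network(spec_u, s1)
  b <- build_network(spec_u, s2)
  expect_identical(a$edges[c("pre", "post", "delay")],
                   b$edges[c("pre", "post", "delay")])
  expect_false(identical(a$edges$weight, b$edges$weight))
})

test_that("delays sit on the step grid with a one-step minimum", {
  net <- build_network(cm_like_spec(n_neurons = 400, mean_in_degree = 10),
                       seed = 3)
  steps <- net$edges$delay / net$dt
  expect_true(all(abs(steps - round(steps)) < 1e-9))
  expect_true(all(steps >= 1))
})

test_that("inhibitory presynaptic weights carry the multiplier", {
  net <- build_network(cm_like_spec(n_neurons = 800, mean_in_degree = 10,
                                    weight = 0.02,
                                    inhibitory_multiplier = -4),
                       seed = 5)
  inhib_pre <- !net$pops$excitatory[net$population[net$edges$pre + 1L]]
  expect_true(all(net$edges$weight[inhib_pre] == -0.08))
  expect_true(all(net$edges$weight[!inhib_pre] == 0.02))
})

test_that("unknown populations and bad probabilities are rejected", {
  expect_error(model_spec(list(population_spec("a", 5)),
                          list(connectivity_rule("a", "zzz", 0.1))),
               "unknown population")
  expect_error(connectivity_rule("a", "b", 1.5), "probability")
  expect_error(connectivity_rule("a", "b", -0.1), "probability")
})

test_that("apply_scale scales sizes, keeps probabilities, rounds to integers", {
  sp <- cm_like_spec(n_neurons = 1000, mean_in_degree = 10)
  expect_identical(vapply(apply_scale(sp, 1)$populations, `[[`, 1L, "size"),
                   vapply(sp$populations, `[[`, 1L, "size"))
  one <- model_spec(list(population_spec("p", 1000)),
                    list(connectivity_rule("p", "p", 0.25)))
  sc <- apply_scale(one, 0.16)
  expect_equal(sc$populations[[1]]$size, 160L)
  expect_equal(sc$rules[[1]]$probability, 0.25)
  expect_error(apply_scale(one, 0), "scale")
})

test_that("the full-size 32-area spec at 16% lands near 660k neurons", {
  sp <- multiarea_spec(neurons_per_area = 128906)
  sc <- apply_scale(sp, 0.16)
  total <- sum(vapply(sc$populations, `[[`, 1L, "size")) * sc$n_areas
  expect_lt(abs(total - 660000), 250)  # per-population rounding slack
})

test_that("multi-area generation respects area structure", {
  # Zero inter-area probability: no synapse crosses areas.
  spec0 <- multiarea_spec(n_areas = 3, neurons_per_area = 120,
                          mean_in_degree_intra = 8,
                          inter_area_probability = 0)
  net0 <- build_multiarea_network(spec0, seed = 2)
  expect_true(all(net0$area[net0$edges$pre + 1L] ==
                    net0$area[net0$edges$post + 1L]))
  # Contiguous layout: area label is floor(id / area_size).
  expect_identical(net0$area,
                   as.integer((seq_len(net0$n_neurons) - 1L) %/%
                                net0$area_size))
  # Cross-area counts are binomial around n_pairs * p.
  spec1 <- model_spec(
    populations = list(population_spec("p", 1000)),
    rules = list(),
    n_areas = 2L,
    inter_area_rules = list(connectivity_rule("*", "*", 0.01,
                                              dist_constant(0.1),
                                              dist_uniform_steps(1, 3))))
  net1 <- build_multiarea_network(spec1, seed = 9)
  n_trials <- 2 * 1000 * 1000  # both ordered area pairs
  mu <- n_trials * 0.01
  sigma <- sqrt(n_trials * 0.01 * 0.99)
  expect_lt(abs(nrow(net1$edges) - mu), 4 * sigma)
})

test_that("network_summary recounts the adjacency exactly", {
  net <- toy_network(3, pre = c(0, 1), post = c(1, 2))
  s <- network_summary(net)
  expect_equal(s$n_synapses, 2L)
  expect_equal(tabulate(net$edges$post + 1L, 3), c(0L, 1L, 1L))
  gen <- build_network(cm_like_spec(n_neurons = 400, mean_in_degree = 8),
                       seed = 4)
  expect_equal(network_summary(gen)$n_synapses, nrow(gen$edges))
  expect_equal(sum(network_summary(gen)$per_population$synapses_out),
               nrow(gen$edges))
})

test_that("model specs load from structured text", {
  path <- tempfile(fileext = ".yaml")
  writeLines(c(
    "populations:",
    "  - name: exc",
    "    size: 80",
    "    excitatory: true",
    "    neuron: {v_rest: -65, v_thresh: -50, i_ext: 1.2}",
    "  - name: inh",
    "    size: 20",
    "    excitatory: false",
    "rules:",
    "  - {pre: exc, post: exc, probability: 0.1, weight: 0.05, delay_steps: [1, 5]}",
    "  - {pre: inh, post: exc, probability: 0.2, weight: 0.05, delay_steps: [1, 5]}",
    "dt: 0.1",
    "synapse: {weight: 0.05, inhibitory_multiplier: -4}"), path)
  sp <- read_model_spec(path)
  expect_s3_class(sp, "snn_model_spec")
  expect_equal(vapply(sp$populations, `[[`, 1L, "size"), c(80L, 20L))
  expect_equal(sp$populations[[1]]$params$i_ext, 1.2)
  net <- build_network(sp, seed = 2)
  inh_pre <- !net$pops$excitatory[net$population[net$edges$pre + 1L]]
  expect_true(all(net$edges$weight[inh_pre] == -0.2))
  expect_error(read_model_spec({
    p2 <- tempfile(fileext = ".yaml"); writeLines("dt: 0.1", p2); p2
  }), "must declare")
})

test_that("wrapper entry points enforce the area preconditions", {
  sp1 <- one_pop_spec(5, 0.5)
  expect_error(build_multiarea_network(sp1, 1), "n_areas")
  sp2 <- multiarea_spec(n_areas = 2, neurons_per_area = 50,
                        mean_in_degree_intra = 4)
  expect_error(build_layered_network(sp2, 1), "single-area")
})
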
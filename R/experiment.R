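#' Configure a strategy-by-pattern comparison experiment
#'
#' Describes a strong-scaling grid: a fixed model simulated under every
#' combination of process count, allocation strategy and communication
#' pattern, repeated over seeds. The two shipped presets are
#' `"cm_like"` ([cm_like_spec()]) and `"multiarea"` ([multiarea_spec()]);
#' alternatively pass an explicit `spec`.
#'
#' @param model Preset name, or `NULL` when `spec` is given.
#' @param spec Optional `snn_model_spec` overriding the preset.
#' @param processes Integer vector of virtual process counts.
#' @param strategies Subset of
#'   `c("round_robin", "random_balanced", "hypergraph")`.
#' @param patterns Subset of `c("pex", "nbx")`.
#' @param duration_ms,dt Simulation length and step (ms).
#' @param seeds Integer vector; each seed builds one network realisation
#'   (and seeds the allocation and initial state).
#' @param tolerance Partitioner imbalance tolerance.
#' @param ... Overrides forwarded to the preset constructor.
#' @return An `snn_experiment_config` list.
#' @export
experiment_config <- function(model = c("cm_like", "multiarea"), spec = NULL,
                              processes = c(8, 32, 96),
                              strategies = c("random_balanced", "hypergraph"),
                              patterns = c("pex", "nbx"),
                              duration_ms = 100, dt = 0.1, seeds = 1,
                              tolerance = 1.001, ...) {
  if (is.null(spec)) {
    model <- match.arg(model)
    spec <- switch(model, cm_like = cm_like_spec(dt = dt, ...),
                   multiarea = multiarea_spec(dt = dt, ...))
  } else {
    model <- "custom"
    stopifnot(inherits(spec, "snn_model_spec"))
  }
  strategies <- match.arg(strategies,
                          c("round_robin", "random_balanced", "hypergraph"),
                          several.ok = TRUE)
  patterns <- match.arg(patterns, c("pex", "nbx"), several.ok = TRUE)
  stopifnot(all(processes >= 1), length(seeds) >= 1)
  structure(list(model = model, spec = spec,
                 processes = as.integer(processes),
                 strategies = strategies, patterns = patterns,
                 duration_ms = duration_ms, dt = dt,
                 seeds = as.integer(seeds), tolerance = tolerance),
            class = "snn_experiment_config")
}

#' Run a comparison grid
#'
#' For every `(seed, P, strategy, pattern)` cell: build the network (once
#' per seed), allocate, simulate, and collect the partition and
#' communication metrics. The spike raster is asserted to be identical
#' across all cells sharing a seed -- allocation and pattern can never
#' change the dynamics, so any difference indicates a bug and aborts the
#' grid.
#'
#' @param cfg An [experiment_config()].
#' @param progress Print one line per cell.
#' @return An `snn_grid`: `results` (one row per cell with `cut_cost`,
#'   `imbalance`, `arn`, `remote_spikes`, `remote_spike_messages`,
#'   `payload_bytes`, `metadata_bytes`, `total_bytes`, `messages_total`,
#'   `mean_rate_hz`, partitioner work counters) plus the config.
#' @export
run_grid <- function(cfg, progress = FALSE) {
  stopifnot(inherits(cfg, "snn_experiment_config"))
  rows <- list()
  for (seed in cfg$seeds) {
    net <- build_network(cfg$spec, seed)
    hg <- network_to_hypergraph(net)
    ref_raster <- NULL
    for (P in cfg$processes) {
      for (strategy in cfg$strategies) {
        a <- allocate(net, strategy, P, seed = seed, hg = hg,
                      tolerance = cfg$tolerance)
        met <- partition_metrics(hg, a)
        for (pattern in cfg$patterns) {
          sim <- run_simulation(net, a, simulation_config(
            duration_ms = cfg$duration_ms, dt = cfg$dt,
            comm_pattern = pattern, seed = seed))
          if (is.null(ref_raster)) {
            ref_raster <- sim$raster
          } else if (!identical(sim$raster, ref_raster)) {
            stop(sprintf(
              paste0("raster mismatch in cell (seed=%d, P=%d, %s, %s): ",
                     "dynamics depend on allocation or pattern"),
              seed, P, strategy, pattern), call. = FALSE)
          }
          if (progress) {
            message(sprintf("seed %d | P %3d | %-15s | %s : ARN %.3f",
                            seed, P, strategy, pattern, sim$comm$arn))
          }
          rows[[length(rows) + 1L]] <- data.frame(
            seed = seed, P = P, strategy = strategy, pattern = pattern,
            cut_cost = met$cut_cost, imbalance = met$imbalance,
            arn = sim$comm$arn,
            remote_spikes = sim$comm$remote_spikes,
            remote_spike_messages = sim$comm$remote_spike_messages,
            payload_bytes = sim$comm$payload_bytes,
            metadata_bytes = sim$comm$metadata_bytes,
            total_bytes = sim$comm$payload_bytes + sim$comm$metadata_bytes,
            messages_total = sim$comm$messages_total,
            mean_rate_hz = sim$mean_rate_hz,
            n_spikes = nrow(sim$raster),
            fm_moves = attr(a, "fm_moves") %||% 0L,
            matching_ops = attr(a, "matching_ops") %||% 0,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  structure(list(results = do.call(rbind, rows), config = cfg),
            class = "snn_grid")
}

#' Percentage reduction relative to a baseline
#'
#' `100 * (baseline - candidate) / baseline`; positive when the candidate
#' improves on (is smaller than) the baseline. Undefined for non-positive
#' baselines, reported as `NA`.
#'
#' @param baseline,candidate Metric values (vectorised).
#' @return Percentage reduction(s).
#' @examples
#' reduction(100, 80)  # 20
#' @export
reduction <- function(baseline, candidate) {
  out <- 100 * (baseline - candidate) / baseline
  out[!is.finite(baseline) | baseline <= 0] <- NA_real_
  out
}

#' Pairwise comparison report against a named baseline
#'
#' Aggregates a grid's cells over seeds (median) and expresses every
#' metric of every `(P, strategy, pattern)` cell as a percentage
#' reduction relative to the baseline cell with the same `P`. Baseline
#' conventions: balanced random + PEX for microcircuit-style comparisons,
#' round robin + PEX for modular multi-area comparisons.
#'
#' @param grid An `snn_grid` from [run_grid()].
#' @param baseline_strategy,baseline_pattern Cell used as the reference.
#' @param metrics Result columns to compare.
#' @return An `snn_comparison`: `cells` (per-cell medians) and
#'   `reductions` (per-cell percentage reductions vs the baseline).
#' @export
comparison_report <- function(grid,
                              baseline_strategy = "random_balanced",
                              baseline_pattern = "pex",
                              metrics = c("arn", "remote_spikes",
                                          "remote_spike_messages",
                                          "payload_bytes", "total_bytes",
                                          "cut_cost")) {
  stopifnot(inherits(grid, "snn_grid"))
  res <- grid$results
  if (!any(res$strategy == baseline_strategy &
             res$pattern == baseline_pattern)) {
    stop("baseline cell absent from the grid", call. = FALSE)
  }
  metrics <- intersect(metrics, names(res))
  agg <- stats::aggregate(res[metrics],
                          by = res[c("P", "strategy", "pattern")],
                          FUN = stats::median)
  base <- agg[agg$strategy == baseline_strategy &
                agg$pattern == baseline_pattern, ]
  red <- agg
  for (m in metrics) {
    bvals <- base[[m]][match(red$P, base$P)]
    red[[m]] <- reduction(bvals, agg[[m]])
  }
  structure(list(cells = agg, reductions = red,
                 baseline = c(strategy = baseline_strategy,
                              pattern = baseline_pattern),
                 seeds = grid$config$seeds),
            class = "snn_comparison")
}

#' Partitioning cost versus communication gain
#'
#' Hardware-independent restatement of the build-time trade-off: the
#' partitioner's one-off work (matching score updates, FM moves) against
#' the communication savings accrued over the simulated duration. The
#' work is independent of simulated time while savings scale linearly
#' with it, so the cost amortises on longer runs.
#'
#' @param grid An `snn_grid` containing a `hypergraph` strategy and a
#'   baseline strategy.
#' @param baseline_strategy Strategy to compare against.
#' @return An `snn_cost_report` data frame: per `P`, the partitioner work
#'   counters and the per-pattern byte savings over the run.
#' @export
build_cost_report <- function(grid, baseline_strategy = "random_balanced") {
  stopifnot(inherits(grid, "snn_grid"))
  res <- grid$results
  if (!any(res$strategy == "hypergraph")) {
    stop("grid has no hypergraph cells", call. = FALSE)
  }
  agg <- stats::aggregate(
    res[c("matching_ops", "fm_moves", "total_bytes")],
    by = res[c("P", "strategy", "pattern")], FUN = stats::median)
  out <- list()
  for (P in unique(agg$P)) {
    for (pattern in unique(agg$pattern)) {
      hp <- agg[agg$P == P & agg$strategy == "hypergraph" &
                  agg$pattern == pattern, ]
      bl <- agg[agg$P == P & agg$strategy == baseline_strategy &
                  agg$pattern == pattern, ]
      if (nrow(hp) == 1L && nrow(bl) == 1L) {
        out[[length(out) + 1L]] <- data.frame(
          P = P, pattern = pattern,
          partition_matching_ops = hp$matching_ops,
          partition_fm_moves = hp$fm_moves,
          bytes_saved = bl$total_bytes - hp$total_bytes,
          duration_ms = grid$config$duration_ms)
      }
    }
  }
  structure(do.call(rbind, out), class = c("snn_cost_report", "data.frame"))
}

#' @export
print.snn_grid <- function(x, ...) {
  cat(sprintf("snn_grid: %d cell(s) [%s model, %d seed(s)]\n",
              nrow(x$results), x$config$model, length(x$config$seeds)))
  print(head(x$results[c("seed", "P", "strategy", "pattern", "arn",
                         "total_bytes")], 10))
  invisible(x)
}

#' @export
print.snn_comparison <- function(x, ...) {
  cat(sprintf("Reductions vs baseline %s + %s (medians over %d seed(s)):\n",
              x$baseline[["strategy"]], toupper(x$baseline[["pattern"]]),
              length(x$seeds)))
  print(x$reductions, row.names = FALSE)
  invisible(x)
}

#' Plot communication metrics against process count
#'
#' Base-graphics strong-scaling view of a grid: one line per
#' (strategy, pattern) cell for the chosen metric.
#'
#' @param x An `snn_grid`.
#' @param metric Result column to plot (default `"total_bytes"`).
#' @param log Axis spec passed to [graphics::matplot()].
#' @param ... Further graphics arguments.
#' @export
plot.snn_grid <- function(x, metric = "total_bytes", log = "", ...) {
  res <- x$results
  agg <- stats::aggregate(res[metric],
                          by = res[c("P", "strategy", "pattern")],
                          FUN = stats::median)
  cells <- unique(agg[c("strategy", "pattern")])
  Ps <- sort(unique(agg$P))
  mat <- sapply(seq_len(nrow(cells)), function(i) {
    sub <- agg[agg$strategy == cells$strategy[i] &
                 agg$pattern == cells$pattern[i], ]
    sub[[metric]][match(Ps, sub$P)]
  })
  graphics::matplot(Ps, mat, type = "b", pch = seq_len(ncol(mat)),
                    xlab = "processes", ylab = metric, log = log, ...)
  graphics::legend("topleft", bty = "n",
                   legend = paste(cells$strategy, toupper(cells$pattern)),
                   pch = seq_len(ncol(mat)), col = seq_len(ncol(mat)))
  invisible(x)
}
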
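#' Serialise and restore a network
#'
#' A network is written as a plain-text CSV edge list
#' (`pre_id,post_id,weight,delay`) next to a JSON metadata sidecar
#' (`<path>.meta.json`) holding the neuron count, population/area layout
#' and parameter tables. Floating-point columns are written with 17
#' significant digits, so `read_network(write_network(net))` reproduces
#' the network bit-exactly.
#'
#' @param net An `snn_network`.
#' @param path Path of the CSV edge list to write / read.
#' @return `write_network()` returns `path` invisibly; `read_network()`
#'   returns the reconstructed `snn_network`.
#' @export
write_network <- function(net, path) {
  stopifnot(inherits(net, "snn_network"))
  e <- net$edges
  out <- data.table::data.table(
    pre_id = e$pre, post_id = e$post,
    weight = sprintf("%.17g", e$weight),
    delay = sprintf("%.17g", e$delay))
  data.table::fwrite(out, path, quote = FALSE)
  meta <- list(
    n_neurons = net$n_neurons,
    n_synapses = nrow(e),
    n_areas = net$n_areas,
    area_size = net$area_size,
    dt = net$dt,
    populations = lapply(seq_len(nrow(net$pops)), function(i) {
      list(name = net$pops$name[i], size = net$pops$size[i],
           excitatory = net$pops$excitatory[i],
           neuron = unclass(net$pop_params[[i]]))
    }),
    synapse = unclass(net$synapse),
    seeds = net$seeds)
  jsonlite::write_json(meta, meta_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  mp <- meta_path(path)
  if (!file.exists(mp)) {
    stop("missing metadata sidecar: ", mp, call. = FALSE)
  }
  meta <- jsonlite::read_json(mp, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  e <- data.table::fread(path, colClasses = list(
    integer = c("pre_id", "post_id"), character = c("weight", "delay")))
  required <- c("pre_id", "post_id", "weight", "delay")
  if (!all(required %in% names(e))) {
    stop("malformed edge list (line 1): expected header ",
         paste(required, collapse = ","), call. = FALSE)
  }
  n <- as.integer(meta$n_neurons)
  bad <- which(is.na(e$pre_id) | is.na(e$post_id) |
                 e$pre_id < 0L | e$pre_id >= n |
                 e$post_id < 0L | e$post_id >= n)
  if (length(bad)) {
    stop(sprintf("malformed edge list at line %d: neuron id out of range [0, %d)",
                 bad[1L] + 1L, n), call. = FALSE)
  }
  w <- as.numeric(e$weight); dl <- as.numeric(e$delay)
  bad <- which(is.na(w) | is.na(dl))
  if (length(bad)) {
    stop(sprintf("malformed edge list at line %d: non-numeric weight/delay",
                 bad[1L] + 1L), call. = FALSE)
  }
  pops <- data.frame(
    name = vapply(meta$populations, `[[`, "", "name"),
    size = vapply(meta$populations, function(p) as.integer(p$size), 0L),
    excitatory = vapply(meta$populations, function(p) isTRUE(p$excitatory), TRUE),
    stringsAsFactors = FALSE)
  pop_params <- lapply(meta$populations, function(p) {
    do.call(neuron_params, lapply(p$neuron, as.numeric))
  })
  names(pop_params) <- pops$name
  n_areas <- as.integer(meta$n_areas)
  area_size <- as.integer(meta$area_size)
  population <- rep.int(rep.int(seq_len(nrow(pops)), pops$size), n_areas)
  area <- if (n > 0) rep(seq_len(n_areas) - 1L, each = area_size) else integer()
  edges <- data.frame(pre = e$pre_id, post = e$post_id, weight = w, delay = dl)
  o <- order(edges$pre, edges$post)
  edges <- edges[o, , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(
    n_neurons = n, edges = edges, population = population, area = area,
    pops = pops, pop_params = pop_params, dt = as.numeric(meta$dt),
    synapse = do.call(synapse_params, lapply(meta$synapse, as.numeric)),
    n_areas = n_areas,
    area_size = area_size,
    seeds = lapply(meta$seeds, as.integer)),
    class = "snn_network")
}

meta_path <- function(path) paste0(path, ".meta.json")

#' Write a spike raster as two-column text
#'
#' gdf-style output: one line per spike, `time_ms neuron_id`, sorted by
#' time then id.
#'
#' @param result An `snn_sim` result from [run_simulation()].
#' @param path Output path.
#' @export
write_raster <- function(result, path) {
  stopifnot(inherits(result, "snn_sim"))
  r <- result$raster
  data.table::fwrite(
    data.table::data.table(time_ms = r$step * result$dt, neuron_id = r$neuron),
    path, sep = " ", col.names = FALSE)
  invisible(path)
}
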
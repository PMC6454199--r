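# Internal helpers: seeded RNG scopes and argument checking.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so package functions never disturb
# the global stream.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  expr
}

# Derive independent named sub-streams (structure / weights / delays) from a
# single user seed. Keeping the streams separate means the synaptic wiring is
# invariant when only the weight or delay seed changes.
derive_seeds <- function(seed) {
  if (is.list(seed)) {
    stopifnot(all(c("structure", "weights", "delays") %in% names(seed)))
    return(lapply(seed[c("structure", "weights", "delays")], as.integer))
  }
  check_number(seed, "seed")
  s <- with_seed(as.integer(seed), sample.int(.Machine$integer.max - 1L, 3L))
  list(structure = s[[1L]], weights = s[[2L]], delays = s[[3L]])
}

check_number <- function(x, name, min = -Inf, max = Inf, integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  if (x < min || x > max) {
    stop(sprintf("`%s` must be in [%s, %s], got %s", name, min, max, x),
         call. = FALSE)
  }
  if (integer && x != round(x)) {
    stop(sprintf("`%s` must be an integer, got %s", name, x), call. = FALSE)
  }
  invisible(x)
}

check_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x)) {
    stop(sprintf("`%s` must be TRUE or FALSE", name), call. = FALSE)
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
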
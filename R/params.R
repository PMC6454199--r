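#' Leaky integrate-and-fire neuron parameters
#'
#' Parameter set for the point-neuron model used throughout the package:
#' a leaky integrate-and-fire (LIF) unit driven by a constant injected
#' current plus exponentially decaying synaptic current.
#'
#' The defaults follow the microcircuit benchmark convention of a resting
#' potential (-45 mV) that sits *above* the spiking threshold (-50 mV),
#' which together with the constant drive produces sustained tonic firing.
#' This is intentional: the networks generated here are communication
#' benchmarks whose purpose is to keep every process firing at a steady,
#' spatially uniform rate, not to reproduce biologically realistic membrane
#' trajectories. All values are configurable.
#'
#' @param v_rest Resting membrane potential (mV).
#' @param v_thresh Spike threshold (mV).
#' @param v_reset Post-spike reset potential (mV).
#' @param tau_m Membrane time constant (ms). Must be positive.
#' @param r_m Membrane resistance (MOhm); multiplies the injected and
#'   synaptic currents in the voltage update.
#' @param t_ref Absolute refractory period (ms). Non-negative; the membrane
#'   is clamped at `v_reset` while refractory.
#' @param i_ext Constant injected current (mA), applied uniformly to every
#'   neuron carrying these parameters.
#' @return An object of class `snn_neuron_params` (a named list).
#' @examples
#' neuron_params()
#' neuron_params(v_rest = -65, v_thresh = -50, i_ext = 0)
#' @export
neuron_params <- function(v_rest = -45, v_thresh = -50, v_reset = -65,
                          tau_m = 10, r_m = 1, t_ref = 2, i_ext = 0.95) {
  p <- list(v_rest = v_rest, v_thresh = v_thresh, v_reset = v_reset,
            tau_m = tau_m, r_m = r_m, t_ref = t_ref, i_ext = i_ext)
  for (nm in names(p)) check_number(p[[nm]], nm)
  check_number(tau_m, "tau_m", min = .Machine$double.xmin)
  check_number(t_ref, "t_ref", min = 0)
  structure(p, class = "snn_neuron_params")
}

#' Synapse parameters
#'
#' Shared synaptic model parameters: an exponential post-synaptic current
#' with decay constant `tau_syn`, an additive `weight` (the kick delivered
#' to the target's synaptic current on spike arrival), and a transmission
#' `delay` on the simulation step grid. `inhibitory_multiplier` scales the
#' outgoing weights of inhibitory populations (conventionally -4 for the
#' microcircuit preset and -15 for the multi-area preset, which needs the
#' stronger inhibition to keep its activity in range).
#'
#' @param weight Default synaptic weight magnitude (drive units added to
#'   the post-synaptic current per spike).
#' @param tau_syn Synaptic current decay constant (ms). Positive.
#' @param delay Default transmission delay (ms); must be at least one
#'   simulation step. Per-synapse delays are usually drawn from a rule's
#'   `delay_dist` instead.
#' @param inhibitory_multiplier Scalar applied to weights of synapses whose
#'   presynaptic neuron is inhibitory (negative by convention).
#' @return An object of class `snn_synapse_params`.
#' @export
synapse_params <- function(weight = 0.05, tau_syn = 2, delay = 0.1,
                           inhibitory_multiplier = -4) {
  check_number(weight, "weight")
  check_number(tau_syn, "tau_syn", min = .Machine$double.xmin)
  check_number(delay, "delay", min = 0)
  check_number(inhibitory_multiplier, "inhibitory_multiplier")
  structure(list(weight = weight, tau_syn = tau_syn, delay = delay,
                 inhibitory_multiplier = inhibitory_multiplier),
            class = "snn_synapse_params")
}

#' Distribution specifications for weights and delays
#'
#' Connection rules draw per-synapse weights and delays from small
#' declarative distribution specs. `dist_constant()` yields a fixed value;
#' `dist_uniform()` a continuous uniform draw; `dist_uniform_steps()` a
#' discrete uniform draw on the step grid, `{min_steps, ..., max_steps} * dt`
#' -- the standard choice for random synaptic delays, whose minimum of one
#' step is what forces processes to exchange spikes at every step.
#'
#' @param value Constant value.
#' @param min,max Bounds of the continuous uniform distribution.
#' @param min_steps,max_steps Integer bounds (in simulation steps, >= 1).
#' @return A distribution spec (named list with a `kind` field).
#' @export
dist_constant <- function(value) {
  check_number(value, "value")
  list(kind = "constant", value = value)
}

#' @rdname dist_constant
#' @export
dist_uniform <- function(min, max) {
  check_number(min, "min")
  check_number(max, "max")
  if (max < min) stop("`max` must be >= `min`", call. = FALSE)
  list(kind = "uniform", min = min, max = max)
}

#' @rdname dist_constant
#' @export
dist_uniform_steps <- function(min_steps = 1, max_steps = 15) {
  check_number(min_steps, "min_steps", min = 1, integer = TRUE)
  check_number(max_steps, "max_steps", min = min_steps, integer = TRUE)
  list(kind = "uniform_steps", min = as.integer(min_steps),
       max = as.integer(max_steps))
}

draw_dist <- function(dist, n, dt = NULL) {
  switch(dist$kind,
    constant = rep(dist$value, n),
    uniform = runif(n, dist$min, dist$max),
    uniform_steps = {
      steps <- if (dist$min == dist$max) rep(dist$min, n)
               else sample(seq.int(dist$min, dist$max), n, replace = TRUE)
      steps * dt
    },
    stop("unknown distribution kind: ", dist$kind, call. = FALSE)
  )
}

#' @export
print.snn_neuron_params <- function(x, ...) {
  cat("LIF neuron parameters:\n")
  cat(sprintf("  v_rest %.3g mV, v_thresh %.3g mV, v_reset %.3g mV\n",
              x$v_rest, x$v_thresh, x$v_reset))
  cat(sprintf("  tau_m %.3g ms, r_m %.3g MOhm, t_ref %.3g ms, i_ext %.3g mA\n",
              x$tau_m, x$r_m, x$t_ref, x$i_ext))
  invisible(x)
}

#' @export
print.snn_synapse_params <- function(x, ...) {
  cat(sprintf(
    "Synapse parameters: weight %.3g, tau_syn %.3g ms, delay %.3g ms, inhibitory x%.3g\n",
    x$weight, x$tau_syn, x$delay, x$inhibitory_multiplier))
  invisible(x)
}
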
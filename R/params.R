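#' Simulation parameters
#'
#' Bundles and validates the fixed parameters of a polychronous network
#' simulation.  One tick is one axon-array update period (62 microseconds by
#' default), the sole clock of the model: all delays, windows and spike times
#' are integer tick counts.
#'
#' @param n_neurons Number of coincidence-detector neurons.  Must be a power
#'   of two (the neuron address is a binary bus address); the hardware-scale
#'   configurations range from 128 to 4096.
#' @param n_axon_arrays Number of axon arrays; each array holds
#'   `modules_per_array` axon modules.
#' @param modules_per_array Axon modules per array (default 4096).
#' @param tick_us Tick duration in microseconds (default 62).
#' @param fanout Delay paths per axon module.  Fixed at 4: each stored spike
#'   drives the next four spikes of its pattern.
#' @param coincidence_threshold Pre-synaptic spikes required within the
#'   coincidence window for a neuron to fire (default 3, i.e. 3-of-4).
#' @param coincidence_window_ticks Coincidence window in ticks (default 16,
#'   about 1 ms).
#' @param refractory_ticks Refractory period in ticks (default 16, about
#'   1 ms).  While refractory a neuron ignores incoming spikes entirely.
#' @param delay_max_ticks Largest programmable delay in ticks.  Default 511,
#'   the ceiling of the 9-bit ramp counter (about 32 ms); `delay_max_ticks +
#'   1` must be a power of two.
#' @param rng_seed Optional integer seed recorded with the parameters; used
#'   by helpers that need randomness but never by the deterministic engine.
#'
#' @return An object of class `polychron_params` (a validated list).
#' @examples
#' p <- sim_params(n_neurons = 512)
#' p$delay_max_ticks
#' @export
sim_params <- function(n_neurons = 4096,
                       n_axon_arrays = 1,
                       modules_per_array = 4096,
                       tick_us = 62,
                       fanout = 4,
                       coincidence_threshold = 3,
                       coincidence_window_ticks = 16,
                       refractory_ticks = 16,
                       delay_max_ticks = 511,
                       rng_seed = NULL) {
  chk <- function(ok, msg) if (!ok) validation_error(msg)
  chk(is_count(n_neurons) && is_pow2(n_neurons),
      "n_neurons must be a power of two")
  chk(is_count(n_axon_arrays), "n_axon_arrays must be a positive integer")
  chk(is_count(modules_per_array), "modules_per_array must be a positive integer")
  chk(is_count(tick_us), "tick_us must be a positive integer")
  chk(fanout == 4, "fanout is fixed at 4 delay paths per axon module")
  chk(is_count(coincidence_threshold) && coincidence_threshold <= fanout,
      "coincidence_threshold must be a positive integer <= fanout")
  chk(is_count(coincidence_window_ticks), "coincidence_window_ticks must be >= 1")
  chk(is_count(refractory_ticks), "refractory_ticks must be >= 1")
  chk(is_count(delay_max_ticks) && is_pow2(delay_max_ticks + 1),
      "delay_max_ticks must be 2^delay_bits - 1")
  structure(list(
    n_neurons = as.integer(n_neurons),
    n_axon_arrays = as.integer(n_axon_arrays),
    modules_per_array = as.integer(modules_per_array),
    tick_us = as.integer(tick_us),
    fanout = 4L,
    coincidence_threshold = as.integer(coincidence_threshold),
    coincidence_window_ticks = as.integer(coincidence_window_ticks),
    refractory_ticks = as.integer(refractory_ticks),
    delay_max_ticks = as.integer(delay_max_ticks),
    rng_seed = if (is.null(rng_seed)) NULL else as.integer(rng_seed)
  ), class = "polychron_params")
}

validation_error <- function(msg) {
  stop(errorCondition(msg,
                      class = c("polychron_validation_error", "error", "condition")))
}

is_count <- function(x) {
  length(x) == 1 && is.numeric(x) && !is.na(x) && x >= 1 && x == trunc(x)
}

is_pow2 <- function(x) x >= 1 && bitwAnd(as.integer(x), as.integer(x) - 1L) == 0L

#' @export
print.polychron_params <- function(x, ...) {
  cat(sprintf(
    "polychron parameters: %d neurons, %d x %d axon modules, tick %d us\n",
    x$n_neurons, x$n_axon_arrays, x$modules_per_array, x$tick_us))
  cat(sprintf("  coincidence %d-of-%d within %d ticks, refractory %d ticks, max delay %d ticks\n",
              x$coincidence_threshold, x$fanout, x$coincidence_window_ticks,
              x$refractory_ticks, x$delay_max_ticks))
  invisible(x)
}
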
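#' Create an idle polychronous network
#'
#' Allocates an empty network: every axon module unconfigured, every neuron
#' idle, the programming index at zero.  A module becomes configured during
#' training, when it latches one input neuron address, the addresses of the
#' next four spikes of the training pattern, and one programmed delay per
#' output (the module's "ramp_latched" values).
#'
#' @param params A [sim_params()] object.
#' @return An object of class `polychron_net`: a list holding the parameter
#'   set, per-module configuration (`mod_input`, `mod_out`, `mod_delay`),
#'   per-module ramp state, per-neuron synapse-timer and refractory state,
#'   the write-once `programming_index`, and `current_tick`.
#' @examples
#' net <- create_network(sim_params(n_neurons = 128, modules_per_array = 8))
#' net$programming_index
#' @export
create_network <- function(params) {
  if (!inherits(params, "polychron_params"))
    validation_error("params must be created by sim_params()")
  m <- params$n_axon_arrays * params$modules_per_array
  n <- params$n_neurons
  structure(list(
    params = params,
    mod_input = rep(NA_integer_, m),
    mod_out = matrix(NA_integer_, m, 4),
    mod_delay = matrix(NA_integer_, m, 4),
    ramp_value = integer(m),
    ramp_active = logical(m),
    neuron_timer = matrix(NA_integer_, n, 4),
    neuron_refract_until = integer(n),
    programming_index = 0L,
    current_tick = 0L
  ), class = "polychron_net")
}

n_modules <- function(net) length(net$mod_input)

#' @export
print.polychron_net <- function(x, ...) {
  cat(sprintf("polychron network: %d neurons, %d axon modules (%d configured)\n",
              x$params$n_neurons, n_modules(x), x$programming_index))
  cat(sprintf("  current tick %d, %d ramps active\n",
              x$current_tick, sum(x$ramp_active)))
  invisible(x)
}

#' Deliver a post-synaptic spike to the axon array
#'
#' Every configured axon module whose input address matches restarts its ramp
#' generator from zero.  Multiple matches are normal: the same neuron may
#' open several stored connections, one per pattern (or pattern position) it
#' belongs to.
#'
#' @param net A `polychron_net`.
#' @param address Neuron address in `[0, n_neurons)`.
#' @return A list with elements `net` (the updated network) and `n_triggered`
#'   (how many module ramps were restarted, possibly 0).
#' @export
axon_receive <- function(net, address) {
  address <- check_address(net, address)
  hit <- which(!is.na(net$mod_input) & net$mod_input == address)
  net$ramp_value[hit] <- 0L
  net$ramp_active[hit] <- TRUE
  list(net = net, n_triggered = length(hit))
}

#' Deliver a pre-synaptic spike to one neuron synapse
#'
#' Starts the 1 ms timer of the addressed synapse line unless the neuron is
#' refractory or that line's timer is already running, in which case the
#' spike is ignored.
#'
#' @param net A `polychron_net`.
#' @param address Target neuron address.
#' @param line Synapse line, 0 to 3.
#' @param tick Arrival tick.
#' @return The updated network.
#' @export
neuron_receive <- function(net, address, line, tick) {
  address <- check_address(net, address)
  if (!(is_count(line + 1) && line <= 3))
    validation_error("line must be in 0..3")
  i <- address + 1L
  if (tick < net$neuron_refract_until[i]) return(net)  # refractory: ignored
  w <- net$params$coincidence_window_ticks
  ts <- net$neuron_timer[i, line + 1L]
  if (!is.na(ts) && tick - ts > w) ts <- NA_integer_   # stale timer expired
  if (is.na(ts)) net$neuron_timer[i, line + 1L] <- as.integer(tick)
  net
}

check_address <- function(net, address) {
  if (!(length(address) == 1 && is.numeric(address) && !is.na(address) &&
        address == trunc(address) && address >= 0 &&
        address < net$params$n_neurons))
    validation_error("address out of range")
  as.integer(address)
}

#' Synaptic integration latency of a coincidence
#'
#' The neuron's output latency emulates the integration time of a biological
#' coincidence detector: it is the sum of the elapsed values of the active
#' synapse timers at the moment the threshold-th spike arrives, so perfectly
#' simultaneous arrivals give a short latency and dispersed arrivals a longer
#' one.  The delay stage counts at the system-clock rate, far below one tick
#' per unit, so at the 62 us tick resolution of the simulation the latency
#' rounds to zero whole ticks: the post-synaptic spike is emitted in the tick
#' in which the coincidence is detected.  This helper exposes the latency
#' count itself for analysis.
#'
#' @param timer_elapsed Integer vector of elapsed tick counts of the active
#'   timers when the threshold-th spike arrives.
#' @return The summed timer count (0 for simultaneous arrivals).
#' @examples
#' integration_delay(c(0, 0, 0))   # simultaneous: 0
#' integration_delay(c(16, 8, 0))  # dispersed over 1 ms: 24
#' @export
integration_delay <- function(timer_elapsed) {
  if (length(timer_elapsed) == 0) return(0L)
  if (any(is.na(timer_elapsed)) || any(timer_elapsed < 0))
    validation_error("timer_elapsed must be non-negative")
  as.integer(sum(timer_elapsed))
}

#' Advance the network by one tick (reference implementation)
#'
#' Pure-R single-tick state machine, kept deliberately close to the prose
#' description of the model; [run_network()] drives the equivalent compiled
#' engine.  Phases within the tick are fixed: ramps advance and emit, spikes
#' are delivered in ascending module index, coincidences fire, post-synaptic
#' and injected spikes restart matching ramps.
#'
#' @param net A `polychron_net`.
#' @param inject Integer vector of neuron addresses whose (external)
#'   post-synaptic spikes are placed on the bus during this tick.
#' @return A list with `net` (advanced by one tick) and `events`, a
#'   data.frame of post-synaptic spikes (columns `tick`, `address`) emitted
#'   by the network this tick.
#' @export
network_step <- function(net, inject = integer(0)) {
  p <- net$params
  tck <- net$current_tick
  w <- p$coincidence_window_ticks

  # (a) ramps advance; a path emits when its ramp reaches the latched delay
  emit <- NULL
  act <- which(net$ramp_active)
  if (length(act)) {
    net$ramp_value[act] <- net$ramp_value[act] + 1L
    for (m in act) {
      j <- which(!is.na(net$mod_delay[m, ]) & net$mod_delay[m, ] == net$ramp_value[m] &
                   !is.na(net$mod_out[m, ]))
      if (length(j))
        emit <- rbind(emit, cbind(m = m, line = j - 1L, tgt = net$mod_out[m, j]))
    }
    sat <- act[net$ramp_value[act] >= p$delay_max_ticks]
    net$ramp_active[sat] <- FALSE
  }

  # (b) delivery in ascending module index, then line
  touched <- integer(0)
  if (!is.null(emit)) {
    emit <- emit[order(emit[, "m"], emit[, "line"]), , drop = FALSE]
    for (k in seq_len(nrow(emit))) {
      tgt <- emit[k, "tgt"]
      i <- tgt + 1L
      if (tck < net$neuron_refract_until[i]) next
      line <- emit[k, "line"] + 1L
      ts <- net$neuron_timer[i, line]
      if (!is.na(ts) && tck - ts > w) ts <- NA_integer_
      if (is.na(ts)) {
        net$neuron_timer[i, line] <- tck
        touched <- c(touched, i)
      }
    }
  }

  # (c) coincidence detection: fire in the tick the threshold is reached
  fired <- integer(0)
  for (i in unique(touched)) {
    ts <- net$neuron_timer[i, ]
    stale <- !is.na(ts) & tck - ts > w
    ts[stale] <- NA_integer_
    net$neuron_timer[i, ] <- ts
    if (sum(!is.na(ts)) >= p$coincidence_threshold) {
      fired <- c(fired, i - 1L)
      net$neuron_timer[i, ] <- NA_integer_
      net$neuron_refract_until[i] <- tck + p$refractory_ticks
    }
  }

  # (d) route post-synaptic and injected spikes back into the axon array
  for (a in c(fired, as.integer(inject))) net <- axon_receive(net, a)$net

  net$current_tick <- tck + 1L
  events <- if (length(fired))
    data.frame(tick = rep(tck, length(fired)), address = fired)
  else data.frame(tick = integer(0), address = integer(0))
  list(net = net, events = events)
}

#' Run the network for many ticks
#'
#' Drives the compiled tick engine (or, for cross-checking, the pure-R
#' [network_step()] loop) over a span of ticks with an optional stream of
#' externally injected post-synaptic spikes (recall cues, noise).
#'
#' @param net A `polychron_net`.
#' @param n_ticks Number of ticks to simulate.
#' @param inject Data.frame with integer columns `tick` and `address`,
#'   sorted by tick: external spikes placed on the post-synaptic bus.
#' @param max_emit Runaway guard: abort once the network has emitted more
#'   than this many spikes (0 = no guard).
#' @param engine `"cpp"` (default) or `"r"`.
#' @return A list with `net` (final state), `events` (data.frame of emitted
#'   post-synaptic spikes) and `runaway` (logical: guard tripped).
#' @export
run_network <- function(net, n_ticks, inject = NULL, max_emit = 0L,
                        engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  inject <- normalize_inject(net, inject)
  if (engine == "r") {
    events <- vector("list", n_ticks)
    runaway <- FALSE
    for (k in seq_len(n_ticks)) {
      now <- net$current_tick
      st <- network_step(net, inject = inject$address[inject$tick == now])
      net <- st$net
      events[[k]] <- st$events
      if (max_emit > 0 && sum(vapply(events, nrow, 1L), na.rm = TRUE) > max_emit) {
        runaway <- TRUE
        break
      }
    }
    ev <- do.call(rbind, events[!vapply(events, is.null, TRUE)])
    return(list(net = net, events = ev, runaway = runaway))
  }
  res <- cpp_run_network(
    na_to_neg(net$mod_input), na_to_neg(net$mod_out), na_to_neg(net$mod_delay),
    net$params$n_neurons,
    net$ramp_value, as.integer(net$ramp_active),
    na_to_neg(net$neuron_timer), net$neuron_refract_until,
    net$current_tick, as.integer(n_ticks),
    inject$tick, inject$address,
    net$params$coincidence_window_ticks, net$params$coincidence_threshold,
    net$params$refractory_ticks, net$params$delay_max_ticks,
    as.integer(max_emit))
  net$ramp_value <- res$ramp
  net$ramp_active <- res$ramp_on != 0L
  net$neuron_timer <- neg_to_na(res$timer_start)
  net$neuron_refract_until <- res$refract_until
  net$current_tick <- res$current_tick
  list(net = net,
       events = data.frame(tick = res$tick, address = res$address),
       runaway = res$runaway)
}

normalize_inject <- function(net, inject) {
  if (is.null(inject) || nrow(inject) == 0)
    return(data.frame(tick = integer(0), address = integer(0)))
  if (is.unsorted(inject$tick))
    validation_error("injected events must be sorted by tick")
  if (any(inject$address < 0 | inject$address >= net$params$n_neurons))
    validation_error("injected address out of range")
  data.frame(tick = as.integer(inject$tick), address = as.integer(inject$address))
}

na_to_neg <- function(x) {
  x[is.na(x)] <- -1L
  x
}

neg_to_na <- function(x) {
  x[x < 0] <- NA_integer_
  x
}

# Idle dynamic state (keeps configuration; used between recall trials).
reset_dynamic_state <- function(net) {
  net$ramp_value[] <- 0L
  net$ramp_active[] <- FALSE
  net$neuron_timer[] <- NA_integer_
  net$neuron_refract_until[] <- 0L
  net$current_tick <- 0L
  net
}
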
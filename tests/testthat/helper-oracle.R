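# Independent brute-force oracle: an event-driven simulator that computes
# every spike time by closed-form addition of programmed delays, with no
# tick loop.  Used to cross-check the compiled engine on tiny networks.

oracle_run <- function(net, duration, inject = NULL) {
  p <- net$params
  n <- p$n_neurons
  window <- p$coincidence_window_ticks
  thr <- p$coincidence_threshold
  refr <- p$refractory_ticks
  dmax <- p$delay_max_ticks

  pending <- data.frame(module = integer(0), line = integer(0),
                        tgt = integer(0), arrive = integer(0))
  timer_start <- matrix(NA_integer_, n, 4)
  refract_until <- integer(n)
  out <- data.frame(tick = integer(0), address = integer(0))

  inj <- if (is.null(inject)) data.frame(tick = integer(0), address = integer(0))
         else inject

  # reset module m at time t: cancel undelivered arrivals scheduled after t,
  # then schedule one arrival per configured path at t + delay
  reset_module <- function(m, t) {
    keep <- !(pending$module == m & pending$arrive > t)
    pending <<- pending[keep, , drop = FALSE]
    for (j in 1:4) {
      d <- net$mod_delay[m, j]
      tgt <- net$mod_out[m, j]
      if (!is.na(d) && !is.na(tgt) && d >= 1 && d <= dmax)
        pending <<- rbind(pending, data.frame(module = m, line = j - 1L,
                                              tgt = tgt, arrive = t + d))
    }
  }

  route <- function(addr, t) {
    for (m in which(!is.na(net$mod_input) & net$mod_input == addr))
      reset_module(m, t)
  }

  repeat {
    cand <- c(pending$arrive, inj$tick)
    cand <- cand[cand < duration]
    if (!length(cand)) break
    t <- min(cand)

    # deliveries at t, ascending module index then line
    due <- pending[pending$arrive == t, , drop = FALSE]
    due <- due[order(due$module, due$line), , drop = FALSE]
    pending <- pending[pending$arrive != t, , drop = FALSE]
    touched <- integer(0)
    for (k in seq_len(nrow(due))) {
      tgt <- due$tgt[k]
      if (t < refract_until[tgt + 1L]) next
      ts <- timer_start[tgt + 1L, due$line[k] + 1L]
      if (!is.na(ts) && t - ts > window) ts <- NA_integer_
      if (is.na(ts)) {
        timer_start[tgt + 1L, due$line[k] + 1L] <- t
        touched <- c(touched, tgt)
      }
    }

    fired <- integer(0)
    for (tgt in unique(touched)) {
      ts <- timer_start[tgt + 1L, ]
      ts[!is.na(ts) & t - ts > window] <- NA_integer_
      timer_start[tgt + 1L, ] <- ts
      if (sum(!is.na(ts)) >= thr) {
        fired <- c(fired, tgt)
        timer_start[tgt + 1L, ] <- NA_integer_
        refract_until[tgt + 1L] <- t + refr
      }
    }

    for (tgt in fired) {
      out <- rbind(out, data.frame(tick = t, address = tgt))
      route(tgt, t)
    }
    hit <- inj$tick == t
    for (addr in inj$address[hit]) route(addr, t)
    inj <- inj[!hit, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

# A random tiny configured network plus a random injection stream.
random_tiny_case <- function(seed, n_neurons = 16, n_modules = 8) {
  set.seed(seed)
  net <- create_network(sim_params(n_neurons = n_neurons, n_axon_arrays = 1,
                                   modules_per_array = n_modules))
  n_conf <- sample(1:n_modules, 1)
  for (m in seq_len(n_conf)) {
    net$mod_input[m] <- sample(0:(n_neurons - 1), 1)
    net$mod_out[m, ] <- sample(0:(n_neurons - 1), 4, replace = TRUE)
    net$mod_delay[m, ] <- sample(1:60, 4, replace = TRUE)
  }
  net$programming_index <- n_conf
  inj <- data.frame(tick = sort(sample(0:80, 12, replace = TRUE)),
                    address = sample(0:(n_neurons - 1), 12, replace = TRUE))
  list(net = net, inject = inj)
}
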
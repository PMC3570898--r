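# Network construction and the tick-level state machines

test_that("network constructor allocates the configured geometry", {
  net <- create_network(sim_params(n_neurons = 4096, n_axon_arrays = 1))
  expect_equal(length(net$mod_input), 4096)          # 4k axon modules
  expect_equal(length(net$mod_delay), 4096 * 4)      # 16k delay paths
  expect_equal(net$programming_index, 0L)
  expect_equal(net$current_tick, 0L)
  small <- create_network(sim_params(n_neurons = 128, modules_per_array = 8))
  expect_equal(length(small$mod_input), 8)
  expect_true(all(is.na(small$mod_input)))
})

test_that("invalid parameter combinations are rejected with a named error", {
  expect_error(sim_params(coincidence_threshold = 5),
               class = "polychron_validation_error")
  expect_error(sim_params(n_neurons = 100),
               class = "polychron_validation_error")
  expect_error(sim_params(delay_max_ticks = 500),
               class = "polychron_validation_error")
})

test_that("axon_receive restarts every matching ramp and reports the count", {
  net <- create_network(sim_params(n_neurons = 128, modules_per_array = 8))
  net$mod_input[1:5] <- c(3L, 9L, 3L, 3L, 20L)
  net$ramp_value[1:5] <- 99L
  r <- axon_receive(net, 3)
  expect_equal(r$n_triggered, 3)
  expect_true(all(r$net$ramp_active[c(1, 3, 4)]))
  expect_true(all(r$net$ramp_value[c(1, 3, 4)] == 0L))
  expect_false(any(r$net$ramp_active[c(2, 5)]))
  expect_equal(axon_receive(net, 50)$n_triggered, 0)   # unconfigured address
  expect_error(axon_receive(net, 128), class = "polychron_validation_error")
})

test_that("neuron_receive starts timers once and respects refractoriness", {
  net <- create_network(sim_params(n_neurons = 128, modules_per_array = 8))
  net <- neuron_receive(net, 10, line = 2, tick = 5)
  expect_equal(net$neuron_timer[11, 3], 5L)
  # second spike on an active line is ignored
  net <- neuron_receive(net, 10, line = 2, tick = 9)
  expect_equal(net$neuron_timer[11, 3], 5L)
  # but an expired timer restarts
  net <- neuron_receive(net, 10, line = 2, tick = 30)
  expect_equal(net$neuron_timer[11, 3], 30L)
  # spikes during the refractory period have no effect at all
  net$neuron_refract_until[11] <- 50L
  net <- neuron_receive(net, 10, line = 0, tick = 45)
  expect_true(is.na(net$neuron_timer[11, 1]))
})

test_that("integration latency is the summed timer count", {
  expect_equal(integration_delay(c(0, 0, 0)), 0L)   # simultaneous arrivals
  expect_equal(integration_delay(c(16, 8, 0)), 24L)
  expect_equal(integration_delay(c(2, 1, 0)), 3L)
  expect_error(integration_delay(c(-1, 2)), class = "polychron_validation_error")
})

# one module wired to four distinct neurons, delays 10/20/30/40
one_module_net <- function() {
  net <- create_network(sim_params(n_neurons = 16, modules_per_array = 4))
  net$mod_input[1] <- 0L
  net$mod_out[1, ] <- c(1L, 2L, 3L, 4L)
  net$mod_delay[1, ] <- c(10L, 20L, 30L, 40L)
  net$programming_index <- 1L
  net
}

test_that("a delay path emits once, when the ramp reaches its programmed delay", {
  net <- one_module_net()
  run <- run_network(net, 60, inject = data.frame(tick = 0, address = 0),
                     engine = "r")
  # pre-synaptic spikes observable as timer starts at the programmed delays
  expect_equal(run$net$neuron_timer[2, 1], 10L)
  expect_equal(run$net$neuron_timer[3, 2], 20L)
  expect_equal(run$net$neuron_timer[4, 3], 30L)
  expect_equal(run$net$neuron_timer[5, 4], 40L)
  expect_equal(nrow(run$events), 0)  # single arrivals never fire a neuron
})

test_that("two coincident inputs never fire a threshold-3 neuron", {
  net <- create_network(sim_params(n_neurons = 16, modules_per_array = 4))
  net$mod_input[1:2] <- c(0L, 1L)
  net$mod_out[1, 1] <- 5L; net$mod_delay[1, 1] <- 10L
  net$mod_out[2, 2] <- 5L; net$mod_delay[2, 2] <- 10L
  net$programming_index <- 2L
  inj <- data.frame(tick = c(0, 0), address = c(0, 1))
  run <- run_network(net, 100, inject = inj)
  expect_equal(nrow(run$events), 0)
})

test_that("timers expire after the coincidence window", {
  net <- create_network(sim_params(n_neurons = 16, modules_per_array = 4))
  # three paths targeting neuron 5 on distinct lines, staggered by 20 ticks
  for (m in 1:3) {
    net$mod_input[m] <- m - 1L
    net$mod_out[m, m] <- 5L
    net$mod_delay[m, m] <- 10L
  }
  net$programming_index <- 3L
  inj <- data.frame(tick = c(0, 20, 40), address = c(0, 1, 2))
  run <- run_network(net, 120, inject = inj)
  expect_equal(nrow(run$events), 0)   # arrivals 20 ticks apart never overlap x3
  # same wiring, arrivals within one window: fires
  inj2 <- data.frame(tick = c(0, 4, 8), address = c(0, 1, 2))
  run2 <- run_network(polychron:::reset_dynamic_state(net), 120, inject = inj2)
  expect_equal(run2$events$address, 5)
  expect_equal(run2$events$tick, 18)  # fires when the third timer starts
})

test_that("a neuron fires at most once per refractory window", {
  net <- create_network(sim_params(n_neurons = 16, modules_per_array = 8))
  # six paths to neuron 5: two volleys 8 ticks apart
  for (m in 1:6) {
    net$mod_input[m] <- 0L
    net$mod_out[m, (m - 1) %% 4 + 1] <- 5L
    net$mod_delay[m, (m - 1) %% 4 + 1] <- if (m <= 3) 10L else 18L
  }
  net$programming_index <- 6L
  run <- run_network(net, 100, inject = data.frame(tick = 0, address = 0))
  expect_equal(nrow(run$events), 1)   # second volley falls in the refractory gap
  expect_equal(run$events$tick, 10)
})

test_that("each ramp activation emits at most one spike per path", {
  net <- one_module_net()
  # restart the ramp at tick 25: paths 1-2 already fired, 3-4 re-schedule
  inj <- data.frame(tick = c(0, 25), address = c(0, 0))
  run <- run_network(net, 100, inject = inj, engine = "r")
  # line 0 timer: first activation at 10, re-fire at 25+10=35
  expect_equal(run$net$neuron_timer[2, 1], 35L)
  # line 2 (delay 30): the first activation was cancelled by the reset at 25,
  # so the only arrival is at 25+30=55
  expect_equal(run$net$neuron_timer[4, 3], 55L)
})

test_that("identical parameters and injections give identical event streams", {
  cs <- random_tiny_case(401)
  r1 <- run_network(cs$net, 200, inject = cs$inject)
  r2 <- run_network(cs$net, 200, inject = cs$inject)
  expect_identical(r1$events, r2$events)
  expect_identical(r1$net, r2$net)
})

test_that("compiled engine, R reference stepper and brute-force oracle agree", {
  for (seed in c(11, 12, 13, 14, 15, 16, 17, 18, 19, 20)) {
    cs <- random_tiny_case(seed)
    cpp <- run_network(cs$net, 200, inject = cs$inject, engine = "cpp")
    rref <- run_network(cs$net, 200, inject = cs$inject, engine = "r")
    orc <- oracle_run(cs$net, 200, inject = cs$inject)
    expect_identical(cpp$events, rref$events)
    expect_equal(unname(as.matrix(cpp$events)), unname(as.matrix(orc)))
    expect_identical(cpp$net$neuron_timer, rref$net$neuron_timer)
    expect_identical(cpp$net$ramp_value, rref$net$ramp_value)
  }
})

test_that("recall of a single stored pattern is exactly time-locked", {
  pat <- generate_pattern(3, 5, n_neurons = 256, n_intervals = 30)
  net <- create_network(sim_params(n_neurons = 256, modules_per_array = 64))
  tr <- train_patterns(net, list(pat), mode = "programming")
  run <- run_network(tr$net, max(pat$tick) + 600,
                     inject = pat[1:4, c("tick", "address")])
  recalled <- run$events
  ref <- pat[5:nrow(pat), ]
  # every reference spike is regenerated at its trained tick
  expect_true(all(paste(ref$tick, ref$address) %in%
                    paste(recalled$tick, recalled$address)))
})
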
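# Delay programming and delay adaptation

toy_pattern <- function(ticks, addrs) {
  structure(data.frame(tick = as.integer(ticks), address = as.integer(addrs)),
            class = c("polychron_pattern", "data.frame"))
}

test_that("delay programming latches the next four spikes of the pattern", {
  pat <- toy_pattern(c(0, 10, 25, 45, 70, 100), c(5, 9, 2, 11, 30, 7))
  net <- create_network(sim_params(n_neurons = 128, modules_per_array = 16))
  r <- program_pattern(net, pat)
  expect_equal(r$report$modules_consumed, 6)
  expect_equal(r$report$patterns_fully_stored, 1)
  # module for the first spike
  expect_equal(r$net$mod_input[1], 5L)
  expect_equal(r$net$mod_out[1, ], c(9L, 2L, 11L, 30L))
  expect_equal(r$net$mod_delay[1, ], c(10L, 25L, 45L, 70L))
  # spikes near the pattern end leave trailing outputs unset
  expect_equal(r$net$mod_out[4, ], c(30L, 7L, NA_integer_, NA_integer_))
  expect_true(all(is.na(r$net$mod_out[6, ])))
  expect_equal(r$net$programming_index, 6L)
})

test_that("one module is consumed per spike and exhaustion configures nothing", {
  pat <- generate_pattern(3, 5, n_neurons = 256, n_intervals = 50)
  net <- create_network(sim_params(n_neurons = 256, modules_per_array = 60))
  r1 <- program_pattern(net, pat)
  expect_equal(r1$report$modules_consumed, 51)
  r2 <- program_pattern(r1$net, pat)       # only 9 slots left
  expect_equal(r2$report$modules_consumed, 9)
  expect_equal(r2$report$patterns_partially_stored, 1)
  r3 <- program_pattern(r2$net, pat)       # exhausted
  expect_equal(r3$report$modules_consumed, 0)
  expect_equal(r3$net$programming_index, 60L)
})

test_that("spans beyond the ramp ceiling are clamped and reported", {
  pat <- toy_pattern(c(0, 200, 400, 600, 800), c(1, 2, 3, 4, 5))
  net <- create_network(sim_params(n_neurons = 128, modules_per_array = 8))
  r <- program_pattern(net, pat)
  expect_equal(r$net$mod_delay[1, ], c(200L, 400L, 511L, 511L))
  expect_equal(r$report$clamped_paths, 3)  # spans 600, 800 and 2->800
})

test_that("adaptation update rules match their definitions", {
  expect_equal(adapt_delay("one_step", 100, 180), 180L)
  expect_equal(adapt_delay("proportional", 100, 180), 140L)
  expect_equal(adapt_delay("single_count", 100, 180), 101L)
  expect_equal(adapt_delay("single_count", 180, 180), 180L)  # fixed point
  expect_equal(adapt_delay("single_count", 200, 180), 199L)
  # clamping to the programmable range
  expect_equal(adapt_delay("one_step", 0, 511), 511L)
  expect_error(adapt_delay("one_step", 600, 100),
               class = "polychron_validation_error")
})

test_that("proportional adaptation approaches the target geometrically", {
  d <- 32L
  seen <- integer(5)
  for (k in 1:5) {
    d <- adapt_delay("proportional", d, 160)
    seen[k] <- d
  }
  expect_equal(seen, c(96L, 128L, 144L, 152L, 156L))
  # error bound (1-c)^k * e0, within one tick of rounding per epoch
  e0 <- 160 - 32
  for (k in 1:5)
    expect_lte(abs(160 - seen[k]), 0.5^k * e0 + 1)
})

test_that("error is non-increasing every epoch for all strategies", {
  set.seed(9)
  for (strategy in c("one_step", "single_count", "proportional")) {
    d <- sample(1:511, 50, replace = TRUE)
    target <- sample(16:480, 50, replace = TRUE)
    err <- abs(d - target)
    for (k in 1:6) {
      d <- adapt_delay(strategy, d, target)
      new_err <- abs(d - target)
      expect_true(all(new_err <= err))   # also rules out overshoot
      err <- new_err
    }
  }
})

test_that("one-step adaptation for one epoch reproduces delay programming", {
  pats <- polychron:::run_patterns(7, 3, 256, 20)
  base <- create_network(sim_params(n_neurons = 256, modules_per_array = 128))
  prog <- train_patterns(base, pats, mode = "programming")$net
  adap <- train_adaptation(base, pats,
                           adaptation_config(strategy = "one_step", epochs = 1,
                                             rng_seed = 3))$net
  expect_identical(prog$mod_input, adap$mod_input)
  expect_identical(prog$mod_out, adap$mod_out)
  # teacher forcing: delays equal exactly wherever the span is measurable
  measurable <- !is.na(adap$mod_delay) & prog$mod_delay < 511
  expect_identical(prog$mod_delay[measurable], adap$mod_delay[measurable])
})

test_that("module addresses are write-once under repeated training", {
  pats <- polychron:::run_patterns(7, 2, 256, 10)
  net <- create_network(sim_params(n_neurons = 256, modules_per_array = 64))
  cfg <- adaptation_config(epochs = 5, rng_seed = 1)
  tr <- train_adaptation(net, pats, cfg)
  one <- train_adaptation(net, pats, adaptation_config(epochs = 1, rng_seed = 1))
  expect_identical(tr$net$mod_input, one$net$mod_input)
  expect_identical(tr$net$mod_out, one$net$mod_out)
})

test_that("adaptation converges toward the true spans over epochs", {
  pats <- polychron:::run_patterns(11, 5, 512, 30)
  net <- create_network(sim_params(n_neurons = 512, modules_per_array = 256))
  tr <- train_adaptation(net, pats, adaptation_config(epochs = 8, rng_seed = 2))
  err <- tr$report$epoch_mean_abs_error
  expect_length(err, 8)
  expect_true(all(diff(err) <= 0))
  expect_lt(err[8], 1)   # essentially converged after 8 halvings
})

test_that("degenerate adaptation configs are rejected", {
  expect_error(adaptation_config(epochs = 0), class = "polychron_validation_error")
  expect_error(adaptation_config(coefficient = 0), class = "polychron_validation_error")
  expect_error(adaptation_config(init_delay_range = c(10, 5)),
               class = "polychron_validation_error")
})
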
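# Pattern generation, noise generation and the recall checker

test_that("generated patterns satisfy the structural contract", {
  p <- generate_pattern(3, 5, n_neurons = 256, n_intervals = 50)
  expect_s3_class(p, "polychron_pattern")
  expect_equal(nrow(p), 51)
  expect_equal(p$tick[1], 0)
  iv <- diff(p$tick)
  expect_true(all(iv >= 16 & iv <= 160))
  expect_true(all(p$address >= 0 & p$address < 256))
  # reproducible from the seed pair
  expect_identical(generate_pattern(3, 5, 256, 50), p)
  # minimal length: one interval -> two events
  expect_equal(nrow(generate_pattern(3, 5, 256, n_intervals = 1)), 2)
})

test_that("a pattern set is one continuous stream and its head is generate_pattern", {
  ps <- generate_pattern_set(7, 11, n_neurons = 512, n_intervals = 20,
                             n_patterns = 5)
  expect_length(ps, 5)
  expect_identical(ps[[1]]$address,
                   generate_pattern(7, 11, 512, 20)$address)
  # same interval seed gives the same intervals regardless of network size
  ps2 <- generate_pattern_set(99, 11, n_neurons = 4096, n_intervals = 20,
                              n_patterns = 5)
  expect_identical(lapply(ps, function(p) diff(p$tick)),
                   lapply(ps2, function(p) diff(p$tick)))
})

test_that("non-power-of-two sizes are rejected", {
  expect_error(generate_pattern(1, 1, n_neurons = 100, n_intervals = 5),
               class = "polychron_validation_error")
})

test_that("pattern addresses are evenly distributed over the array", {
  ps <- generate_pattern_set(13, 17, n_neurons = 256, n_intervals = 50,
                             n_patterns = 120)
  addr <- unlist(lapply(ps, function(p) p$address))
  counts <- tabulate(addr + 1L, nbins = 256)
  expected <- length(addr) / 256
  sigma <- sqrt(expected)
  expect_lt(max(abs(counts - expected)), 5 * sigma)
  expect_gt(min(counts), 0)
})

test_that("noise stream follows the configured Poisson rate", {
  # 100 Hz over ~10 s worth of ticks: count within 3 sigma of 1000
  dur <- as.integer(10 / 62e-6)
  nz <- generate_noise(100, dur, n_neurons = 4096, seed = 5)
  expect_true(abs(nrow(nz) - 1000) < 3 * sqrt(1000))
  expect_true(all(diff(nz$tick) >= 0))
  expect_true(all(nz$address >= 0 & nz$address < 4096))
  expect_identical(generate_noise(100, dur, 4096, seed = 5), nz)
  expect_equal(nrow(generate_noise(0, dur, 4096, seed = 5)), 0)
})

test_that("noise generation does not disturb the global RNG stream", {
  set.seed(77)
  a <- runif(1)
  set.seed(77)
  generate_noise(50, 10000, 256, seed = 1)
  expect_identical(runif(1), a)
})

make_reference <- function(n_checked, cue_len = 4) {
  n <- n_checked + cue_len
  structure(data.frame(tick = seq(0, by = 40, length.out = n),
                       address = seq_len(n)),
            class = c("polychron_pattern", "data.frame"))
}

test_that("checker scores perfect recall as full success", {
  ref <- make_reference(50)
  recalled <- ref[5:54, ]
  rep <- check_recall(ref, recalled)
  expect_equal(rep$n_checked, 50)
  expect_equal(rep$spike_fraction, 1.0)
  expect_true(rep$success)
})

test_that("the 70% success threshold is strict", {
  ref <- make_reference(50)
  rep35 <- check_recall(ref, ref[5:39, ])  # 35 of 50 coincident
  expect_equal(rep35$n_coincident, 35)
  expect_equal(rep35$spike_fraction, 0.70)
  expect_false(rep35$success)              # exactly 70% is not "larger than"
  rep40 <- check_recall(ref, ref[5:44, ])  # 40 of 50 -> 0.80
  expect_true(rep40$success)
})

test_that("checker accepts spikes anywhere inside the 4 ms pulse", {
  ref <- make_reference(10)
  # spikes 40 ticks late are still inside the pulse (starts 8-16 early, 64 wide)
  late <- data.frame(tick = ref$tick[5:14] + 40, address = ref$address[5:14])
  expect_equal(check_recall(ref, late)$spike_fraction, 1.0)
  # spikes 60 ticks late are past every pulse end
  very_late <- data.frame(tick = ref$tick[5:14] + 60, address = ref$address[5:14])
  expect_equal(check_recall(ref, very_late)$n_coincident, 0)
})

test_that("checker never double-counts and is order-invariant", {
  ref <- make_reference(10)
  ref$address[5:14] <- 7L  # all checked spikes share one address
  one_spike <- data.frame(tick = ref$tick[5], address = 7L)
  expect_equal(check_recall(ref, one_spike)$n_coincident, 1)
  recalled <- data.frame(tick = ref$tick[5:14], address = 7L)
  base <- check_recall(ref, recalled)
  shuffled <- recalled[sample(nrow(recalled)), ]
  expect_equal(check_recall(ref, shuffled)$n_coincident, base$n_coincident)
})
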
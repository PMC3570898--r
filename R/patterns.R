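#' Generate a pseudo-random spatio-temporal spike pattern
#'
#' Two maximal-length LFSRs drive the generator: a 16-bit register, reduced
#' modulo the array size, picks the address of each successive neuron in the
#' sequence; a 9-bit register shared by all network sizes sets the
#' inter-spike interval to the previous spike, so runs with the same
#' interval seed have identical interval sequences at every array size.
#' The same seed pair always reproduces the same pattern, which is how
#' training and recall use identical patterns.
#'
#' Intervals are mapped uniformly onto `interval_range` ticks, by default 16
#' to 160 (about 1-10 ms).  The upper bound is chosen so that the span from a
#' spike to the fourth spike after it -- the longest delay an axon module
#' must store -- almost always fits the 511-tick programmable-delay ceiling.
#'
#' @param seed_neuron,seed_interval Positive integer seeds for the two LFSRs.
#' @param n_neurons Network size; must be a power of two.
#' @param n_intervals Number of inter-spike intervals; the pattern has
#'   `n_intervals + 1` spikes, the first at tick 0.
#' @param interval_range Inclusive tick range the interval register is
#'   mapped into.
#' @return A `polychron_pattern`: a data.frame with columns `tick` and
#'   `address` (strictly increasing ticks) and attributes recording the
#'   seeds and generator settings.
#' @examples
#' p <- generate_pattern(3, 5, n_neurons = 256, n_intervals = 10)
#' nrow(p)   # 11 spikes
#' @export
generate_pattern <- function(seed_neuron, seed_interval, n_neurons,
                             n_intervals, interval_range = c(16L, 160L)) {
  if (!is_pow2(n_neurons))
    validation_error("n_neurons must be a power of two")
  if (!is_count(n_intervals))
    validation_error("n_intervals must be >= 1")
  generate_pattern_set(seed_neuron, seed_interval, n_neurons,
                       n_intervals, n_patterns = 1L,
                       interval_range = interval_range)[[1L]]
}

#' Generate a training set of patterns from one continuous LFSR stream
#'
#' The generator runs its two LFSRs continuously: the training stream for a
#' whole run is one long spike sequence that is chopped into patterns, and a
#' single seed pair reproduces the entire set (for training and for recall
#' alike).  The address register is wider than the array's address bus and
#' reduced modulo the array size, so the stream never wraps a register orbit
#' within a run and patterns are statistically independent of each other.
#' Smaller networks still reuse each neuron address in many patterns (there
#' are simply fewer addresses than stream spikes), which is the origin of
#' cross-talk between stored patterns.
#'
#' @inheritParams generate_pattern
#' @param n_patterns Number of consecutive patterns to cut from the stream.
#' @return A list of `polychron_pattern` objects; each pattern's ticks
#'   restart at 0.
#' @export
generate_pattern_set <- function(seed_neuron, seed_interval, n_neurons,
                                 n_intervals, n_patterns,
                                 interval_range = c(16L, 160L)) {
  if (!is_pow2(n_neurons))
    validation_error("n_neurons must be a power of two")
  if (!is_count(n_intervals))
    validation_error("n_intervals must be >= 1")
  if (!is_count(n_patterns))
    validation_error("n_patterns must be >= 1")
  lo <- as.integer(interval_range[1]); hi <- as.integer(interval_range[2])
  if (!(lo >= 1 && hi >= lo))
    validation_error("invalid interval_range")
  # a 16-bit address register, reduced modulo the array size: wider than any
  # array's address bus, so the sampled stream never wraps within a run
  la <- lfsr_new(16L, seed_neuron)
  lb <- lfsr_new(9L, seed_interval)
  n_spikes <- n_patterns * (n_intervals + 1L)
  stream <- cpp_pattern_stream(la$width, la$taps, la$state,
                               lb$width, lb$taps, lb$state,
                               n_spikes, lo, hi, as.integer(n_neurons))
  lapply(seq_len(n_patterns), function(p) {
    k <- (p - 1L) * (n_intervals + 1L) + seq_len(n_intervals + 1L)
    a <- stream$address[k]
    v <- stream$interval[k[seq_len(n_intervals)]]
    structure(
      data.frame(tick = c(0L, cumsum(v)), address = as.integer(a)),
      seed_neuron = as.integer(seed_neuron),
      seed_interval = as.integer(seed_interval),
      n_neurons = as.integer(n_neurons),
      n_intervals = as.integer(n_intervals),
      interval_range = c(lo, hi),
      pattern_id = p,
      class = c("polychron_pattern", "data.frame"))
  })
}

#' Generate a Poisson noise spike stream
#'
#' A network-wide Poisson process: `rate_hz` is the total rate of extra
#' spikes entering the network per second (not a per-neuron rate), each
#' assigned to a uniformly random neuron.  Exponential inter-arrival times
#' are quantized to ticks.
#'
#' @param rate_hz Total noise rate in spikes per second (0 gives an empty
#'   stream).
#' @param duration_ticks Length of the stream in ticks.
#' @param n_neurons Address range for the random targets.
#' @param seed Integer seed; the same seed reproduces the same stream.
#' @param tick_us Tick duration in microseconds.
#' @return Data.frame with columns `tick`, `address`, sorted by tick.
#' @export
generate_noise <- function(rate_hz, duration_ticks, n_neurons, seed,
                           tick_us = 62) {
  if (rate_hz < 0) validation_error("rate_hz must be >= 0")
  if (rate_hz == 0 || duration_ticks < 1)
    return(data.frame(tick = integer(0), address = integer(0)))
  rate_per_tick <- rate_hz * tick_us * 1e-6
  with_seed(seed, {
    n_draw <- max(16, ceiling(duration_ticks * rate_per_tick * 1.5 + 10))
    gaps <- rexp(n_draw, rate = rate_per_tick)
    t <- cumsum(gaps)
    while (sum(gaps) < duration_ticks) {
      more <- rexp(n_draw, rate = rate_per_tick)
      gaps <- c(gaps, more)
      t <- c(t, t[length(t)] + cumsum(more))
    }
    tick <- as.integer(floor(t[t < duration_ticks]))
    addr <- as.integer(sample.int(n_neurons, length(tick), replace = TRUE) - 1L)
    data.frame(tick = tick, address = addr)
  })
}

#' Score a recall against its reference pattern
#'
#' Mirrors the hardware pattern checker.  For every reference spike after
#' the cue it opens a 4 ms acceptance pulse (64 ticks) that starts a random
#' 8-16 ticks (about 0.5-1 ms) before the reference tick; a coincidence is
#' recorded when a network spike with the matching address falls inside the
#' pulse.  Each pulse accepts at most one spike (the earliest match) and each
#' network spike is counted at most once.  The pattern counts as successfully
#' recalled when the coincident fraction strictly exceeds `threshold`.
#'
#' @param reference The stored [generate_pattern()] pattern.
#' @param recalled Data.frame of network spikes (`tick`, `address`).
#' @param cue_len Number of leading cue spikes excluded from checking
#'   (default 4).
#' @param threshold Success threshold on the recalled fraction (default 0.7,
#'   strict inequality).
#' @param checker_seed Seed for the per-spike random early offsets, so a
#'   check is reproducible.
#' @param pulse_ticks Acceptance pulse width in ticks (default 64, 4 ms).
#' @param early_offset_range Inclusive range of the random early offset in
#'   ticks (default 8..16).
#' @param pattern_id Optional identifier copied into the report.
#' @return A `recall_report` list: `pattern_id`, `n_reference_spikes`,
#'   `n_checked`, `n_coincident`, `spike_fraction`, `success`, `threshold`.
#' @export
check_recall <- function(reference, recalled, cue_len = 4, threshold = 0.7,
                         checker_seed = 1, pulse_ticks = 64,
                         early_offset_range = c(8L, 16L), pattern_id = NA) {
  if (!(threshold > 0 && threshold < 1))
    validation_error("threshold must be in (0, 1)")
  n_ref <- nrow(reference)
  idx <- seq_len(n_ref)
  idx <- idx[idx > cue_len]
  n_checked <- length(idx)
  lo <- early_offset_range[1]; span <- early_offset_range[2] - lo + 1L
  used <- rep(FALSE, nrow(recalled))
  hit <- 0L
  # per-pulse early offsets from a small dedicated generator, so that a
  # check is reproducible without touching R's global RNG
  x0 <- as.numeric(mix_seed(checker_seed))
  offs <- lo + ((x0 * 69069 + 1013904223 * seq_along(idx)) %% 2147483647) %% span
  for (k in seq_along(idx)) {
    i <- idx[k]
    off <- offs[k]
    start <- reference$tick[i] - off
    cand <- which(!used & recalled$address == reference$address[i] &
                    recalled$tick >= start & recalled$tick < start + pulse_ticks)
    if (length(cand)) {
      used[cand[which.min(recalled$tick[cand])]] <- TRUE
      hit <- hit + 1L
    }
  }
  frac <- if (n_checked > 0) hit / n_checked else NA_real_
  structure(list(
    pattern_id = pattern_id,
    n_reference_spikes = n_ref,
    n_checked = n_checked,
    n_coincident = hit,
    spike_fraction = frac,
    success = isTRUE(frac > threshold),
    threshold = threshold
  ), class = "recall_report")
}

#' @export
print.recall_report <- function(x, ...) {
  cat(sprintf("recall report%s: %d/%d spikes coincident (%.1f%%) -> %s\n",
              if (is.na(x$pattern_id)) "" else paste0(" [", x$pattern_id, "]"),
              x$n_coincident, x$n_checked, 100 * x$spike_fraction,
              if (x$success) "success" else "failure"))
  invisible(x)
}
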
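# Experiment harnesses: capacity arithmetic, cued recall trials, and the
# sweeps over network size, noise rate and full-capacity load.

#' Storage capacity of a module budget
#'
#' Connections are generated de novo and never shared between patterns, so
#' each spike of a stored pattern consumes exactly one axon module and the
#' capacity is simply `floor(total_modules / pattern_len_spikes)`.
#'
#' @param total_modules Total axon modules available.
#' @param pattern_len_spikes Spikes per pattern.
#' @return Maximum number of storable patterns.
#' @examples
#' capacity(70 * 4096, 51)   # 5621
#' capacity(70 * 4096, 21)   # 13653
#' @export
capacity <- function(total_modules, pattern_len_spikes) {
  if (!is_count(pattern_len_spikes))
    validation_error("pattern_len_spikes must be >= 1")
  if (!is_count(total_modules))
    validation_error("total_modules must be >= 1")
  as.integer(total_modules %/% pattern_len_spikes)
}

# Cue + noise injection stream for one trial
trial_injection <- function(pattern, cue_len, noise_rate_hz, duration_ticks,
                            n_neurons, noise_seed, tick_us) {
  cue <- pattern[seq_len(min(cue_len, nrow(pattern))), c("tick", "address")]
  inj <- cue
  if (noise_rate_hz > 0) {
    noise <- generate_noise(noise_rate_hz, duration_ticks, n_neurons,
                            seed = noise_seed, tick_us = tick_us)
    inj <- rbind(inj, noise)
    inj <- inj[order(inj$tick), , drop = FALSE]
  }
  inj
}

# Run and score recall of many patterns against one trained network.
batch_recall <- function(net, patterns, run_seed, noise_rate_hz = 0,
                         success_threshold = 0.7, cue_len = 4,
                         max_emit_factor = 50) {
  p <- net$params
  n_trials <- length(patterns)
  inj_tick <- vector("list", n_trials)
  inj_addr <- vector("list", n_trials)
  durations <- integer(n_trials)
  guards <- integer(n_trials)
  for (i in seq_len(n_trials)) {
    pat <- patterns[[i]]
    durations[i] <- max(pat$tick) + 10L * p$delay_max_ticks
    guards[i] <- max_emit_factor * nrow(pat)
    inj <- trial_injection(pat, cue_len, noise_rate_hz, durations[i],
                           p$n_neurons, noise_seed = mix_seed(run_seed, i, 4),
                           tick_us = p$tick_us)
    inj_tick[[i]] <- inj$tick
    inj_addr[[i]] <- inj$address
  }
  offs <- c(0L, cumsum(vapply(inj_tick, length, 1L)))
  res <- cpp_recall_batch(
    na_to_neg(net$mod_input), na_to_neg(net$mod_out), na_to_neg(net$mod_delay),
    p$n_neurons, p$coincidence_window_ticks, p$coincidence_threshold,
    p$refractory_ticks, p$delay_max_ticks,
    as.integer(unlist(inj_tick)), as.integer(unlist(inj_addr)),
    as.integer(offs), durations, guards)
  out <- data.frame(pattern = seq_len(n_trials), n_checked = NA_integer_,
                    n_coincident = NA_integer_, fraction = NA_real_,
                    success = FALSE, runaway = FALSE)
  for (i in seq_len(n_trials)) {
    r <- res[[i]]
    if (isTRUE(r$runaway)) {
      # runaway cross-talk: trial aborted and scored as failure
      out$n_checked[i] <- nrow(patterns[[i]]) - cue_len
      out$n_coincident[i] <- 0L
      out$fraction[i] <- 0
      out$runaway[i] <- TRUE
      next
    }
    rep <- check_recall(patterns[[i]],
                        data.frame(tick = r$tick, address = r$address),
                        cue_len = cue_len, threshold = success_threshold,
                        checker_seed = mix_seed(run_seed, i, 3),
                        pattern_id = i)
    out$n_checked[i] <- rep$n_checked
    out$n_coincident[i] <- rep$n_coincident
    out$fraction[i] <- rep$spike_fraction
    out$success[i] <- rep$success
  }
  out
}

#' Cue a trained network and score the recall
#'
#' Injects the first `cue_len` spikes of the pattern at their trained
#' relative ticks (plus optional Poisson noise), lets the network run until
#' any residual activity has died out, and scores the emitted spikes with
#' [check_recall()].  A trial whose emitted-spike count explodes past
#' `max_emit_factor` times the pattern length (the all-fire cross-talk
#' state) is aborted and scored as a failure.
#'
#' @param net A trained `polychron_net`.
#' @param pattern The reference pattern.
#' @param noise_rate_hz Total Poisson noise rate during recall (Hz).
#' @param seed Seed for noise and checker randomness.
#' @param success_threshold Strict success threshold on the recalled
#'   fraction (default 0.7).
#' @param cue_len Cue length in spikes (default 4).
#' @param duration_ticks Simulation length; default pattern duration plus
#'   ten delay ceilings.
#' @param max_emit_factor Runaway guard multiplier (default 50).
#' @return A `recall_report`, with an extra `runaway` flag.
#' @export
run_recall_trial <- function(net, pattern, noise_rate_hz = 0, seed = 1,
                             success_threshold = 0.7, cue_len = 4,
                             duration_ticks = NULL, max_emit_factor = 50) {
  p <- net$params
  if (is.null(duration_ticks))
    duration_ticks <- max(pattern$tick) + 10L * p$delay_max_ticks
  inj <- trial_injection(pattern, cue_len, noise_rate_hz, duration_ticks,
                         p$n_neurons, noise_seed = mix_seed(seed, 1, 4),
                         tick_us = p$tick_us)
  net <- reset_dynamic_state(net)
  run <- run_network(net, duration_ticks, inject = inj,
                     max_emit = max_emit_factor * nrow(pattern))
  rep <- check_recall(pattern, run$events, cue_len = cue_len,
                      threshold = success_threshold,
                      checker_seed = mix_seed(seed, 1, 3))
  if (isTRUE(run$runaway)) {
    rep$success <- FALSE
    rep$spike_fraction <- 0
    rep$n_coincident <- 0L
  }
  rep$runaway <- isTRUE(run$runaway)
  rep
}

# Patterns for one run: one continuous two-LFSR stream chopped into
# patterns.  The interval seed does not depend on the network size, so runs
# with the same seed share inter-spike intervals across sizes.
run_patterns <- function(run_seed, n_patterns, n_neurons, n_intervals,
                         interval_range = c(16L, 160L)) {
  generate_pattern_set(seed_neuron = mix_seed(run_seed, 1),
                       seed_interval = mix_seed(run_seed, 2),
                       n_neurons = n_neurons, n_intervals = n_intervals,
                       n_patterns = n_patterns, interval_range = interval_range)
}

# Train + recall one configuration for one run seed.
run_one_config <- function(n_neurons, total_modules, mode, n_patterns,
                           n_intervals, run_seed, noise_rate_hz = 0,
                           epochs = 5, coefficient = 0.5,
                           success_threshold = 0.7, cue_len = 4) {
  params <- sim_params(n_neurons = n_neurons, n_axon_arrays = 1L,
                       modules_per_array = as.integer(total_modules))
  net <- create_network(params)
  patterns <- run_patterns(run_seed, n_patterns, n_neurons, n_intervals)
  tr <- if (mode == "programming") {
    train_patterns(net, patterns, mode = "programming")
  } else {
    train_adaptation(net, patterns,
                     adaptation_config(strategy = "proportional",
                                       coefficient = coefficient,
                                       epochs = epochs,
                                       rng_seed = mix_seed(run_seed, 0, 5)))
  }
  scores <- batch_recall(tr$net, patterns, run_seed = run_seed,
                         noise_rate_hz = noise_rate_hz,
                         success_threshold = success_threshold,
                         cue_len = cue_len)
  list(scores = scores, report = tr$report)
}

sweep_aggregate <- function(runs, by) {
  agg <- aggregate(runs$success_pct, runs[, by, drop = FALSE],
                   function(x) c(mean = mean(x), sd = sd(x)))
  out <- cbind(agg[, by, drop = FALSE],
               mean_success_pct = agg$x[, "mean"],
               sd_success_pct = agg$x[, "sd"])
  out[do.call(order, out[, by, drop = FALSE]), , drop = FALSE]
}

#' Sweep recall success over network sizes
#'
#' For each neuron-array size and each of `n_runs` seeded runs: generate
#' `n_patterns` patterns of `n_intervals` intervals, store them (delay
#' programming trains each pattern once; delay adaptation uses `epochs`
#' presentations with the proportional strategy), recall each pattern from
#' its 4-spike cue, and record the percentage recalled successfully.  The
#' aggregate reports mean and standard deviation over the runs.
#'
#' @param sizes Neuron-array sizes (powers of two).
#' @param mode `"programming"` or `"adaptation"`.
#' @param n_patterns Patterns stored per run (default 82: the 82-pattern
#'   regime of a single 4096-module axon array holding 50-interval patterns;
#'   the last patterns may be only partially stored and still count).
#' @param n_intervals Inter-spike intervals per pattern (default 50).
#' @param n_runs Seeded runs per size (default 10).
#' @param master_seed Master seed; expands to one seed per run, shared
#'   across sizes.
#' @param noise_rate_hz Poisson noise rate during recall (default 0).
#' @param epochs,coefficient Adaptation settings.
#' @param total_modules Axon modules available (default 4096, one array).
#' @param success_threshold Strict per-pattern success threshold.
#' @return A `polychron_sweep` list: `summary` (per size), `runs` (per size
#'   x run) and `patterns` (per-pattern spike-recall fractions).
#' @export
sweep_network_size <- function(sizes = c(256, 512, 1024, 2048, 4096),
                               mode = c("programming", "adaptation"),
                               n_patterns = 82, n_intervals = 50, n_runs = 10,
                               master_seed = 1, noise_rate_hz = 0,
                               epochs = 5, coefficient = 0.5,
                               total_modules = 4096,
                               success_threshold = 0.7) {
  mode <- match.arg(mode)
  seeds <- seed_stream(master_seed, n_runs)
  runs <- NULL
  pats <- NULL
  for (size in sizes) {
    for (r in seq_len(n_runs)) {
      res <- run_one_config(size, total_modules, mode, n_patterns,
                            n_intervals, run_seed = seeds[r],
                            noise_rate_hz = noise_rate_hz,
                            epochs = epochs, coefficient = coefficient,
                            success_threshold = success_threshold)
      sc <- res$scores
      runs <- rbind(runs, data.frame(
        size = size, run = r, seed = seeds[r], mode = mode,
        success_pct = 100 * mean(sc$success),
        mean_fraction = mean(sc$fraction),
        n_runaway = sum(sc$runaway)))
      pats <- rbind(pats, data.frame(size = size, run = r, mode = mode,
                                     pattern = sc$pattern,
                                     fraction = sc$fraction,
                                     success = sc$success))
    }
  }
  structure(list(summary = sweep_aggregate(runs, "size"),
                 runs = runs, patterns = pats, mode = mode),
            class = "polychron_sweep")
}

#' @export
print.polychron_sweep <- function(x, ...) {
  cat(sprintf("polychron sweep (%s mode)\n", x$mode))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Per-pattern spike-recall distribution
#'
#' Runs the size sweep and returns the full distribution of per-pattern
#' spike-recall fractions, characterizing recall quality beyond the binary
#' 70% success criterion.
#'
#' @inheritParams sweep_network_size
#' @return Data.frame with columns `size`, `run`, `mode`, `pattern`,
#'   `fraction`, `success`.
#' @export
spike_recall_distribution <- function(sizes = c(256, 512, 1024, 2048, 4096),
                                      mode = c("programming", "adaptation"),
                                      n_patterns = 82, n_intervals = 50,
                                      n_runs = 10, master_seed = 1, ...) {
  sw <- sweep_network_size(sizes = sizes, mode = mode,
                           n_patterns = n_patterns, n_intervals = n_intervals,
                           n_runs = n_runs, master_seed = master_seed, ...)
  sw$patterns
}

#' Sweep recall success over noise rates
#'
#' Fixes the network configuration (4096 neurons by default) and varies the
#' total Poisson noise rate injected during recall.  Training itself is
#' noise-free.
#'
#' @inheritParams sweep_network_size
#' @param rates Noise rates in spikes per second.
#' @param modes Training modes to sweep.
#' @param size Neuron-array size.
#' @return A `polychron_sweep` with `rate` and `mode` columns.
#' @export
sweep_noise <- function(rates = c(2, 4, 8, 16, 32, 64, 128),
                        modes = c("programming", "adaptation"),
                        size = 4096, n_patterns = 82, n_intervals = 50,
                        n_runs = 10, master_seed = 1, epochs = 5,
                        coefficient = 0.5, total_modules = 4096,
                        success_threshold = 0.7) {
  seeds <- seed_stream(master_seed, n_runs)
  runs <- NULL
  for (mode in modes) {
    for (rate in rates) {
      for (r in seq_len(n_runs)) {
        res <- run_one_config(size, total_modules, mode, n_patterns,
                              n_intervals, run_seed = seeds[r],
                              noise_rate_hz = rate, epochs = epochs,
                              coefficient = coefficient,
                              success_threshold = success_threshold)
        runs <- rbind(runs, data.frame(
          mode = mode, rate = rate, run = r, seed = seeds[r],
          success_pct = 100 * mean(res$scores$success),
          mean_fraction = mean(res$scores$fraction),
          n_runaway = sum(res$scores$runaway)))
      }
    }
  }
  structure(list(summary = sweep_aggregate(runs, c("mode", "rate")),
                 runs = runs, patterns = NULL, mode = paste(modes, collapse = "+")),
            class = "polychron_sweep")
}

#' Load the network to capacity and test recall
#'
#' Stores the capacity-determined number of patterns -- every axon module
#' consumed -- and recalls each one.  At full scale the configuration is 70
#' axon arrays of 4096 modules with 4096 neurons (1.15M delay paths); the
#' `scale` factor shrinks the module budget and hence the pattern count
#' proportionally for desk-scale runs (note the scaled network is sparser in
#' connections per neuron, an easier cross-talk regime).
#'
#' @param scale Fraction of the full module budget (default 0.1).
#' @param lengths Pattern lengths in spikes (default 21 and 51).
#' @param modes Training modes.
#' @param n_runs Seeded runs per scenario (default 10).
#' @param master_seed Master seed.
#' @param n_neurons Neuron-array size (default 4096).
#' @param total_modules_full Module budget at scale 1 (default 70 x 4096).
#' @param epochs,coefficient Adaptation settings.
#' @param success_threshold Strict per-pattern success threshold.
#' @return A `polychron_sweep` whose `summary` has one row per
#'   (mode, length) scenario and whose `patterns` element carries all
#'   per-pattern spike fractions.
#' @export
full_capacity_test <- function(scale = 0.1, lengths = c(21, 51),
                               modes = c("programming", "adaptation"),
                               n_runs = 10, master_seed = 1,
                               n_neurons = 4096, total_modules_full = 70 * 4096,
                               epochs = 5, coefficient = 0.5,
                               success_threshold = 0.7) {
  total_modules <- as.integer(round(total_modules_full * scale))
  seeds <- seed_stream(master_seed, n_runs)
  runs <- NULL
  pats <- NULL
  for (mode in modes) {
    for (len in lengths) {
      n_patterns <- capacity(total_modules, len)
      for (r in seq_len(n_runs)) {
        res <- run_one_config(n_neurons, total_modules, mode, n_patterns,
                              n_intervals = len - 1L, run_seed = seeds[r],
                              epochs = epochs, coefficient = coefficient,
                              success_threshold = success_threshold)
        sc <- res$scores
        runs <- rbind(runs, data.frame(
          mode = mode, length = len, run = r, seed = seeds[r],
          n_patterns = n_patterns,
          success_pct = 100 * mean(sc$success),
          pct_gt95 = 100 * mean(sc$fraction > 0.95),
          n_runaway = sum(sc$runaway)))
        pats <- rbind(pats, data.frame(mode = mode, length = len, run = r,
                                       pattern = sc$pattern,
                                       fraction = sc$fraction,
                                       success = sc$success))
      }
    }
  }
  summary <- sweep_aggregate(runs, c("mode", "length"))
  g95 <- aggregate(runs$pct_gt95, runs[, c("mode", "length")], mean)
  summary$mean_pct_gt95 <- g95$x[match(paste(summary$mode, summary$length),
                                       paste(g95$mode, g95$length))]
  structure(list(summary = summary, runs = runs, patterns = pats,
                 mode = paste(modes, collapse = "+"), scale = scale),
            class = "polychron_sweep")
}
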
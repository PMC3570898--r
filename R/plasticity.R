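# Training: sequential write-once delay programming and the three
# delay-adaptation strategies.  Training is teacher-forced: the full pattern
# is presented externally, so every module's ramp comparison uses the trained
# spike times, which makes both procedures analytic in the spike times.

# Wiring that a pattern induces: spike k's module takes spike k's address as
# input, the addresses of spikes k+1..k+4 as outputs, and the tick spans
# k -> k+j as delay targets.
pattern_wiring <- function(pattern) {
  s <- nrow(pattern)
  addr <- pattern$address
  tick <- pattern$tick
  out <- matrix(NA_integer_, s, 4)
  span <- matrix(NA_integer_, s, 4)
  for (j in 1:4) {
    k <- seq_len(max(0L, s - j))
    out[k, j] <- addr[k + j]
    span[k, j] <- tick[k + j] - tick[k]
  }
  list(input = addr, out = out, span = span, n_spikes = s)
}

new_training_report <- function(modules_consumed, fully, partially,
                                clamped_paths = 0L, unmeasurable_paths = 0L,
                                epoch_mean_abs_error = NULL) {
  structure(list(
    modules_consumed = as.integer(modules_consumed),
    patterns_fully_stored = as.integer(fully),
    patterns_partially_stored = as.integer(partially),
    clamped_paths = as.integer(clamped_paths),
    unmeasurable_paths = as.integer(unmeasurable_paths),
    epoch_mean_abs_error = epoch_mean_abs_error
  ), class = "training_report")
}

#' @export
print.training_report <- function(x, ...) {
  cat(sprintf("training report: %d modules consumed, %d patterns fully / %d partially stored\n",
              x$modules_consumed, x$patterns_fully_stored, x$patterns_partially_stored))
  if (x$clamped_paths > 0)
    cat(sprintf("  %d delay paths clamped at the delay ceiling\n", x$clamped_paths))
  if (x$unmeasurable_paths > 0)
    cat(sprintf("  %d delay paths beyond the ramp range (not adapted)\n", x$unmeasurable_paths))
  if (!is.null(x$epoch_mean_abs_error))
    cat("  per-epoch mean |delay error| (ticks):",
        paste(sprintf("%.2f", x$epoch_mean_abs_error), collapse = ", "), "\n")
  invisible(x)
}

#' Store a pattern by delay programming
#'
#' Write-once training: each spike of the pattern consumes the next
#' unconfigured axon module (the programming index advances by one per
#' spike).  The module latches the spike's address as its input address, the
#' addresses of the next four pattern spikes as its output addresses, and the
#' corresponding inter-spike spans as its programmed delays.  Spikes within
#' four of the pattern end leave their trailing outputs unset; spans beyond
#' the programmable-delay ceiling are clamped there and reported.  Once all
#' modules are consumed further spikes configure nothing.
#'
#' @param net A `polychron_net`.
#' @param pattern A [generate_pattern()] pattern (strictly increasing ticks).
#' @return A list with `net` (updated) and `report` (a `training_report`).
#' @export
program_pattern <- function(net, pattern) {
  s <- nrow(pattern)
  if (s == 0)
    return(list(net = net, report = new_training_report(0L, 0L, 0L)))
  if (s > 1 && any(diff(pattern$tick) <= 0))
    validation_error("pattern ticks must be strictly increasing")
  w <- pattern_wiring(pattern)
  avail <- n_modules(net) - net$programming_index
  consumed <- min(s, avail)
  clamped <- 0L
  if (consumed > 0) {
    k <- seq_len(consumed)
    slots <- net$programming_index + k
    net$mod_input[slots] <- w$input[k]
    dmax <- net$params$delay_max_ticks
    d <- w$span[k, , drop = FALSE]
    clamped <- sum(d > dmax, na.rm = TRUE)
    d[!is.na(d) & d > dmax] <- dmax
    net$mod_out[slots, ] <- w$out[k, , drop = FALSE]
    net$mod_delay[slots, ] <- d
    net$programming_index <- net$programming_index + as.integer(consumed)
  }
  report <- new_training_report(
    consumed,
    fully = as.integer(consumed == s),
    partially = as.integer(consumed > 0 && consumed < s),
    clamped_paths = clamped)
  list(net = net, report = report)
}

#' One delay-adaptation update
#'
#' Shifts a programmed delay toward the observed timing of its output
#' neuron's firing (the ramp value at fire time).  Three strategies:
#' `"one_step"` jumps straight to the ramp value; `"single_count"` moves one
#' tick toward it; `"proportional"` moves by `coefficient` times the
#' difference, rounded half away from zero so any nonzero error produces
#' movement.  Results are clamped to the programmable range.  All arguments
#' are vectorized.
#'
#' @param strategy `"one_step"`, `"single_count"` or `"proportional"`.
#' @param programmed Current programmed delay(s), ticks.
#' @param ramp_at_fire Ramp value(s) when the output neuron fired, ticks.
#' @param coefficient Proportional coefficient in (0, 1] (default 0.5).
#' @param delay_max_ticks Programmable-range ceiling for clamping.
#' @return The updated delay(s), integer ticks.
#' @examples
#' adapt_delay("one_step", 100, 180)               # 180
#' adapt_delay("proportional", 100, 180)           # 140
#' adapt_delay("single_count", c(100, 180), 180)   # 101, 180
#' @export
adapt_delay <- function(strategy = c("one_step", "single_count", "proportional"),
                        programmed, ramp_at_fire, coefficient = 0.5,
                        delay_max_ticks = 511L) {
  strategy <- match.arg(strategy)
  if (!(coefficient > 0 && coefficient <= 1))
    validation_error("coefficient must be in (0, 1]")
  if (any(programmed < 0 | programmed > delay_max_ticks, na.rm = TRUE) ||
      any(ramp_at_fire < 0 | ramp_at_fire > delay_max_ticks, na.rm = TRUE))
    validation_error("delays must lie in [0, delay_max_ticks]")
  diffs <- ramp_at_fire - programmed
  upd <- switch(strategy,
    one_step = ramp_at_fire,
    single_count = programmed + sign(diffs),
    proportional = programmed + round_half_away(coefficient * diffs))
  as.integer(pmin(pmax(upd, 0L), delay_max_ticks))
}

round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Adaptation settings
#'
#' @param strategy Adaptation strategy, see [adapt_delay()].  Default
#'   `"proportional"`.
#' @param coefficient Proportional coefficient (default 0.5).
#' @param epochs Training presentations per pattern (default 5).  Every
#'   epoch applies one [adapt_delay()] update per delay path.
#' @param init_delay_range Inclusive tick range for the random initial
#'   delays written when a module is first configured.
#' @param rng_seed Seed for the random initialization.
#' @return An `adaptation_config` list.
#' @export
adaptation_config <- function(strategy = "proportional", coefficient = 0.5,
                              epochs = 5, init_delay_range = c(1L, 511L),
                              rng_seed = 1) {
  strategy <- match.arg(strategy, c("one_step", "single_count", "proportional"))
  if (!is_count(epochs)) validation_error("epochs must be >= 1")
  if (!(coefficient > 0 && coefficient <= 1))
    validation_error("coefficient must be in (0, 1]")
  lo <- init_delay_range[1]; hi <- init_delay_range[2]
  if (!(is_count(lo) && is_count(hi) && lo <= hi))
    validation_error("init_delay_range must satisfy 1 <= low <= high")
  structure(list(strategy = strategy, coefficient = coefficient,
                 epochs = as.integer(epochs),
                 init_delay_range = as.integer(c(lo, hi)),
                 rng_seed = as.integer(rng_seed)),
            class = "adaptation_config")
}

#' Store patterns by delay adaptation
#'
#' The first presentation of each pattern configures module addresses exactly
#' as [program_pattern()] does but initializes the programmed delays with
#' random values from `init_delay_range`.  Every epoch then presents each
#' full pattern externally (teacher forcing: the post-synaptic firing times
#' are the trained spike times) and applies one [adapt_delay()] update per
#' delay path, moving the delay toward the true inter-spike span.  Addresses
#' are write-once and never re-written.  Paths whose true span exceeds the
#' ramp ceiling cannot be measured by the ramp and are never adapted; they
#' retain their random delays (a cross-talk source, reported).
#'
#' @param net A `polychron_net`.
#' @param patterns A list of patterns (or a single pattern).
#' @param config An [adaptation_config()].
#' @return A list with `net` and `report` (`training_report` whose
#'   `epoch_mean_abs_error` tracks convergence of the adaptable delays).
#' @export
train_adaptation <- function(net, patterns, config = adaptation_config()) {
  if (!inherits(config, "adaptation_config"))
    validation_error("config must be created by adaptation_config()")
  if (inherits(patterns, "polychron_pattern")) patterns <- list(patterns)
  if (config$init_delay_range[2] > net$params$delay_max_ticks)
    validation_error("init_delay_range exceeds delay_max_ticks")
  dmax <- net$params$delay_max_ticks

  slots_all <- integer(0)
  targets_all <- NULL
  consumed_total <- 0L
  fully <- 0L
  partially <- 0L
  for (pat in patterns) {
    s <- nrow(pat)
    if (s == 0) next
    if (s > 1 && any(diff(pat$tick) <= 0))
      validation_error("pattern ticks must be strictly increasing")
    w <- pattern_wiring(pat)
    avail <- n_modules(net) - net$programming_index
    consumed <- min(s, avail)
    if (consumed > 0) {
      k <- seq_len(consumed)
      slots <- net$programming_index + k
      net$mod_input[slots] <- w$input[k]
      net$mod_out[slots, ] <- w$out[k, , drop = FALSE]
      net$programming_index <- net$programming_index + as.integer(consumed)
      tg <- w$span[k, , drop = FALSE]
      tg[!is.na(tg) & tg > dmax] <- NA_integer_   # beyond ramp range: unmeasurable
      slots_all <- c(slots_all, slots)
      targets_all <- rbind(targets_all, tg)
    }
    consumed_total <- consumed_total + consumed
    fully <- fully + as.integer(consumed == s)
    partially <- partially + as.integer(consumed > 0 && consumed < s)
  }

  epoch_err <- numeric(0)
  unmeasurable <- 0L
  if (length(slots_all)) {
    has_out <- !is.na(net$mod_out[slots_all, , drop = FALSE])
    unmeasurable <- sum(has_out & is.na(targets_all))
    # random initial delays for every existing path
    init <- matrix(NA_integer_, length(slots_all), 4)
    lo <- config$init_delay_range[1]; hi <- config$init_delay_range[2]
    init[has_out] <- with_seed(config$rng_seed,
      as.integer(sample(seq.int(lo, hi), sum(has_out), replace = TRUE)))
    d <- init
    adaptable <- has_out & !is.na(targets_all)
    for (e in seq_len(config$epochs)) {
      d[adaptable] <- adapt_delay(config$strategy, d[adaptable],
                                  targets_all[adaptable], config$coefficient,
                                  delay_max_ticks = dmax)
      epoch_err <- c(epoch_err,
                     mean(abs(d[adaptable] - targets_all[adaptable])))
    }
    net$mod_delay[slots_all, ] <- d
  }

  report <- new_training_report(
    consumed_total, fully, partially,
    unmeasurable_paths = unmeasurable,
    epoch_mean_abs_error = epoch_err)
  list(net = net, report = report)
}

#' Train a set of patterns in either mode
#'
#' Convenience wrapper: `mode = "programming"` applies [program_pattern()]
#' to each pattern in order; `mode = "adaptation"` calls
#' [train_adaptation()].
#'
#' @param net A `polychron_net`.
#' @param patterns List of patterns.
#' @param mode `"programming"` or `"adaptation"`.
#' @param config [adaptation_config()] used in adaptation mode.
#' @return A list with `net` and an aggregate `report`.
#' @export
train_patterns <- function(net, patterns, mode = c("programming", "adaptation"),
                           config = adaptation_config()) {
  mode <- match.arg(mode)
  if (inherits(patterns, "polychron_pattern")) patterns <- list(patterns)
  if (mode == "adaptation") return(train_adaptation(net, patterns, config))
  consumed <- 0L; fully <- 0L; partially <- 0L; clamped <- 0L
  for (pat in patterns) {
    r <- program_pattern(net, pat)
    net <- r$net
    consumed <- consumed + r$report$modules_consumed
    fully <- fully + r$report$patterns_fully_stored
    partially <- partially + r$report$patterns_partially_stored
    clamped <- clamped + r$report$clamped_paths
  }
  list(net = net,
       report = new_training_report(consumed, fully, partially,
                                    clamped_paths = clamped))
}
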
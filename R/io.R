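# Plain-text readers/writers: spike-event files, pattern files, network
# snapshots and run manifests.  Round-trip fidelity is the contract.

#' Write / read a spike-event file
#'
#' Delimited text, one event per line, columns `tick,address[,line]`, with a
#' header line and 0-based addresses.  Events must be sorted by tick.
#'
#' @param events Data.frame with integer columns `tick`, `address` and
#'   optionally `line` (0-3, pre-synaptic events only).
#' @param path File path.
#' @return `write_events` returns `path` invisibly; `read_events` returns
#'   the events data.frame.
#' @export
write_events <- function(events, path) {
  if (nrow(events) > 0 && is.unsorted(events$tick))
    validation_error("events must be sorted by tick")
  cols <- c("tick", "address", if ("line" %in% names(events)) "line")
  write.csv(events[, cols, drop = FALSE], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @param n_neurons Optional address bound; loading an event with
#'   `address >= n_neurons` is an error.
#' @rdname write_events
#' @export
read_events <- function(path, n_neurons = NULL) {
  lines <- readLines(path)
  if (length(lines) == 0) validation_error("empty event file")
  header <- strsplit(lines[1], ",", fixed = TRUE)[[1]]
  if (!identical(header[1:2], c("tick", "address")))
    validation_error("event file must start with a tick,address header")
  has_line <- length(header) >= 3 && header[3] == "line"
  n <- length(lines) - 1L
  tick <- integer(n); address <- integer(n)
  line_col <- if (has_line) integer(n)
  for (i in seq_len(n)) {
    f <- strsplit(lines[i + 1L], ",", fixed = TRUE)[[1]]
    v <- suppressWarnings(as.integer(f))
    if (length(v) < 2 || length(v) > 3 || any(is.na(v[1:2])))
      validation_error(sprintf("malformed event on line %d", i + 1L))
    tick[i] <- v[1]; address[i] <- v[2]
    if (has_line) line_col[i] <- if (length(v) >= 3) v[3] else NA_integer_
  }
  if (n > 1 && is.unsorted(tick))
    validation_error("event file is not sorted by tick")
  if (!is.null(n_neurons) && any(address < 0 | address >= n_neurons))
    validation_error("event address out of range for this network")
  ev <- data.frame(tick = tick, address = address)
  if (has_line) ev$line <- line_col
  ev
}

#' Write / read a pattern file
#'
#' The spike-event format plus `#`-prefixed metadata lines recording the
#' generator seeds and settings, so a pattern file regenerates bit-identically.
#'
#' @param pattern A `polychron_pattern`.
#' @param path File path.
#' @export
write_pattern <- function(pattern, path) {
  meta <- sprintf("# %s=%d",
                  c("seed_neuron", "seed_interval", "n_neurons", "n_intervals",
                    "interval_lo", "interval_hi"),
                  c(attr(pattern, "seed_neuron"), attr(pattern, "seed_interval"),
                    attr(pattern, "n_neurons"), attr(pattern, "n_intervals"),
                    attr(pattern, "interval_range")))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(meta, con)
  writeLines("tick,address", con)
  writeLines(sprintf("%d,%d", pattern$tick, pattern$address), con)
  invisible(path)
}

#' @rdname write_pattern
#' @export
read_pattern <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^# ", lines, value = TRUE)
  kv <- do.call(rbind, strsplit(sub("^# ", "", meta_lines), "=", fixed = TRUE))
  meta <- as.integer(kv[, 2])
  names(meta) <- kv[, 1]
  body <- lines[!startsWith(lines, "# ")]
  tmp <- tempfile(fileext = ".csv")
  writeLines(body, tmp)
  ev <- read_events(tmp)
  unlink(tmp)
  structure(ev,
            seed_neuron = meta[["seed_neuron"]],
            seed_interval = meta[["seed_interval"]],
            n_neurons = meta[["n_neurons"]],
            n_intervals = meta[["n_intervals"]],
            interval_range = c(meta[["interval_lo"]], meta[["interval_hi"]]),
            class = c("polychron_pattern", "data.frame"))
}

snapshot_version <- "polychron-snapshot v1"

#' Save / load a trained network snapshot
#'
#' Structured text: the parameter set, the programming index, and one record
#' per configured axon module (input address, four output addresses, four
#' programmed delays; unset fields as `.`).  The snapshot captures the
#' learned structure exactly, so a reloaded network reproduces identical
#' recall behavior on any cue.  Dynamic state (ramps, timers) is not saved;
#' networks load idle.
#'
#' @param net A `polychron_net`.
#' @param path File path.
#' @export
save_snapshot <- function(net, path) {
  p <- net$params
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(snapshot_version, con)
  for (f in c("n_neurons", "n_axon_arrays", "modules_per_array", "tick_us",
              "fanout", "coincidence_threshold", "coincidence_window_ticks",
              "refractory_ticks", "delay_max_ticks"))
    writeLines(sprintf("%s %d", f, p[[f]]), con)
  writeLines(sprintf("programming_index %d", net$programming_index), con)
  conf <- which(!is.na(net$mod_input))
  fmt <- function(x) ifelse(is.na(x), ".", as.character(x))
  if (length(conf)) {
    writeLines(sprintf("module %d %s %s %s", conf - 1L,
                       fmt(net$mod_input[conf]),
                       apply(net$mod_out[conf, , drop = FALSE], 1,
                             function(r) paste(fmt(r), collapse = " ")),
                       apply(net$mod_delay[conf, , drop = FALSE], 1,
                             function(r) paste(fmt(r), collapse = " "))), con)
  }
  invisible(path)
}

#' @rdname save_snapshot
#' @export
load_snapshot <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0 || lines[1] != snapshot_version)
    validation_error("not a polychron snapshot (version mismatch)")
  kv <- lines[!startsWith(lines, "module ") & seq_along(lines) > 1]
  fields <- strsplit(kv, " ", fixed = TRUE)
  vals <- stats::setNames(
    as.integer(vapply(fields, `[`, "", 2)),
    vapply(fields, `[`, "", 1))
  needed <- c("n_neurons", "n_axon_arrays", "modules_per_array", "tick_us",
              "coincidence_threshold", "coincidence_window_ticks",
              "refractory_ticks", "delay_max_ticks", "programming_index")
  if (!all(needed %in% names(vals)))
    validation_error("truncated snapshot: missing header fields")
  params <- sim_params(
    n_neurons = vals[["n_neurons"]], n_axon_arrays = vals[["n_axon_arrays"]],
    modules_per_array = vals[["modules_per_array"]], tick_us = vals[["tick_us"]],
    coincidence_threshold = vals[["coincidence_threshold"]],
    coincidence_window_ticks = vals[["coincidence_window_ticks"]],
    refractory_ticks = vals[["refractory_ticks"]],
    delay_max_ticks = vals[["delay_max_ticks"]])
  net <- create_network(params)
  mod_lines <- lines[startsWith(lines, "module ")]
  if (length(mod_lines)) {
    f <- strsplit(mod_lines, " ", fixed = TRUE)
    bad <- which(vapply(f, length, 1L) != 11L)
    if (length(bad))
      validation_error(sprintf("malformed module record: %s", mod_lines[bad[1]]))
    m <- do.call(rbind, lapply(f, function(x) {
      x <- x[-1]
      suppressWarnings(ifelse(x == ".", NA_integer_, as.integer(x)))
    }))
    idx <- m[, 1] + 1L
    if (any(is.na(idx)) || any(idx < 1 | idx > n_modules(net)))
      validation_error("module index out of range in snapshot")
    if (any(m[, 2] < 0 | m[, 2] >= params$n_neurons, na.rm = TRUE) ||
        any(m[, 3:6] < 0 | m[, 3:6] >= params$n_neurons, na.rm = TRUE))
      validation_error("module address out of range in snapshot")
    if (any(m[, 7:10] < 0 | m[, 7:10] > params$delay_max_ticks, na.rm = TRUE))
      validation_error("programmed delay out of range in snapshot")
    net$mod_input[idx] <- m[, 2]
    net$mod_out[idx, ] <- m[, 3:6]
    net$mod_delay[idx, ] <- m[, 7:10]
  }
  net$programming_index <- vals[["programming_index"]]
  net
}

#' Write a run manifest
#'
#' Records the resolved configuration, the seeds and checksums of the output
#' files of an experiment run, sufficient to re-execute it bit-identically.
#'
#' @param path Manifest path (JSON).
#' @param config Named list of resolved configuration values.
#' @param seeds Integer vector of run seeds.
#' @param files Character vector of output file paths to checksum.
#' @export
write_manifest <- function(path, config, seeds, files = character(0)) {
  manifest <- list(
    artifact = "polychron",
    version = as.character(utils::packageVersion("polychron")),
    config = config,
    seeds = as.integer(seeds),
    files = if (length(files))
      data.frame(path = files, md5 = unname(tools::md5sum(files)))
    else NULL)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) jsonlite::read_json(path, simplifyVector = TRUE)
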
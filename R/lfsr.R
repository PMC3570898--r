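# Maximal-length feedback polynomials (1-based tap positions) per register
# width.  Any maximal-length choice reproduces the pattern statistics; these
# are the standard published sets.
lfsr_tap_table <- list(
  `3` = c(3L, 2L), `4` = c(4L, 3L), `5` = c(5L, 3L), `6` = c(6L, 5L),
  `7` = c(7L, 6L), `8` = c(8L, 6L, 5L, 4L), `9` = c(9L, 5L),
  `10` = c(10L, 7L), `11` = c(11L, 9L), `12` = c(12L, 11L, 10L, 4L),
  `13` = c(13L, 12L, 11L, 8L), `14` = c(14L, 13L, 12L, 2L),
  `15` = c(15L, 14L), `16` = c(16L, 15L, 13L, 4L))

#' Create a linear feedback shift register
#'
#' A Fibonacci LFSR with a maximal-length feedback polynomial: starting from
#' any nonzero state it cycles through all `2^width - 1` nonzero register
#' values before repeating.  Two such registers drive the pattern generator
#' (one for neuron addresses, one for inter-spike intervals).
#'
#' @param width Register width in bits (3 to 16 with the built-in tap table).
#' @param seed Any positive integer; it is reduced to a nonzero state.
#' @param taps Optional 1-based tap positions overriding the built-in
#'   maximal-length set for this width.
#' @return An object of class `polychron_lfsr` with fields `width`, `taps`,
#'   `state`.
#' @examples
#' l <- lfsr_new(7, seed = 1)
#' lfsr_next(l)$value
#' @export
lfsr_new <- function(width, seed = 1, taps = NULL) {
  if (!(is_count(width) && width >= 3 && width <= 16))
    validation_error("width must be in 3..16")
  if (is.null(taps)) taps <- lfsr_tap_table[[as.character(width)]]
  if (!(is_count(seed)))
    validation_error("seed must be a positive integer (zero state is invalid)")
  state <- as.integer((seed - 1) %% (2^width - 1) + 1)
  structure(list(width = as.integer(width), taps = as.integer(taps),
                 state = state), class = "polychron_lfsr")
}

#' Advance an LFSR one step
#'
#' @param l A [lfsr_new()] register.
#' @return A list with `lfsr` (advanced register) and `value` (the new
#'   register value, in `1 .. 2^width - 1`).
#' @export
lfsr_next <- function(l) {
  fb <- 0L
  for (t in l$taps) fb <- bitwXor(fb, bitwAnd(bitwShiftR(l$state, t - 1L), 1L))
  l$state <- bitwOr(bitwAnd(bitwShiftL(l$state, 1L), bitwShiftL(1L, l$width) - 1L), fb)
  list(lfsr = l, value = l$state)
}

#' Draw a sequence of LFSR values
#'
#' Draws `n` register values, advancing the register `stride` shifts per
#' value.  `stride = 1` is equivalent to calling [lfsr_next()] `n` times;
#' `stride = l$width` clocks a full register turnover between draws (the
#' usual serial word output), which decorrelates successive values -- with
#' stride 1 each value is just a one-bit shift of its predecessor.
#'
#' @inheritParams lfsr_next
#' @param n Number of values.
#' @param stride Register shifts per value (default 1).
#' @return Integer vector of the `n` drawn register values.
#' @export
lfsr_sequence <- function(l, n, stride = 1) {
  cpp_lfsr_sequence(l$width, l$taps, l$state, as.integer(n), as.integer(stride))
}
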
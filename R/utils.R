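#' Round half away from zero
#'
#' Commercial ("half-up") rounding, used for all printed percentages so that
#' e.g. 27.305 reports as 27.31 rather than banker's-rounded 27.30.
#'
#' @param x numeric vector
#' @param digits integer number of decimal places
#' @return numeric vector rounded half-up to `digits`
#' @export
round_half_up <- function(x, digits = 2) {
  m <- 10^digits
  # the sqrt(eps) nudge keeps decimal halves (e.g. 2.675) rounding upward
  # despite their inexact binary representation
  sign(x) * floor(abs(x) * m + 0.5 + sqrt(.Machine$double.eps)) / m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_if <- function(cond, msg) if (isTRUE(cond)) stop(msg, call. = FALSE)

# deterministic child seed, kept well below 2^31
child_seed <- function(seed, offset) {
  (as.integer(seed) %% 1000000L) * 1000L + as.integer(offset)
}
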
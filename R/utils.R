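# Shared numeric helpers.

#' Round half away from zero
#'
#' Commercial rounding used for VCF POS/SVLEN refinement, so that e.g. a mean
#' length of 100.5 becomes 101 rather than base R's round-half-even 100.
#'
#' @param x numeric vector.
#' @return integer-valued numeric vector.
#' @keywords internal
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

#' Population standard deviation
#'
#' Divides by n (not n - 1); a single observation has SD 0. This is the
#' convention used for the length-difference test between haplotypes and for
#' the consistent score, keeping both well-defined on minimal clusters.
#'
#' @param x numeric vector, length >= 1.
#' @return non-negative scalar.
#' @keywords internal
pop_sd <- function(x) {
  n <- length(x)
  if (n == 0L) return(NA_real_)
  sqrt(sum((x - mean(x))^2) / n)
}

# scalar numeric check used by parameter validators
.is_num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

.stop_param <- function(key, msg) {
  stop(sprintf("invalid parameter '%s': %s", key, msg), call. = FALSE)
}
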
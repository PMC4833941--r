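# Shared small helpers.

#' Round half away from zero
#'
#' Rounds to the nearest integer with ties going away from zero, the
#' convention used for percent displays in trial reports (so 12.5 -> 13 and
#' -1.5 -> -2, unlike [base::round()]'s banker's rounding).
#'
#' @param x numeric vector.
#' @return integer-valued numeric vector.
#' @export
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

#' Prevalence in percent
#'
#' @param numerator count of respondents with the indicator true.
#' @param denominator count of respondents eligible and non-missing
#'   (true + false).
#' @return prevalence on the 0--100 scale; `NaN` when the denominator is 0.
#' @export
prevalence_pct <- function(numerator, denominator) {
  100 * numerator / denominator
}

# Weighted mean of x with weights w plus a t-based CI treating the weighted
# residual variance as homoscedastic (WLS intercept-only fit).
weighted_mean_ci <- function(x, w, level = 0.95) {
  stopifnot(length(x) == length(w), all(w > 0))
  n <- length(x)
  m <- sum(w * x) / sum(w)
  if (n < 2) {
    return(list(mean = m, se = NA_real_, lower = NA_real_, upper = NA_real_,
                df = NA_integer_))
  }
  s2 <- sum(w * (x - m)^2) / (n - 1)
  se <- sqrt(s2 / sum(w))
  tq <- stats::qt(1 - (1 - level) / 2, df = n - 1)
  list(mean = m, se = se, lower = m - tq * se, upper = m + tq * se,
       df = n - 1L)
}

# Deterministic 32-bit sub-seed from a tuple, so each (wave, community, EA)
# owns its own pseudo-random substream.
sub_seed <- function(seed, wave_idx, comm_idx = 0, ea_idx = 0) {
  v <- (as.numeric(seed) * 48271 +
          wave_idx * 16807 +
          comm_idx * 69621 +
          ea_idx * 630360016) %% 2147483629
  as.integer(v)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
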
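#' Derive a reproducible sub-seed from a master seed and a counter
#'
#' All stochastic generators in the package draw their randomness from one
#' integer master seed. Independent streams (one per curve, image or
#' correlogram) are obtained by mixing the master seed with a stream counter
#' through a multiplicative congruential scramble, so that batch element `i`
#' is reproducible on its own and batches are bit-identical across reruns.
#'
#' @param seed integer master seed (< 2^31).
#' @param counter non-negative integer stream index.
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @export
sub_seed <- function(seed, counter = 0L) {
  m <- 2147483647 # 2^31 - 1, Mersenne prime
  s <- as.double(seed) %% m
  s <- (s * 69069 + 1) %% m
  s <- (s + as.double(counter) * 9973) %% m
  s <- (s * 69069 + 1) %% m
  as.integer(s %% (m - 2) + 1)
}

# normal draw truncated below at `lower` (rejection; draws are scalar or short)
rnorm_trunc <- function(n, mean, sd, lower = 0) {
  if (sd <= 0) return(rep(pmax(mean, lower), n))
  out <- rnorm(n, mean, sd)
  bad <- which(out <= lower)
  guard <- 0L
  while (length(bad) > 0 && guard < 1000L) {
    out[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] <= lower]
    guard <- guard + 1L
  }
  out[out <= lower] <- lower + abs(out[out <= lower] - lower) + 1e-9
  out
}

is_odd <- function(x) x %% 2 == 1

stopifnot_scalar_num <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x)) {
    abort(sprintf("`%s` must be a finite numeric scalar", name))
  }
  if (positive && x <= 0) abort(sprintf("`%s` must be > 0", name))
  invisible(x)
}
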
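# Analytic detection power for a resistance allele in a resequencing
# sample: a sample of N diploids carries 2N alleles drawn binomially, so
# the probability of seeing no copy of an allele at frequency p is
# (1 - p)^(2N). Assumes independent alleles (no inbreeding, no pooling).

#' Probability of missing an allele in a resequencing sample
#'
#' `(1 - p)^(2N)`, the chance that none of the 2N sampled alleles is the
#' resistance allele. Evaluated in log space (`exp(2N log1p(-p))`) so small
#' p and large N do not underflow.
#'
#' @param p allele frequency in `[0, 1]` (vectorized).
#' @param N number of diploid individuals (>= 0, vectorized).
#' @return miss probability in `[0, 1]`.
#' @examples
#' missProbability(0.01, 99)   # ~0.1367: a p = 0.01 allele is missed in
#'                             # 99 diploids about 13.67% of the time
#' @export
missProbability <- function(p, N) {
  if (any(p < 0 | p > 1)) stop("allele frequency must be in [0, 1]")
  if (any(N < 0)) stop("N must be non-negative")
  out <- exp(2 * N * log1p(-p))
  out[N == 0] <- 1
  out[p == 0] <- 1
  out
}

#' Smallest sample size detecting an allele with given confidence
#'
#' The smallest N with `(1 - p)^(2N) <= alpha`, i.e.
#' `ceil(log(alpha) / (2 log(1 - p)))`.
#'
#' @param p allele frequency in (0, 1).
#' @param alpha acceptable miss probability in (0, 1).
#' @return integer N.
#' @export
minSampleSize <- function(p, alpha) {
  if (p <= 0 || p >= 1) stop("p must be in (0, 1) for a finite sample size")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  N <- as.integer(ceiling(log(alpha) / (2 * log1p(-p))))
  # guard the boundary against floating error in the closed form
  while (missProbability(p, N) > alpha) N <- N + 1L
  while (N > 1L && missProbability(p, N - 1L) <= alpha) N <- N - 1L
  N
}

#' Detection power curve over a frequency grid
#'
#' @param freqs allele frequencies.
#' @param N number of diploids.
#' @return data.frame(freq, N, miss_probability, detection_probability).
#' @export
powerCurve <- function(freqs, N) {
  miss <- missProbability(freqs, N)
  data.frame(freq = freqs, N = N, miss_probability = miss,
             detection_probability = 1 - miss)
}
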
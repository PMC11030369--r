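#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: p-values are ranked, scaled by n/rank, and a
#' cumulative minimum from the largest rank downward enforces monotonicity.
#' `NA` entries are excluded from the ranking (they do not count toward n)
#' and are returned as `NA`.
#'
#' @param p numeric vector of p-values in \[0, 1\] (NA allowed).
#' @return numeric vector of adjusted values, same length and order as `p`.
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03, 0.04)) # all 0.04
#' @export
bh_fdr <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  stopifnot(is.numeric(p))
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must lie in [0, 1]")
  q <- rep(NA_real_, length(p))
  pv <- p[ok]
  n <- length(pv)
  if (n > 0L) {
    o <- order(pv, decreasing = TRUE)
    ro <- order(o)
    q[ok] <- pmin(1, cummin(n / seq(n, 1L) * pv[o]))[ro]
  }
  q
}

#' One-sided hypergeometric upper-tail probability
#'
#' P(X >= k) for X ~ Hypergeometric(N, K, n): the probability of drawing at
#' least `k` "category" members in a signature of size `n` sampled without
#' replacement from a universe of `N` identifiers of which `K` belong to the
#' category. This is the one-sided Fisher over-representation p-value.
#'
#' @param k observed overlap.
#' @param K category size within the universe.
#' @param n signature size.
#' @param N universe size.
#' @keywords internal
hyper_upper_tail <- function(k, K, n, N) {
  stopifnot(k >= 0, K >= 0, n >= 0, N >= 0)
  if (k > min(n, K)) stop("overlap k cannot exceed min(signature, category) size")
  if (N < n + K - k) stop("inconsistent counts: N < n + K - k")
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Symmetric trimmed mean
#'
#' Mean after removing `floor(trim * n)` observations from each tail. With
#' `trim = 0.1` this is the "10% trimmed mean" in the usual per-tail
#' convention; `total = TRUE` instead trims `floor(trim/2 * n)` per tail so
#' that 10% of observations are removed in total.
#'
#' @param x numeric vector (NAs dropped).
#' @param trim proportion trimmed.
#' @param total trim `trim` overall rather than per tail.
#' @export
trimmed_mean <- function(x, trim = 0.1, total = FALSE) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n == 0L) return(NaN)
  g <- floor(if (total) trim / 2 * n else trim * n)
  if (2L * g >= n) stop("trim removes all observations")
  x <- sort(x)
  mean(x[(g + 1L):(n - g)])
}

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Stable small-integer sub-seed: keeps derived seeds well below 2^31.
sub_seed <- function(seed, offset) {
  (as.integer(seed) %% 1000000L) * 1000L + as.integer(offset)
}
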
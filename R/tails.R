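#' Hypergeometric upper-tail probability
#'
#' Probability of observing at least `k` shared elements between a set of
#' size `size_a` and an independent draw of size `size_b` from a population
#' of `n_pop` elements, i.e. `P(X >= k)` for `X ~ Hypergeometric(n_pop,
#' size_a, size_b)`. This is the p-value behind the hypergeometric overlap
#' index used throughout the package. Computed in log space via
#' [stats::phyper()] so that tails far below the double minimum do not
#' underflow before the index is taken.
#'
#' @param k Integer vector, observed shared-element count.
#' @param size_a,size_b Integer vectors, the two neighbour-set sizes.
#' @param n_pop Integer vector, population size.
#' @return Numeric vector of upper-tail probabilities in (0, 1].
#' @examples
#' hypergeom_tail(3, 4, 5, 10) # 11/42
#' @seealso [hyi_from_p()], [enum_hypergeom_tail()] for the brute-force twin.
#' @export
hypergeom_tail <- function(k, size_a, size_b, n_pop) {
  check_hypergeom_args(k, size_a, size_b, n_pop)
  exp(hypergeom_log_tail(k, size_a, size_b, n_pop))
}

# log P(X >= k); shared by the public tail, the index and the projection
hypergeom_log_tail <- function(k, size_a, size_b, n_pop) {
  phyper(k - 1, size_a, n_pop - size_a, size_b,
         lower.tail = FALSE, log.p = TRUE)
}

check_hypergeom_args <- function(k, size_a, size_b, n_pop) {
  if (any(!is.finite(k)) || any(!is.finite(size_a)) ||
      any(!is.finite(size_b)) || any(!is.finite(n_pop))) {
    abort_argument("k, size_a, size_b and n_pop must be finite integers")
  }
  if (any(size_a < 0) || any(size_a > n_pop)) {
    abort_argument("violated bound: 0 <= size_a <= n_pop")
  }
  if (any(size_b < 0) || any(size_b > n_pop)) {
    abort_argument("violated bound: 0 <= size_b <= n_pop")
  }
  if (any(k < 0) || any(k > pmin(size_a, size_b))) {
    abort_argument("violated bound: 0 <= k <= min(size_a, size_b)")
  }
  invisible(TRUE)
}

#' Binomial upper-tail probability
#'
#' `P(Bin(n, q) >= x)`, used to test whether a FunFam is overrepresented
#' among a drug's targets given its background proportion `q`.
#'
#' @param x Integer vector, observed successes.
#' @param n Integer vector, number of trials.
#' @param q Numeric vector, success probability in \[0, 1\].
#' @return Numeric vector of upper-tail probabilities in (0, 1].
#' @examples
#' binom_tail(3, 5, 0.2) # 0.05792
#' @export
binom_tail <- function(x, n, q) {
  if (any(!is.finite(x)) || any(!is.finite(n)) || any(!is.finite(q))) {
    abort_argument("x, n and q must be finite")
  }
  if (any(x < 0) || any(x > n)) {
    abort_argument("violated bound: 0 <= x <= n")
  }
  if (any(q < 0) || any(q > 1)) {
    abort_argument("violated bound: 0 <= q <= 1")
  }
  pbinom(x - 1, n, q, lower.tail = FALSE)
}

#' Convert between p-values and the hypergeometric index
#'
#' The hypergeometric index (HyI) is `-log10(p)`: an index of 2 corresponds
#' to p = 0.01 and 3.5 to p ~= 0.0003. `hyi_from_p()` maps a p-value to the
#' index; `p_from_hyi()` inverts it.
#'
#' @param p Numeric vector of probabilities in (0, 1].
#' @param hyi Numeric vector of non-negative index values.
#' @return Numeric vector.
#' @examples
#' hyi_from_p(0.01) # 2
#' p_from_hyi(3.5) # 0.000316...
#' @export
hyi_from_p <- function(p) {
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1)) {
    abort_argument("p must lie in (0, 1]")
  }
  -log10(p)
}

#' @rdname hyi_from_p
#' @export
p_from_hyi <- function(hyi) {
  if (any(!is.finite(hyi)) || any(hyi < 0)) {
    abort_argument("hyi must be non-negative and finite")
  }
  10^(-hyi)
}

# index from a log-scale p-value, capped so reports never carry infinities
HYI_CAP <- 300

hyi_from_log_p <- function(log_p) {
  hyi <- -log_p / log(10)
  if (any(hyi > HYI_CAP)) {
    warn(sprintf("%d overlap score(s) exceeded hyi = %d and were capped",
                 sum(hyi > HYI_CAP), HYI_CAP))
    hyi <- pmin(hyi, HYI_CAP)
  }
  hyi
}
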
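#' Brute-force hypergeometric tail by subset enumeration
#'
#' Independent twin of [hypergeom_tail()] for testing: enumerates every
#' possible draw of `size_b` elements from a population of `n_pop` (the
#' first `size_a` of which are marked) and counts the draws sharing at
#' least `k` marked elements. Both counts are exact integers well inside
#' double precision for the allowed population sizes, so the returned
#' ratio is exact.
#'
#' @param k,size_a,size_b,n_pop As in [hypergeom_tail()]; `n_pop` must be
#'   at most 14.
#' @return The exact tail probability.
#' @examples
#' enum_hypergeom_tail(3, 4, 5, 10) # exactly 11/42
#' @export
enum_hypergeom_tail <- function(k, size_a, size_b, n_pop) {
  if (length(k) != 1 || length(size_a) != 1 || length(size_b) != 1 ||
      length(n_pop) != 1) {
    abort_argument("enum_hypergeom_tail is scalar-only")
  }
  if (n_pop > 14) abort_argument("n_pop must be <= 14 for enumeration")
  check_hypergeom_args(k, size_a, size_b, n_pop)
  if (k == 0) return(1)
  if (size_b == 0) return(0) # k >= 1 impossible with an empty draw
  draws <- combn(n_pop, size_b)
  overlaps <- colSums(draws <= size_a)
  sum(overlaps >= k) / ncol(draws)
}
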
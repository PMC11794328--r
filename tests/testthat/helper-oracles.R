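# Independent brute-force oracles used against the analytic tails.

# Binomial upper tail by explicit enumeration of all 2^n outcome vectors,
# weighted by q^successes * (1-q)^failures.
enum_binom_tail <- function(x, n, q) {
  if (n > 14) stop("enumeration limited to n <= 14")
  if (n == 0) return(as.numeric(0 >= x))
  outcomes <- 0:(2^n - 1)
  popcount <- vapply(outcomes, function(o) {
    sum(as.integer(intToBits(o))[seq_len(n)])
  }, numeric(1))
  weights <- q^popcount * (1 - q)^(n - popcount)
  sum(weights[popcount >= x])
}

# All simple bipartite configurations with the same row/column degree
# sequences as `pairs`, enumerated as 0/1 matrices; returns the exact mean
# overlap with `gold` under the uniform distribution over configurations.
enum_config_mean_overlap <- function(pairs, gold) {
  hp <- sort(unique(pairs$hpo_id))
  dr <- sort(unique(pairs$drug_id))
  row_deg <- vapply(hp, function(h) sum(pairs$hpo_id == h), numeric(1))
  col_deg <- vapply(dr, function(d) sum(pairs$drug_id == d), numeric(1))
  gold_m <- matrix(FALSE, length(hp), length(dr), dimnames = list(hp, dr))
  hit <- gold$hpo_id %in% hp & gold$drug_id %in% dr
  gold_m[cbind(match(gold$hpo_id[hit], hp), match(gold$drug_id[hit], dr))] <- TRUE

  n_col <- length(dr)
  total <- 0
  overlap_sum <- 0
  recurse <- function(i, remaining, overlap) {
    if (i > length(hp)) {
      if (all(remaining == 0)) {
        total <<- total + 1
        overlap_sum <<- overlap_sum + overlap
      }
      return(invisible())
    }
    cols_avail <- which(remaining > 0)
    if (length(cols_avail) < row_deg[i]) return(invisible())
    for (pick in combn(cols_avail, row_deg[i], simplify = FALSE)) {
      rem <- remaining
      rem[pick] <- rem[pick] - 1
      recurse(i + 1, rem, overlap + sum(gold_m[i, pick]))
    }
  }
  recurse(1, col_deg, 0)
  list(mean = overlap_sum / total, n_configs = total)
}

degree_multiset <- function(pairs, col) sort(table(pairs[[col]]))
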
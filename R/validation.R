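# Normalize a predicted/gold pair table to (hpo_id, drug_id)
as_pair_set <- function(x) {
  if (is_hyi_pairs(x)) {
    return(distinct(tibble(hpo_id = x$a_id, drug_id = x$b_id)))
  }
  if (!is.data.frame(x) || !all(c("hpo_id", "drug_id") %in% names(x))) {
    abort_argument("expected an hyi_pairs object or a data frame with hpo_id, drug_id")
  }
  distinct(tibble(hpo_id = as.character(x$hpo_id),
                  drug_id = as.character(x$drug_id)))
}

#' Restrict predictions to the gold-standard entity universe
#'
#' Keeps predicted pairs whose drug appears in at least one gold pair and
#' whose phenotype appears in at least one gold pair; membership is checked
#' per entity, not jointly. Mirrors restricting ChEMBL-wide predictions to
#' drugs and effects covered by a marketed-drug gold standard.
#'
#' @param predicted `hyi_pairs` (phenotype as `a_id`, drug as `b_id`).
#' @param gold Data frame of gold pairs with columns `hpo_id`, `drug_id`.
#' @return The filtered `hyi_pairs`.
#' @export
restrict_to_gold <- function(predicted, gold) {
  if (!is_hyi_pairs(predicted)) {
    abort_argument("`predicted` must be an hyi_pairs object")
  }
  gold <- as_pair_set(gold)
  if (nrow(gold) == 0) abort_contract("gold standard is empty")
  keep <- predicted$a_id %in% gold$hpo_id & predicted$b_id %in% gold$drug_id
  new_hyi_pairs(predicted[keep, , drop = FALSE],
                a_role = attr(predicted, "a_role"),
                b_role = attr(predicted, "b_role"),
                threshold_applied = attr(predicted, "threshold_applied"))
}

#' Degree-preserving randomization of a phenotype-drug pair list
#'
#' Rewires the connections of a pair list while keeping every phenotype's
#' and every drug's pair count unchanged, by attempted double-edge swaps:
#' two pairs (h1,d1), (h2,d2) become (h1,d2), (h2,d1) unless that would
#' duplicate an existing pair. Each attempted swap is additionally accepted
#' with probability 1/2 (a lazy chain), which keeps the sampler aperiodic
#' on small, tightly constrained pair sets. Deterministic given `seed`.
#'
#' @param pairs Data frame of pairs (`hpo_id`, `drug_id`) or `hyi_pairs`.
#' @param seed Integer seed.
#' @param n_swaps Number of attempted swaps; defaults to `10 * nrow(pairs)`.
#' @param warn_rigid Warn when no swap succeeds (the degree sequence may
#'   admit only the input configuration).
#' @return A tibble (`hpo_id`, `drug_id`) with the same degree sequences.
#' @export
randomize_links <- function(pairs, seed, n_swaps = NULL, warn_rigid = TRUE) {
  ps <- as_pair_set(pairs)
  m <- nrow(ps)
  if (m == 0) abort_contract("cannot randomize an empty pair set")
  if (is.null(n_swaps)) n_swaps <- 10L * m
  a <- ps$hpo_id
  b <- ps$drug_id
  if (m == 1 || n_swaps == 0) {
    return(tibble(hpo_id = a, drug_id = b))
  }
  withr::with_seed(seed, {
    keys <- new.env(hash = TRUE, parent = emptyenv())
    for (i in seq_len(m)) assign(paste0(a[i], "\t", b[i]), TRUE, envir = keys)
    successes <- 0L
    for (t in seq_len(n_swaps)) {
      ij <- sample.int(m, 2L)
      lazy <- runif(1) < 0.5
      if (lazy) next
      i <- ij[1L]; j <- ij[2L]
      if (b[i] == b[j]) next
      new1 <- paste0(a[i], "\t", b[j])
      new2 <- paste0(a[j], "\t", b[i])
      if (exists(new1, envir = keys, inherits = FALSE) ||
          exists(new2, envir = keys, inherits = FALSE)) next
      rm(list = c(paste0(a[i], "\t", b[i]), paste0(a[j], "\t", b[j])),
         envir = keys)
      assign(new1, TRUE, envir = keys)
      assign(new2, TRUE, envir = keys)
      tmp <- b[i]; b[i] <- b[j]; b[j] <- tmp
      successes <- successes + 1L
    }
  })
  if (warn_rigid && successes == 0L) {
    warn("no swap succeeded; the degree sequence may admit only the input configuration")
  }
  tibble(hpo_id = a, drug_id = b)
}

count_overlap <- function(pairs, gold) {
  nrow(semi_join(as_pair_set(pairs), gold, by = c("hpo_id", "drug_id")))
}

#' Confirmed pairs versus a degree-preserving random null
#'
#' Counts the predicted pairs found in the gold standard ("confirmed"),
#' rebuilds the null distribution of that count by randomizing the
#' predicted list `n_replicates` times with [randomize_links()] (replicate
#' r uses `seed + r`), and reports the real/random ratio. A ratio above 1
#' means the predictions hit the gold standard more often than degree-
#' matched chance.
#'
#' @param predicted `hyi_pairs`, normally already passed through
#'   [restrict_to_gold()].
#' @param gold Gold-standard pair table (`hpo_id`, `drug_id`).
#' @param n_replicates Number of randomized replicates.
#' @param seed Integer base seed.
#' @param n_swaps Swap budget per replicate (see [randomize_links()]).
#' @return A one-row `validation_report` tibble: `threshold`, `confirmed`,
#'   `random_mean`, `random_sd`, `ratio`, `n_replicates`, `seed`. `ratio`
#'   is `Inf` when the random mean is zero.
#' @export
overlap_ratio <- function(predicted, gold, n_replicates = 100, seed,
                          n_swaps = NULL) {
  gold <- as_pair_set(gold)
  if (nrow(gold) == 0) abort_contract("gold standard is empty")
  pred <- as_pair_set(predicted)
  confirmed <- count_overlap(pred, gold)
  overlaps <- vapply(seq_len(n_replicates), function(r) {
    rand <- randomize_links(pred, seed = seed + r, n_swaps = n_swaps,
                            warn_rigid = FALSE)
    count_overlap(rand, gold)
  }, numeric(1))
  random_mean <- mean(overlaps)
  random_sd <- if (n_replicates > 1) sd(overlaps) else 0
  ratio <- if (random_mean > 0) confirmed / random_mean else Inf
  new_validation_report(tibble(
    threshold = attr(predicted, "threshold_applied") %||% NA_real_,
    confirmed = confirmed,
    random_mean = random_mean,
    random_sd = random_sd,
    ratio = ratio,
    n_replicates = as.integer(n_replicates),
    seed = as.integer(seed)
  ))
}

new_validation_report <- function(df) {
  structure(as_tibble(df),
            class = c("validation_report", class(tibble())))
}

#' Literature co-occurrence significance
#'
#' Upper-tail probability that a drug and an HPO term co-appear in at least
#' `n_both` articles given their marginal mention counts and the corpus
#' size: the hypergeometric tail with population `n_total`, successes
#' `n_hpo` and draws `n_drug` (one-sided Fisher). `cooccurrence_significance()`
#' applies it row-wise to a co-mention table and flags pairs with
#' `p < alpha`.
#'
#' @param n_both,n_drug,n_hpo,n_total Integer vectors of article counts:
#'   mentioning both terms, the drug, the HPO term, and the whole corpus.
#' @return `cooccurrence_pvalue()`: numeric vector of probabilities.
#' @examples
#' cooccurrence_pvalue(2, 3, 3, 10) # 22/120
#' @export
cooccurrence_pvalue <- function(n_both, n_drug, n_hpo, n_total) {
  if (any(n_both > pmin(n_drug, n_hpo)) ||
      any(n_drug > n_total) || any(n_hpo > n_total) || any(n_both < 0)) {
    abort_argument(
      "inconsistent counts: need n_both <= min(n_drug, n_hpo) and n_drug, n_hpo <= n_total")
  }
  hypergeom_tail(n_both, n_hpo, n_drug, n_total)
}

#' @rdname cooccurrence_pvalue
#' @param comentions Data frame with columns `drug_id`, `hpo_id`, `n_drug`,
#'   `n_hpo`, `n_both`, `n_total`.
#' @param alpha Significance threshold (strict).
#' @return `cooccurrence_significance()`: the input tibble with `p_value`
#'   and `significant` columns added.
#' @export
cooccurrence_significance <- function(comentions, alpha = 0.001) {
  required <- c("drug_id", "hpo_id", "n_drug", "n_hpo", "n_both", "n_total")
  missing_cols <- setdiff(required, names(comentions))
  if (length(missing_cols) > 0) {
    abort_format(paste0("missing required column(s): ",
                        paste(missing_cols, collapse = ", ")))
  }
  mutate(as_tibble(comentions),
         p_value = cooccurrence_pvalue(.data$n_both, .data$n_drug,
                                       .data$n_hpo, .data$n_total),
         significant = .data$p_value < alpha)
}

#' Overlap with literature-supported phenotype-drug pairs
#'
#' Builds the set of phenotype-drug pairs significantly co-mentioned in the
#' literature (`p < alpha` under [cooccurrence_pvalue()]) and benchmarks
#' the predicted list against it with the same randomization machinery as
#' [overlap_ratio()].
#'
#' @inheritParams overlap_ratio
#' @param comentions Co-mention count table (see
#'   [cooccurrence_significance()]).
#' @param alpha Co-occurrence significance threshold.
#' @return A one-row `validation_report` tibble.
#' @export
literature_overlap <- function(predicted, comentions, n_replicates = 100,
                               seed, alpha = 0.001, n_swaps = NULL) {
  sig <- cooccurrence_significance(comentions, alpha = alpha)
  sig_pairs <- as_pair_set(sig[sig$significant, , drop = FALSE])
  if (nrow(sig_pairs) == 0) {
    return(new_validation_report(tibble(
      threshold = attr(predicted, "threshold_applied") %||% NA_real_,
      confirmed = 0L, random_mean = 0, random_sd = 0, ratio = NA_real_,
      n_replicates = as.integer(n_replicates), seed = as.integer(seed))))
  }
  overlap_ratio(predicted, sig_pairs, n_replicates = n_replicates,
                seed = seed, n_swaps = n_swaps)
}

#' Validate a threshold sweep against gold standard and literature
#'
#' Runs [restrict_to_gold()] + [overlap_ratio()] (and, when co-mention
#' counts are given, [literature_overlap()]) for every thresholded list of
#' a [associate_drugs()] sweep.
#'
#' @param sweep A `phenodrug_sweep`.
#' @param gold Gold-standard pair table.
#' @param comentions Optional co-mention count table.
#' @param n_replicates,seed,n_swaps Passed to the ratio machinery.
#' @return A `validation_report` tibble, one row per threshold (and per
#'   source when both validations run), with a `source` column.
#' @export
validate_sweep <- function(sweep, gold, comentions = NULL,
                           n_replicates = 100, seed = 1, n_swaps = NULL) {
  if (!inherits(sweep, "phenodrug_sweep")) {
    abort_argument("`sweep` must come from associate_drugs()")
  }
  rows <- purrr::map(sweep$by_threshold, function(pairs) {
    if (nrow(pairs) == 0) {
      return(new_validation_report(tibble(
        threshold = attr(pairs, "threshold_applied"), confirmed = 0L,
        random_mean = 0, random_sd = 0, ratio = NA_real_,
        n_replicates = as.integer(n_replicates), seed = as.integer(seed),
        source = "gold")))
    }
    restricted <- restrict_to_gold(pairs, gold)
    gold_row <- if (nrow(restricted) == 0) {
      new_validation_report(tibble(
        threshold = attr(pairs, "threshold_applied"), confirmed = 0L,
        random_mean = 0, random_sd = 0, ratio = NA_real_,
        n_replicates = as.integer(n_replicates), seed = as.integer(seed)))
    } else {
      overlap_ratio(restricted, gold, n_replicates = n_replicates,
                    seed = seed, n_swaps = n_swaps)
    }
    gold_row$source <- "gold"
    out <- gold_row
    if (!is.null(comentions)) {
      lit_row <- literature_overlap(pairs, comentions,
                                    n_replicates = n_replicates,
                                    seed = seed, n_swaps = n_swaps)
      lit_row$source <- "literature"
      out <- bind_rows(gold_row, lit_row)
    }
    out
  })
  new_validation_report(bind_rows(rows))
}
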
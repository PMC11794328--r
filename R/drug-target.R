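ACTIVITY_COLUMNS <- c("drug_id", "target_id", "therapeutic_flag",
                      "assay_type", "relationship_type", "target_type",
                      "pchembl")

#' Filter a ChEMBL-style activity table to reliable drug-target edges
#'
#' Keeps small molecules with therapeutic application (therapeutic flag 1)
#' showing a direct binding interaction with a single protein (assay type
#' B, relationship type D, target type "Single Protein") at sub-micromolar
#' potency (pChEMBL >= 6, boundary inclusive), and deduplicates to unique
#' (drug, target) edges. The number of records removed by each criterion is
#' reported and attached as the `filter_counts` attribute.
#'
#' @param activities Data frame with the ChEMBL-style columns `drug_id`,
#'   `target_id`, `therapeutic_flag`, `assay_type`, `relationship_type`,
#'   `target_type`, `pchembl`.
#' @param pchembl_min Minimum pChEMBL value (inclusive).
#' @param quiet Suppress the per-criterion messages.
#' @return `bipartite_edges` drug -> target.
#' @export
filter_activities <- function(activities, pchembl_min = 6, quiet = FALSE) {
  if (!is.data.frame(activities)) {
    abort_argument("`activities` must be a data frame")
  }
  missing_cols <- setdiff(ACTIVITY_COLUMNS, names(activities))
  if (length(missing_cols) > 0) {
    abort_format(paste0("missing required column(s): ",
                        paste(missing_cols, collapse = ", ")))
  }
  criteria <- list(
    "therapeutic_flag != 1" = function(d)
      !is.na(d$therapeutic_flag) & d$therapeutic_flag == 1,
    "assay_type != B" = function(d)
      !is.na(d$assay_type) & toupper(d$assay_type) == "B",
    "relationship_type != D" = function(d)
      !is.na(d$relationship_type) & toupper(d$relationship_type) == "D",
    "target_type != Single Protein" = function(d)
      !is.na(d$target_type) & tolower(d$target_type) == "single protein",
    "pchembl missing or below threshold" = function(d)
      !is.na(d$pchembl) & d$pchembl >= pchembl_min
  )
  kept <- activities
  removed <- integer(length(criteria))
  names(removed) <- names(criteria)
  for (nm in names(criteria)) {
    pass <- criteria[[nm]](kept)
    removed[[nm]] <- sum(!pass)
    kept <- kept[pass, , drop = FALSE]
  }
  if (!quiet) {
    for (nm in names(removed)[removed > 0]) {
      inform(sprintf("filter_activities: removed %d record(s) with %s",
                     removed[[nm]], nm))
    }
  }
  edges <- bipartite_edges(kept, outer = "drug_id", middle = "target_id",
                           outer_role = "drug", middle_role = "target",
                           quiet = TRUE)
  attr(edges, "filter_counts") <- removed
  edges
}

#' FunFams overrepresented among a drug's targets
#'
#' For each drug with `n` distinct filtered targets, a FunFam carried by
#' `x >= 1` of them is tested against the binomial null `Bin(n, q)`, where
#' `q` is the proportion of the background target universe (all distinct
#' proteins in `drug_targets`) carrying that FunFam. Pairs with p strictly
#' below `alpha` are emitted as drug-FunFam associations. A protein carrying
#' several domains of one FunFam counts once.
#'
#' @param drug_targets `bipartite_edges` drug -> target (from
#'   [filter_activities()] or equivalent).
#' @param gene_funfam Data frame with columns `gene_id`, `funfam_id`
#'   assigning FunFams to target proteins.
#' @param alpha Significance threshold (strict `p < alpha`).
#' @param p_adjust `"none"` (raw threshold, the default) or `"BH"` for a
#'   Benjamini-Hochberg corrected threshold.
#' @param background Optional named numeric vector overriding `q` per
#'   FunFam ID.
#' @return A `ff_enrichment` tibble: `drug_id`, `funfam_id`, `n`, `x`, `q`,
#'   `p_value`, sorted by ascending p then IDs.
#' @export
drug_funfam_enrichment <- function(drug_targets, gene_funfam, alpha = 0.05,
                                   p_adjust = c("none", "BH"),
                                   background = NULL) {
  p_adjust <- match.arg(p_adjust)
  if (!is_bipartite_edges(drug_targets)) {
    abort_argument("`drug_targets` must be bipartite_edges (drug -> target)")
  }
  if (nrow(drug_targets) == 0) {
    abort_contract("empty background universe: no drug-target edges")
  }
  if (!is.data.frame(gene_funfam)) {
    abort_argument("`gene_funfam` must be a data frame")
  }
  ff <- bipartite_edges(gene_funfam, outer = "gene_id", middle = "funfam_id",
                        outer_role = "gene", middle_role = "funfam",
                        quiet = TRUE)
  validate_ids(ff$middle_id, "funfam_id")

  universe <- unique(drug_targets$middle_id)
  ff_universe <- ff[ff$outer_id %in% universe, , drop = FALSE]
  if (nrow(ff_universe) == 0) {
    abort_contract("the domain map covers none of the filtered targets")
  }
  q_tbl <- summarise(group_by(ff_universe, funfam_id = .data$middle_id),
                     q = n_distinct(.data$outer_id) / length(universe),
                     .groups = "drop")
  if (!is.null(background)) {
    idx <- match(q_tbl$funfam_id, names(background))
    q_tbl$q <- ifelse(is.na(idx), q_tbl$q, background[idx])
  }

  deg <- count(as_tibble(drug_targets), drug_id = .data$outer_id, name = "n")
  hits <- inner_join(as_tibble(drug_targets),
                     tibble(target_id = ff_universe$outer_id,
                            funfam_id = ff_universe$middle_id),
                     by = c(middle_id = "target_id"),
                     relationship = "many-to-many")
  hits <- summarise(group_by(hits, drug_id = .data$outer_id,
                             funfam_id = .data$funfam_id),
                    x = n_distinct(.data$middle_id), .groups = "drop")
  res <- inner_join(hits, deg, by = "drug_id")
  res <- inner_join(res, q_tbl, by = "funfam_id")
  res <- mutate(res, p_value = binom_tail(.data$x, .data$n, .data$q))
  keep_p <- if (p_adjust == "BH") {
    stats::p.adjust(res$p_value, method = "BH")
  } else {
    res$p_value
  }
  n_boundary <- sum(keep_p == alpha)
  if (n_boundary > 0) {
    inform(sprintf("%d test(s) exactly at alpha = %g excluded (strict threshold)",
                   n_boundary, alpha))
  }
  res <- res[keep_p < alpha, , drop = FALSE]
  res <- select(res, "drug_id", "funfam_id", "n", "x", "q", "p_value")
  res <- arrange(res, .data$p_value, .data$drug_id, .data$funfam_id)
  structure(as_tibble(res), class = c("ff_enrichment", class(tibble())),
            alpha = alpha, p_adjust = p_adjust,
            universe_size = length(universe))
}

#' Drug-FunFam edges from an enrichment result
#'
#' @param enrichment A `ff_enrichment` tibble.
#' @return `bipartite_edges` drug -> funfam.
#' @export
enrichment_edges <- function(enrichment) {
  if (!inherits(enrichment, "ff_enrichment")) {
    abort_argument("`enrichment` must come from drug_funfam_enrichment()")
  }
  bipartite_edges(enrichment, outer = "drug_id", middle = "funfam_id",
                  outer_role = "drug", middle_role = "funfam", quiet = TRUE)
}
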
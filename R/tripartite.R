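#' Associate phenotypes with drugs through shared targets
#'
#' Combines a thresholded phenotype-target pair list with drug-target edges
#' into the final tripartite projection: phenotype-drug pairs scored by the
#' hypergeometric index over the target universe (distinct targets in the
#' union of both layers). One filtered list is returned per requested
#' threshold; threshold 0 is the unfiltered "Total" list.
#'
#' @param phenotype_targets `hyi_pairs` (phenotype as `a_id`, target -
#'   gene or FunFam - as `b_id`).
#' @param drug_targets `bipartite_edges` drug -> target in the same target
#'   namespace.
#' @param thresholds Numeric vector of index thresholds.
#' @return A `phenodrug_sweep`: list with `scores` (the full `hyi_pairs`)
#'   and `by_threshold` (named list of filtered `hyi_pairs`).
#' @export
associate_drugs <- function(phenotype_targets, drug_targets,
                            thresholds = c(0, 2, 3, 3.5)) {
  if (!is_hyi_pairs(phenotype_targets)) {
    abort_argument("`phenotype_targets` must be an hyi_pairs object")
  }
  if (!is_bipartite_edges(drug_targets)) {
    abort_argument("`drug_targets` must be bipartite_edges")
  }
  if (nrow(phenotype_targets) == 0 || nrow(drug_targets) == 0) {
    abort_contract("phenotype-target and drug-target layers must be non-empty")
  }
  shared_ns <- intersect(phenotype_targets$b_id, drug_targets$middle_id)
  if (length(shared_ns) == 0) {
    abort_contract(
      "target namespaces do not intersect between the phenotype and drug layers")
  }
  pheno_edges <- pairs_as_edges(phenotype_targets, use = "a")
  # the ID namespaces were checked above; align the middle-role label so
  # gene-labelled and target-labelled layers project together
  drug_edges <- bipartite_edges(drug_targets, outer = "outer_id",
                                middle = "middle_id",
                                outer_role = edge_roles(drug_targets)[["outer"]],
                                middle_role = edge_roles(pheno_edges)[["middle"]],
                                quiet = TRUE)
  scores <- project_pairs(pheno_edges, drug_edges)
  by_threshold <- lapply(thresholds, function(t) filter_pairs(scores, t))
  names(by_threshold) <- format_thresholds(thresholds)
  structure(list(scores = scores, by_threshold = by_threshold,
                 thresholds = thresholds),
            class = "phenodrug_sweep")
}

format_thresholds <- function(x) formatC(x, format = "g")

#' Phenotype-drug associations through shared protein targets
#'
#' End-to-end protein-target chain: phenotype-gene pairs from disease
#' annotations, drug-gene edges from filtered activities, and the tripartite
#' projection, swept over the requested final thresholds. Deterministic
#' given identical inputs.
#'
#' @param disease_phenotype,disease_gene Annotation tables (see
#'   [phenotype_gene_pairs()]).
#' @param activities ChEMBL-style activity table (see
#'   [filter_activities()]).
#' @param thresholds Thresholds for the final phenotype-drug scores.
#' @param pheno_threshold Threshold applied to the phenotype-gene layer.
#' @param quiet Suppress progress messages from the stages.
#' @return A `phenodrug_run`: list with the intermediate layers and the
#'   final `phenodrug_sweep`.
#' @export
run_protein_chain <- function(disease_phenotype, disease_gene, activities,
                              thresholds = c(0, 2, 3, 3.5),
                              pheno_threshold = 2, quiet = TRUE) {
  maybe_quiet <- if (quiet) suppressMessages else identity
  maybe_quiet({
    pheno_gene <- phenotype_gene_pairs(disease_phenotype, disease_gene,
                                       threshold = pheno_threshold)
    if (nrow(activities) == 0) {
      abort_contract("activity table is empty")
    }
    drug_target <- filter_activities(activities)
    if (nrow(drug_target) == 0) {
      abort_contract("no activity records survive the filtering criteria")
    }
    sweep <- associate_drugs(pheno_gene, drug_target, thresholds)
  })
  structure(list(mode = "protein", phenotype_targets = pheno_gene,
                 drug_targets = drug_target, sweep = sweep,
                 pheno_threshold = pheno_threshold),
            class = "phenodrug_run")
}

#' Phenotype-drug associations through shared FunFam domain targets
#'
#' End-to-end domain-target chain: phenotype-gene pairs are composed with
#' the gene-FunFam map into phenotype-FunFam pairs; filtered drug-target
#' edges are decomposed into drug-FunFam pairs by binomial
#' overrepresentation; the two FunFam layers are combined by the tripartite
#' projection.
#'
#' @inheritParams run_protein_chain
#' @param gene_funfam Gene-to-FunFam membership table.
#' @param funfam_threshold Threshold for the phenotype-FunFam layer.
#' @param alpha Binomial significance threshold for drug-FunFam pairs.
#' @return A `phenodrug_run` over the FunFam namespace.
#' @export
run_domain_chain <- function(disease_phenotype, disease_gene, activities,
                             gene_funfam, thresholds = c(0, 2, 3, 3.5),
                             pheno_threshold = 2, funfam_threshold = 2,
                             alpha = 0.05, quiet = TRUE) {
  maybe_quiet <- if (quiet) suppressMessages else identity
  maybe_quiet({
    pheno_gene <- phenotype_gene_pairs(disease_phenotype, disease_gene,
                                       threshold = pheno_threshold)
    pheno_funfam <- phenotype_funfam_pairs(pheno_gene, gene_funfam,
                                           threshold = funfam_threshold)
    if (nrow(activities) == 0) {
      abort_contract("activity table is empty")
    }
    drug_target <- filter_activities(activities)
    if (nrow(drug_target) == 0) {
      abort_contract("no activity records survive the filtering criteria")
    }
    enrichment <- drug_funfam_enrichment(drug_target, gene_funfam,
                                         alpha = alpha)
    drug_funfam <- enrichment_edges(enrichment)
    sweep <- associate_drugs(pheno_funfam, drug_funfam, thresholds)
  })
  structure(list(mode = "domain", phenotype_targets = pheno_funfam,
                 drug_targets = drug_funfam, enrichment = enrichment,
                 pheno_gene = pheno_gene, sweep = sweep,
                 pheno_threshold = pheno_threshold,
                 funfam_threshold = funfam_threshold, alpha = alpha),
            class = "phenodrug_run")
}

#' Explain one phenotype-drug association
#'
#' Recovers the witnessing shared targets and all score components for a
#' (phenotype, drug) pair from a finished run.
#'
#' @param run A `phenodrug_run`.
#' @param hpo_id,drug_id The pair to explain.
#' @return A list with the witnessing target IDs and the `hyi_pairs` row.
#' @export
explain_association <- function(run, hpo_id, drug_id) {
  if (!inherits(run, "phenodrug_run")) {
    abort_argument("`run` must come from run_protein_chain() or run_domain_chain()")
  }
  pheno_targets <- run$phenotype_targets$b_id[run$phenotype_targets$a_id == hpo_id]
  drug_targets <- run$drug_targets$middle_id[run$drug_targets$outer_id == drug_id]
  witnesses <- sort(intersect(pheno_targets, drug_targets))
  score <- filter(run$sweep$scores, .data$a_id == hpo_id, .data$b_id == drug_id)
  list(hpo_id = hpo_id, drug_id = drug_id, witnesses = witnesses,
       score = as_tibble(score))
}

#' @export
print.phenodrug_sweep <- function(x, ...) {
  cat("<phenodrug_sweep>\n")
  counts <- purrr::imap_int(x$by_threshold, ~ nrow(.x))
  for (nm in names(counts)) {
    cat(sprintf("  hyi >= %-5s %d pairs\n", nm, counts[[nm]]))
  }
  invisible(x)
}

#' @export
print.phenodrug_run <- function(x, ...) {
  cat(sprintf("<phenodrug_run mode=%s>\n", x$mode))
  cat(sprintf("  phenotype-target pairs: %d\n", nrow(x$phenotype_targets)))
  cat(sprintf("  drug-target edges: %d\n", nrow(x$drug_targets)))
  print(x$sweep)
  invisible(x)
}
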
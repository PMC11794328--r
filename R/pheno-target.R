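#' Score phenotype-gene pairs through shared diseases
#'
#' Genes and phenotypes annotated to common diseases (OMIM-like or
#' Orphanet-like annotation sets, always processed separately) are paired
#' and scored with the hypergeometric index over the disease universe, then
#' filtered at the given index threshold.
#'
#' @param disease_phenotype Data frame with columns `disease_id`, `hpo_id`.
#' @param disease_gene Data frame with columns `disease_id`, `gene_id`.
#' @param threshold Index threshold (2 keeps p <= 0.01).
#' @param universe Optional disease-population override (see
#'   [project_pairs()]).
#' @return `hyi_pairs` with phenotypes as `a_id` and genes as `b_id`.
#' @export
phenotype_gene_pairs <- function(disease_phenotype, disease_gene,
                                 threshold = 2, universe = NULL) {
  if (!is.data.frame(disease_phenotype) || nrow(disease_phenotype) == 0 ||
      !is.data.frame(disease_gene) || nrow(disease_gene) == 0) {
    abort_contract("disease-phenotype and disease-gene tables must be non-empty")
  }
  ph <- bipartite_edges(disease_phenotype, outer = "hpo_id",
                        middle = "disease_id",
                        outer_role = "phenotype", middle_role = "disease")
  validate_ids(ph$outer_id, "hpo_id")
  gn <- bipartite_edges(disease_gene, outer = "gene_id",
                        middle = "disease_id",
                        outer_role = "gene", middle_role = "disease")
  filter_pairs(project_pairs(ph, gn, universe = universe), threshold)
}

#' Score phenotype-FunFam pairs through shared genes
#'
#' The genes of already-thresholded phenotype-gene pairs become the middle
#' layer: each gene is paired with every CATH FunFam containing domains of
#' its protein product, and phenotype-FunFam overlap across genes is scored
#' with the hypergeometric index.
#'
#' @param pheno_gene `hyi_pairs` from [phenotype_gene_pairs()].
#' @param gene_funfam Data frame with columns `gene_id`, `funfam_id`.
#' @param threshold Index threshold for the phenotype-FunFam scores.
#' @return `hyi_pairs` with phenotypes as `a_id` and FunFams as `b_id`.
#' @export
phenotype_funfam_pairs <- function(pheno_gene, gene_funfam, threshold = 2) {
  if (!is_hyi_pairs(pheno_gene)) {
    abort_argument("`pheno_gene` must be the scored phenotype-gene pair list")
  }
  if (!is.data.frame(gene_funfam) || nrow(gene_funfam) == 0) {
    abort_contract("gene-FunFam table must be non-empty")
  }
  ff <- bipartite_edges(gene_funfam, outer = "gene_id", middle = "funfam_id",
                        outer_role = "gene", middle_role = "funfam")
  validate_ids(ff$middle_id, "funfam_id")

  genes_retained <- unique(pheno_gene$b_id)
  covered <- intersect(genes_retained, ff$outer_id)
  if (length(covered) == 0) {
    abort_contract(sprintf(
      paste0("gene ID namespaces do not overlap: %d genes in the ",
             "phenotype-gene pairs, %d in the domain map, 0 shared"),
      length(genes_retained), n_distinct(ff$outer_id)))
  }
  n_unmapped <- length(setdiff(genes_retained, ff$outer_id))
  if (n_unmapped > 0) {
    inform(sprintf("%d gene(s) without FunFam annotation dropped from the domain chain",
                   n_unmapped))
  }

  pheno_edges <- pairs_as_edges(pheno_gene, use = "a")
  ff_restricted <- ff[ff$outer_id %in% genes_retained, , drop = FALSE]
  funfam_edges <- bipartite_edges(
    tibble(funfam_id = ff_restricted$middle_id,
           gene_id = ff_restricted$outer_id),
    outer = "funfam_id", middle = "gene_id",
    outer_role = "funfam", middle_role = "gene", quiet = TRUE)
  filter_pairs(project_pairs(pheno_edges, funfam_edges), threshold)
}
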
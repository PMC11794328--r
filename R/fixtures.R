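#' Configuration for the synthetic tripartite universe
#'
#' Defines the study conditions the generator emulates: entity counts per
#' layer, background Bernoulli edge densities, and the planted
#' phenotype-drug signal (chains drug -> target set -> disease block ->
#' phenotype wired so that each planted pair is guaranteed to share at
#' least `planted_overlap` targets end to end).
#'
#' @param n_diseases,n_genes,n_phenotypes,n_funfams,n_drugs Entity counts.
#' @param density_disease_gene,density_disease_phenotype,density_gene_funfam,density_drug_target
#'   Background edge probabilities per node pair.
#' @param n_planted Number of planted phenotype-drug chains.
#' @param planted_overlap Shared targets per planted pair.
#' @param planted_diseases Dedicated diseases wiring each planted chain.
#' @param gold_noise Probability that a planted gold pair is replaced by a
#'   random pair.
#' @param gold_background Extra random gold pairs.
#' @param activity_pass_rate Probability that a background activity record
#'   satisfies all filtering criteria.
#' @param comention_background Number of background co-mention records.
#' @param seed Integer seed; the whole universe is deterministic given it.
#' @return A `fixture_config` list.
#' @export
fixture_config <- function(n_diseases = 60, n_genes = 80, n_phenotypes = 40,
                           n_funfams = 30, n_drugs = 30,
                           density_disease_gene = 0.03,
                           density_disease_phenotype = 0.05,
                           density_gene_funfam = 0.04,
                           density_drug_target = 0.04,
                           n_planted = 5, planted_overlap = 3,
                           planted_diseases = 6,
                           gold_noise = 0.1, gold_background = 15,
                           activity_pass_rate = 0.7,
                           comention_background = 40,
                           seed = 1) {
  counts <- c(n_diseases = n_diseases, n_genes = n_genes,
              n_phenotypes = n_phenotypes, n_funfams = n_funfams,
              n_drugs = n_drugs)
  if (any(counts < 1)) abort_argument("all entity counts must be >= 1")
  densities <- c(density_disease_gene, density_disease_phenotype,
                 density_gene_funfam, density_drug_target,
                 gold_noise, activity_pass_rate)
  if (any(densities < 0) || any(densities > 1)) {
    abort_argument("densities and rates must lie in [0, 1]")
  }
  if (n_planted < 0 || planted_overlap < 1 || planted_diseases < 1) {
    abort_argument("n_planted must be >= 0; planted_overlap and planted_diseases >= 1")
  }
  if (n_planted > 0) {
    if (n_planted * planted_overlap > n_genes) {
      abort_argument("infeasible config: n_planted * planted_overlap exceeds n_genes")
    }
    if (n_planted * planted_diseases > n_diseases) {
      abort_argument("infeasible config: n_planted * planted_diseases exceeds n_diseases")
    }
    if (n_planted > min(n_phenotypes, n_drugs, n_funfams)) {
      abort_argument("infeasible config: n_planted exceeds a layer's entity count")
    }
  }
  structure(list(
    n_diseases = n_diseases, n_genes = n_genes, n_phenotypes = n_phenotypes,
    n_funfams = n_funfams, n_drugs = n_drugs,
    density_disease_gene = density_disease_gene,
    density_disease_phenotype = density_disease_phenotype,
    density_gene_funfam = density_gene_funfam,
    density_drug_target = density_drug_target,
    n_planted = n_planted, planted_overlap = planted_overlap,
    planted_diseases = planted_diseases,
    gold_noise = gold_noise, gold_background = gold_background,
    activity_pass_rate = activity_pass_rate,
    comention_background = comention_background,
    seed = as.integer(seed)
  ), class = "fixture_config")
}

bernoulli_edges <- function(ids_a, ids_b, density, col_a, col_b) {
  grid <- expand.grid(a = ids_a, b = ids_b, stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  keep <- runif(nrow(grid)) < density
  out <- tibble(!!col_a := grid$a[keep], !!col_b := grid$b[keep])
  out
}

passing_activity <- function(drug, target, pchembl) {
  tibble(drug_id = drug, target_id = target, therapeutic_flag = 1L,
         assay_type = "B", relationship_type = "D",
         target_type = "Single Protein", pchembl = pchembl)
}

violate_one <- function(rec, which) {
  switch(which,
         flag = mutate(rec, therapeutic_flag = 0L),
         assay = mutate(rec, assay_type = "A"),
         relationship = mutate(rec, relationship_type = "N"),
         target = mutate(rec, target_type = "Protein complex"),
         pchembl = mutate(rec, pchembl = round(runif(dplyr::n(), 3, 5.9), 2)))
}

#' Generate a synthetic tripartite universe with planted signal
#'
#' Emulates every input table the pipeline consumes - disease-gene and
#' disease-phenotype annotations, gene-FunFam membership, a ChEMBL-style
#' activity table, a gold-standard effect list and literature co-mention
#' counts - from independent Bernoulli background edges plus `n_planted`
#' fully wired phenotype-drug chains. Planted chains use dedicated disease
#' blocks and dedicated FunFams, so each planted pair shares at least
#' `planted_overlap` targets in both the protein and the domain chain by
#' construction; their activity records satisfy all filtering criteria and
#' their co-mention counts are significant. Deterministic given the seed.
#'
#' @param cfg A [fixture_config()].
#' @return A `phenodrug_universe` list: `disease_gene`, `disease_phenotype`,
#'   `gene_funfam`, `activities`, `gold`, `comentions`, `planted` (the
#'   truth manifest) and `config`.
#' @export
generate_universe <- function(cfg) {
  if (!inherits(cfg, "fixture_config")) {
    abort_argument("`cfg` must come from fixture_config()")
  }
  diseases <- sprintf("OMIM:%06d", 100000 + seq_len(cfg$n_diseases))
  phenotypes <- sprintf("HP:%07d", seq_len(cfg$n_phenotypes))
  genes <- sprintf("GENE%04d", seq_len(cfg$n_genes))
  funfams <- sprintf("1.10.8.%d-ff-%d", seq_len(cfg$n_funfams),
                     seq_len(cfg$n_funfams))
  drugs <- sprintf("CHEMBL%d", 100 + seq_len(cfg$n_drugs))

  withr::with_seed(cfg$seed, {
    # planted FunFams are dedicated: background FunFam edges avoid them
    bg_funfams <- funfams[setdiff(seq_along(funfams), seq_len(cfg$n_planted))]
    disease_gene <- bernoulli_edges(diseases, genes,
                                    cfg$density_disease_gene,
                                    "disease_id", "gene_id")
    disease_phenotype <- bernoulli_edges(diseases, phenotypes,
                                         cfg$density_disease_phenotype,
                                         "disease_id", "hpo_id")
    gene_funfam <- if (length(bg_funfams) > 0) {
      bernoulli_edges(genes, bg_funfams, cfg$density_gene_funfam,
                      "gene_id", "funfam_id")
    } else {
      tibble(gene_id = character(), funfam_id = character())
    }
    bg_target_edges <- bernoulli_edges(drugs, genes,
                                       cfg$density_drug_target,
                                       "drug_id", "target_id")
    n_bg <- nrow(bg_target_edges)
    activities <- passing_activity(bg_target_edges$drug_id,
                                   bg_target_edges$target_id,
                                   round(runif(n_bg, 6, 9), 2))
    if (n_bg > 0) {
      fail_idx <- which(runif(n_bg) >= cfg$activity_pass_rate)
      if (length(fail_idx) > 0) {
        reasons <- sample(c("flag", "assay", "relationship", "target",
                            "pchembl"), length(fail_idx), replace = TRUE)
        for (r in unique(reasons)) {
          rows <- fail_idx[reasons == r]
          activities[rows, ] <- violate_one(activities[rows, ], r)
        }
      }
    }

    planted <- tibble(hpo_id = character(), drug_id = character(),
                      funfam_id = character(), genes = character(),
                      diseases = character())
    if (cfg$n_planted > 0) {
      for (i in seq_len(cfg$n_planted)) {
        chain_genes <- genes[((i - 1) * cfg$planted_overlap + 1):
                               (i * cfg$planted_overlap)]
        chain_diseases <- diseases[((i - 1) * cfg$planted_diseases + 1):
                                     (i * cfg$planted_diseases)]
        h <- phenotypes[i]; d <- drugs[i]; f <- funfams[i]
        disease_gene <- bind_rows(disease_gene,
          expand_tbl(chain_diseases, chain_genes, "disease_id", "gene_id"))
        disease_phenotype <- bind_rows(disease_phenotype,
          tibble(disease_id = chain_diseases, hpo_id = h))
        gene_funfam <- bind_rows(gene_funfam,
          tibble(gene_id = chain_genes, funfam_id = f))
        activities <- bind_rows(activities,
          passing_activity(d, chain_genes, round(runif(length(chain_genes), 7, 9), 2)))
        planted <- bind_rows(planted, tibble(
          hpo_id = h, drug_id = d, funfam_id = f,
          genes = paste(chain_genes, collapse = ","),
          diseases = paste(chain_diseases, collapse = ",")))
      }
    }
    disease_gene <- distinct(disease_gene)
    disease_phenotype <- distinct(disease_phenotype)
    gene_funfam <- distinct(gene_funfam)

    gold <- tibble(hpo_id = planted$hpo_id, drug_id = planted$drug_id)
    if (nrow(gold) > 0 && cfg$gold_noise > 0) {
      noisy <- runif(nrow(gold)) < cfg$gold_noise
      if (any(noisy)) {
        gold$hpo_id[noisy] <- sample(phenotypes, sum(noisy), replace = TRUE)
        gold$drug_id[noisy] <- sample(drugs, sum(noisy), replace = TRUE)
      }
    }
    if (cfg$gold_background > 0) {
      gold <- bind_rows(gold, tibble(
        hpo_id = sample(phenotypes, cfg$gold_background, replace = TRUE),
        drug_id = sample(drugs, cfg$gold_background, replace = TRUE)))
    }
    gold <- distinct(gold)

    n_total <- 1e6
    comentions <- tibble(
      drug_id = planted$drug_id, hpo_id = planted$hpo_id,
      n_drug = 2000L, n_hpo = 2000L, n_both = 40L, n_total = n_total)
    if (cfg$comention_background > 0) {
      nd <- sample(500:3000, cfg$comention_background, replace = TRUE)
      nh <- sample(500:3000, cfg$comention_background, replace = TRUE)
      bg_com <- tibble(
        drug_id = sample(drugs, cfg$comention_background, replace = TRUE),
        hpo_id = sample(phenotypes, cfg$comention_background, replace = TRUE),
        n_drug = nd, n_hpo = nh,
        n_both = pmin(rpois(cfg$comention_background, nd * nh / n_total),
                      pmin(nd, nh)),
        n_total = n_total)
      comentions <- distinct(bind_rows(comentions, bg_com),
                             .data$drug_id, .data$hpo_id, .keep_all = TRUE)
    }
  })

  structure(list(disease_gene = disease_gene,
                 disease_phenotype = disease_phenotype,
                 gene_funfam = gene_funfam,
                 activities = activities,
                 gold = gold,
                 comentions = comentions,
                 planted = planted,
                 config = cfg),
            class = "phenodrug_universe")
}

expand_tbl <- function(a, b, col_a, col_b) {
  grid <- expand.grid(a = a, b = b, stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  tibble(!!col_a := grid$a, !!col_b := grid$b)
}

#' @export
print.phenodrug_universe <- function(x, ...) {
  cat("<phenodrug_universe>\n")
  for (nm in c("disease_gene", "disease_phenotype", "gene_funfam",
               "activities", "gold", "comentions", "planted")) {
    cat(sprintf("  %-18s %d rows\n", nm, nrow(x[[nm]])))
  }
  invisible(x)
}
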
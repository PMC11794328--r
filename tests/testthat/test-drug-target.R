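test_that("activity filtering applies every criterion with an inclusive potency bound", {
  base <- passing_activity_row("CHEMBL1", "T1", pchembl = 6.0)
  kept <- suppressMessages(filter_activities(base))
  expect_equal(nrow(kept), 1) # pchembl exactly 6 is kept

  variants <- rbind(
    transform(base, pchembl = 5.9),
    transform(base, therapeutic_flag = 0),
    transform(base, assay_type = "F"),
    transform(base, relationship_type = "N"),
    transform(base, target_type = "Protein complex"),
    transform(base, pchembl = NA_real_))
  expect_equal(nrow(suppressMessages(filter_activities(variants))), 0)

  # case-insensitive target type
  expect_equal(nrow(suppressMessages(filter_activities(
    transform(base, target_type = "SINGLE PROTEIN")))), 1)
})

test_that("activity filtering deduplicates and is order-independent", {
  recs <- rbind(
    passing_activity_row("CHEMBL1", "T1", 6.5),
    passing_activity_row("CHEMBL1", "T1", 8.0),
    passing_activity_row("CHEMBL1", "T2", 7.0),
    passing_activity_row("CHEMBL2", "T1", 7.0),
    passing_activity_row("CHEMBL1", "T1", 9.0))
  e1 <- suppressMessages(filter_activities(recs))
  expect_equal(nrow(e1), 3)
  e2 <- suppressMessages(filter_activities(recs[rev(seq_len(nrow(recs))), ]))
  expect_equal(dplyr::arrange(tibble::as_tibble(e1), outer_id, middle_id),
               dplyr::arrange(tibble::as_tibble(e2), outer_id, middle_id))
  # idempotence: refiltering the surviving records changes nothing
  survivors <- passing_activity_row(e1$outer_id, e1$middle_id, 7)
  e3 <- suppressMessages(filter_activities(survivors))
  expect_equal(dplyr::arrange(tibble::as_tibble(e3), outer_id, middle_id),
               dplyr::arrange(tibble::as_tibble(e1), outer_id, middle_id))
})

test_that("missing activity columns are named in the error", {
  expect_error(filter_activities(data.frame(drug_id = "d", target_id = "t")),
               "therapeutic_flag", class = "phenodrug_format_error")
})

test_that("binomial upper tail matches the closed-form sums and the oracle", {
  expect_equal(binom_tail(0, 5, 0.2), 1.0)
  expect_equal(binom_tail(3, 5, 0.2), 0.05792, tolerance = 1e-10)
  expect_equal(binom_tail(4, 4, 1.0), 1.0)
  expect_error(binom_tail(6, 5, 0.2), class = "phenodrug_argument_error")
  expect_error(binom_tail(1, 5, 1.2), class = "phenodrug_argument_error")

  for (n in c(1, 4, 7)) {
    for (q in c(0, 0.2, 0.5, 0.9, 1)) {
      for (x in 0:n) {
        expected <- enum_binom_tail(x, n, q)
        got <- binom_tail(x, n, q)
        expect_equal(got, expected, tolerance = 1e-12)
      }
      # monotone in x
      tails <- binom_tail(0:n, n, q)
      expect_true(all(diff(tails) <= 1e-15))
    }
  }
})

make_enrichment_universe <- function(n_universe, n_with_funfam) {
  # drug CHEMBL1 has 5 targets, 3 carrying the FunFam; padding drugs
  # carry the remaining targets so the background universe is n_universe
  targets <- sprintf("T%02d", seq_len(n_universe))
  edges <- rbind(
    data.frame(drug_id = "CHEMBL1", target_id = targets[1:5]),
    data.frame(drug_id = "CHEMBL99", target_id = targets[6:n_universe]))
  activities <- passing_activity_row(edges$drug_id, edges$target_id, 7)
  gene_funfam <- data.frame(gene_id = targets[seq_len(n_with_funfam)],
                            funfam_id = funfam(1))
  list(drug_targets = suppressMessages(filter_activities(activities)),
       gene_funfam = gene_funfam)
}

test_that("FunFam enrichment uses the target-universe background and a strict alpha", {
  # q = 3/15 = 0.2: p = 0.05792, excluded at alpha = 0.05
  u15 <- make_enrichment_universe(15, 3)
  enr15 <- suppressMessages(
    drug_funfam_enrichment(u15$drug_targets, u15$gene_funfam))
  row15 <- enr15[enr15$drug_id == "CHEMBL1", ]
  expect_equal(nrow(row15), 0)

  # q = 3/30 = 0.1: p = 0.00856, included
  u30 <- make_enrichment_universe(30, 3)
  enr30 <- suppressMessages(
    drug_funfam_enrichment(u30$drug_targets, u30$gene_funfam))
  row30 <- enr30[enr30$drug_id == "CHEMBL1", ]
  expect_equal(nrow(row30), 1)
  expect_equal(row30$n, 5)
  expect_equal(row30$x, 3)
  expect_equal(row30$q, 0.1)
  expect_equal(row30$p_value, 0.00856, tolerance = 1e-10)
  expect_equal(row30$p_value, enum_binom_tail(3, 5, 0.1), tolerance = 1e-12)
})

test_that("a FunFam carried by every universe protein is never enriched", {
  u <- make_enrichment_universe(15, 15)
  enr <- suppressMessages(drug_funfam_enrichment(u$drug_targets, u$gene_funfam))
  expect_equal(nrow(enr), 0)
})

test_that("proteins with several domains of one FunFam count once", {
  targets <- sprintf("T%02d", 1:10)
  activities <- passing_activity_row(
    c(rep("CHEMBL1", 3), rep("CHEMBL2", 7)),
    c(targets[1:3], targets[4:10]), 7)
  # T01 carries two domain instances of the same FunFam
  gene_funfam <- data.frame(gene_id = c("T01", "T01", "T02"),
                            funfam_id = funfam(1))
  dt <- suppressMessages(filter_activities(activities))
  enr <- suppressMessages(
    drug_funfam_enrichment(dt, gene_funfam, alpha = 1))
  row <- enr[enr$drug_id == "CHEMBL1" & enr$funfam_id == funfam(1), ]
  expect_equal(row$x, 2)
  expect_equal(row$q, 0.2)
})

test_that("every drug-FunFam edge is witnessed by a filtered target", {
  set.seed(5)
  targets <- sprintf("T%02d", 1:20)
  activities <- passing_activity_row(
    sample(sprintf("CHEMBL%d", 1:4), 40, replace = TRUE),
    sample(targets, 40, replace = TRUE), 7)
  gene_funfam <- data.frame(gene_id = sample(targets, 12),
                            funfam_id = funfam(rep(1:3, each = 4)))
  dt <- suppressMessages(filter_activities(activities))
  enr <- suppressMessages(drug_funfam_enrichment(dt, gene_funfam, alpha = 1))
  for (r in seq_len(nrow(enr))) {
    drug_ts <- dt$middle_id[dt$outer_id == enr$drug_id[r]]
    ff_ts <- gene_funfam$gene_id[gene_funfam$funfam_id == enr$funfam_id[r]]
    expect_gte(length(intersect(drug_ts, ff_ts)), 1)
  }
})

test_that("degenerate enrichment inputs raise contract errors", {
  u <- make_enrichment_universe(15, 3)
  empty <- u$drug_targets[0, ]
  expect_error(drug_funfam_enrichment(empty, u$gene_funfam),
               class = "phenodrug_contract_error")
  expect_error(drug_funfam_enrichment(u$drug_targets,
                                      data.frame(gene_id = "ZZZ",
                                                 funfam_id = funfam(1))),
               "covers none", class = "phenodrug_contract_error")
})
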
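gold_df <- function(...) {
  m <- matrix(c(...), ncol = 2, byrow = TRUE)
  data.frame(hpo_id = m[, 1], drug_id = m[, 2])
}

test_that("gold-universe restriction is per-entity, not per-pair", {
  pred <- fake_pairs(c(hpo(1), hpo(1), hpo(9)),
                     c("CHEMBL1", "CHEMBL9", "CHEMBL1"), hyi = rep(3, 3))
  gold <- gold_df(hpo(1), "CHEMBL1", hpo(2), "CHEMBL2")
  kept <- restrict_to_gold(pred, gold)
  expect_equal(nrow(kept), 1)
  expect_equal(kept$a_id, hpo(1))
  expect_equal(kept$b_id, "CHEMBL1")

  # both entities known to gold but never together: still retained
  pred2 <- fake_pairs(hpo(1), "CHEMBL2", hyi = 3)
  expect_equal(nrow(restrict_to_gold(pred2, gold)), 1)

  # predictions already inside the gold universe pass unchanged
  pred3 <- fake_pairs(c(hpo(1), hpo(2)), c("CHEMBL2", "CHEMBL1"),
                      hyi = c(3, 4))
  expect_equal(nrow(restrict_to_gold(pred3, gold)), 2)
  expect_error(restrict_to_gold(pred, gold[0, ]),
               class = "phenodrug_contract_error")
})

test_that("randomization preserves both degree multisets on every draw", {
  set.seed(3)
  for (rep in 1:20) {
    pairs <- data.frame(
      hpo_id = hpo(sample(1:6, 12, replace = TRUE)),
      drug_id = sprintf("CHEMBL%d", sample(1:6, 12, replace = TRUE)))
    pairs <- unique(pairs)
    rand <- randomize_links(pairs, seed = rep, warn_rigid = FALSE)
    expect_equal(degree_multiset(rand, "hpo_id"),
                 degree_multiset(pairs, "hpo_id"))
    expect_equal(degree_multiset(rand, "drug_id"),
                 degree_multiset(pairs, "drug_id"))
    expect_equal(nrow(unique(rand)), nrow(pairs)) # simple pair set
  }
})

test_that("a rigid configuration is returned unchanged with a warning", {
  complete <- expand.grid(hpo_id = hpo(1:2),
                          drug_id = c("CHEMBL1", "CHEMBL2"),
                          stringsAsFactors = FALSE)
  expect_warning(rand <- randomize_links(complete, seed = 1),
                 "only the input configuration")
  expect_setequal(paste(rand$hpo_id, rand$drug_id),
                  paste(complete$hpo_id, complete$drug_id))
})

test_that("the sampler is unbiased over the two configurations of a 2-matching", {
  pairs <- gold_df(hpo(1), "CHEMBL1", hpo(2), "CHEMBL2")
  gold <- gold_df(hpo(1), "CHEMBL1")
  overlaps <- vapply(1:1000, function(s) {
    rand <- randomize_links(pairs, seed = s, warn_rigid = FALSE)
    nrow(merge(rand, gold))
  }, numeric(1))
  # the two valid configurations hold 1 and 0 gold pairs; uniform
  # sampling gives mean 0.5
  se <- sd(overlaps) / sqrt(length(overlaps))
  expect_lt(abs(mean(overlaps) - 0.5), 3 * se)
})

test_that("Monte-Carlo random overlap matches exhaustive enumeration on a small set", {
  pairs <- gold_df(hpo(1), "CHEMBL1", hpo(1), "CHEMBL2",
                   hpo(2), "CHEMBL1", hpo(3), "CHEMBL3",
                   hpo(4), "CHEMBL2")
  gold <- gold_df(hpo(1), "CHEMBL1", hpo(3), "CHEMBL3", hpo(4), "CHEMBL1")
  exact <- enum_config_mean_overlap(pairs, gold)
  expect_gt(exact$n_configs, 1)
  overlaps <- vapply(1:1000, function(s) {
    rand <- randomize_links(pairs, seed = s, warn_rigid = FALSE)
    nrow(merge(rand, gold))
  }, numeric(1))
  se <- max(sd(overlaps) / sqrt(length(overlaps)), 1e-6)
  expect_lt(abs(mean(overlaps) - exact$mean), 3 * se)
})

test_that("overlap_ratio reports confirmed, null mean and ratio reproducibly", {
  pred <- fake_pairs(hpo(c(1, 1, 2, 3)),
                     sprintf("CHEMBL%d", c(1, 2, 1, 3)), hyi = rep(3, 4))
  gold <- gold_df(hpo(1), "CHEMBL1", hpo(3), "CHEMBL3", hpo(2), "CHEMBL2")
  rep1 <- overlap_ratio(pred, gold, n_replicates = 50, seed = 9)
  rep2 <- overlap_ratio(pred, gold, n_replicates = 50, seed = 9)
  expect_identical(rep1, rep2)
  expect_equal(rep1$confirmed, 2)
  expect_true(rep1$random_mean >= 0)
  if (rep1$random_mean > 0) {
    expect_equal(rep1$ratio, rep1$confirmed / rep1$random_mean)
  }

  # gold disjoint from the predicted universe: confirmed 0, ratio Inf
  far_gold <- gold_df(hpo(8), "CHEMBL8")
  rep3 <- overlap_ratio(pred, far_gold, n_replicates = 20, seed = 2)
  expect_equal(rep3$confirmed, 0)
  expect_equal(rep3$random_mean, 0)
  expect_true(is.infinite(rep3$ratio))
})

test_that("co-occurrence significance is the hypergeometric tail on counts", {
  expect_equal(cooccurrence_pvalue(0, 3, 3, 10), 1.0)
  expect_equal(cooccurrence_pvalue(2, 3, 3, 10), 22 / 120, tolerance = 1e-12)
  expect_equal(cooccurrence_pvalue(10, 10, 10, 100), 1 / choose(100, 10),
               tolerance = 1e-9)
  # shared implementation with the overlap index
  expect_equal(cooccurrence_pvalue(2, 3, 3, 10),
               hypergeom_tail(2, 3, 3, 10))
  expect_equal(cooccurrence_pvalue(2, 3, 3, 10),
               enum_hypergeom_tail(2, 3, 3, 10), tolerance = 1e-12)
  expect_error(cooccurrence_pvalue(4, 3, 3, 10),
               class = "phenodrug_argument_error")
  expect_error(cooccurrence_pvalue(1, 11, 3, 10),
               class = "phenodrug_argument_error")
})

test_that("literature overlap confirms against significant co-mentions only", {
  pred <- fake_pairs(hpo(1:3), sprintf("CHEMBL%d", 1:3), hyi = rep(3, 3))
  insignificant <- data.frame(
    drug_id = sprintf("CHEMBL%d", 1:3), hpo_id = hpo(1:3),
    n_drug = 100, n_hpo = 100, n_both = 1, n_total = 10000)
  rep0 <- literature_overlap(pred, insignificant, n_replicates = 20, seed = 4)
  expect_equal(rep0$confirmed, 0)

  significant <- transform(insignificant, n_both = 50)
  expect_true(all(cooccurrence_significance(significant)$significant))
  rep1 <- literature_overlap(pred, significant, n_replicates = 20, seed = 4)
  expect_equal(rep1$confirmed, 3)
})

test_that("sweep validation returns one gold and one literature row per threshold", {
  u <- generate_universe(fixture_config(seed = 53))
  run <- run_protein_chain(u$disease_phenotype, u$disease_gene, u$activities,
                           thresholds = c(0, 2))
  report <- validate_sweep(run$sweep, u$gold, u$comentions,
                           n_replicates = 30, seed = 5)
  expect_equal(nrow(report), 4)
  expect_setequal(unique(report$source), c("gold", "literature"))
  gold_row <- report[report$source == "gold" & report$threshold == 2, ]
  expect_gt(gold_row$ratio, 1)
})
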
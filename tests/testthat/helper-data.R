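# Small deterministic builders shared across test files.

hpo <- function(i) sprintf("HP:%07d", i)
funfam <- function(i) sprintf("1.1.1.%d-ff-%d", i, i)

edges_df <- function(...) {
  # edges_df("P1", c("D1","D2"), "P2", "D3") -> long two-column frame
  args <- list(...)
  stopifnot(length(args) %% 2 == 0)
  out <- NULL
  for (i in seq(1, length(args), by = 2)) {
    out <- rbind(out, data.frame(a = args[[i]], b = args[[i + 1]]))
  }
  out
}

make_edges <- function(df, outer_role, middle_role) {
  bipartite_edges(df, outer = "a", middle = "b",
                  outer_role = outer_role, middle_role = middle_role,
                  quiet = TRUE)
}

# hyi_pairs with prescribed scores, for threshold-filter tests
fake_pairs <- function(a_id, b_id, hyi, a_role = "phenotype",
                       b_role = "drug") {
  phenodrug:::new_hyi_pairs(
    tibble::tibble(a_id = a_id, b_id = b_id, k = 1L, size_a = 1L,
                   size_b = 1L, n_pop = 10L, p_value = 10^(-hyi),
                   hyi = hyi),
    a_role = a_role, b_role = b_role)
}

passing_activity_row <- function(drug, target, pchembl = 7) {
  data.frame(drug_id = drug, target_id = target, therapeutic_flag = 1,
             assay_type = "B", relationship_type = "D",
             target_type = "Single Protein", pchembl = pchembl)
}
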
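#' Project two edge lists sharing a middle layer into scored pairs
#'
#' Every (left-outer, right-outer) pair sharing at least one middle-layer
#' neighbour is scored with the hypergeometric overlap index: the upper-tail
#' probability that two neighbour sets of the observed sizes share at least
#' the observed number of middle entities, given the population of distinct
#' middle entities, transformed to `-log10`. Pairs with no shared neighbour
#' are never emitted. Output order is deterministic: descending index, then
#' lexicographic IDs.
#'
#' @param left,right `bipartite_edges` with matching middle roles.
#' @param universe Optional population-size override. Defaults to the number
#'   of distinct middle entities in the union of both edge lists; an
#'   override must be at least that count.
#' @return An `hyi_pairs` tibble with columns `a_id`, `b_id`, `k`, `size_a`,
#'   `size_b`, `n_pop`, `p_value`, `hyi`. The roles and applied threshold
#'   travel as attributes.
#' @examples
#' ph <- bipartite_edges(data.frame(p = "P1", d = c("D1", "D2")),
#'                       "p", "d", "phenotype", "disease")
#' gn <- bipartite_edges(data.frame(g = "G1", d = c("D1", "D2")),
#'                       "g", "d", "gene", "disease")
#' project_pairs(ph, gn, universe = 5)
#' @export
project_pairs <- function(left, right, universe = NULL) {
  if (!is_bipartite_edges(left) || !is_bipartite_edges(right)) {
    abort_argument("`left` and `right` must be bipartite_edges objects")
  }
  roles_l <- edge_roles(left)
  roles_r <- edge_roles(right)
  if (roles_l["middle"] != roles_r["middle"]) {
    abort_contract(sprintf(
      "middle roles differ: left shares '%s', right shares '%s'",
      roles_l["middle"], roles_r["middle"]))
  }
  n_pop <- n_distinct(c(left$middle_id, right$middle_id))
  if (!is.null(universe)) {
    if (universe < n_pop) {
      abort_argument(sprintf(
        "universe override (%d) is below the %d distinct middle entities observed",
        universe, n_pop))
    }
    n_pop <- as.integer(universe)
  }

  deg_a <- count(left, .data$outer_id, name = "size_a")
  deg_b <- count(right, .data$outer_id, name = "size_b")
  shared <- inner_join(left, right, by = "middle_id",
                       relationship = "many-to-many",
                       suffix = c("_a", "_b"))
  pairs <- count(shared, a_id = .data$outer_id_a, b_id = .data$outer_id_b,
                 name = "k")
  pairs <- left_join(pairs, rename(deg_a, a_id = "outer_id"), by = "a_id")
  pairs <- left_join(pairs, rename(deg_b, b_id = "outer_id"), by = "b_id")
  log_p <- hypergeom_log_tail(pairs$k, pairs$size_a, pairs$size_b, n_pop)
  hyi <- hyi_from_log_p(log_p)
  pairs <- mutate(pairs,
                  n_pop = n_pop,
                  p_value = p_from_hyi(hyi),
                  hyi = hyi)
  pairs <- select(pairs, "a_id", "b_id", "k", "size_a", "size_b",
                  "n_pop", "p_value", "hyi")
  new_hyi_pairs(arrange(pairs, dplyr::desc(.data$hyi), .data$a_id, .data$b_id),
                a_role = unname(roles_l["outer"]),
                b_role = unname(roles_r["outer"]),
                threshold_applied = NA_real_)
}

new_hyi_pairs <- function(df, a_role = "a", b_role = "b",
                          threshold_applied = NA_real_) {
  structure(as_tibble(df),
            class = c("hyi_pairs", class(tibble())),
            a_role = a_role, b_role = b_role,
            threshold_applied = threshold_applied)
}

is_hyi_pairs <- function(x) inherits(x, "hyi_pairs")

#' Filter scored pairs by hypergeometric-index threshold
#'
#' Keeps the pairs whose index is at least `threshold` (so threshold 2 keeps
#' p-values of at most 0.01). Thresholding is monotone: a higher threshold
#' always yields a subset.
#'
#' @param pairs An `hyi_pairs` tibble.
#' @param threshold Non-negative index threshold.
#' @return The filtered `hyi_pairs`, recording `threshold_applied`.
#' @export
filter_pairs <- function(pairs, threshold) {
  if (!is_hyi_pairs(pairs)) abort_argument("`pairs` must be an hyi_pairs object")
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      !is.finite(threshold) || threshold < 0) {
    abort_argument("`threshold` must be a single non-negative number")
  }
  new_hyi_pairs(filter(pairs, .data$hyi >= threshold),
                a_role = attr(pairs, "a_role"),
                b_role = attr(pairs, "b_role"),
                threshold_applied = threshold)
}

# hyi_pairs reinterpreted as outer->middle edges for the next projection
pairs_as_edges <- function(pairs, use = c("a", "b")) {
  use <- match.arg(use)
  a_role <- attr(pairs, "a_role") %||% "a"
  b_role <- attr(pairs, "b_role") %||% "b"
  if (use == "a") {
    bipartite_edges(pairs, outer = "a_id", middle = "b_id",
                    outer_role = a_role, middle_role = b_role, quiet = TRUE)
  } else {
    bipartite_edges(pairs, outer = "b_id", middle = "a_id",
                    outer_role = b_role, middle_role = a_role, quiet = TRUE)
  }
}
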
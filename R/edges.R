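#' Construct a bipartite edge list
#'
#' One layer pair of the tripartite network: a deduplicated set of
#' (outer, middle) edges, e.g. phenotype-disease, gene-disease or
#' drug-target. Input is any data frame; the named columns are taken as
#' outer and middle IDs and the result is a two-column tibble
#' (`outer_id`, `middle_id`) carrying the role labels as attributes.
#'
#' @param x Data frame with at least the two ID columns.
#' @param outer,middle Column names holding the outer and middle IDs.
#' @param outer_role,middle_role Labels for the two layers (e.g.
#'   `"phenotype"`, `"disease"`).
#' @param quiet Suppress the duplicate-edge message.
#' @return A `bipartite_edges` tibble with columns `outer_id`, `middle_id`.
#' @examples
#' bipartite_edges(
#'   data.frame(hpo_id = "HP:0000001", disease_id = "OMIM:100001"),
#'   outer = "hpo_id", middle = "disease_id",
#'   outer_role = "phenotype", middle_role = "disease"
#' )
#' @export
bipartite_edges <- function(x, outer, middle, outer_role = outer,
                            middle_role = middle, quiet = FALSE) {
  if (!is.data.frame(x)) abort_argument("`x` must be a data frame")
  missing_cols <- setdiff(c(outer, middle), names(x))
  if (length(missing_cols) > 0) {
    abort_format(paste0("missing required column(s): ",
                        paste(missing_cols, collapse = ", ")))
  }
  edges <- tibble(outer_id = as.character(x[[outer]]),
                  middle_id = as.character(x[[middle]]))
  if (any(is.na(edges$outer_id)) || any(is.na(edges$middle_id)) ||
      any(edges$outer_id == "") || any(edges$middle_id == "")) {
    abort_format("edge lists must not contain missing or empty-string IDs")
  }
  n_in <- nrow(edges)
  edges <- distinct(edges)
  if (!quiet && nrow(edges) < n_in) {
    inform(sprintf("dropped %d duplicate edge(s) (%s-%s)",
                   n_in - nrow(edges), outer_role, middle_role))
  }
  structure(edges,
            class = c("bipartite_edges", class(tibble())),
            outer_role = outer_role, middle_role = middle_role)
}

is_bipartite_edges <- function(x) inherits(x, "bipartite_edges")

edge_roles <- function(x) {
  c(outer = attr(x, "outer_role") %||% "outer",
    middle = attr(x, "middle_role") %||% "middle")
}

#' Swap the outer and middle layers of an edge list
#'
#' @param edges A `bipartite_edges` object.
#' @return A `bipartite_edges` object with roles and columns exchanged.
#' @export
swap_layers <- function(edges) {
  if (!is_bipartite_edges(edges)) abort_argument("`edges` must be bipartite_edges")
  roles <- edge_roles(edges)
  bipartite_edges(
    tibble(a = edges$middle_id, b = edges$outer_id),
    outer = "a", middle = "b",
    outer_role = unname(roles["middle"]), middle_role = unname(roles["outer"]),
    quiet = TRUE
  )
}

# ID format validators, shared by readers and the fixture generator
ID_PATTERNS <- list(
  hpo_id = "^HP:[0-9]{7}$",
  funfam_id = "^[0-9]+\\.[0-9]+\\.[0-9]+\\.[0-9]+-ff-[0-9]+$"
)

validate_ids <- function(ids, field) {
  pattern <- ID_PATTERNS[[field]]
  if (is.null(pattern)) return(invisible(TRUE))
  bad <- ids[!stringr::str_detect(ids, pattern)]
  if (length(bad) > 0) {
    abort_format(sprintf("malformed %s value(s): %s", field,
                         paste(unique(head(bad, 5)), collapse = ", ")))
  }
  invisible(TRUE)
}
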
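#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy scored pair lists
#'
#' `tidy()` returns the pair table as a plain tibble with the applied
#' threshold as a column; `glance()` gives a one-row summary.
#'
#' @param x An `hyi_pairs` tibble.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.hyi_pairs <- function(x, ...) {
  mutate(as_tibble(x),
         threshold_applied = attr(x, "threshold_applied") %||% NA_real_)
}

#' @rdname tidy.hyi_pairs
#' @export
glance.hyi_pairs <- function(x, ...) {
  tibble(n_pairs = nrow(x),
         n_a = n_distinct(x$a_id),
         n_b = n_distinct(x$b_id),
         n_pop = if (nrow(x) > 0) x$n_pop[1] else NA_integer_,
         threshold_applied = attr(x, "threshold_applied") %||% NA_real_,
         median_hyi = if (nrow(x) > 0) stats::median(x$hyi) else NA_real_,
         max_hyi = if (nrow(x) > 0) max(x$hyi) else NA_real_)
}

#' Tidy a threshold sweep
#'
#' One row per threshold with pair, phenotype and drug counts - the shape
#' of the count-versus-threshold tables the method reports.
#'
#' @param x A `phenodrug_sweep` from [associate_drugs()].
#' @param ... Unused.
#' @return A tibble with columns `threshold`, `n_pairs`, `n_phenotypes`,
#'   `n_drugs`.
#' @export
tidy.phenodrug_sweep <- function(x, ...) {
  bind_rows(purrr::map(x$by_threshold, function(p) {
    tibble(threshold = attr(p, "threshold_applied"),
           n_pairs = nrow(p),
           n_phenotypes = n_distinct(p$a_id),
           n_drugs = n_distinct(p$b_id))
  }))
}

#' @rdname tidy.phenodrug_sweep
#' @export
glance.phenodrug_sweep <- function(x, ...) {
  tibble(n_thresholds = length(x$by_threshold),
         n_pairs_total = nrow(x$scores),
         n_pop = if (nrow(x$scores) > 0) x$scores$n_pop[1] else NA_integer_)
}

#' Tidy validation reports
#'
#' @param x A `validation_report` tibble.
#' @param ... Unused.
#' @return `tidy()`: the report as a plain tibble. `glance()`: one row with
#'   the best ratio.
#' @export
tidy.validation_report <- function(x, ...) as_tibble(x)

#' @rdname tidy.validation_report
#' @export
glance.validation_report <- function(x, ...) {
  finite <- x$ratio[is.finite(x$ratio)]
  tibble(n_rows = nrow(x),
         max_confirmed = max(x$confirmed),
         best_ratio = if (length(finite) > 0) max(finite) else NA_real_)
}
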
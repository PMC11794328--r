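#' @importFrom ggplot2 autoplot ggplot aes geom_histogram geom_vline
#'   geom_line geom_point geom_col geom_errorbar labs theme_minimal
#'   position_dodge
#' @export
ggplot2::autoplot

#' Plot the score distribution of a pair list
#'
#' Histogram of hypergeometric-index values, with the commonly swept
#' thresholds marked.
#'
#' @param object An `hyi_pairs` tibble.
#' @param thresholds Thresholds drawn as vertical reference lines.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.hyi_pairs <- function(object, thresholds = c(2, 3, 3.5), ...) {
  ggplot(as_tibble(object), aes(x = .data$hyi)) +
    geom_histogram(bins = 30, fill = "grey35") +
    geom_vline(xintercept = thresholds, linetype = "dashed",
               colour = "firebrick") +
    labs(x = "hypergeometric index (-log10 p)", y = "pairs") +
    theme_minimal()
}

#' Plot pair counts across thresholds
#'
#' The monotone count-versus-threshold curve of a tripartite sweep.
#'
#' @param object A `phenodrug_sweep`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.phenodrug_sweep <- function(object, ...) {
  counts <- tidy.phenodrug_sweep(object)
  ggplot(counts, aes(x = .data$threshold, y = .data$n_pairs)) +
    geom_line(colour = "grey40") +
    geom_point(size = 2) +
    labs(x = "hypergeometric index threshold", y = "phenotype-drug pairs") +
    theme_minimal()
}

#' Plot confirmed counts against the randomized null
#'
#' Bars for the confirmed pair count and the random-overlap mean (with
#' one-sd error bars), per threshold and validation source.
#'
#' @param object A `validation_report` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.validation_report <- function(object, ...) {
  long <- tidyr::pivot_longer(
    as_tibble(object), c("confirmed", "random_mean"),
    names_to = "kind", values_to = "count")
  long$sd <- ifelse(long$kind == "random_mean", long$random_sd, 0)
  if (!"source" %in% names(long)) long$source <- "gold"
  ggplot(long, aes(x = factor(.data$threshold), y = .data$count,
                   fill = .data$kind)) +
    geom_col(position = position_dodge(width = 0.9)) +
    geom_errorbar(aes(ymin = .data$count - .data$sd,
                      ymax = .data$count + .data$sd),
                  position = position_dodge(width = 0.9), width = 0.2) +
    ggplot2::facet_wrap(~source) +
    labs(x = "hypergeometric index threshold", y = "overlapping pairs",
         fill = NULL) +
    theme_minimal()
}
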
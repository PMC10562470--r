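# ggplot2 views of the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Conservation profile plot
#'
#' Per-column conservation along the alignment with the selected conserved
#' windows shaded; the classic picture of conserved stretches flanking
#' hypervariable regions.
#'
#' @param profiles Tibble from [column_profiles()].
#' @param windows Optional tibble from [find_conserved_windows()].
#' @param min_mean_cons Threshold line to draw (default 0.90).
#' @return A ggplot object.
#' @export
plot_conservation <- function(profiles, windows = NULL, min_mean_cons = 0.90) {
  p <- ggplot2::ggplot(profiles, ggplot2::aes(x = .data$col, y = .data$conservation)) +
    ggplot2::geom_line(color = "grey30") +
    ggplot2::geom_hline(yintercept = min_mean_cons, linetype = "dashed",
                        color = "firebrick") +
    ggplot2::labs(x = "alignment column", y = "conservation",
                  title = "Per-column conservation") +
    ggplot2::theme_minimal()
  if (!is.null(windows) && nrow(windows) > 0) {
    p <- p + ggplot2::geom_rect(
      data = windows, inherit.aes = FALSE,
      ggplot2::aes(xmin = .data$start, xmax = .data$end, ymin = 0, ymax = 1),
      fill = "steelblue", alpha = 0.2)
  }
  p
}

#' @rdname panel_coverage
#' @param object A `coverage_report`.
#' @export
autoplot.coverage_report <- function(object, ...) {
  ggplot2::ggplot(object$per_taxon,
                  ggplot2::aes(x = stats::reorder(.data$taxon, .data$coverage),
                               y = .data$coverage)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_flip() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = "fraction of sequences amplified",
                  title = sprintf("In-silico PCR coverage by %s", object$rank)) +
    ggplot2::theme_minimal()
}

#' @rdname abundance_table
#' @param object An `abundance_table`.
#' @export
autoplot.abundance_table <- function(object, ...) {
  ggplot2::ggplot(object$counts,
                  ggplot2::aes(x = stats::reorder(.data$taxon, .data$count),
                               y = .data$count)) +
    ggplot2::geom_col(fill = "darkseagreen4") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "reads",
                  title = sprintf("Read abundance at %s level (%d reads; %d unclassified)",
                                  object$rank, object$total_reads,
                                  object$n_unclassified)) +
    ggplot2::theme_minimal()
}

#' @rdname compare_classifiers
#' @param object An `agreement_report`.
#' @param ... Unused.
#' @export
autoplot.agreement_report <- function(object, ...) {
  df <- as_tibble(object)
  df$rank <- factor(df$rank, levels = tax_ranks())
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$agreement, group = 1)) +
    ggplot2::geom_line(color = "grey40") +
    ggplot2::geom_point(ggplot2::aes(size = .data$n_both_classified),
                        color = "steelblue") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = "agreement",
                  title = "Classifier agreement by taxonomic rank",
                  size = "reads compared") +
    ggplot2::theme_minimal()
}
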
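#' Hydropathy distribution of a fragment library
#'
#' @param fragments Fragment tibble (descriptors computed if missing).
#' @param binwidth Histogram bin width on the GRAVY axis (default 0.25).
#' @return A ggplot object.
#' @export
plot_hydropathy <- function(fragments, binwidth = 0.25) {
  if (!"gravy" %in% names(fragments)) {
    fragments <- fragment_descriptors(fragments)
  }
  ggplot2::ggplot(fragments, ggplot2::aes(x = .data$gravy,
                                          fill = .data$klass)) +
    ggplot2::geom_histogram(binwidth = binwidth, boundary = 0,
                            colour = "grey30", linewidth = 0.2) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::scale_fill_manual(values = c(hydrophilic = "#4477AA",
                                          hydrophobic = "#EE6677")) +
    ggplot2::labs(x = "GRAVY (Kyte-Doolittle)", y = "fragments",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' @describeIn aggregate_profiles Bar chart of the interaction-category
#'   partition of a dataset summary.
#' @param object A `pep_dataset_summary`.
#' @param ... Unused.
#' @export
autoplot.pep_dataset_summary <- function(object, ...) {
  cats <- object$categories
  cats$category <- factor(cats$category, levels = cats$category)
  ggplot2::ggplot(cats, ggplot2::aes(x = .data$category,
                                     y = .data$fraction)) +
    ggplot2::geom_col(fill = "#4477AA") +
    ggplot2::scale_y_continuous(labels = function(x) sprintf("%.0f%%", 100 * x)) +
    ggplot2::labs(x = NULL, y = "fraction of systems",
                  title = "Salt bridges and pi-pi stacking across systems") +
    ggplot2::theme_minimal()
}

#' @describeIn contribution_summary Mean binding contribution per
#'   amino-acid type, split by chain role.
#' @param object A `pep_contribution_summary`.
#' @param ... Unused.
#' @export
autoplot.pep_contribution_summary <- function(object, ...) {
  ggplot2::ggplot(object$by_residue,
                  ggplot2::aes(x = .data$res_name, y = .data$mean_dg,
                               fill = .data$chain_role)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_hline(yintercept = 0) +
    ggplot2::labs(x = NULL, y = "mean dG contribution (kcal/mol)",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
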
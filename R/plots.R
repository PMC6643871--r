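# ggplot2 views of the main result tables.

#' Stacked per-species class fractions
#'
#' @param classification output of [classify_genes()].
#' @return A ggplot.
#' @export
plot_class_fractions <- function(classification) {
  df <- classification |>
    dplyr::count(.data$species, .data$class) |>
    dplyr::group_by(.data$species) |>
    dplyr::mutate(frac = .data$n / sum(.data$n)) |>
    dplyr::ungroup()
  df$class <- factor(df$class, levels = c("SSOG", "TROG", "Conserved"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$species, y = .data$frac,
                                   fill = .data$class)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "fraction of genes", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Focal orphan counts per phylostratum
#'
#' @param classification output of [classify_genes()]; only focal rows with
#'   a phylostratum are used, conserved genes are excluded.
#' @return A ggplot.
#' @export
plot_phylostrata <- function(classification) {
  df <- classification[!is.na(classification$phylostratum) &
                         classification$class != "Conserved", ]
  df <- dplyr::count(df, .data$phylostratum)
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$phylostratum),
                                   y = .data$n)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "phylostratum (0 = species-specific)",
                  y = "orphan genes") +
    ggplot2::theme_minimal()
}

#' Trace-of-homology heatmap
#'
#' Gene-by-(species x database) grid of homology traces for the
#' species-specific orphans.
#'
#' @param traces output of [trace_homology()].
#' @return A ggplot.
#' @export
plot_trace_matrix <- function(traces) {
  cells <- traces$cells
  cells$col <- paste(cells$species, cells$db_kind, sep = "\n")
  ggplot2::ggplot(cells, ggplot2::aes(x = .data$col, y = .data$gene_id,
                                      fill = .data$hit)) +
    ggplot2::geom_tile(color = "grey80") +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#2166ac",
                                          `FALSE` = "#b2182b"),
                               na.value = "grey60") +
    ggplot2::labs(x = NULL, y = NULL, fill = "trace") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(size = 6),
                   axis.text.y = ggplot2::element_text(size = 6))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Per-branch omega estimates of a selection fit
#'
#' @param object an `omega_fit`.
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot omega_fit
#' @export
autoplot.omega_fit <- function(object, ...) {
  assert_that(object$status == "ok", "no estimates: insufficient data")
  df <- object$omega
  ggplot2::ggplot(df, ggplot2::aes(x = .data$branch, y = .data$omega)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::labs(x = "branch", y = expression(omega)) +
    ggplot2::theme_minimal()
}
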
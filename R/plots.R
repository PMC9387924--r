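# ggplot2 figures for each result type.

#' Per-cell segmentation plot
#'
#' Corrected bin counts along the genome with the decoded copy-number path
#' overlaid -- the standard per-cell view of a single-cell CNV profile.
#'
#' @param states A `cnv_states` tibble from [infer_copy_number()].
#' @param cell_id The cell to plot.
#' @return A ggplot object.
#' @export
plot_segmentation <- function(states, cell_id) {
  df <- states[states$cell_id == cell_id & !states$masked, , drop = FALSE]
  if (!nrow(df)) stop("no unmasked bins for cell ", cell_id)
  df$chrom <- factor(df$chrom, levels = unique(df$chrom))
  df$idx <- seq_len(nrow(df))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$idx)) +
    ggplot2::geom_point(ggplot2::aes(y = 2 * .data$corrected),
                        size = 0.3, alpha = 0.4, colour = "grey40") +
    ggplot2::geom_step(ggplot2::aes(y = .data$state), colour = "firebrick",
                       linewidth = 0.6, na.rm = TRUE) +
    ggplot2::facet_grid(. ~ chrom, scales = "free_x", space = "free_x") +
    ggplot2::coord_cartesian(ylim = c(0, 5)) +
    ggplot2::labs(x = NULL, y = "copy number", title = cell_id) +
    ggplot2::theme_minimal(base_size = 9) +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   panel.spacing.x = ggplot2::unit(0, "pt"),
                   strip.text.x = ggplot2::element_text(angle = 90, size = 6))
}

#' @export
autoplot.cnv_states <- function(object, cell_id = unique(object$cell_id)[1], ...) {
  plot_segmentation(object, cell_id)
}

#' Variability-score distribution
#'
#' Density of VS with retained/excluded cells distinguished, mirroring the
#' usual QC view of a single-cell batch.
#'
#' @param scores A `vs_scores` tibble with a `retained` column (from
#'   [filter_cells()]), or any tibble with `vs` and `retained`.
#' @return A ggplot object.
#' @export
plot_vs_distribution <- function(scores) {
  stopifnot(all(c("vs", "retained") %in% names(scores)))
  df <- dplyr::mutate(scores,
                      set = ifelse(.data$retained, "analyzed", "excluded"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$vs, fill = .data$set)) +
    ggplot2::geom_histogram(bins = 40, alpha = 0.7, position = "identity") +
    ggplot2::labs(x = "variability score (VS)", y = "cells", fill = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.vs_scores <- function(object, ...) {
  if (!"retained" %in% names(object)) object$retained <- TRUE
  plot_vs_distribution(object)
}

#' Mosaicism incidence bar chart
#'
#' @param incidence A tibble from [cohort_incidence()].
#' @return A ggplot object.
#' @export
plot_incidence <- function(incidence) {
  ggplot2::ggplot(incidence,
                  ggplot2::aes(x = .data$lineage, y = .data$pct)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%d/%d", .data$n_mosaic,
                                                    .data$n_evaluable)),
                       vjust = -0.4, size = 3) +
    ggplot2::labs(x = NULL, y = "mosaic embryos (%)") +
    ggplot2::ylim(0, 100) +
    ggplot2::theme_minimal()
}

#' Mosaic-subtype bar chart
#'
#' @param types A tibble from [mosaic_type_distribution()].
#' @return A ggplot object.
#' @export
plot_mosaic_types <- function(types) {
  ggplot2::ggplot(types, ggplot2::aes(x = .data$lineage, y = .data$pct,
                                      fill = .data$subtype)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::labs(x = NULL, y = "share of mosaic embryos (%)", fill = NULL) +
    ggplot2::theme_minimal()
}
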
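# broom-style tidiers and print methods.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy an embryo classification
#'
#' One row per embryo x lineage, without the list-column of major-karyotype
#' calls.
#'
#' @param x An `embryo_classification` from [classify_embryos()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.embryo_classification <- function(x, ...) {
  tibble::as_tibble(dplyr::select(x, -"major_karyotype"))
}

#' One-row cohort summary of an embryo classification
#'
#' @param x An `embryo_classification` from [classify_embryos()].
#' @param ... Unused.
#' @return A one-row tibble: numbers of lineage sets, evaluable sets, mosaic
#'   sets, overall incidence and mean mosaic rate.
#' @export
glance.embryo_classification <- function(x, ...) {
  ev <- x[x$evaluable, , drop = FALSE]
  tibble::tibble(
    n_sets = nrow(x),
    n_evaluable = nrow(ev),
    n_mosaic = sum(ev$status == "mosaic"),
    incidence = ifelse(nrow(ev) > 0, sum(ev$status == "mosaic") / nrow(ev), NA_real_),
    mean_mosaic_rate = mean(ev$mosaic_rate, na.rm = TRUE)
  )
}

#' Tidy an origin classification
#'
#' @param x An `origin_classification` from [classify_origin()]; the tidied
#'   form is the per-event table (one row per clustered CNV event).
#' @param ... Unused.
#' @return A tibble of clustered events with origin labels.
#' @export
tidy.origin_classification <- function(x, ...) {
  ev <- attr(x, "events")
  if (is.null(ev)) tibble::tibble() else tibble::as_tibble(ev)
}

#' One-row summary of an origin classification
#'
#' @param x An `origin_classification` from [classify_origin()].
#' @param ... Unused.
#' @return A one-row tibble with embryo counts per origin label and the
#'   distribution among aneuploid embryos (percentages).
#' @export
glance.origin_classification <- function(x, ...) {
  cl <- x$origin[x$origin != "insufficient_cells"]
  n_aneu <- sum(cl != "euploid")
  tibble::tibble(
    n_embryos = length(cl),
    n_euploid = sum(cl == "euploid"),
    n_meiotic_only = sum(cl == "meiotic_only"),
    n_mitotic_only = sum(cl == "mitotic_only"),
    n_both = sum(cl == "both"),
    pct_meiotic_only = round(100 * sum(cl == "meiotic_only") / n_aneu, 2),
    pct_mitotic_only = round(100 * sum(cl == "mitotic_only") / n_aneu, 2),
    pct_both = round(100 * sum(cl == "both") / n_aneu, 2)
  )
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf("<sim_truth> %d cells x %d bins, %d planted event(s)\n",
              nrow(x$cell_truth), ncol(x$cell_truth), nrow(x$events)))
  invisible(x)
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat(sprintf("<sim_cohort> %d embryos, %d cells, %d bins (seed %s)\n",
              length(x$truth), nrow(x$metadata), nrow(x$grid), format(x$seed)))
  invisible(x)
}

#' @export
print.run_config <- function(x, ...) {
  cat(sprintf("<run_config> hash %s\n", attr(x, "hash")))
  utils::str(unclass(x), give.attr = FALSE)
  invisible(x)
}
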
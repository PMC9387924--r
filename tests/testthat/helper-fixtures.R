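# Shared fixture builders: small grids, deterministic counts, hand-made
# truth objects. Everything is generated in code at test time.

tiny_grid <- function(n_chrom = 3, n_bins = 20, bin_width = 1e6) {
  pieces <- lapply(seq_len(n_chrom), function(i) {
    starts <- (seq_len(n_bins) - 1) * bin_width
    tibble::tibble(chrom = paste0("chr", i), start = starts, end = starts + bin_width)
  })
  embryomosaic::bin_grid(
    chrom = unlist(lapply(pieces, `[[`, "chrom")),
    start = unlist(lapply(pieces, `[[`, "start")),
    end = unlist(lapply(pieces, `[[`, "end"))
  )
}

flat_tracks <- function(grid, gc = 0.41, mappability = 1) {
  dplyr::bind_cols(grid[, c("chrom", "start", "end")],
                   tibble::tibble(gc = rep(gc, nrow(grid)),
                                  mappability = rep(mappability, nrow(grid))))
}

# Deterministic, noiseless counts from an integer copy-number matrix
# (cells x bins): count = round(copy/2 * depth).
counts_from_cn <- function(cn, grid, depth = 1000) {
  stopifnot(ncol(cn) == nrow(grid))
  cols <- lapply(seq_len(nrow(cn)), function(i) as.integer(round(cn[i, ] / 2 * depth)))
  names(cols) <- rownames(cn) %||% paste0("cell", seq_len(nrow(cn)))
  dplyr::bind_cols(grid[, c("chrom", "start", "end")], tibble::as_tibble(cols))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Minimal sim_truth wrapper around a hand-made copy-number matrix.
manual_truth <- function(cn, grid, sex = "XX") {
  structure(list(events = tibble::tibble(), cell_truth = cn,
                 cells = tibble::tibble(cell_id = rownames(cn),
                                        embryo_id = "E01",
                                        lineage = rep("TE", nrow(cn))),
                 grid = grid, baseline = rep(2L, nrow(grid)), sex = sex),
            class = "sim_truth")
}

# Long profile tibble straight from a corrected matrix (cells x bins),
# bypassing count emission -- used by the VS tests.
profiles_from_matrix <- function(m, grid) {
  stopifnot(ncol(m) == nrow(grid))
  cells <- rownames(m) %||% paste0("cell", seq_len(nrow(m)))
  out <- dplyr::bind_rows(lapply(seq_len(nrow(m)), function(i) {
    tibble::tibble(cell_id = cells[i], chrom = grid$chrom,
                   start = grid$start, end = grid$end,
                   gc = 0.41, raw = NA_real_, corrected = m[i, ], masked = FALSE)
  }))
  attr(out, "cell_status") <- tibble::tibble(cell_id = cells, analyzable = TRUE,
                                             note = "")
  class(out) <- unique(c("cnv_profiles", class(out)))
  out
}

# One-call karyotype tibbles for equality/classification tests.
k_whole <- function(chrom, delta, cell_id = NULL) {
  len <- c(chr1 = 249, chr2 = 243, chr16 = 90, chr21 = 48)[chrom]
  len <- ifelse(is.na(len), 100, len) * 1e6
  k <- tibble::tibble(chrom = chrom, start = 0, end = len,
                      delta = as.integer(delta), class = "whole", length_bp = len)
  if (!is.null(cell_id)) k <- dplyr::mutate(k, cell_id = cell_id, .before = 1)
  k
}

k_seg <- function(chrom, start_mb, end_mb, delta, cell_id = NULL) {
  k <- tibble::tibble(chrom = chrom, start = start_mb * 1e6, end = end_mb * 1e6,
                      delta = as.integer(delta), class = "segmental",
                      length_bp = (end_mb - start_mb) * 1e6)
  if (!is.null(cell_id)) k <- dplyr::mutate(k, cell_id = cell_id, .before = 1)
  k
}

# Assemble a karyotype_calls object from per-cell call tibbles.
calls_object <- function(..., cells = NULL) {
  template <- tibble::tibble(cell_id = character(), chrom = character(),
                             start = numeric(), end = numeric(),
                             delta = integer(), class = character(),
                             length_bp = numeric())
  parts <- list(...)
  calls <- dplyr::bind_rows(template, parts)
  if (is.null(cells)) cells <- unique(calls$cell_id)
  attr(calls, "cells") <- cells
  attr(calls, "sex") <- "XX"
  class(calls) <- unique(c("karyotype_calls", class(calls)))
  calls
}
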
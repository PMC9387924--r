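# Per-cell QC: windowed variability score (VS) and batch-relative exclusion
# of the most variable cells before any mosaicism analysis.

# Window starts for covering n bins with exactly n_windows equal-length
# windows: evenly spaced starts, overlapping when necessary, disjoint when
# n is a multiple of the window length.
.vs_windows <- function(n, n_windows) {
  if (n < n_windows) {
    return(list(starts = seq_len(n), len = 1L, degenerate = TRUE))
  }
  len <- ceiling(n / n_windows)
  starts <- floor(seq(0, n - len, length.out = n_windows)) + 1L
  list(starts = as.integer(starts), len = as.integer(len), degenerate = FALSE)
}

#' Per-cell variability score
#'
#' For each chromosome of each cell, the corrected counts are covered by
#' `n_windows` sliding windows (equal length, evenly spaced starts); the
#' sample SD is computed within each window and the `n_windows` SDs are
#' averaged. The variability score (VS) of the cell is the mean of the five
#' largest per-chromosome averages -- a scale-equivariant summary of
#' amplification noise that is 0 iff the profile is constant within every
#' window. Chromosomes with fewer unmasked bins than `n_windows` fall back to
#' one-bin windows (SD 0) and are flagged.
#'
#' @param profiles A `cnv_profiles` tibble from [correct_counts()] (columns
#'   `cell_id`, `chrom`, `corrected`, `masked`).
#' @param n_windows Number of windows per chromosome (default 30).
#' @param n_top Number of top chromosomes averaged into the VS (default 5).
#' @return A tibble of class `vs_scores`: `cell_id`, `vs`, and a list-column
#'   `chrom_sd` of named per-chromosome windowed-SD averages.
#' @export
variability_score <- function(profiles, n_windows = 30, n_top = 5) {
  stopifnot(all(c("cell_id", "chrom", "corrected", "masked") %in% names(profiles)))
  cells <- unique(profiles$cell_id)
  res <- vector("list", length(cells))
  for (i in seq_along(cells)) {
    rows <- profiles$cell_id == cells[i]
    x_all <- profiles$corrected[rows]
    ch_all <- profiles$chrom[rows]
    keep <- !profiles$masked[rows] & !is.na(x_all)
    chroms <- unique(ch_all)
    avg <- vapply(chroms, function(ch) {
      x <- x_all[keep & ch_all == ch]
      n <- length(x)
      if (n < 2) return(NA_real_)
      w <- .vs_windows(n, n_windows)
      sds <- vapply(w$starts, function(s) {
        win <- x[s:min(s + w$len - 1L, n)]
        if (length(win) < 2) 0 else stats::sd(win)
      }, numeric(1))
      mean(sds)
    }, numeric(1))
    avg <- avg[!is.na(avg)]
    if (length(avg) < n_top) {
      stop(sprintf("cell '%s': only %d analyzable chromosome(s); cannot form top-%d VS",
                   cells[i], length(avg), n_top))
    }
    vs <- mean(sort(avg, decreasing = TRUE)[seq_len(n_top)])
    res[[i]] <- tibble::tibble(cell_id = cells[i], vs = vs,
                               chrom_sd = list(avg))
  }
  out <- dplyr::bind_rows(res)
  class(out) <- unique(c("vs_scores", class(out)))
  out
}

#' Exclude the most variable cells of a batch
#'
#' Cohort-relative filtering: exactly `floor(n * exclude_fraction)` cells with
#' the highest VS are excluded (515 cells at the default 15% give 77 excluded
#' and 438 retained). Ties at the boundary are broken by stable input order,
#' with a warning. An absolute-threshold mode (`vs_cutoff`) is provided for
#' reuse outside batch settings.
#'
#' @param scores A `vs_scores` tibble from [variability_score()] (or any
#'   tibble with `cell_id` and `vs`).
#' @param exclude_fraction Fraction of the batch to exclude, in `[0, 1)`.
#' @param vs_cutoff Optional absolute VS threshold; when given, cells with
#'   `vs > vs_cutoff` are excluded instead of the batch percentile.
#' @return The input tibble with a logical `retained` column added.
#' @export
filter_cells <- function(scores, exclude_fraction = 0.15, vs_cutoff = NULL) {
  stopifnot(nrow(scores) >= 1, all(c("cell_id", "vs") %in% names(scores)))
  if (!is.null(vs_cutoff)) {
    scores$retained <- scores$vs <= vs_cutoff
    return(scores)
  }
  if (exclude_fraction < 0 || exclude_fraction >= 1) {
    stop("exclude_fraction must be in [0, 1)")
  }
  n <- nrow(scores)
  n_excl <- floor(n * exclude_fraction)
  retained <- rep(TRUE, n)
  if (n_excl > 0) {
    ord <- order(-scores$vs, seq_len(n))  # stable: ties broken by input order
    excl <- ord[seq_len(n_excl)]
    boundary <- scores$vs[ord[n_excl]]
    if (n_excl < n && any(scores$vs[ord[(n_excl + 1):n]] == boundary)) {
      warning("VS ties at the exclusion boundary broken by input order")
    }
    retained[excl] <- FALSE
  }
  scores$retained <- retained
  scores
}
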
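# Coordinate frame: ordered fixed-width genomic bins shared by all counts.

# Approximate GRCh37 chromosome lengths in Mb, used for the default grid.
.chrom_lengths_mb <- c(
  chr1 = 249, chr2 = 243, chr3 = 198, chr4 = 191, chr5 = 181, chr6 = 171,
  chr7 = 159, chr8 = 146, chr9 = 141, chr10 = 136, chr11 = 135, chr12 = 134,
  chr13 = 115, chr14 = 107, chr15 = 103, chr16 = 90, chr17 = 81, chr18 = 78,
  chr19 = 59, chr20 = 63, chr21 = 48, chr22 = 51, chrX = 155, chrY = 59
)

.autosomes <- paste0("chr", 1:22)

#' Construct and validate a bin grid
#'
#' A bin grid is the coordinate frame every other object in the package is
#' aligned to: an ordered tibble of genomic bins with 0-based half-open
#' `[start, end)` coordinates. Within each chromosome bins must be sorted,
#' non-overlapping and contiguous, and all bins share a fixed width except the
#' terminal bin of each chromosome, which may be shorter.
#'
#' @param chrom Character vector of chromosome labels.
#' @param start,end Integer vectors of bin boundaries in bp (0-based,
#'   half-open).
#' @return A tibble with class `bin_grid` and columns `chrom`, `start`, `end`.
#' @examples
#' bin_grid(c("chr1", "chr1"), c(0, 1e6), c(1e6, 2e6))
#' @export
bin_grid <- function(chrom, start, end) {
  grid <- tibble::tibble(
    chrom = as.character(chrom),
    start = as.numeric(start),
    end = as.numeric(end)
  )
  validate_bin_grid(grid)
}

validate_bin_grid <- function(grid) {
  stopifnot(all(c("chrom", "start", "end") %in% names(grid)))
  if (nrow(grid) == 0L) stop("bin grid is empty")
  bad <- which(grid$end <= grid$start)
  if (length(bad)) {
    stop(sprintf("bin grid line %d: end <= start (%s:%d-%d)",
                 bad[1], grid$chrom[bad[1]], grid$start[bad[1]], grid$end[bad[1]]))
  }
  for (ch in unique(grid$chrom)) {
    idx <- which(grid$chrom == ch)
    s <- grid$start[idx]; e <- grid$end[idx]
    if (is.unsorted(s, strictly = TRUE)) {
      stop(sprintf("bin grid: bins on %s are not sorted (line %d)",
                   ch, idx[which(diff(s) <= 0)[1] + 1L]))
    }
    ov <- which(s[-1] < e[-length(e)])
    if (length(ov)) {
      stop(sprintf("bin grid: overlapping bins on %s at line %d (%s:%d-%d overlaps %s:%d-%d)",
                   ch, idx[ov[1] + 1L], ch, s[ov[1]], e[ov[1]], ch, s[ov[1] + 1L], e[ov[1] + 1L]))
    }
    gap <- which(s[-1] > e[-length(e)])
    if (length(gap)) {
      stop(sprintf("bin grid: gap between bins on %s at line %d", ch, idx[gap[1] + 1L]))
    }
    w <- e - s
    if (length(w) > 1 && length(unique(w[-length(w)])) > 1) {
      stop(sprintf("bin grid: non-constant bin width on %s", ch))
    }
  }
  class(grid) <- unique(c("bin_grid", class(tibble::tibble())))
  grid
}

#' Default human-like 1 Mb bin grid
#'
#' Builds the grid used throughout the package: fixed-width bins tiling a
#' human-like genome (approximate GRCh37 chromosome lengths). For an XX
#' baseline (the default) chrY is omitted.
#'
#' @param bin_width Bin width in bp (default 1 Mb).
#' @param sex `"XX"` (no chrY) or `"XY"`.
#' @param chroms Optional subset of chromosome labels, e.g. `c("chr1","chr21")`;
#'   useful for small examples and tests.
#' @return A `bin_grid` tibble.
#' @export
default_bin_grid <- function(bin_width = 1e6, sex = c("XX", "XY"), chroms = NULL) {
  sex <- match.arg(sex)
  lens <- .chrom_lengths_mb * 1e6
  if (sex == "XX") lens <- lens[names(lens) != "chrY"]
  if (!is.null(chroms)) {
    missing <- setdiff(chroms, names(lens))
    if (length(missing)) stop("unknown chromosome(s): ", paste(missing, collapse = ", "))
    lens <- lens[chroms]
  }
  pieces <- purrr::imap(lens, function(len, ch) {
    starts <- seq(0, len - 1, by = bin_width)
    tibble::tibble(chrom = ch, start = starts, end = pmin(starts + bin_width, len))
  })
  validate_bin_grid(dplyr::bind_rows(pieces))
}

strip_readr_attrs <- function(x) {
  attr(x, "spec") <- NULL
  attr(x, "problems") <- NULL
  x
}

bin_key <- function(grid) {
  sprintf("%s:%d-%d", grid$chrom, as.integer(grid$start), as.integer(grid$end))
}

#' Read / write a bin grid as BED
#'
#' The grid is stored as 3-column BED (chrom, start, end), tab-separated,
#' no header. `read_bin_grid(write_bin_grid(g, f))` returns records identical
#' to `g`.
#'
#' @param path File path.
#' @param grid A `bin_grid`.
#' @return `read_bin_grid` returns a validated `bin_grid`;
#'   `write_bin_grid` returns `path` invisibly.
#' @export
read_bin_grid <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- strip_readr_attrs(readr::read_tsv(path, col_names = c("chrom", "start", "end"),
                                           col_types = "cdd", progress = FALSE))
  validate_bin_grid(raw)
}

#' @rdname read_bin_grid
#' @export
write_bin_grid <- function(grid, path) {
  validate_bin_grid(grid)
  readr::write_tsv(grid[, c("chrom", "start", "end")], path, col_names = FALSE)
  invisible(path)
}

#' Read / write per-bin reference tracks (GC, mappability)
#'
#' Tracks are stored as TSV with header `bin`, `gc`, `mappability`, where
#' `bin` is the `chrom:start-end` key of the grid row. Values must lie in
#' [0, 1] or be `NA` (flagged missing).
#'
#' @param path File path.
#' @param grid The `bin_grid` the tracks must align to, row for row.
#' @param tracks A tibble with columns `chrom`, `start`, `end`, `gc`,
#'   `mappability` aligned to a grid.
#' @return `read_tracks` returns a tibble aligned 1:1 with `grid`.
#' @export
read_tracks <- function(path, grid) {
  if (!file.exists(path)) stop("no such file: ", path)
  grid <- validate_bin_grid(grid)
  tab <- readr::read_tsv(path, col_types = readr::cols(
    bin = readr::col_character(),
    gc = readr::col_double(),
    mappability = readr::col_double()
  ), progress = FALSE)
  keys <- bin_key(grid)
  if (nrow(tab) != length(keys)) {
    stop(sprintf("track file has %d rows but grid has %d bins", nrow(tab), length(keys)))
  }
  mism <- which(tab$bin != keys)
  if (length(mism)) {
    stop(sprintf("track row %d: bin key '%s' does not match grid bin '%s'",
                 mism[1], tab$bin[mism[1]], keys[mism[1]]))
  }
  for (col in c("gc", "mappability")) {
    v <- tab[[col]]
    bad <- which(!is.na(v) & (v < 0 | v > 1))
    if (length(bad)) stop(sprintf("track row %d: %s = %g outside [0, 1]", bad[1], col, v[bad[1]]))
  }
  dplyr::bind_cols(grid[, c("chrom", "start", "end")],
                   tab[, c("gc", "mappability")])
}

#' @rdname read_tracks
#' @export
write_tracks <- function(tracks, path) {
  stopifnot(all(c("chrom", "start", "end", "gc", "mappability") %in% names(tracks)))
  out <- tibble::tibble(bin = sprintf("%s:%d-%d", tracks$chrom,
                                      as.integer(tracks$start), as.integer(tracks$end)),
                        gc = tracks$gc, mappability = tracks$mappability)
  readr::write_tsv(out, path)
  invisible(path)
}

#' Read / write a count matrix
#'
#' Counts are stored as TSV with one row per bin and one column per cell; the
#' first column, `bin`, holds the `chrom:start-end` key. All counts must be
#' non-negative integers; validation errors name the offending row and column.
#'
#' @param path File path.
#' @param grid The `bin_grid` the counts must align to.
#' @param counts A wide counts tibble (columns `chrom`, `start`, `end`, then
#'   one integer column per cell).
#' @return `read_counts` returns a wide counts tibble: `chrom`, `start`,
#'   `end`, then one column per cell.
#' @export
read_counts <- function(path, grid) {
  if (!file.exists(path)) stop("no such file: ", path)
  grid <- validate_bin_grid(grid)
  tab <- readr::read_tsv(path, col_types = readr::cols(
    bin = readr::col_character(), .default = readr::col_double()
  ), progress = FALSE)
  keys <- bin_key(grid)
  if (nrow(tab) != length(keys)) {
    stop(sprintf("count file has %d rows but grid has %d bins", nrow(tab), length(keys)))
  }
  mism <- which(tab$bin != keys)
  if (length(mism)) {
    stop(sprintf("count row %d: bin key '%s' does not match grid bin '%s'",
                 mism[1], tab$bin[mism[1]], keys[mism[1]]))
  }
  cells <- setdiff(names(tab), "bin")
  if (!length(cells)) stop("count file has no cell columns")
  for (cell in cells) {
    v <- tab[[cell]]
    bad <- which(is.na(v) | v < 0 | v != floor(v))
    if (length(bad)) {
      stop(sprintf("count row %d, cell '%s': invalid count %s",
                   bad[1], cell, format(v[bad[1]])))
    }
  }
  dplyr::bind_cols(grid[, c("chrom", "start", "end")], tab[, cells])
}

#' @rdname read_counts
#' @export
write_counts <- function(counts, path) {
  stopifnot(all(c("chrom", "start", "end") %in% names(counts)))
  cells <- setdiff(names(counts), c("chrom", "start", "end"))
  out <- dplyr::bind_cols(
    tibble::tibble(bin = sprintf("%s:%d-%d", counts$chrom,
                                 as.integer(counts$start), as.integer(counts$end))),
    counts[, cells]
  )
  readr::write_tsv(out, path)
  invisible(path)
}

#' Read / write cell metadata
#'
#' Metadata is a TSV with header `cell_id`, `embryo_id`, `lineage`; lineage
#' must be one of TE, ICM, hESC.
#'
#' @param path File path.
#' @param metadata A tibble with columns `cell_id`, `embryo_id`, `lineage`.
#' @return `read_cell_metadata` returns the validated metadata tibble.
#' @export
read_cell_metadata <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- strip_readr_attrs(readr::read_tsv(path, col_types = "ccc", progress = FALSE))
  stopifnot(all(c("cell_id", "embryo_id", "lineage") %in% names(tab)))
  bad <- which(!tab$lineage %in% c("TE", "ICM", "hESC"))
  if (length(bad)) {
    stop(sprintf("metadata row %d: unknown lineage '%s'", bad[1], tab$lineage[bad[1]]))
  }
  if (anyDuplicated(tab$cell_id)) stop("duplicated cell_id in metadata")
  tab
}

#' @rdname read_cell_metadata
#' @export
write_cell_metadata <- function(metadata, path) {
  stopifnot(all(c("cell_id", "embryo_id", "lineage") %in% names(metadata)))
  readr::write_tsv(metadata[, c("cell_id", "embryo_id", "lineage")], path)
  invisible(path)
}

#' Count alignments per bin for one cell
#'
#' Bins retained alignments from a SAM/BAM file onto a bin grid. Following the
#' usual single-cell CNV convention, an alignment is retained if it is a
#' primary, mapped, non-duplicate record with mapping quality at least
#' `min_mapq` (the proxy for "uniquely mapped"), and it increments exactly one
#' bin, chosen by its leftmost aligned position. Records on contigs absent
#' from the grid are skipped and counted in the `skipped_contigs` attribute.
#'
#' @param path Path to a SAM or BAM file (coordinate order not required for
#'   counting; every record is streamed).
#' @param grid A `bin_grid`.
#' @param min_mapq Minimum mapping quality (default 30).
#' @return A tibble `chrom`, `start`, `end`, `count` aligned to `grid`, with
#'   attributes `n_retained` (equals `sum(count)`) and `skipped_contigs`.
#' @export
count_reads_from_alignments <- function(path, grid, min_mapq = 30) {
  if (!requireNamespace("Rsamtools", quietly = TRUE)) {
    stop("Rsamtools is required to read alignment files")
  }
  grid <- validate_bin_grid(grid)
  if (!file.exists(path)) stop("no such file: ", path)
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE, indexDestination = FALSE)
  }
  flags <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE, isDuplicate = FALSE,
                                  isSecondaryAlignment = FALSE, isSupplementaryAlignment = FALSE)
  param <- Rsamtools::ScanBamParam(flag = flags, what = c("rname", "pos", "mapq"))
  rec <- Rsamtools::scanBam(bam, param = param)[[1]]
  keep <- !is.na(rec$pos) & !is.na(rec$mapq) & rec$mapq >= min_mapq
  chrom <- as.character(rec$rname)[keep]
  pos0 <- rec$pos[keep] - 1L  # SAM is 1-based; grid is 0-based half-open

  known <- chrom %in% unique(grid$chrom)
  skipped <- sum(!known)
  if (skipped > 0) {
    warning(sprintf("%d alignment(s) on contigs absent from the grid were skipped", skipped))
  }
  chrom <- chrom[known]; pos0 <- pos0[known]

  counts <- integer(nrow(grid))
  for (ch in unique(chrom)) {
    idx <- which(grid$chrom == ch)
    p <- pos0[chrom == ch]
    in_range <- p >= grid$start[idx[1]] & p < grid$end[idx[length(idx)]]
    p <- p[in_range]
    if (!length(p)) next
    b <- findInterval(p, grid$start[idx])
    tab <- tabulate(b, nbins = length(idx))
    counts[idx] <- counts[idx] + tab
  }
  out <- dplyr::bind_cols(grid[, c("chrom", "start", "end")],
                          tibble::tibble(count = counts))
  attr(out, "n_retained") <- sum(counts)
  attr(out, "skipped_contigs") <- skipped
  out
}
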
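# Copy-number inference: GC/mappability correction of binned counts, 6-state
# Viterbi HMM over each chromosome, run-length segmentation, and >=10 Mb CNV
# calls relative to the euploid baseline.

#' Correct bin counts for GC content and mappability
#'
#' Fits a robust smooth curve of count versus GC fraction on unmasked
#' autosomal bins (loess, falling back to a binned-median curve when too few
#' bins are available), divides counts by the fitted GC rate and by bin
#' mappability, and rescales each cell so the median over unmasked autosomal
#' bins is 1 -- the baseline-ploidy anchor every downstream stage assumes.
#' Bins with mappability below `min_mappability` or missing GC are masked.
#' Cells with too few informative bins (or all-zero counts) are flagged
#' unanalyzable rather than raising an error, so batch runs proceed.
#'
#' @param counts Wide counts tibble (`chrom`, `start`, `end`, one column per
#'   cell), e.g. from [read_counts()] or [simulate_cohort()].
#' @param tracks Per-bin GC/mappability tracks aligned to the same grid.
#' @param min_mappability Bins below this mappability are masked
#'   (default 0.8).
#' @param gc_span Loess span for the GC curve.
#' @param min_fit_bins Minimum unmasked, non-zero autosomal bins for the
#'   loess fit; below it a 10-bin median curve is used, and below 20 bins the
#'   cell is unanalyzable.
#' @return A long tibble of class `cnv_profiles` with columns `cell_id`,
#'   `chrom`, `start`, `end`, `gc`, `raw`, `corrected`, `masked`, and an
#'   attribute `cell_status` (tibble: cell_id, analyzable, note).
#' @export
correct_counts <- function(counts, tracks, min_mappability = 0.8,
                           gc_span = 0.3, min_fit_bins = 100) {
  stopifnot(all(c("chrom", "start", "end") %in% names(counts)),
            all(c("gc", "mappability") %in% names(tracks)))
  if (nrow(counts) != nrow(tracks)) {
    stop(sprintf("counts have %d bins but tracks have %d", nrow(counts), nrow(tracks)))
  }
  cells <- setdiff(names(counts), c("chrom", "start", "end"))
  gc <- tracks$gc
  mapp <- tracks$mappability
  base_mask <- is.na(gc) | is.na(mapp) | mapp < min_mappability
  autosomal <- counts$chrom %in% .autosomes

  status <- vector("list", length(cells))
  profs <- vector("list", length(cells))
  for (i in seq_along(cells)) {
    raw <- counts[[cells[i]]]
    fit_idx <- which(!base_mask & autosomal & raw > 0)
    corrected <- rep(NA_real_, length(raw))
    analyzable <- TRUE
    note <- ""
    if (length(fit_idx) < 20) {
      analyzable <- FALSE
      note <- "too few informative bins"
    } else {
      pred <- .gc_curve(raw, gc, fit_idx, gc_span, min_fit_bins)
      corrected <- raw / pmax(pred, 1e-8) / ifelse(base_mask, NA, mapp)
      med <- stats::median(corrected[!base_mask & autosomal], na.rm = TRUE)
      if (!is.finite(med) || med <= 0) {
        analyzable <- FALSE
        note <- "degenerate normalization"
        corrected <- rep(NA_real_, length(raw))
      } else {
        corrected <- corrected / med
      }
    }
    corrected[base_mask] <- NA_real_
    profs[[i]] <- tibble::tibble(
      cell_id = cells[i],
      chrom = counts$chrom, start = counts$start, end = counts$end,
      gc = gc, raw = raw, corrected = corrected, masked = base_mask
    )
    status[[i]] <- tibble::tibble(cell_id = cells[i], analyzable = analyzable, note = note)
  }
  out <- dplyr::bind_rows(profs)
  attr(out, "cell_status") <- dplyr::bind_rows(status)
  class(out) <- unique(c("cnv_profiles", class(out)))
  out
}

# Fitted expected count as a function of GC, evaluated at every bin.
.gc_curve <- function(raw, gc, fit_idx, gc_span, min_fit_bins) {
  # (near-)constant GC carries no bias information: plain median scaling
  if (length(unique(round(gc[fit_idx], 4))) < 5) {
    return(rep(stats::median(raw[fit_idx]), length(gc)))
  }
  if (length(fit_idx) >= min_fit_bins) {
    gcf <- gc[fit_idx]
    fit <- try(suppressWarnings(
      stats::loess(raw[fit_idx] ~ gcf, span = gc_span,
                   degree = 2, family = "symmetric")),
               silent = TRUE)
    if (!inherits(fit, "try-error")) {
      # clamp into the fitted GC range: loess does not extrapolate
      gc_new <- pmin(pmax(gc, min(gcf)), max(gcf))
      pred <- stats::predict(fit, newdata = data.frame(gcf = gc_new))
      ok <- is.finite(pred) & pred > 0
      if (mean(ok) > 0.5) {
        pred[!ok] <- stats::median(raw[fit_idx])
        return(pred)
      }
    }
  }
  # binned-median fallback: 10 equal-occupancy GC bins
  br <- unique(stats::quantile(gc[fit_idx], probs = seq(0, 1, length.out = 11), na.rm = TRUE))
  if (length(br) < 3) return(rep(stats::median(raw[fit_idx]), length(gc)))
  grp <- cut(gc, breaks = br, include.lowest = TRUE)
  med <- tapply(raw[fit_idx], grp[fit_idx], stats::median)
  pred <- med[as.character(grp)]
  pred[is.na(pred)] <- stats::median(raw[fit_idx])
  as.numeric(pred)
}

#' HMM parameters for copy-number decoding
#'
#' Six integer states 0-5 with Gaussian emissions centred at `state / 2` on
#' the corrected-count scale (state 0 uses a small positive floor for residual
#' background signal). The per-cell emission SD is estimated robustly from
#' first differences of the corrected profile; `self_transition` is the single
#' knob controlling segmentation granularity -- the default makes events
#' shorter than about 5 bins unlikely to be called, consistent with reporting
#' only CNVs of at least 10 Mb on a 1 Mb grid.
#'
#' Emissions are a robust mixture: with probability `1 - outlier_prob` the
#' corrected value is Gaussian around the state mean, otherwise it comes from
#' a flat outlier component of density `outlier_density` -- so isolated
#' amplification-dropout bins do not flip the decoded state.
#'
#' @param n_states Number of states (fixed-spacing means `0:(n-1) / 2`).
#' @param self_transition Probability of staying in the same state between
#'   adjacent bins.
#' @param zero_mean Emission mean of the copy-0 state.
#' @param min_sd Lower floor for the estimated emission SD.
#' @param outlier_prob,outlier_density Mixture weight and density of the
#'   flat outlier emission component.
#' @return A list of class `hmm_params`.
#' @export
hmm_params <- function(n_states = 6, self_transition = 0.99999,
                       zero_mean = 0.05, min_sd = 0.05,
                       outlier_prob = 0.01, outlier_density = 0.1) {
  stopifnot(n_states >= 2, self_transition > 0, self_transition < 1,
            outlier_prob >= 0, outlier_prob < 1, outlier_density > 0)
  means <- (seq_len(n_states) - 1) / 2
  means[1] <- zero_mean
  structure(list(n_states = n_states, means = means,
                 self_transition = self_transition, min_sd = min_sd,
                 outlier_prob = outlier_prob, outlier_density = outlier_density),
            class = "hmm_params")
}

# Robust emission log-likelihood matrix (states x bins).
.emission_ll <- function(x, means, sd, outlier_prob, outlier_density) {
  S <- length(means)
  n <- length(x)
  dens <- matrix(stats::dnorm(rep(x, each = S), rep(means, times = n), sd),
                 nrow = S)
  log((1 - outlier_prob) * dens + outlier_prob * outlier_density)
}

# Viterbi decoding for a homogeneous chain with a symmetric 2-parameter
# transition matrix (stay with prob p, switch uniformly otherwise).
.viterbi <- function(x, means, sd, self_transition,
                     outlier_prob = 0, outlier_density = 0.1) {
  S <- length(means)
  n <- length(x)
  log_self <- log(self_transition)
  log_switch <- log((1 - self_transition) / (S - 1))
  ll <- .emission_ll(x, means, sd, outlier_prob, outlier_density)  # S x n
  if (n == 1L) return(which.max(ll[, 1]) - 1L)
  back <- matrix(0L, S, n)
  v <- ll[, 1]
  for (i in 2:n) {
    m1 <- which.max(v)
    v2 <- v
    v2[m1] <- -Inf
    m2 <- which.max(v2)
    stay <- v + log_self
    sw_src <- ifelse(seq_len(S) == m1, m2, m1)
    sw <- v[sw_src] + log_switch
    take_stay <- stay >= sw
    back[, i] <- ifelse(take_stay, seq_len(S), sw_src)
    v <- ifelse(take_stay, stay, sw) + ll[, i]
  }
  path <- integer(n)
  path[n] <- which.max(v)
  for (i in n:2) path[i - 1L] <- back[path[i], i]
  path - 1L
}

#' Infer per-bin integer copy number
#'
#' Viterbi decoding of the most probable copy-number path over each
#' chromosome of each cell independently, on the corrected-count scale.
#' Masked bins carry no state; decoding is deterministic given the inputs.
#'
#' @param profiles A `cnv_profiles` tibble from [correct_counts()].
#' @param params An [hmm_params()].
#' @return The input tibble with an integer `state` column added (class
#'   `cnv_states`); the `cell_status` attribute is carried through.
#' @export
infer_copy_number <- function(profiles, params = hmm_params()) {
  stopifnot(inherits(params, "hmm_params"),
            all(c("cell_id", "chrom", "corrected", "masked") %in% names(profiles)))
  status <- attr(profiles, "cell_status")
  bad <- profiles$cell_id[!profiles$masked &
                            (is.infinite(profiles$corrected) | is.nan(profiles$corrected))]
  if (length(bad)) stop("non-finite corrected values in cell ", bad[1])
  out <- profiles
  out$state <- NA_integer_
  analyzable <- if (is.null(status)) unique(profiles$cell_id) else
    status$cell_id[status$analyzable]
  for (cell in unique(profiles$cell_id)) {
    rows_cell <- which(profiles$cell_id == cell)
    if (!cell %in% analyzable) next
    x_all <- profiles$corrected[rows_cell]
    usable <- !profiles$masked[rows_cell] & !is.na(x_all)
    d <- diff(x_all[usable])
    sd_cell <- max(stats::mad(d) / sqrt(2), params$min_sd)
    for (ch in unique(profiles$chrom[rows_cell])) {
      rows <- rows_cell[profiles$chrom[rows_cell] == ch & usable]
      if (!length(rows)) next
      out$state[rows] <- .viterbi(profiles$corrected[rows], params$means,
                                  sd_cell, params$self_transition,
                                  params$outlier_prob, params$outlier_density)
    }
  }
  attr(out, "cell_status") <- status
  class(out) <- unique(c("cnv_states", class(out)))
  out
}

#' Collapse per-bin states into segments
#'
#' Maximal runs of constant copy-number state over the unmasked bins of each
#' chromosome (a masked gap does not break a run). Concatenating segments
#' reconstructs the per-bin states exactly.
#'
#' @param states A `cnv_states` tibble from [infer_copy_number()].
#' @return A tibble: `cell_id`, `chrom`, `start`, `end`, `state`, `n_bins`,
#'   `length_bp` (summed widths of the member unmasked bins).
#' @export
segment_states <- function(states) {
  stopifnot(all(c("cell_id", "chrom", "start", "end", "state") %in% names(states)))
  ok <- !is.na(states$state)
  df <- states[ok, c("cell_id", "chrom", "start", "end", "state")]
  if (!nrow(df)) {
    return(tibble::tibble(cell_id = character(), chrom = character(),
                          start = numeric(), end = numeric(), state = integer(),
                          n_bins = integer(), length_bp = numeric()))
  }
  df |>
    dplyr::group_by(.data$cell_id, .data$chrom) |>
    dplyr::group_modify(function(d, key) {
      r <- rle(d$state)
      stops <- cumsum(r$lengths)
      starts <- stops - r$lengths + 1L
      tibble::tibble(
        start = d$start[starts], end = d$end[stops],
        state = as.integer(r$values), n_bins = r$lengths,
        length_bp = vapply(seq_along(starts), function(i) {
          sum(d$end[starts[i]:stops[i]] - d$start[starts[i]:stops[i]])
        }, numeric(1))
      )
    }) |>
    dplyr::ungroup()
}

chrom_baseline <- function(chrom, sex) {
  base <- rep(2L, length(chrom))
  if (sex == "XY") base[chrom %in% c("chrX", "chrY")] <- 1L
  if (sex == "XX") base[chrom == "chrY"] <- 0L
  base
}

#' Call a per-cell karyotype from segments
#'
#' Reports non-baseline segments of at least `min_cnv_size` as CNV calls,
#' classed `whole` when they cover at least `whole_fraction` of the
#' chromosome's analyzable (unmasked) length and `segmental` otherwise.
#' Cells whose calls cover most of the genome are flagged as possible
#' whole-genome ploidy shifts, which the median-anchored pipeline cannot
#' resolve.
#'
#' @param states A `cnv_states` tibble from [infer_copy_number()].
#' @param min_cnv_size Minimum reported call size in bp (default 10 Mb).
#' @param whole_fraction Fraction of the analyzable chromosome length above
#'   which a call is whole-chromosome (default 0.9).
#' @param sex Declared sex, `"XX"` or `"XY"`; sets the per-chromosome
#'   baseline copy number.
#' @return A tibble of class `karyotype_calls`: `cell_id`, `chrom`, `start`,
#'   `end`, `delta`, `class`, `length_bp`. Attributes: `cells` (all analyzable
#'   cell ids, so euploid cells -- zero rows here -- stay countable), `sex`,
#'   `flagged` (cell ids with suspected ploidy shifts).
#' @export
call_karyotypes <- function(states, min_cnv_size = 1e7, whole_fraction = 0.9,
                            sex = c("XX", "XY")) {
  sex <- match.arg(sex)
  segs <- segment_states(states)
  status <- attr(states, "cell_status")
  cells <- if (!is.null(status)) status$cell_id[status$analyzable] else
    unique(states$cell_id)

  chr_len <- segs |>
    dplyr::group_by(.data$cell_id, .data$chrom) |>
    dplyr::summarise(analyzable_bp = sum(.data$length_bp), .groups = "drop")

  calls <- segs |>
    dplyr::mutate(baseline = chrom_baseline(.data$chrom, sex),
                  delta = .data$state - .data$baseline) |>
    dplyr::filter(.data$delta != 0, .data$length_bp >= min_cnv_size) |>
    dplyr::left_join(chr_len, by = c("cell_id", "chrom")) |>
    dplyr::mutate(class = ifelse(.data$length_bp >= whole_fraction * .data$analyzable_bp,
                                 "whole", "segmental")) |>
    dplyr::select("cell_id", "chrom", "start", "end", "delta", "class", "length_bp")

  genome_bp <- chr_len |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::summarise(bp = sum(.data$analyzable_bp), .groups = "drop")
  call_bp <- calls |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::summarise(bp_called = sum(.data$length_bp), .groups = "drop")
  flagged <- call_bp |>
    dplyr::left_join(genome_bp, by = "cell_id") |>
    dplyr::filter(.data$bp_called > 0.6 * .data$bp) |>
    dplyr::pull(.data$cell_id)

  attr(calls, "cells") <- cells
  attr(calls, "sex") <- sex
  attr(calls, "flagged") <- flagged
  class(calls) <- unique(c("karyotype_calls", class(calls)))
  calls
}

#' Run correction, decoding and karyotype calling in one step
#'
#' Convenience wrapper chaining [correct_counts()], [infer_copy_number()] and
#' [call_karyotypes()].
#'
#' @inheritParams correct_counts
#' @inheritParams call_karyotypes
#' @param params An [hmm_params()].
#' @return A list with `profiles`, `states` and `calls`.
#' @export
call_cells <- function(counts, tracks, params = hmm_params(),
                       min_cnv_size = 1e7, whole_fraction = 0.9,
                       sex = c("XX", "XY"), min_mappability = 0.8) {
  sex <- match.arg(sex)
  profiles <- correct_counts(counts, tracks, min_mappability = min_mappability)
  states <- infer_copy_number(profiles, params)
  calls <- call_karyotypes(states, min_cnv_size = min_cnv_size,
                           whole_fraction = whole_fraction, sex = sex)
  list(profiles = profiles, states = states, calls = calls)
}

#' ISCN-like summary string for one cell's calls
#'
#' @param calls A `karyotype_calls` tibble (or subset) for one cell.
#' @param sex Declared sex used for the modal chromosome number.
#' @return A character scalar such as `"46,XX"` or
#'   `"47,XX,+21,seg(chr2:10.0-60.0Mb x1)"`.
#' @export
karyotype_string <- function(calls, sex = "XX") {
  n_base <- if (sex == "XX") 46L else 46L
  whole <- calls[calls$class == "whole", , drop = FALSE]
  seg <- calls[calls$class == "segmental", , drop = FALSE]
  n <- n_base + sum(whole$delta)
  parts <- sprintf("%d,%s", n, sex)
  if (nrow(whole)) {
    parts <- c(parts, sprintf("%s%s", ifelse(whole$delta > 0, "+", "-"),
                              sub("^chr", "", whole$chrom)))
  }
  if (nrow(seg)) {
    parts <- c(parts, sprintf("seg(%s:%.1f-%.1fMb x%+d)", seg$chrom,
                              seg$start / 1e6, seg$end / 1e6, seg$delta))
  }
  paste(parts, collapse = ",")
}
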
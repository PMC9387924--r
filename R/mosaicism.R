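# Embryo-level analytics: karyotype equivalence and clustering, mosaic
# calling and typing, incidence, meiotic/mitotic origin, TE-ICM discordance,
# complementary CNV pairs, pseudo-bulk biopsies and per-chromosome tallies.

# Reciprocal-overlap compatibility of two single calls.
.call_match <- function(chrom_a, start_a, end_a, delta_a,
                        chrom_b, start_b, end_b, delta_b, thr) {
  if (chrom_a != chrom_b || delta_a != delta_b) return(FALSE)
  ov <- min(end_a, end_b) - max(start_a, start_b)
  if (ov <= 0) return(FALSE)
  ov / (end_a - start_a) >= thr && ov / (end_b - start_b) >= thr
}

# Does a perfect matching exist in the bipartite compatibility matrix?
.perfect_matching <- function(compat) {
  n <- nrow(compat)
  if (n == 0L) return(TRUE)
  assign_rows <- function(row, used) {
    if (row > n) return(TRUE)
    for (col in which(compat[row, ] & !used)) {
      used[col] <- TRUE
      if (assign_rows(row + 1L, used)) return(TRUE)
      used[col] <- FALSE
    }
    FALSE
  }
  assign_rows(1L, rep(FALSE, n))
}

#' Are two karyotypes equivalent?
#'
#' Two karyotypes (call sets) are equal iff a one-to-one matching exists
#' between their calls pairing same-chromosome, same-delta calls whose
#' reciprocal overlap is at least `reciprocal_overlap`. Two euploid (empty)
#' karyotypes are equal.
#'
#' @param k1,k2 Call tibbles with columns `chrom`, `start`, `end`, `delta`
#'   (zero rows = euploid).
#' @param reciprocal_overlap Minimum reciprocal overlap (default 0.8).
#' @return Logical scalar.
#' @export
karyotypes_equal <- function(k1, k2, reciprocal_overlap = 0.8) {
  n1 <- nrow(k1); n2 <- nrow(k2)
  if (n1 != n2) return(FALSE)
  if (n1 == 0L) return(TRUE)
  compat <- matrix(FALSE, n1, n2)
  for (i in seq_len(n1)) for (j in seq_len(n2)) {
    compat[i, j] <- .call_match(k1$chrom[i], k1$start[i], k1$end[i], k1$delta[i],
                                k2$chrom[j], k2$start[j], k2$end[j], k2$delta[j],
                                reciprocal_overlap)
  }
  .perfect_matching(compat)
}

# Split a calls tibble into a per-cell list (cells without calls -> empty
# tibble), preserving the supplied cell order.
.calls_by_cell <- function(calls, cell_ids) {
  empty <- calls[0, , drop = FALSE]
  by_cell <- split(calls, factor(calls$cell_id, levels = cell_ids))
  lapply(cell_ids, function(id) {
    k <- by_cell[[id]]
    if (is.null(k)) empty else k
  })
}

# Assign cells to karyotype equivalence classes (first matching
# representative, stable order). Returns integer class ids.
.karyotype_classes <- function(klist, reciprocal_overlap) {
  reps <- list()
  ids <- integer(length(klist))
  for (i in seq_along(klist)) {
    hit <- 0L
    for (r in seq_along(reps)) {
      if (karyotypes_equal(klist[[i]], reps[[r]], reciprocal_overlap)) {
        hit <- r
        break
      }
    }
    if (hit == 0L) {
      reps[[length(reps) + 1L]] <- klist[[i]]
      hit <- length(reps)
    }
    ids[i] <- hit
  }
  list(ids = ids, reps = reps)
}

# Calls of k that have no match (same chrom/delta, reciprocal overlap) in ref.
.nonshared_calls <- function(k, ref, thr) {
  if (nrow(k) == 0L || nrow(ref) == 0L) return(k)
  keep <- vapply(seq_len(nrow(k)), function(i) {
    !any(vapply(seq_len(nrow(ref)), function(j) {
      .call_match(k$chrom[i], k$start[i], k$end[i], k$delta[i],
                  ref$chrom[j], ref$start[j], ref$end[j], ref$delta[j], thr)
    }, logical(1)))
  }, logical(1))
  k[keep, , drop = FALSE]
}

.analyzed_cells <- function(calls, metadata) {
  analyzable <- attr(calls, "cells")
  if (is.null(analyzable)) return(metadata)
  metadata[metadata$cell_id %in% analyzable, , drop = FALSE]
}

#' Classify mosaicism per embryo and lineage
#'
#' A lineage set is evaluable with at least `min_cells` cells. It is mosaic
#' iff its cells fall into two or more karyotype equivalence classes (one
#' divergent cell suffices); the major karyotype is the most frequent class
#' (ties go to the euploid class when present, else to the first class by
#' stable cell order, with a warning), and the mosaic rate is the fraction of
#' cells outside the major class. Mosaic subtype comes from the CNV classes
#' present among divergent cells' calls: only whole-chromosome calls give
#' `whole`, only segmental calls give `segmental`, both give `complex`; when
#' the divergent cells are euploid, the major karyotype's own (non-shared)
#' calls are typed instead.
#'
#' @param calls A `karyotype_calls` tibble from [call_karyotypes()] or
#'   [demo_cohort()].
#' @param metadata Cell metadata (`cell_id`, `embryo_id`, `lineage`).
#' @param min_cells Minimum cells for an evaluable lineage set (default 3).
#' @param reciprocal_overlap Karyotype-equality threshold.
#' @return A tibble of class `embryo_classification`: one row per
#'   embryo x lineage with `n_cells`, `evaluable`, `status`
#'   (`non_mosaic_euploid`, `non_mosaic_aneuploid`, `mosaic`, or
#'   `insufficient_cells`), `subtype` (`whole`, `segmental`, `complex`,
#'   `none`), `mosaic_rate`, `n_classes`, and list-column `major_karyotype`.
#' @export
classify_embryos <- function(calls, metadata, min_cells = 3,
                             reciprocal_overlap = 0.8) {
  meta <- .analyzed_cells(calls, metadata)
  groups <- dplyr::distinct(meta[, c("embryo_id", "lineage")])
  out <- vector("list", nrow(groups))
  for (g in seq_len(nrow(groups))) {
    cells <- meta$cell_id[meta$embryo_id == groups$embryo_id[g] &
                            meta$lineage == groups$lineage[g]]
    n <- length(cells)
    if (n < min_cells) {
      out[[g]] <- tibble::tibble(
        embryo_id = groups$embryo_id[g], lineage = groups$lineage[g],
        n_cells = n, evaluable = FALSE, status = "insufficient_cells",
        subtype = "none", mosaic_rate = NA_real_, n_classes = NA_integer_,
        major_karyotype = list(NULL)
      )
      next
    }
    kl <- .calls_by_cell(calls, cells)
    cls <- .karyotype_classes(kl, reciprocal_overlap)
    tab <- tabulate(cls$ids)
    top <- which(tab == max(tab))
    if (length(top) > 1L) {
      eup <- which(vapply(cls$reps, nrow, integer(1)) == 0L)
      if (length(eup) && eup[1] %in% top) {
        major <- eup[1]
      } else {
        major <- top[1]
        warning(sprintf("embryo %s %s: major-karyotype tie broken by cell order",
                        groups$embryo_id[g], groups$lineage[g]))
      }
    } else {
      major <- top
    }
    n_classes <- length(cls$reps)
    mosaic <- n_classes >= 2L
    rate <- sum(cls$ids != major) / n
    major_k <- cls$reps[[major]]
    if (!mosaic) {
      status <- if (nrow(major_k) == 0L) "non_mosaic_euploid" else "non_mosaic_aneuploid"
      subtype <- "none"
    } else {
      status <- "mosaic"
      div_calls <- dplyr::bind_rows(
        lapply(kl[cls$ids != major], .nonshared_calls, ref = major_k,
               thr = reciprocal_overlap))
      if (nrow(div_calls) == 0L) {
        # divergent cells lack private calls (e.g. euploid divergents):
        # type from the major karyotype's own non-shared calls
        div_union <- dplyr::bind_rows(kl[cls$ids != major])
        div_calls <- .nonshared_calls(major_k, div_union, reciprocal_overlap)
      }
      has_w <- any(div_calls$class == "whole")
      has_s <- any(div_calls$class == "segmental")
      subtype <- if (has_w && has_s) "complex" else if (has_w) "whole" else "segmental"
    }
    out[[g]] <- tibble::tibble(
      embryo_id = groups$embryo_id[g], lineage = groups$lineage[g],
      n_cells = n, evaluable = TRUE, status = status, subtype = subtype,
      mosaic_rate = rate, n_classes = n_classes, major_karyotype = list(major_k)
    )
  }
  res <- dplyr::bind_rows(out)
  class(res) <- unique(c("embryo_classification", class(res)))
  res
}

#' Mosaicism incidence per lineage
#'
#' Fraction of evaluable lineage sets classified mosaic; lineage sets with
#' fewer than the minimum cells never enter the denominator.
#'
#' @param classification An `embryo_classification` from [classify_embryos()].
#' @param lineage Optional lineage filter (e.g. `"TE"`).
#' @return A tibble: `lineage`, `n_mosaic`, `n_evaluable`, `fraction`, `pct`
#'   (percentage rounded to 2 decimals).
#' @export
cohort_incidence <- function(classification, lineage = NULL) {
  df <- classification[classification$evaluable, , drop = FALSE]
  if (!is.null(lineage)) df <- df[df$lineage %in% lineage, , drop = FALSE]
  if (nrow(df) == 0L) stop("no evaluable lineage sets")
  df |>
    dplyr::group_by(lineage = .data$lineage) |>
    dplyr::summarise(n_mosaic = sum(.data$status == "mosaic"),
                     n_evaluable = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(fraction = .data$n_mosaic / .data$n_evaluable,
                  pct = round(100 * .data$fraction, 2))
}

#' Distribution of mosaic subtypes per lineage
#'
#' Among mosaic lineage sets only: counts and percentages of whole,
#' segmental and complex mosaicism.
#'
#' @inheritParams cohort_incidence
#' @return A tibble: `lineage`, `subtype`, `n`, `n_mosaic`, `fraction`, `pct`.
#' @export
mosaic_type_distribution <- function(classification, lineage = NULL) {
  df <- classification[classification$evaluable &
                         classification$status == "mosaic", , drop = FALSE]
  if (!is.null(lineage)) df <- df[df$lineage %in% lineage, , drop = FALSE]
  df |>
    dplyr::count(lineage = .data$lineage, subtype = .data$subtype) |>
    dplyr::group_by(.data$lineage) |>
    dplyr::mutate(n_mosaic = sum(.data$n),
                  fraction = .data$n / .data$n_mosaic,
                  pct = round(100 * .data$fraction, 2)) |>
    dplyr::ungroup()
}

#' Classify the meiotic/mitotic origin of each embryo's CNV events
#'
#' Pools every analyzed cell of the embryo across lineages, clusters
#' individual CNV calls across cells by the reciprocal-overlap rule, and
#' labels a clustered event meiotic when carried by every analyzed cell
#' (tunable via `meiotic_tolerance`, the minimum carrier fraction; default
#' strict 1) and mitotic when carried by a proper subset. Embryos are then
#' labeled `euploid`, `meiotic_only`, `mitotic_only` or `both`.
#'
#' @inheritParams classify_embryos
#' @param min_cells Minimum pooled cells for classification (default 3).
#' @param meiotic_tolerance Minimum fraction of cells that must carry an
#'   event for a meiotic label (1 = all cells).
#' @return A tibble: `embryo_id`, `n_cells`, `origin`, with attribute
#'   `events` -- one row per clustered event (`embryo_id`, `chrom`, `start`,
#'   `end`, `delta`, `class`, `n_carriers`, `origin`).
#' @export
classify_origin <- function(calls, metadata, min_cells = 3,
                            reciprocal_overlap = 0.8, meiotic_tolerance = 1) {
  meta <- .analyzed_cells(calls, metadata)
  embryos <- unique(meta$embryo_id)
  rows <- vector("list", length(embryos))
  ev_rows <- vector("list", length(embryos))
  for (i in seq_along(embryos)) {
    cells <- meta$cell_id[meta$embryo_id == embryos[i]]
    n <- length(cells)
    if (n < min_cells) {
      rows[[i]] <- tibble::tibble(embryo_id = embryos[i], n_cells = n,
                                  origin = "insufficient_cells")
      next
    }
    ec <- calls[calls$cell_id %in% cells, , drop = FALSE]
    if (nrow(ec) == 0L) {
      rows[[i]] <- tibble::tibble(embryo_id = embryos[i], n_cells = n,
                                  origin = "euploid")
      next
    }
    # cluster single calls across cells
    reps <- list()
    members <- list()
    for (r in seq_len(nrow(ec))) {
      hit <- 0L
      for (k in seq_along(reps)) {
        if (.call_match(ec$chrom[r], ec$start[r], ec$end[r], ec$delta[r],
                        reps[[k]]$chrom, reps[[k]]$start, reps[[k]]$end,
                        reps[[k]]$delta, reciprocal_overlap)) {
          hit <- k
          break
        }
      }
      if (hit == 0L) {
        reps[[length(reps) + 1L]] <- ec[r, ]
        members[[length(reps)]] <- character(0)
        hit <- length(reps)
      }
      members[[hit]] <- union(members[[hit]], ec$cell_id[r])
    }
    ev <- dplyr::bind_rows(reps)
    ev$n_carriers <- lengths(members)
    ev$origin <- ifelse(ev$n_carriers >= meiotic_tolerance * n, "meiotic", "mitotic")
    ev <- dplyr::mutate(ev, embryo_id = embryos[i], n_cells = n, .before = 1)
    ev_rows[[i]] <- dplyr::select(ev, "embryo_id", "chrom", "start", "end",
                                  "delta", "class", "n_carriers", "n_cells", "origin")
    has_mei <- any(ev$origin == "meiotic")
    has_mit <- any(ev$origin == "mitotic")
    origin <- if (has_mei && has_mit) "both" else if (has_mei) "meiotic_only" else "mitotic_only"
    rows[[i]] <- tibble::tibble(embryo_id = embryos[i], n_cells = n, origin = origin)
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "events") <- dplyr::bind_rows(ev_rows)
  class(out) <- unique(c("origin_classification", class(out)))
  out
}

#' Per-embryo TE versus ICM karyotype concordance
#'
#' For each embryo with evaluable TE and ICM lineage sets, clusters the
#' pooled cells into karyotype classes and compares the set of classes seen
#' in TE with that seen in ICM; the embryo is concordant iff the sets are
#' identical.
#'
#' @inheritParams classify_embryos
#' @return A tibble: `embryo_id`, `n_te`, `n_icm`, `concordant`.
#' @export
te_icm_concordance <- function(calls, metadata, min_cells = 3,
                               reciprocal_overlap = 0.8) {
  meta <- .analyzed_cells(calls, metadata)
  embryos <- unique(meta$embryo_id)
  rows <- list()
  for (e in embryos) {
    te <- meta$cell_id[meta$embryo_id == e & meta$lineage == "TE"]
    icm <- meta$cell_id[meta$embryo_id == e & meta$lineage == "ICM"]
    if (length(te) < min_cells || length(icm) < min_cells) next
    cells <- c(te, icm)
    kl <- .calls_by_cell(calls, cells)
    cls <- .karyotype_classes(kl, reciprocal_overlap)
    te_set <- sort(unique(cls$ids[seq_along(te)]))
    icm_set <- sort(unique(cls$ids[length(te) + seq_along(icm)]))
    rows[[length(rows) + 1L]] <- tibble::tibble(
      embryo_id = e, n_te = length(te), n_icm = length(icm),
      concordant = identical(te_set, icm_set)
    )
  }
  dplyr::bind_rows(rows)
}

#' Resampled TE-ICM discordance fraction
#'
#' For each embryo with evaluable TE and ICM sets: per resample, draw
#' `m = min(|TE|, |ICM|)` cells from each lineage without replacement, pair
#' them at random, and record the fraction of pairs with unequal karyotypes;
#' the statistic is the mean over resamples. Because both the draw and the
#' pairing are uniform, its expectation equals the mean over all TE x ICM
#' cell pairs of the inequality indicator, available as `method = "exact"`.
#'
#' @inheritParams classify_embryos
#' @param n_resamples Monte-Carlo resamples (ignored for `method="exact"`).
#' @param seed Integer seed for the resampling.
#' @param method `"resample"` (default) or `"exact"` (analytic expectation).
#' @return A tibble: `embryo_id`, `m`, `discordance`.
#' @export
te_icm_discordance <- function(calls, metadata, n_resamples = 1000, seed = 1,
                               min_cells = 3, reciprocal_overlap = 0.8,
                               method = c("resample", "exact")) {
  method <- match.arg(method)
  meta <- .analyzed_cells(calls, metadata)
  set.seed(seed)
  embryos <- unique(meta$embryo_id)
  rows <- list()
  for (e in embryos) {
    te <- meta$cell_id[meta$embryo_id == e & meta$lineage == "TE"]
    icm <- meta$cell_id[meta$embryo_id == e & meta$lineage == "ICM"]
    if (length(te) < min_cells || length(icm) < min_cells) next
    m <- min(length(te), length(icm))
    if (m == 0L) stop("no cells to pair")
    cells <- c(te, icm)
    kl <- .calls_by_cell(calls, cells)
    cls <- .karyotype_classes(kl, reciprocal_overlap)
    te_cl <- cls$ids[seq_along(te)]
    icm_cl <- cls$ids[length(te) + seq_along(icm)]
    if (method == "exact") {
      d <- mean(outer(te_cl, icm_cl, "!="))
    } else {
      d <- mean(vapply(seq_len(n_resamples), function(r) {
        x <- te_cl[sample.int(length(te_cl), m)]
        y <- icm_cl[sample.int(length(icm_cl), m)]
        mean(x != y)
      }, numeric(1)))
    }
    rows[[length(rows) + 1L]] <- tibble::tibble(embryo_id = e, m = m, discordance = d)
  }
  dplyr::bind_rows(rows)
}

#' Find complementary (reciprocal) CNV pairs between cells
#'
#' Reports every unordered cell pair sharing at least one pair of calls on
#' the same chromosome with opposite equal-magnitude deltas and reciprocal
#' overlap at or above the threshold -- the single-cell signature of a
#' mitotic non-disjunction, whose summed signal is euploid and therefore
#' masked in bulk assays.
#'
#' @inheritParams classify_embryos
#' @param metadata Optional; when given, only pairs within the same embryo
#'   are considered.
#' @return A tibble: `cell_a`, `cell_b`, `chrom`, `start`, `end` (shared
#'   region), `delta` (magnitude), `overlap` (minimum reciprocal overlap).
#' @export
find_complementary_pairs <- function(calls, metadata = NULL,
                                     reciprocal_overlap = 0.8) {
  rows <- list()
  cc <- calls
  if (!is.null(metadata)) {
    cc <- dplyr::left_join(cc, metadata[, c("cell_id", "embryo_id")], by = "cell_id")
  } else {
    cc$embryo_id <- "all"
  }
  for (i in seq_len(max(nrow(cc) - 1L, 0L))) {
    for (j in (i + 1L):nrow(cc)) {
      if (cc$cell_id[i] == cc$cell_id[j]) next
      if (cc$embryo_id[i] != cc$embryo_id[j]) next
      if (cc$chrom[i] != cc$chrom[j]) next
      if (cc$delta[i] != -cc$delta[j]) next
      ov <- min(cc$end[i], cc$end[j]) - max(cc$start[i], cc$start[j])
      if (ov <= 0) next
      ro <- min(ov / (cc$end[i] - cc$start[i]), ov / (cc$end[j] - cc$start[j]))
      if (ro < reciprocal_overlap) next
      a <- min(cc$cell_id[i], cc$cell_id[j])
      b <- max(cc$cell_id[i], cc$cell_id[j])
      rows[[length(rows) + 1L]] <- tibble::tibble(
        cell_a = a, cell_b = b, chrom = cc$chrom[i],
        start = max(cc$start[i], cc$start[j]), end = min(cc$end[i], cc$end[j]),
        delta = abs(cc$delta[i]), overlap = ro
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out)) out <- dplyr::distinct(out)
  out
}

#' In-silico multi-cell biopsy
#'
#' Sums the raw bin counts of a sampled subset of cells (default the 5-10
#' cell scale of a clinical TE biopsy), re-runs correction, HMM decoding and
#' karyotype calling on the summed profile, and returns the resulting bulk
#' karyotype for comparison with the member cells' single-cell karyotypes.
#' An exactly balanced complementary pair sums to a flat profile, so the
#' bulk karyotype over that region is euploid: the mechanism by which bulk
#' PGT-A masks reciprocal mosaic aneuploidy.
#'
#' @param counts Wide counts tibble.
#' @param tracks Tracks aligned to the same grid.
#' @param cells Cell ids available for the biopsy.
#' @param biopsy_size Number of cells to draw (must not exceed
#'   `length(cells)`).
#' @param seed Integer seed for the draw.
#' @param ... Passed to [call_cells()] (e.g. `sex`, `params`).
#' @return A `karyotype_calls` tibble for the single pseudo-bulk sample
#'   `"bulk"`, with attribute `members` (the sampled cell ids).
#' @export
simulate_multicell_biopsy <- function(counts, tracks, cells,
                                      biopsy_size = length(cells), seed = 1, ...) {
  missing_cells <- setdiff(cells, names(counts))
  if (length(missing_cells)) stop("cells not in counts: ", paste(missing_cells, collapse = ", "))
  if (biopsy_size > length(cells)) {
    stop(sprintf("biopsy_size (%d) exceeds available cells (%d)",
                 biopsy_size, length(cells)))
  }
  set.seed(seed)
  members <- if (biopsy_size == length(cells)) cells else sample(cells, biopsy_size)
  bulk <- counts[, c("chrom", "start", "end")]
  bulk$bulk <- as.integer(rowSums(as.matrix(counts[, members, drop = FALSE])))
  res <- call_cells(bulk, tracks, ...)
  out <- res$calls
  attr(out, "members") <- members
  out
}

#' Per-chromosome tally of whole and segmental aneuploidies
#'
#' Counts, per lineage and chromosome, the cells carrying at least one whole
#' (respectively segmental) event, and the events themselves.
#'
#' @inheritParams classify_embryos
#' @param lineage Optional lineage filter.
#' @return A tibble: `lineage`, `chrom`, `class`, `n_cells`, `n_events`.
#' @export
chromosome_aneuploidy_table <- function(calls, metadata, lineage = NULL) {
  meta <- .analyzed_cells(calls, metadata)
  if (!is.null(lineage)) meta <- meta[meta$lineage %in% lineage, , drop = FALSE]
  df <- if (nrow(calls) == 0L) calls else
    dplyr::inner_join(calls, meta[, c("cell_id", "lineage")], by = "cell_id")
  if (nrow(df) == 0L) {
    return(tibble::tibble(lineage = character(), chrom = character(),
                          class = character(), n_cells = integer(),
                          n_events = integer()))
  }
  df |>
    dplyr::group_by(lineage = .data$lineage, chrom = .data$chrom,
                    class = .data$class) |>
    dplyr::summarise(n_cells = dplyr::n_distinct(.data$cell_id),
                     n_events = dplyr::n(), .groups = "drop")
}

#' Compare single-cell karyotypes against an initial diagnostic karyotype
#'
#' Clinical workflows often hold a prior multi-cell (bulk) diagnosis per
#' embryo; the single-cell result is discordant with it as soon as one or
#' more analyzed cells show a karyotype different from that reference.
#'
#' @inheritParams classify_embryos
#' @param cells Cell ids to compare (e.g. all analyzed cells of one embryo).
#' @param reference A call tibble (`chrom`, `start`, `end`, `delta`); zero
#'   rows for a euploid reference.
#' @return A one-row tibble: `n_cells`, `n_discordant_cells`, `concordant`.
#' @export
compare_to_reference <- function(calls, cells, reference,
                                 reciprocal_overlap = 0.8) {
  stopifnot(length(cells) >= 1)
  kl <- .calls_by_cell(calls, cells)
  bad <- !vapply(kl, karyotypes_equal, logical(1), k2 = reference,
                 reciprocal_overlap = reciprocal_overlap)
  tibble::tibble(n_cells = length(cells), n_discordant_cells = sum(bad),
                 concordant = !any(bad))
}

#' Two-tailed unpaired Student's t-test between two groups of rates
#'
#' Thin reporting wrapper around the standard pooled-variance two-sample
#' t-test. Groups whose pooled variance is zero are handled explicitly:
#' equal means give `t = 0, p = 1` (flagged degenerate); unequal constant
#' groups give `p = 0`.
#'
#' @param group_a,group_b Numeric vectors, each of length >= 2.
#' @return A one-row tibble: `estimate_a`, `estimate_b`, `statistic`, `df`,
#'   `p_value`, `method`, `degenerate`.
#' @export
compare_rates <- function(group_a, group_b) {
  if (length(group_a) < 2 || length(group_b) < 2) {
    stop("insufficient observations: each group needs at least 2 values")
  }
  ma <- mean(group_a); mb <- mean(group_b)
  df <- length(group_a) + length(group_b) - 2
  if (stats::sd(group_a) == 0 && stats::sd(group_b) == 0) {
    if (ma == mb) {
      return(tibble::tibble(estimate_a = ma, estimate_b = mb, statistic = 0,
                            df = df, p_value = 1,
                            method = "Two-sample t-test (pooled variance)",
                            degenerate = TRUE))
    }
    return(tibble::tibble(estimate_a = ma, estimate_b = mb,
                          statistic = sign(ma - mb) * Inf, df = df, p_value = 0,
                          method = "Two-sample t-test (pooled variance)",
                          degenerate = TRUE))
  }
  tt <- stats::t.test(group_a, group_b, var.equal = TRUE)
  tibble::tibble(estimate_a = ma, estimate_b = mb,
                 statistic = unname(tt$statistic), df = unname(tt$parameter),
                 p_value = tt$p.value,
                 method = "Two-sample t-test (pooled variance)",
                 degenerate = FALSE)
}
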
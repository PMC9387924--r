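# A deterministic, fully worked example cohort at the karyotype level:
# 39 embryos whose per-cell call sets exercise every classifier -- mosaic
# status and subtype, meiotic/mitotic origin, TE-ICM concordance and
# denominator discipline -- with the class proportions typical of single-cell
# blastocyst studies.

.demo_whole <- function(chrom, delta) {
  len <- .chrom_lengths_mb[[chrom]] * 1e6
  tibble::tibble(chrom = chrom, start = 0, end = len, delta = as.integer(delta),
                 class = "whole", length_bp = len)
}

.demo_seg <- function(chrom, start_mb, end_mb, delta) {
  tibble::tibble(chrom = chrom, start = start_mb * 1e6, end = end_mb * 1e6,
                 delta = as.integer(delta), class = "segmental",
                 length_bp = (end_mb - start_mb) * 1e6)
}

.demo_join <- function(...) dplyr::bind_rows(...)

#' Built-in demonstration cohort
#'
#' A deterministic 39-embryo cohort specified directly at the karyotype
#' level (cell metadata plus per-cell CNV calls; no counts), sized like a
#' typical single-cell blastocyst mosaicism study: 35 embryos with an
#' evaluable (>= 3 cell) TE set, 15 with an evaluable ICM set (12 with both),
#' 6 with evaluable hESC lines, and one embryo below per-lineage
#' evaluability that still contributes 3 pooled cells. Running the
#' classifiers on it yields TE/ICM/hESC mosaicism incidences of 23/35, 9/15
#' and 2/6; 16/23 complex mosaics in TE; 4/9 complex and 4/9 segmental in
#' ICM; 10/12 TE-ICM discordant embryos; and an origin distribution of 4
#' meiotic-only, 19 mitotic-only and 11 both among the 34 aneuploid embryos.
#'
#' @return A list with `metadata` (cell_id, embryo_id, lineage) and `calls`
#'   (a `karyotype_calls` tibble with the full cell list in its `cells`
#'   attribute).
#' @examples
#' demo <- demo_cohort()
#' cohort_incidence(classify_embryos(demo$calls, demo$metadata))
#' @export
demo_cohort <- function() {
  eu <- list()  # euploid cell: no calls

  # Recurring call sets.
  cx_a <- .demo_join(.demo_whole("chr19", +1), .demo_seg("chr1", 50, 100, -1))
  cx_b <- .demo_join(.demo_whole("chr7", +1), .demo_seg("chr4", 10, 50, -1))
  cx_c <- .demo_join(.demo_whole("chr20", +1), .demo_seg("chr3", 40, 90, -1))
  cx_d <- .demo_join(.demo_whole("chr8", -1), .demo_seg("chr2", 30, 70, +1))
  cx_e <- .demo_join(.demo_whole("chr9", +1), .demo_seg("chr5", 20, 60, -1))
  cx_f <- .demo_join(.demo_whole("chr10", -1), .demo_seg("chr6", 30, 80, +1))
  wh_a <- .demo_whole("chr15", -1)
  wh_b <- .demo_whole("chr14", -1)
  sg_a <- .demo_seg("chr2", 30, 70, +1)
  sg_b <- .demo_seg("chr11", 10, 45, +1)
  sg_c <- .demo_seg("chr1", 50, 100, -1)

  mei <- list(  # per-embryo meiotic event, carried by every cell
    E01 = .demo_whole("chr16", +1), E02 = .demo_whole("chr16", +1),
    E03 = .demo_whole("chr16", +1), E04 = .demo_whole("chr16", +1),
    E05 = .demo_whole("chr16", +1), E06 = .demo_whole("chr16", +1),
    E18 = .demo_whole("chr21", +1), E19 = .demo_whole("chr21", +1),
    E20 = .demo_whole("chr22", -1), E21 = .demo_whole("chr13", +1),
    E26 = .demo_whole("chr16", +1), E31 = .demo_whole("chr13", +1),
    E32 = .demo_whole("chr18", +1), E33 = .demo_whole("chr21", +1),
    E36 = .demo_whole("chr22", +1)
  )
  M <- function(e) mei[[e]]
  with_m <- function(e, extra = NULL) {
    if (is.null(extra)) M(e) else .demo_join(M(e), extra)
  }

  spec <- list()
  add <- function(embryo, lineage, cell_karyotypes) {
    spec[[length(spec) + 1L]] <<- list(embryo = embryo, lineage = lineage,
                                       k = cell_karyotypes)
  }
  rep_k <- function(k, n) replicate(n, k, simplify = FALSE)

  # E01-E06: TE-only, mosaic complex, meiotic + mitotic origin.
  for (e in sprintf("E%02d", 1:6)) {
    add(e, "TE", c(rep_k(with_m(e), 4), list(with_m(e, cx_b))))
  }
  # E07-E12: TE-only, mosaic complex, mitotic only.
  for (e in sprintf("E%02d", 7:12)) {
    add(e, "TE", c(rep_k(eu, 4), list(cx_a)))
  }
  # E13-E16: TE-only, mosaic whole.
  for (e in sprintf("E%02d", 13:16)) {
    add(e, "TE", c(rep_k(eu, 4), list(wh_a)))
  }
  # E17: TE-only, mosaic segmental.
  add("E17", "TE", c(rep_k(eu, 4), list(sg_a)))
  # E18-E21: TE-only, uniform aneuploid (meiotic only, non-mosaic).
  for (e in sprintf("E%02d", 18:21)) {
    add(e, "TE", rep_k(M(e), 5))
  }
  # E22-E23: TE-only, euploid.
  for (e in c("E22", "E23")) add(e, "TE", rep_k(eu, 5))

  # E24-E25: TE mosaic, ICM uniformly euploid (aneuploidy confined to TE).
  for (e in c("E24", "E25")) {
    add(e, "TE", c(rep_k(eu, 3), rep_k(cx_a, 2)))
    add(e, "ICM", rep_k(eu, 4))
  }
  # E26: meiotic trisomy everywhere; TE additionally mosaic, ICM uniform.
  add("E26", "TE", c(rep_k(with_m("E26"), 3), rep_k(with_m("E26", cx_c), 2)))
  add("E26", "ICM", rep_k(with_m("E26"), 4))
  # E27-E30: TE euploid, ICM mosaic segmental.
  for (e in sprintf("E%02d", 27:30)) {
    add(e, "TE", rep_k(eu, 5))
    add(e, "ICM", c(rep_k(eu, 3), list(sg_b)))
  }
  # E31: mosaic in both lineages (complex/complex), meiotic + mitotic.
  add("E31", "TE", c(rep_k(with_m("E31"), 4), list(with_m("E31", cx_b))))
  add("E31", "ICM", c(rep_k(with_m("E31"), 3), list(with_m("E31", cx_d))))
  # E32: TE segmental, ICM complex.
  add("E32", "TE", c(rep_k(with_m("E32"), 4), list(with_m("E32", sg_a))))
  add("E32", "ICM", c(rep_k(with_m("E32"), 3), list(with_m("E32", cx_e))))
  # E33: TE segmental, ICM complex, hESC complex.
  add("E33", "TE", c(rep_k(with_m("E33"), 4), list(with_m("E33", sg_c))))
  add("E33", "ICM", c(rep_k(with_m("E33"), 3), list(with_m("E33", cx_f))))
  add("E33", "hESC", c(rep_k(with_m("E33"), 3), list(with_m("E33", cx_f))))
  # E34-E35: concordant euploid TE + ICM, euploid hESC.
  for (e in c("E34", "E35")) {
    add(e, "TE", rep_k(eu, 5))
    add(e, "ICM", rep_k(eu, 4))
    add(e, "hESC", rep_k(eu, 4))
  }
  # E36: ICM-only, mosaic complex with meiotic event; hESC mosaic complex.
  add("E36", "ICM", c(rep_k(with_m("E36"), 3), list(with_m("E36", cx_e))))
  add("E36", "hESC", c(rep_k(with_m("E36"), 3), list(with_m("E36", cx_e))))
  # E37: ICM-only, mosaic whole (mitotic); hESC euploid.
  add("E37", "ICM", c(rep_k(eu, 3), list(wh_b)))
  add("E37", "hESC", rep_k(eu, 4))
  # E38: ICM-only euploid; hESC euploid.
  add("E38", "ICM", rep_k(eu, 4))
  add("E38", "hESC", rep_k(eu, 4))
  # E39: below per-lineage evaluability (2 TE + 1 ICM) but 3 pooled cells.
  add("E39", "TE", list(eu, .demo_whole("chr12", +1)))
  add("E39", "ICM", list(eu))

  meta_rows <- list()
  call_rows <- list()
  counter <- new.env()
  for (s in spec) {
    for (k in s$k) {
      key <- paste(s$embryo, s$lineage, sep = "_")
      n <- (get0(key, envir = counter, ifnotfound = 0L)) + 1L
      assign(key, n, envir = counter)
      cid <- sprintf("%s_%s_%02d", s$embryo, s$lineage, n)
      meta_rows[[length(meta_rows) + 1L]] <- tibble::tibble(
        cell_id = cid, embryo_id = s$embryo, lineage = s$lineage)
      if (length(k)) {
        call_rows[[length(call_rows) + 1L]] <- dplyr::mutate(k, cell_id = cid, .before = 1)
      }
    }
  }
  metadata <- dplyr::bind_rows(meta_rows)
  calls <- dplyr::bind_rows(call_rows)
  attr(calls, "cells") <- metadata$cell_id
  attr(calls, "sex") <- "XX"
  class(calls) <- unique(c("karyotype_calls", class(calls)))
  list(metadata = metadata, calls = calls)
}
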
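# Embryo-level analytics: equality, classification, incidence, origin,
# discordance, complementary pairs, pseudo-bulk masking, rate comparison.

test_that("karyotype equality follows the reciprocal-overlap rule", {
  eu <- k_whole("chr1", 1)[0, ]
  expect_true(karyotypes_equal(eu, eu))
  expect_false(karyotypes_equal(k_whole("chr16", +1), k_whole("chr16", -1)))
  expect_false(karyotypes_equal(k_whole("chr16", +1), eu))
  # chr2 gain 10-60 Mb vs 12-58 Mb: overlap 46 Mb; 46/50 = 0.92, 46/46 = 1.0
  expect_true(karyotypes_equal(k_seg("chr2", 10, 60, 1), k_seg("chr2", 12, 58, 1),
                               reciprocal_overlap = 0.8))
  expect_false(karyotypes_equal(k_seg("chr2", 10, 60, 1), k_seg("chr2", 12, 58, 1),
                                reciprocal_overlap = 0.95))
  expect_false(karyotypes_equal(k_seg("chr2", 10, 60, 1), k_seg("chr2", 50, 100, 1)))
  # multi-call karyotypes need a full matching, order-independent
  a <- dplyr::bind_rows(k_whole("chr16", 1), k_seg("chr2", 10, 60, 1))
  b <- dplyr::bind_rows(k_seg("chr2", 12, 58, 1), k_whole("chr16", 1))
  expect_true(karyotypes_equal(a, b))
})

test_that("embryo classification covers euploid, mosaic and rate arithmetic", {
  md <- tibble::tibble(cell_id = sprintf("c%d", 1:5), embryo_id = "E1",
                       lineage = "TE")
  calls <- calls_object(cells = md$cell_id)
  cl <- classify_embryos(calls, md)
  expect_equal(cl$status, "non_mosaic_euploid")
  expect_equal(cl$mosaic_rate, 0)
  expect_equal(cl$subtype, "none")

  md4 <- tibble::tibble(cell_id = sprintf("c%d", 1:4), embryo_id = "E1",
                        lineage = "TE")
  calls <- calls_object(k_whole("chr21", 1, cell_id = "c4"), cells = md4$cell_id)
  cl <- classify_embryos(calls, md4)
  expect_equal(cl$status, "mosaic")
  expect_equal(cl$subtype, "whole")
  expect_equal(cl$mosaic_rate, 0.25)

  md10 <- tibble::tibble(cell_id = sprintf("c%02d", 1:10), embryo_id = "E1",
                         lineage = "ICM")
  calls <- calls_object(
    dplyr::bind_rows(lapply(sprintf("c%02d", 7:10), function(id)
      k_seg("chr2", 30, 70, 1, cell_id = id))),
    cells = md10$cell_id)
  cl <- classify_embryos(calls, md10)
  expect_equal(cl$mosaic_rate, 0.4)
  expect_equal(cl$subtype, "segmental")
})

test_that("uniform aneuploid cells are non-mosaic aneuploid", {
  md <- tibble::tibble(cell_id = sprintf("c%d", 1:4), embryo_id = "E1",
                       lineage = "TE")
  calls <- calls_object(
    dplyr::bind_rows(lapply(md$cell_id, function(id) k_whole("chr16", 1, cell_id = id))),
    cells = md$cell_id)
  cl <- classify_embryos(calls, md)
  expect_equal(cl$status, "non_mosaic_aneuploid")
  expect_equal(cl$mosaic_rate, 0)
})

test_that("sub-evaluable lineage sets are excluded from incidence denominators", {
  md <- tibble::tibble(cell_id = c("a", "b", "c", "d", "e"),
                       embryo_id = c("E1", "E1", "E2", "E2", "E2"),
                       lineage = "TE")
  calls <- calls_object(k_whole("chr21", 1, cell_id = "c"), cells = md$cell_id)
  cl <- classify_embryos(calls, md)
  expect_equal(cl$status[cl$embryo_id == "E1"], "insufficient_cells")
  inc <- cohort_incidence(cl)
  expect_equal(inc$n_evaluable, 1L)
  expect_equal(inc$n_mosaic, 1L)
})

test_that("incidence percentages are reported to two decimals", {
  mk <- function(n_mosaic, n_total, lineage) {
    tibble::tibble(
      embryo_id = sprintf("%s_E%d", lineage, seq_len(n_total)), lineage = lineage,
      n_cells = 5L, evaluable = TRUE,
      status = c(rep("mosaic", n_mosaic),
                 rep("non_mosaic_euploid", n_total - n_mosaic)),
      subtype = "none", mosaic_rate = 0, n_classes = 1L,
      major_karyotype = replicate(n_total, NULL, simplify = FALSE))
  }
  inc <- cohort_incidence(dplyr::bind_rows(mk(23, 35, "TE"), mk(2, 6, "hESC"),
                                           mk(0, 4, "ICM")))
  expect_equal(inc$pct[inc$lineage == "TE"], 65.71)
  expect_equal(inc$pct[inc$lineage == "hESC"], 33.33)
  expect_equal(inc$pct[inc$lineage == "ICM"], 0)
})

test_that("origin labels follow carrier counts and match simulated truth", {
  # definition: carried by every analyzed cell -> meiotic
  md <- tibble::tibble(cell_id = sprintf("c%d", 1:4), embryo_id = "E1",
                       lineage = "TE")
  all_cells <- dplyr::bind_rows(lapply(md$cell_id, function(id)
    k_whole("chr16", 1, cell_id = id)))
  calls <- calls_object(all_cells, k_whole("chr21", 1, cell_id = "c2"),
                        cells = md$cell_id)
  orig <- classify_origin(calls, md)
  expect_equal(orig$origin, "both")
  ev <- attr(orig, "events")
  expect_equal(ev$origin[ev$chrom == "chr16"], "meiotic")
  expect_equal(ev$origin[ev$chrom == "chr21"], "mitotic")

  # noiseless end-to-end: per-event labels consistent with SimTruth carriers
  cfg <- sim_config(grid = default_bin_grid(chroms = paste0("chr", 1:8)),
                    meiotic_prob = 1, mitotic_rate = 0.35, n_te = 4, n_icm = 3)
  tr <- simulate_embryo(cfg, seed = 14)
  cnt <- counts_from_cn(tr$cell_truth, cfg$grid, depth = 1000)
  res <- call_cells(cnt, flat_tracks(cfg$grid))
  orig <- classify_origin(res$calls, tr$cells)
  truth_ev <- tr$events[lengths(tr$events$carriers) > 0 &
                          (tr$events$end - tr$events$start) >= 1e7, ]
  got_ev <- attr(orig, "events")
  for (i in seq_len(nrow(truth_ev))) {
    carried_by_all <- setequal(truth_ev$carriers[[i]], tr$cells$cell_id)
    match <- got_ev[got_ev$chrom == truth_ev$chrom[i] &
                      sign(got_ev$delta) == sign(truth_ev$delta[i]), ]
    if (nrow(match) == 1) {
      expect_equal(match$origin, if (carried_by_all) "meiotic" else "mitotic",
                   label = sprintf("event %d", i))
    }
  }
})

test_that("TE-ICM discordance hits the exact boundary cases", {
  md <- tibble::tibble(cell_id = sprintf("c%d", 1:6), embryo_id = "E1",
                       lineage = rep(c("TE", "ICM"), each = 3))
  # identical karyotypes everywhere -> 0
  calls <- calls_object(cells = md$cell_id)
  d <- te_icm_discordance(calls, md, n_resamples = 50, seed = 3)
  expect_equal(d$discordance, 0)
  # disjoint karyotypes -> 1
  calls <- calls_object(
    dplyr::bind_rows(lapply(c("c4", "c5", "c6"), function(id)
      k_whole("chr16", 1, cell_id = id))),
    cells = md$cell_id)
  d <- te_icm_discordance(calls, md, n_resamples = 50, seed = 3)
  expect_equal(d$discordance, 1)
})

test_that("Monte-Carlo discordance converges to exhaustive enumeration", {
  # TE = {A, A, B}, ICM = {A, B, B}
  md <- tibble::tibble(cell_id = sprintf("c%d", 1:6), embryo_id = "E1",
                       lineage = rep(c("TE", "ICM"), each = 3))
  calls <- calls_object(
    k_whole("chr16", 1, cell_id = "c3"),
    k_whole("chr16", 1, cell_id = "c5"),
    k_whole("chr16", 1, cell_id = "c6"),
    cells = md$cell_id)
  want <- discordance_enum_oracle(c(1L, 1L, 2L), c(1L, 2L, 2L))
  got_mc <- te_icm_discordance(calls, md, n_resamples = 20000, seed = 8)$discordance
  got_exact <- te_icm_discordance(calls, md, method = "exact")$discordance
  expect_equal(got_exact, want, tolerance = 1e-12)
  expect_lt(abs(got_mc - want), 0.01)
})

test_that("complementary pairs require opposite deltas and shared regions", {
  md <- tibble::tibble(cell_id = c("A", "B", "C"), embryo_id = "E1", lineage = "TE")
  calls <- calls_object(k_whole("chr16", 1, cell_id = "A"),
                        k_whole("chr16", -1, cell_id = "B"),
                        k_whole("chr16", 1, cell_id = "C"),
                        cells = md$cell_id)
  pairs <- find_complementary_pairs(calls, md)
  # A(+1) pairs with B(-1), and B(-1) pairs with C(+1); A and C share a sign
  expect_equal(nrow(pairs), 2L)
  expect_setequal(paste(pairs$cell_a, pairs$cell_b), c("A B", "B C"))
  expect_true(all(pairs$delta == 1L))

  # same-sign calls never pair
  calls2 <- calls_object(k_whole("chr16", 1, cell_id = "A"),
                         k_whole("chr16", 1, cell_id = "C"),
                         cells = md$cell_id)
  expect_equal(nrow(find_complementary_pairs(calls2, md)), 0L)
})

test_that("simulated non-disjunction daughters are found as a pair", {
  cfg <- sim_config(grid = default_bin_grid(chroms = paste0("chr", 1:6)),
                    meiotic_prob = 0, mitotic_rate = 0, n_te = 4, n_icm = 0,
                    n_generations = 2)
  tr <- simulate_embryo(cfg, seed = 6)
  # plant one whole-chr3 non-disjunction by hand at the first division
  idx <- cfg$grid$chrom == "chr3"
  tr$cell_truth[tr$cells$leaf <= 2, idx] <- 3L
  tr$cell_truth[tr$cells$leaf > 2, idx] <- 1L
  tracks <- simulate_gc_track(cfg$grid, seed = 2)
  cnt <- emit_counts(tr, noise_model(), tracks, seed = 3)
  res <- call_cells(cnt, tracks)
  pairs <- find_complementary_pairs(res$calls, tr$cells)
  expect_gt(nrow(pairs), 0L)
  expect_true(all(pairs$chrom == "chr3"))
})

test_that("a balanced complementary pair is masked in the pseudo-bulk", {
  g <- default_bin_grid(chroms = c("chr1", "chr2", "chr3"))
  cn <- matrix(2L, 2, nrow(g), dimnames = list(c("gain", "loss"), NULL))
  cn["gain", g$chrom == "chr2"] <- 3L
  cn["loss", g$chrom == "chr2"] <- 1L
  cnt <- counts_from_cn(cn, g, depth = 1000)
  tracks <- flat_tracks(g)
  singles <- call_cells(cnt, tracks)$calls
  expect_setequal(singles$cell_id, c("gain", "loss"))
  expect_equal(sort(singles$delta), c(-1L, 1L))

  bulk <- simulate_multicell_biopsy(cnt, tracks, c("gain", "loss"))
  expect_equal(nrow(bulk), 0L)  # euploid bulk: the masking phenomenon
})

test_that("a uniform trisomy survives pseudo-bulk; a 20% minority does not", {
  g <- default_bin_grid(chroms = c("chr1", "chr2", "chr21"))
  tri_row <- function() { x <- rep(2L, nrow(g)); x[g$chrom == "chr21"] <- 3L; x }
  cn10 <- matrix(rep(tri_row(), each = 10), nrow = 10,
                 dimnames = list(sprintf("t%02d", 1:10), NULL))
  tr <- manual_truth(cn10, g)
  tracks <- simulate_gc_track(g, seed = 4)
  cnt <- emit_counts(tr, noise_model(), tracks, seed = 5)
  bulk <- simulate_multicell_biopsy(cnt, tracks, rownames(cn10), 10, seed = 1)
  expect_true(any(bulk$chrom == "chr21" & bulk$delta == 1L))

  cn_mix <- matrix(2L, 10, nrow(g), dimnames = list(sprintf("m%02d", 1:10), NULL))
  cn_mix[9:10, g$chrom == "chr21"] <- 3L  # 20% mosaic fraction
  cnt2 <- emit_counts(manual_truth(cn_mix, g), noise_model(), tracks, seed = 6)
  bulk2 <- simulate_multicell_biopsy(cnt2, tracks, rownames(cn_mix), 10, seed = 1)
  expect_false(any(bulk2$chrom == "chr21"))

  expect_error(simulate_multicell_biopsy(cnt2, tracks, rownames(cn_mix), 11),
               "exceeds available cells")
})

test_that("the per-chromosome tally reconciles with the calls", {
  md <- tibble::tibble(cell_id = c("a", "b", "c"), embryo_id = "E1",
                       lineage = c("TE", "TE", "ICM"))
  calls <- calls_object(k_whole("chr21", 1, cell_id = "a"),
                        k_whole("chr21", 1, cell_id = "b"),
                        k_seg("chr21", 1, 15, -1, cell_id = "b"),
                        cells = md$cell_id)
  tab <- chromosome_aneuploidy_table(calls, md)
  expect_true(all(tab$chrom == "chr21"))
  expect_equal(tab$n_cells[tab$class == "whole"], 2L)
  expect_equal(tab$n_cells[tab$class == "segmental"], 1L)
  expect_equal(sum(tab$n_events), nrow(calls))

  empty <- chromosome_aneuploidy_table(calls_object(cells = md$cell_id), md)
  expect_equal(nrow(empty), 0L)
})

test_that("one divergent cell makes the set discordant with a reference diagnosis", {
  md_cells <- c("a", "b", "c")
  ref_tri16 <- k_whole("chr16", 1)
  calls <- calls_object(
    dplyr::bind_rows(lapply(c("a", "b"), function(id) k_whole("chr16", 1, cell_id = id))),
    cells = md_cells)
  res <- compare_to_reference(calls, md_cells, ref_tri16)
  expect_false(res$concordant)          # cell c is euploid, reference is not
  expect_equal(res$n_discordant_cells, 1L)

  calls_all <- calls_object(
    dplyr::bind_rows(lapply(md_cells, function(id) k_whole("chr16", 1, cell_id = id))),
    cells = md_cells)
  expect_true(compare_to_reference(calls_all, md_cells, ref_tri16)$concordant)
  # euploid cells against a euploid reference
  expect_true(compare_to_reference(calls_object(cells = md_cells), md_cells,
                                   ref_tri16[0, ])$concordant)
})

test_that("rate comparison matches the closed-form pooled t-test", {
  a <- c(0.38, 0.42, 0.51, 0.29, 0.44)
  b <- c(0.21, 0.33, 0.27, 0.19)
  res <- compare_rates(a, b)
  # closed form: t = (xbar - ybar) / (sp * sqrt(1/n1 + 1/n2))
  sp <- sqrt(((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
               (length(a) + length(b) - 2))
  t_hand <- (mean(a) - mean(b)) / (sp * sqrt(1 / length(a) + 1 / length(b)))
  p_hand <- 2 * pt(-abs(t_hand), length(a) + length(b) - 2)
  expect_equal(res$statistic, t_hand, tolerance = 1e-12)
  expect_equal(res$p_value, p_hand, tolerance = 1e-12)

  same <- compare_rates(c(1, 1, 1), c(1, 1))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  expect_true(same$degenerate)

  expect_error(compare_rates(1, c(1, 2)), "insufficient observations")
})

test_that("glance and tidy methods summarise classification objects", {
  demo <- demo_cohort()
  cl <- classify_embryos(demo$calls, demo$metadata)
  td <- tidy(cl)
  expect_false("major_karyotype" %in% names(td))
  gl <- glance(cl)
  expect_equal(gl$n_evaluable, 56L)  # 35 TE + 15 ICM + 6 hESC
  orig <- classify_origin(demo$calls, demo$metadata)
  go <- glance(orig)
  expect_equal(go$n_embryos, 39L)
  expect_equal(nrow(tidy(orig)) > 0, TRUE)
})
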
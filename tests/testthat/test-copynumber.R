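# GC/mappability correction, HMM decoding, segmentation, karyotype calls.

test_that("flat counts with flat GC and full mappability correct to 1", {
  g <- tiny_grid(3, 80)
  cnt <- counts_from_cn(matrix(2L, 1, nrow(g), dimnames = list("c1", NULL)), g,
                        depth = 500)
  prof <- correct_counts(cnt, flat_tracks(g))
  expect_true(all(abs(prof$corrected - 1) < 1e-8))
  expect_true(attr(prof, "cell_status")$analyzable)
})

test_that("a known monotone GC bias is removed by correction", {
  set.seed(31)
  g <- default_bin_grid(bin_width = 5e4, chroms = c("chr1", "chr2"))
  tracks <- flat_tracks(g)
  tracks$gc <- pmin(pmax(rnorm(nrow(g), 0.41, 0.06), 0.25), 0.65)
  cn <- matrix(2L, 1, nrow(g), dimnames = list("c1", NULL))
  nm <- noise_model(mean_depth = 300, dispersion = 0.01, dropout_rate = 0,
                    gc_bias_curve = function(gc) exp(2 * gc))  # strong monotone bias
  cnt <- emit_counts(manual_truth(cn, g), nm, tracks, seed = 17)
  raw_r <- cor(cnt$c1, tracks$gc)
  expect_gt(abs(raw_r), 0.5)  # bias clearly present before correction
  prof <- correct_counts(cnt, tracks)
  ok <- !prof$masked & !is.na(prof$corrected)
  expect_lt(abs(cor(prof$corrected[ok], tracks$gc[ok])), 0.05)
})

test_that("low-mappability bins are masked and excluded from the median anchor", {
  g <- tiny_grid(3, 60)
  tracks <- flat_tracks(g)
  low <- c(5, 50, 120)
  tracks$mappability[low] <- 0
  cnt <- counts_from_cn(matrix(2L, 1, nrow(g), dimnames = list("c1", NULL)), g,
                        depth = 400)
  cnt$c1[low] <- 0L  # no signal where unmappable
  prof <- correct_counts(cnt, tracks)
  expect_true(all(prof$masked[low]))
  expect_true(all(is.na(prof$corrected[low])))
  expect_equal(median(prof$corrected[!prof$masked]), 1)
})

test_that("an all-zero cell is flagged unanalyzable, not an error", {
  g <- tiny_grid(3, 40)
  cnt <- counts_from_cn(matrix(2L, 1, nrow(g), dimnames = list("good", NULL)), g)
  cnt$dead <- 0L
  prof <- correct_counts(cnt, flat_tracks(g))
  status <- attr(prof, "cell_status")
  expect_false(status$analyzable[status$cell_id == "dead"])
  expect_true(status$analyzable[status$cell_id == "good"])
  states <- infer_copy_number(prof)
  expect_true(all(is.na(states$state[states$cell_id == "dead"])))
})

test_that("a constant corrected profile decodes to the baseline state everywhere", {
  g <- tiny_grid(4, 50)
  cnt <- counts_from_cn(matrix(2L, 1, nrow(g), dimnames = list("c1", NULL)), g,
                        depth = 1000)
  states <- infer_copy_number(correct_counts(cnt, flat_tracks(g)))
  expect_true(all(states$state == 2L))
})

test_that("Viterbi decoding matches exhaustive path enumeration", {
  p <- hmm_params()
  # two-bin toy chromosome: all 36 paths enumerated
  x2 <- c(1.02, 1.55)
  expect_equal(embryomosaic:::.viterbi(x2, p$means, 0.12, p$self_transition,
                                       p$outlier_prob, p$outlier_density),
               viterbi_enum_oracle(x2, p$means, 0.12, p$self_transition,
                                   p$outlier_prob, p$outlier_density))
  # random profiles up to 8 bins, several noise levels
  set.seed(1234)
  for (rep in 1:20) {
    n <- sample(2:8, 1)
    sd <- runif(1, 0.08, 0.3)
    truth <- cumsum(c(2, sample(c(-1, 0, 0, 0, 1), n - 1, replace = TRUE)))
    truth <- pmin(pmax(truth, 0), 5)
    x <- truth / 2 + rnorm(n, 0, sd)
    got <- embryomosaic:::.viterbi(x, p$means, sd, p$self_transition,
                                   p$outlier_prob, p$outlier_density)
    want <- viterbi_enum_oracle(x, p$means, sd, p$self_transition,
                                p$outlier_prob, p$outlier_density)
    expect_equal(got, want, label = sprintf("rep %d (n=%d, sd=%.2f)", rep, n, sd))
  }
})

test_that("a planted whole-chromosome trisomy is recovered at default noise", {
  cfg <- sim_config(grid = default_bin_grid(chroms = paste0("chr", c(1, 2, 21))),
                    meiotic_prob = 0, mitotic_rate = 0, n_te = 1, n_icm = 0)
  tr <- simulate_embryo(cfg, seed = 10)
  tr$cell_truth[1, cfg$grid$chrom == "chr21"] <- 3L
  tracks <- simulate_gc_track(cfg$grid, seed = 10)
  cnt <- emit_counts(tr, noise_model(), tracks, seed = 11)
  states <- infer_copy_number(correct_counts(cnt, tracks))
  on21 <- states$chrom == "chr21" & !is.na(states$state)
  off21 <- states$chrom != "chr21" & !is.na(states$state)
  expect_gte(mean(states$state[on21] == 3L), 0.95)
  expect_gte(mean(states$state[off21] == 2L), 0.95)
})

test_that("segments are maximal constant-state runs that reconstruct the states", {
  g <- tiny_grid(1, 5)
  st <- tibble::tibble(cell_id = "c1", chrom = g$chrom, start = g$start,
                       end = g$end, state = c(2L, 2L, 3L, 3L, 2L), masked = FALSE)
  segs <- segment_states(st)
  expect_equal(nrow(segs), 3L)
  expect_equal(segs$state, c(2L, 3L, 2L))
  expect_equal(segs$n_bins, c(2L, 2L, 1L))

  st$state <- 2L
  expect_equal(nrow(segment_states(st)), 1L)

  # property: concatenated segments reproduce arbitrary state vectors
  set.seed(7)
  for (rep in 1:25) {
    n <- sample(3:40, 1)
    gg <- tiny_grid(1, n)
    sv <- sample(0:5, n, replace = TRUE)
    stt <- tibble::tibble(cell_id = "c", chrom = gg$chrom, start = gg$start,
                          end = gg$end, state = sv, masked = FALSE)
    segs <- segment_states(stt)
    recon <- unlist(mapply(rep, segs$state, segs$n_bins, SIMPLIFY = FALSE))
    expect_equal(recon, sv)
    expect_equal(sum(segs$n_bins), n)
  }
})

test_that("karyotype calls respect the 10 Mb rule and whole/segmental classes", {
  g <- default_bin_grid(chroms = c("chr2", "chr21"))
  mk_states <- function(state_vec) {
    out <- tibble::tibble(cell_id = "c1", chrom = g$chrom, start = g$start,
                          end = g$end, state = state_vec, masked = FALSE)
    attr(out, "cell_status") <- tibble::tibble(cell_id = "c1", analyzable = TRUE,
                                               note = "")
    out
  }
  base <- rep(2L, nrow(g))

  # 9 Mb gain: below threshold, karyotype stays euploid
  s <- base
  s[g$chrom == "chr2"][10:18] <- 3L
  calls <- call_karyotypes(mk_states(s))
  expect_equal(nrow(calls), 0L)
  expect_equal(attr(calls, "cells"), "c1")

  # whole chr21 gain
  s <- base
  s[g$chrom == "chr21"] <- 3L
  calls <- call_karyotypes(mk_states(s))
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$class, "whole")
  expect_equal(calls$delta, 1L)
  expect_equal(karyotype_string(calls), "47,XX,+21")

  # 30 Mb loss on 243 Mb chr2: segmental
  s <- base
  s[g$chrom == "chr2"][21:50] <- 1L
  calls <- call_karyotypes(mk_states(s))
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$class, "segmental")
  expect_equal(calls$delta, -1L)
  expect_equal(calls$length_bp, 3e7)
})

test_that("same-state runs merge across masked gaps before the size test", {
  g <- default_bin_grid(chroms = "chr2")
  s <- rep(2L, nrow(g))
  s[30:45] <- 3L
  masked <- rep(FALSE, nrow(g))
  masked[37:38] <- TRUE  # masked gap inside a 16 Mb event: 7 + 7 called bins
  st <- tibble::tibble(cell_id = "c1", chrom = g$chrom, start = g$start,
                       end = g$end, state = ifelse(masked, NA_integer_, s),
                       masked = masked)
  attr(st, "cell_status") <- tibble::tibble(cell_id = "c1", analyzable = TRUE,
                                            note = "")
  calls <- call_karyotypes(st)
  expect_equal(nrow(calls), 1L)  # one merged 14-bin call, not two sub-10 Mb pieces
  expect_equal(calls$delta, 1L)
  expect_equal(calls$length_bp, 14e6)
})

test_that("karyotype calling is deterministic and recovery improves with less noise", {
  cfg <- sim_config(grid = default_bin_grid(chroms = paste0("chr", 1:6)),
                    meiotic_prob = 0.5, mitotic_rate = 0.3, n_te = 2, n_icm = 2)
  co <- simulate_cohort(6, cfg, noise_model(), seed = 55)
  r1 <- call_cells(co$counts, co$tracks)
  r2 <- call_cells(co$counts, co$tracks)
  expect_equal(r1$calls, r2$calls)

  recovery_at <- function(alpha, seed = 91) {
    nm <- noise_model(dispersion = alpha, dispersion_sdlog = 0)
    co <- simulate_cohort(8, cfg, nm, seed = seed)
    res <- call_cells(co$counts, co$tracks)
    ev <- co$events
    if (is.null(ev) || !nrow(ev)) return(NA_real_)
    hits <- 0L; tot <- 0L
    for (i in seq_len(nrow(ev))) {
      for (cell in ev$carriers[[i]]) {
        tot <- tot + 1L
        ok <- any(res$calls$cell_id == cell & res$calls$chrom == ev$chrom[i] &
                    sign(res$calls$delta) == sign(ev$delta[i]))
        hits <- hits + ok
      }
    }
    if (tot == 0L) NA_real_ else hits / tot
  }
  r_noisy <- recovery_at(0.08)
  r_clean <- recovery_at(0.005)
  expect_gte(r_clean, r_noisy - 0.03)  # monotone within Monte-Carlo tolerance
})
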
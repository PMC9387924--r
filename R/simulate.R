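# Synthetic embryo cohorts: known meiotic/mitotic CNV events propagated
# through a balanced binary lineage tree, emitted as noisy binned counts that
# emulate low-coverage (~0.3x) single-cell whole-genome-amplification data.

#' Simulation parameters for a synthetic embryo
#'
#' Defaults describe the cohorts used for validation: 8 TE and 7 ICM cells
#' sampled from a 6-generation balanced binary lineage tree, a 38% chance of
#' one meiotic (zygotic) whole-chromosome-biased event, and a per-division
#' mitotic error rate of 0.05 split evenly between non-disjunction (reciprocal
#' +1/-1 daughters) and anaphase lagging (a single -1 daughter).
#'
#' @param n_te,n_icm,n_hesc Cells sampled per lineage (hESC cells are drawn
#'   from ICM-descended leaves).
#' @param n_generations Depth of the balanced binary lineage tree.
#' @param meiotic_prob Probability that the embryo carries one meiotic event,
#'   present in every cell.
#' @param p_whole_meiotic Probability a meiotic event is whole-chromosome.
#' @param mitotic_rate Per-division probability of a mitotic error.
#' @param p_nondisjunction Given a mitotic error, probability it is a
#'   non-disjunction (otherwise anaphase lag).
#' @param p_whole Probability a mitotic event is whole-chromosome.
#' @param seg_size_range Segmental event length range in bp.
#' @param hesc_selection Multiplicative fitness penalty per aneuploid
#'   chromosome during hESC sampling; 0 disables selection.
#' @param sex `"XX"` or `"XY"`; sets the baseline copy of sex chromosomes.
#' @param grid The `bin_grid` to simulate on (default: 1 Mb human-like grid).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_te = 8, n_icm = 7, n_hesc = 0,
                       n_generations = 6,
                       meiotic_prob = 0.38, p_whole_meiotic = 0.9,
                       mitotic_rate = 0.05, p_nondisjunction = 0.5,
                       p_whole = 0.6, seg_size_range = c(10e6, 80e6),
                       hesc_selection = 0,
                       sex = c("XX", "XY"), grid = NULL) {
  sex <- match.arg(sex)
  if (is.null(grid)) grid <- default_bin_grid(sex = sex)
  stopifnot(n_te >= 0, n_icm >= 0, n_hesc >= 0, n_generations >= 1,
            meiotic_prob >= 0, meiotic_prob <= 1,
            mitotic_rate >= 0, mitotic_rate <= 1,
            2^n_generations >= n_te + n_icm)
  structure(list(
    n_te = n_te, n_icm = n_icm, n_hesc = n_hesc,
    n_generations = n_generations,
    meiotic_prob = meiotic_prob, p_whole_meiotic = p_whole_meiotic,
    mitotic_rate = mitotic_rate, p_nondisjunction = p_nondisjunction,
    p_whole = p_whole, seg_size_range = seg_size_range,
    hesc_selection = hesc_selection, sex = sex, grid = grid
  ), class = "sim_config")
}

#' Amplification-noise model for count emission
#'
#' Counts are drawn from a negative binomial with mean proportional to copy
#' number, GC bias and mappability, the usual model for overdispersed
#' low-coverage single-cell counts: `var = mu + alpha * mu^2`. The dispersion
#' `alpha` is drawn per cell from a lognormal with mean `dispersion`,
#' emulating cell-to-cell amplification variability; `dispersion = 0` gives
#' Poisson counts and `dispersion_sdlog = 0` removes cell-to-cell spread.
#'
#' @param mean_depth Expected reads per bin in a copy-2 bin with neutral GC
#'   and full mappability (about 1000 reads/Mb at 0.3x coverage with 100 bp
#'   reads).
#' @param dispersion Mean negative-binomial dispersion `alpha`.
#' @param dispersion_sdlog Lognormal sdlog of the per-cell dispersion.
#' @param dropout_rate Per-bin probability of complete amplification failure
#'   (count forced to 0).
#' @param gc_bias_curve Positive function of GC fraction giving the relative
#'   amplification rate; default a smooth bump peaked at GC 0.45.
#' @return A list of class `noise_model`.
#' @export
noise_model <- function(mean_depth = 1000, dispersion = 0.02,
                        dispersion_sdlog = 0.5, dropout_rate = 0.01,
                        gc_bias_curve = function(gc) exp(-8 * (gc - 0.45)^2)) {
  stopifnot(mean_depth > 0, dispersion >= 0, dispersion_sdlog >= 0,
            dropout_rate >= 0, dropout_rate <= 1)
  if (any(gc_bias_curve(seq(0, 1, by = 0.05)) <= 0)) {
    stop("gc_bias_curve must be positive on [0, 1]")
  }
  structure(list(mean_depth = mean_depth, dispersion = dispersion,
                 dispersion_sdlog = dispersion_sdlog,
                 dropout_rate = dropout_rate, gc_bias_curve = gc_bias_curve),
            class = "noise_model")
}

baseline_copies <- function(grid, sex) {
  base <- rep(2L, nrow(grid))
  if (sex == "XY") base[grid$chrom %in% c("chrX", "chrY")] <- 1L
  base
}

# Leaves (0-based block indices) descending from one daughter of a division.
# Division at generation k splits each of the 2^(k-1) nodes; daughter `side`
# (1 or 2) of node j covers a contiguous block of 2^(g-k) leaves.
.daughter_leaves <- function(g, k, j, side) {
  block <- 2^(g - k)
  first <- j * 2 * block + (side - 1) * block
  seq.int(first + 1L, first + block)
}

# Draw a candidate event region on the grid; returns grid row indices.
.draw_region <- function(grid, whole, seg_size_range, bin_width) {
  chroms <- unique(grid$chrom)
  ch <- sample(chroms, 1)
  idx <- which(grid$chrom == ch)
  if (whole) return(idx)
  n_bins_chr <- length(idx)
  len_bins <- max(1L, round(stats::runif(1, seg_size_range[1], seg_size_range[2]) / bin_width))
  len_bins <- min(len_bins, n_bins_chr)
  s <- sample.int(n_bins_chr - len_bins + 1L, 1)
  idx[s:(s + len_bins - 1L)]
}

#' Simulate one embryo with known CNV events
#'
#' Grows a balanced binary lineage tree from the zygote, plants an optional
#' meiotic event (carried by every cell) and per-division mitotic errors
#' (non-disjunction yields reciprocal +1/-1 daughter lineages over identical
#' bins; anaphase lag yields a single -1 daughter), then samples TE, ICM and
#' optionally hESC cells from the leaves. An event whose application would
#' drive copy number below zero is re-placed (up to 50 attempts) and dropped
#' if no valid placement exists.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed; `NULL` uses the current RNG state (as when
#'   called from [simulate_cohort()]).
#' @param embryo_id Label stored in the cell table.
#' @return A list of class `sim_truth` with elements `events` (tibble: one row
#'   per planted event with coordinates, delta, origin, division index,
#'   reciprocal partner and carrier cells), `cell_truth` (integer matrix,
#'   cells x bins), `cells` (tibble: cell_id, embryo_id, lineage), `grid`,
#'   `baseline`, `sex`.
#' @export
simulate_embryo <- function(config, seed = NULL, embryo_id = "E01") {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  grid <- config$grid
  g <- config$n_generations
  n_leaves <- 2^g
  bin_width <- max(grid$end - grid$start)
  base <- baseline_copies(grid, config$sex)
  truth <- matrix(rep(base, each = n_leaves), nrow = n_leaves)

  events <- list()
  ev_id <- 0L
  add_event <- function(region, delta, origin, division_index, leaves, partner = NA_integer_) {
    ev_id <<- ev_id + 1L
    events[[ev_id]] <<- tibble::tibble(
      event_id = ev_id,
      chrom = grid$chrom[region[1]],
      start = grid$start[region[1]], end = grid$end[region[length(region)]],
      start_bin = region[1] - 1L, end_bin = region[length(region)],
      delta = delta, origin = origin,
      division_index = division_index,
      reciprocal_partner = partner,
      class = if (length(region) == sum(grid$chrom == grid$chrom[region[1]])) "whole" else "segmental",
      leaves = list(leaves)
    )
    truth[leaves, region] <<- truth[leaves, region] + delta
    ev_id
  }

  # Meiotic event: present in all cells, placed before any division.
  if (stats::runif(1) < config$meiotic_prob) {
    for (attempt in 1:50) {
      whole <- stats::runif(1) < config$p_whole_meiotic
      region <- .draw_region(grid, whole, config$seg_size_range, bin_width)
      delta <- sample(c(-1L, 1L), 1)
      if (all(truth[, region] + delta >= 0)) {
        add_event(region, delta, "meiotic", NA_integer_, seq_len(n_leaves))
        break
      }
    }
  }

  # Mitotic errors, chronologically through the divisions.
  for (k in seq_len(g)) {
    for (j in seq_len(2^(k - 1)) - 1L) {
      if (stats::runif(1) >= config$mitotic_rate) next
      nd <- stats::runif(1) < config$p_nondisjunction
      placed <- FALSE
      for (attempt in 1:50) {
        whole <- stats::runif(1) < config$p_whole
        region <- .draw_region(grid, whole, config$seg_size_range, bin_width)
        gain_side <- sample(1:2, 1)
        la <- .daughter_leaves(g, k, j, gain_side)
        lb <- .daughter_leaves(g, k, j, 3 - gain_side)
        if (nd) {
          if (all(truth[lb, region] - 1L >= 0)) {
            a <- add_event(region, +1L, "mitotic", k, la)
            b <- add_event(region, -1L, "mitotic", k, lb, partner = a)
            events[[a]]$reciprocal_partner <- b
            placed <- TRUE
          }
        } else {
          if (all(truth[lb, region] - 1L >= 0)) {
            add_event(region, -1L, "mitotic", k, lb)
            placed <- TRUE
          }
        }
        if (placed) break
      }
    }
  }

  events <- if (length(events)) dplyr::bind_rows(events) else tibble::tibble(
    event_id = integer(), chrom = character(), start = numeric(), end = numeric(),
    start_bin = integer(), end_bin = integer(), delta = integer(),
    origin = character(), division_index = integer(),
    reciprocal_partner = integer(), class = character(), leaves = list()
  )

  # Sample cells from the leaves: TE/ICM by random partition, hESC from
  # ICM-descended leaves with optional selection against aneuploid genomes.
  picked <- sample.int(n_leaves, config$n_te + config$n_icm)
  te_leaves <- picked[seq_len(config$n_te)]
  icm_leaves <- setdiff(picked, te_leaves)
  hesc_leaves <- integer(0)
  if (config$n_hesc > 0) {
    if (!length(icm_leaves)) stop("hESC cells require ICM leaves to sample from")
    n_aneu <- vapply(icm_leaves, function(l) {
      dev <- truth[l, ] != base
      length(unique(grid$chrom[dev]))
    }, integer(1))
    w <- exp(-config$hesc_selection * n_aneu)
    hesc_leaves <- sample(icm_leaves, config$n_hesc, replace = TRUE, prob = w)
  }

  leaves_used <- c(te_leaves, icm_leaves, hesc_leaves)
  lineage <- c(rep("TE", config$n_te), rep("ICM", config$n_icm),
               rep("hESC", config$n_hesc))
  cell_id <- sprintf("%s_%s_%02d", embryo_id, lineage,
                     stats::ave(seq_along(lineage), lineage, FUN = seq_along))
  cells <- tibble::tibble(cell_id = cell_id, embryo_id = embryo_id,
                          lineage = lineage, leaf = leaves_used)
  cell_truth <- truth[leaves_used, , drop = FALSE]
  rownames(cell_truth) <- cell_id

  if (nrow(events)) {
    events$carriers <- purrr::map(events$leaves, function(lv) cells$cell_id[cells$leaf %in% lv])
  } else {
    events$carriers <- list()
  }

  structure(list(events = events, cell_truth = cell_truth, cells = cells,
                 grid = grid, baseline = base, sex = config$sex),
            class = "sim_truth")
}

#' Emit noisy binned counts for a simulated embryo
#'
#' For cell c and bin b the expected count is
#' `copy[c,b]/2 * mean_depth * gc_bias(gc[b]) * mappability[b]` with the GC
#' curve rescaled to mean 1 over the track, so a copy-3 bin carries on average
#' 1.5x the reads of a copy-2 bin. Counts are negative-binomial with the
#' per-cell dispersion of the noise model; dropout bins are zeroed.
#'
#' @param truth A `sim_truth` from [simulate_embryo()].
#' @param noise A [noise_model()].
#' @param tracks Per-bin reference tracks aligned to the truth's grid
#'   (columns `gc`, `mappability`).
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return A wide counts tibble: `chrom`, `start`, `end`, then one integer
#'   column per cell.
#' @export
emit_counts <- function(truth, noise, tracks, seed = NULL) {
  stopifnot(inherits(truth, "sim_truth"), inherits(noise, "noise_model"))
  if (nrow(tracks) != nrow(truth$grid)) {
    stop(sprintf("tracks have %d bins but grid has %d", nrow(tracks), nrow(truth$grid)))
  }
  if (!is.null(seed)) set.seed(seed)
  gfac <- noise$gc_bias_curve(tracks$gc)
  gfac[is.na(gfac)] <- 1
  gfac <- gfac / mean(gfac)
  map <- ifelse(is.na(tracks$mappability), 0, tracks$mappability)
  n_bins <- nrow(truth$grid)
  out <- lapply(seq_len(nrow(truth$cell_truth)), function(i) {
    mu <- truth$cell_truth[i, ] / 2 * noise$mean_depth * gfac * map
    if (noise$dispersion <= 0) {
      cnt <- stats::rpois(n_bins, mu)
    } else {
      alpha <- stats::rlnorm(1, log(noise$dispersion) - noise$dispersion_sdlog^2 / 2,
                             noise$dispersion_sdlog)
      cnt <- stats::rnbinom(n_bins, mu = mu, size = 1 / alpha)
    }
    if (noise$dropout_rate > 0) {
      cnt[stats::runif(n_bins) < noise$dropout_rate] <- 0L
    }
    as.integer(cnt)
  })
  names(out) <- rownames(truth$cell_truth)
  dplyr::bind_cols(truth$grid[, c("chrom", "start", "end")], tibble::as_tibble(out))
}

#' Simulate per-bin GC and mappability tracks
#'
#' GC fractions are drawn around a genome-like mean with mild spread and a
#' configurable fraction of low-mappability bins (which downstream correction
#' masks).
#'
#' @param grid A `bin_grid`.
#' @param gc_mean,gc_sd Mean and SD of per-bin GC fraction.
#' @param low_map_frac Fraction of bins given mappability below 0.5.
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return A tracks tibble aligned to `grid`.
#' @export
simulate_gc_track <- function(grid, gc_mean = 0.41, gc_sd = 0.05,
                              low_map_frac = 0.02, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(grid)
  gc <- pmin(pmax(stats::rnorm(n, gc_mean, gc_sd), 0.2), 0.8)
  mapp <- rep(1, n)
  n_low <- round(low_map_frac * n)
  if (n_low > 0) {
    low <- sample.int(n, n_low)
    mapp[low] <- stats::runif(n_low, 0, 0.5)
  }
  dplyr::bind_cols(grid[, c("chrom", "start", "end")],
                   tibble::tibble(gc = gc, mappability = mapp))
}

#' Simulate a cohort of embryos
#'
#' Repeats [simulate_embryo()] + [emit_counts()] over `n_embryos` embryos on a
#' shared grid and GC/mappability track. Fully reproducible for a fixed seed.
#'
#' @param n_embryos Number of embryos (>= 1).
#' @param config A [sim_config()] shared by all embryos.
#' @param noise A [noise_model()].
#' @param tracks Optional tracks tibble; simulated once if `NULL`.
#' @param seed Integer seed for the whole cohort.
#' @return A list of class `sim_cohort`: `grid`, `tracks`, `counts` (wide
#'   tibble over all cells), `metadata`, `truth` (list of `sim_truth`),
#'   `events` (all events with `embryo_id`).
#' @export
simulate_cohort <- function(n_embryos, config = sim_config(),
                            noise = noise_model(), tracks = NULL, seed = 1) {
  stopifnot(n_embryos >= 1)
  set.seed(seed)
  grid <- config$grid
  if (is.null(tracks)) tracks <- simulate_gc_track(grid)
  ids <- sprintf("E%03d", seq_len(n_embryos))
  truths <- vector("list", n_embryos)
  counts <- vector("list", n_embryos)
  for (i in seq_len(n_embryos)) {
    truths[[i]] <- simulate_embryo(config, seed = NULL, embryo_id = ids[i])
    counts[[i]] <- emit_counts(truths[[i]], noise, tracks, seed = NULL)
  }
  names(truths) <- ids
  all_counts <- dplyr::bind_cols(
    grid[, c("chrom", "start", "end")],
    purrr::map_dfc(counts, ~ .x[, setdiff(names(.x), c("chrom", "start", "end"))])
  )
  metadata <- purrr::map_dfr(truths, ~ .x$cells[, c("cell_id", "embryo_id", "lineage")])
  events <- purrr::map_dfr(truths, function(tr) {
    if (!nrow(tr$events)) return(NULL)
    dplyr::mutate(tr$events, embryo_id = tr$cells$embryo_id[1], .before = 1)
  })
  structure(list(grid = grid, tracks = tracks, counts = all_counts,
                 metadata = metadata, truth = truths, events = events,
                 seed = seed),
            class = "sim_cohort")
}

#' Write a simulated cohort to disk
#'
#' Emits the standard interchange files: `grid.bed`, `counts.tsv`,
#' `tracks.tsv`, `metadata.tsv` and `truth.json` (events and per-cell labels)
#' plus `truth_copynumber.tsv` (integer copy number per bin per cell, in the
#' counts layout).
#'
#' @param cohort A `sim_cohort`.
#' @param outdir Output directory, created if needed.
#' @return `outdir`, invisibly.
#' @export
write_cohort <- function(cohort, outdir) {
  stopifnot(inherits(cohort, "sim_cohort"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_bin_grid(cohort$grid, file.path(outdir, "grid.bed"))
  write_counts(cohort$counts, file.path(outdir, "counts.tsv"))
  write_tracks(cohort$tracks, file.path(outdir, "tracks.tsv"))
  write_cell_metadata(cohort$metadata, file.path(outdir, "metadata.tsv"))
  ev <- cohort$events
  if (!is.null(ev) && nrow(ev)) {
    ev <- dplyr::select(ev, -dplyr::any_of(c("leaves")))
  }
  truth_cn <- dplyr::bind_cols(
    cohort$grid[, c("chrom", "start", "end")],
    tibble::as_tibble(t(do.call(rbind, lapply(cohort$truth, function(tr) tr$cell_truth))))
  )
  write_counts(truth_cn, file.path(outdir, "truth_copynumber.tsv"))
  jsonlite::write_json(
    list(seed = cohort$seed,
         events = ev,
         cells = cohort$metadata),
    file.path(outdir, "truth.json"),
    dataframe = "rows", auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(outdir)
}
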
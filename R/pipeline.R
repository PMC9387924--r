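# Config-driven pipeline entry points tying the stages together:
# simulate -> call -> analyze -> report. Each step reads/writes the standard
# interchange files (BED grid, TSV counts/tracks/metadata, TSV/JSON results)
# and embeds the config hash so a run is reproducible from its outputs.

default_run_config <- function() {
  list(
    outdir = "embryomosaic_run",
    seed = 1,
    n_embryos = 5,
    sex = "XX",
    bin_width = 1e6,
    n_te = 8, n_icm = 7, n_hesc = 0,
    meiotic_prob = 0.38, mitotic_rate = 0.05,
    mean_depth = 1000, dispersion = 0.02, dropout_rate = 0.01,
    min_mappability = 0.8,
    min_cnv_size = 1e7, whole_fraction = 0.9,
    exclude_fraction = 0.15, n_windows = 30,
    reciprocal_overlap = 0.8,
    n_resamples = 1000,
    biopsy_size = 5
  )
}

#' Load a run configuration
#'
#' Reads a YAML (or JSON) configuration file and fills unspecified fields
#' with package defaults. A list is passed through with the same defaulting.
#'
#' @param config Path to a YAML/JSON file, a list of overrides, or `NULL`
#'   for all defaults.
#' @return A named list of class `run_config` with a `hash` attribute.
#' @export
load_run_config <- function(config = NULL) {
  base <- default_run_config()
  user <- list()
  if (is.character(config)) {
    if (!file.exists(config)) stop("no such config file: ", config)
    user <- if (grepl("\\.json$", config)) jsonlite::read_json(config, simplifyVector = TRUE)
    else yaml::read_yaml(config)
  } else if (is.list(config)) {
    user <- config
  }
  unknown <- setdiff(names(user), names(base))
  if (length(unknown)) stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  base[names(user)] <- user
  key <- paste(names(base),
               vapply(base, function(v) paste(format(v), collapse = ","), ""),
               sep = "=", collapse = ";")
  ints <- utf8ToInt(key)
  hash <- sprintf("%08x", sum(ints * seq_along(ints)) %% .Machine$integer.max)
  attr(base, "hash") <- hash
  class(base) <- "run_config"
  base
}

.write_run_config <- function(cfg, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(c(unclass(cfg), list(config_hash = attr(cfg, "hash"))),
                   file.path(outdir, "run_config.yaml"))
}

#' Simulate a cohort to disk
#'
#' @param config A config path, list or `run_config` (see
#'   [load_run_config()]).
#' @return The output directory, invisibly.
#' @export
run_simulate <- function(config = NULL) {
  cfg <- if (inherits(config, "run_config")) config else load_run_config(config)
  sc <- sim_config(n_te = cfg$n_te, n_icm = cfg$n_icm, n_hesc = cfg$n_hesc,
                   meiotic_prob = cfg$meiotic_prob, mitotic_rate = cfg$mitotic_rate,
                   sex = cfg$sex,
                   grid = default_bin_grid(bin_width = cfg$bin_width, sex = cfg$sex))
  nm <- noise_model(mean_depth = cfg$mean_depth, dispersion = cfg$dispersion,
                    dropout_rate = cfg$dropout_rate)
  cohort <- simulate_cohort(cfg$n_embryos, sc, nm, seed = cfg$seed)
  write_cohort(cohort, cfg$outdir)
  .write_run_config(cfg, cfg$outdir)
  message(sprintf("simulated %d embryos, %d cells [config %s]",
                  cfg$n_embryos, nrow(cohort$metadata), attr(cfg, "hash")))
  invisible(cfg$outdir)
}

#' Call per-cell karyotypes and QC from a cohort directory
#'
#' Reads `grid.bed`, `counts.tsv`, `tracks.tsv` and `metadata.tsv` from the
#' configured directory, runs GC/mappability correction, the variability
#' score with batch-relative exclusion, HMM copy-number decoding and
#' karyotype calling on the retained cells, and writes `qc_report.tsv` and
#' `karyotypes.tsv`.
#'
#' @inheritParams run_simulate
#' @return Invisibly, a list with `profiles`, `scores`, `states`, `calls`.
#' @export
run_call <- function(config = NULL) {
  cfg <- if (inherits(config, "run_config")) config else load_run_config(config)
  outdir <- cfg$outdir
  grid <- read_bin_grid(file.path(outdir, "grid.bed"))
  counts <- read_counts(file.path(outdir, "counts.tsv"), grid)
  tracks <- read_tracks(file.path(outdir, "tracks.tsv"), grid)
  metadata <- read_cell_metadata(file.path(outdir, "metadata.tsv"))

  profiles <- correct_counts(counts, tracks, min_mappability = cfg$min_mappability)
  status <- attr(profiles, "cell_status")
  scores <- variability_score(profiles[profiles$cell_id %in%
                                         status$cell_id[status$analyzable], ],
                              n_windows = cfg$n_windows)
  scores <- filter_cells(scores, exclude_fraction = cfg$exclude_fraction)
  retained <- scores$cell_id[scores$retained]
  message(sprintf("cells: %d input, %d analyzable, %d retained, %d excluded by VS",
                  nrow(metadata), nrow(scores), length(retained),
                  sum(!scores$retained)))

  keep_prof <- profiles[profiles$cell_id %in% retained, ]
  attr(keep_prof, "cell_status") <- status[status$cell_id %in% retained, ]
  states <- infer_copy_number(keep_prof)
  calls <- call_karyotypes(states, min_cnv_size = cfg$min_cnv_size,
                           whole_fraction = cfg$whole_fraction, sex = cfg$sex)

  qc <- dplyr::select(scores, "cell_id", "vs", "retained")
  readr::write_tsv(qc, file.path(outdir, "qc_report.tsv"))
  readr::write_tsv(dplyr::select(calls, dplyr::everything()),
                   file.path(outdir, "karyotypes.tsv"))
  readr::write_tsv(tibble::tibble(cell_id = attr(calls, "cells")),
                   file.path(outdir, "analyzed_cells.tsv"))
  invisible(list(profiles = profiles, scores = scores, states = states,
                 calls = calls))
}

.read_calls_dir <- function(outdir) {
  calls <- readr::read_tsv(file.path(outdir, "karyotypes.tsv"),
                           col_types = readr::cols(
                             cell_id = readr::col_character(),
                             chrom = readr::col_character(),
                             class = readr::col_character(),
                             .default = readr::col_double()),
                           progress = FALSE)
  calls$delta <- as.integer(calls$delta)
  cells <- readr::read_tsv(file.path(outdir, "analyzed_cells.tsv"),
                           col_types = "c", progress = FALSE)$cell_id
  attr(calls, "cells") <- cells
  class(calls) <- unique(c("karyotype_calls", class(calls)))
  calls
}

#' Embryo-level analysis of called karyotypes
#'
#' Runs mosaicism classification, incidence, subtype distribution, origin
#' classification, TE-ICM concordance and resampled discordance, and
#' complementary-pair detection; writes `embryo_summary.tsv`,
#' `incidence.tsv`, `origin.tsv`, `discordance.tsv`, `pairs.tsv` and a
#' machine-readable `analysis.json` (raw fractions; tables carry 2-decimal
#' percentages).
#'
#' @inheritParams run_simulate
#' @return Invisibly, a list of the computed tables.
#' @export
run_analyze <- function(config = NULL) {
  cfg <- if (inherits(config, "run_config")) config else load_run_config(config)
  outdir <- cfg$outdir
  metadata <- read_cell_metadata(file.path(outdir, "metadata.tsv"))
  calls <- .read_calls_dir(outdir)

  classification <- classify_embryos(calls, metadata,
                                     reciprocal_overlap = cfg$reciprocal_overlap)
  incidence <- cohort_incidence(classification)
  types <- mosaic_type_distribution(classification)
  origin <- classify_origin(calls, metadata,
                            reciprocal_overlap = cfg$reciprocal_overlap)
  concord <- te_icm_concordance(calls, metadata,
                                reciprocal_overlap = cfg$reciprocal_overlap)
  discord <- te_icm_discordance(calls, metadata, n_resamples = cfg$n_resamples,
                                seed = cfg$seed,
                                reciprocal_overlap = cfg$reciprocal_overlap)
  pairs <- find_complementary_pairs(calls, metadata,
                                    reciprocal_overlap = cfg$reciprocal_overlap)

  summary_tab <- dplyr::select(classification, -"major_karyotype") |>
    dplyr::left_join(origin[, c("embryo_id", "origin")], by = "embryo_id") |>
    dplyr::mutate(mosaic_rate_pct = round(100 * .data$mosaic_rate, 2))
  readr::write_tsv(summary_tab, file.path(outdir, "embryo_summary.tsv"))
  readr::write_tsv(incidence, file.path(outdir, "incidence.tsv"))
  readr::write_tsv(attr(origin, "events"), file.path(outdir, "origin_events.tsv"))
  readr::write_tsv(origin, file.path(outdir, "origin.tsv"))
  if (nrow(discord)) {
    readr::write_tsv(dplyr::mutate(discord, discordance_pct = round(100 * .data$discordance, 2)),
                     file.path(outdir, "discordance.tsv"))
  }
  if (nrow(pairs)) readr::write_tsv(pairs, file.path(outdir, "pairs.tsv"))
  jsonlite::write_json(
    list(config_hash = attr(cfg, "hash"),
         incidence = incidence, mosaic_types = types,
         origin = table_to_list(origin$origin),
         n_concordant = if (nrow(concord)) sum(concord$concordant) else 0,
         n_te_icm_pairs = nrow(concord)),
    file.path(outdir, "analysis.json"),
    dataframe = "rows", auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(classification = classification, incidence = incidence,
                 types = types, origin = origin, concordance = concord,
                 discordance = discord, pairs = pairs))
}

table_to_list <- function(x) as.list(table(x))

#' Render figures for a completed run
#'
#' Writes per-cell segmentation plots for a sample of cells, the VS
#' distribution, and incidence/subtype bar charts as PNG files under
#' `<outdir>/figures/`.
#'
#' @inheritParams run_simulate
#' @param max_cells Maximum number of per-cell segmentation plots.
#' @return Invisibly, the figures directory.
#' @export
run_report <- function(config = NULL, max_cells = 4) {
  cfg <- if (inherits(config, "run_config")) config else load_run_config(config)
  outdir <- cfg$outdir
  figdir <- file.path(outdir, "figures")
  dir.create(figdir, recursive = TRUE, showWarnings = FALSE)
  grid <- read_bin_grid(file.path(outdir, "grid.bed"))
  counts <- read_counts(file.path(outdir, "counts.tsv"), grid)
  tracks <- read_tracks(file.path(outdir, "tracks.tsv"), grid)
  metadata <- read_cell_metadata(file.path(outdir, "metadata.tsv"))
  profiles <- correct_counts(counts, tracks, min_mappability = cfg$min_mappability)
  states <- infer_copy_number(profiles)
  cells <- utils::head(unique(states$cell_id), max_cells)
  for (cell in cells) {
    p <- plot_segmentation(states, cell)
    ggplot2::ggsave(file.path(figdir, paste0("segmentation_", cell, ".png")),
                    p, width = 10, height = 3, dpi = 120)
  }
  qc_path <- file.path(outdir, "qc_report.tsv")
  if (file.exists(qc_path)) {
    qc <- readr::read_tsv(qc_path, col_types = "cdl", progress = FALSE)
    ggplot2::ggsave(file.path(figdir, "vs_distribution.png"),
                    plot_vs_distribution(qc), width = 6, height = 4, dpi = 120)
  }
  summ_path <- file.path(outdir, "incidence.tsv")
  if (file.exists(summ_path)) {
    inc <- readr::read_tsv(summ_path, col_types = "ciidd", progress = FALSE)
    ggplot2::ggsave(file.path(figdir, "incidence.png"), plot_incidence(inc),
                    width = 5, height = 4, dpi = 120)
  }
  invisible(figdir)
}
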
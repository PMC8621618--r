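required_cell_cols <- function() {
  c("cell_id", "animal_id", "section_index", "region", "cell_type",
    reporter_cols())
}

#' Read a per-cell measurement table
#'
#' Tab-separated text, one row per labeled cell. Required columns:
#' `cell_id`, `animal_id`, `section_index` (0-based; the first section with
#' labeled cells is 0 = "0 um"), `region` (`UL`/`LL`/`CC`), `cell_type`
#' (`astrocyte`/`NG2`/`oligodendrocyte`/`unknown`) and the 12 intensity
#' columns of [reporter_cols()]. `layer`, `barcode` and any extra
#' annotation columns are preserved untouched. Validation errors name the
#' offending row.
#'
#' @param path File path.
#' @return A validated tibble.
#' @export
read_cell_table <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  validate_cell_table(tab)
}

#' @rdname read_cell_table
#' @param cells Cell table to validate or write.
#' @export
validate_cell_table <- function(cells) {
  missing <- setdiff(required_cell_cols(), names(cells))
  if (length(missing) > 0L) {
    abort(paste0("cell table missing required column(s): ",
                 paste(missing, collapse = ", ")))
  }
  for (col in reporter_cols()) {
    v <- cells[[col]]
    if (!is.numeric(v)) {
      abort(paste0("column ", col, " is not numeric."))
    }
    bad <- which(is.na(v) | v < 0)
    if (length(bad) > 0L) {
      abort(sprintf("row %d: negative or missing intensity in %s.",
                    bad[1L], col))
    }
  }
  bad_sec <- which(is.na(cells$section_index) | cells$section_index < 0)
  if (length(bad_sec) > 0L) {
    abort(sprintf("row %d: section_index must be a non-negative integer.",
                  bad_sec[1L]))
  }
  dup <- cells |>
    dplyr::count(.data$animal_id, .data$cell_id) |>
    dplyr::filter(.data$n > 1L)
  if (nrow(dup) > 0L) {
    abort(sprintf("duplicate cell_id within animal: %s / %s",
                  dup$animal_id[1L], dup$cell_id[1L]))
  }
  bad_reg <- which(!cells$region %in% REGIONS)
  if (length(bad_reg) > 0L) {
    abort(sprintf("row %d: region must be one of UL, LL, CC.", bad_reg[1L]))
  }
  cells$section_index <- as.integer(cells$section_index)
  tibble::as_tibble(cells)
}

#' @rdname read_cell_table
#' @export
write_cell_table <- function(cells, path) {
  validate_cell_table(cells)
  readr::write_tsv(cells, path, progress = FALSE)
  invisible(path)
}

#' Read or write a clone table
#'
#' TSV with one row per clone; member cell ids are semicolon-joined in
#' `cell_ids`.
#'
#' @param path File path.
#' @param clones Clone table from [call_clones()].
#' @return The clone table (read) or `path` invisibly (write).
#' @export
read_clone_table <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  class(tab) <- c("clone_table", class(tab))
  tab
}

#' @rdname read_clone_table
#' @export
write_clone_table <- function(clones, path) {
  readr::write_tsv(clones, path, progress = FALSE)
  invisible(path)
}

#' Write the cohort report
#'
#' Writes the cohort summary as TSV tables (composition, per-class
#' statistics, size-dispersion pairs) plus one machine-readable JSON file
#' with the full structured summary.
#'
#' @param cohort A [summarize_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_cohort_report <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort_summary"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_tsv(cohort$composition,
                   file.path(dir, "cohort_composition.tsv"), progress = FALSE)
  readr::write_tsv(cohort$class_stats,
                   file.path(dir, "cohort_class_stats.tsv"), progress = FALSE)
  readr::write_tsv(cohort$uniformity_stats,
                   file.path(dir, "cohort_uniformity_stats.tsv"),
                   progress = FALSE)
  readr::write_tsv(cohort$pairs,
                   file.path(dir, "cohort_pairs.tsv"), progress = FALSE)
  jsonlite::write_json(
    list(
      n_clones = cohort$n_clones,
      n_cells = cohort$n_cells,
      composition = cohort$composition,
      class_stats = cohort$class_stats,
      uniformity_stats = cohort$uniformity_stats,
      layer = cohort$layer
    ),
    file.path(dir, "cohort_summary.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(dir)
}

#' Run the full clonal-analysis pipeline
#'
#' Executes simulate (optional) -> barcode -> clone calling -> per-clone
#' summaries -> cohort summary -> group statistics, logging the
#' configuration hash, seed and per-stage row counts. Deterministic given
#' the seed.
#'
#' The statistical stage reproduces the study's battery on the cohort:
#' Mann-Whitney comparisons of clone size and of rostro-caudal dispersion
#' between uniform and mixed clones, Kruskal-Wallis comparisons across
#' uniform composition classes, and the Lilliefors normality gate on clone
#' size (informative only; reporting stays nonparametric).
#'
#' @param cells Optional cell table; when `NULL`, a synthetic cohort is
#'   generated from `config`.
#' @param config [sim_config()] for the synthetic branch.
#' @param params [clone_params()].
#' @param seed Optional override of `config$seed`.
#' @param outdir Optional directory; when given, the cell table, clone
#'   table and cohort report are written there.
#' @param verbose Log stage progress? Default `TRUE`.
#' @return List of class `glia_pipeline`: `cells`, `clones`, `summaries`,
#'   `cohort`, `stats` (list of `clone_test`s), `truth` (synthetic branch
#'   only), `config`, `log`.
#' @export
run_pipeline <- function(cells = NULL, config = sim_config(),
                         params = clone_params(), seed = NULL,
                         outdir = NULL, verbose = TRUE) {
  if (!is.null(seed)) config$seed <- as.integer(seed)
  say <- function(...) if (verbose) message("[gliaclone] ", ...)
  log <- list(config_hash = rlang::hash(config), seed = config$seed)
  say("config hash ", log$config_hash, ", seed ", config$seed %||% "none")

  truth <- NULL
  if (is.null(cells)) {
    cohort_sim <- generate_cohort(config)
    cells <- cohort_sim$cells
    truth <- cohort_sim$truth
    say("simulate: ", nrow(cells), " cells from ",
        nrow(cohort_sim$profiles), " progenitors")
  }
  cells <- add_barcodes(cells, config$presence_threshold)
  log$n_cells <- nrow(cells)
  say("barcode: ", dplyr::n_distinct(cells$barcode), " distinct codes")

  clones <- call_clones(cells, params,
                        presence_threshold = config$presence_threshold)
  log$n_clones <- nrow(clones)
  say("clones: ", nrow(clones), " called (",
      sum(clones$is_fragment), " fragments)")

  summaries <- clone_summaries(clones, cells,
                               thickness = config$section_thickness)
  cohort <- summarize_cohort(summaries)
  say("summarize: ", cohort$n_clones, " clones, ", cohort$n_cells,
      " cells in cohort report")

  stats <- list()
  stats$size_normality <- normality_gate(summaries$size)
  uni <- summaries$size[summaries$uniformity == "uniform"]
  mix <- summaries$size[summaries$uniformity == "mixed"]
  uni_d <- summaries$rc_dispersion[summaries$uniformity == "uniform"]
  mix_d <- summaries$rc_dispersion[summaries$uniformity == "mixed"]
  if (length(uni) > 0L && length(mix) > 0L) {
    stats$size_uniform_vs_mixed <- mann_whitney(uni, mix)
    stats$dispersion_uniform_vs_mixed <- mann_whitney(uni_d, mix_d)
  }
  by_class <- split(summaries$size,
                    summaries$composition_class)[UNIFORM_CLASSES]
  by_class <- by_class[!vapply(by_class, is.null, logical(1))]
  if (length(by_class) >= 2L) {
    stats$size_across_uniform_classes <- kruskal_wallis(by_class)
    disp_class <- split(summaries$rc_dispersion,
                        summaries$composition_class)[names(by_class)]
    stats$dispersion_across_uniform_classes <- kruskal_wallis(disp_class)
  }

  if (!is.null(outdir)) {
    if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
    write_cell_table(cells, file.path(outdir, "cells.tsv"))
    write_clone_table(clones, file.path(outdir, "clones.tsv"))
    write_cohort_report(cohort, outdir)
    say("wrote outputs to ", outdir)
  }

  structure(
    list(cells = cells, clones = clones, summaries = summaries,
         cohort = cohort, stats = stats, truth = truth,
         config = config, log = log),
    class = "glia_pipeline"
  )
}

#' @export
print.glia_pipeline <- function(x, ...) {
  cat("<glia_pipeline> ", x$log$n_cells, " cells -> ", x$log$n_clones,
      " clones (config ", x$log$config_hash, ")\n", sep = "")
  print(x$cohort)
  invisible(x)
}
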
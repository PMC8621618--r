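#' Rostro-caudal dispersion of a clone
#'
#' The anterior-posterior extent of a clone across serial coronal sections,
#' under the inclusive-span convention: `(max section - min section + 1) *
#' thickness`. A clone confined to one 50-micron section therefore has a
#' dispersion of 50 um, and a clone spanning seven consecutive sections has
#' 350 um — the observed minimum and maximum of the glial cohort this
#' package models. (An exclusive difference could not produce the 50 um
#' minimum.)
#'
#' @param section_index Integer vector of member section indices (0-based;
#'   the first section containing labeled cells is index 0 = "0 um").
#' @param thickness Section thickness in microns, default 50.
#' @return Dispersion in microns (positive multiple of `thickness`).
#' @examples
#' rc_dispersion(c(0, 0, 0)) # 50
#' rc_dispersion(c(0, 3, 6)) # 350
#' @export
rc_dispersion <- function(section_index, thickness = 50) {
  if (length(section_index) == 0L || anyNA(section_index)) {
    abort("empty clone or missing section index.")
  }
  if (any(section_index < 0)) abort("section indices must be >= 0.")
  (max(section_index) - min(section_index) + 1) * thickness
}

#' Classify clone composition and uniformity
#'
#' A clone containing one glial cell type is uniform (Ast, NG2 or OL), and
#' so is an NG2+OL clone, because NG2-glia can act as oligodendrocyte
#' precursors. Clones combining astrocytes with NG2-glia or with
#' oligodendrocytes are mixed — but a mixed label requires the clone's
#' color code to have passed the rarity filter; otherwise the multi-type
#' group is reported as `"ambiguous"` (a possible barcode collision).
#'
#' @param cell_types Character vector of member cell types (or the set of
#'   unique types); values among `astrocyte`, `NG2`, `oligodendrocyte`.
#' @param rarity_eligible Is the clone's barcode rare enough to support a
#'   mixed call? Default `TRUE`.
#' @return List with `composition` (one of Ast, NG2, OL, NG2+OL, Ast+NG2,
#'   Ast+OL, ambiguous) and `uniformity` (`"uniform"`, `"mixed"` or
#'   `"ambiguous"`).
#' @export
classify_composition <- function(cell_types, rarity_eligible = TRUE) {
  types <- sort(unique(cell_types))
  unknown <- setdiff(types, CELL_TYPES)
  if (length(unknown) > 0L) {
    abort(paste0("unknown cell type label: ", paste(unknown, collapse = ", ")))
  }
  if (length(types) == 0L) abort("empty clone.")
  key <- paste(types, collapse = "+")
  out <- switch(
    key,
    "astrocyte" = list(composition = "Ast", uniformity = "uniform"),
    "NG2" = list(composition = "NG2", uniformity = "uniform"),
    "oligodendrocyte" = list(composition = "OL", uniformity = "uniform"),
    "NG2+oligodendrocyte" = list(composition = "NG2+OL", uniformity = "uniform"),
    "NG2+astrocyte" = ,
    "astrocyte+NG2" = list(composition = "Ast+NG2", uniformity = "mixed"),
    "astrocyte+oligodendrocyte" = list(composition = "Ast+OL", uniformity = "mixed"),
    list(composition = "ambiguous", uniformity = "ambiguous")
  )
  if (out$uniformity == "mixed" && !isTRUE(rarity_eligible)) {
    out <- list(composition = "ambiguous", uniformity = "ambiguous")
  }
  out
}

#' Laminar spread of a clone
#'
#' Clones are selected in the lower cortical layers (V-VI); this classifies
#' whether the clone stayed there. `"restricted-LL"` means every member
#' lies in the lower layers; any member in the upper layers (I-IV) or the
#' corpus callosum makes the clone `"spread"`.
#'
#' @param region Character vector of member regions (`"UL"`, `"LL"`,
#'   `"CC"`).
#' @return `"restricted-LL"` or `"spread"`.
#' @export
layer_spread <- function(region) {
  if (length(region) == 0L || anyNA(region)) {
    abort("missing region label.")
  }
  bad <- setdiff(unique(region), REGIONS)
  if (length(bad) > 0L) {
    abort(paste0("unknown region label: ", paste(bad, collapse = ", ")))
  }
  if (all(region == "LL")) "restricted-LL" else "spread"
}

#' Per-clone summaries
#'
#' Joins a clone table back onto its cell table and computes the per-clone
#' metrics: size (cells), rostro-caudal dispersion (um), composition class,
#' uniformity and laminar spread.
#'
#' @param clones Clone table from [call_clones()].
#' @param cells The cell table the clones were called from.
#' @param thickness Section thickness in microns, default 50.
#' @param include_fragments Keep clones below the minimum reported size?
#'   Default `FALSE` (they are excluded from cohort summaries).
#' @return Tibble with one row per clone: `clone_id`, `animal_id`,
#'   `barcode`, `size`, `rc_dispersion`, `composition_class`, `uniformity`,
#'   `layer_spread`, `rarity_eligible`, `is_fragment`.
#' @export
clone_summaries <- function(clones, cells, thickness = 50,
                            include_fragments = FALSE) {
  if (!include_fragments) {
    clones <- dplyr::filter(clones, !.data$is_fragment)
  }
  members <- clone_assignments(clones) |>
    dplyr::left_join(
      dplyr::select(cells, "cell_id", "section_index", "region"),
      by = "cell_id"
    )
  if (anyNA(members$section_index)) {
    abort("clone members missing from the cell table.")
  }
  per_clone <- members |>
    dplyr::group_by(.data$clone_id) |>
    dplyr::summarise(
      size = dplyr::n(),
      rc_dispersion = rc_dispersion(.data$section_index, thickness),
      layer_spread = layer_spread(.data$region),
      .groups = "drop"
    )
  clones |>
    dplyr::select("clone_id", "animal_id", "barcode",
                  "composition_class", "uniformity",
                  "rarity_eligible", "is_fragment") |>
    dplyr::left_join(per_clone, by = "clone_id") |>
    dplyr::select("clone_id", "animal_id", "barcode", "size",
                  "rc_dispersion", "composition_class", "uniformity",
                  "layer_spread", "rarity_eligible", "is_fragment")
}

#' Cohort-level summary of clonal statistics
#'
#' Aggregates per-clone summaries into the cohort report: per-composition
#' counts and integer percentages (rounded half-up, matching how such
#' figures are conventionally printed), mean, SD and SEM of clone size and
#' rostro-caudal dispersion per composition class and for uniform versus
#' mixed clones, laminar-spread counts, and the size-dispersion pairs for
#' plotting.
#'
#' @param summaries Per-clone summary tibble from [clone_summaries()] (any
#'   tibble with `size`, `rc_dispersion`, `composition_class`, `uniformity`
#'   and optionally `layer_spread` columns works).
#' @return Object of class `cohort_summary`: a list with `composition`,
#'   `class_stats`, `uniformity_stats`, `layer`, `pairs`, `n_clones`,
#'   `n_cells`. Has [tidy()], [glance()] and [autoplot()] methods.
#' @examples
#' cohort <- generate_cohort(sim_config(n_progenitors = 30, seed = 3))
#' clones <- call_clones(cohort$cells)
#' summarize_cohort(clone_summaries(clones, cohort$cells))
#' @export
summarize_cohort <- function(summaries) {
  if (nrow(summaries) == 0L) abort("no clones to summarise.")
  lv <- c(FATE_CLASSES, "ambiguous")
  composition <- summaries |>
    dplyr::count(composition_class = factor(.data$composition_class, lv),
                 name = "n", .drop = FALSE) |>
    dplyr::mutate(
      composition_class = as.character(.data$composition_class),
      percent = round_half_up(100 * .data$n / sum(.data$n))
    ) |>
    dplyr::filter(.data$n > 0 | .data$composition_class %in% FATE_CLASSES)

  stat_block <- function(df, key) {
    df |>
      dplyr::group_by(dplyr::across(dplyr::all_of(key))) |>
      dplyr::summarise(
        n = dplyr::n(),
        mean_size = mean(.data$size),
        sd_size = stats::sd(.data$size),
        sem_size = sem(.data$size),
        mean_dispersion = mean(.data$rc_dispersion),
        sd_dispersion = stats::sd(.data$rc_dispersion),
        sem_dispersion = sem(.data$rc_dispersion),
        .groups = "drop"
      )
  }
  class_stats <- stat_block(summaries, "composition_class")
  uniformity_stats <- stat_block(
    dplyr::filter(summaries, .data$uniformity %in% c("uniform", "mixed")),
    "uniformity"
  )
  layer <- if ("layer_spread" %in% names(summaries)) {
    dplyr::count(summaries, .data$layer_spread, name = "n")
  } else {
    tibble::tibble(layer_spread = character(), n = integer())
  }
  structure(
    list(
      composition = composition,
      class_stats = class_stats,
      uniformity_stats = uniformity_stats,
      layer = layer,
      pairs = dplyr::select(summaries, dplyr::any_of(c(
        "clone_id", "size", "rc_dispersion", "composition_class",
        "uniformity"
      ))),
      n_clones = nrow(summaries),
      n_cells = sum(summaries$size)
    ),
    class = "cohort_summary"
  )
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("<cohort_summary> ", x$n_clones, " clones, ", x$n_cells, " cells\n",
      sep = "")
  comp <- dplyr::filter(x$composition, .data$n > 0)
  cat(paste(sprintf("  %-9s n = %2d (%d%%)", comp$composition_class,
                    comp$n, comp$percent), collapse = "\n"), "\n")
  u <- x$uniformity_stats
  for (i in seq_len(nrow(u))) {
    cat(sprintf(
      "  %s clones: size %.2f +/- %.2f (SEM), dispersion %.1f +/- %.2f um (SEM)\n",
      u$uniformity[i], u$mean_size[i], u$sem_size[i],
      u$mean_dispersion[i], u$sem_dispersion[i]))
  }
  invisible(x)
}
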
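#' Clone-calling parameters
#'
#' @param intensity_tolerance Sibling cells must agree on every reporter
#'   present in their barcode to within strictly less than this many
#'   intensity units (default 80); groups violating it are split.
#' @param rarity_threshold A barcode supports a mixed-clone call only when
#'   its dataset frequency is strictly below this fraction (default 0.01).
#' @param consistency_method `"pairwise"` (default) compares the maximum
#'   pairwise difference per present reporter; `"mean"` compares each cell
#'   against the group mean (tolerance halved so pairwise spread is still
#'   bounded by `intensity_tolerance`).
#' @param min_clone_size Clones smaller than this are flagged `is_fragment`
#'   and excluded from cohort summaries by default (default 4, the smallest
#'   reported clone).
#' @param frequency_scope Denominator for barcode fractions: the whole
#'   `"dataset"` (default) or per `"animal"`.
#' @return A list of class `clone_params`.
#' @export
clone_params <- function(intensity_tolerance = 80,
                         rarity_threshold = 0.01,
                         consistency_method = c("pairwise", "mean"),
                         min_clone_size = 4L,
                         frequency_scope = c("dataset", "animal")) {
  if (intensity_tolerance <= 0) abort("`intensity_tolerance` must be > 0.")
  if (rarity_threshold <= 0 || rarity_threshold > 1) {
    abort("`rarity_threshold` must lie in (0, 1].")
  }
  structure(
    list(
      intensity_tolerance = intensity_tolerance,
      rarity_threshold = rarity_threshold,
      consistency_method = match.arg(consistency_method),
      min_clone_size = as.integer(min_clone_size),
      frequency_scope = match.arg(frequency_scope)
    ),
    class = "clone_params"
  )
}

#' Group labeled cells by identical barcode
#'
#' Cells with the same 12-digit color code (same XFPs in the same
#' compartments) are candidate sibling cells. All-zero barcodes (unlabeled
#' cells) are excluded. Grouping never crosses animals.
#'
#' @param cells Cell table with `barcode` (see [add_barcodes()]).
#' @return Tibble with `animal_id`, `barcode`, `n_cells` and a list-column
#'   `cell_ids`, one row per candidate group, ordered by animal then
#'   barcode.
#' @export
group_by_barcode <- function(cells) {
  if (!"barcode" %in% names(cells)) {
    abort("no `barcode` column; run add_barcodes() first.")
  }
  if (!"animal_id" %in% names(cells)) cells$animal_id <- "a1"
  cells |>
    dplyr::filter(.data$barcode != ZERO_BARCODE) |>
    dplyr::arrange(.data$animal_id, .data$barcode, .data$cell_id) |>
    dplyr::group_by(.data$animal_id, .data$barcode) |>
    dplyr::summarise(
      n_cells = dplyr::n(),
      cell_ids = list(.data$cell_id),
      .groups = "drop"
    )
}

# Chebyshev distance matrix over the reporters present in the barcode
present_reporter_dist <- function(group_cells, barcode) {
  present <- decode_barcode(barcode)
  cols <- reporter_cols()[present]
  m <- as.matrix(group_cells[cols])
  n <- nrow(m)
  d <- matrix(0, n, n)
  for (j in seq_len(ncol(m))) {
    d <- pmax(d, abs(outer(m[, j], m[, j], "-")))
  }
  d
}

#' Check and enforce intensity consistency within a barcode group
#'
#' Integration copy number scales fluorescence, so true sibling cells have
#' near-identical intensities: for every reporter present in the barcode,
#' member intensities must differ by strictly less than
#' `intensity_tolerance` (80 points by default). A group that violates this
#' is split by single-linkage clustering on the per-reporter Chebyshev
#' distance, cut at the tolerance, which reproduces the manual
#' "same intensity, same clone" judgement deterministically.
#'
#' @param group_cells Cell table rows of one barcode group (all sharing one
#'   barcode).
#' @param params [clone_params()].
#' @return List with `consistent` (logical: was the whole group within
#'   tolerance) and `subgroup` (integer vector assigning each row to a
#'   consistent subgroup; all 1 when consistent).
#' @export
check_intensity_consistency <- function(group_cells, params = clone_params()) {
  n <- nrow(group_cells)
  if (n == 0L) abort("empty barcode group.")
  if (n == 1L) return(list(consistent = TRUE, subgroup = 1L))
  tol <- params$intensity_tolerance
  d <- present_reporter_dist(group_cells, group_cells$barcode[[1L]])

  if (params$consistency_method == "mean") {
    present <- decode_barcode(group_cells$barcode[[1L]])
    m <- as.matrix(group_cells[reporter_cols()[present]])
    dev <- abs(sweep(m, 2L, colMeans(m)))
    consistent <- max(dev) < tol / 2
  } else {
    consistent <- max(d) < tol
  }
  if (consistent) {
    return(list(consistent = TRUE, subgroup = rep(1L, n)))
  }
  hc <- stats::hclust(stats::as.dist(d), method = "single")
  # strict "< tolerance": a pair exactly at the tolerance must split
  sub <- stats::cutree(hc, h = tol * (1 - 1e-9))
  list(consistent = FALSE, subgroup = as.integer(sub))
}

#' Flag barcode rarity eligibility
#'
#' A clone may be classified as mixed (two glial cell types) only when its
#' color code is rare — dataset frequency strictly below
#' `rarity_threshold` (1% by default) — since common codes may arise in
#' several independent progenitors by chance. Ineligible multi-type groups
#' are retained but reported as `"ambiguous"` downstream.
#'
#' @param groups Tibble with a `barcode` column (e.g. from
#'   [group_by_barcode()] or [call_clones()]).
#' @param freq Barcode frequency table from [barcode_frequency()].
#' @param params [clone_params()].
#' @return `groups` with `barcode_fraction` and logical `rarity_eligible`
#'   columns added.
#' @export
apply_rarity_filter <- function(groups, freq, params = clone_params()) {
  by <- if ("animal_id" %in% names(freq)) c("animal_id", "barcode") else "barcode"
  out <- dplyr::left_join(
    groups,
    dplyr::select(freq, dplyr::all_of(by), barcode_fraction = "fraction"),
    by = by
  )
  if (anyNA(out$barcode_fraction)) {
    missing <- unique(out$barcode[is.na(out$barcode_fraction)])
    abort(paste0("barcode missing from frequency table: ",
                 paste(utils::head(missing, 3L), collapse = ", ")))
  }
  out$rarity_eligible <- out$barcode_fraction < params$rarity_threshold
  out
}

#' Call clones from a labeled cell table
#'
#' The full clone-calling pipeline: group cells by identical barcode within
#' each animal, split groups that violate the intensity-consistency rule,
#' and flag barcode rarity. Every labeled cell is assigned to exactly one
#' clone; the result is invariant to the row order of the input.
#'
#' @param cells Cell table; a `barcode` column is added with
#'   `presence_threshold` if absent.
#' @param params [clone_params()].
#' @param presence_threshold Used only if barcodes must be computed.
#' @return Tibble of class `clone_table`, one row per clone: `clone_id`,
#'   `animal_id`, `barcode`, `n_cells`, `consistency_ok` (whole barcode
#'   group was within tolerance), `barcode_fraction`, `rarity_eligible`,
#'   `composition_class`, `uniformity`, `is_fragment`, and `cell_ids`
#'   (semicolon-joined member ids).
#' @examples
#' cohort <- generate_cohort(sim_config(n_progenitors = 10, seed = 7))
#' clones <- call_clones(cohort$cells)
#' clones[, c("clone_id", "barcode", "n_cells", "composition_class")]
#' @export
call_clones <- function(cells, params = clone_params(),
                        presence_threshold = 40) {
  if (!"barcode" %in% names(cells)) {
    cells <- add_barcodes(cells, presence_threshold)
  }
  if (!"animal_id" %in% names(cells)) cells$animal_id <- "a1"
  labeled <- dplyr::filter(cells, .data$barcode != ZERO_BARCODE)
  if (nrow(labeled) == 0L) {
    abort("no labeled cells: every barcode is all-zero.")
  }
  freq <- barcode_frequency(labeled, scope = params$frequency_scope)

  labeled <- dplyr::arrange(labeled, .data$animal_id, .data$barcode,
                            .data$cell_id)
  keys <- dplyr::distinct(labeled, .data$animal_id, .data$barcode)
  clone_rows <- purrr::pmap(keys, function(animal_id, barcode) {
    g <- labeled[labeled$animal_id == animal_id &
                   labeled$barcode == barcode, , drop = FALSE]
    cons <- check_intensity_consistency(g, params)
    sub <- cons$subgroup
    # stable subgroup ids: ordered by smallest member cell_id
    first_id <- tapply(g$cell_id, sub, min)
    relabel <- match(names(sort(first_id)), names(first_id))
    sub <- match(sub, relabel)
    purrr::map(sort(unique(sub)), function(s) {
      mem <- g[sub == s, , drop = FALSE]
      tibble::tibble(
        animal_id = animal_id,
        barcode = barcode,
        n_cells = nrow(mem),
        consistency_ok = cons$consistent,
        member_types = list(unique(mem$cell_type)),
        cell_ids = paste(mem$cell_id, collapse = ";")
      )
    })
  })
  clones <- dplyr::bind_rows(purrr::flatten(clone_rows))
  clones <- apply_rarity_filter(clones, freq, params)

  comp <- purrr::map2(clones$member_types, clones$rarity_eligible,
                      classify_composition)
  clones$composition_class <- purrr::map_chr(comp, "composition")
  clones$uniformity <- purrr::map_chr(comp, "uniformity")
  clones$member_types <- NULL
  clones$is_fragment <- clones$n_cells < params$min_clone_size
  clones$clone_id <- sprintf("cl%04d", seq_len(nrow(clones)))

  out <- dplyr::select(
    clones, "clone_id", "animal_id", "barcode", "n_cells",
    "consistency_ok", "barcode_fraction", "rarity_eligible",
    "composition_class", "uniformity", "is_fragment", "cell_ids"
  )
  class(out) <- c("clone_table", class(out))
  out
}

#' Per-cell clone assignments
#'
#' Expands the semicolon-joined member list of a clone table into one row
#' per cell, for joining back onto the cell table or for scoring partition
#' recovery against a ground truth.
#'
#' @param clones A clone table from [call_clones()].
#' @return Tibble with `cell_id` and `clone_id`.
#' @export
clone_assignments <- function(clones) {
  tibble::tibble(
    clone_id = rep(clones$clone_id,
                   lengths(strsplit(clones$cell_ids, ";", fixed = TRUE))),
    cell_id = unlist(strsplit(clones$cell_ids, ";", fixed = TRUE),
                     use.names = FALSE)
  )[, c("cell_id", "clone_id")]
}
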
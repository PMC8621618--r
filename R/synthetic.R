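#' Draw a reporter integration profile for one progenitor
#'
#' Each of the 12 reporters (6 XFPs x cytoplasm/nucleus) integrates
#' independently with probability `p_integration`; an integrated reporter
#' carries `1 + Poisson(copy_lambda)` copies, a non-integrated one carries 0.
#' All-zero draws are rejected and resampled, because a progenitor with no
#' integrated reporter is invisible and cannot appear in the analysed table.
#'
#' Uses the current RNG state; call inside `withr::with_seed()` or after
#' `set.seed()` for reproducibility.
#'
#' @param config A [sim_config()].
#' @return Named integer vector of 12 copy numbers (names from
#'   [reporter_cols()]), at least one positive.
#' @export
sample_integration_profile <- function(config) {
  if (config$p_integration <= 0) {
    abort("cannot generate labeled progenitor: `p_integration` is 0.")
  }
  repeat {
    present <- stats::rbinom(12L, 1L, config$p_integration) == 1L
    if (any(present)) break
  }
  copies <- integer(12L)
  copies[present] <- 1L + stats::rpois(sum(present), config$copy_lambda)
  names(copies) <- reporter_cols()
  copies
}

# truncated draw from NB(mu, size), rejected into [lo, hi]
rtrunc_size <- function(mu, size, lo, hi) {
  for (i in 1:1000) {
    x <- stats::rnbinom(1L, mu = mu, size = size)
    if (x >= lo && x <= hi) return(as.integer(x))
  }
  as.integer(pmin(pmax(round(mu), lo), hi))
}

# member cell types for a fate class of a given clone size
fate_cell_types <- function(fate_class, size, astro_fraction) {
  split2 <- function(t1, t2, frac) {
    n1 <- max(1L, min(size - 1L, as.integer(round(size * frac))))
    c(rep(t1, n1), rep(t2, size - n1))
  }
  switch(fate_class,
    "Ast" = rep("astrocyte", size),
    "NG2" = rep("NG2", size),
    "OL" = rep("oligodendrocyte", size),
    "NG2+OL" = split2("NG2", "oligodendrocyte", 0.5),
    "Ast+NG2" = split2("astrocyte", "NG2", astro_fraction),
    "Ast+OL" = split2("astrocyte", "oligodendrocyte", 0.5),
    abort(paste0("unknown fate class: ", fate_class))
  )
}

#' Simulate the cell progeny of one labeled progenitor
#'
#' Generates the sibling cells of a single clone: a clone size from the
#' per-class truncated negative-binomial law, a run of consecutive sections
#' of drawn span (both extreme sections are always occupied so the realised
#' rostro-caudal extent equals the drawn span), per-cell regions from the
#' per-class placement probabilities, and the 12 measured intensities.
#' A present reporter measures `copies * gain + N(0, noise_sd)`; an absent
#' one measures `background_level + N(0, noise_sd)`; both floored at 0.
#'
#' @param profile Integration profile from [sample_integration_profile()].
#' @param fate_class One of `r paste(FATE_CLASSES, collapse = ", ")`.
#' @param config A [sim_config()].
#' @param size,span Optional overrides of the drawn clone size and section
#'   span (mainly for tests).
#' @return A tibble of cell records (one row per sibling cell) without
#'   cell ids; [generate_cohort()] adds ids and positions.
#' @export
sample_clone <- function(profile, fate_class, config, size = NULL, span = NULL) {
  if (!fate_class %in% FATE_CLASSES) {
    abort(paste0("unknown fate class: ", fate_class))
  }
  rng <- config$clone_size_range
  if (is.null(size)) {
    size <- rtrunc_size(config$clone_size_mean[[fate_class]],
                        config$clone_size_shape, rng[1], rng[2])
  }
  size <- as.integer(size)
  if (size < rng[1] || size > rng[2]) {
    abort(sprintf("clone size %d outside [%d, %d]", size, rng[1], rng[2]))
  }
  if (is.null(span)) {
    p_span <- (config$span_mean[[fate_class]] - 1) / 6
    span <- 1L + stats::rbinom(1L, 6L, p_span)
  }
  span <- as.integer(span)
  stopifnot(span >= 1L, span <= 7L, span <= config$n_sections)

  first <- sample.int(config$n_sections - span + 1L, 1L) - 1L
  sections <- if (span == 1L) {
    rep(first, size)
  } else {
    # pin the two extremes so the realised extent equals the drawn span
    c(first, first + span - 1L,
      first + sample.int(span, size - 2L, replace = TRUE) - 1L)
  }

  region <- sample(REGIONS, size, replace = TRUE,
                   prob = config$region_probs[fate_class, ])
  layer <- dplyr::case_when(
    region == "LL" ~ sample(c("V", "VI"), size, replace = TRUE),
    region == "UL" ~ sample(c("I", "II", "III", "IV"), size, replace = TRUE),
    TRUE ~ NA_character_
  )

  cell_type <- sample(fate_cell_types(fate_class, size,
                                      config$mixed_astro_fraction))

  expected <- ifelse(profile > 0, profile * config$gain, config$background_level)
  intens <- matrix(rep(expected, each = size), nrow = size) +
    matrix(stats::rnorm(size * 12L, 0, config$noise_sd), nrow = size)
  intens <- pmax(intens, 0)
  colnames(intens) <- reporter_cols()

  dplyr::bind_cols(
    tibble::tibble(
      section_index = as.integer(sections),
      region = region,
      layer = layer,
      cell_type = cell_type
    ),
    tibble::as_tibble(intens)
  )
}

#' Generate a synthetic labeled-cell cohort with known clonal ground truth
#'
#' Simulates `n_progenitors` independently labeled progenitors and their
#' glial progeny, producing the standard cell table plus the ground-truth
#' clonal partition, so that barcoding, clone calling and clone statistics
#' can be validated against a known answer. Deterministic given
#' `config$seed`.
#'
#' Cells are laid out on a per-section grid of image coordinates (columns
#' `x`, `y`, pixels) compatible with [render_section()] defaults, so the
#' cohort can also exercise the imaging path.
#'
#' @param config A [sim_config()].
#' @return A list of class `glia_cohort` with elements:
#'   * `cells`: tibble, one row per labeled cell (schema of
#'     [read_cell_table()] plus `x`, `y`);
#'   * `truth`: tibble `cell_id`, `progenitor_id`, `fate_class`;
#'   * `profiles`: tibble of per-progenitor integration profiles with the
#'     true barcode implied by each profile.
#' @examples
#' cohort <- generate_cohort(sim_config(n_progenitors = 5, seed = 42))
#' dplyr::count(cohort$truth, progenitor_id)
#' @export
generate_cohort <- function(config = sim_config()) {
  validate_sim_config(config)
  if (config$n_progenitors == 0L) {
    return(empty_cohort(config))
  }
  with_seed_if(config$seed, {
    profiles <- vector("list", config$n_progenitors)
    fates <- sample(FATE_CLASSES, config$n_progenitors, replace = TRUE,
                    prob = config$fate_class_probs[FATE_CLASSES])
    clones <- vector("list", config$n_progenitors)
    for (i in seq_len(config$n_progenitors)) {
      prof <- if (config$n_collided > 0L && i > 1L &&
                  i <= config$n_collided + 1L) {
        profiles[[1L]]
      } else {
        sample_integration_profile(config)
      }
      profiles[[i]] <- prof
      cl <- sample_clone(prof, fates[i], config)
      cl$progenitor_id <- sprintf("p%04d", i)
      clones[[i]] <- cl
    }
    cells <- dplyr::bind_rows(clones)
    cells$animal_id <- config$animal_id
    cells$cell_id <- sprintf("%s_%s_c%03d", cells$animal_id,
                             cells$progenitor_id,
                             stats::ave(seq_len(nrow(cells)),
                                        cells$progenitor_id,
                                        FUN = seq_along))
    cells <- assign_grid_positions(cells)

    truth <- tibble::tibble(
      cell_id = cells$cell_id,
      progenitor_id = cells$progenitor_id,
      fate_class = rep(fates, vapply(clones, nrow, 1L))
    )
    prof_mat <- do.call(rbind, profiles)
    prof_tbl <- tibble::as_tibble(prof_mat)
    prof_tbl <- dplyr::bind_cols(
      tibble::tibble(
        progenitor_id = sprintf("p%04d", seq_len(config$n_progenitors)),
        fate_class = fates,
        true_barcode = apply(prof_mat > 0, 1L, encode_barcode)
      ),
      prof_tbl
    )

    cells <- dplyr::select(
      cells, "cell_id", "animal_id", "section_index", "region", "layer",
      "cell_type", "x", "y", "frame", dplyr::all_of(reporter_cols())
    )
    structure(list(cells = cells, truth = truth, profiles = prof_tbl,
                   config = config),
              class = "glia_cohort")
  })
}

empty_cohort <- function(config) {
  cells <- tibble::tibble(
    cell_id = character(), animal_id = character(),
    section_index = integer(), region = character(), layer = character(),
    cell_type = character(), x = numeric(), y = numeric(),
    frame = integer()
  )
  for (col in reporter_cols()) cells[[col]] <- numeric()
  structure(
    list(
      cells = cells,
      truth = tibble::tibble(cell_id = character(),
                             progenitor_id = character(),
                             fate_class = character()),
      profiles = tibble::tibble(),
      config = config
    ),
    class = "glia_cohort"
  )
}

# deterministic per-section grid placement compatible with a 512 px frame;
# sections holding more cells than one frame spill into further frames
# (mosaic tiles), recorded in the `frame` column
assign_grid_positions <- function(cells, width = 512L, spacing = 24L,
                                  margin = 16L) {
  per_row <- (width - 2L * margin) %/% spacing + 1L
  capacity <- per_row^2
  cells$x <- NA_real_
  cells$y <- NA_real_
  cells$frame <- NA_integer_
  for (s in unique(cells$section_index)) {
    idx <- which(cells$section_index == s)
    pos <- seq_along(idx) - 1L
    slot <- pos %% capacity
    cells$frame[idx] <- pos %/% capacity
    cells$x[idx] <- margin + (slot %% per_row) * spacing
    cells$y[idx] <- margin + (slot %/% per_row) * spacing
  }
  cells
}

#' @export
print.glia_cohort <- function(x, ...) {
  cat("<glia_cohort> ", nrow(x$cells), " cells from ",
      nrow(x$profiles), " progenitors (seed ",
      x$config$seed %||% "none", ")\n", sep = "")
  invisible(x)
}
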
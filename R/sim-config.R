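#' Simulation configuration for synthetic clonal cohorts
#'
#' Bundles every generative parameter of the synthetic-cohort model:
#' stochastic reporter integration, copy-number-dependent intensities, glial
#' fate classes, clone-size and section-span laws, and laminar placement.
#' Defaults reproduce the study conditions of an E14 pallial progenitor
#' cohort analysed at P30: six fate classes in proportions
#' (Ast 26%, NG2 34%, OL 17%, NG2+OL 11%, Ast+NG2 6%, Ast+OL 6%),
#' clone sizes within 4-49 cells, rostro-caudal spans of 1-7 consecutive
#' 50-micron sections.
#'
#' @param n_progenitors Number of labeled progenitors (clones) to simulate.
#' @param p_integration Per-reporter integration probability; each of the 12
#'   reporters (6 XFPs x cytoplasm/nucleus) integrates independently.
#' @param copy_lambda Poisson rate of extra copies: an integrated reporter
#'   carries `1 + Poisson(copy_lambda)` copies.
#' @param gain Intensity units per integrated copy.
#' @param noise_sd SD of additive Gaussian measurement noise per intensity.
#' @param background_level Intensity of reporters that did not integrate.
#' @param presence_threshold Intensity at or above which a reporter is called
#'   present when barcoding (see [call_presence()]).
#' @param fate_class_probs Named probabilities over the six fate classes
#'   `r paste(FATE_CLASSES, collapse = ", ")`; must sum to 1.
#' @param clone_size_mean Named per-class mean clone size (cells/clone).
#' @param clone_size_shape Negative-binomial shape (size) parameter shared by
#'   all classes; draws are rejected until they fall in `clone_size_range`.
#' @param clone_size_range Inclusive clone-size support, default `c(4, 49)`.
#' @param span_mean Named per-class mean rostro-caudal span in sections; the
#'   span is drawn as `1 + Binomial(6, (mean - 1)/6)`, so support is 1-7.
#' @param region_probs 6 x 3 matrix of per-fate-class placement probabilities
#'   over regions `UL` (upper layers I-IV), `LL` (lower layers V-VI), `CC`
#'   (corpus callosum); rows must sum to 1.
#' @param mixed_astro_fraction Fraction of astrocytes in Ast+NG2 mixed clones
#'   (Ast+OL clones are always split evenly).
#' @param section_thickness Section thickness in microns (50).
#' @param n_sections Number of serial sections available for placement.
#' @param animal_id Animal label stamped on every generated cell.
#' @param n_collided Number of additional progenitors forced to share the
#'   integration profile of progenitor 1 (for rarity-filter tests); 0 for
#'   none.
#' @param seed Integer seed; `generate_cohort()` is deterministic given it.
#'
#' @return A validated list of class `sim_config`.
#' @seealso [generate_cohort()]
#' @export
sim_config <- function(n_progenitors = 200,
                       p_integration = 0.4,
                       copy_lambda = 1,
                       gain = 100,
                       noise_sd = 8,
                       background_level = 5,
                       presence_threshold = 40,
                       fate_class_probs = c(
                         "Ast" = 0.26, "NG2" = 0.34, "OL" = 0.17,
                         "NG2+OL" = 0.11, "Ast+NG2" = 0.06, "Ast+OL" = 0.06
                       ),
                       clone_size_mean = c(
                         "Ast" = 11.58, "NG2" = 16.58, "OL" = 11.88,
                         "NG2+OL" = 14.40, "Ast+NG2" = 32, "Ast+OL" = 12.67
                       ),
                       clone_size_shape = 3,
                       clone_size_range = c(4L, 49L),
                       span_mean = c(
                         "Ast" = 3.4, "NG2" = 2.42, "OL" = 2.0,
                         "NG2+OL" = 2.5, "Ast+NG2" = 4.67, "Ast+OL" = 4.67
                       ),
                       region_probs = default_region_probs(),
                       mixed_astro_fraction = 0.5,
                       section_thickness = 50,
                       n_sections = 12L,
                       animal_id = "a1",
                       n_collided = 0L,
                       seed = 1L) {
  cfg <- structure(
    list(
      n_progenitors = as.integer(n_progenitors),
      p_integration = p_integration,
      copy_lambda = copy_lambda,
      gain = gain,
      noise_sd = noise_sd,
      background_level = background_level,
      presence_threshold = presence_threshold,
      fate_class_probs = fate_class_probs,
      clone_size_mean = clone_size_mean,
      clone_size_shape = clone_size_shape,
      clone_size_range = as.integer(clone_size_range),
      span_mean = span_mean,
      region_probs = region_probs,
      mixed_astro_fraction = mixed_astro_fraction,
      section_thickness = section_thickness,
      n_sections = as.integer(n_sections),
      animal_id = animal_id,
      n_collided = as.integer(n_collided),
      seed = if (is.null(seed)) NULL else as.integer(seed)
    ),
    class = "sim_config"
  )
  validate_sim_config(cfg)
}

default_region_probs <- function() {
  m <- rbind(
    "Ast"     = c(0.30, 0.70, 0.00),
    "NG2"     = c(0.05, 0.90, 0.05),
    "OL"      = c(0.05, 0.70, 0.25),
    "NG2+OL"  = c(0.20, 0.60, 0.20),
    "Ast+NG2" = c(0.30, 0.50, 0.20),
    "Ast+OL"  = c(0.10, 0.60, 0.30)
  )
  colnames(m) <- REGIONS
  m
}

validate_sim_config <- function(cfg) {
  stopifnot(is.list(cfg))
  if (cfg$n_progenitors < 0) abort("`n_progenitors` must be >= 0.")
  if (cfg$p_integration < 0 || cfg$p_integration > 1) {
    abort("`p_integration` must be a probability in [0, 1].")
  }
  if (cfg$copy_lambda < 0) abort("`copy_lambda` must be >= 0.")
  if (cfg$noise_sd < 0) abort("`noise_sd` must be >= 0.")
  if (cfg$background_level < 0) abort("`background_level` must be >= 0.")
  p <- cfg$fate_class_probs
  if (!setequal(names(p), FATE_CLASSES)) {
    abort(paste0("`fate_class_probs` must be named over: ",
                 paste(FATE_CLASSES, collapse = ", ")))
  }
  if (any(p < 0) || any(p > 1)) abort("fate-class probabilities must lie in [0, 1].")
  if (abs(sum(p) - 1) > 1e-9) abort("`fate_class_probs` must sum to 1 (tol 1e-9).")
  if (!all(FATE_CLASSES %in% names(cfg$clone_size_mean))) {
    abort("`clone_size_mean` must be named over all six fate classes.")
  }
  if (!all(FATE_CLASSES %in% names(cfg$span_mean))) {
    abort("`span_mean` must be named over all six fate classes.")
  }
  if (any(cfg$span_mean < 1) || any(cfg$span_mean > 7)) {
    abort("`span_mean` must lie in [1, 7] sections.")
  }
  r <- cfg$clone_size_range
  if (length(r) != 2 || r[1] < 1 || r[2] < r[1]) {
    abort("`clone_size_range` must be an increasing pair of positive integers.")
  }
  m <- cfg$region_probs
  if (!is.matrix(m) || !setequal(rownames(m), FATE_CLASSES) ||
      !identical(colnames(m), REGIONS)) {
    abort("`region_probs` must be a 6 x 3 matrix, rows = fate classes, cols = UL/LL/CC.")
  }
  if (any(m < 0) || any(abs(rowSums(m) - 1) > 1e-9)) {
    abort("each row of `region_probs` must be a probability vector summing to 1.")
  }
  if (cfg$section_thickness <= 0) abort("`section_thickness` must be > 0.")
  if (cfg$n_sections < 7) abort("`n_sections` must be >= 7 to accommodate the span law.")
  if (cfg$n_collided < 0 || cfg$n_collided > max(0, cfg$n_progenitors - 1)) {
    abort("`n_collided` must lie in [0, n_progenitors - 1].")
  }
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat("  progenitors:", x$n_progenitors,
      " seed:", x$seed %||% "none", "\n")
  cat("  p_integration:", x$p_integration,
      " copies ~ 1 + Poisson(", x$copy_lambda, ")\n", sep = "")
  cat("  intensity: gain ", x$gain, ", noise_sd ", x$noise_sd,
      ", background ", x$background_level,
      ", presence threshold ", x$presence_threshold, "\n", sep = "")
  cat("  fate classes:",
      paste(sprintf("%s %.0f%%", names(x$fate_class_probs),
                    100 * x$fate_class_probs), collapse = ", "), "\n")
  cat("  sections:", x$n_sections, "x", x$section_thickness, "um\n")
  invisible(x)
}
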
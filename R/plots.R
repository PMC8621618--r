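#' Clone size versus rostro-caudal dispersion scatter
#'
#' One point per clone, colored by composition class — the standard view of
#' how clonal expansion relates to anterior-posterior spread.
#'
#' @param summaries Per-clone summaries from [clone_summaries()] (or the
#'   `pairs` element of a [summarize_cohort()] result).
#' @return A ggplot.
#' @export
plot_size_dispersion <- function(summaries) {
  ggplot2::ggplot(
    summaries,
    ggplot2::aes(x = .data$size, y = .data$rc_dispersion,
                 colour = .data$composition_class)
  ) +
    ggplot2::geom_jitter(width = 0.25, height = 6, alpha = 0.8) +
    ggplot2::labs(
      x = "clone size (cells)",
      y = "rostro-caudal dispersion (µm)",
      colour = "composition"
    ) +
    ggplot2::theme_minimal()
}

#' Clone composition bar chart
#'
#' @param cohort A [summarize_cohort()] result.
#' @return A ggplot of per-class clone counts with percentage labels.
#' @export
plot_composition <- function(cohort) {
  stopifnot(inherits(cohort, "cohort_summary"))
  comp <- dplyr::filter(cohort$composition, .data$n > 0)
  ggplot2::ggplot(
    comp,
    ggplot2::aes(x = .data$composition_class, y = .data$n)
  ) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::geom_text(ggplot2::aes(label = paste0(.data$percent, "%")),
                       vjust = -0.4, size = 3.2) +
    ggplot2::labs(x = NULL, y = "clones") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.cohort_summary <- function(object,
                                    type = c("size_dispersion",
                                             "composition"), ...) {
  type <- match.arg(type)
  switch(type,
    size_dispersion = plot_size_dispersion(object$pairs),
    composition = plot_composition(object)
  )
}

#' @exportS3Method generics::tidy
tidy.cohort_summary <- function(x, ...) {
  dplyr::left_join(
    x$composition,
    dplyr::select(x$class_stats, -"n"),
    by = "composition_class"
  )
}

#' @exportS3Method generics::glance
glance.cohort_summary <- function(x, ...) {
  u <- x$uniformity_stats
  pick <- function(which, col) {
    v <- u[[col]][u$uniformity == which]
    if (length(v) == 0L) NA_real_ else v
  }
  tibble::tibble(
    n_clones = x$n_clones,
    n_cells = x$n_cells,
    pct_uniform = round_half_up(
      100 * sum(x$pairs$uniformity == "uniform") / x$n_clones),
    mean_size_uniform = pick("uniform", "mean_size"),
    sem_size_uniform = pick("uniform", "sem_size"),
    mean_size_mixed = pick("mixed", "mean_size"),
    sem_size_mixed = pick("mixed", "sem_size"),
    mean_dispersion_uniform = pick("uniform", "mean_dispersion"),
    mean_dispersion_mixed = pick("mixed", "mean_dispersion")
  )
}
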
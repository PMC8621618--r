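#' Round half away from zero
#'
#' Rounds to the nearest integer with ties going up (standard "half-up"
#' rounding), the convention used for the printed composition percentages.
#' Base `round()` rounds half to even, which would turn 10.5 into 10.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal digits to keep.
#' @return Numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

# standard error of the mean; NA for n < 2
sem <- function(x) {
  n <- sum(!is.na(x))
  if (n < 2) return(NA_real_)
  stats::sd(x, na.rm = TRUE) / sqrt(n)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items; 1 for
#' identical partitions, about 0 for independent ones. Used to score how well
#' clone calling recovers a known ground-truth partition.
#'
#' @param a,b Vectors of equal length giving the two partition labels.
#' @return A single number in (-1, 1].
#' @examples
#' adjusted_rand_index(c(1, 1, 2, 2), c("x", "x", "y", "y"))
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) {
    abort("`a` and `b` must label the same items (equal length).")
  }
  tab <- table(a, b)
  n <- length(a)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  expected <- sum_a * sum_b / comb2(n)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}

#' Significance stars
#'
#' Maps p-values to the conventional star labels: `***` p < 0.001,
#' `**` p < 0.01, `*` p < 0.05, `ns` otherwise.
#'
#' @param p Numeric vector of p-values.
#' @return Character vector.
#' @export
significance_stars <- function(p) {
  dplyr::case_when(
    is.na(p) ~ NA_character_,
    p < 0.001 ~ "***",
    p < 0.01 ~ "**",
    p < 0.05 ~ "*",
    TRUE ~ "ns"
  )
}

# run body with the RNG seeded if seed is non-NULL, otherwise as-is
with_seed_if <- function(seed, code) {
  if (is.null(seed)) force(code) else withr::with_seed(seed, code)
}
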
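new_clone_test <- function(method, statistic, p_value, n, exact,
                           alternative = NA_character_, note = NA_character_) {
  structure(
    list(
      method = method,
      statistic = statistic,
      p_value = p_value,
      n = n,
      exact = exact,
      alternative = alternative,
      stars = significance_stars(p_value),
      note = note
    ),
    class = "clone_test"
  )
}

#' @export
print.clone_test <- function(x, ...) {
  cat(x$method, "\n")
  cat("  n =", paste(x$n, collapse = ", "),
      if (isTRUE(x$exact)) " (exact)" else if (isFALSE(x$exact)) " (approximate)" else "",
      "\n")
  if (!is.na(x$statistic)) {
    cat(sprintf("  %s = %.4g, p = %.4g %s\n",
                names(x$statistic) %||% "stat",
                x$statistic, x$p_value, x$stars %||% ""))
  }
  if (!is.na(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}

#' Normality gate (Lilliefors-corrected Kolmogorov-Smirnov test)
#'
#' Tests a sample against the normal family with estimated mean and SD,
#' using the Lilliefors correction with the Dallal-Wilkinson approximation
#' for the p-value. In this pipeline the gate is informative only: group
#' comparisons are always reported nonparametrically (the data this models
#' were non-Gaussian), but the gate documents that choice.
#'
#' Samples with fewer than 4 values or zero variance are not assessable and
#' default to the nonparametric branch.
#'
#' @param x Numeric sample.
#' @return A `clone_test` with fields `statistic` (D), `p_value`,
#'   `assessable`, `normal_rejected` and `recommendation`
#'   (`"nonparametric"` or `"parametric"`).
#' @export
normality_gate <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 4L || stats::sd(x) == 0) {
    out <- new_clone_test(
      method = "Lilliefors (Kolmogorov-Smirnov) normality test",
      statistic = c(D = NA_real_), p_value = NA_real_,
      n = length(x), exact = NA,
      note = "not assessable (n < 4 or zero variance); defaulting to nonparametric"
    )
    out$assessable <- FALSE
    out$normal_rejected <- NA
    out$recommendation <- "nonparametric"
    return(out)
  }
  lt <- nortest::lillie.test(x)
  out <- new_clone_test(
    method = "Lilliefors (Kolmogorov-Smirnov) normality test, Dallal-Wilkinson p",
    statistic = c(D = unname(lt$statistic)),
    p_value = lt$p.value,
    n = length(x), exact = FALSE
  )
  out$assessable <- TRUE
  out$normal_rejected <- lt$p.value < 0.05
  out$recommendation <- if (lt$p.value < 0.05) "nonparametric" else "parametric"
  out
}

#' Mann-Whitney (Wilcoxon rank-sum) test for two groups
#'
#' Exact p-value by enumeration of the U distribution when both groups have
#' at most 8 observations and the pooled sample is tie-free; otherwise the
#' normal approximation with tie correction (no continuity correction, so
#' the two-group case agrees asymptotically with [kruskal_wallis()]). The
#' `exact` field records which branch ran.
#'
#' @param x,y Numeric samples for the two groups.
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`.
#' @param exact Force the exact (`TRUE`) or approximate (`FALSE`) branch;
#'   default `NULL` applies the size/ties rule above. The exact branch is
#'   unavailable with ties.
#' @return A `clone_test` with the U statistic (number of (x, y) pairs with
#'   x > y), the p-value, group sizes and the exact/approximate flag.
#' @examples
#' mann_whitney(c(1, 2), c(3, 4), alternative = "less") # exact p = 1/6
#' @export
mann_whitney <- function(x, y, alternative = c("two.sided", "less", "greater"),
                         exact = NULL) {
  alternative <- match.arg(alternative)
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  if (length(x) == 0L || length(y) == 0L) abort("empty sample.")
  ties <- anyDuplicated(c(x, y)) > 0L
  if (is.null(exact)) {
    exact <- length(x) <= 8L && length(y) <= 8L && !ties
  }
  if (exact && ties) {
    abort("exact Mann-Whitney p is unavailable with ties; use exact = FALSE.")
  }
  wt <- stats::wilcox.test(x, y, alternative = alternative,
                           exact = exact, correct = FALSE)
  new_clone_test(
    method = "Mann-Whitney (Wilcoxon rank-sum) test",
    statistic = c(U = unname(wt$statistic)),
    p_value = wt$p.value,
    n = c(n1 = length(x), n2 = length(y)),
    exact = exact,
    alternative = alternative
  )
}

# tie-corrected Kruskal-Wallis H for pooled ranks r and group labels g
kw_statistic <- function(r, g, N) {
  rbar <- tapply(r, g, sum)
  ni <- tapply(r, g, length)
  h <- 12 / (N * (N + 1)) * sum(rbar^2 / ni) - 3 * (N + 1)
  t <- table(r)
  corr <- 1 - sum(t^3 - t) / (N^3 - N)
  if (corr == 0) return(NA_real_)
  h / corr
}

# all distinct assignments of idx into consecutive groups of given sizes
kw_assignments <- function(idx, sizes) {
  if (length(sizes) == 1L) return(list(list(idx)))
  out <- list()
  for (s in utils::combn(seq_along(idx), sizes[1L], simplify = FALSE)) {
    rest <- kw_assignments(idx[-s], sizes[-1L])
    for (r in rest) out[[length(out) + 1L]] <- c(list(idx[s]), r)
  }
  out
}

#' Kruskal-Wallis rank test for k groups
#'
#' Tie-corrected H statistic. For small problems (total n at most 10 and at
#' most `max_perm` distinct group assignments) the p-value is exact, by
#' complete enumeration of all assignments of the pooled ranks to groups;
#' otherwise the chi-square approximation with k - 1 degrees of freedom is
#' used.
#'
#' @param samples List of numeric vectors, one per group (k >= 2).
#' @param exact Force exact enumeration (`TRUE`) or the chi-square
#'   approximation (`FALSE`); default `NULL` uses the total-n rule.
#' @param max_perm Enumeration budget guard, default 2e5 assignments.
#' @return A `clone_test` with the H statistic, p-value, group sizes and
#'   exact flag.
#' @examples
#' kruskal_wallis(list(c(1), c(2), c(3))) # H = 2 exactly
#' @export
kruskal_wallis <- function(samples, exact = NULL, max_perm = 2e5) {
  if (!is.list(samples) || length(samples) < 2L) {
    abort("need at least 2 groups.")
  }
  samples <- lapply(samples, function(v) v[!is.na(v)])
  if (any(lengths(samples) == 0L)) abort("empty group.")
  sizes <- lengths(samples)
  N <- sum(sizes)
  pooled <- unlist(samples, use.names = FALSE)
  g <- rep(seq_along(samples), sizes)
  r <- rank(pooled)
  h <- kw_statistic(r, g, N)

  if (is.null(exact)) exact <- N <= 10L
  n_assign <- round(exp(lgamma(N + 1) - sum(lgamma(sizes + 1))))
  if (exact && n_assign > max_perm) exact <- FALSE

  if (exact) {
    assigns <- kw_assignments(seq_len(N), sizes)
    hs <- vapply(assigns, function(a) {
      gp <- integer(N)
      for (k in seq_along(a)) gp[a[[k]]] <- k
      kw_statistic(r, gp, N)
    }, numeric(1))
    p <- mean(hs >= h - 1e-10)
  } else {
    kt <- stats::kruskal.test(pooled, factor(g))
    p <- kt$p.value
  }
  new_clone_test(
    method = "Kruskal-Wallis rank test",
    statistic = c(H = h),
    p_value = p,
    n = sizes,
    exact = exact
  )
}

#' @exportS3Method generics::tidy
tidy.clone_test <- function(x, ...) {
  tibble::tibble(
    method = x$method,
    statistic = unname(x$statistic),
    p_value = x$p_value,
    exact = x$exact,
    stars = x$stars %||% NA_character_
  )
}

#' @exportS3Method generics::glance
glance.clone_test <- function(x, ...) {
  tibble::tibble(
    method = x$method,
    p_value = x$p_value,
    n_total = sum(x$n),
    n_groups = length(x$n),
    exact = x$exact
  )
}
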
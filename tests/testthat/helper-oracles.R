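# Independent brute-force oracles used to check the implementation.

# Exact Mann-Whitney p by exhaustive enumeration of all C(n1+n2, n1)
# assignments of the pooled (tie-free) values to group 1.
mw_enum_oracle <- function(x, y, alternative = "two.sided") {
  pooled <- c(x, y)
  n1 <- length(x)
  u_of <- function(xs, ys) sum(outer(xs, ys, ">"))
  u_obs <- u_of(x, y)
  splits <- utils::combn(length(pooled), n1, simplify = FALSE)
  us <- vapply(splits, function(ix) {
    u_of(pooled[ix], pooled[-ix])
  }, numeric(1))
  p_le <- mean(us <= u_obs)
  p_ge <- mean(us >= u_obs)
  switch(alternative,
    greater = p_ge,
    less = p_le,
    two.sided = min(1, 2 * min(p_le, p_ge))
  )
}

# Clone dispersion as the max over all member pairs of (|di - dj| + 1) * t
rc_dispersion_oracle <- function(sections, thickness = 50) {
  max(outer(sections, sections, function(a, b) abs(a - b) + 1)) * thickness
}

# A minimal hand-built cell table: one row per (section, type, intensities)
make_cells <- function(intensity_rows, section = 0L, region = "LL",
                       cell_type = "astrocyte", animal = "a1") {
  n <- nrow(intensity_rows)
  base <- tibble::tibble(
    cell_id = sprintf("%s_c%03d", animal, seq_len(n)),
    animal_id = animal,
    section_index = rep_len(section, n),
    region = rep_len(region, n),
    layer = NA_character_,
    cell_type = rep_len(cell_type, n)
  )
  dplyr::bind_cols(base, tibble::as_tibble(intensity_rows))
}

# intensity matrix with named reporters set high, everything else low
intensity_matrix <- function(n, present = character(), value = 200,
                             background = 5) {
  m <- matrix(background, n, 12, dimnames = list(NULL, reporter_cols()))
  m[, present] <- value
  m
}

expect_same_partition <- function(assign, truth_ids) {
  expect_equal(adjusted_rand_index(assign, truth_ids), 1)
}
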
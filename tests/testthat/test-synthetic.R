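test_that("sim_config validates its probability structure", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(fate_class_probs = c(Ast = 1)), "named over")
  p <- c("Ast" = 0.3, "NG2" = 0.3, "OL" = 0.2, "NG2+OL" = 0.1,
         "Ast+NG2" = 0.05, "Ast+OL" = 0.06)
  expect_error(sim_config(fate_class_probs = p), "sum to 1")
  expect_error(sim_config(p_integration = 1.2), "probability")
  bad_region <- default_probs <- sim_config()$region_probs
  bad_region[1, 1] <- 0.5
  expect_error(sim_config(region_probs = bad_region), "summing to 1")
  expect_error(sim_config(n_progenitors = -1), ">= 0")
})

test_that("integration profiles are forced by degenerate parameters", {
  cfg <- sim_config(p_integration = 1, copy_lambda = 0)
  prof <- sample_integration_profile(cfg)
  expect_named(prof, reporter_cols())
  expect_equal(unname(prof), rep(1L, 12))
  expect_error(sample_integration_profile(sim_config(p_integration = 0)),
               "cannot generate labeled progenitor")
})

test_that("reporter presence frequency follows the binomial law", {
  cfg <- sim_config(p_integration = 0.5)
  n <- 4e4
  withr::with_seed(101, {
    hits <- vapply(seq_len(n), function(i) {
      sample_integration_profile(cfg)[["yfp_cyt"]] > 0
    }, logical(1))
  })
  # all-zero profiles are resampled, so presence is slightly enriched:
  # P(present | not all absent) = p / (1 - (1-p)^12)
  p_exp <- 0.5 / (1 - 0.5^12)
  band <- 3 * sqrt(p_exp * (1 - p_exp) / n)
  expect_lt(abs(mean(hits) - p_exp), band)
})

test_that("pairwise profile collision probability matches the closed form", {
  q <- 0.35
  cfg <- sim_config(p_integration = q)
  n_pairs <- 5e4
  withr::with_seed(202, {
    a <- replicate(n_pairs, sample_integration_profile(cfg) > 0)
    b <- replicate(n_pairs, sample_integration_profile(cfg) > 0)
  })
  same <- colSums(a == b) == 12L
  # closed form for unconditioned draws; correct for the all-zero
  # resampling of each profile (all-zero patterns never occur)
  p0 <- (1 - q)^12
  p_closed <- ((q^2 + (1 - q)^2)^12 - p0^2) / (1 - p0)^2
  band <- 3 * sqrt(p_closed * (1 - p_closed) / n_pairs)
  expect_lt(abs(mean(same) - p_closed), band)
})

test_that("sample_clone honors size, span, composition and noise contracts", {
  cfg <- sim_config(noise_sd = 0, seed = NULL)
  prof <- c(2L, 0L, 0L, 1L, 0L, 0L, 0L, 3L, 0L, 0L, 0L, 0L)
  names(prof) <- reporter_cols()

  withr::with_seed(7, {
    cl <- sample_clone(prof, "Ast", cfg, size = 10)
  })
  # zero noise: sibling intensities identical per reporter
  for (col in reporter_cols()) {
    expect_equal(length(unique(cl[[col]])), 1)
  }
  expect_equal(unique(cl$yfp_cyt), 200)      # 2 copies x gain 100
  expect_equal(unique(cl$mko_nuc), 300)
  expect_equal(unique(cl$mcerulean_cyt), 5)  # background for absent

  withr::with_seed(8, {
    mixed <- sample_clone(prof, "Ast+OL", cfg, size = 12)
  })
  expect_setequal(unique(mixed$cell_type), c("astrocyte", "oligodendrocyte"))
  expect_equal(sum(mixed$cell_type == "astrocyte"), 6) # even split

  withr::with_seed(9, {
    wide <- sample_clone(prof, "NG2", cfg, size = 8, span = 7)
  })
  expect_equal(rc_dispersion(wide$section_index, 50), 350)
  expect_equal(diff(range(wide$section_index)), 6)

  expect_error(sample_clone(prof, "neuron", cfg), "unknown fate class")
})

test_that("generate_cohort is deterministic and partitions its cells", {
  cfg <- sim_config(n_progenitors = 25, seed = 33)
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  f1 <- tempfile(fileext = ".tsv")
  f2 <- tempfile(fileext = ".tsv")
  write_cell_table(c1$cells, f1)
  write_cell_table(c2$cells, f2)
  expect_identical(readLines(f1), readLines(f2))

  # ground truth covers every cell exactly once
  expect_setequal(c1$truth$cell_id, c1$cells$cell_id)
  expect_equal(anyDuplicated(c1$truth$cell_id), 0L)
  sizes <- table(c1$truth$progenitor_id)
  expect_true(all(sizes >= 4 & sizes <= 49))
  expect_true(all(c1$cells$section_index >= 0 &
                    c1$cells$section_index < cfg$n_sections))
})

test_that("an empty cohort is empty but well-formed", {
  co <- generate_cohort(sim_config(n_progenitors = 0))
  expect_equal(nrow(co$cells), 0)
  expect_equal(nrow(co$truth), 0)
  expect_true(all(required_cols <- c("cell_id", reporter_cols()) %in%
                    names(co$cells)))
})

test_that("fate-class fractions follow the configured probabilities", {
  co <- generate_cohort(sim_config(n_progenitors = 2000, seed = 55))
  fates <- dplyr::distinct(co$truth, progenitor_id, fate_class)$fate_class
  p_ast <- mean(fates == "Ast")
  band <- 3 * sqrt(0.26 * 0.74 / 2000)
  expect_lt(abs(p_ast - 0.26), band)
  # and the realised composition classes converge on the same law
  cl <- call_clones(add_barcodes(co$cells))
  summ <- clone_summaries(cl, co$cells)
  p_ast_called <- mean(summ$composition_class == "Ast")
  expect_lt(abs(p_ast_called - 0.26), band + 0.01)
})

test_that("ground-truth clones pass the intensity-consistency rule", {
  # noise_sd = 8 puts 6 sigma of a pairwise difference well under 80
  co <- generate_cohort(sim_config(n_progenitors = 1000, seed = 77))
  tt <- dplyr::inner_join(
    co$truth, co$cells[, c("cell_id", reporter_cols())], by = "cell_id")
  prof <- co$profiles
  ok <- vapply(seq_len(nrow(prof)), function(i) {
    present <- reporter_cols()[as.matrix(prof[i, reporter_cols()]) > 0]
    m <- as.matrix(tt[tt$progenitor_id == prof$progenitor_id[i], present,
                      drop = FALSE])
    all(apply(m, 2, function(v) diff(range(v))) < 80)
  }, logical(1))
  expect_gt(mean(ok), 0.99)
})

test_that("collision injection makes progenitors share a profile", {
  co <- generate_cohort(sim_config(n_progenitors = 10, n_collided = 2,
                                   seed = 5))
  expect_equal(length(unique(co$profiles$true_barcode[1:3])), 1L)
  expect_gt(length(unique(co$profiles$true_barcode)), 1L)
})
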
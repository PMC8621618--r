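render_one <- function(intensities, x = 60, y = 60, ...) {
  cells <- make_cells(intensities)
  cells$x <- x[seq_len(nrow(cells))]
  cells$y <- y[seq_len(nrow(cells))]
  render_section(cells, width = 120L, height = 120L, ...)
}

test_that("an empty section renders to pure background", {
  img <- render_section(make_cells(intensity_matrix(0))[0, ],
                        width = 64L, height = 64L, background_level = 5)
  expect_equal(dim(img$pixels), c(64, 64, 6))
  expect_true(all(img$pixels == 5))

  withr::with_seed(7, {
    noisy <- render_section(make_cells(intensity_matrix(0))[0, ],
                            width = 64L, height = 64L,
                            background_level = 5, noise_sd = 2)
  })
  expect_equal(mean(noisy$pixels), 5, tolerance = 0.05)
  expect_true(all(noisy$pixels >= 0))
})

test_that("a nuclear-only cell lights the disk but not the annulus", {
  m <- intensity_matrix(1, present = "yfp_nuc", value = 150, background = 0)
  img <- render_one(m, background_level = 5)
  masks <- gliaclone:::compartment_masks(60, 60, 4, 9, 120, 120)
  disk <- img$pixels[cbind(masks$nucleus, 1L)]
  annulus <- img$pixels[cbind(masks$cytoplasm, 1L)]
  expect_equal(mean(disk), 155)  # background + nuclear intensity
  expect_equal(mean(annulus), 5) # background only
})

test_that("well-separated cells have disjoint masks; overlap is refused", {
  m <- intensity_matrix(2, present = "egfp_cyt", value = 100)
  far <- make_cells(m)
  far$x <- c(30, 90) # 60 px apart >> 2 x cell radius
  far$y <- c(30, 30)
  img <- render_section(far, width = 120L, height = 120L)
  m1 <- gliaclone:::compartment_masks(30, 30, 4, 9, 120, 120)
  m2 <- gliaclone:::compartment_masks(90, 30, 4, 9, 120, 120)
  keys <- function(mm) paste(rbind(mm$nucleus, mm$cytoplasm)[, 1],
                             rbind(mm$nucleus, mm$cytoplasm)[, 2])
  expect_length(intersect(keys(m1), keys(m2)), 0)

  near <- far
  near$x <- c(30, 40)
  expect_error(render_section(near, width = 120L, height = 120L), "overlap")
  out_of_bounds <- far
  out_of_bounds$x <- c(3, 90)
  expect_error(render_section(out_of_bounds, width = 120L, height = 120L),
               "out of image bounds")
})

test_that("detection finds each rendered cell within 2 px", {
  withr::with_seed(17, {
    co <- generate_cohort(sim_config(n_progenitors = 3, seed = 17))
  })
  cells <- co$cells[co$cells$section_index == co$cells$section_index[1], ]
  cells <- cells[1:min(nrow(cells), 20), ]
  cells <- gliaclone:::assign_grid_positions(cells)
  withr::with_seed(18, {
    img <- render_section(cells, noise_sd = 2)
  })
  found <- detect_cells(img)
  expect_equal(nrow(found), nrow(cells))
  nearest <- vapply(seq_len(nrow(cells)), function(i) {
    min(sqrt((found$x - cells$x[i])^2 + (found$y - cells$y[i])^2))
  }, numeric(1))
  expect_true(all(nearest <= 2))

  blank <- render_section(cells[0, ], width = 128L, height = 128L)
  expect_equal(nrow(detect_cells(blank)), 0)
})

test_that("quantification inverts rendering and is linear", {
  withr::with_seed(19, {
    vals <- matrix(runif(12 * 8, 50, 600), nrow = 8,
                   dimnames = list(NULL, reporter_cols()))
  })
  cells <- make_cells(vals)
  cells <- gliaclone:::assign_grid_positions(cells)
  img <- render_section(cells) # noiseless
  q <- quantify_cells(img, cells[, c("x", "y")])
  expect_false(any(q$border))
  for (col in reporter_cols()) {
    expect_equal(q[[col]], cells[[col]], tolerance = 0.01)
  }

  # doubling the rendered intensity doubles the recovered one
  cells2 <- cells
  cells2[reporter_cols()] <- cells[reporter_cols()] * 2
  q2 <- quantify_cells(render_section(cells2), cells2[, c("x", "y")])
  ratio <- as.matrix(q2[reporter_cols()]) / as.matrix(q[reporter_cols()])
  expect_equal(unname(ratio), matrix(2, 8, 12), tolerance = 1e-6)

  # linear sweep: slope 1, R^2 > 0.99 after background subtraction
  sweep_vals <- intensity_matrix(20, present = "mcherry_cyt",
                                 value = seq(50, 800, length.out = 20))
  sc <- make_cells(sweep_vals)
  sc <- gliaclone:::assign_grid_positions(sc)
  qs <- quantify_cells(render_section(sc, noise_sd = 1), sc[, c("x", "y")])
  fit <- stats::lm(qs$mcherry_cyt ~ sc$mcherry_cyt)
  expect_equal(unname(stats::coef(fit)[2]), 1, tolerance = 0.02)
  expect_gt(summary(fit)$r.squared, 0.99)
})

test_that("cells with silent cytoplasm quantify below the presence threshold", {
  m <- intensity_matrix(1, value = 5) # background everywhere
  m[, "mko_nuc"] <- 300
  m[, "yfp_nuc"] <- 250
  cells <- make_cells(m)
  cells$x <- 60
  cells$y <- 60
  img <- render_section(cells, width = 120L, height = 120L)
  q <- quantify_cells(img, cells[, c("x", "y")])
  cyt <- unlist(q[paste0(gliaclone:::XFP_NAMES, "_cyt")])
  expect_true(all(cyt < 40))
  expect_gt(q$mko_nuc, 40)
})

test_that("border centroids are flagged, not cropped", {
  img <- render_section(make_cells(intensity_matrix(0))[0, ],
                        width = 64L, height = 64L)
  q <- quantify_cells(img, tibble::tibble(x = c(5, 32), y = c(5, 32)))
  expect_true(q$border[1])
  expect_false(q$border[2])
  expect_true(all(is.na(q$yfp_cyt[1])))
})

test_that("TIFF roundtrip preserves a section image", {
  withr::with_seed(23, {
    m <- matrix(runif(12 * 4, 0, 500), nrow = 4,
                dimnames = list(NULL, reporter_cols()))
  })
  cells <- make_cells(m)
  cells <- gliaclone:::assign_grid_positions(cells)
  img <- render_section(cells, width = 128L, height = 128L)
  path <- tempfile(fileext = ".tiff")
  write_section_tiff(img, path)
  back <- read_section_tiff(path)
  expect_equal(dim(back$pixels), dim(img$pixels))
  expect_equal(back$pixels, img$pixels, tolerance = 1e-5)
})

test_that("render-quantify-barcode reproduces ground-truth codes", {
  cfg <- sim_config(n_progenitors = 8, noise_sd = 0, seed = 29)
  co <- generate_cohort(cfg)
  truth_codes <- add_barcodes(co$cells)$barcode
  recovered <- co$cells
  for (s in unique(co$cells$section_index)) {
    idx <- which(co$cells$section_index == s)
    sec <- co$cells[idx, ]
    img <- render_section(sec)
    q <- quantify_cells(img, sec[, c("x", "y")])
    recovered[idx, reporter_cols()] <- q[reporter_cols()]
  }
  expect_identical(add_barcodes(recovered)$barcode, truth_codes)
})
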
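test_that("rostro-caudal dispersion uses the inclusive-span convention", {
  expect_equal(rc_dispersion(c(0, 0, 0)), 50)     # single section: minimum
  expect_equal(rc_dispersion(c(0, 6)), 350)       # 7-section span: maximum
  expect_equal(rc_dispersion(c(10, 12)), 150)
  expect_equal(rc_dispersion(c(3, 3), thickness = 70), 70)
  expect_error(rc_dispersion(integer()), "empty clone")
  expect_error(rc_dispersion(c(1, NA)), "empty clone|missing")
})

test_that("dispersion equals the brute-force pairwise oracle", {
  withr::with_seed(31, {
    for (i in 1:50) {
      sections <- sample.int(12, size = sample(2:20, 1), replace = TRUE) - 1L
      expect_equal(rc_dispersion(sections),
                   rc_dispersion_oracle(sections))
    }
  })
})

test_that("composition classification follows the NG2/OPC convention", {
  u <- classify_composition(c("NG2", "oligodendrocyte"))
  expect_equal(u$composition, "NG2+OL")
  expect_equal(u$uniformity, "uniform")

  a <- classify_composition("astrocyte")
  expect_equal(a$composition, "Ast")
  expect_equal(a$uniformity, "uniform")

  m <- classify_composition(c("astrocyte", "oligodendrocyte"),
                            rarity_eligible = TRUE)
  expect_equal(m$composition, "Ast+OL")
  expect_equal(m$uniformity, "mixed")

  m2 <- classify_composition(c("astrocyte", "NG2"), rarity_eligible = FALSE)
  expect_equal(m2$composition, "ambiguous")

  tri <- classify_composition(c("astrocyte", "NG2", "oligodendrocyte"))
  expect_equal(tri$composition, "ambiguous")

  expect_error(classify_composition("neuron"), "unknown cell type")
})

test_that("laminar spread is restricted only for pure lower-layer clones", {
  expect_equal(layer_spread(c("LL", "LL", "LL")), "restricted-LL")
  expect_equal(layer_spread(c("LL", "LL", "CC")), "spread")
  expect_equal(layer_spread(c("LL", "UL")), "spread")
  expect_error(layer_spread(c("LL", NA)), "missing region")
  expect_error(layer_spread("cortex"), "unknown region")
})

test_that("cohort percentages reproduce integer rounding of class counts", {
  counts <- c("Ast" = 12, "NG2" = 15, "OL" = 8, "NG2+OL" = 5,
              "Ast+NG2" = 3, "Ast+OL" = 3)
  summaries <- tibble::tibble(
    clone_id = sprintf("cl%02d", 1:46),
    size = 10,
    rc_dispersion = 100,
    composition_class = rep(names(counts), counts),
    uniformity = rep(c("uniform", "mixed"), c(40, 6)),
    layer_spread = "spread"
  )
  cohort <- summarize_cohort(summaries)
  pct <- stats::setNames(cohort$composition$percent,
                         cohort$composition$composition_class)
  expect_equal(pct[["Ast"]], 26)
  expect_equal(pct[["OL"]], 17)
  expect_equal(pct[["NG2+OL"]], 11)
  expect_lte(abs(sum(cohort$composition$percent) - 100), 1)

  single <- summarize_cohort(summaries[1, ])
  expect_equal(single$composition$percent[
    single$composition$composition_class == "Ast"], 100)
})

test_that("summary moments match direct computation (SEM = SD/sqrt(n))", {
  withr::with_seed(41, {
    summaries <- tibble::tibble(
      clone_id = sprintf("cl%02d", 1:30),
      size = sample(4:49, 30, replace = TRUE),
      rc_dispersion = 50 * sample(1:7, 30, replace = TRUE),
      composition_class = sample(c("Ast", "NG2", "OL"), 30, replace = TRUE),
      uniformity = "uniform",
      layer_spread = "spread"
    )
  })
  cohort <- summarize_cohort(summaries)
  ast <- summaries$size[summaries$composition_class == "Ast"]
  row <- cohort$class_stats[cohort$class_stats$composition_class == "Ast", ]
  expect_equal(row$mean_size, mean(ast))
  expect_equal(row$sem_size, sd(ast) / sqrt(length(ast)))
  expect_equal(row$sd_size, sd(ast))
  expect_error(summarize_cohort(summaries[0, ]), "no clones")
})

test_that("clone summaries carry sizes, dispersion and spread end to end", {
  co <- generate_cohort(sim_config(n_progenitors = 30, seed = 61))
  clones <- call_clones(co$cells)
  summ <- clone_summaries(clones, co$cells)
  expect_equal(sum(summ$size), nrow(co$cells))
  expect_true(all(summ$rc_dispersion %% 50 == 0))
  expect_true(all(summ$rc_dispersion >= 50 & summ$rc_dispersion <= 350))
  expect_true(all(summ$layer_spread %in% c("restricted-LL", "spread")))

  # dispersion agrees with the oracle on the underlying member sections
  asg <- dplyr::inner_join(clone_assignments(clones), co$cells,
                           by = "cell_id")
  for (cid in summ$clone_id[1:5]) {
    secs <- asg$section_index[asg$clone_id == cid]
    expect_equal(summ$rc_dispersion[summ$clone_id == cid],
                 rc_dispersion_oracle(secs))
  }
})

test_that("tidy, glance and autoplot work on a cohort summary", {
  co <- generate_cohort(sim_config(n_progenitors = 40, seed = 71))
  pl <- run_pipeline(cells = co$cells, config = co$config, verbose = FALSE)
  td <- tidy(pl$cohort)
  expect_true(all(c("composition_class", "n", "percent", "mean_size") %in%
                    names(td)))
  gl <- glance(pl$cohort)
  expect_equal(gl$n_clones, pl$cohort$n_clones)
  p1 <- autoplot(pl$cohort)
  p2 <- autoplot(pl$cohort, type = "composition")
  expect_s3_class(p1, "ggplot")
  expect_s3_class(p2, "ggplot")
})
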
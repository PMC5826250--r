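test_that("centering is exact within each arrangement x range cell", {
  d <- center_numerosity(data.frame(
    arrangement = c(rep("random", 7), rep("dice", 5)),
    numerosity = c(2:8, 2:6)
  ))
  # subitizing cells {2,3,4} center on 3; random estimation {5..8} on 6.5;
  # dice estimation {5,6} on 5.5
  expect_equal(d$centered[d$arrangement == "random" & d$range == "subitizing"],
               c(-1, 0, 1))
  expect_equal(d$centered[d$arrangement == "random" & d$range == "estimation"],
               c(-1.5, -0.5, 0.5, 1.5))
  expect_equal(d$centered[d$arrangement == "dice" & d$range == "estimation"],
               c(-0.5, 0.5))
  # cell means of the centered covariate are zero
  agg <- tapply(d$centered, paste(d$arrangement, d$range), mean)
  expect_true(all(abs(agg) < 1e-12))
})

test_that("constant PSC gives zero slopes with zero SE", {
  sl <- range_slopes(toy_psc(n_subjects = 4))
  expect_true(all(abs(sl$slope) < 1e-12))
  expect_true(all(sl$se < 1e-12))
  expect_true(all(sl$n_subjects == 4))
})

test_that("slopes recover a noise-free linear structure exactly", {
  slopes <- c("random subitizing" = -0.02, "random estimation" = 0.04,
              "canonical subitizing" = 0.00, "canonical estimation" = 0.00,
              "dice subitizing" = 0.01, "dice estimation" = -0.14)
  d <- toy_psc(n_subjects = 5, slopes = slopes)
  sl <- range_slopes(d)
  got <- setNames(sl$slope, paste(sl$arrangement, sl$range))
  expect_equal(got[names(slopes)], slopes, tolerance = 1e-12)
})

test_that("slopes are invariant to per-cell constant shifts", {
  set.seed(5)
  d <- toy_psc(n_subjects = 5, noise_sd = 0.1)
  sl1 <- range_slopes(d)
  shift <- c("random subitizing" = 1, "random estimation" = -2,
             "canonical subitizing" = 0.5, "canonical estimation" = 3,
             "dice subitizing" = -1, "dice estimation" = 10)
  d2 <- center_numerosity(d)
  d2$psc <- d2$psc + shift[paste(d2$arrangement, d2$range)]
  sl2 <- range_slopes(d2[names(d)])
  expect_equal(sl1$slope, sl2$slope, tolerance = 1e-10)
})

test_that("hemisphere pooling equals averaging hemisphere-specific slopes", {
  set.seed(6)
  d <- toy_psc(n_subjects = 5, noise_sd = 0.1)
  pooled <- range_slopes(d)
  by_hemi <- range_slopes(d, by_hemisphere = TRUE)
  for (i in seq_len(nrow(pooled))) {
    sel <- by_hemi$arrangement == pooled$arrangement[i] &
      by_hemi$range == pooled$range[i]
    expect_equal(pooled$slope[i], mean(by_hemi$slope[sel]), tolerance = 1e-10)
  }
})

test_that("subjects with a single numerosity in a cell are omitted", {
  d <- toy_psc(n_subjects = 4)
  drop <- d$subject_id == "S01" & d$arrangement == "dice" &
    d$numerosity == 6
  sl <- range_slopes(d[!drop, ])
  cell <- sl[sl$arrangement == "dice" & sl$range == "estimation", ]
  expect_equal(cell$n_subjects, 3)
  expect_equal(cell$n_omitted, 1)
})

test_that("discontinuity test handles null and saturated cases", {
  d <- toy_psc(n_subjects = 24)
  sl <- range_slopes(d) # all-zero slopes: differences exactly 0
  res <- discontinuity_test(sl, "random", seed = 3)
  expect_equal(res$delta_slope, 0)
  expect_equal(res$p_value, 1.0)

  # constant +0.1 difference across 24 subjects: sign-flip null can only
  # reach |obs| on the all-plus/all-minus assignments, p <= ~2 * 2^-24 + MC
  slopes <- c("random subitizing" = 0, "random estimation" = 0.1,
              "canonical subitizing" = 0, "canonical estimation" = 0,
              "dice subitizing" = 0, "dice estimation" = 0)
  d2 <- toy_psc(n_subjects = 24, slopes = slopes)
  res2 <- discontinuity_test(range_slopes(d2), "random",
                             n_permutations = 10000, seed = 4)
  expect_equal(res2$delta_slope, 0.1, tolerance = 1e-10)
  expect_lte(res2$p_value, 0.001)
})

test_that("discontinuity test demands enough subjects", {
  d <- toy_psc(n_subjects = 2)
  expect_error(discontinuity_test(range_slopes(d), "random"), "insufficient")
})

test_that("permutation p-values are reproducible and seed-sensitive", {
  set.seed(8)
  d <- toy_psc(n_subjects = 8, noise_sd = 0.15)
  sl <- range_slopes(d)
  r1 <- discontinuity_test(sl, "canonical", seed = 42)
  r2 <- discontinuity_test(sl, "canonical", seed = 42)
  expect_identical(r1$p_value, r2$p_value)
})

test_that("range amplitude contrast detects the built-in range effect", {
  d <- toy_psc(n_subjects = 6)
  d2 <- center_numerosity(d)
  bump <- c(random = 0.185, canonical = 0.155, dice = 0.035)
  d2$psc <- d2$psc + ifelse(d2$range == "estimation", bump[d2$arrangement], 0)
  res <- range_amplitude_contrast(d2[names(d)], seed = 2)
  expect_equal(res$delta_psc[res$arrangement == "random"], 0.185,
               tolerance = 1e-10)
  expect_equal(res$delta_psc[res$arrangement == "dice"], 0.035,
               tolerance = 1e-10)
  # identical psc in both ranges: delta 0, p = 1
  res0 <- range_amplitude_contrast(d, seed = 2)
  expect_true(all(res0$delta_psc == 0))
  expect_true(all(res0$p_value == 1))
})

test_that("permutation test is super-uniform under the null", {
  # 200 null simulations of 12 subject differences; sign-flip p-values must
  # not be anticonservative
  set.seed(9)
  pvals <- replicate(200, {
    diffs <- rnorm(12)
    numerotune:::sign_flip_test(diffs, n_permutations = 500,
                                seed = sample.int(1e6, 1))$p_value
  })
  expect_lte(mean(pvals < 0.05), 0.075)
})

test_that("PSC summary table reproduces configured cell means at zero noise", {
  cfg <- generator_config(n_subjects = 8, psc_subject_sd = 0)
  cfg$psc_cell_means$sd[] <- 0
  d <- generate_psc(cfg, seed = 1)
  tab <- psc_summary_table(d)
  merged <- merge(tab, cfg$psc_cell_means,
                  by = c("arrangement", "range", "hemisphere"))
  expect_equal(merged$mean.x, merged$mean.y, tolerance = 1e-12)
  expect_true(all(merged$sd.x < 1e-12))
})
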
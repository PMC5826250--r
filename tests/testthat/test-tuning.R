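test_that("tuning density matches the closed form and is symmetric", {
  # peak heights 1/(sqrt(2*pi) w n)
  expect_equal(tuning_density(5, 5, 0.276), 1 / (sqrt(2 * pi) * 0.276 * 5),
               tolerance = 1e-12)
  expect_equal(tuning_density(3, 3, 0.094), 1 / (sqrt(2 * pi) * 0.094 * 3),
               tolerance = 1e-12)
  expect_equal(round(tuning_density(5, 5, 0.276), 4), 0.2891)
  expect_equal(round(tuning_density(3, 3, 0.094), 4), 1.4147)
  # symmetry about the reference numerosity
  for (d in c(0.3, 1, 2.5)) {
    expect_equal(tuning_density(4 + d, 4, 0.2), tuning_density(4 - d, 4, 0.2))
  }
  expect_gt(min(tuning_density(seq(-5, 30, by = 0.5), 5, 0.25)), 0)
})

test_that("tuning density rejects non-positive parameters", {
  expect_error(tuning_density(3, 0, 0.2), "positive")
  expect_error(tuning_density(3, -2, 0.2), "positive")
  expect_error(tuning_density(3, 4, 0), "positive")
  expect_error(curve_overlap(0, 3, 0.2), "positive")
  expect_error(curve_overlap(2, 3, -0.1), "positive")
})

test_that("tuning density integrates to 1 over a wide support", {
  for (n in c(2, 4, 8)) {
    for (w in c(0.094, 0.241, 0.276, 0.5)) {
      val <- stats::integrate(function(x) tuning_density(x, n, w),
                              n - 10 * w * n, n + 10 * w * n,
                              rel.tol = 1e-10)$value
      expect_equal(val, 1, tolerance = 1e-6)
    }
  }
})

test_that("peak height falls with numerosity (size effect)", {
  peaks <- vapply(2:8, function(n) tuning_density(n, n, 0.241), 1)
  expect_true(all(diff(peaks) < 0))
})

test_that("curve overlap matches fine-grid integration and is symmetric", {
  grid_overlap <- function(n1, n2, w) {
    x <- seq(-40, 90, by = 5e-4) # densities are Gaussian: cover both tails
    sum(pmin(tuning_density(x, n1, w), tuning_density(x, n2, w))) * 5e-4
  }
  cases <- list(c(2, 3, 0.094), c(2, 3, 0.276), c(5, 6, 0.276), c(3, 7, 0.4))
  for (cs in cases) {
    expect_equal(curve_overlap(cs[1], cs[2], cs[3]),
                 grid_overlap(cs[1], cs[2], cs[3]), tolerance = 1e-3)
    expect_equal(curve_overlap(cs[1], cs[2], cs[3]),
                 curve_overlap(cs[2], cs[1], cs[3]), tolerance = 1e-12)
  }
  expect_equal(curve_overlap(4, 4, 0.2), 1)
})

test_that("overlap reflects scalar variability and tuning precision", {
  # wider curves at larger n: consecutive numerosities overlap more
  expect_gt(curve_overlap(5, 6, 0.2), curve_overlap(2, 3, 0.2))
  # overlap of consecutive numerosities is nondecreasing in n
  for (w in c(0.094, 0.276)) {
    ov <- vapply(2:7, function(n) curve_overlap(n, n + 1, w), 1)
    expect_true(all(diff(ov) > -1e-10))
  }
  # sharper tuning -> less overlap
  expect_lt(curve_overlap(2, 3, 0.094), curve_overlap(2, 3, 0.276))
})

test_that("noise-free curves recover the generating width exactly", {
  for (w in c(0.1, 0.25)) {
    fit <- fit_tuning_width(exact_curves(w), fit_scale = FALSE)
    expect_true(fit$converged)
    expect_equal(fit$w_hat, w, tolerance = 1e-6)
    # free amplitude must not disturb the exact solution
    fit2 <- fit_tuning_width(exact_curves(w, scale = 0.4))
    expect_equal(fit2$w_hat, w, tolerance = 1e-6)
    expect_equal(fit2$scale_hat, 0.4, tolerance = 1e-5)
  }
})

test_that("width fit agrees with a dense grid-search oracle on noisy curves", {
  set.seed(101)
  for (rep in 1:20) {
    w_true <- runif(1, 0.08, 0.45)
    curves <- lapply(2:8, function(n) {
      v <- tuning_density(2:8, n, w_true) * 0.3 + rnorm(7, 0, 0.01)
      numerosity_curve(n, 2:8, pmin(pmax(v, 0), 1))
    })
    fit <- fit_tuning_width(curves)
    oracle <- grid_search_w(curves)
    expect_equal(fit$w_hat, oracle, tolerance = 1e-3)
  }
})

test_that("width recovery from noisy curves is unbiased within 5%", {
  set.seed(202)
  w_hats <- replicate(200, {
    curves <- lapply(2:8, function(n) {
      v <- tuning_density(2:8, n, 0.10) + rnorm(7, 0, 0.005)
      numerosity_curve(n, 2:8, pmin(pmax(v, 0), 1))
    })
    fit_tuning_width(curves)$w_hat
  })
  expect_lt(abs(mean(w_hats) - 0.10), 0.005)
})

test_that("fit is invariant to curve and probe ordering", {
  set.seed(7)
  curves <- lapply(2:8, function(n) {
    v <- tuning_density(2:8, n, 0.2) * 0.5 + rnorm(7, 0, 0.02)
    numerosity_curve(n, 2:8, pmin(pmax(v, 0), 1))
  })
  fit1 <- fit_tuning_width(curves)
  fit2 <- fit_tuning_width(rev(curves))
  expect_equal(fit1$w_hat, fit2$w_hat, tolerance = 1e-10)
})

test_that("degenerate inputs are flagged, not fatal", {
  expect_error(fit_tuning_width(list(numerosity_curve(4, 4L, 0.3))),
               "insufficient")
  flat <- lapply(2:4, function(n) numerosity_curve(n, 2:4, rep(0.3, 3)))
  fit <- fit_tuning_width(flat, fit_scale = FALSE)
  expect_false(fit$converged)
  expect_error(fit_tuning_width(exact_curves(0.2), start_w = -1), "positive")
})

test_that("self-pairs are excluded by default but can anchor the peak", {
  curves <- lapply(2:5, function(n) {
    v <- tuning_density(2:5, n, 0.25)
    v[n - 1] <- NA # diagonal undefined, as from a decoder
    numerosity_curve(n, 2:5, v)
  })
  fit <- fit_tuning_width(curves, fit_scale = FALSE)
  expect_equal(fit$n_points, 12) # 16 cells minus 4 self-pairs
  fit_anchored <- fit_tuning_width(curves, include_self = TRUE)
  expect_equal(fit_anchored$n_points, 16)
})
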
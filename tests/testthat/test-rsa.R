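test_that("indistinguishable classes decode at chance, separated ones perfectly", {
  same <- two_class_patterns(separation = 0, n_exemplars = 25, n_voxels = 100,
                             seed = 21)
  acc <- pairwise_decode(same$a, same$b, n_folds = 5, seed = 1)
  expect_gte(acc, 0.35)
  expect_lte(acc, 0.65)

  far <- two_class_patterns(separation = 10, n_exemplars = 10, n_voxels = 40,
                            seed = 22)
  expect_equal(pairwise_decode(far$a, far$b, n_folds = 5, seed = 1), 1.0)
})

test_that("decoding is deterministic given the seed and rejects bad pairs", {
  fx <- two_class_patterns(separation = 1, seed = 23)
  expect_identical(pairwise_decode(fx$a, fx$b, seed = 5),
                   pairwise_decode(fx$a, fx$b, seed = 5))
  # mismatched voxel counts
  short <- pattern_set("S01", "dice", 3L, fx$a$patterns[, 1:10])
  expect_error(pairwise_decode(fx$a, short), "voxel counts")
  # same condition twice
  twin <- pattern_set("S01", fx$a$arrangement, fx$a$numerosity, fx$b$patterns)
  expect_error(pairwise_decode(fx$a, twin), "itself")
  # different subjects
  other <- pattern_set("S02", "canonical", 4L, fx$b$patterns)
  expect_error(pairwise_decode(fx$a, other), "same subject")
})

test_that("decoding accuracy is invariant to voxel permutation", {
  fx <- two_class_patterns(separation = 1.5, seed = 24)
  perm <- sample(ncol(fx$a$patterns))
  a2 <- pattern_set("S01", fx$a$arrangement, fx$a$numerosity,
                    fx$a$patterns[, perm])
  b2 <- pattern_set("S01", fx$b$arrangement, fx$b$numerosity,
                    fx$b$patterns[, perm])
  expect_equal(pairwise_decode(fx$a, fx$b, seed = 7),
               pairwise_decode(a2, b2, seed = 7), tolerance = 1e-12)
})

test_that("the ridge logit agrees with glmnet as an independent oracle", {
  skip_if_not_installed("glmnet")
  set.seed(31)
  for (rep in 1:10) {
    n <- 14; p <- 60
    Xtr <- matrix(rnorm(2 * n * p), 2 * n, p)
    Xtr[seq_len(n), ] <- Xtr[seq_len(n), ] + rnorm(p) * runif(1, 0, 0.6)
    y <- rep(0:1, each = n)
    Xte <- matrix(rnorm(10 * p), 10, p)
    eta <- numerotune:::ridge_logit_predict(Xtr, y, Xte, penalty = 1)
    fit <- glmnet::glmnet(Xtr, y, family = "binomial", alpha = 0,
                          lambda = 1 / (2 * n), standardize = FALSE,
                          thresh = 1e-11)
    eta_ref <- drop(stats::predict(fit, Xte, type = "link"))
    expect_equal(eta > 0, eta_ref > 0)
    expect_equal(eta, eta_ref, tolerance = 0.05)
  }
})

test_that("label shuffling drives accuracy to chance on average", {
  set.seed(41)
  base <- two_class_patterns(separation = 3, n_exemplars = 12, n_voxels = 50,
                             seed = 41)
  X <- rbind(base$a$patterns, base$b$patterns)
  accs <- vapply(1:100, function(s) {
    set.seed(s)
    idx <- sample(nrow(X))
    a <- pattern_set("S01", "random", 2L, X[idx[1:12], ])
    b <- pattern_set("S01", "random", 5L, X[idx[13:24], ])
    pairwise_decode(a, b, n_folds = 3, seed = s)
  }, 1)
  expect_gte(mean(accs), 0.45)
  expect_lte(mean(accs), 0.55)
})

test_that("similarity matrix is the symmetric mean of subject matrices", {
  cfg <- scale_config(generator_config(), n_subjects = 3, n_voxels = 30,
                      exemplars_per_condition = 4)
  pats <- generate_patterns(cfg, seed = 51)
  # restrict to a small condition subset for speed
  keep <- Filter(function(p) p$arrangement %in% c("random", "dice") &
                   p$numerosity %in% 2:4, pats)
  m <- similarity_matrix(keep, n_folds = 3, seed = 51)
  expect_equal(m$errors, t(m$errors))
  expect_true(all(is.na(diag(m$errors))))
  off <- !diag(nrow(m$errors))
  expect_true(all(m$errors[off] >= 0 & m$errors[off] <= 1))
  expect_equal(m$errors[off], apply(m$per_subject, c(1, 2), mean)[off],
               tolerance = 1e-12)
  expect_equal(m$n_subjects, 3)
})

test_that("subjects with inconsistent condition sets are named in the error", {
  cfg <- scale_config(generator_config(), n_subjects = 2, n_voxels = 10,
                      exemplars_per_condition = 3)
  pats <- generate_patterns(cfg, seed = 52)
  drop_one <- !(vapply(pats, function(p) p$subject_id, "") == "S02" &
                  vapply(pats, function(p) p$arrangement, "") == "dice" &
                  vapply(pats, function(p) p$numerosity, 1L) == 4L)
  expect_error(similarity_matrix(pats[drop_one]), "S02")
})

test_that("similarity curves carry the right combinatorics", {
  conditions <- condition_grid()
  K <- nrow(conditions)
  errors <- matrix(0.3, K, K)
  diag(errors) <- NA
  m <- structure(list(conditions = conditions, errors = errors,
                      per_subject = NULL, n_subjects = 1),
                 class = "similarity_matrix")
  can <- similarity_curves(m, "canonical")
  expect_length(can, 7)
  for (cv in can) {
    expect_length(cv$probes, 7) # 6 defined probes + NA self-entry
    expect_equal(sum(is.finite(cv$values)), 6)
  }
  dice <- similarity_curves(m, "dice")
  expect_length(dice, 5)
  for (cv in dice) expect_equal(sum(is.finite(cv$values)), 4)
  expect_error(similarity_curves(m, "hexagonal"), "arrangement")
})

test_that("widths are recovered from a matrix synthesized from the model", {
  conditions <- condition_grid()
  K <- nrow(conditions)
  errors <- matrix(NA_real_, K, K)
  for (i in seq_len(K)) {
    for (j in seq_len(K)) {
      if (i != j && conditions$arrangement[i] == conditions$arrangement[j]) {
        errors[i, j] <- 0.4 * tuning_density(conditions$numerosity[j],
                                             conditions$numerosity[i], 0.2)
      }
    }
  }
  m <- structure(list(conditions = conditions, errors = errors,
                      per_subject = NULL, n_subjects = 1),
                 class = "similarity_matrix")
  # errors built exactly as scale * f(x; n, w): the off-diagonal fit must
  # recover both parameters to high precision
  fit <- estimate_arrangement_width(m, "random", include_self = FALSE)
  expect_true(fit$converged)
  expect_equal(fit$w_hat, 0.2, tolerance = 1e-4)
  expect_equal(fit$scale_hat, 0.4, tolerance = 1e-3)
})

test_that("numerical-distance effect: far pairs decode better than near pairs", {
  # under wide tuning (w = 0.276), patterns for 5 vs 8 are less similar than
  # 5 vs 6; averaged over seeds the decoder must see that
  cfg <- scale_config(generator_config(n_subjects = 1), n_voxels = 60,
                      exemplars_per_condition = 8)
  d_near <- d_far <- numeric(12)
  for (s in seq_len(12)) {
    pats <- generate_patterns(cfg, seed = 60 + s)
    get <- function(n) Filter(function(p) p$arrangement == "random" &
                                p$numerosity == n, pats)[[1]]
    d_near[s] <- pairwise_decode(get(5), get(6), n_folds = 3, seed = s)
    d_far[s] <- pairwise_decode(get(5), get(8), n_folds = 3, seed = s)
  }
  expect_gt(mean(d_far), mean(d_near))
})

test_that("confusion of adjacent large numerosities grows with tuning width", {
  # Scalar variability puts the tuning s.d. at w * n: for the pair (5, 6) the
  # three arrangement widths straddle the unit probe spacing, so sharper
  # tuning must yield lower classification error -- the generator's central
  # ordinal prediction. (Means over ALL pairs are not monotone in w: at small
  # numerosities a narrow curve recruits too few voxels to separate patterns,
  # so the per-pair, large-n comparison is the faithful one.)
  cfg <- scale_config(generator_config(n_subjects = 3), n_voxels = 80)
  errs <- c(dice = 0, canonical = 0, random = 0)
  n_seeds <- 6
  for (s in seq_len(n_seeds)) {
    pats <- generate_patterns(cfg, seed = 70 + s)
    for (arr in names(errs)) {
      sets <- Filter(function(p) p$arrangement == arr &
                       p$numerosity %in% 5:6, pats)
      for (subj in unique(vapply(sets, function(p) p$subject_id, ""))) {
        pair <- Filter(function(p) p$subject_id == subj, sets)
        errs[arr] <- errs[arr] +
          (1 - pairwise_decode(pair[[1]], pair[[2]], n_folds = 3,
                               seed = 70 + s)) / (n_seeds * cfg$n_subjects)
      }
    }
  }
  expect_lt(errs["dice"], errs["canonical"])
  expect_lt(errs["canonical"], errs["random"])
})
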
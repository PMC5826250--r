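# Shared fixtures, built in code at test time.

# Noise-free similarity curves sampled exactly from scale * f(x; n, w).
exact_curves <- function(w, scale = 1, ns = 2:8, probes = ns) {
  lapply(ns, function(n) {
    numerosity_curve(n, probes, pmin(scale * tuning_density(probes, n, w), 1))
  })
}

# Dense grid-search oracle for the tuning width: profiles out the amplitude
# in closed form (for fixed w the model is linear in the scale), then scans
# w on a fine grid. Independent of the Levenberg-Marquardt path.
grid_search_w <- function(curves, w_grid = seq(0.02, 1.5, by = 1e-4),
                          fit_scale = TRUE, include_self = FALSE) {
  pts <- numerotune:::curves_to_points(curves, include_self = include_self)
  sse <- vapply(w_grid, function(w) {
    f <- tuning_density(pts$x, pts$n, w)
    s <- if (fit_scale) sum(pts$value * f) / sum(f^2) else 1
    sum((pts$value - s * f)^2)
  }, 1)
  w_grid[which.min(sse)]
}

# Small pattern fixture: two classes of Gaussian patterns with a given mean
# separation (in units of noise SD).
two_class_patterns <- function(separation, n_exemplars = 10, n_voxels = 40,
                               seed = 1, subject = "S01") {
  set.seed(seed)
  shift <- rnorm(n_voxels)
  shift <- shift / sqrt(sum(shift^2)) * separation
  Xa <- matrix(rnorm(n_exemplars * n_voxels), n_exemplars, n_voxels)
  Xb <- matrix(rnorm(n_exemplars * n_voxels), n_exemplars, n_voxels) +
    matrix(rep(shift, each = n_exemplars), n_exemplars, n_voxels)
  list(a = pattern_set(subject, "random", 2L, Xa),
       b = pattern_set(subject, "random", 5L, Xb))
}

# Tiny PSC dataset with known cell structure, optionally with noise.
toy_psc <- function(n_subjects = 6, slopes = NULL, noise_sd = 0, seed = 1,
                    intercept = 0.3) {
  set.seed(seed)
  grid <- condition_grid()
  rows <- expand.grid(subject = seq_len(n_subjects),
                      hemisphere = c("left", "right"),
                      i = seq_len(nrow(grid)), stringsAsFactors = FALSE)
  d <- tibble::tibble(
    subject_id = sprintf("S%02d", rows$subject),
    hemisphere = rows$hemisphere,
    arrangement = grid$arrangement[rows$i],
    numerosity = grid$numerosity[rows$i],
    psc = intercept
  )
  d <- center_numerosity(d)
  if (!is.null(slopes)) {
    key <- paste(d$arrangement, d$range)
    d$psc <- d$psc + slopes[key] * d$centered
  }
  d$psc <- d$psc + rnorm(nrow(d), 0, noise_sd)
  d
}

# Well-behaved behavioral trials: correct, comfortably slow, log-normal.
toy_trials <- function(n_subjects = 4, n_per_cond = 6, seed = 1,
                       rt_log_mean = 6.5, rt_sd = 0.2) {
  set.seed(seed)
  grid <- condition_grid()
  idx <- rep(seq_len(nrow(grid)), n_per_cond)
  do.call(rbind, lapply(seq_len(n_subjects), function(s) {
    tibble::tibble(
      subject_id = sprintf("S%02d", s),
      run = rep_len(1:2, length(idx)),
      arrangement = grid$arrangement[idx],
      numerosity = grid$numerosity[idx],
      rt = exp(rnorm(length(idx), rt_log_mean, rt_sd)),
      correct = TRUE
    )
  }))
}
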
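#' Generator configuration
#'
#' Bundles every parameter of the synthetic-data generators. Defaults are
#' calibrated to the published condition-level statistics of the dot-pattern
#' quantification study the package models: tuning widths per arrangement
#' (0.094 dice / 0.241 canonical / 0.276 random), percent-signal-change cell
#' means and SDs per arrangement x range x hemisphere, the per-cell PSC and
#' log-RT slopes, log-RT condition means, and error-rate log odds. Quantities
#' the source publication does not determine (voxel count, exemplar count,
#' tuning-preference distribution, pattern gain and noise, subject-level SDs,
#' fast-guess contamination) are free parameters with defaults stated here and
#' motivated in the package vignette.
#'
#' Note: the published canonical-estimation RT slope (0.010) is reported with
#' an inconsistent z statistic in the source; the printed slope value is used
#' as the default and the inconsistency is deliberately not reconciled.
#'
#' @param n_subjects Number of subjects (default 24).
#' @param n_voxels Voxels per subject pattern (default 200).
#' @param exemplars_per_condition Pattern exemplars per condition (default 12).
#' @param widths Named tuning widths per arrangement.
#' @param pattern_gain Peak amplitude of a voxel's tuning response (default 1).
#' @param pattern_noise_sd Exemplar noise s.d. per voxel (default 0.65 at the
#'   default 200 voxels; see [scale_config()] for the SNR-preserving scaling
#'   used when running at reduced size).
#' @param psc_cell_means Data frame of PSC means/SDs per
#'   arrangement x range x hemisphere (defaults: published Table of PSC
#'   condition statistics).
#' @param psc_slopes Data frame of PSC-on-numerosity slopes per
#'   arrangement x range.
#' @param psc_subject_sd Between-subject intercept s.d. for PSC (default 0.10).
#' @param rt_log_means Data frame of log-RT means (log-ms) per
#'   arrangement x range.
#' @param rt_slopes Data frame of log-RT-on-numerosity slopes per
#'   arrangement x range.
#' @param rt_noise_sd Trial-level log-RT noise s.d. (default 0.25).
#' @param rt_subject_sd Between-subject log-RT intercept s.d. (default 0.10).
#' @param er_log_odds Data frame of error log odds per arrangement x range.
#' @param trials_per_subject Behavioral trials per subject (default 336).
#' @param fast_guess_rate Fraction of contaminant trials with RT uniform on
#'   [50, 200) ms (default 0.01), included so trimming has work to do.
#' @return Object of class `generator_config` (a named list).
#' @export
generator_config <- function(n_subjects = 24L,
                             n_voxels = 200L,
                             exemplars_per_condition = 12L,
                             widths = c(random = 0.276, canonical = 0.241, dice = 0.094),
                             pattern_gain = 1,
                             pattern_noise_sd = 0.65,
                             psc_cell_means = default_psc_cell_means(),
                             psc_slopes = default_psc_slopes(),
                             psc_subject_sd = 0.10,
                             rt_log_means = default_rt_log_means(),
                             rt_slopes = default_rt_slopes(),
                             rt_noise_sd = 0.25,
                             rt_subject_sd = 0.10,
                             er_log_odds = default_er_log_odds(),
                             trials_per_subject = 336L,
                             fast_guess_rate = 0.01) {
  cfg <- structure(
    list(n_subjects = as.integer(n_subjects), n_voxels = as.integer(n_voxels),
         exemplars_per_condition = as.integer(exemplars_per_condition),
         widths = widths, pattern_gain = pattern_gain,
         pattern_noise_sd = pattern_noise_sd,
         psc_cell_means = psc_cell_means, psc_slopes = psc_slopes,
         psc_subject_sd = psc_subject_sd,
         rt_log_means = rt_log_means, rt_slopes = rt_slopes,
         rt_noise_sd = rt_noise_sd, rt_subject_sd = rt_subject_sd,
         er_log_odds = er_log_odds,
         trials_per_subject = as.integer(trials_per_subject),
         fast_guess_rate = fast_guess_rate),
    class = "generator_config"
  )
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  stopifnot(cfg$n_subjects >= 1, cfg$n_voxels >= 1,
            cfg$exemplars_per_condition >= 2, cfg$trials_per_subject >= 1)
  if (!setequal(names(cfg$widths), ARRANGEMENTS) || any(cfg$widths <= 0)) {
    stop("`widths` must be positive and named random/canonical/dice")
  }
  if (cfg$pattern_noise_sd < 0 || cfg$psc_subject_sd < 0 ||
      cfg$rt_noise_sd < 0 || cfg$rt_subject_sd < 0) {
    stop("standard deviations must be non-negative")
  }
  if (cfg$fast_guess_rate < 0 || cfg$fast_guess_rate >= 1) {
    stop("`fast_guess_rate` must be in [0, 1)")
  }
  for (tab in c("psc_slopes", "rt_log_means", "rt_slopes", "er_log_odds")) {
    d <- cfg[[tab]]
    validate_conditions(d$arrangement, rep(2L, nrow(d)))
    if (any(d$arrangement == "dice" & !d$range %in% c("subitizing", "estimation"))) {
      stop(tab, ": bad range labels")
    }
  }
  invisible(TRUE)
}

#' @rdname generator_config
#' @export
default_psc_cell_means <- function() {
  tibble::tibble(
    arrangement = rep(c("random", "canonical", "dice"), each = 4L),
    range = rep(rep(c("subitizing", "estimation"), each = 2L), 3L),
    hemisphere = rep(c("left", "right"), 6L),
    mean = c(0.24, 0.14, 0.42, 0.33,
             0.23, 0.12, 0.38, 0.28,
             0.28, 0.16, 0.32, 0.19),
    sd   = c(0.15, 0.17, 0.17, 0.23,
             0.16, 0.18, 0.17, 0.22,
             0.25, 0.24, 0.23, 0.28)
  )
}

#' @rdname generator_config
#' @export
default_psc_slopes <- function() {
  tibble::tibble(
    arrangement = rep(c("random", "canonical", "dice"), each = 2L),
    range = rep(c("subitizing", "estimation"), 3L),
    slope = c(-0.02, 0.04, 0.00, 0.00, 0.01, -0.14)
  )
}

#' @rdname generator_config
#' @export
default_rt_log_means <- function() {
  tibble::tibble(
    arrangement = rep(c("random", "canonical", "dice"), each = 2L),
    range = rep(c("subitizing", "estimation"), 3L),
    log_rt = c(6.27, 6.82, 6.23, 6.47, 6.23, 6.27)
  )
}

#' @rdname generator_config
#' @export
default_rt_slopes <- function() {
  tibble::tibble(
    arrangement = rep(c("random", "canonical", "dice"), each = 2L),
    range = rep(c("subitizing", "estimation"), 3L),
    slope = c(0.045, 0.155, 0.041, 0.010, 0.004, -0.021)
  )
}

#' @rdname generator_config
#' @export
default_er_log_odds <- function() {
  tibble::tibble(
    arrangement = rep(c("random", "canonical", "dice"), each = 2L),
    range = rep(c("subitizing", "estimation"), 3L),
    log_odds = c(-5.51, -1.46, -5.44, -3.38, -6.35, -5.94)
  )
}

#' Scale a generator configuration down while preserving the decoding regime
#'
#' Simulation studies in this package sometimes run at reduced size (fewer
#' subjects, voxels, exemplars) to keep run times short. Because the
#' separation of two condition means grows with the square root of the voxel
#' count, holding the pattern-level signal-to-noise ratio constant requires
#' scaling the exemplar noise by `sqrt(n_voxels / original_n_voxels)`. This
#' helper applies that rule so that a scaled-down run probes the same
#' error-curve regime as the default configuration.
#'
#' @param cfg A `generator_config`.
#' @param n_subjects,n_voxels,exemplars_per_condition New sizes (defaults:
#'   keep).
#' @return A rescaled `generator_config`.
#' @export
scale_config <- function(cfg, n_subjects = cfg$n_subjects,
                         n_voxels = cfg$n_voxels,
                         exemplars_per_condition = cfg$exemplars_per_condition) {
  stopifnot(inherits(cfg, "generator_config"))
  out <- cfg
  out$pattern_noise_sd <- cfg$pattern_noise_sd * sqrt(n_voxels / cfg$n_voxels)
  out$n_subjects <- as.integer(n_subjects)
  out$n_voxels <- as.integer(n_voxels)
  out$exemplars_per_condition <- as.integer(exemplars_per_condition)
  validate_config(out)
  out
}

#' Sample voxel tuning preferences
#'
#' Each voxel is assigned a preferred numerosity, log-uniform on [1, 10]:
#' numerosity-tuned neural populations tile the number line approximately
#' uniformly on a logarithmic scale.
#'
#' @param n_voxels Number of voxels (>= 1).
#' @param seed Integer seed.
#' @return Numeric vector of preferred numerosities.
#' @export
sample_voxel_tuning <- function(n_voxels, seed = 1L) {
  if (n_voxels < 1) stop("`n_voxels` must be >= 1")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed %% 2147483647))
  exp(stats::runif(n_voxels, 0, log(10)))
}

#' Generate voxel-pattern exemplars for all conditions and subjects
#'
#' For each subject, voxel preferences are drawn once (fixed within subject,
#' resampled across subjects). The mean pattern of condition (arrangement, n)
#' is, per voxel with preference p,
#' `gain * exp(-(n - p)^2 / (2 (w_arr * p)^2))` -- the Gaussian tuning
#' response with scalar variability, evaluated at the presented numerosity --
#' and each exemplar adds independent Gaussian noise. Narrower widths
#' (e.g. dice) give less overlapping condition patterns, hence better pairwise
#' decodability.
#'
#' @param config A [generator_config()].
#' @param seed Integer seed; the full output is reproducible bit-identically.
#' @return List of [pattern_set()] objects (subjects x 19 conditions), with
#'   attribute `"voxel_tuning"` holding each subject's preferred numerosities.
#' @export
generate_patterns <- function(config = generator_config(), seed = 1L) {
  validate_config(config)
  grid <- condition_grid()
  out <- vector("list", config$n_subjects * nrow(grid))
  tuning <- vector("list", config$n_subjects)
  k <- 0L
  for (s in seq_len(config$n_subjects)) {
    p_v <- sample_voxel_tuning(config$n_voxels, seed = derive_seed(seed, s))
    tuning[[s]] <- p_v
    old <- .Random.seed_save()
    set.seed(derive_seed(seed, 10000L + s))
    for (i in seq_len(nrow(grid))) {
      arr <- grid$arrangement[i]
      n <- grid$numerosity[i]
      w <- config$widths[[arr]]
      mu <- config$pattern_gain * exp(-(n - p_v)^2 / (2 * (w * p_v)^2))
      E <- config$exemplars_per_condition
      X <- matrix(rep(mu, each = E), nrow = E) +
        matrix(stats::rnorm(E * config$n_voxels, 0, config$pattern_noise_sd),
               nrow = E)
      k <- k + 1L
      out[[k]] <- pattern_set(sprintf("S%02d", s), arr, n, X)
    }
    .Random.seed_restore(old)
  }
  names(tuning) <- sprintf("S%02d", seq_len(config$n_subjects))
  attr(out, "voxel_tuning") <- tuning
  out
}

#' Generate percent-signal-change records
#'
#' One PSC observation per subject x hemisphere x arrangement x numerosity:
#' `psc = cell_mean + subject_intercept + slope * centered_numerosity + noise`,
#' where the cell mean and slope come from the configured
#' arrangement x range (x hemisphere) tables, the subject intercept is
#' `N(0, psc_subject_sd)`, and the residual s.d. is chosen so the marginal SD
#' matches the configured cell SD
#' (`residual_sd = sqrt(max(cell_sd^2 - psc_subject_sd^2, 0))`).
#'
#' @param config A [generator_config()].
#' @param seed Integer seed.
#' @return Tibble with columns `subject_id`, `hemisphere`, `arrangement`,
#'   `numerosity`, `psc`.
#' @export
generate_psc <- function(config = generator_config(), seed = 1L) {
  validate_config(config)
  grid <- condition_grid()
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(derive_seed(seed, 777L))
  subj_int <- stats::rnorm(config$n_subjects, 0, config$psc_subject_sd)

  rows <- expand.grid(subject = seq_len(config$n_subjects),
                      hemisphere = c("left", "right"),
                      idx = seq_len(nrow(grid)),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  arr <- grid$arrangement[rows$idx]
  num <- grid$numerosity[rows$idx]
  rng <- as.character(number_range(num))
  cell_mean_of <- function(a, r, h) {
    m <- config$psc_cell_means
    m$mean[m$arrangement == a & m$range == r & m$hemisphere == h]
  }
  cell_sd_of <- function(a, r, h) {
    m <- config$psc_cell_means
    m$sd[m$arrangement == a & m$range == r & m$hemisphere == h]
  }
  slope_of <- function(a, r) {
    s <- config$psc_slopes
    s$slope[s$arrangement == a & s$range == r]
  }
  key <- paste(arr, rng, rows$hemisphere)
  ukey <- unique(key)
  parts <- strsplit(ukey, " ")
  mean_map <- stats::setNames(vapply(parts, function(p) cell_mean_of(p[1], p[2], p[3]), 1), ukey)
  sd_map <- stats::setNames(vapply(parts, function(p) cell_sd_of(p[1], p[2], p[3]), 1), ukey)
  skey <- paste(arr, rng)
  uskey <- unique(skey)
  sparts <- strsplit(uskey, " ")
  slope_map <- stats::setNames(vapply(sparts, function(p) slope_of(p[1], p[2]), 1), uskey)

  # centered numerosity within arrangement x range (design is balanced, so
  # the cell mean numerosity is known exactly)
  centered <- num - stats::ave(num, arr, rng, FUN = mean)
  resid_sd <- sqrt(pmax(sd_map[key]^2 - config$psc_subject_sd^2, 0))
  psc <- mean_map[key] + subj_int[rows$subject] + slope_map[skey] * centered +
    stats::rnorm(nrow(rows), 0, resid_sd)

  tibble::tibble(
    subject_id = sprintf("S%02d", rows$subject),
    hemisphere = rows$hemisphere,
    arrangement = arr,
    numerosity = as.integer(num),
    psc = as.numeric(psc)
  )
}

#' Generate behavioral trial records
#'
#' Simulates each subject's quantification session: `trials_per_subject`
#' trials balanced across the 19 valid (arrangement, numerosity) conditions
#' (the remainder after integer division is assigned to a seeded random subset
#' of conditions). Correctness is Bernoulli with error probability
#' `plogis(log_odds)` from the configured arrangement x range table; RTs of
#' ordinary trials are log-normal,
#' `log RT ~ N(log_mean + slope * centered_n + subject_intercept, rt_noise_sd)`
#' (in log-ms), and a `fast_guess_rate` fraction of trials is replaced by
#' contaminant fast guesses uniform on [50, 200) ms so that the trimming
#' pipeline is exercised.
#'
#' @param config A [generator_config()].
#' @param seed Integer seed.
#' @return Tibble with columns `subject_id`, `run`, `arrangement`,
#'   `numerosity`, `rt` (ms), `correct` (logical).
#' @export
generate_behavior <- function(config = generator_config(), seed = 1L) {
  validate_config(config)
  grid <- condition_grid()
  K <- nrow(grid)
  n_rep <- config$trials_per_subject %/% K
  n_extra <- config$trials_per_subject %% K

  lm_of <- function(tab, col) {
    stats::setNames(tab[[col]], paste(tab$arrangement, tab$range))
  }
  log_means <- lm_of(config$rt_log_means, "log_rt")
  slopes <- lm_of(config$rt_slopes, "slope")
  log_odds <- lm_of(config$er_log_odds, "log_odds")

  grid$range <- as.character(number_range(grid$numerosity))
  grid$centered <- grid$numerosity -
    stats::ave(grid$numerosity, grid$arrangement, grid$range, FUN = mean)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  out <- vector("list", config$n_subjects)
  for (s in seq_len(config$n_subjects)) {
    set.seed(derive_seed(seed, 20000L + s))
    subj_int <- stats::rnorm(1, 0, config$rt_subject_sd)
    idx <- rep(seq_len(K), n_rep)
    if (n_extra > 0) idx <- c(idx, sample(K, n_extra))
    idx <- sample(idx)  # shuffle trial order
    n_tr <- length(idx)
    key <- paste(grid$arrangement[idx], grid$range[idx])
    p_err <- stats::plogis(log_odds[key])
    correct <- stats::runif(n_tr) >= p_err
    log_rt <- stats::rnorm(n_tr,
                           log_means[key] + slopes[key] * grid$centered[idx] + subj_int,
                           config$rt_noise_sd)
    rt <- exp(log_rt)
    fast <- stats::runif(n_tr) < config$fast_guess_rate
    rt[fast] <- stats::runif(sum(fast), 50, 200)
    out[[s]] <- tibble::tibble(
      subject_id = sprintf("S%02d", s),
      run = rep_len(1:2, n_tr),
      arrangement = grid$arrangement[idx],
      numerosity = as.integer(grid$numerosity[idx]),
      rt = rt,
      correct = correct
    )
  }
  do.call(rbind, out)
}

#' Generate a full synthetic dataset
#'
#' Convenience wrapper producing voxel patterns, PSC records and behavioral
#' trials from one configuration and seed, with the ground truth retained.
#'
#' @param config A [generator_config()].
#' @param seed Integer seed.
#' @return List with elements `pattern_sets`, `psc_records`, `trial_records`
#'   and `ground_truth` (the config plus per-subject voxel tuning and the
#'   seed).
#' @export
generate_dataset <- function(config = generator_config(), seed = 1L) {
  patterns <- generate_patterns(config, seed = seed)
  list(
    pattern_sets = patterns,
    psc_records = generate_psc(config, seed = seed),
    trial_records = generate_behavior(config, seed = seed),
    ground_truth = list(config = config, seed = as.integer(seed),
                        voxel_tuning = attr(patterns, "voxel_tuning"))
  )
}
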
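#' Center numerosity within arrangement x range cells
#'
#' Adds a `centered` column: numerosity minus the mean numerosity of its
#' arrangement x range cell (computed from the distinct numerosities present
#' in that cell, matching the convention of centering the numerosity predictor
#' separately per condition cell). The `range` column is added as well.
#'
#' @param records Data frame with columns `arrangement` and `numerosity`
#'   (PSC records, trial records, or any tidy table of observations).
#' @return The input with added `range` and `centered` columns.
#' @export
#' @examples
#' center_numerosity(data.frame(arrangement = "random", numerosity = 2:4))$centered
center_numerosity <- function(records) {
  stopifnot(nrow(records) > 0)
  validate_conditions(records$arrangement, records$numerosity)
  records$range <- as.character(number_range(records$numerosity))
  cell <- paste(records$arrangement, records$range)
  # cell mean over the *distinct* numerosities of the cell, so unbalanced
  # trial counts do not shift the centering
  cell_means <- tapply(records$numerosity, cell,
                       function(v) mean(unique(v)))
  records$centered <- as.numeric(records$numerosity - cell_means[cell])
  records
}

# Per-subject OLS slope of `value` on centered numerosity within each
# arrangement x range cell; shared engine for PSC and log-RT slopes.
cell_slopes <- function(records, value_col) {
  records <- center_numerosity(records)
  cells <- unique(records[c("arrangement", "range")])
  cells <- cells[order(cells$arrangement, cells$range), , drop = FALSE]
  out <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    sel <- records$arrangement == cells$arrangement[i] &
      records$range == cells$range[i]
    d <- records[sel, , drop = FALSE]
    subj <- unique(d$subject_id)
    slopes <- stats::setNames(rep(NA_real_, length(subj)), subj)
    for (j in seq_along(subj)) {
      ds <- d[d$subject_id == subj[j], , drop = FALSE]
      if (length(unique(ds$numerosity)) < 2L) next  # slope not estimable
      xc <- ds$centered
      yv <- ds[[value_col]]
      slopes[j] <- sum((xc - mean(xc)) * (yv - mean(yv))) / sum((xc - mean(xc))^2)
    }
    omitted <- sum(is.na(slopes))
    slopes <- slopes[!is.na(slopes)]
    n <- length(slopes)
    out[[i]] <- tibble::tibble(
      arrangement = cells$arrangement[i],
      range = cells$range[i],
      slope = mean(slopes),
      se = if (n > 1) stats::sd(slopes) / sqrt(n) else 0,
      n_subjects = n,
      n_omitted = omitted,
      per_subject = list(slopes)
    )
  }
  do.call(rbind, out)
}

#' Per-range amplitude slopes
#'
#' Two-stage summary-statistics analysis of the percent-signal-change (PSC)
#' response: within each arrangement x range cell, an ordinary least-squares
#' slope of PSC on centered numerosity is fitted per subject (hemispheres
#' pooled by default), and the group slope is the mean of subject slopes with
#' `se = sd / sqrt(n_subjects)`. Subjects contributing fewer than two distinct
#' numerosities to a cell are omitted from that cell and counted in
#' `n_omitted`.
#'
#' @param records Tidy PSC records: columns `subject_id`, `hemisphere`,
#'   `arrangement`, `numerosity`, `psc`.
#' @param by_hemisphere Keep hemispheres separate (default `FALSE`, pooling
#'   both into one slope per subject and cell).
#' @return Tibble with one row per arrangement x range (x hemisphere):
#'   `slope`, `se`, `n_subjects`, `n_omitted` and a `per_subject` list-column.
#' @export
range_slopes <- function(records, by_hemisphere = FALSE) {
  stopifnot(all(c("subject_id", "arrangement", "numerosity", "psc") %in%
                  names(records)))
  if (any(!is.finite(records$psc))) stop("non-finite PSC values")
  if (by_hemisphere) {
    parts <- split(records, records$hemisphere)
    out <- lapply(names(parts), function(h) {
      res <- cell_slopes(parts[[h]], "psc")
      res$hemisphere <- h
      res
    })
    return(do.call(rbind, out))
  }
  cell_slopes(records, "psc")
}

#' Subitizing-estimation slope discontinuity test
#'
#' Tests whether the effect of numerosity on the ROI response differs between
#' the estimation and the subitizing range for one arrangement: the statistic
#' is the mean over subjects of the per-subject slope difference
#' (estimation - subitizing), and the two-sided p-value comes from a sign-flip
#' permutation of the subject differences (under the null of no difference the
#' sign of each subject's difference is exchangeable), with the add-one
#' correction `p = (1 + #{|perm| >= |obs|}) / (1 + n_permutations)`.
#'
#' @param slopes Output of [range_slopes()] (or [behavioral_slopes()])
#'   restricted to one arrangement, containing both ranges.
#' @param arrangement Which arrangement to test (required if `slopes` holds
#'   several).
#' @param n_permutations Number of random sign assignments (default 10000).
#' @param seed Integer seed; the permutation draw is deterministic given it.
#' @return List of class `discontinuity_result`: `arrangement`, `delta_slope`,
#'   `p_value`, `n_permutations`, `n_subjects`.
#' @export
discontinuity_test <- function(slopes, arrangement = NULL,
                               n_permutations = 10000L, seed = 1L) {
  if (!is.null(arrangement)) {
    slopes <- slopes[slopes$arrangement == arrangement, , drop = FALSE]
  } else {
    arrangement <- unique(slopes$arrangement)
    if (length(arrangement) != 1L) stop("specify `arrangement`")
  }
  sub <- slopes$per_subject[[which(slopes$range == "subitizing")]]
  est <- slopes$per_subject[[which(slopes$range == "estimation")]]
  common <- intersect(names(sub), names(est))
  if (length(common) < 3L) stop("insufficient data: need >= 3 matched subjects")
  diffs <- est[common] - sub[common]
  structure(
    c(list(arrangement = arrangement),
      sign_flip_test(diffs, n_permutations = n_permutations, seed = seed),
      list(n_subjects = length(common))),
    class = "discontinuity_result"
  )
}

# Sign-flip permutation test of mean(diffs) == 0; returns delta, p, B.
sign_flip_test <- function(diffs, n_permutations = 10000L, seed = 1L) {
  n <- length(diffs)
  obs <- mean(diffs)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed %% 2147483647))
  signs <- matrix(sample(c(-1, 1), n_permutations * n, replace = TRUE),
                  nrow = n_permutations)
  perm <- as.vector(signs %*% diffs) / n
  p <- (1 + sum(abs(perm) >= abs(obs))) / (1 + n_permutations)
  list(delta_slope = obs, p_value = p, n_permutations = as.integer(n_permutations))
}

#' @export
print.discontinuity_result <- function(x, ...) {
  cat(sprintf("%s: estimation - subitizing slope = %.4f, p = %.4g (%d subjects, %d permutations)\n",
              x$arrangement, x$delta_slope, x$p_value, x$n_subjects,
              x$n_permutations))
  invisible(x)
}

#' Range amplitude contrast
#'
#' Compares the mean ROI amplitude between estimation and subitizing range per
#' arrangement: each subject contributes their cell-mean PSC in both ranges
#' (numerosities and hemispheres averaged); the group difference
#' (estimation - subitizing) is tested with the same sign-flip permutation as
#' [discontinuity_test()].
#'
#' @param records Tidy PSC records.
#' @param n_permutations,seed As in [discontinuity_test()].
#' @return Tibble with one row per arrangement: `delta_psc`, `p_value`,
#'   `n_subjects`.
#' @export
range_amplitude_contrast <- function(records, n_permutations = 10000L, seed = 1L) {
  records <- center_numerosity(records)
  out <- lapply(sort(unique(records$arrangement)), function(arr) {
    d <- records[records$arrangement == arr, , drop = FALSE]
    cellmean <- tapply(d$psc, list(d$subject_id, d$range), mean)
    keep <- stats::complete.cases(cellmean)
    diffs <- cellmean[keep, "estimation"] - cellmean[keep, "subitizing"]
    if (length(diffs) < 3L) stop("insufficient data: need >= 3 subjects with both ranges")
    res <- sign_flip_test(diffs, n_permutations = n_permutations,
                          seed = derive_seed(seed, match(arr, ARRANGEMENTS)))
    tibble::tibble(arrangement = arr, delta_psc = res$delta_slope,
                   p_value = res$p_value, n_subjects = length(diffs))
  })
  do.call(rbind, out)
}

#' Condition-level PSC summary table
#'
#' Mean, SD, minimum and maximum PSC per arrangement x range x hemisphere,
#' where each subject first contributes their cell mean (so SD is a
#' between-subject SD).
#'
#' @param records Tidy PSC records.
#' @return Tibble with `arrangement`, `range`, `hemisphere`, `mean`, `sd`,
#'   `min`, `max`, `n_subjects`.
#' @export
psc_summary_table <- function(records) {
  records <- center_numerosity(records)
  subj_means <- stats::aggregate(
    records$psc,
    by = list(arrangement = records$arrangement, range = records$range,
              hemisphere = records$hemisphere, subject = records$subject_id),
    FUN = mean
  )
  agg <- stats::aggregate(
    subj_means$x,
    by = subj_means[c("arrangement", "range", "hemisphere")],
    FUN = function(v) c(mean = mean(v), sd = stats::sd(v), min = min(v),
                        max = max(v), n = length(v))
  )
  tibble::tibble(
    arrangement = agg$arrangement, range = agg$range, hemisphere = agg$hemisphere,
    mean = agg$x[, "mean"], sd = agg$x[, "sd"],
    min = agg$x[, "min"], max = agg$x[, "max"],
    n_subjects = as.integer(agg$x[, "n"])
  )
}
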
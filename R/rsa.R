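#' Construct a per-subject pattern set for one condition
#'
#' Holds the voxel-pattern exemplars (e.g. per-run GLM coefficient estimates
#' from unsmoothed images, masked to a bilateral ROI) of one subject for one
#' (arrangement, numerosity) condition.
#'
#' @param subject_id Subject identifier (scalar).
#' @param arrangement One of `"random"`, `"canonical"`, `"dice"`.
#' @param numerosity Integer numerosity, valid for the arrangement.
#' @param patterns Numeric matrix, exemplars x voxels, no missing values,
#'   at least 2 rows.
#' @return Object of class `pattern_set`.
#' @export
pattern_set <- function(subject_id, arrangement, numerosity, patterns) {
  validate_conditions(arrangement, numerosity)
  patterns <- as.matrix(patterns)
  if (nrow(patterns) < 2L) stop("need at least 2 exemplars per condition")
  if (any(!is.finite(patterns))) stop("patterns contain missing/non-finite values")
  structure(
    list(subject_id = subject_id, arrangement = arrangement,
         numerosity = as.integer(numerosity), patterns = patterns),
    class = "pattern_set"
  )
}

#' Pairwise decoding of two conditions
#'
#' Cross-validated two-class decoding between the voxel patterns of two
#' conditions of one subject, using a ridge-penalized logistic regression
#' (logit link) on standardized voxel features. Standardization parameters are
#' estimated on the training folds only. The stratified fold assignment and
#' hence the returned accuracy are deterministic given `seed`.
#'
#' The classifier minimizes the penalized binomial deviance
#' `-loglik + penalty/2 * ||beta||^2` (intercept unpenalized) by iteratively
#' reweighted least squares solved in the dual (Gram) space, which is exact
#' for this convex objective and fast when exemplars are far fewer than
#' voxels -- the typical ROI regime, and the reason an unpenalized logit
#' would not even be identified.
#'
#' @param a,b `pattern_set` objects of the same subject with equal voxel
#'   counts and different conditions.
#' @param n_folds Number of stratified CV folds (default 5); silently reduced
#'   to the smaller class's exemplar count when that is smaller.
#' @param penalty Ridge penalty strength (default 1).
#' @param seed Integer seed controlling the fold assignment.
#' @return Classification accuracy in `[0, 1]`.
#' @export
pairwise_decode <- function(a, b, n_folds = 5L, penalty = 1, seed = 1L) {
  stopifnot(inherits(a, "pattern_set"), inherits(b, "pattern_set"))
  if (!identical(a$subject_id, b$subject_id)) {
    stop("`a` and `b` must belong to the same subject")
  }
  if (ncol(a$patterns) != ncol(b$patterns)) {
    stop("voxel counts differ: ", ncol(a$patterns), " vs ", ncol(b$patterns))
  }
  if (a$arrangement == b$arrangement && a$numerosity == b$numerosity) {
    stop("cannot decode a condition against itself")
  }
  X <- rbind(a$patterns, b$patterns)
  y <- c(rep(0L, nrow(a$patterns)), rep(1L, nrow(b$patterns)))
  n_folds <- max(2L, min(n_folds, nrow(a$patterns), nrow(b$patterns)))

  folds <- integer(length(y))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed %% 2147483647))
  folds[y == 0L] <- sample(rep_len(seq_len(n_folds), sum(y == 0L)))
  folds[y == 1L] <- sample(rep_len(seq_len(n_folds), sum(y == 1L)))

  n_correct <- 0L
  for (k in seq_len(n_folds)) {
    tr <- folds != k
    mu <- colMeans(X[tr, , drop = FALSE])
    sd <- apply(X[tr, , drop = FALSE], 2, stats::sd)
    sd[sd == 0 | !is.finite(sd)] <- 1
    Xtr <- sweep(sweep(X[tr, , drop = FALSE], 2, mu), 2, sd, "/")
    Xte <- sweep(sweep(X[!tr, , drop = FALSE], 2, mu), 2, sd, "/")
    eta <- ridge_logit_predict(Xtr, y[tr], Xte, penalty = penalty)
    n_correct <- n_correct + sum((eta > 0) == (y[!tr] == 1L))
  }
  n_correct / length(y)
}

# Ridge-penalized logistic regression, fitted by IRLS in the dual (Gram)
# space and returning test-set linear predictors. The intercept rides along
# as an augmented constant column scaled so its effective penalty is
# negligible. Exact for the convex ridge-logit objective; agreement with
# glmnet(alpha = 0) is asserted in the test suite.
ridge_logit_predict <- function(Xtr, y, Xte, penalty = 1, k_int = 30,
                                max_iter = 40L, tol = 1e-9) {
  n <- nrow(Xtr)
  A <- cbind(k_int, Xtr)
  B <- cbind(k_int, Xte)
  G <- tcrossprod(A)
  Cte <- tcrossprod(B, A)
  alpha <- numeric(n)
  eta <- numeric(n)
  dev_old <- Inf
  for (it in seq_len(max_iter)) {
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    alpha <- solve(G + penalty * diag(1 / w, n), z)
    eta <- drop(G %*% alpha)
    dev <- -2 * sum(y * eta - log1p(exp(eta))) + penalty * sum(alpha * eta)
    if (!is.finite(dev) || abs(dev_old - dev) < tol * (abs(dev) + 1)) break
    dev_old <- dev
  }
  drop(Cte %*% alpha)
}

# Save/restore the global RNG state so seeded internals do not disturb the
# caller's random stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Group-level classification-error similarity matrix
#'
#' Runs [pairwise_decode()] for every unordered pair of conditions within each
#' subject, converts accuracies to classification errors (`1 - accuracy`), and
#' averages the per-subject error matrices into a group matrix. Higher error
#' means the two conditions' patterns are more similar (harder to tell apart),
#' so the error matrix is a similarity matrix.
#'
#' @param pattern_sets List of `pattern_set` objects; every subject must
#'   supply the same set of conditions.
#' @param n_folds,penalty Passed to [pairwise_decode()].
#' @param seed Integer seed; per-subject/pair decode seeds are derived from it.
#' @return Object of class `similarity_matrix`: list with `conditions` (tibble
#'   of arrangement/numerosity in fixed order), `errors` (symmetric group-mean
#'   matrix, `NA` diagonal), `per_subject` (3-d array condition x condition x
#'   subject) and `n_subjects`.
#' @export
similarity_matrix <- function(pattern_sets, n_folds = 5L, penalty = 1, seed = 1L) {
  stopifnot(length(pattern_sets) >= 1)
  meta <- tibble::tibble(
    subject = vapply(pattern_sets, function(p) as.character(p$subject_id), ""),
    arrangement = vapply(pattern_sets, function(p) p$arrangement, ""),
    numerosity = vapply(pattern_sets, function(p) p$numerosity, 1L)
  )
  meta$key <- paste(meta$arrangement, meta$numerosity)
  subjects <- unique(meta$subject)
  cond_keys <- sort(unique(meta$key))
  by_subj <- split(meta$key, meta$subject)
  bad <- names(by_subj)[!vapply(by_subj, function(k) setequal(k, cond_keys) &&
                                  !anyDuplicated(k), TRUE)]
  if (length(bad)) {
    stop("subjects with inconsistent condition sets: ", paste(bad, collapse = ", "))
  }

  # fixed condition ordering: arrangement blocks, ascending numerosity
  conditions <- condition_grid()
  conditions <- conditions[paste(conditions$arrangement, conditions$numerosity)
                           %in% cond_keys, , drop = FALSE]
  extra <- setdiff(cond_keys, paste(conditions$arrangement, conditions$numerosity))
  if (length(extra)) stop("unknown conditions: ", paste(extra, collapse = ", "))
  K <- nrow(conditions)
  ckey <- paste(conditions$arrangement, conditions$numerosity)

  per_subject <- array(NA_real_, dim = c(K, K, length(subjects)),
                       dimnames = list(ckey, ckey, subjects))
  idx <- stats::setNames(seq_along(pattern_sets), paste(meta$subject, meta$key))
  for (s in seq_along(subjects)) {
    for (i in seq_len(K - 1L)) {
      for (j in seq((i + 1L), K)) {
        a <- pattern_sets[[idx[[paste(subjects[s], ckey[i])]]]]
        b <- pattern_sets[[idx[[paste(subjects[s], ckey[j])]]]]
        acc <- pairwise_decode(a, b, n_folds = n_folds, penalty = penalty,
                               seed = derive_seed(seed, s * 1000L + i * 37L + j))
        per_subject[i, j, s] <- per_subject[j, i, s] <- 1 - acc
      }
    }
  }
  errors <- apply(per_subject, c(1, 2), mean)
  diag(errors) <- NA_real_
  structure(
    list(conditions = conditions, errors = errors, per_subject = per_subject,
         n_subjects = length(subjects)),
    class = "similarity_matrix"
  )
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat(sprintf("Similarity matrix: %d conditions, %d subjects\n",
              nrow(x$conditions), x$n_subjects))
  print(round(x$errors, 3))
  invisible(x)
}

#' Extract per-arrangement similarity curves
#'
#' For each reference numerosity of one arrangement, collects the group
#' classification errors against every probe numerosity of the same
#' arrangement into a [numerosity_curve()]. The undefined self-pair is carried
#' as `NA` at the probe equal to the reference.
#'
#' @param m A `similarity_matrix`.
#' @param arrangement Arrangement to extract.
#' @return List of `numerosity_curve` objects, one per reference numerosity.
#' @export
similarity_curves <- function(m, arrangement) {
  stopifnot(inherits(m, "similarity_matrix"))
  if (length(arrangement) != 1L || !arrangement %in% ARRANGEMENTS) {
    stop("unknown arrangement: ", arrangement)
  }
  sel <- which(m$conditions$arrangement == arrangement)
  if (!length(sel)) stop("arrangement not present in matrix: ", arrangement)
  ns <- m$conditions$numerosity[sel]
  lapply(seq_along(sel), function(i) {
    numerosity_curve(ns[i], ns, m$errors[sel[i], sel])
  })
}

#' Estimate the tuning width of one arrangement
#'
#' Composes [similarity_curves()] and [fit_tuning_width()]: extracts the
#' arrangement's classification-error curves and fits a single tuning width
#' `w` jointly across all reference numerosities.
#'
#' By default the undefined diagonal is pinned at the two-class chance error
#' (0.5). This anchors each curve's peak, without which a tuning s.d. smaller
#' than the unit probe spacing (`w * n < 1`) is not identifiable from the
#' off-diagonal errors alone: a very sharp representation yields near-equal
#' errors at all probe distances, and the fitted width would no longer track
#' the underlying precision. See the package vignette for the full argument.
#'
#' @param m A `similarity_matrix`.
#' @param arrangement Arrangement to fit.
#' @param start_w Starting width (default 0.4).
#' @param include_self Pin the diagonal at chance (default `TRUE`).
#' @param ... Passed to [fit_tuning_width()].
#' @return A `tuning_fit`.
#' @export
estimate_arrangement_width <- function(m, arrangement, start_w = 0.4,
                                       include_self = TRUE, ...) {
  curves <- similarity_curves(m, arrangement)
  fit_tuning_width(curves, start_w = start_w, include_self = include_self, ...)
}
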
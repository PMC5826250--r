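#' Gaussian numerosity tuning density
#'
#' Density of the linear numerosity-tuning model with scalar variability: a
#' population tuned to reference numerosity `n` responds to probe numerosity
#' `x` as a Gaussian centered on `n` whose standard deviation grows
#' proportionally with `n`,
#' \deqn{f(x) = \frac{1}{\sqrt{2\pi}\,w n}
#'       \exp\left(-\frac{(x-n)^2}{2 (w n)^2}\right),}
#' where `w` is the dimensionless Weber-like tuning width. Smaller `w` means a
#' sharper, more precise representation; the peak height
#' \eqn{1/(\sqrt{2\pi} w n)} falls with `n` (the size effect).
#'
#' @param x Probe numerosity (real vector).
#' @param n Reference numerosity (positive real).
#' @param w Tuning width fraction (positive real); the curve's s.d. is `w * n`.
#' @return Density value(s), strictly positive.
#' @export
#' @examples
#' tuning_density(5, 5, 0.276) # peak height at the preferred numerosity
tuning_density <- function(x, n, w) {
  if (any(!is.finite(n)) || any(n <= 0)) stop("`n` must be positive and finite")
  if (any(!is.finite(w)) || any(w <= 0)) stop("`w` must be positive and finite")
  stats::dnorm(x, mean = n, sd = w * n)
}

#' Overlap of two numerosity tuning curves
#'
#' Integral of the pointwise minimum of two tuning densities sharing a width
#' fraction `w`, \eqn{\int \min\{f(x; n_1, w), f(x; n_2, w)\}\,dx}. Equals 1
#' for identical curves and decreases toward 0 as the curves separate. Because
#' of scalar variability (s.d. `w * n`), curves for larger numerosities are
#' wider, so the overlap of consecutive numerosities increases with magnitude
#' -- the classic ratio-dependence of numerosity discrimination.
#'
#' The two densities are Gaussians with different s.d. (unless `n1 == n2`), so
#' their crossing points solve a quadratic in `x`; the integral is accumulated
#' piecewise from exact Gaussian CDF differences between crossings.
#'
#' @param n1,n2 Reference numerosities (positive reals).
#' @param w Shared tuning width fraction (positive real).
#' @return Overlap in `[0, 1]`; symmetric in `(n1, n2)`.
#' @export
#' @examples
#' curve_overlap(5, 6, 0.276) > curve_overlap(2, 3, 0.276)
curve_overlap <- function(n1, n2, w) {
  if (!is.finite(n1) || n1 <= 0 || !is.finite(n2) || n2 <= 0) {
    stop("`n1` and `n2` must be positive and finite")
  }
  if (!is.finite(w) || w <= 0) stop("`w` must be positive and finite")
  if (n1 == n2) return(1)
  s1 <- w * n1
  s2 <- w * n2
  # log f1 = log f2  <=>  a x^2 + b x + c = 0
  a <- 1 / s2^2 - 1 / s1^2
  b <- 2 * (n1 / s1^2 - n2 / s2^2)
  c <- n2^2 / s2^2 - n1^2 / s1^2 + 2 * log(s2 / s1)
  disc <- b^2 - 4 * a * c
  roots <- if (disc > 0) sort((-b + c(-1, 1) * sqrt(disc)) / (2 * a)) else numeric(0)
  cuts <- c(-Inf, roots, Inf)
  total <- 0
  for (k in seq_len(length(cuts) - 1L)) {
    lo <- cuts[k]
    hi <- cuts[k + 1L]
    mid <- if (is.infinite(lo) && is.infinite(hi)) n1 else
      if (is.infinite(lo)) hi - 1 else if (is.infinite(hi)) lo + 1 else (lo + hi) / 2
    use1 <- tuning_density(mid, n1, w) <= tuning_density(mid, n2, w)
    total <- total + if (use1) {
      stats::pnorm(hi, n1, s1) - stats::pnorm(lo, n1, s1)
    } else {
      stats::pnorm(hi, n2, s2) - stats::pnorm(lo, n2, s2)
    }
  }
  min(max(total, 0), 1)
}

#' Construct a similarity curve for one reference numerosity
#'
#' A similarity curve records, for a reference numerosity, how similar (here:
#' how confusable under pairwise decoding) its activity pattern is to each
#' probe numerosity. Values are classification error rates in `[0, 1]`.
#'
#' @param reference_n Integer reference numerosity (the curve's center).
#' @param probes Integer probe numerosities, strictly increasing.
#' @param values Similarity values in `[0, 1]`, one per probe.
#' @return Object of class `numerosity_curve`.
#' @export
numerosity_curve <- function(reference_n, probes, values) {
  stopifnot(length(reference_n) == 1L, reference_n > 0)
  if (length(probes) != length(values)) stop("`probes` and `values` lengths differ")
  if (is.unsorted(probes, strictly = TRUE)) stop("`probes` must be strictly increasing")
  if (any(values < 0 | values > 1, na.rm = TRUE)) stop("`values` must lie in [0, 1]")
  structure(
    list(reference_n = as.integer(reference_n), probes = as.integer(probes),
         values = as.numeric(values)),
    class = "numerosity_curve"
  )
}

#' @export
print.numerosity_curve <- function(x, ...) {
  cat("Similarity curve, reference n =", x$reference_n, "\n")
  print(stats::setNames(round(x$values, 3), x$probes))
  invisible(x)
}

# Flatten a list of numerosity_curve objects into (n, x, value) rows.
curves_to_points <- function(curves, include_self = FALSE, chance_error = 0.5) {
  stopifnot(length(curves) >= 1)
  rows <- lapply(curves, function(cv) {
    stopifnot(inherits(cv, "numerosity_curve"))
    tibble::tibble(n = as.numeric(cv$reference_n), x = as.numeric(cv$probes),
                   value = cv$values)
  })
  pts <- do.call(rbind, rows)
  if (include_self) {
    pts$value[pts$x == pts$n] <- chance_error
  } else {
    pts <- pts[pts$x != pts$n, , drop = FALSE]
  }
  pts[is.finite(pts$value), , drop = FALSE]
}

#' Estimate the tuning width from similarity curves
#'
#' Fits the scalar-variability tuning model to similarity-curve data by
#' nonlinear least squares: minimizes
#' \deqn{\sum_i \left(v_i - s\, f(x_i; n_i, w)\right)^2}
#' over the width `w` (and optionally an amplitude `s`) with a damped
#' Gauss-Newton (Levenberg-Marquardt) iteration. Positivity of `w` (and `s`)
#' is enforced by optimizing on the log scale. All curves are fitted jointly
#' with a single `w`, so the absolute tuning s.d. at reference `n` is `w * n`.
#'
#' The classification-error similarity is bounded by chance (~0.5) while the
#' literal density peak \eqn{1/(\sqrt{2\pi} w n)} can exceed 1 for small
#' `w * n`; by default a free amplitude `s` absorbs this scale mismatch. Set
#' `fit_scale = FALSE` for the literal `s = 1` model.
#'
#' Self-similarity points (`x == n`) are dropped by default: a two-class
#' decoder cannot be run on a condition against itself, so the diagonal is
#' undefined. With `include_self = TRUE` they are instead pinned at the
#' two-class chance error `chance_error`, which anchors the curve's peak --
#' useful when tuning is narrow relative to the integer probe spacing (see
#' [estimate_arrangement_width()]).
#'
#' @param curves List of [numerosity_curve()] objects.
#' @param start_w Starting value for `w` (default 0.4).
#' @param fit_scale Estimate a free amplitude (default `TRUE`).
#' @param include_self Pin self-similarity points at `chance_error` instead of
#'   dropping them (default `FALSE`).
#' @param chance_error Value used for pinned self-pairs (default 0.5).
#' @param max_iter Iteration cap (default 500).
#' @param tol Convergence tolerance on the change in residual sum of squares
#'   (default 1e-8).
#' @return Object of class `tuning_fit`: list with `w_hat`, `scale_hat`,
#'   `sse`, `converged`, `n_points`, `start_w`.
#' @export
#' @examples
#' curves <- lapply(2:8, function(n)
#'   numerosity_curve(n, 2:8, tuning_density(2:8, n, 0.25)))
#' fit_tuning_width(curves, fit_scale = FALSE)$w_hat
fit_tuning_width <- function(curves, start_w = 0.4, fit_scale = TRUE,
                             include_self = FALSE, chance_error = 0.5,
                             max_iter = 500L, tol = 1e-8) {
  if (!is.finite(start_w) || start_w <= 0) stop("`start_w` must be positive")
  pts <- curves_to_points(curves, include_self = include_self,
                          chance_error = chance_error)
  usable <- if (include_self) pts else pts[pts$x != pts$n, , drop = FALSE]
  if (nrow(unique(usable[c("n", "x")])) < 2L) {
    stop("insufficient data: need at least 2 distinct (reference, probe) pairs")
  }
  n <- pts$n
  x <- pts$x
  v <- pts$value

  degenerate <- stats::var(v) == 0 && !fit_scale
  model <- function(lw, ls) exp(ls) * tuning_density(x, n, exp(lw))
  sse_at <- function(th) sum((v - model(th[1], th[2]))^2)

  theta <- c(log(start_w), 0)
  if (fit_scale) {
    # closed-form optimal amplitude at the start width stabilizes the first step
    f0 <- tuning_density(x, n, start_w)
    s0 <- sum(v * f0) / sum(f0^2)
    if (is.finite(s0) && s0 > 0) theta[2] <- log(s0)
  }
  sse <- sse_at(theta)
  lambda <- 1e-3
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    w <- exp(theta[1])
    s <- exp(theta[2])
    f <- tuning_density(x, n, w)
    r <- v - s * f
    # d(s f)/d log w = s f ((x-n)^2/(w n)^2 - 1);  d(s f)/d log s = s f
    J <- cbind(s * f * ((x - n)^2 / (w * n)^2 - 1), s * f)
    if (!fit_scale) J <- J[, 1, drop = FALSE]
    A <- crossprod(J)
    g <- crossprod(J, r)
    improved <- FALSE
    repeat {
      damp <- A + lambda * diag(diag(A) + 1e-12, nrow(A))
      step <- tryCatch(solve(damp, g), error = function(e) NULL)
      if (!is.null(step)) {
        cand <- theta
        if (fit_scale) cand <- cand + as.vector(step) else cand[1] <- cand[1] + step[1]
        cand_sse <- sse_at(cand)
        if (is.finite(cand_sse) && cand_sse <= sse) {
          theta <- cand
          lambda <- max(lambda / 3, 1e-12)
          improved <- TRUE
          delta <- sse - cand_sse
          sse <- cand_sse
          break
        }
      }
      lambda <- lambda * 10
      if (lambda > 1e12) break
    }
    if (!improved) { converged <- TRUE; break }  # stuck at a (local) minimum
    if (delta < tol) { converged <- TRUE; break }
  }
  if (degenerate) converged <- FALSE

  structure(
    list(w_hat = exp(theta[1]),
         scale_hat = if (fit_scale) exp(theta[2]) else 1.0,
         sse = sse, converged = converged,
         n_points = nrow(pts), start_w = start_w),
    class = "tuning_fit"
  )
}

#' @export
print.tuning_fit <- function(x, ...) {
  cat(sprintf("Tuning-width fit: w = %.4f (scale = %.3f, sse = %.4g, %s, %d points)\n",
              x$w_hat, x$scale_hat, x$sse,
              if (x$converged) "converged" else "not converged", x$n_points))
  invisible(x)
}
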
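#' Trim reaction times
#'
#' Reaction-time preprocessing for the quantification task, in fixed order:
#' error trials are removed, RTs below `min_rt_ms` are removed, remaining RTs
#' are log-transformed, residuals are formed from a per-subject linear model
#' of log RT on arrangement x range cell (as factor) plus centered numerosity,
#' residuals are z-standardized globally, and trials with `|z|` above
#' `z_threshold` are removed. The residual screen is iterated until no trial
#' exceeds the threshold, which makes the whole procedure idempotent:
#' re-trimming trimmed data removes nothing.
#'
#' The per-subject fixed-effect residualization approximates model-based
#' trimming against a mixed model's fitted values; for balanced designs the
#' two residual definitions agree in expectation.
#'
#' @param trials Tidy trial records: columns `subject_id`, `arrangement`,
#'   `numerosity`, `rt` (ms), `correct` (logical).
#' @param min_rt_ms Fast-guess cutoff in milliseconds (default 200).
#' @param z_threshold Residual cutoff in standard deviations (default 3).
#' @return List with `trials` (retained rows of the input, plus `log_rt`,
#'   `range`, `centered` columns) and `report` (class `trim_report`):
#'   `n_input`, `n_removed_error`, `n_removed_fast`, `n_removed_residual`,
#'   `n_retained`, `fraction_removed`, and `flagged_subjects` (subjects left
#'   with fewer than 5 trials).
#' @export
trim_rts <- function(trials, min_rt_ms = 200, z_threshold = 3.0) {
  stopifnot(nrow(trials) > 0,
            all(c("subject_id", "arrangement", "numerosity", "rt", "correct")
                %in% names(trials)))
  if (any(trials$rt <= 0)) stop("non-positive RTs")
  n_input <- nrow(trials)

  keep <- trials$correct
  n_err <- sum(!keep)
  t1 <- trials[keep, , drop = FALSE]

  fast <- t1$rt < min_rt_ms
  n_fast <- sum(fast)
  t2 <- t1[!fast, , drop = FALSE]

  t2 <- center_numerosity(t2)
  t2$log_rt <- log(t2$rt)

  # Residual screening, iterated to a fixpoint so the procedure is
  # idempotent: after outliers are removed, residuals are recomputed on the
  # retained trials, and screening stops when no further trial exceeds the
  # threshold. Residuals come from a per-subject linear model whose cell
  # factor absorbs arrangement x range means and whose centered-numerosity
  # term absorbs the within-cell slope.
  n_resid <- 0L
  t3 <- t2
  repeat {
    resid <- rep(NA_real_, nrow(t3))
    for (s in unique(t3$subject_id)) {
      sel <- t3$subject_id == s
      d <- t3[sel, , drop = FALSE]
      cell <- factor(paste(d$arrangement, d$range))
      fit <- stats::lm(log_rt ~ cell + cell:centered, data =
                         data.frame(log_rt = d$log_rt, cell = cell,
                                    centered = d$centered))
      resid[sel] <- stats::residuals(fit)
    }
    s_resid <- stats::sd(resid)
    if (!is.finite(s_resid) || s_resid < 1e-10) break
    z <- (resid - mean(resid)) / s_resid
    out_resid <- abs(z) > z_threshold
    if (!any(out_resid)) break
    n_resid <- n_resid + sum(out_resid)
    t3 <- t3[!out_resid, , drop = FALSE]
  }

  counts <- table(t3$subject_id)
  flagged <- names(counts)[counts < 5L]
  missing_subj <- setdiff(unique(trials$subject_id), names(counts))
  flagged <- union(flagged, missing_subj)

  report <- structure(
    list(n_input = n_input, n_removed_error = n_err, n_removed_fast = n_fast,
         n_removed_residual = n_resid, n_retained = nrow(t3),
         fraction_removed = (n_input - nrow(t3)) / n_input,
         flagged_subjects = flagged),
    class = "trim_report"
  )
  list(trials = t3, report = report)
}

#' @export
print.trim_report <- function(x, ...) {
  cat(sprintf(
    "Trimmed %d -> %d trials (%.1f%% removed): %d errors, %d fast (<cutoff), %d residual outliers\n",
    x$n_input, x$n_retained, 100 * x$fraction_removed,
    x$n_removed_error, x$n_removed_fast, x$n_removed_residual))
  if (length(x$flagged_subjects)) {
    cat("Subjects with < 5 retained trials:",
        paste(x$flagged_subjects, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Back-transform error log odds to percent
#'
#' Inverse-logit on the percent scale: `100 / (1 + exp(-log_odds))`.
#'
#' @param log_odds Real vector of log odds.
#' @return Percent error in (0, 100).
#' @export
#' @examples
#' logit_to_percent(-1.46) # ~18.8% errors
logit_to_percent <- function(log_odds) {
  100 * stats::plogis(log_odds)
}

#' Back-transform a log-scale RT mean to milliseconds
#'
#' `exp(log_rt)`: the geometric-mean reaction time implied by a mean of
#' log-transformed RTs (in log-ms).
#'
#' @param log_rt Real vector of log-ms values.
#' @return Milliseconds.
#' @export
#' @examples
#' logmean_to_ms(6.82) # ~916 ms
logmean_to_ms <- function(log_rt) {
  exp(log_rt)
}

#' Condition summaries of behavioral performance
#'
#' Per arrangement x range cell: the mean log RT of correct, trimmed trials
#' (back-transformed to ms, i.e. a geometric mean) and the pooled error log
#' odds (back-transformed to percent). Error proportions pool trials across
#' subjects within the cell; cells with zero (or all) errors receive a
#' 0.5-count continuity correction so the log odds stay finite. Error rates
#' are computed from all trials; the RT path applies [trim_rts()] internally
#' (unless `trim = FALSE`).
#'
#' @param trials Tidy trial records (untrimmed).
#' @param trim Apply RT trimming for the RT summaries (default `TRUE`).
#' @param pool_subjects Pool trials within cell for the error log odds
#'   (default `TRUE`); otherwise average subject-level log odds (each
#'   continuity-corrected).
#' @return Tibble with `arrangement`, `range`, `n_trials`, `n_errors`,
#'   `er_log_odds`, `er_backtransformed_percent`, `log_rt_mean`,
#'   `rt_backtransformed`.
#' @export
condition_summaries <- function(trials, trim = TRUE, pool_subjects = TRUE) {
  trials <- center_numerosity(trials)
  rt_trials <- if (trim) trim_rts(trials)$trials else {
    t2 <- trials[trials$correct, , drop = FALSE]
    t2$log_rt <- log(t2$rt)
    t2
  }

  cells <- unique(trials[c("arrangement", "range")])
  cells <- cells[order(cells$arrangement, cells$range), , drop = FALSE]
  out <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    in_cell <- trials$arrangement == cells$arrangement[i] &
      trials$range == cells$range[i]
    n_tr <- sum(in_cell)
    n_er <- sum(!trials$correct[in_cell])
    log_odds <- if (pool_subjects) {
      pooled_log_odds(n_er, n_tr)
    } else {
      d <- trials[in_cell, , drop = FALSE]
      mean(vapply(split(d$correct, d$subject_id),
                  function(cv) pooled_log_odds(sum(!cv), length(cv)), 1))
    }
    in_rt <- rt_trials$arrangement == cells$arrangement[i] &
      rt_trials$range == cells$range[i]
    lrt <- if (any(in_rt)) mean(rt_trials$log_rt[in_rt]) else NA_real_
    out[[i]] <- tibble::tibble(
      arrangement = cells$arrangement[i], range = cells$range[i],
      n_trials = n_tr, n_errors = n_er,
      er_log_odds = log_odds,
      er_backtransformed_percent = logit_to_percent(log_odds),
      log_rt_mean = lrt,
      rt_backtransformed = logmean_to_ms(lrt)
    )
  }
  do.call(rbind, out)
}

# Pooled log odds with continuity correction for empty margins.
pooled_log_odds <- function(errors, total) {
  if (total == 0) return(NA_real_)
  if (errors == 0 || errors == total) {
    log((errors + 0.5) / (total - errors + 0.5))
  } else {
    log(errors / (total - errors))
  }
}

#' Behavioral log-RT slopes
#'
#' Per-subject OLS slopes of log RT (correct, trimmed trials) on centered
#' numerosity within arrangement x range cells, aggregated as in
#' [range_slopes()].
#'
#' @param trials Tidy trial records (untrimmed; trimming is applied
#'   internally unless `trim = FALSE`).
#' @param trim Apply [trim_rts()] first (default `TRUE`).
#' @return Tibble as in [range_slopes()], slopes in log-ms per dot.
#' @export
behavioral_slopes <- function(trials, trim = TRUE) {
  t2 <- if (trim) trim_rts(trials)$trials else {
    d <- center_numerosity(trials[trials$correct, , drop = FALSE])
    d$log_rt <- log(d$rt)
    d
  }
  cell_slopes(t2, "log_rt")
}
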
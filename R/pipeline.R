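#' Run the full synthetic-analysis pipeline
#'
#' Executes the package's stages end to end on synthetic data: simulate
#' (patterns, PSC, behavior) -> pairwise decoding into a similarity matrix ->
#' per-arrangement tuning-width fits -> amplitude slope/discontinuity
#' analyses -> behavioral summaries and slopes. Writes result tables and a
#' run manifest into `output_dir` and returns the results invisibly. On any
#' stage failure, partial outputs are removed and the error is rethrown.
#'
#' @param config A [generator_config()], or the path to a YAML config file.
#' @param output_dir Output directory (created if needed).
#' @param seed Integer seed for all randomness.
#' @param n_folds,penalty Decoding parameters, see [pairwise_decode()].
#' @return Invisibly, a list with `similarity`, `fits`, `slopes`,
#'   `discontinuities`, `contrasts`, `behavior_summaries`,
#'   `behavior_slopes`, `trim_report` and the output paths.
#' @export
run_pipeline <- function(config = generator_config(), output_dir, seed = 1L,
                         n_folds = 5L, penalty = 1) {
  if (is.character(config)) config <- read_config(config)
  validate_config(config)
  if (!dir.exists(output_dir)) dir.create(output_dir, recursive = TRUE)
  written <- character(0)
  emit <- function(writer, obj, file) {
    p <- file.path(output_dir, file)
    writer(obj, p)
    written <<- c(written, p)
    p
  }
  result <- tryCatch({
    dataset <- generate_dataset(config, seed = seed)

    m <- similarity_matrix(dataset$pattern_sets, n_folds = n_folds,
                           penalty = penalty, seed = seed)
    emit(write_similarity, m, "similarity.csv")
    curves <- stats::setNames(lapply(ARRANGEMENTS, similarity_curves, m = m),
                              ARRANGEMENTS)
    emit(function(x, p) write_curves(x, p), curves, "similarity_curves.csv")
    fits <- stats::setNames(
      lapply(ARRANGEMENTS, function(a) estimate_arrangement_width(m, a)),
      ARRANGEMENTS)
    emit(write_fits, fits, "tuning_widths.csv")

    slopes <- range_slopes(dataset$psc_records)
    emit(function(x, p) write_table_csv(x[setdiff(names(x), "per_subject")], p),
         slopes, "psc_slopes.csv")
    disc <- do.call(rbind, lapply(ARRANGEMENTS, function(a) {
      r <- discontinuity_test(slopes, a, seed = derive_seed(seed, 50L + match(a, ARRANGEMENTS)))
      tibble::tibble(arrangement = a, delta_slope = r$delta_slope,
                     p_value = r$p_value, n_subjects = r$n_subjects)
    }))
    emit(write_table_csv, disc, "psc_discontinuity.csv")
    contrasts <- range_amplitude_contrast(dataset$psc_records, seed = seed)
    emit(write_table_csv, contrasts, "psc_range_contrast.csv")
    emit(write_table_csv, psc_summary_table(dataset$psc_records), "psc_summary.csv")

    trim <- trim_rts(dataset$trial_records)
    summaries <- condition_summaries(dataset$trial_records)
    emit(write_table_csv, summaries, "behavior_summaries.csv")
    bslopes <- behavioral_slopes(dataset$trial_records)
    emit(function(x, p) write_table_csv(x[setdiff(names(x), "per_subject")], p),
         bslopes, "behavior_slopes.csv")

    manifest <- file.path(output_dir, "manifest.yaml")
    write_manifest("run_pipeline", config, seed,
                   c(list(output_dir = output_dir),
                     stats::setNames(as.list(written), basename(written))),
                   manifest)

    list(similarity = m, curves = curves, fits = fits, slopes = slopes,
         discontinuities = disc, contrasts = contrasts,
         behavior_summaries = summaries, behavior_slopes = bslopes,
         trim_report = trim$report, paths = c(written, manifest))
  }, error = function(e) {
    unlink(written)
    stop(e)
  })
  invisible(result)
}

#' Import ROI voxel patterns from NIfTI coefficient maps
#'
#' Extracts within-mask voxel vectors from per-condition coefficient images
#' (e.g. GLM beta maps) into the tidy pattern representation the decoding
#' pipeline consumes. Voxels are ordered by ascending linear index of the
#' mask grid (column-major, as stored), so repeated imports of the same mask
#' are reproducible.
#'
#' Requires the RNifti package.
#'
#' @param volume_files Character vector of NIfTI image paths, one coefficient
#'   map per exemplar.
#' @param mask_file NIfTI binary mask path; must share grid dimensions with
#'   every volume.
#' @param labels Data frame mapping each file to its condition: columns
#'   `file`, `subject`, `arrangement`, `numerosity`, `exemplar`.
#' @return List of [pattern_set()] objects.
#' @export
import_roi_patterns <- function(volume_files, mask_file, labels) {
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    stop("import_roi_patterns requires the RNifti package")
  }
  stopifnot(all(c("file", "subject", "arrangement", "numerosity", "exemplar")
                %in% names(labels)))
  unlabeled <- setdiff(basename(volume_files), basename(labels$file))
  if (length(unlabeled)) {
    stop("unlabeled volume(s): ", paste(unlabeled, collapse = ", "))
  }
  mask <- RNifti::readNifti(mask_file)
  mask_dim <- dim(mask)
  idx <- which(as.vector(mask) != 0)  # ascending linear index
  if (!length(idx)) stop("mask contains no voxels")

  rows <- lapply(volume_files, function(f) {
    vol <- RNifti::readNifti(f)
    if (!identical(dim(vol), mask_dim)) {
      stop("grid mismatch between ", basename(f), " and mask: ",
           paste(dim(vol), collapse = "x"), " vs ",
           paste(mask_dim, collapse = "x"))
    }
    as.vector(vol)[idx]
  })
  lab <- labels[match(basename(volume_files), basename(labels$file)), , drop = FALSE]
  key <- paste(lab$subject, lab$arrangement, lab$numerosity)
  lapply(unique(key), function(k) {
    sel <- which(key == k)
    sel <- sel[order(lab$exemplar[sel])]
    pattern_set(lab$subject[sel[1]], lab$arrangement[sel[1]],
                lab$numerosity[sel[1]], do.call(rbind, rows[sel]))
  })
}

#' One width-recovery simulation run
#'
#' Generates synthetic patterns, decodes all same-arrangement condition
#' pairs, and fits the tuning width per arrangement. Cross-arrangement pairs
#' are skipped (they do not enter the width fit), which keeps a run fast
#' enough to repeat across many seeds when estimating how reliably the
#' fitted widths recover the configured ordering.
#'
#' @param config A [generator_config()].
#' @param seed Integer seed.
#' @param n_folds Cross-validation folds for decoding (default 3).
#' @return Named numeric vector of fitted widths (`random`, `canonical`,
#'   `dice`).
#' @export
width_recovery_run <- function(config, seed = 1L, n_folds = 3L) {
  pats <- generate_patterns(config, seed = seed)
  arrs <- vapply(pats, function(p) p$arrangement, "")
  out <- c(random = NA_real_, canonical = NA_real_, dice = NA_real_)
  for (arr in names(out)) {
    m <- similarity_matrix(pats[arrs == arr], n_folds = n_folds,
                           seed = derive_seed(seed, match(arr, ARRANGEMENTS)))
    out[arr] <- estimate_arrangement_width(m, arr)$w_hat
  }
  out
}
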
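#' Read and write tidy result tables
#'
#' All tabular output uses one fixed dialect to avoid locale drift:
#' comma-separated, UTF-8, mandatory header row, `.` decimal separator,
#' missing values empty.
#'
#' @param x Data frame to write.
#' @param path CSV file path.
#' @return `write_table_csv` returns `path` invisibly; `read_table_csv`
#'   returns a tibble.
#' @export
write_table_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_table_csv
#' @export
read_table_csv <- function(path) {
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Write / read voxel-pattern tables
#'
#' Patterns travel as a tidy wide table: one row per exemplar with columns
#' `subject`, `arrangement`, `numerosity`, `exemplar`, `voxel_0` ...
#' `voxel_{V-1}`.
#'
#' @param pattern_sets List of [pattern_set()] objects.
#' @param path CSV file path.
#' @return `write_patterns` returns the path invisibly; `read_patterns`
#'   returns a list of `pattern_set` objects.
#' @export
write_patterns <- function(pattern_sets, path) {
  rows <- lapply(pattern_sets, function(p) {
    V <- ncol(p$patterns)
    d <- as.data.frame(p$patterns)
    names(d) <- paste0("voxel_", seq_len(V) - 1L)
    cbind(data.frame(subject = p$subject_id, arrangement = p$arrangement,
                     numerosity = p$numerosity,
                     exemplar = seq_len(nrow(p$patterns))),
          d)
  })
  write_table_csv(do.call(rbind, rows), path)
}

#' @rdname write_patterns
#' @param path CSV file path.
#' @export
read_patterns <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  vox <- grep("^voxel_", names(d), value = TRUE)
  vox <- vox[order(as.integer(sub("voxel_", "", vox)))]
  key <- paste(d$subject, d$arrangement, d$numerosity)
  lapply(unique(key), function(k) {
    sel <- key == k
    dd <- d[sel, , drop = FALSE]
    dd <- dd[order(dd$exemplar), , drop = FALSE]
    pattern_set(dd$subject[1], dd$arrangement[1], dd$numerosity[1],
                as.matrix(dd[vox]))
  })
}

#' Write / read a similarity matrix as a long-format table
#'
#' Long format: one row per unordered condition pair with columns
#' `arrangement_a`, `n_a`, `arrangement_b`, `n_b`, `error`, `n_subjects`.
#' Cross-arrangement pairs are included. Reading restores the symmetric
#' matrix (without the per-subject stack, which is not serialized).
#'
#' @param m A `similarity_matrix`.
#' @param path CSV file path.
#' @export
write_similarity <- function(m, path) {
  stopifnot(inherits(m, "similarity_matrix"))
  K <- nrow(m$conditions)
  ij <- which(upper.tri(matrix(0, K, K)), arr.ind = TRUE)
  write_table_csv(data.frame(
    arrangement_a = m$conditions$arrangement[ij[, 1]],
    n_a = m$conditions$numerosity[ij[, 1]],
    arrangement_b = m$conditions$arrangement[ij[, 2]],
    n_b = m$conditions$numerosity[ij[, 2]],
    error = m$errors[ij],
    n_subjects = m$n_subjects
  ), path)
}

#' @rdname write_similarity
#' @export
read_similarity <- function(path) {
  d <- read_table_csv(path)
  keys <- unique(rbind(data.frame(arrangement = d$arrangement_a, numerosity = d$n_a),
                       data.frame(arrangement = d$arrangement_b, numerosity = d$n_b)))
  conditions <- condition_grid()
  conditions <- conditions[paste(conditions$arrangement, conditions$numerosity) %in%
                             paste(keys$arrangement, keys$numerosity), , drop = FALSE]
  K <- nrow(conditions)
  ckey <- paste(conditions$arrangement, conditions$numerosity)
  errors <- matrix(NA_real_, K, K, dimnames = list(ckey, ckey))
  ia <- match(paste(d$arrangement_a, d$n_a), ckey)
  ib <- match(paste(d$arrangement_b, d$n_b), ckey)
  errors[cbind(ia, ib)] <- d$error
  errors[cbind(ib, ia)] <- d$error
  structure(
    list(conditions = conditions, errors = errors, per_subject = NULL,
         n_subjects = d$n_subjects[1]),
    class = "similarity_matrix"
  )
}

#' Write / read similarity curves as a tidy table
#'
#' Columns: `arrangement`, `reference_n`, `probe_n`, `error_rate`.
#'
#' @param curves Named list (by arrangement) of lists of [numerosity_curve()]
#'   objects, or a single list of curves with `arrangement` given.
#' @param path CSV file path.
#' @param arrangement Arrangement label when `curves` is a plain list.
#' @export
write_curves <- function(curves, path, arrangement = NULL) {
  if (!is.null(arrangement)) curves <- stats::setNames(list(curves), arrangement)
  rows <- lapply(names(curves), function(arr) {
    do.call(rbind, lapply(curves[[arr]], function(cv) {
      data.frame(arrangement = arr, reference_n = cv$reference_n,
                 probe_n = cv$probes, error_rate = cv$values)
    }))
  })
  write_table_csv(do.call(rbind, rows), path)
}

#' @rdname write_curves
#' @export
read_curves <- function(path) {
  d <- read_table_csv(path)
  lapply(split(d, d$arrangement), function(da) {
    lapply(split(da, da$reference_n), function(dr) {
      dr <- dr[order(dr$probe_n), , drop = FALSE]
      numerosity_curve(dr$reference_n[1], dr$probe_n, dr$error_rate)
    })
  })
}

#' Write a tuning-fit summary table
#'
#' One row per arrangement: `arrangement`, `w_hat`, `scale_hat`, `sse`,
#' `converged`, `n_points`.
#'
#' @param fits Named list of `tuning_fit` objects (names = arrangements).
#' @param path CSV file path.
#' @export
write_fits <- function(fits, path) {
  write_table_csv(do.call(rbind, lapply(names(fits), function(arr) {
    f <- fits[[arr]]
    data.frame(arrangement = arr, w_hat = f$w_hat, scale_hat = f$scale_hat,
               sse = f$sse, converged = f$converged, n_points = f$n_points)
  })), path)
}

#' Write a run manifest
#'
#' Records everything needed to reproduce a pipeline run: command name, the
#' configuration snapshot, the seed, input/output paths, package version and a
#' timestamp. Written as YAML next to the outputs.
#'
#' @param command Character name of the command/stage.
#' @param config A `generator_config` (or any list snapshot).
#' @param seed Integer seed used.
#' @param paths Named list/character of input and output paths.
#' @param path Manifest file path.
#' @export
write_manifest <- function(command, config, seed, paths, path) {
  snap <- lapply(unclass(config), function(v) {
    if (is.data.frame(v)) lapply(as.list(v), unname) else unname(v)
  })
  if (!is.null(config$widths)) snap$widths <- as.list(config$widths)
  yaml::write_yaml(list(
    command = command,
    seed = as.integer(seed),
    config = snap,
    paths = as.list(paths),
    package_version = as.character(utils::packageVersion("numerotune")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  ), path)
  invisible(path)
}

#' Read a manifest or configuration file
#'
#' @param path YAML file written by [write_manifest()] or a hand-written
#'   config file whose keys override [generator_config()] defaults.
#' @return Parsed list; `read_config` returns a `generator_config`.
#' @export
read_manifest <- function(path) {
  yaml::read_yaml(path)
}

#' @rdname read_manifest
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$config)) raw <- raw$config  # accept a manifest too
  defaults <- generator_config()
  known <- names(unclass(defaults))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  args <- raw
  for (tab in c("psc_cell_means", "psc_slopes", "rt_log_means", "rt_slopes",
                "er_log_odds")) {
    if (!is.null(args[[tab]])) args[[tab]] <- tibble::as_tibble(args[[tab]])
  }
  if (!is.null(args$widths)) args$widths <- unlist(args$widths)
  do.call(generator_config, args)
}
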
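#' @keywords internal
"_PACKAGE"

# Valid dot arrangements and their numerosity ranges. Random and canonical
# patterns span 2-8 dots; dice patterns exist only up to the largest die face
# used in the design (6).
ARRANGEMENTS <- c("random", "canonical", "dice")

#' Numerosity range of an arrangement
#'
#' Dot patterns come in three spatial arrangements: `random` (unstructured),
#' `canonical` (structured, frequently perceived configurations) and `dice`
#' (the overlearned die faces). Random and canonical stimuli span 2-8 dots,
#' dice stimuli 2-6.
#'
#' @param arrangement One of `"random"`, `"canonical"`, `"dice"`.
#' @return Integer vector of valid numerosities.
#' @export
#' @examples
#' arrangement_range("dice")
arrangement_range <- function(arrangement) {
  arrangement <- match.arg(arrangement, ARRANGEMENTS)
  if (arrangement == "dice") 2:6 else 2:8
}

#' Classify numerosities into subitizing vs. estimation range
#'
#' Small sets up to four elements are enumerated by the fast, near-errorless
#' subitizing process; larger sets (when counting is prevented) by approximate
#' estimation. The boundary is fixed at four.
#'
#' @param numerosity Integer vector of set sizes.
#' @return Factor with levels `"subitizing"` and `"estimation"`.
#' @export
#' @examples
#' number_range(2:8)
number_range <- function(numerosity) {
  factor(ifelse(numerosity <= 4, "subitizing", "estimation"),
         levels = c("subitizing", "estimation"))
}

#' Validate (arrangement, numerosity) condition labels
#'
#' @param arrangement Character vector of arrangements.
#' @param numerosity Integer vector of the same length.
#' @return Invisibly `TRUE`; stops with an informative error on any invalid
#'   combination (e.g. a dice pattern with 8 dots, which does not exist).
#' @export
validate_conditions <- function(arrangement, numerosity) {
  stopifnot(length(arrangement) == length(numerosity))
  bad_arr <- !arrangement %in% ARRANGEMENTS
  if (any(bad_arr)) {
    stop("unknown arrangement(s): ", paste(unique(arrangement[bad_arr]), collapse = ", "))
  }
  hi <- ifelse(arrangement == "dice", 6L, 8L)
  bad <- !is.finite(numerosity) | numerosity < 2 | numerosity > hi |
    numerosity != round(numerosity)
  if (any(bad)) {
    off <- unique(paste0(arrangement[bad], ":", numerosity[bad]))
    stop("invalid (arrangement, numerosity) combination(s): ",
         paste(off, collapse = ", "))
  }
  invisible(TRUE)
}

#' All valid study conditions
#'
#' @return Tibble with columns `arrangement` and `numerosity`: 7 random +
#'   7 canonical + 5 dice = 19 conditions.
#' @export
condition_grid <- function() {
  tibble::tibble(
    arrangement = rep(ARRANGEMENTS, times = c(7L, 7L, 5L)),
    numerosity  = c(2:8, 2:8, 2:6)
  )
}

# Derive a stream-specific 31-bit seed from a master seed, so independent
# generator components do not share random streams.
derive_seed <- function(seed, stream) {
  (as.integer(seed) * 48271 + stream * 1009) %% 2147483647L
}
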
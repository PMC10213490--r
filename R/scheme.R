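#' Frequency classification scheme
#'
#' Defines how nonzero allele frequencies are partitioned into classes. In
#' the default three-class mode an allelic type is *unobserved* (U) when it
#' has zero copies, *rare* (R) when its frequency is positive and at most
#' `z`, and *common* (C) otherwise. In multi-window mode the unit interval is
#' partitioned by `boundaries` into K frequency windows, each a class of its
#' own (the unobserved class is always kept separate).
#'
#' The rare/common boundary is inclusive on the rare side: a type with
#' frequency exactly `100z`% is classified rare, via the floor function in
#' the count bound. Two boundary conventions are supported for windows:
#' half-open intervals `(z1, z2]` (the default) or `[z1, z2)`.
#'
#' The count bound for "rare" can be taken on the full-sample scale
#' (`floor(z * N_j)`, the default) or on the subsample scale
#' (`floor(z * g)`). The full-sample basis classifies by the frequency an
#' allelic type has in the complete population sample; the subsample basis
#' classifies by its frequency within the subsample of size g.
#'
#' @param z Rare/common frequency cutoff in (0, 1). Default 0.05.
#' @param boundaries Optional strictly increasing cut points
#'   `0 = z_0 < z_1 < ... < z_K = 1` selecting multi-window mode.
#' @param boundary_convention `"lower-open-upper-closed"` for `(z1, z2]`
#'   windows (default) or `"lower-closed-upper-open"` for `[z1, z2)`.
#' @param threshold_basis `"full-sample"` (default) or `"subsample"`.
#'
#' @return An object of class `class_scheme`.
#' @examples
#' class_scheme()                       # three classes, z = 0.05
#' class_scheme(boundaries = c(0, 0.01, 0.05, 1))  # three frequency windows
#' @export
class_scheme <- function(z = 0.05,
                         boundaries = NULL,
                         boundary_convention = c("lower-open-upper-closed",
                                                 "lower-closed-upper-open"),
                         threshold_basis = c("full-sample", "subsample")) {
  boundary_convention <- match.arg(boundary_convention)
  threshold_basis <- match.arg(threshold_basis)
  if (is.null(boundaries)) {
    if (!is.numeric(z) || length(z) != 1L || is.na(z) || z <= 0 || z >= 1) {
      abort("`z` must be a single number in (0, 1).", class = "rp_scheme_error")
    }
    scheme <- list(mode = "three-class", z = z, boundaries = c(0, z, 1),
                   boundary_convention = boundary_convention,
                   threshold_basis = threshold_basis,
                   alphabet = c("U", "R", "C"))
  } else {
    if (!is.numeric(boundaries) || length(boundaries) < 3L ||
        any(diff(boundaries) <= 0) ||
        boundaries[1L] != 0 || boundaries[length(boundaries)] != 1) {
      abort(paste("`boundaries` must be strictly increasing cut points",
                  "starting at 0 and ending at 1, with at least 2 windows."),
            class = "rp_scheme_error")
    }
    k <- length(boundaries) - 1L
    labels <- c("U", paste0("W", seq_len(k)))
    scheme <- list(mode = "multi-window", z = NA_real_, boundaries = boundaries,
                   boundary_convention = boundary_convention,
                   threshold_basis = threshold_basis,
                   alphabet = labels)
  }
  structure(scheme, class = "class_scheme")
}

#' @export
print.class_scheme <- function(x, ...) {
  if (x$mode == "three-class") {
    cat(sprintf("<class_scheme> three-class (U/R/C), z = %g\n", x$z))
  } else {
    cat("<class_scheme> multi-window, boundaries:",
        paste(x$boundaries, collapse = ", "), "\n")
  }
  cat("  boundary convention:", x$boundary_convention, "\n")
  cat("  threshold basis:    ", x$threshold_basis, "\n")
  invisible(x)
}

is_class_scheme <- function(x) inherits(x, "class_scheme")

check_scheme <- function(scheme, mode = NULL) {
  if (!is_class_scheme(scheme)) {
    abort("`scheme` must be a `class_scheme` object.",
          class = "rp_scheme_error")
  }
  if (!is.null(mode) && scheme$mode != mode) {
    abort(sprintf("This operation requires a %s scheme.", mode),
          class = "rp_scheme_error")
  }
  invisible(scheme)
}

# floor/ceiling of z*N with a tiny guard so that products like 0.29 * 100,
# which fall just below an integer in binary floating point, land on the
# intended bound
floor_bound <- function(x) floor(x + 1e-9)
ceil_bound <- function(x) ceiling(x - 1e-9)

# largest count classified "rare" for a given population sample size and
# subsample size, under the scheme's threshold basis
rare_kmax <- function(scheme, n_total, g) {
  if (scheme$threshold_basis == "full-sample") {
    floor_bound(scheme$z * n_total)
  } else {
    floor_bound(scheme$z * g)
  }
}
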
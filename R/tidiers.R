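#' Tidy and glance methods
#'
#' broom-style accessors for the package's result objects. `tidy()`
#' returns the underlying long tibble stripped of the result class;
#' `glance()` returns a one-row summary.
#'
#' @param x A `g_sweep`, `window_scan`, `match_curve` or `pattern_dist`
#'   object.
#' @param ... Unused.
#' @return A tibble.
#' @name tidiers
NULL

#' @rdname tidiers
#' @method tidy g_sweep
#' @export
tidy.g_sweep <- function(x, ...) tibble::as_tibble(unclass_result(x))

#' @rdname tidiers
#' @method glance g_sweep
#' @export
glance.g_sweep <- function(x, ...) {
  gs <- unique(x$g)
  J <- length(attr(x, "populations"))
  all_u <- paste(rep("U", J), collapse = "")
  p_u <- x$probability[x$pattern == all_u]
  tibble::tibble(
    n_g = length(gs), g_min = min(gs), g_max = max(gs),
    n_loci = attr(x, "n_loci"), n_patterns = sum(x$g == gs[1L]),
    exclude_singletons = attr(x, "exclude_singletons"),
    normalize_all_u = attr(x, "normalize_all_u"),
    p_all_unobserved_gmin = if (length(p_u) > 0L) p_u[which.min(gs)] else
      NA_real_,
    p_all_unobserved_gmax = if (length(p_u) > 0L) p_u[which.max(gs)] else
      NA_real_
  )
}

#' @rdname tidiers
#' @method tidy window_scan
#' @export
tidy.window_scan <- function(x, ...) tibble::as_tibble(unclass_result(x))

#' @rdname tidiers
#' @method glance window_scan
#' @export
glance.window_scan <- function(x, ...) {
  w <- dplyr::distinct(tibble::as_tibble(x),
                       .data$chrom, .data$start, .data$n_loci)
  tibble::tibble(
    n_windows = nrow(w), n_empty = sum(w$n_loci == 0L),
    n_loci = sum(w$n_loci), g = attr(x, "g"),
    window_size = attr(x, "window_size")
  )
}

#' @rdname tidiers
#' @method tidy match_curve
#' @export
tidy.match_curve <- function(x, ...) tibble::as_tibble(unclass_result(x))

#' @rdname tidiers
#' @method glance match_curve
#' @export
glance.match_curve <- function(x, ...) {
  tibble::tibble(n_g = nrow(x), n_loci = attr(x, "n_loci"),
                 match_rate_gmin = x$match_rate[which.min(x$g)],
                 match_rate_gmax = x$match_rate[which.max(x$g)])
}

#' @rdname tidiers
#' @method tidy pattern_dist
#' @export
tidy.pattern_dist <- function(x, ...) tibble::as_tibble(unclass_result(x))

#' @rdname tidiers
#' @method glance pattern_dist
#' @export
glance.pattern_dist <- function(x, ...) {
  tibble::tibble(n_patterns = nrow(x), g = attr(x, "g"),
                 n_loci = attr(x, "n_loci"),
                 normalized = isTRUE(attr(x, "normalized")))
}

unclass_result <- function(x) {
  out <- x
  class(out) <- class(tibble::tibble())
  attr(out, "g") <- NULL
  attr(out, "populations") <- NULL
  attr(out, "n_loci") <- NULL
  attr(out, "alphabet") <- NULL
  attr(out, "normalized") <- NULL
  attr(out, "window_size") <- NULL
  attr(out, "exclude_singletons") <- NULL
  attr(out, "normalize_all_u") <- NULL
  out
}
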
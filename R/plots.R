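#' Stacked composition plot of a g-sweep
#'
#' Pattern probabilities as a stacked area chart over the subsample size
#' g. Patterns whose probability falls below `display_threshold` at the
#' reference subsample size (by default the middle value of the g grid)
#' are grouped into a single "other" band, keeping the legend readable.
#'
#' @param sweep A [g_sweep()] result.
#' @param display_threshold Minimum probability at the reference g for a
#'   pattern to keep its own band (default 0.01).
#' @param at_g Reference subsample size; defaults to the middle of the
#'   grid.
#' @return A ggplot object.
#' @export
plot_sweep <- function(sweep, display_threshold = 0.01, at_g = NULL) {
  if (display_threshold <= 0 || display_threshold >= 1) {
    abort("`display_threshold` must lie in (0, 1).",
          class = "rp_window_error")
  }
  gs <- sort(unique(sweep$g))
  if (is.null(at_g)) at_g <- gs[ceiling(length(gs) / 2)]
  keep <- sweep$pattern[sweep$g == at_g &
                          sweep$probability >= display_threshold]
  df <- sweep |>
    dplyr::mutate(band = ifelse(.data$pattern %in% keep, .data$pattern,
                                "other")) |>
    dplyr::summarise(probability = sum(.data$probability),
                     .by = c("g", "band"))
  band_levels <- c(sort(unique(keep)), "other")
  df$band <- factor(df$band, levels = band_levels)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$g, y = .data$probability,
                                   fill = .data$band)) +
    ggplot2::geom_area(position = "stack") +
    ggplot2::scale_fill_viridis_d(name = "pattern") +
    ggplot2::labs(x = "subsample size g", y = "probability") +
    ggplot2::theme_minimal()
}

#' @method autoplot g_sweep
#' @export
autoplot.g_sweep <- function(object, ...) plot_sweep(object, ...)

#' Match-rate curve plot
#'
#' @param curve A [match_curve()] result.
#' @return A ggplot object.
#' @export
plot_match_curve <- function(curve) {
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$g, y = .data$match_rate)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "subsample size g",
                  y = "P(top corrected pattern = empirical pattern)") +
    ggplot2::theme_minimal()
}

#' @method autoplot match_curve
#' @export
autoplot.match_curve <- function(object, ...) plot_match_curve(object)

#' Per-window summary-triple probability plot
#'
#' Stacked probabilities of the (|U|,|R|,|C|) summary triples along the
#' genome; empty windows appear as gaps.
#'
#' @param scan A [window_summaries()] result.
#' @return A ggplot object.
#' @export
plot_window_probs <- function(scan) {
  df <- dplyr::filter(tibble::as_tibble(scan), .data$n_loci > 0L) |>
    dplyr::mutate(triple = triple_label(.data$n_unobserved, .data$n_rare,
                                        .data$n_common))
  ggplot2::ggplot(df, ggplot2::aes(x = (.data$start + .data$end) / 2e6,
                                   y = .data$probability,
                                   fill = .data$triple)) +
    ggplot2::geom_col(width = attr(scan, "window_size") / 1e6) +
    ggplot2::facet_wrap(~chrom, ncol = 1, scales = "free_x") +
    ggplot2::scale_fill_viridis_d(name = "(|U|,|R|,|C|)") +
    ggplot2::labs(x = "position (Mb)", y = "probability") +
    ggplot2::theme_minimal()
}

#' Rank track plot of summary triples along the genome
#'
#' Local frequency ranks of the summary triples (all-unobserved triple
#' excluded), as in a genome scan for locally atypical geographic
#' distributions. Only triples that reach rank 1 or 2 in at least one
#' window are coloured; the rest are grey. Empty windows leave gaps.
#'
#' @param scan A ranked [rank_track()] result.
#' @param top_rank Colour triples achieving at most this rank somewhere
#'   (default 2).
#' @return A ggplot object.
#' @export
plot_rank_track <- function(scan, top_rank = 2) {
  if (!"rank" %in% names(scan)) scan <- rank_track(scan)
  df <- dplyr::filter(tibble::as_tibble(scan), !is.na(.data$rank)) |>
    dplyr::mutate(triple = triple_label(.data$n_unobserved, .data$n_rare,
                                        .data$n_common))
  hot <- df |>
    dplyr::summarise(best = min(.data$rank), .by = "triple") |>
    dplyr::filter(.data$best <= top_rank)
  df$colour_group <- ifelse(df$triple %in% hot$triple, df$triple, NA)
  pal_values <- grDevices::hcl.colors(max(nrow(hot), 1L), "Dark 3")
  names(pal_values) <- sort(hot$triple)
  ggplot2::ggplot(df, ggplot2::aes(x = (.data$start + .data$end) / 2e6,
                                   y = .data$rank,
                                   colour = .data$colour_group,
                                   group = .data$triple)) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::facet_wrap(~chrom, ncol = 1, scales = "free_x") +
    ggplot2::scale_colour_manual(values = pal_values, na.value = "grey80",
                                 name = "(|U|,|R|,|C|)") +
    ggplot2::scale_y_reverse(breaks = function(l) {
      seq(1, max(l[is.finite(l)]), by = 2)
    }) +
    ggplot2::labs(x = "position (Mb)", y = "local frequency rank") +
    ggplot2::theme_minimal()
}

#' @method autoplot window_scan
#' @export
autoplot.window_scan <- function(object, type = c("rank", "probability"),
                                 ...) {
  type <- match.arg(type)
  if (type == "rank") plot_rank_track(object, ...) else
    plot_window_probs(object)
}

triple_label <- function(u, r, c) sprintf("(%d,%d,%d)", u, r, c)

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
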
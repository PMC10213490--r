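#' Sweep the subsample size g across a locus panel
#'
#' Recomputes the across-loci averaged pattern distribution for each value
#' of `g`, optionally excluding singleton loci first and optionally
#' removing the all-unobserved pattern (renormalising by `1 - P[all-U]`).
#' The default grid is every multiple of 10 in `[10, 500]`, capped at the
#' smallest population total of the panel.
#'
#' @param counts An [allele_counts()] table.
#' @param g_values Strictly increasing subsample sizes; `NULL` for the
#'   default grid.
#' @param scheme A [class_scheme()].
#' @param exclude_singletons Drop loci whose global minor count is 1.
#' @param normalize_all_u Remove the all-unobserved pattern per g and
#'   renormalise.
#' @return A tibble of class `g_sweep` with columns `g`, `pattern`,
#'   `probability` (long format, one distribution per g), and attributes
#'   recording the options used.
#' @export
g_sweep <- function(counts, g_values = NULL, scheme = class_scheme(),
                    exclude_singletons = FALSE, normalize_all_u = FALSE) {
  if (exclude_singletons) {
    counts <- filter_loci(counts, min_total = 1, exclude_singletons = TRUE)
  }
  m <- count_matrices(counts)
  if (is.null(g_values)) {
    g_values <- default_g_grid(min(m$total))
  }
  if (any(diff(g_values) <= 0)) {
    abort("`g_values` must be strictly increasing.",
          class = "rp_subsample_error")
  }
  dists <- purrr::map(g_values, function(g) {
    d <- pattern_distribution(counts, g, scheme)
    if (normalize_all_u) d <- drop_all_unobserved(d)
    tibble::tibble(g = as.integer(g), pattern = d$pattern,
                   probability = d$probability)
  })
  structure(purrr::list_rbind(dists),
            populations = populations(counts), n_loci = nrow(counts),
            alphabet = scheme$alphabet,
            exclude_singletons = exclude_singletons,
            normalize_all_u = normalize_all_u,
            class = c("g_sweep", class(tibble::tibble())))
}

#' Default subsample-size grid: multiples of 10 in [10, 500], capped
#' at the panel's smallest population total.
#' @param n_min Smallest population total.
#' @return Integer vector of subsample sizes.
#' @export
default_g_grid <- function(n_min = 500) {
  seq.int(10L, min(500L, (n_min %/% 10L) * 10L), by = 10L)
}

#' Collapse a g-sweep to summary triples
#'
#' @param sweep A `g_sweep` result (three-class alphabet).
#' @return A tibble with columns `g`, `n_unobserved`, `n_rare`,
#'   `n_common`, `probability`.
#' @export
sweep_summaries <- function(sweep) {
  if (!identical(attr(sweep, "alphabet"), c("U", "R", "C"))) {
    abort("Summary triples are defined only for the three-class scheme.",
          class = "rp_pattern_error")
  }
  dplyr::bind_cols(sweep["g"], pattern_triples(sweep$pattern),
                   sweep["probability"]) |>
    dplyr::summarise(probability = sum(.data$probability),
                     .by = c("g", "n_unobserved", "n_rare", "n_common"))
}

#' Tile a chromosome extent with nonoverlapping windows
#'
#' Windows are half-open `[start, end)` intervals in 0-based coordinates,
#' aligned to absolute multiples of `window_size` (dataset-independent
#' tiling), starting at the window containing `min_pos` and continuing
#' until `max_pos` is covered. The final window may extend beyond
#' `max_pos`.
#'
#' @param chrom Chromosome label.
#' @param min_pos,max_pos 0-based positions bounding the extent.
#' @param window_size Window width in base pairs (default 100 kb).
#' @return A tibble with columns `chrom`, `start`, `end`.
#' @examples
#' tile_windows("chr22", 0, 250000)
#' @export
tile_windows <- function(chrom, min_pos, max_pos, window_size = 1e5) {
  if (window_size <= 0) {
    abort("`window_size` must be positive.", class = "rp_window_error")
  }
  if (max_pos < min_pos) {
    abort("Inverted extent: `max_pos` < `min_pos`.",
          class = "rp_window_error")
  }
  first <- (min_pos %/% window_size) * window_size
  starts <- seq(first, max_pos, by = window_size)
  tibble::tibble(chrom = chrom, start = starts, end = starts + window_size)
}

#' Per-window averaged summary-triple distributions
#'
#' For each genomic window, averages (with equal weight) the
#' summary-collapsed pattern distributions of the SNPs falling inside it.
#' A VCF-style 1-based SNP at position p falls in the half-open 0-based
#' window containing p - 1. Windows containing no SNPs are retained and
#' flagged empty (`n_loci = 0`, probabilities `NA`), preserving genomic
#' continuity.
#'
#' @param counts An [allele_counts()] table (1-based `pos`).
#' @param g Subsample size.
#' @param scheme A three-class [class_scheme()].
#' @param window_size Window width in base pairs (default 100 kb).
#' @param exclude_singletons Drop singleton loci before averaging
#'   (default `TRUE`, as window scans focus on nonsingleton variation).
#' @param windows Optional window table from [tile_windows()]; defaults
#'   to tiling each chromosome's extent.
#' @return A tibble of class `window_scan`, long over windows and triples:
#'   columns `chrom`, `start`, `end`, `n_loci`, `n_unobserved`, `n_rare`,
#'   `n_common`, `probability`.
#' @export
window_summaries <- function(counts, g, scheme = class_scheme(),
                             window_size = 1e5, exclude_singletons = TRUE,
                             windows = NULL) {
  check_scheme(scheme, "three-class")
  if (exclude_singletons) {
    counts <- filter_loci(counts, min_total = 1, exclude_singletons = TRUE)
  }
  m <- count_matrices(counts)
  check_g(g, m$total)
  J <- ncol(m$total)

  if (is.null(windows)) {
    windows <- dplyr::summarise(
      dplyr::group_by(tibble::as_tibble(counts[c("chrom", "pos")]),
                      .data$chrom),
      min_pos = min(.data$pos) - 1, max_pos = max(.data$pos) - 1,
      .groups = "drop") |>
      purrr::pmap(function(chrom, min_pos, max_pos) {
        tile_windows(chrom, min_pos, max_pos, window_size)
      }) |>
      purrr::list_rbind()
  }

  # collapse per-locus pattern probabilities to per-locus triple
  # probabilities, then average within windows
  pat <- pattern_prob_matrix(m$minor, m$total, g, scheme)
  tri <- pattern_triples(colnames(pat))
  tri_label <- paste(tri$n_unobserved, tri$n_rare, tri$n_common)
  locus_tri <- t(rowsum(t(pat), group = tri_label))  # loci x triples

  triples <- enumerate_summaries(J)
  lab <- paste(triples$n_unobserved, triples$n_rare, triples$n_common)
  locus_tri <- locus_tri[, lab, drop = FALSE]

  pos0 <- counts$pos - 1  # 0-based position of each SNP
  out <- purrr::pmap(windows, function(chrom, start, end) {
    in_w <- counts$chrom == chrom & pos0 >= start & pos0 < end
    n <- sum(in_w)
    p <- if (n > 0L) colMeans(locus_tri[in_w, , drop = FALSE]) else
      rep(NA_real_, nrow(triples))
    dplyr::bind_cols(
      tibble::tibble(chrom = chrom, start = start, end = end, n_loci = n),
      triples, probability = unname(p))
  }) |>
    purrr::list_rbind()
  structure(out, g = g, populations = populations(counts),
            window_size = window_size,
            exclude_singletons = exclude_singletons,
            class = c("window_scan", class(tibble::tibble())))
}

#' Rank summary triples within each window
#'
#' Within each nonempty window, ranks the summary triples other than the
#' all-unobserved triple (J, 0, 0) by descending probability: rank 1 is
#' the most probable, giving ranks 1..20 for J = 5. Ties are broken by
#' lexicographic triple order. The all-unobserved triple and empty
#' windows get rank `NA`.
#'
#' @param scan A `window_scan` from [window_summaries()].
#' @return The same tibble with a `rank` column added.
#' @export
rank_track <- function(scan) {
  J <- length(attr(scan, "populations"))
  ranked <- tibble::as_tibble(scan) |>
    dplyr::mutate(
      rank = rank_desc_lex(.data$probability, .data$n_unobserved,
                           .data$n_rare,
                           .data$n_unobserved == J | .data$n_loci == 0L),
      .by = c("chrom", "start")
    )
  structure(ranked, g = attr(scan, "g"),
            populations = attr(scan, "populations"),
            window_size = attr(scan, "window_size"),
            exclude_singletons = attr(scan, "exclude_singletons"),
            class = c("window_scan", class(tibble::tibble())))
}

#' Write / read per-window summaries as BED-like TSV
#'
#' One row per window (`chrom`, `start`, `end`, `n_loci`), one probability
#' column per summary triple (`p_<U>_<R>_<C>`) and, if ranks have been
#' computed, one rank column per triple. `#` header lines record the
#' subsample size, window size, population order and singleton handling,
#' so that the file re-parses to an identical scan.
#'
#' @param scan A `window_scan`, optionally ranked with [rank_track()].
#' @param path Output (or input) TSV path.
#' @return `write_window_summaries()` returns `path` invisibly;
#'   `read_window_summaries()` returns a `window_scan`.
#' @export
write_window_summaries <- function(scan, path) {
  has_rank <- "rank" %in% names(scan)
  lab <- function(u, r, c) sprintf("%d_%d_%d", u, r, c)
  wide <- tibble::as_tibble(scan) |>
    dplyr::mutate(triple = lab(.data$n_unobserved, .data$n_rare,
                               .data$n_common)) |>
    dplyr::select(-"n_unobserved", -"n_rare", -"n_common") |>
    tidyr::pivot_wider(
      names_from = "triple",
      values_from = dplyr::all_of(c("probability",
                                    if (has_rank) "rank")),
      names_glue = if (has_rank) "{.value}_{triple}" else "p_{triple}")
  if (has_rank) {
    names(wide) <- sub("^probability_", "p_", names(wide))
  }
  meta <- c(
    paste0("# g=", attr(scan, "g")),
    paste0("# window_size=", format(attr(scan, "window_size"),
                                    scientific = FALSE)),
    paste0("# populations=", paste(attr(scan, "populations"),
                                   collapse = ",")),
    paste0("# exclude_singletons=", attr(scan, "exclude_singletons"))
  )
  writeLines(meta, path)
  readr::write_tsv(wide, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' @rdname write_window_summaries
#' @export
read_window_summaries <- function(path) {
  lines <- readLines(path, n = 20L)
  meta <- grep("^# ", lines, value = TRUE)
  get_meta <- function(key) {
    m <- grep(paste0("^# ", key, "="), meta, value = TRUE)
    if (length(m) == 0L) return(NULL)
    sub(paste0("^# ", key, "="), "", m[1L])
  }
  wide <- readr::read_tsv(path, comment = "# ", show_col_types = FALSE,
                          progress = FALSE)
  p_cols <- grep("^p_\\d+_\\d+_\\d+$", names(wide), value = TRUE)
  if (length(p_cols) == 0L) {
    abort("No summary-triple probability columns found.",
          class = "rp_format_error")
  }
  rank_cols <- grep("^rank_\\d+_\\d+_\\d+$", names(wide), value = TRUE)
  long <- wide |>
    tidyr::pivot_longer(dplyr::all_of(c(p_cols, rank_cols)),
                        names_to = c(".value", "triple"),
                        names_pattern = "^(p|rank)_(\\d+_\\d+_\\d+)$") |>
    tidyr::separate_wider_delim("triple", "_",
                                names = c("n_unobserved", "n_rare",
                                          "n_common")) |>
    dplyr::mutate(dplyr::across(dplyr::all_of(c("n_unobserved", "n_rare",
                                                "n_common")),
                                as.integer)) |>
    dplyr::rename(probability = "p") |>
    dplyr::arrange(.data$chrom, .data$start, .data$n_unobserved,
                   .data$n_rare) |>
    dplyr::relocate("chrom", "start", "end", "n_loci", "n_unobserved",
                    "n_rare", "n_common", "probability")
  structure(long,
            g = as.numeric(get_meta("g")),
            populations = strsplit(get_meta("populations") %||% "",
                                   ",")[[1L]],
            window_size = as.numeric(get_meta("window_size")),
            exclude_singletons = identical(get_meta("exclude_singletons"),
                                           "TRUE"),
            class = c("window_scan", class(tibble::tibble())))
}

# descending-probability ranks with lexicographic (n_unobserved, n_rare)
# tie-break; excluded entries marked TRUE get NA
rank_desc_lex <- function(p, n_u, n_r, excluded) {
  out <- rep(NA_real_, length(p))
  idx <- which(!excluded)
  ord <- idx[order(-p[idx], n_u[idx], n_r[idx])]
  out[ord] <- seq_along(ord)
  out
}
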
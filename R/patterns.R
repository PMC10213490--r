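#' Enumerate the multi-population pattern space
#'
#' A *pattern* is the J-vector of per-population frequency classes of one
#' allelic type, written as a string in population order (e.g. `"RUUUU"`:
#' rare in the first population, unobserved in the other four). With K
#' classes and J populations there are K^J patterns; they are returned in
#' lexicographic order under the class order of the scheme's alphabet
#' (U < R < C in three-class mode).
#'
#' @param J Number of populations.
#' @param scheme A [class_scheme()]; its alphabet defines K and the letter
#'   order.
#' @return Character vector of length K^J.
#' @examples
#' pattern_space(2)   # 9 patterns: UU, UR, UC, RU, ...
#' @export
pattern_space <- function(J, scheme = class_scheme()) {
  check_scheme(scheme)
  apply(pattern_index_matrix(J, length(scheme$alphabet)), 1L,
        function(i) paste(scheme$alphabet[i], collapse = ""))
}

# (K^J x J) integer matrix of class indices, rows in lexicographic order
# (position 1 most significant)
pattern_index_matrix <- function(J, K) {
  grid <- do.call(expand.grid,
                  c(rep(list(seq_len(K)), J), KEEP.OUT.ATTRS = FALSE))
  as.matrix(grid)[, rev(seq_len(J)), drop = FALSE]
}

#' Probability of one geographic distribution pattern
#'
#' The probability that the focal allelic type of a locus has a given
#' pattern at subsample size `g` is the product over populations of the
#' per-population class probability selected by the pattern letter
#' (populations are subsampled independently).
#'
#' @param counts An [allele_counts()] table.
#' @param g Subsample size.
#' @param pattern A pattern string over the scheme's alphabet, length-J.
#' @param scheme A [class_scheme()].
#' @return Numeric vector with one probability per locus.
#' @examples
#' x <- allele_counts(data.frame(chrom = "1", pos = 1, ref = "A", alt = "T",
#'                               P1_minor = 2, P1_total = 4,
#'                               P2_minor = 3, P2_total = 6))
#' pattern_probability(x, g = 2, "RR", class_scheme(z = 0.25))
#' @export
pattern_probability <- function(counts, g, pattern, scheme = class_scheme()) {
  m <- count_matrices(counts)
  check_g(g, m$total)
  J <- ncol(m$total)
  letters_idx <- parse_pattern(pattern, J, scheme)
  probs <- class_prob_matrices(m$minor, m$total, g, scheme)
  out <- rep(1, nrow(m$total))
  for (j in seq_len(J)) {
    out <- out * probs[[letters_idx[j]]][, j]
  }
  out
}

parse_pattern <- function(pattern, J, scheme) {
  if (!is.character(pattern) || length(pattern) != 1L) {
    abort("`pattern` must be a single string.", class = "rp_pattern_error")
  }
  letters <- strsplit(pattern, "")[[1L]]
  if (all(nchar(scheme$alphabet) == 1L)) {
    if (length(letters) != J) {
      abort(sprintf("Pattern '%s' has length %d; expected %d populations.",
                    pattern, length(letters), J),
            class = "rp_pattern_error")
    }
    idx <- match(letters, scheme$alphabet)
  } else {
    # multi-character labels: split on the known alphabet greedily
    idx <- match(strsplit(pattern, "(?<=.)(?=U|W)", perl = TRUE)[[1L]],
                 scheme$alphabet)
    if (length(idx) != J) {
      abort(sprintf("Pattern '%s' does not parse into %d class labels.",
                    pattern, J), class = "rp_pattern_error")
    }
  }
  if (anyNA(idx)) {
    abort(sprintf("Pattern '%s' uses letters outside the scheme alphabet (%s).",
                  pattern, paste(scheme$alphabet, collapse = "")),
          class = "rp_pattern_error")
  }
  idx
}

#' Distribution over all K^J patterns
#'
#' Computes, for each locus, the probability of every pattern at subsample
#' size `g`, and (by default) averages these per-locus distributions with
#' equal weight across loci — the expected pattern distribution of a
#' randomly chosen locus. Probabilities over the full pattern space sum
#' to 1 for every locus.
#'
#' @param counts An [allele_counts()] table.
#' @param g Subsample size.
#' @param scheme A [class_scheme()].
#' @param average If `TRUE` (default) return the across-loci average; if
#'   `FALSE` return a per-locus matrix (loci x patterns).
#' @return For `average = TRUE`, a tibble of class `pattern_dist` with
#'   columns `pattern`, `probability` and attributes `g`, `populations`,
#'   `n_loci`, `alphabet`. For `average = FALSE`, a numeric matrix with
#'   one column per pattern.
#' @export
pattern_distribution <- function(counts, g, scheme = class_scheme(),
                                 average = TRUE) {
  m <- count_matrices(counts)
  check_g(g, m$total)
  mat <- pattern_prob_matrix(m$minor, m$total, g, scheme)
  if (!average) return(mat)
  new_pattern_dist(colnames(mat), colMeans(mat), g = g,
                   populations = colnames(m$total), n_loci = nrow(mat),
                   alphabet = scheme$alphabet)
}

# loci x K^J matrix of pattern probabilities
pattern_prob_matrix <- function(minor, total, g, scheme) {
  J <- ncol(total)
  K <- length(scheme$alphabet)
  probs <- class_prob_matrices(minor, total, g, scheme)
  idx <- pattern_index_matrix(J, K)
  out <- matrix(1, nrow = nrow(total), ncol = nrow(idx))
  for (p in seq_len(nrow(idx))) {
    v <- probs[[idx[p, 1L]]][, 1L]
    for (j in seq_len(J)[-1L]) v <- v * probs[[idx[p, j]]][, j]
    out[, p] <- v
  }
  colnames(out) <- apply(idx, 1L,
                         function(i) paste(scheme$alphabet[i], collapse = ""))
  out
}

new_pattern_dist <- function(pattern, probability, g, populations, n_loci,
                             alphabet, normalized = FALSE) {
  structure(
    tibble::tibble(pattern = pattern, probability = unname(probability)),
    g = g, populations = populations, n_loci = n_loci, alphabet = alphabet,
    normalized = normalized,
    class = c("pattern_dist", class(tibble::tibble()))
  )
}

#' @export
print.pattern_dist <- function(x, ...) {
  cat(sprintf("# Pattern distribution: %d patterns, g = %d, %d loci%s\n",
              nrow(x), attr(x, "g"), attr(x, "n_loci"),
              if (isTRUE(attr(x, "normalized")))
                " (all-unobserved pattern excluded)" else ""))
  NextMethod()
}

#' Average per-type probabilities at a locus
#'
#' At a locus with I allelic types, the expected fraction of allelic types
#' with a given pattern is the unweighted mean of the per-type pattern
#' probabilities.
#'
#' @param per_type Numeric vector of per-type probabilities (length I >= 1).
#' @return Their arithmetic mean.
#' @export
average_over_types <- function(per_type) {
  if (length(per_type) == 0L) {
    abort("Need at least one per-type probability.",
          class = "rp_aggregation_error")
  }
  mean(per_type)
}

#' Average pattern distributions across loci
#'
#' Unweighted mean of per-locus pattern distributions (each locus counts
#' equally). All distributions must share the same subsample size,
#' pattern space and population set.
#'
#' @param dists A list of `pattern_dist` objects.
#' @return A `pattern_dist` averaging the inputs.
#' @export
average_over_loci <- function(dists) {
  if (length(dists) == 0L) {
    abort("Need at least one distribution.", class = "rp_aggregation_error")
  }
  g <- unique(purrr::map_int(dists, ~ as.integer(attr(.x, "g"))))
  pats <- purrr::map(dists, "pattern")
  if (length(g) != 1L || length(unique(pats)) != 1L) {
    abort("Distributions differ in g or pattern space; cannot average.",
          class = "rp_aggregation_error")
  }
  p <- rowMeans(do.call(cbind, purrr::map(dists, "probability")))
  new_pattern_dist(pats[[1L]], p, g = g,
                   populations = attr(dists[[1L]], "populations"),
                   n_loci = sum(purrr::map_int(
                     dists, ~ as.integer(attr(.x, "n_loci")))),
                   alphabet = attr(dists[[1L]], "alphabet"))
}

#' Collapse patterns to (|U|, |R|, |C|) summary triples
#'
#' Groups the three-class patterns by the numbers of populations in which
#' the allelic type is unobserved, rare, and common — the ordered triple
#' (|U|, |R|, |C|) — summing their probabilities. For J = 5 the 243
#' patterns collapse to 21 triples. Total probability is preserved.
#'
#' @param dist A three-class `pattern_dist`.
#' @return A tibble of class `summary_dist` with columns `n_unobserved`,
#'   `n_rare`, `n_common`, `probability`, one row per triple summing to J,
#'   in lexicographic order.
#' @export
collapse_to_summary <- function(dist) {
  alphabet <- attr(dist, "alphabet")
  if (!identical(alphabet, c("U", "R", "C"))) {
    abort("Summary triples are defined only for the three-class scheme.",
          class = "rp_pattern_error")
  }
  J <- nchar(dist$pattern[1L])
  triples <- pattern_triples(dist$pattern)
  out <- enumerate_summaries(J) |>
    dplyr::left_join(
      dplyr::summarise(
        dplyr::group_by(
          dplyr::bind_cols(triples, probability = dist$probability),
          .data$n_unobserved, .data$n_rare, .data$n_common),
        probability = sum(.data$probability), .groups = "drop"),
      by = c("n_unobserved", "n_rare", "n_common")
    ) |>
    dplyr::mutate(probability = dplyr::coalesce(.data$probability, 0))
  structure(out,
            g = attr(dist, "g"), populations = attr(dist, "populations"),
            n_loci = attr(dist, "n_loci"),
            normalized = attr(dist, "normalized"),
            class = c("summary_dist", class(tibble::tibble())))
}

# letter counts of three-class pattern strings
pattern_triples <- function(patterns) {
  tibble::tibble(
    n_unobserved = nchar(gsub("[^U]", "", patterns)),
    n_rare = nchar(gsub("[^R]", "", patterns)),
    n_common = nchar(gsub("[^C]", "", patterns))
  )
}

#' Enumerate all (|U|, |R|, |C|) summary triples
#'
#' All ordered triples of nonnegative integers summing to J, in
#' lexicographic order; there are (J+1)(J+2)/2 of them (21 for J = 5).
#'
#' @param J Number of populations.
#' @return A tibble with columns `n_unobserved`, `n_rare`, `n_common`.
#' @export
enumerate_summaries <- function(J) {
  if (J < 1) abort("`J` must be >= 1.", class = "rp_pattern_error")
  grid <- tidyr::expand_grid(n_unobserved = 0:J, n_rare = 0:J) |>
    dplyr::mutate(n_common = J - .data$n_unobserved - .data$n_rare) |>
    dplyr::filter(.data$n_common >= 0)
  grid
}

#' Remove the all-unobserved pattern and renormalise
#'
#' Empirical analyses condition on polymorphism, so every observed locus
#' has a non-all-U pattern. To compare the subsampled distribution with
#' such analyses, the all-unobserved pattern (e.g. `"UUUUU"`) is removed
#' and the remaining probabilities divided by `1 - P[all-U]`.
#'
#' @param dist A `pattern_dist`.
#' @return A `pattern_dist` without the all-U row, summing to 1, flagged
#'   `normalized`.
#' @export
drop_all_unobserved <- function(dist) {
  J <- length(attr(dist, "populations"))
  all_u <- paste(rep(attr(dist, "alphabet")[1L], J), collapse = "")
  i <- match(all_u, dist$pattern)
  p_u <- if (is.na(i)) 0 else dist$probability[i]
  if (p_u >= 1 - 1e-12) {
    abort("All probability mass is on the all-unobserved pattern.",
          class = "rp_degenerate_error")
  }
  keep <- if (is.na(i)) dist else dist[-i, ]
  new_pattern_dist(keep$pattern, keep$probability / (1 - p_u),
                   g = attr(dist, "g"),
                   populations = attr(dist, "populations"),
                   n_loci = attr(dist, "n_loci"),
                   alphabet = attr(dist, "alphabet"), normalized = TRUE)
}

#' Empirical full-sample pattern of each locus
#'
#' The classification without any subsampling: per population, `U` if the
#' minor count is 0, `R` if it is between 1 and `floor(z * N_j)`, `C`
#' otherwise.
#'
#' @param counts An [allele_counts()] table.
#' @param scheme A three-class [class_scheme()].
#' @return Character vector of pattern strings, one per locus.
#' @export
empirical_pattern <- function(counts, scheme = class_scheme()) {
  check_scheme(scheme, "three-class")
  m <- count_matrices(counts)
  kmax <- floor_bound(scheme$z * m$total)
  cls <- matrix("C", nrow(m$minor), ncol(m$minor))
  cls[m$minor <= kmax] <- "R"
  cls[m$minor == 0] <- "U"
  apply(cls, 1L, paste, collapse = "")
}

#' Agreement of the top corrected pattern with the empirical pattern
#'
#' For each locus, finds the pattern (excluding all-unobserved) with the
#' highest subsampling-corrected probability at subsample size `g`, and
#' reports the fraction of loci for which it coincides with the empirical
#' full-sample pattern. Argmax ties are broken by lexicographic pattern
#' order with U < R < C.
#'
#' @param counts An [allele_counts()] table.
#' @param g Subsample size.
#' @param scheme A three-class [class_scheme()].
#' @return The match proportion, a number in `[0, 1]`.
#' @export
top_pattern_match_rate <- function(counts, g, scheme = class_scheme()) {
  check_scheme(scheme, "three-class")
  if (nrow(counts) == 0L) {
    abort("Empty locus table.", class = "rp_aggregation_error")
  }
  m <- count_matrices(counts)
  check_g(g, m$total)
  mat <- pattern_prob_matrix(m$minor, m$total, g, scheme)
  all_u <- strrep("U", ncol(m$total))
  mat[, colnames(mat) == all_u] <- -Inf
  # columns are in lexicographic order, so "first" tie-breaking picks the
  # lexicographically smallest pattern
  top <- colnames(mat)[max.col(mat, ties.method = "first")]
  mean(top == empirical_pattern(counts, scheme))
}

#' Match-rate curve over subsample sizes
#'
#' [top_pattern_match_rate()] evaluated on a grid of subsample sizes.
#'
#' @param counts An [allele_counts()] table.
#' @param g_values Increasing vector of subsample sizes.
#' @param scheme A three-class [class_scheme()].
#' @return A tibble of class `match_curve` with columns `g`, `match_rate`.
#' @export
match_curve <- function(counts, g_values, scheme = class_scheme()) {
  out <- tibble::tibble(
    g = as.integer(g_values),
    match_rate = purrr::map_dbl(g_values, top_pattern_match_rate,
                                counts = counts, scheme = scheme)
  )
  structure(out, n_loci = nrow(counts),
            class = c("match_curve", class(tibble::tibble())))
}
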
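#' Per-locus, per-population allele count table
#'
#' The central data container: one row per biallelic locus, with the count
#' of the focal (globally minor) allelic type and the total number of
#' alleles sampled in each population group. Expected columns are `chrom`,
#' `pos` (1-based), `ref`, `alt`, and for every population `<pop>_minor`
#' and `<pop>_total`. Any other columns are carried along.
#'
#' @param x A data frame with the columns described above.
#' @param populations Optional character vector fixing the population
#'   order; defaults to the order in which `<pop>_minor` columns appear.
#' @param filters Character vector describing filters already applied
#'   (provenance metadata).
#' @param seed Optional integer seed used for minor-allele tie-breaking
#'   (provenance metadata).
#' @return A tibble of class `counts_tbl` with a `populations` attribute.
#' @examples
#' allele_counts(data.frame(chrom = "1", pos = 500, ref = "A", alt = "G",
#'                          AFR_minor = 3, AFR_total = 1008,
#'                          EUR_minor = 0, EUR_total = 808))
#' @export
allele_counts <- function(x, populations = NULL, filters = character(),
                          seed = NULL) {
  x <- tibble::as_tibble(x)
  required <- c("chrom", "pos", "ref", "alt")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0L) {
    abort(paste0("Missing required column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "rp_format_error")
  }
  found <- sub("_minor$", "", grep("_minor$", names(x), value = TRUE))
  if (is.null(populations)) populations <- found
  need <- c(paste0(populations, "_minor"), paste0(populations, "_total"))
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols) > 0L) {
    abort(paste0("Missing count column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "rp_format_error")
  }
  minor <- as.matrix(x[paste0(populations, "_minor")])
  total <- as.matrix(x[paste0(populations, "_total")])
  if (any(total < 0)) {
    abort("Population totals must be nonnegative integers.",
          class = "rp_counts_error")
  }
  if (any(minor < 0) || any(minor > total)) {
    abort("Minor counts must satisfy 0 <= minor <= total in every population.",
          class = "rp_counts_error")
  }
  if (is.unsorted(order(x$chrom, x$pos))) {
    x <- dplyr::arrange(x, .data$chrom, .data$pos)
  }
  new_counts_tbl(x, populations, filters, seed)
}

new_counts_tbl <- function(x, populations, filters = character(),
                           seed = NULL) {
  structure(tibble::as_tibble(x),
            populations = populations,
            filters = filters,
            seed = seed,
            class = c("counts_tbl", class(tibble::tibble())))
}

#' @export
print.counts_tbl <- function(x, ...) {
  pops <- attr(x, "populations")
  cat(sprintf("# Allele counts: %d loci x %d populations (%s)\n",
              nrow(x), length(pops), paste(pops, collapse = ", ")))
  f <- attr(x, "filters")
  if (length(f) > 0L) cat("# Filters:", paste(f, collapse = "; "), "\n")
  NextMethod()
}

#' @export
`[.counts_tbl` <- function(x, ...) {
  out <- NextMethod()
  pops <- attr(x, "populations")
  need <- c(paste0(pops, "_minor"), paste0(pops, "_total"))
  if (is.data.frame(out) && all(need %in% names(out))) {
    new_counts_tbl(out, pops, attr(x, "filters"), attr(x, "seed"))
  } else {
    out
  }
}

#' Population labels of a counts table
#' @param x A `counts_tbl`.
#' @return Character vector of population labels, in pattern order.
#' @export
populations <- function(x) attr(x, "populations")

# minor-count and total matrices (n_loci x J), population labels as colnames
count_matrices <- function(x) {
  pops <- populations(x)
  if (is.null(pops)) {
    abort("Not an allele_counts() table (no populations attribute).",
          class = "rp_format_error")
  }
  minor <- as.matrix(x[paste0(pops, "_minor")])
  total <- as.matrix(x[paste0(pops, "_total")])
  colnames(minor) <- colnames(total) <- pops
  storage.mode(minor) <- "double"
  storage.mode(total) <- "double"
  list(minor = minor, total = total)
}

#' Filter loci by minimum per-population sample size and singleton status
#'
#' Retains loci whose total sampled alleles reach `min_total` in every
#' population and, optionally, drops singletons — loci whose minor allele
#' appears exactly once in the combined sample across all populations.
#' The number of loci removed by each filter is recorded in the table's
#' `filters` attribute.
#'
#' @param counts An [allele_counts()] table.
#' @param min_total Minimum per-population total (default 500).
#' @param exclude_singletons Drop loci with a global minor count of 1.
#' @return A filtered `counts_tbl`.
#' @export
filter_loci <- function(counts, min_total = 500, exclude_singletons = FALSE) {
  m <- count_matrices(counts)
  keep <- rowSums(m$total < min_total) == 0
  n_small <- sum(!keep)
  filt <- c(attr(counts, "filters"),
            sprintf("min_total>=%d removed %d loci", min_total, n_small))
  if (exclude_singletons) {
    global_minor <- rowSums(m$minor)
    singleton <- global_minor == 1
    n_single <- sum(keep & singleton)
    keep <- keep & !singleton
    filt <- c(filt, sprintf("singletons removed %d loci", n_single))
  }
  new_counts_tbl(counts[keep, , drop = FALSE], populations(counts),
                 filters = filt, seed = attr(counts, "seed"))
}

#' Global minor-allele count per locus
#' @param counts An [allele_counts()] table.
#' @return Integer vector of summed minor counts across populations.
#' @export
global_minor_count <- function(counts) {
  rowSums(count_matrices(counts)$minor)
}
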
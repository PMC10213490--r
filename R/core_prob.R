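#' Exact subsampling class probabilities for a single population
#'
#' Under subsampling without replacement of `g` alleles from the `n_total`
#' alleles sampled in one population, these functions give the exact
#' probability that an allelic type present in `n_focal` copies is
#' unobserved, rare, common, or inside an arbitrary frequency window. All
#' `C(n_total, g)` subsamples are equally likely, so the number of focal
#' copies in the subsample is hypergeometric; the class probabilities are
#' sums of hypergeometric terms computed in log-gamma space.
#'
#' `prob_unobserved()` is the probability that no focal copy enters the
#' subsample, `C(n_total - n_focal, g) / C(n_total, g)`.
#'
#' `prob_rare()` is the probability of drawing at least 1 and at most
#' `kmax` focal copies, where `kmax = floor(z * n_total)` under the
#' full-sample threshold basis (the default) or `floor(z * g)` under the
#' subsample basis. The floor makes a type with frequency exactly `100z`%
#' rare rather than common.
#'
#' `prob_common()` is the complement `1 - prob_unobserved - prob_rare`,
#' clamped to `[0, 1]` against rounding.
#'
#' All three are vectorised over `n_focal`, `n_total` and `g`.
#'
#' @param n_focal Copies of the focal allelic type in the population sample
#'   (nonnegative integer, at most `n_total`).
#' @param n_total Total alleles sampled in the population (positive integer).
#' @param g Subsample size, `1 <= g <= n_total`.
#' @param scheme A [class_scheme()] in three-class mode.
#'
#' @return A probability (vectorised).
#' @examples
#' prob_unobserved(2, 4, 2)                 # 1/6
#' prob_rare(2, 4, 2, class_scheme(z = 0.25))   # 4/6
#' prob_common(2, 4, 2, class_scheme(z = 0.25)) # 1/6
#' @export
prob_unobserved <- function(n_focal, n_total, g) {
  check_counts(n_focal, n_total, g)
  out <- exp(lchoose(n_total - n_focal, g) - lchoose(n_total, g))
  clamp01(out)
}

#' @rdname prob_unobserved
#' @export
prob_rare <- function(n_focal, n_total, g, scheme = class_scheme()) {
  check_counts(n_focal, n_total, g)
  check_scheme(scheme, "three-class")
  kmax <- rare_kmax(scheme, n_total, g)
  hyper_range_prob(n_focal, n_total, g, k_lo = rep_len(1L, length(kmax)),
                   k_hi = kmax)
}

#' @rdname prob_unobserved
#' @export
prob_common <- function(n_focal, n_total, g, scheme = class_scheme()) {
  clamp01(1 - prob_unobserved(n_focal, n_total, g) -
            prob_rare(n_focal, n_total, g, scheme))
}

#' Probability that a subsampled allelic type lies in a frequency window
#'
#' Exact probability, under subsampling of `g` alleles without replacement,
#' that the focal allelic type's full-sample count corresponds to a
#' frequency inside the window `(z1, z2]` (default convention) or
#' `[z1, z2)`. The count k of the hypergeometric sum runs from
#' `floor(z1 * n_total) + 1` to `floor(z2 * n_total)` under the default
#' convention, or from `ceiling(z1 * n_total)` to
#' `ceiling(z2 * n_total) - 1` under the alternate one. A degenerate window
#' whose bounds floor to the same count has probability 0.
#'
#' @inheritParams prob_unobserved
#' @param z1,z2 Window bounds, `0 <= z1 < z2 <= 1`.
#' @param convention Boundary convention; see [class_scheme()].
#' @return A probability (vectorised over the count arguments).
#' @examples
#' prob_window(5, 20, 10, 0.05, 0.5)  # frequency in (5%, 50%]
#' @export
prob_window <- function(n_focal, n_total, g, z1, z2,
                        convention = c("lower-open-upper-closed",
                                       "lower-closed-upper-open")) {
  convention <- match.arg(convention)
  check_counts(n_focal, n_total, g)
  if (any(z1 < 0) || any(z2 > 1) || any(z1 >= z2)) {
    abort("Window bounds must satisfy 0 <= z1 < z2 <= 1.",
          class = "rp_window_error")
  }
  if (convention == "lower-open-upper-closed") {
    k_lo <- floor_bound(z1 * n_total) + 1L
    k_hi <- floor_bound(z2 * n_total)
  } else {
    k_lo <- ceil_bound(z1 * n_total)
    k_hi <- ceil_bound(z2 * n_total) - 1L
  }
  hyper_range_prob(n_focal, n_total, g, k_lo, k_hi)
}

#' Per-population class probabilities for every locus
#'
#' Applies the subsampling class probabilities to each population of each
#' locus in a counts table, returning a tidy table with one row per locus,
#' population, and frequency class. In three-class mode the classes are
#' `U`, `R`, `C`; in multi-window mode they are `U` plus one label per
#' frequency window.
#'
#' @param counts An [allele_counts()] table.
#' @param g Subsample size; must not exceed any population's total.
#' @param scheme A [class_scheme()].
#' @return A tibble with columns `chrom`, `pos`, `population`, `class`,
#'   `probability`. Per locus and population the probabilities sum to 1.
#' @examples
#' x <- allele_counts(data.frame(chrom = "1", pos = 100, ref = "A", alt = "T",
#'                               P1_minor = 2, P1_total = 4,
#'                               P2_minor = 3, P2_total = 6))
#' class_probabilities(x, g = 2, class_scheme(z = 0.25))
#' @export
class_probabilities <- function(counts, g, scheme = class_scheme()) {
  m <- count_matrices(counts)
  check_g(g, m$total)
  pops <- colnames(m$total)
  n <- nrow(m$total)
  probs <- class_prob_matrices(m$minor, m$total, g, scheme)
  purrr::imap(probs, function(mat, cls) {
    tibble::tibble(
      locus = rep(seq_len(n), times = length(pops)),
      chrom = rep(counts$chrom, times = length(pops)),
      pos = rep(counts$pos, times = length(pops)),
      population = rep(pops, each = n),
      class = cls,
      probability = as.vector(mat)
    )
  }) |>
    purrr::list_rbind() |>
    dplyr::mutate(
      population = factor(.data$population, levels = pops),
      class = factor(.data$class, levels = scheme$alphabet)
    ) |>
    dplyr::arrange(.data$locus, .data$population, .data$class) |>
    dplyr::select("chrom", "pos", "population", "class", "probability")
}

#' Rare-classification probability in an infinite population
#'
#' The binomial analogue of [prob_rare()] for a population of effectively
#' infinite size: the probability that an allelic type of true frequency
#' `freq` is observed in at least 1 and at most `floor(z * n)` copies in a
#' sample of `n` alleles, and hence classified rare. This quantifies how
#' sharply the rare/common call can depend on sample size: at the 5% cutoff
#' an allele of true frequency 5% is called rare with probability about
#' 0.278 in a sample of 39 alleles but about 0.548 in a sample of 40,
#' because the count bound floor(0.05 n) jumps from 1 to 2.
#'
#' @param freq True population frequency of the allelic type, in `[0, 1]`.
#' @param n Sample size (number of alleles drawn).
#' @param z Rare/common cutoff in (0, 1).
#' @return A probability (vectorised).
#' @examples
#' binomial_class_prob(0.05, 39, 0.05)
#' binomial_class_prob(0.05, 40, 0.05)
#' @export
binomial_class_prob <- function(freq, n, z = 0.05) {
  if (any(freq < 0) || any(freq > 1)) {
    abort("`freq` must lie in [0, 1].", class = "rp_counts_error")
  }
  if (any(n < 1)) abort("`n` must be >= 1.", class = "rp_counts_error")
  if (any(z <= 0) || any(z >= 1)) {
    abort("`z` must lie in (0, 1).", class = "rp_scheme_error")
  }
  args <- vctrs_recycle(freq = freq, n = n, z = z)
  purrr::pmap_dbl(args, function(freq, n, z) {
    kmax <- floor_bound(z * n)
    if (kmax < 1) return(0)
    sum(dbinom(seq_len(kmax), n, freq))
  })
}

# --- internals ---------------------------------------------------------

# P(k_lo <= K <= k_hi) for hypergeometric K, with binomial coefficients in
# log-gamma space. Vectorised over all count arguments by looping over the
# offset within the k range (ranges are short; panels are long); empty
# ranges give 0.
hyper_range_prob <- function(n_focal, n_total, g, k_lo, k_hi) {
  args <- vctrs_recycle(n_focal = n_focal, n_total = n_total, g = g,
                        k_lo = k_lo, k_hi = k_hi)
  n_focal <- args$n_focal; n_total <- args$n_total; g <- args$g
  lo <- pmax(args$k_lo, 0)
  hi <- pmin(args$k_hi, g, n_focal)
  out <- numeric(length(lo))
  width <- hi - lo
  if (any(width >= 0)) {
    denom <- lchoose(n_total, g)
    for (off in 0:max(width)) {
      act <- which(width >= off)
      k <- lo[act] + off
      out[act] <- out[act] +
        exp(lchoose(n_focal[act], k) +
              lchoose(n_total[act] - n_focal[act], g[act] - k) -
              denom[act])
    }
  }
  clamp01(out)
}

# U/R/C (or U/windows) probabilities for matrices of minor counts and
# totals: returns a list of matrices, one per class label, each n_loci x J
class_prob_matrices <- function(minor, total, g, scheme) {
  u <- exp(lchoose(total - minor, g) - lchoose(total, g))
  u <- clamp01(u)
  dim(u) <- dim(total)
  if (scheme$mode == "three-class") {
    kmax <- rare_kmax(scheme, total, g)
    r <- hyper_range_prob(as.vector(minor), as.vector(total), g,
                          1L, as.vector(kmax))
    dim(r) <- dim(total)
    out <- list(U = u, R = r, C = clamp01(1 - u - r))
  } else {
    b <- scheme$boundaries
    out <- vector("list", length(b))
    out[[1L]] <- u
    for (w in seq_len(length(b) - 1L)) {
      pw <- prob_window(as.vector(minor), as.vector(total), g,
                        b[w], b[w + 1L], scheme$boundary_convention)
      # keep the unobserved class separate: remove any k = 0 term that a
      # lower-closed window starting at 0 would otherwise absorb
      if (scheme$boundary_convention == "lower-closed-upper-open" &&
          b[w] == 0) {
        pw <- clamp01(pw - as.vector(u))
      }
      dim(pw) <- dim(total)
      out[[w + 1L]] <- pw
    }
    # under the (z1, z2] convention the top windows exclude frequency-1
    # counts only through the printed limits; any residual mass from the
    # k = n_total term of the last window is already included since
    # floor(1 * n_total) = n_total
    names(out) <- scheme$alphabet
    return(out)
  }
  names(out) <- scheme$alphabet
  out
}

check_counts <- function(n_focal, n_total, g) {
  if (any(n_focal < 0) || any(n_focal > n_total)) {
    abort("`n_focal` must satisfy 0 <= n_focal <= n_total.",
          class = "rp_counts_error")
  }
  if (any(g < 1)) {
    abort("Subsample size `g` must be at least 1.",
          class = "rp_subsample_error")
  }
  if (any(g > n_total)) {
    abort("Subsample size `g` exceeds the population sample size.",
          class = "rp_subsample_error")
  }
  invisible(TRUE)
}

check_g <- function(g, total) {
  if (length(g) != 1L || g < 1) {
    abort("`g` must be a single positive integer.",
          class = "rp_subsample_error")
  }
  bad <- which(total < g, arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    pop <- colnames(total)[bad[1L, 2L]]
    abort(sprintf(
      "g = %d exceeds the sample size %d of population '%s' at locus %d.",
      g, total[bad[1L, , drop = FALSE]], pop, bad[1L, 1L]),
      class = "rp_subsample_error")
  }
  invisible(TRUE)
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

# recycle arguments to a common length, tibble-style
vctrs_recycle <- function(...) {
  args <- list(...)
  n <- max(lengths(args))
  lapply(args, rep_len, length.out = n)
}
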
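#' Specification of a synthetic multi-population SNP panel
#'
#' Describes a panel of independent biallelic loci with controlled
#' frequency structure across J population groups, emulating the classes
#' of variation that drive geographic distribution patterns: loci fixed
#' for the major allele, singletons (one minor copy in one group),
#' low-frequency variants, variants straddling the rare/common boundary,
#' and globally common variants.
#'
#' For the non-singleton variable classes a global frequency is drawn for
#' each locus and per-group frequencies are dispersed around it with a
#' Balding–Nichols beta model with differentiation `f_st`; per-group minor
#' counts are then binomial. Realised counts whose unweighted mean
#' relative frequency across groups exceeds 1/2 are complemented, so the
#' tabulated type is always the globally minor allele.
#'
#' Default group sizes are allele counts of 1008, 808, 978, 1008 and 1206
#' — twice the 504/404/489/504/603 individuals of the five continental
#' super-populations of a modern whole-genome reference panel.
#'
#' @param n_loci Number of loci.
#' @param totals Named or unnamed vector of per-group allele totals N_j.
#' @param weights Mixture weights over the classes `zero`, `singleton`,
#'   `low`, `boundary`, `common`; must sum to 1.
#' @param z Rare/common cutoff the `boundary` class straddles.
#' @param f_st Balding–Nichols differentiation among groups.
#' @param low_shape Beta shape parameters for the low-frequency class.
#' @param common_shape Beta shape parameters for the common class
#'   (truncated to mean-minor frequencies below 1/2 by complementation).
#' @param chrom Chromosome label for the simulated loci.
#' @param pos_step Base-pair spacing of consecutive loci.
#' @param seed Integer seed; all randomness flows through it.
#' @return An object of class `panel_spec`.
#' @export
panel_spec <- function(n_loci = 1000,
                       totals = c(AFR = 1008, EUR = 808, SAS = 978,
                                  EAS = 1008, AMR = 1206),
                       weights = c(zero = 0, singleton = 0.30, low = 0.55,
                                   boundary = 0.05, common = 0.10),
                       z = 0.05, f_st = 0.1,
                       low_shape = c(0.5, 30), common_shape = c(2, 5),
                       chrom = "chrS", pos_step = 1000, seed = 1L) {
  need <- c("zero", "singleton", "low", "boundary", "common")
  if (!all(need %in% names(weights))) {
    weights <- setNames(rep_len(weights, 5L), need)
  }
  weights <- weights[need]
  if (abs(sum(weights) - 1) > 1e-9 || any(weights < 0)) {
    abort("Mixture `weights` must be nonnegative and sum to 1.",
          class = "rp_spec_error")
  }
  if (any(totals < 1)) {
    abort("Group totals must be >= 1.", class = "rp_spec_error")
  }
  if (is.null(names(totals))) {
    names(totals) <- paste0("P", seq_along(totals))
  }
  structure(list(n_loci = n_loci, totals = totals, weights = weights,
                 z = z, f_st = f_st, low_shape = low_shape,
                 common_shape = common_shape, chrom = chrom,
                 pos_step = pos_step, seed = seed),
            class = "panel_spec")
}

#' Simulate a synthetic allele counts panel
#'
#' Draws a locus panel from a [panel_spec()] mixture. Reproducible: the
#' same spec (including its seed) always yields the same panel.
#'
#' @param spec A [panel_spec()].
#' @return An [allele_counts()] table with `n_loci` rows and one
#'   `true_class` provenance column.
#' @export
simulate_panel <- function(spec) {
  stopifnot(inherits(spec, "panel_spec"))
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))
  set.seed(spec$seed)

  J <- length(spec$totals)
  n <- spec$n_loci
  totals <- matrix(rep(spec$totals, each = n), nrow = n,
                   dimnames = list(NULL, names(spec$totals)))
  cls <- sample(names(spec$weights), n, replace = TRUE, prob = spec$weights)
  minor <- matrix(0L, n, J, dimnames = list(NULL, names(spec$totals)))

  i_single <- which(cls == "singleton")
  if (length(i_single) > 0L) {
    grp <- sample.int(J, length(i_single), replace = TRUE,
                      prob = spec$totals / sum(spec$totals))
    minor[cbind(i_single, grp)] <- 1L
  }

  draw_counts <- function(idx, p_global) {
    if (length(idx) == 0L) return()
    a <- p_global * (1 - spec$f_st) / spec$f_st
    b <- (1 - p_global) * (1 - spec$f_st) / spec$f_st
    for (j in seq_len(J)) {
      pj <- rbeta(length(idx), a, b)
      minor[idx, j] <<- rbinom(length(idx), spec$totals[j], pj)
    }
  }
  i_low <- which(cls == "low")
  draw_counts(i_low, rbeta(length(i_low), spec$low_shape[1L],
                           spec$low_shape[2L]))
  i_bnd <- which(cls == "boundary")
  draw_counts(i_bnd, runif(length(i_bnd), max(spec$z - 0.02, 0.001),
                           spec$z + 0.02))
  i_com <- which(cls == "common")
  draw_counts(i_com, rbeta(length(i_com), spec$common_shape[1L],
                           spec$common_shape[2L]))

  # loci are SNPs: variable classes are conditioned on polymorphism, so
  # all-zero draws (possible for tiny frequencies) are redrawn
  redraw <- function(idx, p_fun) {
    repeat {
      idx <- idx[rowSums(minor[idx, , drop = FALSE]) == 0]
      if (length(idx) == 0L) break
      draw_counts(idx, p_fun(length(idx)))
    }
  }
  redraw(i_low, function(k) rbeta(k, spec$low_shape[1L], spec$low_shape[2L]))
  redraw(i_bnd, function(k) runif(k, max(spec$z - 0.02, 0.001),
                                  spec$z + 0.02))
  redraw(i_com, function(k) rbeta(k, spec$common_shape[1L],
                                  spec$common_shape[2L]))

  # tabulate the globally minor type: complement counts whose unweighted
  # mean relative frequency across groups exceeds 1/2
  flip <- rowMeans(minor / totals) > 0.5
  minor[flip, ] <- totals[flip, ] - minor[flip, ]

  out <- tibble::tibble(
    chrom = spec$chrom,
    pos = seq_len(n) * spec$pos_step,
    ref = "A", alt = "T", true_class = cls
  )
  for (j in seq_len(J)) {
    out[[paste0(names(spec$totals)[j], "_minor")]] <- as.integer(minor[, j])
    out[[paste0(names(spec$totals)[j], "_total")]] <- as.integer(totals[, j])
  }
  allele_counts(out, populations = names(spec$totals),
                filters = character(), seed = spec$seed)
}

#' Exhaustive subsampling distribution (enumeration oracle)
#'
#' Enumerates every one of the `C(n_total, g)` subsamples of size `g` and
#' tabulates the exact probability of each possible number of focal
#' copies. This brute-force construction is the independent reference
#' against which the closed-form hypergeometric class probabilities are
#' validated; it is guarded to `n_total <= 20` because the subset count
#' grows combinatorially.
#'
#' @param n_focal Focal copies in the sample.
#' @param n_total Total alleles in the sample (at most 20).
#' @param g Subsample size.
#' @return A tibble with columns `k` (focal copies in the subsample),
#'   `n_subsets` (exact integer count) and `probability`.
#' @examples
#' enumerate_subsample_distribution(2, 4, 2)
#' @export
enumerate_subsample_distribution <- function(n_focal, n_total, g) {
  if (n_total > 20) {
    abort("Exhaustive enumeration is limited to n_total <= 20.",
          class = "rp_size_error")
  }
  check_counts(n_focal, n_total, g)
  is_focal <- c(rep(TRUE, n_focal), rep(FALSE, n_total - n_focal))
  k_per_subset <- combn(n_total, g, FUN = function(i) sum(is_focal[i]))
  tab <- tabulate(k_per_subset + 1L, nbins = g + 1L)
  tibble::tibble(k = 0:g, n_subsets = tab,
                 probability = tab / length(k_per_subset))
}

#' Write a counts panel as a toy diploid VCF
#'
#' Packs per-group minor-allele counts into diploid genotypes so that
#' [extract_counts()] recovers the panel exactly. Each group contributes
#' `max(N_j) / 2` samples named `<group>_<i>`; loci where a group has
#' fewer called alleles than the group's sample count allows are padded
#' with fully missing genotypes. Group totals must be even. The focal
#' (minor) allelic type is written as REF or ALT so that the seeded
#' minor-allele designation of [extract_counts()] (same `seed`)
#' re-designates exactly the tabulated type, including at exact 50/50
#' frequency ties.
#'
#' @param counts An [allele_counts()] table.
#' @param path Optional output path; when `NULL` the VCF text is only
#'   returned.
#' @param seed Integer seed; must match the `seed` later given to
#'   [extract_counts()].
#' @return Character vector of VCF lines, invisibly when `path` is given.
#' @export
panel_to_vcf <- function(counts, path = NULL, seed = 1L) {
  m <- count_matrices(counts)
  if (any(m$total %% 2 != 0)) {
    abort("Diploid packing requires every group total to be even.",
          class = "rp_packing_error")
  }
  pops <- populations(counts)
  n_samples <- apply(m$total, 2L, max) / 2
  sample_names <- unlist(purrr::map2(pops, n_samples, function(p, k) {
    paste0(p, "_", seq_len(k))
  }))

  # decide REF/ALT orientation so that extract_counts(seed) designates the
  # focal type minor: focal goes to ALT except at exact 50/50 ties where
  # the seeded coin says the REF type will be called minor
  # groups with no called alleles are excluded from the mean frequency
  mean_freq <- rowMeans(m$minor / m$total, na.rm = TRUE)
  tie <- abs(mean_freq - 0.5) < 1e-12
  focal_is_alt <- rep(TRUE, nrow(counts))
  if (any(tie)) {
    focal_is_alt[tie] <- tie_break_coin(seed, sum(tie))
  }

  ref <- ifelse(focal_is_alt, counts$ref, counts$alt)
  alt <- ifelse(focal_is_alt, counts$alt, counts$ref)

  gt_line <- function(i) {
    cells <- purrr::map2(seq_along(pops), n_samples, function(j, k) {
      called_ind <- m$total[i, j] / 2
      copies <- m$minor[i, j]
      # focal copies packed two per individual, then a possible het
      n_hom <- copies %/% 2
      n_het <- copies %% 2
      focal_gt <- if (focal_is_alt[i]) c("1|1", "1|0", "0|0") else
        c("0|0", "0|1", "1|1")
      cell <- c(rep(focal_gt[1L], n_hom), rep(focal_gt[2L], n_het),
                rep(focal_gt[3L], called_ind - n_hom - n_het),
                rep(".|.", k - called_ind))
      cell
    })
    paste(c(counts$chrom[i], counts$pos[i], ".", ref[i], alt[i], ".",
            "PASS", ".", "GT", unlist(cells)), collapse = "\t")
  }

  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##source=rarepatterns synthetic panel (seed=%s)",
            format(seed)),
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample_names), collapse = "\t")
  )
  body <- purrr::map_chr(seq_len(nrow(counts)), gt_line)
  lines <- c(header, body)
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

#' Population map matching [panel_to_vcf()] sample names
#' @param counts The [allele_counts()] table passed to [panel_to_vcf()].
#' @return A `pop_map` for the toy VCF's samples.
#' @export
panel_sample_map <- function(counts) {
  m <- count_matrices(counts)
  pops <- populations(counts)
  n_samples <- apply(m$total, 2L, max) / 2
  population_map(
    sample = unlist(purrr::map2(pops, n_samples, function(p, k) {
      paste0(p, "_", seq_len(k))
    })),
    group = rep(pops, times = n_samples)
  )
}
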
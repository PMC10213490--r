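#' Read a sample-to-population map
#'
#' Reads a two-column TSV mapping sample identifiers to population group
#' labels. A header row is detected when the first line's fields look like
#' column names (e.g. `sample`, `group`, `pop`, `population`,
#' `super_pop`). Group order — which fixes the population order of every
#' downstream pattern — is the order of first appearance.
#'
#' @param path Path to the TSV file.
#' @return A tibble of class `pop_map` with columns `sample`, `group` and
#'   a `groups` attribute giving the ordered group labels.
#' @export
read_population_map <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  if (length(lines) == 0L) {
    abort("Population map is empty.", class = "rp_format_error")
  }
  fields <- strsplit(lines, "\t| +")
  if (any(lengths(fields) < 2L)) {
    bad <- which(lengths(fields) < 2L)[1L]
    abort(sprintf("Population map line %d does not have two columns.", bad),
          class = "rp_format_error")
  }
  header_words <- c("sample", "sample_id", "id", "group", "pop",
                    "population", "super_pop", "superpop")
  if (all(tolower(fields[[1L]][1:2]) %in% header_words)) {
    fields <- fields[-1L]
  }
  if (length(fields) == 0L) {
    abort("Population map contains no samples.", class = "rp_format_error")
  }
  df <- tibble::tibble(sample = purrr::map_chr(fields, 1L),
                       group = purrr::map_chr(fields, 2L))
  dup <- df |>
    dplyr::distinct() |>
    dplyr::count(.data$sample) |>
    dplyr::filter(.data$n > 1L)
  if (nrow(dup) > 0L) {
    abort(sprintf("Sample '%s' is mapped to more than one group.",
                  dup$sample[1L]), class = "rp_format_error")
  }
  df <- dplyr::distinct(df)
  new_pop_map(df)
}

new_pop_map <- function(df) {
  structure(df, groups = unique(df$group),
            class = c("pop_map", class(tibble::tibble())))
}

#' Construct a population map from vectors
#' @param sample Character vector of sample identifiers.
#' @param group Character vector of group labels (same length).
#' @return A `pop_map` tibble.
#' @export
population_map <- function(sample, group) {
  if (length(sample) != length(group) || length(sample) == 0L) {
    abort("`sample` and `group` must be nonempty vectors of equal length.",
          class = "rp_format_error")
  }
  if (anyDuplicated(sample)) {
    abort("Duplicate sample identifiers.", class = "rp_format_error")
  }
  new_pop_map(tibble::tibble(sample = as.character(sample),
                             group = as.character(group)))
}

#' Extract per-population minor-allele counts from a VCF
#'
#' Reads a multi-sample VCF, keeps biallelic SNPs (single-base REF and
#' ALT), counts called alleles per population group, designates the
#' globally minor allele — the allelic type whose unweighted mean relative
#' frequency across groups is below 1/2, with exact 50/50 ties resolved
#' by a seeded coin — and tabulates its per-group counts. Sites at which
#' any group has no called alleles are dropped.
#'
#' Each called allele of a genotype contributes 1 to the group total, so
#' haploid and half-missing diploid calls contribute their called alleles
#' only.
#'
#' @param vcf_path Path to a VCF file (plain text or bgzipped).
#' @param popmap A [population_map()] or [read_population_map()] result.
#' @param seed Integer seed for 50/50 minor-allele tie-breaks (required;
#'   recorded in the output's provenance).
#' @param unmapped_samples `"fail"` (default) to error when the VCF has
#'   samples absent from the map, `"skip"` to ignore them.
#' @return An [allele_counts()] table with a `minor_allele` column and a
#'   `log` attribute summarising skipped records.
#' @export
extract_counts <- function(vcf_path, popmap, seed,
                           unmapped_samples = c("fail", "skip")) {
  unmapped_samples <- match.arg(unmapped_samples)
  if (missing(seed) || !is.numeric(seed)) {
    abort("`seed` is required for reproducible minor-allele tie-breaks.",
          class = "rp_format_error")
  }
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  n_in <- nrow(fix)
  bases <- c("A", "C", "G", "T")
  snp <- fix[, "REF"] %in% bases & fix[, "ALT"] %in% bases
  n_not_snp <- sum(!snp)

  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = n_in)
  gt <- gt[snp, , drop = FALSE]
  fix <- fix[snp, , drop = FALSE]

  samples <- colnames(gt)
  unknown <- setdiff(samples, popmap$sample)
  if (length(unknown) > 0L) {
    if (unmapped_samples == "fail") {
      abort(sprintf("VCF sample(s) not in the population map: %s",
                    paste(head(unknown, 5L), collapse = ", ")),
            class = "rp_format_error")
    }
    gt <- gt[, !samples %in% unknown, drop = FALSE]
    samples <- colnames(gt)
  }
  groups <- attr(popmap, "groups")
  sample_group <- popmap$group[match(samples, popmap$sample)]

  # per-sample allele counts: number of '1' alleles and number of called
  # ('0' or '1') alleles in the GT string
  alt_copies <- nchar(gsub("[^1]", "", gt))
  called <- nchar(gsub("[^01]", "", gt))
  alt_copies[is.na(gt)] <- 0L
  called[is.na(gt)] <- 0L
  dim(alt_copies) <- dim(called) <- dim(gt)

  alt_by_group <- sapply(groups, function(grp) {
    cols <- which(sample_group == grp)
    rowSums(alt_copies[, cols, drop = FALSE])
  })
  tot_by_group <- sapply(groups, function(grp) {
    cols <- which(sample_group == grp)
    rowSums(called[, cols, drop = FALSE])
  })
  if (is.null(dim(alt_by_group))) {
    alt_by_group <- matrix(alt_by_group, nrow = nrow(gt))
    tot_by_group <- matrix(tot_by_group, nrow = nrow(gt))
    colnames(alt_by_group) <- colnames(tot_by_group) <- groups
  }

  keep <- rowSums(tot_by_group == 0) == 0
  n_missing_group <- sum(!keep)
  alt_by_group <- alt_by_group[keep, , drop = FALSE]
  tot_by_group <- tot_by_group[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]

  # globally minor allele: unweighted mean of per-group ALT frequencies
  mean_alt_freq <- rowMeans(alt_by_group / tot_by_group)
  tie <- abs(mean_alt_freq - 0.5) < 1e-12
  alt_is_minor <- mean_alt_freq < 0.5
  if (any(tie)) {
    alt_is_minor[tie] <- tie_break_coin(seed, sum(tie))
  }
  minor <- alt_by_group
  minor[!alt_is_minor, ] <- (tot_by_group - alt_by_group)[!alt_is_minor, ]

  out <- tibble::tibble(
    chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
    ref = fix[, "REF"], alt = fix[, "ALT"],
    minor_allele = ifelse(alt_is_minor, fix[, "ALT"], fix[, "REF"])
  )
  for (j in seq_along(groups)) {
    out[[paste0(groups[j], "_minor")]] <- as.integer(minor[, j])
    out[[paste0(groups[j], "_total")]] <- as.integer(tot_by_group[, j])
  }
  res <- allele_counts(out, populations = groups,
                       filters = c(
                         sprintf("non-biallelic-SNP records skipped: %d",
                                 n_not_snp),
                         sprintf("sites with a fully missing group: %d",
                                 n_missing_group)),
                       seed = seed)
  attr(res, "log") <- list(records_in = n_in, non_snp = n_not_snp,
                           fully_missing_group = n_missing_group,
                           ties = sum(tie))
  res
}

# deterministic coin sequence for 50/50 minor-allele ties: TRUE means the
# ALT (or focal) allelic type is designated minor
tie_break_coin <- function(seed, n) {
  if (n == 0L) return(logical(0))
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))
  set.seed(seed)
  runif(n) < 0.5
}

.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_set <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Designate the globally minor allelic type
#'
#' Given the focal allelic type's relative frequency in each population
#' group, decides whether the focal type is the globally minor allele:
#' minor means its unweighted mean frequency across groups is below 1/2.
#' An exact mean of 1/2 is resolved by a seeded coin.
#'
#' @param per_group_freqs Frequencies of the focal type, one per group
#'   with data.
#' @param seed Integer seed for the tie coin.
#' @return `"focal"` if the focal type is minor, otherwise `"other"`.
#' @export
determine_minor_allele <- function(per_group_freqs, seed) {
  if (any(per_group_freqs < 0) || any(per_group_freqs > 1)) {
    abort("Frequencies must lie in [0, 1].", class = "rp_counts_error")
  }
  m <- mean(per_group_freqs)
  if (abs(m - 0.5) < 1e-12) {
    if (tie_break_coin(seed, 1L)) "focal" else "other"
  } else if (m < 0.5) "focal" else "other"
}

#' Write / read an allele counts table
#'
#' TSV round trip for [allele_counts()] tables. The writer emits `#`
#' metadata lines recording the population order, applied filters and
#' tie-break seed, followed by a header and one row per locus. The reader
#' restores the table and its provenance; malformed rows raise an error
#' naming the offending line.
#'
#' @param counts An [allele_counts()] table.
#' @param path Output (or input) TSV path.
#' @return `write_counts()` returns `path` invisibly; `read_counts()`
#'   returns a `counts_tbl`.
#' @export
write_counts <- function(counts, path) {
  pops <- populations(counts)
  meta <- c(
    paste0("# populations=", paste(pops, collapse = ",")),
    paste0("# filters=", paste(attr(counts, "filters"), collapse = "; ")),
    paste0("# seed=", attr(counts, "seed") %||% "NA")
  )
  writeLines(meta, path)
  readr::write_tsv(tibble::as_tibble(counts), path, append = TRUE,
                   col_names = TRUE)
  invisible(path)
}

#' @rdname write_counts
#' @export
read_counts <- function(path) {
  lines <- readLines(path, n = 50L)
  meta <- grep("^# ", lines, value = TRUE)
  get_meta <- function(key) {
    m <- grep(paste0("^# ", key, "="), meta, value = TRUE)
    if (length(m) == 0L) return(NULL)
    sub(paste0("^# ", key, "="), "", m[1L])
  }
  pops <- get_meta("populations")
  pops <- if (is.null(pops)) NULL else strsplit(pops, ",")[[1L]]
  filters <- get_meta("filters")
  filters <- if (is.null(filters) || !nzchar(filters)) character() else
    strsplit(filters, "; ")[[1L]]
  seed <- get_meta("seed")
  seed <- if (is.null(seed) || seed == "NA") NULL else as.integer(seed)

  header <- grep("^# ", readLines(path), value = TRUE, invert = TRUE)[1L]
  cols <- strsplit(header, "\t")[[1L]]
  chr_cols <- intersect(cols, c("chrom", "ref", "alt", "minor_allele",
                                "true_class"))
  spec <- readr::cols(.default = readr::col_guess())
  spec$cols <- setNames(rep(list(readr::col_character()),
                            length(chr_cols)), chr_cols)
  df <- readr::read_tsv(path, comment = "# ", show_col_types = FALSE,
                        progress = FALSE, col_types = spec)
  probs <- readr::problems(df)
  if (nrow(probs) > 0L) {
    abort(sprintf("Malformed counts table at line %d: %s",
                  probs$row[1L], probs$expected[1L]),
          class = "rp_format_error")
  }
  required <- c("chrom", "pos", "ref", "alt")
  if (!all(required %in% names(df))) {
    abort(paste0("Counts table is missing column(s): ",
                 paste(setdiff(required, names(df)), collapse = ", ")),
          class = "rp_format_error")
  }
  allele_counts(df, populations = pops, filters = filters, seed = seed)
}
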
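# Small in-code fixtures shared across test files.

# a counts table built directly from per-population (minor, total) pairs
make_counts <- function(minor, total, pops = NULL, pos = NULL,
                        chrom = "chr1") {
  minor <- rbind(minor)
  total <- rbind(total)
  if (is.null(pops)) pops <- paste0("P", seq_len(ncol(minor)))
  if (is.null(pos)) pos <- seq_len(nrow(minor)) * 100L
  df <- data.frame(chrom = chrom, pos = pos, ref = "A", alt = "G")
  for (j in seq_along(pops)) {
    df[[paste0(pops[j], "_minor")]] <- minor[, j]
    df[[paste0(pops[j], "_total")]] <- total[, j]
  }
  allele_counts(df, populations = pops)
}

# class probabilities recomputed from the exhaustive enumeration oracle:
# P(subsample count falls in [k_lo, k_hi])
oracle_range_prob <- function(n_focal, n_total, g, k_lo, k_hi) {
  d <- enumerate_subsample_distribution(n_focal, n_total, g)
  sum(d$probability[d$k >= k_lo & d$k <= k_hi])
}

# U/R/C triple for one population from the oracle, full-sample basis
oracle_urc <- function(n_focal, n_total, g, z) {
  kmax <- floor(z * n_total + 1e-9)
  c(U = oracle_range_prob(n_focal, n_total, g, 0, 0),
    R = if (kmax >= 1) oracle_range_prob(n_focal, n_total, g, 1, kmax) else 0,
    C = if (kmax < g) oracle_range_prob(n_focal, n_total, g, kmax + 1, g)
        else 0)
}

# a tiny 5-sample diploid VCF written line by line
write_toy_vcf <- function(body_rows, samples, path = tempfile(".vcf")) {
  header <- c("##fileformat=VCFv4.2",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                      "FILTER", "INFO", "FORMAT", samples),
                    collapse = "\t"))
  writeLines(c(header, body_rows), path)
  path
}
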
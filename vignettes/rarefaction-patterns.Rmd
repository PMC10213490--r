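---
title: "Sample-size-corrected geographic distribution patterns of genetic variants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sample-size-corrected geographic distribution patterns of genetic variants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rarepatterns)
```

## The problem

Whether an allele is called *rare* or *common* — or seen at all — depends
on how many alleles were sampled. An allele with true frequency exactly
5% is classified rare (at most $\lfloor 0.05\,n \rfloor$ copies) with
probability about 0.278 in a sample of $n = 39$ alleles, but about 0.548
in a sample of $n = 40$, because the integer count bound jumps from 1 to
2:

```{r binomial-demo}
binomial_class_prob(0.05, c(39, 40), z = 0.05)
```

When populations are sampled at different depths, comparisons of where
variants are rare, common, or unobserved are therefore confounded by
sample size. This package removes the confound by *rarefaction*:
evaluating the classification over all subsamples of a fixed size $g$
drawn without replacement from each population.

## The model

Let a biallelic locus have $N_{j}$ sampled alleles in population $j$
($j = 1, \dots, J$), of which $N_{1j}$ carry the focal (globally minor)
allelic type. In a uniformly random subsample of $g$ alleles from
population $j$, the number of focal copies $K$ is hypergeometric, and

$$
U_{jg} = \frac{\binom{N_j - N_{1j}}{g}}{\binom{N_j}{g}}, \qquad
R_{jg} = \sum_{k=1}^{\lfloor z N_j \rfloor}
  \frac{\binom{N_{1j}}{k}\binom{N_j - N_{1j}}{g-k}}{\binom{N_j}{g}},
\qquad
C_{jg} = 1 - U_{jg} - R_{jg}
$$

are the exact probabilities that the type is unobserved, rare (nonzero
frequency at most $100z\%$), or common. The floor makes a type with
frequency exactly $100z\%$ rare. More generally, the probability that
the type's frequency lies in a window $(z_1, z_2]$ sums the same
hypergeometric terms for $k$ from $\lfloor z_1 N_j \rfloor + 1$ to
$\lfloor z_2 N_j \rfloor$; for $[z_1, z_2)$ windows the limits become
$\lceil z_1 N_j \rceil$ to $\lceil z_2 N_j \rceil - 1$
(`prob_window()`).

Because populations are subsampled independently, the probability that
the type has a *pattern* $x = (x_1, \dots, x_J)$ over the classes — for
example `RUUCU`, rare in population 1, common in population 4,
unobserved elsewhere — is the product $\prod_j f_{jg}(x_j)$ of the
per-population class probabilities selected by the letters
(`pattern_probability()`). With three classes and $J = 5$ populations
there are $3^5 = 243$ patterns. Averaging the per-locus pattern
distributions with equal weight across loci gives the expected pattern
distribution of a randomly chosen locus (`pattern_distribution()`),
and collapsing patterns by their letter counts gives the
$(|U|, |R|, |C|)$ summary triples, of which there are
$(J+1)(J+2)/2 = 21$ for $J = 5$ (`collapse_to_summary()`).

### Threshold basis

As printed above, the rare count bound $\lfloor z N_j \rfloor$ is taken
on the *full-sample* scale: the subsample inherits the full sample's
notion of which counts are rare. This is the default, and it is the
convention consistent with reading an all-rare pattern at small $g$ as
"exactly one copy seen in each population". A consequence is that when
$\lfloor z N_j \rfloor \ge g$ the common class is empty at that $g$
(every possible subsample count is rare). The alternative *subsample*
basis bounds rare counts by $\lfloor z g \rfloor$ instead, classifying
by frequency within the subsample; it is available as
`class_scheme(threshold_basis = "subsample")`. Neither is silently
substituted for the other.

## Tunable parameters

* `z` (default 0.05): maximal rare frequency, dimensionless; 5% is the
  conventional rare/common demarcation in population genomics.
* `g`: subsample size in alleles. The default grid,
  `default_g_grid()`, is every multiple of 10 in $[10, 500]$, capped at
  the panel's smallest population total — 500 alleles is 250 diploid
  individuals, a size all five continental reference groups exceed.
* `min_total` (default 500 alleles) in `filter_loci()`: loci must reach
  this sample size in every population so that all $g$ values on the
  grid are valid.
* `exclude_singletons`: drops loci whose minor allele occurs exactly
  once in the combined sample. Singletons dominate sequencing panels
  and can only ever be rare in one population, so scans and sweeps
  often run with and without them.
* `window_size` (default 100 kb): genomic window for scans; windows are
  0-based, half-open, and aligned to absolute multiples of the window
  size so that tiling does not depend on the data extent. A 1-based
  variant position $p$ falls in the window containing $p - 1$.

## What the synthetic generator emulates

`simulate_panel()` draws independent loci from a mixture of the classes
that drive geographic distribution patterns: singletons (one copy in
one group, chosen with probability proportional to group size),
low-frequency variants (global frequency Beta(0.5, 30)), variants
straddling the 5% boundary (uniform within ±0.02 of `z`), and globally
common variants (Beta(2, 5)). Per-group frequencies disperse around the
global frequency by a Balding–Nichols beta model with differentiation
$F_{st} = 0.1$, a typical continental-scale value; counts are binomial.
Default group totals are 1008, 808, 978, 1008 and 1206 alleles — twice
the 504/404/489/504/603 individuals of the five continental
super-populations of a modern whole-genome reference panel. Default
weights (singleton 0.30, low 0.55, boundary 0.05, common 0.10) make
rare-dominated pattern groups the most probable, with
common-everywhere next — the composition the method is designed to
exhibit. Variable classes are conditioned on polymorphism: all-zero
count draws are redrawn, since the panel emulates a SNP table. Tabulated
counts are complemented where needed so the focal type is always the
globally minor allele (unweighted mean frequency across groups at most
1/2).

The generator does *not* emulate linkage disequilibrium between loci,
demographic history, mutation-rate heterogeneity along the genome, or
genotyping error. Tests passing on these panels validate the
probability machinery and the scan plumbing, not any claim about real
demography.

## Numerical choices

* Binomial coefficients are computed in log-gamma space (`lchoose`)
  and exponentiated at the end, so population totals in the thousands
  cannot overflow; final probabilities are clamped to $[0, 1]$, and the
  common class is the complement $1 - U - R$ rather than a long
  alternating sum.
* Count bounds $\lfloor z N \rfloor$ and $\lceil z N \rceil$ are taken
  with a $10^{-9}$ guard (`floor(z * N + 1e-9)`) because products such
  as $0.29 \times 100$ land just below the intended integer in binary
  floating point.
* A degenerate frequency window whose bounds floor to the same count is
  an empty sum (probability 0), not an error; $g = 0$ is rejected.
* Argmax ties in `top_pattern_match_rate()` and rank ties in
  `rank_track()` are broken lexicographically (patterns under
  $U < R < C$; triples by $(|U|, |R|)$). The data carry no information
  to break such ties, so a deterministic convention is used.
* Minor-allele designation at an exact 50/50 mean frequency is resolved
  by a coin drawn from a caller-supplied seed, recorded in the output's
  provenance; `panel_to_vcf()` replays the same coin sequence so that
  extraction inverts packing exactly.
* The closed forms are validated against an exhaustive subset
  enumeration oracle (`enumerate_subsample_distribution()`) for every
  $n \le 12$, every focal count, and every $g$, to $10^{-12}$ absolute.

## Design choices

* Population order is fixed by the population map's group order and
  defines pattern string order; for five continental groups the
  conventional order is Africa, Europe, South Asia, East Asia,
  Americas.
* Locus averaging is unweighted — each SNP counts equally.
* "Minor" is defined by the unweighted mean of per-group relative
  frequencies (not the pooled count), so the designation does not
  depend on group sample sizes; groups with no called alleles are
  excluded from the mean.
* Partially missing genotypes contribute their called alleles to
  $N_j$; sites with a fully missing group are dropped.
* Summary triples are defined only for the three-class scheme;
  multi-window patterns are not improvised into triples.
* Empty windows are reported with `n_loci = 0` and `NA` probabilities
  rather than dropped, preserving genomic continuity in plots.
* Windows align to absolute coordinates rather than to the first
  variant, so tiling is reproducible across datasets.

## Problem sizes

The test suite validates the closed forms exhaustively at $n \le 12$,
and exercises sweeps, scans and round trips on panels of 30–10,000
loci; the largest single computation (a 50-value $g$ sweep over a
10,000-locus, five-population panel) takes well under a minute. The
acceptance script regenerates a 10,000-locus default panel and reports
the all-unobserved probability at the grid ends, match rates, and the
total-variation distance between the normalised corrected distribution
and the empirical pattern frequencies.

## Known limitations

* At any admissible subsample size ($g \le \min_j N_j$), the corrected
  pattern distribution is not expected to coincide with the empirical
  full-sample classification when group totals are unequal: a rare
  allele in a larger group retains non-vanishing probability of being
  missed in the subsample. The normalised corrected distribution
  therefore approaches, but does not match, empirical pattern
  frequencies — the residual distance is reported by the acceptance
  script rather than assumed away.
* Loci are treated as independent both in the generator and in the
  pattern probabilities; windows inherit whatever correlation real
  linkage induces.
* No variances or confidence intervals for the rarefaction estimates
  are provided, and multi-allelic sites are handled only by iterating
  the general formulas per allelic type.
* The exhaustive oracle is limited to $n \le 20$ by combinatorial
  growth; beyond that, validation relies on the hypergeometric
  cross-check.
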
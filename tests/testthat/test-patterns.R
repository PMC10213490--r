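test_that("pattern probabilities are products of per-population class terms", {
  s25 <- class_scheme(z = 0.25)
  x <- make_counts(minor = c(2, 3), total = c(4, 6))
  expect_equal(pattern_probability(x, 2, "RR", s25), (2 / 3) * 0.6,
               tolerance = 1e-12)
  # every letter combination agrees with the enumeration oracle product
  o1 <- oracle_urc(2, 4, 2, 0.25)
  o2 <- oracle_urc(3, 6, 2, 0.25)
  for (a in c("U", "R", "C")) {
    for (b in c("U", "R", "C")) {
      expect_equal(pattern_probability(x, 2, paste0(a, b), s25),
                   unname(o1[a] * o2[b]), tolerance = 1e-12)
    }
  }
  # single population: the pattern is the class itself
  x1 <- make_counts(minor = 2, total = 8)
  expect_equal(pattern_probability(x1, 3, "U"), prob_unobserved(2, 8, 3))
  # an absent type is all-unobserved with certainty
  x0 <- make_counts(minor = cbind(0, 0), total = cbind(6, 8))
  expect_equal(pattern_probability(x0, 2, "UU"), 1)
  expect_error(pattern_probability(x, 2, "RX", s25),
               class = "rp_pattern_error")
  expect_error(pattern_probability(x, 2, "R", s25),
               class = "rp_pattern_error")
})

test_that("the full pattern distribution spans K^J patterns and sums to 1", {
  x <- make_counts(minor = c(2, 3), total = c(6, 8))
  d <- pattern_distribution(x, 3)
  expect_equal(nrow(d), 9L)
  expect_equal(sum(d$probability), 1, tolerance = 1e-9)

  x5 <- make_counts(minor = c(1, 0, 2, 0, 3), total = rep(10, 5))
  d5 <- pattern_distribution(x5, 4)
  expect_equal(nrow(d5), 243L)
  expect_equal(sum(d5$probability), 1, tolerance = 1e-9)
  expect_equal(d5$pattern[1], "UUUUU")  # lexicographic, U < R < C

  # a singleton locus can only be U everywhere or R where its copy sits
  # (z = 0.25 keeps the rare class nonempty at N = 10)
  xs <- make_counts(minor = c(0, 1, 0), total = c(10, 10, 10))
  ds <- pattern_distribution(xs, 5, class_scheme(z = 0.25))
  nz <- ds$pattern[ds$probability > 1e-12]
  expect_setequal(nz, c("UUU", "URU"))
})

test_that("per-type and per-locus averaging are unweighted means", {
  expect_equal(average_over_types(c(0.2, 0.4)), 0.3)
  expect_equal(average_over_types(rep(0.17, 6)), 0.17)
  expect_error(average_over_types(numeric(0)),
               class = "rp_aggregation_error")

  # both allelic types of a biallelic locus, summed over the full pattern
  # space, give total mass 1 after type-averaging
  x <- make_counts(minor = c(3, 2), total = c(9, 6))
  y <- make_counts(minor = c(6, 4), total = c(9, 6))  # the other type
  d1 <- pattern_distribution(x, 3)
  d2 <- pattern_distribution(y, 3)
  expect_equal(sum(purrr::map2_dbl(d1$probability, d2$probability,
                                   ~ average_over_types(c(.x, .y)))),
               1, tolerance = 1e-9)

  d <- pattern_distribution(x, 3)
  expect_equal(average_over_loci(list(d, d))$probability, d$probability)
  # point masses average to an even split
  u <- make_counts(minor = cbind(0, 0), total = cbind(4, 4))
  cc <- make_counts(minor = cbind(4, 4), total = cbind(4, 4))
  du <- pattern_distribution(u, 4)
  dc <- pattern_distribution(cc, 4)
  avg <- average_over_loci(list(du, dc))
  expect_equal(avg$probability[avg$pattern == "UU"], 0.5)
  expect_equal(avg$probability[avg$pattern == "CC"], 0.5)

  # averaging many loci equals the independently recomputed mean
  pan <- simulate_panel(panel_spec(n_loci = 100,
                                   totals = c(A = 20, B = 26), seed = 3))
  per_locus <- purrr::map(seq_len(nrow(pan)), function(i) {
    pattern_distribution(pan[i, ], 8)
  })
  joint <- pattern_distribution(pan, 8)
  manual <- rowMeans(do.call(cbind, purrr::map(per_locus, "probability")))
  expect_equal(average_over_loci(per_locus)$probability, manual,
               tolerance = 1e-12)
  expect_equal(joint$probability, manual, tolerance = 1e-12)

  d_other_g <- pattern_distribution(x, 2)
  expect_error(average_over_loci(list(d, d_other_g)),
               class = "rp_aggregation_error")
})

test_that("summary triples partition the pattern space", {
  expect_equal(nrow(enumerate_summaries(5)), 21L)
  expect_equal(nrow(enumerate_summaries(1)), 3L)
  expect_equal(nrow(enumerate_summaries(2)), 6L)
  tri <- enumerate_summaries(5)
  expect_true(all(tri$n_unobserved + tri$n_rare + tri$n_common == 5))

  # "RUUUU" summarises as (4,1,0)
  x5 <- make_counts(minor = c(1, 0, 0, 0, 0), total = rep(40, 5))
  d5 <- pattern_distribution(x5, 10)
  s5 <- collapse_to_summary(d5)
  p_ruuuu <- d5$probability[d5$pattern == "RUUUU"]
  got <- s5$probability[s5$n_unobserved == 4 & s5$n_rare == 1]
  expect_equal(got, p_ruuuu)
  expect_equal(sum(s5$probability), sum(d5$probability), tolerance = 1e-12)

  # a uniform distribution over the 243 patterns collapses to multinomial
  # coefficients 5!/(a! b! c!) / 243
  uni <- rarepatterns:::new_pattern_dist(
    pattern_space(5), rep(1 / 243, 243), g = 10,
    populations = paste0("P", 1:5), n_loci = 1,
    alphabet = c("U", "R", "C"))
  su <- collapse_to_summary(uni)
  expected <- purrr::pmap_dbl(su[c("n_unobserved", "n_rare", "n_common")],
                              function(n_unobserved, n_rare, n_common) {
    factorial(5) / (factorial(n_unobserved) * factorial(n_rare) *
                      factorial(n_common)) / 243
  })
  expect_equal(su$probability, expected, tolerance = 1e-12)

  # all mass on the all-common pattern lands on (0, 0, J)
  xc <- make_counts(minor = cbind(4, 4), total = cbind(4, 4))
  sc <- collapse_to_summary(pattern_distribution(xc, 4))
  expect_equal(sc$probability[sc$n_common == 2], 1)
})

test_that("removing the all-unobserved pattern renormalises and is invertible", {
  d <- rarepatterns:::new_pattern_dist(
    c("UU", "RU", "CC"), c(0.5, 0.25, 0.25), g = 2,
    populations = c("A", "B"), n_loci = 1, alphabet = c("U", "R", "C"))
  nd <- drop_all_unobserved(d)
  expect_equal(nd$probability, c(0.5, 0.5))
  expect_false("UU" %in% nd$pattern)

  # reinserting P[all-U] recovers the input
  x <- make_counts(minor = c(1, 3), total = c(10, 12))
  full <- pattern_distribution(x, 6)
  norm <- drop_all_unobserved(full)
  p_u <- full$probability[full$pattern == "UU"]
  rebuilt <- c(p_u, norm$probability * (1 - p_u))
  expect_equal(rebuilt, full$probability, tolerance = 1e-12)

  # distributions with no all-U mass are unchanged
  xc <- make_counts(minor = cbind(4, 4), total = cbind(4, 4))
  dc <- pattern_distribution(xc, 4)
  expect_equal(drop_all_unobserved(dc)$probability,
               dc$probability[dc$pattern != "UU"])

  all_u <- rarepatterns:::new_pattern_dist(
    c("UU", "RU"), c(1, 0), g = 2, populations = c("A", "B"),
    n_loci = 1, alphabet = c("U", "R", "C"))
  expect_error(drop_all_unobserved(all_u), class = "rp_degenerate_error")
})

test_that("empirical classification uses the floor(z*N) bound per population", {
  # 1 copy of 39 is rare at z = 0.05 (floor(1.95) = 1); 2 of 40 is rare
  # (floor(2) = 2); 3 of 40 is common
  x <- make_counts(minor = c(1, 2, 3), total = c(39, 40, 40))
  expect_equal(empirical_pattern(x), c("RRC"))
  y <- make_counts(minor = rbind(c(0, 1), c(5, 0)),
                   total = rbind(c(39, 40), c(39, 40)))
  expect_equal(empirical_pattern(y), c("UR", "CU"))
})

test_that("top-pattern match rate has its degenerate and oracle behaviour", {
  # all-singleton panels match perfectly at any valid g
  spec <- panel_spec(n_loci = 60, totals = c(A = 30, B = 24, C = 40),
                     weights = c(zero = 0, singleton = 1, low = 0,
                                 boundary = 0, common = 0), seed = 2)
  singles <- simulate_panel(spec)
  for (g in c(2, 10, 24)) {
    expect_equal(top_pattern_match_rate(singles, g), 1)
  }

  # at g = N_j the corrected classification is the empirical one
  pan <- simulate_panel(panel_spec(n_loci = 80, totals = c(A = 30, B = 30),
                                   seed = 9))
  expect_equal(top_pattern_match_rate(pan, 30), 1)

  # brute-force argmax oracle over the explicit pattern space
  mixed <- simulate_panel(panel_spec(n_loci = 50,
                                     totals = c(A = 24, B = 36), seed = 4))
  g <- 6
  scheme <- class_scheme()
  pats <- pattern_space(2)
  pats <- pats[pats != "UU"]
  oracle_match <- mean(purrr::map_lgl(seq_len(nrow(mixed)), function(i) {
    probs <- purrr::map_dbl(pats, function(p) {
      pattern_probability(mixed[i, ], g, p, scheme)
    })
    pats[which.max(probs)] == empirical_pattern(mixed[i, ], scheme)
  }))
  expect_equal(top_pattern_match_rate(mixed, g), oracle_match)
  expect_error(top_pattern_match_rate(mixed[0, ], 5),
               class = "rp_aggregation_error")
})

test_that("match rate trends upward in g on smooth synthetic panels", {
  pan <- simulate_panel(panel_spec(n_loci = 400,
                                   totals = c(A = 100, B = 120, C = 90),
                                   seed = 8))
  mc <- match_curve(pan, c(10, 30, 60, 90))
  # monotone as a trend: final value above initial, no deep dips
  expect_gt(mc$match_rate[4], mc$match_rate[1])
  expect_true(all(diff(mc$match_rate) > -0.05))
})

test_that("argmax ties resolve to the lexicographically smallest pattern", {
  # one copy in each of two equal-sized groups: RU and UR are symmetric,
  # so their corrected probabilities tie exactly; RU wins under U < R < C
  x <- make_counts(minor = c(1, 1), total = c(20, 20))
  d <- pattern_distribution(x, 4)
  expect_equal(d$probability[d$pattern == "RU"],
               d$probability[d$pattern == "UR"], tolerance = 1e-12)
  m <- rarepatterns:::count_matrices(x)
  mat <- rarepatterns:::pattern_prob_matrix(m$minor, m$total, 4,
                                            class_scheme())
  mat[, colnames(mat) == "UU"] <- -Inf
  top <- colnames(mat)[max.col(mat, ties.method = "first")]
  expect_equal(top, "UR")
  # pattern space order puts U-first patterns ahead
  expect_lt(match("UR", colnames(mat)), match("RU", colnames(mat)))
})
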
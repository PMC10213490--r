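test_that("unobserved probability matches enumeration and closed form", {
  # absent type is never observed; omnipresent type always is
  expect_equal(prob_unobserved(0, 10, 5), 1)
  expect_equal(prob_unobserved(3, 3, 1), 0)
  # 2 focal copies among 4: exactly one of the 6 pairs omits both
  expect_equal(prob_unobserved(2, 4, 2), 1 / 6)
  # independent route: hypergeometric mass at zero
  for (n in c(7, 11)) {
    for (f in 0:n) {
      for (g in 1:n) {
        expect_equal(prob_unobserved(f, n, g), dhyper(0, f, n - f, g),
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("rare probability follows the floor(z*N) count bound", {
  s25 <- class_scheme(z = 0.25)
  # kmax = floor(0.25 * 4) = 1: 4 of the 6 pairs hold exactly one copy
  expect_equal(prob_rare(2, 4, 2, s25), 4 / 6)
  # kmax = floor(0.05 * 10) = 0: empty sum
  expect_equal(prob_rare(1, 10, 5, class_scheme(z = 0.05)), 0)
  # kmax = 1 at n_total = 20, z = 0.05: single k = 1 term
  expect_equal(prob_rare(5, 20, 10, class_scheme(z = 0.05)),
               choose(5, 1) * choose(15, 9) / choose(20, 10),
               tolerance = 1e-12)
  expect_equal(25025 / 184756, choose(5, 1) * choose(15, 9) / choose(20, 10))
})

test_that("subsample threshold basis bounds rare counts by floor(z*g)", {
  s <- class_scheme(z = 0.25, threshold_basis = "subsample")
  # g = 8, z = 0.25: kmax = 2 regardless of n_total
  expect_equal(prob_rare(5, 20, 8, s),
               oracle_range_prob(5, 20, 8, 1, 2), tolerance = 1e-12)
  # full-sample basis at same counts uses kmax = floor(0.25*20) = 5
  expect_equal(prob_rare(5, 20, 8, class_scheme(z = 0.25)),
               oracle_range_prob(5, 20, 8, 1, 5), tolerance = 1e-12)
})

test_that("the three class probabilities sum to one and common is their complement", {
  s <- class_scheme(z = 0.05)
  expect_equal(prob_common(2, 4, 2, class_scheme(z = 0.25)), 1 / 6)
  expect_equal(prob_common(1, 10, 5, s), 1 - 126 / 252)
  expect_equal(prob_common(0, 8, 4, s), 0)
  for (n in c(5, 9, 13, 40)) {
    for (f in c(0, 1, n %/% 3, n)) {
      for (g in c(1, n %/% 2, n)) {
        u <- prob_unobserved(f, n, g)
        r <- prob_rare(f, n, g, s)
        cc <- prob_common(f, n, g, s)
        expect_equal(u + r + cc, 1, tolerance = 1e-9)
        expect_true(all(c(u, r, cc) >= 0 & c(u, r, cc) <= 1))
      }
    }
  }
})

test_that("unobserved probability is nonincreasing in g", {
  for (n in c(6, 12, 30)) {
    for (f in c(1, 2, n %/% 4)) {
      u <- prob_unobserved(f, n, 1:n)
      expect_true(all(diff(u) <= 1e-12))
    }
  }
})

test_that("frequency-window probability matches its printed sum limits", {
  # k from floor(.05*20)+1 = 2 to floor(.5*20) = 10
  expect_equal(prob_window(5, 20, 10, 0.05, 0.5),
               oracle_range_prob(5, 20, 10, 2, 10), tolerance = 1e-12)
  expect_equal(prob_window(5, 20, 10, 0.05, 0.5), 156728 / 184756,
               tolerance = 1e-9)
  # the (0, z] window coincides with the rare class
  expect_equal(prob_window(5, 20, 10, 0, 0.05),
               prob_rare(5, 20, 10, class_scheme(z = 0.05)),
               tolerance = 1e-12)
  # the whole interval captures every nonzero count
  for (f in c(0, 3, 9)) {
    expect_equal(prob_window(f, 12, 6, 0, 1),
                 1 - prob_unobserved(f, 12, 6), tolerance = 1e-12)
  }
  # degenerate window (same floored bound) is an empty sum, not an error
  expect_equal(prob_window(5, 20, 10, 0.26, 0.29), 0)
})

test_that("window probabilities over a partition complete the unit mass", {
  cuts <- c(0, 0.07, 0.33, 0.62, 1)
  for (f in c(0, 1, 4, 11, 15)) {
    p <- sum(purrr::map_dbl(seq_len(length(cuts) - 1), function(w) {
      prob_window(f, 15, 7, cuts[w], cuts[w + 1])
    }))
    expect_equal(p + prob_unobserved(f, 15, 7), 1, tolerance = 1e-9)
  }
})

test_that("the lower-closed-upper-open convention uses ceiling limits", {
  # [z1, z2) with z1 = 0.1, n = 20: k from ceil(2) = 2 to ceil(0.5*20)-1 = 9
  expect_equal(
    prob_window(6, 20, 10, 0.1, 0.5,
                convention = "lower-closed-upper-open"),
    oracle_range_prob(6, 20, 10, 2, 9), tolerance = 1e-12)
  # exact boundary: frequency z sits in the upper window under [z1, z2)
  # but in the lower window under (z1, z2]
  expect_equal(prob_window(4, 20, 10, 0.2, 0.5),
               oracle_range_prob(4, 20, 10, 5, 10), tolerance = 1e-12)
  expect_equal(prob_window(4, 20, 10, 0.2, 0.5,
                           convention = "lower-closed-upper-open"),
               oracle_range_prob(4, 20, 10, 4, 9), tolerance = 1e-12)
})

test_that("floored count bounds are robust to binary representation of z*N", {
  # 0.29 * 100 sits just below 29 in double precision
  expect_equal(prob_rare(30, 100, 50, class_scheme(z = 0.29)),
               oracle_p <- sum(dhyper(1:29, 30, 70, 50)), tolerance = 1e-12)
})

test_that("invalid counts, subsample sizes, and windows are rejected", {
  expect_error(prob_unobserved(5, 4, 2), class = "rp_counts_error")
  expect_error(prob_unobserved(2, 4, 5), class = "rp_subsample_error")
  expect_error(prob_unobserved(2, 4, 0), class = "rp_subsample_error")
  expect_error(prob_window(2, 4, 2, 0.5, 0.5), class = "rp_window_error")
  expect_error(prob_window(2, 4, 2, 0.6, 0.2), class = "rp_window_error")
  expect_error(class_scheme(z = 0), class = "rp_scheme_error")
  expect_error(class_scheme(boundaries = c(0, 0.5)),
               class = "rp_scheme_error")
})

test_that("per-locus class distributions are exact and degenerate correctly", {
  s25 <- class_scheme(z = 0.25)
  x <- make_counts(minor = c(2, 3), total = c(4, 6))
  cp <- class_probabilities(x, g = 2, s25)
  p1 <- cp$probability[cp$population == "P1"]
  p2 <- cp$probability[cp$population == "P2"]
  expect_equal(p1, unname(oracle_urc(2, 4, 2, 0.25)), tolerance = 1e-12)
  expect_equal(p2, unname(oracle_urc(3, 6, 2, 0.25)), tolerance = 1e-12)
  expect_equal(p2, c(0.2, 0.6, 0.2), tolerance = 1e-12)

  # g equal to the full sample size: indicator of the empirical class
  y <- make_counts(minor = c(0, 1, 9), total = c(12, 12, 12))
  cpN <- class_probabilities(y, g = 12, class_scheme(z = 0.1))
  probs <- matrix(cpN$probability, ncol = 3, byrow = TRUE)
  expect_equal(probs, rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
               tolerance = 1e-9, ignore_attr = TRUE)

  # an absent type is unobserved with certainty in every population
  z <- make_counts(minor = cbind(0, 0), total = cbind(10, 14))
  cp0 <- class_probabilities(z, g = 5)
  expect_equal(cp0$probability[cp0$class == "U"], c(1, 1))

  # g exceeding a population's sample size names the population
  expect_error(class_probabilities(x, g = 5), regexp = "P1",
               class = "rp_subsample_error")
})

test_that("multi-window schemes give a full class vector per population", {
  s <- class_scheme(boundaries = c(0, 0.1, 0.5, 1))
  x <- make_counts(minor = 4, total = 12)
  cp <- class_probabilities(x, g = 6, s)
  expect_equal(sum(cp$probability), 1, tolerance = 1e-9)
  expect_equal(as.character(unique(cp$class)), c("U", "W1", "W2", "W3"))
  # each window agrees with prob_window
  expect_equal(cp$probability[cp$class == "W2"],
               prob_window(4, 12, 6, 0.1, 0.5), tolerance = 1e-12)
})

test_that("biallelic complement-count formulation is numerically identical", {
  # with two allelic types the unobserved probability can be written with
  # the other type's count in the numerator; both routes must agree
  for (n in c(10, 25)) {
    for (f in c(0, 1, 5, n)) {
      for (g in c(1, 5, n %/% 2)) {
        n2 <- n - f
        expect_identical(prob_unobserved(f, n, g),
                         clamp <- exp(lchoose(n2, g) - lchoose(n, g)))
      }
    }
  }
})

test_that("binomial rare-classification demo reproduces the sample-size jump", {
  expect_equal(binomial_class_prob(0.05, 39, 0.05), 0.278, tolerance = 2e-3)
  expect_equal(binomial_class_prob(0.05, 40, 0.05), 0.548, tolerance = 2e-3)
  expect_equal(binomial_class_prob(0, 40, 0.05), 0)
  # closed form for n = 39: only the k = 1 term
  expect_equal(binomial_class_prob(0.05, 39, 0.05),
               39 * 0.05 * 0.95^38, tolerance = 1e-12)
})
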
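test_that("plug-in Hill numbers match closed forms", {
  expect_equal(hill_number(c(1, 1, 1, 1), q = 1), 4)
  expect_equal(hill_number(rep(1, 5), q = 0), 5)
  # H = -(1/2 log 1/2 + 2 * 1/4 log 1/4)
  expect_equal(hill_number(c(2, 1, 1), q = 1),
               exp(-(0.5 * log(0.5) + 0.5 * log(0.25))), tolerance = 1e-12)
  expect_error(hill_number(integer(0)), "empty")
})

test_that("interpolation matches exhaustive enumeration (n <= 10)", {
  # independent oracle: average over all C(n, m) subsamples
  for (n in c(4, 7, 10)) {
    for (x in all_abundance_vectors(n, 5)) {
      for (m in seq_len(n)) {
        oracle <- enum_subsample_oracle(x, m)
        expect_equal(rarefied_richness(x, m), oracle$richness,
                     tolerance = 1e-9)
        sh <- rarefied_shannon_hill(x, m, mode = "exact")
        expect_equal(sh$H, oracle$entropy, tolerance = 1e-9)
        expect_equal(sh$D, exp(oracle$entropy), tolerance = 1e-9)
      }
    }
  }
})

test_that("worked interpolation examples hold", {
  expect_equal(rarefied_richness(c(1, 1, 1), 1), 1)
  expect_equal(rarefied_richness(c(3, 2), 5), 2)
  expect_equal(rarefied_richness(c(2, 2), 2), 5 / 3)   # 6 subsamples, 4 mixed
  sh <- rarefied_shannon_hill(c(2, 2), 2, mode = "exact")
  expect_equal(sh$H, (4 / 6) * log(2), tolerance = 1e-12)
  expect_equal(rarefied_shannon_hill(c(1, 1), 2, mode = "exact")$D, 2)
  expect_equal(rarefied_shannon_hill(c(5, 5), 10, mode = "exact")$D, 2,
               tolerance = 1e-12)
  expect_error(rarefied_richness(c(2, 2), 5), "m")
  expect_error(rarefied_shannon_hill(c(2, 2), 5), "outside")
})

test_that("rarefied richness agrees with vegan's rarefy", {
  skip_if_not_installed("vegan")
  set.seed(9)
  for (i in 1:5) {
    x <- sample(1:30, 12, replace = TRUE)
    m <- sample(seq_len(sum(x) - 1), 1)
    expect_equal(rarefied_richness(x, m),
                 as.numeric(suppressWarnings(vegan::rarefy(x, m))),
                 tolerance = 1e-8)
  }
})

test_that("Monte-Carlo mode agrees with exact within its error", {
  x <- c(40, 20, 10, 5, 5, 2, 1, 1)
  ex <- rarefied_shannon_hill(x, 30, mode = "exact")
  mc <- rarefied_shannon_hill(x, 30, mode = "monte_carlo",
                              n_draws = 4000, seed = 5)
  expect_lt(abs(mc$H - ex$H), 0.03)
})

test_that("extrapolated richness follows the unseen-clone estimate", {
  # no singletons -> sample treated as complete
  expect_equal(extrapolate_richness(c(2, 3, 4), c(0, 10, 1e6)),
               rep(3, 3))
  x <- c(2, 1, 1, 1)  # n = 5, f1 = 3, f2 = 1: f0 = (4/5)*9/2 = 3.6
  expect_equal(extrapolate_richness(x, 0), 4)
  x2 <- c(3, 1, 1)    # n = 5, f1 = 2, f2 = 0: f0 = (4/5)*2*1/2 = 0.8
  fc_limit <- extrapolate_richness(x2, 1e9)
  expect_equal(fc_limit, 3 + 0.8, tolerance = 1e-6)
  # f1 = 2, f2 = 1 (n = 4): f0 = (3/4) * 4/2 = 1.5; limit S_obs + f0
  x3 <- c(2, 1, 1)
  expect_equal(extrapolate_richness(x3, 1e9), 3 + 1.5, tolerance = 1e-6)
  expect_true(all(diff(extrapolate_richness(x, 0:50)) >= 0))
})

test_that("bootstrap assemblage reproduces the worked coverage example", {
  # x = [4,2,1,1]: n = 8, f1 = 2, f2 = 1
  asm <- build_bootstrap_assemblage(c(4, 2, 1, 1))
  expect_equal(asm$coverage, 1 - (2 / 8) * (14 / 16))   # 0.78125
  expect_equal(asm$n_unseen, 2L)                        # ceil(1.75)
  expect_equal(asm$n_unseen * asm$p_unseen, 1 - 0.78125)
  expect_equal(sum(asm$p_hat) + asm$n_unseen * asm$p_unseen, 1,
               tolerance = 1e-9)
  # single clone: complete coverage, no unseen mass
  one <- build_bootstrap_assemblage(c(7))
  expect_equal(one$p_hat, 1)
  expect_equal(one$n_unseen, 0L)
  expect_equal(one$coverage, 1)
})

test_that("assemblage probabilities always sum to one (property)", {
  set.seed(31)
  for (i in 1:50) {
    x <- sample(1:20, sample(2:30, 1), replace = TRUE)
    asm <- suppressWarnings(build_bootstrap_assemblage(x))
    expect_equal(sum(asm$p_hat) + asm$n_unseen * asm$p_unseen, 1,
                 tolerance = 1e-9)
    expect_true(all(asm$p_hat >= 0))
  }
  # degenerate case falls back with a warning
  expect_warning(build_bootstrap_assemblage(c(1)), "degenerate")
})

test_that("bootstrap estimates are seeded and reproducible", {
  x <- c(30, 20, 10, 5, 3, 2, 1, 1, 1)
  spec <- rarefaction_spec(q = 1, m = 50, B = 50, seed = 17)
  a <- bootstrap_diversity(x, spec)
  b <- bootstrap_diversity(x, spec)
  expect_identical(a$replicate_values, b$replicate_values)
  expect_equal(length(a$replicate_values), 50)
  expect_lte(a$ci_low, a$estimate)
  expect_gte(a$ci_high, a$estimate)
  expect_equal(a$estimate, exp(a$H))
  expect_error(rarefaction_spec(B = 1), "at least 2")
  expect_error(bootstrap_diversity(c(2, 2), rarefaction_spec(m = 10)),
               "exceeds")
})

test_that("CI contains the truth for a deep uniform census (q = 0)", {
  x <- rep(10, 100)
  est <- bootstrap_diversity(x, rarefaction_spec(q = 0, m = sum(x), B = 50,
                                                 seed = 2))
  expect_lte(est$ci_low, 100)
  expect_gte(est$ci_high, 100)
})

test_that("fixed-point comparison is symmetric-safe and detects truth", {
  x <- c(40, 30, 20, 10, 5, 5)
  same <- compare_diversity_at_point(x, x,
                                     rarefaction_spec(q = 1, m = 50, B = 50,
                                                      seed = 4))
  expect_equal(same$mean_a, same$mean_b)
  expect_equal(same$p_value, 1, tolerance = 1e-9)
  expect_error(
    compare_diversity_at_point(c(2, 1), x,
                               rarefaction_spec(m = 50, B = 10)),
    "sample a")
})

test_that("D50 uses the smallest top-clone prefix reaching half the chains", {
  u <- d50(rep(1, 10))
  expect_equal(u$k, 5L)
  expect_equal(u$normalized, 0.5)
  expect_equal(d50(c(5, 3, 1, 1))$k, 1L)       # 5 >= 10/2
  expect_equal(d50(c(5, 3, 1, 1))$normalized, 0.25)
  expect_equal(d50(c(4, 3, 2, 1))$k, 2L)       # 4+3 = 7 >= 5
  expect_equal(d50(c(4, 3, 2, 1))$normalized, 0.5)
  # duplicating every count leaves normalized D50 unchanged
  set.seed(8)
  for (i in 1:20) {
    x <- sample(1:50, sample(3:20, 1), replace = TRUE)
    expect_equal(d50(x)$normalized, d50(2 * x)$normalized)
  }
})

test_that("diversity curves are monotone and anchored at the census", {
  set.seed(13)
  for (i in 1:10) {
    x <- sample(1:15, sample(3:12, 1), replace = TRUE)
    for (q in c(0, 1)) {
      cv <- diversity_curve(x, q = q, knots = 12, B = 0)
      expect_true(all(diff(cv$estimate) >= -1e-9))
      at_n <- cv$estimate[cv$method == "observed"]
      expect_equal(at_n, diversity_at_size(x, sum(x), q = q),
                   tolerance = 1e-9)
      if (q == 0) expect_equal(at_n, length(x))
    }
  }
  flat <- diversity_curve(c(6), q = 0, knots = 5, B = 0)
  expect_true(all(flat$estimate == 1))
})

test_that("richness dominates exponential Shannon along the curve", {
  x <- c(12, 7, 4, 2, 1, 1)
  for (m in c(1, 3, 9, sum(x))) {
    expect_gte(rarefied_richness(x, m) + 1e-9,
               rarefied_shannon_hill(x, m, mode = "exact")$D)
  }
  # equality at the census for a uniform vector
  u <- rep(4, 6)
  expect_equal(rarefied_richness(u, sum(u)),
               rarefied_shannon_hill(u, sum(u), mode = "exact")$D,
               tolerance = 1e-9)
})

test_that("q = 1 extrapolation approaches the asymptotic estimator", {
  set.seed(21)
  p <- zipf_frequencies(60, 0.8)
  x <- as.numeric(stats::rmultinom(1, 400, p))
  x <- x[x > 0]
  d_n <- diversity_at_size(x, sum(x), q = 1)
  d_far <- diversity_at_size(x, 20 * sum(x), q = 1)
  expect_gte(d_far, d_n)
  true_d1 <- exp(-sum(p * log(p)))
  # the asymptotic blend should land nearer the truth than the plug-in
  expect_lt(abs(d_far - true_d1), abs(d_n - true_d1) + 2)
})
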
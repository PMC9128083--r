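# Validation mathematics: expected mixture VAFs, error rate, ICC,
# concordance, and cross-platform comparison.

test_that("expected mixture VAF is the dosage-weighted proportion mean", {
  mix <- five_line_mixture()
  # het only in the 0.25% line: the smallest nonzero expected VAF
  expect_equal(expected_mixture_vaf(mix, c(0, 0, 0, 0, 1)), 0.00125,
               tolerance = 1e-3)
  # hom in every line: 100%
  expect_equal(expected_mixture_vaf(mix, c(2, 2, 2, 2, 2)), 1,
               tolerance = 1e-12)
  # het everywhere: 50% (proportions sum to 1)
  expect_equal(expected_mixture_vaf(mix, c(1, 1, 1, 1, 1)), 0.5,
               tolerance = 1e-12)
  expect_error(expected_mixture_vaf(mix, c(3, 0, 0, 0, 0)), "\\{0, 1, 2\\}")

  # linear in dosage, bounded in [0, 1]; minimum nonzero = min(p) / 2
  all_cfg <- enumerate_mixture_vafs(mix)
  expect_true(all(all_cfg$expected_vaf >= 0 & all_cfg$expected_vaf <= 1))
  expect_equal(min(all_cfg$expected_vaf), min(mix$proportions) / 2,
               tolerance = 1e-12)
  set.seed(10)
  for (i in 1:10) {
    d1 <- sample(0:1, 5, TRUE); d2 <- sample(0:1, 5, TRUE)
    expect_equal(expected_mixture_vaf(mix, d1 + d2),
                 expected_mixture_vaf(mix, d1) + expected_mixture_vaf(mix, d2),
                 tolerance = 1e-12)
  }
})

test_that("error rate is pooled over reads, not averaged over sites", {
  est <- estimate_error_rate(45, 100000)
  expect_equal(est$rate, 0.00045, tolerance = 1e-15)
  expect_equal(est$one_in_bp, 1 / 0.00045, tolerance = 1e-9)
  expect_equal(estimate_error_rate(0, 5000)$rate, 0)
  # pooling vs averaging: (10 + 0) / 20000, not mean(1e-3, 0)
  est <- estimate_error_rate(c(10, 0), c(10000, 10000))
  expect_equal(est$rate, 0.0005, tolerance = 1e-15)
  expect_equal(est$per_site, c(0.001, 0))
  # partition invariance
  set.seed(20)
  counts <- rpois(30, 2); depths <- rep(5000, 30)
  whole <- estimate_error_rate(counts, depths)$rate
  grp <- sample(1:3, 30, TRUE)
  merged <- estimate_error_rate(tapply(counts, grp, sum),
                                tapply(depths, grp, sum))$rate
  expect_equal(whole, merged, tolerance = 1e-15)
  expect_error(estimate_error_rate(numeric(0), numeric(0)), "positive")
})

test_that("ICC(1) matches a brute-force ANOVA decomposition", {
  set.seed(30)
  for (i in 1:12) {
    mat <- matrix(rnorm(20, rep(rnorm(5, 0, 2), each = 4), 0.5), 5, 4,
                  byrow = TRUE)
    expect_equal(icc(mat)$icc, oracle_icc_anova(mat), tolerance = 1e-10)
  }
  # identical columns: perfect reliability
  mat <- matrix(rep(c(0.1, 0.2, 0.5, 0.9), 4), 4, 4)
  expect_equal(icc(mat)$icc, 1)
  # no between-site variance: ICC <= 0, reported as computed
  set.seed(31)
  mat <- matrix(rnorm(20, 5, 1), 5, 4)
  mat <- mat - rowMeans(mat) + 5    # rows share the same mean exactly
  expect_lte(icc(mat)$icc, 0)
  expect_error(icc(matrix(1, 3, 3)), "zero total variance")
  expect_error(icc(matrix(1:3, 3, 1)), ">= 2")
  # CI brackets the estimate
  set.seed(32)
  mat <- matrix(rnorm(40, rep(rnorm(10, 0, 3), each = 4), 0.3), 10, 4,
                byrow = TRUE)
  r <- icc(mat)
  expect_lt(r$ci[1], r$icc); expect_gt(r$ci[2], r$icc)
})

test_that("replicate mixture reliability reaches reported levels", {
  set.seed(33)
  ev <- 10^runif(40, log10(0.00125), 0)
  mat <- t(vapply(ev, function(v)
    simulate_site_reads(rep(v, 27), rep(2803L, 27), 0.00045) / 2803,
    numeric(27)))
  expect_gte(icc(mat)$icc, 0.998)
})

test_that("concordance matches two-pass Pearson and stratifies at the split", {
  set.seed(40)
  ev <- c(0.00125, 0.005, 0.01, 0.02, 0.05, 0.25, 0.5, 1)
  obs <- ev * (1 + rnorm(8, 0, 0.02))
  cc <- concordance(obs, ev)
  expect_equal(cc$r_overall, oracle_pearson(obs, ev), tolerance = 1e-12)
  expect_identical(cc$n_low, 4L)
  expect_equal(cc$r_low, oracle_pearson(obs[ev <= 0.02], ev[ev <= 0.02]),
               tolerance = 1e-12)
  # identical vectors and scale invariance
  expect_equal(concordance(ev, ev)$r_overall, 1, tolerance = 1e-12)
  expect_equal(concordance(2 * ev, ev)$r_overall, 1, tolerance = 1e-12)
  # exact linear inverse -> r = -1
  expect_equal(concordance(1 - ev, ev)$r_overall, -1, tolerance = 1e-12)
  # zero-variance stratum undefined
  cc <- concordance(rep(0.5, 4), c(0.01, 0.02, 0.3, 0.4), split_at = 0.02)
  expect_true(is.na(cc$r_overall))
  expect_error(concordance(1:2, 1:3), "equal-length")
})

test_that("platform comparison reports sensitivity and shared-VAF correlation", {
  ref <- data.frame(subject_id = rep("S1", 81),
                    variant_id = paste0("v", 1:81),
                    vaf = seq(0.02, 0.42, length.out = 81))
  panel <- ref[1:75, ]
  panel$vaf <- panel$vaf * 1.05
  res <- platform_comparison(panel, ref)
  expect_equal(res$sensitivity, 75 / 81, tolerance = 1e-12)
  expect_identical(res$n_shared, 75L)
  expect_gt(res$r, 0.99)
  # identical sets: sensitivity 1; disjoint: 0
  expect_equal(platform_comparison(ref, ref)$sensitivity, 1)
  other <- ref; other$variant_id <- paste0("w", 1:81)
  expect_equal(platform_comparison(other, ref)$sensitivity, 0)
  expect_error(platform_comparison(panel, ref[0, ]), "empty")
})
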
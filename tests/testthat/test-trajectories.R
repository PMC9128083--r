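# Trajectory assembly rules, dominant-clone selection, competition, and
# the gene-group statistics.

mk_obs <- function(subject, variant, gene, timepoints, vafs, depths,
                   alts = NULL) {
  alts <- alts %||% round(vafs * depths)
  data.frame(subject_id = subject, variant_id = variant, gene = gene,
             timepoint = timepoints, depth = depths, alt_count = alts,
             vaf = alts / depths, stringsAsFactors = FALSE)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

mk_manifest <- function(subject, timepoints, ages) {
  data.frame(subject_id = subject, timepoint = timepoints, age = ages)
}

test_that("assembly enforces the timepoint, peak-VAF and depth rules", {
  manifest <- rbind(
    mk_manifest("A", 1:3, c(60, 63, 66)),
    mk_manifest("B", 1:2, c(60, 65)),
    mk_manifest("C", 1:3, c(58, 61, 64))
  )
  drivers <- rbind(
    mk_obs("A", "vA", "TET2", 1:3, c(0.02, 0.03, 0.05), c(2000, 150, 2500)),
    mk_obs("B", "vB", "TET2", 1:2, c(0.05, 0.08), c(2000, 2000)),
    mk_obs("C", "vC", "TET2", 1:3, c(0.004, 0.005, 0.005), c(2000, 2000, 2000))
  )
  tr <- assemble_trajectories(drivers, manifest)
  # subject B: only two timepoints -> excluded
  expect_false("B" %in% tr$subject_id)
  # subject C: no VAF above 1% -> excluded
  expect_false("C" %in% tr$subject_id)
  # subject A: depth-150 observation dropped, others kept with ages joined
  a <- tr[tr$subject_id == "A", ]
  expect_identical(nrow(a), 2L)
  expect_equal(a$age, c(60, 66))
})

test_that("low-count detections at adequate depth become zero VAFs", {
  manifest <- mk_manifest("A", 1:3, c(60, 63, 66))
  drivers <- mk_obs("A", "v", "TET2", 1:3, c(0, 0, 0), c(2000, 2000, 2000),
                    alts = c(1L, 60L, 120L))
  tr <- assemble_trajectories(drivers, manifest)
  expect_equal(tr$vaf[tr$age == 60], 0)
  expect_equal(tr$vaf[tr$age == 63], 0.03)
})

test_that("peak-VAF eligibility is strict at 1%", {
  manifest <- mk_manifest("A", 1:3, c(60, 63, 66))
  at_boundary <- mk_obs("A", "v", "TET2", 1:3, c(0.01, 0.01, 0.01),
                        c(2000, 2000, 2000))
  expect_identical(nrow(assemble_trajectories(at_boundary, manifest)), 0L)
})

test_that("high-start exclusion is strict above 10%", {
  manifest <- mk_manifest("A", 1:3, c(60, 63, 66))
  mk <- function(v0, id) mk_obs("A", id, "TET2", 1:3, c(v0, 0.1, 0.1),
                                c(2000, 2000, 2000))
  tr <- assemble_trajectories(rbind(mk(0.12, "v_over"), mk(0.10, "v_at"),
                                    mk(0.004, "v_low")), manifest)
  kept <- exclude_high_start(tr)
  expect_false("v_over" %in% kept$variant_id)
  expect_true("v_at" %in% kept$variant_id)
  expect_true("v_low" %in% kept$variant_id)
})

test_that("per-mutation fits carry labels and two-timepoint direction calls", {
  manifest <- rbind(mk_manifest("A", 1:4, c(60, 63, 66, 70)),
                    mk_manifest("B", 1:3, c(55, 60, 65)))
  drivers <- rbind(
    mk_obs("A", "v_up", "DNMT3A", 1:4, c(0.01, 0.02, 0.04, 0.1),
           rep(2000, 4)),
    mk_obs("B", "v2", "JAK2", c(1, 3), c(0.02, 0.08), rep(2000, 2))
  )
  tr <- assemble_trajectories(drivers, manifest)
  fits <- fit_trajectories(tr)
  up <- fits[fits$variant_id == "v_up", ]
  expect_identical(up$label, "growing")
  expect_gt(up$beta, 0)
  expect_gt(up$doubling_period, 0)
  two <- fits[fits$variant_id == "v2", ]
  expect_identical(two$label, "growing")
  expect_true(is.na(two$p_value))
})

test_that("dominant clones maximize peak VAF with documented tie-breaks", {
  tr <- rbind(
    mk_obs("A", "v_small", "TET2", 1:3, c(0.01, 0.02, 0.03), rep(2000, 3)),
    mk_obs("A", "v_big", "DNMT3A", 1:3, c(0.02, 0.05, 0.08), rep(2000, 3))
  )
  tr$age <- rep(c(60, 63, 66), 2)
  dom <- select_dominant(tr)
  expect_identical(dom$variant_id, "v_big")
  expect_equal(dom$peak_vaf, 0.08)
  # one-decade rise
  tr2 <- mk_obs("B", "v", "TET2", 1:3, c(0.005, 0.02, 0.05), rep(2000, 3))
  tr2$age <- c(60, 63, 66)
  expect_equal(select_dominant(tr2)$delta_log10_vaf, 1, tolerance = 1e-12)
  # tie on peak -> larger final VAF wins
  tr3 <- rbind(
    mk_obs("C", "v_fall", "TET2", 1:3, c(0.08, 0.05, 0.01), rep(2000, 3)),
    mk_obs("C", "v_hold", "ASXL1", 1:3, c(0.08, 0.06, 0.05), rep(2000, 3))
  )
  tr3$age <- rep(c(60, 63, 66), 2)
  expect_identical(select_dominant(tr3)$variant_id, "v_hold")
  # no trajectory with two non-zero VAFs -> no dominant clone
  tr4 <- mk_obs("D", "v", "TET2", 1:3, c(0, 0.02, 0), rep(2000, 3),
                alts = c(0L, 40L, 0L))
  tr4$age <- c(60, 63, 66)
  expect_identical(nrow(select_dominant(tr4)), 0L)
})

test_that("competition flags non-growing CHIP clones beside growing ones", {
  tr <- rbind(
    mk_obs("A", "v_grow", "DNMT3A", 1:3, c(0.01, 0.03, 0.09), rep(2000, 3)),
    mk_obs("A", "v_shrink", "TET2", 1:3, c(0.05, 0.03, 0.01), rep(2000, 3)),
    mk_obs("B", "v_solo", "TET2", 1:3, c(0.01, 0.02, 0.04), rep(2000, 3)),
    mk_obs("C", "v_s1", "TET2", 1:3, c(0.010, 0.011, 0.010), rep(2000, 3)),
    mk_obs("C", "v_s2", "ASXL1", 1:3, c(0.012, 0.011, 0.012), rep(2000, 3))
  )
  tr$age <- rep(c(60, 63, 66), 5)
  fits <- fit_trajectories(tr)
  rep_ <- competition_report(fits, tr)
  # growing + shrinking clone peaking at 5%: flagged
  expect_true(all(rep_$competition[rep_$subject_id == "A"]))
  # single-clone subject: absent from the report
  expect_false("B" %in% rep_$subject_id)
  # two static clones: listed, not flagged
  expect_false(any(rep_$competition[rep_$subject_id == "C"]))
})

test_that("Mann-Whitney comparison matches full enumeration on small groups", {
  fits <- data.frame(gene = c(rep("DNMT3A", 3), rep("JAK2", 3)),
                     beta = c(1, 2, 3, 4, 5, 6) / 100)
  res <- compare_gene_groups(fits)
  expect_equal(res$statistic, 0)
  expect_equal(res$p.value, 0.1, tolerance = 1e-12)
  # random small groups against the enumeration oracle
  set.seed(55)
  for (i in 1:12) {
    nx <- sample(2:5, 1); ny <- sample(2:5, 1)
    x <- round(rnorm(nx, 0.04, 0.02), 6)
    y <- round(rnorm(ny, 0.06, 0.02), 6)
    fits <- data.frame(gene = c(rep("TET2", nx), rep("CBL", ny)),
                       beta = c(x, y))
    res <- compare_gene_groups(fits)
    expect_equal(res$statistic, oracle_u_stat(x, y))
    expect_equal(res$p.value, oracle_mw_exact_p(x, y), tolerance = 1e-10)
  }
  # identical groups -> p = 1
  fits <- data.frame(gene = c("DNMT3A", "DNMT3A", "CBL", "CBL"),
                     beta = c(0.01, 0.02, 0.01, 0.02))
  expect_equal(compare_gene_groups(fits)$p.value, 1)
  expect_error(compare_gene_groups(data.frame(gene = "DNMT3A", beta = 1)),
               "non-empty")
})

test_that("a two-s.d. shift is detected with good power at n = 20 + 20", {
  set.seed(66)
  hits <- replicate(50, {
    fits <- data.frame(gene = c(rep("DNMT3A", 20), rep("CBL", 20)),
                       beta = c(rnorm(20, 0.02, 0.01), rnorm(20, 0.04, 0.01)))
    compare_gene_groups(fits)$p.value < 0.05
  })
  expect_gt(mean(hits), 0.8)
})

test_that("growth odds ratios follow ad/bc with zero-cell correction", {
  mk_fits <- function(a, b, c_, d, gene = "DNMT3A") {
    data.frame(
      gene = c(rep(gene, a + b), rep("OTHER", c_ + d)),
      label = c(rep("growing", a), rep("static", b),
                rep("growing", c_), rep("static", d))
    )
  }
  res <- gene_growth_odds(mk_fits(10, 20, 20, 10), "DNMT3A")
  expect_equal(res$odds_ratio, 0.25, tolerance = 1e-12)
  expect_false(res$corrected)
  expect_equal(res$p.value,
               fisher.test(matrix(c(10, 20, 20, 10), 2, byrow = TRUE))$p.value,
               tolerance = 1e-12)
  # independence: OR 1, p 1
  res <- gene_growth_odds(mk_fits(5, 5, 5, 5), "DNMT3A")
  expect_equal(res$odds_ratio, 1)
  expect_equal(res$p.value, 1)
  # zero cell: Haldane-Anscombe keeps the OR finite
  res <- gene_growth_odds(mk_fits(0, 10, 10, 10), "DNMT3A")
  expect_true(res$corrected)
  expect_true(is.finite(res$odds_ratio))
  expect_equal(res$odds_ratio, (0.5 * 10.5) / (10.5 * 10.5), tolerance = 1e-12)
  expect_error(gene_growth_odds(mk_fits(5, 5, 0, 0)[1:10, ], "DNMT3A"),
               "both in and outside")
})

test_that("simulated clone slopes are recovered with small error", {
  set.seed(88)
  n_clones <- 120
  err <- numeric(n_clones); ok_sign <- logical(n_clones)
  for (i in seq_len(n_clones)) {
    beta <- sample(c(-1, 1), 1) * runif(1, 0.04, 0.1)
    ntp <- sample(4:6, 1)
    # observation window over which the clone stays inside [1%, 10%]
    t_eff <- min(16, 1 / abs(beta))
    ages <- 60 + sort(c(0, runif(ntp - 2, 0.1, 0.9) * t_eff, t_eff))
    span <- 10^(beta * (ages - 60))
    v0 <- if (beta > 0) 0.01 else 0.1
    vafs <- v0 * span
    depth <- rep(2803L, ntp)
    alt <- simulate_site_reads(vafs, depth, 0.00045)
    fit <- chip_growth(vaf ~ age, data.frame(age = ages, vaf = alt / depth),
                       depth = depth)
    err[i] <- abs(unname(coef(fit)["beta"]) - beta)
    lab <- fit$label
    ok_sign[i] <- (beta > 0 && lab == "growing") ||
      (beta < 0 && lab == "shrinking")
  }
  expect_lt(median(err), 0.01)
  expect_gte(mean(ok_sign), 0.95)
})
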
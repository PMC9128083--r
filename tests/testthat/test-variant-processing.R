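# UMI dedup consensus rules, the binomial caller, and the post-call
# filters with their exact boundary behaviour.

test_that("UMI consensus takes the majority allele and drops ties", {
  base <- list(chrom = "2", pos = 100L, ref = "A", alt = "G")
  mk <- function(umi, alleles)
    data.frame(probe_id = "p1", umi = umi, chrom = base$chrom, pos = base$pos,
               ref = base$ref, alt = base$alt, observed_allele = alleles,
               stringsAsFactors = FALSE)
  # 3 reads, one UMI, alleles A,A,G -> one molecule, consensus ref
  dd <- dedup_umis(mk(rep("AAAAAAAAA", 3), c("A", "A", "G")))
  expect_identical(dd$depth, 1L)
  expect_identical(dd$alt_count, 0L)
  # 2 reads, one UMI, alleles A,G -> exact tie, group dropped
  dd <- dedup_umis(mk(rep("AAAAAAAAA", 2), c("A", "G")))
  expect_identical(nrow(dd), 0L)
  # 5 distinct UMIs all alternate -> depth 5, alt 5
  dd <- dedup_umis(mk(c("AAAAAAAAA", "AAAAAAAAC", "AAAAAAAAG",
                        "AAAAAAAAT", "AAAAAAACA"), rep("G", 5)))
  expect_identical(dd$depth, 5L)
  expect_identical(dd$alt_count, 5L)
  expect_equal(dd$vaf, 1)
})

test_that("malformed UMIs are rejected record-wise with a log message", {
  reads <- data.frame(probe_id = "p", umi = c("AAAAAAAAA", "SHORT"),
                      chrom = "2", pos = 1L, ref = "A", alt = "G",
                      observed_allele = c("G", "G"), stringsAsFactors = FALSE)
  expect_message(dd <- dedup_umis(reads), "rejected 1")
  expect_identical(dd$depth, 1L)
})

test_that("dedup is idempotent at the count level", {
  obs <- data.frame(chrom = "4", pos = 500L, ref = "C", alt = "T",
                    depth = 40L, alt_count = 7L)
  reads <- simulate_umi_reads(obs, 4, seed = 13)
  once <- dedup_umis(reads)
  again <- dedup_umis(simulate_umi_reads(once, 1, seed = 14))
  expect_equal(once[c("depth", "alt_count")], again[c("depth", "alt_count")])
})

test_that("the binomial caller matches the exact tail probability", {
  obs <- data.frame(depth = c(2800L, 40L, 100L), alt_count = c(56L, 1L, 0L))
  out <- call_variants(obs, error_rate = 0.00045, alpha = 1e-6)
  # closed form for a single success: 1 - (1 - e)^n
  expect_equal(out$p_value[2], 1 - (1 - 0.00045)^40, tolerance = 1e-12)
  expect_equal(out$p_value[3], 1)
  expect_false(out$candidate[2])
  expect_false(out$candidate[3])
  expect_true(out$candidate[1])
  expect_lt(out$p_value[1], 1e-6)
  # binom.test as the independent oracle
  for (i in 1:2) {
    bt <- binom.test(out$alt_count[i], out$depth[i], 0.00045,
                     alternative = "greater")
    expect_equal(out$p_value[i], bt$p.value, tolerance = 1e-12)
  }
  expect_error(call_variants(obs, error_rate = 0), "in \\(0, 1\\)")
})

test_that("caller p-values are conservative on null (error-only) sites", {
  set.seed(31)
  n <- 2000
  depth <- rep(2803L, n)
  obs <- data.frame(depth = depth, alt_count = rbinom(n, depth, 0.00045))
  out <- call_variants(obs, 0.00045, alpha = 1e-6)
  alpha_cal <- 0.01
  frac <- mean(out$p_value < alpha_cal)
  expect_lte(frac, alpha_cal + 3 * sqrt(alpha_cal * (1 - alpha_cal) / n))
  expect_equal(sum(out$candidate), 0L)
})

test_that("per-call filter thresholds are inclusive at the boundary", {
  calls <- data.frame(
    depth = c(4000L, 39L, 10000L, 40L),
    alt_count = c(5L, 10L, 9L, 5L)
  )
  calls$vaf <- calls$alt_count / calls$depth
  out <- apply_call_filters(calls)
  # depth 4000, alt 5, vaf 0.00125: all three pass at/above the boundary
  expect_false(out$low_coverage[1] || out$low_alt_support[1] || out$low_vaf[1])
  expect_true(out$low_coverage[2])
  # depth 10000, alt 9: support passes (9 >= 5), vaf 0.0009 fails
  expect_false(out$low_alt_support[3])
  expect_true(out$low_vaf[3])
  # exact boundary depth 40, alt 5, vaf 0.125 passes everything
  expect_false(any(out[4, c("low_coverage", "low_alt_support", "low_vaf")] == TRUE))
})

test_that("filter flags are order-independent", {
  set.seed(7)
  calls <- data.frame(depth = sample(30:60, 50, TRUE),
                      alt_count = sample(0:10, 50, TRUE))
  calls$alt_count <- pmin(calls$alt_count, calls$depth)
  calls$vaf <- calls$alt_count / calls$depth
  a <- apply_call_filters(calls)
  perm <- sample(nrow(calls))
  b <- apply_call_filters(calls[perm, ])
  b <- b[order(perm), ]
  expect_equal(a$low_coverage, b$low_coverage)
  expect_equal(a$low_alt_support, b$low_alt_support)
  expect_equal(a$low_vaf, b$low_vaf)
})

test_that("recurrent-artifact rule uses a closed 1-10% window at >= 5% of samples", {
  mk_calls <- function(n_hit, vaf, n_samples = 100) {
    hit <- data.frame(sample_id = paste0("s", seq_len(n_hit)),
                      variant_id = "v1", vaf = vaf)
    anchor <- data.frame(sample_id = paste0("s", seq_len(n_samples)),
                         variant_id = "v0", vaf = 0.5)
    rbind(hit, anchor)
  }
  # exactly 5 of 100 samples in-window -> flagged everywhere
  out <- filter_recurrent_artifacts(mk_calls(5, 0.05))
  expect_true(all(out$recurrent_artifact[out$variant_id == "v1"]))
  # 4 of 100 -> kept
  out <- filter_recurrent_artifacts(mk_calls(4, 0.05))
  expect_false(any(out$recurrent_artifact[out$variant_id == "v1"]))
  # 50 of 100 but VAF 0.30, outside the window -> kept
  out <- filter_recurrent_artifacts(mk_calls(50, 0.30))
  expect_false(any(out$recurrent_artifact[out$variant_id == "v1"]))
  # window boundaries are closed
  out <- filter_recurrent_artifacts(mk_calls(10, 0.01))
  expect_true(all(out$recurrent_artifact[out$variant_id == "v1"]))
  out <- filter_recurrent_artifacts(mk_calls(10, 0.10))
  expect_true(all(out$recurrent_artifact[out$variant_id == "v1"]))
})

test_that("simulated clones at VAF >= 1% and depth >= 1000 are recovered", {
  set.seed(77)
  n <- 400
  vaf <- runif(n, 0.01, 0.2)
  depth <- sample(1000:3000, n, TRUE)
  obs <- data.frame(
    sample_id = paste0("s", seq_len(n)),
    variant_id = paste0("v", seq_len(n)),
    depth = depth,
    alt_count = simulate_site_reads(vaf, depth, 0.00045)
  )
  obs$vaf <- obs$alt_count / obs$depth
  out <- process_observations(obs)
  expect_gt(mean(out$pass), 0.99)
})
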
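# Assay-validation mathematics: expected mixture VAFs, pooled error rate,
# intraclass correlation, observed-vs-expected and cross-platform
# concordance.

#' Expected VAF of a variant in a defined gDNA mixture
#'
#' For lines mixed at proportions `p_i` with genotype dosages `d_i` in
#' \{0, 1, 2\}, the expected VAF is `sum(p_i * d_i / 2)`.
#'
#' @param mixture a [mixture_spec()]; its dosage matrix is used unless
#'   `dosages` is given.
#' @param dosages optional dosage vector/matrix overriding the spec's.
#' @return expected VAF per variant (numeric vector).
#' @export
expected_mixture_vaf <- function(mixture, dosages = NULL) {
  if (!inherits(mixture, "mixture_spec")) stop("mixture must be a mixture_spec")
  d <- dosages %||% mixture$dosages
  if (is.null(d)) stop("no dosages supplied")
  if (is.vector(d)) d <- matrix(d, nrow = 1)
  if (!all(d %in% c(0, 1, 2))) stop("dosages must be in {0, 1, 2}")
  if (ncol(d) != length(mixture$proportions))
    stop("dosages must have one column per mixture line")
  as.numeric(d %*% mixture$proportions) / 2
}

#' All expected mixture VAFs over genotype configurations
#'
#' Enumerates every genotype-dosage configuration in \{0, 1, 2\}^k over
#' the mixture's k lines and returns the expected VAF of each; useful for
#' the attainable VAF range of a validation mixture.
#'
#' @param mixture a [mixture_spec()].
#' @param drop_null drop the all-zero configuration (default TRUE).
#' @return data frame of dosage configurations with their `expected_vaf`.
#' @export
enumerate_mixture_vafs <- function(mixture, drop_null = TRUE) {
  k <- length(mixture$proportions)
  grid <- as.matrix(expand.grid(rep(list(0:2), k)))
  colnames(grid) <- names(mixture$proportions)
  if (drop_null) grid <- grid[rowSums(grid) > 0, , drop = FALSE]
  data.frame(grid, expected_vaf = expected_mixture_vaf(mixture, grid),
             row.names = NULL)
}

#' Pooled per-base error rate from invariant sites
#'
#' Total non-reference reads divided by total reads, pooled across
#' invariant sites (not a mean of per-site rates).
#'
#' @param nonref_counts non-reference read counts per invariant site.
#' @param depths total read counts per site.
#' @return list with `rate` (pooled), `per_site` rates, and
#'   `one_in_bp` (the reciprocal, "1 in N bp"; `Inf` when no errors).
#' @export
estimate_error_rate <- function(nonref_counts, depths) {
  if (length(depths) == 0 || sum(depths) <= 0)
    stop("total depth must be positive")
  if (any(nonref_counts < 0) || any(nonref_counts > depths))
    stop("nonref_counts must lie in [0, depth]")
  rate <- sum(nonref_counts) / sum(depths)
  list(rate = rate, per_site = nonref_counts / depths,
       one_in_bp = if (rate > 0) 1 / rate else Inf)
}

#' One-way random-effects intraclass correlation, ICC(1)
#'
#' Reliability of replicate VAF measurements across variant sites:
#' `(MS_between - MS_within) / (MS_between + (k0 - 1) MS_within)`, where
#' `k0` is the (effective mean) replicate count. Missing entries are
#' excluded; the 95% CI comes from F-distribution bounds on the variance
#' ratio.
#'
#' @param mat numeric matrix, rows = variant sites, columns = replicates.
#' @param conf_level confidence level for the interval (default 0.95).
#' @return list with `icc`, `ci` (length-2 vector), `ms_between`,
#'   `ms_within`, `k0`.
#' @export
icc <- function(mat, conf_level = 0.95) {
  mat <- as.matrix(mat)
  if (nrow(mat) < 2 || ncol(mat) < 2)
    stop("need >= 2 sites and >= 2 replicates")
  ni <- rowSums(!is.na(mat))
  keep <- ni >= 1
  mat <- mat[keep, , drop = FALSE]; ni <- ni[keep]
  a <- nrow(mat); N <- sum(ni)
  grand <- mean(mat, na.rm = TRUE)
  mi <- rowMeans(mat, na.rm = TRUE)
  ssb <- sum(ni * (mi - grand)^2)
  ssw <- sum((mat - mi)^2, na.rm = TRUE)
  if (ssb + ssw == 0) stop("zero total variance; ICC undefined")
  msb <- ssb / (a - 1)
  msw <- ssw / (N - a)
  k0 <- (N - sum(ni^2) / N) / (a - 1)
  est <- (msb - msw) / (msb + (k0 - 1) * msw)
  alpha <- 1 - conf_level
  if (msw > 0) {
    f <- msb / msw
    fl <- f / stats::qf(1 - alpha / 2, a - 1, N - a)
    fu <- f * stats::qf(1 - alpha / 2, N - a, a - 1)
    ci <- c((fl - 1) / (fl + k0 - 1), (fu - 1) / (fu + k0 - 1))
  } else {
    ci <- c(NA_real_, NA_real_)
  }
  list(icc = est, ci = ci, ms_between = msb, ms_within = msw, k0 = k0)
}

#' Observed-vs-expected VAF concordance
#'
#' Pearson correlation of observed against expected VAFs on the
#' untransformed scale, overall and stratified at a VAF split (default
#' 2%): one coefficient for variants with expected VAF at or below the
#' split and one above. Strata with fewer than 3 points or zero variance
#' report NA.
#'
#' @param observed,expected equal-length VAF vectors (length >= 3).
#' @param split_at stratification threshold on `expected` (default 0.02).
#' @return list with `r_overall`, `r_low`, `r_high`, and stratum sizes.
#' @export
concordance <- function(observed, expected, split_at = 0.02) {
  if (length(observed) != length(expected) || length(observed) < 3)
    stop("need equal-length vectors of length >= 3")
  safe_cor <- function(x, y) {
    if (length(x) < 3 || stats::sd(x) == 0 || stats::sd(y) == 0)
      return(NA_real_)
    stats::cor(x, y)
  }
  low <- expected <= split_at
  list(r_overall = safe_cor(observed, expected),
       r_low = safe_cor(observed[low], expected[low]),
       r_high = safe_cor(observed[!low], expected[!low]),
       n_low = sum(low), n_high = sum(!low))
}

#' Cross-platform driver-call comparison
#'
#' Sensitivity of a panel call set against a reference call set
#' (shared / reference), with the VAF correlation computed on variants
#' reaching `vaf_threshold` in both sets.
#'
#' @param panel,reference data frames keyed by `subject_id` and
#'   `variant_id`, each with a `vaf` column.
#' @param vaf_threshold threshold for the correlation subset
#'   (default 0.02).
#' @return list with `sensitivity`, `n_shared`, `n_reference`, and `r`
#'   on the thresholded shared variants (NA if fewer than 3).
#' @export
platform_comparison <- function(panel, reference, vaf_threshold = 0.02) {
  if (nrow(reference) == 0) stop("reference call set is empty")
  m <- merge(reference, panel, by = c("subject_id", "variant_id"),
             suffixes = c("_ref", "_panel"))
  sens <- nrow(m) / nrow(reference)
  big <- m[m$vaf_ref >= vaf_threshold & m$vaf_panel >= vaf_threshold, ,
           drop = FALSE]
  r <- if (nrow(big) >= 3 && stats::sd(big$vaf_ref) > 0 &&
           stats::sd(big$vaf_panel) > 0)
    stats::cor(big$vaf_ref, big$vaf_panel) else NA_real_
  list(sensitivity = sens, n_shared = nrow(m), n_reference = nrow(reference),
       r = r)
}
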
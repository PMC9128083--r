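# Independent oracles used across the suite. These are deliberately
# naive implementations kept separate from the package code paths.

# Mann-Whitney U for group x vs y (ties get 1/2)
oracle_u_stat <- function(x, y) {
  sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
}

# exact two-sided Mann-Whitney p by full enumeration of group assignments
oracle_mw_exact_p <- function(x, y) {
  m <- length(x)
  pooled <- c(x, y)
  n_tot <- length(pooled)
  u_obs <- oracle_u_stat(x, y)
  combos <- utils::combn(n_tot, m)
  u_all <- apply(combos, 2, function(ix)
    oracle_u_stat(pooled[ix], pooled[-ix]))
  lo <- mean(u_all <= u_obs + 1e-12)
  hi <- mean(u_all >= u_obs - 1e-12)
  min(1, 2 * min(lo, hi))
}

# brute-force one-way ANOVA ICC(1) on a complete matrix (rows = groups)
oracle_icc_anova <- function(mat) {
  df <- data.frame(value = as.vector(t(mat)),
                   site = factor(rep(seq_len(nrow(mat)), each = ncol(mat))))
  ms <- summary(stats::aov(value ~ site, data = df))[[1]][["Mean Sq"]]
  k <- ncol(mat)
  (ms[1] - ms[2]) / (ms[1] + (k - 1) * ms[2])
}

# textbook two-pass Pearson correlation
oracle_pearson <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# closed-form WLS fit via lm(), the reference for chip_growth()
oracle_wls <- function(age, vaf, depth, vaf_floor = 1e-4) {
  y <- log10(pmax(vaf, vaf_floor))
  fit <- stats::lm(y ~ age, weights = sqrt(depth))
  s <- summary(fit)$coefficients
  list(C = unname(coef(fit)[1]), beta = unname(coef(fit)[2]),
       p = if (nrow(s) == 2 && ncol(s) == 4) s[2, 4] else NA_real_)
}

# small deterministic trajectory data frame for reuse
make_traj_df <- function(ages, vafs, depths = rep(1000, length(ages))) {
  data.frame(age = ages, vaf = vafs, depth = depths)
}
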
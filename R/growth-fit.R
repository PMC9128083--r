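# The clone-growth model: weighted least squares of log10(VAF) on age.
#
# The model is log10(VAF) = C + beta * age, fitted by WLS with weight
# sqrt(depth) per observation; zero VAFs are floored at a detection limit
# before the log transform. The normal equations are solved in closed
# form; lm() is deliberately not used so the fit is a single transparent
# computation.

#' Fit a weighted log-linear clone-growth model
#'
#' Fits `log10(VAF) = C + beta * age` by weighted least squares, each
#' observation weighted by the square root of its read depth. VAFs of
#' zero (or below the floor) are set to `vaf_floor`, a conservative
#' detection limit for deep targeted sequencing. The slope is tested
#' against zero with a t-statistic on `n - 2` degrees of freedom and the
#' trajectory is classified as growing (`beta > 0`, `P < p_threshold`),
#' shrinking (`beta <= 0`, `P < p_threshold`) or static
#' (`P >= p_threshold`). A perfect fit (zero residual variance) is
#' treated as `P = 0`; with exactly two observations `beta` is exact and
#' `P` is `NA` (no residual degrees of freedom), as is the label.
#'
#' @param formula model formula `vaf ~ age`.
#' @param data data frame holding the VAF, age and depth columns.
#' @param depth read depths: an unquoted column name in `data` or a
#'   numeric vector. Omitted, all weights are equal.
#' @param vaf_floor detection-limit floor applied before `log10`
#'   (default 1e-4).
#' @param p_threshold classification threshold on the slope p-value
#'   (default 0.5).
#' @return an object of class `chip_growth` with components
#'   `coefficients` (C, beta), `se`, `statistic`, `p.value`, `df`,
#'   `label`, `doubling_period` (years per VAF doubling, `beta > 0`
#'   only), `fitted.values` and `residuals` (log10 scale), `weights`,
#'   `model`, `perfect_fit`.
#' @examples
#' d <- data.frame(age = c(60, 65, 70), vaf = c(0.01, 0.02, 0.04),
#'                 depth = c(1000, 1000, 1000))
#' fit <- chip_growth(vaf ~ age, d, depth = depth)
#' coef(fit)           # beta = log10(2) / 5: doubling every 5 years
#' fit$doubling_period
#' @export
chip_growth <- function(formula, data, depth, vaf_floor = 1e-4,
                        p_threshold = 0.5) {
  mf <- stats::model.frame(formula, data)
  vaf <- unname(stats::model.response(mf))
  if (ncol(mf) != 2L) stop("formula must have a single predictor (age)")
  age <- unname(mf[[2L]])
  dep <- if (missing(depth)) rep(1, length(age)) else {
    d <- eval(substitute(depth), data, parent.frame())
    if (is.null(d)) rep(1, length(age)) else d
  }
  if (length(dep) != length(age)) stop("depth length mismatch")
  if (any(vaf < 0 | vaf > 1)) stop("VAFs must lie in [0, 1]")
  n <- length(age)
  if (n < 2L) stop("need at least 2 observations")
  if (length(unique(age)) < 2L) stop("all ages equal; slope is undefined")

  y <- log10(pmax(vaf, vaf_floor))
  w <- sqrt(dep)

  sw <- sum(w); swx <- sum(w * age); swy <- sum(w * y)
  swxx <- sum(w * age^2); swxy <- sum(w * age * y)
  det <- sw * swxx - swx^2
  beta <- (sw * swxy - swx * swy) / det
  C <- (swy - beta * swx) / sw

  fitted <- C + beta * age
  resid <- y - fitted
  wrss <- sum(w * resid^2)
  perfect <- wrss <= 1e-12 * max(1, sum(w * y^2))
  df <- n - 2L
  if (df > 0L) {
    sigma2 <- wrss / df
    se_beta <- sqrt(sigma2 * sw / det)
    if (perfect || se_beta == 0) {
      tstat <- if (beta == 0) 0 else sign(beta) * Inf
      p <- 0
    } else {
      tstat <- beta / se_beta
      p <- 2 * stats::pt(-abs(tstat), df)
    }
  } else {
    sigma2 <- NA_real_; se_beta <- NA_real_; tstat <- NA_real_; p <- NA_real_
  }

  label <- classify_trajectory(beta, p, p_threshold)
  structure(list(
    coefficients = c("(Intercept)" = C, beta = beta),
    se = c("(Intercept)" = sqrt(if (df > 0L && !perfect) sigma2 * swxx / det else NA),
           beta = se_beta),
    statistic = tstat, p.value = p, df = df,
    label = label,
    doubling_period = if (beta > 0) log10(2) / beta else NA_real_,
    fitted.values = fitted, residuals = resid, weights = w,
    model = data.frame(age = age, vaf = vaf, depth = dep, log10_vaf = y),
    vaf_floor = vaf_floor, p_threshold = p_threshold,
    perfect_fit = perfect, sigma2 = sigma2,
    call = match.call()
  ), class = "chip_growth")
}

#' Classify a fitted trajectory
#'
#' Growing when `beta > 0` and `P < p_threshold`; shrinking when
#' `beta <= 0` and `P < p_threshold`; static when `P >= p_threshold`.
#' `P = NA` yields an `NA` label.
#'
#' @param beta fitted per-year slope of log10(VAF).
#' @param p two-sided p-value for `beta = 0`.
#' @param p_threshold classification threshold (default 0.5).
#' @return `"growing"`, `"shrinking"`, `"static"`, or `NA`.
#' @export
classify_trajectory <- function(beta, p, p_threshold = 0.5) {
  out <- rep(NA_character_, length(beta))
  ok <- !is.na(p)
  out[ok & p >= p_threshold] <- "static"
  out[ok & p < p_threshold & beta > 0] <- "growing"
  out[ok & p < p_threshold & beta <= 0] <- "shrinking"
  out
}

#' Doubling period of a growing clone
#'
#' Under exponential growth with per-year log10 slope `beta`, the VAF
#' doubles every `log10(2) / beta` years.
#'
#' @param beta per-year slope of log10(VAF); must be positive.
#' @return doubling period in years.
#' @export
doubling_period <- function(beta) {
  if (any(beta <= 0)) stop("doubling period is undefined for beta <= 0")
  log10(2) / beta
}

#' @export
print.chip_growth <- function(x, digits = 4, ...) {
  cat("Weighted log-linear clone-growth fit: log10(VAF) = C + beta * age\n")
  cat("  n =", nrow(x$model), "observations\n")
  cat("  C    =", format(x$coefficients[1], digits = digits), "\n")
  cat("  beta =", format(x$coefficients[2], digits = digits), "per year  (P =",
      format(x$p.value, digits = digits), ")\n")
  cat("  label:", x$label)
  if (!is.na(x$doubling_period))
    cat("   doubling period:", format(x$doubling_period, digits = digits), "years")
  cat("\n")
  invisible(x)
}

#' @export
summary.chip_growth <- function(object, ...) {
  ct <- cbind(Estimate = object$coefficients, `Std. Error` = object$se,
              `t value` = c(NA, object$statistic),
              `Pr(>|t|)` = c(NA, object$p.value))
  structure(list(coefficients = ct, label = object$label,
                 doubling_period = object$doubling_period,
                 df = object$df, n = nrow(object$model),
                 perfect_fit = object$perfect_fit,
                 p_threshold = object$p_threshold),
            class = "summary.chip_growth")
}

#' @export
print.summary.chip_growth <- function(x, digits = 4, ...) {
  cat("Clone-growth model (WLS on log10 VAF, weights = sqrt(depth))\n\n")
  stats::printCoefmat(x$coefficients, digits = digits, na.print = "")
  cat("\nn =", x$n, " residual df =", x$df,
      if (x$perfect_fit) " (perfect fit)" else "", "\n")
  cat("label:", x$label, "(P threshold", x$p_threshold, ")\n")
  if (!is.na(x$doubling_period))
    cat("doubling period:", format(x$doubling_period, digits = digits), "years\n")
  invisible(x)
}

#' @export
coef.chip_growth <- function(object, ...) object$coefficients

#' @export
residuals.chip_growth <- function(object, ...) object$residuals

#' @export
fitted.chip_growth <- function(object, ...) object$fitted.values

#' Predict clone VAF at new ages
#'
#' @param object a [chip_growth()] fit.
#' @param newdata data frame with an `age` column; defaults to the fitted
#'   ages.
#' @param type `"vaf"` (back-transformed) or `"log10"`.
#' @param ... unused.
#' @return numeric vector of predictions.
#' @export
predict.chip_growth <- function(object, newdata = NULL,
                                type = c("vaf", "log10"), ...) {
  type <- match.arg(type)
  age <- if (is.null(newdata)) object$model$age else newdata$age
  eta <- object$coefficients[1] + object$coefficients[2] * age
  if (type == "vaf") unname(10^eta) else unname(eta)
}

#' Simulate replicate VAF series from a fitted trajectory
#'
#' Draws binomial read counts at the fitted VAFs using the observed
#' depths, mirroring the sequencing noise model.
#'
#' @param object a [chip_growth()] fit.
#' @param nsim number of simulated series.
#' @param seed optional seed.
#' @param ... unused.
#' @return data frame with `age`, `depth` and one `sim_k` VAF column per
#'   simulation.
#' @export
simulate.chip_growth <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  mu <- pmin(1, predict(object))
  dep <- object$model$depth
  sims <- vapply(seq_len(nsim), function(k)
    stats::rbinom(length(mu), dep, mu) / dep, numeric(length(mu)))
  out <- data.frame(age = object$model$age, depth = dep, sims)
  names(out)[-(1:2)] <- paste0("sim_", seq_len(nsim))
  out
}

#' Plot a fitted clone trajectory
#'
#' Observed VAFs (log10 scale, floored) against age with the fitted line.
#'
#' @param x a [chip_growth()] fit.
#' @param ... passed to [plot()].
#' @export
plot.chip_growth <- function(x, ...) {
  m <- x$model
  graphics::plot(m$age, m$log10_vaf, xlab = "age (years)",
                 ylab = "log10 VAF", pch = 19, ...)
  graphics::abline(x$coefficients[1], x$coefficients[2], col = "firebrick")
  graphics::legend("topleft", bty = "n",
                   legend = sprintf("%s, beta = %.4f/yr", x$label,
                                    x$coefficients[2]))
  invisible(x)
}
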
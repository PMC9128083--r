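# Covariate models: cross-sectional CHIP prevalence / clone size, and the
# longitudinal dominant-clone growth delta.

# shared coefficient-table extraction with singularity checks
.coef_table <- function(fit, data_used) {
  cf <- stats::coef(fit)
  if (anyNA(cf)) {
    stop("singular design; aliased term(s): ",
         paste(names(cf)[is.na(cf)], collapse = ", "))
  }
  s <- summary(fit)$coefficients
  data.frame(term = rownames(s), estimate = s[, 1], std_error = s[, 2],
             statistic = s[, 3], p_value = s[, 4],
             row.names = NULL, stringsAsFactors = FALSE)
}

.complete_cases <- function(data, vars, what) {
  use <- stats::complete.cases(data[, vars, drop = FALSE])
  if (any(!use))
    message(what, ": excluded ", sum(!use), " subject(s) with missing values")
  data[use, , drop = FALSE]
}

#' Cross-sectional covariate models at the first timepoint
#'
#' Relates a subject-level CHIP measure at the initial draw to participant
#' characteristics: logistic regression for prevalence outcomes
#' (`chip_prevalence`: any driver at VAF >= 2%; `large_clone_prevalence`:
#' any driver at VAF >= 10%) and linear regression for `log10_vaf`
#' (log10 of the largest driver VAF, CHIP-positive subjects only).
#' Categorical covariates are dummy-coded; p-values are Wald tests.
#'
#' @param data one row per subject with the outcome column
#'   (`chip_positive`, `large_clone`, or `log10_vaf`) and covariates.
#' @param outcome one of `"chip_prevalence"`, `"large_clone_prevalence"`,
#'   `"log10_vaf"`.
#' @param covariates covariate column names (default age, race, smoking,
#'   BMI).
#' @return coefficient table: `term`, `estimate`, `std_error`,
#'   `statistic`, `p_value`.
#' @export
cross_sectional_model <- function(data,
                                  outcome = c("chip_prevalence",
                                              "large_clone_prevalence",
                                              "log10_vaf"),
                                  covariates = c("age", "race", "smoking", "bmi")) {
  outcome <- match.arg(outcome)
  ycol <- switch(outcome, chip_prevalence = "chip_positive",
                 large_clone_prevalence = "large_clone",
                 log10_vaf = "log10_vaf")
  if (!ycol %in% names(data)) stop("data lacks outcome column ", ycol)
  data <- .complete_cases(data, c(ycol, covariates), "cross_sectional_model")
  fml <- stats::reformulate(covariates, response = ycol)
  if (outcome == "log10_vaf") {
    fit <- stats::lm(fml, data = data)
  } else {
    fit <- stats::glm(fml, data = data, family = stats::binomial())
    if (!fit$converged || any(abs(stats::coef(fit)) > 20, na.rm = TRUE))
      warning("possible separation in logistic model")
  }
  .coef_table(fit, data)
}

#' Longitudinal dominant-clone growth model
#'
#' Linear regression of the dominant clone's log10 VAF change (last
#' non-zero minus first non-zero, log10 scale) on participant
#' characteristics, adjusted for first-visit calendar year.
#'
#' @param data one row per subject with `delta_log10_vaf` and covariates.
#' @param covariates covariate column names.
#' @param adjust adjustment column(s), default `"first_visit_year"`;
#'   set `NULL` to drop.
#' @return coefficient table as in [cross_sectional_model()].
#' @export
longitudinal_growth_model <- function(data,
                                      covariates = c("age", "race",
                                                     "smoking", "bmi"),
                                      adjust = "first_visit_year") {
  vars <- c(covariates, adjust)
  data <- .complete_cases(data, c("delta_log10_vaf", vars),
                          "longitudinal_growth_model")
  if (nrow(data) < 3) stop("fewer than 3 usable subjects")
  fml <- stats::reformulate(vars, response = "delta_log10_vaf")
  .coef_table(stats::lm(fml, data = data), data)
}
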
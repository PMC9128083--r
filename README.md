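# chipdyn

Longitudinal clonal hematopoiesis dynamics from targeted deep
sequencing.

Clonal hematopoiesis of indeterminate potential (CHIP) is the
age-related expansion of blood stem-cell clones carrying somatic driver
mutations (most often in *DNMT3A*, *TET2*, *ASXL1*, *JAK2*), defined by
a variant allele fraction (VAF) ≥ 2%. UMI-based targeted deep
sequencing can track such clones across repeated blood draws spanning
years. `chipdyn` is for analysts working with that kind of data (or
planning such a study): it provides the full path from read counts to
clone dynamics, plus a cohort simulator and the assay-validation
statistics used to qualify a panel.

## The model

For a driver mutation observed at ages `t_i` with allele fractions
`v_i` and site depths `d_i`, the clone trajectory is modelled as

    log10(v_i) = C + beta * t_i,        weights w_i = sqrt(d_i)

fitted by weighted least squares, with zero VAFs floored at 1e-4.
`beta` is the per-year slope of log10 VAF; under exponential growth a
clone doubles every `log10(2) / beta` years. Trajectories are labelled
**growing** (`beta > 0`, `P < 0.5`), **shrinking** (`beta <= 0`,
`P < 0.5`) or **static** (`P >= 0.5`).

Around this core the package implements:

* `simulate_cohort()` — multi-subject, multi-timepoint cohorts with
  exponential clone trajectories, binomial read noise, UMI-tagged
  reads, invariant background sites, and ground truth for recovery
  tests; `simulate_mixture()` for defined cell-line mixtures.
* `dedup_umis()`, `call_variants()`, `apply_call_filters()`,
  `filter_recurrent_artifacts()` — UMI consensus, a binomial
  candidate caller, and the somatic filters (depth ≥ 40, alt reads
  ≥ 5, VAF ≥ 0.1%, recurrent-artifact removal).
* `annotate_drivers()`, `chip_status()`, `prevalence_by_age()` —
  whitelist-driven CHIP calling and prevalence summaries.
* `chip_growth()`, `assemble_trajectories()`, `select_dominant()`,
  `competition_report()`, `compare_gene_groups()`,
  `gene_growth_odds()` — the growth model and cohort-level dynamics.
* `expected_mixture_vaf()`, `estimate_error_rate()`, `icc()`,
  `concordance()`, `platform_comparison()` — assay validation.
* `cross_sectional_model()`, `longitudinal_growth_model()` —
  covariate associations.
* `run_chip_pipeline()` — the end-to-end driver writing TSV outputs
  and a run manifest.

## Worked example

Fit a single clone trajectory:

```r
library(chipdyn)
d <- data.frame(age   = c(60, 65, 70, 75),
                vaf   = c(0.010, 0.018, 0.045, 0.070),
                depth = c(2600, 3100, 2400, 2900))
fit <- chip_growth(vaf ~ age, d, depth = depth)
summary(fit)
#> Clone-growth model (WLS on log10 VAF, weights = sqrt(depth))
#>
#>              Estimate Std. Error t value Pr(>|t|)
#> (Intercept) -5.517014   0.355406
#> beta         0.058570   0.005246   11.17  0.00793 **
#>
#> n = 4  residual df = 2
#> label: growing (P threshold 0.5 )
#> doubling period: 5.14 years
predict(fit, data.frame(age = 80))
#> [1] 0.1474
```

The clone gains 0.0586 log10 units of VAF per year — doubling every
5.1 years — and is confidently labelled growing (`P = 0.008`); if it
continues, it reaches ~15% VAF by age 80.

Run the whole pipeline on a simulated 50-subject cohort:

```r
res <- run_chip_pipeline(cohort_config(n_subjects = 50, seed = 11))
nrow(res$fits)                 # 44 trackable driver mutations
table(res$fits$label)          # growing 28, shrinking 6, static 10
median(res$fits$doubling_period[res$fits$label == "growing"])  # 5.52 yr
res$error_rate$rate            # 0.000459 (simulated truth: 0.00045)
```

With this seed, 44 mutations are trackable (subjects with ≥ 3
timepoints and a clone above 1% VAF), most on growing trajectories with
a median doubling period of about five and a half years, and the
per-base error rate estimated from invariant sites recovers the
simulated 0.045%.

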
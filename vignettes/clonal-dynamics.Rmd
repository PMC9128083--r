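---
title: "Modelling longitudinal clonal hematopoiesis with chipdyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling longitudinal clonal hematopoiesis with chipdyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chipdyn)
```

## The problem

Clonal hematopoiesis of indeterminate potential (CHIP) is the age-related
expansion of hematopoietic stem-cell clones carrying cancer-associated
somatic mutations, conventionally defined by a variant allele fraction
(VAF) of at least 2% in blood. Deep targeted sequencing with unique
molecular identifiers (UMIs) can measure clone sizes well below that
threshold, and repeated blood draws from the same person turn those
measurements into clone *trajectories*: is a mutant clone growing,
shrinking, or holding steady, and how fast?

`chipdyn` implements that analysis end to end: a cohort simulator with
the statistical structure the analysis assumes, UMI deduplication, a
binomial candidate-variant caller with the standard somatic filters,
whitelist-based CHIP driver annotation, the clone-growth model itself,
and the assay-validation statistics used to qualify a targeted panel
(defined gDNA mixtures, error rate, intraclass correlation,
concordance).

## The growth model

The central object is a weighted log-linear model of clone size against
age. For a driver mutation observed at ages $t_1 < \dots < t_n$ with
allele fractions $v_i$ and site read depths $d_i$,

$$\log_{10} v_i = C + \beta\, t_i + \varepsilon_i,$$

fitted by weighted least squares with weights $w_i = \sqrt{d_i}$. This
is exponential clone growth (or decline) with a constant per-year
fitness effect; $\beta$ is the slope of $\log_{10}$ VAF per year, and a
growing clone doubles every $\log_{10}(2)/\beta$ years. Observed VAFs of
zero are floored at $10^{-4}$ before the transform, a conservative
detection limit for UMI-deduplicated sequencing at the depths the
assay produces, so that confident absence still informs the fit.

`chip_growth()` solves the weighted normal equations in closed form and
returns a classed model object:

```{r growth-example}
d <- data.frame(age = c(60, 65, 70, 75),
                vaf = c(0.010, 0.018, 0.045, 0.070),
                depth = c(2600, 3100, 2400, 2900))
fit <- chip_growth(vaf ~ age, d, depth = depth)
summary(fit)
predict(fit, data.frame(age = 80))
```

The slope is tested against zero with a t statistic on $n - 2$ degrees
of freedom, and each trajectory is labelled

* **growing** when $\beta > 0$ and $P < 0.5$,
* **shrinking** when $\beta \le 0$ and $P < 0.5$,
* **static** when $P \ge 0.5$.

The 0.5 threshold is deliberately permissive — it asks only whether the
direction of change is better supported than not, with three to six
points per clone — and is exposed as `p_threshold` for users who want a
conventional cutoff. Two numerical conventions matter at the edges: a
perfect fit (zero residual variance, as happens with exactly log-linear
synthetic input) is treated as $P = 0$ and labelled by the sign of
$\beta$; a two-point trajectory has no residual degrees of freedom, so
it gets an exact slope, no $P$, and is summarized downstream only as
growing versus non-growing by the sign of its VAF change.

## Trajectory eligibility

`assemble_trajectories()` applies the eligibility rules before any
fitting: subjects need at least three sequenced timepoints and at least
one driver above 1% VAF at some visit; observations need site depth of
at least 200; and fewer than 2 alternate reads at adequate depth is
treated as non-detection, entering the fit as a (floored) zero rather
than being discarded — absence at depth 200+ is informative, whereas a
shallow site is simply unassayed and is dropped. Clones whose first
retained observation exceeds 10% VAF are excluded from trajectory
analysis by `exclude_high_start()` (strictly above 10%; exactly 10%
stays), because an unbounded exponential is a poor description of a
clone already nearing its heterozygous ceiling.

Cohort-level summaries then follow: `select_dominant()` picks each
subject's largest clone (peak VAF at any timepoint; ties break to the
larger final VAF, then lexicographic variant id) and computes its
log10 VAF change between first and last non-zero observations;
`competition_report()` flags subjects where a non-growing clone that
reached the 2% CHIP threshold co-exists with a growing clone;
`compare_gene_groups()` contrasts growth rates between the major CHIP
genes (*DNMT3A*, *TET2*, *ASXL1*) and the rest by Mann-Whitney U
(exact by enumeration for small untied samples); and
`gene_growth_odds()` computes the odds that one gene's trajectories are
growing versus all others ($\mathrm{OR} = ad/bc$, with the
Haldane–Anscombe 0.5 correction for empty cells, Fisher's exact
p-value).

## Variant processing

Upstream of the model, raw UMI-tagged reads are collapsed by
`dedup_umis()`: reads sharing a (probe, UMI) pair came from one source
molecule and contribute one consensus observation, taken as the
majority allele; exact ties are dropped rather than broken arbitrarily,
keeping the operation deterministic. The candidate caller is a
one-sided exact binomial test of the alternate count against the
per-base error rate — a transparent stand-in preserving the contract of
a somatic caller (calls with p-values) at simulation scale; externally
produced VCFs can be supplied instead through `read_site_vcf()`.

Post-call filters follow the standard somatic thresholds, inclusive at
every boundary: depth $\ge 40$, alternate reads $\ge 5$, VAF
$\ge 0.1\%$. Variants seen in at least 5% of samples at VAFs inside the
closed 1–10% window are flagged as recurrent artifacts everywhere. The
artifact rule counts *samples*, not subjects; with multiple timepoints
per subject this is the more conservative reading and is the one
implemented. All thresholds live in `pipeline_config()`, in one place.

## CHIP calling

Driver annotation is configuration-driven: a YAML whitelist with one
block per gene giving the accepted functional classes (e.g. the
truncating set for tumor-suppressor-like genes), explicit hotspot
protein changes (e.g. JAK2 V617F), and a population allele-frequency
ceiling for germline exclusion (default 0.001). The shipped whitelist
covers the 15 genes of a typical CHIP panel — 11 fully tiled genes plus
4 hotspot-only targets — with *ZBTB33* and *ZNF318* additionally
accepting any nonsynonymous change. The hotspot lists are illustrative
defaults meant to be edited; the annotation logic, not a specific
mutation list, is the tested content. Functional classes are consumed
as an input column, as produced by any annotator; no consequence
prediction is performed.

## The simulator

`simulate_cohort()` generates the study conditions the analysis
assumes, and its defaults are fixed at realistic values rather than
tuned: baseline ages uniform on 50–79; visit gaps (1, 2, 3, 3, 6.4)
years so six visits span ~15.4 years; read depths lognormal with median
2803 (the depth scale of a UMI-deduplicated targeted panel); per-base
substitution error 0.045%; clones per subject Poisson with mean 1.2;
gene frequencies following the familiar CHIP spectrum (*DNMT3A* 57%,
*TET2* 19%, *ASXL1* 6%, the remainder spread over 12 genes); baseline
VAFs log-uniform on 0.2–15%; and a growth-rate mixture with half the
clones growing (|slope| centred near 0.045/yr, i.e. doubling every
~6.7 years), a quarter shrinking, and a quarter near-static. The
growth-rate distribution is *illustrative*: the real distribution of
clonal fitness effects is not identified by any single printed number,
so these defaults exist to exercise the pipeline, not to estimate
biology. Covariates (BMI, smoking, race/ethnicity, first-visit year)
are independent draws from plausible marginals, with an optional BMI
effect on baseline log-VAF to give the association stage signal.

Read counts at clone sites are binomial with effective success
probability $p = v(1-e) + (1-v)e/3$ (a true alternate read survives
unless mis-read; a reference read is mis-read as this particular
alternate a third of the time). Invariant background sites instead pool
all three substitution classes, $\mathrm{Binomial}(d, e)$, because that
is what an error-rate estimator sees. Clone VAF trajectories are exact
exponentials capped at 0.5 — clones are heterozygous, so a fully clonal
sample sits at 50% VAF — with a constant per-clone slope (no
age-varying fitness), matching the model the pipeline fits. What the
simulator does **not** emulate keeps the recovery tests honest about
real data: no indels or multi-nucleotide events, no alignment or
strand artifacts, no batch effects, no UMI collisions beyond random
9-mers, and no clone interactions — passing recovery tests demonstrate
correctness of the estimator under its own assumptions, not robustness
to every failure mode of real sequencing.

## Assay validation

The validation module reproduces the arithmetic used to qualify a
panel against defined gDNA mixtures. For cell lines mixed at
proportions $p_i$ with genotype dosages $g_i \in \{0,1,2\}$, the
expected VAF is $\sum_i p_i g_i / 2$; the standard five-line mixture at
78.8/16/4/1/0.25% spans expected VAFs from 0.125% (a heterozygote
private to the rarest line) to 100%. The printed proportions sum to
100.05% — they are rounded bench values — so `five_line_mixture()`
renormalizes them; the attainable minimum is then 0.12494%, the printed
0.125% at printed precision.

The error rate is estimated as pooled non-reference reads over pooled
reads at invariant sites (a ratio estimator, invariant to how reads are
split across sites — not a mean of per-site rates). Replicate
reliability uses the one-way random-effects intraclass correlation
ICC(1), $(MS_B - MS_W)/(MS_B + (k_0-1)MS_W)$, chosen because replicates
of the same mixture are interchangeable measurements with no
replicate-specific effect worth modelling; the 95% CI comes from
F-distribution bounds. Concordance between observed and expected VAFs
is plain Pearson correlation on the untransformed scale, overall and
split at 2% expected VAF, computed on replicate-mean VAFs.

## Association stage

Cross-sectional models at the first draw relate CHIP prevalence
(logistic) or log10 VAF (linear) to age, race/ethnicity, smoking and
BMI; the longitudinal model regresses the dominant clone's log10 VAF
change on the same covariates. Both adjust for first-visit calendar
year — "time of year" is read as calendar year of enrollment, an
assumption documented here because season would be an alternative
reading. Missing covariates are handled by complete-case analysis with
logged exclusion counts. Singular designs fail loudly, naming the
aliased term.

## Problem sizes and determinism

Every stochastic component takes or derives from a single integer
seed, and equal configurations give byte-identical outputs (the test
suite hashes written files to enforce this). The shipped tests run the
validation surrogate at the experiment's own scale (152 sites x 27
replicates at depth 2803), classification recovery on 500 simulated
clones, and cohort pipelines of 20-50 subjects — sizes chosen so the
whole suite completes in well under a minute while keeping Monte-Carlo
error far below every asserted margin.

## Known limitations

* The binomial caller is a stand-in: it shares LoFreq's contract, not
  its error model; quality scores and strand information do not exist
  here.
* Indels pass through the data model untested; the simulator emits
  SNVs only.
* The trajectory model is a single exponential per clone; logistic
  saturation, subclonal structure and mosaic chromosomal alterations
  are out of scope.
* The whitelist ships with illustrative hotspot lists, not a complete
  mutation query catalogue.
* Two-timepoint subjects receive direction calls but no significance
  statement, and subjects with a single timepoint contribute only to
  prevalence.
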
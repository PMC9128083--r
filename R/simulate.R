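# Synthetic longitudinal CHIP cohorts: clone trajectories, binomial read
# counts, UMI-tagged raw reads, and defined cell-line mixtures.

# Synthetic panel loci (GRCh37-like coordinates, one anchor per gene).
# Hotspot genes carry a canonical protein change used for annotation.
.panel_loci <- data.frame(
  gene  = c("DNMT3A", "TET2", "ASXL1", "PPM1D", "JAK2", "CBL", "SF3B1",
            "TP53", "ZBTB33", "ZNF318", "SRSF2", "GNB1", "U2AF1",
            "IDH1", "IDH2"),
  chrom = c("2", "4", "20", "17", "9", "11", "2",
            "17", "X", "6", "17", "1", "21", "2", "15"),
  base  = c(25457000L, 106155000L, 31017000L, 58677000L, 5073770L,
            119148000L, 198266000L, 7574000L, 119384000L, 43337000L,
            74732959L, 1747000L, 44514000L, 209113112L, 90631934L),
  hotspot = c(FALSE, FALSE, FALSE, FALSE, TRUE, FALSE, FALSE, FALSE,
              FALSE, FALSE, TRUE, FALSE, FALSE, TRUE, TRUE),
  hotspot_change = c(NA, NA, NA, NA, "V617F", NA, NA, NA, NA, NA,
                     "P95H", NA, NA, "R132H", "R140Q"),
  stringsAsFactors = FALSE
)

# Default driver-gene spectrum (fractions sum to 1); modelled on the
# baseline mutation spectrum of large CHIP cohorts (DNMT3A >> TET2 >>
# ASXL1 >> the rest) and editable through cohort_config().
.default_gene_freq <- c(
  DNMT3A = 0.570, TET2 = 0.190, ASXL1 = 0.060, PPM1D = 0.035, JAK2 = 0.030,
  CBL = 0.020, SF3B1 = 0.020, TP53 = 0.020, ZBTB33 = 0.015, ZNF318 = 0.010,
  SRSF2 = 0.010, GNB1 = 0.008, U2AF1 = 0.005, IDH1 = 0.0035, IDH2 = 0.0035
)

#' Configuration for a simulated longitudinal CHIP cohort
#'
#' Collects every parameter of the cohort simulator. Defaults emulate a
#' longitudinal post-menopausal cohort profiled by targeted deep sequencing:
#' baseline ages 50-79, up to six visits spanning roughly 16 years, read
#' depths lognormal around a median of 2803, and a per-base substitution
#' error rate of 0.045%.
#'
#' @param n_subjects number of subjects.
#' @param timepoints_per_subject integer vector of length 1 or `n_subjects`
#'   giving the number of sequenced visits (1-6), or `NULL` to draw from
#'   `timepoint_probs`.
#' @param timepoint_probs sampling weights over 1-6 visits, used when
#'   `timepoints_per_subject` is `NULL`.
#' @param baseline_age_range range (years) of age at first draw.
#' @param inter_visit_gaps gaps (years) between successive visits; the
#'   default visit schedule (1, 2, 3, 3, 6.4) spans ~15.4 years over six
#'   visits.
#' @param clone_rate expected number of driver clones per subject
#'   (Poisson mean).
#' @param gene_frequencies named probability vector over driver genes;
#'   must sum to 1.
#' @param growth_rate_fn function of `n` returning per-year slopes of
#'   log10(VAF); the default is a mixture with growing, shrinking and
#'   near-static mass.
#' @param initial_vaf_fn function of `n` returning baseline VAFs in
#'   (0, 0.5].
#' @param depth_fn function of `n` returning positive integer read depths;
#'   default lognormal with median 2803.
#' @param error_rate per-base substitution probability (default 0.00045).
#' @param umi_duplication_rate expected raw reads per unique molecule
#'   (must be >= 1).
#' @param n_background_sites invariant panel sites carried per sample
#'   (used for error-rate estimation and caller calibration).
#' @param vaf_ceiling heterozygous clone-size ceiling (default 0.5).
#' @param bmi_vaf_effect optional linear effect of (BMI - 28.5) on
#'   log10 baseline VAF, to exercise the association stage.
#' @param seed integer seed fixing all simulator output.
#'
#' @return an object of class `cohort_config` (a validated list).
#' @export
cohort_config <- function(n_subjects = 50L,
                          timepoints_per_subject = NULL,
                          timepoint_probs = c(0.10, 0.15, 0.25, 0.20, 0.15, 0.15),
                          baseline_age_range = c(50, 79),
                          inter_visit_gaps = c(1, 2, 3, 3, 6.4),
                          clone_rate = 1.2,
                          gene_frequencies = .default_gene_freq,
                          growth_rate_fn = NULL,
                          initial_vaf_fn = NULL,
                          depth_fn = NULL,
                          error_rate = 0.00045,
                          umi_duplication_rate = 3,
                          n_background_sites = 20L,
                          vaf_ceiling = 0.5,
                          bmi_vaf_effect = 0,
                          seed = 1L) {
  growth_rate_fn <- growth_rate_fn %||% function(n) {
    comp <- sample.int(3L, n, replace = TRUE, prob = c(0.5, 0.25, 0.25))
    out <- numeric(n)
    out[comp == 1L] <- abs(stats::rnorm(sum(comp == 1L), 0.045, 0.020))
    out[comp == 2L] <- -abs(stats::rnorm(sum(comp == 2L), 0.030, 0.015))
    out[comp == 3L] <- stats::rnorm(sum(comp == 3L), 0, 0.005)
    out
  }
  initial_vaf_fn <- initial_vaf_fn %||% function(n) {
    10^stats::runif(n, log10(0.002), log10(0.15))
  }
  depth_fn <- depth_fn %||% function(n) {
    pmax(40L, as.integer(round(stats::rlnorm(n, log(2803), 0.35))))
  }
  cfg <- structure(list(
    n_subjects = as.integer(n_subjects),
    timepoints_per_subject = timepoints_per_subject,
    timepoint_probs = timepoint_probs,
    baseline_age_range = baseline_age_range,
    inter_visit_gaps = inter_visit_gaps,
    clone_rate = clone_rate,
    gene_frequencies = gene_frequencies,
    growth_rate_fn = growth_rate_fn,
    initial_vaf_fn = initial_vaf_fn,
    depth_fn = depth_fn,
    error_rate = error_rate,
    umi_duplication_rate = umi_duplication_rate,
    n_background_sites = as.integer(n_background_sites),
    vaf_ceiling = vaf_ceiling,
    bmi_vaf_effect = bmi_vaf_effect,
    seed = as.integer(seed)
  ), class = "cohort_config")
  validate_cohort_config(cfg)
}

#' @rdname cohort_config
#' @param config a `cohort_config` object.
#' @export
validate_cohort_config <- function(config) {
  if (!inherits(config, "cohort_config")) stop("not a cohort_config")
  if (config$n_subjects < 1L) stop("n_subjects must be >= 1")
  gf <- config$gene_frequencies
  if (is.null(names(gf)) || any(names(gf) == ""))
    stop("gene_frequencies must be a named vector")
  stopifnot_prob(gf, "gene_frequencies")
  if (abs(sum(gf) - 1) > 1e-9)
    stop("gene_frequencies must sum to 1 (got ", sum(gf), ")")
  if (!all(names(gf) %in% .panel_loci$gene))
    stop("unknown gene(s): ",
         paste(setdiff(names(gf), .panel_loci$gene), collapse = ", "))
  stopifnot_prob(config$error_rate, "error_rate")
  if (config$umi_duplication_rate < 1)
    stop("umi_duplication_rate must be >= 1")
  if (config$clone_rate < 0) stop("clone_rate must be >= 0")
  if (!is.null(config$timepoints_per_subject)) {
    tp <- config$timepoints_per_subject
    if (any(tp < 1L | tp > 6L)) stop("timepoints_per_subject must be in 1..6")
    if (!length(tp) %in% c(1L, config$n_subjects))
      stop("timepoints_per_subject must have length 1 or n_subjects")
  }
  if (config$vaf_ceiling <= 0 || config$vaf_ceiling > 1)
    stop("vaf_ceiling must be in (0, 1]")
  config
}

#' Noiseless clone VAF under exponential growth
#'
#' A clone's VAF follows `vaf0 * 10^(beta * (age - age0))` on the log10
#' scale, capped at the heterozygous ceiling.
#'
#' @param vaf0 baseline VAF.
#' @param beta per-year slope of log10(VAF).
#' @param age,age0 current and baseline age in years.
#' @param ceiling maximum VAF (default 0.5, heterozygous clone).
#' @return the true VAF at `age`.
#' @export
true_clone_vaf <- function(vaf0, beta, age, age0, ceiling = 0.5) {
  pmin(ceiling, vaf0 * 10^(beta * (age - age0)))
}

#' Simulate read counts at a single variant site
#'
#' Draws an alternate-allele read count `Binomial(depth, p_eff)` with
#' `p_eff = vaf * (1 - e) + (1 - vaf) * e / 3`: a true alternate read
#' survives unless it is mis-read (rate `e`), and a reference read is
#' mis-read as this specific alternate base with rate `e / 3`.
#'
#' @param true_vaf true variant allele fraction(s) in `[0, 1]`.
#' @param depth read depth(s), positive integers.
#' @param error_rate per-base substitution probability.
#' @param seed optional integer seed.
#' @return integer vector of alternate read counts.
#' @export
simulate_site_reads <- function(true_vaf, depth, error_rate, seed = NULL) {
  stopifnot_prob(true_vaf, "true_vaf")
  stopifnot_prob(error_rate, "error_rate")
  if (any(depth <= 0) || any(depth != round(depth)))
    stop("depth must be a positive integer")
  if (!is.null(seed)) set.seed(seed)
  p_eff <- true_vaf * (1 - error_rate) + (1 - true_vaf) * error_rate / 3
  stats::rbinom(max(length(true_vaf), length(depth)), depth, p_eff)
}

#' Simulate invariant (error-only) sites
#'
#' Draws total non-reference read counts at sites with no true variant,
#' pooling the three substitution classes: `Binomial(depth, error_rate)`.
#' These are the inputs to [estimate_error_rate()].
#'
#' @param n_sites number of invariant sites.
#' @param depth read depth (scalar or per-site).
#' @param error_rate per-base substitution probability.
#' @param seed optional integer seed.
#' @return data frame with `site`, `depth`, `nonref_count`.
#' @export
simulate_invariant_sites <- function(n_sites, depth, error_rate, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  depth <- rep_len(depth, n_sites)
  data.frame(
    site = seq_len(n_sites),
    depth = depth,
    nonref_count = stats::rbinom(n_sites, depth, error_rate)
  )
}

# one synthetic variant per clone, hotspot-aware annotation
.draw_clone_variants <- function(genes) {
  loci <- .panel_loci[match(genes, .panel_loci$gene), ]
  n <- length(genes)
  bases <- c("A", "C", "G", "T")
  pos <- integer(n); fclass <- character(n); pchange <- character(n)
  for (i in seq_len(n)) {
    if (loci$hotspot[i]) {
      pos[i] <- loci$base[i]
      fclass[i] <- "missense"
      pchange[i] <- loci$hotspot_change[i]
    } else if (genes[i] == "DNMT3A" && stats::runif(1) < 0.10) {
      pos[i] <- loci$base[i] + 3999L            # R882 hotspot stand-in
      fclass[i] <- "missense"
      pchange[i] <- sample(c("R882H", "R882C"), 1)
    } else {
      pos[i] <- loci$base[i] + sample.int(3000L, 1)
      fclass[i] <- sample(c("nonsense", "frameshift", "splice"), 1)
      pchange[i] <- paste0("Q", sample.int(900L, 1), "*")
    }
  }
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
  data.frame(gene = genes, chrom = loci$chrom, pos = pos, ref = ref, alt = alt,
             functional_class = fclass, protein_change = pchange,
             pop_af = 0, stringsAsFactors = FALSE)
}

#' Simulate a longitudinal CHIP cohort
#'
#' Generates subjects with 1-6 sequenced visits, per-subject driver clones
#' with exponential (log10-linear) VAF trajectories, binomial read counts
#' at clone sites, invariant background sites, and a sample manifest with
#' covariates. Fully reproducible under the configured seed.
#'
#' @param config a [cohort_config()] object.
#' @return a list with components
#'   \describe{
#'     \item{truth}{one row per simulated clone: subject, gene, variant,
#'       `beta_true`, `vaf_baseline`, annotation columns.}
#'     \item{observations}{one row per (sample, site): `sample_id`,
#'       `subject_id`, `timepoint`, site coordinates, `depth`, `alt_count`,
#'       `vaf`, and `site_class` ("clone" or "background"). Background-site
#'       `alt_count` pools all non-reference reads.}
#'     \item{manifest}{one row per sample: `sample_id`, `subject_id`,
#'       `timepoint`, `age`, covariates.}
#'     \item{annotations}{variant-level annotation table for the driver
#'       whitelist stage.}
#'   }
#' @export
simulate_cohort <- function(config) {
  config <- validate_cohort_config(config)
  set.seed(config$seed)
  ns <- config$n_subjects
  subj <- sprintf("S%03d", seq_len(ns))

  ntp <- config$timepoints_per_subject
  if (is.null(ntp)) {
    ntp <- sample.int(6L, ns, replace = TRUE, prob = config$timepoint_probs)
  } else ntp <- rep_len(as.integer(ntp), ns)

  age0 <- stats::runif(ns, config$baseline_age_range[1], config$baseline_age_range[2])
  offsets <- c(0, cumsum(config$inter_visit_gaps))

  race <- sample(c("White", "Black", "Hispanic", "Asian"), ns, replace = TRUE,
                 prob = c(0.60, 0.20, 0.12, 0.08))
  smoking <- sample(c("Never", "Former", "Current"), ns, replace = TRUE,
                    prob = c(0.50, 0.35, 0.15))
  bmi <- pmax(15, stats::rnorm(ns, 28.5, 5.5))
  first_year <- sample(1993:1998, ns, replace = TRUE)

  manifest <- do.call(rbind, lapply(seq_len(ns), function(i) {
    tp <- seq_len(ntp[i])
    data.frame(
      sample_id = paste0(subj[i], "_T", tp),
      subject_id = subj[i], timepoint = tp,
      age = age0[i] + offsets[tp],
      race = race[i], smoking = smoking[i], bmi = bmi[i],
      first_visit_year = first_year[i], stringsAsFactors = FALSE
    )
  }))
  rownames(manifest) <- NULL

  # clones
  n_clones <- stats::rpois(ns, config$clone_rate)
  total <- sum(n_clones)
  if (total > 0) {
    genes <- sample(names(config$gene_frequencies), total, replace = TRUE,
                    prob = config$gene_frequencies)
    vars <- .draw_clone_variants(genes)
    vafs0 <- pmin(config$vaf_ceiling, config$initial_vaf_fn(total))
    betas <- config$growth_rate_fn(total)
    owner <- rep(seq_len(ns), n_clones)
    if (config$bmi_vaf_effect != 0)
      vafs0 <- pmin(config$vaf_ceiling,
                    vafs0 * 10^(config$bmi_vaf_effect * (bmi[owner] - 28.5)))
    truth <- data.frame(
      subject_id = subj[owner],
      clone_id = paste0(subj[owner], "_c", sequence(n_clones)),
      vars,
      variant_id = variant_key(vars$chrom, vars$pos, vars$ref, vars$alt),
      beta_true = betas, vaf_baseline = vafs0,
      age_baseline = age0[owner], stringsAsFactors = FALSE
    )
  } else {
    truth <- data.frame(subject_id = character(), clone_id = character(),
                        gene = character(), chrom = character(), pos = integer(),
                        ref = character(), alt = character(),
                        functional_class = character(), protein_change = character(),
                        pop_af = numeric(), variant_id = character(),
                        beta_true = numeric(), vaf_baseline = numeric(),
                        age_baseline = numeric(), stringsAsFactors = FALSE)
  }

  # shared invariant background sites
  nb <- config$n_background_sites
  bg <- NULL
  if (nb > 0) {
    bgl <- .panel_loci[sample.int(nrow(.panel_loci), nb, replace = TRUE), ]
    bases <- c("A", "C", "G", "T")
    bref <- sample(bases, nb, replace = TRUE)
    balt <- vapply(bref, function(r) sample(setdiff(bases, r), 1), character(1))
    bg <- data.frame(chrom = bgl$chrom, pos = bgl$base + 10000L + sample.int(5000L, nb),
                     ref = bref, alt = balt, stringsAsFactors = FALSE)
  }

  obs <- vector("list", nrow(manifest))
  for (r in seq_len(nrow(manifest))) {
    sid <- manifest$subject_id[r]
    age <- manifest$age[r]
    cl <- truth[truth$subject_id == sid, , drop = FALSE]
    rows <- NULL
    if (nrow(cl) > 0) {
      tv <- true_clone_vaf(cl$vaf_baseline, cl$beta_true, age, cl$age_baseline,
                           config$vaf_ceiling)
      dp <- config$depth_fn(nrow(cl))
      ac <- simulate_site_reads(tv, dp, config$error_rate)
      rows <- data.frame(chrom = cl$chrom, pos = cl$pos, ref = cl$ref,
                         alt = cl$alt, depth = dp, alt_count = ac,
                         site_class = "clone", stringsAsFactors = FALSE)
    }
    if (!is.null(bg)) {
      dp <- config$depth_fn(nb)
      ac <- stats::rbinom(nb, dp, config$error_rate)
      rows <- rbind(rows, data.frame(chrom = bg$chrom, pos = bg$pos,
                                     ref = bg$ref, alt = bg$alt, depth = dp,
                                     alt_count = ac, site_class = "background",
                                     stringsAsFactors = FALSE))
    }
    if (is.null(rows)) next
    obs[[r]] <- data.frame(sample_id = manifest$sample_id[r],
                           subject_id = sid, timepoint = manifest$timepoint[r],
                           rows, stringsAsFactors = FALSE)
  }
  observations <- do.call(rbind, obs)
  if (!is.null(observations)) {
    observations$vaf <- observations$alt_count / observations$depth
    observations$variant_id <- variant_key(observations$chrom, observations$pos,
                                           observations$ref, observations$alt)
    rownames(observations) <- NULL
  }

  annotations <- unique(truth[, c("variant_id", "gene", "functional_class",
                                  "protein_change", "pop_af")])
  rownames(annotations) <- NULL
  list(truth = truth, observations = observations, manifest = manifest,
       annotations = annotations)
}

#' Expand site observations into UMI-tagged raw read records
#'
#' Each unique source molecule receives a distinct 9-mer UMI within its
#' probe and is emitted `1 + Poisson(rate - 1)` times. Duplicate copies
#' carry the molecule's allele, except for an optional per-copy
#' substitution error.
#'
#' @param observations data frame with `chrom`, `pos`, `ref`, `alt`,
#'   `depth`, `alt_count` (one row per site).
#' @param umi_duplication_rate expected raw reads per molecule (>= 1).
#' @param per_copy_error probability that a duplicate copy is mis-read as
#'   the other allele (default 0).
#' @param seed optional integer seed.
#' @return data frame of raw read records: `probe_id`, `umi`, `chrom`,
#'   `pos`, `ref`, `alt`, `observed_allele`.
#' @export
simulate_umi_reads <- function(observations, umi_duplication_rate,
                               per_copy_error = 0, seed = NULL) {
  if (umi_duplication_rate < 1) stop("umi_duplication_rate must be >= 1")
  stopifnot_prob(per_copy_error, "per_copy_error")
  if (!is.null(seed)) set.seed(seed)
  out <- vector("list", nrow(observations))
  for (i in seq_len(nrow(observations))) {
    o <- observations[i, ]
    n_mol <- o$depth
    if (n_mol == 0) next
    probe <- paste0("probe_", o$chrom, "_", o$pos)
    umis <- random_umis(n_mol)
    allele <- c(rep(o$alt, o$alt_count), rep(o$ref, n_mol - o$alt_count))
    copies <- 1L + stats::rpois(n_mol, umi_duplication_rate - 1)
    idx <- rep(seq_len(n_mol), copies)
    obs_allele <- allele[idx]
    if (per_copy_error > 0) {
      flip <- stats::runif(length(idx)) < per_copy_error
      obs_allele[flip] <- ifelse(obs_allele[flip] == o$ref, o$alt, o$ref)
    }
    out[[i]] <- data.frame(
      probe_id = probe, umi = umis[idx], chrom = o$chrom, pos = o$pos,
      ref = o$ref, alt = o$alt, observed_allele = obs_allele,
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Specification of a defined multi-line gDNA mixture
#'
#' @param proportions numeric vector of line proportions, summing to 1
#'   (within 1e-9). Names are line identifiers.
#' @param dosages integer matrix (variants x lines) of genotype dosages in
#'   \{0, 1, 2\}, or a vector for a single variant.
#' @return object of class `mixture_spec`.
#' @export
mixture_spec <- function(proportions, dosages = NULL) {
  if (abs(sum(proportions) - 1) > 1e-9)
    stop("mixture proportions must sum to 1 (got ", sum(proportions), ")")
  stopifnot_prob(proportions, "proportions")
  if (is.null(names(proportions)))
    names(proportions) <- paste0("line", seq_along(proportions))
  if (!is.null(dosages)) {
    if (is.vector(dosages)) dosages <- matrix(dosages, nrow = 1)
    if (ncol(dosages) != length(proportions))
      stop("dosages must have one column per line")
    if (!all(dosages %in% c(0, 1, 2)))
      stop("dosages must be in {0, 1, 2}")
  }
  structure(list(proportions = proportions, dosages = dosages),
            class = "mixture_spec")
}

#' The five-line validation mixture
#'
#' Convenience constructor for the standard five-way control mixture with
#' line proportions 78.8, 16, 4, 1 and 0.25%. The nominal percentages sum
#' to 100.05 (they are rounded bench values), so they are renormalized to
#' exact proportions.
#' @param dosages optional dosage matrix, see [mixture_spec()].
#' @return a `mixture_spec`.
#' @export
five_line_mixture <- function(dosages = NULL) {
  p <- c(lineA = 78.8, lineB = 16, lineC = 4, lineD = 1, lineE = 0.25)
  mixture_spec(p / sum(p), dosages)
}

#' Simulate replicate sequencing of a defined mixture
#'
#' Per-variant true VAF is the expected mixture VAF (proportion-weighted
#' mean of dosage / 2); read counts are binomial as in
#' [simulate_site_reads()].
#'
#' @param mixture a [mixture_spec()] with a dosage matrix.
#' @param depth read depth per measurement (scalar or per-variant).
#' @param error_rate per-base substitution probability.
#' @param n_replicates number of replicate measurements.
#' @param seed optional integer seed.
#' @return data frame with one row per (replicate, variant):
#'   `replicate`, `variant`, `expected_vaf`, `depth`, `alt_count`, `vaf`.
#' @export
simulate_mixture <- function(mixture, depth = 2803L, error_rate = 0.00045,
                             n_replicates = 27L, seed = NULL) {
  if (!inherits(mixture, "mixture_spec")) stop("mixture must be a mixture_spec")
  if (is.null(mixture$dosages)) stop("mixture has no dosage matrix")
  if (!is.null(seed)) set.seed(seed)
  ev <- expected_mixture_vaf(mixture)
  nv <- length(ev)
  depth <- rep_len(as.integer(depth), nv)
  out <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    ac <- simulate_site_reads(ev, depth, error_rate)
    out[[r]] <- data.frame(replicate = r, variant = seq_len(nv),
                           expected_vaf = ev, depth = depth, alt_count = ac,
                           vaf = ac / depth)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
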
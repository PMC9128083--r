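# Cohort-level trajectory analysis: eligibility filtering, per-mutation
# fits, dominant-clone selection, competition and gene-group comparisons.

#' Assemble eligible longitudinal trajectories
#'
#' Joins per-timepoint driver observations with the manifest ages and
#' applies the trajectory eligibility rules: subjects must have at least
#' `min_timepoints` sequenced visits and at least one driver mutation
#' exceeding `min_peak_vaf` at some visit. Observations with depth below
#' `min_depth` are dropped as unassayed; observations with adequate depth
#' but fewer than `min_alt` alternate reads are recorded as VAF 0
#' (undetected at an informative depth).
#'
#' @param drivers per-timepoint observations of driver mutations:
#'   `subject_id`, `timepoint`, `gene`, `variant_id`, `depth`,
#'   `alt_count`, `vaf`.
#' @param manifest manifest with `subject_id`, `timepoint`, `age`.
#' @param min_timepoints minimum sequenced visits per subject (default 3).
#' @param min_peak_vaf minimum peak VAF (strict `>`) required of at least
#'   one driver per subject (default 0.01).
#' @param min_depth minimum site depth for a retained observation
#'   (default 200).
#' @param min_alt minimum alternate reads for a detection (default 2).
#' @return long data frame of retained observations, one row per
#'   (mutation, timepoint): `subject_id`, `gene`, `variant_id`,
#'   `protein_change` (if present), `timepoint`, `age`, `depth`,
#'   `alt_count`, `vaf`; ordered by subject, variant, age.
#' @export
assemble_trajectories <- function(drivers, manifest, min_timepoints = 3L,
                                  min_peak_vaf = 0.01, min_depth = 200L,
                                  min_alt = 2L) {
  n_tp <- table(manifest$subject_id)
  eligible_subj <- names(n_tp)[n_tp >= min_timepoints]

  d <- drivers[drivers$subject_id %in% eligible_subj, , drop = FALSE]
  if (nrow(d) == 0) return(d)

  # ages from the manifest; subjects with missing ages are excluded
  mkey <- paste(manifest$subject_id, manifest$timepoint)
  d$age <- manifest$age[match(paste(d$subject_id, d$timepoint), mkey)]
  no_age <- is.na(d$age)
  if (any(no_age)) {
    message("assemble_trajectories: excluded ", sum(no_age),
            " observation(s) with no manifest age")
    d <- d[!no_age, , drop = FALSE]
  }

  # subject must carry a driver above the peak-VAF threshold
  peak <- tapply(d$vaf, d$subject_id, max)
  keep_subj <- names(peak)[peak > min_peak_vaf]
  d <- d[d$subject_id %in% keep_subj, , drop = FALSE]

  # depth rule: < min_depth -> unassayed (dropped);
  # adequate depth but < min_alt alternate reads -> VAF 0 (undetected)
  d <- d[d$depth >= min_depth, , drop = FALSE]
  undetected <- d$alt_count < min_alt
  d$vaf[undetected] <- 0
  d$alt_count[undetected] <- 0L

  d <- d[order(d$subject_id, d$variant_id, d$age), , drop = FALSE]
  rownames(d) <- NULL
  d
}

#' Exclude trajectories starting above the exponential-model range
#'
#' Removes trajectories whose first retained observation has VAF strictly
#' above `max_start_vaf`, for which an exponential growth assumption may
#' not hold; a starting VAF exactly at the bound is retained.
#'
#' @param trajectories output of [assemble_trajectories()].
#' @param max_start_vaf starting-VAF bound (default 0.10).
#' @return filtered trajectory table.
#' @export
exclude_high_start <- function(trajectories, max_start_vaf = 0.10) {
  if (nrow(trajectories) == 0) return(trajectories)
  key <- paste(trajectories$subject_id, trajectories$variant_id)
  first_idx <- !duplicated(key)  # rows sorted by age within mutation
  start_vaf <- trajectories$vaf[first_idx][match(key, key[first_idx])]
  out <- trajectories[start_vaf <= max_start_vaf, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Fit growth models to every assembled trajectory
#'
#' Applies [chip_growth()] per mutation. Mutations with fewer than two
#' retained observations at distinct ages are skipped. Mutations with
#' exactly two timepoints are classified only by the sign of the VAF
#' change (growing vs non-growing) and receive no p-value.
#'
#' @param trajectories output of [assemble_trajectories()] (optionally
#'   after [exclude_high_start()]).
#' @param vaf_floor,p_threshold passed to [chip_growth()].
#' @return data frame with one row per mutation: `subject_id`, `gene`,
#'   `variant_id`, `n_obs`, `C`, `beta`, `p_value`, `label`,
#'   `doubling_period`.
#' @export
fit_trajectories <- function(trajectories, vaf_floor = 1e-4,
                             p_threshold = 0.5) {
  if (nrow(trajectories) == 0)
    return(data.frame(subject_id = character(), gene = character(),
                      variant_id = character(), n_obs = integer(),
                      C = numeric(), beta = numeric(), p_value = numeric(),
                      label = character(), doubling_period = numeric()))
  key <- paste(trajectories$subject_id, trajectories$variant_id, sep = "\r")
  pieces <- split(trajectories, key)
  rows <- lapply(pieces, function(tr) {
    if (nrow(tr) < 2L || length(unique(tr$age)) < 2L) return(NULL)
    fit <- chip_growth(vaf ~ age, tr, depth = depth, vaf_floor = vaf_floor,
                       p_threshold = p_threshold)
    label <- fit$label
    if (nrow(tr) == 2L) {
      # two-timepoint subjects: direction only, no significance test
      label <- if (fit$coefficients[2] > 0) "growing" else "non-growing"
    }
    data.frame(subject_id = tr$subject_id[1], gene = tr$gene[1],
               variant_id = tr$variant_id[1], n_obs = nrow(tr),
               C = unname(fit$coefficients[1]),
               beta = unname(fit$coefficients[2]),
               p_value = fit$p.value, label = label,
               doubling_period = fit$doubling_period,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(fit_trajectories(trajectories[0, , drop = FALSE]))
  out <- out[order(out$subject_id, out$variant_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Select each subject's dominant clone
#'
#' The dominant clone is the mutation with the highest VAF at any
#' timepoint; ties break to the larger final VAF, then lexicographic
#' variant id. Requires at least one trajectory with two or more
#' non-zero VAFs. The log10 change `delta_log10_vaf` is last non-zero
#' VAF minus first non-zero VAF, on the log10 scale.
#'
#' @param trajectories assembled trajectory observations for one or more
#'   subjects.
#' @return data frame with one row per subject owning a dominant clone:
#'   `subject_id`, `variant_id`, `gene`, `peak_vaf`, `delta_log10_vaf`.
#' @export
select_dominant <- function(trajectories) {
  out <- lapply(split(trajectories, trajectories$subject_id), function(tr) {
    stats_by_var <- lapply(split(tr, tr$variant_id), function(v) {
      nz <- v$vaf[v$vaf > 0]
      list(variant_id = v$variant_id[1], gene = v$gene[1],
           peak = max(v$vaf), final = v$vaf[nrow(v)], n_nonzero = length(nz),
           delta = if (length(nz) >= 2) log10(nz[length(nz)]) - log10(nz[1])
                   else NA_real_)
    })
    ok <- vapply(stats_by_var, function(s) s$n_nonzero >= 2L, logical(1))
    if (!any(ok)) return(NULL)
    cand <- stats_by_var[ok]
    peaks <- vapply(cand, `[[`, numeric(1), "peak")
    finals <- vapply(cand, `[[`, numeric(1), "final")
    ids <- vapply(cand, `[[`, character(1), "variant_id")
    ord <- order(-peaks, -finals, ids)
    ch <- cand[[ord[1]]]
    data.frame(subject_id = tr$subject_id[1], variant_id = ch$variant_id,
               gene = ch$gene, peak_vaf = ch$peak,
               delta_log10_vaf = ch$delta, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(res))
    return(data.frame(subject_id = character(), variant_id = character(),
                      gene = character(), peak_vaf = numeric(),
                      delta_log10_vaf = numeric()))
  rownames(res) <- NULL
  res
}

#' Report co-occurring clone trajectories within subjects
#'
#' For each subject carrying two or more fitted trajectories, lists every
#' clone with its label and flags a "competition candidate" when a
#' non-growing clone that reached the CHIP threshold co-occurs with a
#' growing clone in the same subject.
#'
#' @param fits per-mutation fit table from [fit_trajectories()].
#' @param trajectories assembled observations (for peak VAFs).
#' @param chip_vaf CHIP threshold on the non-growing clone's peak VAF
#'   (default 0.02).
#' @return data frame: one row per clone in multi-clone subjects, with
#'   `label`, `peak_vaf`, and a subject-level `competition` flag.
#' @export
competition_report <- function(fits, trajectories, chip_vaf = 0.02) {
  if (nrow(fits) == 0)
    return(data.frame(subject_id = character(), variant_id = character(),
                      gene = character(), label = character(),
                      peak_vaf = numeric(), competition = logical()))
  key <- paste(trajectories$subject_id, trajectories$variant_id)
  peak <- tapply(trajectories$vaf, key, max)
  fits$peak_vaf <- as.numeric(peak[paste(fits$subject_id, fits$variant_id)])
  multi <- names(which(table(fits$subject_id) >= 2L))
  fits <- fits[fits$subject_id %in% multi, , drop = FALSE]
  if (nrow(fits) == 0)
    return(data.frame(subject_id = character(), variant_id = character(),
                      gene = character(), label = character(),
                      peak_vaf = numeric(), competition = logical()))
  comp <- vapply(split(fits, fits$subject_id), function(f) {
    any(f$label == "growing", na.rm = TRUE) &&
      any(f$label %in% c("shrinking", "static", "non-growing") &
            f$peak_vaf >= chip_vaf, na.rm = TRUE)
  }, logical(1))
  fits$competition <- unname(comp[fits$subject_id])
  out <- fits[, c("subject_id", "variant_id", "gene", "label", "peak_vaf",
                  "competition")]
  rownames(out) <- NULL
  out
}

#' Compare growth rates between major CHIP genes and the rest
#'
#' Two-sided Mann-Whitney U test of the per-year slope (or doubling
#' period) between dominant growing clones in the major CHIP genes and
#' those in all other genes. The p-value is exact (full enumeration) for
#' small untied samples and uses the normal approximation with tie
#' correction otherwise.
#'
#' @param fits per-mutation fit table restricted to the trajectories to
#'   compare (e.g. dominant growing clones); columns `gene` and `beta`
#'   (or `doubling_period`).
#' @param major_genes character vector defining the major-gene group.
#' @param measure `"beta"` or `"doubling_period"`.
#' @return list with `statistic` (U for the major-gene group), `p.value`,
#'   and the two group sizes.
#' @export
compare_gene_groups <- function(fits, major_genes = c("DNMT3A", "TET2", "ASXL1"),
                                measure = c("beta", "doubling_period")) {
  measure <- match.arg(measure)
  x <- fits[[measure]][fits$gene %in% major_genes]
  y <- fits[[measure]][!fits$gene %in% major_genes]
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) == 0 || length(y) == 0)
    stop("both gene groups must be non-empty")
  exact <- (length(x) + length(y)) <= 20L && !anyDuplicated(c(x, y))
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided", exact = exact)
  )
  list(statistic = unname(wt$statistic), p.value = wt$p.value,
       n_major = length(x), n_other = length(y))
}

#' Odds of a growing trajectory for one gene versus the rest
#'
#' Builds the 2x2 table (gene vs other) x (growing vs not) over labeled
#' trajectories. The odds ratio is `ad / bc` with the Haldane-Anscombe
#' 0.5 correction when any cell is zero; the p-value is Fisher's exact
#' test on the uncorrected table.
#'
#' @param fits labeled fit table with `gene` and `label` columns
#'   (`"growing"` counts as growing; `NA` labels are dropped).
#' @param gene the gene of interest.
#' @return list with `odds_ratio`, `p.value`, the 2x2 `table`, and
#'   `corrected` (whether the continuity correction was applied).
#' @export
gene_growth_odds <- function(fits, gene) {
  fits <- fits[!is.na(fits$label), , drop = FALSE]
  is_gene <- fits$gene == gene
  if (all(is_gene) || !any(is_gene))
    stop("need trajectories both in and outside gene ", gene)
  growing <- fits$label == "growing"
  a <- sum(is_gene & growing); b <- sum(is_gene & !growing)
  c_ <- sum(!is_gene & growing); d <- sum(!is_gene & !growing)
  tab <- matrix(c(a, b, c_, d), 2, byrow = TRUE,
                dimnames = list(c(gene, "other"), c("growing", "not_growing")))
  corrected <- any(tab == 0)
  if (corrected) {
    or <- ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c_ + 0.5))
  } else {
    or <- (a * d) / (b * c_)
  }
  p <- stats::fisher.test(tab)$p.value
  list(odds_ratio = or, p.value = p, table = tab, corrected = corrected)
}
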
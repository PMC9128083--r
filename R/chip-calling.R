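# Whitelist-driven CHIP driver annotation and prevalence summaries.

.truncating_classes <- c("nonsense", "frameshift", "splice")

#' Read a CHIP driver whitelist
#'
#' The whitelist is a YAML file with one block per gene:
#' `gene`, `classes` (functional classes accepted anywhere in the gene,
#' e.g. the truncating set), `changes` (explicit hotspot protein changes
#' accepted regardless of class) and `af_ceiling` (population allele
#' frequency below which a variant is considered somatic).
#'
#' @param path path to the YAML whitelist; default is the whitelist of the
#'   15 panel genes shipped with the package.
#' @return object of class `driver_whitelist`: a named list of gene rules.
#' @export
read_whitelist <- function(path = system.file("extdata", "chip_whitelist.yaml",
                                              package = "chipdyn")) {
  raw <- yaml::read_yaml(path)
  rules <- lapply(raw, function(g) {
    list(gene = g$gene,
         classes = as.character(g$classes %||% character()),
         changes = as.character(g$changes %||% character()),
         af_ceiling = as.numeric(g$af_ceiling %||% 0.001))
  })
  names(rules) <- vapply(rules, `[[`, character(1), "gene")
  if (anyDuplicated(names(rules)))
    stop("whitelist lists a gene more than once")
  empty <- vapply(rules, function(g)
    length(g$classes) == 0 && length(g$changes) == 0, logical(1))
  if (any(empty))
    stop("whitelist gene(s) with no rule: ",
         paste(names(rules)[empty], collapse = ", "))
  structure(rules, class = "driver_whitelist")
}

#' Annotate PASS calls as CHIP driver mutations
#'
#' A call is a driver when its gene is on the whitelist, its functional
#' class or explicit protein change matches the gene's rule, and its
#' population allele frequency is below the gene's germline-exclusion
#' ceiling. Calls without an annotation entry raise a warning and are
#' treated as non-drivers.
#'
#' @param calls PASS call table with `variant_id` (rows with `pass ==
#'   FALSE`, if present, are ignored).
#' @param annotations variant-level table: `variant_id`, `gene`,
#'   `functional_class`, `protein_change`, `pop_af`.
#' @param whitelist a [read_whitelist()] object.
#' @return the driver subset of `calls` with `gene`, `functional_class`,
#'   `protein_change` columns attached, ordered by subject/sample.
#' @export
annotate_drivers <- function(calls, annotations, whitelist = read_whitelist()) {
  if (!inherits(whitelist, "driver_whitelist"))
    stop("whitelist must come from read_whitelist()")
  if (!is.null(calls$pass)) calls <- calls[calls$pass, , drop = FALSE]
  if (nrow(calls) == 0) return(cbind(calls, gene = character(0),
                                     functional_class = character(0),
                                     protein_change = character(0)))
  m <- match(calls$variant_id, annotations$variant_id)
  if (anyNA(m)) {
    warning(sum(is.na(m)), " PASS call(s) lack annotation; treated as non-driver")
  }
  calls$gene <- annotations$gene[m]
  calls$functional_class <- annotations$functional_class[m]
  calls$protein_change <- annotations$protein_change[m]
  calls$pop_af <- annotations$pop_af[m]
  is_driver <- vapply(seq_len(nrow(calls)), function(i) {
    g <- calls$gene[i]
    if (is.na(g) || is.null(whitelist[[g]])) return(FALSE)
    rule <- whitelist[[g]]
    af <- calls$pop_af[i]
    if (is.null(af) || is.na(af)) af <- 0
    af_ok <- af < rule$af_ceiling
    hit <- (calls$functional_class[i] %in% rule$classes) ||
      (calls$protein_change[i] %in% rule$changes)
    isTRUE(af_ok && hit)
  }, logical(1))
  out <- calls[is_driver, , drop = FALSE]
  out <- out[order(out$variant_id), , drop = FALSE]
  if (!is.null(out$sample_id)) out <- out[order(out$sample_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-sample CHIP status
#'
#' Counts driver mutations reaching the CHIP (VAF >= 2%) and large-clone
#' (VAF >= 10%) thresholds, inclusively, for every sample in the manifest
#' (samples without drivers get zero counts).
#'
#' @param drivers driver call table with `subject_id`, `timepoint`, `vaf`.
#' @param manifest sample manifest with `subject_id`, `timepoint`.
#' @param chip_vaf,large_vaf thresholds (defaults 0.02, 0.10).
#' @return data frame: `subject_id`, `timepoint`, `n_clones_2pct`,
#'   `n_clones_10pct`, `chip_positive`.
#' @export
chip_status <- function(drivers, manifest, chip_vaf = 0.02, large_vaf = 0.10) {
  key <- paste(manifest$subject_id, manifest$timepoint)
  dkey <- paste(drivers$subject_id, drivers$timepoint)
  n2 <- vapply(key, function(k)
    sum(dkey == k & drivers$vaf >= chip_vaf), integer(1))
  n10 <- vapply(key, function(k)
    sum(dkey == k & drivers$vaf >= large_vaf), integer(1))
  data.frame(subject_id = manifest$subject_id, timepoint = manifest$timepoint,
             n_clones_2pct = n2, n_clones_10pct = n10,
             chip_positive = n2 >= 1L, row.names = NULL)
}

#' CHIP prevalence by age bin
#'
#' Prevalence of CHIP at the 2% and 10% VAF thresholds among subjects'
#' initial timepoints, binned by age at first draw. Empty bins report NA.
#'
#' @param status per-sample [chip_status()] table.
#' @param manifest manifest with `subject_id`, `timepoint`, `age`.
#' @param breaks age bin edges passed to [cut()] (right-open bins).
#' @return data frame: `age_bin`, `n`, `prev_2pct`, `prev_10pct`.
#' @export
prevalence_by_age <- function(status, manifest,
                              breaks = c(50, 60, 70, 80, Inf)) {
  first_tp <- stats::aggregate(timepoint ~ subject_id, manifest, min)
  first <- merge(first_tp, manifest, by = c("subject_id", "timepoint"))
  first <- merge(first, status, by = c("subject_id", "timepoint"))
  bins <- cut(first$age, breaks = breaks, right = FALSE, include.lowest = TRUE)
  lv <- levels(bins)
  out <- data.frame(age_bin = lv, n = as.integer(table(bins)[lv]))
  out$prev_2pct <- vapply(lv, function(b) {
    x <- first$n_clones_2pct[bins == b & !is.na(bins)]
    if (length(x) == 0) NA_real_ else mean(x >= 1)
  }, numeric(1))
  out$prev_10pct <- vapply(lv, function(b) {
    x <- first$n_clones_10pct[bins == b & !is.na(bins)]
    if (length(x) == 0) NA_real_ else mean(x >= 1)
  }, numeric(1))
  rownames(out) <- NULL
  out
}
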
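# Raw reads -> deduplicated site observations -> candidate calls -> filters.

#' Collapse UMI-tagged reads into unique-molecule site observations
#'
#' Reads are grouped by (probe_id, umi); each group contributes one
#' consensus molecule whose allele is the within-group majority. Groups
#' with an exact allele tie are dropped. Records whose UMI is not exactly
#' 9 characters are rejected (with a message giving the count).
#'
#' @param reads data frame of raw read records as produced by
#'   [simulate_umi_reads()]: `probe_id`, `umi`, `chrom`, `pos`, `ref`,
#'   `alt`, `observed_allele`.
#' @return per-site observations: `chrom`, `pos`, `ref`, `alt`, `depth`
#'   (unique molecules), `alt_count`, `vaf`.
#' @export
dedup_umis <- function(reads) {
  bad <- nchar(reads$umi) != 9L
  if (any(bad)) {
    message("dedup_umis: rejected ", sum(bad), " record(s) with malformed UMI")
    reads <- reads[!bad, , drop = FALSE]
  }
  if (nrow(reads) == 0)
    return(data.frame(chrom = character(), pos = integer(), ref = character(),
                      alt = character(), depth = integer(),
                      alt_count = integer(), vaf = numeric()))
  grp <- paste(reads$probe_id, reads$umi, sep = "\r")
  idx <- split(seq_len(nrow(reads)), grp)
  cons <- lapply(idx, function(ii) {
    tab <- table(reads$observed_allele[ii])
    top <- tab[tab == max(tab)]
    if (length(top) > 1L) return(NULL)  # exact tie: drop the molecule
    i1 <- ii[1L]
    list(chrom = reads$chrom[i1], pos = reads$pos[i1], ref = reads$ref[i1],
         alt = reads$alt[i1], allele = names(top))
  })
  cons <- cons[!vapply(cons, is.null, logical(1))]
  if (length(cons) == 0)
    return(data.frame(chrom = character(), pos = integer(), ref = character(),
                      alt = character(), depth = integer(),
                      alt_count = integer(), vaf = numeric()))
  mol <- data.frame(
    chrom = vapply(cons, `[[`, character(1), "chrom"),
    pos = vapply(cons, function(x) as.integer(x$pos), integer(1)),
    ref = vapply(cons, `[[`, character(1), "ref"),
    alt = vapply(cons, `[[`, character(1), "alt"),
    allele = vapply(cons, `[[`, character(1), "allele"),
    stringsAsFactors = FALSE
  )
  key <- variant_key(mol$chrom, mol$pos, mol$ref, mol$alt)
  depth <- as.integer(table(key))
  alt_count <- as.integer(tapply(mol$allele == mol$alt, key, sum))
  sites <- mol[!duplicated(key), c("chrom", "pos", "ref", "alt")]
  ord <- names(table(key))  # table/tapply order (sorted by key)
  sites <- sites[match(ord, variant_key(sites$chrom, sites$pos, sites$ref, sites$alt)), ]
  out <- data.frame(sites, depth = depth, alt_count = alt_count,
                    stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$pos, out$alt), ]
  out$vaf <- out$alt_count / out$depth
  rownames(out) <- NULL
  out
}

#' Binomial candidate-variant caller
#'
#' A stand-in somatic caller: a one-sided exact binomial test of the
#' alternate read count against `Binomial(depth, error_rate)`. A site is a
#' candidate when the tail probability falls below `alpha`.
#'
#' @param observations site observations with `depth` and `alt_count`.
#' @param error_rate per-base substitution probability (the null rate).
#' @param alpha candidate threshold on the tail p-value (default 1e-6).
#' @return the input with `p_value` and `candidate` columns added.
#' @export
call_variants <- function(observations, error_rate, alpha = 1e-6) {
  if (any(observations$depth <= 0)) stop("depth must be > 0")
  if (error_rate <= 0 || error_rate >= 1)
    stop("error_rate must be in (0, 1)")
  p <- stats::pbinom(observations$alt_count - 1L, observations$depth,
                     error_rate, lower.tail = FALSE)
  observations$p_value <- p
  observations$candidate <- p < alpha
  observations
}

#' Apply per-call somatic filters
#'
#' Flags calls failing the post-call thresholds: minimum coverage 40,
#' at least 5 alternate reads, and VAF at least 0.1%. All thresholds are
#' inclusive at the boundary (equality passes).
#'
#' @param calls data frame with `depth`, `alt_count` (and `vaf`, else
#'   recomputed).
#' @param min_depth,min_alt,min_vaf filter thresholds.
#' @return input with logical columns `low_coverage`, `low_alt_support`,
#'   `low_vaf` added.
#' @export
apply_call_filters <- function(calls, min_depth = 40L, min_alt = 5L,
                               min_vaf = 0.001) {
  vaf <- calls$vaf %||% (calls$alt_count / calls$depth)
  calls$vaf <- vaf
  calls$low_coverage <- calls$depth < min_depth
  calls$low_alt_support <- calls$alt_count < min_alt
  calls$low_vaf <- vaf < min_vaf
  calls
}

#' Flag recurrent artifacts across samples
#'
#' A variant observed in at least `min_prop` of all samples at a VAF
#' inside the artifact window (1-10%, closed on both ends) is flagged as a
#' recurrent artifact in every sample.
#'
#' @param calls multi-sample call table with `sample_id`, `variant_id`,
#'   `vaf`.
#' @param min_prop sample-fraction threshold (default 0.05).
#' @param vaf_window closed VAF window defining the artifact band.
#' @return input with a logical `recurrent_artifact` column added.
#' @export
filter_recurrent_artifacts <- function(calls, min_prop = 0.05,
                                       vaf_window = c(0.01, 0.10)) {
  if (nrow(calls) == 0) {
    calls$recurrent_artifact <- logical(0)
    return(calls)
  }
  n_samples <- length(unique(calls$sample_id))
  in_win <- calls$vaf >= vaf_window[1] & calls$vaf <= vaf_window[2]
  hits <- tapply(calls$sample_id[in_win], calls$variant_id[in_win],
                 function(s) length(unique(s)))
  flagged <- names(hits)[hits / n_samples >= min_prop]
  calls$recurrent_artifact <- calls$variant_id %in% flagged
  calls
}

#' Combine candidate status and filter flags into PASS calls
#'
#' @param calls output of the caller and filter steps.
#' @return input with a `filter` string column (`PASS` or
#'   semicolon-separated codes `LOW_COV`, `LOW_ALT`, `LOW_VAF`,
#'   `RECURRENT_ARTIFACT`, `NOT_CANDIDATE`) and a logical `pass` column.
#' @export
resolve_filters <- function(calls) {
  n <- nrow(calls)
  ra <- calls$recurrent_artifact %||% rep(FALSE, n)
  cand <- calls$candidate %||% rep(TRUE, n)
  codes <- cbind(
    LOW_COV = calls$low_coverage, LOW_ALT = calls$low_alt_support,
    LOW_VAF = calls$low_vaf, RECURRENT_ARTIFACT = ra,
    NOT_CANDIDATE = !cand
  )
  calls$filter <- apply(codes, 1, function(f) {
    if (any(f)) paste(colnames(codes)[f], collapse = ";") else "PASS"
  })
  calls$pass <- calls$filter == "PASS"
  calls
}

#' Full per-sample variant processing
#'
#' Runs the caller, the per-call filters and the cross-sample artifact
#' filter over a multi-sample observation table and resolves PASS status.
#'
#' @param observations multi-sample site observations (must carry
#'   `sample_id` and `variant_id`).
#' @param error_rate caller null substitution rate.
#' @param alpha caller candidate threshold.
#' @param min_depth,min_alt,min_vaf per-call thresholds.
#' @param artifact_prop,artifact_window recurrent-artifact rule.
#' @return annotated call table with `p_value`, flags, `filter`, `pass`.
#' @export
process_observations <- function(observations, error_rate = 0.00045,
                                 alpha = 1e-6, min_depth = 40L, min_alt = 5L,
                                 min_vaf = 0.001, artifact_prop = 0.05,
                                 artifact_window = c(0.01, 0.10)) {
  calls <- call_variants(observations, error_rate, alpha)
  calls <- apply_call_filters(calls, min_depth, min_alt, min_vaf)
  calls <- filter_recurrent_artifacts(calls, artifact_prop, artifact_window)
  resolve_filters(calls)
}
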
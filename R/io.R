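# File formats: the package's VCF v4.2 dialect (INFO DP/AD, FILTER
# codes), TSV tables, and serialized configurations.

#' Write site observations as VCF
#'
#' Writes a VCF v4.2 file with `DP` (deduplicated depth) and `AD`
#' (reference,alternate read counts) in INFO, and the call filter string
#' (`PASS`, `LOW_COV`, `LOW_ALT`, `LOW_VAF`, `RECURRENT_ARTIFACT`,
#' `NOT_CANDIDATE`) in FILTER. Coordinates are 1-based inclusive.
#'
#' @param observations data frame with `chrom`, `pos`, `ref`, `alt`,
#'   `depth`, `alt_count`, optionally `filter`.
#' @param path output path.
#' @param sample_id recorded in the header.
#' @return `path`, invisibly.
#' @export
write_site_vcf <- function(observations, path, sample_id = "sample") {
  hdr <- c(
    "##fileformat=VCFv4.2",
    paste0("##source=chipdyn; sample=", sample_id, "; coordinates=1-based"),
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Deduplicated read depth\">",
    "##INFO=<ID=AD,Number=R,Type=Integer,Description=\"Read counts (ref,alt)\">",
    "##FILTER=<ID=LOW_COV,Description=\"Depth below minimum coverage\">",
    "##FILTER=<ID=LOW_ALT,Description=\"Fewer than minimum alternate reads\">",
    "##FILTER=<ID=LOW_VAF,Description=\"VAF below minimum\">",
    "##FILTER=<ID=RECURRENT_ARTIFACT,Description=\"Recurrent artifact across samples\">",
    "##FILTER=<ID=NOT_CANDIDATE,Description=\"Failed binomial caller threshold\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  o <- observations[order(observations$chrom, observations$pos,
                          observations$alt), , drop = FALSE]
  filt <- o$filter %||% rep(".", nrow(o))
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\t%s\tDP=%d;AD=%d,%d",
                  o$chrom, as.integer(o$pos), o$ref, o$alt, filt,
                  as.integer(o$depth),
                  as.integer(o$depth - o$alt_count), as.integer(o$alt_count))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read site observations from a VCF
#'
#' Reads a VCF v4.x with `DP` and `AD` INFO fields; multi-allelic records
#' are decomposed into biallelic observations (AD is split per alternate
#' allele). If `AD` is absent, a sidecar TSV `<path>.counts.tsv` with
#' `chrom`, `pos`, `alt`, `alt_count` is consulted; otherwise an error is
#' raised.
#'
#' @param path VCF path.
#' @return data frame: `chrom`, `pos`, `ref`, `alt`, `depth`,
#'   `alt_count`, `vaf`, `filter`, `variant_id`.
#' @export
read_site_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fm <- vcfR::getFIX(v)
  if (is.null(dim(fm))) fm <- t(fm)   # single-record VCFs drop to a vector
  fix <- as.data.frame(fm, stringsAsFactors = FALSE)
  fix[] <- lapply(fix, as.character)
  dp <- as.integer(vcfR::extract.info(v, "DP"))
  ad <- vcfR::extract.info(v, "AD")
  rows <- vector("list", nrow(fix))
  sidecar <- NULL
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    if (!is.na(ad[i])) {
      counts <- as.integer(strsplit(ad[i], ",", fixed = TRUE)[[1]])
      if (length(counts) != length(alts) + 1L)
        stop("malformed AD at record ", i, " of ", path)
      alt_counts <- counts[-1L]
    } else {
      if (is.null(sidecar)) {
        sc_path <- paste0(path, ".counts.tsv")
        if (!file.exists(sc_path))
          stop("record ", i, " of ", path,
               " lacks AD and no sidecar ", sc_path, " exists")
        sidecar <- utils::read.delim(sc_path, stringsAsFactors = FALSE)
      }
      alt_counts <- vapply(alts, function(a) {
        hit <- sidecar$chrom == fix$CHROM[i] &
          sidecar$pos == as.integer(fix$POS[i]) & sidecar$alt == a
        if (!any(hit)) stop("sidecar lacks counts for record ", i)
        as.integer(sidecar$alt_count[hit][1])
      }, integer(1))
    }
    rows[[i]] <- data.frame(
      chrom = fix$CHROM[i], pos = as.integer(fix$POS[i]), ref = fix$REF[i],
      alt = alts, depth = dp[i], alt_count = alt_counts,
      filter = fix$FILTER[i] %||% NA_character_, stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  out$vaf <- out$alt_count / out$depth
  out$variant_id <- variant_key(out$chrom, out$pos, out$ref, out$alt)
  rownames(out) <- NULL
  out
}

#' Write a cohort simulation to disk
#'
#' Writes manifest, truth, annotations and per-sample observation TSVs
#' plus one VCF per sample; byte-identical across runs of the same
#' configuration.
#'
#' @param sim a [simulate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, name)
    utils::write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  wt(sim$manifest, "manifest.tsv")
  wt(sim$truth, "truth.tsv")
  wt(sim$annotations, "annotations.tsv")
  wt(sim$observations, "observations.tsv")
  vdir <- file.path(dir, "vcf")
  dir.create(vdir, showWarnings = FALSE)
  for (sid in unique(sim$observations$sample_id)) {
    o <- sim$observations[sim$observations$sample_id == sid, ]
    write_site_vcf(o, file.path(vdir, paste0(sid, ".vcf")), sample_id = sid)
  }
  invisible(dir)
}

#' Pipeline configuration
#'
#' Every threshold used by any pipeline stage lives here, once, with
#' defaults equal to the standard analysis values: caller alpha 1e-6 at
#' error rate 0.045%; call filters depth >= 40, alt reads >= 5,
#' VAF >= 0.1%; recurrent-artifact rule >= 5% of samples at VAF 1-10%;
#' CHIP threshold 2% and large-clone threshold 10%; trajectory
#' eligibility >= 3 timepoints, peak VAF > 1%, depth >= 200, alt >= 2,
#' starting VAF <= 10%; VAF floor 1e-4; classification P threshold 0.5.
#'
#' @param ... overrides of any default, by name.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    error_rate = 0.00045, alpha = 1e-6,
    min_depth = 40L, min_alt = 5L, min_vaf = 0.001,
    artifact_prop = 0.05, artifact_window = c(0.01, 0.10),
    chip_vaf = 0.02, large_vaf = 0.10,
    traj_min_timepoints = 3L, traj_min_peak_vaf = 0.01,
    traj_min_depth = 200L, traj_min_alt = 2L,
    max_start_vaf = 0.10, vaf_floor = 1e-4, p_threshold = 0.5,
    age_breaks = c(50, 60, 70, 80, Inf)
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("unknown pipeline parameter(s): ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = "pipeline_config")
}

#' Serialize / restore a pipeline configuration
#'
#' @param config a [pipeline_config()].
#' @param path YAML file path.
#' @return `read_pipeline_config` returns a `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  vals <- lapply(vals, function(v) if (is.list(v)) unlist(v) else v)
  do.call(pipeline_config, vals)
}
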
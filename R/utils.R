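`%||%` <- function(a, b) if (is.null(a)) b else a

# variant identity used as a join key everywhere
variant_key <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

stopifnot_prob <- function(x, what) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0) || any(x > 1))
    stop(what, " must be a probability in [0, 1]", call. = FALSE)
  invisible(x)
}

# random 9-mer UMIs, unique within the returned vector
random_umis <- function(n, width = 9L) {
  draw <- function(k) {
    vapply(seq_len(k), function(i)
      paste(sample(c("A", "C", "G", "T"), width, replace = TRUE), collapse = ""),
      character(1))
  }
  umis <- draw(n)
  while (anyDuplicated(umis)) {
    dup <- duplicated(umis)
    umis[dup] <- draw(sum(dup))
  }
  umis
}
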
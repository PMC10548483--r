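# Consensus, quality, consequence, expression and fusion-confidence
# filters for candidate somatic events.  Each filter returns a subset of
# its input with order preserved and records unmodified.

NONSYNONYMOUS <- c("missense", "frameshift", "inframe_indel")
CONSEQUENCE_CLASSES <- c(NONSYNONYMOUS, "synonymous", "noncoding")

#' Consensus and read-quality filter for somatic variants
#'
#' Keeps exactly the variants called by at least two of the six ensemble
#' callers, with read depth of at least 10 in both tumor and normal, and
#' with strictly more than three reads supporting the mutation in the
#' tumor.
#'
#' @param variants Data frame with columns `n_callers`, `depth_tumor`,
#'   `depth_normal`, `alt_reads_tumor` (plus `id` for error reporting).
#' @param min_callers,min_depth,min_alt_reads Thresholds; callers and
#'   depth are inclusive, alt reads strict (`> min_alt_reads`).
#' @return The retained subset, order preserved.
#' @export
consensus_quality_filter <- function(variants, min_callers = 2L,
                                     min_depth = 10L, min_alt_reads = 3L) {
  req <- c("n_callers", "depth_tumor", "depth_normal", "alt_reads_tumor")
  assert_columns(variants, req, "variant table")
  for (col in req) {
    bad <- which(is.na(variants[[col]]))
    if (length(bad) > 0L)
      stop_config("variant %s has missing %s",
                  variants$id[bad[1]] %||% bad[1], col)
  }
  keep <- variants$n_callers >= min_callers &
    variants$depth_tumor >= min_depth &
    variants$depth_normal >= min_depth &
    variants$alt_reads_tumor > min_alt_reads
  variants[keep, , drop = FALSE]
}

#' Expression filter: retain variants on expressed transcripts
#'
#' A variant is expressed when the TPM values of its harboring
#' transcripts sum strictly above `min_tpm` (default 0).  Transcripts
#' absent from the abundance map count as 0.
#'
#' @param variants Data frame with a `transcript_ids` column
#'   (comma-separated transcript ids; `NA` for noncoding variants).
#' @param tpm Named numeric vector mapping transcript id to TPM, or a
#'   data frame with columns `transcript_id` and `tpm`.
#' @param min_tpm Strict lower bound on the summed TPM.
#' @return The retained subset, order preserved.
#' @export
expression_filter <- function(variants, tpm, min_tpm = 0) {
  assert_columns(variants, "transcript_ids", "variant table")
  if (is.data.frame(tpm)) {
    assert_columns(tpm, c("transcript_id", "tpm"), "TPM table")
    tpm <- stats::setNames(tpm$tpm, tpm$transcript_id)
  }
  summed <- vapply(split_ids(variants$transcript_ids), function(tx) {
    if (length(tx) == 0 || all(is.na(tx))) return(0)
    sum(tpm[tx], na.rm = TRUE)
  }, numeric(1))
  variants[summed > min_tpm, , drop = FALSE]
}

#' Restrict to non-synonymous variants
#'
#' Retains consequences that alter the amino-acid sequence (missense,
#' frameshift, in-frame indel); synonymous and noncoding variants are
#' dropped.
#'
#' @param variants Data frame with a `consequence` column.
#' @return The retained subset, order preserved.
#' @export
nonsynonymous_subset <- function(variants) {
  assert_columns(variants, "consequence", "variant table")
  unknown <- setdiff(unique(variants$consequence), CONSEQUENCE_CLASSES)
  unknown <- unknown[!is.na(unknown)]
  if (length(unknown) > 0L)
    stop_config("unknown consequence label(s): %s",
                paste(unknown, collapse = ", "))
  variants[variants$consequence %in% NONSYNONYMOUS, , drop = FALSE]
}

#' Discard low-confidence gene fusions
#'
#' @param fusions Data frame with a `confidence` column taking values
#'   `low`, `medium` or `high`.
#' @return Fusions of medium or high confidence, order preserved.
#' @export
fusion_confidence_filter <- function(fusions) {
  assert_columns(fusions, "confidence", "fusion table")
  fusions[fusions$confidence %in% c("medium", "high"), , drop = FALSE]
}
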
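# Per-patient scalar immunogenomic covariates: tumor mutational burden,
# neoantigen load, neoantigen quality and per-allele load.

#' Tumor mutational burden
#'
#' Number of non-synonymous somatic SNVs and indels with a DNA VAF of at
#' least 5% ("at least" is inclusive), per megabase of coding sequence.
#' Fusions, CNVs, noncoding and synonymous mutations do not count.
#'
#' @param variants Variant data frame with `consequence` and `vaf_dna`.
#' @param coding_mb Coding footprint in megabases (> 0); no default is
#'   assumed silently.
#' @param min_vaf Inclusive VAF threshold, default 0.05.
#' @return Variants per megabase.
#' @export
compute_tmb <- function(variants, coding_mb, min_vaf = 0.05) {
  if (missing(coding_mb) || !is.numeric(coding_mb) || length(coding_mb) != 1 ||
      is.na(coding_mb) || coding_mb <= 0)
    stop_config("coding_mb must be a single value > 0")
  assert_columns(variants, c("consequence", "vaf_dna"), "variant table")
  qualifying <- variants$consequence %in% NONSYNONYMOUS &
    !is.na(variants$vaf_dna) & variants$vaf_dna >= min_vaf
  sum(qualifying) / coding_mb
}

#' Neoantigen load (NAL)
#'
#' Count of candidates with an AP score strictly above the threshold
#' (default 0.5).  By default, (peptide x allele) pairs are counted;
#' `unique_peptides = TRUE` counts distinct peptide sequences instead.
#'
#' @param candidates Candidate data frame with `ap_score` (and `peptide`
#'   when `unique_peptides`).
#' @param threshold Strict lower bound on the AP score.
#' @param unique_peptides Count distinct peptide sequences only.
#' @return Integer count.
#' @export
compute_nal <- function(candidates, threshold = 0.5,
                        unique_peptides = FALSE) {
  if (nrow(candidates) == 0) return(0L)
  assert_columns(candidates, "ap_score", "candidate table")
  hit <- !is.na(candidates$ap_score) & candidates$ap_score > threshold
  if (unique_peptides) {
    assert_columns(candidates, "peptide", "candidate table")
    length(unique(candidates$peptide[hit]))
  } else sum(hit)
}

#' Neoantigen quality
#'
#' Mean AP score of the top ten candidates ranked by AP score.  Patients
#' with fewer than ten candidates contribute the mean over what they
#' have; with none, 0 (or `NA` under `strict_top10`).  Ties at the tenth
#' rank are resolved by lexicographic peptide order for determinism (the
#' mean is unaffected when tied scores are equal).
#'
#' @param candidates Candidate data frame with `ap_score`.
#' @param top_n Number of top candidates, default 10.
#' @param strict_top10 Return `NA` when fewer than `top_n` candidates
#'   are available.
#' @return Mean AP score in \[0, 1\] (or `NA`).
#' @export
neoantigen_quality <- function(candidates, top_n = 10L,
                               strict_top10 = FALSE) {
  if (nrow(candidates) == 0)
    return(if (strict_top10) NA_real_ else 0)
  assert_columns(candidates, "ap_score", "candidate table")
  if (strict_top10 && nrow(candidates) < top_n) return(NA_real_)
  tie <- candidates$peptide %||% seq_len(nrow(candidates))
  ord <- order(-candidates$ap_score, tie)
  top <- candidates$ap_score[ord][seq_len(min(top_n, nrow(candidates)))]
  mean(top)
}

#' Per-allele neoantigen load
#'
#' NAL restricted to each HLA allele.  Because candidates are
#' allele-resolved (one row per peptide x allele), the per-allele counts
#' sum to the overall pairwise NAL.
#'
#' @inheritParams compute_nal
#' @return Named integer vector, allele to count.
#' @export
per_allele_nal <- function(candidates, threshold = 0.5) {
  if (nrow(candidates) == 0) return(stats::setNames(integer(0), character(0)))
  assert_columns(candidates, c("ap_score", "hla_allele"), "candidate table")
  counts <- tapply(candidates$ap_score > threshold, candidates$hla_allele,
                   sum)
  stats::setNames(as.integer(counts), names(counts))
}

#' Peptides predicted to bind more than one HLA allele
#'
#' @param candidates Allele-resolved candidate data frame.
#' @param threshold Strict AP threshold, default 0.5.
#' @return Count of distinct peptides above threshold for two or more
#'   alleles within the same patient (column `patient_id` optional).
#' @export
multi_allele_binders <- function(candidates, threshold = 0.5) {
  if (nrow(candidates) == 0) return(0L)
  assert_columns(candidates, c("ap_score", "hla_allele", "peptide"),
                 "candidate table")
  hit <- candidates[!is.na(candidates$ap_score) &
                      candidates$ap_score > threshold, , drop = FALSE]
  if (nrow(hit) == 0) return(0L)
  key <- paste(hit$patient_id %||% "", hit$peptide)
  n_alleles <- tapply(hit$hla_allele, key, function(a) length(unique(a)))
  sum(n_alleles > 1)
}

#' Assemble the per-patient covariate table
#'
#' Runs the filter chain and the metric definitions for every patient in
#' a cohort-shaped input and returns one row per patient with `tmb`,
#' `nal`, `neoantigen_quality` and the CD8+ T-cell fraction.
#'
#' @param variants Filtered (or raw) variant table with `patient_id`.
#' @param candidates Candidate table with `patient_id` and `ap_score`.
#' @param cell_fractions Wide per-patient cell-fraction table (column
#'   `T.cells.CD8`), or `NULL` to omit.
#' @param coding_mb Coding footprint in megabases for TMB.
#' @param patient_ids Patients to report (defaults to the union seen).
#' @return Data frame, one row per patient.
#' @export
patient_covariates <- function(variants, candidates,
                               cell_fractions = NULL, coding_mb,
                               patient_ids = NULL) {
  if (is.null(patient_ids))
    patient_ids <- sort(unique(c(variants$patient_id,
                                 candidates$patient_id)))
  rows <- lapply(patient_ids, function(p) {
    v <- variants[variants$patient_id == p, , drop = FALSE]
    cc <- candidates[candidates$patient_id == p, , drop = FALSE]
    data.frame(patient_id = p,
               tmb = compute_tmb(v, coding_mb),
               nal = compute_nal(cc),
               neoantigen_quality = neoantigen_quality(cc),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(cell_fractions)) {
    assert_columns(cell_fractions, c("patient_id", "T.cells.CD8"),
                   "cell-fraction table")
    out$t_cell_fraction <- cell_fractions$T.cells.CD8[
      match(out$patient_id, cell_fractions$patient_id)]
  }
  out
}
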
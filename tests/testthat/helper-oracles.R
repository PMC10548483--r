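# Shared fixtures and independent oracles used across the suite.

# Small hand-built variant table exercising every filter boundary.
make_variant_row <- function(id = "v1", n_callers = 3L, depth_tumor = 50L,
                             depth_normal = 40L, alt_reads_tumor = 10L,
                             vaf_dna = 0.2, vaf_rna = 0.2,
                             consequence = "missense",
                             phase_set = NA_character_,
                             transcript_ids = "tx1",
                             protein_id = "P1", protein_pos = 10L,
                             aa_ref = "A", aa_alt = "V") {
  data.frame(id = id, patient_id = "p01", chrom = "chr1", pos = 100L,
             ref = "A", alt = "T", n_callers = n_callers,
             depth_tumor = depth_tumor, depth_normal = depth_normal,
             alt_reads_tumor = alt_reads_tumor, vaf_dna = vaf_dna,
             vaf_rna = vaf_rna, consequence = consequence,
             phase_set = phase_set, protein_id = protein_id,
             protein_pos = protein_pos, aa_ref = aa_ref, aa_alt = aa_alt,
             transcript_ids = transcript_ids, stringsAsFactors = FALSE)
}

random_protein <- function(n) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n,
               replace = TRUE), collapse = "")
}

# Brute-force window oracle: test every possible window of every length
# by direct string comparison against the position-aligned wild type.
oracle_windows <- function(mutant, wildtype, lengths = c(9L, 10L)) {
  n <- nchar(mutant)
  nw <- nchar(wildtype)
  out <- list()
  for (L in lengths) {
    if (n < L) next
    for (s in 1:(n - L + 1L)) {
      win <- substr(mutant, s, s + L - 1L)
      wt_win <- if (s + L - 1L <= nw) substr(wildtype, s, s + L - 1L)
      else NA_character_
      # altered = positional mismatch against wild type
      overlap <- FALSE
      for (i in s:(s + L - 1L)) {
        wt_ch <- if (i <= nw) substr(wildtype, i, i) else ""
        if (substr(mutant, i, i) != wt_ch) { overlap <- TRUE; break }
      }
      differs <- is.na(wt_win) || win != wt_win
      if (overlap && differs)
        out[[length(out) + 1L]] <- data.frame(sequence = win,
                                              window_start = s,
                                              length = L)
    }
  }
  if (length(out) == 0)
    data.frame(sequence = character(0), window_start = integer(0),
               length = integer(0))
  else do.call(rbind, out)
}

# Brute-force fusion-window oracle.
oracle_fusion_windows <- function(up, down, frame, lengths = c(9L, 10L)) {
  ctx <- paste0(up, down)
  n5 <- nchar(up)
  n <- nchar(ctx)
  out <- list()
  for (L in lengths) {
    if (n < L) next
    for (s in 1:(n - L + 1L)) {
      e <- s + L - 1L
      keep <- if (frame == "in_frame") s <= n5 && e >= n5 + 1L
      else e >= n5 + 1L
      if (keep)
        out[[length(out) + 1L]] <- data.frame(
          sequence = substr(ctx, s, e), window_start = s, length = L)
    }
  }
  if (length(out) == 0)
    data.frame(sequence = character(0), window_start = integer(0),
               length = integer(0))
  else do.call(rbind, out)
}

# Exhaustive optimal-binning oracle built on survival::survdiff.
oracle_binning <- function(covariate, records, min_group = 10L) {
  value <- covariate[records$patient_id]
  thresholds <- sort(unique(value))
  best <- NULL
  for (t in thresholds) {
    low <- value <= t
    if (sum(low) < min_group || sum(!low) < min_group) next
    sd <- survival::survdiff(
      survival::Surv(records$time, records$event) ~ low)
    p <- stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE)
    if (is.null(best) || p < best$p - 1e-12)
      best <- list(threshold = t, p = p)
  }
  best
}

random_survival_records <- function(n, rate = 0.01, censor = 0.3) {
  t <- stats::rexp(n, rate)
  ev <- stats::rbinom(n, 1, 1 - censor)
  data.frame(patient_id = sprintf("s%03d", seq_len(n)),
             time = round(t, 3) + 1e-3, event = ev,
             stringsAsFactors = FALSE)
}

quadrant_medians <- function(cohort) {
  p <- cohort$patients
  rec <- data.frame(patient_id = p$patient_id,
                    time = cohort$clinical$pfs_days,
                    event = cohort$clinical$event,
                    stringsAsFactors = FALSE)
  bi <- bivariate_stratify(
    stats::setNames(p$t_cell_fraction, p$patient_id),
    stats::setNames(p$neoantigen_quality, p$patient_id),
    stats::median(p$t_cell_fraction),
    stats::median(p$neoantigen_quality), rec)
  bi$medians
}
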
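# Phasing-aware reconstruction of mutant proteins, enumeration of 9/10-mer
# mutant peptides (SNV, indel, fusion junction), per-HLA scoring through a
# pluggable scorer contract, and expression-adjusted peptide abundance.
#
# Residue coordinates are 1-based; windows are closed intervals.

PEPTIDE_LENGTHS <- c(9L, 10L)

#' Apply phased variant sets to a wild-type protein
#'
#' Variants sharing a `phase_set` tag co-occur on one haplotype and are
#' applied jointly to a single mutant sequence; unphased variants
#' (`phase_set` `NA`) each yield their own mutant sequence carrying only
#' that edit.  Edits are applied from the C-terminus down so residue
#' coordinates stay valid.  A frameshift truncates the protein at the
#' preceding residue and appends its novel tail (the translation up to
#' the next stop).
#'
#' @param wild_type Wild-type protein sequence (single string).
#' @param variants Data frame with columns `id`, `protein_pos`, `aa_ref`,
#'   `aa_alt`, `consequence`, `phase_set` for one protein.
#' @return Named character vector of mutant sequences; names are the
#'   phase-set tag or, for unphased variants, the variant id.  The
#'   `variant_ids` attribute maps each sequence to its source variants.
#' @export
apply_phasing <- function(wild_type, variants) {
  if (!is.character(wild_type) || length(wild_type) != 1 ||
      nchar(wild_type) == 0)
    stop_config("wild_type must be a single non-empty sequence")
  assert_columns(variants, c("protein_pos", "aa_ref", "aa_alt",
                             "consequence"), "variant table")
  if (is.null(variants$phase_set))
    variants$phase_set <- NA_character_
  if (is.null(variants$id))
    variants$id <- paste0("v", seq_len(nrow(variants)))
  bad <- setdiff(unique(variants$consequence),
                 c("missense", "synonymous", "frameshift", "inframe_indel"))
  if (length(bad) > 0L)
    stop_config("unsupported consequence for protein editing: %s",
                paste(bad, collapse = ", "))
  grp <- ifelse(is.na(variants$phase_set), variants$id,
                variants$phase_set)
  groups <- split(seq_len(nrow(variants)), factor(grp, unique(grp)))
  out <- vapply(groups, function(rows)
    apply_edit_group(wild_type, variants[rows, , drop = FALSE]),
    character(1))
  attr(out, "variant_ids") <- lapply(groups, function(rows)
    variants$id[rows])
  out
}

apply_edit_group <- function(wt, ed) {
  ed$end <- ed$protein_pos + nchar(ed$aa_ref) - 1L
  ord <- order(ed$protein_pos)
  ed <- ed[ord, , drop = FALSE]
  if (nrow(ed) > 1) {
    overlap <- ed$protein_pos[-1] <= ed$end[-nrow(ed)]
    if (any(overlap))
      stop_config("conflicting overlapping edits in one phase set: %s",
                  paste(ed$id[c(which(overlap), which(overlap) + 1)],
                        collapse = ", "))
  }
  seqc <- wt
  for (i in rev(seq_len(nrow(ed)))) { # C-terminal first
    pos <- ed$protein_pos[i]
    ref <- ed$aa_ref[i]
    if (pos < 1 || ed$end[i] > nchar(wt))
      stop_config("edit %s outside protein bounds", ed$id[i])
    if (substr(wt, pos, ed$end[i]) != ref)
      stop_config("reference residues of %s do not match the protein",
                  ed$id[i])
    if (ed$consequence[i] == "frameshift") {
      seqc <- paste0(substr(seqc, 1, pos - 1L), ed$aa_alt[i])
    } else {
      seqc <- paste0(substr(seqc, 1, pos - 1L), ed$aa_alt[i],
                     substr(seqc, ed$end[i] + 1L, nchar(seqc)))
    }
  }
  seqc
}

#' Enumerate mutant peptide windows over a mutant protein
#'
#' Returns every window of each requested length that overlaps at least
#' one altered residue and differs from the position-aligned wild-type
#' window.  Altered residues are the positions at which the mutant and
#' wild-type sequences disagree (positions beyond the shorter sequence
#' count as altered), so frameshift tails yield every window from the
#' first altered residue to the stop.
#'
#' @param mutant_protein,wild_type_protein Sequences (single strings).
#' @param lengths Window lengths, default 9 and 10.
#' @param protein_id,source_variant_ids Optional provenance carried into
#'   the output.
#' @return Data frame with columns `sequence`, `window_start`, `length`,
#'   `altered_positions` (comma-joined indices within the window),
#'   `protein_id`, `source_variant_ids`.
#' @export
enumerate_windows <- function(mutant_protein, wild_type_protein,
                              lengths = PEPTIDE_LENGTHS,
                              protein_id = NA_character_,
                              source_variant_ids = NA_character_) {
  if (nchar(mutant_protein) == 0 || nchar(wild_type_protein) == 0)
    stop_config("sequences must be non-empty")
  n <- nchar(mutant_protein)
  nw <- nchar(wild_type_protein)
  m <- utf8ToInt(mutant_protein)
  w <- utf8ToInt(wild_type_protein)
  k <- min(n, nw)
  altered <- which(m[seq_len(k)] != w[seq_len(k)])
  if (n > nw) altered <- c(altered, (nw + 1L):n)
  if (length(altered) == 0)
    return(empty_peptides())
  out <- lapply(lengths, function(L) {
    ns <- n - L + 1L
    if (ns < 1L) return(NULL)
    mark <- logical(ns)
    for (a in altered) {
      lo <- max(1L, a - L + 1L)
      hi <- min(a, ns)
      if (lo <= hi) mark[lo:hi] <- TRUE
    }
    starts <- which(mark)
    if (length(starts) == 0) return(NULL)
    seqs <- substring(mutant_protein, starts, starts + L - 1L)
    wtw <- substring(wild_type_protein, starts, starts + L - 1L)
    differs <- seqs != wtw | (starts + L - 1L) > nw
    starts <- starts[differs]
    if (length(starts) == 0) return(NULL)
    ap <- vapply(starts, function(s)
      paste(altered[altered >= s & altered <= s + L - 1L] - s + 1L,
            collapse = ","), character(1))
    data.frame(sequence = seqs[differs], window_start = starts,
               length = L, altered_positions = ap,
               protein_id = protein_id,
               source_variant_ids = source_variant_ids,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) empty_peptides() else out
}

empty_peptides <- function() {
  data.frame(sequence = character(0), window_start = integer(0),
             length = integer(0), altered_positions = character(0),
             protein_id = character(0), source_variant_ids = character(0),
             stringsAsFactors = FALSE)
}

#' Peptides spanning a fusion junction
#'
#' For in-frame fusions, every window containing at least one residue
#' from each side of the junction; for out-of-frame fusions, every
#' window containing at least one residue of the novel downstream
#' translation (which runs to the next stop).  Shorter context yields
#' fewer windows, never an error.
#'
#' @param fusion One-row data frame (or list) with fields `id`,
#'   `gene5`, `gene3`, `junction_seq5`, `junction_seq3`, `frame`.
#' @param lengths Window lengths, default 9 and 10.
#' @return A peptide data frame as in [enumerate_windows()];
#'   `window_start` is relative to the concatenated junction context.
#' @export
fusion_junction_peptides <- function(fusion, lengths = PEPTIDE_LENGTHS) {
  up <- fusion$junction_seq5
  down <- fusion$junction_seq3
  if (is.na(up) || is.na(down) || !fusion$frame %in%
      c("in_frame", "out_of_frame"))
    stop_config("fusion %s needs junction context and a frame label",
                fusion$id %||% "?")
  ctx <- paste0(up, down)
  n5 <- nchar(up)
  n <- nchar(ctx)
  out <- lapply(lengths, function(L) {
    lo <- max(1L, n5 - L + 2L)
    hi <- if (fusion$frame == "in_frame") min(n5, n - L + 1L) else
      n - L + 1L
    if (lo > hi) return(NULL)
    starts <- lo:hi
    # every window here already includes >= 1 downstream residue
    ap <- vapply(starts, function(s) {
      novel <- seq.int(s, s + L - 1L)
      paste(novel[novel > n5] - s + 1L, collapse = ",")
    }, character(1))
    data.frame(sequence = substring(ctx, starts, starts + L - 1L),
               window_start = starts, length = L,
               altered_positions = ap,
               protein_id = paste0(fusion$gene5, "::", fusion$gene3),
               source_variant_ids = fusion$id %||% NA_character_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) empty_peptides() else out
}

#' Build the wild-type reference k-mer set
#'
#' @param proteome Named character vector of wild-type protein sequences
#'   or a `Biostrings::AAStringSet`.
#' @param lengths k-mer lengths, default 9 and 10.
#' @return Character vector of all distinct wild-type k-mers.
#' @export
build_reference_kmers <- function(proteome, lengths = PEPTIDE_LENGTHS) {
  if (inherits(proteome, "AAStringSet"))
    proteome <- as.character(proteome)
  kmers <- lapply(lengths, function(L) {
    unlist(lapply(proteome, function(s) {
      n <- nchar(s)
      if (n < L) return(character(0))
      substring(s, 1:(n - L + 1L), L:n)
    }), use.names = FALSE)
  })
  unique(unlist(kmers))
}

#' Drop mutant peptides present in the wild-type proteome
#'
#' Candidate neoantigens must be absent from normal tissue; any mutant
#' peptide whose sequence occurs in the reference k-mer set is removed.
#'
#' @param peptides Peptide data frame (column `sequence`).
#' @param reference_kmers Character vector from [build_reference_kmers()].
#' @return The unique subset, order preserved.
#' @export
uniqueness_filter <- function(peptides, reference_kmers) {
  assert_columns(peptides, "sequence", "peptide table")
  peptides[!(peptides$sequence %in% reference_kmers), , drop = FALSE]
}

#' Deterministic surrogate antigen-presentation scorer
#'
#' Stands in for proprietary presentation models: each (peptide, allele)
#' pair is mapped by a string hash to a uniform deviate and through the
#' Beta quantile function, giving reproducible scores in \[0, 1\] with a
#' realistic right-skewed distribution.  Real models plug in through the
#' same contract: a list with a vectorized `score(peptides, alleles)`
#' function returning values in \[0, 1\], and a `deterministic` flag.
#'
#' @param shape1,shape2 Beta parameters of the marginal score
#'   distribution.
#' @return A list of class `neo_scorer`.
#' @export
surrogate_scorer <- function(shape1 = 1.5, shape2 = 4) {
  force(shape1); force(shape2)
  structure(list(
    score = function(peptides, alleles)
      stats::qbeta(hash_unit(paste0(peptides, "|", alleles)),
                   shape1, shape2),
    deterministic = TRUE,
    label = sprintf("surrogate Beta(%g, %g) hash scorer", shape1, shape2)
  ), class = "neo_scorer")
}

#' Score peptides against a patient's HLA-A/-B alleles
#'
#' One candidate per (peptide, allele) pair.  HLA-C alleles are excluded
#' by default (class I presentation models are not validated for C), and
#' duplicate peptides arising from different windows of the same protein
#' are collapsed to one candidate per (sequence, protein) before
#' expansion.
#'
#' @param peptides Peptide data frame (from [enumerate_windows()] /
#'   [fusion_junction_peptides()]).
#' @param patient_hla Character vector of alleles, e.g. `"A*02:01"`
#'   (an optional `"HLA-"` prefix is tolerated).
#' @param scorer A scorer honouring the `neo_scorer` contract.
#' @param include_hla_c Score HLA-C alleles too (default `FALSE`).
#' @return Data frame of candidates: peptide fields plus `hla_allele`
#'   and `ap_score`.
#' @export
score_candidates <- function(peptides, patient_hla,
                             scorer = surrogate_scorer(),
                             include_hla_c = FALSE) {
  if (length(patient_hla) == 0)
    stop_config("patient allele list is empty")
  if (!is.list(scorer) || !is.function(scorer$score))
    stop_config("scorer must provide a score(peptides, alleles) function")
  loci <- substr(sub("^HLA-", "", patient_hla), 1, 1)
  keep_loci <- if (include_hla_c) c("A", "B", "C") else c("A", "B")
  alleles <- unique(patient_hla[loci %in% keep_loci])
  peptides <- peptides[!duplicated(peptides[c("sequence", "protein_id")]),
                       , drop = FALSE]
  if (nrow(peptides) == 0 || length(alleles) == 0) {
    out <- peptides[integer(0), , drop = FALSE]
    out$hla_allele <- character(0)
    out$ap_score <- numeric(0)
    return(out)
  }
  idx <- rep(seq_len(nrow(peptides)), times = length(alleles))
  out <- peptides[idx, , drop = FALSE]
  out$hla_allele <- rep(alleles, each = nrow(peptides))
  out$ap_score <- as.numeric(scorer$score(out$sequence, out$hla_allele))
  if (anyNA(out$ap_score) || any(out$ap_score < 0 | out$ap_score > 1))
    stop_config("scorer returned values outside [0, 1]")
  rownames(out) <- NULL
  out
}

#' Expression-adjusted peptide abundance
#'
#' The abundance of a mutant peptide is the summed TPM of the isoforms
#' coding for it, scaled by the variant allele frequency measured at the
#' RNA level.
#'
#' @param tpm Numeric TPM values of the coding isoforms.
#' @param vaf_rna RNA-level VAF in \[0, 1\].
#' @return `sum(tpm) * vaf_rna`.
#' @export
peptide_abundance <- function(tpm, vaf_rna) {
  if (is.na(vaf_rna) || vaf_rna < 0 || vaf_rna > 1)
    stop_config("vaf_rna must lie in [0, 1]")
  sum(tpm, na.rm = TRUE) * vaf_rna
}
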
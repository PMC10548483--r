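# On-disk representation of a cohort: plain TSV tables, a minimal VCF
# dialect mirroring the variant TSV, a wild-type protein FASTA and the
# generator configuration as JSON.

COHORT_FILES <- c(
  clinical = "clinical.tsv", patients = "patients.tsv", hla = "hla.tsv",
  variants = "variants.tsv", fusions = "fusions.tsv", tpm = "tpm.tsv",
  expression = "expression.tsv", cell_fractions = "cell_fractions.tsv",
  bulk = "bulk_expression.tsv",
  candidates = "candidates.tsv", transcripts = "transcripts.tsv"
)

#' Write a synthetic cohort to a directory
#'
#' Emits the exact formats the pipeline stages read: per-table TSVs, the
#' variant table additionally as a minimal VCF (INFO keys `NCALLERS`,
#' `DPT`, `DPN`, `ALTT`, `VAFD`, `VAFR`, `CSQCLASS`, `PS`, plus the
#' protein-level annotation keys `PROT`, `PPOS`, `AAREF`, `AAALT`,
#' `TRID`), the proteome as FASTA and the configuration as JSON.
#'
#' @param cohort A `synthetic_cohort` from [generate_cohort()].
#' @param directory Output directory, created if needed.
#' @return Invisibly, the vector of file paths written.
#' @export
write_cohort <- function(cohort, directory) {
  if (!inherits(cohort, "synthetic_cohort"))
    stop_config("cohort must be a synthetic_cohort")
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(directory))
    stop_config("cannot create output directory: %s", directory)
  paths <- character(0)
  for (nm in names(COHORT_FILES)) {
    p <- file.path(directory, COHORT_FILES[[nm]])
    write_tsv(cohort[[nm]], p)
    paths <- c(paths, p)
  }
  vcf <- file.path(directory, "variants.vcf")
  write_variants_vcf(cohort$variants, vcf)
  fa <- file.path(directory, "proteome.fasta")
  Biostrings::writeXStringSet(
    Biostrings::AAStringSet(cohort$proteome), fa)
  cfg <- file.path(directory, "config.json")
  cfg_out <- unclass(cohort$truth$config)
  for (nm in c("subtype_weights", "response_weights",
               "cell_fraction_concentration", "hazard_coefficients"))
    cfg_out[[nm]] <- as.list(cfg_out[[nm]]) # keep names in JSON
  jsonlite::write_json(cfg_out, cfg,
                       auto_unbox = TRUE, digits = NA, null = "null")
  truth <- file.path(directory, "truth.json")
  jsonlite::write_json(list(lambda0 = cohort$truth$lambda0,
                            tau = cohort$truth$tau),
                       truth, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, vcf, fa, cfg, truth))
}

#' Read a cohort back from a directory written by [write_cohort()]
#'
#' @param directory Directory containing the cohort files.
#' @return A list of class `synthetic_cohort`.
#' @export
read_cohort <- function(directory) {
  if (!dir.exists(directory))
    stop_config("cohort directory does not exist: %s", directory)
  out <- lapply(names(COHORT_FILES), function(nm)
    read_tsv(file.path(directory, COHORT_FILES[[nm]])))
  names(out) <- names(COHORT_FILES)
  for (nm in names(out)) {
    # empty or all-NA columns read back as logical; every logical in the
    # cohort schema is really a character column
    for (col in names(out[[nm]]))
      if (is.logical(out[[nm]][[col]]))
        out[[nm]][[col]] <- as.character(out[[nm]][[col]])
  }
  fa <- Biostrings::readAAStringSet(file.path(directory, "proteome.fasta"))
  out$proteome <- stats::setNames(as.character(fa), names(fa))
  cfg <- jsonlite::read_json(file.path(directory, "config.json"))
  # unlist() preserves names, which jsonlite's simplification drops
  for (nm in c("subtype_weights", "response_weights",
               "cell_fraction_concentration", "hazard_coefficients",
               "protein_length"))
    cfg[[nm]] <- unlist(cfg[[nm]])
  cfg$ap_score_distribution <- lapply(cfg$ap_score_distribution,
                                      as.numeric)
  cfg$mutation_rate_ranges <- lapply(cfg$mutation_rate_ranges,
                                     function(x) lapply(x, unlist))
  for (nm in c("n_patients", "baseline_median_pfs", "censoring_rate",
               "response_quality_shift", "n_proteins", "bulk_noise_sd",
               "seed"))
    cfg[[nm]] <- as.numeric(cfg[[nm]])
  config <- do.call(cohort_config, cfg)
  truth <- jsonlite::read_json(file.path(directory, "truth.json"),
                               simplifyVector = TRUE)
  out$truth <- list(config = config, lambda0 = truth$lambda0,
                    tau = truth$tau)
  class(out) <- "synthetic_cohort"
  out
}

#' Write the variant table as a minimal VCF
#'
#' One record per somatic variant; quality-model fields travel in INFO.
#' @param variants Variant data frame (see [generate_cohort()]).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_variants_vcf <- function(variants, path) {
  info_keys <- c(
    "##INFO=<ID=PATIENT,Number=1,Type=String,Description=\"Patient id\">",
    "##INFO=<ID=NCALLERS,Number=1,Type=Integer,Description=\"Supporting callers (of 6)\">",
    "##INFO=<ID=DPT,Number=1,Type=Integer,Description=\"Tumor depth\">",
    "##INFO=<ID=DPN,Number=1,Type=Integer,Description=\"Normal depth\">",
    "##INFO=<ID=ALTT,Number=1,Type=Integer,Description=\"Tumor alt reads\">",
    "##INFO=<ID=VAFD,Number=1,Type=Float,Description=\"DNA VAF\">",
    "##INFO=<ID=VAFR,Number=1,Type=Float,Description=\"RNA VAF\">",
    "##INFO=<ID=CSQCLASS,Number=1,Type=String,Description=\"Consequence class\">",
    "##INFO=<ID=PS,Number=1,Type=String,Description=\"Phase set\">",
    "##INFO=<ID=PROT,Number=1,Type=String,Description=\"Protein id\">",
    "##INFO=<ID=PPOS,Number=1,Type=Integer,Description=\"1-based residue\">",
    "##INFO=<ID=AAREF,Number=1,Type=String,Description=\"Reference residue(s)\">",
    "##INFO=<ID=AAALT,Number=1,Type=String,Description=\"Alternate residue(s)\">",
    "##INFO=<ID=TRID,Number=.,Type=String,Description=\"Transcript ids\">")
  hdr <- c("##fileformat=VCFv4.2", "##source=sarcneo", info_keys,
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  kv <- function(key, val) ifelse(is.na(val), NA,
                                  paste0(key, "=", val))
  fields <- cbind(kv("PATIENT", variants$patient_id),
                  kv("NCALLERS", variants$n_callers),
                  kv("DPT", variants$depth_tumor),
                  kv("DPN", variants$depth_normal),
                  kv("ALTT", variants$alt_reads_tumor),
                  kv("VAFD", format(variants$vaf_dna, digits = 15)),
                  kv("VAFR", format(variants$vaf_rna, digits = 15)),
                  kv("CSQCLASS", variants$consequence),
                  kv("PS", variants$phase_set),
                  kv("PROT", variants$protein_id),
                  kv("PPOS", variants$protein_pos),
                  kv("AAREF", variants$aa_ref),
                  kv("AAALT", variants$aa_alt),
                  kv("TRID", variants$transcript_ids))
  info <- apply(fields, 1, function(r) paste(r[!is.na(r)], collapse = ";"))
  if (nrow(variants) == 0) info <- character(0)
  body <- if (nrow(variants) == 0) character(0) else
    paste(variants$chrom, variants$pos, variants$id, variants$ref,
          variants$alt, ".", "PASS", info, sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a variant table (TSV dialect or minimal VCF)
#'
#' @param path Path to a `.tsv` written by [write_cohort()] or a `.vcf`
#'   in the package's minimal dialect.
#' @return A variant data frame with the standard columns.
#' @export
read_variants <- function(path) {
  if (grepl("\\.vcf(\\.gz)?$", path)) read_variants_vcf_file(path)
  else read_tsv(path)
}

read_variants_vcf_file <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop_config("reading VCF requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  gi <- function(key) vcfR::extract.info(v, element = key)
  ni <- function(key) suppressWarnings(as.numeric(gi(key)))
  n <- nrow(fix)
  if (is.null(n) || n == 0)
    return(make_variants(character(0), integer(0), integer(0),
                         character(0), integer(0), list()))
  data.frame(
    id = fix$ID, patient_id = gi("PATIENT"), chrom = fix$CHROM,
    pos = as.integer(fix$POS), ref = fix$REF, alt = fix$ALT,
    n_callers = as.integer(ni("NCALLERS")),
    depth_tumor = as.integer(ni("DPT")),
    depth_normal = as.integer(ni("DPN")),
    alt_reads_tumor = as.integer(ni("ALTT")),
    vaf_dna = ni("VAFD"), vaf_rna = ni("VAFR"),
    consequence = gi("CSQCLASS"), phase_set = gi("PS"),
    protein_id = gi("PROT"),
    protein_pos = as.integer(ni("PPOS")),
    aa_ref = gi("AAREF"), aa_alt = gi("AAALT"),
    transcript_ids = gi("TRID"),
    stringsAsFactors = FALSE)
}
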
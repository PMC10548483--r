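# Synthetic cohort generation.
#
# Emulates the statistical structure of a small multi-subtype sarcoma
# immunotherapy cohort: 31 patients across seven histological subtypes
# (13 soft-tissue, 18 bone), heterogeneous SNV/indel/fusion counts,
# Beta-mixture antigen-presentation scores, Dirichlet immune cell
# fractions, and right-censored progression-free survival whose hazard
# carries a planted T-cell-fraction x neoantigen-quality interaction.

SARCOMA_SUBTYPES <- data.frame(
  subtype = c("SS", "LMS", "DDLPS", "UPS", "ES", "OS", "CS"),
  group   = c("STS", "STS", "STS", "STS", "bone", "bone", "bone"),
  stringsAsFactors = FALSE
)

CELL_TYPES <- c("B.cells", "Macrophages.M1", "Macrophages.M2", "Monocytes",
                "Neutrophils", "NK.cells", "T.cells.CD4", "T.cells.CD8",
                "Tregs", "Dendritic.cells")

HLA_POOL <- list(
  A = c("A*01:01", "A*02:01", "A*03:01", "A*11:01", "A*24:02", "A*26:01"),
  B = c("B*07:02", "B*08:01", "B*18:01", "B*35:01", "B*44:02", "B*51:01"),
  C = c("C*04:01", "C*05:01", "C*07:01", "C*07:02")
)

APM_GENES <- c("HLA-A", "HLA-B", "HLA-C", "B2M", "CIITA", "ERAP2",
               "TAP2", "TAPBPL")

default_mutation_ranges <- function() {
  # Per-subtype count ranges (uniform over integers).  Bone osteosarcoma
  # and UPS carry the largest small-variant loads, chondrosarcoma the
  # smallest; fusion-driven subtypes (ES, SS) and DDLPS get elevated
  # fusion counts.
  list(
    SS    = list(snv = c(3, 25),  indel = c(0, 4), fusion = c(2, 10)),
    LMS   = list(snv = c(10, 60), indel = c(0, 6), fusion = c(0, 4)),
    DDLPS = list(snv = c(8, 50),  indel = c(0, 6), fusion = c(3, 15)),
    UPS   = list(snv = c(15, 80), indel = c(0, 8), fusion = c(0, 4)),
    ES    = list(snv = c(3, 20),  indel = c(0, 4), fusion = c(2, 12)),
    OS    = list(snv = c(20, 90), indel = c(0, 8), fusion = c(0, 5)),
    CS    = list(snv = c(1, 12),  indel = c(0, 3), fusion = c(0, 3))
  )
}

#' Configuration for a synthetic sarcoma ICI cohort
#'
#' Captures every knob of the generator: cohort size and subtype
#' composition, per-subtype mutation count ranges, the Beta mixture used
#' for antigen presentation (AP) scores, the Dirichlet concentration over
#' immune cell types, the planted log-hazard coefficients (including the
#' T-cell x neoantigen-quality interaction), the censoring rate and the
#' seed.
#'
#' @param n_patients Number of patients (>= 1). Default 31, the size of
#'   the cohort the generator emulates.
#' @param subtype_weights Named probabilities over subtypes, summing to 1.
#'   The default reproduces the 13 STS / 18 bone composition
#'   (4 SS, 4 LMS, 2 DDLPS, 3 UPS / 6 ES, 9 OS, 3 CS).
#' @param response_weights Named probabilities over clinical response
#'   classes `R`, `SD`, `PD`, `NA` (unknown). Default 3/9/18/1 out of 31.
#' @param mutation_rate_ranges Per-subtype list with integer ranges
#'   `snv`, `indel`, `fusion`; see [default_mutation_ranges()] source.
#' @param ap_score_distribution Beta-mixture parameters for AP scores:
#'   `shape1`, `shape2` for the bulk component, `high_shape1`,
#'   `high_shape2` and mixing weight `high_prob` for the minority
#'   high-quality component.
#' @param cell_fraction_concentration Named Dirichlet concentration over
#'   the ten immune cell types plus `Other` (uncharacterized / tumor).
#' @param hazard_coefficients Named log-hazard weights `t_cell`,
#'   `quality`, `interaction` applied to within-cohort z-scores of the
#'   CD8+ T-cell fraction, the neoantigen quality, and their product.
#' @param baseline_median_pfs Median PFS in days of the baseline
#'   exponential (all coefficients zero). Default 100 days.
#' @param censoring_rate Target probability in \[0, 1\] that a patient is
#'   administratively censored under the baseline hazard.
#' @param response_quality_shift Additive shift applied to the AP scores
#'   of non-PD patients (responders and stable disease); 0 disables the
#'   planted response effect.
#' @param n_proteins,protein_length Size of the synthetic wild-type
#'   proteome (count, and min/max residue length).
#' @param seed Integer seed; the generator is bit-reproducible given the
#'   full configuration.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 31,
                          subtype_weights = NULL,
                          response_weights = c(R = 3, SD = 9, PD = 18,
                                               "NA" = 1) / 31,
                          mutation_rate_ranges = default_mutation_ranges(),
                          ap_score_distribution = list(
                            shape1 = 1.5, shape2 = 4,
                            high_prob = 0.12,
                            high_shape1 = 9, high_shape2 = 2),
                          cell_fraction_concentration = c(
                            B.cells = 1.2, Macrophages.M1 = 1,
                            Macrophages.M2 = 1.5, Monocytes = 1.2,
                            Neutrophils = 0.8, NK.cells = 0.8,
                            T.cells.CD4 = 1.8, T.cells.CD8 = 1.8,
                            Tregs = 0.7, Dendritic.cells = 0.7,
                            Other = 10),
                          hazard_coefficients = c(t_cell = -1.2,
                                                  quality = -0.8,
                                                  interaction = -1.0),
                          baseline_median_pfs = 100,
                          censoring_rate = 0.15,
                          response_quality_shift = 0,
                          n_proteins = 60,
                          protein_length = c(150, 400),
                          bulk_noise_sd = 0.05,
                          seed = 1L) {
  if (is.null(subtype_weights)) {
    subtype_weights <- c(SS = 4, LMS = 4, DDLPS = 2, UPS = 3,
                         ES = 6, OS = 9, CS = 3) / 31
  }
  if (!is.numeric(n_patients) || length(n_patients) != 1 ||
      is.na(n_patients) || n_patients < 1)
    stop_config("n_patients must be a single integer >= 1")
  n_patients <- as.integer(n_patients)
  if (abs(sum(subtype_weights) - 1) > 1e-9)
    stop_config("subtype_weights must sum to 1 (got %.12f)",
                sum(subtype_weights))
  if (!all(names(subtype_weights) %in% SARCOMA_SUBTYPES$subtype))
    stop_config("unknown subtype(s): %s",
                paste(setdiff(names(subtype_weights),
                              SARCOMA_SUBTYPES$subtype), collapse = ", "))
  if (abs(sum(response_weights) - 1) > 1e-9)
    stop_config("response_weights must sum to 1")
  if (censoring_rate < 0 || censoring_rate > 1 || is.na(censoring_rate))
    stop_config("censoring_rate must lie in [0, 1]")
  ap <- ap_score_distribution
  for (p in c("shape1", "shape2", "high_shape1", "high_shape2"))
    if (is.null(ap[[p]]) || ap[[p]] <= 0)
      stop_config("ap_score_distribution$%s must be > 0", p)
  if (ap$high_prob < 0 || ap$high_prob > 1)
    stop_config("ap_score_distribution$high_prob must lie in [0, 1]")
  if (any(cell_fraction_concentration <= 0))
    stop_config("cell_fraction_concentration must be positive")
  if (!all(c("t_cell", "quality", "interaction") %in%
           names(hazard_coefficients)))
    stop_config("hazard_coefficients needs t_cell, quality, interaction")
  if (baseline_median_pfs <= 0)
    stop_config("baseline_median_pfs must be > 0")
  for (st in names(subtype_weights)) {
    rr <- mutation_rate_ranges[[st]]
    if (is.null(rr))
      stop_config("mutation_rate_ranges missing subtype %s", st)
    for (k in c("snv", "indel", "fusion"))
      if (length(rr[[k]]) != 2 || any(rr[[k]] < 0) || rr[[k]][1] > rr[[k]][2])
        stop_config("mutation_rate_ranges$%s$%s must be a valid range", st, k)
  }
  structure(list(
    n_patients = n_patients,
    subtype_weights = subtype_weights,
    response_weights = response_weights,
    mutation_rate_ranges = mutation_rate_ranges,
    ap_score_distribution = ap,
    cell_fraction_concentration = cell_fraction_concentration,
    hazard_coefficients = hazard_coefficients,
    baseline_median_pfs = baseline_median_pfs,
    censoring_rate = censoring_rate,
    response_quality_shift = response_quality_shift,
    n_proteins = as.integer(n_proteins),
    protein_length = protein_length,
    bulk_noise_sd = bulk_noise_sd,
    seed = as.integer(seed)
  ), class = "cohort_config")
}

# Largest-remainder apportionment: deterministic integer counts whose sum
# is n and whose proportions track the weights as closely as possible.
apportion <- function(weights, n) {
  raw <- weights * n
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  stats::setNames(as.integer(base), names(weights))
}

rdirichlet1 <- function(n, alpha) {
  g <- matrix(stats::rgamma(n * length(alpha), shape = alpha),
              nrow = n, byrow = TRUE)
  g / rowSums(g)
}

random_peptides <- function(n, lengths = c(9L, 10L)) {
  if (n == 0) return(character(0))
  maxl <- max(lengths)
  m <- matrix(sample(AA20, n * maxl, replace = TRUE), ncol = maxl)
  full <- do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
  substr(full, 1, sample(lengths, n, replace = TRUE))
}

# Solve for the administrative censoring horizon tau such that, under the
# baseline exponential with rate lambda0 and C ~ Uniform(0, tau),
# P(C < T) = censoring_rate.  The probability (1 - exp(-l*tau))/(l*tau)
# decreases from 1 to 0 in tau, so the root is unique.
censoring_horizon <- function(lambda0, censoring_rate) {
  if (censoring_rate <= 0) return(Inf)
  if (censoring_rate >= 1) return(0)
  f <- function(tau) (1 - exp(-lambda0 * tau)) / (lambda0 * tau) -
    censoring_rate
  stats::uniroot(f, lower = 1e-9, upper = 1e12, tol = 1e-12)$root
}

zscore <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

#' Generate a complete synthetic cohort
#'
#' Draws, deterministically given the seed, a full multi-table cohort:
#' clinical records with right-censored PFS, per-patient somatic variant
#' and fusion tables (with caller support, depths, DNA/RNA VAFs,
#' consequence classes and phase-set tags), a synthetic wild-type
#' proteome with transcript TPM abundances, HLA class I genotypes,
#' Dirichlet immune cell fractions, and planted neoantigen candidate
#' tables with Beta-mixture AP scores.  PFS is exponential with a
#' log-hazard linear in the within-cohort z-scores of the CD8+ T-cell
#' fraction, the neoantigen quality and their product; censoring is
#' independent uniform administrative censoring.
#'
#' @param config A [cohort_config()].
#' @return A list of class `synthetic_cohort` with elements `patients`,
#'   `clinical`, `hla`, `variants`, `fusions`, `tpm`, `expression`,
#'   `cell_fractions`, `candidates`, `proteome`, `transcripts` and
#'   `truth` (the planted parameters).
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "cohort_config"))
    stop_config("config must be created by cohort_config()")
  set.seed(config$seed)
  n <- config$n_patients
  ids <- sprintf("p%02d", seq_len(n))

  ## --- subtype and response assignment (exact composition, shuffled) ---
  sub_counts <- apportion(config$subtype_weights, n)
  subtype <- sample(rep(names(sub_counts), sub_counts))
  group <- SARCOMA_SUBTYPES$group[match(subtype, SARCOMA_SUBTYPES$subtype)]
  resp_counts <- apportion(config$response_weights, n)
  response <- sample(rep(names(resp_counts), resp_counts))
  response[response == "NA"] <- NA_character_

  ## --- HLA genotypes (2 alleles per locus, homozygosity allowed) ---
  hla <- do.call(rbind, lapply(c("A", "B", "C"), function(loc) {
    data.frame(patient_id = rep(ids, each = 2),
               locus = loc,
               allele = sample(HLA_POOL[[loc]], 2 * n, replace = TRUE),
               stringsAsFactors = FALSE)
  }))
  ab_mat <- matrix(hla$allele[hla$locus %in% c("A", "B")], nrow = n)

  ## --- synthetic proteome and transcript model ---
  np <- config$n_proteins
  prot_ids <- sprintf("PROT%03d", seq_len(np))
  plen <- sample(config$protein_length[1]:config$protein_length[2], np,
                 replace = TRUE)
  proteome <- vapply(plen, function(L)
    paste(sample(AA20, L, replace = TRUE), collapse = ""), character(1))
  names(proteome) <- prot_ids
  has_iso2 <- stats::runif(np) < 0.25
  transcripts <- data.frame(
    transcript_id = c(paste0(prot_ids, "_t1"),
                      paste0(prot_ids[has_iso2], "_t2")),
    protein_id = c(prot_ids, prot_ids[has_iso2]),
    stringsAsFactors = FALSE
  )
  tx_by_prot <- split(transcripts$transcript_id, transcripts$protein_id)

  ## --- transcript abundance (TPM), per patient ---
  ntx <- nrow(transcripts)
  tpm <- data.frame(
    patient_id = rep(ids, each = ntx),
    transcript_id = rep(transcripts$transcript_id, n),
    tpm = ifelse(stats::runif(n * ntx) < 0.15, 0,
                 stats::rlnorm(n * ntx, meanlog = 1.5, sdlog = 1)),
    stringsAsFactors = FALSE
  )

  ## --- antigen-processing-machinery expression covariates ---
  expression <- data.frame(patient_id = ids, stringsAsFactors = FALSE)
  for (g in APM_GENES)
    expression[[g]] <- stats::rlnorm(n, meanlog = log(50), sdlog = 0.8)

  ## --- somatic small variants ---
  rr <- config$mutation_rate_ranges
  rint <- function(range, k) {
    if (range[2] == range[1]) rep(range[1], k)
    else sample(range[1]:range[2], k, replace = TRUE)
  }
  n_snv <- n_indel <- n_fus <- integer(n)
  for (st in unique(subtype)) {
    idx <- which(subtype == st)
    n_snv[idx] <- rint(rr[[st]]$snv, length(idx))
    n_indel[idx] <- rint(rr[[st]]$indel, length(idx))
    n_fus[idx] <- rint(rr[[st]]$fusion, length(idx))
  }
  variants <- make_variants(ids, n_snv, n_indel, proteome, plen, tx_by_prot)
  fusions <- make_fusions(ids, n_fus)

  ## --- planted neoantigen candidates ---
  nonsyn <- variants$consequence %in% c("missense", "frameshift",
                                        "inframe_indel")
  n_nonsyn <- tabulate(match(variants$patient_id[nonsyn], ids), nbins = n)
  fus_kept <- fusions$confidence %in% c("medium", "high")
  n_fk <- tabulate(match(fusions$patient_id[fus_kept], ids), nbins = n)
  # fusion junctions yield many distinct windows per event, while most
  # SNV-derived peptides fall to the expression/uniqueness filters, so
  # fusions dominate the planted candidate counts
  n_cand <- stats::rpois(n, lambda = pmax(1 * n_nonsyn + 15 * n_fk, 0.5))
  candidates <- make_candidates(ids, n_cand, ab_mat, response, config)

  ## --- patient-level covariates from the planted candidates ---
  frac <- rdirichlet1(n, config$cell_fraction_concentration)
  colnames(frac) <- names(config$cell_fraction_concentration)
  cell_fractions <- data.frame(patient_id = ids, frac,
                               check.names = FALSE,
                               stringsAsFactors = FALSE)
  t_cell <- frac[, "T.cells.CD8"]

  ## --- bulk expression over the signature gene panel ---
  # mixture = signature %*% immune fractions, with multiplicative
  # lognormal noise; the "Other" component contributes no signal on the
  # immune marker panel.
  sig <- synthetic_signature()
  mix <- sig %*% t(frac[, colnames(sig), drop = FALSE])
  mix <- mix * matrix(exp(stats::rnorm(length(mix), 0,
                                       config$bulk_noise_sd)),
                      nrow = nrow(mix))
  bulk <- data.frame(gene = rownames(sig), mix, check.names = FALSE,
                     stringsAsFactors = FALSE)
  names(bulk) <- c("gene", ids)
  scores_by_patient <- split(candidates$ap_score,
                             factor(candidates$patient_id, levels = ids))
  quality <- vapply(scores_by_patient, function(s) {
    if (length(s) == 0) return(0)
    mean(sort(s, decreasing = TRUE)[seq_len(min(10L, length(s)))])
  }, numeric(1))
  nal <- vapply(scores_by_patient, function(s) sum(s > 0.5), numeric(1))

  ## --- survival with planted interaction ---
  b <- config$hazard_coefficients
  z_t <- zscore(t_cell)
  z_q <- zscore(quality)
  lp <- b[["t_cell"]] * z_t + b[["quality"]] * z_q +
    b[["interaction"]] * z_t * z_q
  lambda0 <- log(2) / config$baseline_median_pfs
  hazard <- lambda0 * exp(lp)
  t_true <- stats::rexp(n, rate = hazard)
  tau <- censoring_horizon(lambda0, config$censoring_rate)
  if (is.finite(tau)) {
    cens <- stats::runif(n, 0, tau)
    pfs <- pmax(pmin(t_true, cens), 1e-6)
    event <- as.integer(t_true <= cens)
  } else {
    pfs <- pmax(t_true, 1e-6)
    event <- rep(1L, n)
  }

  patients <- data.frame(
    patient_id = ids, subtype = subtype, group = group,
    response = response,
    t_cell_fraction = t_cell,
    neoantigen_quality = quality,
    nal = nal,
    z_t_cell = z_t, z_quality = z_q,
    linear_predictor = lp, hazard = hazard,
    stringsAsFactors = FALSE
  )
  clinical <- data.frame(
    patient_id = ids, subtype = subtype,
    pfs_days = pfs, event = event, response = response,
    stringsAsFactors = FALSE
  )

  rownames(patients) <- rownames(clinical) <- rownames(bulk) <- NULL
  structure(list(
    patients = patients, clinical = clinical, hla = hla,
    variants = variants, fusions = fusions, tpm = tpm,
    expression = expression, cell_fractions = cell_fractions,
    bulk = bulk, candidates = candidates, proteome = proteome,
    transcripts = transcripts,
    truth = list(config = config, lambda0 = lambda0, tau = tau)
  ), class = "synthetic_cohort")
}

make_variants <- function(ids, n_snv, n_indel, proteome, plen, tx_by_prot) {
  n <- length(ids)
  N <- sum(n_snv) + sum(n_indel)
  empty <- data.frame(
    id = character(0), patient_id = character(0), chrom = character(0),
    pos = integer(0), ref = character(0), alt = character(0),
    n_callers = integer(0), depth_tumor = integer(0),
    depth_normal = integer(0), alt_reads_tumor = integer(0),
    vaf_dna = numeric(0), vaf_rna = numeric(0),
    consequence = character(0), phase_set = character(0),
    protein_id = character(0), protein_pos = integer(0),
    aa_ref = character(0), aa_alt = character(0),
    transcript_ids = character(0), stringsAsFactors = FALSE)
  if (N == 0) return(empty)
  patient <- c(rep(ids, n_snv), rep(ids, n_indel))
  type <- c(rep("snv", sum(n_snv)), rep("indel", sum(n_indel)))
  consequence <- character(N)
  is_snv <- type == "snv"
  consequence[is_snv] <- sample(c("missense", "synonymous", "noncoding"),
                                sum(is_snv), replace = TRUE,
                                prob = c(0.68, 0.20, 0.12))
  consequence[!is_snv] <- sample(c("frameshift", "inframe_indel",
                                   "noncoding"),
                                 sum(!is_snv), replace = TRUE,
                                 prob = c(0.55, 0.35, 0.10))
  coding <- consequence != "noncoding"
  prot_idx <- rep(NA_integer_, N)
  prot_idx[coding] <- sample(length(proteome), sum(coding), replace = TRUE)
  protein_id <- ifelse(coding, names(proteome)[prot_idx], NA_character_)
  protein_pos <- rep(NA_integer_, N)
  protein_pos[coding] <- 1L +
    floor(stats::runif(sum(coding)) * plen[prot_idx[coding]])
  aa_ref <- rep(NA_character_, N)
  aa_ref[coding] <- substr(proteome[prot_idx[coding]],
                           protein_pos[coding], protein_pos[coding])
  aa_alt <- rep(NA_character_, N)
  mis <- consequence == "missense"
  # vectorized draw of a residue different from the reference
  ri <- match(aa_ref[mis], AA20)
  draw <- sample(length(AA20) - 1L, sum(mis), replace = TRUE)
  aa_alt[mis] <- AA20[draw + (draw >= ri)]
  aa_alt[consequence == "synonymous"] <-
    aa_ref[consequence == "synonymous"]
  fs <- consequence == "frameshift"
  aa_alt[fs] <- random_peptides(sum(fs), lengths = 5:25)
  inf <- consequence == "inframe_indel"
  if (any(inf)) {
    ins <- stats::runif(sum(inf)) < 0.5
    w <- which(inf)
    aa_alt[w[ins]] <- paste0(aa_ref[w[ins]],
                             random_peptides(sum(ins), lengths = 1:3))
    # deletions: remove 1-3 residues starting at the site
    if (any(!ins)) {
      wd <- w[!ins]
      k <- sample(1:3, length(wd), replace = TRUE)
      end <- pmin(protein_pos[wd] + k,
                  nchar(proteome[prot_idx[wd]]))
      aa_ref[wd] <- substr(proteome[prot_idx[wd]], protein_pos[wd], end)
      aa_alt[wd] <- substr(aa_ref[wd], 1, 1)
    }
  }
  tx_str <- vapply(tx_by_prot, paste, character(1), collapse = ",")
  transcript_ids <- rep(NA_character_, N)
  transcript_ids[coding] <- tx_str[protein_id[coding]]

  depth_tumor <- stats::rnbinom(N, mu = 80, size = 8)
  depth_normal <- stats::rnbinom(N, mu = 50, size = 8)
  vaf_dna <- stats::rbeta(N, 1.8, 4)
  alt_reads <- stats::rbinom(N, depth_tumor, vaf_dna)
  vaf_rna <- pmin(1, pmax(0, vaf_dna + stats::rnorm(N, 0, 0.08)))

  base <- c("A", "C", "G", "T")
  ref <- sample(base, N, replace = TRUE)
  bi <- match(ref, base)
  bdraw <- sample(3L, N, replace = TRUE)
  alt <- base[bdraw + (bdraw >= bi)]
  if (any(!is_snv)) {
    extra <- vapply(sample(1:3, sum(!is_snv), replace = TRUE), function(k)
      paste(sample(base, k, replace = TRUE), collapse = ""), character(1))
    ins <- stats::runif(sum(!is_snv)) < 0.5
    alt[!is_snv][ins] <- paste0(ref[!is_snv][ins], extra[ins])
    ref[!is_snv][!ins] <- paste0(ref[!is_snv][!ins], extra[!ins])
    alt[!is_snv][!ins] <- substr(ref[!is_snv][!ins], 1, 1)
  }

  ord <- order(match(patient, ids))
  df <- data.frame(
    id = NA_character_, patient_id = patient,
    chrom = sample(paste0("chr", 1:22), N, replace = TRUE),
    pos = sample.int(5e7, N, replace = TRUE),
    ref = ref, alt = alt,
    n_callers = sample(0:6, N, replace = TRUE,
                       prob = c(0.03, 0.10, 0.17, 0.25, 0.20, 0.15, 0.10)),
    depth_tumor = depth_tumor, depth_normal = depth_normal,
    alt_reads_tumor = alt_reads,
    vaf_dna = vaf_dna, vaf_rna = vaf_rna,
    consequence = consequence, phase_set = NA_character_,
    protein_id = protein_id, protein_pos = protein_pos,
    aa_ref = aa_ref, aa_alt = aa_alt,
    transcript_ids = transcript_ids,
    stringsAsFactors = FALSE)[ord, ]
  rownames(df) <- NULL
  df$id <- paste0(df$patient_id, "_v",
                  stats::ave(seq_len(N), df$patient_id, FUN = seq_along))

  # Phase sets: where a patient carries >= 2 coding variants on the same
  # protein at distinct residues, tag the first such pair with a shared
  # phase set with probability 0.25.
  key <- paste(df$patient_id, df$protein_id)
  cod <- !is.na(df$protein_id)
  dup <- cod & duplicated(key) & !duplicated(paste(key, df$protein_pos))
  cand_rows <- which(dup)[!duplicated(key[dup])]
  keep <- cand_rows[stats::runif(length(cand_rows)) < 0.25]
  first_idx <- match(key, key) # first row of each (patient, protein)
  mates <- first_idx[keep]
  ok <- !is.na(mates) & mates < keep
  tags <- paste0("ps_", gsub(" ", "_", key[keep[ok]]))
  df$phase_set[keep[ok]] <- tags
  df$phase_set[mates[ok]] <- tags
  df
}

make_fusions <- function(ids, n_fus) {
  N <- sum(n_fus)
  genes <- c("EWSR1", "FLI1", "SS18", "SSX1", "SSX2", "FUS", "DDIT3",
             "COL1A1", "PDGFB", "TAF15", sprintf("GENE%02d", 1:20))
  if (N == 0)
    return(data.frame(id = character(0), patient_id = character(0),
                      gene5 = character(0), gene3 = character(0),
                      junction_seq5 = character(0),
                      junction_seq3 = character(0),
                      frame = character(0), confidence = character(0),
                      stringsAsFactors = FALSE))
  patient <- rep(ids, n_fus)
  df <- data.frame(
    id = NA_character_, patient_id = patient,
    gene5 = sample(genes, N, replace = TRUE),
    gene3 = sample(genes, N, replace = TRUE),
    junction_seq5 = random_peptides(N, lengths = 6:14),
    junction_seq3 = random_peptides(N, lengths = 6:14),
    frame = sample(c("in_frame", "out_of_frame"), N, replace = TRUE),
    confidence = sample(c("low", "medium", "high"), N, replace = TRUE,
                        prob = c(0.3, 0.4, 0.3)),
    stringsAsFactors = FALSE)
  df$id <- paste0(df$patient_id, "_f",
                  stats::ave(seq_len(N), df$patient_id, FUN = seq_along))
  df
}

make_candidates <- function(ids, n_cand, ab_mat, response, config) {
  n <- length(ids)
  N <- sum(n_cand)
  if (N == 0)
    return(data.frame(patient_id = character(0), peptide = character(0),
                      hla_allele = character(0), ap_score = numeric(0),
                      abundance = numeric(0),
                      source_variant_ids = character(0),
                      stringsAsFactors = FALSE))
  ap <- config$ap_score_distribution
  patient_idx <- rep(seq_len(n), n_cand)
  # patient-level variation of the high-quality mixing weight, so the
  # top-10 mean varies across patients
  hp <- pmin(0.6, ap$high_prob * 2 * stats::rbeta(n, 2, 2))
  hi <- stats::runif(N) < hp[patient_idx]
  score <- ifelse(hi,
                  stats::rbeta(N, ap$high_shape1, ap$high_shape2),
                  stats::rbeta(N, ap$shape1, ap$shape2))
  if (config$response_quality_shift != 0) {
    nonpd <- !is.na(response) & response %in% c("R", "SD")
    score[nonpd[patient_idx]] <-
      pmin(1, score[nonpd[patient_idx]] + config$response_quality_shift)
  }
  allele <- ab_mat[cbind(patient_idx,
                         sample(ncol(ab_mat), N, replace = TRUE))]
  data.frame(
    patient_id = ids[patient_idx],
    peptide = random_peptides(N),
    hla_allele = allele,
    ap_score = score,
    abundance = stats::rlnorm(N, log(8), 1) * stats::rbeta(N, 5, 2),
    source_variant_ids = NA_character_,
    stringsAsFactors = FALSE)
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cfg <- x$truth$config
  cat("Synthetic sarcoma ICI cohort\n")
  cat(sprintf("  patients:   %d (%s)\n", nrow(x$patients),
              paste(sprintf("%s=%d", names(table(x$patients$subtype)),
                            table(x$patients$subtype)), collapse = ", ")))
  cat(sprintf("  variants:   %d small, %d fusions\n",
              nrow(x$variants), nrow(x$fusions)))
  cat(sprintf("  candidates: %d planted (AP Beta mixture)\n",
              nrow(x$candidates)))
  cat(sprintf("  events:     %d/%d observed; baseline median PFS %g d\n",
              sum(x$clinical$event), nrow(x$clinical),
              cfg$baseline_median_pfs))
  cat(sprintf("  seed:       %d\n", cfg$seed))
  invisible(x)
}
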
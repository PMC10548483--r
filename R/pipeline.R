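# End-to-end orchestration: simulate -> filter -> enumerate -> metrics ->
# tme -> survival -> stats, as one reproducible run with a manifest.

#' Pipeline run configuration
#'
#' A single flat configuration covering stage toggles and every stage
#' parameter.  Stages consume each other's outputs in dependency order;
#' disabling `tme` makes the survival stage use the externally supplied
#' cell-fraction table of the cohort instead of deconvolved fractions.
#'
#' @param out_dir Output directory for all stage artifacts.
#' @param input_dir Existing cohort directory (read with
#'   [read_cohort()]); `NULL` to simulate one (stage `simulate`).
#' @param cohort A [cohort_config()] used when simulating.
#' @param stages Named logical vector toggling `simulate`, `filter`,
#'   `neo`, `metrics`, `tme`, `survival`, `stats`.
#' @param min_tpm Expression-filter threshold (strict, TPM).
#' @param coding_mb Coding footprint for TMB, in megabases.
#' @param min_group Minimum bin size for optimal binning.
#' @param survival_covariates Covariate columns analysed univariately;
#'   the first two are crossed in the bivariate analysis.
#' @param use_planted_candidates Use the generator's planted candidate
#'   table for metrics/stats instead of the pipeline's own enumeration.
#' @param scorer Scorer for the enumeration stage (default
#'   [surrogate_scorer()]).
#' @param signature Signature matrix for the tme stage (default
#'   [synthetic_signature()]).
#' @param seed Seed recorded in the manifest and used for simulation.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir,
                            input_dir = NULL,
                            cohort = cohort_config(),
                            stages = c(simulate = TRUE, filter = TRUE,
                                       neo = TRUE, metrics = TRUE,
                                       tme = TRUE, survival = TRUE,
                                       stats = TRUE),
                            min_tpm = 0,
                            coding_mb = 30,
                            min_group = 10L,
                            survival_covariates = c("t_cell_fraction",
                                                    "neoantigen_quality"),
                            use_planted_candidates = FALSE,
                            scorer = surrogate_scorer(),
                            signature = synthetic_signature(),
                            seed = NULL) {
  all_stages <- c(simulate = TRUE, filter = TRUE, neo = TRUE,
                  metrics = TRUE, tme = TRUE, survival = TRUE,
                  stats = TRUE)
  all_stages[names(stages)] <- stages
  if (!is.null(seed)) cohort$seed <- as.integer(seed)
  structure(list(out_dir = out_dir, input_dir = input_dir,
                 cohort = cohort, stages = all_stages,
                 min_tpm = min_tpm, coding_mb = coding_mb,
                 min_group = as.integer(min_group),
                 survival_covariates = survival_covariates,
                 use_planted_candidates = use_planted_candidates,
                 scorer = scorer, signature = signature,
                 seed = seed %||% cohort$seed),
            class = "pipeline_config")
}

run_stage <- function(name, log, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE))
}

#' Run the full immunogenomic pipeline
#'
#' Executes the enabled stages in dependency order, writes every stage
#' output under `out_dir` and returns (and writes) a manifest recording
#' the package version, seed, parameters, per-stage record counts and
#' MD5 checksums of all written files.  A stage failure aborts the run
#' with the stage name; outputs of completed stages remain on disk.
#'
#' @param config A [pipeline_config()].
#' @return The manifest, invisibly (also written to
#'   `out_dir/manifest.json`).
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config"))
    stop_config("config must be created by pipeline_config()")
  st <- config$stages
  # pre-flight validation before any stage runs
  if (!st[["simulate"]]) {
    if (is.null(config$input_dir) || !dir.exists(config$input_dir))
      stop_config("input_dir does not exist: %s",
                  config$input_dir %||% "<missing>")
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log <- list()
  files <- character(0)

  cohort <- run_stage("simulate", log, {
    if (st[["simulate"]]) {
      co <- generate_cohort(config$cohort)
      cdir <- file.path(config$out_dir, "cohort")
      files <- c(files, write_cohort(co, cdir))
      co
    } else read_cohort(config$input_dir)
  })
  log$simulate <- c(patients = nrow(cohort$patients),
                    variants = nrow(cohort$variants),
                    fusions = nrow(cohort$fusions))

  filtered <- cohort$variants
  fusions_kept <- cohort$fusions
  if (st[["filter"]]) {
    run_stage("filter", log, {
      n0 <- nrow(filtered)
      filtered <- consensus_quality_filter(filtered)
      n1 <- nrow(filtered)
      tpm_by_patient <- split(cohort$tpm, cohort$tpm$patient_id)
      parts <- lapply(split(filtered, filtered$patient_id), function(v) {
        tp <- tpm_by_patient[[v$patient_id[1]]]
        expression_filter(v, tp %||%
                            data.frame(transcript_id = character(0),
                                       tpm = numeric(0)),
                          min_tpm = config$min_tpm)
      })
      filtered <- do.call(rbind, c(parts,
                                    list(filtered[integer(0), ])))
      rownames(filtered) <- NULL
      fusions_kept <- fusion_confidence_filter(cohort$fusions)
      log$filter <- c(input = n0, after_consensus = n1,
                       after_expression = nrow(filtered),
                       fusions_in = nrow(cohort$fusions),
                       fusions_kept = nrow(fusions_kept))
      f1 <- file.path(config$out_dir, "filtered_variants.tsv")
      f2 <- file.path(config$out_dir, "filtered_fusions.tsv")
      write_tsv(filtered, f1); write_tsv(fusions_kept, f2)
      files <- c(files, f1, f2)
    })
  }

  pipeline_candidates <- NULL
  if (st[["neo"]]) {
    run_stage("neo", log, {
      pipeline_candidates <- enumerate_cohort_candidates(
        filtered, fusions_kept, cohort$proteome, cohort$tpm,
        cohort$transcripts, cohort$hla, config$scorer)
      f <- file.path(config$out_dir, "pipeline_candidates.tsv")
      write_tsv(pipeline_candidates, f)
      files <- c(files, f)
      log$neo <- c(candidates = nrow(pipeline_candidates))
    })
  }
  candidates <- if (config$use_planted_candidates || is.null(pipeline_candidates))
    cohort$candidates else pipeline_candidates

  tme_fractions <- NULL
  if (st[["tme"]]) {
    run_stage("tme", log, {
      S <- config$signature
      rows <- lapply(cohort$clinical$patient_id, function(p) {
        m <- stats::setNames(cohort$bulk[[p]], cohort$bulk$gene)
        f <- deconvolve(m, S)
        data.frame(patient_id = p, t(unclass(f)), check.names = FALSE,
                   stringsAsFactors = FALSE)
      })
      tme_fractions <- do.call(rbind, rows)
      f <- file.path(config$out_dir, "tme_fractions.tsv")
      write_tsv(tme_fractions, f)
      files <- c(files, f)
      log$tme <- c(patients = nrow(tme_fractions))
    })
  }
  fractions <- tme_fractions %||% cohort$cell_fractions

  covariates <- NULL
  if (st[["metrics"]]) {
    run_stage("metrics", log, {
      covariates <- patient_covariates(
        filtered, candidates, fractions,
        coding_mb = config$coding_mb,
        patient_ids = cohort$clinical$patient_id)
      nf <- table(factor(fusions_kept$patient_id,
                         levels = cohort$clinical$patient_id))
      covariates$n_fusions <- as.integer(nf)
      f <- file.path(config$out_dir, "patient_covariates.tsv")
      write_tsv(covariates, f)
      files <- c(files, f)
      log$metrics <- c(patients = nrow(covariates))
    })
  }

  survival_results <- NULL
  if (st[["survival"]]) {
    run_stage("survival", log, {
      if (is.null(covariates))
        stop("survival stage requires the metrics stage")
      records <- data.frame(patient_id = cohort$clinical$patient_id,
                            time = cohort$clinical$pfs_days,
                            event = cohort$clinical$event,
                            stringsAsFactors = FALSE)
      uni <- list()
      for (cv in config$survival_covariates) {
        vals <- stats::setNames(covariates[[cv]], covariates$patient_id)
        uni[[cv]] <- tryCatch(
          optimal_binning(vals, records, min_group = config$min_group),
          error = function(e) e)
        if (!inherits(uni[[cv]], "error")) {
          f <- file.path(config$out_dir,
                         sprintf("binning_%s.tsv", cv))
          write_tsv(uni[[cv]]$landscape, f)
          fg <- file.path(config$out_dir,
                          sprintf("groups_%s.tsv", cv))
          write_tsv(data.frame(patient_id = names(uni[[cv]]$groups),
                               group = unname(uni[[cv]]$groups)), fg)
          files <- c(files, f, fg)
          for (g in c("low", "high")) {
            km <- km_estimate(records[uni[[cv]]$groups == g, ,
                                      drop = FALSE])
            fk <- file.path(config$out_dir,
                            sprintf("km_%s_%s.tsv", cv, g))
            write_tsv(summary(km), fk)
            files <- c(files, fk)
          }
        }
      }
      bi <- NULL
      cvs <- config$survival_covariates[1:2]
      if (length(cvs) == 2 && !inherits(uni[[cvs[1]]], "error") &&
          !inherits(uni[[cvs[2]]], "error")) {
        bi <- bivariate_stratify(
          stats::setNames(covariates[[cvs[1]]], covariates$patient_id),
          stats::setNames(covariates[[cvs[2]]], covariates$patient_id),
          uni[[cvs[1]]]$threshold, uni[[cvs[2]]]$threshold, records)
        f <- file.path(config$out_dir, "bivariate_groups.tsv")
        write_tsv(data.frame(patient_id = names(bi$groups),
                             group = unname(bi$groups)), f)
        files <- c(files, f)
        for (g in names(bi$curves)) {
          fk <- file.path(config$out_dir,
                          sprintf("km_bivariate_%s.tsv", g))
          write_tsv(summary(bi$curves[[g]]), fk)
          files <- c(files, fk)
        }
      }
      survival_results <- list(univariate = uni, bivariate = bi)
      log$survival <- c(covariates_analysed = length(uni))
    })
  }

  stats_results <- NULL
  if (st[["stats"]]) {
    run_stage("stats", log, {
      resp <- withCallingHandlers(
        compare_response_groups(candidates, cohort$clinical),
        warning = function(w) invokeRestart("muffleWarning"))
      pairs <- list(c("tmb", "nal"), c("n_fusions", "nal"))
      pairs <- Filter(function(pr)
        !is.null(covariates) && all(pr %in% names(covariates)), pairs)
      corr <- if (length(pairs) > 0 && nrow(covariates) >= 3)
        correlate_covariates(covariates, pairs) else
          data.frame()
      f1 <- file.path(config$out_dir, "response_comparisons.tsv")
      f2 <- file.path(config$out_dir, "correlations.tsv")
      write_tsv(resp, f1); write_tsv(corr, f2)
      files <- c(files, f1, f2)
      stats_results <- list(response = resp, correlations = corr)
      log$stats <- c(comparisons = nrow(resp),
                      correlations = nrow(corr))
    })
  }

  manifest <- list(
    package = "sarcneo",
    version = as.character(utils::packageVersion("sarcneo")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = config$seed,
    parameters = list(min_tpm = config$min_tpm,
                      coding_mb = config$coding_mb,
                      min_group = config$min_group,
                      survival_covariates = config$survival_covariates,
                      use_planted_candidates = config$use_planted_candidates,
                      censoring_rate = config$cohort$censoring_rate,
                      hazard_coefficients =
                        as.list(config$cohort$hazard_coefficients)),
    stages = as.list(st),
    counts = log,
    checksums = as.list(tools::md5sum(sort(unique(files))))
  )
  jsonlite::write_json(manifest, file.path(config$out_dir,
                                           "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(manifest = manifest, cohort = cohort,
                 covariates = covariates,
                 candidates = candidates,
                 survival = survival_results, stats = stats_results))
}

#' Enumerate and score candidates for a whole cohort
#'
#' Runs the phasing-aware enumeration over every (patient, protein) with
#' retained nonsynonymous variants plus every retained fusion, removes
#' peptides present in the wild-type proteome, scores the survivors
#' against each patient's HLA-A/-B alleles and attaches
#' expression-adjusted abundances (fusion candidates get unit pseudo
#' abundance, having no transcript model).
#'
#' @param variants Filtered variant table (whole cohort).
#' @param fusions Filtered fusion table.
#' @param proteome Named wild-type protein sequences.
#' @param tpm Long TPM table (`patient_id`, `transcript_id`, `tpm`).
#' @param transcripts Transcript-to-protein map.
#' @param hla Long HLA table (`patient_id`, `allele`).
#' @param scorer A `neo_scorer`.
#' @return Candidate table: `patient_id`, `peptide`, `hla_allele`,
#'   `ap_score`, `abundance`, `source_variant_ids`.
#' @export
enumerate_cohort_candidates <- function(variants, fusions, proteome, tpm,
                                        transcripts, hla,
                                        scorer = surrogate_scorer()) {
  kmers <- build_reference_kmers(proteome)
  coding <- nonsynonymous_subset(variants)
  patients <- unique(c(coding$patient_id, fusions$patient_id))
  tx_by_prot <- split(transcripts$transcript_id, transcripts$protein_id)
  out <- lapply(patients, function(p) {
    pv <- coding[coding$patient_id == p, , drop = FALSE]
    pf <- fusions[fusions$patient_id == p, , drop = FALSE]
    ptpm <- tpm[tpm$patient_id == p, , drop = FALSE]
    tpm_map <- stats::setNames(ptpm$tpm, ptpm$transcript_id)
    peps <- list()
    for (prot in unique(pv$protein_id)) {
      wt <- proteome[[prot]]
      pvp <- pv[pv$protein_id == prot, , drop = FALSE]
      muts <- apply_phasing(wt, pvp)
      vids <- attr(muts, "variant_ids")
      for (i in seq_along(muts)) {
        pw <- enumerate_windows(muts[[i]], wt, protein_id = prot,
                                source_variant_ids =
                                  paste(vids[[i]], collapse = ","))
        if (nrow(pw) > 0) {
          v1 <- pvp[match(vids[[i]][1], pvp$id), ]
          pw$abundance <- peptide_abundance(
            tpm_map[tx_by_prot[[prot]]], v1$vaf_rna)
          peps[[length(peps) + 1L]] <- pw
        }
      }
    }
    for (j in seq_len(nrow(pf))) {
      pw <- fusion_junction_peptides(pf[j, ])
      if (nrow(pw) > 0) {
        pw$abundance <- 1
        peps[[length(peps) + 1L]] <- pw
      }
    }
    if (length(peps) == 0) return(NULL)
    peps <- do.call(rbind, peps)
    peps <- uniqueness_filter(peps, kmers)
    if (nrow(peps) == 0) return(NULL)
    alleles <- hla$allele[hla$patient_id == p]
    cand <- score_candidates(peps, alleles, scorer)
    if (nrow(cand) == 0) return(NULL)
    data.frame(patient_id = p, peptide = cand$sequence,
               hla_allele = cand$hla_allele, ap_score = cand$ap_score,
               abundance = cand$abundance,
               source_variant_ids = cand$source_variant_ids,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(patient_id = character(0), peptide = character(0),
                      hla_allele = character(0), ap_score = numeric(0),
                      abundance = numeric(0),
                      source_variant_ids = character(0),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
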
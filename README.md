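# sarcneo

Immunogenomic analysis of immune-checkpoint-inhibitor (ICI) treated
sarcoma cohorts: neoantigen candidate enumeration, tumor mutational
burden, immune cell-fraction deconvolution, and a supervised
optimal-binning Kaplan–Meier survival framework — implemented as a
tested, reusable R package with a synthetic cohort generator, so every
stage can be exercised and validated without access-restricted
patient-level trial data.

## The problem

Sarcomas respond modestly and heterogeneously to anti-PD-1 therapy.
Characterizing which immunogenomic features — neoantigen load and
quality, tumor mutational burden, the immune composition of the tumor
microenvironment (TME) — track with progression-free survival (PFS)
requires a chain of bespoke computations that published studies rarely
ship as reusable code. `sarcneo` implements that chain:

1. **Variant screening** — consensus filter (called by ≥ 2 of 6
   ensemble callers), read-quality filter (depth ≥ 10 in tumor and
   normal, > 3 alt reads in tumor), RNA-expression filter, and a
   fusion-confidence filter (low-confidence fusions discarded).
2. **Neoantigen enumeration** — phasing-aware reconstruction of mutant
   proteins (variants sharing a phase set are applied to one
   haplotype), enumeration of every 9/10-mer window that overlaps an
   altered residue and differs from wild type (SNV, indel, frameshift
   tails and fusion-junction peptides), removal of peptides present in
   the normal proteome, scoring per HLA-A/-B allele through a pluggable
   antigen-presentation (AP) scorer contract, and expression-adjusted
   abundance `sum(isoform TPM) x RNA VAF`.
3. **Per-patient metrics** —
   - TMB = nonsynonymous SNVs/indels with VAF ≥ 5%, per megabase of
     coding sequence;
   - NAL (neoantigen load) = candidates with AP score strictly > 0.5;
   - neoantigen quality = mean AP score of the top ten candidates.
4. **TME deconvolution** — cell fractions `f` from bulk expression `m`
   and a signature matrix `S` by constrained least squares:
   `min ||S f − m||²` subject to `f ≥ 0`, `Σf ≤ 1`, with the remainder
   reported as an uncharacterized "Other" fraction (Lawson–Hanson
   active-set solver, in-package).
5. **Survival analysis from first principles** — Kaplan–Meier
   product-limit estimation `S(t) = Π (1 − d_i/n_i)`, the k-sample
   log-rank test, supervised optimal binning (every observed covariate
   value is tried as a threshold; only splits with ≥ 10 patients per
   bin are admissible; the split minimizing the log-rank p is chosen),
   and bivariate four-group (low/low … high/high) stratification.
6. **Cohort statistics** — Welch's unequal-variance t test and Spearman
   rank correlation against their closed-form definitions, applied to
   response-group comparisons of pooled top-10 AP scores and
   cross-covariate correlations.

The **synthetic cohort generator** emulates the study conditions end to
end: 31 patients across seven sarcoma subtypes (13 soft-tissue / 18
bone), heterogeneous SNV/indel/fusion counts, Beta-mixture AP scores,
Dirichlet cell fractions, and exponential PFS whose log-hazard is
linear in the z-scored CD8+ T-cell fraction, neoantigen quality and
their product — a planted protective T-cell × quality interaction that
the survival framework must recover.

## Worked example

```r
library(sarcneo)

co <- generate_cohort(cohort_config(seed = 1))
co
#> Synthetic sarcoma ICI cohort
#>   patients:   31 (CS=3, DDLPS=2, ES=6, LMS=4, OS=9, SS=4, UPS=3)
#>   variants:   1016 small, 129 fusions
#>   candidates: 2273 planted (AP Beta mixture)
#>   events:     23/31 observed; baseline median PFS 100 d
#>   seed:       1

p   <- co$patients
rec <- data.frame(patient_id = p$patient_id,
                  time = co$clinical$pfs_days, event = co$clinical$event)

## univariate: optimal binning of the CD8+ T-cell fraction against PFS
ob <- optimal_binning(setNames(p$t_cell_fraction, p$patient_id), rec,
                      min_group = 10)
ob
#> Supervised optimal binning: threshold = 0.0709945 (low n = 13, high n = 18)
#>   minimal log-rank p = 7.387e-05 over 31 thresholds (12 admissible, min group 10)

## bivariate: T-cell fraction x neoantigen quality, four groups
bi <- bivariate_stratify(setNames(p$t_cell_fraction, p$patient_id),
                         setNames(p$neoantigen_quality, p$patient_id),
                         ob$threshold, median(p$neoantigen_quality), rec)
bi
#> Bivariate four-group survival stratification
#>   thresholds: cov1 <= 0.0709945, cov2 <= 0.712883
#>   HH: n = 11, median PFS = 541.235
#>   HL: n = 7, median PFS = 105.001
#>   LH: n = 4, median PFS = 23.5994
#>   LL: n = 9, median PFS = 34.9679
#>   log-rank chi-square = 19.8879 on 3 df, p = 0.0001791
```

The four-group medians show the planted interaction: patients high in
both T-cell infiltration and neoantigen quality (HH) live longest,
high T cells with low-quality neoantigens (HL) are intermediate, and a
T-cell-poor TME (LH/LL) does poorly regardless of neoantigen quality.
`plot(ob)` draws the p-value landscape over thresholds (admissible
splits filled, chosen split highlighted); `plot(bi)` draws the four KM
curves.

The whole chain — simulate, filter, enumerate, metrics, deconvolve,
survival, statistics — runs as one reproducible, manifest-tracked
pipeline:

```r
res <- run_pipeline(pipeline_config(out_dir = "run1", seed = 1))
res$manifest$counts
```

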
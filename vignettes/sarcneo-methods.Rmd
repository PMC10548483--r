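---
title: "Models and methods behind sarcneo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind sarcneo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sarcneo)
```

`sarcneo` packages the computational chain of an immunogenomic survival
analysis for ICI-treated sarcoma cohorts. This vignette documents the
models, the tunable parameters and their defaults, the numerical
conventions, and what the synthetic cohort generator does and does not
emulate — i.e. what a green test suite does and does not certify about
real patient data.

## Variant screening

Somatic events arrive pre-called and pre-annotated (caller support
counts, read depths, DNA/RNA variant allele frequencies, consequence
classes, phase-set tags); the package models the *screening policy*,
not the callers:

* consensus: kept iff called by at least 2 of the 6 ensemble callers
  (inclusive);
* quality: read depth at least 10 in tumor **and** normal (inclusive),
  strictly more than 3 reads supporting the mutation in the tumor;
* expression: the summed TPM of the transcripts harboring the variant
  must be strictly positive (threshold configurable via `min_tpm`; the
  notion of "expressed" has no published cutoff, so the default is the
  weakest one). Whether expression should be assessed at gene or
  transcript level is unspecified in the source analyses; transcript
  sum is used;
* consequence: nonsynonymous = {missense, frameshift, in-frame indel};
* fusions: low-confidence events are discarded, medium and high kept.

All filters are pure subsets: idempotent, order preserving, never
mutating a record — properties the suite asserts directly.

## Neoantigen enumeration

Mutant proteins are reconstructed with phasing: variants sharing a
`phase_set` tag co-occur on one haplotype and are applied jointly;
unphased variants each yield their own mutant sequence. Edits are
applied C-terminal-first so residue coordinates stay valid; overlapping
edits within one phase set are a validation error. Frameshifts truncate
at the preceding residue and append the supplied novel tail (the
translation to the next stop). Stop-loss and start-loss events are
rejected explicitly rather than mis-modeled.

Candidate peptides are every window of length 9 or 10 that (a) overlaps
at least one altered residue and (b) differs from the position-aligned
wild-type window. "Altered" is defined by positional mismatch between
mutant and wild type, with positions beyond the shorter sequence
counting as altered; this makes frameshift tails produce every window
from the divergence point to the stop. For indels, positional
comparison marks all downstream residues altered; the uniqueness filter
(below) rather than positional alignment is the authoritative
difference test there, since no alignment convention is given for
indel-derived windows. Fusion-junction peptides must contain at least
one residue from each side of an in-frame junction, or at least one
novel residue for out-of-frame fusions; short context yields fewer
windows, never an error.

Mutant peptides found anywhere in the wild-type reference k-mer set are
removed: a candidate must be absent from normal tissue. Duplicate
peptides from different windows of the same protein collapse to one
candidate per (sequence, protein) — identical ligands are one candidate.

Scoring is a contract, not a model: `score(peptides, alleles)` must
return values in [0, 1] deterministically when claimed deterministic.
The proprietary presentation models used in the source study are out of
scope; the default `surrogate_scorer()` maps a string hash of each
(peptide, allele) pair through the Beta(1.5, 4) quantile function,
giving reproducible right-skewed scores so pipelines are exercisable
end to end. Only HLA-A and HLA-B alleles are scored by default
(class I presentation models are not validated for HLA-C); HLA-C can be
opted in. Peptide abundance is the summed TPM of the coding isoforms
scaled by the RNA-level VAF.

## Per-patient metrics

* **TMB**: nonsynonymous SNVs and indels with DNA VAF at least 5%
  (inclusive — "at least" reads as ≥), divided by the coding footprint
  in megabases. No default footprint is assumed: `coding_mb` is a
  required argument (the pipeline default of 30 Mb is an explicit
  configuration value, not a hidden constant).
* **NAL**: candidates with AP score strictly above 0.5. Whether NAL
  counts unique peptides or (peptide × allele) pairs is not specified
  in the source analyses; pairs are the default and
  `unique_peptides = TRUE` switches. Per-allele NAL therefore
  partitions the pairwise NAL exactly.
* **Quality**: mean AP of the top ten candidates. With fewer than ten,
  the mean over what is available (0 for none); `strict_top10 = TRUE`
  returns `NA` instead. Ties at the tenth rank resolve by lexicographic
  peptide order — deterministic, and irrelevant to the mean when tied
  scores are equal.

## TME deconvolution

Bulk expression is modeled as a nonnegative mixture of cell-type
signature profiles: minimize ‖S f − m‖² subject to f ≥ 0 and Σf ≤ 1,
the unexplained remainder reported as "Other". The solver is a
Lawson–Hanson active-set NNLS written in-package (tolerance 1e-10):
plain NNLS first; only when Σf exceeds 1 is the sum constraint active,
and the problem is re-solved with a weighted sum-row (weight 10³ × the
problem magnitude — large enough to enforce the constraint, small
enough that the data rows keep numerical influence) followed by a
simplex projection. Noiseless mixtures of signature columns are
therefore recovered exactly, which the suite asserts to 1e-6 over
random trials, alongside agreement with an independent NNLS
implementation.

Mixture and signature are solved in the units supplied rather than
being re-normalized internally: rescaling signature columns with
unequal totals would silently change the meaning of the recovered
fractions, and the mRNA-content scaling that absolute-fraction methods
apply is not modeled here. A `normalize` flag performs a common-total
rescale when inputs genuinely arrive on different scales. The shipped
50-gene × 10-cell-type signature (`inst/extdata/signature_synthetic.tsv`)
is synthetic — marker blocks over a low baseline, generated by
`synthetic_signature()` — and is not derived from any published
signature matrix.

The CD8+ T-cell fraction covariate can come from deconvolution or pass
through an external estimate (e.g. from V(D)J-recombination copy-number
methods), mirroring how orthogonal T-cell estimates are used in
practice.

## Survival analysis

Everything is implemented from first principles and cross-checked
against an independent reference implementation in the tests.

* **Kaplan–Meier**: S(t) = Π_{t_i ≤ t} (1 − d_i/n_i) over distinct
  event times. At tied times, events precede censorings (the censored
  subject counts as at risk) — the standard convention, stated here
  because the source analyses leave it implicit. The median is the
  smallest t with S(t) ≤ 0.5 and is undefined (NA, serialized as an
  empty field) when the curve never reaches 0.5.
* **Log-rank**: the k-sample observed-minus-expected chi-square with
  the multivariate hypergeometric covariance, df = k − 1. What the
  source calls the "multivariate log-rank" is interpreted as this
  k-sample test (a stratified test is the other reading; the k-sample
  test is what four-group KM figures display). A singular covariance
  (e.g. duplicated groups) falls back to a pseudoinverse.
* **Supervised optimal binning**: only observed covariate values can
  change group composition, so exactly those are tried. The split is
  low = {value ≤ t} (the largest observed value is then never
  admissible, since its high group is empty); both bins must hold at
  least `min_group = 10` patients; the admissible threshold with
  minimal log-rank p wins, ties resolving to the smallest threshold so
  a unique split is always reported. The full landscape (threshold, p,
  bin sizes, admissibility) is returned and plotted. No
  multiple-testing correction is applied by default, matching the
  exploratory use of this procedure; the landscape is returned so a
  Benjamini–Hochberg adjustment can be applied downstream if p-values
  are to be interpreted confirmatorily.
* **Bivariate stratification**: two covariates, typically at their
  univariate optimal thresholds, cross into LL/LH/HL/HH; the k-sample
  log-rank runs over the non-empty groups, with per-group KM medians
  reported. Fewer than two non-empty groups is an error.
* Display capping of PFS (e.g. truncating a plot at 500 days) is a
  plotting concern only; no analysis function takes a cap, and the
  suite asserts that plotting leaves the computed statistics unchanged.

## Cohort statistics

Welch's t statistic with Welch–Satterthwaite degrees of freedom and a
two-sided p; Spearman's rho as the Pearson correlation of midranks with
the t approximation for p. Both are asserted against their closed forms
and the standard implementations. Response-group comparisons pool each
patient's top-10 AP scores as separate observations (the distributions
the comparisons visualize are pooled score distributions);
`per_patient = TRUE` pools one mean per patient instead. Patients with
fewer than ten candidates contribute what they have, consistent with
the quality metric. Comparisons run for R vs PD, R vs SD, SD vs PD and
PD vs pooled non-PD; empty or singleton groups skip their comparisons
with a warning, and two constant groups report p = 1 (equal means) or
p = 0 (complete separation) rather than a 0/0 statistic.

## The synthetic cohort generator

The generator is first-class, tested code that plants known structure
for the rest of the package to recover.

* **Composition**: 31 patients, 13 soft-tissue (4 SS, 4 LMS, 2 DDLPS,
  3 UPS) and 18 bone (6 ES, 9 OS, 3 CS), assigned by largest-remainder
  apportionment of the configured weights so requested compositions are
  met exactly; response classes 3 R / 9 SD / 18 PD / 1 unknown.
* **Mutations**: per-subtype uniform count ranges (osteosarcoma and UPS
  highest small-variant loads, chondrosarcoma lowest; fusion-driven
  subtypes and DDLPS elevated fusion counts), with caller support,
  depths, VAFs, consequence classes and occasional shared phase sets
  drawn per variant. Planted candidate counts are fusion-dominant
  (roughly one candidate per nonsynonymous variant versus fifteen per
  retained fusion): a junction yields many distinct windows while most
  substitution-derived peptides fall to the expression and uniqueness
  filters — which also decorrelates NAL from TMB, as observed in
  fusion-driven sarcomas.
* **AP scores**: a Beta mixture — bulk Beta(1.5, 4) plus a minority
  high-quality component Beta(9, 2) whose per-patient mixing weight
  varies, so top-10 means differ across patients.
  `response_quality_shift` adds a constant to the scores of non-PD
  patients to plant a response-group effect for power checks.
* **Cell fractions**: Dirichlet over ten immune cell types plus a
  dominant "Other" (tumor/stromal) component; bulk expression over the
  signature panel is `S f` with multiplicative lognormal noise
  (`bulk_noise_sd`, default 5%), so the deconvolution stage has an
  honest, noisy input with known truth.
* **Survival**: exponential PFS with baseline median 100 days and
  log-hazard `b_t z_t + b_q z_q + b_int z_t z_q` over within-cohort
  z-scores of the CD8+ fraction and the neoantigen quality. Z-scoring
  makes the coefficients scale-free. The defaults
  (b_t, b_q, b_int) = (−1.2, −0.8, −1.0) were fixed once by quadrant
  algebra: writing the typical quadrant z-magnitude as ±0.8, the
  expected log-hazard ordering is HH ≪ HL < LH ≈ LL exactly when
  b_q ≈ 0.8·b_int and b_t < b_q, so the planted truth is the
  qualitative pattern the bivariate analysis should find — high-T-cell
  patients with high-quality neoantigens longest, high T cells alone
  intermediate, and a T-cell-poor TME poor regardless of quality. No
  effect sizes exist to estimate these from; they are free parameters
  of the emulation, not estimates of any study. The no-effect control
  sets all three coefficients to zero (leaving protective main effects
  in place would keep the HH quadrant on top by construction, which is
  why "no interaction" alone is not the null).
* **Censoring**: independent uniform administrative censoring on
  [0, τ], with τ solved numerically so that the expected censored
  fraction under the baseline hazard equals `censoring_rate` (default
  0.15). With rate 0 every event is observed, which the calibration
  test exploits: with all coefficients zero, 10,000 simulated PFS times
  match the baseline exponential within Kolmogorov–Smirnov distance
  0.02.

**What the generator does not emulate** — and therefore what passing
tests do not certify about real data: mutational signatures and
subclonal structure; linkage to real sarcoma genomes or a real
proteome (proteins are random sequences); a trained presentation model
(the surrogate scorer's scores are calibrated in distribution, not in
biology); batch effects, purity variation or mRNA-content differences
in bulk expression; non-exponential hazards or informative censoring.
The suite certifies the *computational* contracts — filters, window
combinatorics, estimators, tests, solvers — and the recoverability of
planted statistical structure at realistic sizes.

## Problem sizes and numerical choices

Property tests run at the sizes stated in their contracts: exhaustive
binning equivalence on 100 random datasets of up to 60 patients;
window-enumeration brute force on 500 random proteins and junctions;
5,000 null simulations each for the Welch and log-rank type-I rates
(accepted band 3.5–6.5% at α = 0.05); 100 noiseless deconvolution
recoveries at 1e-6; 100 planted and 100 null cohorts of 400 patients
for interaction recovery (HH must lead in at least 95 of 100 planted
seeds, and no quadrant may lead in more than half the null seeds).
Numerical agreement with reference implementations is asserted at
1e-8; the NNLS active-set tolerance is 1e-10; survival ties and
threshold ties follow the conventions above so every reported result
is deterministic given a seed.
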
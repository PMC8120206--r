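---
title: "Methods: neoantigen landscape analysis with neoscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: neoantigen landscape analysis with neoscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neoscape)
```

# Scope and model

neoscape analyses the *downstream* neoantigen landscape of tumor cohorts
with paired primary and metastatic samples. It starts where variant
callers, copy-number/purity estimators (CCF intervals), HLA typers and
MHC-binding predictors stop: its inputs are per-sample somatic variant
tables with read counts and CCF confidence intervals, pVACseq-style
neoepitope tables with per-predictor IC50 values and pMHC half-lives,
expression matrices on the log2(TPM+1) scale, copy-number segments,
immune-cell fraction tables and TCR clonotype tables.

The analysis stages, each exposed as plain functions and orchestrated by
`runPipeline()`:

1. **Variant QC** (`qcFilterVariants`): a somatic SNV is retained when it
   has >= 5 alt-supporting tumor reads and the two-sided Fisher exact test
   on the tumor-vs-normal allele composition is significant at alpha
   (default 0.05). "Presence" of a variant in a sample always means it
   passed this filter there; there is no cross-sample rescue or
   force-calling, so a variant "disappearing" in a metastasis is an
   absence-by-filter convention.
2. **Clonality** (`classifyClonality`): a mutation is clonal when the 95%
   CCF confidence interval contains 1, with a *closed*-interval convention
   (an interval touching 1 at an endpoint counts as clonal); the wording
   of the rule does not exclude boundary contact, and the closed choice is
   the one that makes the boundary case [1, 1] clonal.
3. **Neoantigen calling** (`callNeoantigens`): an epitope's binding
   affinity is the minimum over its per-predictor IC50s; it is called a
   neoantigen when that best affinity is < 500 nM and the source
   transcript's FPKM is > 1. Affinity classes are STRONG (< 50 nM),
   MEDIUM ([50, 150) nM) and WEAK otherwise — the defining inequalities
   are strict, so boundary values fall to the weaker class. Stability is
   HIGH when the predicted half-life exceeds 2 h. Neoantigen identity is
   the pair (peptide, HLA allele): the same peptide presented on a
   different allele is a different presentation event.
4. **Tracking** (`trackVariants`, `reductionRatio`): variants keyed by
   (chrom, pos, ref, alt) are classified between a primary and a
   metastasis as REDUCED (present only in the primary, or clonal there
   and subclonal in the metastasis), INCREASED (the mirror image), or
   PERSISTENT. The reduction ratio is
   (n_increased - n_reduced) / primary load; a pair with a negative ratio
   is flagged as net neoantigen reduction. The flag threshold is 0 (net
   loss), the natural reading absent a stated cutoff.
5. **Depletion odds ratios** (`depletionCall`): per sample, 2x2 tables of
   neoantigenic vs non-neoantigenic nonsynonymous mutations against
   (a) lying in a copy-loss region and (b) being expressed. Copy-loss
   depletion is called when OR > 1, transcriptional depletion when
   OR < 1. Calls are direction-only by default; a significance gate
   (Fisher p < alpha) is a config switch, since per-site depletion
   percentages are more naturally direction-based. Important subtlety:
   *neoantigenic* here is binding-level (the mutation yields at least one
   predicted binder < 500 nM) and deliberately ignores the FPKM gate —
   if fully-gated neoantigens were used, every neoantigenic mutation
   would be expressed by construction and the transcriptional table
   would be degenerate.
6. **Heterogeneity and instability**: `mathScore` is
   100 x MAD / median of the VAFs with the 1.4826-scaled MAD;
   `wgii` is the mean over the 22 autosomes of the length-weighted
   fraction of each autosome whose total copy number differs from
   round(ploidy), with CIN+ called above 0.2; `branchProportion` is
   1 - |intersection| / |union| over multiregion feature sets (the union
   denominator makes it the fraction of all observed features that are
   not ubiquitous).
7. **Immunogram** (`immunogram`): eight axes of the cancer-immunity
   cycle. Seven are scored from expression by a single-sample enrichment
   engine, one (tumor antigenicity) from the per-sample neoantigen load,
   log10(x+1)-transformed because loads are heavy-tailed (the raw scale
   is a switch). Scores are z-scored across the cohort (population-sd
   convention, switchable) and mapped to the immunogram score
   3 + 1.5 z for stimulatory axes and 3 - 1.5 z for inhibitory axes
   (scored as absence of the inhibitory feature), clamped to the radar
   range [1, 5] for display with the raw value retained.
8. **TMIT and cell ratios**: quadrants on CD8A and PD-L1 split at the
   per-marker cohort median (ties low); Treg/CD8 and M2/M1 ratios with a
   1e-3 pseudocount because deconvolved fractions contain exact zeros.
9. **Subtype model** (`extractSignature`, `trainSubtypeModel`,
   `predictSubtype`): per-class signatures are genes that beat *both*
   other classes by Wilcoxon rank-sum test at BH-FDR < 0.05 with the
   median higher in the class. The rank-sum (not signed-rank) form is
   used because the groups are independent samples, not pairs. Training
   uses a stratified 2/3 split, tunes the random forest's mtry over 100
   bootstrap resamples (each candidate evaluated on the out-of-bootstrap
   samples), and records held-out accuracy. Patient-level prediction
   averages class probabilities over a patient's regions and assigns the
   argmax only when the maximum mean probability reaches 0.4, otherwise
   UNCLASSIFIED; argmax ties break by class order with a warning.

## The enrichment engine

The single-sample engine (`ssgseaScore`) is a deterministic
rank-weighted running sum: per sample, genes get rank-normalized weights
u = rank/N (average ranks for ties), the list is walked in decreasing
expression order (gene name breaks expression ties, making the walk
fully deterministic), set genes advance an in-sum proportionally to
u^0.25 and non-set genes advance the out-sum uniformly; the score is the
integrated difference, then normalized by the cohort score range. The
exponent 0.25 keeps the weighting mild. Any deterministic monotone
single-sample engine would serve here because every downstream use goes
through cohort z-scores, which are invariant to the engine's location
and scale; the engine sits behind one function and can be swapped. The
shipped axis gene sets (`immunogramCatalog()`) are *documented
placeholders* — plausible marker genes per axis, not a reproduction of
any published signature — and are meant to be replaced via the `catalog`
argument (e.g. from a GMT file).

# The synthetic cohort generator

`simulateCohort()` produces every input table with the statistical
structure the analyses assume, plus the planted truth. Its defaults are
fixed study conditions, not tuning knobs:

* **Cohort structure**: 26 patients; every patient a primary tumor,
  three patients a second primary region, 16 lymph-node and 12
  distant-metastasis samples (57 samples in all), mirroring a
  paired-design metastatic cohort.
* **Mutations**: ~150 per patient pool (Poisson); class mix 60% missense,
  5% frameshift indel, 5% other nonsilent, 30% silent; 57% of nonsilent
  mutations yield at least one predicted binder. Positions are drawn on
  22 autosomes with GRCh38 lengths rounded to the megabase.
* **Reads and CCF**: depth fixed at 100x; VAF follows from CCF, purity
  (uniform 0.4-0.9) and local copy number under a one-mutated-allele
  model (copy number 1 in copy-loss regions, else 2); that is just
  enough realism for the QC filter and MATH. The CCF interval is the
  point estimate +/- 1.96 binomial standard errors of the implied
  allele fraction — a stand-in chosen so the "CI contains 1" rule
  exercises both outcomes, not a reproduction of any caller's interval.
* **Planted depletion**: neoantigenic mutations sit in copy-loss regions
  with odds multiplied by `thetaCnv` (default 2.0) and are expressed
  with odds multiplied by `thetaTxn` (default 0.5); the defaults plant
  depletion in the direction observed in metastatic disease. Setting
  both to 1 gives the null.
* **Epitopes and immunogenicity**: each neoantigenic mutation draws an
  affinity *scale* (lognormal, meanlog log(250), sdlog 1.0) and its
  epitopes (~8, doubled for frameshifts) scatter around it (sdlog
  0.35). The within-mutation correlation matters: with independent
  epitope affinities, essentially every mutation with several epitopes
  would have a best affinity < 150 nM and mutation-level immunogenicity
  would be a near-constant, leaving nothing for the reduction bias to
  act on. Non-neoantigenic nonsilent mutations occasionally emit decoy
  epitopes at >= 500 nM to exercise the filtering gates.
* **Metastatic drift**: a metastasis inherits the patient pool minus
  drops plus private gains (~15% of the pool). The baseline drop
  probability is 0.2; for immunogenic neoantigenic mutations (best
  affinity < 150 nM) the drop *odds* are multiplied by
  exp(`betaReduction`) (default 1.5), planting the
  immunogenicity-biased loss the bias odds ratio is designed to detect.
  10% of retained variants flip clonality, modelling CCF drift.
* **Expression**: three patient-level subtypes (default mix 0.2/0.3/0.5)
  shift their 50 signature genes by `subtypeEffect` residual sd
  (default 1.5) over a N(5, 1) background that also contains the
  immunogram catalog genes and the CD8A/CD274 markers.
* **Cell fractions** are Dirichlet; **TCR clone sizes** follow a power
  law (exponent 2.5) drawn from a patient-level clonotype pool so that
  multiregion samples share clones.

Peptides are random 9/10-mers per patient, so neoantigen sharing occurs
within patients (shared variants) and cross-patient sharing is
structurally absent — matching the observed pattern that no neoantigen
recurs across patients.

What the generator does **not** emulate: mutational signatures, germline
variation, linked segments between the variant-level copy-loss flags and
the segment table (variant flags follow the odds model; segments
independently drive wGII), predictor-specific biases, or any real HLA
binding landscape. Passing recovery tests therefore demonstrates that
the estimators recover what was planted under the stated noise model —
not that the biology of any real cohort is reproduced.

# Recovery experiments and problem sizes

The test suite and `scripts/acceptance.R` rerun these experiments from
scratch; sizes were chosen at design time from Monte-Carlo calibration
of the estimators' sampling variance:

* **Odds-ratio oracle**: 500 random 2x2 tables (cells 0-40) against the
  direct cross-product formula, and full hypergeometric enumeration of
  the Fisher p for tables with total <= 60.
* **Transcriptional depletion**: 50 single-site samples with ~200
  nonsynonymous mutations each at thetaTxn = 0.5; the median estimated
  OR is expected in [0.40, 0.62] and >= 80% of samples flag depleted
  under the direction rule. A 100-sample null cohort with the p < 0.05
  gate bounds the false-call rate at 7%.
* **Reduction bias**: 40 primary/lymph pairs with 1500-mutation pools at
  betaReduction = 3. Epitopes cluster within mutations, so the
  effective sample size of the bias OR is mutations, not epitopes; the
  pool size keeps the qualifying groups (>= 30 called neoantigens each)
  large enough that the planted bias yields OR > 1 in >= 90% of pairs.
* **Subtype recovery**: 120 single-region patients, balanced classes
  (so the permuted-label null accuracy target of 1/3 is meaningful;
  the generator's default mix is 0.2/0.3/0.5), 50 signature genes per
  class at 1.5 sd, 100 tuning resamples: held-out accuracy >= 0.9 and a
  permuted null within 0.33 +/- 0.1. The permuted-null forest reuses
  the feature set extracted from the true labels, because honest
  FDR-controlled extraction on permuted labels returns a (near-)empty
  signature — which is itself verified as a type-I control.
* **End to end**: the default 26-patient cohort through `runPipeline()`
  twice, checking schema validity and byte-identical outputs.

# Numerical conventions and degenerate inputs

* Zero cells in a 2x2 table get the Haldane-Anscombe +0.5 on every cell
  before the OR and its Woolf logit CI (flagged in the result); the
  Fisher p always uses the uncorrected counts.
* A sample whose neoantigenic or non-neoantigenic row is empty yields an
  UNDETERMINED depletion call, excluded from cohort denominators and
  reported separately; a site with no determined samples reports NA, not
  0.
* `cohortZ` on a zero-dispersion vector returns all zeros with a
  warning. MATH with median VAF 0, wGII with an uncovered autosome, and
  reduction ratio with primary load 0 are errors.
* Yields divide by *all* mutations of the class by default; counting
  only epitope-generating mutations is exposed as
  `generatingDenominator = "generating"` since the per-mutation reading
  is ambiguous.
* The clonal-TCR clone-frequency threshold (default 1% of chain reads)
  is a configurable convention; no established definition exists.
* Genomic coordinates are 1-based inclusive in all user-facing tables;
  segment ends are exclusive. VCF AD fields are parsed in the standard
  ref,alt order.

# A worked example

```{r example, eval = FALSE}
co <- simulateCohort(cohortConfig(seed = 7))
res <- runPipeline(co, "results_dir")
head(res$depletion_summary)
```

See the README for the printed output of this example and for how to
reproduce the acceptance quantities.

# Known limitations

* The generator's CCF interval model is a stand-in; real caller
  intervals are asymmetric and correlated with purity estimation error.
* The segment table and the variant-level copy-loss flags are generated
  independently; analyses that would join them spatially (e.g. expected
  overlap of neoantigens with called segments) are out of scope.
* The shipped immunogram catalog is a placeholder; conclusions about
  axis biology require a curated catalog supplied by the user.
* The subtype model's hyperparameter search is limited to mtry; the
  protocol (split, resamples, gate) is the fixed part, the search space
  is not claimed optimal.
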
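# neoscape

Downstream analysis of predicted tumor neoantigens in cohorts with paired
primary and metastatic samples — for cancer-genomics analysts who already
have somatic variant calls, CCF estimates, epitope predictions, expression
and immune-deconvolution tables, and want the neoantigen-landscape layer on
top of them.

## What it computes

* **Neoantigen calling**: an epitope is a neoantigen when its best
  (minimum over predictors) MHC-I binding affinity is < 500 nM and its
  transcript FPKM is > 1; affinity classes STRONG (< 50 nM) /
  MEDIUM (< 150 nM) / WEAK, stability HIGH when the pMHC half-life
  exceeds 2 h.
* **Clonality tracking** between paired primary and metastatic samples:
  a mutation is clonal when the 95% CCF confidence interval contains 1;
  between the members of a pair every variant is REDUCED, INCREASED or
  PERSISTENT, and the reduction ratio is
  (n_increased − n_reduced) / primary load.
* **Neoantigen depletion odds ratios** per sample: for nonsynonymous
  mutations, OR of being neoantigenic × lying in a copy-loss region
  (OR > 1 ⇒ DNA-level depletion) and of being neoantigenic × expressed
  (OR < 1 ⇒ transcriptional depletion), with Haldane–Anscombe correction,
  Woolf logit CIs and Fisher exact p.
* **Immunogenicity bias** of metastatic loss: OR of strong/medium
  affinity (< 150 nM) or high stability (> 2 h) between the REDUCED and
  INCREASED neoantigen groups.
* **Heterogeneity / instability**: MATH score
  (100 × 1.4826·MAD / median of VAFs), wGII (mean per-autosome aberrant
  length fraction, CIN+ above 0.2), branch proportions
  (1 − |∩|/|∪| over multiregion feature sets) for neoantigens and TCR
  clonotypes.
* **Immunogram**: eight axes of the cancer-immunity cycle, each scored
  per sample (single-sample enrichment, or the neoantigen load for the
  antigenicity axis), z-scored over the cohort and mapped to
  IGS = 3 ± 1.5·Z (clamped to the radar range [1, 5]).
* **TMIT quadrants** on CD8A/PD-L1 and Treg/CD8, M2/M1 cell ratios.
* **Molecular subtyping**: pairwise Wilcoxon rank-sum signature
  extraction, a random forest trained on a stratified 2/3 split with 100
  tuning resamples, and patient-level calls that average probabilities
  over regions and require max probability ≥ 0.4 (else UNCLASSIFIED).
* **Synthetic cohorts** (`simulateCohort`): seed-deterministic generator
  of all input tables for a 26-patient paired-design cohort with planted
  depletion odds, immunogenicity-biased metastatic neoantigen loss and
  three-subtype expression structure, plus the ground truth for
  parameter-recovery testing.

See `vignettes/neoantigen-landscape.Rmd` for the full model description,
conventions and design choices.

## Worked example

```r
library(neoscape)
co  <- simulateCohort(cohortConfig(seed = 7))   # 26 patients, 57 samples
co
#> NeoCohort: 26 patients, 57 samples
#>   sites: PRIMARY=29, LYMPH=16, DISTANT=12
#>   variants: 8148 | epitopes: 28517 | genes: 486
#>   TCR clonotypes: 8550 | ground truth: planted
res <- runPipeline(co, "results_dir")
res$depletion_summary
#>     site n_determined n_undetermined n_cnv_depleted cnv_depleted_fraction n_txn_depleted txn_depleted_fraction
#>  PRIMARY           29              0             25              0.862069             25             0.8620690
#>    LYMPH           16              0             15              0.937500             14             0.8750000
#>  DISTANT           12              0             12              1.000000             11             0.9166667
head(res$tracking, 4)
#>            pair_id n_reduced n_increased n_persistent reduction_ratio reduction_flag
#>  P01_Pri1|P01_Lyn1        31          18           35     -0.05349794           TRUE
#>  P02_Pri1|P02_Lyn1        28          15           38     -0.05752212           TRUE
#>  P03_Pri1|P03_Lyn1        28          14           30     -0.07692308           TRUE
#>  P04_Pri1|P04_Lyn1        27          12           26     -0.11904762           TRUE
```

The depletion summary gives, per anatomic site, the fraction of samples
whose copy-loss OR exceeds 1 and whose transcriptional OR is below 1 —
with this cohort's planted thetaCnv = 2 and thetaTxn = 0.5, most samples
are called depleted in both senses. Each tracking row is one
primary/metastasis pair; the negative reduction ratios say the reduced
group outweighs the increased group, i.e. net neoantigen loss during
metastasis (the planted immunogenicity-biased drop). `results_dir`
additionally holds the called-neoantigen table, per-sample ITH/wGII
indices, the immunogram radar JSON, TMIT/cell-ratio tables, subtype calls
(when a model or labeled reference is supplied) and a run manifest with
the config hash; outputs are byte-identical under a fixed seed.

A thin command-line wrapper is included:

```sh
Rscript inst/cli/neoscape.R simulate --seed 7 --out cohort_dir
Rscript inst/cli/neoscape.R run --cohort cohort_dir --out results_dir
```

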
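#' NeoCohort: container for one cohort's analysis inputs
#'
#' Bundles the per-sample tables the downstream analyses consume: somatic
#' variants, predicted neoepitopes, a log2(TPM+1) expression matrix,
#' copy-number segments, immune-cell fractions, TCR clonotypes, and the
#' sample sheet mapping samples to patients and anatomic sites
#' (PRIMARY / LYMPH / DISTANT). Cohorts simulated by [simulateCohort()]
#' additionally carry the planted ground truth.
#'
#' @slot samples data.frame with columns `sample_id`, `patient_id`, `site`,
#'   `region` (integer multiregion index, 1 when single-region).
#' @slot variants data.frame of somatic variants (see [readVariants()] for
#'   the column contract).
#' @slot epitopes data.frame of predicted neoepitopes (see [readEpitopes()]).
#' @slot expression numeric matrix, genes in rows, samples in columns,
#'   log2(TPM+1) scale.
#' @slot segments data.frame of copy-number segments (see [readSegments()]).
#' @slot cellFractions numeric matrix, samples in rows, cell types in
#'   columns; rows sum to 1.
#' @slot tcr data.frame of TCR clonotypes with `sample_id`, `chain`,
#'   `cdr3`, `count`.
#' @slot groundTruth list of planted truth (empty for real data).
#'
#' @seealso [simulateCohort()], [runPipeline()]
#' @export
setClass("NeoCohort", representation(
  samples = "data.frame",
  variants = "data.frame",
  epitopes = "data.frame",
  expression = "matrix",
  segments = "data.frame",
  cellFractions = "matrix",
  tcr = "data.frame",
  groundTruth = "list"
))

setValidity("NeoCohort", function(object) {
  msg <- character()
  smp <- object@samples
  need <- c("sample_id", "patient_id", "site", "region")
  if (!all(need %in% names(smp)))
    msg <- c(msg, paste("samples must have columns:", paste(need, collapse = ", ")))
  else {
    if (anyDuplicated(smp$sample_id))
      msg <- c(msg, "duplicate sample_id in samples")
    bad <- setdiff(unique(smp$site), c("PRIMARY", "LYMPH", "DISTANT"))
    if (length(bad) > 0)
      msg <- c(msg, paste("unknown site label(s):", paste(bad, collapse = ", ")))
    for (tab in c("variants", "epitopes", "tcr")) {
      d <- slot(object, tab)
      if (nrow(d) > 0 && "sample_id" %in% names(d) &&
          !all(d$sample_id %in% smp$sample_id))
        msg <- c(msg, paste(tab, "refers to sample_id absent from samples"))
    }
    if (ncol(object@expression) > 0 &&
        !all(colnames(object@expression) %in% smp$sample_id))
      msg <- c(msg, "expression columns must be sample ids")
  }
  if (nrow(object@cellFractions) > 0) {
    rs <- rowSums(object@cellFractions)
    if (any(abs(rs - 1) > 1e-6))
      msg <- c(msg, "cellFractions rows must sum to 1 (tolerance 1e-6)")
  }
  if (length(msg) == 0) TRUE else msg
})

#' OddsRatioResult: a 2x2 odds ratio with CI and Fisher p
#'
#' Produced by [oddsRatio()]. The odds ratio is (a*d)/(b*c) on the table,
#' with a Haldane-Anscombe +0.5 continuity correction applied to every cell
#' when any cell is zero (flagged in `corrected`). The 95% CI is the Woolf
#' logit interval on the (possibly corrected) table; the two-sided Fisher
#' exact p is computed on the uncorrected table.
#'
#' @slot table integer-valued 2x2 matrix (uncorrected counts a, b / c, d).
#' @slot oddsRatio numeric odds ratio.
#' @slot logOR natural log of the odds ratio.
#' @slot ci95 numeric length-2 (lower, upper) Woolf interval.
#' @slot pFisher two-sided Fisher exact p-value.
#' @slot corrected logical; TRUE when the +0.5 correction was applied.
#' @export
setClass("OddsRatioResult", representation(
  table = "matrix",
  oddsRatio = "numeric",
  logOR = "numeric",
  ci95 = "numeric",
  pFisher = "numeric",
  corrected = "logical"
))

setValidity("OddsRatioResult", function(object) {
  msg <- character()
  if (!identical(dim(object@table), c(2L, 2L)))
    msg <- c(msg, "table must be 2x2")
  if (any(object@table < 0)) msg <- c(msg, "counts must be non-negative")
  if (length(object@ci95) != 2L || object@ci95[1] > object@ci95[2])
    msg <- c(msg, "ci95 must be an ordered (lower, upper) pair")
  if (length(msg) == 0) TRUE else msg
})

#' SubtypeModel: trained probability-gated subtype classifier
#'
#' Produced by [trainSubtypeModel()]. Holds the per-class signature gene
#' lists, the fitted random forest, the training/validation split, and the
#' probability gate used by [predictSubtype()].
#'
#' @slot signatures named list of character vectors, signature genes per class.
#' @slot forest fitted randomForest object.
#' @slot classes character vector of class labels (e.g. I, II, III).
#' @slot gate numeric in (0,1); calls with max mean probability below the
#'   gate are returned UNCLASSIFIED.
#' @slot training list: train/validation sample ids, seed, train fraction,
#'   resampling iterations, chosen mtry.
#' @slot accuracy held-out validation accuracy.
#' @export
setClass("SubtypeModel", representation(
  signatures = "list",
  forest = "ANY",
  classes = "character",
  gate = "numeric",
  training = "list",
  accuracy = "numeric"
))

setValidity("SubtypeModel", function(object) {
  if (object@gate <= 0 || object@gate >= 1) "gate must lie in (0,1)" else TRUE
})
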
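#' Call neoantigens from predicted neoepitopes
#'
#' Applies the two filtering gates that turn candidate neoepitopes into
#' called neoantigens: the best (minimum over predictors) MHC-I binding
#' affinity must be below `affinityGate` nM, and the source transcript must
#' be expressed with FPKM above `fpkmGate`. Peptides are 9- or 10-mers by
#' convention. Each kept record is annotated with its best affinity, the
#' affinity class (STRONG < 50 nM, MEDIUM < 150 nM, WEAK otherwise) and the
#' stability class (HIGH when the predicted pMHC half-life exceeds 2 h).
#'
#' @param epitopes data.frame with columns `variant_id`, `peptide`,
#'   `hla_allele`, `fpkm`, one or more predictor affinity columns (nM), and
#'   optionally `stability_halflife` (hours).
#' @param predictorCols character vector naming the affinity columns;
#'   default: every column ending in `_ic50`.
#' @param affinityGate affinity gate in nM (default 500).
#' @param fpkmGate expression gate in FPKM (default 1).
#' @return the kept rows with added columns `best_affinity`,
#'   `affinity_class`, `stability_class`.
#' @examples
#' ep <- data.frame(variant_id = "v1", peptide = "ACDEFGHIK",
#'                  hla_allele = "HLA-A*02:01",
#'                  netmhc_ic50 = 620, netmhcpan_ic50 = 480,
#'                  pickpocket_ic50 = 700, fpkm = 2.3)
#' callNeoantigens(ep)  # kept: best 480 nM, WEAK
#' @export
callNeoantigens <- function(epitopes, predictorCols = NULL,
                            affinityGate = 500, fpkmGate = 1) {
  .checkCols(epitopes, c("variant_id", "peptide", "hla_allele", "fpkm"),
             "epitopes")
  if (is.null(predictorCols))
    predictorCols <- grep("_ic50$", names(epitopes), value = TRUE)
  if (length(predictorCols) == 0)
    .stopf("no predictor affinity columns found (expected *_ic50)")
  .checkCols(epitopes, predictorCols, "epitopes")
  if (nrow(epitopes) == 0) {
    out <- epitopes
    out$best_affinity <- numeric(0)
    out$affinity_class <- character(0)
    out$stability_class <- character(0)
    return(out)
  }
  plen <- nchar(epitopes$peptide)
  if (any(!plen %in% c(9L, 10L)))
    .stopf("peptides must be 9- or 10-mers; offending row(s): %s",
           paste(head(which(!plen %in% c(9L, 10L)), 5), collapse = ", "))
  aff <- as.matrix(epitopes[predictorCols])
  if (any(aff <= 0, na.rm = TRUE)) .stopf("affinities must be positive (nM)")
  if (any(rowSums(!is.na(aff)) == 0))
    .stopf("every epitope needs at least one predictor affinity")
  best <- apply(aff, 1, min, na.rm = TRUE)
  keep <- best < affinityGate & epitopes$fpkm > fpkmGate
  out <- epitopes[keep, , drop = FALSE]
  out$best_affinity <- best[keep]
  out$affinity_class <- classifyAffinity(out$best_affinity,
                                         affinityGate = affinityGate)
  hl <- if ("stability_halflife" %in% names(out)) out$stability_halflife
        else rep(NA_real_, nrow(out))
  out$stability_class <- classifyStability(hl)
  rownames(out) <- NULL
  out
}

#' Affinity class of a called neoantigen
#'
#' STRONG below 50 nM, MEDIUM in [50, 150) nM, WEAK in [150, 500) nM.
#' Boundaries fall to the weaker class (the defining inequalities are
#' strict).
#'
#' @param bestAffinity numeric vector of best affinities in (0, affinityGate).
#' @param strongCut,mediumCut class cuts in nM.
#' @param affinityGate upper gate; affinities at or above it are an error
#'   because such epitopes are never called.
#' @return character vector of STRONG/MEDIUM/WEAK.
#' @export
classifyAffinity <- function(bestAffinity, strongCut = 50, mediumCut = 150,
                             affinityGate = 500) {
  if (any(is.na(bestAffinity)) || any(bestAffinity <= 0) ||
      any(bestAffinity >= affinityGate))
    .stopf("best affinity must lie in (0, %g) nM", affinityGate)
  ifelse(bestAffinity < strongCut, "STRONG",
         ifelse(bestAffinity < mediumCut, "MEDIUM", "WEAK"))
}

#' Stability class of a called neoantigen
#'
#' HIGH when the predicted peptide-MHC half-life strictly exceeds
#' `stabilityCut` hours, LOW otherwise, UNKNOWN when missing.
#'
#' @param halflife numeric vector of half-lives in hours (NA allowed).
#' @param stabilityCut cut in hours (default 2).
#' @return character vector of HIGH/LOW/UNKNOWN.
#' @export
classifyStability <- function(halflife, stabilityCut = 2) {
  if (any(halflife < 0, na.rm = TRUE)) .stopf("half-life must be non-negative")
  ifelse(is.na(halflife), "UNKNOWN",
         ifelse(halflife > stabilityCut, "HIGH", "LOW"))
}

#' Neoantigen yield per mutation and generating fraction
#'
#' Yield is the number of called neoantigens arising from mutations of the
#' requested class divided by the number of mutations of that class (all
#' mutations of the class, not only those generating epitopes). The
#' generating fraction is the proportion of nonsilent mutations with at
#' least one called neoantigen.
#'
#' @param variants data.frame with `variant_id` and `variant_class`.
#' @param neoantigens called-neoantigen data.frame with `variant_id`.
#' @param byClass variant class for the yield (default MISSENSE).
#' @param generatingDenominator "all" (default) counts every mutation of the
#'   class in the yield denominator; "generating" counts only mutations with
#'   at least one neoantigen.
#' @return list with `yield_per_mutation` and `fraction_generating`.
#' @export
neoantigenYield <- function(variants, neoantigens, byClass = "MISSENSE",
                            generatingDenominator = c("all", "generating")) {
  generatingDenominator <- match.arg(generatingDenominator)
  .checkCols(variants, c("variant_id", "variant_class"), "variants")
  .checkCols(neoantigens, "variant_id", "neoantigens")
  inClass <- variants$variant_class == byClass
  if (!any(inClass)) .stopf("no variants of class %s; yield undefined", byClass)
  classIds <- variants$variant_id[inClass]
  nNeo <- sum(neoantigens$variant_id %in% classIds)
  denom <- if (generatingDenominator == "all") length(classIds)
           else sum(classIds %in% neoantigens$variant_id)
  yield <- if (denom == 0) 0 else nNeo / denom
  nonsilent <- variants$variant_id[variants$variant_class != "SILENT"]
  frac <- if (length(nonsilent) == 0) 0
          else mean(nonsilent %in% neoantigens$variant_id)
  list(yield_per_mutation = yield, fraction_generating = frac)
}

#' Within- and cross-patient neoantigen sharing
#'
#' A neoantigen instance (one identity key observed in one sample) counts as
#' within-patient shared when its identity key, (peptide, HLA allele),
#' occurs in at least two samples of the same patient. The cross-patient
#' set lists keys seen in two or more patients.
#'
#' @param neoantigens data.frame with `patient_id`, `sample_id`, `peptide`,
#'   `hla_allele`.
#' @return list with `within_patient_shared_fraction`, `n_shared`,
#'   `n_instances`, and `cross_patient_shared` (character vector of keys).
#' @export
sharingStats <- function(neoantigens) {
  .checkCols(neoantigens,
             c("patient_id", "sample_id", "peptide", "hla_allele"),
             "neoantigens")
  key <- paste(neoantigens$peptide, neoantigens$hla_allele, sep = "|")
  inst <- unique(data.frame(patient = neoantigens$patient_id,
                            sample = neoantigens$sample_id,
                            key = key, stringsAsFactors = FALSE))
  if (nrow(inst) == 0)
    return(list(within_patient_shared_fraction = NA_real_, n_shared = 0L,
                n_instances = 0L, cross_patient_shared = character(0)))
  pk <- paste(inst$patient, inst$key, sep = "|")
  nSamplesPerPK <- table(pk)
  shared <- nSamplesPerPK[pk] >= 2
  byKey <- tapply(inst$patient, inst$key, function(p) length(unique(p)))
  list(within_patient_shared_fraction = mean(shared),
       n_shared = sum(shared), n_instances = nrow(inst),
       cross_patient_shared = names(byKey)[byKey >= 2])
}

#' Branch proportion: intratumor heterogeneity of a feature set
#'
#' For multiregion samples of one tumor, the proportion of features
#' (neoantigen keys, TCR clonotypes, mutations) not shared by all regions:
#' 1 - |intersection| / |union|. 0 means all regions identical (all trunk),
#' 1 means no feature is ubiquitous.
#'
#' @param regionSets list (length >= 2) of character vectors, one feature
#'   set per region.
#' @return numeric in [0, 1].
#' @examples
#' branchProportion(list(letters[1:8], letters[3:10]))
#' @export
branchProportion <- function(regionSets) {
  if (!is.list(regionSets) || length(regionSets) < 2)
    .stopf("need at least 2 region sets")
  regionSets <- lapply(regionSets, unique)
  uni <- Reduce(union, regionSets)
  if (length(uni) == 0) .stopf("all region sets are empty")
  inter <- Reduce(intersect, regionSets)
  1 - length(inter) / length(uni)
}

#' Proportion of reads in clonal TCR clonotypes
#'
#' Per chain, the fraction of reads carried by clonotypes whose frequency
#' exceeds `threshold` of that chain's reads. The clonal-clone frequency cut
#' is a convention, not a measured constant; 1% is the default.
#'
#' @param clonotypes data.frame with `chain`, `cdr3`, `count`.
#' @param threshold clone-frequency cut (default 0.01).
#' @return named numeric vector, one proportion per chain.
#' @export
tcrClonalProportion <- function(clonotypes, threshold = 0.01) {
  .checkCols(clonotypes, c("chain", "cdr3", "count"), "clonotypes")
  if (any(clonotypes$count < 0)) .stopf("clone counts must be non-negative")
  chains <- sort(unique(as.character(clonotypes$chain)))
  vapply(chains, function(ch) {
    cnt <- clonotypes$count[clonotypes$chain == ch]
    tot <- sum(cnt)
    if (tot == 0) .stopf("chain %s has zero total reads", ch)
    freq <- cnt / tot
    sum(cnt[freq > threshold]) / tot
  }, numeric(1))
}
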
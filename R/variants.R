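#' QC filter for somatic SNVs
#'
#' A variant is kept when it has at least `minAltReads` supporting reads in
#' the tumor and the two-sided Fisher exact test comparing the mutant/wild-type
#' read composition between tumor and matched normal is significant at
#' `alpha`. This is the final sanity filter applied after variant calling:
#' it removes weakly supported calls and calls whose allele composition is
#' indistinguishable from the matched normal (germline leakage, artifacts).
#'
#' @param variants data.frame with columns `tumor_alt_reads`,
#'   `tumor_ref_reads`, `normal_alt_reads`, `normal_ref_reads`.
#' @param alpha significance level for the Fisher composition test.
#' @param minAltReads minimum tumor alt-supporting reads (default 5).
#' @return logical vector, TRUE for variants passing both gates.
#' @examples
#' v <- data.frame(tumor_alt_reads = c(4, 20, 5),
#'                 tumor_ref_reads = c(96, 80, 95),
#'                 normal_alt_reads = c(0, 0, 5),
#'                 normal_ref_reads = c(100, 100, 95))
#' qcFilterVariants(v)  # FALSE TRUE FALSE
#' @export
qcFilterVariants <- function(variants, alpha = 0.05, minAltReads = 5) {
  cols <- c("tumor_alt_reads", "tumor_ref_reads",
            "normal_alt_reads", "normal_ref_reads")
  .checkCols(variants, cols, "variants")
  counts <- as.matrix(variants[cols])
  if (any(is.na(counts)) || any(counts < 0))
    .stopf("read counts must be non-negative and non-missing")
  p <- vapply(seq_len(nrow(counts)), function(i) {
    m <- matrix(counts[i, ], nrow = 2, byrow = TRUE)
    stats::fisher.test(m)$p.value
  }, numeric(1))
  variants$tumor_alt_reads >= minAltReads & p < alpha
}

#' Classify mutation clonality from a CCF confidence interval
#'
#' A mutation is clonal when the 95% confidence interval of its cancer cell
#' fraction overlaps 1 (closed interval: endpoint contact counts), and
#' subclonal otherwise.
#'
#' @param lo,hi numeric vectors of CI bounds, `lo <= hi`.
#' @return character vector of "CLONAL" / "SUBCLONAL".
#' @examples
#' classifyClonality(c(0.92, 0.40, 1.00), c(1.04, 0.80, 1.00))
#' @export
classifyClonality <- function(lo, hi) {
  if (length(lo) != length(hi)) .stopf("lo and hi must have equal length")
  if (any(is.na(lo)) || any(is.na(hi))) .stopf("CI bounds must not be missing")
  if (any(lo > hi)) .stopf("invalid CCF interval: lo > hi")
  ifelse(lo <= 1 & hi >= 1, "CLONAL", "SUBCLONAL")
}

#' Track variant fate between a paired primary and metastatic sample
#'
#' Classifies every variant observed in either member of a primary/metastasis
#' pair into REDUCED, INCREASED or PERSISTENT. A variant is REDUCED when it
#' is present only in the primary, or clonal in the primary but subclonal in
#' the metastasis; INCREASED when present only in the metastasis, or
#' subclonal in the primary but clonal in the metastasis; PERSISTENT when
#' present in both with unchanged clonality. Presence means the variant
#' passed QC in that sample; variants are keyed by (chrom, pos, ref, alt).
#'
#' @param primary,metastasis data.frames with columns `chrom`, `pos`, `ref`,
#'   `alt`, `clonality` ("CLONAL"/"SUBCLONAL").
#' @return data.frame with `key`, `group`, and provenance columns
#'   `in_primary`, `in_metastasis`, `clonality_primary`,
#'   `clonality_metastasis` (NA when absent).
#' @export
trackVariants <- function(primary, metastasis) {
  need <- c("chrom", "pos", "ref", "alt", "clonality")
  .checkCols(primary, need, "primary")
  .checkCols(metastasis, need, "metastasis")
  kp <- variantKey(primary$chrom, primary$pos, primary$ref, primary$alt)
  km <- variantKey(metastasis$chrom, metastasis$pos, metastasis$ref,
                   metastasis$alt)
  if (anyDuplicated(kp)) .stopf("duplicate variant keys in primary sample")
  if (anyDuplicated(km)) .stopf("duplicate variant keys in metastasis sample")
  keys <- union(kp, km)
  cp <- setNames(primary$clonality, kp)[keys]
  cm <- setNames(metastasis$clonality, km)[keys]
  inP <- keys %in% kp
  inM <- keys %in% km
  group <- character(length(keys))
  group[inP & !inM] <- "REDUCED"
  group[!inP & inM] <- "INCREASED"
  both <- inP & inM
  group[both & cp == "CLONAL" & cm == "SUBCLONAL"] <- "REDUCED"
  group[both & cp == "SUBCLONAL" & cm == "CLONAL"] <- "INCREASED"
  group[both & cp == cm] <- "PERSISTENT"
  data.frame(key = keys, group = group,
             in_primary = inP, in_metastasis = inM,
             clonality_primary = unname(cp),
             clonality_metastasis = unname(cm),
             stringsAsFactors = FALSE)
}

#' Neoantigen reduction ratio for one primary/metastasis pair
#'
#' The reduction ratio is (increased - reduced) / primary load; a negative
#' ratio flags net neoantigen reduction during metastasis.
#'
#' @param groups character vector of tracked group labels
#'   (REDUCED/INCREASED/PERSISTENT), one per variant in the pair union.
#' @param primaryLoad positive count: the neoantigen (or variant) load of
#'   the primary sample.
#' @param pairId optional identifier carried into the output.
#' @return one-row data.frame: `pair_id`, `n_reduced`, `n_increased`,
#'   `n_persistent`, `primary_load`, `reduction_ratio`, `reduction_flag`.
#' @examples
#' reductionRatio(rep(c("INCREASED", "REDUCED", "PERSISTENT"),
#'                    c(10, 30, 60)), primaryLoad = 100)
#' @export
reductionRatio <- function(groups, primaryLoad, pairId = NA_character_) {
  bad <- setdiff(unique(groups), c("REDUCED", "INCREASED", "PERSISTENT"))
  if (length(bad) > 0)
    .stopf("unknown group label(s): %s", paste(bad, collapse = ", "))
  if (length(primaryLoad) != 1 || is.na(primaryLoad) || primaryLoad <= 0)
    .stopf("primaryLoad must be a positive count; ratio undefined at 0")
  nr <- sum(groups == "REDUCED")
  ni <- sum(groups == "INCREASED")
  np <- sum(groups == "PERSISTENT")
  ratio <- (ni - nr) / primaryLoad
  data.frame(pair_id = pairId, n_reduced = nr, n_increased = ni,
             n_persistent = np, primary_load = primaryLoad,
             reduction_ratio = ratio, reduction_flag = ratio < 0,
             stringsAsFactors = FALSE)
}

#' MATH score: mutant-allele tumor heterogeneity
#'
#' 100 * MAD / median of the variant allele frequencies, with the median
#' absolute deviation scaled by the consistency constant 1.4826. Higher
#' values indicate a wider VAF spread, i.e. more intratumor heterogeneity.
#'
#' @param vafs numeric vector of variant allele frequencies (at least 3).
#' @return non-negative numeric score.
#' @examples
#' mathScore(c(0.1, 0.2, 0.3, 0.4, 0.5))  # 49.42
#' @export
mathScore <- function(vafs) {
  if (length(vafs) < 3) .stopf("MATH needs at least 3 VAFs")
  if (any(is.na(vafs)) || any(vafs < 0)) .stopf("VAFs must be non-negative")
  med <- stats::median(vafs)
  if (med == 0) .stopf("median VAF is 0; MATH undefined")
  100 * stats::mad(vafs, constant = 1.4826) / med
}

#' Weighted genome instability index (wGII)
#'
#' For each of the 22 autosomes, the fraction of its covered length whose
#' total copy number differs from the rounded sample ploidy; wGII is the
#' unweighted mean of these 22 per-chromosome fractions, so every autosome
#' contributes equally regardless of size. Samples with wGII above
#' `cinThreshold` are flagged chromosomally unstable (CIN+).
#'
#' @param segments data.frame with columns `chrom` (1..22), `start`, `end`
#'   (1-based, end exclusive), `total_cn`. All 22 autosomes must carry at
#'   least one segment.
#' @param ploidy sample ploidy (> 0); the aberration baseline is
#'   `round(ploidy)`.
#' @param cinThreshold CIN+ cut on wGII (default 0.2).
#' @return list with `wgii` (in [0,1]) and `cin` (logical).
#' @export
wgii <- function(segments, ploidy = 2, cinThreshold = 0.2) {
  .checkCols(segments, c("chrom", "start", "end", "total_cn"), "segments")
  if (ploidy <= 0) .stopf("ploidy must be positive")
  chrom <- as.character(segments$chrom)
  lens <- autosomeLengths()
  if (!all(chrom %in% names(lens)))
    .stopf("segments on non-autosome chromosome(s): %s",
           paste(setdiff(unique(chrom), names(lens)), collapse = ", "))
  if (any(segments$end <= segments$start))
    .stopf("segment with end <= start")
  if (any(segments$end - 1 > lens[chrom] | segments$start < 1))
    .stopf("segment outside chromosome bounds")
  baseline <- round(ploidy)
  segLen <- segments$end - segments$start
  aberrant <- segments$total_cn != baseline
  perChrom <- vapply(names(lens), function(cc) {
    i <- chrom == cc
    if (!any(i)) return(NA_real_)
    sum(segLen[i & aberrant]) / sum(segLen[i])
  }, numeric(1))
  if (any(is.na(perChrom)))
    .stopf("no segments on autosome(s): %s",
           paste(names(perChrom)[is.na(perChrom)], collapse = ", "))
  w <- mean(perChrom)
  list(wgii = w, cin = w > cinThreshold)
}
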
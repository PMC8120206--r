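#' Single-sample gene-set enrichment score
#'
#' A deterministic single-sample enrichment engine in the ssGSEA style. Per
#' sample, genes receive rank-normalized weights u = rank/N (average ranks
#' for ties), the gene list is walked in decreasing-expression order, and
#' set genes advance a running sum in proportion to u^alpha (non-set genes
#' advance the complementary sum uniformly); the score is the integrated
#' difference of the two running sums. Scores are then normalized by the
#' range of scores across the cohort, so all downstream use via cohort
#' z-scores is invariant to the engine's scale. Higher scores mean the set's
#' genes sit higher in the sample's expression ranking.
#'
#' @param expr numeric matrix, genes in rows (unique rownames), samples in
#'   columns, log2(TPM+1) scale.
#' @param genes character vector of set member genes.
#' @param alpha rank-weight exponent (default 0.25).
#' @param normalize divide by the cohort score range (default TRUE; skipped
#'   when the range is zero, e.g. a single sample).
#' @param minGenes minimum set genes present in the matrix (default 2).
#' @return named numeric vector of per-sample scores.
#' @export
ssgseaScore <- function(expr, genes, alpha = 0.25, normalize = TRUE,
                        minGenes = 2) {
  if (!is.matrix(expr) || is.null(rownames(expr)))
    .stopf("expr must be a matrix with gene rownames")
  if (anyDuplicated(rownames(expr))) .stopf("duplicate gene identifiers")
  present <- intersect(unique(genes), rownames(expr))
  if (length(present) < minGenes)
    .stopf("gene set has %d member(s) in the matrix (< %d); missing: %s",
           length(present), minGenes,
           paste(setdiff(genes, rownames(expr)), collapse = ", "))
  N <- nrow(expr)
  m <- length(present)
  if (m == N) .stopf("gene set covers the whole matrix; no background genes")
  inSet <- rownames(expr) %in% present
  es <- vapply(seq_len(ncol(expr)), function(j) {
    e <- expr[, j]
    u <- rank(e, ties.method = "average") / N
    ord <- order(-e, rownames(expr))   # gene name breaks expression ties
    w <- u^alpha
    stepIn <- ifelse(inSet, w / sum(w[inSet]), 0)[ord]
    stepOut <- ifelse(inSet, 0, 1 / (N - m))[ord]
    sum(cumsum(stepIn) - cumsum(stepOut))
  }, numeric(1))
  names(es) <- colnames(expr)
  if (normalize) {
    rng <- diff(range(es))
    if (rng > 0) es <- es / rng
  }
  es
}

#' Cohort z-scores
#'
#' Centers and scales a per-sample score vector to mean 0 and population
#' standard deviation 1 (divides by n, not n-1; switch with `popsd`). A
#' zero-dispersion input returns all zeros with a warning.
#'
#' @param scores numeric vector, length >= 2.
#' @param popsd use the population sd convention (default TRUE).
#' @return numeric vector of z-scores, names preserved.
#' @export
cohortZ <- function(scores, popsd = TRUE) {
  if (length(scores) < 2) .stopf("cohort z-score needs at least 2 samples")
  if (any(is.na(scores))) .stopf("scores must not be missing")
  s <- if (popsd) popSd(scores) else stats::sd(scores)
  if (s == 0) {
    warning("zero dispersion; returning all-zero z-scores")
    return(setNames(rep(0, length(scores)), names(scores)))
  }
  (scores - mean(scores)) / s
}

#' Immunogram score from a cohort z-score
#'
#' Stimulatory axes score 3 + 1.5 z; inhibitory axes (scored as *absence*
#' of the inhibitory feature) score 3 - 1.5 z. The display value is clamped
#' to the radar range [1, 5]; the raw value is also returned.
#'
#' @param z numeric vector of cohort z-scores.
#' @param orientation "STIMULATORY" or "INHIBITORY".
#' @return data.frame with `z`, `igs_raw`, `igs` (clamped display value).
#' @examples
#' igs(1, "STIMULATORY")$igs   # 4.5
#' igs(1, "INHIBITORY")$igs    # 1.5
#' @export
igs <- function(z, orientation = c("STIMULATORY", "INHIBITORY")) {
  orientation <- match.arg(orientation)
  if (any(!is.finite(z))) .stopf("z must be finite")
  raw <- if (orientation == "STIMULATORY") 3 + 1.5 * z else 3 - 1.5 * z
  data.frame(z = z, igs_raw = raw, igs = .clamp(raw, 1, 5))
}

#' Antigenicity axis from neoantigen loads
#'
#' The tumor-antigenicity axis of the immunogram is scored from the
#' per-sample neoantigen load rather than a gene set: loads are
#' log10(x + 1)-transformed (they are heavy-tailed), z-scored over the
#' cohort, and converted to a stimulatory immunogram score.
#'
#' @param loads non-negative per-sample neoantigen counts, length >= 2.
#' @param logTransform apply log10(x+1) first (default TRUE).
#' @return data.frame with `z`, `igs_raw`, `igs`; row order follows `loads`.
#' @export
antigenicityAxis <- function(loads, logTransform = TRUE) {
  if (length(loads) < 2) .stopf("antigenicity axis needs >= 2 samples")
  if (any(loads < 0)) .stopf("loads must be non-negative")
  x <- if (logTransform) log10(loads + 1) else loads
  z <- cohortZ(x)
  out <- igs(z, "STIMULATORY")
  rownames(out) <- names(loads)
  out
}

#' Placeholder immunogram gene-set catalog
#'
#' The eight immunogram axes of the cancer-immunity cycle: five stimulatory
#' (anti-tumor T-cell immunity, tumor antigenicity, T-cell priming and
#' activation, T-cell trafficking and infiltration, recognition of cancer
#' cells) and three inhibitory (inhibitory cells, checkpoint expression,
#' other inhibitory molecules). Axis 2 (antigenicity) is scored from
#' neoantigen loads, not expression. The member gene lists shipped here are
#' documented placeholders — plausible marker genes for each axis, not a
#' reproduction of any published signature — and are meant to be replaced
#' via the `catalog` argument of [immunogram()] (e.g. from a GMT file).
#'
#' @return list of axis descriptors: `axis` (1-8), `name`, `orientation`,
#'   `genes` (NULL for the antigenicity axis).
#' @export
immunogramCatalog <- function() {
  list(
    list(axis = 1L, name = "antitumor_T_cell_immunity",
         orientation = "STIMULATORY",
         genes = c("CD8A", "CD3E", "GZMB", "PRF1", "IFNG")),
    list(axis = 2L, name = "tumor_antigenicity",
         orientation = "STIMULATORY", genes = NULL),
    list(axis = 3L, name = "T_cell_priming_activation",
         orientation = "STIMULATORY",
         genes = c("CD80", "CD86", "CD40", "IL12A", "BATF3")),
    list(axis = 4L, name = "T_cell_trafficking_infiltration",
         orientation = "STIMULATORY",
         genes = c("CXCL9", "CXCL10", "CXCL11", "ICAM1", "SELP")),
    list(axis = 5L, name = "cancer_cell_recognition",
         orientation = "STIMULATORY",
         genes = c("HLA-A", "HLA-B", "HLA-C", "B2M", "TAP1", "TAP2")),
    list(axis = 6L, name = "inhibitory_cells",
         orientation = "INHIBITORY",
         genes = c("FOXP3", "IL2RA", "CCR8", "ARG1", "S100A8")),
    list(axis = 7L, name = "checkpoint_expression",
         orientation = "INHIBITORY",
         genes = c("PDCD1", "CD274", "CTLA4", "LAG3", "HAVCR2")),
    list(axis = 8L, name = "other_inhibitory_molecules",
         orientation = "INHIBITORY",
         genes = c("IDO1", "TGFB1", "IL10", "VEGFA", "PTGS2"))
  )
}

#' Eight-axis immunogram of the cancer-immunity cycle
#'
#' Scores every sample on eight axes: seven expression axes via
#' [ssgseaScore()] + [cohortZ()] + [igs()], and the antigenicity axis from
#' neoantigen loads via [antigenicityAxis()]. Stimulatory axes map z to
#' 3 + 1.5 z, inhibitory axes to 3 - 1.5 z, so values above 3 always read
#' as "favorable for anti-tumor immunity" on the radar.
#'
#' @param expr genes x samples log2(TPM+1) matrix.
#' @param loads named per-sample neoantigen loads (names matching
#'   `colnames(expr)`).
#' @param catalog axis catalog as from [immunogramCatalog()].
#' @return data.frame with one row per sample x axis: `sample_id`, `axis`,
#'   `name`, `orientation`, `nes`, `z`, `igs_raw`, `igs`.
#' @export
immunogram <- function(expr, loads, catalog = immunogramCatalog()) {
  if (is.null(colnames(expr))) .stopf("expr must have sample column names")
  if (is.null(names(loads)) || !all(colnames(expr) %in% names(loads)))
    .stopf("loads must be named for every expression sample")
  loads <- loads[colnames(expr)]
  rows <- lapply(catalog, function(ax) {
    if (is.null(ax$genes)) {
      a <- antigenicityAxis(loads)
      nes <- log10(loads + 1)
    } else {
      present <- intersect(ax$genes, rownames(expr))
      if (length(present) < 2)
        .stopf("axis %d (%s): fewer than 2 catalog genes in the matrix",
               ax$axis, ax$name)
      nes <- ssgseaScore(expr, ax$genes)
      a <- igs(suppressWarnings(cohortZ(nes)), ax$orientation)
    }
    data.frame(sample_id = colnames(expr), axis = ax$axis, name = ax$name,
               orientation = ax$orientation, nes = as.numeric(nes),
               z = a$z, igs_raw = a$igs_raw, igs = a$igs,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$sample_id, out$axis), , drop = FALSE]
}

#' Tumor microenvironment immune type (TMIT) quadrants
#'
#' Splits the cohort at the per-marker median (ties count as "low") and
#' assigns: TMIT I = high PD-L1 and high CD8A (inflamed), II = low/low,
#' III = high PD-L1 / low CD8A, IV = low PD-L1 / high CD8A.
#'
#' @param cd8a,pdl1 per-sample expression of CD8A and PD-L1 (CD274),
#'   parallel vectors.
#' @return character vector of "I"/"II"/"III"/"IV".
#' @export
tmitClassify <- function(cd8a, pdl1) {
  if (length(cd8a) != length(pdl1)) .stopf("marker vectors differ in length")
  if (any(is.na(cd8a)) || any(is.na(pdl1))) .stopf("missing marker values")
  hiC <- cd8a > stats::median(cd8a)
  hiP <- pdl1 > stats::median(pdl1)
  out <- character(length(cd8a))
  out[hiP & hiC] <- "I"
  out[!hiP & !hiC] <- "II"
  out[hiP & !hiC] <- "III"
  out[!hiP & hiC] <- "IV"
  names(out) <- names(cd8a)
  out
}

#' Treg/CD8 and M2/M1 immune-cell ratios
#'
#' Per-sample ratios of regulatory to cytotoxic T-cell fractions and of M2
#' to M1 macrophage fractions, with a pseudocount added to numerator and
#' denominator because deconvolved fractions contain exact zeros.
#'
#' @param fractions samples x cell-types matrix or data.frame of
#'   proportions.
#' @param tregCol,cd8Col,m2Col,m1Col column names (defaults "Tregs",
#'   "CD8_T", "M2", "M1").
#' @param eps pseudocount (default 1e-3).
#' @return data.frame with `sample_id`, `treg_cd8_ratio`, `m2_m1_ratio`.
#' @export
cellRatios <- function(fractions, tregCol = "Tregs", cd8Col = "CD8_T",
                       m2Col = "M2", m1Col = "M1", eps = 1e-3) {
  fractions <- as.data.frame(fractions)
  .checkCols(fractions, c(tregCol, cd8Col, m2Col, m1Col), "fractions")
  data.frame(
    sample_id = if (!is.null(rownames(fractions))) rownames(fractions)
                else as.character(seq_len(nrow(fractions))),
    treg_cd8_ratio = (fractions[[tregCol]] + eps) / (fractions[[cd8Col]] + eps),
    m2_m1_ratio = (fractions[[m2Col]] + eps) / (fractions[[m1Col]] + eps),
    stringsAsFactors = FALSE)
}
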
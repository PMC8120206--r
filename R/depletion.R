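#' Build a 2x2 contingency table over nonsynonymous mutations
#'
#' Rows split mutations into neoantigenic vs non-neoantigenic; columns split
#' them by an attribute (e.g. lying in a copy-loss region, or being
#' expressed). Cell a counts neoantigenic mutations with the attribute, b
#' without; c and d the same for non-neoantigenic mutations.
#'
#' @param variants data.frame of nonsynonymous mutations.
#' @param rowPredicate,colPredicate logical vectors (or functions of the
#'   data.frame returning logical vectors): is-neoantigenic and
#'   has-attribute.
#' @return 2x2 integer matrix with dimnames
#'   (neoantigenic/other x attribute/no_attribute).
#' @export
buildTable <- function(variants, rowPredicate, colPredicate) {
  if (nrow(variants) == 0) .stopf("empty variant table")
  evalPred <- function(p, what) {
    v <- if (is.function(p)) p(variants) else p
    if (!is.logical(v) || length(v) != nrow(variants) || any(is.na(v)))
      .stopf("%s must yield one non-missing logical per variant", what)
    v
  }
  r <- evalPred(rowPredicate, "rowPredicate")
  cc <- evalPred(colPredicate, "colPredicate")
  m <- matrix(c(sum(r & cc), sum(r & !cc), sum(!r & cc), sum(!r & !cc)),
              nrow = 2, byrow = TRUE,
              dimnames = list(c("neoantigenic", "other"),
                              c("attribute", "no_attribute")))
  storage.mode(m) <- "integer"
  m
}

#' Odds ratio with Woolf CI and Fisher exact p
#'
#' OR = (a*d)/(b*c). When any cell is zero the Haldane-Anscombe correction
#' adds 0.5 to every cell before computing the OR and its CI (flagged in the
#' result); the two-sided Fisher exact p is always computed on the
#' uncorrected counts. The 95% CI is the Woolf logit interval
#' exp(log OR +/- 1.96 * sqrt(1/a + 1/b + 1/c + 1/d)).
#'
#' @param tab 2x2 numeric matrix of counts (rows: neoantigenic/other;
#'   columns: attribute/no-attribute), as from [buildTable()].
#' @return an [OddsRatioResult-class].
#' @examples
#' res <- oddsRatio(matrix(c(5, 15, 2, 38), nrow = 2, byrow = TRUE))
#' res@oddsRatio  # 6.333
#' @export
oddsRatio <- function(tab) {
  if (!is.matrix(tab) || !identical(dim(tab), c(2L, 2L)))
    .stopf("tab must be a 2x2 matrix")
  if (any(tab < 0) || any(is.na(tab))) .stopf("counts must be non-negative")
  if (sum(tab) == 0) .stopf("empty table")
  corrected <- any(tab == 0)
  ct <- if (corrected) tab + 0.5 else tab
  a <- ct[1, 1]; b <- ct[1, 2]; c <- ct[2, 1]; d <- ct[2, 2]
  or <- (a * d) / (b * c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  ci <- exp(log(or) + c(-1, 1) * stats::qnorm(0.975) * se)
  p <- stats::fisher.test(tab)$p.value
  m <- tab
  storage.mode(m) <- "integer"
  new("OddsRatioResult", table = m, oddsRatio = or, logOR = log(or),
      ci95 = ci, pFisher = p, corrected = corrected)
}

#' Per-sample neoantigen depletion call
#'
#' Computes the copy-loss and transcriptional depletion odds ratios for one
#' sample's nonsynonymous mutations and calls depletion by direction:
#' copy-loss depletion when OR > 1 (neoantigenic mutations preferentially in
#' copy-loss regions), transcriptional depletion when OR < 1 (neoantigenic
#' mutations preferentially unexpressed). Neoantigenic status is
#' binding-level (the mutation yields at least one predicted binder),
#' independent of expression, so the transcriptional table is non-degenerate.
#' With `significanceGate = TRUE` a call additionally requires the Fisher p
#' below `alpha`. A sample with an empty neoantigenic or non-neoantigenic
#' row is UNDETERMINED.
#'
#' @param variants one sample's nonsynonymous mutations with logical columns
#'   `is_neoantigenic`, `in_copy_loss`, `expressed`.
#' @param sampleId identifier carried into the result.
#' @param significanceGate logical, default FALSE (direction-only calls).
#' @param alpha significance level for the optional gate.
#' @return list with `sample_id`, `cnv_or` and `txn_or`
#'   ([OddsRatioResult-class] or NULL), `cnv_depleted`, `txn_depleted`
#'   (logical or NA), and `determined`.
#' @export
depletionCall <- function(variants, sampleId = NA_character_,
                          significanceGate = FALSE, alpha = 0.05) {
  .checkCols(variants, c("is_neoantigenic", "in_copy_loss", "expressed"),
             "variants")
  undet <- list(sample_id = sampleId, cnv_or = NULL, txn_or = NULL,
                cnv_depleted = NA, txn_depleted = NA, determined = FALSE)
  if (nrow(variants) == 0) return(undet)
  neo <- variants$is_neoantigenic
  if (!any(neo) || all(neo)) return(undet)
  cnv <- oddsRatio(buildTable(variants, neo, variants$in_copy_loss))
  txn <- oddsRatio(buildTable(variants, neo, variants$expressed))
  cnvDep <- cnv@oddsRatio > 1
  txnDep <- txn@oddsRatio < 1
  if (significanceGate) {
    cnvDep <- cnvDep && cnv@pFisher < alpha
    txnDep <- txnDep && txn@pFisher < alpha
  }
  list(sample_id = sampleId, cnv_or = cnv, txn_or = txn,
       cnv_depleted = cnvDep, txn_depleted = txnDep, determined = TRUE)
}

#' Immunogenicity bias between reduced and increased neoantigens
#'
#' Tests whether high-immunogenicity neoantigens are over-represented in the
#' REDUCED group relative to the INCREASED group of a tracked pair. The
#' property is either strong/medium binding (best affinity < 150 nM) or high
#' pMHC stability (half-life > 2 h). OR > 1 means more-immunogenic
#' neoantigens are preferentially lost during metastasis.
#'
#' @param reduced,increased data.frames of called neoantigens (need
#'   `best_affinity` for the affinity property, `stability_halflife` for the
#'   stability property).
#' @param property "affinity" (default) or "stability".
#' @param affinityCut,stabilityCut property cuts (150 nM / 2 h).
#' @return an [OddsRatioResult-class] of group (reduced/increased) by
#'   property (present/absent).
#' @export
immunogenicityBiasOR <- function(reduced, increased,
                                 property = c("affinity", "stability"),
                                 affinityCut = 150, stabilityCut = 2) {
  property <- match.arg(property)
  if (nrow(reduced) == 0 || nrow(increased) == 0)
    .stopf("both the reduced and increased group must be non-empty")
  hasProp <- function(df) {
    if (property == "affinity") {
      .checkCols(df, "best_affinity", "neoantigens")
      df$best_affinity < affinityCut
    } else {
      .checkCols(df, "stability_halflife", "neoantigens")
      !is.na(df$stability_halflife) & df$stability_halflife > stabilityCut
    }
  }
  rp <- hasProp(reduced)
  ip <- hasProp(increased)
  tab <- matrix(c(sum(rp), sum(!rp), sum(ip), sum(!ip)), nrow = 2,
                byrow = TRUE,
                dimnames = list(c("reduced", "increased"),
                                c("property", "no_property")))
  storage.mode(tab) <- "integer"
  oddsRatio(tab)
}

#' Cohort summary of depletion calls by anatomic site
#'
#' Fractions of samples called copy-loss- and transcriptionally depleted per
#' site (PRIMARY / LYMPH / DISTANT). UNDETERMINED samples are excluded from
#' denominators and reported separately; a site with no determined samples
#' reports NA fractions, not 0.
#'
#' @param calls list of [depletionCall()] results.
#' @param sites character vector of site labels, parallel to `calls`.
#' @return data.frame with one row per site: `site`, `n_determined`,
#'   `n_undetermined`, `n_cnv_depleted`, `cnv_depleted_fraction`,
#'   `n_txn_depleted`, `txn_depleted_fraction`.
#' @export
cohortDepletionSummary <- function(calls, sites) {
  if (length(calls) != length(sites))
    .stopf("calls and sites must have equal length")
  known <- c("PRIMARY", "LYMPH", "DISTANT")
  bad <- setdiff(unique(sites), known)
  if (length(bad) > 0)
    .stopf("unknown site label(s): %s", paste(bad, collapse = ", "))
  det <- vapply(calls, function(x) isTRUE(x$determined), logical(1))
  cnv <- vapply(calls, function(x) isTRUE(x$cnv_depleted), logical(1))
  txn <- vapply(calls, function(x) isTRUE(x$txn_depleted), logical(1))
  do.call(rbind, lapply(known, function(s) {
    i <- sites == s
    nd <- sum(i & det)
    data.frame(site = s,
               n_determined = nd,
               n_undetermined = sum(i & !det),
               n_cnv_depleted = sum(i & det & cnv),
               cnv_depleted_fraction = if (nd > 0) sum(i & det & cnv) / nd
                                       else NA_real_,
               n_txn_depleted = sum(i & det & txn),
               txn_depleted_fraction = if (nd > 0) sum(i & det & txn) / nd
                                       else NA_real_,
               stringsAsFactors = FALSE)
  }))
}
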
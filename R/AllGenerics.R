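#' @name NeoCohort-accessors
#' @title Accessors for NeoCohort slots
#' @description Accessor generics for the tables bundled in a
#'   [NeoCohort-class] object.
#' @param x a `NeoCohort`.
#' @return The requested table (data.frame or matrix).
NULL

#' @rdname NeoCohort-accessors
#' @export
setGeneric("sampleInfo", function(x) standardGeneric("sampleInfo"))
#' @rdname NeoCohort-accessors
#' @export
setGeneric("variants", function(x) standardGeneric("variants"))
#' @rdname NeoCohort-accessors
#' @export
setGeneric("epitopes", function(x) standardGeneric("epitopes"))
#' @rdname NeoCohort-accessors
#' @export
setGeneric("exprMatrix", function(x) standardGeneric("exprMatrix"))
#' @rdname NeoCohort-accessors
#' @export
setGeneric("segments", function(x) standardGeneric("segments"))
#' @rdname NeoCohort-accessors
#' @export
setGeneric("cellFractions", function(x) standardGeneric("cellFractions"))
#' @rdname NeoCohort-accessors
#' @export
setGeneric("clonotypes", function(x) standardGeneric("clonotypes"))
#' @rdname NeoCohort-accessors
#' @export
setGeneric("groundTruth", function(x) standardGeneric("groundTruth"))

#' @rdname NeoCohort-accessors
setMethod("sampleInfo", "NeoCohort", function(x) x@samples)
#' @rdname NeoCohort-accessors
setMethod("variants", "NeoCohort", function(x) x@variants)
#' @rdname NeoCohort-accessors
setMethod("epitopes", "NeoCohort", function(x) x@epitopes)
#' @rdname NeoCohort-accessors
setMethod("exprMatrix", "NeoCohort", function(x) x@expression)
#' @rdname NeoCohort-accessors
setMethod("segments", "NeoCohort", function(x) x@segments)
#' @rdname NeoCohort-accessors
setMethod("cellFractions", "NeoCohort", function(x) x@cellFractions)
#' @rdname NeoCohort-accessors
setMethod("clonotypes", "NeoCohort", function(x) x@tcr)
#' @rdname NeoCohort-accessors
setMethod("groundTruth", "NeoCohort", function(x) x@groundTruth)

setMethod("show", "NeoCohort", function(object) {
  smp <- object@samples
  cat("NeoCohort:", length(unique(smp$patient_id)), "patients,",
      nrow(smp), "samples\n")
  tab <- table(factor(smp$site, levels = c("PRIMARY", "LYMPH", "DISTANT")))
  cat("  sites:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  cat("  variants:", nrow(object@variants),
      "| epitopes:", nrow(object@epitopes),
      "| genes:", nrow(object@expression), "\n")
  cat("  TCR clonotypes:", nrow(object@tcr),
      "| ground truth:", if (length(object@groundTruth)) "planted" else "none",
      "\n")
})

setMethod("show", "OddsRatioResult", function(object) {
  cat(sprintf("OddsRatioResult: OR = %.4g [%.4g, %.4g], Fisher p = %.3g%s\n",
              object@oddsRatio, object@ci95[1], object@ci95[2],
              object@pFisher,
              if (object@corrected) " (Haldane-Anscombe corrected)" else ""))
  print(object@table)
})

setMethod("show", "SubtypeModel", function(object) {
  cat("SubtypeModel:", paste(object@classes, collapse = "/"),
      "| gate =", object@gate, "\n")
  cat("  signature genes:",
      paste(vapply(object@signatures, length, 1L), collapse = "/"),
      "per class\n")
  cat(sprintf("  validation accuracy: %.3f (n = %d held out)\n",
              object@accuracy, length(object@training$validation_ids)))
})
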
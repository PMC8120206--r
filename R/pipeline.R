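#' Pipeline configuration
#'
#' Thresholds and mode switches for [runPipeline()], with the analysis
#' constants as defaults: 500 nM affinity gate, 50/150 nM affinity classes,
#' 2 h stability cut, FPKM > 1 expression gate, wGII 0.2 CIN cut, 0.4
#' subtype probability gate, alpha 0.05.
#'
#' @param affinityGate,strongCut,mediumCut,stabilityCut,fpkmGate,
#'   cinThreshold,probabilityGate,alpha thresholds (see Description).
#' @param significanceGate gate depletion calls on Fisher p < alpha
#'   (default FALSE: direction-only).
#' @param tcrClonalThreshold clone-frequency cut for clonal TCR.
#' @param seed RNG seed for the model-training step.
#' @return validated config list (class `neoscapePipelineConfig`).
#' @export
pipelineConfig <- function(affinityGate = 500, strongCut = 50,
                           mediumCut = 150, stabilityCut = 2, fpkmGate = 1,
                           cinThreshold = 0.2, probabilityGate = 0.4,
                           alpha = 0.05, significanceGate = FALSE,
                           tcrClonalThreshold = 0.01, seed = 1) {
  cfg <- as.list(environment())
  for (f in c("affinityGate", "strongCut", "mediumCut", "stabilityCut",
              "fpkmGate", "cinThreshold", "probabilityGate", "alpha",
              "tcrClonalThreshold"))
    if (!is.numeric(cfg[[f]]) || cfg[[f]] <= 0)
      .stopf("invalid config field %s: must be positive", f)
  if (cfg$probabilityGate >= 1)
    .stopf("invalid config field probabilityGate: must lie in (0,1)")
  class(cfg) <- "neoscapePipelineConfig"
  cfg
}

# neoantigenic variant keys of one sample's QC-passing variants
.neoKeys <- function(v) {
  variantKey(v$chrom, v$pos, v$ref, v$alt)[v$is_neoantigenic]
}

#' Run the full neoantigen-landscape pipeline on a cohort
#'
#' Executes every analysis stage on a [NeoCohort-class]: per-sample variant
#' QC, neoantigen calling and classification, per-sample depletion odds
#' ratios with a cohort-by-site summary, primary/metastasis tracking with
#' reduction ratios and immunogenicity-bias odds ratios, MATH and wGII
#' heterogeneity indices, the eight-axis immunogram, TMIT quadrants and
#' immune-cell ratios, and (when a subtype model or labeled reference
#' cohort is supplied) probability-gated subtype calls per patient. All
#' outputs are written to `outDir` as TSV/JSON plus a run manifest with the
#' config hash; outputs are byte-reproducible for a fixed cohort and
#' config.
#'
#' @param cohort a [NeoCohort-class].
#' @param outDir output directory.
#' @param config a [pipelineConfig()].
#' @param model optional pre-trained [SubtypeModel-class].
#' @param referenceExpr,referenceLabels optional labeled reference
#'   expression cohort used to train a subtype model when `model` is NULL.
#' @return (invisibly) list of the result tables, with the paths written.
#' @export
runPipeline <- function(cohort, outDir, config = pipelineConfig(),
                        model = NULL, referenceExpr = NULL,
                        referenceLabels = NULL) {
  stopifnot(is(cohort, "NeoCohort"))
  if (!inherits(config, "neoscapePipelineConfig"))
    .stopf("config must come from pipelineConfig()")
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  smp <- sampleInfo(cohort)
  var <- variants(cohort)
  ep <- epitopes(cohort)

  ## 1. QC filter, clonality
  var <- var[qcFilterVariants(var, alpha = config$alpha), , drop = FALSE]
  var$clonality <- classifyClonality(var$ccf_lo, var$ccf_hi)

  ## 2. called neoantigens (restricted to QC-passing variants per sample)
  keyVE <- paste(ep$sample_id, ep$variant_id)
  keyV <- paste(var$sample_id, var$variant_id)
  ep <- ep[keyVE %in% keyV, , drop = FALSE]
  neo <- callNeoantigens(ep, affinityGate = config$affinityGate,
                         fpkmGate = config$fpkmGate)
  clonMap <- setNames(var$clonality, keyV)
  neo$clonality <- unname(clonMap[paste(neo$sample_id, neo$variant_id)])
  load <- setNames(integer(nrow(smp)), smp$sample_id)
  tab <- table(neo$sample_id)
  load[names(tab)] <- as.integer(tab)

  ## 3. per-sample depletion
  calls <- lapply(smp$sample_id, function(sid) {
    v <- var[var$sample_id == sid & var$variant_class != "SILENT", ,
             drop = FALSE]
    depletionCall(v, sampleId = sid,
                  significanceGate = config$significanceGate,
                  alpha = config$alpha)
  })
  depletion <- do.call(rbind, lapply(calls, function(x) {
    data.frame(sample_id = x$sample_id, determined = x$determined,
               cnv_or = if (x$determined) x$cnv_or@oddsRatio else NA_real_,
               cnv_p = if (x$determined) x$cnv_or@pFisher else NA_real_,
               txn_or = if (x$determined) x$txn_or@oddsRatio else NA_real_,
               txn_p = if (x$determined) x$txn_or@pFisher else NA_real_,
               cnv_depleted = x$cnv_depleted, txn_depleted = x$txn_depleted,
               stringsAsFactors = FALSE)
  }))
  depSummary <- cohortDepletionSummary(calls, smp$site)

  ## 4. tracking and reduction per primary/metastasis pair
  tracking <- list()
  for (pid in unique(smp$patient_id)) {
    ps <- smp[smp$patient_id == pid, , drop = FALSE]
    priId <- ps$sample_id[ps$site == "PRIMARY"][1]
    if (is.na(priId)) next
    metIds <- ps$sample_id[ps$site %in% c("LYMPH", "DISTANT")]
    priV <- var[var$sample_id == priId & var$is_neoantigenic, , drop = FALSE]
    for (mid in metIds) {
      metV <- var[var$sample_id == mid & var$is_neoantigenic, , drop = FALSE]
      if (nrow(priV) == 0 && nrow(metV) == 0) next
      tr <- trackVariants(priV, metV)
      primaryLoad <- load[priId]
      row <- if (primaryLoad > 0)
        reductionRatio(tr$group, primaryLoad,
                       pairId = paste0(priId, "|", mid))
      else data.frame(pair_id = paste0(priId, "|", mid),
                      n_reduced = sum(tr$group == "REDUCED"),
                      n_increased = sum(tr$group == "INCREASED"),
                      n_persistent = sum(tr$group == "PERSISTENT"),
                      primary_load = 0L, reduction_ratio = NA_real_,
                      reduction_flag = NA, stringsAsFactors = FALSE)
      # immunogenicity bias on the called neoantigens of grouped variants
      redKeys <- tr$key[tr$group == "REDUCED"]
      incKeys <- tr$key[tr$group == "INCREASED"]
      neoPair <- neo[neo$sample_id %in% c(priId, mid), , drop = FALSE]
      vkMap <- setNames(variantKey(var$chrom, var$pos, var$ref, var$alt),
                        paste(var$sample_id, var$variant_id))
      neoPair$key <- unname(vkMap[paste(neoPair$sample_id,
                                        neoPair$variant_id)])
      red <- neoPair[neoPair$key %in% redKeys, , drop = FALSE]
      inc <- neoPair[neoPair$key %in% incKeys, , drop = FALSE]
      row$bias_or <- if (nrow(red) > 0 && nrow(inc) > 0)
        immunogenicityBiasOR(red, inc)@oddsRatio else NA_real_
      row$site <- smp$site[smp$sample_id == mid]
      tracking[[length(tracking) + 1]] <- row
    }
  }
  tracking <- if (length(tracking)) do.call(rbind, tracking)
              else data.frame()

  ## 5. heterogeneity and instability indices
  seg <- segments(cohort)
  ith <- do.call(rbind, lapply(smp$sample_id, function(sid) {
    v <- var[var$sample_id == sid, , drop = FALSE]
    math <- if (nrow(v) >= 3 && stats::median(v$vaf) > 0) mathScore(v$vaf)
            else NA_real_
    s <- seg[seg$sample_id == sid, , drop = FALSE]
    w <- if (nrow(s) > 0)
      wgii(s, ploidy = 2, cinThreshold = config$cinThreshold)
    else list(wgii = NA_real_, cin = NA)
    tcrS <- clonotypes(cohort)
    tcrS <- tcrS[tcrS$sample_id == sid, , drop = FALSE]
    tcl <- if (nrow(tcrS) > 0)
      tcrClonalProportion(tcrS, threshold = config$tcrClonalThreshold)
    else c(TRA = NA_real_, TRB = NA_real_)
    data.frame(sample_id = sid, n_variants = nrow(v),
               neoantigen_load = load[sid], math = math,
               wgii = w$wgii, cin = w$cin,
               tcr_clonal_tra = unname(tcl["TRA"]),
               tcr_clonal_trb = unname(tcl["TRB"]),
               stringsAsFactors = FALSE)
  }))

  # branch proportions for patients with multiregion primaries
  branch <- list()
  for (pid in unique(smp$patient_id)) {
    pri <- smp$sample_id[smp$patient_id == pid & smp$site == "PRIMARY"]
    if (length(pri) < 2) next
    neoSets <- lapply(pri, function(sid)
      paste(neo$peptide, neo$hla_allele)[neo$sample_id == sid])
    tcrAll <- clonotypes(cohort)
    tcrSets <- lapply(pri, function(sid)
      tcrAll$cdr3[tcrAll$sample_id == sid])
    branch[[length(branch) + 1]] <- data.frame(
      patient_id = pid, n_regions = length(pri),
      neoantigen_branch = if (all(lengths(neoSets) == 0)) NA_real_
                          else branchProportion(neoSets),
      tcr_branch = branchProportion(tcrSets),
      stringsAsFactors = FALSE)
  }
  branch <- if (length(branch)) do.call(rbind, branch) else data.frame()

  ## 6. immune scores
  expr <- exprMatrix(cohort)
  ig <- immunogram(expr, load)
  tmit <- tmitClassify(expr["CD8A", ], expr["CD274", ])
  ratios <- cellRatios(cellFractions(cohort))
  tmitTab <- data.frame(sample_id = colnames(expr), tmit = unname(tmit),
                        stringsAsFactors = FALSE)
  tmitTab <- merge(tmitTab, ratios, by = "sample_id", sort = TRUE)

  ## 7. subtype calls (primary regions per patient)
  subtype <- data.frame()
  if (is.null(model) && !is.null(referenceExpr)) {
    model <- trainSubtypeModel(referenceExpr, referenceLabels,
                               seed = config$seed,
                               gate = config$probabilityGate)
  }
  if (!is.null(model)) {
    subtype <- do.call(rbind, lapply(unique(smp$patient_id), function(pid) {
      pri <- smp$sample_id[smp$patient_id == pid & smp$site == "PRIMARY"]
      if (length(pri) == 0) return(NULL)
      call <- predictSubtype(model, expr[, pri, drop = FALSE],
                             patientId = pid)
      data.frame(patient_id = pid, subtype = call$subtype,
                 t(call$probabilities), n_regions = length(pri),
                 stringsAsFactors = FALSE, check.names = FALSE)
    }))
  }

  ## 8. write outputs + manifest
  paths <- list(
    neoantigens = file.path(outDir, "neoantigens.tsv"),
    depletion = file.path(outDir, "depletion.tsv"),
    depletion_summary = file.path(outDir, "depletion_summary.tsv"),
    tracking = file.path(outDir, "tracking.tsv"),
    ith = file.path(outDir, "ith.tsv"),
    branch = file.path(outDir, "branch.tsv"),
    immunogram = file.path(outDir, "immunogram.json"),
    tmit = file.path(outDir, "tmit_ratios.tsv"),
    subtype = file.path(outDir, "subtype.tsv"),
    manifest = file.path(outDir, "manifest.json"))
  .writeTsv(neo, paths$neoantigens)
  .writeTsv(depletion, paths$depletion)
  .writeTsv(depSummary, paths$depletion_summary)
  .writeTsv(tracking, paths$tracking)
  .writeTsv(ith, paths$ith)
  .writeTsv(branch, paths$branch)
  radar <- lapply(split(ig, ig$sample_id), function(d)
    setNames(as.list(d$igs[order(d$axis)]), d$name[order(d$axis)]))
  jsonlite::write_json(radar, paths$immunogram, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  .writeTsv(tmitTab, paths$tmit)
  .writeTsv(subtype, paths$subtype)
  cfgJson <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA)
  manifest <- list(
    package = "neoscape",
    version = as.character(utils::packageVersion("neoscape")),
    seed = config$seed,
    config = unclass(config),
    config_hash = fnv1a32(as.character(cfgJson)),
    n_patients = length(unique(smp$patient_id)),
    n_samples = nrow(smp))
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  invisible(list(neoantigens = neo, depletion = depletion,
                 depletion_summary = depSummary, tracking = tracking,
                 ith = ith, branch = branch, immunogram = ig,
                 tmit = tmitTab, subtype = subtype, model = model,
                 paths = paths))
}
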
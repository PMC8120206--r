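#' Configuration for the synthetic cohort generator
#'
#' Builds and validates the parameter set for [simulateCohort()]. Defaults
#' describe a 26-patient cohort with paired primary / regional-lymph-node /
#' distant-metastasis samples (29/16/12 sites, a few multiregion primaries),
#' roughly 150 somatic mutations per sample, 57% of nonsilent mutations
#' yielding at least one predicted MHC-I binder, planted copy-loss
#' (`thetaCnv`) and transcriptional (`thetaTxn`) depletion odds, an
#' immunogenicity-biased loss of neoantigens during metastasis
#' (`betaReduction`, a log-odds increment on the drop probability of
#' strong/medium-affinity neoantigenic mutations), and a three-subtype
#' expression structure.
#'
#' @param nPatients number of patients.
#' @param sitesPerPatient list (one element per patient) of site label
#'   vectors drawn from PRIMARY/LYMPH/DISTANT; repeated labels are
#'   multiregion samples. NULL uses [defaultSiteMap()].
#' @param nMutationsMean Poisson mean of somatic mutations per patient pool.
#' @param missenseFraction,frameshiftFraction,otherNonsilentFraction class
#'   mix; the remainder is silent.
#' @param neoantigenicFraction probability a nonsilent mutation yields at
#'   least one predicted binder (affinity < 500 nM).
#' @param epitopesPerMutation Poisson mean of epitopes per neoantigenic
#'   mutation (doubled for frameshift indels).
#' @param affinityLognormParams,fpkmLognormParams,stabilityLognormParams
#'   (meanlog, sdlog) pairs for the per-mutation affinity scale (nM; epitope
#'   affinities scatter lognormally around their mutation's scale), FPKM of
#'   expressed transcripts, and pMHC half-lives (hours).
#' @param thetaCnv copy-loss odds multiplier for neoantigenic mutations:
#'   the true DNA-level depletion odds ratio (> 1 plants depletion).
#' @param thetaTxn expression odds multiplier for neoantigenic mutations:
#'   the true transcriptional depletion odds ratio (< 1 plants depletion).
#' @param betaReduction log-odds increment on the metastatic drop
#'   probability of strong/medium-affinity neoantigenic mutations (0 = no
#'   immunogenicity bias).
#' @param subtypeEffect mean shift (residual-sd units) on a subtype's
#'   signature genes.
#' @param nSignatureGenes signature genes per subtype.
#' @param nBackgroundGenes additional unstructured genes.
#' @param subtypeProbs sampling probabilities of subtypes I/II/III.
#' @param cellFractionDirichlet named Dirichlet concentration vector for
#'   immune-cell fractions.
#' @param tcrPowerlawExponent clone-size power-law exponent (> 1).
#' @param depth sequencing depth per variant (reads).
#' @param purityRange uniform range of tumor purity.
#' @param baseCopyLossRate,baseExpressedRate baseline probabilities of the
#'   copy-loss and expressed attributes for non-neoantigenic mutations.
#' @param dropRate baseline probability a primary variant is lost in a
#'   metastatic sample.
#' @param gainRate expected private-gain mutations in a metastasis, as a
#'   fraction of the primary pool.
#' @param clonalFraction probability a mutation is truly clonal.
#' @param clonalityFlipRate probability a variant retained in a metastasis
#'   flips clonality (clonal to subclonal or vice versa), modelling CCF
#'   drift between sites.
#' @param seed RNG seed; a fixed seed makes the output byte-identical.
#' @return validated config list (class `neoscapeConfig`).
#' @export
cohortConfig <- function(nPatients = 26,
                         sitesPerPatient = NULL,
                         nMutationsMean = 150,
                         missenseFraction = 0.60,
                         frameshiftFraction = 0.05,
                         otherNonsilentFraction = 0.05,
                         neoantigenicFraction = 0.57,
                         epitopesPerMutation = 8,
                         affinityLognormParams = c(log(250), 1.0),
                         fpkmLognormParams = c(1.5, 1.0),
                         stabilityLognormParams = c(log(1.5), 0.9),
                         thetaCnv = 2.0,
                         thetaTxn = 0.5,
                         betaReduction = 1.5,
                         subtypeEffect = 1.5,
                         nSignatureGenes = 50,
                         nBackgroundGenes = 300,
                         subtypeProbs = c(0.2, 0.3, 0.5),
                         cellFractionDirichlet = c(CD8_T = 8, Tregs = 3,
                                                   M1 = 3, M2 = 4, B = 4,
                                                   NK = 3, DC = 2,
                                                   Other = 10),
                         tcrPowerlawExponent = 2.5,
                         depth = 100,
                         purityRange = c(0.4, 0.9),
                         baseCopyLossRate = 0.15,
                         baseExpressedRate = 0.60,
                         dropRate = 0.20,
                         gainRate = 0.15,
                         clonalFraction = 0.60,
                         clonalityFlipRate = 0.10,
                         seed = 1) {
  cfg <- as.list(environment())
  validateConfig(cfg)
  if (is.null(cfg$sitesPerPatient))
    cfg$sitesPerPatient <- defaultSiteMap(cfg$nPatients)
  if (length(cfg$sitesPerPatient) != cfg$nPatients)
    .stopf("invalid config field sitesPerPatient: needs one entry per patient")
  class(cfg) <- "neoscapeConfig"
  cfg
}

validateConfig <- function(cfg) {
  chkFrac <- function(field) {
    v <- cfg[[field]]
    if (!is.numeric(v) || any(v < 0) || any(v > 1))
      .stopf("invalid config field %s: must lie in [0, 1]", field)
  }
  for (f in c("missenseFraction", "frameshiftFraction",
              "otherNonsilentFraction", "neoantigenicFraction",
              "baseCopyLossRate", "baseExpressedRate", "dropRate",
              "clonalFraction", "clonalityFlipRate")) chkFrac(f)
  if (cfg$missenseFraction + cfg$frameshiftFraction +
      cfg$otherNonsilentFraction > 1)
    .stopf("invalid config field missenseFraction: class fractions exceed 1")
  for (f in c("thetaCnv", "thetaTxn"))
    if (!is.numeric(cfg[[f]]) || cfg[[f]] < 0)
      .stopf("invalid config field %s: must be >= 0", f)
  if (cfg$nPatients < 1) .stopf("invalid config field nPatients")
  if (cfg$tcrPowerlawExponent <= 1)
    .stopf("invalid config field tcrPowerlawExponent: must exceed 1")
  if (cfg$depth < 1) .stopf("invalid config field depth")
  if (length(cfg$purityRange) != 2 || any(cfg$purityRange <= 0) ||
      any(cfg$purityRange > 1) || cfg$purityRange[1] > cfg$purityRange[2])
    .stopf("invalid config field purityRange")
  if (abs(sum(cfg$subtypeProbs) - 1) > 1e-8 || length(cfg$subtypeProbs) != 3)
    .stopf("invalid config field subtypeProbs: three values summing to 1")
  invisible(TRUE)
}

#' Default site map for a synthetic cohort
#'
#' Emulates the site structure of a paired-design metastatic cohort: every
#' patient has a primary tumor, the first three patients carry a second
#' primary region (multiregion sampling), roughly the first 60% of patients
#' have a regional lymph-node metastasis and the last ~45% a distant
#' metastasis. At the default 26 patients this yields 29 primary, 16
#' lymph-node and 12 distant-metastasis samples.
#'
#' @param nPatients number of patients.
#' @return list of per-patient site-label vectors.
#' @export
defaultSiteMap <- function(nPatients) {
  nLymph <- round(nPatients * 16 / 26)
  nDistant <- round(nPatients * 12 / 26)
  nMultiregion <- min(3, nPatients)
  lapply(seq_len(nPatients), function(p) {
    sites <- "PRIMARY"
    if (p <= nMultiregion) sites <- c(sites, "PRIMARY")
    if (p <= nLymph) sites <- c(sites, "LYMPH")
    if (p > nPatients - nDistant) sites <- c(sites, "DISTANT")
    sites
  })
}

.randPeptide <- function(n) {
  len <- sample(c(9L, 10L), n, replace = TRUE)
  vapply(len, function(l) paste(sample(.AA, l, replace = TRUE),
                                collapse = ""), character(1))
}

.hlaPool <- c("HLA-A*02:01", "HLA-A*11:01", "HLA-A*24:02", "HLA-B*40:01",
              "HLA-B*46:01", "HLA-B*58:01", "HLA-C*01:02", "HLA-C*03:04",
              "HLA-C*07:02", "HLA-A*33:03")

# odds-scaled Bernoulli probability: base rate r, odds multiplied by theta
.oddsProb <- function(r, theta) {
  o <- r / (1 - r) * theta
  o / (1 + o)
}

# Draw read counts and CCF interval for variants carried by one sample.
.sampleReadData <- function(ccfTrue, inLoss, purity, depth) {
  cn <- ifelse(inLoss, 1, 2)
  denom <- purity * cn + 2 * (1 - purity)
  vafTrue <- ccfTrue * purity / denom
  alt <- rbinom(length(ccfTrue), depth, pmin(vafTrue, 1))
  vafObs <- alt / depth
  ccfHat <- .clamp(vafObs * denom / purity, 0, 1.5)
  se <- 1.96 * sqrt(pmax(vafObs * (1 - vafObs), 1e-4) / depth) * denom / purity
  list(tumor_alt = alt, tumor_ref = depth - alt,
       normal_alt = rbinom(length(ccfTrue), depth, 0.002),
       normal_ref = depth, vaf = vafObs,
       ccf_point = ccfHat,
       ccf_lo = .clamp(ccfHat - se, 0, 1.5),
       ccf_hi = .clamp(ccfHat + se, 0, 1.5))
}

# One patient's mutation pool: identity, class, planted flags, epitopes.
.makeMutationPool <- function(cfg, patientId, n, geneUniverse) {
  if (n == 0) n <- 1
  classProbs <- c(MISSENSE = cfg$missenseFraction,
                  FRAMESHIFT_INDEL = cfg$frameshiftFraction,
                  OTHER_NONSILENT = cfg$otherNonsilentFraction)
  classProbs <- c(classProbs, SILENT = 1 - sum(classProbs))
  lens <- autosomeLengths()
  chrom <- sample(names(lens), n, replace = TRUE,
                  prob = lens / sum(lens))
  pool <- data.frame(
    variant_id = sprintf("%s_v%04d", patientId, seq_len(n)),
    gene = sample(geneUniverse, n, replace = TRUE),
    variant_class = sample(names(classProbs), n, replace = TRUE,
                           prob = classProbs),
    chrom = chrom,
    pos = floor(runif(n, 1, lens[chrom])),
    ref = sample(c("A", "C", "G", "T"), n, replace = TRUE),
    stringsAsFactors = FALSE)
  pool$alt <- vapply(pool$ref, function(r)
    sample(setdiff(c("A", "C", "G", "T"), r), 1), character(1))
  nonsilent <- pool$variant_class != "SILENT"
  pool$is_neoantigenic <- nonsilent &
    runif(n) < cfg$neoantigenicFraction
  pool$in_copy_loss <- runif(n) < .oddsProb(
    cfg$baseCopyLossRate, ifelse(pool$is_neoantigenic, cfg$thetaCnv, 1))
  pool$expressed <- runif(n) < .oddsProb(
    cfg$baseExpressedRate, ifelse(pool$is_neoantigenic, cfg$thetaTxn, 1))
  pool$ccf_true <- ifelse(runif(n) < cfg$clonalFraction, 1,
                          runif(n, 0.2, 0.9))
  pool
}

# Epitopes for one patient's pool: neoantigenic mutations yield >= 1 binder
# (< 500 nM); some non-neoantigenic nonsilent mutations yield decoys
# (>= 500 nM) to exercise the filtering gates. Affinities are correlated
# within a mutation (one mutant peptide region): each mutation draws an
# affinity scale from the configured lognormal and its epitopes scatter
# around it, so mutation-level immunogenicity (best affinity < 150 nM) is a
# genuine split rather than a near-certain event.
.makeEpitopes <- function(cfg, pool, hla) {
  al <- cfg$affinityLognormParams
  rows <- list()
  for (i in which(pool$is_neoantigenic)) {
    mean_e <- cfg$epitopesPerMutation *
      (if (pool$variant_class[i] == "FRAMESHIFT_INDEL") 2 else 1)
    k <- 1 + rpois(1, max(mean_e - 1, 0))
    muMut <- rnorm(1, al[1], al[2])
    aff <- rlnorm(k, muMut, 0.35)
    if (all(aff >= 500)) aff[sample(k, 1)] <- runif(1, 20, 499)
    rows[[length(rows) + 1]] <- data.frame(
      variant_id = pool$variant_id[i], affinity = aff,
      stringsAsFactors = FALSE)
  }
  decoy <- which(!pool$is_neoantigenic & pool$variant_class != "SILENT" &
                   runif(nrow(pool)) < 0.3)
  for (i in decoy) {
    k <- sample(1:3, 1)
    rows[[length(rows) + 1]] <- data.frame(
      variant_id = pool$variant_id[i], affinity = runif(k, 500, 5000),
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) return(NULL)
  ep <- do.call(rbind, rows)
  k <- nrow(ep)
  ep$peptide <- .randPeptide(k)
  ep$hla_allele <- sample(hla, k, replace = TRUE)
  # three predictors whose minimum equals the drawn affinity
  mult <- t(apply(matrix(1 + stats::rexp(k * 2, 1.5), ncol = 2), 1,
                  function(x) sample(c(1, x))))
  ep$netmhc_ic50 <- ep$affinity * mult[, 1]
  ep$netmhcpan_ic50 <- ep$affinity * mult[, 2]
  ep$pickpocket_ic50 <- ep$affinity * mult[, 3]
  sl <- cfg$stabilityLognormParams
  ep$stability_halflife <- rlnorm(k, sl[1], sl[2])
  ep$affinity <- NULL
  ep
}

#' Simulate a synthetic cohort with planted ground truth
#'
#' Generates every input table the downstream analyses consume — somatic
#' variants with read counts and CCF intervals, predicted neoepitopes,
#' a log2(TPM+1) expression matrix with three-subtype signature structure,
#' copy-number segments, immune-cell fractions and TCR clonotypes — for a
#' cohort of paired primary/metastatic samples, together with the planted
#' ground truth (depletion odds, reduction bias, subtypes). Fully
#' deterministic given the config seed.
#'
#' Metastatic samples inherit the patient's primary mutation pool minus
#' biased drops (immunogenic neoantigenic mutations are dropped with odds
#' multiplied by `exp(betaReduction)`) plus private gains; neoantigenic
#' mutations sit in copy-loss regions with odds multiplied by `thetaCnv`
#' and are expressed with odds multiplied by `thetaTxn`.
#'
#' @param config a [cohortConfig()] object.
#' @return a [NeoCohort-class] whose `groundTruth` slot holds the planted
#'   truth (see [groundTruthReport()]).
#' @export
simulateCohort <- function(config = cohortConfig()) {
  if (!inherits(config, "neoscapeConfig"))
    config <- do.call(cohortConfig, config)
  cfg <- config
  set.seed(cfg$seed)

  patientIds <- sprintf("P%02d", seq_len(cfg$nPatients))
  geneUniverse <- sprintf("GENE%04d", 1:5000)
  subtypes <- sample(c("I", "II", "III"), cfg$nPatients, replace = TRUE,
                     prob = cfg$subtypeProbs)
  names(subtypes) <- patientIds

  samples <- do.call(rbind, lapply(seq_len(cfg$nPatients), function(p) {
    sites <- cfg$sitesPerPatient[[p]]
    region <- stats::ave(seq_along(sites), sites, FUN = seq_along)
    abbrev <- c(PRIMARY = "Pri", LYMPH = "Lyn", DISTANT = "Met")[sites]
    data.frame(sample_id = sprintf("%s_%s%d", patientIds[p], abbrev, region),
               patient_id = patientIds[p], site = sites, region = region,
               stringsAsFactors = FALSE)
  }))
  rownames(samples) <- NULL

  variantRows <- list()
  epitopeRows <- list()
  tcrRows <- list()
  segRows <- list()
  truthDrops <- list()
  purity <- setNames(runif(nrow(samples), cfg$purityRange[1],
                           cfg$purityRange[2]), samples$sample_id)
  lens <- autosomeLengths()

  for (p in seq_len(cfg$nPatients)) {
    pid <- patientIds[p]
    smp <- samples[samples$patient_id == pid, , drop = FALSE]
    nPool <- rpois(1, cfg$nMutationsMean)
    pool <- .makeMutationPool(cfg, pid, nPool, geneUniverse)
    hla <- sample(.hlaPool, 4)
    ep <- .makeEpitopes(cfg, pool, hla)
    # mutation-level immunogenicity: best epitope affinity < 150 nM
    immunogenic <- rep(FALSE, nrow(pool))
    if (!is.null(ep)) {
      best <- tapply(pmin(ep$netmhc_ic50, ep$netmhcpan_ic50,
                          ep$pickpocket_ic50), ep$variant_id, min)
      immunogenic <- pool$is_neoantigenic &
        pool$variant_id %in% names(best)[best < 150]
    }
    # fpkm at patient level; small per-sample noise added below
    fl <- cfg$fpkmLognormParams
    fpkmPool <- ifelse(pool$expressed, 1 + rlnorm(nrow(pool), fl[1], fl[2]),
                       runif(nrow(pool), 0, 1))
    # patient-level TCR clonotype pool, shared across the patient's samples
    nTcrPool <- 250
    u <- runif(nTcrPool)
    tcrPool <- data.frame(
      cdr3 = paste0("CASS", .randPeptide(nTcrPool), "F"),
      chain = sample(c("TRA", "TRB"), nTcrPool, replace = TRUE),
      size = pmax(1, floor(u^(-1 / (cfg$tcrPowerlawExponent - 1)))),
      stringsAsFactors = FALSE)

    for (s in seq_len(nrow(smp))) {
      sid <- smp$sample_id[s]
      isPrimary <- smp$site[s] == "PRIMARY"
      if (isPrimary) {
        vars <- pool
        ccf <- pool$ccf_true
      } else {
        dropP <- .oddsProb(cfg$dropRate,
                           ifelse(immunogenic, exp(cfg$betaReduction), 1))
        dropped <- runif(nrow(pool)) < dropP
        vars <- pool[!dropped, , drop = FALSE]
        nGain <- rpois(1, cfg$gainRate * nrow(pool))
        gains <- .makeMutationPool(cfg, paste0(pid, "g", s), nGain,
                                   geneUniverse)
        gainEp <- .makeEpitopes(cfg, gains, hla)
        gainFpkm <- ifelse(gains$expressed,
                           1 + rlnorm(nrow(gains), fl[1], fl[2]),
                           runif(nrow(gains), 0, 1))
        # clonality drift in the metastasis
        flip <- runif(nrow(vars)) < cfg$clonalityFlipRate
        ccf <- ifelse(flip,
                      ifelse(vars$ccf_true == 1, runif(nrow(vars), 0.2, 0.9), 1),
                      vars$ccf_true)
        truthDrops[[length(truthDrops) + 1]] <- data.frame(
          pair_id = paste0(smp$sample_id[1], "|", sid),
          sample_id = sid, patient_id = pid,
          n_dropped = sum(dropped),
          n_dropped_immunogenic = sum(dropped & immunogenic),
          n_gained = nGain, stringsAsFactors = FALSE)
        if (nGain > 0) {
          vars <- rbind(vars, gains)
          ccf <- c(ccf, gains$ccf_true)
          fpkmS <- c(fpkmPool[!dropped], gainFpkm)
          if (!is.null(gainEp)) ep <- rbind(ep, gainEp)
        } else fpkmS <- fpkmPool[!dropped]
      }
      if (isPrimary) fpkmS <- fpkmPool
      rd <- .sampleReadData(ccf, vars$in_copy_loss, purity[sid], cfg$depth)
      variantRows[[length(variantRows) + 1]] <- data.frame(
        sample_id = sid, patient_id = pid,
        variant_id = vars$variant_id, gene = vars$gene,
        variant_class = vars$variant_class, chrom = vars$chrom,
        pos = vars$pos, ref = vars$ref, alt = vars$alt,
        tumor_alt_reads = rd$tumor_alt, tumor_ref_reads = rd$tumor_ref,
        normal_alt_reads = rd$normal_alt, normal_ref_reads = rd$normal_ref,
        vaf = rd$vaf, in_copy_loss = vars$in_copy_loss,
        expressed = vars$expressed, fpkm = fpkmS,
        ccf_point = rd$ccf_point, ccf_lo = rd$ccf_lo, ccf_hi = rd$ccf_hi,
        is_neoantigenic = vars$is_neoantigenic,
        stringsAsFactors = FALSE)
      # epitope rows for this sample's variants
      if (!is.null(ep)) {
        es <- ep[ep$variant_id %in% vars$variant_id, , drop = FALSE]
        if (nrow(es) > 0) {
          fpkmByVar <- setNames(fpkmS, vars$variant_id)
          epitopeRows[[length(epitopeRows) + 1]] <- data.frame(
            sample_id = sid, patient_id = pid,
            variant_id = es$variant_id, peptide = es$peptide,
            hla_allele = es$hla_allele,
            netmhc_ic50 = es$netmhc_ic50,
            netmhcpan_ic50 = es$netmhcpan_ic50,
            pickpocket_ic50 = es$pickpocket_ic50,
            stability_halflife = es$stability_halflife,
            fpkm = unname(fpkmByVar[es$variant_id]),
            stringsAsFactors = FALSE)
        }
      }
      # TCR: each sample observes a subset of the patient pool
      take <- sort(sample(nTcrPool, 150))
      obs <- tcrPool[take, , drop = FALSE]
      tcrRows[[length(tcrRows) + 1]] <- data.frame(
        sample_id = sid, chain = obs$chain, cdr3 = obs$cdr3,
        count = obs$size + rpois(nrow(obs), 0.5), stringsAsFactors = FALSE)
      # copy-number segments: per-sample aberration rate drives wGII
      abRate <- runif(1, 0, 0.4)
      segRows[[length(segRows) + 1]] <- do.call(rbind, lapply(
        names(lens), function(cc) {
          nSeg <- sample(1:3, 1)
          bounds <- sort(c(1, floor(runif(nSeg - 1, 2, lens[cc] - 1)),
                           lens[cc] + 1))
          cn <- ifelse(runif(nSeg) < abRate,
                       sample(c(0, 1, 3, 4), nSeg, replace = TRUE), 2)
          data.frame(sample_id = sid, chrom = cc,
                     start = bounds[-length(bounds)], end = bounds[-1],
                     total_cn = cn, loh = cn <= 1, stringsAsFactors = FALSE)
        }))
    }
  }

  variantsTab <- do.call(rbind, variantRows)
  epitopesTab <- if (length(epitopeRows)) do.call(rbind, epitopeRows)
                 else data.frame()
  rownames(variantsTab) <- NULL
  rownames(epitopesTab) <- NULL

  # expression matrix: immunogram catalog genes + markers + signatures + noise
  catGenes <- unique(unlist(lapply(immunogramCatalog(), `[[`, "genes")))
  sigGenes <- lapply(c(I = "I", II = "II", III = "III"), function(k)
    sprintf("SIG%s_%03d", k, seq_len(cfg$nSignatureGenes)))
  bgGenes <- sprintf("BG%04d", seq_len(cfg$nBackgroundGenes))
  allGenes <- c(catGenes, unlist(sigGenes, use.names = FALSE), bgGenes)
  expr <- matrix(rnorm(length(allGenes) * nrow(samples), 5, 1),
                 nrow = length(allGenes),
                 dimnames = list(allGenes, samples$sample_id))
  for (p in seq_len(cfg$nPatients)) {
    sid <- samples$sample_id[samples$patient_id == patientIds[p]]
    expr[sigGenes[[subtypes[p]]], sid] <-
      expr[sigGenes[[subtypes[p]]], sid] + cfg$subtypeEffect
  }

  conc <- cfg$cellFractionDirichlet
  fr <- matrix(rgamma(nrow(samples) * length(conc),
                      shape = rep(conc, each = nrow(samples))),
               nrow = nrow(samples),
               dimnames = list(samples$sample_id, names(conc)))
  fr <- fr / rowSums(fr)

  pairs <- if (length(truthDrops)) do.call(rbind, truthDrops)
           else data.frame()
  truth <- list(
    config = cfg,
    theta_cnv = cfg$thetaCnv, theta_txn = cfg$thetaTxn,
    beta_reduction = cfg$betaReduction,
    subtype = subtypes,
    purity = purity,
    pairs = pairs)

  new("NeoCohort",
      samples = samples, variants = variantsTab, epitopes = epitopesTab,
      expression = expr, segments = do.call(rbind, segRows),
      cellFractions = fr, tcr = do.call(rbind, tcrRows),
      groundTruth = truth)
}

#' Summarise the planted ground truth of a synthetic cohort
#'
#' @param truth the `groundTruth` list of a simulated [NeoCohort-class]
#'   (or the cohort itself).
#' @return list of data.frames: `samples` (per-sample true depletion odds
#'   ratios), `patients` (true subtype), `pairs` (per primary/metastasis
#'   pair: dropped, immunogenic-dropped and gained counts).
#' @export
groundTruthReport <- function(truth) {
  if (is(truth, "NeoCohort")) truth <- groundTruth(truth)
  if (length(truth) == 0) .stopf("cohort carries no ground truth")
  list(
    samples = data.frame(sample_id = names(truth$purity),
                         true_cnv_or = truth$theta_cnv,
                         true_txn_or = truth$theta_txn,
                         stringsAsFactors = FALSE),
    patients = data.frame(patient_id = names(truth$subtype),
                          true_subtype = unname(truth$subtype),
                          stringsAsFactors = FALSE),
    pairs = truth$pairs)
}
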
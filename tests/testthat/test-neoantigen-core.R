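test_that("neoantigen calling applies the 500 nM and FPKM > 1 gates", {
  ep <- data.frame(variant_id = c("v1", "v2", "v3"),
                   peptide = c("ACDEFGHIK", "ACDEFGHIKL", "MNPQRSTVW"),
                   hla_allele = "HLA-A*02:01",
                   netmhc_ic50 = c(620, 45, 300),
                   netmhcpan_ic50 = c(480, 60, 310),
                   pickpocket_ic50 = c(700, 80, 320),
                   fpkm = c(2.3, 5, 0.8))
  neo <- callNeoantigens(ep)
  expect_equal(neo$variant_id, c("v1", "v2"))      # v3 fails FPKM gate
  expect_equal(neo$best_affinity, c(480, 45))      # min over the predictors
  expect_equal(neo$affinity_class, c("WEAK", "STRONG"))
  # peptide length convention
  ep12 <- transform(ep, peptide = "ACDEFGHIKLMN")
  expect_error(callNeoantigens(ep12), "9- or 10-mers")
  expect_error(callNeoantigens(transform(ep, netmhc_ic50 = -1)), "positive")
  # monotonicity: relaxing either gate never shrinks the called set
  set.seed(11)
  tab <- toyEpitopes(ic50 = exp(runif(80, log(5), log(2000))),
                     fpkm = exp(runif(80, log(0.05), log(50))))
  base <- callNeoantigens(tab)
  wider <- callNeoantigens(tab, affinityGate = 1000)
  expect_true(all(base$variant_id %in% wider$variant_id))
  wider2 <- callNeoantigens(tab, fpkmGate = 0.5)
  expect_true(all(base$variant_id %in% wider2$variant_id))
})

test_that("affinity classes are strict at 50 and 150 nM, stability at 2 h", {
  expect_equal(classifyAffinity(c(45, 49.99, 50, 149, 150, 499)),
               c("STRONG", "STRONG", "MEDIUM", "MEDIUM", "WEAK", "WEAK"))
  expect_error(classifyAffinity(500), "0, 500")
  expect_error(classifyAffinity(0), "0, 500")
  expect_equal(classifyStability(c(3.5, 2.0, 2.001, 0, NA)),
               c("HIGH", "LOW", "HIGH", "LOW", "UNKNOWN"))
  expect_error(classifyStability(-1), "non-negative")
  # every called neoantigen gets exactly one affinity class
  set.seed(5)
  aff <- runif(200, 1, 499)
  cls <- classifyAffinity(aff)
  expect_true(all(cls %in% c("STRONG", "MEDIUM", "WEAK")))
  expect_equal(cls == "STRONG", aff < 50)
  expect_equal(cls == "MEDIUM", aff >= 50 & aff < 150)
})

test_that("yield per mutation and generating fraction follow their definitions", {
  variants <- data.frame(
    variant_id = sprintf("v%02d", 1:15),
    variant_class = rep(c("MISSENSE", "SILENT"), c(10, 5)))
  neo <- data.frame(variant_id = rep(sprintf("v%02d", 1:9),
                                     c(10, 8, 7, 6, 5, 4, 3, 1, 1)))
  y <- neoantigenYield(variants, neo, byClass = "MISSENSE")
  expect_equal(y$yield_per_mutation, 4.5)     # 45 neoantigens / 10 missense
  expect_equal(y$fraction_generating, 0.9)    # 9 of 10 nonsilent
  y0 <- neoantigenYield(variants, neo[0, , drop = FALSE], "MISSENSE")
  expect_equal(y0$yield_per_mutation, 0)
  expect_equal(y0$fraction_generating, 0)
  one <- data.frame(variant_id = variants$variant_id[1:10])
  y1 <- neoantigenYield(variants, one, "MISSENSE")
  expect_equal(y1$yield_per_mutation, 1)
  expect_equal(y1$fraction_generating, 1)
  expect_error(neoantigenYield(variants, neo, byClass = "FRAMESHIFT_INDEL"),
               "undefined")
  # alternative denominator counts only generating mutations
  yg <- neoantigenYield(variants, neo, "MISSENSE",
                        generatingDenominator = "generating")
  expect_equal(yg$yield_per_mutation, 5)      # 45 / 9
})

test_that("sharing statistics match exhaustive enumeration", {
  mk <- function(patient, sample, pep)
    data.frame(patient_id = patient, sample_id = sample, peptide = pep,
               hla_allele = "HLA-A*02:01", stringsAsFactors = FALSE)
  # one patient, identical neoantigen in both samples
  s <- sharingStats(rbind(mk("P1", "a", "AAAAAAAAA"),
                          mk("P1", "b", "AAAAAAAAA")))
  expect_equal(s$within_patient_shared_fraction, 1)
  expect_length(s$cross_patient_shared, 0)
  # all private
  s0 <- sharingStats(rbind(mk("P1", "a", "AAAAAAAAA"),
                           mk("P1", "b", "CCCCCCCCC"),
                           mk("P2", "c", "DDDDDDDDD")))
  expect_equal(s0$within_patient_shared_fraction, 0)
  # three patients with partial overlap: compare to brute force
  df <- rbind(mk("P1", "a", c("AAAAAAAAA", "CCCCCCCCC")),
              mk("P1", "b", c("AAAAAAAAA", "DDDDDDDDD")),
              mk("P2", "c", c("DDDDDDDDD", "EEEEEEEEE")),
              mk("P2", "d", c("EEEEEEEEE")),
              mk("P3", "e", c("FFFFFFFFF")))
  s3 <- sharingStats(df)
  inst <- unique(df[c("patient_id", "sample_id", "peptide")])
  shared <- vapply(seq_len(nrow(inst)), function(i) {
    sum(inst$patient_id == inst$patient_id[i] &
          inst$peptide == inst$peptide[i]) >= 2
  }, logical(1))
  expect_equal(s3$within_patient_shared_fraction, mean(shared))
  byPat <- tapply(df$patient_id, df$peptide,
                  function(p) length(unique(p)))
  expect_setequal(s3$cross_patient_shared,
                  paste(names(byPat)[byPat >= 2], "HLA-A*02:01", sep = "|"))
})

test_that("branch proportion is 1 - |intersection|/|union|", {
  a <- sprintf("k%02d", 1:8)
  b <- sprintf("k%02d", 3:10)   # union 10, intersection 6
  expect_equal(branchProportion(list(a, b)), 0.4)
  # union 10, intersection 4
  expect_equal(branchProportion(list(sprintf("k%02d", 1:8),
                                     sprintf("k%02d", c(1:4, 9, 10)))), 0.6)
  expect_equal(branchProportion(list(a, a, a)), 0)
  expect_equal(branchProportion(list(c("x"), c("y"), c("z"))), 1)
  expect_error(branchProportion(list(character(0), character(0))), "empty")
  expect_error(branchProportion(list(a)), "at least 2")
  # permutation invariance + brute force on random small instances
  set.seed(9)
  for (i in 1:20) {
    sets <- lapply(1:3, function(j) sample(letters, sample(3:10, 1)))
    bp <- branchProportion(sets)
    expect_equal(branchProportion(rev(sets)), bp)
    uni <- unique(unlist(sets))
    inter <- sum(vapply(uni, function(k)
      all(vapply(sets, function(s) k %in% s, logical(1))), logical(1)))
    expect_equal(bp, 1 - inter / length(uni))
  }
})

test_that("clonal TCR proportion counts reads in clones above the cut", {
  one <- data.frame(chain = "TRB", cdr3 = "CASSF", count = 500)
  expect_equal(unname(tcrClonalProportion(one)), 1)
  unif <- data.frame(chain = "TRA", cdr3 = sprintf("C%04d", 1:1000),
                     count = 1)
  expect_equal(unname(tcrClonalProportion(unif)), 0)
  three <- data.frame(chain = "TRB", cdr3 = c("a", "b", "c"),
                      count = c(50, 30, 20))
  expect_equal(unname(tcrClonalProportion(three)), 1)
  expect_error(tcrClonalProportion(
    data.frame(chain = "TRA", cdr3 = "x", count = 0)), "zero total")
})
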
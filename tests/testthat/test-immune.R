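test_that("single-sample enrichment matches the step-by-step oracle", {
  set.seed(13)
  expr <- matrix(rnorm(10, 5, 2), nrow = 5, ncol = 2,
                 dimnames = list(paste0("g", 1:5), c("s1", "s2")))
  set <- c("g2", "g4")
  es <- ssgseaScore(expr, set, normalize = FALSE)
  for (j in 1:2)
    expect_equal(unname(es[j]),
                 ssgseaOracle(expr[, j], rownames(expr), set),
                 tolerance = 1e-12)
  # gene-row permutation invariance
  perm <- sample(5)
  expect_equal(ssgseaScore(expr[perm, ], set, normalize = FALSE), es)
  # monotonicity: a set of top-ranked genes outscores a bottom set
  e2 <- matrix(c(10, 8, 6, 4, 2, 1), ncol = 1,
               dimnames = list(paste0("g", 1:6), "s"))
  top <- ssgseaScore(e2, c("g1", "g2"), normalize = FALSE)
  bottom <- ssgseaScore(e2, c("g5", "g6"), normalize = FALSE)
  expect_gt(top, bottom)
  # raising a set gene's expression above all others raises the score
  e3 <- e2
  e3["g5", 1] <- 100
  expect_gt(ssgseaScore(e3, c("g5", "g6"), normalize = FALSE), bottom)
  expect_error(ssgseaScore(expr, c("g1", "nope")), "fewer|member")
})

test_that("cohort z-scores have mean 0 and population sd 1", {
  z <- cohortZ(c(1, 2, 3))
  expect_equal(z, c(-1.2247, 0, 1.2247), tolerance = 1e-4)
  expect_warning(z0 <- cohortZ(rep(2, 5)), "zero dispersion")
  expect_equal(z0, rep(0, 5))
  set.seed(17)
  x <- rnorm(40, 3, 7)
  z1 <- cohortZ(x)
  expect_equal(mean(z1), 0, tolerance = 1e-12)
  expect_equal(sqrt(mean(z1^2)), 1, tolerance = 1e-12)
  expect_equal(cohortZ(z1), z1, tolerance = 1e-12)   # idempotence
  # sample-sd convention differs by the usual factor
  zs <- cohortZ(x, popsd = FALSE)
  expect_equal(zs * sd(x) / sqrt(mean((x - mean(x))^2)), z1,
               tolerance = 1e-12)
})

test_that("IGS is 3 +/- 1.5 z with display clamped to [1, 5]", {
  expect_equal(igs(0, "STIMULATORY")$igs, 3)
  expect_equal(igs(0, "INHIBITORY")$igs, 3)
  expect_equal(igs(1, "STIMULATORY")$igs, 4.5)
  expect_equal(igs(1, "INHIBITORY")$igs, 1.5)
  r <- igs(2, "STIMULATORY")
  expect_equal(r$igs_raw, 6)
  expect_equal(r$igs, 5)
  r2 <- igs(-2, "STIMULATORY")
  expect_equal(r2$igs_raw, 0)
  expect_equal(r2$igs, 1)
  # orientation flip reflects about 3 (within the clamp range)
  z <- seq(-1.2, 1.2, by = 0.3)
  expect_equal(igs(z, "STIMULATORY")$igs_raw + igs(z, "INHIBITORY")$igs_raw,
               rep(6, length(z)))
})

test_that("antigenicity axis z-scores log-transformed neoantigen loads", {
  expect_warning(a0 <- antigenicityAxis(rep(50, 4)), "zero dispersion")
  expect_equal(a0$igs, rep(3, 4))
  loads <- c(10, 100, 1000)
  a <- antigenicityAxis(loads)
  x <- log10(loads + 1)
  expect_equal(a$z, (x - mean(x)) / sqrt(mean((x - mean(x))^2)),
               tolerance = 1e-12)
  set.seed(23)
  l2 <- sample(20:200, 10)   # distinct loads: max is unambiguous
  a2 <- antigenicityAxis(l2)
  expect_equal(which.max(a2$igs), which.max(l2))
  expect_error(antigenicityAxis(5), ">= 2")
})

test_that("immunogram always yields 8 oriented axes and detects planting", {
  cat <- immunogramCatalog()
  expect_length(cat, 8)
  genes <- unique(unlist(lapply(cat, `[[`, "genes")))
  set.seed(29)
  n <- 12
  expr <- matrix(rnorm(length(genes) * n, 5, 1), nrow = length(genes),
                 dimnames = list(genes, sprintf("s%02d", 1:n)))
  loads <- setNames(rpois(n, 100), colnames(expr))
  ig <- immunogram(expr, loads)
  expect_equal(nrow(ig), 8 * n)
  expect_equal(sort(unique(ig$axis)), 1:8)
  expect_setequal(ig$orientation[ig$axis %in% 1:5], "STIMULATORY")
  expect_setequal(ig$orientation[ig$axis %in% 6:8], "INHIBITORY")
  # planted inflamed sample: T-cell/trafficking axes high, checkpoint low
  inflamedSets <- c(1, 3, 4, 7)
  for (ax in inflamedSets) {
    g <- cat[[ax]]$genes
    expr[g, "s01"] <- expr[g, "s01"] + 4
  }
  ig2 <- immunogram(expr, loads)
  s1 <- ig2[ig2$sample_id == "s01", ]
  expect_true(all(s1$igs[s1$axis %in% c(1, 3, 4)] > 3))
  expect_lt(s1$igs[s1$axis == 7], 3)
  # missing gene set errors with the axis named
  crippled <- expr[!rownames(expr) %in% c("CD80", "CD86", "CD40", "IL12A"), ,
                   drop = FALSE]   # axis 3 left with one gene
  expect_error(immunogram(crippled, loads), "axis 3")
})

test_that("TMIT quadrants split at cohort medians with ties low", {
  cd8a <- c(a = 5, b = 1, c = 5, d = 1)
  pdl1 <- c(a = 6, b = 2, c = 2, d = 6)
  lab <- tmitClassify(cd8a, pdl1)
  expect_equal(unname(lab), c("I", "II", "IV", "III"))
  # labels partition the cohort
  set.seed(37)
  l2 <- tmitClassify(rnorm(20), rnorm(20))
  expect_true(all(l2 %in% c("I", "II", "III", "IV")))
  # exact median values count as low
  l3 <- tmitClassify(c(1, 2, 3), c(1, 2, 3))
  expect_equal(unname(l3[2]), "II")
  expect_error(tmitClassify(c(1, NA), c(1, 2)), "missing")
})

test_that("cell ratios use the pseudocount and never divide by zero", {
  fr <- matrix(c(0.10, 0.05, 0.20, 0.00, 0.65,
                 0.10, 0.10, 0.10, 0.10, 0.60),
               nrow = 2, byrow = TRUE,
               dimnames = list(c("s1", "s2"),
                               c("Tregs", "CD8_T", "M2", "M1", "Other")))
  r <- cellRatios(fr)
  expect_equal(r$treg_cd8_ratio[1], 0.101 / 0.051, tolerance = 1e-12)
  expect_equal(r$m2_m1_ratio[1], 0.201 / 0.001, tolerance = 1e-12)
  expect_equal(r$treg_cd8_ratio[2], 1, tolerance = 1e-2)
  expect_true(all(is.finite(r$m2_m1_ratio)))
  expect_error(cellRatios(fr[, 1:2]), "missing")
})
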
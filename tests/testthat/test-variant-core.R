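test_that("QC filter requires >= 5 alt reads and a significant Fisher test", {
  v <- data.frame(tumor_alt_reads = c(4, 20, 5),
                  tumor_ref_reads = c(96, 80, 95),
                  normal_alt_reads = c(0, 0, 5),
                  normal_ref_reads = c(100, 100, 95))
  keep <- qcFilterVariants(v)
  # 4 alt reads: below the support cut regardless of p
  expect_false(keep[1])
  # 20/80 vs 0/100: enumeration oracle confirms p well under 0.05
  expect_lt(fisherOracle(20, 80, 0, 100), 1e-5)
  expect_true(keep[2])
  # identical compositions: p = 1
  expect_false(keep[3])
  expect_error(qcFilterVariants(transform(v, tumor_alt_reads = -1)),
               "non-negative")
})

test_that("clonality rule: clonal iff the closed CCF interval contains 1", {
  expect_equal(classifyClonality(0.92, 1.04), "CLONAL")
  expect_equal(classifyClonality(0.40, 0.80), "SUBCLONAL")
  expect_equal(classifyClonality(1.00, 1.00), "CLONAL")  # boundary contact
  expect_equal(classifyClonality(1.01, 1.30), "SUBCLONAL")
  expect_error(classifyClonality(1.2, 0.8), "lo > hi")
  # brute-force containment oracle on random intervals
  set.seed(42)
  lo <- runif(200, 0, 1.4)
  hi <- lo + runif(200, 0, 0.6)
  oracle <- ifelse(vapply(seq_along(lo),
                          function(i) lo[i] <= 1 && 1 <= hi[i], logical(1)),
                   "CLONAL", "SUBCLONAL")
  expect_equal(classifyClonality(lo, hi), oracle)
})

test_that("variant tracking partitions the pair union into the three groups", {
  pri <- data.frame(chrom = "1", pos = 1:3, ref = "A", alt = "T",
                    clonality = c("CLONAL", "CLONAL", "SUBCLONAL"))
  met <- data.frame(chrom = "1", pos = c(2, 3, 4), ref = "A", alt = "T",
                    clonality = c("SUBCLONAL", "SUBCLONAL", "CLONAL"))
  tr <- trackVariants(pri, met)
  grp <- setNames(tr$group, tr$key)
  expect_equal(unname(grp["1:1:A:T"]), "REDUCED")     # present only in primary
  expect_equal(unname(grp["1:2:A:T"]), "REDUCED")     # clonal -> subclonal
  expect_equal(unname(grp["1:3:A:T"]), "PERSISTENT")  # subclonal in both
  expect_equal(unname(grp["1:4:A:T"]), "INCREASED")   # metastasis-private
  # duplicate keys rejected
  expect_error(trackVariants(rbind(pri, pri[1, ]), met), "duplicate")
  # property: group labels partition the union on random pairs
  set.seed(7)
  for (i in 1:20) {
    a <- unique(randomVariantSet(30))
    b <- unique(randomVariantSet(30))
    a <- a[!duplicated(paste(a$chrom, a$pos, a$ref, a$alt)), ]
    b <- b[!duplicated(paste(b$chrom, b$pos, b$ref, b$alt)), ]
    tr <- trackVariants(a, b)
    keys <- union(paste(a$chrom, a$pos, a$ref, a$alt, sep = ":"),
                  paste(b$chrom, b$pos, b$ref, b$alt, sep = ":"))
    expect_setequal(tr$key, keys)
    expect_true(all(tr$group %in% c("REDUCED", "INCREASED", "PERSISTENT")))
  }
})

test_that("reduction ratio is (increased - reduced) / primary load", {
  r <- reductionRatio(rep(c("INCREASED", "REDUCED", "PERSISTENT"),
                          c(10, 30, 60)), primaryLoad = 100)
  expect_equal(r$reduction_ratio, -0.20)
  expect_true(r$reduction_flag)
  r2 <- reductionRatio(rep(c("INCREASED", "REDUCED"), c(25, 5)),
                       primaryLoad = 100)
  expect_equal(r2$reduction_ratio, 0.20)
  expect_false(r2$reduction_flag)
  r3 <- reductionRatio(rep(c("INCREASED", "REDUCED"), c(7, 7)),
                       primaryLoad = 50)
  expect_equal(r3$reduction_ratio, 0)
  expect_false(r3$reduction_flag)
  expect_equal(r3$n_persistent + r3$n_reduced + r3$n_increased, 14)
  expect_error(reductionRatio("REDUCED", primaryLoad = 0), "positive")
  expect_error(reductionRatio("GONE", primaryLoad = 10), "unknown group")
})

test_that("MATH score matches its definition and is scale invariant", {
  vafs <- c(0.1, 0.2, 0.3, 0.4, 0.5)
  # median 0.3, scaled MAD 1.4826 * 0.1 = 0.14826 -> 49.42
  expect_equal(mathScore(vafs), 49.42, tolerance = 1e-4)
  expect_equal(mathScore(rep(0.25, 5)), 0)
  expect_equal(mathScore(vafs * 2), mathScore(vafs))
  set.seed(3)
  x <- runif(50, 0.05, 0.6)
  expect_equal(mathScore(x * 3.7), mathScore(x))
  expect_error(mathScore(c(0.1, 0.2)), "at least 3")
  expect_error(mathScore(c(0, 0, 0)), "median")
})

test_that("wGII averages per-autosome aberrant fractions and gates CIN at 0.2", {
  lens <- neoscape::autosomeLengths()
  allNormal <- data.frame(chrom = names(lens), start = 1,
                          end = unname(lens) + 1, total_cn = 2)
  w0 <- wgii(allNormal, ploidy = 2)
  expect_equal(w0$wgii, 0)
  expect_false(w0$cin)
  oneAberrant <- allNormal
  oneAberrant$total_cn[oneAberrant$chrom == "5"] <- 3
  w1 <- wgii(oneAberrant, ploidy = 2)
  expect_equal(w1$wgii, 1 / 22)
  expect_false(w1$cin)
  allAberrant <- transform(allNormal, total_cn = 1)
  w2 <- wgii(allAberrant, ploidy = 2)
  expect_equal(w2$wgii, 1)
  expect_true(w2$cin)
  # monotone non-decreasing as more chromosomes become aberrant
  prev <- 0
  seg <- allNormal
  for (cc in c("1", "7", "13", "21")) {
    seg$total_cn[seg$chrom == cc] <- 4
    w <- wgii(seg, ploidy = 2)$wgii
    expect_gte(w, prev)
    prev <- w
  }
  # bounds checking
  bad <- allNormal
  bad$end[1] <- lens["1"] + 100
  expect_error(wgii(bad, ploidy = 2), "bounds")
  expect_error(wgii(allNormal[-1, ], ploidy = 2), "no segments")
})
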
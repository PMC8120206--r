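test_that("contingency tables match brute-force counting", {
  set.seed(21)
  v <- data.frame(is_neo = runif(60) < 0.4, attr = runif(60) < 0.3)
  tab <- buildTable(v, v$is_neo, v$attr)
  expect_equal(sum(tab), 60L)
  expect_equal(tab["neoantigenic", "attribute"], sum(v$is_neo & v$attr))
  expect_equal(tab["other", "no_attribute"], sum(!v$is_neo & !v$attr))
  # degenerate rows/columns
  allNeo <- buildTable(v, rep(TRUE, 60), v$attr)
  expect_equal(unname(allNeo["other", ]), c(0L, 0L))
  noAttr <- buildTable(v, v$is_neo, rep(FALSE, 60))
  expect_equal(unname(noAttr[, "attribute"]), c(0L, 0L))
  expect_error(buildTable(v[0, ], logical(0), logical(0)), "empty")
  # functional predicates
  tab2 <- buildTable(v, function(d) d$is_neo, function(d) d$attr)
  expect_identical(tab, tab2)
})

test_that("odds ratio, correction, CI and Fisher p match hand computation", {
  r <- oddsRatio(matrix(c(5, 15, 2, 38), 2, byrow = TRUE))
  expect_equal(r@oddsRatio, (5 * 38) / (15 * 2), tolerance = 1e-12)
  expect_false(r@corrected)
  expect_true(r@ci95[1] <= r@oddsRatio && r@oddsRatio <= r@ci95[2])
  # independence: equal row proportions
  r1 <- oddsRatio(matrix(c(10, 30, 20, 60), 2, byrow = TRUE))
  expect_equal(r1@oddsRatio, 1, tolerance = 1e-12)
  expect_equal(r1@pFisher, 1, tolerance = 1e-9)
  # Haldane-Anscombe correction on a zero cell
  r0 <- oddsRatio(matrix(c(0, 10, 5, 35), 2, byrow = TRUE))
  expect_true(r0@corrected)
  expect_equal(r0@oddsRatio, (0.5 * 35.5) / (10.5 * 5.5), tolerance = 1e-12)
  # Woolf CI reproduces the closed form
  expect_equal(r@ci95,
               exp(log(r@oddsRatio) + c(-1, 1) * qnorm(0.975) *
                     sqrt(1/5 + 1/15 + 1/2 + 1/38)),
               tolerance = 1e-12)
  # invariances: row+column double swap preserves; row swap inverts
  set.seed(2)
  for (i in 1:25) {
    m <- matrix(sample(1:40, 4, replace = TRUE), 2)
    orig <- oddsRatio(m)@oddsRatio
    expect_equal(oddsRatio(m[2:1, 2:1])@oddsRatio, orig, tolerance = 1e-12)
    expect_equal(oddsRatio(m[2:1, ])@oddsRatio, 1 / orig, tolerance = 1e-12)
    expect_equal(orig, (m[1,1] * m[2,2]) / (m[1,2] * m[2,1]),
                 tolerance = 1e-12)
  }
})

test_that("Fisher p equals hypergeometric enumeration for small tables", {
  set.seed(31)
  for (i in 1:50) {
    repeat {
      m <- sample(0:15, 4, replace = TRUE)
      if (sum(m) > 0 && sum(m) <= 60) break
    }
    r <- oddsRatio(matrix(m, 2, byrow = TRUE))
    expect_equal(r@pFisher, fisherOracle(m[1], m[2], m[3], m[4]),
                 tolerance = 1e-9)
  }
})

test_that("depletion calls follow odds-ratio direction with optional gate", {
  # construction forcing direction: all neoantigenic expressed, others not
  v <- data.frame(is_neoantigenic = rep(c(TRUE, FALSE), c(20, 20)),
                  in_copy_loss = FALSE,
                  expressed = rep(c(TRUE, FALSE), c(20, 20)))
  call <- depletionCall(v, "s1")
  expect_true(call$determined)
  expect_gt(call$txn_or@oddsRatio, 1)
  expect_false(call$txn_depleted)
  # degenerate sample: one row empty -> UNDETERMINED, not an error
  und <- depletionCall(transform(v, is_neoantigenic = TRUE), "s2")
  expect_false(und$determined)
  expect_true(is.na(und$txn_depleted))
  # significance gate turns a weak direction into a negative call
  v2 <- data.frame(is_neoantigenic = rep(c(TRUE, FALSE), c(10, 10)),
                   in_copy_loss = FALSE,
                   expressed = c(rep(c(TRUE, FALSE), c(4, 6)),
                                 rep(c(TRUE, FALSE), c(5, 5))))
  ungated <- depletionCall(v2, "s3")
  gated <- depletionCall(v2, "s3", significanceGate = TRUE)
  expect_true(ungated$txn_depleted)
  expect_false(gated$txn_depleted)
})

test_that("immunogenicity bias OR compares reduced vs increased groups", {
  red <- data.frame(best_affinity = c(rep(50, 8), rep(300, 2)))
  inc <- data.frame(best_affinity = c(rep(50, 3), rep(300, 7)))
  r <- immunogenicityBiasOR(red, inc)
  expect_equal(r@oddsRatio, (8 * 7) / (2 * 3), tolerance = 1e-12)
  same <- data.frame(best_affinity = c(rep(50, 5), rep(300, 5)))
  expect_equal(immunogenicityBiasOR(same, same)@oddsRatio, 1,
               tolerance = 1e-12)
  expect_error(immunogenicityBiasOR(red[0, , drop = FALSE], inc),
               "non-empty")
  # stability property uses the 2 h cut
  redS <- data.frame(stability_halflife = c(rep(5, 7), rep(1, 3)))
  incS <- data.frame(stability_halflife = c(rep(5, 2), rep(1, 8)))
  rs <- immunogenicityBiasOR(redS, incS, property = "stability")
  expect_equal(rs@oddsRatio, (7 * 8) / (3 * 2), tolerance = 1e-12)
})

test_that("cohort depletion summary reports per-site fractions", {
  mkCall <- function(det, cnv, txn)
    list(determined = det, cnv_depleted = cnv, txn_depleted = txn)
  calls <- list(mkCall(TRUE, TRUE, FALSE), mkCall(TRUE, FALSE, TRUE),
                mkCall(TRUE, FALSE, FALSE), mkCall(TRUE, FALSE, FALSE),
                mkCall(FALSE, NA, NA))
  s <- cohortDepletionSummary(calls, c(rep("PRIMARY", 4), "LYMPH"))
  pri <- s[s$site == "PRIMARY", ]
  expect_equal(pri$cnv_depleted_fraction, 0.25)
  expect_equal(pri$txn_depleted_fraction, 0.25)
  expect_equal(pri$n_determined, 4)
  lym <- s[s$site == "LYMPH", ]
  expect_equal(lym$n_undetermined, 1)
  expect_true(is.na(lym$cnv_depleted_fraction))   # no determined samples
  dis <- s[s$site == "DISTANT", ]
  expect_true(is.na(dis$cnv_depleted_fraction))   # empty site is NA, not 0
  expect_error(cohortDepletionSummary(calls, rep("LIVER", 5)),
               "unknown site")
})
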
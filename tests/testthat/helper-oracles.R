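# Independent oracles used across tests. These deliberately re-derive the
# quantities from first principles (enumeration, explicit loops) rather than
# calling the implementation paths they check.

# Two-sided Fisher exact p by full hypergeometric enumeration over the 2x2
# table with fixed margins: sum the probabilities of all tables no more
# likely than the observed one (same relative tolerance fisher.test uses).
fisherOracle <- function(a, b, c, d) {
  K <- a + b           # row-1 total
  n1 <- a + c          # col-1 total
  N <- a + b + c + d
  xs <- max(0, K - (N - n1)):min(K, n1)
  probs <- vapply(xs, function(x) {
    choose(n1, x) * choose(N - n1, K - x) / choose(N, K)
  }, numeric(1))
  pObs <- probs[xs == a]
  sum(probs[probs <= pObs * (1 + 1e-7)])
}

# Step-by-step single-sample running-sum enrichment, written as an explicit
# walk: rank-normalized weights u = rank/N, genes visited in decreasing
# expression (gene name breaks ties), set genes advance the in-sum by
# u^alpha (normalized), others advance the out-sum by 1/(N - m); score is
# the sum of the pointwise difference.
ssgseaOracle <- function(e, geneNames, setGenes, alpha = 0.25) {
  N <- length(e)
  u <- rank(e, ties.method = "average") / N
  ord <- order(-e, geneNames)
  inSet <- geneNames %in% setGenes
  m <- sum(inSet)
  wsum <- sum(u[inSet]^alpha)
  runIn <- 0; runOut <- 0; score <- 0
  for (i in ord) {
    if (inSet[i]) runIn <- runIn + u[i]^alpha / wsum
    else runOut <- runOut + 1 / (N - m)
    score <- score + (runIn - runOut)
  }
  unname(score)
}

# Small random variant table for property tests.
randomVariantSet <- function(n, prefix = "v") {
  data.frame(
    chrom = as.character(sample(1:22, n, replace = TRUE)),
    pos = sample(1e6, n),
    ref = sample(c("A", "C", "G", "T"), n, replace = TRUE),
    alt = sample(c("A", "C", "G", "T"), n, replace = TRUE),
    clonality = sample(c("CLONAL", "SUBCLONAL"), n, replace = TRUE),
    stringsAsFactors = FALSE)
}

# Minimal epitope table builder.
toyEpitopes <- function(ic50, fpkm, halflife = NA_real_,
                        peptide = NULL) {
  n <- length(ic50)
  if (is.null(peptide))
    peptide <- vapply(seq_len(n), function(i)
      paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], 9,
                   replace = TRUE), collapse = ""), character(1))
  data.frame(variant_id = sprintf("v%03d", seq_len(n)),
             peptide = peptide,
             hla_allele = "HLA-A*02:01",
             netmhc_ic50 = ic50, netmhcpan_ic50 = ic50 * 1.3,
             pickpocket_ic50 = ic50 * 1.7,
             stability_halflife = halflife,
             fpkm = fpkm, stringsAsFactors = FALSE)
}

# A stand-in classifier whose predicted probabilities are fixed, used to
# test the probability-gate logic of predictSubtype in isolation.
fakeForestModel <- function(probMatrix, genes, classes = c("I", "II", "III")) {
  forest <- structure(list(prob = probMatrix), class = "neoscapeFakeForest")
  methods::new("SubtypeModel",
               signatures = stats::setNames(
                 lapply(classes, function(k) genes), classes),
               forest = forest, classes = classes, gate = 0.4,
               training = list(validation_ids = character(0)),
               accuracy = NA_real_)
}

predict.neoscapeFakeForest <- function(object, newdata, type = "prob", ...) {
  object$prob[seq_len(nrow(newdata)), , drop = FALSE]
}
registerS3method("predict", "neoscapeFakeForest",
                 predict.neoscapeFakeForest)
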
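#' Extract per-class signature genes by pairwise rank-sum tests
#'
#' A gene belongs to class k's signature when, against each of the other two
#' classes separately, the Wilcoxon rank-sum test is significant after
#' Benjamini-Hochberg adjustment (within comparison, across genes) and the
#' median expression is higher in k. A gene must beat BOTH other classes,
#' so a gene elevated in two classes is selected for neither.
#'
#' @param expr genes x samples log2(TPM+1) matrix.
#' @param labels per-sample class labels, parallel to `colnames(expr)`;
#'   every class needs >= 3 samples.
#' @param fdr BH-adjusted p cut (default 0.05).
#' @return named list, one character vector of signature genes per class.
#' @export
extractSignature <- function(expr, labels, fdr = 0.05) {
  if (ncol(expr) != length(labels)) .stopf("labels must match expr columns")
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  small <- classes[table(labels)[classes] < 3]
  if (length(small) > 0)
    .stopf("class(es) with fewer than 3 samples: %s",
           paste(small, collapse = ", "))
  # one adjusted p matrix and one median-difference matrix per ordered pair
  pairP <- list()
  pairUp <- list()
  for (k in classes) for (o in setdiff(classes, k)) {
    id <- paste(k, o, sep = ">")
    xk <- expr[, labels == k, drop = FALSE]
    xo <- expr[, labels == o, drop = FALSE]
    p <- vapply(seq_len(nrow(expr)), function(g) {
      suppressWarnings(
        stats::wilcox.test(xk[g, ], xo[g, ], exact = FALSE)$p.value)
    }, numeric(1))
    pairP[[id]] <- stats::p.adjust(p, method = "BH")
    pairUp[[id]] <- apply(xk, 1, stats::median) > apply(xo, 1, stats::median)
  }
  out <- lapply(classes, function(k) {
    others <- setdiff(classes, k)
    hit <- rep(TRUE, nrow(expr))
    for (o in others) {
      id <- paste(k, o, sep = ">")
      hit <- hit & pairP[[id]] < fdr & pairUp[[id]]
    }
    rownames(expr)[hit]
  })
  names(out) <- classes
  out
}

# Stratified train/validation split preserving class proportions.
.stratifiedSplit <- function(labels, trainFraction) {
  idx <- split(seq_along(labels), labels)
  train <- unlist(lapply(idx, function(i) {
    sample(i, max(1, round(length(i) * trainFraction)))
  }), use.names = FALSE)
  sort(train)
}

#' Train a probability-gated random-forest subtype classifier
#'
#' Splits the cohort into a stratified 2/3 training and 1/3 validation set,
#' extracts signature genes on the training set (or uses a supplied list),
#' tunes the random forest's mtry over `iterations` bootstrap resamples of
#' the training set (each candidate evaluated on the out-of-bootstrap
#' samples), fits the final forest, and records held-out validation
#' accuracy. Entirely seed-deterministic.
#'
#' @param expr genes x samples log2(TPM+1) matrix.
#' @param labels per-sample class labels (three classes expected).
#' @param trainFraction fraction of samples in the training set (default 2/3).
#' @param iterations bootstrap resampling iterations for tuning (default 100).
#' @param seed RNG seed.
#' @param signatures optional precomputed signature list (as from
#'   [extractSignature()]); when NULL, extracted from the training split.
#' @param gate probability gate for downstream calls (default 0.4).
#' @param ntree trees in the final forest (default 500; tuning forests use
#'   fewer).
#' @return a [SubtypeModel-class].
#' @export
trainSubtypeModel <- function(expr, labels, trainFraction = 2 / 3,
                              iterations = 100, seed = 1,
                              signatures = NULL, gate = 0.4, ntree = 500) {
  if (ncol(expr) != length(labels)) .stopf("labels must match expr columns")
  labels <- factor(as.character(labels))
  if (nlevels(labels) < 2) .stopf("need at least two classes")
  set.seed(seed)
  trainIdx <- .stratifiedSplit(labels, trainFraction)
  if (nlevels(droplevels(labels[trainIdx])) < nlevels(labels))
    .stopf("a class is absent from the training split; enlarge the cohort")
  if (is.null(signatures))
    signatures <- extractSignature(expr[, trainIdx, drop = FALSE],
                                   labels[trainIdx])
  feat <- unique(unlist(signatures))
  if (length(feat) == 0) .stopf("empty signature; no genes to train on")
  X <- t(expr[feat, , drop = FALSE])
  xtr <- X[trainIdx, , drop = FALSE]
  ytr <- droplevels(labels[trainIdx])
  p <- length(feat)
  cand <- unique(pmax(1, pmin(p, c(floor(sqrt(p) / 2), floor(sqrt(p)),
                                   2 * floor(sqrt(p))))))
  acc <- matrix(NA_real_, nrow = iterations, ncol = length(cand))
  n <- nrow(xtr)
  for (it in seq_len(iterations)) {
    boot <- sample(n, n, replace = TRUE)
    oob <- setdiff(seq_len(n), unique(boot))
    if (length(oob) == 0 || nlevels(droplevels(ytr[boot])) < nlevels(ytr))
      next
    for (ci in seq_along(cand)) {
      rf <- randomForest::randomForest(xtr[boot, , drop = FALSE], ytr[boot],
                                       mtry = cand[ci], ntree = 100)
      pred <- predict(rf, xtr[oob, , drop = FALSE])
      acc[it, ci] <- mean(pred == ytr[oob])
    }
  }
  meanAcc <- colMeans(acc, na.rm = TRUE)
  mtry <- cand[which.max(meanAcc)]
  forest <- randomForest::randomForest(xtr, ytr, mtry = mtry, ntree = ntree)
  valIdx <- setdiff(seq_along(labels), trainIdx)
  valAcc <- if (length(valIdx) > 0) {
    pred <- predict(forest, X[valIdx, , drop = FALSE])
    mean(pred == labels[valIdx])
  } else NA_real_
  new("SubtypeModel",
      signatures = signatures, forest = forest,
      classes = levels(ytr), gate = gate,
      training = list(
        train_ids = colnames(expr)[trainIdx],
        validation_ids = colnames(expr)[valIdx],
        seed = seed, train_fraction = trainFraction,
        iterations = iterations, mtry = mtry,
        tuning_accuracy = setNames(meanAcc, paste0("mtry", cand))),
      accuracy = valAcc)
}

#' Predict a patient's molecular subtype from one or more regions
#'
#' Computes class probabilities per region, averages them over the
#' patient's regions, and assigns the argmax class when the maximum mean
#' probability reaches the model's gate (default 0.4); otherwise the
#' patient is UNCLASSIFIED. Probability ties at the argmax are broken by
#' class order with a warning.
#'
#' @param model a [SubtypeModel-class].
#' @param regionExpr genes x regions matrix (one column per region of one
#'   patient); all signature genes must be present.
#' @param patientId identifier carried into the result.
#' @return list with `patient_id`, `probabilities` (named mean
#'   probabilities), `subtype` (class label or "UNCLASSIFIED"), `regions`.
#' @export
predictSubtype <- function(model, regionExpr, patientId = NA_character_) {
  stopifnot(is(model, "SubtypeModel"))
  if (is.null(dim(regionExpr)))
    regionExpr <- matrix(regionExpr, ncol = 1,
                         dimnames = list(names(regionExpr), "region1"))
  feat <- unique(unlist(model@signatures))
  miss <- setdiff(feat, rownames(regionExpr))
  if (length(miss) > 0)
    .stopf("missing signature gene(s): %s", paste(miss, collapse = ", "))
  X <- t(regionExpr[feat, , drop = FALSE])
  prob <- predict(model@forest, X, type = "prob")
  meanProb <- colMeans(prob)
  top <- which(meanProb == max(meanProb))
  if (length(top) > 1)
    warning("probability tie; broken by class order ",
            paste(model@classes, collapse = " < "))
  label <- if (max(meanProb) >= model@gate) names(meanProb)[top[1]]
           else "UNCLASSIFIED"
  list(patient_id = patientId, probabilities = meanProb, subtype = label,
       regions = colnames(regionExpr))
}
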
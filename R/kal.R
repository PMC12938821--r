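#' @include chemstore.R
NULL

#' Assemble a KAL training set
#'
#' Pools target-family positives against all other-family ligands plus a
#' seeded uniform subsample of a drug-like background pool, the subsample
#' sized to keep the background from overwhelming the minority positive
#' class. All pools are deduplicated by canonical SMILES; molecules that
#' occur in the positive class are removed from the negatives (the removal
#' count is logged in the assembly).
#'
#' @param positives \linkS4class{MoleculeSet} of target-family ligands.
#' @param kinaseNegatives \linkS4class{MoleculeSet} of other-family ligands
#'   (all retained).
#' @param backgroundPool \linkS4class{MoleculeSet} of background molecules.
#' @param backgroundN size of the background subsample; NULL uses the
#'   whole deduplicated pool.
#' @param positiveClass,negativeClass class labels.
#' @param seed subsample seed.
#' @return a \linkS4class{TrainingAssembly}.
#' @export
assembleTrainingSet <- function(positives, kinaseNegatives, backgroundPool,
                                backgroundN = NULL,
                                positiveClass = "positive",
                                negativeClass = "negative", seed = 1L) {
  dedup <- function(m) m[!duplicated(smiles(m))]
  positives <- dedup(positives)
  kinaseNegatives <- dedup(kinaseNegatives)
  backgroundPool <- dedup(backgroundPool)
  posSmi <- smiles(positives)

  inPos <- smiles(kinaseNegatives) %in% posSmi
  kinaseNegatives <- kinaseNegatives[!inPos]
  bgInPos <- smiles(backgroundPool) %in% posSmi |
    smiles(backgroundPool) %in% smiles(kinaseNegatives)
  backgroundPool <- backgroundPool[!bgInPos]
  backgroundN <- backgroundN %||% length(backgroundPool)
  if (length(backgroundPool) < backgroundN) {
    stop(sprintf("background pool (%d) smaller than requested subsample (%d)",
                 length(backgroundPool), backgroundN))
  }
  bg <- withSeed(seed,
                 backgroundPool[sample.int(length(backgroundPool),
                                           backgroundN)])
  mols <- c(positives, kinaseNegatives, bg)
  labels <- factor(rep(c(positiveClass, negativeClass),
                       c(length(positives),
                         length(kinaseNegatives) + length(bg))),
                   levels = c(negativeClass, positiveClass))
  new("TrainingAssembly", molecules = mols, labels = labels,
      positiveClass = positiveClass, seed = as.integer(seed),
      log = list(nPositive = length(positives),
                 nKinaseNegative = length(kinaseNegatives),
                 nBackground = length(bg),
                 overlapRemoved = sum(inPos) + sum(bgInPos)))
}

# descriptor matrix for training/scoring; drops failed rows with their index
.kalDescriptors <- function(mols) {
  desc <- computeDescriptors(mols)
  status <- attr(desc, "status")
  ok <- status == "ok"
  list(x = as.matrix(desc[ok, descriptorNames(), drop = FALSE]), ok = ok)
}

#' Train the KAL random-forest classifier
#'
#' Fits a random forest on the 20-descriptor panel. In binary mode the
#' positive class is the target family and the score is the forest's
#' positive-class vote fraction; multiclass mode fits one forest over all
#' family labels with the same descriptors. Defaults: 500 trees, unlimited
#' depth, sqrt(p) candidate features per split, fixed seed. Evaluation is
#' stratified k-fold cross-validation with pooled predictions by default;
#' a "resubstitution" mode re-scores the training set instead.
#'
#' @param x a \linkS4class{TrainingAssembly}, or a
#'   \linkS4class{MoleculeSet} with \code{labels} supplied.
#' @param labels factor of class labels (ignored for assemblies).
#' @param positiveClass positive class for binary scoring/metrics; defaults
#'   to the assembly's positive class or the last factor level.
#' @param ntree,mtry random-forest hyperparameters.
#' @param evaluation "cv", "resubstitution" or "none".
#' @param folds number of CV folds.
#' @param seed training seed.
#' @return a \linkS4class{KalModel}; the evaluation slot holds pooled
#'   scores, a \code{\link{classificationMetrics}} report and the ROC-AUC.
#' @export
trainKal <- function(x, labels = NULL, positiveClass = NULL, ntree = 500L,
                     mtry = NULL, evaluation = c("cv", "resubstitution",
                                                 "none"),
                     folds = 5L, seed = 1L) {
  evaluation <- match.arg(evaluation)
  if (is(x, "TrainingAssembly")) {
    labels <- x@labels
    positiveClass <- positiveClass %||% x@positiveClass
    mols <- x@molecules
  } else {
    mols <- x
    stopifnot(!is.null(labels))
    labels <- as.factor(labels)
  }
  if (nlevels(droplevels(labels)) < 2L) {
    stop("training labels contain a single class")
  }
  labels <- droplevels(labels)
  positiveClass <- positiveClass %||% levels(labels)[nlevels(labels)]
  mode <- if (nlevels(labels) == 2L) "binary" else "multiclass"

  kd <- .kalDescriptors(mols)
  if (!all(kd$ok)) {
    warning(sprintf("%d molecules dropped (descriptor failure)",
                    sum(!kd$ok)))
  }
  xmat <- kd$x
  y <- labels[kd$ok]
  mtry <- mtry %||% max(1L, floor(sqrt(ncol(xmat))))

  forest <- withSeed(seed,
    randomForest::randomForest(x = xmat, y = y, ntree = ntree, mtry = mtry,
                               importance = FALSE))

  ev <- list(method = "none")
  if (evaluation == "resubstitution") {
    prob <- stats::predict(forest, xmat, type = "prob")
    pred <- factor(colnames(prob)[max.col(prob, ties.method = "first")],
                   levels = levels(y))
    ev <- .kalEvaluation("resubstitution", y, pred, prob, positiveClass)
  } else if (evaluation == "cv") {
    cvres <- withSeed(spawnSeed(seed, "cv"),
                      .kalCrossValidate(xmat, y, folds, ntree, mtry))
    ev <- .kalEvaluation(sprintf("%d-fold CV", folds), y, cvres$pred,
                         cvres$prob, positiveClass)
  }

  new("KalModel", forest = forest, featureNames = colnames(xmat),
      mode = mode, positiveClass = positiveClass,
      classLevels = levels(y), evaluation = ev, seed = as.integer(seed))
}

# stratified k-fold CV with pooled out-of-fold predictions
.kalCrossValidate <- function(xmat, y, folds, ntree, mtry) {
  foldId <- integer(length(y))
  for (cl in levels(y)) {
    idx <- which(y == cl)
    foldId[idx] <- sample(rep_len(seq_len(folds), length(idx)))
  }
  prob <- matrix(NA_real_, length(y), nlevels(y),
                 dimnames = list(NULL, levels(y)))
  for (f in seq_len(folds)) {
    tr <- foldId != f
    fit <- randomForest::randomForest(x = xmat[tr, , drop = FALSE],
                                      y = y[tr], ntree = ntree,
                                      mtry = mtry)
    prob[!tr, ] <- stats::predict(fit, xmat[!tr, , drop = FALSE],
                                  type = "prob")
  }
  pred <- factor(colnames(prob)[max.col(prob, ties.method = "first")],
                 levels = levels(y))
  list(pred = pred, prob = prob)
}

.kalEvaluation <- function(method, y, pred, prob, positiveClass) {
  metrics <- classificationMetrics(y, pred)
  auc <- if (positiveClass %in% colnames(prob) && nlevels(y) == 2L) {
    rocAuc(y == positiveClass, prob[, positiveClass])
  } else NULL
  list(method = method, truth = y, pred = pred, scores = prob,
       metrics = metrics, auc = auc)
}

#' @describeIn trainKal score molecules with a trained model: the forest
#'   vote fraction for the positive class (binary) or the per-class vote
#'   matrix (multiclass). Molecules whose descriptors cannot be computed
#'   score NA with a warning.
#' @param model a \linkS4class{KalModel}.
#' @param ... unused.
#' @export
setMethod("kalScore", "KalModel", function(model, x, ...) {
  if (is.character(x)) x <- MoleculeSet(x)
  kd <- .kalDescriptors(x)
  if (!all(kd$ok)) {
    warning(sprintf("%d molecules could not be scored (descriptor failure)",
                    sum(!kd$ok)))
  }
  colnames(kd$x) <- model@featureNames
  if (model@mode == "binary") {
    out <- rep(NA_real_, length(kd$ok))
    if (nrow(kd$x)) {
      prob <- stats::predict(model@forest, kd$x, type = "prob")
      out[kd$ok] <- prob[, model@positiveClass]
    }
    out
  } else {
    out <- matrix(NA_real_, length(kd$ok), length(model@classLevels),
                  dimnames = list(NULL, model@classLevels))
    if (nrow(kd$x)) {
      out[kd$ok, ] <- stats::predict(model@forest, kd$x, type = "prob")
    }
    out
  }
})

#' @describeIn trainKal ranked Gini feature importances (mean decrease in
#'   node impurity), normalized to sum to one and sorted descending.
#' @export
setMethod("featureImportances", "KalModel", function(model, ...) {
  imp <- randomForest::importance(model@forest, type = 2L)[, 1L]
  imp <- imp / sum(imp)
  ord <- order(imp, decreasing = TRUE)
  data.frame(feature = names(imp)[ord], importance = unname(imp[ord]),
             stringsAsFactors = FALSE)
})

#' Classification metrics report
#'
#' Per-class precision, recall, F1 and support computed one-vs-rest from
#' the confusion matrix, plus accuracy, macro averages (unweighted class
#' means) and weighted averages (support-weighted means):
#' accuracy = (TP + TN) / all, precision = TP / (TP + FP),
#' recall = TP / (TP + FN), F1 = 2 P R / (P + R). Divisions by zero yield
#' 0. Labels present in the predictions but not in the truth are counted
#' with zero support (with a warning).
#'
#' @param truth,predicted equal-length label vectors (coerced to factors
#'   over the union of their levels).
#' @return object of class \code{kalMetrics}: list with \code{perClass}
#'   data.frame, \code{accuracy}, \code{macro}, \code{weighted},
#'   \code{nobs} and the confusion \code{table}.
#' @export
classificationMetrics <- function(truth, predicted) {
  if (!length(truth)) stop("empty input")
  if (length(truth) != length(predicted)) stop("label lengths differ")
  lev <- union(levels(as.factor(truth)), levels(as.factor(predicted)))
  truth <- factor(truth, levels = lev)
  predicted <- factor(predicted, levels = lev)
  if (any(!as.character(unique(predicted)) %in% as.character(unique(truth)))) {
    warning("predicted labels absent from truth counted with zero support")
  }
  cm <- table(truth = truth, predicted = predicted)
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  safeDiv <- function(a, b) ifelse(b == 0, 0, a / b)
  precision <- safeDiv(tp, tp + fp)
  recall <- safeDiv(tp, tp + fn)
  f1 <- safeDiv(2 * precision * recall, precision + recall)
  support <- rowSums(cm)
  perClass <- data.frame(class = lev, precision = unname(precision),
                         recall = unname(recall), f1 = unname(f1),
                         support = unname(as.integer(support)),
                         stringsAsFactors = FALSE)
  w <- support / sum(support)
  structure(list(
    perClass = perClass,
    accuracy = sum(tp) / length(truth),
    macro = c(precision = mean(precision), recall = mean(recall),
              f1 = mean(f1)),
    weighted = c(precision = sum(w * precision), recall = sum(w * recall),
                 f1 = sum(w * f1)),
    nobs = length(truth), table = cm), class = "kalMetrics")
}

#' @export
print.kalMetrics <- function(x, ...) {
  cat("Classification metrics (", x$nobs, " samples)\n", sep = "")
  print(transform(x$perClass, precision = round(precision, 3),
                  recall = round(recall, 3), f1 = round(f1, 3)))
  cat(sprintf("accuracy %.3f | macro F1 %.3f | weighted F1 %.3f\n",
              x$accuracy, x$macro["f1"], x$weighted["f1"]))
  invisible(x)
}

#' Rank-probability ROC-AUC
#'
#' The probability that a randomly chosen positive receives a higher score
#' than a randomly chosen negative, with ties counted half (the
#' Mann-Whitney statistic divided by n+ n-).
#'
#' @param truth logical vector (or two-level factor with \code{positive}
#'   naming the positive level).
#' @param scores numeric scores.
#' @param positive positive level when \code{truth} is a factor.
#' @return AUC in [0, 1].
#' @export
rocAuc <- function(truth, scores, positive = NULL) {
  if (!is.logical(truth)) {
    truth <- as.factor(truth)
    positive <- positive %||% levels(truth)[nlevels(truth)]
    truth <- truth == positive
  }
  stopifnot(length(truth) == length(scores))
  nPos <- sum(truth); nNeg <- sum(!truth)
  if (nPos == 0L || nNeg == 0L) {
    stop("AUC undefined: both classes must be present")
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[truth]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}
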
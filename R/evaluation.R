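#' @include model.R
NULL

#' Tally a binary confusion matrix
#'
#' @param labels True labels (\code{"positive"}/\code{"negative"}, 0/1 or
#'   logical).
#' @param predictions Predicted labels, same encoding and length.
#' @return A \linkS4class{ConfusionCounts}.
#' @examples
#' confusionCounts(c(1, 1, 0, 0), c(1, 1, 0, 0))
#' @export
confusionCounts <- function(labels, predictions) {
  y <- .asLabel01(labels)
  p <- .asLabel01(predictions)
  .stopIfNot(length(y) == length(p) && length(y) >= 1L,
             "labels and predictions must have equal, positive length")
  new("ConfusionCounts",
      TP = sum(y == 1L & p == 1L), FP = sum(y == 0L & p == 1L),
      TN = sum(y == 0L & p == 0L), FN = sum(y == 1L & p == 0L))
}

setMethod("show", "ConfusionCounts", function(object) {
  cat(sprintf("ConfusionCounts: TP=%d FP=%d TN=%d FN=%d (n=%d)\n",
              object@TP, object@FP, object@TN, object@FN,
              object@TP + object@FP + object@TN + object@FN))
})

#' Scalar metrics from confusion counts
#'
#' Computes accuracy, precision, recall (true-positive rate), F1, the
#' Matthews correlation coefficient and the false-positive rate:
#' \deqn{\mathrm{acc} = \frac{TP+TN}{TP+FP+TN+FN},\quad
#'       \mathrm{prec} = \frac{TP}{TP+FP},\quad
#'       \mathrm{rec} = \frac{TP}{TP+FN},}
#' \deqn{F_1 = \frac{2\,\mathrm{prec}\,\mathrm{rec}}
#'                  {\mathrm{prec}+\mathrm{rec}},\quad
#'       \mathrm{MCC} = \frac{TP\cdot TN - FP\cdot FN}
#'         {\sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}},\quad
#'       \mathrm{FPR} = \frac{FP}{FP+TN}.}
#' Any metric whose denominator is zero is reported as 0 and flagged in the
#' \code{"zeroDenominator"} attribute (degenerate folds in ablation runs can
#' produce such tables).
#'
#' @param counts A \linkS4class{ConfusionCounts}.
#' @return Named numeric vector (accuracy, precision, recall, f1, mcc, fpr)
#'   with attribute \code{zeroDenominator} naming the flagged metrics.
#' @export
metricsFromConfusion <- function(counts) {
  stopifnot(is(counts, "ConfusionCounts"))
  tp <- as.numeric(counts@TP); fp <- as.numeric(counts@FP)
  tn <- as.numeric(counts@TN); fn <- as.numeric(counts@FN)
  total <- tp + fp + tn + fn
  .stopIfNot(total > 0, "all counts are zero")
  flagged <- character(0)
  safeDiv <- function(num, den, name) {
    if (den == 0) {
      flagged <<- c(flagged, name)
      0
    } else {
      num / den
    }
  }
  acc <- (tp + tn) / total
  prec <- safeDiv(tp, tp + fp, "precision")
  rec <- safeDiv(tp, tp + fn, "recall")
  f1 <- safeDiv(2 * prec * rec, prec + rec, "f1")
  mccDen <- sqrt((tp + fp) * (tp + fn)) * sqrt((tn + fp) * (tn + fn))
  mcc <- safeDiv(tp * tn - fp * fn, mccDen, "mcc")
  fpr <- safeDiv(fp, fp + tn, "fpr")
  out <- c(accuracy = acc, precision = prec, recall = rec, f1 = f1,
           mcc = mcc, fpr = fpr)
  attr(out, "zeroDenominator") <- flagged
  out
}

#' ROC and PR curves with AUC and AUPR
#'
#' Sweeps the decision threshold over the distinct scores in descending
#' order (tied scores are grouped into one operating point). AUC is the
#' trapezoidal area under the (FPR, TPR) curve; AUPR is the step-wise
#' (average-precision) area under the (recall, precision) curve.
#'
#' @param labels True labels (both classes must be present).
#' @param scores Numeric classification scores (higher = more positive).
#' @return List: \code{roc} (data.frame threshold/fpr/tpr), \code{pr}
#'   (data.frame threshold/recall/precision), \code{auc}, \code{aupr}.
#' @export
rocPrCurves <- function(labels, scores) {
  y <- .asLabel01(labels)
  .stopIfNot(length(y) == length(scores), "labels/scores length mismatch")
  nPos <- sum(y == 1L)
  nNeg <- sum(y == 0L)
  if (nPos == 0L || nNeg == 0L)
    stop("both classes must be present: AUC/AUPR are undefined otherwise",
         call. = FALSE)
  o <- order(scores, decreasing = TRUE)
  ys <- y[o]
  ss <- scores[o]
  # last index of each tie group
  grpEnd <- which(c(ss[-length(ss)] != ss[-1], TRUE))
  cumTP <- cumsum(ys)[grpEnd]
  cumFP <- cumsum(1L - ys)[grpEnd]
  tpr <- cumTP / nPos
  fpr <- cumFP / nNeg
  prec <- cumTP / (cumTP + cumFP)
  auc <- sum(diff(c(0, fpr)) * (tpr + c(0, tpr[-length(tpr)])) / 2)
  aupr <- sum(diff(c(0, tpr)) * prec)
  list(roc = data.frame(threshold = c(Inf, ss[grpEnd]),
                        fpr = c(0, fpr), tpr = c(0, tpr)),
       pr = data.frame(threshold = ss[grpEnd], recall = tpr,
                       precision = prec),
       auc = auc, aupr = aupr)
}

#' Stratified k-fold partition
#'
#' Splits indices 1..n into k disjoint folds, stratified by class: within
#' each class the (seeded) shuffled indices are dealt round-robin, so per
#' fold the class counts deviate from the global proportions by at most one
#' sample.
#'
#' @param n Number of samples.
#' @param k Number of folds (>= 2).
#' @param labels Class labels of the n samples.
#' @param seed Integer seed.
#' @return List of k integer index vectors (union = 1..n, pairwise
#'   disjoint).
#' @export
kFoldSplit <- function(n, k, labels, seed) {
  .stopIfNot(k >= 2L, "k must be >= 2")
  .stopIfNot(n >= k, "need at least k samples")
  .stopIfNot(length(labels) == n, "one label per sample is required")
  classes <- split(seq_len(n), labels)
  small <- names(classes)[vapply(classes, length, 1L) < k]
  if (length(small))
    stop(sprintf("class '%s' has fewer than k = %d members", small[1], k),
         call. = FALSE)
  folds <- vector("list", k)
  .withSeed(.mixSeed(seed, 41L), {
    for (cl in classes) {
      shuffled <- sample(cl)
      assign <- rep(seq_len(k), length.out = length(shuffled))
      for (f in seq_len(k)) {
        folds[[f]] <- c(folds[[f]], shuffled[assign == f])
      }
    }
  })
  lapply(folds, sort)
}

#' k-fold cross-validation of the hybrid classifier
#'
#' Trains one model per fold on the remaining folds and evaluates it on the
#' held-out fold (decision threshold 0.5; the whole fold is the evaluation
#' batch in the faithful token mode), collecting scalar metrics and ROC/PR
#' curves per fold and their across-fold arithmetic means.
#'
#' @param embeddings \linkS4class{EmbeddingSet} or feature matrix.
#' @param y Labels aligned with the embedding rows.
#' @param config A \linkS4class{ModelConfig}.
#' @param k Number of folds.
#' @param seed Seed for the fold split and per-fold model seeds.
#' @param folds Optional precomputed fold index list (e.g. shared across
#'   ablation variants for paired comparison); overrides \code{k}/
#'   \code{seed}.
#' @return A \linkS4class{FoldReport}.
#' @export
crossValidate <- function(embeddings, y, config, k = 5L, seed = 1L,
                          folds = NULL) {
  if (is(embeddings, "EmbeddingSet")) embeddings <- featureMatrix(embeddings)
  embeddings <- as.matrix(embeddings)
  y01 <- .asLabel01(y)
  if (is.null(folds))
    folds <- kFoldSplit(nrow(embeddings), k, y01, seed)
  k <- length(folds)
  rows <- vector("list", k)
  curves <- vector("list", k)
  for (f in seq_len(k)) {
    testIdx <- folds[[f]]
    trainIdx <- setdiff(seq_len(nrow(embeddings)), testIdx)
    cfgF <- config
    cfgF@seed <- .mixSeed(config@seed, 1000L + f)
    fit <- trainModel(embeddings[trainIdx, , drop = FALSE], y01[trainIdx],
                      cfgF)
    prob <- predictProba(fit, embeddings[testIdx, , drop = FALSE])
    pred <- as.integer(prob >= 0.5)
    mets <- metricsFromConfusion(confusionCounts(y01[testIdx], pred))
    cur <- rocPrCurves(y01[testIdx], prob)
    rows[[f]] <- data.frame(fold = f, accuracy = mets[["accuracy"]],
                            precision = mets[["precision"]],
                            recall = mets[["recall"]], f1 = mets[["f1"]],
                            mcc = mets[["mcc"]], auc = cur$auc,
                            aupr = cur$aupr)
    curves[[f]] <- list(roc = cur$roc, pr = cur$pr)
  }
  foldsDf <- do.call(rbind, rows)
  metricCols <- setdiff(colnames(foldsDf), "fold")
  aggregate <- colMeans(foldsDf[, metricCols])
  new("FoldReport", folds = foldsDf, curves = curves,
      aggregate = aggregate, nFolds = as.integer(k))
}

#' Per-fold metrics of a FoldReport
#' @param report A \linkS4class{FoldReport}.
#' @return data.frame with one row per fold.
#' @export
foldMetrics <- function(report) report@folds

#' Across-fold mean metrics of a FoldReport
#' @param report A \linkS4class{FoldReport}.
#' @return Named numeric vector.
#' @export
aggregateMetrics <- function(report) report@aggregate

#' Per-fold ROC/PR curve points of a FoldReport
#' @param report A \linkS4class{FoldReport}.
#' @return List (one element per fold) of lists with \code{roc} and
#'   \code{pr} data.frames.
#' @export
foldCurves <- function(report) report@curves

setMethod("show", "FoldReport", function(object) {
  cat(sprintf("FoldReport over %d folds; across-fold means:\n",
              object@nFolds))
  print(round(object@aggregate, 4))
})

#' Serialize a FoldReport to JSON plus curve TSVs
#'
#' Writes \code{report.json} (per-fold and aggregate metrics) and, per fold,
#' \code{roc_fold<f>.tsv} / \code{pr_fold<f>.tsv} curve files suitable for
#' plotting.
#'
#' @param report A \linkS4class{FoldReport}.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the path of the JSON file.
#' @export
serializeFoldReport <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  jsonPath <- file.path(dir, "report.json")
  jsonlite::write_json(
    list(folds = foldMetrics(report),
         aggregate = as.list(aggregateMetrics(report))),
    jsonPath, auto_unbox = TRUE, digits = NA)
  for (f in seq_len(report@nFolds)) {
    utils::write.table(report@curves[[f]]$roc,
                       file.path(dir, sprintf("roc_fold%d.tsv", f)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(report@curves[[f]]$pr,
                       file.path(dir, sprintf("pr_fold%d.tsv", f)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(jsonPath)
}
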
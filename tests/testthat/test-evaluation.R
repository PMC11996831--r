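test_that("confusion tallies match a per-element loop count", {
  cc <- confusionCounts(c(1, 1, 0, 0), c(1, 1, 0, 0))
  expect_equal(c(cc@TP, cc@TN, cc@FP, cc@FN), c(2L, 2L, 0L, 0L))
  cc2 <- confusionCounts(c(1, 0), c(0, 1))
  expect_equal(c(cc2@FN, cc2@FP, cc2@TP, cc2@TN), c(1L, 1L, 0L, 0L))
  expect_error(confusionCounts(c(1, 0), c(1, 0, 1)), "length")

  y <- ProtFuse:::.withSeed(50L, rbinom(1000, 1, 0.4))
  p <- ProtFuse:::.withSeed(51L, rbinom(1000, 1, 0.5))
  cc3 <- confusionCounts(y, p)
  tp <- 0L; fp <- 0L; tn <- 0L; fn <- 0L
  for (i in seq_along(y)) {
    if (y[i] == 1 && p[i] == 1) tp <- tp + 1L
    if (y[i] == 0 && p[i] == 1) fp <- fp + 1L
    if (y[i] == 0 && p[i] == 0) tn <- tn + 1L
    if (y[i] == 1 && p[i] == 0) fn <- fn + 1L
  }
  expect_equal(c(cc3@TP, cc3@FP, cc3@TN, cc3@FN), c(tp, fp, tn, fn))
  expect_equal(cc3@TP + cc3@FP + cc3@TN + cc3@FN, 1000L)
})

test_that("scalar metrics reproduce hand-computed values", {
  perfect <- metricsFromConfusion(
    new("ConfusionCounts", TP = 5L, FP = 0L, TN = 5L, FN = 0L))
  expect_equal(unname(perfect[c("accuracy", "precision", "recall", "f1",
                                "mcc")]), rep(1, 5))
  expect_equal(perfect[["fpr"]], 0)

  m <- metricsFromConfusion(
    new("ConfusionCounts", TP = 3L, FP = 1L, TN = 4L, FN = 2L))
  expect_equal(m[["precision"]], 0.75)
  expect_equal(m[["recall"]], 0.6)
  expect_equal(m[["accuracy"]], 0.7)
})

test_that("metrics agree with the formula oracle on random tables", {
  set.seed(52)
  for (rep in 1:1000) {
    counts <- as.integer(rmultinom(1, sample(1:200, 1), rep(0.25, 4)))
    cc <- new("ConfusionCounts", TP = counts[1], FP = counts[2],
              TN = counts[3], FN = counts[4])
    got <- metricsFromConfusion(cc)
    want <- oracleMetrics(counts[1], counts[2], counts[3], counts[4])
    expect_equal(unname(got[names(want)]), unname(want), tolerance = 1e-12)
    expect_true(all(got[c("accuracy", "precision", "recall", "f1",
                          "fpr")] >= 0 &
                    got[c("accuracy", "precision", "recall", "f1",
                          "fpr")] <= 1))
    expect_true(got[["mcc"]] >= -1 && got[["mcc"]] <= 1)
  }
})

test_that("swapping the class convention mirrors MCC's sign", {
  cc <- new("ConfusionCounts", TP = 30L, FP = 10L, TN = 25L, FN = 5L)
  swapped <- new("ConfusionCounts", TP = 25L, FP = 5L, TN = 30L, FN = 10L)
  m1 <- metricsFromConfusion(cc)[["mcc"]]
  m2 <- metricsFromConfusion(swapped)[["mcc"]]
  expect_equal(m1, m2)   # relabelling both classes keeps MCC
  # inverting the predictions negates the numerator
  inverted <- new("ConfusionCounts", TP = 5L, FP = 25L, TN = 10L, FN = 30L)
  expect_equal(metricsFromConfusion(inverted)[["mcc"]], -m1)
})

test_that("zero-denominator metrics return 0 with a flag", {
  cc <- new("ConfusionCounts", TP = 0L, FP = 0L, TN = 10L, FN = 0L)
  m <- metricsFromConfusion(cc)
  expect_equal(m[["precision"]], 0)
  expect_equal(m[["recall"]], 0)
  expect_true(all(c("precision", "recall") %in%
                  attr(m, "zeroDenominator")))
  expect_error(metricsFromConfusion(
    new("ConfusionCounts", TP = 0L, FP = 0L, TN = 0L, FN = 0L)), "zero")
})

test_that("F1 is the harmonic mean and vanishes exactly when TP = 0", {
  set.seed(53)
  for (rep in 1:200) {
    counts <- as.integer(rmultinom(1, 100, rep(0.25, 4)))
    m <- metricsFromConfusion(new("ConfusionCounts", TP = counts[1],
                                  FP = counts[2], TN = counts[3],
                                  FN = counts[4]))
    expect_lte(m[["f1"]], min(1, 2 * min(m[["precision"]], m[["recall"]])))
    if (counts[1] == 0) expect_equal(m[["f1"]], 0)
    if (m[["f1"]] == 0) expect_equal(counts[1], 0L)
  }
})

test_that("ROC/PR handle perfect, constant and random scores", {
  y <- c(rep(1, 5), rep(0, 5))
  perfect <- rocPrCurves(y, c(10:6, 5:1) / 10)
  expect_equal(perfect$auc, 1)
  expect_equal(perfect$aupr, 1)

  constant <- rocPrCurves(y, rep(0.5, 10))
  expect_equal(constant$auc, 0.5)

  expect_error(rocPrCurves(rep(1, 5), rnorm(5)), "both classes")
})

test_that("AUC equals the Mann-Whitney rank statistic on random data", {
  set.seed(54)
  for (rep in 1:50) {
    n <- 200L
    y <- rbinom(n, 1, 0.5)
    if (sum(y) == 0 || sum(y) == n) next
    scores <- round(rnorm(n), 2)  # rounding forces some ties
    got <- rocPrCurves(y, scores)$auc
    expect_equal(got, oracleAucRank(y, scores), tolerance = 1e-10)
  }
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(55)
  y <- rbinom(100, 1, 0.5)
  s <- rnorm(100)
  base <- rocPrCurves(y, s)$auc
  expect_equal(rocPrCurves(y, exp(s))$auc, base)
  expect_equal(rocPrCurves(y, 3 * s - 7)$auc, base)
  expect_equal(rocPrCurves(y, atan(s))$auc, base)
})

test_that("stratified folds partition the data with balanced classes", {
  y <- ProtFuse:::.withSeed(56L, sample(c(rep(1, 33), rep(0, 27))))
  folds <- kFoldSplit(60L, 5L, y, seed = 57L)
  expect_length(folds, 5L)
  expect_setequal(unlist(folds), 1:60)
  expect_equal(sum(lengths(folds)), 60L)     # pairwise disjoint
  posPerFold <- vapply(folds, function(f) sum(y[f] == 1), numeric(1))
  expect_true(max(posPerFold) - min(posPerFold) <= 1)
  expect_identical(folds, kFoldSplit(60L, 5L, y, seed = 57L))
  expect_error(kFoldSplit(10L, 5L, c(rep(1, 8), 0, 0), seed = 1L),
               "fewer than k")
  expect_error(kFoldSplit(10L, 1L, rep(1, 10), seed = 1L), ">= 2")

  foldsEqual <- kFoldSplit(10L, 5L, rep(c(0, 1), 5), seed = 58L)
  expect_true(all(lengths(foldsEqual) == 2L))
})

test_that("cross-validation aggregates fold metrics as arithmetic means", {
  gen <- generateCorpus(generatorSpec(nPerClass = 40L,
                                      lengthRange = c(40L, 60L),
                                      motifRate = 0, seed = 59L))
  emb <- embedSynthetic(gen$corpus, numFeature = 16L, classShift = 1,
                        noiseSd = 0.2, seed = 60L)
  cfg <- modelConfig(dModel = 16L, nHead = 2L, nEncoderLayers = 1L,
                     epochs = 5L, batchSize = 32L, patience = 0L,
                     validFraction = 0, seed = 61L)
  rep <- crossValidate(emb, labels(gen$corpus), cfg, k = 4L, seed = 62L)
  expect_s4_class(rep, "FoldReport")
  expect_equal(nrow(foldMetrics(rep)), 4L)
  expect_length(foldCurves(rep), 4L)
  expect_equal(aggregateMetrics(rep)[["auc"]],
               mean(foldMetrics(rep)$auc))
  expect_equal(aggregateMetrics(rep)[["accuracy"]],
               mean(foldMetrics(rep)$accuracy))

  dir <- tempfile("report")
  serializeFoldReport(rep, dir)
  expect_true(file.exists(file.path(dir, "report.json")))
  expect_true(file.exists(file.path(dir, "roc_fold4.tsv")))
  parsed <- jsonlite::read_json(file.path(dir, "report.json"))
  expect_length(parsed$folds, 4L)
})
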
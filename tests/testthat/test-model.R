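test_that("model config enforces the head-width divisibility and bounds", {
  expect_error(modelConfig(dModel = 10L, nHead = 3L), "divisible")
  expect_error(modelConfig(nEncoderLayers = 0L), ">= 1")
  expect_error(modelConfig(dropout = 1), "dropout")
  expect_error(modelConfig(variant = "bogus"), "variant")
  cfg <- modelConfig(dModel = 12L, nHead = 3L)
  expect_equal(cfg@dModel %/% cfg@nHead, 4L)
})

test_that("analytic gradients match finite differences for every block", {
  cfg <- tinyConfig()
  n <- 5L; d <- 8L
  X <- ProtFuse:::.withSeed(31L, matrix(rnorm(n * d), n, d))
  y <- c(1L, 0L, 1L, 0L, 1L)
  P <- initModelParams(cfg, d)
  geom <- ProtFuse:::.geometry(cfg, d)
  theta <- ProtFuse:::.pflatten(P)
  lossAt <- function(th) {
    P2 <- ProtFuse:::.punflatten(th, P)$value
    fw <- ProtFuse:::.modelF(X, cfg, P2, geom, train = FALSE)
    ProtFuse:::.ceLoss(fw$probs, y)
  }
  fw <- ProtFuse:::.modelF(X, cfg, P, geom, train = FALSE)
  Y <- matrix(0, n, 2L); Y[cbind(1:n, y + 1L)] <- 1
  dlogits <- (fw$probs - Y) / n
  g <- ProtFuse:::.modelB(fw, dlogits, cfg, P, geom)
  gvec <- ProtFuse:::.pflatten(ProtFuse:::.alignGrads(g, P))
  expect_length(gvec, length(theta))
  idx <- ProtFuse:::.withSeed(32L, sample(length(theta), 250L))
  eps <- 1e-5
  num <- vapply(idx, function(i) {
    tp <- theta; tp[i] <- tp[i] + eps
    tm <- theta; tm[i] <- tm[i] - eps
    (lossAt(tp) - lossAt(tm)) / (2 * eps)
  }, numeric(1))
  expect_lt(max(abs(num - gvec[idx])), 1e-6)
})

test_that("transformer branch is permutation-equivariant over the batch", {
  cfg <- tinyConfig(nEncoderLayers = 2L)
  X <- ProtFuse:::.withSeed(33L, matrix(rnorm(6 * 8), 6, 8))
  P <- initModelParams(cfg, 8L)
  T1 <- transformerBranch(X, cfg, P)
  perm <- c(4, 1, 6, 2, 5, 3)
  T2 <- transformerBranch(X[perm, ], cfg, P)
  expect_equal(T2, T1[perm, ], tolerance = 1e-10)
  # batch of one: attention puts weight 1 on the sole token
  T3 <- transformerBranch(X[1, , drop = FALSE], cfg, P)
  expect_equal(dim(T3), c(1L, 8L))
})

test_that("cnn branch composes reshape, convolution and pooling", {
  cfg <- modelConfig(dModel = 9L, nHead = 3L, convOutChannels = 2L,
                     kernelH = 2L, kernelW = 2L, poolH = 2L, poolW = 2L,
                     seed = 5L)
  X <- ProtFuse:::.withSeed(34L, matrix(rnorm(3 * 9), 3, 9))
  P <- initModelParams(cfg, 9L)
  C <- cnnBranch(X, cfg, P)
  expect_equal(nrow(C), 3L)
  # per sample, the branch equals the three primitives composed
  for (i in 1:3) {
    grid <- reshapeToGrid(X[i, ])
    maps <- convForward(grid, P$conv$W, P$conv$b)
    pooled <- maxPool2d(maps, 2L, 2L)
    # flatten: window index varies fastest within each channel
    want <- as.vector(aperm(pooled, c(3, 2, 1)))
    expect_equal(unname(C[i, ]), want, tolerance = 1e-10)
  }
  expect_true(all(apply(C, 1, length) == ncol(C)))
})

test_that("forward produces valid, deterministic probabilities", {
  cfg <- tinyConfig()
  X <- ProtFuse:::.withSeed(35L, matrix(rnorm(10 * 8), 10, 8))
  p1 <- modelForward(X, cfg)
  p2 <- modelForward(X, cfg)
  expect_true(all(p1 >= 0 & p1 <= 1))
  expect_identical(p1, p2)
  for (v in c("no-fusion", "cnn-only", "transformer-only")) {
    cfgV <- tinyConfig(variant = v)
    pv <- modelForward(X, cfgV)
    expect_true(all(pv >= 0 & pv <= 1), info = v)
  }
})

test_that("training reduces loss on separable data and is seed-stable", {
  gen <- generateCorpus(generatorSpec(nPerClass = 60L,
                                      lengthRange = c(40L, 80L),
                                      motifRate = 0, seed = 36L))
  emb <- embedSynthetic(gen$corpus, numFeature = 16L, classShift = 1,
                        noiseSd = 0.1, seed = 37L)
  y <- labels(gen$corpus)
  cfg <- modelConfig(dModel = 16L, nHead = 4L, nEncoderLayers = 1L,
                     epochs = 15L, batchSize = 32L, patience = 0L,
                     validFraction = 0, dropout = 0, seed = 38L)
  fit <- trainModel(emb, y, cfg)
  tr <- fit@lossTrace$train
  expect_lt(tail(tr, 1), head(tr, 1))
  # overall downward trend on an easily separable set
  expect_lt(mean(tail(tr, 3)), mean(head(tr, 3)))

  fit2 <- trainModel(emb, y, cfg)
  expect_identical(fit@params, fit2@params)
  expect_identical(predictProba(fit, emb), predictProba(fit2, emb))

  # held-in accuracy should be essentially perfect on this signal
  expect_gte(mean(predictLabels(fit, emb) ==
                  as.integer(y == "positive")), 0.95)
})

test_that("ablated variants train without the removed branch", {
  gen <- generateCorpus(generatorSpec(nPerClass = 30L,
                                      lengthRange = c(40L, 60L),
                                      motifRate = 0, seed = 39L))
  emb <- embedSynthetic(gen$corpus, numFeature = 16L, classShift = 1,
                        noiseSd = 0.1, seed = 40L)
  y <- labels(gen$corpus)
  for (v in c("cnn-only", "transformer-only", "no-fusion")) {
    cfg <- modelConfig(dModel = 16L, nHead = 2L, nEncoderLayers = 1L,
                       epochs = 3L, batchSize = 20L, patience = 0L,
                       validFraction = 0, variant = v, seed = 41L)
    fit <- trainModel(emb, y, cfg)
    p <- predictProba(fit, emb)
    expect_true(all(is.finite(p)) && all(p >= 0 & p <= 1), info = v)
  }
})

test_that("per-sample token mode chunks embeddings and trains", {
  gen <- generateCorpus(generatorSpec(nPerClass = 20L,
                                      lengthRange = c(40L, 60L),
                                      motifRate = 0, seed = 42L))
  emb <- embedSynthetic(gen$corpus, numFeature = 24L, classShift = 1,
                        noiseSd = 0.1, seed = 43L)
  cfg <- modelConfig(dModel = 8L, nHead = 2L, nEncoderLayers = 1L,
                     tokenMode = "per-sample", epochs = 2L, batchSize = 16L,
                     patience = 0L, validFraction = 0, seed = 44L)
  fit <- trainModel(emb, labels(gen$corpus), cfg)
  p <- predictProba(fit, emb)
  expect_length(p, 40L)
  expect_true(all(p >= 0 & p <= 1))
  # per-sample mode: a sample's features do not depend on the batch
  P <- initModelParams(cfg, 24L)
  M <- featureMatrix(emb)
  Tall <- transformerBranch(M, cfg, P)
  Tone <- transformerBranch(M[3, , drop = FALSE], cfg, P)
  expect_equal(Tall[3, , drop = FALSE], Tone, tolerance = 1e-10)
})

test_that("batch token mode rejects a mismatched dModel", {
  X <- matrix(rnorm(40), 5, 8)
  cfg <- modelConfig(dModel = 16L, nHead = 4L, epochs = 1L, seed = 1L)
  expect_error(trainModel(X, c(1, 0, 1, 0, 1), cfg), "dModel")
})
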
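#' @include layers.R
NULL

#' Construct a ModelConfig
#'
#' All arguments have desk-scale defaults; see \linkS4class{ModelConfig} for
#' the meaning of each slot. In the faithful \code{"batch"} token mode the
#' Transformer treats the samples of a batch as attention tokens, so
#' \code{dModel} must equal the embedding dimension.
#'
#' @param dModel,nHead,nEncoderLayers Transformer width, head count and
#'   encoder depth.
#' @param convOutChannels,kernelH,kernelW,poolH,poolW CNN branch geometry.
#' @param fusionHidden Hidden width of the fusion scoring layer.
#' @param dropout Dropout rate during training.
#' @param variant \code{"full"}, \code{"no-fusion"}, \code{"cnn-only"} or
#'   \code{"transformer-only"}.
#' @param tokenMode \code{"batch"} or \code{"per-sample"}.
#' @param learningRate,epochs,batchSize,patience,validFraction Training
#'   schedule (Adam).
#' @param seed Integer seed for initialisation, batching and dropout.
#' @return A validated \linkS4class{ModelConfig}.
#' @export
modelConfig <- function(dModel = 64L, nHead = 4L, nEncoderLayers = 2L,
                        convOutChannels = 4L, kernelH = 3L, kernelW = 3L,
                        poolH = 2L, poolW = 2L, fusionHidden = 32L,
                        dropout = 0.1, variant = "full", tokenMode = "batch",
                        learningRate = 1e-3, epochs = 40L, batchSize = 64L,
                        patience = 8L, validFraction = 0.1, seed = 1L) {
  new("ModelConfig", dModel = as.integer(dModel), nHead = as.integer(nHead),
      nEncoderLayers = as.integer(nEncoderLayers),
      convOutChannels = as.integer(convOutChannels),
      kernelH = as.integer(kernelH), kernelW = as.integer(kernelW),
      poolH = as.integer(poolH), poolW = as.integer(poolW),
      fusionHidden = as.integer(fusionHidden), dropout = dropout,
      variant = variant, tokenMode = tokenMode,
      learningRate = learningRate, epochs = as.integer(epochs),
      batchSize = as.integer(batchSize), patience = as.integer(patience),
      validFraction = validFraction, seed = as.integer(seed))
}

setMethod("show", "ModelConfig", function(object) {
  cat(sprintf(paste0(
    "ModelConfig (%s, %s tokens): dModel=%d, nHead=%d (dK=%d), ",
    "encoders=%d,\n  conv %dx%d -> %d ch, pool %dx%d, fusionHidden=%d, ",
    "lr=%g, epochs<=%d, seed=%d\n"),
    object@variant, object@tokenMode, object@dModel, object@nHead,
    object@dModel %/% object@nHead, object@nEncoderLayers,
    object@kernelH, object@kernelW, object@convOutChannels,
    object@poolH, object@poolW, object@fusionHidden,
    object@learningRate, object@epochs, object@seed))
})

## ---------------------------------------------------------------------------
## Geometry and parameter initialisation
## ---------------------------------------------------------------------------

# Static shapes derived from a config and the embedding dimension: the CNN
# grid/pool layout, im2col index tables and the widths of each feature block.
.geometry <- function(cfg, nFeat) {
  side <- ceiling(sqrt(nFeat))
  kh <- cfg@kernelH; kw <- cfg@kernelW
  .stopIfNot(side >= kh && side >= kw,
             "convolution kernel larger than the embedding grid")
  hout <- side - kh + 1L
  wout <- side - kw + 1L
  nh <- hout %/% cfg@poolH
  nw <- wout %/% cfg@poolW
  .stopIfNot(nh >= 1L && nw >= 1L, "pooling window exceeds the feature map")
  npos <- hout * wout
  # kernel offsets, dim-1-fastest to match as.vector() of the weight array
  offs <- expand.grid(p = seq_len(kh), q = seq_len(kw))
  iv <- rep(seq_len(hout), each = wout)
  jv <- rep(seq_len(wout), times = hout)
  idx <- matrix(0L, npos, nrow(offs))
  for (t in seq_len(nrow(offs))) {
    idx[, t] <- (iv + offs$p[t] - 2L) * side + (jv + offs$q[t] - 1L)
  }
  pq <- cfg@poolH * cfg@poolW
  members <- matrix(0L, nh * nw, pq)
  for (wi in seq_len(nh)) {
    for (wj in seq_len(nw)) {
      rows <- ((wi - 1L) * cfg@poolH + 1L):(wi * cfg@poolH)
      cols <- ((wj - 1L) * cfg@poolW + 1L):(wj * cfg@poolW)
      members[(wi - 1L) * nw + wj, ] <-
        as.integer(outer((rows - 1L) * wout, cols, "+"))
    }
  }
  dC <- nh * nw * cfg@convOutChannels
  dT <- cfg@dModel
  headIn <- switch(cfg@variant,
                   "full" = dT + dC,
                   "no-fusion" = dT + dC,
                   "cnn-only" = dC,
                   "transformer-only" = dT)
  list(side = side, hout = hout, wout = wout, nh = nh, nw = nw, npos = npos,
       nWind = nh * nw, idx = idx, members = members, pq = pq,
       dC = dC, dT = dT, headIn = headIn)
}

.glorot <- function(nin, nout) {
  matrix(rnorm(nin * nout, 0, sqrt(2 / (nin + nout))), nin, nout)
}

#' Initialise hybrid-model parameters
#'
#' Draws every weight tensor of the architecture (encoder layers, CNN
#' kernel, fusion module, classification head) from seeded Glorot-scaled
#' normals; layer-norm gains start at 1 and all biases at 0.
#'
#' @param config A \linkS4class{ModelConfig}.
#' @param nFeat The embedding dimension the model will consume.
#' @return Nested parameter list (\code{enc}, \code{conv}, \code{fus},
#'   \code{head}).
#' @export
initModelParams <- function(config, nFeat) {
  if (config@tokenMode == "batch")
    .stopIfNot(config@dModel == nFeat,
               "batch token mode requires dModel == embedding dimension")
  geom <- .geometry(config, nFeat)
  d <- config@dModel
  dk <- d %/% config@nHead
  .withSeed(.mixSeed(config@seed, 17L), {
    enc <- lapply(seq_len(config@nEncoderLayers), function(l) {
      heads <- lapply(seq_len(config@nHead), function(h) {
        list(Wq = .glorot(d, dk), Wk = .glorot(d, dk), Wv = .glorot(d, dk))
      })
      list(ln1 = list(g = rep(1, d), b = rep(0, d)),
           heads = heads,
           Wo = .glorot(d, d),
           ln2 = list(g = rep(1, d), b = rep(0, d)),
           ff = list(W1 = .glorot(d, 4L * d), b1 = rep(0, 4L * d),
                     W2 = .glorot(4L * d, d), b2 = rep(0, d)))
    })
    kh <- config@kernelH; kw <- config@kernelW; M <- config@convOutChannels
    conv <- list(
      W = array(rnorm(kh * kw * M, 0, sqrt(2 / (kh * kw + 1))),
                c(kh, kw, 1L, M)),
      b = rep(0, M))
    fus <- list(W1 = t(.glorot(geom$dT + geom$dC, config@fusionHidden)),
                b1 = rep(0, config@fusionHidden),
                W2 = t(.glorot(config@fusionHidden, 2L)),
                b2 = rep(0, 2L),
                Wt = t(.glorot(geom$dT, geom$dT)),
                Wc = t(.glorot(geom$dC, geom$dC)))
    head <- list(W = t(.glorot(geom$headIn, 2L)), b = rep(0, 2L))
    list(enc = enc, conv = conv, fus = fus, head = head)
  })
}

## ---------------------------------------------------------------------------
## Internal forward/backward engine (vectorised over the batch)
## ---------------------------------------------------------------------------

.lnF <- function(x, g, b) {
  d <- ncol(x)
  mu <- rowMeans(x)
  xc <- x - mu
  inv <- 1 / sqrt(rowMeans(xc^2) + 1e-5)
  xh <- xc * inv
  y <- sweep(sweep(xh, 2L, g, "*"), 2L, b, "+")
  list(y = y, xh = xh, inv = inv)
}

.lnB <- function(dy, cache, g) {
  xh <- cache$xh
  d <- ncol(dy)
  dxh <- sweep(dy, 2L, g, "*")
  dg <- colSums(dy * xh)
  db <- colSums(dy)
  dx <- (cache$inv / d) *
    (d * dxh - rowSums(dxh) - xh * rowSums(dxh * xh))
  list(dx = dx, dg = dg, db = db)
}

.mhaF <- function(u, layer) {
  nHead <- length(layer$heads)
  dk <- ncol(layer$heads[[1]]$Wq)
  scale <- 1 / sqrt(dk)
  hc <- vector("list", nHead)
  outs <- vector("list", nHead)
  for (i in seq_len(nHead)) {
    hp <- layer$heads[[i]]
    Q <- u %*% hp$Wq
    K <- u %*% hp$Wk
    V <- u %*% hp$Wv
    A <- .softmaxRows(Q %*% t(K) * scale)
    outs[[i]] <- A %*% V
    hc[[i]] <- list(Q = Q, K = K, V = V, A = A)
  }
  O <- do.call(cbind, outs)
  list(M = O %*% layer$Wo, O = O, heads = hc, scale = scale, dk = dk)
}

.mhaB <- function(dM, cache, layer, u) {
  nHead <- length(layer$heads)
  dk <- cache$dk
  dWo <- t(cache$O) %*% dM
  dO <- dM %*% t(layer$Wo)
  du <- matrix(0, nrow(u), ncol(u))
  gheads <- vector("list", nHead)
  for (i in seq_len(nHead)) {
    cols <- ((i - 1L) * dk + 1L):(i * dk)
    dOi <- dO[, cols, drop = FALSE]
    hc <- cache$heads[[i]]
    hp <- layer$heads[[i]]
    dA <- dOi %*% t(hc$V)
    dV <- t(hc$A) %*% dOi
    dS <- .softmaxRowsB(dA, hc$A) * cache$scale
    dQ <- dS %*% hc$K
    dK <- t(dS) %*% hc$Q
    gheads[[i]] <- list(Wq = t(u) %*% dQ, Wk = t(u) %*% dK, Wv = t(u) %*% dV)
    du <- du + dQ %*% t(hp$Wq) + dK %*% t(hp$Wk) + dV %*% t(hp$Wv)
  }
  list(du = du, heads = gheads, Wo = dWo)
}

# Pre-norm encoder stack over a token matrix; dropout masks (inverted
# scaling) are drawn from the ambient RNG when train = TRUE.
.encF <- function(X, enc, cfg, train) {
  h <- X
  p <- if (train) cfg@dropout else 0
  caches <- vector("list", length(enc))
  for (l in seq_along(enc)) {
    layer <- enc[[l]]
    ln1 <- .lnF(h, layer$ln1$g, layer$ln1$b)
    at <- .mhaF(ln1$y, layer)
    M <- at$M
    m1 <- NULL
    if (p > 0) {
      m1 <- matrix((runif(length(M)) >= p) / (1 - p), nrow(M), ncol(M))
      M <- M * m1
    }
    h <- h + M
    ln2 <- .lnF(h, layer$ln2$g, layer$ln2$b)
    F1 <- sweep(ln2$y %*% layer$ff$W1, 2L, layer$ff$b1, "+")
    R <- pmax(F1, 0)
    F2 <- sweep(R %*% layer$ff$W2, 2L, layer$ff$b2, "+")
    m2 <- NULL
    if (p > 0) {
      m2 <- matrix((runif(length(F2)) >= p) / (1 - p), nrow(F2), ncol(F2))
      F2 <- F2 * m2
    }
    h <- h + F2
    caches[[l]] <- list(ln1 = ln1, at = at, m1 = m1, ln2 = ln2, R = R,
                        m2 = m2)
  }
  list(T = h, caches = caches)
}

.encB <- function(dT, fw, enc) {
  dh <- dT
  grads <- vector("list", length(enc))
  for (l in rev(seq_along(enc))) {
    layer <- enc[[l]]
    cc <- fw$caches[[l]]
    # feed-forward sublayer
    dF2 <- if (is.null(cc$m2)) dh else dh * cc$m2
    dW2 <- t(cc$R) %*% dF2
    db2 <- colSums(dF2)
    dR <- dF2 %*% t(layer$ff$W2)
    dF1 <- dR * (cc$R > 0)
    dW1 <- t(cc$ln2$y) %*% dF1
    db1 <- colSums(dF1)
    dvy <- dF1 %*% t(layer$ff$W1)
    ln2b <- .lnB(dvy, cc$ln2, layer$ln2$g)
    dh <- dh + ln2b$dx
    # attention sublayer
    dM <- if (is.null(cc$m1)) dh else dh * cc$m1
    mb <- .mhaB(dM, cc$at, layer, cc$ln1$y)
    ln1b <- .lnB(mb$du, cc$ln1, layer$ln1$g)
    dh <- dh + ln1b$dx
    grads[[l]] <- list(ln1 = list(g = ln1b$dg, b = ln1b$db),
                       heads = mb$heads, Wo = mb$Wo,
                       ln2 = list(g = ln2b$dg, b = ln2b$db),
                       ff = list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2))
  }
  list(dX = dh, grads = grads)
}

# Transformer branch over a batch. In "batch" mode the samples themselves
# are the attention tokens; in "per-sample" mode each embedding is chunked
# into tokens of width dModel (zero-padded) and token outputs are averaged.
.tbF <- function(X, P, cfg, train) {
  if (cfg@tokenMode == "batch") {
    fw <- .encF(X, P$enc, cfg, train)
    return(list(T = fw$T, mode = "batch", fw = fw))
  }
  d <- cfg@dModel
  nt <- as.integer(ceiling(ncol(X) / d))
  padded <- cbind(X, matrix(0, nrow(X), nt * d - ncol(X)))
  fws <- vector("list", nrow(X))
  T <- matrix(0, nrow(X), d)
  for (i in seq_len(nrow(X))) {
    tok <- matrix(padded[i, ], nt, d, byrow = TRUE)
    fws[[i]] <- .encF(tok, P$enc, cfg, train)
    T[i, ] <- colMeans(fws[[i]]$T)
  }
  list(T = T, mode = "per-sample", fws = fws, nt = nt)
}

.tbB <- function(dT, cache, P, cfg) {
  if (cache$mode == "batch") {
    bk <- .encB(dT, cache$fw, P$enc)
    return(bk$grads)
  }
  grads <- NULL
  for (i in seq_len(nrow(dT))) {
    dtok <- matrix(rep(dT[i, ] / cache$nt, each = cache$nt), cache$nt,
                   cfg@dModel)
    bk <- .encB(dtok, cache$fws[[i]], P$enc)
    grads <- if (is.null(grads)) bk$grads else
      .paccum(grads, bk$grads)
  }
  grads
}

# CNN branch: zero-pad each embedding row to side^2 (row-major grid),
# convolve via im2col, ReLU, non-overlapping max-pool, flatten.
.cnnF <- function(X, conv, cfg, geom) {
  n <- nrow(X)
  G <- cbind(X, matrix(0, n, geom$side^2 - ncol(X)))
  khkw <- dim(conv$W)[1] * dim(conv$W)[2]
  M <- cfg@convOutChannels
  Pmat <- matrix(0, n * geom$npos, khkw)
  for (t in seq_len(khkw)) {
    Pmat[, t] <- as.vector(G[, geom$idx[, t], drop = FALSE])
  }
  Wmat <- matrix(conv$W, khkw, M)
  Zpre <- sweep(Pmat %*% Wmat, 2L, conv$b, "+")
  Zrelu <- pmax(Zpre, 0)
  Z3 <- array(Zrelu, c(n, geom$npos, M))
  pooled <- array(0, c(n, geom$nWind, M))
  argm <- array(1L, c(n, geom$nWind, M))
  for (w in seq_len(geom$nWind)) {
    mem <- geom$members[w, ]
    cur <- Z3[, mem[1], , drop = TRUE]
    if (is.null(dim(cur))) cur <- matrix(cur, n, M)
    arg <- matrix(1L, n, M)
    for (m in seq_len(geom$pq)[-1]) {
      cand <- Z3[, mem[m], , drop = TRUE]
      if (is.null(dim(cand))) cand <- matrix(cand, n, M)
      upd <- cand > cur
      cur[upd] <- cand[upd]
      arg[upd] <- m
    }
    pooled[, w, ] <- cur
    argm[, w, ] <- arg
  }
  C <- matrix(pooled, n, geom$nWind * M)
  list(C = C, Pmat = Pmat, relu = (Zpre > 0), argm = argm, n = n)
}

.cnnB <- function(dC, cache, conv, cfg, geom) {
  n <- cache$n
  M <- cfg@convOutChannels
  khkw <- dim(conv$W)[1] * dim(conv$W)[2]
  dpooled <- array(dC, c(n, geom$nWind, M))
  dZ3 <- array(0, c(n, geom$npos, M))
  for (w in seq_len(geom$nWind)) {
    mem <- geom$members[w, ]
    arg <- matrix(cache$argm[, w, ], n, M)
    dwin <- matrix(dpooled[, w, ], n, M)
    for (m in seq_len(geom$pq)) {
      mask <- arg == m
      if (any(mask)) {
        slab <- matrix(dZ3[, mem[m], ], n, M)
        slab[mask] <- slab[mask] + dwin[mask]
        dZ3[, mem[m], ] <- slab
      }
    }
  }
  dZpre <- matrix(dZ3, n * geom$npos, M) * cache$relu
  Wmat <- matrix(conv$W, khkw, M)
  dWmat <- t(cache$Pmat) %*% dZpre
  db <- colSums(dZpre)
  dPmat <- dZpre %*% t(Wmat)
  dG <- matrix(0, n, geom$side^2)
  for (t in seq_len(khkw)) {
    cols <- geom$idx[, t]
    dG[, cols] <- dG[, cols] + matrix(dPmat[, t], n, geom$npos)
  }
  list(W = array(dWmat, dim(conv$W)), b = db,
       dX = dG[, seq_len(geom$side^2), drop = FALSE])
}

.fuseF <- function(T, C, fus) {
  Z <- cbind(T, C)
  U <- tanh(sweep(Z %*% t(fus$W1), 2L, fus$b1, "+"))
  a <- .softmaxRows(sweep(U %*% t(fus$W2), 2L, fus$b2, "+"))
  Twt <- T %*% t(fus$Wt)
  Cwt <- C %*% t(fus$Wc)
  Fz <- cbind(Twt * a[, 1L], Cwt * a[, 2L])
  list(Fz = Fz, Z = Z, U = U, a = a, Twt = Twt, Cwt = Cwt)
}

.fuseB <- function(dF, cache, fus, T, C) {
  dT <- ncol(T); dC <- ncol(C)
  dTp <- dF[, seq_len(dT), drop = FALSE]
  dCp <- dF[, dT + seq_len(dC), drop = FALSE]
  a <- cache$a
  dTwt <- dTp * a[, 1L]
  dCwt <- dCp * a[, 2L]
  dat <- rowSums(dTp * cache$Twt)
  dac <- rowSums(dCp * cache$Cwt)
  gWt <- t(dTwt) %*% T
  gWc <- t(dCwt) %*% C
  dTacc <- dTwt %*% fus$Wt
  dCacc <- dCwt %*% fus$Wc
  dSc <- .softmaxRowsB(cbind(dat, dac), a)
  gW2 <- t(dSc) %*% cache$U
  gb2 <- colSums(dSc)
  dU <- dSc %*% fus$W2
  dPre <- dU * (1 - cache$U^2)
  gW1 <- t(dPre) %*% cache$Z
  gb1 <- colSums(dPre)
  dZ <- dPre %*% fus$W1
  dTacc <- dTacc + dZ[, seq_len(dT), drop = FALSE]
  dCacc <- dCacc + dZ[, dT + seq_len(dC), drop = FALSE]
  list(dT = dTacc, dC = dCacc,
       grads = list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2,
                    Wt = gWt, Wc = gWc))
}

# Full forward pass over one batch; returns positive-class probabilities
# plus every cache needed for the backward pass.
.modelF <- function(X, cfg, P, geom, train = FALSE) {
  useT <- cfg@variant != "cnn-only"
  useC <- cfg@variant != "transformer-only"
  tb <- NULL; cb <- NULL; fu <- NULL
  Tfeat <- NULL; Cfeat <- NULL
  if (useT) {
    tb <- .tbF(X, P, cfg, train)
    Tfeat <- tb$T
  }
  if (useC) {
    cb <- .cnnF(X, P$conv, cfg, geom)
    Cfeat <- cb$C
  }
  Fz <- switch(cfg@variant,
               "full" = {
                 fu <- .fuseF(Tfeat, Cfeat, P$fus)
                 fu$Fz
               },
               "no-fusion" = cbind(Tfeat, Cfeat),
               "cnn-only" = Cfeat,
               "transformer-only" = Tfeat)
  logits <- sweep(Fz %*% t(P$head$W), 2L, P$head$b, "+")
  if (!all(is.finite(logits)))
    stop(sprintf(
      "non-finite activations in forward pass (variant %s, batch of %d)",
      cfg@variant, nrow(X)), call. = FALSE)
  prob <- .softmaxRows(logits)
  list(prob = prob[, 2L], probs = prob, logits = logits, Fz = Fz,
       tb = tb, cb = cb, fu = fu, Tfeat = Tfeat, Cfeat = Cfeat)
}

# Backward pass from dlogits; returns a gradient list mirroring P.
.modelB <- function(fw, dlogits, cfg, P, geom) {
  gHead <- list(W = t(dlogits) %*% fw$Fz, b = colSums(dlogits))
  dF <- dlogits %*% P$head$W
  gEnc <- NULL; gConv <- NULL; gFus <- NULL
  dT <- NULL; dC <- NULL
  if (cfg@variant == "full") {
    fb <- .fuseB(dF, fw$fu, P$fus, fw$Tfeat, fw$Cfeat)
    gFus <- fb$grads
    dT <- fb$dT
    dC <- fb$dC
  } else if (cfg@variant == "no-fusion") {
    dT <- dF[, seq_len(geom$dT), drop = FALSE]
    dC <- dF[, geom$dT + seq_len(geom$dC), drop = FALSE]
  } else if (cfg@variant == "cnn-only") {
    dC <- dF
  } else {
    dT <- dF
  }
  if (!is.null(dT)) gEnc <- .tbB(dT, fw$tb, P, cfg)
  if (!is.null(dC)) {
    cbk <- .cnnB(dC, fw$cb, P$conv, cfg, geom)
    gConv <- list(W = cbk$W, b = cbk$b)
  }
  out <- list(head = gHead)
  if (!is.null(gEnc)) out$enc <- gEnc
  if (!is.null(gConv)) out$conv <- gConv
  if (!is.null(gFus)) out$fus <- gFus
  out
}

## ---------------------------------------------------------------------------
## Parameter flattening and Adam
## ---------------------------------------------------------------------------

.pflatten <- function(x) {
  if (is.list(x)) {
    unlist(lapply(x, .pflatten), use.names = FALSE)
  } else {
    as.numeric(x)
  }
}

.punflatten <- function(vec, skel, pos = 1L) {
  if (is.list(skel)) {
    out <- vector("list", length(skel))
    names(out) <- names(skel)
    for (i in seq_along(skel)) {
      r <- .punflatten(vec, skel[[i]], pos)
      out[[i]] <- r$value
      pos <- r$pos
    }
    list(value = out, pos = pos)
  } else {
    n <- length(skel)
    v <- vec[pos:(pos + n - 1L)]
    if (!is.null(dim(skel))) dim(v) <- dim(skel)
    list(value = v, pos = pos + n)
  }
}

# Accumulate two structurally identical gradient lists.
.paccum <- function(a, b) {
  if (is.list(a)) {
    for (i in seq_along(a)) a[[i]] <- .paccum(a[[i]], b[[i]])
    a
  } else {
    a + b
  }
}

# Gradients arrive with the same nesting as the parameters except that
# variant ablations omit blocks; align them to the parameter skeleton with
# zeros for missing blocks so flattening stays positional. Unnamed lists
# (layers, heads) are matched positionally.
.alignGrads <- function(g, P) {
  if (!is.list(P)) {
    return(if (is.null(g)) P * 0 else g)
  }
  nms <- names(P)
  out <- vector("list", length(P))
  names(out) <- nms
  for (i in seq_along(P)) {
    gi <- if (is.null(g)) {
      NULL
    } else if (!is.null(nms) && !is.null(names(g))) {
      g[[nms[i]]]
    } else {
      g[[i]]
    }
    out[[i]] <- .alignGrads(gi, P[[i]])
  }
  out
}

.pmapZero <- function(x) {
  if (is.list(x)) lapply(x, .pmapZero) else x * 0
}

## ---------------------------------------------------------------------------
## Training, prediction and exported forward functions
## ---------------------------------------------------------------------------

.asLabel01 <- function(y) {
  if (is.character(y) || is.factor(y)) {
    y <- as.character(y)
    .stopIfNot(all(y %in% c("positive", "negative")),
               "labels must be 'positive'/'negative' (or 0/1)")
    as.integer(y == "positive")
  } else {
    .stopIfNot(all(y %in% c(0, 1)), "numeric labels must be 0/1")
    as.integer(y)
  }
}

.ceLoss <- function(prob2, y01) {
  p <- pmax(prob2[cbind(seq_along(y01), y01 + 1L)], 1e-12)
  -mean(log(p))
}

#' Train the hybrid Transformer-CNN classifier
#'
#' Standardises the features (per-coordinate zero mean / unit variance
#' learned on the training data only), initialises all weights from the
#' config seed, and minimises the cross-entropy of the softmax head with
#' Adam over shuffled minibatches. In the faithful batch-token mode each
#' minibatch is one attention context. When early stopping is enabled
#' (patience > 0) a stratified internal validation split (or the supplied
#' one) monitors the loss and the best parameters are restored. Fully
#' reproducible from the config seed.
#'
#' @param x Feature matrix or \linkS4class{EmbeddingSet}.
#' @param y Labels: \code{"positive"}/\code{"negative"} or 0/1.
#' @param config A \linkS4class{ModelConfig}.
#' @param validX,validY Optional explicit validation set (same feature
#'   space).
#' @return A \linkS4class{HybridFit}.
#' @export
trainModel <- function(x, y, config, validX = NULL, validY = NULL) {
  if (is(x, "EmbeddingSet")) x <- featureMatrix(x)
  x <- as.matrix(x)
  y01 <- .asLabel01(y)
  .stopIfNot(nrow(x) == length(y01), "one label per sample is required")
  .stopIfNot(nrow(x) >= 2L, "at least two samples are required")
  if (config@tokenMode == "batch" && config@dModel != ncol(x))
    stop(sprintf(
      "batch token mode requires dModel == embedding dimension (%d != %d)",
      config@dModel, ncol(x)), call. = FALSE)
  center <- colMeans(x)
  scl <- pmax(apply(x, 2L, sd), 1e-8)
  xs <- sweep(sweep(x, 2L, center), 2L, scl, "/")
  if (!is.null(validX)) {
    if (is(validX, "EmbeddingSet")) validX <- featureMatrix(validX)
    validX <- sweep(sweep(as.matrix(validX), 2L, center), 2L, scl, "/")
    validY <- .asLabel01(validY)
  }
  geom <- .geometry(config, ncol(xs))
  P <- initModelParams(config, ncol(xs))
  skel <- P
  theta <- .pflatten(P)
  mAd <- numeric(length(theta))
  vAd <- numeric(length(theta))
  b1 <- 0.9; b2 <- 0.999; epsAd <- 1e-8
  stepCount <- 0L
  trace <- data.frame(epoch = integer(0), train = numeric(0),
                      valid = numeric(0))
  useEarly <- config@patience > 0L
  .withSeed(.mixSeed(config@seed, 29L), {
    if (useEarly && is.null(validX) && config@validFraction > 0) {
      vIdx <- unlist(lapply(split(seq_along(y01), y01), function(ix) {
        nv <- max(1L, round(length(ix) * config@validFraction))
        sample(ix, nv)
      }))
      validX <- xs[vIdx, , drop = FALSE]
      validY <- y01[vIdx]
      xs <- xs[-vIdx, , drop = FALSE]
      y01 <- y01[-vIdx]
    }
    if (is.null(validX)) useEarly <- FALSE
    n <- nrow(xs)
    bestTheta <- theta
    bestVal <- Inf
    badEpochs <- 0L
    for (epoch in seq_len(config@epochs)) {
      ord <- sample(n)
      batches <- split(ord, ceiling(seq_along(ord) / config@batchSize))
      lossSum <- 0
      diverged <- FALSE
      for (bt in batches) {
        Xb <- xs[bt, , drop = FALSE]
        yb <- y01[bt]
        fw <- tryCatch(.modelF(Xb, config, P, geom, train = TRUE),
                       error = function(e) NULL)
        if (is.null(fw)) { diverged <- TRUE; break }
        loss <- .ceLoss(fw$probs, yb)
        if (!is.finite(loss)) { diverged <- TRUE; break }
        lossSum <- lossSum + loss * length(bt)
        Y <- matrix(0, length(bt), 2L)
        Y[cbind(seq_along(yb), yb + 1L)] <- 1
        dlogits <- (fw$probs - Y) / length(bt)
        g <- .modelB(fw, dlogits, config, P, geom)
        gvec <- .pflatten(.alignGrads(g, P))
        stepCount <- stepCount + 1L
        mAd <- b1 * mAd + (1 - b1) * gvec
        vAd <- b2 * vAd + (1 - b2) * gvec^2
        mh <- mAd / (1 - b1^stepCount)
        vh <- vAd / (1 - b2^stepCount)
        theta <- theta - config@learningRate * mh / (sqrt(vh) + epsAd)
        P <- .punflatten(theta, skel)$value
      }
      if (diverged) {
        warning("training diverged (non-finite loss); ",
                "restoring the last stable parameters")
        theta <- bestTheta
        P <- .punflatten(theta, skel)$value
        break
      }
      valLoss <- NA_real_
      if (!is.null(validX)) {
        fwv <- .modelF(validX, config, P, geom, train = FALSE)
        valLoss <- .ceLoss(fwv$probs, validY)
      }
      trace <- rbind(trace, data.frame(epoch = epoch, train = lossSum / n,
                                       valid = valLoss))
      if (useEarly) {
        if (valLoss < bestVal - 1e-6) {
          bestVal <- valLoss
          bestTheta <- theta
          badEpochs <- 0L
        } else {
          badEpochs <- badEpochs + 1L
          if (badEpochs >= config@patience) break
        }
      } else {
        bestTheta <- theta
      }
    }
    if (useEarly) {
      theta <- bestTheta
      P <- .punflatten(theta, skel)$value
    }
  })
  new("HybridFit", config = config, params = P, lossTrace = trace,
      center = center, scale = scl)
}

setMethod("show", "HybridFit", function(object) {
  cat(sprintf("HybridFit (%s): %d trained epochs, final train loss %.4f\n",
              object@config@variant, nrow(object@lossTrace),
              utils::tail(object@lossTrace$train, 1)))
})

#' Positive-class probabilities from a trained model
#'
#' Standardises incoming features with the training-fold centre/scale and
#' runs the forward pass. In batch token mode the supplied matrix is the
#' attention context (one fixed evaluation batch), the documented default
#' deployment of the faithful mode.
#'
#' @param fit A \linkS4class{HybridFit}.
#' @param x Feature matrix or \linkS4class{EmbeddingSet}.
#' @return Numeric vector of probabilities in [0, 1].
#' @export
predictProba <- function(fit, x) {
  if (is(x, "EmbeddingSet")) x <- featureMatrix(x)
  x <- as.matrix(x)
  xs <- sweep(sweep(x, 2L, fit@center), 2L, fit@scale, "/")
  geom <- .geometry(fit@config, ncol(xs))
  .modelF(xs, fit@config, fit@params, geom, train = FALSE)$prob
}

#' Hard labels from a trained model
#'
#' @param fit A \linkS4class{HybridFit}.
#' @param x Feature matrix or \linkS4class{EmbeddingSet}.
#' @param threshold Decision threshold on the positive-class probability.
#' @return Integer vector (1 = positive, 0 = negative).
#' @export
predictLabels <- function(fit, x, threshold = 0.5) {
  as.integer(predictProba(fit, x) >= threshold)
}

#' Transformer branch features
#'
#' Runs the embedding batch through the encoder stack. In the faithful batch
#' mode the batch axis is the token axis: each sample attends over the other
#' samples of the batch (no positional encoding), so the operation is
#' permutation-equivariant over samples.
#'
#' @param X Embedding batch (samples x features).
#' @param config A \linkS4class{ModelConfig}.
#' @param params Optional parameter list (defaults to a fresh seeded
#'   initialisation).
#' @return Feature matrix (samples x dModel).
#' @export
transformerBranch <- function(X, config, params = NULL) {
  X <- as.matrix(X)
  .stopIfNot(nrow(X) >= 1L, "empty batch")
  if (is.null(params)) params <- initModelParams(config, ncol(X))
  .tbF(X, params, config, train = FALSE)$T
}

#' CNN branch features
#'
#' Per sample: reshape the embedding to a zero-padded square grid, apply the
#' valid convolution with ReLU, non-overlapping max pooling, and flatten.
#'
#' @inheritParams transformerBranch
#' @return Feature matrix (samples x flattened pooled maps).
#' @export
cnnBranch <- function(X, config, params = NULL) {
  X <- as.matrix(X)
  .stopIfNot(nrow(X) >= 1L, "empty batch")
  if (is.null(params)) params <- initModelParams(config, ncol(X))
  geom <- .geometry(config, ncol(X))
  .cnnF(X, params$conv, config, geom)$C
}

#' Raw forward pass of the hybrid model
#'
#' Runs both branches, the fusion module (per variant) and the softmax head
#' on an already-standardised batch with explicit parameters, returning the
#' per-sample positive-class probability.
#'
#' @inheritParams transformerBranch
#' @param params Parameter list from \code{\link{initModelParams}} or a
#'   \linkS4class{HybridFit}'s \code{params}.
#' @return Numeric vector of probabilities in [0, 1].
#' @export
modelForward <- function(X, config, params = NULL) {
  X <- as.matrix(X)
  if (is.null(params)) params <- initModelParams(config, ncol(X))
  geom <- .geometry(config, ncol(X))
  .modelF(X, config, params, geom, train = FALSE)$prob
}
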
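# Independent, loop-written reference implementations of the model equations
# and the evaluation formulas. These deliberately avoid the package's
# vectorised code paths: everything is scalar loops and explicit sums.

oracleSoftmax <- function(v) {
  e <- exp(v - max(v))
  e / sum(e)
}

# Single attention head, term by term: projections, scaled dot products,
# row softmax, weighted sum of values.
oracleAttentionHead <- function(X, Wq, Wk, Wv) {
  n <- nrow(X)
  dk <- ncol(Wq)
  Q <- matrix(0, n, dk); K <- matrix(0, n, dk); V <- matrix(0, n, dk)
  for (i in seq_len(n)) {
    for (j in seq_len(dk)) {
      Q[i, j] <- sum(X[i, ] * Wq[, j])
      K[i, j] <- sum(X[i, ] * Wk[, j])
      V[i, j] <- sum(X[i, ] * Wv[, j])
    }
  }
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    s <- numeric(n)
    for (j in seq_len(n)) s[j] <- sum(Q[i, ] * K[j, ]) / sqrt(dk)
    A[i, ] <- oracleSoftmax(s)
  }
  O <- matrix(0, n, dk)
  for (i in seq_len(n)) {
    for (j in seq_len(dk)) O[i, j] <- sum(A[i, ] * V[, j])
  }
  list(output = O, attention = A)
}

oracleMultiHead <- function(X, params) {
  outs <- lapply(params$heads, function(h) {
    oracleAttentionHead(X, h$Wq, h$Wk, h$Wv)$output
  })
  O <- do.call(cbind, outs)
  n <- nrow(O)
  res <- matrix(0, n, ncol(params$Wo))
  for (i in seq_len(n)) {
    for (j in seq_len(ncol(params$Wo))) {
      res[i, j] <- sum(O[i, ] * params$Wo[, j])
    }
  }
  res
}

# Triple-loop valid convolution with ReLU.
oracleConv <- function(grid, W, b) {
  if (is.matrix(grid)) grid <- array(grid, c(1, nrow(grid), ncol(grid)))
  kh <- dim(W)[1]; kw <- dim(W)[2]; cin <- dim(W)[3]; cout <- dim(W)[4]
  hout <- dim(grid)[2] - kh + 1
  wout <- dim(grid)[3] - kw + 1
  Y <- array(0, c(cout, hout, wout))
  for (o in seq_len(cout)) {
    for (i in seq_len(hout)) {
      for (j in seq_len(wout)) {
        acc <- b[o]
        for (cc in seq_len(cin)) {
          for (p in 0:(kh - 1)) {
            for (q in 0:(kw - 1)) {
              acc <- acc + W[p + 1, q + 1, cc, o] * grid[cc, i + p, j + q]
            }
          }
        }
        Y[o, i, j] <- max(0, acc)
      }
    }
  }
  Y
}

oracleMaxPool <- function(maps, ph, pw) {
  if (is.matrix(maps)) maps <- array(maps, c(1, nrow(maps), ncol(maps)))
  ch <- dim(maps)[1]
  nh <- dim(maps)[2] %/% ph
  nw <- dim(maps)[3] %/% pw
  Y <- array(0, c(ch, nh, nw))
  for (cc in seq_len(ch)) {
    for (i in seq_len(nh)) {
      for (j in seq_len(nw)) {
        m <- -Inf
        for (p in seq_len(ph)) {
          for (q in seq_len(pw)) {
            m <- max(m, maps[cc, (i - 1) * ph + p, (j - 1) * pw + q])
          }
        }
        Y[cc, i, j] <- m
      }
    }
  }
  Y
}

# Hand-composed fusion: score, softmax weights, per-branch reweighting.
oracleFuse <- function(T, C, params) {
  n <- nrow(T)
  fused <- matrix(0, n, ncol(T) + ncol(C))
  weights <- matrix(0, n, 2)
  for (i in seq_len(n)) {
    z <- c(T[i, ], C[i, ])
    u <- tanh(as.numeric(params$W1 %*% z) + params$b1)
    sc <- as.numeric(params$W2 %*% u) + params$b2
    a <- oracleSoftmax(sc)
    tp <- a[1] * as.numeric(params$Wt %*% T[i, ])
    cp <- a[2] * as.numeric(params$Wc %*% C[i, ])
    fused[i, ] <- c(tp, cp)
    weights[i, ] <- a
  }
  list(fused = fused, weights = weights)
}

# Formula-by-formula scalar metrics with the same zero-denominator policy.
oracleMetrics <- function(tp, fp, tn, fn) {
  total <- tp + fp + tn + fn
  div <- function(a, b) if (b == 0) 0 else a / b
  prec <- div(tp, tp + fp)
  rec <- div(tp, tp + fn)
  c(accuracy = (tp + tn) / total,
    precision = prec,
    recall = rec,
    f1 = div(2 * prec * rec, prec + rec),
    mcc = div(tp * tn - fp * fn,
              sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)),
    fpr = div(fp, fp + tn))
}

# AUC as the Mann-Whitney rank statistic: ties get half credit.
oracleAucRank <- function(labels01, scores) {
  pos <- scores[labels01 == 1]
  neg <- scores[labels01 == 0]
  wins <- 0
  for (p in pos) {
    for (q in neg) {
      wins <- wins + (p > q) + 0.5 * (p == q)
    }
  }
  wins / (length(pos) * length(neg))
}

randomHeadParams <- function(d, dk) {
  list(Wq = matrix(rnorm(d * dk), d, dk),
       Wk = matrix(rnorm(d * dk), d, dk),
       Wv = matrix(rnorm(d * dk), d, dk))
}

randomMhaParams <- function(d, nHead) {
  dk <- d / nHead
  list(heads = lapply(seq_len(nHead), function(i) randomHeadParams(d, dk)),
       Wo = matrix(rnorm(d * d), d, d))
}

randomFuseParams <- function(dT, dC, H = 6L) {
  list(W1 = matrix(rnorm(H * (dT + dC)), H, dT + dC),
       b1 = rnorm(H),
       W2 = matrix(rnorm(2 * H), 2, H),
       b2 = rnorm(2),
       Wt = matrix(rnorm(dT * dT), dT, dT),
       Wc = matrix(rnorm(dC * dC), dC, dC))
}
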
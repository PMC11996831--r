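#' @include AllClasses.R
NULL

# Row-wise softmax with max-subtraction for numerical stability.
.softmaxRows <- function(S) {
  m <- apply(S, 1L, max)
  E <- exp(S - m)
  E / rowSums(E)
}

# Backward of row-wise softmax: given dA and A = softmaxRows(S), return dS.
.softmaxRowsB <- function(dA, A) {
  (dA - rowSums(dA * A)) * A
}

#' Scaled dot-product attention for a single head
#'
#' Computes one self-attention head over a token matrix: queries, keys and
#' values are linear projections of the input, attention weights are the
#' row-softmax of the scaled query-key dot products, and the head output is
#' the attention-weighted sum of values:
#' \deqn{Q = X W^Q,\; K = X W^K,\; V = X W^V,\;
#'       A = \mathrm{softmax}(QK^\top/\sqrt{d_k}),\; O = AV.}
#' Every row of \code{A} sums to one.
#'
#' @param X Token matrix (tokens in rows, width = model dimension).
#' @param Wq,Wk,Wv Projection matrices of width \code{dK} (the per-head
#'   dimension, model dimension / number of heads).
#' @return List with \code{output} (tokens x dK) and \code{attention}
#'   (tokens x tokens).
#' @examples
#' X <- matrix(rnorm(8), 2, 4)
#' W <- diag(4)[, 1:2]
#' attentionHead(X, W, W, W)$attention
#' @export
attentionHead <- function(X, Wq, Wk, Wv) {
  .stopIfNot(ncol(X) == nrow(Wq) && ncol(X) == nrow(Wk) &&
             ncol(X) == nrow(Wv),
             "projection matrices must match the token width")
  .stopIfNot(ncol(Wq) == ncol(Wk) && ncol(Wq) == ncol(Wv),
             "Q/K/V projections must share the per-head width")
  Q <- X %*% Wq
  K <- X %*% Wk
  V <- X %*% Wv
  dk <- ncol(Wq)
  A <- .softmaxRows(Q %*% t(K) / sqrt(dk))
  list(output = A %*% V, attention = A)
}

#' Multi-head self-attention
#'
#' Runs \code{length(params$heads)} attention heads in parallel, concatenates
#' their outputs along the feature axis and applies the output projection
#' \code{Wo}; the result has the same width as the input.
#'
#' @param X Token matrix (tokens x dModel).
#' @param params List with \code{heads} (a list of per-head lists holding
#'   \code{Wq}, \code{Wk}, \code{Wv}) and \code{Wo} (dModel x dModel).
#' @return Matrix of the same shape as \code{X}.
#' @export
multiHeadAttention <- function(X, params) {
  heads <- params$heads
  .stopIfNot(length(heads) >= 1L, "at least one head is required")
  dk <- ncol(heads[[1]]$Wq)
  .stopIfNot(dk * length(heads) == ncol(X),
             "head width times head count must equal the model width")
  outs <- lapply(heads, function(h) attentionHead(X, h$Wq, h$Wk, h$Wv)$output)
  O <- do.call(cbind, outs)
  .stopIfNot(nrow(params$Wo) == ncol(O),
             "output projection must match the concatenated head width")
  O %*% params$Wo
}

#' Reshape an embedding vector to a single-channel square grid
#'
#' Zero-pads the vector to the next perfect square and reshapes it row-major
#' to a side x side matrix, where side = ceiling(sqrt(length(x))). This is
#' the input representation of the CNN branch.
#'
#' @param x Numeric vector.
#' @return A side x side numeric matrix.
#' @examples
#' dim(reshapeToGrid(rnorm(1280)))  # 36 x 36 (1296 = 36^2, 16 zero pads)
#' @export
reshapeToGrid <- function(x) {
  .stopIfNot(length(x) >= 1L, "input vector must be non-empty")
  side <- ceiling(sqrt(length(x)))
  padded <- c(x, numeric(side * side - length(x)))
  matrix(padded, side, side, byrow = TRUE)
}

#' Valid 2-D convolution with ReLU activation
#'
#' Computes, for every output channel o and output pixel (i, j),
#' \deqn{Y_{o,i,j} = \max\Big(0, \sum_c \sum_p \sum_q W_{o,c,p,q}
#'   X_{c,i+p,j+q} + b_o\Big)}
#' over the valid (no-padding) extent.
#'
#' @param grid Input feature map: a matrix (one channel) or an array with
#'   dimensions (channels, height, width).
#' @param W Kernel weights, array (kernelH, kernelW, inChannels,
#'   outChannels).
#' @param b Per-output-channel bias vector.
#' @return Array (outChannels, outH, outW).
#' @export
convForward <- function(grid, W, b) {
  if (is.matrix(grid)) grid <- array(grid, c(1L, nrow(grid), ncol(grid)))
  .stopIfNot(length(dim(grid)) == 3L, "grid must be a matrix or 3-D array")
  kh <- dim(W)[1]; kw <- dim(W)[2]; cin <- dim(W)[3]; cout <- dim(W)[4]
  h <- dim(grid)[2]; w <- dim(grid)[3]
  .stopIfNot(dim(grid)[1] == cin, "channel count mismatch")
  .stopIfNot(h >= kh && w >= kw, "kernel larger than the input grid")
  .stopIfNot(length(b) == cout, "one bias per output channel is required")
  hout <- h - kh + 1L
  wout <- w - kw + 1L
  Y <- array(0, c(cout, hout, wout))
  for (o in seq_len(cout)) {
    acc <- matrix(b[o], hout, wout)
    for (cc in seq_len(cin)) {
      for (p in seq_len(kh)) {
        for (q in seq_len(kw)) {
          acc <- acc + W[p, q, cc, o] *
            grid[cc, (p):(p + hout - 1L), (q):(q + wout - 1L)]
        }
      }
    }
    Y[o, , ] <- pmax(acc, 0)
  }
  Y
}

#' Non-overlapping max pooling
#'
#' Takes the maximum over non-overlapping poolH x poolW windows (stride =
#' window size); trailing rows/columns that do not fill a window are
#' dropped.
#'
#' @param maps Feature maps: matrix (one channel) or array (channels,
#'   height, width).
#' @param poolH,poolW Pooling window height and width.
#' @return Array (channels, floor(h/poolH), floor(w/poolW)).
#' @export
maxPool2d <- function(maps, poolH, poolW) {
  if (is.matrix(maps)) maps <- array(maps, c(1L, nrow(maps), ncol(maps)))
  ch <- dim(maps)[1]; h <- dim(maps)[2]; w <- dim(maps)[3]
  .stopIfNot(h >= poolH && w >= poolW, "pooling window exceeds the map")
  nh <- h %/% poolH
  nw <- w %/% poolW
  Y <- array(0, c(ch, nh, nw))
  for (cc in seq_len(ch)) {
    for (i in seq_len(nh)) {
      for (j in seq_len(nw)) {
        Y[cc, i, j] <- max(maps[cc,
                                ((i - 1L) * poolH + 1L):(i * poolH),
                                ((j - 1L) * poolW + 1L):(j * poolW)])
      }
    }
  }
  Y
}

#' Attention-weighted fusion of Transformer and CNN features
#'
#' Scores the concatenated branch features per sample,
#' \deqn{a = \mathrm{softmax}(W_2 \tanh(W_1 [T; C] + b_1) + b_2),}
#' obtaining a two-component weight vector per sample whose entries sum to
#' one (first component weights the Transformer branch, second the CNN
#' branch), then reweights each branch through its own linear map and
#' concatenates:
#' \deqn{T' = a_t W_t T,\quad C' = a_c W_c C,\quad F = [T'; C'].}
#'
#' @param T Transformer-branch feature matrix (samples x dT).
#' @param C CNN-branch feature matrix (samples x dC).
#' @param params List with \code{W1} (hidden x (dT+dC)), \code{b1},
#'   \code{W2} (2 x hidden), \code{b2}, \code{Wt} (dT x dT), \code{Wc}
#'   (dC x dC).
#' @return List with \code{fused} (samples x (dT+dC)) and \code{weights}
#'   (samples x 2, columns \code{a_t}, \code{a_c}).
#' @export
fuseFeatures <- function(T, C, params) {
  .stopIfNot(nrow(T) == nrow(C),
             "branch features must cover the same samples")
  Z <- cbind(T, C)
  U <- tanh(sweep(Z %*% t(params$W1), 2L, params$b1, "+"))
  Sc <- sweep(U %*% t(params$W2), 2L, params$b2, "+")
  a <- .softmaxRows(Sc)
  Tp <- (T %*% t(params$Wt)) * a[, 1L]
  Cp <- (C %*% t(params$Wc)) * a[, 2L]
  colnames(a) <- c("a_t", "a_c")
  list(fused = cbind(Tp, Cp), weights = a)
}
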
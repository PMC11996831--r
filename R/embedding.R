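#' @include AllGenerics.R
NULL

#' Construct an EmbeddingSet
#'
#' @param features Numeric matrix (rows = sequences) or data.frame.
#' @param ids Character ids; defaults to the matrix rownames.
#' @param metadata Provenance list.
#' @return An \linkS4class{EmbeddingSet}.
#' @export
embeddingSet <- function(features, ids = rownames(features),
                         metadata = list()) {
  features <- as.matrix(features)
  .stopIfNot(!is.null(ids), "embedding ids are required")
  rownames(features) <- ids
  new("EmbeddingSet", ids = as.character(ids), features = features,
      numFeature = ncol(features), metadata = metadata)
}

#' @rdname seqIds
#' @export
setMethod("seqIds", "EmbeddingSet", function(x) x@ids)

#' @rdname featureMatrix
#' @export
setMethod("featureMatrix", "EmbeddingSet", function(x) x@features)

#' @rdname numFeature
#' @export
setMethod("numFeature", "EmbeddingSet", function(x) x@numFeature)

#' Number of embedded sequences
#' @param x An \linkS4class{EmbeddingSet}.
#' @export
setMethod("length", "EmbeddingSet", function(x) length(x@ids))

#' Subset an EmbeddingSet by index or id
#' @param x An \linkS4class{EmbeddingSet}.
#' @param i Integer, logical or character index.
#' @param j,...,drop Ignored.
#' @export
setMethod("[", "EmbeddingSet", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) i <- match(i, x@ids)
  embeddingSet(x@features[i, , drop = FALSE], ids = x@ids[i],
               metadata = x@metadata)
})

setMethod("show", "EmbeddingSet", function(object) {
  cat(sprintf("EmbeddingSet: %d sequences x %d features\n",
              length(object@ids), object@numFeature))
  if (!is.null(object@metadata$embedder))
    cat(sprintf("  embedder: %s\n", object@metadata$embedder))
})

# Deterministic k-mer composition signal: each distinct k-mer of the
# sequence is hashed to a coordinate and a sign; counts accumulate there.
# The vector is L2-normalised so sequence length does not dominate.
.kmerSignal <- function(seq, numFeature, k = 3L, salt = 7L) {
  v <- numeric(numFeature)
  n <- nchar(seq)
  if (n >= k) {
    kmers <- substring(seq, seq_len(n - k + 1L), k:n)
    tab <- table(kmers)
    for (i in seq_along(tab)) {
      h <- .hashString(names(tab)[i], salt = salt)
      idx <- (h %% numFeature) + 1L
      sgn <- if ((h %/% numFeature) %% 2 == 0) 1 else -1
      v[idx] <- v[idx] + sgn * as.numeric(tab[i])
    }
  }
  nrm <- sqrt(sum(v^2))
  if (nrm > 0) v / nrm else v
}

#' Deterministic synthetic embedder with controllable class separability
#'
#' Maps each sequence to a fixed-length vector composed of (i) a
#' deterministic, hash-derived signal from its 3-mer composition, (ii) a
#' label-dependent mean shift of magnitude \code{classShift} applied
#' per-coordinate on a fixed seed-chosen coordinate subset (positives are
#' shifted up by \code{classShift/2}, negatives down by the same amount, so
#' the between-class mean difference on those coordinates equals
#' \code{classShift}), and (iii) Gaussian noise. Noise is drawn from a
#' per-record RNG substream derived from the seed and the record id, so a
#' record's embedding does not depend on its position in the batch. Class
#' separability grows with \code{classShift / noiseSd}.
#'
#' @param corpus A \linkS4class{ProteinCorpus}; labels must be known when
#'   \code{classShift > 0}.
#' @param numFeature Embedding dimension (>= 4); default 1280, a common
#'   protein-language-model hidden size.
#' @param classShift Between-class mean difference per shifted coordinate
#'   (>= 0).
#' @param noiseSd Standard deviation of the additive Gaussian noise (> 0).
#' @param signalScale Multiplier of the k-mer composition component; set to 0
#'   to remove all sequence-content signal.
#' @param seed Integer seed.
#' @return An \linkS4class{EmbeddingSet}; metadata records the parameters and
#'   the shifted coordinate subset (\code{shiftCoords}).
#' @export
embedSynthetic <- function(corpus, numFeature = 1280L, classShift = 1,
                           noiseSd = 0.1, signalScale = 1, seed) {
  numFeature <- as.integer(numFeature)
  .stopIfNot(numFeature >= 4L, "numFeature must be >= 4")
  .stopIfNot(noiseSd > 0, "noiseSd must be > 0")
  .stopIfNot(classShift >= 0, "classShift must be >= 0")
  lab <- labels(corpus)
  if (classShift > 0 && any(lab == "unknown"))
    stop("classShift > 0 requires labelled records", call. = FALSE)
  nShift <- max(4L, numFeature %/% 16L)
  shiftCoords <- .withSeed(.mixSeed(seed, 1L),
                           sort(sample(numFeature, nShift)))
  seqs <- as.character(sequences(corpus))
  ids <- seqIds(corpus)
  M <- matrix(0, length(ids), numFeature)
  for (i in seq_along(ids)) {
    base <- .kmerSignal(seqs[i], numFeature) * signalScale
    noise <- .withSeed(.mixSeed(seed, .hashString(ids[i], salt = 3L)),
                       rnorm(numFeature, 0, noiseSd))
    v <- base + noise
    if (classShift > 0) {
      half <- classShift / 2
      if (lab[i] == "positive") v[shiftCoords] <- v[shiftCoords] + half
      else v[shiftCoords] <- v[shiftCoords] - half
    }
    M[i, ] <- v
  }
  embeddingSet(M, ids = ids,
               metadata = list(embedder = "synthetic", pooling = "none",
                               numFeature = numFeature,
                               classShift = classShift, noiseSd = noiseSd,
                               signalScale = signalScale, seed = seed,
                               shiftCoords = shiftCoords))
}

#' Embed sequences through an external protein language model
#'
#' Adapter around an external protein-language-model runtime. The caller
#' supplies \code{embedFun}, a function taking one residue string and
#' returning a numeric matrix of per-residue representations (positions in
#' rows); these are pooled to one vector per sequence (\code{"mean"} over
#' positions, or \code{"cls"} = first position). Results are cached on disk
#' keyed by model name, pooling and sequence content, so a second call is
#' served from the cache without recomputation.
#'
#' @param corpus A \linkS4class{ProteinCorpus} (cleaned).
#' @param embedFun Function \code{sequence -> matrix(L x D)} wrapping the
#'   model runtime.
#' @param modelName Name of the language model (cache key and provenance).
#' @param pooling \code{"mean"} or \code{"cls"}.
#' @param maxLen Model context limit; longer sequences are truncated with a
#'   warning.
#' @param cacheDir Optional directory for the on-disk cache.
#' @return An \linkS4class{EmbeddingSet}.
#' @export
embedWithPLM <- function(corpus, embedFun = NULL, modelName, pooling =
                           c("mean", "cls"), maxLen = 1022L,
                         cacheDir = NULL) {
  pooling <- match.arg(pooling)
  if (is.null(embedFun))
    stop(paste("no protein-language-model runtime supplied (embedFun);",
               "for model-free workflows use embedSynthetic()"),
         call. = FALSE)
  seqs <- as.character(sequences(corpus))
  ids <- seqIds(corpus)
  if (!is.null(cacheDir) && !dir.exists(cacheDir))
    dir.create(cacheDir, recursive = TRUE)
  rows <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    s <- seqs[i]
    if (nchar(s) > maxLen) {
      warning(sprintf("sequence %s exceeds model context (%d > %d); truncated",
                      ids[i], nchar(s), maxLen))
      s <- substr(s, 1L, maxLen)
    }
    key <- sprintf("%s_%s_%d", modelName, pooling,
                   .hashString(paste0(pooling, s), salt = 11L))
    cacheFile <- if (!is.null(cacheDir)) {
      file.path(cacheDir, paste0(key, ".rds"))
    }
    if (!is.null(cacheFile) && file.exists(cacheFile)) {
      rows[[i]] <- readRDS(cacheFile)
      next
    }
    rep <- embedFun(s)
    .stopIfNot(is.matrix(rep) && nrow(rep) >= 1L,
               sprintf("embedFun must return a per-residue matrix (id %s)",
                       ids[i]))
    v <- if (pooling == "mean") colMeans(rep) else rep[1L, ]
    if (!is.null(cacheFile)) saveRDS(v, cacheFile)
    rows[[i]] <- v
  }
  dims <- unique(vapply(rows, length, integer(1)))
  .stopIfNot(length(dims) == 1L,
             "embedFun returned inconsistent feature dimensions")
  M <- do.call(rbind, rows)
  embeddingSet(M, ids = ids,
               metadata = list(embedder = modelName, pooling = pooling,
                               numFeature = dims))
}

.EMB_MAGIC <- "ProtFuseEmbeddings"

#' Save / load an EmbeddingSet container
#'
#' Lossless single-file container (serialized R object) storing the ids, the
#' embedding matrix, the feature dimension and the provenance metadata.
#' Loading verifies the container signature and internal dimensions and
#' raises an integrity error on truncation or mismatch.
#'
#' @param set An \linkS4class{EmbeddingSet}.
#' @param path File path.
#' @return \code{saveEmbeddings}: invisibly, \code{path};
#'   \code{loadEmbeddings}: the restored \linkS4class{EmbeddingSet}.
#' @export
saveEmbeddings <- function(set, path) {
  stopifnot(is(set, "EmbeddingSet"))
  payload <- list(magic = .EMB_MAGIC, version = 1L, ids = set@ids,
                  features = set@features, numFeature = set@numFeature,
                  metadata = set@metadata)
  saveRDS(payload, path)
  invisible(path)
}

#' @rdname saveEmbeddings
#' @export
loadEmbeddings <- function(path) {
  .stopIfNot(file.exists(path), sprintf("no such file: %s", path))
  payload <- tryCatch(readRDS(path), error = function(e)
    stop(sprintf("integrity error reading %s: %s", path, conditionMessage(e)),
         call. = FALSE))
  if (!is.list(payload) || !identical(payload$magic, .EMB_MAGIC))
    stop(sprintf("integrity error: %s is not an embedding container", path),
         call. = FALSE)
  if (ncol(payload$features) != payload$numFeature ||
      nrow(payload$features) != length(payload$ids))
    stop(sprintf("integrity error: dimension mismatch in %s", path),
         call. = FALSE)
  embeddingSet(payload$features, ids = payload$ids,
               metadata = payload$metadata)
}

#' Merge two EmbeddingSets with disjoint ids
#'
#' @param x,y \linkS4class{EmbeddingSet}s of equal dimension, disjoint ids.
#' @return The row-bound \linkS4class{EmbeddingSet}.
#' @export
mergeEmbeddings <- function(x, y) {
  .stopIfNot(numFeature(x) == numFeature(y),
             "cannot merge embeddings of different dimension")
  .stopIfNot(length(intersect(seqIds(x), seqIds(y))) == 0L,
             "embedding sets share ids; cannot merge")
  embeddingSet(rbind(featureMatrix(x), featureMatrix(y)),
               ids = c(seqIds(x), seqIds(y)), metadata = x@metadata)
}
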
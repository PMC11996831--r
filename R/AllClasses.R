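#' @import methods
#' @importClassesFrom Biostrings AAStringSet
NULL

.LABELS <- c("positive", "negative", "unknown")

#' ProteinCorpus: a labelled set of protein sequences
#'
#' Container for a set of amino-acid sequences together with a binary
#' disease-association label per sequence (\code{"positive"},
#' \code{"negative"} or \code{"unknown"}) and a free-text provenance tag.
#' Sequences are stored as a \linkS4class{AAStringSet}; record identifiers
#' are the names of that set and must be unique.
#'
#' @slot sequences An \code{AAStringSet}; names are the record ids.
#' @slot label Character vector, one of \code{"positive"}, \code{"negative"},
#'   \code{"unknown"} per sequence.
#' @slot source Character vector of provenance tags, one per sequence.
#' @slot metadata List of free-form metadata (e.g. cleaning logs).
#'
#' @seealso \code{\link{proteinCorpus}}, \code{\link{readFastaCorpus}}
#' @export
setClass("ProteinCorpus",
  representation(sequences = "AAStringSet", label = "character",
                 source = "character", metadata = "list"),
  prototype(metadata = list()))

setValidity("ProteinCorpus", function(object) {
  n <- length(object@sequences)
  msg <- character(0)
  ids <- names(object@sequences)
  if (n > 0 && (is.null(ids) || any(!nzchar(ids))))
    msg <- c(msg, "every sequence must have a non-empty id")
  if (!is.null(ids) && anyDuplicated(ids))
    msg <- c(msg, "sequence ids must be unique")
  if (length(object@label) != n)
    msg <- c(msg, "label must have one entry per sequence")
  if (!all(object@label %in% .LABELS))
    msg <- c(msg, sprintf("labels must be one of: %s",
                          paste(.LABELS, collapse = ", ")))
  if (length(object@source) != n)
    msg <- c(msg, "source must have one entry per sequence")
  if (length(msg)) msg else TRUE
})

#' EmbeddingSet: per-sequence fixed-length numeric feature vectors
#'
#' An aligned table of embeddings: one numeric vector of dimension
#' \code{numFeature} per sequence id. Row order carries the id order; all
#' entries must be finite.
#'
#' @slot ids Character vector of sequence ids (unique).
#' @slot features Numeric matrix, rows = ids, columns = features.
#' @slot numFeature Integer, the embedding dimension.
#' @slot metadata List of provenance (embedder name, pooling, parameters).
#'
#' @seealso \code{\link{embedSynthetic}}, \code{\link{embedWithPLM}},
#'   \code{\link{saveEmbeddings}}
#' @export
setClass("EmbeddingSet",
  representation(ids = "character", features = "matrix",
                 numFeature = "integer", metadata = "list"),
  prototype(metadata = list()))

setValidity("EmbeddingSet", function(object) {
  msg <- character(0)
  if (nrow(object@features) != length(object@ids))
    msg <- c(msg, "features must have one row per id")
  if (anyDuplicated(object@ids))
    msg <- c(msg, "ids must be unique")
  if (ncol(object@features) != object@numFeature)
    msg <- c(msg, "feature matrix width must equal numFeature")
  if (object@numFeature < 1L)
    msg <- c(msg, "numFeature must be >= 1")
  if (!all(is.finite(object@features)))
    msg <- c(msg, "embedding matrix must contain only finite values")
  if (!is.null(rownames(object@features)) &&
      !identical(rownames(object@features), object@ids))
    msg <- c(msg, "feature rownames must match ids")
  if (length(msg)) msg else TRUE
})

#' ModelConfig: hyperparameters of the hybrid classifier
#'
#' Bundles every architecture and training hyperparameter of the hybrid
#' Transformer-CNN model. \code{dModel} must be divisible by \code{nHead};
#' the per-head width is \code{dModel / nHead}.
#'
#' @slot dModel Feature width the Transformer branch operates on (equals the
#'   embedding dimension in batch-token mode).
#' @slot nHead Number of self-attention heads.
#' @slot nEncoderLayers Number of stacked encoder layers (>= 1).
#' @slot convOutChannels Output channels of the convolution layer.
#' @slot kernelH,kernelW Convolution kernel height and width.
#' @slot poolH,poolW Max-pooling window height and width (stride = window).
#' @slot fusionHidden Hidden width of the fusion scoring layer.
#' @slot dropout Dropout rate applied after each encoder sublayer in training.
#' @slot variant Architecture variant: \code{"full"}, \code{"no-fusion"},
#'   \code{"cnn-only"} or \code{"transformer-only"}.
#' @slot tokenMode \code{"batch"} (samples are attention tokens, the faithful
#'   mode) or \code{"per-sample"} (each embedding is chunked into tokens of
#'   width \code{dModel}).
#' @slot learningRate,epochs,batchSize Adam learning rate, maximum epochs and
#'   minibatch size.
#' @slot patience Early-stopping patience (epochs without validation-loss
#'   improvement); \code{0} disables early stopping.
#' @slot validFraction Fraction of the training set held out internally for
#'   early stopping when no validation set is supplied.
#' @slot seed Integer seed governing initialisation, batching and dropout.
#'
#' @seealso \code{\link{modelConfig}}, \code{\link{trainModel}}
#' @export
setClass("ModelConfig",
  representation(dModel = "integer", nHead = "integer",
                 nEncoderLayers = "integer",
                 convOutChannels = "integer", kernelH = "integer",
                 kernelW = "integer", poolH = "integer", poolW = "integer",
                 fusionHidden = "integer", dropout = "numeric",
                 variant = "character", tokenMode = "character",
                 learningRate = "numeric", epochs = "integer",
                 batchSize = "integer", patience = "integer",
                 validFraction = "numeric", seed = "integer"))

.VARIANTS <- c("full", "no-fusion", "cnn-only", "transformer-only")

setValidity("ModelConfig", function(object) {
  msg <- character(0)
  dims <- c(object@dModel, object@nHead, object@nEncoderLayers,
            object@convOutChannels, object@kernelH, object@kernelW,
            object@poolH, object@poolW, object@fusionHidden,
            object@epochs, object@batchSize)
  if (any(dims < 1L)) msg <- c(msg, "all dimensions must be >= 1")
  if (object@dModel %% object@nHead != 0L)
    msg <- c(msg, "dModel must be divisible by nHead")
  if (!object@variant %in% .VARIANTS)
    msg <- c(msg, sprintf("variant must be one of: %s",
                          paste(.VARIANTS, collapse = ", ")))
  if (!object@tokenMode %in% c("batch", "per-sample"))
    msg <- c(msg, "tokenMode must be 'batch' or 'per-sample'")
  if (object@dropout < 0 || object@dropout >= 1)
    msg <- c(msg, "dropout must lie in [0, 1)")
  if (object@validFraction < 0 || object@validFraction >= 1)
    msg <- c(msg, "validFraction must lie in [0, 1)")
  if (object@learningRate <= 0) msg <- c(msg, "learningRate must be > 0")
  if (length(msg)) msg else TRUE
})

#' ConfusionCounts: binary confusion-matrix tallies
#'
#' TP/FP/TN/FN counts of a binary classifier, the basis of all scalar
#' evaluation metrics.
#'
#' @slot TP,FP,TN,FN Non-negative integer tallies.
#' @seealso \code{\link{confusionCounts}}, \code{\link{metricsFromConfusion}}
#' @export
setClass("ConfusionCounts",
  representation(TP = "integer", FP = "integer", TN = "integer",
                 FN = "integer"))

setValidity("ConfusionCounts", function(object) {
  counts <- c(object@TP, object@FP, object@TN, object@FN)
  if (any(counts < 0L)) "all counts must be non-negative" else TRUE
})

#' FoldReport: per-fold and aggregated cross-validation results
#'
#' Holds per-fold scalar metrics, the ROC and PR curve points of each fold,
#' and the across-fold arithmetic means.
#'
#' @slot folds data.frame with one row per fold (accuracy, precision,
#'   recall, f1, mcc, auc, aupr).
#' @slot curves List (one element per fold) of lists with \code{roc} and
#'   \code{pr} data.frames.
#' @slot aggregate Named numeric vector of across-fold means.
#' @slot nFolds Integer number of folds.
#' @seealso \code{\link{crossValidate}}
#' @export
setClass("FoldReport",
  representation(folds = "data.frame", curves = "list",
                 aggregate = "numeric", nFolds = "integer"))

setValidity("FoldReport", function(object) {
  msg <- character(0)
  if (nrow(object@folds) != object@nFolds)
    msg <- c(msg, "folds must have one row per fold")
  if (length(object@curves) != object@nFolds)
    msg <- c(msg, "curves must have one entry per fold")
  rate <- intersect(c("accuracy", "precision", "recall", "f1", "auc", "aupr"),
                    colnames(object@folds))
  for (m in rate) {
    v <- object@folds[[m]]
    if (any(v < -1e-9 | v > 1 + 1e-9)) {
      msg <- c(msg, sprintf("metric %s must lie in [0, 1]", m))
    }
  }
  if ("mcc" %in% colnames(object@folds) &&
      any(abs(object@folds$mcc) > 1 + 1e-9))
    msg <- c(msg, "mcc must lie in [-1, 1]")
  if (length(msg)) msg else TRUE
})

#' GeneratorSpec: parameters of the synthetic corpus generator
#'
#' Describes a two-class synthetic protein corpus: class size, length range,
#' the motif planted in positives and its prevalence, the fraction of
#' near-duplicate records (for exercising redundancy filtering), and whether
#' the motif is biased towards the sequence prefix (positional signal).
#'
#' @slot nPerClass Records per class.
#' @slot lengthRange Integer vector of length 2: min and max residues.
#' @slot motif Residue string planted in positive sequences.
#' @slot motifRate Fraction of positives carrying the motif.
#' @slot nearDuplicateRate Fraction of records emitted as >90\%-identical
#'   copies of another record of the same class.
#' @slot positionalSignal Logical; if TRUE the motif is planted within the
#'   first fifth of the sequence, so prefix truncation preserves the signal
#'   and heavy segment shuffling destroys it.
#' @slot seed Integer seed; the corpus is a pure function of the spec.
#' @seealso \code{\link{generatorSpec}}, \code{\link{generateCorpus}}
#' @export
setClass("GeneratorSpec",
  representation(nPerClass = "integer", lengthRange = "integer",
                 motif = "character", motifRate = "numeric",
                 nearDuplicateRate = "numeric", positionalSignal = "logical",
                 seed = "integer"))

setValidity("GeneratorSpec", function(object) {
  msg <- character(0)
  if (object@nPerClass < 1L) msg <- c(msg, "nPerClass must be >= 1")
  if (length(object@lengthRange) != 2L ||
      object@lengthRange[1] > object@lengthRange[2] ||
      object@lengthRange[1] < 1L)
    msg <- c(msg, "lengthRange must be (min, max) with 1 <= min <= max")
  if (object@motifRate < 0 || object@motifRate > 1)
    msg <- c(msg, "motifRate must lie in [0, 1]")
  if (object@nearDuplicateRate < 0 || object@nearDuplicateRate > 1)
    msg <- c(msg, "nearDuplicateRate must lie in [0, 1]")
  if (nchar(object@motif) > object@lengthRange[1])
    msg <- c(msg, "motif cannot be longer than the minimum sequence length")
  if (nchar(object@motif) > 0 &&
      !all(strsplit(object@motif, "")[[1]] %in% .AA20))
    msg <- c(msg, "motif must use canonical residues only")
  if (length(msg)) msg else TRUE
})

#' HybridFit: a trained hybrid Transformer-CNN classifier
#'
#' A fitted model: configuration, all weight tensors, the training loss
#' trace, and the feature standardisation (centre/scale learned on the
#' training data) applied before the network.
#'
#' @slot config The \linkS4class{ModelConfig} used.
#' @slot params Nested list of weight matrices and biases.
#' @slot lossTrace data.frame with per-epoch training (and, when available,
#'   validation) cross-entropy.
#' @slot center,scale Numeric vectors standardising incoming features.
#' @seealso \code{\link{trainModel}}, \code{\link{predictProba}}
#' @export
setClass("HybridFit",
  representation(config = "ModelConfig", params = "list",
                 lossTrace = "data.frame", center = "numeric",
                 scale = "numeric"))
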
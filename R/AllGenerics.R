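#' @include AllClasses.R
NULL

#' Record identifiers of a container
#' @param x A \linkS4class{ProteinCorpus} or \linkS4class{EmbeddingSet}.
#' @return Character vector of ids.
#' @export
setGeneric("seqIds", function(x) standardGeneric("seqIds"))

#' Sequences of a corpus
#' @param x A \linkS4class{ProteinCorpus}.
#' @return The underlying \code{AAStringSet}.
#' @export
setGeneric("sequences", function(x) standardGeneric("sequences"))

#' Provenance tags of a corpus
#' @param x A \linkS4class{ProteinCorpus}.
#' @return Character vector of source tags.
#' @export
setGeneric("sources", function(x) standardGeneric("sources"))

#' Embedding matrix of an EmbeddingSet
#' @param x An \linkS4class{EmbeddingSet}.
#' @return Numeric matrix (rows = sequences).
#' @export
setGeneric("featureMatrix", function(x) standardGeneric("featureMatrix"))

#' Embedding dimension
#' @param x An \linkS4class{EmbeddingSet}.
#' @return Integer feature dimension.
#' @export
setGeneric("numFeature", function(x) standardGeneric("numFeature"))
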
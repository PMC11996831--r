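#' @include corpus.R
NULL

#' Construct a GeneratorSpec
#'
#' @param nPerClass Records per class.
#' @param lengthRange Integer (min, max) sequence length in residues; the
#'   default spans the length range typical of disease-gene corpora.
#' @param motif Residue string planted in positives.
#' @param motifRate Fraction of positives carrying the motif.
#' @param nearDuplicateRate Fraction of records emitted as near-identical
#'   (>90\%) copies of another record of the same class.
#' @param positionalSignal If TRUE, motifs are planted within the first
#'   fifth of each sequence.
#' @param seed Integer seed.
#' @return A validated \linkS4class{GeneratorSpec}.
#' @export
generatorSpec <- function(nPerClass = 500L, lengthRange = c(100L, 1500L),
                          motif = "WKDHQCNEYR", motifRate = 1,
                          nearDuplicateRate = 0, positionalSignal = FALSE,
                          seed = 1L) {
  new("GeneratorSpec", nPerClass = as.integer(nPerClass),
      lengthRange = as.integer(lengthRange), motif = motif,
      motifRate = motifRate, nearDuplicateRate = nearDuplicateRate,
      positionalSignal = positionalSignal, seed = as.integer(seed))
}

setMethod("show", "GeneratorSpec", function(object) {
  cat(sprintf(paste0(
    "GeneratorSpec: %d/class, length %d-%d, motif '%s' at rate %.2f",
    " (%s), dup rate %.2f, seed %d\n"),
    object@nPerClass, object@lengthRange[1], object@lengthRange[2],
    object@motif, object@motifRate,
    if (object@positionalSignal) "prefix-biased" else "uniform position",
    object@nearDuplicateRate, object@seed))
})

.randomProtein <- function(len) {
  paste(sample(.AA20, len, replace = TRUE), collapse = "")
}

# Mutate ~rate of the positions to a different residue (>= 1 mutation).
.pointMutate <- function(seq, rate = 0.01) {
  chars <- strsplit(seq, "")[[1]]
  nMut <- max(1L, round(rate * length(chars)))
  pos <- sample.int(length(chars), nMut)
  for (p in pos) {
    chars[p] <- sample(setdiff(.AA20, chars[p]), 1L)
  }
  paste(chars, collapse = "")
}

#' Generate a labelled synthetic protein corpus
#'
#' Emits a balanced two-class corpus over the 20-letter amino-acid alphabet:
#' negatives are i.i.d. uniform residue strings; positives additionally
#' carry the spec motif (at the spec rate) planted at a seeded position —
#' uniform along the sequence, or within the first fifth when
#' \code{positionalSignal} is set, so that prefix truncation retains the
#' class signal while heavy segment shuffling destroys it. Both classes
#' share the same length distribution. A fraction of records per class are
#' near-duplicates: copies of a previously generated record of the same
#' class with ~1\% point mutations (>90\% identity), for exercising
#' redundancy filtering. The returned manifest records every planted motif
#' position and every duplicate pairing. The output is a pure function of
#' the spec (including its seed).
#'
#' @param spec A \linkS4class{GeneratorSpec}.
#' @return List: \code{corpus} (a \linkS4class{ProteinCorpus}) and
#'   \code{manifest} (list with \code{motifs} — data.frame id/start/end —
#'   and \code{duplicates} — data.frame id/donor).
#' @export
generateCorpus <- function(spec) {
  stopifnot(is(spec, "GeneratorSpec"))
  validObject(spec)
  motifLen <- nchar(spec@motif)
  .withSeed(.mixSeed(spec@seed, 5L), {
    n <- spec@nPerClass
    nDup <- round(spec@nearDuplicateRate * n)
    nBase <- n - nDup
    .stopIfNot(nBase >= 1L,
               "nearDuplicateRate leaves no base records to copy from")
    seqs <- character(0)
    ids <- character(0)
    labs <- character(0)
    motifRows <- list()
    dupRows <- list()
    for (cls in c("positive", "negative")) {
      prefix <- if (cls == "positive") "P" else "N"
      baseIds <- sprintf("%s%04d", prefix, seq_len(nBase))
      baseSeqs <- character(nBase)
      nMotif <- round(spec@motifRate * nBase)
      motifCarriers <- if (cls == "positive" && motifLen > 0) {
        sort(sample.int(nBase, nMotif))
      } else {
        integer(0)
      }
      for (i in seq_len(nBase)) {
        L <- sample(spec@lengthRange[1]:spec@lengthRange[2], 1L)
        s <- .randomProtein(L)
        if (i %in% motifCarriers) {
          maxStart <- if (spec@positionalSignal) {
            max(1L, min(round(0.2 * L), L - motifLen + 1L))
          } else {
            L - motifLen + 1L
          }
          start <- sample.int(maxStart, 1L)
          substr(s, start, start + motifLen - 1L) <- spec@motif
          motifRows[[length(motifRows) + 1L]] <-
            data.frame(id = baseIds[i], start = start,
                       end = start + motifLen - 1L)
        }
        baseSeqs[i] <- s
      }
      dupIds <- character(0)
      dupSeqs <- character(0)
      if (nDup > 0) {
        # unique donors keep duplicate families pairwise, so the greedy
        # filter removes exactly one record per planted pairing
        donors <- sample.int(nBase, nDup, replace = nDup > nBase)
        dupIds <- sprintf("%s%04dDUP", prefix, seq_len(nDup))
        dupSeqs <- vapply(seq_len(nDup), function(j) {
          .pointMutate(baseSeqs[donors[j]], 0.01)
        }, character(1))
        dupRows[[length(dupRows) + 1L]] <-
          data.frame(id = dupIds, donor = baseIds[donors])
      }
      seqs <- c(seqs, baseSeqs, dupSeqs)
      ids <- c(ids, baseIds, dupIds)
      labs <- c(labs, rep(cls, nBase + nDup))
    }
    names(seqs) <- ids
    corpus <- proteinCorpus(seqs, label = labs, source = "synthetic")
    manifest <- list(
      motifs = if (length(motifRows)) do.call(rbind, motifRows) else
        data.frame(id = character(0), start = integer(0), end = integer(0)),
      duplicates = if (length(dupRows)) do.call(rbind, dupRows) else
        data.frame(id = character(0), donor = character(0)))
    list(corpus = corpus, manifest = manifest)
  })
}

#' Write a generated corpus to disk
#'
#' Emits FASTA, a two-column label TSV and a JSON manifest.
#'
#' @param generated The list returned by \code{\link{generateCorpus}}.
#' @param dir Output directory (created if needed).
#' @return Invisibly, \code{dir}.
#' @export
writeGeneratedCorpus <- function(generated, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  writeFastaCorpus(generated$corpus, file.path(dir, "corpus.fasta"),
                   file.path(dir, "labels.tsv"))
  jsonlite::write_json(generated$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
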
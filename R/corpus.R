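#' @include AllGenerics.R
#' @importFrom Biostrings AAStringSet readAAStringSet writeXStringSet width
NULL

#' Construct a ProteinCorpus
#'
#' @param sequences An \code{AAStringSet}, or a named character vector of
#'   residue strings.
#' @param label Character vector of labels (\code{"positive"},
#'   \code{"negative"}, \code{"unknown"}); recycled if scalar.
#' @param source Character vector of provenance tags; recycled if scalar.
#' @return A \linkS4class{ProteinCorpus}.
#' @examples
#' proteinCorpus(c(a = "MKV", b = "ACDY"), label = "positive")
#' @export
proteinCorpus <- function(sequences, label = "unknown", source = "") {
  if (is.character(sequences)) sequences <- AAStringSet(sequences)
  n <- length(sequences)
  if (length(label) == 1L) label <- rep(label, n)
  if (length(source) == 1L) source <- rep(source, n)
  new("ProteinCorpus", sequences = sequences, label = label, source = source)
}

#' @rdname seqIds
#' @export
setMethod("seqIds", "ProteinCorpus", function(x) names(x@sequences))

#' @rdname sequences
#' @export
setMethod("sequences", "ProteinCorpus", function(x) x@sequences)

#' @rdname sources
#' @export
setMethod("sources", "ProteinCorpus", function(x) x@source)

#' Labels of a corpus
#' @param object A \linkS4class{ProteinCorpus}.
#' @param ... Ignored.
#' @return Character vector of labels.
#' @export
setMethod("labels", "ProteinCorpus", function(object, ...) object@label)

#' Number of records in a corpus
#' @param x A \linkS4class{ProteinCorpus}.
#' @export
setMethod("length", "ProteinCorpus", function(x) length(x@sequences))

#' Subset a corpus by index or id
#' @param x A \linkS4class{ProteinCorpus}.
#' @param i Integer, logical or character (ids) index.
#' @param j,...,drop Ignored.
#' @export
setMethod("[", "ProteinCorpus", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) i <- match(i, seqIds(x))
  initialize(x, sequences = x@sequences[i], label = x@label[i],
             source = x@source[i])
})

setMethod("show", "ProteinCorpus", function(object) {
  tab <- table(factor(object@label, levels = .LABELS))
  cat(sprintf(
    "ProteinCorpus with %d sequences (%d positive, %d negative, %d unknown)\n",
    length(object), tab[["positive"]], tab[["negative"]], tab[["unknown"]]))
  if (length(object)) {
    w <- width(object@sequences)
    cat(sprintf("  length range: %d-%d residues\n", min(w), max(w)))
  }
})

#' Read a FASTA file into a ProteinCorpus
#'
#' Reads amino-acid FASTA, upper-casing residues, and optionally attaches
#' labels from a two-column sidecar TSV (id, label) or from the FASTA header
#' itself after a delimiter (e.g. \code{">P1|positive"}).
#'
#' @param path FASTA file path.
#' @param labels Optional: path to a headerless two-column TSV (id, label),
#'   or a named character vector of labels keyed by id.
#' @param labelDelim Optional single character; when given, the part of each
#'   header after the last occurrence of this delimiter is taken as the label
#'   and stripped from the id.
#' @param onDuplicateIds \code{"error"} (default) or \code{"suffix"}:
#'   duplicate ids either abort or are made unique with \code{.1}, \code{.2}
#'   suffixes.
#' @param source Provenance tag stored on every record.
#' @return A \linkS4class{ProteinCorpus}; records without label information
#'   are labelled \code{"unknown"}.
#' @export
readFastaCorpus <- function(path, labels = NULL, labelDelim = NULL,
                            onDuplicateIds = c("error", "suffix"),
                            source = basename(path)) {
  onDuplicateIds <- match.arg(onDuplicateIds)
  .stopIfNot(file.exists(path), sprintf("FASTA file not found: %s", path))
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) == 0L)
    stop(sprintf("parse error in %s at line 1: file is empty", path),
         call. = FALSE)
  if (!startsWith(first, ">"))
    stop(sprintf("parse error in %s at line 1: expected a '>' header", path),
         call. = FALSE)
  aa <- readAAStringSet(path)
  if (length(aa) == 0L)
    stop(sprintf("parse error in %s: no FASTA records", path), call. = FALSE)
  ids <- sub("\\s.*$", "", names(aa))
  lab <- rep("unknown", length(aa))
  if (!is.null(labelDelim)) {
    hasDelim <- grepl(labelDelim, ids, fixed = TRUE)
    lab[hasDelim] <- sub(paste0("^.*\\", labelDelim), "", ids[hasDelim])
    ids[hasDelim] <- sub(paste0("\\", labelDelim, "[^", "\\", labelDelim,
                                "]*$"), "", ids[hasDelim])
  }
  if (anyDuplicated(ids)) {
    if (onDuplicateIds == "error") {
      dup <- ids[duplicated(ids)][1]
      stop(sprintf("duplicate FASTA id '%s' in %s", dup, path), call. = FALSE)
    }
    ids <- make.unique(ids, sep = ".")
  }
  seqs <- toupper(as.character(aa))
  emptyIdx <- which(nchar(seqs) == 0L)
  if (length(emptyIdx))
    stop(sprintf("parse error in %s: record '%s' has an empty sequence",
                 path, ids[emptyIdx[1]]), call. = FALSE)
  names(seqs) <- ids
  if (!is.null(labels)) {
    if (is.character(labels) && length(labels) == 1L && file.exists(labels)) {
      tab <- utils::read.table(labels, sep = "\t", header = FALSE,
                               col.names = c("id", "label"),
                               colClasses = "character")
      labels <- stats::setNames(tab$label, tab$id)
    }
    hit <- ids %in% names(labels)
    lab[hit] <- unname(labels[ids[hit]])
  }
  bad <- setdiff(unique(lab), .LABELS)
  .stopIfNot(length(bad) == 0L,
             sprintf("unrecognised label(s): %s", paste(bad, collapse = ", ")))
  proteinCorpus(seqs, label = lab, source = source)
}

#' Write a corpus to FASTA plus a label sidecar TSV
#'
#' @param corpus A \linkS4class{ProteinCorpus}.
#' @param fastaPath Output FASTA path.
#' @param labelsPath Optional output path of a two-column TSV (id, label).
#' @return Invisibly, \code{fastaPath}.
#' @export
writeFastaCorpus <- function(corpus, fastaPath, labelsPath = NULL) {
  writeXStringSet(sequences(corpus), fastaPath)
  if (!is.null(labelsPath)) {
    utils::write.table(
      data.frame(id = seqIds(corpus), label = labels(corpus)),
      labelsPath, sep = "\t", quote = FALSE,
      row.names = FALSE, col.names = FALSE)
  }
  invisible(fastaPath)
}

#' Clean non-canonical residues
#'
#' Restricts sequences to the 20 canonical amino acids. Non-canonical
#' characters (B, Z, J, U, O, X, *, gaps, ...) are handled per policy:
#' \code{"substitute-X"} replaces them with \code{X} (preserving length, the
#' default), \code{"strip"} deletes them, and \code{"drop"} discards any
#' record containing one. Records left empty are rejected. The actions taken
#' are recorded in the returned corpus' metadata as \code{cleaningLog}.
#'
#' @param corpus A \linkS4class{ProteinCorpus}.
#' @param policy One of \code{"substitute-X"}, \code{"strip"}, \code{"drop"}.
#' @return A cleaned \linkS4class{ProteinCorpus}; metadata holds a
#'   \code{cleaningLog} data.frame (id, action, reason) and
#'   \code{nCorrected}, the number of records altered or removed.
#' @examples
#' cc <- proteinCorpus(c(a = "ACB*EF"))
#' sequences(cleanSequences(cc, "strip"))
#' @export
cleanSequences <- function(corpus,
                           policy = c("substitute-X", "strip", "drop")) {
  policy <- match.arg(policy)
  seqs <- as.character(sequences(corpus))
  canonical <- paste(.AA20, collapse = "")
  badPattern <- sprintf("[^%s]", canonical)
  dirty <- grepl(badPattern, seqs)
  log <- data.frame(id = character(0), action = character(0),
                    reason = character(0))
  keep <- rep(TRUE, length(seqs))
  if (any(dirty)) {
    idsD <- seqIds(corpus)[dirty]
    if (policy == "substitute-X") {
      seqs[dirty] <- gsub(badPattern, "X", seqs[dirty])
      log <- rbind(log, data.frame(id = idsD, action = "substitute-X",
                                   reason = "non-canonical residues"))
    } else if (policy == "strip") {
      seqs[dirty] <- gsub(badPattern, "", seqs[dirty])
      log <- rbind(log, data.frame(id = idsD, action = "strip",
                                   reason = "non-canonical residues"))
      empty <- dirty & nchar(seqs) == 0L
      if (any(empty)) {
        keep[empty] <- FALSE
        log <- rbind(log, data.frame(
          id = seqIds(corpus)[empty], action = "reject",
          reason = "empty after stripping non-canonical residues"))
      }
    } else {
      keep[dirty] <- FALSE
      log <- rbind(log, data.frame(id = idsD, action = "reject",
                                   reason = "contains non-canonical residues"))
    }
  }
  out <- corpus[which(keep)]
  cleaned <- AAStringSet(seqs[keep])
  names(cleaned) <- seqIds(out)
  out@sequences <- cleaned
  out@metadata$cleaningLog <- log
  out@metadata$nCorrected <- sum(dirty)
  validObject(out)
  out
}

# Shared-k-mer identity estimate between two residue strings: fraction of
# the shorter sequence's distinct k-mers found in the longer one. Sequences
# shorter than k fall back to exact string equality.
.kmerIdentity <- function(a, b, k = 5L) {
  ka <- .kmerSet(a, k)
  kb <- .kmerSet(b, k)
  if (length(ka) == 0L || length(kb) == 0L) return(as.numeric(a == b))
  if (length(ka) <= length(kb)) {
    sum(ka %in% kb) / length(ka)
  } else {
    sum(kb %in% ka) / length(kb)
  }
}

#' Greedy redundancy filtering of near-identical sequences
#'
#' Removes sequences sharing more than \code{identityThreshold} identity with
#' an already-kept sequence, in the greedy longest-first fashion of CD-HIT:
#' records are sorted by length (descending, ties broken by id), each record
#' joins the first cluster whose representative it matches at or above the
#' threshold, otherwise it founds a new cluster, and cluster representatives
#' are returned. Identity is estimated as the shared 5-mer fraction over the
#' shorter sequence; this approximation is fast and, on realistic corpora,
#' agrees with exact alignment identity at the 0.9 operating point.
#'
#' @param corpus A \linkS4class{ProteinCorpus}.
#' @param identityThreshold Identity threshold in (0, 1]; default 0.9.
#' @param k k-mer size of the identity estimate.
#' @param method \code{"builtin"} (greedy k-mer filter) or \code{"cdhit"}
#'   (delegate to an installed \command{cd-hit} binary).
#' @return A list: \code{kept} (representatives, a
#'   \linkS4class{ProteinCorpus}), \code{summary} (named counts: kept per
#'   label and number removed), and \code{clusters} (data.frame mapping every
#'   input id to its representative id).
#' @export
redundancyFilter <- function(corpus, identityThreshold = 0.9, k = 5L,
                             method = c("builtin", "cdhit")) {
  method <- match.arg(method)
  .stopIfNot(identityThreshold > 0 && identityThreshold <= 1,
             "identityThreshold must lie in (0, 1]")
  .stopIfNot(length(corpus) >= 1L, "corpus must contain at least one record")
  if (method == "cdhit") {
    if (Sys.which("cd-hit") == "")
      stop("cd-hit binary not found on PATH; use method = 'builtin'",
           call. = FALSE)
    return(.cdhitFilter(corpus, identityThreshold))
  }
  seqs <- as.character(sequences(corpus))
  ids <- seqIds(corpus)
  ord <- order(-nchar(seqs), ids)
  repIdx <- integer(0)         # indices (into original order) of reps
  assignment <- integer(length(seqs))
  for (i in ord) {
    placed <- FALSE
    for (r in repIdx) {
      if (.kmerIdentity(seqs[i], seqs[r], k) >= identityThreshold) {
        assignment[i] <- r
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      repIdx <- c(repIdx, i)
      assignment[i] <- i
    }
  }
  keptIdx <- sort(repIdx)
  kept <- corpus[keptIdx]
  lab <- labels(kept)
  summary <- c(nKept = length(keptIdx),
               nPositive = sum(lab == "positive"),
               nNegative = sum(lab == "negative"),
               nRemovedRedundant = length(corpus) - length(keptIdx))
  clusters <- data.frame(id = ids, representative = ids[assignment])
  list(kept = kept, summary = summary, clusters = clusters)
}

# Adapter around an external cd-hit binary (only reachable when the binary
# is installed; the builtin filter is the supported default).
.cdhitFilter <- function(corpus, identityThreshold) {
  dir <- tempfile("cdhit")
  dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE), add = TRUE)
  fin <- file.path(dir, "in.fasta")
  fout <- file.path(dir, "out.fasta")
  writeFastaCorpus(corpus, fin)
  status <- system2("cd-hit", c("-i", fin, "-o", fout,
                                "-c", format(identityThreshold), "-n", "5"),
                    stdout = FALSE, stderr = FALSE)
  .stopIfNot(status == 0L, "cd-hit invocation failed")
  keptIds <- sub("\\s.*$", "", names(readAAStringSet(fout)))
  kept <- corpus[keptIds]
  lab <- labels(kept)
  list(kept = kept,
       summary = c(nKept = length(kept),
                   nPositive = sum(lab == "positive"),
                   nNegative = sum(lab == "negative"),
                   nRemovedRedundant = length(corpus) - length(kept)),
       clusters = NULL)
}

#' Sample background (negative) sequences
#'
#' Draws \code{n} records uniformly without replacement from a candidate
#' pool, excluding anything sharing an id or an exact sequence with the
#' positive set, and labels the draw \code{"negative"}. Reproducible from
#' the seed.
#'
#' @param pool Candidate \linkS4class{ProteinCorpus}.
#' @param positives Positive \linkS4class{ProteinCorpus} to exclude.
#' @param n Number of records to draw (typically \code{length(positives)}
#'   for a balanced corpus).
#' @param seed Integer seed.
#' @return A \linkS4class{ProteinCorpus} of \code{n} negative records.
#' @export
sampleNegatives <- function(pool, positives, n = length(positives), seed) {
  posIds <- seqIds(positives)
  posSeqs <- as.character(sequences(positives))
  eligible <- which(!(seqIds(pool) %in% posIds) &
                    !(as.character(sequences(pool)) %in% posSeqs))
  if (length(eligible) < n)
    stop(sprintf(
      "insufficient eligible pool: need %d, have %d (short by %d)",
      n, length(eligible), n - length(eligible)), call. = FALSE)
  pick <- .withSeed(seed, sort(sample(eligible, n)))
  out <- pool[pick]
  out@label <- rep("negative", n)
  out
}

#' Combine two corpora
#'
#' @param x,y \linkS4class{ProteinCorpus} objects with disjoint ids.
#' @return The concatenated \linkS4class{ProteinCorpus}.
#' @export
combineCorpora <- function(x, y) {
  .stopIfNot(length(intersect(seqIds(x), seqIds(y))) == 0L,
             "corpora share ids; cannot combine")
  new("ProteinCorpus",
      sequences = c(sequences(x), sequences(y)),
      label = c(labels(x), labels(y)),
      source = c(sources(x), sources(y)),
      metadata = c(x@metadata, y@metadata))
}
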
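#' @include evaluation.R
NULL

#' Truncate sequences to a prefix
#'
#' Replaces each sequence by its first \code{limit} residues (sequences
#' already shorter are unchanged); models the incomplete-sequence study in
#' which only the first 500 amino acids of each protein are available.
#' Idempotent.
#'
#' @param corpus A \linkS4class{ProteinCorpus}.
#' @param limit Maximum residue count (>= 1); default 500.
#' @return The truncated \linkS4class{ProteinCorpus}.
#' @export
truncateSequences <- function(corpus, limit = 500L) {
  .stopIfNot(limit >= 1L, "limit must be >= 1")
  seqs <- as.character(sequences(corpus))
  out <- corpus
  trunc <- Biostrings::AAStringSet(substr(seqs, 1L, limit))
  names(trunc) <- seqIds(corpus)
  out@sequences <- trunc
  out
}

#' Shuffle a contiguous segment of each sequence
#'
#' Sequence-level noise model: per record, a contiguous window covering
#' \code{round(ratio * length)} residues is placed at a seeded uniform start
#' position and its residues are uniformly permuted; everything outside the
#' window is untouched. Length and residue multiset are always conserved.
#' The window position and permutation are drawn from a per-record RNG
#' substream (seed mixed with the record id), so the perturbation of one
#' record does not depend on corpus order. With \code{windows > 1} the
#' shuffled mass is split over several non-overlapping windows whose lengths
#' sum to the same total.
#'
#' @param corpus A \linkS4class{ProteinCorpus}.
#' @param ratio Fraction of each sequence's length to shuffle, in [0, 1].
#' @param seed Integer seed.
#' @param windows Number of contiguous windows per sequence (default 1).
#' @return The perturbed \linkS4class{ProteinCorpus}.
#' @export
shuffleSegment <- function(corpus, ratio, seed, windows = 1L) {
  .stopIfNot(ratio >= 0 && ratio <= 1, "ratio must lie in [0, 1]")
  .stopIfNot(windows >= 1L, "windows must be >= 1")
  if (ratio == 0) return(corpus)
  seqs <- as.character(sequences(corpus))
  ids <- seqIds(corpus)
  for (i in seq_along(seqs)) {
    L <- nchar(seqs[i])
    total <- round(ratio * L)
    if (total < 2L) next
    chars <- strsplit(seqs[i], "")[[1]]
    .withSeed(.mixSeed(seed, .hashString(ids[i], salt = 13L)), {
      lens <- diff(round(seq(0, total, length.out = windows + 1L)))
      lens <- lens[lens >= 1L]
      used <- rep(FALSE, L)
      for (wl in lens) {
        # rejection-sample a start so windows do not overlap
        for (try in seq_len(50L)) {
          s <- sample.int(L - wl + 1L, 1L)
          if (!any(used[s:(s + wl - 1L)])) break
        }
        win <- s:(s + wl - 1L)
        used[win] <- TRUE
        if (wl >= 2L) chars[win] <- chars[win][sample.int(wl)]
      }
    })
    seqs[i] <- paste(chars, collapse = "")
  }
  out <- corpus
  shuf <- Biostrings::AAStringSet(seqs)
  names(shuf) <- ids
  out@sequences <- shuf
  out
}

#' Run a paired ablation grid
#'
#' Cross-validates one model per ablation specification — a variant
#' (\code{"full"}, \code{"no-fusion"}, \code{"cnn-only"},
#' \code{"transformer-only"}) optionally combined with an encoder depth —
#' using a single shared fold split so the comparisons are paired.
#'
#' @param embeddings \linkS4class{EmbeddingSet} or feature matrix.
#' @param y Labels.
#' @param specs data.frame with columns \code{variant} and (optionally)
#'   \code{nEncoderLayers}; one row per ablation.
#' @param config Base \linkS4class{ModelConfig}; each spec row overrides its
#'   variant / encoder depth.
#' @param k Number of folds.
#' @param seed Seed of the shared fold split and training.
#' @return List: \code{summary} (data.frame, one row per spec with mean
#'   metrics), \code{reports} (list of \linkS4class{FoldReport}s),
#'   \code{folds} (the shared split).
#' @export
runAblationGrid <- function(embeddings, y, specs, config, k = 5L,
                            seed = 1L) {
  .stopIfNot(is.data.frame(specs) && "variant" %in% colnames(specs),
             "specs must be a data.frame with a 'variant' column")
  if (is(embeddings, "EmbeddingSet")) embeddings <- featureMatrix(embeddings)
  y01 <- .asLabel01(y)
  folds <- kFoldSplit(nrow(embeddings), k, y01, seed)
  reports <- vector("list", nrow(specs))
  rows <- vector("list", nrow(specs))
  for (i in seq_len(nrow(specs))) {
    cfg <- config
    cfg@variant <- as.character(specs$variant[i])
    if ("nEncoderLayers" %in% colnames(specs) &&
        !is.na(specs$nEncoderLayers[i]))
      cfg@nEncoderLayers <- as.integer(specs$nEncoderLayers[i])
    validObject(cfg)
    rep <- crossValidate(embeddings, y01, cfg, folds = folds, seed = seed)
    reports[[i]] <- rep
    agg <- aggregateMetrics(rep)
    rows[[i]] <- data.frame(variant = cfg@variant,
                            nEncoderLayers = cfg@nEncoderLayers,
                            t(agg))
  }
  list(summary = do.call(rbind, rows), reports = reports, folds = folds)
}

#' Shuffle-ratio robustness sweep
#'
#' For every shuffle ratio: perturb the sequences (\code{shuffleSegment}),
#' re-embed the perturbed corpus, and cross-validate with the same fold
#' seed. A ratio of 0 reproduces the unperturbed result exactly. Returns the
#' mean AUC/AUPR per ratio (the data behind a robustness curve).
#'
#' @param corpus A labelled \linkS4class{ProteinCorpus}.
#' @param embedder Function \code{corpus -> EmbeddingSet} (e.g. a wrapper
#'   around \code{\link{embedSynthetic}}).
#' @param ratios Numeric vector of shuffle ratios in [0, 1].
#' @param config A \linkS4class{ModelConfig}.
#' @param k Number of folds.
#' @param seed Seed for perturbation, fold split and training.
#' @param windows Windows per sequence passed to \code{shuffleSegment}.
#' @return List: \code{summary} (data.frame ratio / meanAuc / meanAupr),
#'   \code{reports} (list of \linkS4class{FoldReport}s, one per ratio).
#' @export
runNoiseSweep <- function(corpus, embedder, ratios, config, k = 5L,
                          seed = 1L, windows = 1L) {
  .stopIfNot(all(ratios >= 0 & ratios <= 1), "ratios must lie in [0, 1]")
  reports <- vector("list", length(ratios))
  rows <- vector("list", length(ratios))
  y <- labels(corpus)
  for (i in seq_along(ratios)) {
    perturbed <- shuffleSegment(corpus, ratios[i], seed, windows = windows)
    emb <- embedder(perturbed)
    reports[[i]] <- crossValidate(emb, y, config, k = k, seed = seed)
    agg <- aggregateMetrics(reports[[i]])
    rows[[i]] <- data.frame(ratio = ratios[i], meanAuc = agg[["auc"]],
                            meanAupr = agg[["aupr"]])
  }
  list(summary = do.call(rbind, rows), reports = reports)
}
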
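# Small in-code fixtures shared across test files.

tinyConfig <- function(...) {
  args <- list(dModel = 8L, nHead = 2L, nEncoderLayers = 1L,
               convOutChannels = 2L, kernelH = 2L, kernelW = 2L,
               poolH = 1L, poolW = 1L, fusionHidden = 5L, dropout = 0,
               epochs = 5L, batchSize = 8L, patience = 0L,
               validFraction = 0, seed = 3L)
  do.call(modelConfig, utils::modifyList(args, list(...)))
}

randomCorpus <- function(n = 6L, lens = 30:60, seed = 1L, label = "unknown",
                         prefix = "S") {
  seqs <- ProtFuse:::.withSeed(seed, {
    vapply(seq_len(n), function(i) {
      paste(sample(ProtFuse:::.AA20, sample(lens, 1), replace = TRUE),
            collapse = "")
    }, character(1))
  })
  names(seqs) <- sprintf("%s%03d", prefix, seq_len(n))
  proteinCorpus(seqs, label = label)
}

writeTempFasta <- function(seqs, ids = names(seqs)) {
  path <- tempfile(fileext = ".fasta")
  writeLines(paste0(">", ids, "\n", seqs), path)
  path
}
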
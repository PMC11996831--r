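test_that("readFastaCorpus preserves entries, order and upper-cases", {
  path <- writeTempFasta(c(a1 = "MKVL", a2 = "acdwy"))
  corp <- readFastaCorpus(path)
  expect_s4_class(corp, "ProteinCorpus")
  expect_equal(length(corp), 2L)
  expect_equal(seqIds(corp), c("a1", "a2"))
  expect_equal(as.character(sequences(corp))[["a2"]], "ACDWY")
  expect_true(all(labels(corp) == "unknown"))
})

test_that("readFastaCorpus errors usefully on empty and malformed input", {
  empty <- tempfile(fileext = ".fasta")
  file.create(empty)
  expect_error(readFastaCorpus(empty), "line 1")
  noHeader <- tempfile(fileext = ".fasta")
  writeLines("MKVLA", noHeader)
  expect_error(readFastaCorpus(noHeader), "header")
  expect_error(readFastaCorpus(tempfile()), "not found")
})

test_that("duplicate FASTA ids error by default and can be suffixed", {
  path <- writeTempFasta(c("MKVL", "ACDY", "MMMM"), ids = c("x", "x", "y"))
  expect_error(readFastaCorpus(path), "duplicate")
  corp <- readFastaCorpus(path, onDuplicateIds = "suffix")
  expect_equal(seqIds(corp), c("x", "x.1", "y"))
})

test_that("labels attach from sidecar TSV and from header delimiters", {
  path <- writeTempFasta(c(p1 = "MKVL", n1 = "ACDY"))
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("p1\tpositive", "n1\tnegative"), tsv)
  corp <- readFastaCorpus(path, labels = tsv)
  expect_equal(labels(corp), c("positive", "negative"))

  path2 <- writeTempFasta(c("MKVL", "ACDY"),
                          ids = c("p1|positive", "n1|negative"))
  corp2 <- readFastaCorpus(path2, labelDelim = "|")
  expect_equal(seqIds(corp2), c("p1", "n1"))
  expect_equal(labels(corp2), c("positive", "negative"))
})

test_that("FASTA round trip through writeFastaCorpus is lossless", {
  corp <- randomCorpus(5L, label = "positive")
  fa <- tempfile(fileext = ".fasta")
  tsv <- tempfile(fileext = ".tsv")
  writeFastaCorpus(corp, fa, tsv)
  back <- readFastaCorpus(fa, labels = tsv)
  expect_equal(as.character(sequences(back)), as.character(sequences(corp)))
  expect_equal(labels(back), labels(corp))
})

test_that("cleanSequences applies each policy correctly", {
  corp <- proteinCorpus(c(ok = "ACDEFG", bad = "ACB*EF", gone = "UUUU"))
  stripped <- cleanSequences(corp, "strip")
  expect_equal(unname(as.character(sequences(stripped))[1:2]),
               c("ACDEFG", "ACEF"))
  expect_equal(length(stripped), 2L)   # all-non-canonical record rejected
  expect_true(any(grepl("empty", stripped@metadata$cleaningLog$reason[
    stripped@metadata$cleaningLog$id == "gone"])))

  subst <- cleanSequences(corp, "substitute-X")
  expect_equal(as.character(sequences(subst))[["bad"]], "ACXXEF")
  expect_equal(as.character(sequences(subst))[["gone"]], "XXXX")
  expect_equal(subst@metadata$nCorrected, 2L)

  dropped <- cleanSequences(corp, "drop")
  expect_equal(seqIds(dropped), "ok")
  expect_equal(as.character(sequences(cleanSequences(corp, "drop"))[["ok"]]),
               "ACDEFG")
})

test_that("redundancy filter removes exact duplicates and keeps disjoint", {
  corp <- proteinCorpus(c(a = strrep("ACDEFGHIKL", 5),
                          b = strrep("ACDEFGHIKL", 5),
                          c = strrep("MNPQRSTVWY", 5)))
  res <- redundancyFilter(corp)
  expect_equal(length(res$kept), 2L)
  expect_equal(res$summary[["nRemovedRedundant"]], 1L)
  expect_setequal(res$clusters$representative[res$clusters$id == "b"], "a")
  expect_error(redundancyFilter(corp, identityThreshold = 1.5), "0, 1")
})

test_that("greedy k-mer filter agrees with an exact alignment oracle", {
  # 10 sequences: 7 unrelated, 3 high-identity copies of the first
  base <- randomCorpus(7L, lens = 80:120, seed = 42L, prefix = "B")
  seqs <- as.character(sequences(base))
  copies <- ProtFuse:::.withSeed(99L, {
    vapply(1:3, function(i) {
      ch <- strsplit(seqs[[1]], "")[[1]]
      pos <- sample(length(ch), 1)
      ch[pos] <- sample(setdiff(ProtFuse:::.AA20, ch[pos]), 1)
      paste(ch, collapse = "")
    }, character(1))
  })
  names(copies) <- paste0("C", 1:3)
  corp <- combineCorpora(base, proteinCorpus(copies))
  res <- redundancyFilter(corp, 0.9)
  # the template plus its three copies collapse to one representative
  expect_equal(length(res$kept), 7L)

  # oracle: exact global alignment identity on every pair
  all <- as.character(sequences(corp))
  for (i in seq_along(all)) {
    for (j in seq_along(all)) {
      if (i >= j) next
      aln <- Biostrings::pairwiseAlignment(all[[i]], all[[j]])
      exact <- Biostrings::pid(aln, type = "PID3") / 100
      approx <- ProtFuse:::.kmerIdentity(all[[i]], all[[j]])
      expect_equal(exact >= 0.9, approx >= 0.9,
                   info = sprintf("pair %d-%d exact=%.3f approx=%.3f",
                                  i, j, exact, approx))
    }
  }
})

test_that("redundancy filter is idempotent and monotone in the threshold", {
  gen <- generateCorpus(generatorSpec(nPerClass = 30L,
                                      lengthRange = c(60L, 120L),
                                      nearDuplicateRate = 0.2, seed = 5L))
  res <- redundancyFilter(gen$corpus, 0.9)
  again <- redundancyFilter(res$kept, 0.9)
  expect_equal(seqIds(again$kept), seqIds(res$kept))
  expect_equal(again$summary[["nRemovedRedundant"]], 0L)

  kept <- vapply(c(0.95, 0.9, 0.6, 0.3),
                 function(th) length(redundancyFilter(gen$corpus, th)$kept),
                 numeric(1))
  expect_true(all(diff(kept) <= 0))
})

test_that("sampleNegatives is seed-reproducible and disjoint from positives", {
  pool <- randomCorpus(40L, seed = 7L, prefix = "U")
  pos <- randomCorpus(10L, seed = 8L, prefix = "P", label = "positive")
  # plant overlaps: shared id and shared exact sequence
  overlap <- proteinCorpus(
    stats::setNames(c(as.character(sequences(pos))[[1]], "MKVLAY"),
                    c("X001", seqIds(pos)[2])))
  pool2 <- combineCorpora(pool[1:38], overlap)
  neg <- sampleNegatives(pool2, pos, n = 10L, seed = 123L)
  expect_equal(length(neg), 10L)
  expect_true(all(labels(neg) == "negative"))
  expect_length(intersect(seqIds(neg), seqIds(pos)), 0L)
  expect_length(intersect(as.character(sequences(neg)),
                          as.character(sequences(pos))), 0L)
  neg2 <- sampleNegatives(pool2, pos, n = 10L, seed = 123L)
  expect_identical(seqIds(neg), seqIds(neg2))
  neg3 <- sampleNegatives(pool2, pos, n = 10L, seed = 124L)
  expect_false(identical(seqIds(neg), seqIds(neg3)))
})

test_that("sampleNegatives reports the shortfall when the pool is too small", {
  pos <- randomCorpus(5L, seed = 1L, prefix = "P", label = "positive")
  expect_error(sampleNegatives(pos, pos, n = 3L, seed = 1L), "short by 3")
})

test_that("balanced assembly yields equal class counts", {
  pos <- randomCorpus(8L, seed = 2L, prefix = "P", label = "positive")
  pool <- randomCorpus(30L, seed = 3L, prefix = "U")
  neg <- sampleNegatives(pool, pos, seed = 9L)
  corp <- combineCorpora(pos, neg)
  expect_equal(sum(labels(corp) == "positive"),
               sum(labels(corp) == "negative"))
})
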
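validWindow <- function(left = strrep("A", 15), right = strrep("G", 15))
  paste0(left, "K", right)

test_that("peptide tables ingest cleanly and reject invariant violations", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("id\tsequence\tlabel",
               paste("w1", validWindow(), 1, sep = "\t"),
               paste("w2", validWindow(strrep("C", 15)), 0, sep = "\t")), path)
  pep <- readPeptideTable(path)
  expect_length(pep, 2L)
  expect_identical(peptideLabels(pep), c(1L, 0L))
  expect_identical(peptideIds(pep), c("w1", "w2"))

  writeLines(c("id\tsequence\tlabel",
               paste("w1", substr(validWindow(), 1, 30), 1, sep = "\t")), path)
  expect_error(readPeptideTable(path), "length 30")
  writeLines(c("id\tsequence\tlabel",
               paste("w1", paste0(strrep("A", 15), "R", strrep("A", 15)), 1,
                     sep = "\t")), path)
  expect_error(readPeptideTable(path), "central residue")
  writeLines(c("id\tsequence\tlabel",
               paste("w1", validWindow(), 2, sep = "\t")), path)
  expect_error(readPeptideTable(path), "label")
})

test_that("FASTA dialect with id|label headers is accepted", {
  path <- tempfile(fileext = ".fasta")
  writeLines(c(">pep1|1", validWindow(), ">pep2|0", validWindow(strrep("S", 15))),
             path)
  pep <- readPeptideTable(path)
  expect_length(pep, 2L)
  expect_identical(peptideLabels(pep), c(1L, 0L))
  expect_identical(peptideIds(pep), c("pep1", "pep2"))
})

test_that("window extraction pads termini and keeps the lysine centered", {
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">prot1", "AAAAKAAAAA"), fa)
  win <- extractWindows(fa)
  expect_length(win, 1L)
  expect_identical(peptideIds(win), "prot1:K5")
  expect_identical(peptideSequences(win),
                   paste0(strrep("X", 11), "AAAA", "K", "AAAAA", strrep("X", 10)))
  expect_true(is.na(peptideLabels(win)))

  writeLines(c(">noK", "AAAAAAAAAA"), fa)
  expect_length(extractWindows(fa), 0L)

  # all-lysine protein: one window per position, every center is K
  writeLines(c(">polyK", strrep("K", 31)), fa)
  win <- extractWindows(fa)
  expect_length(win, 31L)
  expect_identical(peptideIds(win), sprintf("polyK:K%d", 1:31))
  expect_true(all(substr(peptideSequences(win), 16, 16) == "K"))
  # brute-force check of flank content for an interior lysine
  expect_identical(peptideSequences(win)[16], strrep("K", 31))

  writeLines(c(">ambig", paste0(strrep("A", 10), "B", strrep("K", 5))), fa)
  expect_warning(win <- extractWindows(fa), "ambig")
  expect_length(win, 0L)
})

test_that("stratified splits honor sizes, balance and determinism", {
  pep <- makeNullSet(6830, seed = 9)
  split <- makeSplit(pep, seed = 4)
  expect_identical(vapply(split[1:3], length, 1L),
                   c(train = 4830L, validation = 1000L, test = 1000L))
  for (part in split[1:3]) {
    labs <- peptideLabels(part)
    expect_lte(abs(sum(labs == 1) - length(labs) / 2), 1)
  }
  ids <- unlist(lapply(split[1:3], peptideIds))
  expect_identical(anyDuplicated(ids), 0L)
  split2 <- makeSplit(pep, seed = 4)
  expect_identical(lapply(split[1:3], peptideIds), lapply(split2[1:3], peptideIds))
  split3 <- makeSplit(pep, seed = 5)
  expect_false(identical(peptideIds(split$train), peptideIds(split3$train)))

  tiny <- makeNullSet(4, seed = 2)
  parts <- makeSplit(tiny, sizes = c(2, 1, 1), seed = 1)
  expect_setequal(unlist(lapply(parts[1:3], peptideIds)), peptideIds(tiny))
  expect_error(makeSplit(tiny, sizes = c(4, 1, 1), seed = 1), "insufficient")
})

test_that("fold plans are disjoint stratified covers with near-equal sizes", {
  pep <- makeNullSet(6830, seed = 9)
  plan <- makeFolds(pep, k = 10, seed = 3)
  sizes <- lengths(plan$folds)
  expect_identical(sizes, rep(683L, 10L))
  expect_setequal(unlist(plan$folds), peptideIds(pep))
  expect_identical(sum(lengths(plan$folds)), 6830L)

  tiny <- makeNullSet(4, seed = 2)
  p2 <- makeFolds(tiny, k = 2, seed = 1)
  expect_identical(lengths(p2$folds), c(2L, 2L))
  labs <- peptideLabels(tiny)
  for (f in p2$folds)
    expect_identical(sum(labs[match(f, peptideIds(tiny))] == 1L), 1L)
  expect_error(makeFolds(tiny, k = 1, seed = 1), "k must be")
  expect_identical(makeFolds(pep, k = 10, seed = 3)$folds, plan$folds)
})

test_that("prediction output is well formed and argmax-labeled", {
  pep <- makeNullSet(3, seed = 7)
  probs <- rbind(c(0.7, 0.3), c(0.2, 0.8), c(0.5, 0.5))
  path <- tempfile(fileext = ".tsv")
  writePredictions(pep, probs, path)
  out <- read.delim(path)
  expect_identical(nrow(out), 3L)
  expect_identical(out$predicted_label, c(1L, 0L, 0L))
  expect_error(writePredictions(pep, probs[1:2, ], path), "3 records")
  expect_error(writePredictions(pep, probs * 2, path), "sum to 1")
})
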
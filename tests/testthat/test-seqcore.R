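test_that("peptide parsing validates alphabet, case and length", {
  expect_identical(parsePeptide("WWHRFMKELYSG", length = 12), "WWHRFMKELYSG")
  expect_identical(parsePeptide("wwhrfmkelysg", length = 12), "WWHRFMKELYSG")
  expect_error(parsePeptide("WWPRFMKELYSG"), "P")
  expect_error(parsePeptide("WWCRFMKELYSG"), "C")
  expect_error(parsePeptide("ww", length = 12), "length")
  expect_error(parsePeptide("WB", alphabet = AWR), "outside")
  expect_error(parsePeptide(""), "empty")
})

test_that("the default alphabet is the 18 canonical residues minus P and C", {
  res <- residues(defaultAlphabet())
  expect_length(res, 18L)
  expect_false(any(c("P", "C") %in% res))
  expect_error(peptideAlphabet(c("A", "A")), "distinct")
  expect_error(peptideAlphabet(c("A", "B")), "non-canonical")
})

test_that("random peptides are uniform, seeded, and alphabet-valid", {
  one <- peptideAlphabet("A")
  expect_identical(randomPeptides(3, 4, one), rep("AAAA", 3))
  a <- withSeed(7L, randomPeptides(20, 12))
  b <- withSeed(7L, randomPeptides(20, 12))
  expect_identical(a, b)
  # law of large numbers: residue frequencies approach 1/18
  x <- withSeed(11L, randomPeptides(10000, 12))
  chars <- unlist(strsplit(x, "", fixed = TRUE))
  freq <- table(factor(chars, levels = residues(defaultAlphabet()))) /
    length(chars)
  p <- 1 / 18
  se <- sqrt(p * (1 - p) / length(chars))
  expect_true(all(abs(freq - p) < 6 * se))
})

test_that("FASTA io round-trips sequences and identifiers", {
  tmp <- withr::local_tempfile(fileext = ".fasta")
  set <- c(p1 = "WWHRFMKELYSG", p2 = "AAAAAAAAAAAA", p3 = "RKDEQNHSTGYV")
  writePeptides(set, tmp)
  expect_identical(readPeptides(tmp), set)
  # wrapped sequence lines concatenate per the FASTA standard
  wrap <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">w1", "WWHR", "FMKE", ">w2", "AAAA"), wrap)
  expect_identical(unname(readPeptides(wrap)), c("WWHRFMKE", "AAAA"))
  # empty file, empty set
  empty <- withr::local_tempfile(fileext = ".fasta")
  writeLines(character(), empty)
  expect_length(readPeptides(empty), 0L)
  # validation applies on read
  badf <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">b", "WWPP"), badf)
  expect_error(readPeptides(badf), "outside the alphabet")
})

test_that("score tables parse, validate and round-trip", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  tab <- scoreTable(c("WWHRFMKELYSG", "AAAAAAAAAAAA"), c(-51.0, -3.25))
  writeScoreTable(tab, tmp)
  back <- readScoreTable(tmp)
  expect_identical(sequences(back), sequences(tab))
  expect_equal(scores(back), scores(tab))
  # comma dialect accepted on read
  csv <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sequence,score", "WWHRFMKELYSG,-51.0"), csv)
  expect_equal(scores(readScoreTable(csv)), -51.0)
  # NaN and text scores rejected
  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sequence\tscore", "WWHRFMKELYSG\tNaN"), bad)
  expect_error(readScoreTable(bad), "score")
  # out-of-alphabet residues rejected at entry
  badres <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sequence\tscore", "WWPRFMKELYSG\t-5"), badres)
  expect_error(readScoreTable(badres), "alphabet")
})

test_that("property scales read and must cover the alphabet", {
  scale <- tthScale()
  expect_length(scale, 20L)
  expect_equal(unname(scale["W"]), 1.53)
  expect_equal(unname(scale["K"]), -3.46)
  part <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("residue\tvalue", "A\t0.5"), part)
  expect_error(readPropertyScale(part, defaultAlphabet()), "missing")
})
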
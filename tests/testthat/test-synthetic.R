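test_that("the oracle formula is additive, affine and seed-stable", {
  alph <- defaultAlphabet()
  zero <- stats::setNames(rep(0, 18), residues(alph))
  flat <- syntheticOracle(zero, noise_sd = 0, a = 1, b = -26)
  expect_equal(predictScore(flat, c("WWHRFMKELYSG", "AAAAAAAAAAAA")),
               c(-26, -26))
  # additive specs are permutation-invariant
  add <- additiveOracle()
  expect_equal(predictScore(add, "WWHRFMKELYSG"),
               predictScore(add, "GSYLEKMFRHWW"))
  # doubling a doubles (score - b)
  add2 <- add; add2@a <- 2 * add@a
  expect_equal(predictScore(add2, "WWHRFMKELYSG") - add2@b,
               2 * (predictScore(add, "WWHRFMKELYSG") - add@b))
  # couplings break permutation invariance
  pe <- peOracle()
  expect_false(isTRUE(all.equal(predictScore(pe, "WWAAAAAAAAAA"),
                                predictScore(pe, "WAWAAAAAAAAA"))))
  # noise is drawn from the ambient RNG stream; noiseless when sd = 0
  n1 <- withSeed(1L, oracleScore(pe, "WWHRFMKELYSG"))
  n2 <- withSeed(1L, oracleScore(pe, "WWHRFMKELYSG"))
  expect_identical(n1, n2)
  expect_false(isTRUE(all.equal(n1, predictScore(pe, "WWHRFMKELYSG"))))
})

test_that("calibration pins the probe mean and sd and is idempotent", {
  o <- calibrateOracle(additiveOracle(), -26, 11, n_probe = 5000, seed = 11)
  fresh <- predictScore(o, withSeed(12L, randomPeptides(5000, 12)))
  expect_lt(abs(mean(fresh) - (-26)), 0.5)
  expect_lt(abs(stats::sd(fresh) - 11), 0.5)
  # an already-calibrated oracle is a fixed point of calibration
  o2 <- calibrateOracle(o, -26, 11, n_probe = 5000, seed = 11)
  expect_equal(o2@a, o@a)
  expect_equal(o2@b, o@b)
  # raw scores already at target leave (a, b) at (1, 0)
  raw <- additiveOracle()
  probe <- withSeed(13L, randomPeptides(5000, 12))
  stats_raw <- c(mean(predictScore(raw, probe)),
                 stats::sd(predictScore(raw, probe)))
  self <- calibrateOracle(raw, stats_raw[1], stats_raw[2],
                          n_probe = 5000, seed = 13)
  expect_equal(self@a, 1, tolerance = 1e-10)
  expect_equal(self@b, 0, tolerance = 1e-7)
  # zero-variance specs cannot be calibrated
  flat <- syntheticOracle(stats::setNames(rep(1, 18),
                                          residues(defaultAlphabet())),
                          noise_sd = 0)
  expect_error(calibrateOracle(flat, -26, 11), "zero score variance")
})

test_that("dataset generation is reproducible and alphabet-clean", {
  pe <- peOracle()
  a <- generateDataset(pe, 5, seed = 21)
  b <- generateDataset(pe, 5, seed = 21)
  expect_identical(sequences(a), sequences(b))
  expect_identical(scores(a), scores(b))
  tab <- generateDataset(pe, 500, seed = 22)
  expect_true(all(nchar(sequences(tab)) == 12L))
  expect_true(all(pepmcts:::validSequences(sequences(tab), pe@alphabet)))
  # the biased source concentrates records at favourable (low) scores
  biased <- generateDataset(pe, 500, source = "biased", seed = 23)
  expect_lt(mean(scores(biased)), mean(scores(tab)) - 3)
})

test_that("paired oracles differ only through the divergence residue", {
  # with equal calibration and no couplings, the noiseless score
  # difference is a * delta * (tryptophan count)
  alph <- defaultAlphabet()
  w <- stats::setNames(seq(-2, 2, length.out = 18), residues(alph))
  w2 <- w; w2["W"] <- w2["W"] - 6
  o1 <- syntheticOracle(w, noise_sd = 0, a = 1.5, b = -4)
  o2 <- syntheticOracle(w2, noise_sd = 0, a = 1.5, b = -4)
  probe <- c("WWWWWWWWWWWW", "WAAAAAAAAAAW", "AAAAAAAAAAAA", "KRDEQNHSTGYV")
  gap <- predictScore(o2, probe) - predictScore(o1, probe)
  expect_equal(gap, 1.5 * (-6) * countResidue(probe, "W"))
  # the constructor wires divergence into the target oracle only
  pair <- pairedOracles(c(W = -6))
  expect_equal(pair$target@weights[setdiff(names(w), "W")],
               pair$off_target@weights[setdiff(names(w), "W")])
  expect_equal(pair$target@weights[["W"]],
               pair$off_target@weights[["W"]] - 6)
  expect_error(pairedOracles(c(P = -1)), "outside the alphabet")
})

test_that("oracle specs round-trip through their YAML serialization", {
  pe <- peOracle()
  path <- withr::local_tempfile(fileext = ".yaml")
  writeOracle(pe, path)
  back <- readOracle(path)
  probe <- withSeed(31L, randomPeptides(50, 12))
  expect_equal(predictScore(back, probe), predictScore(pe, probe))
  expect_equal(back@noise_sd, pe@noise_sd)
})
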
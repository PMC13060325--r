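pep12 <- "WWHRFMKELYSG"

test_that("a constant model attributes nothing", {
  const <- tableOracle(stats::setNames(numeric(), character()), default = -7)
  sh <- shapleySampling(const, pep12, attributionConfig(n_samples = 50,
                                                        seed = 1))
  expect_true(all(sh$values == 0))
  expect_equal(sh$baseline, -7)
})

test_that("additive models recover their closed-form Shapley values", {
  oracle <- additiveOracle()
  w <- oracle@weights * oracle@a
  sh <- shapleySampling(oracle, pep12, attributionConfig(n_samples = 400,
                                                         seed = 2))
  expected <- unname(w[strsplit(pep12, "")[[1]]] - mean(w))
  expect_true(all(abs(sh$values - expected) < pmax(4 * sh$se, 1e-9)))
  # efficiency: values sum to prediction minus baseline expectation
  resid <- sum(sh$values) - (sh$prediction - sh$baseline)
  expect_lt(abs(resid), max(3 * sh$sum_se, 1e-9))
  # symmetry: the two tryptophan positions agree in expectation
  expect_lt(abs(sh$values[1] - sh$values[2]),
            4 * sqrt(sh$se[1]^2 + sh$se[2]^2) + 1e-9)
})

test_that("context-dependent models still satisfy efficiency", {
  oracle <- peOracle()   # has nearest-neighbour couplings
  sh <- shapleySampling(oracle, pep12, attributionConfig(n_samples = 150,
                                                         seed = 3))
  resid <- sum(sh$values) - (sh$prediction - sh$baseline)
  expect_lt(abs(resid), max(3 * sh$sum_se, 1e-9))
})

test_that("set attribution assembles rows, aggregations and efficiency", {
  oracle <- additiveOracle()
  peps <- withSeed(4L, randomPeptides(15, 12))
  rep <- attributeSet(oracle, peps, attributionConfig(n_samples = 60,
                                                      seed = 5))
  expect_equal(nrow(rep@values), 15L * 12L)
  expect_equal(nrow(rep@efficiency), 15L)
  # per-type aggregation partitions all attributed positions
  ptv <- perTypeValues(rep)
  expect_equal(nrow(ptv), 15L * 12L)
  expect_equal(sum(table(ptv$residue)), 180L)
  tp <- typePositionMeans(rep)
  expect_equal(dim(tp), c(18L, 12L))
  # an additive model's per-type means are position-independent: every
  # filled cell of a residue row sits near w(residue) - mean(w)
  w <- oracle@weights * oracle@a
  centred <- w - mean(w)
  filled <- which(!is.na(tp), arr.ind = TRUE)
  expect_lt(max(abs(tp[filled] - centred[rownames(tp)[filled[, 1]]])), 0.9)
})

test_that("shap gaps localise a weight difference to its residue", {
  alph <- defaultAlphabet()
  w <- stats::setNames(seq(-2, 2, length.out = 18), residues(alph))
  base <- syntheticOracle(w, noise_sd = 0)
  shifted <- w; shifted["W"] <- shifted["W"] + 3
  target <- syntheticOracle(shifted, noise_sd = 0)
  peps <- withSeed(6L, randomPeptides(12, 12))
  cfg <- attributionConfig(n_samples = 250, seed = 7)
  rep_t <- attributeSet(target, peps, cfg)
  rep_o <- attributeSet(base, peps, cfg)
  gap <- shapGap(rep_t, rep_o)
  # closed form: delta * (1 - 1/18) at W, -delta/18 elsewhere
  expect_lt(abs(gap[["W"]] - 3 * (1 - 1 / 18)), 0.35)
  expect_lt(max(abs(gap[setdiff(names(gap), "W")] - (-3 / 18))), 0.35)
  # identical reports gap to zero; swapping is antisymmetric
  expect_true(all(abs(shapGap(rep_t, rep_t)) == 0))
  expect_equal(shapGap(rep_o, rep_t), -gap)
  expect_error(shapGap(rep_t, attributeSet(base, peps[1:3], cfg)),
               "different peptide sets")
})

test_that("attribution reports serialize to their TSV artefacts", {
  oracle <- additiveOracle()
  rep <- attributeSet(oracle, withSeed(8L, randomPeptides(3, 12)),
                      attributionConfig(n_samples = 30, seed = 9))
  dir <- withr::local_tempdir()
  writeAttributionReport(rep, dir)
  vals <- utils::read.table(file.path(dir, "shap_values.tsv"), header = TRUE,
                            sep = "\t")
  expect_equal(nrow(vals), 36L)
  expect_named(vals, c("peptide_id", "peptide", "position", "residue",
                       "value", "std_error"))
  eff <- utils::read.table(file.path(dir, "shap_efficiency.tsv"),
                           header = TRUE, sep = "\t")
  expect_equal(nrow(eff), 3L)
})
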
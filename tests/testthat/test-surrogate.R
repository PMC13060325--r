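tinySpec <- surrogateSpec(embedding_dim = 8, recurrent_layers = 1,
                          hidden_dim = 16)

test_that("training on a constant target converges to the constant", {
  seqs <- withSeed(1L, randomPeptides(240, 12))
  tab <- scoreTable(seqs, rep(-10, 240))
  parts <- splitScoreTable(tab, seed = 1)
  m <- trainSurrogate(parts$train, parts$validation, spec = tinySpec,
                      config = trainConfig(epochs = 15, batch_size = 64,
                                           seed = 2))
  pred <- predictScore(m, withSeed(3L, randomPeptides(20, 12)))
  expect_true(all(abs(pred - (-10)) < 0.5))
  expect_lt(m@history$val_loss[m@best_epoch], 0.05)
})

test_that("training history and validation-based selection are bookkept", {
  oracle <- additiveOracle()
  tab <- generateDataset(oracle, 400, seed = 4)
  parts <- splitScoreTable(tab, seed = 4)
  m <- trainSurrogate(parts$train, parts$validation, spec = tinySpec,
                      config = trainConfig(epochs = 6, batch_size = 128,
                                           seed = 5))
  expect_equal(nrow(m@history), 6L)
  expect_equal(m@best_epoch, which.min(m@history$val_loss))
  # selected snapshot is never worse than the final epoch
  expect_lte(m@history$val_loss[m@best_epoch],
             m@history$val_loss[nrow(m@history)])
  # embedding rows = alphabet size (integer encoding is a bijection)
  expect_equal(nrow(m@params$E), 18L)
  # inference is deterministic and batch equals element-wise
  probe <- withSeed(6L, randomPeptides(10, 12))
  p1 <- predictScore(m, probe)
  expect_identical(p1, predictScore(m, probe))
  expect_equal(p1, vapply(probe, function(s) predictScore(m, s),
                          numeric(1), USE.NAMES = FALSE))
  expect_error(predictScore(m, "WWPRFMKELYSG"), "alphabet")
  expect_error(predictScore(m, "WWW"), "length")
})

test_that("a small recurrent model recovers an additive score function", {
  oracle <- additiveOracle()
  oracle@noise_sd <- 1
  tab <- dedupeBest(generateDataset(oracle, 3000, seed = 7))
  parts <- splitScoreTable(tab, seed = 7)
  m <- trainSurrogate(parts$train, parts$validation,
                      spec = surrogateSpec(8, 2, 24),
                      config = trainConfig(epochs = 14, batch_size = 256,
                                           seed = 8))
  ev <- evaluateSurrogate(m, parts$test)
  expect_gt(ev$r_squared, 0.7)
})

test_that("evaluation metrics match their closed forms", {
  tab <- generateDataset(peOracle(), 200, seed = 10)
  exact <- tableOracle(tab)
  ev <- evaluateSurrogate(exact, tab)
  expect_equal(ev$r_squared, 1)
  expect_equal(ev$rmse, 0)
  # predicting the mean everywhere gives R^2 = 0
  mean_model <- tableOracle(stats::setNames(numeric(), character()),
                            default = mean(scores(tab)))
  ev0 <- evaluateSurrogate(mean_model, tab)
  expect_equal(ev0$r_squared, 0, tolerance = 1e-12)
  # constant offset c from truth gives RMSE = |c|
  off <- tableOracle(stats::setNames(scores(tab) + 2.5, sequences(tab)))
  expect_equal(evaluateSurrogate(off, tab)$rmse, 2.5)
  expect_error(evaluateSurrogate(exact, scoreTable(character(), numeric())),
               "empty")
})

test_that("table oracles look up exactly and police unseen sequences", {
  o <- tableOracle(c(WWHRFMKELYSG = -51), alphabet = defaultAlphabet())
  expect_equal(predictScore(o, "WWHRFMKELYSG"), -51)
  expect_error(predictScore(o, "AAAAAAAAAAAA"), "not in the lookup")
  with_default <- tableOracle(c(WWHRFMKELYSG = -51), default = 0)
  expect_equal(predictScore(with_default,
                            c("AAAAAAAAAAAA", "WWHRFMKELYSG")), c(0, -51))
})

test_that("surrogate save/load round-trips predictions and rejects damage", {
  seqs <- withSeed(11L, randomPeptides(150, 12))
  tab <- scoreTable(seqs, withSeed(12L, stats::rnorm(150, -26, 11)))
  parts <- splitScoreTable(tab, seed = 11)
  m <- trainSurrogate(parts$train, parts$validation, spec = tinySpec,
                      config = trainConfig(epochs = 2, batch_size = 64,
                                           seed = 12))
  dir <- withr::local_tempdir()
  saveSurrogate(m, dir)
  m2 <- loadSurrogate(dir)
  probe <- withSeed(13L, randomPeptides(25, 12))
  expect_identical(predictScore(m, probe), predictScore(m2, probe))
  # wrong alphabet in the manifest is refused
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  manifest$alphabet <- c("A", "W", "R")
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  expect_error(loadSurrogate(dir), "alphabet")
  # truncated weights fail loudly
  jsonlite::write_json(jsonlite::read_json(file.path(dir, "manifest.json")),
                       file.path(dir, "manifest.json"))
  writeLines("garbage", file.path(dir, "weights.rds"))
  expect_error(loadSurrogate(dir), "corrupt|truncated|alphabet")
})
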
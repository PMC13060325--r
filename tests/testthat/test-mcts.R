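test_that("ucb1 matches its closed form and edge conventions", {
  expect_equal(ucb1(5, 0, 100, 7), 5)              # C = 0: pure exploitation
  expect_equal(ucb1(1, 1, exp(1), 1), 2)           # ln(e)/1 under the radical
  expect_identical(ucb1(3, 1, 10, 0), Inf)         # unvisited first
  expect_equal(ucb1(1, 1, exp(1), 1, form = "printed"), 2)
  # the printed (no-radical) form and the canonical form disagree once
  # n_i > ln(parent_n)
  expect_equal(ucb1(0, 2, exp(1), 4, form = "printed"), 0.5)
  expect_equal(ucb1(0, 2, exp(1), 4, form = "sqrt"), 1)
  expect_error(ucb1(0, 1, 0, 1), "parent_n")
  expect_error(ucb1(0, 1, 1, -1), "n_i")
})

test_that("legal actions prune exactly the constrained residues", {
  expect_setequal(legalActions("WWW", constraints = c(W = 3L)),
                  setdiff(residues(defaultAlphabet()), "W"))
  expect_setequal(legalActions("WW", constraints = c(W = 3L)),
                  residues(defaultAlphabet()))
  expect_setequal(legalActions("", constraints = c(A = 0L)),
                  setdiff(residues(defaultAlphabet()), "A"))
  expect_setequal(legalActions(""), residues(defaultAlphabet()))
  # a residue stays legal only while the remainder is completable
  expect_setequal(legalActions("AA", AWR, c(A = 4L, W = 1L, R = 1L),
                               length = 6),
                  c("A", "W", "R"))
  expect_setequal(legalActions("AAAA", AWR, c(A = 4L, W = 1L, R = 1L),
                               length = 6),
                  c("W", "R"))
  expect_error(legalActions("", AWR, c(A = 1L, W = 1L, R = 1L), length = 4),
               "unsatisfiable")
})

test_that("every harvested sequence satisfies every count constraint", {
  oracle <- awr4Oracle()
  cfg <- searchConfig(AWR, length = 4, iterations = 2000, pool_size = 500,
                      constraints = c(W = 2L, A = 2L), seed = 21)
  res <- searchPeptides(cfg, rewardSpec(oracle, "affinity"))
  tab <- designTable(res)
  expect_gt(nrow(tab), 10)
  expect_true(all(countResidue(tab$sequence, "W") <= 2L))
  expect_true(all(countResidue(tab$sequence, "A") <= 2L))
  expect_true(all(nchar(tab$sequence) == 4L))
})

test_that("search is reproducible per seed and ranks by reward", {
  oracle <- awr4Oracle()
  cfg <- searchConfig(AWR, length = 4, iterations = 1000, pool_size = 20,
                      seed = 31)
  a <- searchPeptides(cfg, rewardSpec(oracle, "affinity"))
  b <- searchPeptides(cfg, rewardSpec(oracle, "affinity"))
  expect_identical(designTable(a), designTable(b))
  expect_false(is.unsorted(rev(designTable(a)$reward)))
  expect_false(anyDuplicated(designTable(a)$sequence) > 0)
  # affinity reward ranking is equivalent to ascending predicted score
  expect_false(is.unsorted(designTable(a)$predicted_score))
})

test_that("enough iterations recover the brute-force optimum", {
  oracle <- awr4Oracle()
  best <- names(which.min(oracle@lookup))
  cfg <- searchConfig(AWR, length = 4, iterations = 5000, pool_size = 5,
                      seed = 41)
  res <- searchPeptides(cfg, rewardSpec(oracle, "affinity"))
  expect_identical(designTable(res)$sequence[1], best)
})

test_that("single-iteration searches hold exactly the first rollouts", {
  oracle <- awr4Oracle()
  cfg <- searchConfig(AWR, length = 4, iterations = 1, pool_size = 10,
                      seed = 51)
  res <- searchPeptides(cfg, rewardSpec(oracle, "affinity"))
  expect_equal(nrow(designTable(res)), 1L)
  expect_equal(res@n_rollouts, 1L)
  cfg3 <- searchConfig(AWR, length = 4, iterations = 1, pool_size = 10,
                       rollouts_per_expansion = 3L, seed = 51)
  res3 <- searchPeptides(cfg3, rewardSpec(oracle, "affinity"))
  expect_lte(nrow(designTable(res3)), 3L)
  expect_equal(res3@n_rollouts, 3L)
})

test_that("visit counts are conserved and exploration spreads the root", {
  # constant reward: with a large C the root children are visited uniformly
  # up to multinomial noise
  flat <- tableOracle(stats::setNames(numeric(), character()), default = -5,
                      alphabet = AWR)
  cfg <- searchConfig(AWR, length = 4, iterations = 3000, pool_size = 10,
                      C = 50, seed = 61)
  res <- searchPeptides(cfg, rewardSpec(flat, "affinity"))
  rv <- res@root_visits
  expect_equal(sum(rv), 3000)           # conservation at the root
  expected <- 3000 / 3
  expect_true(all(abs(rv - expected) < 6 * sqrt(expected * 2 / 3)))
})

test_that("design results serialize with their config echo", {
  oracle <- awr4Oracle()
  cfg <- searchConfig(AWR, length = 4, iterations = 300, pool_size = 10,
                      constraints = c(W = 2L), seed = 71)
  res <- searchPeptides(cfg, rewardSpec(oracle, "affinity"))
  dir <- withr::local_tempdir()
  writeDesignResult(res, dir)
  expect_true(file.exists(file.path(dir, "design.tsv")))
  fasta <- readPeptides(file.path(dir, "design.fasta"), AWR)
  expect_identical(unname(fasta), designTable(res)$sequence)
  echo <- yaml::read_yaml(file.path(dir, "design_config.yaml"))
  expect_equal(echo$seed, 71)
  expect_equal(echo$constraints$W, 2)
  expect_equal(echo$alphabet, "AWR")
})
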
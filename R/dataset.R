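#' Collapse duplicate sequences to their best score
#'
#' Upstream design runs sample a sequence many times in different
#' conformations, each with its own score; for training only the best
#' (most negative) score per sequence is kept. The input order of first
#' occurrence is preserved. Idempotent.
#'
#' @param table a [ScoreTable-class]
#' @return a [ScoreTable-class] with unique sequences
#' @export
dedupeBest <- function(table) {
  if (!length(table)) return(table)
  best <- tapply(table@scores, table@sequences, min)
  first <- !duplicated(table@sequences)
  seqs <- table@sequences[first]
  initialize(table, sequences = seqs, scores = as.numeric(best[seqs]))
}

#' Split a score table into train / validation / test
#'
#' Random per-record partition with the standard 80/10/10 default. The three
#' parts are disjoint, cover the input, have sizes within one record of
#' `fraction * N` (largest-remainder rounding), and are reproducible per
#' seed.
#'
#' @param table a deduplicated [ScoreTable-class]
#' @param fractions numeric of length 3 (train, validation, test), positive,
#'   summing to 1
#' @param seed integer seed
#' @return named list of three [ScoreTable-class] objects:
#'   `train`, `validation`, `test`
#' @export
splitScoreTable <- function(table, fractions = c(0.8, 0.1, 0.1), seed = 1L) {
  stopifnot(length(fractions) == 3L)
  if (any(fractions <= 0) || abs(sum(fractions) - 1) > 1e-8)
    stop("fractions must be positive and sum to 1")
  n <- length(table)
  sizes <- largestRemainder(fractions * n, n)
  perm <- withSeed(seed, sample.int(n))
  idx <- split(perm, factor(rep.int(seq_len(3L), sizes), levels = 1:3))
  list(train = table[idx[[1L]]],
       validation = table[idx[[2L]]],
       test = table[idx[[3L]]])
}

# run expr under a temporary RNG state seeded with `seed`
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# integer allocation of `total` proportional to `raw` (largest remainder)
largestRemainder <- function(raw, total) {
  base <- floor(raw)
  rem <- total - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Stratified sample of a score table
#'
#' Scores are binned into `bins` equal-width intervals over the observed
#' [min, max]; the sample allocation is proportional to bin occupancy
#' (largest-remainder rounding; empty bins get nothing) and records are
#' drawn without replacement within each bin. Proportional allocation
#' preserves the marginal score distribution, which downstream attribution
#' summaries depend on.
#'
#' @param table a [ScoreTable-class]
#' @param n sample size, at most `length(table)`
#' @param bins number of equal-width score bins (default 10)
#' @param seed integer seed
#' @return a [ScoreTable-class] of `n` records
#' @export
stratifiedSample <- function(table, n, bins = 10L, seed = 1L) {
  N <- length(table)
  if (n > N) stop("requested sample of ", n, " from a table of ", N, " records")
  if (bins < 1L) stop("bins must be >= 1")
  if (n == N) return(table)
  s <- table@scores
  rng <- range(s)
  bin <- if (rng[1L] == rng[2L]) rep.int(1L, N) else
    pmin(pmax(findInterval(s, seq(rng[1L], rng[2L], length.out = bins + 1L),
                           rightmost.closed = TRUE), 1L), bins)
  occ <- tabulate(bin, nbins = bins)
  alloc <- largestRemainder(n * occ / N, n)
  # largest-remainder can ask for more than a bin holds in edge cases;
  # push the surplus into bins with spare capacity, largest first
  over <- pmax(alloc - occ, 0L)
  if (any(over > 0L)) {
    alloc <- pmin(alloc, occ)
    spare <- occ - alloc
    need <- n - sum(alloc)
    for (b in order(spare, decreasing = TRUE)) {
      take <- min(spare[b], need)
      alloc[b] <- alloc[b] + take
      need <- need - take
      if (need == 0L) break
    }
  }
  idx <- withSeed(seed, {
    unlist(lapply(seq_len(bins), function(b) {
      members <- which(bin == b)
      if (alloc[b] == 0L) integer() else
        members[sample.int(length(members), alloc[b])]
    }), use.names = FALSE)
  })
  table[sort(idx)]
}

#' Summary statistics of a score table
#'
#' @param table a non-empty [ScoreTable-class]
#' @param probs quantile probabilities
#' @return list with `n`, `mean`, `sd` (n-1 denominator), `min`, `max`,
#'   `quantiles`, and `degenerate` (TRUE when a single record makes the
#'   standard deviation undefined; it is then reported as 0)
#' @export
summarizeScores <- function(table, probs = c(0.05, 0.25, 0.5, 0.75, 0.95)) {
  if (!length(table)) stop("empty score table")
  s <- table@scores
  degenerate <- length(s) < 2L
  list(n = length(s),
       mean = mean(s),
       sd = if (degenerate) 0 else stats::sd(s),
       min = min(s), max = max(s),
       quantiles = stats::quantile(s, probs = probs, names = TRUE),
       degenerate = degenerate)
}

#' Write a train/validation/test split with its manifest
#'
#' Emits `train.tsv`, `validation.tsv`, `test.tsv` in the standard score
#' table dialect plus `split_manifest.json` recording seed, fractions and
#' sizes, so the split is reproducible from its artefacts alone.
#'
#' @param parts list as returned by [splitScoreTable()]
#' @param dir output directory (created if needed)
#' @param fractions,seed values echoed into the manifest
#' @return the directory, invisibly
#' @export
writeSplit <- function(parts, dir, fractions = c(0.8, 0.1, 0.1), seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(parts))
    writeScoreTable(parts[[nm]], file.path(dir, paste0(nm, ".tsv")))
  manifest <- list(seed = seed, fractions = fractions,
                   sizes = as.list(vapply(parts, length, integer(1L))))
  jsonlite::write_json(manifest, file.path(dir, "split_manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
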
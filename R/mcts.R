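#' UCB1 node selection score
#'
#' The canonical upper-confidence-bound rule
#' `X_bar + C * sqrt(ln(parent_n) / n_i)`; unvisited nodes (`n_i = 0`)
#' return `+Inf` so they are selected first. The `form = "printed"` variant
#' drops the radical (`X_bar + C * ln(parent_n) / n_i`) for users who want
#' the literal non-radical form; the square-root form is the default because
#' it is the canonical UCB1 bound.
#'
#' @param mean_reward average reward of the node
#' @param C exploration constant (> 0 in a search; any real accepted here)
#' @param parent_n visit count of the parent (>= 1)
#' @param n_i visit count of the node itself (>= 0)
#' @param form "sqrt" (canonical) or "printed" (no radical)
#' @return the selection score
#' @export
ucb1 <- function(mean_reward, C, parent_n, n_i, form = c("sqrt", "printed")) {
  form <- match.arg(form)
  if (any(parent_n < 1L)) stop("parent_n must be >= 1")
  if (any(n_i < 0L)) stop("n_i must be >= 0")
  explore <- ifelse(n_i == 0L, Inf,
                    if (form == "sqrt") sqrt(log(parent_n) / pmax(n_i, 1L))
                    else log(parent_n) / pmax(n_i, 1L))
  ifelse(n_i == 0L, Inf, mean_reward + C * explore)
}

#' Build a search configuration
#'
#' Defaults: `C = sqrt(2)` on the normalised reward scale, 20,000
#' iterations, one rollout per expansion, design length 12, harvest pool of
#' 100 sequences, running min-max reward normalisation (the raw rewards are
#' unbounded and UCB1's exploration balance presumes comparable scales).
#'
#' @param alphabet a [PeptideAlphabet-class]
#' @param length design length
#' @param iterations search rounds
#' @param C exploration constant
#' @param constraints named integer vector of per-residue maximum counts,
#'   e.g. `c(W = 3L)` for the three-tryptophan constraint
#' @param pool_size number of top sequences harvested
#' @param rollouts_per_expansion random completions per round
#' @param seed integer seed
#' @param normalization "running_minmax" or "none"
#' @param ucb1_form "sqrt" or "printed" (see [ucb1()])
#' @return a [SearchConfig-class]
#' @export
searchConfig <- function(alphabet = defaultAlphabet(), length = 12L,
                         iterations = 20000L, C = sqrt(2),
                         constraints = integer(), pool_size = 100L,
                         rollouts_per_expansion = 1L, seed = 1L,
                         normalization = "running_minmax",
                         ucb1_form = "sqrt") {
  cons <- stats::setNames(as.integer(constraints), names(constraints))
  cfg <- new("SearchConfig", alphabet = alphabet)
  cfg@C <- C
  cfg@iterations <- as.integer(iterations)
  cfg@rollouts_per_expansion <- as.integer(rollouts_per_expansion)
  cfg@length <- as.integer(length)
  cfg@constraints <- cons
  cfg@pool_size <- as.integer(pool_size)
  cfg@seed <- as.integer(seed)
  cfg@normalization <- normalization
  cfg@ucb1_form <- ucb1_form
  validObject(cfg)
  cfg
}

# per-residue maximum counts as a numeric vector aligned to the alphabet
# (Inf = unconstrained)
constraintVector <- function(constraints, alphabet) {
  K <- length(alphabet@residues)
  v <- rep.int(Inf, K)
  if (length(constraints)) {
    idx <- match(names(constraints), alphabet@residues)
    if (anyNA(idx))
      stop("constraint on residue(s) outside the alphabet: ",
           paste(names(constraints)[is.na(idx)], collapse = ", "))
    v[idx] <- constraints
  }
  v
}

# logical mask of residues legal to append, given current counts and the
# number of residues already placed. A residue is legal when its count
# constraint has head-room and the remaining positions can still be filled.
legalMaskCounts <- function(counts, placed, maxVec, length) {
  mask <- counts < maxVec
  spare <- sum(maxVec - counts)   # Inf when any residue is unconstrained
  if (spare < length - placed) mask[] <- FALSE
  mask
}

#' Legal residues to append to a partial sequence
#'
#' Returns the residues whose addition cannot make the count constraints
#' unsatisfiable by full length. Errors when the constraint set cannot
#' produce any sequence of the requested length at all.
#'
#' @param prefix partial sequence (possibly "")
#' @param alphabet a [PeptideAlphabet-class]
#' @param constraints named integer vector of per-residue maximum counts
#' @param length design length
#' @return character vector of legal residues
#' @export
legalActions <- function(prefix, alphabet = defaultAlphabet(),
                         constraints = integer(), length = 12L) {
  maxVec <- constraintVector(constraints, alphabet)
  if (sum(maxVec) < length)
    stop("unsatisfiable constraints: at most ", sum(maxVec),
         " residues available for length ", length)
  ch <- if (nchar(prefix)) strsplit(toupper(prefix), "", fixed = TRUE)[[1L]]
        else character()
  if (base::length(ch) >= length) stop("prefix is already at full length")
  counts <- tabulate(match(ch, alphabet@residues),
                     nbins = base::length(alphabet@residues))
  mask <- legalMaskCounts(counts, base::length(ch), maxVec, length)
  alphabet@residues[mask]
}

#' Run the constrained Monte Carlo tree search
#'
#' Repeats selection (UCB1 over legal children), expansion (one unvisited
#' legal child), random rollout (uniform legal completion, evaluated by the
#' reward), and backpropagation for `iterations` rounds. Every complete
#' sequence produced by a rollout is deposited into the harvest pool; the
#' result ranks the top `pool_size` unique sequences by reward. Constraint
#' pruning guarantees that no rollout can violate a count constraint. The
#' whole run is reproducible from its seed.
#'
#' @param config a [SearchConfig-class]
#' @param reward a [RewardSpec-class]
#' @param verbose print progress every 1000 iterations
#' @return a [DesignResult-class]
#' @export
searchPeptides <- function(config, reward, verbose = FALSE) {
  alph <- config@alphabet
  res <- alph@residues
  K <- length(res)
  L <- config@length
  maxVec <- constraintVector(config@constraints, alph)
  if (sum(maxVec) < L)
    stop("unsatisfiable constraints: at most ", sum(maxVec),
         " residues available for length ", L)
  nIter <- config@iterations
  nRoll <- config@rollouts_per_expansion
  useSqrt <- config@ucb1_form == "sqrt"
  normalize <- config@normalization == "running_minmax"

  maxNodes <- nIter + 2L
  parent <- integer(maxNodes)
  nvis <- numeric(maxNodes)
  total <- numeric(maxNodes)
  children <- matrix(0L, nrow = K, ncol = maxNodes)
  nNodes <- 1L                       # node 1 = root (empty prefix)
  pool <- new.env(parent = emptyenv())
  nDeposits <- 0L
  mn <- Inf; mx <- -Inf              # running reward range

  withSeed(config@seed, {
    for (iter in seq_len(nIter)) {
      # --- selection / expansion ---
      node <- 1L
      depth <- 0L
      counts <- integer(K)
      path <- integer(L + 1L)
      path[1L] <- 1L
      prefix <- integer(L)
      while (depth < L) {
        mask <- counts < maxVec
        if (sum(maxVec - counts) < L - depth) mask[] <- FALSE
        legal <- which(mask)
        kids <- children[legal, node]
        open <- kids == 0L
        if (any(open)) {
          r <- legal[open][[if (sum(open) == 1L) 1L else
            sample.int(sum(open), 1L)]]
          nNodes <- nNodes + 1L
          children[r, node] <- nNodes
          parent[nNodes] <- node
          node <- nNodes
          depth <- depth + 1L
          prefix[depth] <- r
          counts[r] <- counts[r] + 1L
          path[depth + 1L] <- node
          break
        }
        nv <- nvis[kids]
        xbar <- total[kids] / nv
        lp <- log(nvis[node])
        u <- xbar + config@C * (if (useSqrt) sqrt(lp / nv) else lp / nv)
        best <- which(u == max(u))
        pick <- if (length(best) == 1L) best else
          best[[sample.int(length(best), 1L)]]
        r <- legal[pick]
        node <- kids[pick]
        depth <- depth + 1L
        prefix[depth] <- r
        counts[r] <- counts[r] + 1L
        path[depth + 1L] <- node
      }
      # --- rollout(s) from the current prefix ---
      pathIdx <- path[seq_len(depth + 1L)]
      for (k in seq_len(nRoll)) {
        cts <- counts
        seqCodes <- prefix
        d <- depth
        while (d < L) {
          mask <- cts < maxVec
          if (sum(maxVec - cts) < L - d) mask[] <- FALSE
          legal <- which(mask)
          r <- legal[[if (length(legal) == 1L) 1L else
            sample.int(length(legal), 1L)]]
          d <- d + 1L
          seqCodes[d] <- r
          cts[r] <- cts[r] + 1L
        }
        seqStr <- paste(res[seqCodes], collapse = "")
        raw <- if (!is.null(pool[[seqStr]])) pool[[seqStr]] else {
          v <- evaluateReward(reward, seqStr)
          assign(seqStr, v, envir = pool)
          v
        }
        nDeposits <- nDeposits + 1L
        if (raw < mn) mn <- raw
        if (raw > mx) mx <- raw
        val <- if (!normalize) raw else if (mx > mn) (raw - mn) / (mx - mn)
               else 0.5
        nvis[pathIdx] <- nvis[pathIdx] + 1
        total[pathIdx] <- total[pathIdx] + val
      }
      if (verbose && iter %% 1000L == 0L)
        message(sprintf("iteration %d: %d unique sequences, best reward %.4f",
                        iter, length(ls(pool)), mx))
    }
  })

  seqs <- ls(pool)
  rewards <- vapply(seqs, function(s) pool[[s]], numeric(1L),
                    USE.NAMES = FALSE)
  ord <- order(rewards, decreasing = TRUE)
  keep <- ord[seq_len(min(config@pool_size, length(ord)))]
  comp <- rewardComponents(reward, seqs[keep])
  tab <- data.frame(sequence = seqs[keep], reward = rewards[keep])
  tab$predicted_score <- comp$score_target
  if (!is.null(comp$score_off_target)) {
    tab$score_target <- comp$score_target
    tab$score_off_target <- comp$score_off_target
    tab$score_gap <- comp$score_gap
  }
  tab$solubility <- comp$solubility
  rownames(tab) <- NULL
  rootKids <- children[, 1L]
  rv <- stats::setNames(ifelse(rootKids > 0L, nvis[pmax(rootKids, 1L)], 0),
                        res)
  new("DesignResult", table = tab, config = config,
      variant = reward@variant, SF = reward@SF,
      n_rollouts = nIter * nRoll, root_visits = rv)
}

#' @rdname DesignResult-class
#' @param x a DesignResult
#' @return `designTable`: the ranked data.frame of harvested sequences
#' @export
designTable <- function(x) x@table

setMethod("show", "DesignResult", function(object) {
  cat(sprintf("DesignResult: %s reward, %d sequences from %d rollouts\n",
              object@variant, nrow(object@table), object@n_rollouts))
  if (nrow(object@table)) {
    cat("  top sequences:\n")
    k <- min(nrow(object@table), 5L)
    for (i in seq_len(k))
      cat(sprintf("  %s  reward %.3f  score %.3f\n",
                  object@table$sequence[i], object@table$reward[i],
                  object@table$predicted_score[i]))
  }
})

#' Write a design result to disk
#'
#' Emits the ranked table as TSV, the sequences as FASTA (identifiers
#' `design1..designN` in rank order), and a YAML sidecar echoing the search
#' configuration and seed so the run can be reproduced.
#'
#' @param result a [DesignResult-class]
#' @param dir output directory (created if needed)
#' @param prefix file name stem (default "design")
#' @return the directory, invisibly
#' @export
writeDesignResult <- function(result, dir, prefix = "design") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(result@table, file.path(dir, paste0(prefix, ".tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  seqs <- stats::setNames(result@table$sequence,
                          paste0(prefix, seq_len(nrow(result@table))))
  writePeptides(seqs, file.path(dir, paste0(prefix, ".fasta")))
  cfg <- result@config
  echo <- list(variant = result@variant, SF = result@SF,
               C = cfg@C, iterations = cfg@iterations,
               rollouts_per_expansion = cfg@rollouts_per_expansion,
               length = cfg@length,
               constraints = as.list(cfg@constraints),
               pool_size = cfg@pool_size, seed = cfg@seed,
               normalization = cfg@normalization,
               ucb1_form = cfg@ucb1_form,
               alphabet = paste(cfg@alphabet@residues, collapse = ""))
  yaml::write_yaml(echo, file.path(dir, paste0(prefix, "_config.yaml")))
  invisible(dir)
}
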
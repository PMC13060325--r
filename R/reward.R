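#' Build a reward specification
#'
#' The search maximises the reward. Variants:
#' \itemize{
#'   \item `affinity`: `-Score(target)` — minimise the predicted score.
#'   \item `solubility_augmented`: `-Score(target) + SF * Sol` — trade
#'     affinity against water solubility, weighted by the scaling factor SF.
#'   \item `competitive`: `-(Score(target) - Score(off_target)) + SF * Sol`
#'     — maximise the predicted score gap favouring the target surface; the
#'     mirror-image design problem is obtained by swapping the two
#'     surrogates.
#' }
#' `Sol` is any [SolubilityScorer-class] under the larger-is-more-soluble
#' convention. SF defaults to 2.0, the value that balances score gap and
#' solubility well in competitive design.
#'
#' @param target target-surface [SurrogatePredictor-class]
#' @param variant reward variant
#' @param SF non-negative scaling factor of the solubility term
#' @param off_target off-target surrogate (required for `competitive`)
#' @param solubility a [SolubilityScorer-class] (required for the
#'   solubility-bearing variants)
#' @return a [RewardSpec-class]
#' @export
rewardSpec <- function(target,
                       variant = c("affinity", "solubility_augmented",
                                   "competitive"),
                       SF = 2.0, off_target = NULL, solubility = NULL) {
  variant <- match.arg(variant)
  new("RewardSpec", variant = variant, SF = SF, target = target,
      off_target = off_target, solubility = solubility)
}

#' Evaluate the search reward for complete peptides
#'
#' @param spec a [RewardSpec-class]
#' @param x character vector of complete (design-length) peptide sequences
#' @return numeric vector of rewards (larger = better)
#' @seealso [rewardComponents()] for the per-term breakdown
#' @export
evaluateReward <- function(spec, x) {
  rewardComponents(spec, x)$total
}

#' Per-term breakdown of the reward
#'
#' Diagnostics behind affinity/solubility trade-off plots: the score term,
#' the solubility term and their total (which equals [evaluateReward()]).
#'
#' @inheritParams evaluateReward
#' @return data.frame with columns `sequence`, `score_target`
#'   (`score_off_target` and `score_gap` for competitive), `solubility`,
#'   `solubility_term` and `total`
#' @export
rewardComponents <- function(spec, x) {
  st <- predictScore(spec@target, x)
  sol <- if (is.null(spec@solubility)) rep.int(0, length(x)) else
    solubilityScore(spec@solubility, x)
  out <- data.frame(sequence = x, score_target = st)
  if (spec@variant == "competitive") {
    so <- predictScore(spec@off_target, x)
    out$score_off_target <- so
    out$score_gap <- st - so
    score_term <- -(st - so)
  } else {
    score_term <- -st
  }
  sol_term <- if (spec@variant == "affinity") rep.int(0, length(x)) else
    spec@SF * sol
  out$solubility <- sol
  out$solubility_term <- sol_term
  out$total <- score_term + sol_term
  out
}

setMethod("show", "RewardSpec", function(object) {
  cat("RewardSpec:", object@variant)
  if (object@variant != "affinity") cat(", SF =", object@SF)
  cat("\n")
})
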
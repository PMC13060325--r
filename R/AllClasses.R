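#' Amino-acid alphabet for peptide design
#'
#' An ordered set of distinct single-letter canonical amino-acid codes.
#' The default design alphabet is the 20 canonical residues minus proline
#' (P) and cysteine (C), i.e. 18 letters, matching the chemistry of the
#' upstream biophysical design runs (proline restricts backbone
#' conformations, cysteine forms disulfides).
#'
#' @slot residues character vector of distinct single-letter codes
#' @aliases residues alphabet
#' @export
setClass("PeptideAlphabet", representation(residues = "character"))

AA_CANONICAL <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                  "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

setValidity("PeptideAlphabet", function(object) {
  r <- object@residues
  if (length(r) < 1L) return("alphabet must contain at least one residue")
  if (anyDuplicated(r)) return("alphabet residues must be distinct")
  bad <- setdiff(r, AA_CANONICAL)
  if (length(bad))
    return(paste0("non-canonical residue code(s): ", paste(bad, collapse = ", ")))
  TRUE
})

#' Deduplicated peptide sequence : score records
#'
#' The training currency of the surrogate: one row per peptide sequence with
#' a real-valued biophysical score (energy-like units, more negative =
#' stronger predicted binding). Sequences are validated against the table's
#' alphabet at construction, so downstream code never sees an out-of-alphabet
#' residue.
#'
#' @slot sequences character vector of peptide sequences
#' @slot scores numeric vector of finite scores, parallel to `sequences`
#' @slot alphabet the [PeptideAlphabet-class] the sequences are drawn from
#' @aliases sequences scores
#' @export
setClass("ScoreTable",
         representation(sequences = "character",
                        scores = "numeric",
                        alphabet = "PeptideAlphabet"))

setValidity("ScoreTable", function(object) {
  if (length(object@sequences) != length(object@scores))
    return("sequences and scores must have equal length")
  if (length(object@scores) && any(!is.finite(object@scores)))
    return("scores must all be finite")
  ok <- validSequences(object@sequences, object@alphabet)
  if (!all(ok))
    return(paste0("sequence(s) with residues outside the alphabet: ",
                  paste(utils::head(object@sequences[!ok], 3L), collapse = ", ")))
  TRUE
})

#' Sequence-to-score predictors
#'
#' Virtual parent of everything that can stand in for the expensive
#' biophysical score during search: the trained recurrent surrogate
#' ([RecurrentSurrogate-class]), an exact lookup table
#' ([TableOracle-class]), and the synthetic scoring oracle
#' ([SyntheticOracle-class]). All implement [predictScore()] and are
#' deterministic at inference.
#'
#' @export
setClass("SurrogatePredictor", representation("VIRTUAL"))

#' Exact lookup-table predictor
#'
#' Maps stored sequences to their stored scores exactly; unseen sequences
#' get the configured default, or raise an error when no default is set.
#' Used as a test double and for reward functions over enumerable spaces.
#'
#' @slot lookup named numeric vector (names = sequences)
#' @slot default numeric; `NA_real_` means unseen sequences are an error
#' @slot alphabet the [PeptideAlphabet-class]
#' @export
setClass("TableOracle", contains = "SurrogatePredictor",
         representation(lookup = "numeric",
                        default = "numeric",
                        alphabet = "PeptideAlphabet"))

setValidity("TableOracle", function(object) {
  if (length(object@lookup) && is.null(names(object@lookup)))
    return("lookup must be a named numeric vector")
  if (length(object@default) != 1L)
    return("default must be a length-1 numeric (possibly NA)")
  TRUE
})

#' Trained recurrent sequence-to-score surrogate
#'
#' An embedding layer followed by stacked LSTM layers and a linear head
#' reading the last hidden state; trained by Adam on mean-squared error with
#' validation-based snapshot selection (see [trainSurrogate()]). Inference is
#' deterministic for a fixed parameter state.
#'
#' @slot params list of parameter matrices (embedding, per-layer LSTM gates,
#'   head weights) for the selected best-validation epoch
#' @slot spec list: embedding_dim, recurrent_layers, hidden_dim
#' @slot alphabet the training [PeptideAlphabet-class]
#' @slot length fixed peptide length the model was trained on
#' @slot norm list(mean, sd): score standardisation used during training
#' @slot history data.frame with per-epoch train/validation loss
#' @slot best_epoch integer epoch whose validation loss was minimal
#' @export
setClass("RecurrentSurrogate", contains = "SurrogatePredictor",
         representation(params = "list",
                        spec = "list",
                        alphabet = "PeptideAlphabet",
                        length = "integer",
                        norm = "list",
                        history = "data.frame",
                        best_epoch = "integer"))

#' Synthetic biophysical scoring oracle
#'
#' A parametric stand-in for the upstream biophysical score: additive
#' per-residue weights plus positional modifiers plus sparse nearest-neighbour
#' couplings, passed through an affine calibration, with optional Gaussian
#' noise when sampling datasets. As a [SurrogatePredictor-class] it returns
#' the noiseless calibrated score (deterministic).
#'
#' @slot weights named numeric, per-residue additive weight
#' @slot positional numeric of length `length`, per-position modifier
#' @slot coupling square numeric matrix (residue x residue), nearest-neighbour
#'   coupling, mostly zero
#' @slot noise_sd non-negative Gaussian noise level used by [generateDataset()]
#' @slot a,b affine calibration: score = b + a * raw + noise
#' @slot alphabet the [PeptideAlphabet-class]
#' @slot length design length
#' @export
setClass("SyntheticOracle", contains = "SurrogatePredictor",
         representation(weights = "numeric",
                        positional = "numeric",
                        coupling = "matrix",
                        noise_sd = "numeric",
                        a = "numeric",
                        b = "numeric",
                        alphabet = "PeptideAlphabet",
                        length = "integer"))

setValidity("SyntheticOracle", function(object) {
  K <- length(object@alphabet@residues)
  if (!identical(sort(names(object@weights)), sort(object@alphabet@residues)))
    return("weights must be named by exactly the alphabet residues")
  if (length(object@positional) != object@length)
    return("positional modifiers must have one entry per position")
  if (!all(dim(object@coupling) == c(K, K)))
    return("coupling must be a residue x residue square matrix")
  if (object@noise_sd < 0) return("noise_sd must be >= 0")
  TRUE
})

#' Peptide solubility scorers
#'
#' Virtual parent of the solubility terms usable inside reward functions.
#' Convention everywhere in this package: larger score = more soluble.
#' Implementations: [TtHScorer-class] (negated transmembrane-tendency sum),
#' [CamsolLikeScorer-class] (smoothed intrinsic-profile stand-in), and
#' [LookupSolubility-class] (externally computed values).
#'
#' @export
setClass("SolubilityScorer", representation("VIRTUAL"))

#' Transmembrane-tendency solubility scorer
#'
#' Sums a per-residue transmembrane-tendency hydrophobicity scale over the
#' peptide. High transmembrane tendency means low aqueous solubility, so by
#' default the scorer exposes the negated sum (`sign = -1`) to honour the
#' package-wide larger-is-more-soluble convention; `sign = +1` gives the raw
#' sum for users who want the literal additive form.
#'
#' @slot scale named numeric per-residue scale values
#' @slot sign +1 or -1 multiplier applied to the raw sum
#' @export
setClass("TtHScorer", contains = "SolubilityScorer",
         representation(scale = "numeric", sign = "numeric"))

#' Intrinsic solubility profile stand-in
#'
#' A transparent sequence-based solubility score in the spirit of
#' intrinsic-profile predictors: each residue gets a raw score combining its
#' hydrophilicity (negated hydropathy), a reward for exposed side-chain
#' charge, and a penalty for bulky/aromatic side chains; the per-residue
#' profile is smoothed by a centred moving average of odd width `window`
#' (truncated at the termini) and the sequence score is the mean of the
#' smoothed profile. This is a documented stand-in, not a reimplementation
#' of any proprietary predictor; externally computed values can be supplied
#' through [externalSolubility()].
#'
#' @slot window odd smoothing window width (residues)
#' @slot w_hydrophilicity,w_charge,w_aromatic weights of the three terms
#' @slot hydropathy named numeric per-residue hydropathy scale
#' @slot charge named numeric per-residue side-chain charge
#' @slot aromatic named numeric per-residue bulky/aromatic indicator
#' @export
setClass("CamsolLikeScorer", contains = "SolubilityScorer",
         representation(window = "integer",
                        w_hydrophilicity = "numeric",
                        w_charge = "numeric",
                        w_aromatic = "numeric",
                        hydropathy = "numeric",
                        charge = "numeric",
                        aromatic = "numeric"))

setValidity("CamsolLikeScorer", function(object) {
  if (object@window < 1L || object@window %% 2L == 0L)
    return("window must be an odd integer >= 1")
  TRUE
})

#' Lookup-backed solubility scorer for external values
#'
#' Wraps a table of externally computed solubility values (for example from
#' a proprietary predictor run elsewhere). Querying a sequence absent from
#' the table is an error: it signals an incomplete external table rather
#' than silently substituting a value.
#'
#' @slot lookup named numeric (names = sequences)
#' @export
setClass("LookupSolubility", contains = "SolubilityScorer",
         representation(lookup = "numeric"))

setClassUnion("SurrogatePredictorOrNULL", c("SurrogatePredictor", "NULL"))
setClassUnion("SolubilityScorerOrNULL", c("SolubilityScorer", "NULL"))

#' Reward specification for peptide search
#'
#' Selects the reward variant optimised by the tree search:
#' \describe{
#'   \item{affinity}{Reward = -Score}
#'   \item{solubility_augmented}{Reward = -Score + SF * Sol}
#'   \item{competitive}{Reward = -(Score_target - Score_offtarget) + SF * Sol}
#' }
#' Score terms are surrogate predictions (more negative = better binding);
#' Sol follows the larger-is-more-soluble convention; SF is the scaling
#' factor weighing the solubility term (default 2.0 for competitive design).
#'
#' @slot variant one of "affinity", "solubility_augmented", "competitive"
#' @slot SF non-negative scaling factor for the solubility term
#' @slot target the target-surface [SurrogatePredictor-class]
#' @slot off_target competing-surface predictor (competitive variant only)
#' @slot solubility a [SolubilityScorer-class] or NULL
#' @export
setClass("RewardSpec",
         representation(variant = "character",
                        SF = "numeric",
                        target = "SurrogatePredictor",
                        off_target = "SurrogatePredictorOrNULL",
                        solubility = "SolubilityScorerOrNULL"))

setValidity("RewardSpec", function(object) {
  if (!object@variant %in% c("affinity", "solubility_augmented", "competitive"))
    return("variant must be affinity, solubility_augmented or competitive")
  if (length(object@SF) != 1L || object@SF < 0)
    return("SF must be a single non-negative number")
  if (object@variant == "competitive" && is.null(object@off_target))
    return("competitive reward requires an off-target surrogate")
  if (object@variant %in% c("solubility_augmented", "competitive") &&
      is.null(object@solubility))
    return(paste0(object@variant, " reward requires a solubility scorer"))
  TRUE
})

#' Search configuration for the constrained tree search
#'
#' @slot C exploration constant of the UCB1 rule (> 0)
#' @slot iterations number of selection/expansion/rollout/backprop rounds
#' @slot rollouts_per_expansion random completions per expanded node
#' @slot length design length (residues)
#' @slot constraints named integer vector: residue -> maximum count allowed
#'   in a full sequence (e.g. `c(W = 3L)`)
#' @slot pool_size number of top unique sequences harvested
#' @slot seed integer seed making the whole search reproducible
#' @slot normalization "running_minmax" (default) rescales rewards to the
#'   running observed range before UCB1 bookkeeping; "none" uses raw rewards
#' @slot ucb1_form "sqrt" (canonical UCB1) or "printed" (no radical)
#' @slot alphabet the [PeptideAlphabet-class] searched over
#' @export
setClass("SearchConfig",
         representation(C = "numeric",
                        iterations = "integer",
                        rollouts_per_expansion = "integer",
                        length = "integer",
                        constraints = "integer",
                        pool_size = "integer",
                        seed = "integer",
                        normalization = "character",
                        ucb1_form = "character",
                        alphabet = "PeptideAlphabet"),
         # prototype keeps a bare new() valid; the constructor fills slots
         # explicitly because a slot named C cannot be passed through new()
         # (it would partially match the Class argument)
         prototype(C = sqrt(2), iterations = 20000L,
                   rollouts_per_expansion = 1L, length = 12L,
                   constraints = integer(), pool_size = 100L, seed = 1L,
                   normalization = "running_minmax", ucb1_form = "sqrt"))

setValidity("SearchConfig", function(object) {
  if (object@C <= 0) return("exploration constant C must be > 0")
  if (object@iterations < 1L) return("iterations must be >= 1")
  if (object@pool_size < 1L) return("pool_size must be >= 1")
  if (object@length < 1L) return("length must be >= 1")
  if (length(object@constraints) &&
      (is.null(names(object@constraints)) || any(object@constraints < 0L)))
    return("constraints must be a named integer vector with counts >= 0")
  if (!object@normalization %in% c("none", "running_minmax"))
    return("normalization must be 'none' or 'running_minmax'")
  if (!object@ucb1_form %in% c("sqrt", "printed"))
    return("ucb1_form must be 'sqrt' or 'printed'")
  TRUE
})

#' Result of a design search
#'
#' Ranked unique sequences harvested from the rollouts, with their predicted
#' score(s), solubility and reward, plus the configuration and seed needed to
#' reproduce the run.
#'
#' @slot table data.frame: sequence, reward, predicted_score
#'   (score_target/score_off_target for competitive runs) and solubility
#' @slot config the [SearchConfig-class] used
#' @slot variant reward variant string
#' @slot SF scaling factor used
#' @slot n_rollouts total rollouts performed
#' @slot root_visits named numeric: visit count of each first-residue child
#'   of the root (diagnostic; sums to the root's visit count)
#' @export
setClass("DesignResult",
         representation(table = "data.frame",
                        config = "SearchConfig",
                        variant = "character",
                        SF = "numeric",
                        n_rollouts = "integer",
                        root_visits = "numeric"))

#' Per-position Shapley attribution report
#'
#' Rows are (peptide, position) pairs with the residue present and its
#' estimated Shapley value in score units; negative values mean the residue
#' pushes the prediction toward stronger binding. Aggregations by residue
#' type and by (type, position) are available through [perTypeValues()] and
#' [typePositionMeans()].
#'
#' @slot values data.frame: peptide_id, peptide, position, residue, value
#' @slot efficiency data.frame per peptide: prediction, baseline, value_sum,
#'   std_error of the Monte-Carlo efficiency residual
#' @slot n_samples Monte-Carlo permutations per peptide
#' @slot background "uniform" or "empirical"
#' @slot alphabet the [PeptideAlphabet-class]
#' @export
setClass("AttributionReport",
         representation(values = "data.frame",
                        efficiency = "data.frame",
                        n_samples = "integer",
                        background = "character",
                        alphabet = "PeptideAlphabet"))
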
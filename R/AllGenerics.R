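#' @import methods
NULL

#' Predict scores for peptide sequences
#'
#' Every surrogate predictor maps a peptide sequence to a predicted
#' biophysical score (energy-like units; more negative = higher predicted
#' binding affinity). Prediction is deterministic for a fixed trained state.
#'
#' @param object a [SurrogatePredictor-class] implementation
#' @param x character vector of peptide sequences over the predictor's alphabet
#' @param ... further arguments passed to methods
#' @return numeric vector of predicted scores, one per sequence
#' @export
setGeneric("predictScore", function(object, x, ...) standardGeneric("predictScore"))

#' Score peptide solubility
#'
#' Package-wide convention: larger values mean more soluble.
#'
#' @param object a [SolubilityScorer-class] implementation
#' @param x character vector of peptide sequences
#' @param ... further arguments passed to methods
#' @return numeric vector of solubility scores (dimensionless)
#' @export
setGeneric("solubilityScore", function(object, x, ...) standardGeneric("solubilityScore"))

#' @rdname ScoreTable-class
#' @param x a ScoreTable
#' @export
setGeneric("sequences", function(x) standardGeneric("sequences"))

#' @rdname ScoreTable-class
#' @export
setGeneric("scores", function(x) standardGeneric("scores"))

#' @rdname PeptideAlphabet-class
#' @param x object carrying an alphabet
#' @export
setGeneric("residues", function(x) standardGeneric("residues"))

#' @rdname PeptideAlphabet-class
#' @export
setGeneric("alphabet", function(x) standardGeneric("alphabet"))
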
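# Kyte-Doolittle hydropathy; larger = more hydrophobic
KD_HYDROPATHY <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5,
                   E = -3.5, G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9,
                   M = 1.9, F = 2.8, P = -1.6, S = -0.8, T = -0.7, W = -0.9,
                   Y = -1.3, V = 4.2)

# nominal side-chain charge at neutral pH (His partially protonated)
SIDECHAIN_CHARGE <- c(A = 0, R = 1, N = 0, D = -1, C = 0, Q = 0, E = -1,
                      G = 0, H = 0.1, I = 0, L = 0, K = 1, M = 0, F = 0,
                      P = 0, S = 0, T = 0, W = 0, Y = 0, V = 0)

# bulky/aromatic side-chain indicator
AROMATIC_BULK <- c(A = 0, R = 0, N = 0, D = 0, C = 0, Q = 0, E = 0, G = 0,
                   H = 0.5, I = 0, L = 0, K = 0, M = 0, F = 1, P = 0, S = 0,
                   T = 0, W = 1, Y = 1, V = 0)

#' The transmembrane-tendency hydrophobicity scale
#'
#' Reads the per-residue transmembrane tendency scale shipped with the
#' package (Zhao & London 2006; larger = stronger membrane tendency = less
#' water-soluble). Values are data inputs, replaceable by any scale file in
#' the same TSV dialect via [readPropertyScale()].
#'
#' @return named numeric vector over the 20 canonical residues
#' @export
tthScale <- function() {
  readPropertyScale(system.file("extdata", "ttH_scale.tsv",
                                package = "pepmcts", mustWork = TRUE))
}

#' Sum a property scale over a peptide
#'
#' The raw additive form used by the transmembrane-tendency solubility term:
#' the sum of the scale value of every residue. Sign conventions are applied
#' by the scorer/reward layers, not here.
#'
#' @param x character vector of peptide sequences
#' @param scale named numeric per-residue scale
#' @return numeric vector of per-sequence sums
#' @export
tthSum <- function(x, scale = tthScale()) {
  chars <- strsplit(toupper(x), "", fixed = TRUE)
  vapply(chars, function(ch) {
    v <- scale[ch]
    if (anyNA(v))
      stop("scale is missing residue(s): ",
           paste(unique(ch[is.na(v)]), collapse = ", "))
    sum(v)
  }, numeric(1L))
}

#' Transmembrane-tendency solubility scorer
#'
#' @param scale named numeric per-residue transmembrane-tendency values
#' @param sign -1 (default) exposes the negated sum so that larger scores
#'   mean more soluble (the package-wide convention); +1 exposes the raw sum
#' @return a [TtHScorer-class]
#' @export
tthScorer <- function(scale = tthScale(), sign = -1) {
  stopifnot(sign %in% c(-1, 1))
  new("TtHScorer", scale = scale, sign = sign)
}

#' @describeIn solubilityScore signed transmembrane-tendency sum
#' @export
setMethod("solubilityScore", "TtHScorer", function(object, x, ...) {
  object@sign * tthSum(x, object@scale)
})

#' Intrinsic-profile solubility stand-in
#'
#' See [CamsolLikeScorer-class] for the model. Default weights give equal
#' importance to hydrophilicity, charge exposure and the aromatic/bulk
#' penalty; the default window of 7 residues makes the score sensitive to
#' whether hydrophobic residues are clustered or dispersed.
#'
#' @param window odd smoothing window (default 7)
#' @param w_hydrophilicity,w_charge,w_aromatic term weights
#' @return a [CamsolLikeScorer-class]
#' @export
camsolLikeScorer <- function(window = 7L, w_hydrophilicity = 1,
                             w_charge = 1, w_aromatic = 1) {
  new("CamsolLikeScorer", window = as.integer(window),
      w_hydrophilicity = w_hydrophilicity, w_charge = w_charge,
      w_aromatic = w_aromatic,
      hydropathy = KD_HYDROPATHY, charge = SIDECHAIN_CHARGE,
      aromatic = AROMATIC_BULK)
}

# raw (unsmoothed) per-residue profile for one residue character vector
camsolRawProfile <- function(object, ch) {
  object@w_hydrophilicity * (-object@hydropathy[ch]) +
    object@w_charge * abs(object@charge[ch]) -
    object@w_aromatic * object@aromatic[ch]
}

# centred moving average truncated at the termini
smoothProfile <- function(v, window) {
  if (window == 1L) return(v)
  half <- (window - 1L) %/% 2L
  n <- length(v)
  vapply(seq_len(n), function(i) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    mean(v[lo:hi])
  }, numeric(1L))
}

#' Per-residue solubility profile of the intrinsic stand-in
#'
#' @param object a [CamsolLikeScorer-class]
#' @param x a single peptide sequence
#' @return list with `raw` and `smoothed` per-residue profiles
#' @export
solubilityProfile <- function(object, x) {
  ch <- strsplit(toupper(x), "", fixed = TRUE)[[1L]]
  raw <- unname(camsolRawProfile(object, ch))
  list(raw = raw, smoothed = smoothProfile(raw, object@window))
}

#' @describeIn solubilityScore mean of the smoothed intrinsic profile;
#'   larger = more soluble
#' @export
setMethod("solubilityScore", "CamsolLikeScorer", function(object, x, ...) {
  vapply(x, function(s) mean(solubilityProfile(object, s)$smoothed),
         numeric(1L), USE.NAMES = FALSE)
})

#' Solubility scorer backed by externally computed values
#'
#' Loads a `sequence<TAB>value` table of solubility scores computed by an
#' external predictor and exposes it as a [SolubilityScorer-class].
#' Querying a sequence absent from the table is an error, signalling an
#' incomplete external table.
#'
#' @param path TSV file with columns `sequence` and `value`, or a named
#'   numeric vector
#' @return a [LookupSolubility-class]
#' @export
externalSolubility <- function(path) {
  lookup <- if (is.numeric(path)) path else {
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            col.names = c("sequence", "value"),
                            colClasses = c("character", "numeric"))
    stats::setNames(df$value, toupper(df$sequence))
  }
  new("LookupSolubility", lookup = lookup)
}

#' @describeIn solubilityScore exact lookup of external values; unseen
#'   sequences are an error
#' @export
setMethod("solubilityScore", "LookupSolubility", function(object, x, ...) {
  out <- object@lookup[x]
  if (anyNA(out))
    stop("no external solubility value for sequence(s): ",
         paste(utils::head(x[!(x %in% names(object@lookup))], 3L),
               collapse = ", "))
  unname(out)
})
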
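#' Construct a peptide alphabet
#'
#' @param residues character vector of distinct single-letter canonical
#'   amino-acid codes (lower case accepted)
#' @return a [PeptideAlphabet-class]
#' @examples
#' peptideAlphabet(c("A", "W", "R"))
#' defaultAlphabet()   # the 18-letter design alphabet (no P, no C)
#' @export
peptideAlphabet <- function(residues) {
  new("PeptideAlphabet", residues = toupper(as.character(residues)))
}

#' @describeIn peptideAlphabet the default 18-letter design alphabet: the 20
#'   canonical amino acids excluding proline and cysteine.
#' @export
defaultAlphabet <- function() {
  peptideAlphabet(setdiff(AA_CANONICAL, c("P", "C")))
}

#' @rdname PeptideAlphabet-class
#' @export
setMethod("residues", "PeptideAlphabet", function(x) x@residues)

setMethod("show", "PeptideAlphabet", function(object) {
  cat("PeptideAlphabet of", length(object@residues), "residues:",
      paste(object@residues, collapse = ""), "\n")
})

# TRUE for sequences whose residues all lie in the alphabet
validSequences <- function(x, alphabet) {
  pattern <- paste0("^[", paste(alphabet@residues, collapse = ""), "]*$")
  grepl(pattern, x)
}

#' Parse and validate a peptide sequence
#'
#' Uppercases the input, checks every residue against the alphabet, and
#' optionally enforces a fixed design length. Characters outside the
#' alphabet (including residues the alphabet deliberately excludes, such as
#' P or C under the default alphabet) are an error, as is a wrong length
#' when one is demanded.
#'
#' @param text character scalar, the candidate sequence
#' @param alphabet a [PeptideAlphabet-class] (default: [defaultAlphabet()])
#' @param length required length, or `NULL` to accept any positive length
#' @return the validated upper-case sequence string
#' @examples
#' parsePeptide("WWHRFMKELYSG", length = 12)
#' @export
parsePeptide <- function(text, alphabet = defaultAlphabet(), length = NULL) {
  stopifnot(is.character(text), base::length(text) == 1L)
  seq <- toupper(trimws(text))
  if (nchar(seq) < 1L) stop("empty peptide sequence")
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  bad <- setdiff(unique(chars), alphabet@residues)
  if (base::length(bad))
    stop("residue(s) outside the alphabet: ", paste(bad, collapse = ", "))
  if (!is.null(length) && nchar(seq) != length)
    stop("peptide has length ", nchar(seq), ", expected ", length)
  seq
}

#' Draw random peptides uniformly over an alphabet
#'
#' Residues are i.i.d. uniform over the alphabet; used as the negative
#' control in score-distribution comparisons and as the probe population for
#' oracle calibration. Reproducible under `set.seed()`.
#'
#' @param n number of peptides
#' @param length peptide length (default 12)
#' @param alphabet a [PeptideAlphabet-class]
#' @return character vector of `n` sequences
#' @export
randomPeptides <- function(n, length = 12L, alphabet = defaultAlphabet()) {
  stopifnot(n >= 0L, length >= 1L)
  res <- alphabet@residues
  if (base::length(res) < 1L) stop("empty alphabet")
  m <- matrix(res[sample.int(base::length(res), n * length, replace = TRUE)],
              nrow = length, ncol = n)
  apply(m, 2L, paste, collapse = "")
}

#' Read and write peptide sets as FASTA
#'
#' Thin wrappers over [Biostrings::readAAStringSet()] /
#' [Biostrings::writeXStringSet()] that validate every record against the
#' design alphabet on the way in. Round trips are lossless for sequences and
#' record identifiers.
#'
#' @param path file path
#' @param alphabet a [PeptideAlphabet-class]; set `NULL` to skip validation
#' @return `readPeptides`: named character vector of sequences
#' @export
readPeptides <- function(path, alphabet = defaultAlphabet()) {
  set <- Biostrings::readAAStringSet(path)
  x <- toupper(as.character(set))
  if (!is.null(alphabet)) {
    ok <- validSequences(x, alphabet)
    if (!all(ok))
      stop("FASTA record(s) with residues outside the alphabet: ",
           paste(utils::head(names(x)[!ok], 3L), collapse = ", "))
  }
  x
}

#' @rdname readPeptides
#' @param x named character vector of sequences (names become identifiers;
#'   unnamed sequences get `pep1`, `pep2`, ...)
#' @export
writePeptides <- function(x, path) {
  if (is.null(names(x)) || any(!nzchar(names(x))))
    names(x) <- paste0("pep", seq_along(x))
  Biostrings::writeXStringSet(Biostrings::AAStringSet(x), path)
  invisible(path)
}

#' Construct a ScoreTable
#'
#' @param sequences character vector of peptide sequences
#' @param scores numeric vector of finite scores
#' @param alphabet a [PeptideAlphabet-class]
#' @return a [ScoreTable-class]
#' @export
scoreTable <- function(sequences, scores, alphabet = defaultAlphabet()) {
  new("ScoreTable", sequences = toupper(as.character(sequences)),
      scores = as.numeric(scores), alphabet = alphabet)
}

#' @rdname ScoreTable-class
#' @export
setMethod("sequences", "ScoreTable", function(x) x@sequences)

#' @rdname ScoreTable-class
#' @export
setMethod("scores", "ScoreTable", function(x) x@scores)

#' @rdname ScoreTable-class
#' @export
setMethod("alphabet", "ScoreTable", function(x) x@alphabet)

#' @rdname ScoreTable-class
#' @export
setMethod("length", "ScoreTable", function(x) base::length(x@sequences))

#' @rdname ScoreTable-class
#' @param i index vector
#' @param j,drop ignored
#' @param ... ignored
#' @export
setMethod("[", "ScoreTable", function(x, i, j, ..., drop = TRUE) {
  initialize(x, sequences = x@sequences[i], scores = x@scores[i])
})

setMethod("show", "ScoreTable", function(object) {
  n <- length(object)
  cat("ScoreTable with", n, "records over a",
      base::length(object@alphabet@residues), "letter alphabet\n")
  if (n) {
    k <- min(n, 5L)
    for (idx in seq_len(k))
      cat(sprintf("  %s  %g\n", object@sequences[idx], object@scores[idx]))
    if (n > k) cat("  ...\n")
  }
})

#' @rdname ScoreTable-class
#' @param row.names,optional passed to the data.frame method
#' @export
as.data.frame.ScoreTable <- function(x, row.names = NULL, optional = FALSE, ...) {
  data.frame(sequence = x@sequences, score = x@scores,
             row.names = row.names, stringsAsFactors = FALSE)
}

#' Read and write sequence : score tables
#'
#' Tables are two-column delimited text with header `sequence`, `score`.
#' Tab and comma delimiters are both accepted on read (auto-detected from
#' the header line); tab is always emitted on write. Sequences are validated
#' against the alphabet; non-numeric or non-finite scores are an error.
#'
#' @param path file path
#' @param alphabet a [PeptideAlphabet-class]
#' @return `readScoreTable`: a [ScoreTable-class]
#' @export
readScoreTable <- function(path, alphabet = defaultAlphabet()) {
  header <- readLines(path, n = 1L)
  if (!length(header)) return(scoreTable(character(), numeric(), alphabet))
  sep <- if (grepl(",", header, fixed = TRUE) &&
             !grepl("\t", header, fixed = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = c("character", "character"),
                          col.names = c("sequence", "score"))
  sc <- suppressWarnings(as.numeric(df$score))
  bad <- !is.finite(sc)
  if (any(bad))
    stop("unparseable or non-finite score(s), e.g. '", df$score[which(bad)[1L]],
         "' for sequence ", df$sequence[which(bad)[1L]])
  scoreTable(df$sequence, sc, alphabet)
}

#' @rdname readScoreTable
#' @param table a [ScoreTable-class]
#' @export
writeScoreTable <- function(table, path) {
  df <- data.frame(sequence = table@sequences, score = table@scores)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a per-residue property scale
#'
#' Scales are two-column TSV `residue<TAB>value` (dimensionless units defined
#' by the scale's source). When an alphabet is given, the scale must cover
#' every residue of it.
#'
#' @param path file path
#' @param alphabet a [PeptideAlphabet-class] the scale must cover, or `NULL`
#' @return named numeric vector, names = residue codes
#' @export
readPropertyScale <- function(path, alphabet = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          comment.char = "#",
                          col.names = c("residue", "value"),
                          colClasses = c("character", "numeric"))
  scale <- stats::setNames(df$value, toupper(df$residue))
  if (!is.null(alphabet)) {
    missing <- setdiff(alphabet@residues, names(scale))
    if (length(missing))
      stop("scale is missing residue(s): ", paste(missing, collapse = ", "))
  }
  scale
}
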
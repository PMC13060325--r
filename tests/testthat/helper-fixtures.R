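# shared fixtures built in code at test time

AWR <- peptideAlphabet(c("A", "W", "R"))

# all sequences of a given length over an alphabet, lexicographic
enumerateSequences <- function(alphabet, length) {
  grid <- expand.grid(rep(list(residues(alphabet)), length),
                      stringsAsFactors = FALSE)
  apply(grid[, rev(seq_len(length)), drop = FALSE], 1L, paste, collapse = "")
}

# per-sequence count of one residue
countResidue <- function(x, residue) {
  vapply(strsplit(x, "", fixed = TRUE),
         function(ch) sum(ch == residue), integer(1L))
}

# small additive oracle with distinct per-residue weights, no noise
additiveOracle <- function(alphabet = defaultAlphabet(), length = 12L) {
  w <- stats::setNames(seq(-2, 2, length.out = base::length(residues(alphabet))),
                       residues(alphabet))
  syntheticOracle(w, noise_sd = 0, alphabet = alphabet, length = length)
}

# a deterministic lookup reward over the full {A,W,R}^4 space with a
# unique optimum at WWWA
awr4Oracle <- function() {
  seqs <- enumerateSequences(AWR, 4L)
  vals <- withSeed(42L, stats::rnorm(length(seqs)))
  vals[seqs == "WWWA"] <- min(vals) - 1
  tableOracle(stats::setNames(vals, seqs), alphabet = AWR)
}

withSeed <- pepmcts:::withSeed
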
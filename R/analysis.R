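#' Amino-acid composition of a peptide set
#'
#' Exact counting over a set of equal-length peptides: the overall
#' per-residue fraction and the position x residue fraction matrix (rows =
#' positions 1..L from the N-terminus, columns = alphabet residues). The
#' positional matrix is exactly the frequency matrix consumed by sequence
#' logo tools; the overall fractions are its column means.
#'
#' @param peptides non-empty character vector of equal-length sequences
#' @param alphabet a [PeptideAlphabet-class]
#' @return list with `overall` (named numeric summing to 1) and
#'   `positional` (L x K matrix, each row summing to 1)
#' @export
composition <- function(peptides, alphabet = defaultAlphabet()) {
  if (!length(peptides)) stop("empty peptide set")
  L <- nchar(peptides[1L])
  if (any(nchar(peptides) != L)) stop("peptides have mixed lengths")
  codes <- encodePeptides(toupper(peptides), alphabet)   # L x N
  K <- length(alphabet@residues)
  positional <- t(apply(codes, 1L, tabulate, nbins = K)) / length(peptides)
  dimnames(positional) <- list(paste0("pos", seq_len(L)), alphabet@residues)
  overall <- colMeans(positional)
  list(overall = overall, positional = positional)
}

#' Log-ratio enrichment of residue frequencies between two sets
#'
#' `log((p_a + eps) / (p_b + eps))` per residue, where `p_a` and `p_b` are
#' the overall residue fractions of the two sets and `eps` is a pseudocount
#' guarding the zero-frequency case (the ratio is undefined at zero). The
#' log base defaults to natural; the statistic is antisymmetric under
#' swapping the sets as `eps -> 0`.
#'
#' @param profile_a,profile_b composition profiles from [composition()], or
#'   peptide sets (characters), over the same alphabet
#' @param pseudocount non-negative `eps`; default `1 / (2 * K)` for a
#'   K-letter alphabet
#' @param base log base (default `exp(1)`)
#' @param alphabet alphabet used when raw peptide sets are given
#' @return named numeric vector of per-residue enrichments
#' @export
enrichment <- function(profile_a, profile_b, pseudocount = NULL,
                       base = exp(1), alphabet = defaultAlphabet()) {
  toProfile <- function(p) if (is.character(p)) composition(p, alphabet) else p
  a <- toProfile(profile_a)$overall
  b <- toProfile(profile_b)$overall
  if (!identical(names(a), names(b)))
    stop("profiles are over different alphabets")
  if (is.null(pseudocount)) pseudocount <- 1 / (2 * length(a))
  if (pseudocount < 0) stop("pseudocount must be >= 0")
  log((a + pseudocount) / (b + pseudocount), base = base)
}

#' Compare score distributions across tables
#'
#' Per-table summary statistics plus binned histograms and Gaussian kernel
#' density estimates evaluated on one shared grid, ready for distribution
#' overlays. Bandwidth follows Scott's rule by default.
#'
#' @param tables named list of non-empty [ScoreTable-class] objects
#' @param n_grid number of shared grid points
#' @param n_bins number of histogram bins over the shared range
#' @param bw bandwidth: "scott" (default), or a number
#' @return list with `summary` (data.frame of n/mean/sd/min/max per table),
#'   `grid`, `density` (grid x table matrix), and `histogram` (list of
#'   per-table data.frames with bin mids and densities)
#' @export
compareScores <- function(tables, n_grid = 512L, n_bins = 50L, bw = "scott") {
  if (!length(tables) || is.null(names(tables)))
    stop("tables must be a non-empty named list")
  for (nm in names(tables))
    if (!length(tables[[nm]])) stop("empty score table: ", nm)
  allScores <- unlist(lapply(tables, scores), use.names = FALSE)
  rng <- range(allScores)
  pad <- 0.05 * diff(rng)
  grid <- seq(rng[1L] - pad, rng[2L] + pad, length.out = n_grid)
  breaks <- seq(rng[1L], rng[2L], length.out = n_bins + 1L)
  summary <- do.call(rbind, lapply(names(tables), function(nm) {
    s <- scores(tables[[nm]])
    data.frame(table = nm, n = length(s), mean = mean(s),
               sd = if (length(s) > 1L) stats::sd(s) else 0,
               min = min(s), max = max(s))
  }))
  dens <- sapply(names(tables), function(nm) {
    s <- scores(tables[[nm]])
    bwv <- if (identical(bw, "scott")) stats::bw.nrd(s) else bw
    stats::density(s, bw = bwv, from = grid[1L], to = grid[n_grid],
                   n = n_grid)$y
  })
  hists <- lapply(tables, function(tb) {
    h <- graphics::hist(scores(tb), breaks = breaks, plot = FALSE)
    data.frame(mid = h$mids, density = h$density, count = h$counts)
  })
  list(summary = summary, grid = grid, density = dens, histogram = hists)
}

#' Write the positional frequency (logo) matrix
#'
#' @param profile a composition profile from [composition()]
#' @param path output TSV (rows = positions, columns = residues)
#' @return the path, invisibly
#' @export
writeLogoMatrix <- function(profile, path) {
  df <- data.frame(position = seq_len(nrow(profile$positional)),
                   profile$positional, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
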
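#' Configuration for sampling-based Shapley attribution
#'
#' Permutation-sampling Shapley estimation is model-agnostic: it works for
#' any [SurrogatePredictor-class] and its axioms (efficiency, symmetry,
#' dummy) are directly testable. Defaults: 200 Monte-Carlo permutations per
#' peptide and a uniform background over the alphabet; an empirical
#' background can be supplied as residue frequencies.
#'
#' @param n_samples Monte-Carlo permutations per peptide (>= 1)
#' @param background "uniform", or a named numeric vector of residue
#'   frequencies (normalised internally)
#' @param seed integer seed
#' @return named list used by [shapleySampling()] / [attributeSet()]
#' @export
attributionConfig <- function(n_samples = 200L, background = "uniform",
                              seed = 1L) {
  stopifnot(n_samples >= 1L)
  list(n_samples = as.integer(n_samples), background = background,
       seed = as.integer(seed))
}

backgroundProbs <- function(background, alphabet) {
  res <- alphabet@residues
  if (identical(background, "uniform"))
    return(stats::setNames(rep.int(1 / length(res), length(res)), res))
  p <- background[res]
  if (anyNA(p)) stop("background frequencies missing for residue(s): ",
                     paste(res[is.na(p)], collapse = ", "))
  p / sum(p)
}

#' Per-position Shapley values of one peptide
#'
#' Permutation-sampling estimate: for each sampled permutation of positions,
#' a background sequence is drawn, the peptide's residues are revealed one
#' position at a time in permutation order, and a position's marginal
#' contribution is the prediction change when it is revealed. The Shapley
#' value of a position is the mean marginal over samples. The values
#' satisfy the efficiency axiom up to Monte-Carlo error: they sum to
#' `f(peptide) - E_background[f]`.
#'
#' @param model a [SurrogatePredictor-class]
#' @param peptide a single sequence over the model's alphabet
#' @param config from [attributionConfig()]
#' @param alphabet the design alphabet
#' @return list: `values` (per position), `se` (their standard errors),
#'   `prediction`, `baseline` (Monte-Carlo estimate of the background
#'   expectation), `sum_se` (standard error of the value sum)
#' @export
shapleySampling <- function(model, peptide, config = attributionConfig(),
                            alphabet = defaultAlphabet()) {
  chars <- strsplit(toupper(peptide), "", fixed = TRUE)[[1L]]
  L <- length(chars)
  M <- config$n_samples
  probs <- backgroundProbs(config$background, alphabet)
  res <- alphabet@residues
  withSeed(config$seed, {
    perms <- matrix(0L, M, L)
    seqs <- character(M * (L + 1L))
    for (m in seq_len(M)) {
      perms[m, ] <- sample.int(L)
      z <- res[sample.int(length(res), L, replace = TRUE, prob = probs)]
      base <- (m - 1L) * (L + 1L)
      seqs[base + 1L] <- paste(z, collapse = "")
      for (k in seq_len(L)) {
        pos <- perms[m, k]
        z[pos] <- chars[pos]
        seqs[base + k + 1L] <- paste(z, collapse = "")
      }
    }
    preds <- matrix(predictScore(model, seqs), nrow = L + 1L)  # (L+1) x M
    marg <- matrix(0, M, L)   # sample x position
    for (k in seq_len(L)) {
      delta <- preds[k + 1L, ] - preds[k, ]
      marg[cbind(seq_len(M), perms[, k])] <- delta
    }
    persample_sum <- rowSums(marg)
    list(values = colMeans(marg),
         se = apply(marg, 2L, stats::sd) / sqrt(M),
         prediction = predictScore(model, paste(chars, collapse = "")),
         baseline = mean(preds[1L, ]),
         sum_se = stats::sd(persample_sum) / sqrt(M))
  })
}

#' Shapley attribution over a peptide set
#'
#' Runs [shapleySampling()] for every peptide (typically a stratified sample
#' of a score table) and assembles the per-(peptide, position) value table
#' with its per-peptide efficiency bookkeeping. Aggregations by residue type
#' and by (type, position) are exposed through [perTypeValues()] and
#' [typePositionMeans()].
#'
#' @param model a [SurrogatePredictor-class]
#' @param peptides character vector of equal-length sequences
#' @param config from [attributionConfig()]
#' @param alphabet the design alphabet
#' @return an [AttributionReport-class]
#' @export
attributeSet <- function(model, peptides, config = attributionConfig(),
                         alphabet = defaultAlphabet()) {
  if (!length(peptides)) stop("empty peptide set")
  L <- nchar(peptides[1L])
  rows <- vector("list", length(peptides))
  eff <- vector("list", length(peptides))
  for (i in seq_along(peptides)) {
    cfg <- config
    cfg$seed <- config$seed + i - 1L   # independent streams per peptide
    s <- shapleySampling(model, peptides[i], cfg, alphabet)
    rows[[i]] <- data.frame(
      peptide_id = i, peptide = peptides[i], position = seq_len(L),
      residue = strsplit(peptides[i], "", fixed = TRUE)[[1L]],
      value = s$values, std_error = s$se)
    eff[[i]] <- data.frame(
      peptide_id = i, peptide = peptides[i],
      prediction = s$prediction, baseline = s$baseline,
      value_sum = sum(s$values), sum_se = s$sum_se)
  }
  new("AttributionReport",
      values = do.call(rbind, rows),
      efficiency = do.call(rbind, eff),
      n_samples = config$n_samples,
      background = if (identical(config$background, "uniform")) "uniform"
                   else "empirical",
      alphabet = alphabet)
}

#' @rdname AttributionReport-class
#' @param x an AttributionReport
#' @return `perTypeValues`: data.frame of residue type and Shapley value
#'   (one row per attributed position; the distribution behind violin-style
#'   summaries)
#' @export
perTypeValues <- function(x) {
  x@values[, c("residue", "value")]
}

#' @rdname AttributionReport-class
#' @return `typePositionMeans`: residue x position matrix of mean Shapley
#'   values (NA where a type never occurs at a position)
#' @export
typePositionMeans <- function(x) {
  v <- x@values
  L <- max(v$position)
  res <- x@alphabet@residues
  out <- matrix(NA_real_, length(res), L,
                dimnames = list(res, paste0("pos", seq_len(L))))
  agg <- stats::aggregate(value ~ residue + position, data = v, FUN = mean)
  out[cbind(match(agg$residue, res), agg$position)] <- agg$value
  out
}

setMethod("show", "AttributionReport", function(object) {
  cat(sprintf(paste0("AttributionReport: %d peptides x %d positions ",
                     "(%d rows), %d samples/peptide, %s background\n"),
              nrow(object@efficiency),
              max(object@values$position), nrow(object@values),
              object@n_samples, object@background))
})

#' Difference in mean Shapley value between two reports
#'
#' For competitive design diagnostics: per residue type, the mean Shapley
#' value under the target-surface model minus the mean under the off-target
#' model, computed over the same peptide set. Antisymmetric under swapping
#' the reports.
#'
#' @param report_target,report_offtarget [AttributionReport-class] objects
#'   over identical peptide sets
#' @return named numeric vector of per-type mean differences
#' @export
shapGap <- function(report_target, report_offtarget) {
  if (!identical(report_target@values$peptide,
                 report_offtarget@values$peptide))
    stop("the two reports cover different peptide sets")
  a <- tapply(report_target@values$value, report_target@values$residue, mean)
  b <- tapply(report_offtarget@values$value,
              report_offtarget@values$residue, mean)
  types <- union(names(a), names(b))
  out <- stats::setNames(rep.int(NA_real_, length(types)), types)
  out[names(a)] <- a
  out[names(b)] <- out[names(b)] - b
  out
}

#' Write an attribution report to disk
#'
#' Emits `shap_values.tsv` (peptide_id, peptide, position, residue, value,
#' std_error), `shap_per_type.tsv` (the per-type value distribution) and
#' `shap_type_position.tsv` (type x position means), plus
#' `shap_efficiency.tsv` with the per-peptide efficiency bookkeeping.
#'
#' @param report an [AttributionReport-class]
#' @param dir output directory
#' @return the directory, invisibly
#' @export
writeAttributionReport <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name)
    utils::write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  w(report@values, "shap_values.tsv")
  w(perTypeValues(report), "shap_per_type.tsv")
  tp <- typePositionMeans(report)
  utils::write.table(data.frame(residue = rownames(tp), tp),
                     file.path(dir, "shap_type_position.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  w(report@efficiency, "shap_efficiency.tsv")
  invisible(dir)
}
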
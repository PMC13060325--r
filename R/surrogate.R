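# ---- residue integer encoding ----------------------------------------------

# L x N integer matrix of 1-based residue indices into alphabet@residues
encodePeptides <- function(x, alphabet, length = NULL) {
  if (!base::length(x)) stop("no sequences to encode")
  L <- nchar(x[1L])
  if (!is.null(length) && L != length)
    stop("sequences have length ", L, ", model expects ", length)
  if (any(nchar(x) != L)) stop("sequences must all have the same length")
  code <- match(unlist(strsplit(x, "", fixed = TRUE), use.names = FALSE),
                alphabet@residues)
  if (anyNA(code)) stop("sequence(s) contain residues outside the alphabet")
  matrix(code, nrow = L)
}

# ---- network parameters ----------------------------------------------------

sigmoid <- function(z) 1 / (1 + exp(-z))

# flat named parameter list: E, W<l>, U<l>, b<l> for each layer, v, c0.
# gate row order inside the stacked 4h blocks: input, forget, cell, output.
lstmInit <- function(K, spec) {
  e <- spec$embedding_dim; h <- spec$hidden_dim; nl <- spec$recurrent_layers
  u <- function(nr, nc, fan) matrix(stats::runif(nr * nc, -1, 1) / sqrt(fan), nr, nc)
  p <- list(E = u(K, e, e))
  for (l in seq_len(nl)) {
    din <- if (l == 1L) e else h
    p[[paste0("W", l)]] <- u(4L * h, din, din)
    p[[paste0("U", l)]] <- u(4L * h, h, h)
    b <- numeric(4L * h)
    b[(h + 1L):(2L * h)] <- 1  # forget-gate bias: remember by default
    p[[paste0("b", l)]] <- b
  }
  p$v <- u(1L, h, h)
  p$c0 <- 0
  p
}

# forward pass; X is L x B integer codes. When `cache` is TRUE the
# per-timestep activations needed for backprop are returned too.
lstmForward <- function(p, X, spec, cache = FALSE) {
  L <- nrow(X); B <- ncol(X)
  h <- spec$hidden_dim; nl <- spec$recurrent_layers
  hs <- cs <- vector("list", nl)
  for (l in seq_len(nl)) hs[[l]] <- cs[[l]] <- matrix(0, h, B)
  cc <- if (cache) {
    list(inp = rep(list(vector("list", L)), nl),
         i = rep(list(vector("list", L)), nl),
         f = rep(list(vector("list", L)), nl),
         g = rep(list(vector("list", L)), nl),
         o = rep(list(vector("list", L)), nl),
         tc = rep(list(vector("list", L)), nl),
         hprev = rep(list(vector("list", L)), nl),
         cprev = rep(list(vector("list", L)), nl),
         h = rep(list(vector("list", L)), nl))
  }
  gi <- seq_len(h); gf <- gi + h; gg <- gf + h; go <- gg + h
  for (t in seq_len(L)) {
    inp <- t(p$E[X[t, ], , drop = FALSE])   # e x B
    for (l in seq_len(nl)) {
      a <- p[[paste0("W", l)]] %*% inp + p[[paste0("U", l)]] %*% hs[[l]] +
        p[[paste0("b", l)]]
      i <- sigmoid(a[gi, , drop = FALSE])
      f <- sigmoid(a[gf, , drop = FALSE])
      g <- tanh(a[gg, , drop = FALSE])
      o <- sigmoid(a[go, , drop = FALSE])
      cnew <- f * cs[[l]] + i * g
      tc <- tanh(cnew)
      hnew <- o * tc
      if (cache) {
        cc$inp[[l]][[t]] <- inp; cc$i[[l]][[t]] <- i; cc$f[[l]][[t]] <- f
        cc$g[[l]][[t]] <- g; cc$o[[l]][[t]] <- o; cc$tc[[l]][[t]] <- tc
        cc$hprev[[l]][[t]] <- hs[[l]]; cc$cprev[[l]][[t]] <- cs[[l]]
        cc$h[[l]][[t]] <- hnew
      }
      hs[[l]] <- hnew; cs[[l]] <- cnew
      inp <- hnew
    }
  }
  y <- as.numeric(p$v %*% hs[[nl]] + p$c0)
  if (cache) list(y = y, cache = cc, h_last = hs[[nl]], X = X) else y
}

# backward pass for MSE loss mean((y - target)^2) over the batch
lstmBackward <- function(p, fwd, target, spec) {
  X <- fwd$X; cc <- fwd$cache
  L <- nrow(X); B <- ncol(X)
  h <- spec$hidden_dim; nl <- spec$recurrent_layers
  gi <- seq_len(h); gf <- gi + h; gg <- gf + h; go <- gg + h
  grads <- list()
  dy <- matrix(2 * (fwd$y - target) / B, 1L, B)
  grads$v <- dy %*% t(fwd$h_last)
  grads$c0 <- sum(dy)
  # external dh arriving at the top layer: only the last timestep sees dy
  dh_ext <- vector("list", L)
  for (t in seq_len(L)) dh_ext[[t]] <- matrix(0, h, B)
  dh_ext[[L]] <- crossprod(p$v, dy)
  for (l in rev(seq_len(nl))) {
    W <- p[[paste0("W", l)]]; U <- p[[paste0("U", l)]]
    dW <- matrix(0, nrow(W), ncol(W)); dU <- matrix(0, 4L * h, h)
    db <- numeric(4L * h)
    dh_next <- matrix(0, h, B); dc_next <- matrix(0, h, B)
    dinp <- vector("list", L)
    for (t in rev(seq_len(L))) {
      dh <- dh_ext[[t]] + dh_next
      i <- cc$i[[l]][[t]]; f <- cc$f[[l]][[t]]; g <- cc$g[[l]][[t]]
      o <- cc$o[[l]][[t]]; tc <- cc$tc[[l]][[t]]
      dct <- dc_next + dh * o * (1 - tc * tc)
      da <- rbind((dct * g) * i * (1 - i),
                  (dct * cc$cprev[[l]][[t]]) * f * (1 - f),
                  (dct * i) * (1 - g * g),
                  (dh * tc) * o * (1 - o))
      dW <- dW + da %*% t(cc$inp[[l]][[t]])
      dU <- dU + da %*% t(cc$hprev[[l]][[t]])
      db <- db + rowSums(da)
      dinp[[t]] <- crossprod(W, da)
      dh_next <- crossprod(U, da)
      dc_next <- dct * f
    }
    grads[[paste0("W", l)]] <- dW
    grads[[paste0("U", l)]] <- dU
    grads[[paste0("b", l)]] <- db
    dh_ext <- dinp
  }
  dE <- matrix(0, nrow(p$E), ncol(p$E))
  for (t in seq_len(L)) {
    r <- rowsum(t(dh_ext[[t]]), group = X[t, ])
    idx <- as.integer(rownames(r))
    dE[idx, ] <- dE[idx, ] + r
  }
  grads$E <- dE
  grads
}

adamStep <- function(p, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    p[[nm]] <- p[[nm]] - lr * (state$m[[nm]] / bc1) /
      (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = p, state = state)
}

# ---- training --------------------------------------------------------------

#' Specification and training configuration for the recurrent surrogate
#'
#' `surrogateSpec()` fixes the architecture: an embedding layer, stacked
#' LSTM layers (default three) and a linear regressor reading the last
#' hidden state. `trainConfig()` fixes the optimisation: Adam on
#' mean-squared error at learning rate 0.001 for 200 epochs by default.
#' Hidden, embedding and batch sizes default to 64 / 16 / 256, sized for a
#' 12-mer design problem on a desktop CPU.
#'
#' @param embedding_dim embedding vector size per residue
#' @param recurrent_layers number of stacked LSTM layers
#' @param hidden_dim hidden state size of every LSTM layer
#' @return a named list
#' @export
surrogateSpec <- function(embedding_dim = 16L, recurrent_layers = 3L,
                          hidden_dim = 64L) {
  stopifnot(embedding_dim >= 1L, recurrent_layers >= 1L, hidden_dim >= 1L)
  list(embedding_dim = as.integer(embedding_dim),
       recurrent_layers = as.integer(recurrent_layers),
       hidden_dim = as.integer(hidden_dim))
}

#' @rdname surrogateSpec
#' @param learning_rate Adam learning rate (> 0)
#' @param epochs training epochs (>= 1)
#' @param batch_size minibatch size
#' @param seed integer seed for initialisation and shuffling
#' @export
trainConfig <- function(learning_rate = 0.001, epochs = 200L,
                        batch_size = 256L, seed = 1L) {
  stopifnot(learning_rate > 0, epochs >= 1L, batch_size >= 1L)
  list(learning_rate = learning_rate, epochs = as.integer(epochs),
       batch_size = as.integer(batch_size), seed = as.integer(seed))
}

#' Train the recurrent sequence-to-score surrogate
#'
#' Trains an embedding + stacked-LSTM + linear-head regressor by Adam on
#' mean-squared error, and returns the parameter snapshot with the lowest
#' validation loss seen across epochs (which need not be the final epoch).
#' Scores are standardised internally to the training mean/sd; predictions
#' are returned on the original score scale. Fully reproducible per seed.
#'
#' @param train,validation non-empty [ScoreTable-class] objects over the
#'   same alphabet, with sequences of one common length
#' @param spec architecture from [surrogateSpec()]
#' @param config optimisation settings from [trainConfig()]
#' @param verbose print per-epoch losses
#' @return a [RecurrentSurrogate-class]; its `history` slot holds per-epoch
#'   train/validation loss (standardised MSE) and `best_epoch` the selected
#'   epoch
#' @export
trainSurrogate <- function(train, validation, spec = surrogateSpec(),
                           config = trainConfig(), verbose = FALSE) {
  if (!length(train) || !length(validation)) stop("empty training tables")
  if (!identical(train@alphabet@residues, validation@alphabet@residues))
    stop("train and validation tables use different alphabets")
  alph <- train@alphabet
  K <- base::length(alph@residues)
  Xtr <- encodePeptides(train@sequences, alph)
  Xval <- encodePeptides(validation@sequences, alph, length = nrow(Xtr))
  mu <- mean(train@scores); sdv <- stats::sd(train@scores)
  if (!is.finite(sdv) || sdv == 0) sdv <- 1
  ytr <- (train@scores - mu) / sdv
  yval <- (validation@scores - mu) / sdv
  n <- ncol(Xtr)
  withSeed(config$seed, {
    p <- lstmInit(K, spec)
    state <- list(t = 0L,
                  m = lapply(p, function(x) x * 0),
                  v = lapply(p, function(x) x * 0))
    hist_train <- hist_val <- numeric(config$epochs)
    best <- list(loss = Inf, params = p, epoch = 0L)
    for (epoch in seq_len(config$epochs)) {
      perm <- sample.int(n)
      starts <- seq(1L, n, by = config$batch_size)
      ep_loss <- 0
      for (s in starts) {
        idx <- perm[s:min(s + config$batch_size - 1L, n)]
        fwd <- lstmForward(p, Xtr[, idx, drop = FALSE], spec, cache = TRUE)
        ep_loss <- ep_loss + sum((fwd$y - ytr[idx])^2)
        grads <- lstmBackward(p, fwd, ytr[idx], spec)
        upd <- adamStep(p, grads, state, config$learning_rate)
        p <- upd$params; state <- upd$state
      }
      hist_train[epoch] <- ep_loss / n
      pv <- predictBatched(p, Xval, spec)
      hist_val[epoch] <- mean((pv - yval)^2)
      if (hist_val[epoch] < best$loss)
        best <- list(loss = hist_val[epoch], params = p, epoch = epoch)
      if (verbose)
        message(sprintf("epoch %d  train %.5f  val %.5f", epoch,
                        hist_train[epoch], hist_val[epoch]))
    }
    new("RecurrentSurrogate",
        params = best$params, spec = spec, alphabet = alph,
        length = nrow(Xtr), norm = list(mean = mu, sd = sdv),
        history = data.frame(epoch = seq_len(config$epochs),
                             train_loss = hist_train, val_loss = hist_val),
        best_epoch = best$epoch)
  })
}

# chunked forward pass on standardised scale
predictBatched <- function(p, X, spec, chunk = 1024L) {
  n <- ncol(X)
  out <- numeric(n)
  for (s in seq(1L, n, by = chunk)) {
    idx <- s:min(s + chunk - 1L, n)
    out[idx] <- lstmForward(p, X[, idx, drop = FALSE], spec)
  }
  out
}

#' @describeIn predictScore trained recurrent surrogate: deterministic batched
#'   forward pass, predictions on the original score scale.
#' @export
setMethod("predictScore", "RecurrentSurrogate", function(object, x, ...) {
  X <- encodePeptides(x, object@alphabet, length = object@length)
  predictBatched(object@params, X, object@spec) * object@norm$sd +
    object@norm$mean
})

setMethod("show", "RecurrentSurrogate", function(object) {
  cat(sprintf(paste0("RecurrentSurrogate: %d-letter alphabet, length %d, ",
                     "embed %d, %d x LSTM(%d)\n"),
              base::length(object@alphabet@residues), object@length,
              object@spec$embedding_dim, object@spec$recurrent_layers,
              object@spec$hidden_dim))
  if (object@best_epoch > 0L)
    cat(sprintf("  best epoch %d, val MSE (standardised) %.5f\n",
                object@best_epoch,
                object@history$val_loss[object@best_epoch]))
})

#' Evaluate a predictor against a held-out score table
#'
#' @param model a [SurrogatePredictor-class]
#' @param test a non-empty [ScoreTable-class]
#' @return list with `r_squared` (coefficient of determination,
#'   1 - SS_res/SS_tot) and `rmse`
#' @export
evaluateSurrogate <- function(model, test) {
  if (!length(test)) stop("empty test table")
  pred <- predictScore(model, test@sequences)
  y <- test@scores
  ss_res <- sum((y - pred)^2)
  ss_tot <- sum((y - mean(y))^2)
  list(r_squared = 1 - ss_res / ss_tot,
       rmse = sqrt(mean((y - pred)^2)))
}

# ---- table oracle ----------------------------------------------------------

#' Exact lookup predictor over a score table
#'
#' @param table a [ScoreTable-class], or a named numeric vector of scores
#' @param default score returned for unseen sequences; `NA` (the default)
#'   makes unseen sequences an error
#' @param alphabet alphabet (taken from the table when one is given)
#' @return a [TableOracle-class]
#' @export
tableOracle <- function(table, default = NA_real_,
                        alphabet = defaultAlphabet()) {
  if (is(table, "ScoreTable")) {
    lookup <- stats::setNames(table@scores, table@sequences)
    alphabet <- table@alphabet
  } else {
    lookup <- table
  }
  new("TableOracle", lookup = lookup, default = as.numeric(default),
      alphabet = alphabet)
}

#' @describeIn predictScore exact lookup; unseen sequences take the oracle's
#'   default or raise an error when no default is set.
#' @export
setMethod("predictScore", "TableOracle", function(object, x, ...) {
  out <- object@lookup[x]
  miss <- is.na(out) & !(x %in% names(object@lookup))
  if (any(miss)) {
    if (is.na(object@default))
      stop("sequence(s) not in the lookup table: ",
           paste(utils::head(x[miss], 3L), collapse = ", "))
    out[miss] <- object@default
  }
  unname(out)
})

# ---- persistence -----------------------------------------------------------

SURROGATE_FORMAT <- 1L

#' Save and load a trained recurrent surrogate
#'
#' The model is written as a directory: a JSON manifest (format version,
#' alphabet, architecture, length, score normalisation, best epoch) plus the
#' weight arrays. `loadSurrogate()` refuses manifests with a different
#' format version or an alphabet inconsistent with the stored weights, and
#' fails loudly on truncated weight files.
#'
#' @param model a [RecurrentSurrogate-class]
#' @param dir directory to create/overwrite
#' @return `loadSurrogate`: the restored [RecurrentSurrogate-class]
#' @export
saveSurrogate <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(format = SURROGATE_FORMAT,
                   alphabet = model@alphabet@residues,
                   spec = model@spec,
                   length = model@length,
                   norm = model@norm,
                   best_epoch = model@best_epoch)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  # weights and normalisation ride together so reloaded predictions are
  # bit-identical (the JSON manifest echoes norm only for human readers)
  saveRDS(list(params = model@params, norm = model@norm),
          file.path(dir, "weights.rds"))
  utils::write.table(model@history, file.path(dir, "history.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' @rdname saveSurrogate
#' @export
loadSurrogate <- function(dir) {
  mpath <- file.path(dir, "manifest.json")
  if (!file.exists(mpath)) stop("no manifest.json under ", dir)
  manifest <- jsonlite::read_json(mpath, simplifyVector = TRUE)
  if (!identical(as.integer(manifest$format), SURROGATE_FORMAT))
    stop("unsupported surrogate format version: ", manifest$format)
  blob <- tryCatch(readRDS(file.path(dir, "weights.rds")),
                   error = function(e) stop("corrupt or truncated weights: ",
                                            conditionMessage(e)))
  if (!is.list(blob) || !all(c("params", "norm") %in% names(blob)))
    stop("corrupt weights payload under ", dir)
  params <- blob$params
  alph <- peptideAlphabet(manifest$alphabet)
  if (nrow(params$E) != base::length(alph@residues))
    stop("manifest alphabet (", base::length(alph@residues),
         " residues) does not match stored embedding rows (",
         nrow(params$E), ")")
  history <- utils::read.table(file.path(dir, "history.tsv"), header = TRUE,
                               sep = "\t")
  new("RecurrentSurrogate", params = params,
      spec = lapply(manifest$spec, as.integer),
      alphabet = alph, length = as.integer(manifest$length),
      norm = blob$norm,
      history = history, best_epoch = as.integer(manifest$best_epoch))
}
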
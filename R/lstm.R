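# Minimal batched LSTM engine.
#
# Stacked LSTM layers followed by a dense head, trained with Adam on
# cross-entropy (classification) or squared error (regression). All heavy
# operations are dense matrix products so the hot path runs in BLAS. Gate
# layout within each layer's weight matrix is [input, forget, cell, output],
# each `h` columns wide; forget-gate biases start at 1.

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Initialise LSTM parameters
#'
#' @param d_in input feature dimension per timestep
#' @param units integer vector of LSTM layer widths (e.g. `c(100, 50)`)
#' @param d_out output dimension (number of classes, or 1 for regression)
#' @return list of parameter matrices
#' @keywords internal
lstm_init <- function(d_in, units, d_out) {
  params <- list(layers = vector("list", length(units)),
                 d_in = d_in, units = units, d_out = d_out)
  din <- d_in
  for (l in seq_along(units)) {
    h <- units[l]
    sc <- sqrt(1 / (din + h))
    W <- matrix(rnorm((din + h) * 4 * h, 0, sc), din + h, 4 * h)
    b <- rep(0, 4 * h)
    b[(h + 1):(2 * h)] <- 1   # forget-gate bias
    params$layers[[l]] <- list(W = W, b = b)
    din <- h
  }
  sc <- sqrt(1 / din)
  params$Wd <- matrix(rnorm(din * d_out, 0, sc), din, d_out)
  params$bd <- rep(0, d_out)
  params
}

# forward pass over a batch; X is (batch, T, d_in)
# returns logits and (optionally) the cache needed for backprop
lstm_forward <- function(params, X, cache = FALSE) {
  nb <- dim(X)[1L]; Tn <- dim(X)[2L]
  inp <- lapply(seq_len(Tn), function(t) matrix(X[, t, ], nb, dim(X)[3L]))
  caches <- vector("list", length(params$units))
  for (l in seq_along(params$units)) {
    h <- params$units[l]
    W <- params$layers[[l]]$W; b <- params$layers[[l]]$b
    H <- matrix(0, nb, h); C <- matrix(0, nb, h)
    out <- vector("list", Tn)
    cc <- if (cache) vector("list", Tn)
    for (t in seq_len(Tn)) {
      A <- cbind(inp[[t]], H) %*% W
      A <- sweep(A, 2L, b, "+")
      ig <- sigmoid(A[, 1:h, drop = FALSE])
      fg <- sigmoid(A[, (h + 1):(2 * h), drop = FALSE])
      gg <- tanh(A[, (2 * h + 1):(3 * h), drop = FALSE])
      og <- sigmoid(A[, (3 * h + 1):(4 * h), drop = FALSE])
      Cn <- fg * C + ig * gg
      tC <- tanh(Cn)
      Hn <- og * tC
      if (cache)
        cc[[t]] <- list(inp = inp[[t]], Hprev = H, Cprev = C,
                        i = ig, f = fg, g = gg, o = og, tC = tC)
      H <- Hn; C <- Cn
      out[[t]] <- Hn
    }
    if (cache) caches[[l]] <- cc
    inp <- out
  }
  H_last <- inp[[Tn]]
  logits <- sweep(H_last %*% params$Wd, 2L, params$bd, "+")
  list(logits = logits, H_last = H_last,
       caches = if (cache) caches, top_seq = if (cache) inp)
}

# backprop; dlogits is (batch, d_out). Returns gradient list shaped like params.
lstm_backward <- function(params, fwd, dlogits) {
  nb <- nrow(dlogits)
  Tn <- length(fwd$top_seq)
  grads <- list(layers = vector("list", length(params$units)))
  grads$Wd <- crossprod(fwd$H_last, dlogits)
  grads$bd <- colSums(dlogits)
  # gradient flowing into each timestep's hidden output, top layer first:
  # only the last timestep feeds the head
  dH_seq <- lapply(seq_len(Tn), function(t)
    if (t == Tn) dlogits %*% t(params$Wd) else NULL)
  for (l in rev(seq_along(params$units))) {
    h <- params$units[l]
    W <- params$layers[[l]]$W
    cc <- fwd$caches[[l]]
    d_in_l <- nrow(W) - h
    dW <- matrix(0, nrow(W), ncol(W)); db <- rep(0, ncol(W))
    dH_rec <- matrix(0, nb, h); dC_rec <- matrix(0, nb, h)
    dInp_seq <- vector("list", Tn)
    for (t in rev(seq_len(Tn))) {
      s <- cc[[t]]
      dH <- dH_rec + (dH_seq[[t]] %||% 0)
      dC <- dC_rec + dH * s$o * (1 - s$tC^2)
      do_ <- dH * s$tC * s$o * (1 - s$o)
      di <- dC * s$g * s$i * (1 - s$i)
      dg <- dC * s$i * (1 - s$g^2)
      df <- dC * s$Cprev * s$f * (1 - s$f)
      dA <- cbind(di, df, dg, do_)
      dW <- dW + crossprod(cbind(s$inp, s$Hprev), dA)
      db <- db + colSums(dA)
      dIH <- dA %*% t(W)
      dInp_seq[[t]] <- dIH[, seq_len(d_in_l), drop = FALSE]
      dH_rec <- dIH[, (d_in_l + 1):(d_in_l + h), drop = FALSE]
      dC_rec <- dC * s$f
    }
    grads$layers[[l]] <- list(W = dW, b = db)
    dH_seq <- dInp_seq
  }
  grads
}

# one Adam step; state holds first/second moments per parameter
adam_step <- function(params, grads, state, lr = 1e-3, b1 = 0.9, b2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  corr <- lr * sqrt(1 - b2^state$t) / (1 - b1^state$t)
  upd <- function(p, g, key) {
    m <- state$m[[key]] %||% (g * 0)
    v <- state$v[[key]] %||% (g * 0)
    m <- b1 * m + (1 - b1) * g
    v <- b2 * v + (1 - b2) * g^2
    state$m[[key]] <<- m
    state$v[[key]] <<- v
    p - corr * m / (sqrt(v) + eps)
  }
  for (l in seq_along(params$layers)) {
    params$layers[[l]]$W <- upd(params$layers[[l]]$W, grads$layers[[l]]$W,
                                paste0("W", l))
    params$layers[[l]]$b <- upd(params$layers[[l]]$b, grads$layers[[l]]$b,
                                paste0("b", l))
  }
  params$Wd <- upd(params$Wd, grads$Wd, "Wd")
  params$bd <- upd(params$bd, grads$bd, "bd")
  list(params = params, state = state)
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

#' Train an LSTM sequence model
#'
#' @param X numeric array (n, T, d_in) of input sequences
#' @param y targets: integer class labels in 1..d_out (`task =
#'   "classification"`) or a numeric vector (`task = "regression"`)
#' @param units LSTM layer widths
#' @param task "classification" or "regression"
#' @param epochs maximum training epochs
#' @param batch_size minibatch size
#' @param lr Adam learning rate
#' @param validation_fraction held-out fraction used for early stopping
#' @param patience epochs without validation improvement before stopping
#' @param seed RNG seed (weight init and shuffling)
#' @param verbose print per-epoch losses
#' @return an `lstm_model` list with `params`, `spec` and `history`
#' @export
lstm_train <- function(X, y, units = c(100L, 50L),
                       task = c("classification", "regression"),
                       epochs = 20L, batch_size = 128L, lr = 1e-3,
                       validation_fraction = 0.1, patience = 3L,
                       seed = NULL, verbose = FALSE) {
  task <- match.arg(task)
  if (!is.null(seed)) set.seed(seed)
  n <- dim(X)[1L]
  d_out <- if (task == "classification") max(y) else 1L
  idx <- sample.int(n)
  n_val <- max(1L, floor(validation_fraction * n))
  val_i <- idx[seq_len(n_val)]; tr_i <- idx[-seq_len(n_val)]
  params <- lstm_init(dim(X)[3L], as.integer(units), d_out)
  state <- list(t = 0L, m = list(), v = list())
  best <- list(loss = Inf, params = params, epoch = 0L)
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_loss = numeric())
  loss_of <- function(p, ii) {
    tot <- 0; nb_all <- 0
    for (bb in split(ii, ceiling(seq_along(ii) / 512L))) {
      fw <- lstm_forward(p, X[bb, , , drop = FALSE])
      if (task == "classification") {
        pr <- softmax_rows(fw$logits)
        tot <- tot - sum(log(pmax(pr[cbind(seq_along(bb), y[bb])], 1e-12)))
      } else {
        tot <- tot + sum((fw$logits[, 1L] - y[bb])^2)
      }
      nb_all <- nb_all + length(bb)
    }
    tot / nb_all
  }
  for (ep in seq_len(epochs)) {
    ord <- sample(tr_i)
    tr_loss <- 0; seen <- 0
    for (bb in split(ord, ceiling(seq_along(ord) / batch_size))) {
      nb <- length(bb)
      fw <- lstm_forward(params, X[bb, , , drop = FALSE], cache = TRUE)
      if (task == "classification") {
        pr <- softmax_rows(fw$logits)
        Y1 <- matrix(0, nb, d_out); Y1[cbind(seq_len(nb), y[bb])] <- 1
        dlogits <- (pr - Y1) / nb
        tr_loss <- tr_loss - sum(log(pmax(pr[cbind(seq_len(nb), y[bb])], 1e-12)))
      } else {
        resid <- fw$logits[, 1L] - y[bb]
        dlogits <- matrix(2 * resid / nb, nb, 1L)
        tr_loss <- tr_loss + sum(resid^2)
      }
      seen <- seen + nb
      gr <- lstm_backward(params, fw, dlogits)
      st <- adam_step(params, gr, state, lr = lr)
      params <- st$params; state <- st$state
    }
    val_loss <- loss_of(params, val_i)
    history <- rbind(history, data.frame(epoch = ep, train_loss = tr_loss / seen,
                                         val_loss = val_loss))
    if (verbose)
      message(sprintf("epoch %2d  train %.4f  val %.4f", ep, tr_loss / seen,
                      val_loss))
    if (val_loss < best$loss - 1e-5) {
      best <- list(loss = val_loss, params = params, epoch = ep)
    } else if (ep - best$epoch >= patience) {
      break
    }
  }
  structure(list(params = best$params, task = task,
                 spec = list(units = as.integer(units), d_in = dim(X)[3L],
                             d_out = d_out, input_steps = dim(X)[2L],
                             seed = seed),
                 history = history, val_loss = best$loss),
            class = "lstm_model")
}

#' Predict with a trained LSTM model
#'
#' @param model an `lstm_model` from [lstm_train]
#' @param X array (n, T, d_in); T must equal the training sequence length
#' @return class-probability matrix (classification) or numeric vector
#'   (regression)
#' @export
lstm_predict <- function(model, X) {
  stopifnot(inherits(model, "lstm_model"),
            dim(X)[2L] == model$spec$input_steps,
            dim(X)[3L] == model$spec$d_in)
  n <- dim(X)[1L]
  out <- NULL
  for (bb in split(seq_len(n), ceiling(seq_len(n) / 512L))) {
    fw <- lstm_forward(model$params, X[bb, , , drop = FALSE])
    piece <- if (model$task == "classification") softmax_rows(fw$logits)
             else fw$logits[, 1L]
    out <- if (is.null(out)) piece else
      if (is.matrix(piece)) rbind(out, piece) else c(out, piece)
  }
  out
}
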
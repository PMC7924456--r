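## Bidirectional LSTM middle-bin regressor, written directly on matrix
## algebra: one biLSTM layer (per-direction hidden size `units`), the two
## final hidden states concatenated into a single linear output, trained by
## minibatch Adam on the weighted-MSE loss with early stopping on the
## validation loss. Window sizes and unit counts stay small in this problem
## (t <= 10, F ~ 5-18), so explicit backpropagation through time in R is
## entirely adequate.

sigmoid <- function(x) 1 / (1 + exp(-x))

lstm_init <- function(t, F, H) {
  glorot <- function(nr, nc) {
    lim <- sqrt(6 / (nr + nc))
    matrix(runif(nr * nc, -lim, lim), nr, nc)
  }
  dir_init <- function() {
    b <- numeric(4 * H)
    b[(H + 1):(2 * H)] <- 1  # forget-gate bias at 1, standard practice
    list(W = glorot(F, 4 * H), U = glorot(H, 4 * H), b = b)
  }
  list(f = dir_init(), b = dir_init(),
       Wo = glorot(2 * H, 1), bo = 0)
}

## Forward pass of one direction over step order `ord`; returns the final
## hidden state and (optionally) the per-step cache for backprop.
lstm_forward_dir <- function(X, p, ord, H, keep_cache = FALSE) {
  B <- dim(X)[1]; F <- dim(X)[3]
  Hs <- matrix(0, B, H); Cs <- matrix(0, B, H)
  cache <- if (keep_cache) vector("list", length(ord)) else NULL
  gi <- 1:H; gf <- (H + 1):(2 * H); go <- (2 * H + 1):(3 * H)
  gg <- (3 * H + 1):(4 * H)
  for (si in seq_along(ord)) {
    s <- ord[si]
    Xs <- matrix(X[, s, ], B, F)
    Z <- Xs %*% p$W + Hs %*% p$U + matrix(p$b, B, 4 * H, byrow = TRUE)
    i <- sigmoid(Z[, gi, drop = FALSE])
    f <- sigmoid(Z[, gf, drop = FALSE])
    o <- sigmoid(Z[, go, drop = FALSE])
    g <- tanh(Z[, gg, drop = FALSE])
    Cnew <- f * Cs + i * g
    tc <- tanh(Cnew)
    Hnew <- o * tc
    if (keep_cache)
      cache[[si]] <- list(Xs = Xs, Hprev = Hs, Cprev = Cs,
                          i = i, f = f, o = o, g = g, tc = tc)
    Hs <- Hnew; Cs <- Cnew
  }
  list(H = Hs, cache = cache)
}

lstm_predict_params <- function(p, X, H) {
  t <- dim(X)[2]
  hf <- lstm_forward_dir(X, p$f, seq_len(t), H)$H
  hb <- lstm_forward_dir(X, p$b, rev(seq_len(t)), H)$H
  drop(cbind(hf, hb) %*% p$Wo) + p$bo
}

## Gradients of the per-direction parameters given the gradient at the
## final hidden state (backpropagation through time).
lstm_backward_dir <- function(p, cache, dH_final, H) {
  B <- nrow(dH_final)
  dW <- p$W * 0; dU <- p$U * 0; db <- p$b * 0
  dh <- dH_final; dc <- matrix(0, B, H)
  for (si in rev(seq_along(cache))) {
    cc <- cache[[si]]
    dc <- dc + dh * cc$o * (1 - cc$tc^2)
    do_ <- dh * cc$tc
    di <- dc * cc$g
    dg <- dc * cc$i
    df <- dc * cc$Cprev
    dZ <- cbind(di * cc$i * (1 - cc$i),
                df * cc$f * (1 - cc$f),
                do_ * cc$o * (1 - cc$o),
                dg * (1 - cc$g^2))
    dW <- dW + crossprod(cc$Xs, dZ)
    dU <- dU + crossprod(cc$Hprev, dZ)
    db <- db + colSums(dZ)
    dh <- dZ %*% t(p$U)
    dc <- dc * cc$f
  }
  list(W = dW, U = dU, b = db)
}

## One minibatch: forward, wMSE gradient, full backward. Returns gradients
## in the same shape as the parameter list.
lstm_batch_grads <- function(p, X, y, wts, H) {
  B <- dim(X)[1]; t <- dim(X)[2]
  fw <- lstm_forward_dir(X, p$f, seq_len(t), H, keep_cache = TRUE)
  bw <- lstm_forward_dir(X, p$b, rev(seq_len(t)), H, keep_cache = TRUE)
  Hcat <- cbind(fw$H, bw$H)
  yhat <- drop(Hcat %*% p$Wo) + p$bo
  dy <- matrix(2 * wts * (yhat - y) / B, B, 1)
  dWo <- crossprod(Hcat, dy)
  dbo <- sum(dy)
  dHcat <- dy %*% t(p$Wo)
  list(f = lstm_backward_dir(p$f, fw$cache, dHcat[, 1:H, drop = FALSE], H),
       b = lstm_backward_dir(p$b, bw$cache,
                             dHcat[, (H + 1):(2 * H), drop = FALSE], H),
       Wo = dWo, bo = dbo,
       loss = mean(wts * (yhat - y)^2))
}

## Flatten/unflatten parameters for a generic Adam update.
param_names <- list(c("f", "W"), c("f", "U"), c("f", "b"),
                    c("b", "W"), c("b", "U"), c("b", "b"),
                    list("Wo"), list("bo"))

param_get <- function(p, path) {
  path <- unlist(path)
  if (length(path) == 2) p[[path[1]]][[path[2]]] else p[[path[1]]]
}
param_set <- function(p, path, value) {
  path <- unlist(path)
  if (length(path) == 2) p[[path[1]]][[path[2]]] <- value
  else p[[path[1]]] <- value
  p
}

adam_step <- function(p, g, state, lr = 1e-3, b1 = 0.9, b2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1
  for (k in seq_along(param_names)) {
    gk <- param_get(g, param_names[[k]])
    state$m[[k]] <- b1 * state$m[[k]] + (1 - b1) * gk
    state$v[[k]] <- b2 * state$v[[k]] + (1 - b2) * gk^2
    mhat <- state$m[[k]] / (1 - b1^state$t)
    vhat <- state$v[[k]] / (1 - b2^state$t)
    p <- param_set(p, param_names[[k]],
                   param_get(p, param_names[[k]]) -
                     lr * mhat / (sqrt(vhat) + eps))
  }
  list(p = p, state = state)
}

#' Bidirectional-LSTM middle-bin regressor
#'
#' Reads a window of `t` consecutive bins (each a vector of chromatin-mark
#' signals) in both directions through an LSTM layer of `units` hidden units
#' per direction; the two final hidden states feed one linear output that
#' predicts the middle bin's transitional gamma. Trained by minibatch Adam
#' on the weighted-MSE loss; training stops when the validation wMSE fails
#' to improve for `patience` epochs and the best-epoch weights are restored.
#' The network sees only neighbouring features, never neighbouring targets.
#'
#' @param train,val `windowed_dataset`s sharing the model's window size.
#' @param units Hidden units per direction.
#' @param max_epochs Training-epoch cap (default 100).
#' @param patience Early-stopping patience in epochs (default 10).
#' @param batch_size Minibatch size (default 128).
#' @param learning_rate Adam step size (default 1e-3).
#' @param alpha wMSE weighting constant; computed from the training targets
#'   when omitted.
#' @param seed One integer seed driving initialization and shuffling.
#' @return A model of class `hichip_bilstm` with the per-epoch train/val
#'   wMSE history.
#' @export
fit_bilstm <- function(train, val, units = 64, max_epochs = 100,
                       patience = 10, batch_size = 128,
                       learning_rate = 1e-3, alpha = NULL, seed = 1L) {
  stopifnot(inherits(train, "windowed_dataset"),
            inherits(val, "windowed_dataset"))
  if (train$t != val$t) stop("shape error: train/val window sizes differ")
  X <- train$windows; y <- train$targets
  m <- dim(X)[1]; t <- dim(X)[2]; F <- dim(X)[3]; H <- as.integer(units)
  if (is.null(alpha)) alpha <- compute_alpha(y)$alpha
  wts <- (alpha - y) / alpha
  wv <- (alpha - val$targets) / alpha
  set.seed(seed)
  p <- lstm_init(t, F, H)
  state <- list(t = 0,
                m = lapply(param_names, function(path) param_get(p, path) * 0),
                v = NULL)
  state$v <- state$m
  best <- list(loss = Inf, p = p, epoch = 0L)
  history <- data.frame(epoch = integer(), train_wmse = numeric(),
                        val_wmse = numeric())
  wait <- 0L
  for (epoch in seq_len(max_epochs)) {
    ord <- sample.int(m)
    ep_loss <- 0; nb <- 0L
    for (start in seq(1L, m, by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1L, m)]
      gr <- lstm_batch_grads(p, X[idx, , , drop = FALSE], y[idx], wts[idx], H)
      upd <- adam_step(p, gr, state, lr = learning_rate)
      p <- upd$p; state <- upd$state
      ep_loss <- ep_loss + gr$loss; nb <- nb + 1L
    }
    val_pred <- lstm_predict_params(p, val$windows, H)
    val_loss <- mean(wv * (val$targets - val_pred)^2)
    history <- rbind(history,
                     data.frame(epoch = epoch, train_wmse = ep_loss / nb,
                                val_wmse = val_loss))
    if (val_loss < best$loss - 1e-9) {
      best <- list(loss = val_loss, p = p, epoch = epoch)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= patience) break
    }
  }
  structure(list(params = best$p, units = H, t = t, n_features = F,
                 mark_names = train$mark_names, alpha = alpha,
                 history = history, best_epoch = best$epoch,
                 best_val_wmse = best$loss, seed = seed,
                 family = "bilstm"),
            class = c("hichip_bilstm", "hichip_model"))
}

#' @rdname predict.hichip_model
#' @export
predict.hichip_bilstm <- function(object, newdata, ...) {
  stopifnot(inherits(newdata, "windowed_dataset"))
  if (newdata$t != object$t)
    stop("shape error: window size differs from the fitted model")
  if (dim(newdata$windows)[3] != object$n_features)
    stop("shape error: feature count differs from the fitted model")
  lstm_predict_params(object$params, newdata$windows, object$units)
}

#' @export
print.hichip_bilstm <- function(x, ...) {
  cat(sprintf(
    "hichipml biLSTM: window %d x %d marks, %d units/direction\n  best epoch %d (val wMSE %.4g, alpha %.3g)\n",
    x$t, x$n_features, x$units, x$best_epoch, x$best_val_wmse, x$alpha))
  invisible(x)
}
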
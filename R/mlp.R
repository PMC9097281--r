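# Single-hidden-layer perceptron classifier: ReLU hidden units, logistic
# output, minibatch Adam, L2 penalty, early stopping when the training
# loss improves by less than `tol` for `patience` consecutive epochs.
# Inputs are fed raw by default; optional training-set standardisation.

mlp_train <- function(X, y, hidden_units = 100, learning_rate = 1e-3,
                      max_epochs = 500, tol = 1e-4, patience = 10,
                      batch_size = 200, l2 = 1e-4, standardize = FALSE,
                      seed = 1) {
  stopifnot(is.matrix(X), length(y) == nrow(X), all(y %in% c(0, 1)))
  set.seed(seed)
  n <- nrow(X); p <- ncol(X); h <- hidden_units
  if (standardize) {
    ctr <- colMeans(X)
    scl <- apply(X, 2, stats::sd)
    scl[scl < 1e-12] <- 1
  } else {
    ctr <- numeric(p)
    scl <- rep(1, p)
  }
  Xs <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  glorot <- function(n_in, n_out) {
    lim <- sqrt(6 / (n_in + n_out))
    matrix(stats::runif(n_in * n_out, -lim, lim), n_in, n_out)
  }
  W1 <- glorot(p, h); b1 <- numeric(h)
  W2 <- glorot(h, 1); b2 <- 0
  adam <- list(mW1 = W1 * 0, vW1 = W1 * 0, mb1 = b1 * 0, vb1 = b1 * 0,
               mW2 = W2 * 0, vW2 = W2 * 0, mb2 = 0, vb2 = 0)
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  t_adam <- 0
  best_loss <- Inf; no_improve <- 0L
  n_batches <- ceiling(n / batch_size)
  loss_hist <- numeric(0)
  for (epoch in seq_len(max_epochs)) {
    perm <- sample.int(n)
    epoch_loss <- 0
    for (bi in seq_len(n_batches)) {
      idx <- perm[seq.int((bi - 1) * batch_size + 1, min(bi * batch_size, n))]
      xb <- Xs[idx, , drop = FALSE]; yb <- y[idx]; m <- length(idx)
      a1 <- xb %*% W1
      a1 <- sweep(a1, 2, b1, "+")
      z1 <- pmax(a1, 0)
      logits <- drop(z1 %*% W2) + b2
      pr <- 1 / (1 + exp(-logits))
      # batch log-loss + L2 (sklearn-style: alpha/(2m) * ||W||^2)
      ll <- -mean(yb * log(pmax(pr, 1e-12)) +
                    (1 - yb) * log(pmax(1 - pr, 1e-12))) +
        l2 / (2 * m) * (sum(W1^2) + sum(W2^2))
      epoch_loss <- epoch_loss + ll * m / n
      d_logit <- (pr - yb) / m
      gW2 <- crossprod(z1, d_logit) + l2 / m * W2
      gb2 <- sum(d_logit)
      dz1 <- (d_logit %*% t(W2)) * (a1 > 0)
      gW1 <- crossprod(xb, dz1) + l2 / m * W1
      gb1 <- colSums(dz1)
      t_adam <- t_adam + 1
      upd <- function(m_, v_, g) {
        m_ <- beta1 * m_ + (1 - beta1) * g
        v_ <- beta2 * v_ + (1 - beta2) * g^2
        mh <- m_ / (1 - beta1^t_adam)
        vh <- v_ / (1 - beta2^t_adam)
        list(m_, v_, learning_rate * mh / (sqrt(vh) + eps))
      }
      u <- upd(adam$mW1, adam$vW1, gW1)
      adam$mW1 <- u[[1]]; adam$vW1 <- u[[2]]; W1 <- W1 - u[[3]]
      u <- upd(adam$mb1, adam$vb1, gb1)
      adam$mb1 <- u[[1]]; adam$vb1 <- u[[2]]; b1 <- b1 - u[[3]]
      u <- upd(adam$mW2, adam$vW2, gW2)
      adam$mW2 <- u[[1]]; adam$vW2 <- u[[2]]; W2 <- W2 - u[[3]]
      u <- upd(adam$mb2, adam$vb2, gb2)
      adam$mb2 <- u[[1]]; adam$vb2 <- u[[2]]; b2 <- b2 - u[[3]]
    }
    loss_hist <- c(loss_hist, epoch_loss)
    if (epoch_loss < best_loss - tol) {
      best_loss <- epoch_loss
      no_improve <- 0L
    } else {
      no_improve <- no_improve + 1L
      if (no_improve >= patience) break
    }
  }
  structure(list(W1 = W1, b1 = b1, W2 = W2, b2 = b2,
                 center = ctr, scale = scl,
                 n_epochs = epoch, loss = loss_hist),
            class = "unbind_mlp")
}

mlp_predict_prob <- function(model, X) {
  Xs <- sweep(sweep(X, 2, model$center), 2, model$scale, "/")
  z1 <- pmax(sweep(Xs %*% model$W1, 2, model$b1, "+"), 0)
  drop(1 / (1 + exp(-(z1 %*% model$W2 + model$b2))))
}

mlp_predict <- function(model, X) as.integer(mlp_predict_prob(model, X) > 0.5)
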
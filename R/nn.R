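# Minimal dense-network trainers (Adam, seeded, pure R). These back the tile
# classifier and the tile autoencoder; both are bit-reproducible given
# (seed, data order) because all stochastic choices are drawn from one
# locally scoped RNG stream.

adam_step <- function(par, grad, state, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$m <- beta1 * state$m + (1 - beta1) * grad
  state$v <- beta2 * state$v + (1 - beta2) * grad^2
  mhat <- state$m / (1 - beta1^t)
  vhat <- state$v / (1 - beta2^t)
  list(par = par - lr * mhat / (sqrt(vhat) + eps), state = state)
}

adam_state <- function(par) list(m = par * 0, v = par * 0)

scale_rows <- function(X, center, scale) {
  sweep(sweep(X, 2, center), 2, scale, "/")
}

# One-hidden-layer softmax classifier with ReLU hidden units and inverted
# dropout on the dense head. Optional `aug_perms` applies feature-space
# dihedral augmentation (random column permutation per sample per step).
mlp_softmax_train <- function(X, y, K, hidden = 64L, epochs = 60L,
                              batch = 64L, lr = 5e-3, dropout = 0.5,
                              l2 = 1e-4, seed = 1L, aug_perms = NULL) {
  n <- nrow(X); p <- ncol(X)
  center <- colMeans(X)
  scl <- pmax(apply(X, 2, stats::sd), 1e-8)
  Y <- diag(K)[y, , drop = FALSE]
  withr::with_seed(seed, {
    W1 <- matrix(stats::rnorm(p * hidden, 0, sqrt(2 / p)), p, hidden)
    b1 <- numeric(hidden)
    W2 <- matrix(stats::rnorm(hidden * K, 0, sqrt(2 / hidden)), hidden, K)
    b2 <- numeric(K)
    st <- list(W1 = adam_state(W1), b1 = adam_state(b1),
               W2 = adam_state(W2), b2 = adam_state(b2))
    tstep <- 0L
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      for (start in seq(1L, n, by = batch)) {
        idx <- ord[start:min(start + batch - 1L, n)]
        Xb <- X[idx, , drop = FALSE]
        if (!is.null(aug_perms)) {
          pid <- sample.int(length(aug_perms), length(idx), replace = TRUE)
          for (u in which(pid > 1L)) Xb[u, ] <- Xb[u, aug_perms[[pid[u]]]]
        }
        Xs <- scale_rows(Xb, center, scl)
        nb <- nrow(Xs)
        A1 <- sweep(Xs %*% W1, 2, b1, "+")
        H <- pmax(A1, 0)
        if (dropout > 0) {
          M <- matrix((stats::runif(nb * hidden) >= dropout) / (1 - dropout),
                      nb, hidden)
          Hd <- H * M
        } else Hd <- H
        logits <- sweep(Hd %*% W2, 2, b2, "+")
        P <- exp(logits - apply(logits, 1, max))
        P <- P / rowSums(P)
        G <- (P - Y[idx, , drop = FALSE]) / nb
        gW2 <- crossprod(Hd, G) + l2 * W2
        gb2 <- colSums(G)
        GH <- tcrossprod(G, W2)
        if (dropout > 0) GH <- GH * M
        GH <- GH * (A1 > 0)
        gW1 <- crossprod(Xs, GH) + l2 * W1
        gb1 <- colSums(GH)
        tstep <- tstep + 1L
        r <- adam_step(W1, gW1, st$W1, lr, tstep); W1 <- r$par; st$W1 <- r$state
        r <- adam_step(b1, gb1, st$b1, lr, tstep); b1 <- r$par; st$b1 <- r$state
        r <- adam_step(W2, gW2, st$W2, lr, tstep); W2 <- r$par; st$W2 <- r$state
        r <- adam_step(b2, gb2, st$b2, lr, tstep); b2 <- r$par; st$b2 <- r$state
      }
    }
    list(W1 = W1, b1 = b1, W2 = W2, b2 = b2, center = center, scale = scl)
  })
}

mlp_softmax_predict <- function(fit, X) {
  Xs <- scale_rows(X, fit$center, fit$scale)
  H <- pmax(sweep(Xs %*% fit$W1, 2, fit$b1, "+"), 0)
  logits <- sweep(H %*% fit$W2, 2, fit$b2, "+")
  P <- exp(logits - apply(logits, 1, max))
  P / rowSums(P)
}

# Dense autoencoder core: tanh bottleneck of size E, linear decoder onto the
# (pooled) reconstruction target; mean-squared-error loss.
mlp_ae_train <- function(X, Yt, embed_dim, epochs = 80L, batch = 64L,
                         lr = 5e-3, seed = 1L) {
  n <- nrow(X); p <- ncol(X); q <- ncol(Yt)
  center <- colMeans(X)
  scl <- pmax(apply(X, 2, stats::sd), 1e-8)
  withr::with_seed(seed, {
    W1 <- matrix(stats::rnorm(p * embed_dim, 0, sqrt(1 / p)), p, embed_dim)
    b1 <- numeric(embed_dim)
    W2 <- matrix(stats::rnorm(embed_dim * q, 0, sqrt(1 / embed_dim)),
                 embed_dim, q)
    b2 <- numeric(q)
    st <- list(W1 = adam_state(W1), b1 = adam_state(b1),
               W2 = adam_state(W2), b2 = adam_state(b2))
    tstep <- 0L
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      for (start in seq(1L, n, by = batch)) {
        idx <- ord[start:min(start + batch - 1L, n)]
        Xs <- scale_rows(X[idx, , drop = FALSE], center, scl)
        Yb <- Yt[idx, , drop = FALSE]
        nb <- nrow(Xs)
        Z <- tanh(sweep(Xs %*% W1, 2, b1, "+"))
        Yhat <- sweep(Z %*% W2, 2, b2, "+")
        G <- 2 * (Yhat - Yb) / (nb * q)
        gW2 <- crossprod(Z, G)
        gb2 <- colSums(G)
        GZ <- tcrossprod(G, W2) * (1 - Z^2)
        gW1 <- crossprod(Xs, GZ)
        gb1 <- colSums(GZ)
        tstep <- tstep + 1L
        r <- adam_step(W1, gW1, st$W1, lr, tstep); W1 <- r$par; st$W1 <- r$state
        r <- adam_step(b1, gb1, st$b1, lr, tstep); b1 <- r$par; st$b1 <- r$state
        r <- adam_step(W2, gW2, st$W2, lr, tstep); W2 <- r$par; st$W2 <- r$state
        r <- adam_step(b2, gb2, st$b2, lr, tstep); b2 <- r$par; st$b2 <- r$state
      }
    }
    list(W1 = W1, b1 = b1, W2 = W2, b2 = b2, center = center, scale = scl)
  })
}

mlp_ae_embed <- function(fit, X) {
  Xs <- scale_rows(X, fit$center, fit$scale)
  tanh(sweep(Xs %*% fit$W1, 2, fit$b1, "+"))
}

mlp_ae_decode <- function(fit, Z) {
  sweep(Z %*% fit$W2, 2, fit$b2, "+")
}
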
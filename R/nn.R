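# Internal feed-forward network engine: dense layers, relu/gelu activations,
# Adam optimizer on mean-absolute-error loss, mini-batch SGD with early
# stopping. All state is plain R matrices so training is bit-reproducible
# given the RNG seed.

act_forward <- function(z, name) {
  switch(name,
    relu = pmax(z, 0),
    gelu = z * pnorm(z),
    abort(paste0("unknown activation: ", name))
  )
}

act_grad <- function(z, name) {
  switch(name,
    relu = (z > 0) * 1,
    gelu = pnorm(z) + z * dnorm(z),
    abort(paste0("unknown activation: ", name))
  )
}

nn_init <- function(d_in, widths) {
  dims <- c(d_in, widths, 1L)
  W <- vector("list", length(dims) - 1L)
  b <- vector("list", length(dims) - 1L)
  for (l in seq_along(W)) {
    fan_in <- dims[l]
    W[[l]] <- matrix(rnorm(fan_in * dims[l + 1L], sd = sqrt(2 / fan_in)),
                     fan_in, dims[l + 1L])
    b[[l]] <- numeric(dims[l + 1L])
  }
  list(W = W, b = b)
}

# forward pass; keeps pre-activations for backprop when `cache = TRUE`
nn_forward <- function(net, X, activations, cache = FALSE) {
  L <- length(net$W)
  A <- X
  Zs <- if (cache) vector("list", L) else NULL
  As <- if (cache) vector("list", L) else NULL
  for (l in seq_len(L)) {
    Z <- A %*% net$W[[l]] + rep(net$b[[l]], each = nrow(A))
    if (cache) { As[[l]] <- A; Zs[[l]] <- Z }
    A <- if (l < L) act_forward(Z, activations[l]) else Z
  }
  if (cache) list(out = A, Zs = Zs, As = As) else A
}

# gradient of mean(|pred - y|) wrt all weights
nn_backward <- function(net, fwd, y, activations) {
  L <- length(net$W)
  m <- length(y)
  delta <- matrix(sign(fwd$out - y) / m, ncol = 1)
  gW <- vector("list", L)
  gb <- vector("list", L)
  for (l in rev(seq_len(L))) {
    gW[[l]] <- crossprod(fwd$As[[l]], delta)
    gb[[l]] <- colSums(delta)
    if (l > 1L) {
      delta <- (delta %*% t(net$W[[l]])) * act_grad(fwd$Zs[[l - 1L]],
                                                   activations[l - 1L])
    }
  }
  list(W = gW, b = gb)
}

nn_train <- function(X_tr, y_tr, X_val, y_val, widths, activations,
                     learning_rate, epochs, batch_size, patience) {
  net <- nn_init(ncol(X_tr), widths)
  L <- length(net$W)
  adam <- list(
    mW = lapply(net$W, function(w) w * 0), vW = lapply(net$W, function(w) w * 0),
    mb = lapply(net$b, function(b) b * 0), vb = lapply(net$b, function(b) b * 0)
  )
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  t <- 0L
  n <- nrow(X_tr)
  best <- list(val = Inf, net = net, epoch = 0L)
  wait <- 0L
  hist_train <- numeric(0)
  hist_val <- numeric(0)

  for (epoch in seq_len(epochs)) {
    perm <- sample.int(n)
    starts <- seq(1L, n, by = batch_size)
    batch_losses <- numeric(length(starts))
    for (k in seq_along(starts)) {
      idx <- perm[starts[k]:min(starts[k] + batch_size - 1L, n)]
      Xb <- X_tr[idx, , drop = FALSE]
      yb <- y_tr[idx]
      fwd <- nn_forward(net, Xb, activations, cache = TRUE)
      batch_losses[k] <- mean(abs(fwd$out - yb))
      g <- nn_backward(net, fwd, yb, activations)
      t <- t + 1L
      c1 <- 1 - beta1^t; c2 <- 1 - beta2^t
      for (l in seq_len(L)) {
        adam$mW[[l]] <- beta1 * adam$mW[[l]] + (1 - beta1) * g$W[[l]]
        adam$vW[[l]] <- beta2 * adam$vW[[l]] + (1 - beta2) * g$W[[l]]^2
        net$W[[l]] <- net$W[[l]] - learning_rate * (adam$mW[[l]] / c1) /
          (sqrt(adam$vW[[l]] / c2) + eps)
        adam$mb[[l]] <- beta1 * adam$mb[[l]] + (1 - beta1) * g$b[[l]]
        adam$vb[[l]] <- beta2 * adam$vb[[l]] + (1 - beta2) * g$b[[l]]^2
        net$b[[l]] <- net$b[[l]] - learning_rate * (adam$mb[[l]] / c1) /
          (sqrt(adam$vb[[l]] / c2) + eps)
      }
    }
    val_loss <- mean(abs(nn_forward(net, X_val, activations) - y_val))
    hist_train[epoch] <- mean(batch_losses)
    hist_val[epoch] <- val_loss
    if (val_loss < best$val - 1e-12) {
      best <- list(val = val_loss, net = net, epoch = epoch)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= patience) break
    }
  }
  list(net = best$net, best_epoch = best$epoch,
       history = tibble::tibble(epoch = seq_along(hist_train),
                                train_loss = hist_train, val_loss = hist_val))
}
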
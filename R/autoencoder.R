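## Minimal seeded single-hidden-layer autoencoder (full-batch Adam).
## Kept in plain R: cohorts at monitoring scale are a few hundred rows by a
## few hundred columns, where matrix-multiply dominates anyway.

ae_train <- function(x, bottleneck, epochs = 200L, lr = 0.01,
                     activation = c("relu", "linear"), seed = 1L,
                     verbose = FALSE) {
  activation <- match.arg(activation)
  x <- as.matrix(x)
  d <- ncol(x); h <- as.integer(bottleneck)
  assert(h >= 1 && d >= 1, "bad dimensions")
  params <- with_seed(seed, {
    lim1 <- sqrt(6 / (d + h)); lim2 <- sqrt(6 / (h + d))
    list(W1 = matrix(stats::runif(d * h, -lim1, lim1), d, h),
         b1 = rep(0, h),
         W2 = matrix(stats::runif(h * d, -lim2, lim2), h, d),
         b2 = rep(0, d))
  })
  mstate <- lapply(params, function(p) p * 0)
  vstate <- lapply(params, function(p) p * 0)
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  n <- nrow(x)
  loss_hist <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    z1 <- sweep(x %*% params$W1, 2, params$b1, "+")
    a1 <- if (activation == "relu") pmax(z1, 0) else z1
    xhat <- sweep(a1 %*% params$W2, 2, params$b2, "+")
    err <- xhat - x
    loss_hist[ep] <- mean(err^2)
    g_out <- 2 * err / (n * d)
    grads <- list(
      W1 = NULL, b1 = NULL,
      W2 = t(a1) %*% g_out,
      b2 = colSums(g_out))
    g_hidden <- g_out %*% t(params$W2)
    if (activation == "relu") g_hidden <- g_hidden * (z1 > 0)
    grads$W1 <- t(x) %*% g_hidden
    grads$b1 <- colSums(g_hidden)
    for (nm in names(params)) {
      mstate[[nm]] <- beta1 * mstate[[nm]] + (1 - beta1) * grads[[nm]]
      vstate[[nm]] <- beta2 * vstate[[nm]] + (1 - beta2) * grads[[nm]]^2
      mhat <- mstate[[nm]] / (1 - beta1^ep)
      vhat <- vstate[[nm]] / (1 - beta2^ep)
      params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
    }
  }
  if (epochs >= 10 && loss_hist[epochs] > 1e-8 &&
      loss_hist[epochs] > loss_hist[ceiling(epochs / 2)] * 1.05) {
    warning("autoencoder loss not decreasing; result returned anyway")
  }
  list(params = params, activation = activation,
       meta = list(bottleneck = h, epochs = epochs, lr = lr, seed = seed,
                   final_loss = loss_hist[epochs]),
       loss = loss_hist)
}

ae_predict <- function(model, x) {
  p <- model$params
  z1 <- sweep(as.matrix(x) %*% p$W1, 2, p$b1, "+")
  a1 <- if (model$activation == "relu") pmax(z1, 0) else z1
  sweep(a1 %*% p$W2, 2, p$b2, "+")
}
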
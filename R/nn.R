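# Dense feed-forward regressor: hidden layers of configurable width, ReLU
# activations each followed by batch normalization, one linear output unit.
# Trained with Adam on MSE loss, mini-batches, and early stopping on a
# held-out validation split. Pure matrix code; networks here are small
# (tens of units), so BLAS-backed R is entirely adequate.

nn_init <- function(p, widths, y_mean = 0) {
  sizes <- c(p, widths)
  layers <- lapply(seq_along(widths), function(l) {
    fan_in <- sizes[l]
    out <- sizes[l + 1]
    list(
      W = matrix(rnorm(fan_in * out, 0, sqrt(2 / fan_in)), fan_in, out),
      b = numeric(out),
      gamma = rep(1, out), beta = numeric(out),
      run_mean = numeric(out), run_var = rep(1, out)
    )
  })
  list(layers = layers,
       # batch-norm keeps hidden activations at unit scale while IC
       # targets have sd well below 1, so the regression head starts
       # small and at the target mean; otherwise early training is spent
       # shrinking the output layer
       W_out = matrix(rnorm(utils::tail(sizes, 1), 0, 0.01), ncol = 1),
       b_out = y_mean)
}

nn_forward <- function(net, X, training = FALSE, momentum = 0.9,
                       eps = 1e-5) {
  cache <- list()
  A <- X
  for (l in seq_along(net$layers)) {
    ly <- net$layers[[l]]
    Z <- sweep(A %*% ly$W, 2, ly$b, "+")
    H <- pmax(Z, 0)
    if (training) {
      mu <- colMeans(H)
      v <- colMeans(sweep(H, 2, mu)^2)  # biased batch variance
      net$layers[[l]]$run_mean <- momentum * ly$run_mean + (1 - momentum) * mu
      net$layers[[l]]$run_var <- momentum * ly$run_var + (1 - momentum) * v
    } else {
      mu <- ly$run_mean
      v <- ly$run_var
    }
    Hc <- sweep(H, 2, mu)
    inv_sd <- 1 / sqrt(v + eps)
    Hhat <- sweep(Hc, 2, inv_sd, "*")
    A_next <- sweep(sweep(Hhat, 2, ly$gamma, "*"), 2, ly$beta, "+")
    cache[[l]] <- list(A_prev = A, Z = Z, H = H, Hc = Hc, Hhat = Hhat,
                       inv_sd = inv_sd)
    A <- A_next
  }
  yhat <- as.numeric(A %*% net$W_out + net$b_out)
  list(net = net, yhat = yhat, A_last = A, cache = cache)
}

nn_gradients <- function(net, fw, y) {
  m <- length(y)
  d_yhat <- matrix(2 * (fw$yhat - y) / m, ncol = 1)
  grads <- list(W_out = t(fw$A_last) %*% d_yhat,
                b_out = sum(d_yhat),
                layers = vector("list", length(net$layers)))
  dA <- d_yhat %*% t(net$W_out)
  for (l in rev(seq_along(net$layers))) {
    ly <- net$layers[[l]]
    cc <- fw$cache[[l]]
    dgamma <- colSums(dA * cc$Hhat)
    dbeta <- colSums(dA)
    dHhat <- sweep(dA, 2, ly$gamma, "*")
    # batch-norm backward (over the batch dimension)
    dvar <- colSums(dHhat * cc$Hc) * (-0.5) * cc$inv_sd^3
    dmu <- colSums(sweep(dHhat, 2, -cc$inv_sd, "*")) +
      dvar * colMeans(-2 * cc$Hc)
    dH <- sweep(dHhat, 2, cc$inv_sd, "*") +
      sweep(cc$Hc, 2, 2 * dvar / m, "*") +
      matrix(dmu / m, nrow(dA), ncol(dA), byrow = TRUE)
    dZ <- dH * (cc$Z > 0)
    grads$layers[[l]] <- list(W = t(cc$A_prev) %*% dZ, b = colSums(dZ),
                              gamma = dgamma, beta = dbeta)
    dA <- dZ %*% t(ly$W)
  }
  grads
}

# Adam state mirrors the parameter tree; one step over all parameters.
nn_adam_step <- function(net, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                         eps = 1e-8) {
  state$t <- state$t + 1
  upd <- function(param, g, key) {
    if (is.null(state$m[[key]])) {
      state$m[[key]] <<- param * 0
      state$v[[key]] <<- param * 0
    }
    state$m[[key]] <<- beta1 * state$m[[key]] + (1 - beta1) * g
    state$v[[key]] <<- beta2 * state$v[[key]] + (1 - beta2) * g^2
    mh <- state$m[[key]] / (1 - beta1^state$t)
    vh <- state$v[[key]] / (1 - beta2^state$t)
    param - lr * mh / (sqrt(vh) + eps)
  }
  net$W_out <- upd(net$W_out, grads$W_out, "W_out")
  net$b_out <- upd(net$b_out, grads$b_out, "b_out")
  for (l in seq_along(net$layers)) {
    for (nm in c("W", "b", "gamma", "beta")) {
      key <- paste0("L", l, ".", nm)
      net$layers[[l]][[nm]] <- upd(net$layers[[l]][[nm]],
                                   grads$layers[[l]][[nm]], key)
    }
  }
  list(net = net, state = state)
}

nn_train <- function(X, y, widths, lr = 1e-3, batch_size = 64,
                     epochs = 200, patience = 20, val_fraction = 0.1,
                     verbose = FALSE) {
  n <- nrow(X)
  p <- ncol(X)
  n_val <- max(1L, floor(val_fraction * n))
  perm <- sample(n)
  val_idx <- perm[seq_len(n_val)]
  tr_idx <- perm[-seq_len(n_val)]
  if (length(tr_idx) < 2L) {  # degenerate tiny datasets: train on all
    tr_idx <- seq_len(n)
    val_idx <- seq_len(n)
  }
  Xtr <- X[tr_idx, , drop = FALSE]; ytr <- y[tr_idx]
  Xv <- X[val_idx, , drop = FALSE]; yv <- y[val_idx]

  net <- nn_init(p, widths, y_mean = mean(ytr))
  state <- list(t = 0, m = list(), v = list())
  best <- list(net = net, val = Inf, since = 0L)
  ntr <- length(ytr)
  for (epoch in seq_len(epochs)) {
    ord <- sample(ntr)
    for (start in seq(1, ntr, by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1, ntr)]
      if (length(idx) < 2L) next  # BN needs a batch
      fw <- nn_forward(net, Xtr[idx, , drop = FALSE], training = TRUE)
      net <- fw$net  # running BN stats updated
      grads <- nn_gradients(net, fw, ytr[idx])
      stepped <- nn_adam_step(net, grads, state, lr)
      net <- stepped$net
      state <- stepped$state
    }
    val_mse <- mean((nn_forward(net, Xv)$yhat - yv)^2)
    if (val_mse < best$val - 1e-9) {
      best <- list(net = net, val = val_mse, since = 0L)
    } else {
      best$since <- best$since + 1L
      if (best$since >= patience) break
    }
    if (verbose) message(sprintf("epoch %d val MSE %.5f", epoch, val_mse))
  }
  best$net
}

nn_predict <- function(net, X) nn_forward(net, X)$yhat
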
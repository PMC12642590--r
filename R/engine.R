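# Minimal feed-forward engine: dense, 1-D convolution over residue positions
# and spectral graph-convolution layers, leaky ReLU, inverted dropout, Adam,
# MSE loss, early stopping.
#
# Two tensor layouts are used. "flat": a batch is n x p with each variant's
# N_res x D matrix flattened position-major. "seq": (n * Len) x C with row
# r = s + n*(p-1), i.e. samples fastest within a position block — position
# blocks are contiguous row ranges, which lets a stride-1 valid convolution
# run as k plain block matmuls (one per kernel offset) with no gather.
# `to_seq` and `flatten` layers convert between the two.

he_init <- function(nin, nout) {
  matrix(stats::rnorm(nin * nout, 0, sqrt(2 / nin)), nin, nout)
}

layer_dense <- function(nin, nout) {
  list(kind = "dense", W = he_init(nin, nout), b = numeric(nout),
       nin = nin, nout = nout)
}

layer_lrelu <- function(slope = 0.01) list(kind = "lrelu", slope = slope)

layer_dropout <- function(rate = 0.2) {
  stopifnot(rate >= 0, rate < 1)
  list(kind = "dropout", rate = rate)
}

# Feature-group (block) dropout on the flat input: each sample independently
# drops whole feature blocks (all positions at once) with probability `rate`,
# scaling survivors by 1/(1-rate) — feature bagging over encoding blocks.
layer_group_dropout <- function(groups, rate) {
  stopifnot(rate >= 0, rate < 1)
  list(kind = "group_dropout", groups = groups, rate = rate)
}

layer_to_seq <- function(Len, C) list(kind = "to_seq", Len = Len, C = C)

layer_flatten <- function(Len, C) list(kind = "flatten", Len = Len, C = C)

# Valid-padding, stride-1 convolution across positions (seq layout in and
# out). W holds one Cin x nf block per kernel offset, stacked row-wise.
layer_conv <- function(Lin, Cin, k, nf) {
  stopifnot(k >= 1, Lin >= k)
  list(kind = "conv", W = he_init(k * Cin, nf), b = numeric(nf),
       Lin = Lin, Cin = Cin, k = k, nf = nf, Tout = Lin - k + 1L)
}

# Graph convolution H' = Ahat %*% H %*% W + b (seq layout).
layer_gcn <- function(L, Cin, nf, Ahat) {
  stopifnot(nrow(Ahat) == L, ncol(Ahat) == L)
  list(kind = "gcn", W = he_init(Cin, nf), b = numeric(nf),
       L = L, Cin = Cin, nf = nf, Ahat = Ahat)
}

# --- forward -----------------------------------------------------------------

layer_forward <- function(layer, X, n, training) {
  switch(layer$kind,
    dense = list(out = sweep(X %*% layer$W, 2L, layer$b, "+"), cache = X),
    lrelu = {
      scale <- (X > 0) * (1 - layer$slope) + layer$slope
      list(out = X * scale, cache = scale)
    },
    dropout = {
      if (!training || layer$rate == 0)
        return(list(out = X, cache = NULL))
      mask <- matrix((stats::runif(length(X)) >= layer$rate) / (1 - layer$rate),
                     nrow(X), ncol(X))
      list(out = X * mask, cache = mask)
    },
    group_dropout = {
      if (!training || layer$rate == 0)
        return(list(out = X, cache = NULL))
      mask <- matrix(1, nrow(X), ncol(X))
      for (g in layer$groups) {
        keep <- (stats::runif(nrow(X)) >= layer$rate) / (1 - layer$rate)
        mask[, g] <- keep        # recycles down columns: one draw per sample
      }
      list(out = X * mask, cache = mask)
    },
    to_seq = {
      arr <- array(X, c(n, layer$C, layer$Len))
      list(out = matrix(aperm(arr, c(1, 3, 2)), n * layer$Len, layer$C),
           cache = NULL)
    },
    flatten = {
      arr <- array(X, c(n, layer$Len, layer$C))
      list(out = matrix(aperm(arr, c(1, 3, 2)), n, layer$Len * layer$C),
           cache = NULL)
    },
    conv = {
      nT <- n * layer$Tout
      # im2col over contiguous row blocks: one wide matmul per batch
      M <- do.call(cbind, lapply(seq_len(layer$k), function(o)
        X[(n * (o - 1L) + 1L):(n * (o - 1L) + nT), , drop = FALSE]))
      Z <- M %*% layer$W
      Z <- Z + rep(layer$b, each = nT)
      list(out = Z, cache = M)
    },
    gcn = {
      Z <- sweep(X %*% layer$W, 2L, layer$b, "+")
      Zarr <- array(Z, c(n, layer$L, layer$nf))
      for (f in seq_len(layer$nf))
        Zarr[, , f] <- array(Zarr[, , f], c(n, layer$L)) %*% layer$Ahat
      list(out = matrix(Zarr, n * layer$L, layer$nf), cache = X)
    },
    stop("unknown layer kind: ", layer$kind))
}

net_forward <- function(layers, X, training = FALSE) {
  n <- nrow(X)
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    fw <- layer_forward(layers[[i]], X, n, training)
    X <- fw$out
    caches[[i]] <- fw$cache
  }
  list(out = X, caches = caches, n = n)
}

# --- backward ----------------------------------------------------------------

layer_backward <- function(layer, cache, dout, n) {
  switch(layer$kind,
    dense = list(dX = dout %*% t(layer$W),
                 dW = crossprod(cache, dout), db = colSums(dout)),
    lrelu = list(dX = dout * cache),
    dropout = list(dX = if (is.null(cache)) dout else dout * cache),
    group_dropout = list(dX = if (is.null(cache)) dout else dout * cache),
    to_seq = {
      arr <- array(dout, c(n, layer$Len, layer$C))
      list(dX = matrix(aperm(arr, c(1, 3, 2)), n, layer$Len * layer$C))
    },
    flatten = {
      arr <- array(dout, c(n, layer$C, layer$Len))
      list(dX = matrix(aperm(arr, c(1, 3, 2)), n * layer$Len, layer$C))
    },
    conv = {
      nT <- (n * layer$Tout)
      dW <- crossprod(cache, dout)
      dM <- dout %*% t(layer$W)
      dX <- matrix(0, n * layer$Lin, layer$Cin)
      for (o in seq_len(layer$k)) {
        rows <- (n * (o - 1L) + 1L):(n * (o - 1L) + nT)
        cols <- ((o - 1L) * layer$Cin + 1L):(o * layer$Cin)
        dX[rows, ] <- dX[rows, , drop = FALSE] + dM[, cols, drop = FALSE]
      }
      list(dX = dX, dW = dW, db = colSums(dout))
    },
    gcn = {
      dZarr <- array(dout, c(n, layer$L, layer$nf))
      for (f in seq_len(layer$nf))
        dZarr[, , f] <- array(dZarr[, , f], c(n, layer$L)) %*% layer$Ahat
      dZ <- matrix(dZarr, n * layer$L, layer$nf)
      list(dX = dZ %*% t(layer$W), dW = crossprod(cache, dZ),
           db = colSums(dZ))
    })
}

net_backward <- function(layers, caches, dout, n) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    bw <- layer_backward(layers[[i]], caches[[i]], dout, n)
    grads[[i]] <- bw[c("dW", "db")]
    dout <- bw$dX
  }
  grads
}

# --- optimizer ---------------------------------------------------------------

adam_init <- function(layers) {
  lapply(layers, function(l) {
    if (is.null(l$W)) return(NULL)
    list(mW = l$W * 0, vW = l$W * 0, mb = l$b * 0, vb = l$b * 0)
  })
}

# AdamW-style update: decoupled weight decay, applied per layer with the
# rate in `wd` (a vector parallel to `layers`; biases are never decayed).
adam_step <- function(layers, grads, state, lr, t, wd,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (i in seq_along(layers)) {
    if (is.null(layers[[i]]$W) || is.null(grads[[i]]$dW)) next
    s <- state[[i]]
    s$mW <- beta1 * s$mW + (1 - beta1) * grads[[i]]$dW
    s$vW <- beta2 * s$vW + (1 - beta2) * grads[[i]]$dW^2
    s$mb <- beta1 * s$mb + (1 - beta1) * grads[[i]]$db
    s$vb <- beta2 * s$vb + (1 - beta2) * grads[[i]]$db^2
    corr <- lr * sqrt(1 - beta2^t) / (1 - beta1^t)
    layers[[i]]$W <- layers[[i]]$W * (1 - lr * wd[i]) -
      corr * s$mW / (sqrt(s$vW) + eps)
    layers[[i]]$b <- layers[[i]]$b - corr * s$mb / (sqrt(s$vb) + eps)
    state[[i]] <- s
  }
  list(layers = layers, state = state)
}

# --- training loop -----------------------------------------------------------

net_predict <- function(layers, X, chunk = 1024L) {
  n <- nrow(X)
  out <- numeric(n)
  for (start in seq(1L, n, by = chunk)) {
    rows <- start:min(start + chunk - 1L, n)
    out[rows] <- drop(net_forward(layers, X[rows, , drop = FALSE],
                                  training = FALSE)$out)
  }
  out
}

# Seeded mini-batch Adam training with early stopping on validation MSE.
# Assumes the caller has already fixed the RNG stream (epoch shuffles and
# dropout masks draw from it).
net_train <- function(layers, X, y, X_val, y_val,
                      lr = 1e-3, batch_size = 64L, epochs = 100L,
                      patience = 10L, weight_decay = 0, lr_decay = 1,
                      select = c("loss", "spearman"), min_epochs = 0L,
                      snapshots = 1L, restart_every = 0L) {
  select <- match.arg(select)
  n <- nrow(X)
  snaps <- list()   # up to `snapshots` weight copies, best validation epochs
  # decay only the dense head(s): the shared convolution / graph-convolution
  # filters carry the position-transferable signal and stay unpenalized
  wd <- ifelse(vapply(layers, function(l) identical(l$kind, "dense"), TRUE),
               weight_decay, 0)
  state <- adam_init(layers)
  step <- 0L
  best <- list(layers = layers, val = Inf, epoch = 0L)
  wait <- 0L
  history <- vector("list", epochs)
  for (epoch in seq_len(epochs)) {
    lr_e <- lr * lr_decay^(epoch - 1)
    perm <- sample.int(n)
    total <- 0
    for (start in seq(1L, n, by = batch_size)) {
      rows <- perm[start:min(start + batch_size - 1L, n)]
      Xb <- X[rows, , drop = FALSE]
      yb <- y[rows]
      fw <- net_forward(layers, Xb, training = TRUE)
      pred <- drop(fw$out)
      err <- pred - yb
      loss <- mean(err^2)
      if (!is.finite(loss))
        stop("non-finite training loss at epoch ", epoch,
             " (learning rate too high or degenerate inputs)")
      total <- total + loss * length(rows)
      dout <- matrix(2 * err / length(rows), ncol = 1L)
      grads <- net_backward(layers, fw$caches, dout, length(rows))
      step <- step + 1L
      upd <- adam_step(layers, grads, state, lr_e, step, wd)
      layers <- upd$layers
      state <- upd$state
    }
    pred_val <- net_predict(layers, X_val)
    val_loss <- mean((pred_val - y_val)^2)
    # selection criterion: MSE, or (negated) rank correlation, which is
    # calibration-insensitive and far more stable under extrapolation splits
    val_crit <- if (select == "loss") val_loss
                else if (stats::sd(pred_val) == 0) Inf
                else -stats::cor(y_val, pred_val, method = "spearman")
    history[[epoch]] <- c(epoch = epoch, train_loss = total / n,
                          val_loss = val_loss, val_crit = val_crit)
    # epochs before `min_epochs` are burn-in: never selected, never kept as
    # snapshots, and the early-stopping clock does not run
    if (epoch >= min_epochs || epoch == epochs) {
      if (length(snaps) < snapshots) {
        snaps[[length(snaps) + 1L]] <- list(crit = val_crit, epoch = epoch,
                                            layers = layers)
      } else {
        crits <- vapply(snaps, `[[`, 0, "crit")
        worst <- which.max(crits)
        if (val_crit < crits[worst])
          snaps[[worst]] <- list(crit = val_crit, epoch = epoch,
                                 layers = layers)
      }
      if (val_crit < best$val - 1e-12) {
        best <- list(layers = layers, val = val_crit, epoch = epoch)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait > patience) break
      }
    }
    # warm restart: periodically reload the best weights seen and reset the
    # optimizer moments, which re-anchors the search at the most
    # generalizable iterate instead of drifting further into memorization
    if (restart_every > 0L && epoch %% restart_every == 0L &&
        is.finite(best$val)) {
      layers <- best$layers
      state <- adam_init(layers)
    }
  }
  history <- as.data.frame(do.call(rbind, history[!vapply(history, is.null,
                                                          TRUE)]))
  list(layers = best$layers, history = history, best_epoch = best$epoch,
       best_val = best$val,
       snapshot_layers = if (snapshots > 1L) lapply(snaps, `[[`, "layers"))
}

# Exact (ridgeless) least squares for the linear family. Primal normal
# equations when n >= p; dual (kernel) form when n < p, which returns the
# minimum-norm interpolant in the ridge -> 0 limit. `ridge` adds lambda*I.
lstsq_fit <- function(X, y, ridge = 0) {
  n <- nrow(X)
  X1 <- cbind(1, X)
  p <- ncol(X1)
  if (n >= p) {
    G <- crossprod(X1) + diag(ridge, p)
    coef <- tryCatch(solve(G, crossprod(X1, y)),
                     error = function(e) solve(G + diag(1e-10, p),
                                               crossprod(X1, y)))
  } else {
    K <- tcrossprod(X1) + diag(ridge + 1e-10, n)
    alpha <- solve(K, y)
    coef <- crossprod(X1, alpha)
  }
  drop(coef)
}

lstsq_predict <- function(coef, X) {
  drop(cbind(1, X) %*% coef)
}
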
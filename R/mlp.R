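## Small dense feedforward network for binary classification:
## tanh hidden layers, sigmoid output, cross-entropy loss, full-batch Adam,
## inverted dropout on the hidden activations during training.

mlp_init <- function(sizes) {
  L <- length(sizes) - 1L
  W <- vector("list", L)
  b <- vector("list", L)
  for (l in seq_len(L)) {
    fan_in <- sizes[l]; fan_out <- sizes[l + 1L]
    lim <- sqrt(6 / (fan_in + fan_out))
    W[[l]] <- matrix(runif(fan_in * fan_out, -lim, lim), fan_in, fan_out)
    b[[l]] <- rep(0, fan_out)
  }
  list(W = W, b = b)
}

mlp_forward <- function(net, X, dropout = 0, training = FALSE) {
  L <- length(net$W)
  A <- vector("list", L + 1L)      # layer inputs (post-dropout)
  H <- vector("list", L)           # pre-dropout tanh activations
  masks <- vector("list", L)
  A[[1]] <- X
  for (l in seq_len(L)) {
    Z <- A[[l]] %*% net$W[[l]] + matrix(net$b[[l]], nrow(X), length(net$b[[l]]), byrow = TRUE)
    if (l < L) {
      H[[l]] <- tanh(Z)
      out <- H[[l]]
      if (training && dropout > 0) {
        m <- matrix(runif(length(out)) >= dropout, nrow(out), ncol(out)) / (1 - dropout)
        out <- out * m
        masks[[l]] <- m
      }
      A[[l + 1L]] <- out
    } else {
      A[[l + 1L]] <- plogis(Z)
    }
  }
  list(A = A, H = H, masks = masks)
}

#' Train a feedforward neural-network mutation predictor
#'
#' A small dense network: tanh hidden layers (default two layers of 57 and 37
#' units), a sigmoid output unit, binary cross-entropy loss, full-batch Adam
#' with initial learning rate 0.01, and dropout (default rate 0.4) on the
#' hidden activations. Training is fully seeded: the same seed gives
#' bit-identical initial weights and a reproducible final loss.
#'
#' @param X binary feature matrix (rows = conditions).
#' @param y 0/1 labels; both classes must be present.
#' @param hidden integer vector of hidden-layer sizes.
#' @param dropout dropout rate in `[0, 1)`.
#' @param lr Adam learning rate.
#' @param epochs full-batch epochs.
#' @param seed RNG seed.
#' @return object of class `ann_model`.
#' @export
train_ann <- function(X, y, hidden = c(57, 37), dropout = 0.4, lr = 0.01,
                      epochs = 300, seed = 1) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (length(unique(y)) < 2L)
    stopf("constant labels: cannot train a classifier on a single class")
  sizes <- c(ncol(X), hidden, 1L)
  local_seed(seed, {
    net <- mlp_init(sizes)
    L <- length(net$W)
    mW <- lapply(net$W, function(w) w * 0); vW <- mW
    mb <- lapply(net$b, function(b) b * 0); vb <- mb
    b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
    n <- nrow(X)
    loss <- NA_real_
    for (t in seq_len(epochs)) {
      fwd <- mlp_forward(net, X, dropout = dropout, training = TRUE)
      p <- fwd$A[[L + 1L]]
      p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
      loss <- -mean(y * log(p) + (1 - y) * log(1 - p))
      if (!is.finite(loss))
        stopf("ANN training diverged (loss=NaN) at epoch %d [seed=%d, hidden=%s, lr=%g]",
              t, seed, paste(hidden, collapse = "-"), lr)
      delta <- (p - y) / n            # dL/dZ at the sigmoid output
      for (l in rev(seq_len(L))) {
        gW <- crossprod(fwd$A[[l]], delta)
        gb <- colSums(delta)
        if (l > 1L) {
          dA <- delta %*% t(net$W[[l]])
          if (dropout > 0 && !is.null(fwd$masks[[l - 1L]])) dA <- dA * fwd$masks[[l - 1L]]
          delta <- dA * (1 - fwd$H[[l - 1L]]^2)  # tanh'(z) via pre-dropout tanh(z)
        }
        mW[[l]] <- b1 * mW[[l]] + (1 - b1) * gW
        vW[[l]] <- b2 * vW[[l]] + (1 - b2) * gW^2
        mb[[l]] <- b1 * mb[[l]] + (1 - b1) * gb
        vb[[l]] <- b2 * vb[[l]] + (1 - b2) * gb^2
        mW_hat <- mW[[l]] / (1 - b1^t); vW_hat <- vW[[l]] / (1 - b2^t)
        mb_hat <- mb[[l]] / (1 - b1^t); vb_hat <- vb[[l]] / (1 - b2^t)
        net$W[[l]] <- net$W[[l]] - lr * mW_hat / (sqrt(vW_hat) + eps)
        net$b[[l]] <- net$b[[l]] - lr * mb_hat / (sqrt(vb_hat) + eps)
      }
    }
    structure(list(net = net, sizes = sizes, hidden = hidden, dropout = dropout,
                   lr = lr, epochs = epochs, seed = seed, final_loss = loss,
                   feature_names = colnames(X)),
              class = "ann_model")
  })
}

#' @export
print.ann_model <- function(x, ...) {
  cat(sprintf("ann_model: %s architecture, dropout %.2f, %d epochs, final loss %.4f\n",
              paste(x$sizes, collapse = "-"), x$dropout, x$epochs, x$final_loss))
  invisible(x)
}

#' Random search over network architectures
#'
#' Samples `budget` architectures (1 or 2 hidden layers, 8-80 units each) and
#' returns the one with the best stratified 3-fold cross-validated AUC.
#'
#' @inheritParams train_ann
#' @param budget number of random architectures to evaluate.
#' @param epochs training epochs per candidate.
#' @return list with `hidden` (best architecture) and `cv_auc`.
#' @export
tune_ann <- function(X, y, budget = 10, epochs = 150, seed = 1) {
  local_seed(seed, {
    cands <- lapply(seq_len(budget), function(i) {
      n_layers <- sample(1:2, 1)
      sample(8:80, n_layers, replace = TRUE)
    })
    aucs <- vapply(seq_along(cands), function(i) {
      cv_auc_trainer(X, y,
                     trainer = function(Xt, yt)
                       train_ann(Xt, yt, hidden = cands[[i]], epochs = epochs,
                                 seed = seed + i),
                     k = 3, seed = seed + 1000L + i)
    }, numeric(1))
    best <- which.max(aucs)
    list(hidden = cands[[best]], cv_auc = aucs[best])
  })
}
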
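# Small 1-D convolutional network over an ordered feature vector:
# conv (ReLU) -> max-pool -> dense (ReLU) -> softmax over the four damage
# levels, trained with mini-batch Adam on cross-entropy. Written in plain
# matrix code: the network is tiny (tens of features, hundreds of trees)
# and full reproducibility per seed matters more than throughput.

.adam_new <- function(shape) list(m = array(0, shape), v = array(0, shape))

.adam_step <- function(state, grad, lr, t, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  state$m <- beta1 * state$m + (1 - beta1) * grad
  state$v <- beta2 * state$v + (1 - beta2) * grad^2
  mhat <- state$m / (1 - beta1^t)
  vhat <- state$v / (1 - beta2^t)
  state$delta <- -lr * mhat / (sqrt(vhat) + eps)
  state
}

# forward pass; returns activations needed for backprop.
# X: n x m. Wc: K x F conv kernels; W1: (Lp*F) x D; W2: D x C.
.cnn_forward <- function(X, par, cfg) {
  n <- nrow(X)
  K <- cfg$kernel; L <- cfg$L; Fn <- cfg$filters; Lp <- cfg$Lp
  conv <- array(0, c(n, L, Fn))
  for (t in seq_len(L))
    conv[, t, ] <- X[, t:(t + K - 1), drop = FALSE] %*% par$Wc +
      rep(par$bc, each = n)
  relu1 <- pmax(conv, 0)
  if (cfg$pool > 1 && L >= cfg$pool) {
    pooled <- array(0, c(n, Lp, Fn))
    argmax <- array(0L, c(n, Lp, Fn))
    for (t in seq_len(Lp)) {
      span <- ((t - 1) * cfg$pool + 1):min(t * cfg$pool, L)
      seg <- relu1[, span, , drop = FALSE]
      for (f in seq_len(Fn)) {
        sf <- seg[, , f, drop = FALSE]
        dim(sf) <- c(n, length(span))
        w <- max.col(sf, ties.method = "first")
        pooled[, t, f] <- sf[cbind(seq_len(n), w)]
        argmax[, t, f] <- span[w]
      }
    }
  } else {
    pooled <- relu1
    argmax <- NULL
  }
  flat <- matrix(pooled, n, Lp * Fn)
  z1 <- flat %*% par$W1 + rep(par$b1, each = n)
  h1 <- pmax(z1, 0)
  z2 <- h1 %*% par$W2 + rep(par$b2, each = n)
  z2 <- z2 - apply(z2, 1, max)
  ez <- exp(z2)
  probs <- ez / rowSums(ez)
  list(conv = conv, relu1 = relu1, argmax = argmax, flat = flat,
       z1 = z1, h1 = h1, probs = probs)
}

# backward pass; returns parameter gradients and the input gradient.
.cnn_backward <- function(X, Y, fwd, par, cfg) {
  n <- nrow(X)
  K <- cfg$kernel; L <- cfg$L; Fn <- cfg$filters; Lp <- cfg$Lp
  dz2 <- (fwd$probs - Y) / n
  gW2 <- t(fwd$h1) %*% dz2
  gb2 <- colSums(dz2)
  dh1 <- dz2 %*% t(par$W2)
  dz1 <- dh1 * (fwd$z1 > 0)
  gW1 <- t(fwd$flat) %*% dz1
  gb1 <- colSums(dz1)
  dflat <- dz1 %*% t(par$W1)
  dpool <- array(dflat, c(n, Lp, Fn))
  dconv <- array(0, c(n, L, Fn))
  if (!is.null(fwd$argmax)) {
    for (t in seq_len(Lp))
      for (f in seq_len(Fn))
        dconv[cbind(seq_len(n), fwd$argmax[, t, f], f)] <-
          dconv[cbind(seq_len(n), fwd$argmax[, t, f], f)] + dpool[, t, f]
  } else {
    dconv <- dpool
  }
  dconv <- dconv * (fwd$conv > 0)
  gWc <- matrix(0, K, Fn)
  gbc <- numeric(Fn)
  dX <- matrix(0, n, ncol(X))
  for (t in seq_len(L)) {
    dt <- dconv[, t, , drop = TRUE]
    if (is.null(dim(dt))) dt <- matrix(dt, n, Fn)
    gWc <- gWc + t(X[, t:(t + K - 1), drop = FALSE]) %*% dt
    gbc <- gbc + colSums(dt)
    dX[, t:(t + K - 1)] <- dX[, t:(t + K - 1)] + dt %*% t(par$Wc)
  }
  list(Wc = gWc, bc = gbc, W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2,
       dX = dX)
}

#' Fit the 1-D convolutional damage classifier
#'
#' @param X Numeric n x m feature matrix (normalised to \[0, 1\]); the
#'   column order is the convolution order.
#' @param y Integer class labels.
#' @param filters Number of convolution kernels.
#' @param kernel Kernel width (clipped to the number of features).
#' @param pool Max-pool width.
#' @param dense Width of the dense hidden layer.
#' @param epochs Training epochs.
#' @param lr Adam learning rate.
#' @param batch Mini-batch size.
#' @param seed Seed for weight initialisation and batch shuffling; fixed
#'   seed gives identical weights and predictions.
#' @return Object of class `cnn_model` with fitted parameters, the class
#'   label set, feature names and mean-absolute-input-gradient
#'   importances (normalised to sum 1).
#' @export
cnn_fit <- function(X, y, filters = 16, kernel = 3, pool = 2, dense = 32,
                    epochs = 200, lr = 1e-3, batch = 32, seed = 1L) {
  X <- as.matrix(X)
  m <- ncol(X)
  if (m < 2) stop("need at least 2 features")
  stopifnot(filters >= 1, kernel >= 1, pool >= 1, dense >= 1,
            epochs >= 1, lr > 0, batch >= 1)
  kernel <- min(kernel, m)
  classes <- sort(unique(y))
  if (length(classes) < 2) stop("training data has a single class")
  Y <- outer(y, classes, "==") * 1
  n <- nrow(X)
  L <- m - kernel + 1
  Lp <- if (pool > 1 && L >= pool) L %/% pool + (L %% pool > 0) else L
  cfg <- list(kernel = kernel, filters = filters, pool = pool,
              L = L, Lp = Lp, dense = dense)

  set.seed(seed)
  par <- list(
    Wc = matrix(stats::rnorm(kernel * filters, 0,
                             sqrt(2 / kernel)), kernel, filters),
    bc = numeric(filters),
    W1 = matrix(stats::rnorm(Lp * filters * dense, 0,
                             sqrt(2 / (Lp * filters))),
                Lp * filters, dense),
    b1 = numeric(dense),
    W2 = matrix(stats::rnorm(dense * length(classes), 0,
                             sqrt(2 / dense)), dense, length(classes)),
    b2 = numeric(length(classes)))
  opt <- lapply(par, function(p) .adam_new(dim(as.array(p))))
  step <- 0
  losses <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0
    for (b0 in seq(1, n, by = batch)) {
      idx <- ord[b0:min(b0 + batch - 1, n)]
      fwd <- .cnn_forward(X[idx, , drop = FALSE], par, cfg)
      grads <- .cnn_backward(X[idx, , drop = FALSE],
                             Y[idx, , drop = FALSE], fwd, par, cfg)
      step <- step + 1
      for (nm in names(par)) {
        opt[[nm]] <- .adam_step(opt[[nm]], as.array(grads[[nm]]), lr, step)
        par[[nm]] <- par[[nm]] + array(opt[[nm]]$delta,
                                       dim(as.array(par[[nm]])))
      }
      ep_loss <- ep_loss - sum(log(pmax(
        fwd$probs[Y[idx, , drop = FALSE] == 1], 1e-12))) / length(idx)
    }
    losses[ep] <- ep_loss / ceiling(n / batch)
    if (!is.finite(losses[ep]))
      stop("training diverged (non-finite loss) at epoch ", ep)
  }

  # importances: mean |dLoss/dX| per input feature over the training set
  fwd <- .cnn_forward(X, par, cfg)
  grads <- .cnn_backward(X, Y, fwd, par, cfg)
  imp <- colMeans(abs(grads$dX))
  imp <- if (sum(imp) > 0) imp / sum(imp) else rep(1 / m, m)
  names(imp) <- colnames(X)

  structure(list(par = par, cfg = cfg, classes = classes,
                 features = colnames(X), importances = imp,
                 losses = losses, seed = seed),
            class = "cnn_model")
}

#' Predict with a fitted CNN
#'
#' @param object A [cnn_fit()] model.
#' @param newdata Feature matrix with the model's feature columns.
#' @param type `"class"` for labels, `"prob"` for the softmax matrix.
#' @param ... Unused.
#' @return Class labels or probability matrix.
#' @export
predict.cnn_model <- function(object, newdata, type = c("class", "prob"),
                              ...) {
  type <- match.arg(type)
  X <- as.matrix(newdata)[, object$features, drop = FALSE]
  probs <- .cnn_forward(X, object$par, object$cfg)$probs
  colnames(probs) <- as.character(object$classes)
  if (type == "prob") probs
  else object$classes[max.col(probs, ties.method = "first")]
}
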
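# Feed-forward classifiers: a single-hidden-layer MLP and a compact 1-D
# convolutional network, both with ReLU activations, a 3-way softmax head,
# Adam optimization and categorical cross-entropy. Implemented directly with
# matrix operations: the per-segment feature vectors are tiny (one value per
# electrode), so dense BLAS arithmetic is entirely adequate.
#
# MLP:    input -> dense(hidden, ReLU) -> softmax(3)
# 1D-CNN: input as a length-d single-channel sequence
#         -> conv1d(filters, kernel, same padding, stride 1, ReLU)
#         -> flatten -> dense(hidden, ReLU) -> dense(hidden, ReLU)
#         -> softmax(3)

#' Network architecture and training specification
#'
#' @param architecture `"mlp"` or `"cnn1d"`.
#' @param hidden Width of the dense hidden layer(s) (default 128).
#' @param conv_filters Number of 1-D convolution filters (default 256,
#'   cnn1d only).
#' @param kernel_size Convolution kernel length (default 3, same padding,
#'   stride 1, no pooling -- the input sequence is only one value per
#'   electrode).
#' @param learning_rate Adam learning rate (default 0.001).
#' @param epochs Maximum training epochs (default 100).
#' @param batch_size Mini-batch size (default 64).
#' @param patience Early-stopping patience on validation loss (default 10;
#'   `Inf` disables early stopping).
#' @param validation_split Fraction of rows held out (stratified) to monitor
#'   validation loss (default 0.1).
#' @param input_width Expected feature count; checked against the training
#'   data when given.
#' @param seed Integer seed covering initialization, batching and the
#'   validation split.
#' @return A `net_spec` object.
#' @export
net_spec <- function(architecture = c("mlp", "cnn1d"), hidden = 128,
                     conv_filters = 256, kernel_size = 3,
                     learning_rate = 0.001, epochs = 100, batch_size = 64,
                     patience = 10, validation_split = 0.1,
                     input_width = NULL, seed = 1L) {
  architecture <- match.arg(architecture)
  if (learning_rate <= 0) abort("`learning_rate` must be positive.")
  if (epochs < 1 || batch_size < 1) abort("`epochs`/`batch_size` must be >= 1.")
  structure(
    list(architecture = architecture, hidden = as.integer(hidden),
         conv_filters = as.integer(conv_filters),
         kernel_size = as.integer(kernel_size),
         learning_rate = learning_rate, epochs = as.integer(epochs),
         batch_size = as.integer(batch_size), patience = patience,
         validation_split = validation_split,
         input_width = input_width, seed = as.integer(seed)),
    class = "net_spec"
  )
}

#' @export
print.net_spec <- function(x, ...) {
  cat(sprintf("<net_spec> %s | hidden=%d%s | Adam(%g), %d epochs, batch %d\n",
              x$architecture, x$hidden,
              if (x$architecture == "cnn1d")
                sprintf(", conv=%dx%d", x$conv_filters, x$kernel_size) else "",
              x$learning_rate, x$epochs, x$batch_size))
  invisible(x)
}

he_init <- function(nr, nc) {
  matrix(rnorm(nr * nc, sd = sqrt(2 / nr)), nr, nc)
}

softmax_rows <- function(L) {
  L <- L - apply(L, 1, max)
  E <- exp(L)
  E / rowSums(E)
}

xent <- function(P, Y) {
  -mean(log(pmax(rowSums(P * Y), 1e-12)))
}

relu <- function(Z) Z * (Z > 0)

init_params <- function(spec, d) {
  if (spec$architecture == "mlp") {
    list(W1 = he_init(d, spec$hidden), b1 = numeric(spec$hidden),
         W2 = he_init(spec$hidden, 3), b2 = numeric(3))
  } else {
    list(Wc = he_init(spec$kernel_size, spec$conv_filters),
         bc = numeric(spec$conv_filters),
         W3 = he_init(d * spec$conv_filters, spec$hidden),
         b3 = numeric(spec$hidden),
         W4 = he_init(spec$hidden, spec$hidden), b4 = numeric(spec$hidden),
         W5 = he_init(spec$hidden, 3), b5 = numeric(3))
  }
}

# "same"-padded conv1d over a batch: X is n x L, returns n x (L * F)
conv1d_forward <- function(X, Wc, bc) {
  n <- nrow(X); L <- ncol(X); K <- nrow(Wc); F <- ncol(Wc)
  pad <- (K - 1) %/% 2
  Xp <- cbind(matrix(0, n, pad), X, matrix(0, n, K - 1 - pad))
  Z <- matrix(0, n, L * F)
  for (t in seq_len(L)) {
    Z[, ((t - 1) * F + 1):(t * F)] <-
      Xp[, t:(t + K - 1), drop = FALSE] %*% Wc +
      matrix(bc, n, F, byrow = TRUE)
  }
  Z
}

conv1d_backward <- function(X, GZ, K, F) {
  n <- nrow(X); L <- ncol(X)
  pad <- (K - 1) %/% 2
  Xp <- cbind(matrix(0, n, pad), X, matrix(0, n, K - 1 - pad))
  gWc <- matrix(0, K, F)
  gbc <- numeric(F)
  for (t in seq_len(L)) {
    Gt <- GZ[, ((t - 1) * F + 1):(t * F), drop = FALSE]
    gWc <- gWc + crossprod(Xp[, t:(t + K - 1), drop = FALSE], Gt)
    gbc <- gbc + colSums(Gt)
  }
  list(gWc = gWc, gbc = gbc)
}

net_forward <- function(par, X, spec) {
  if (spec$architecture == "mlp") {
    Z1 <- X %*% par$W1 + matrix(par$b1, nrow(X), length(par$b1), byrow = TRUE)
    A1 <- relu(Z1)
    logits <- A1 %*% par$W2 + matrix(par$b2, nrow(X), 3, byrow = TRUE)
    list(P = softmax_rows(logits), cache = list(Z1 = Z1, A1 = A1))
  } else {
    Zc <- conv1d_forward(X, par$Wc, par$bc)
    Ac <- relu(Zc)
    Z3 <- Ac %*% par$W3 + matrix(par$b3, nrow(X), spec$hidden, byrow = TRUE)
    A3 <- relu(Z3)
    Z4 <- A3 %*% par$W4 + matrix(par$b4, nrow(X), spec$hidden, byrow = TRUE)
    A4 <- relu(Z4)
    logits <- A4 %*% par$W5 + matrix(par$b5, nrow(X), 3, byrow = TRUE)
    list(P = softmax_rows(logits),
         cache = list(Zc = Zc, Ac = Ac, Z3 = Z3, A3 = A3, Z4 = Z4, A4 = A4))
  }
}

net_gradients <- function(par, X, Y, fwd, spec) {
  n <- nrow(X)
  G <- (fwd$P - Y) / n
  cc <- fwd$cache
  if (spec$architecture == "mlp") {
    gW2 <- crossprod(cc$A1, G); gb2 <- colSums(G)
    GZ1 <- (G %*% t(par$W2)) * (cc$Z1 > 0)
    list(W1 = crossprod(X, GZ1), b1 = colSums(GZ1), W2 = gW2, b2 = gb2)
  } else {
    gW5 <- crossprod(cc$A4, G); gb5 <- colSums(G)
    GZ4 <- (G %*% t(par$W5)) * (cc$Z4 > 0)
    gW4 <- crossprod(cc$A3, GZ4); gb4 <- colSums(GZ4)
    GZ3 <- (GZ4 %*% t(par$W4)) * (cc$Z3 > 0)
    gW3 <- crossprod(cc$Ac, GZ3); gb3 <- colSums(GZ3)
    GZc <- (GZ3 %*% t(par$W3)) * (cc$Zc > 0)
    cv <- conv1d_backward(X, GZc, spec$kernel_size, spec$conv_filters)
    list(Wc = cv$gWc, bc = cv$gbc, W3 = gW3, b3 = gb3,
         W4 = gW4, b4 = gb4, W5 = gW5, b5 = gb5)
  }
}

#' Train an MLP or 1D-CNN emotion classifier
#'
#' Trains the architecture described by a [net_spec()] with Adam and
#' categorical cross-entropy; a stratified validation split monitors the
#' loss for early stopping (best weights are restored). Fully deterministic
#' for a fixed spec seed.
#'
#' @param ds An `emotion_dataset` (or list with `X`, `y`).
#' @param spec A [net_spec()].
#' @return An `eeg_net` with the fitted parameters and a per-epoch loss
#'   history; use [predict_emotion()] for inference and `tidy()` for the
#'   loss curve.
#' @export
train_net <- function(ds, spec = net_spec()) {
  stopifnot(inherits(spec, "net_spec"))
  X <- as.matrix(ds$X)
  y <- factor(as.character(ds$y), levels = EMOTION_LABELS)
  if (!is.null(spec$input_width) && ncol(X) != spec$input_width) {
    abort(sprintf("Input width %d does not match spec input_width %d.",
                  ncol(X), spec$input_width))
  }
  if (anyNA(X)) abort("Feature matrix contains NA; drop undefined rows first.")
  Y <- matrix(0, nrow(X), 3, dimnames = list(NULL, EMOTION_LABELS))
  Y[cbind(seq_len(nrow(X)), as.integer(y))] <- 1

  with_local_seed(spec$seed, {
    # stratified validation split
    val_idx <- integer(0)
    if (spec$validation_split > 0 && is.finite(spec$patience)) {
      val_idx <- unlist(lapply(split(seq_len(nrow(X)), y), function(ix) {
        n_val <- max(1L, floor(length(ix) * spec$validation_split))
        sample(ix, n_val)
      }))
    }
    tr_idx <- setdiff(seq_len(nrow(X)), val_idx)
    Xtr <- X[tr_idx, , drop = FALSE]; Ytr <- Y[tr_idx, , drop = FALSE]
    Xva <- X[val_idx, , drop = FALSE]; Yva <- Y[val_idx, , drop = FALSE]

    par <- init_params(spec, ncol(X))
    mo <- lapply(par, function(p) p * 0)
    vo <- lapply(par, function(p) p * 0)
    step <- 0
    b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
    history <- vector("list", spec$epochs)
    best <- list(loss = Inf, par = par, epoch = 0)
    wait <- 0

    for (epoch in seq_len(spec$epochs)) {
      ord <- sample(nrow(Xtr))
      batch_losses <- c()
      for (start in seq(1, length(ord), by = spec$batch_size)) {
        ix <- ord[start:min(start + spec$batch_size - 1, length(ord))]
        fwd <- net_forward(par, Xtr[ix, , drop = FALSE], spec)
        batch_losses <- c(batch_losses, xent(fwd$P, Ytr[ix, , drop = FALSE]))
        gr <- net_gradients(par, Xtr[ix, , drop = FALSE],
                            Ytr[ix, , drop = FALSE], fwd, spec)
        step <- step + 1
        for (nm in names(par)) {
          mo[[nm]] <- b1 * mo[[nm]] + (1 - b1) * gr[[nm]]
          vo[[nm]] <- b2 * vo[[nm]] + (1 - b2) * gr[[nm]]^2
          mhat <- mo[[nm]] / (1 - b1^step)
          vhat <- vo[[nm]] / (1 - b2^step)
          par[[nm]] <- par[[nm]] - spec$learning_rate * mhat / (sqrt(vhat) + eps)
        }
      }
      val_loss <- NA_real_
      if (length(val_idx)) {
        val_loss <- xent(net_forward(par, Xva, spec)$P, Yva)
        if (val_loss < best$loss - 1e-6) {
          best <- list(loss = val_loss, par = par, epoch = epoch)
          wait <- 0
        } else {
          wait <- wait + 1
        }
      }
      history[[epoch]] <- tibble::tibble(
        epoch = epoch, train_loss = mean(batch_losses), val_loss = val_loss)
      if (length(val_idx) && wait >= spec$patience) break
    }
    if (length(val_idx) && is.finite(best$loss)) par <- best$par
    structure(
      list(par = par, spec = spec, input_width = ncol(X),
           history = dplyr::bind_rows(history),
           best_epoch = if (length(val_idx)) best$epoch else NA_integer_),
      class = "eeg_net")
  })
}

#' @export
print.eeg_net <- function(x, ...) {
  cat(sprintf("<eeg_net> %s, %d inputs | trained %d epochs%s\n",
              x$spec$architecture, x$input_width, nrow(x$history),
              if (!is.na(x$best_epoch))
                sprintf(" (best at %d)", x$best_epoch) else ""))
  invisible(x)
}

#' @export
predict_emotion.eeg_net <- function(model, X) {
  X <- as.matrix(X)
  if (ncol(X) != model$input_width) {
    abort(sprintf("Feature width %d does not match the %d training features.",
                  ncol(X), model$input_width))
  }
  P <- net_forward(model$par, X, model$spec)$P
  colnames(P) <- EMOTION_LABELS
  cls <- factor(EMOTION_LABELS[max.col(P, ties.method = "first")],
                levels = EMOTION_LABELS)
  list(class = cls, scores = P)
}

#' @exportS3Method generics::tidy
tidy.eeg_net <- function(x, ...) {
  x$history
}
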
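# Compact depthwise-separable convolutional network for 4-class SSMVEP
# recognition, implemented directly in R (im2col convolutions, analytic
# backpropagation, Adam). Architecture: a temporal convolution whose kernel
# length is half the sampling rate (1200 Hz -> 600 samples), a depthwise
# spatial convolution spanning all channels, and a separable
# (depthwise-temporal + pointwise) stage, each followed by ELU, average
# pooling and dropout, then a dense softmax readout.

#' Compact CNN specification
#'
#' The temporal kernel length follows the architecture rule
#' `L = floor(sampling_rate / 2)`; the depthwise spatial kernel spans all
#' channels. Remaining hyperparameters follow published compact-EEG-network
#' practice: 8 temporal filters, depth multiplier 2, 16 separable filters,
#' average pooling, dropout 0.25, Adam with cross-entropy loss and early
#' stopping.
#'
#' @param sampling_rate_hz Sampling rate of the input segments.
#' @param n_channels Number of EEG channels (default 6).
#' @param n_classes Number of stimulation frequencies (default 4).
#' @param n_temporal_filters,depth_multiplier,n_separable_filters Filter
#'   counts of the three stages.
#' @param separable_kernel Depthwise-temporal kernel length of the
#'   separable stage.
#' @param pool1,pool2 Average-pooling factors after stages 2 and 3.
#' @param dropout Dropout probability.
#' @param learning_rate,batch_size,n_epochs,patience,min_delta Training
#'   hyperparameters (Adam step size, minibatch size, epoch cap, early
#'   stopping patience on the training loss).
#' @param temporal_kernel Override for the temporal kernel length; default
#'   `floor(sampling_rate_hz / 2)`.
#' @return Object of class `compact_cnn_spec`.
#' @export
compact_cnn_spec <- function(sampling_rate_hz,
                             n_channels = 6,
                             n_classes = 4,
                             n_temporal_filters = 8,
                             depth_multiplier = 2,
                             n_separable_filters = 16,
                             separable_kernel = 16,
                             pool1 = 4,
                             pool2 = 8,
                             dropout = 0.25,
                             learning_rate = 1e-3,
                             batch_size = 32,
                             n_epochs = 200,
                             patience = 10,
                             min_delta = 1e-4,
                             temporal_kernel = NULL) {
  if (is.null(temporal_kernel)) temporal_kernel <- floor(sampling_rate_hz / 2)
  structure(list(
    sampling_rate_hz = sampling_rate_hz,
    n_channels = as.integer(n_channels),
    n_classes = as.integer(n_classes),
    temporal_kernel = as.integer(temporal_kernel),
    n_temporal_filters = as.integer(n_temporal_filters),
    depth_multiplier = as.integer(depth_multiplier),
    n_separable_filters = as.integer(n_separable_filters),
    separable_kernel = as.integer(separable_kernel),
    pool1 = as.integer(pool1),
    pool2 = as.integer(pool2),
    dropout = dropout,
    learning_rate = learning_rate,
    batch_size = as.integer(batch_size),
    n_epochs = as.integer(n_epochs),
    patience = as.integer(patience),
    min_delta = min_delta
  ), class = "compact_cnn_spec")
}

#' @export
print.compact_cnn_spec <- function(x, ...) {
  cat(sprintf(
    "compact_cnn_spec: L=%d (fs %g Hz), %d ch -> %d classes, F1=%d D=%d F2=%d\n",
    x$temporal_kernel, x$sampling_rate_hz, x$n_channels, x$n_classes,
    x$n_temporal_filters, x$depth_multiplier, x$n_separable_filters))
  invisible(x)
}

.elu <- function(z) ifelse(z > 0, z, exp(pmin(z, 0)) - 1)
.elu_grad <- function(z, fz) ifelse(z > 0, 1, fz + 1)

.avg_pool <- function(m, p) {
  # m: T x M; average non-overlapping blocks of p rows
  t1 <- nrow(m) %/% p
  dim_m <- dim(m)
  a <- array(m[seq_len(t1 * p), , drop = FALSE], c(p, t1, ncol(m)))
  out <- apply(a, c(2L, 3L), mean)
  matrix(out, t1, ncol(m))
}

.unpool <- function(d, p, t_full) {
  # inverse of .avg_pool for gradients
  up <- matrix(0, t_full, ncol(d))
  idx <- rep(seq_len(nrow(d)), each = p)
  up[seq_along(idx), ] <- d[idx, , drop = FALSE] / p
  up
}

.cnn_init <- function(spec, seed) {
  L <- spec$temporal_kernel; F1 <- spec$n_temporal_filters
  C <- spec$n_channels; D <- spec$depth_multiplier
  F2 <- spec$n_separable_filters; k3 <- spec$separable_kernel
  .with_seed(seed, {
    he <- function(nr, nc, fan) matrix(stats::rnorm(nr * nc, 0, sqrt(2 / fan)),
                                       nr, nc)
    list(W1 = he(L, F1, L),
         W2 = he(C, F1 * D, C),
         b2 = numeric(F1 * D),
         W3 = he(k3, F1 * D, k3),
         W4 = he(F1 * D, F2, F1 * D),
         b4 = numeric(F2),
         W5 = NULL,   # sized lazily from the flattened feature length
         b5 = numeric(spec$n_classes))
  })
}

# Forward pass for one sample. x: C x T. Returns the class probabilities
# and, when cache = TRUE, the intermediates needed for backprop.
.cnn_forward <- function(params, x, spec, masks = NULL, cache = FALSE) {
  C <- spec$n_channels; L <- spec$temporal_kernel
  F1 <- spec$n_temporal_filters; D <- spec$depth_multiplier
  F2 <- spec$n_separable_filters; k3 <- spec$separable_kernel
  T_ <- ncol(x)
  padL <- (L - 1L) %/% 2L
  idx1 <- outer(seq_len(T_), seq_len(L) - 1L, `+`)

  # stage 1: temporal convolution per channel (same padding)
  Z1 <- array(0, c(T_, F1, C))
  Xcol <- vector("list", C)
  for (c_i in seq_len(C)) {
    xp <- c(numeric(padL), x[c_i, ], numeric(L - 1L - padL))
    xc <- matrix(xp[idx1], T_, L)
    Z1[, , c_i] <- xc %*% params$W1
    if (cache) Xcol[[c_i]] <- xc
  }

  # stage 2: depthwise spatial convolution across channels
  A2 <- matrix(0, T_, F1 * D)
  for (f1 in seq_len(F1)) {
    blk <- ((f1 - 1L) * D + 1L):(f1 * D)
    A2[, blk] <- Z1[, f1, ] %*% params$W2[, blk, drop = FALSE]
  }
  A2 <- sweep(A2, 2L, params$b2, `+`)
  E2 <- .elu(A2)
  P1 <- .avg_pool(E2, spec$pool1)
  if (!is.null(masks)) P1 <- P1 * masks$m1
  T1 <- nrow(P1)

  # stage 3: separable convolution (depthwise temporal + pointwise)
  pad3 <- (k3 - 1L) %/% 2L
  idx3 <- outer(seq_len(T1), seq_len(k3) - 1L, `+`)
  S <- matrix(0, T1, F1 * D)
  Pcol <- vector("list", F1 * D)
  for (m in seq_len(F1 * D)) {
    pp <- c(numeric(pad3), P1[, m], numeric(k3 - 1L - pad3))
    pc <- matrix(pp[idx3], T1, k3)
    S[, m] <- pc %*% params$W3[, m, drop = FALSE]
    if (cache) Pcol[[m]] <- pc
  }
  A3 <- sweep(S %*% params$W4, 2L, params$b4, `+`)
  E3 <- .elu(A3)
  P2 <- .avg_pool(E3, spec$pool2)
  if (!is.null(masks)) P2 <- P2 * masks$m2
  flat <- as.vector(P2)

  logits <- drop(crossprod(params$W5, flat)) + params$b5
  p <- exp(logits - max(logits))
  p <- p / sum(p)

  if (!cache) return(list(prob = p))
  list(prob = p, Xcol = Xcol, Z1 = Z1, A2 = A2, E2 = E2, P1 = P1,
       Pcol = Pcol, S = S, A3 = A3, E3 = E3, P2 = P2, flat = flat,
       T_ = T_, T1 = T1)
}

# Backward pass for one sample; returns gradients with the params' shapes.
.cnn_backward <- function(params, fw, y_onehot, spec, masks) {
  C <- spec$n_channels; F1 <- spec$n_temporal_filters
  D <- spec$depth_multiplier; k3 <- spec$separable_kernel
  M <- F1 * D
  dlogits <- fw$prob - y_onehot

  g <- list()
  g$W5 <- fw$flat %o% dlogits
  g$b5 <- dlogits
  dP2 <- matrix(params$W5 %*% dlogits, nrow(fw$P2), ncol(fw$P2))
  if (!is.null(masks)) dP2 <- dP2 * masks$m2
  dE3 <- .unpool(dP2, spec$pool2, nrow(fw$E3))
  dA3 <- dE3 * .elu_grad(fw$A3, fw$E3)
  g$W4 <- crossprod(fw$S, dA3)
  g$b4 <- colSums(dA3)
  dS <- dA3 %*% t(params$W4)

  g$W3 <- matrix(0, k3, M)
  T1 <- fw$T1
  pad3 <- (k3 - 1L) %/% 2L
  dPpad <- matrix(0, T1 + k3 - 1L, M)
  for (m in seq_len(M)) {
    g$W3[, m] <- crossprod(fw$Pcol[[m]], dS[, m])
  }
  for (l in seq_len(k3)) {
    dPpad[l:(l + T1 - 1L), ] <- dPpad[l:(l + T1 - 1L), ] +
      dS * matrix(params$W3[l, ], T1, M, byrow = TRUE)
  }
  dP1 <- dPpad[(pad3 + 1L):(pad3 + T1), , drop = FALSE]
  if (!is.null(masks)) dP1 <- dP1 * masks$m1

  dE2 <- .unpool(dP1, spec$pool1, nrow(fw$E2))
  dA2 <- dE2 * .elu_grad(fw$A2, fw$E2)
  g$b2 <- colSums(dA2)
  g$W2 <- matrix(0, C, M)
  dZ1 <- array(0, dim(fw$Z1))
  for (f1 in seq_len(F1)) {
    blk <- ((f1 - 1L) * D + 1L):(f1 * D)
    g$W2[, blk] <- crossprod(fw$Z1[, f1, ], dA2[, blk, drop = FALSE])
    dZ1[, f1, ] <- dA2[, blk, drop = FALSE] %*%
      t(params$W2[, blk, drop = FALSE])
  }
  g$W1 <- matrix(0, nrow(params$W1), F1)
  for (c_i in seq_len(C)) {
    g$W1 <- g$W1 + crossprod(fw$Xcol[[c_i]], dZ1[, , c_i])
  }
  g
}

#' Train the compact CNN
#'
#' Minibatch Adam on softmax cross-entropy with inverted dropout and early
#' stopping on the training loss. Fully deterministic given `seed` and the
#' data order: initialisation, shuffling and dropout masks all draw from
#' one seeded stream.
#'
#' @param tensor A [trial_tensor()] with a `frequency_hz` label column, or
#'   a `n x channels x samples` array (then supply `labels`).
#' @param spec A [compact_cnn_spec()]; defaults to one built from the
#'   tensor's sampling rate.
#' @param seed Integer training seed.
#' @param labels Class labels (stimulation frequencies), one per trial.
#' @param verbose Print the loss once per 10 epochs.
#' @return Object of class `compact_cnn` with the trained parameters,
#'   `classes`, `loss_history` and the input scale.
#' @export
train_compact_cnn <- function(tensor, spec = NULL, seed = 1, labels = NULL,
                              verbose = FALSE) {
  if (inherits(tensor, "trial_tensor")) {
    x <- tensor$data
    labels <- labels %||% tensor$info$frequency_hz
    fs <- tensor$sampling_rate_hz
  } else {
    x <- tensor
    fs <- spec$sampling_rate_hz
  }
  if (is.null(labels)) .err("labels are required", "ssmvep_domain_error")
  classes <- sort(unique(labels))
  if (length(classes) < 2L ||
      (!is.null(spec) && length(classes) != spec$n_classes)) {
    .err("training data must contain every class", "ssmvep_class_error")
  }
  if (is.null(spec)) {
    spec <- compact_cnn_spec(fs, n_channels = dim(x)[[2L]],
                             n_classes = length(classes))
  }
  n <- dim(x)[[1L]]
  y <- match(labels, classes)
  if (any(tabulate(y, length(classes)) == 0L)) {
    .err("training data must contain every class", "ssmvep_class_error")
  }
  x_scale <- stats::sd(x)
  x <- x / x_scale

  params <- .cnn_init(spec, seed)
  T_ <- dim(x)[[3L]]
  T1 <- T_ %/% spec$pool1
  T2 <- T1 %/% spec$pool2
  flat_len <- T2 * spec$n_separable_filters
  K <- length(classes)

  .with_seed(.derive_seed(seed, 1L), {
    params$W5 <- matrix(stats::rnorm(flat_len * K, 0, sqrt(2 / flat_len)),
                        flat_len, K)
    adam <- lapply(params, function(p) list(m = p * 0, v = p * 0))
    lr <- spec$learning_rate
    beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
    step <- 0L
    best <- Inf; wait <- 0L
    loss_hist <- numeric(0)

    for (epoch in seq_len(spec$n_epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0
      for (b0 in seq(1L, n, by = spec$batch_size)) {
        idx <- ord[b0:min(b0 + spec$batch_size - 1L, n)]
        grads <- NULL
        for (i in idx) {
          masks <- if (spec$dropout > 0) {
            keep <- 1 - spec$dropout
            list(m1 = matrix(stats::rbinom(T1 * spec$n_temporal_filters *
                                             spec$depth_multiplier, 1, keep),
                             T1) / keep,
                 m2 = matrix(stats::rbinom(T2 * spec$n_separable_filters,
                                           1, keep), T2) / keep)
          } else NULL
          fw <- .cnn_forward(params, x[i, , ], spec, masks, cache = TRUE)
          y1 <- numeric(K); y1[[y[[i]]]] <- 1
          ep_loss <- ep_loss - log(max(fw$prob[[y[[i]]]], 1e-12))
          g <- .cnn_backward(params, fw, y1, spec, masks)
          grads <- if (is.null(grads)) g else
            Map(`+`, grads, g)
        }
        step <- step + 1L
        for (nm in names(grads)) {
          gr <- grads[[nm]] / length(idx)
          adam[[nm]]$m <- beta1 * adam[[nm]]$m + (1 - beta1) * gr
          adam[[nm]]$v <- beta2 * adam[[nm]]$v + (1 - beta2) * gr^2
          mhat <- adam[[nm]]$m / (1 - beta1^step)
          vhat <- adam[[nm]]$v / (1 - beta2^step)
          params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
        }
      }
      ep_loss <- ep_loss / n
      loss_hist <- c(loss_hist, ep_loss)
      if (verbose && epoch %% 10L == 0L) {
        cat(sprintf("epoch %d loss %.4f\n", epoch, ep_loss))
      }
      if (ep_loss < best - spec$min_delta) {
        best <- ep_loss; wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= spec$patience) break
      }
    }
  })

  structure(list(params = params, spec = spec, classes = classes,
                 x_scale = x_scale, loss_history = loss_hist, seed = seed),
            class = "compact_cnn")
}

#' @export
print.compact_cnn <- function(x, ...) {
  cat(sprintf(
    "compact_cnn: %d classes (%s), L=%d, trained %d epoch(s), final loss %.4f\n",
    length(x$classes), paste(x$classes, collapse = "/"),
    x$spec$temporal_kernel, length(x$loss_history),
    utils::tail(x$loss_history, 1)))
  invisible(x)
}

#' Predict with a trained compact CNN
#'
#' @param object A `compact_cnn`.
#' @param newdata A [trial_tensor()] or `n x channels x samples` array.
#' @param type `"class"` (predicted stimulation frequency) or `"prob"`
#'   (softmax matrix, rows summing to 1).
#' @param ... Unused.
#' @export
predict.compact_cnn <- function(object, newdata, type = c("class", "prob"),
                                ...) {
  type <- match.arg(type)
  x <- if (inherits(newdata, "trial_tensor")) newdata$data else newdata
  if (length(dim(x)) == 2L) x <- array(x, c(1L, dim(x)))
  x <- x / object$x_scale
  n <- dim(x)[[1L]]
  probs <- matrix(0, n, length(object$classes),
                  dimnames = list(NULL, object$classes))
  for (i in seq_len(n)) {
    probs[i, ] <- .cnn_forward(object$params, x[i, , ], object$spec)$prob
  }
  if (type == "prob") probs else
    object$classes[apply(probs, 1L, which.max)]
}
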
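#' Unsupervised generative hidden layer
#'
#' The second hidden layer is a restricted Boltzmann machine with stochastic
#' binary hidden units over the (rectified, `[0,1]`-bounded) filter features.
#' It is trained purely generatively — single-step contrastive divergence on
#' unlabelled images — so no numerosity information ever reaches the weights.
#' Deterministic mean-field probabilities are used when the layer encodes
#' images for read-out and neuron-level analyses.
#'
#' @name generative
NULL

#' Create a randomly initialised generative layer
#'
#' This is the "initial network" condition: filter features are projected
#' through random weights with no experience-dependent learning.
#'
#' @param n_visible Number of input features (filter-bank kernels).
#' @param n_hidden Number of hidden units.
#' @param init_sd Standard deviation of the Gaussian weight initialisation.
#' @param seed Optional seed for the initialisation.
#' @return A `generative_layer`: `W` (hidden x visible), `b_vis`, `b_hid`,
#'   `epoch`.
#' @export
new_generative_layer <- function(n_visible, n_hidden = 400L, init_sd = 0.3,
                                 seed = NULL) {
  with_seed(seed, {
    structure(list(
      W = matrix(rnorm(n_hidden * n_visible, sd = init_sd), n_hidden, n_visible),
      b_vis = numeric(n_visible),
      b_hid = numeric(n_hidden),
      epoch = 0L
    ), class = "generative_layer")
  })
}

#' @export
print.generative_layer <- function(x, ...) {
  cat(sprintf("<generative_layer  %d hidden x %d visible  epoch %d>\n",
              nrow(x$W), ncol(x$W), x$epoch))
  invisible(x)
}

#' Train the generative layer on an unlabelled corpus
#'
#' Single-step contrastive divergence with momentum and weight decay.
#' The interface is label-blind by construction: only pixel data reach the
#' update rule (the corpus metadata is never consulted).
#'
#' @param corpus A `num_corpus`, a list of `num_img`, or a pre-computed
#'   images x features matrix.
#' @param layer A [new_generative_layer()] (its state is the epoch-0
#'   snapshot).
#' @param bank Filter bank used to compute features when `corpus` holds
#'   images.
#' @param epochs Number of passes over the corpus.
#' @param checkpoint_every Epoch interval between stored snapshots.
#' @param batch_size Minibatch size.
#' @param learning_rate Contrastive-divergence step size.
#' @param momentum Two values: momentum before and after
#'   `momentum_switch` epochs.
#' @param momentum_switch Epoch at which momentum switches.
#' @param weight_decay L2 weight decay.
#' @param seed Optional seed for minibatch order and hidden sampling.
#' @return A `training_trajectory`: list with `snapshots` (named by epoch,
#'   each a `generative_layer`), `recon_error` tibble (epoch, mse) and the
#'   training settings.
#' @export
train_unsupervised <- function(corpus, layer, bank = NULL, epochs = 300L,
                               checkpoint_every = 30L, batch_size = 100L,
                               learning_rate = 0.05, momentum = c(0.5, 0.9),
                               momentum_switch = 5L, weight_decay = 2e-4,
                               seed = NULL) {
  stopifnot(inherits(layer, "generative_layer"), epochs >= 1)
  V <- if (is.matrix(corpus) && !inherits(corpus, "num_img")) corpus
       else propagate(corpus, bank)
  if (nrow(V) == 0) abort("empty corpus", class = "numerosense_precondition")
  if (ncol(V) != ncol(layer$W)) {
    abort("feature dimensionality does not match the layer",
          class = "numerosense_config")
  }
  n <- nrow(V)
  W <- layer$W; b_vis <- layer$b_vis; b_hid <- layer$b_hid
  dW <- W * 0; db_vis <- b_vis * 0; db_hid <- b_hid * 0
  snapshots <- list(); recon <- numeric(epochs)
  with_seed(seed, {
    for (ep in seq_len(epochs)) {
      mom <- if (ep <= momentum_switch) momentum[1] else momentum[2]
      ord <- sample.int(n)
      starts <- seq(1L, n, by = batch_size)
      err <- 0
      for (s in starts) {
        idx <- ord[s:min(s + batch_size - 1L, n)]
        v0 <- V[idx, , drop = FALSE]
        b <- nrow(v0)
        hp0 <- sigmoid(sweep(tcrossprod(v0, W), 2, b_hid, "+"))
        hs <- matrix(runif(length(hp0)) < hp0, nrow(hp0), ncol(hp0)) * 1
        v1 <- sigmoid(sweep(hs %*% W, 2, b_vis, "+"))
        hp1 <- sigmoid(sweep(tcrossprod(v1, W), 2, b_hid, "+"))
        dW <- mom * dW + learning_rate *
          ((crossprod(hp0, v0) - crossprod(hp1, v1)) / b - weight_decay * W)
        db_vis <- mom * db_vis + learning_rate * colMeans(v0 - v1)
        db_hid <- mom * db_hid + learning_rate * colMeans(hp0 - hp1)
        W <- W + dW; b_vis <- b_vis + db_vis; b_hid <- b_hid + db_hid
        err <- err + sum((v0 - v1)^2)
      }
      if (!all(is.finite(W))) {
        abort(sprintf("generative training diverged at epoch %d (non-finite weights)", ep),
              class = "numerosense_divergence")
      }
      recon[ep] <- err / (n * ncol(V))
      if (ep %% checkpoint_every == 0) {
        snapshots[[as.character(ep)]] <- structure(
          list(W = W, b_vis = b_vis, b_hid = b_hid, epoch = ep),
          class = "generative_layer")
      }
    }
  })
  structure(list(
    snapshots = snapshots,
    recon_error = tibble::tibble(epoch = seq_len(epochs), mse = recon),
    initial = layer,
    settings = list(epochs = epochs, checkpoint_every = checkpoint_every,
                    batch_size = batch_size, learning_rate = learning_rate,
                    momentum = momentum, weight_decay = weight_decay)
  ), class = "training_trajectory")
}

#' @export
print.training_trajectory <- function(x, ...) {
  cat(sprintf("<training_trajectory  %d checkpoints (every %d of %d epochs)>\n",
              length(x$snapshots), x$settings$checkpoint_every,
              x$settings$epochs))
  invisible(x)
}

#' Checkpoint epochs of a trajectory
#' @param trajectory A `training_trajectory`.
#' @return Integer vector of snapshot epochs.
#' @export
checkpoint_epochs <- function(trajectory) {
  as.integer(names(trajectory$snapshots))
}

#' Encode images as hidden-layer representations
#'
#' Deterministic mean-field activation probabilities of the hidden units,
#' in `[0, 1]` per unit.
#'
#' @param x Images (anything [propagate()] accepts) or a pre-computed
#'   feature matrix.
#' @param bank Filter bank (ignored when `x` is already a feature matrix).
#' @param layer A `generative_layer` (trained or randomly initialised).
#' @return For a single image a numeric vector (length = hidden units);
#'   otherwise an images x hidden-units matrix.
#' @export
encode <- function(x, bank, layer) {
  stopifnot(inherits(layer, "generative_layer"))
  feats <- if (is.matrix(x) && !inherits(x, "num_img") &&
               ncol(x) == ncol(layer$W)) x
           else propagate(x, bank)
  single <- is.null(dim(feats))
  if (single) feats <- matrix(feats, 1)
  H <- sigmoid(sweep(tcrossprod(feats, layer$W), 2, layer$b_hid, "+"))
  if (single) H[1, ] else H
}

#' Mean one-step reconstruction error of a layer on a corpus
#'
#' Mean-field encode/decode pass; used to monitor generative learning.
#'
#' @inheritParams encode
#' @return Mean squared reconstruction error (scalar).
#' @export
reconstruction_error <- function(x, bank, layer) {
  feats <- if (is.matrix(x) && !inherits(x, "num_img") &&
               ncol(x) == ncol(layer$W)) x
           else propagate(x, bank)
  if (is.null(dim(feats))) feats <- matrix(feats, 1)
  H <- sigmoid(sweep(tcrossprod(feats, layer$W), 2, layer$b_hid, "+"))
  V1 <- sigmoid(sweep(H %*% layer$W, 2, layer$b_vis, "+"))
  mean((feats - V1)^2)
}
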
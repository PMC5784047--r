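#' Delta-rule read-out for two-alternative numerosity comparison
#'
#' The read-out head maps the hidden representations of the two images of a
#' pair onto a two-alternative choice ("left larger" vs "right larger"). A
#' single evidence template is applied to both sides and the two evidence
#' values are compared — equivalently, a linear-logistic unit on the
#' difference of the two hidden representations. Training is plain
#' error-driven associative learning (Rescorla–Wagner / delta rule); the
#' hidden-layer weights are never touched.
#'
#' @name readout
NULL

pair_design <- function(pairs, bank, layer) {
  imgs <- purrr::flatten(purrr::map(pairs, function(p) list(p$left, p$right)))
  H <- encode(imgs, bank, layer)
  left <- H[seq(1, nrow(H), by = 2), , drop = FALSE]
  right <- H[seq(2, nrow(H), by = 2), , drop = FALSE]
  list(X = left - right,
       target = vapply(pairs, function(p) p$correct_side == "left", logical(1)))
}

#' Train the read-out head on a (possibly small) fraction of pairs
#'
#' Only a random subset of the available pairs carries feedback, mirroring
#' training regimes in which explicit reinforcement is scarce. Either a
#' fraction or an absolute pair count can be given.
#'
#' @param pairs List of `num_pair` objects.
#' @param bank Filter bank.
#' @param layer Generative layer (random = "initial network"; trained =
#'   "mature network").
#' @param feedback_fraction Fraction of pairs sampled for supervised
#'   training, in `(0, 1]`.
#' @param n_feedback Absolute number of training pairs; overrides
#'   `feedback_fraction` when given.
#' @param learning_rate Delta-rule step size.
#' @param epochs Passes over the sampled training pairs.
#' @param seed Optional seed (pair sampling and presentation order).
#' @return A `readout_head`: `v` (evidence template over hidden units),
#'   `b` (side bias), `train_index` (indices of the sampled pairs),
#'   settings.
#' @export
train_readout <- function(pairs, bank, layer, feedback_fraction = 0.25,
                          n_feedback = NULL, learning_rate = 0.05,
                          epochs = 30L, seed = NULL) {
  if (length(pairs) == 0) abort("no pairs", class = "numerosense_precondition")
  if (is.null(n_feedback)) {
    if (feedback_fraction <= 0 || feedback_fraction > 1) {
      abort("feedback_fraction must be in (0, 1]",
            class = "numerosense_precondition")
    }
    n_feedback <- max(1L, round(feedback_fraction * length(pairs)))
  }
  n_feedback <- min(as.integer(n_feedback), length(pairs))
  with_seed(seed, {
    train_index <- sort(sample.int(length(pairs), n_feedback))
    d <- pair_design(pairs[train_index], bank, layer)
    X <- d$X
    t_left <- as.numeric(d$target)
    v <- numeric(ncol(X)); b <- 0
    # tail averaging (Polyak-Ruppert) over the second half of training
    # stabilises the online estimate without changing the update rule
    v_bar <- v; b_bar <- 0; n_bar <- 0L
    for (ep in seq_len(epochs)) {
      for (i in sample.int(nrow(X))) {
        x <- X[i, ]
        err <- t_left[i] - sigmoid(sum(v * x) + b)
        v <- v + learning_rate * err * x
        b <- b + learning_rate * err
      }
      if (ep > epochs / 2) {
        v_bar <- v_bar + v; b_bar <- b_bar + b; n_bar <- n_bar + 1L
      }
    }
    if (n_bar > 0L) { v <- v_bar / n_bar; b <- b_bar / n_bar }
    structure(list(v = v, b = b, train_index = train_index,
                   n_hidden = ncol(X),
                   settings = list(learning_rate = learning_rate,
                                   epochs = epochs,
                                   n_feedback = n_feedback)),
              class = "readout_head")
  })
}

#' @export
print.readout_head <- function(x, ...) {
  cat(sprintf("<readout_head  template over %d hidden units  trained on %d pairs>\n",
              length(x$v), x$settings$n_feedback))
  invisible(x)
}

#' Compare the two images of a pair
#'
#' @param pair A `num_pair`.
#' @param bank,layer,head Network components.
#' @return One-row tibble: `choice` ("left"/"right"), `correct` (logical),
#'   `ratio`, `congruency`.
#' @export
compare <- function(pair, bank, layer, head) {
  evaluate_pairs(list(pair), bank, layer, head)
}

#' Evaluate the read-out on a set of pairs
#'
#' @param pairs List of `num_pair` objects.
#' @param bank,layer,head Network components.
#' @return Tibble with one row per pair: numerosities, `ratio`,
#'   `congruency`, `choice`, `correct`.
#' @export
evaluate_pairs <- function(pairs, bank, layer, head) {
  stopifnot(inherits(head, "readout_head"))
  d <- pair_design(pairs, bank, layer)
  score <- as.numeric(d$X %*% head$v) + head$b
  choice <- ifelse(score > 0, "left", "right")
  meta <- pairs_meta(pairs)
  tibble::tibble(
    n_left = meta$n_left, n_right = meta$n_right,
    ratio = meta$ratio, congruency = meta$congruency,
    choice = choice,
    correct = choice == meta$correct_side
  )
}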
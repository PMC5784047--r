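#' Psychophysical analyses of comparison behaviour
#'
#' Choices from the comparison task are summarised as accuracy per numerical
#' ratio and condensed into a Weber fraction `w` by fitting the standard
#' approximate-number-system psychometric model
#' \deqn{p(\mathrm{correct} \mid r) = \Phi\!\left(\frac{|\ln r|}{\sqrt{2}\,w}\right)}
#' where `r` is the smaller:larger numerosity ratio and \eqn{\Phi} the
#' standard normal CDF. Smaller `w` means finer number acuity.
#'
#' @name psychophysics
NULL

#' Accuracy by numerical ratio
#'
#' @param trials Tibble of evaluated trials (e.g. from [evaluate_pairs()])
#'   with columns `ratio` and `correct`.
#' @return Tibble with one row per distinct ratio: `ratio`, `n_trials`,
#'   `accuracy`. Cell counts sum to the number of input trials.
#' @export
accuracy_by_ratio <- function(trials) {
  if (nrow(trials) == 0) abort("no trials", class = "numerosense_precondition")
  trials |>
    dplyr::group_by(ratio = .data$ratio) |>
    dplyr::summarise(n_trials = dplyr::n(),
                     accuracy = mean(.data$correct), .groups = "drop") |>
    dplyr::arrange(.data$ratio)
}

#' Psychometric prediction of the ratio-dependent comparison model
#'
#' @param ratio Numerosity ratio(s) in `(0, 1)`.
#' @param w Weber fraction.
#' @param lapse Lapse rate (probability of a random guess).
#' @return Predicted probability of a correct choice.
#' @export
weber_model <- function(ratio, w, lapse = 0) {
  p <- pnorm(abs(log(ratio)) / (sqrt(2) * w))
  lapse * 0.5 + (1 - lapse) * p
}

#' Fit the Weber fraction to an accuracy-by-ratio table
#'
#' Least-squares fit of [weber_model()] to the per-ratio accuracies. Fits in
#' which all accuracies sit at chance or at ceiling are flagged unreliable
#' rather than silently reported.
#'
#' @param acc_table Tibble from [accuracy_by_ratio()] (`ratio`, `n_trials`,
#'   `accuracy`).
#' @param lapse Fixed lapse rate (default 0).
#' @param condition Optional condition label carried into the result.
#' @param interval Search interval for `w`.
#' @return A `weber_fit`: `w`, `sse`, `status` ("ok"/"unreliable"),
#'   `table` (input plus fitted values and residuals), `condition`.
#' @export
fit_weber <- function(acc_table, lapse = 0, condition = NA_character_,
                      interval = c(1e-3, 10)) {
  stopifnot(all(c("ratio", "n_trials", "accuracy") %in% names(acc_table)))
  if (nrow(acc_table) < 3) {
    abort("need >= 3 distinct ratios to fit a Weber fraction",
          class = "numerosense_precondition")
  }
  if (any(acc_table$n_trials < 20)) {
    warn("fewer than 20 trials in at least one ratio cell; estimate may be noisy")
  }
  if (any(acc_table$ratio <= 0 | acc_table$ratio >= 1)) {
    abort("ratios must lie in (0, 1)", class = "numerosense_precondition")
  }
  sse <- function(w) sum((acc_table$accuracy -
                            weber_model(acc_table$ratio, w, lapse))^2)
  opt <- optimize(sse, interval, tol = 1e-10)
  w <- opt$minimum
  status <- "ok"
  chance_band <- all(abs(acc_table$accuracy - 0.5) < 0.03)
  ceiling_band <- all(acc_table$accuracy > 0.99)
  if (chance_band || ceiling_band ||
      w <= interval[1] * 1.01 || w >= interval[2] * 0.99) {
    status <- "unreliable"
  }
  table <- acc_table |>
    dplyr::mutate(fitted = weber_model(.data$ratio, w, lapse),
                  residual = .data$accuracy - .data$fitted)
  structure(list(w = w, sse = opt$objective, lapse = lapse, status = status,
                 table = table, condition = condition),
            class = "weber_fit")
}

#' @export
print.weber_fit <- function(x, ...) {
  cat(sprintf("<weber_fit  w = %.4f  (%s%s)>\n", x$w, x$status,
              if (is.na(x$condition)) "" else paste0(", ", x$condition)))
  invisible(x)
}

#' Tidy a Weber-fraction fit
#' @param x A `weber_fit`.
#' @param ... Unused.
#' @return One-row tibble with `term`, `estimate`.
#' @importFrom generics tidy
#' @export
tidy.weber_fit <- function(x, ...) {
  tibble::tibble(term = "weber_fraction", estimate = x$w)
}

#' One-row summary of a Weber-fraction fit
#' @param x A `weber_fit`.
#' @param ... Unused.
#' @return Tibble with `w`, `sse`, `n_ratios`, `n_trials`, `status`,
#'   `condition`.
#' @importFrom generics glance
#' @export
glance.weber_fit <- function(x, ...) {
  tibble::tibble(w = x$w, sse = x$sse, n_ratios = nrow(x$table),
                 n_trials = sum(x$table$n_trials), status = x$status,
                 condition = x$condition)
}

#' @export
generics::tidy

#' @export
generics::glance

#' Weber-fraction trajectory across unsupervised-learning checkpoints
#'
#' At every checkpoint of a training trajectory the read-out is retrained
#' with an identical protocol (same pairs, same feedback fraction, same
#' seed) and the Weber fraction is fitted on a fixed, disjoint evaluation
#' set, tracking how number acuity develops with unsupervised experience.
#'
#' @param trajectory A [train_unsupervised()] result.
#' @param bank Filter bank.
#' @param train_pairs Pairs available to the read-out (feedback is sampled
#'   from these).
#' @param eval_pairs Held-out pairs used for the psychometric fit.
#' @param include_initial Also evaluate the epoch-0 (random) layer.
#' @param feedback_fraction,readout_epochs,learning_rate Read-out protocol.
#' @param seed Seed reused identically at every checkpoint.
#' @return Tibble: `epoch`, `w`, `status`.
#' @export
learning_trajectory <- function(trajectory, bank, train_pairs, eval_pairs,
                                include_initial = TRUE,
                                feedback_fraction = 0.25,
                                readout_epochs = 30L, learning_rate = 0.1,
                                seed = 1L) {
  stopifnot(inherits(trajectory, "training_trajectory"))
  layers <- trajectory$snapshots
  epochs <- checkpoint_epochs(trajectory)
  if (include_initial) {
    layers <- c(list(`0` = trajectory$initial), layers)
    epochs <- c(0L, epochs)
  }
  purrr::map2_dfr(layers, epochs, function(layer, ep) {
    head <- train_readout(train_pairs, bank, layer,
                          feedback_fraction = feedback_fraction,
                          learning_rate = learning_rate,
                          epochs = readout_epochs, seed = seed)
    fit <- fit_weber(accuracy_by_ratio(evaluate_pairs(eval_pairs, bank, layer, head)),
                     condition = sprintf("epoch %d", ep))
    tibble::tibble(epoch = ep, w = fit$w, status = fit$status)
  })
}

#' Cost of incongruency by numerical ratio
#'
#' Difference in accuracy between congruent and incongruent trials at each
#' ratio (positive cost = congruent advantage).
#'
#' @param trials Evaluated trials with columns `ratio`, `congruency`
#'   (values "congruent"/"incongruent") and `correct`.
#' @return Tibble: `ratio`, `n_congruent`, `n_incongruent`,
#'   `acc_congruent`, `acc_incongruent`, `cost`; plus an `overall`
#'   attribute with the pooled means.
#' @export
congruency_cost <- function(trials) {
  acc <- trials |>
    dplyr::filter(.data$congruency %in% c("congruent", "incongruent")) |>
    dplyr::group_by(.data$ratio, .data$congruency) |>
    dplyr::summarise(n = dplyr::n(), accuracy = mean(.data$correct),
                     .groups = "drop")
  wide <- tidyr::pivot_wider(acc, names_from = "congruency",
                             values_from = c("n", "accuracy"))
  missing <- wide |>
    dplyr::filter(is.na(.data$accuracy_congruent) |
                    is.na(.data$accuracy_incongruent))
  if (nrow(missing) > 0) {
    abort(sprintf("unmatched ratio cells (one condition missing): %s",
                  paste(format(missing$ratio, digits = 3), collapse = ", ")),
          class = "numerosense_precondition")
  }
  out <- wide |>
    dplyr::transmute(ratio = .data$ratio,
                     n_congruent = .data$n_congruent,
                     n_incongruent = .data$n_incongruent,
                     acc_congruent = .data$accuracy_congruent,
                     acc_incongruent = .data$accuracy_incongruent,
                     cost = .data$acc_congruent - .data$acc_incongruent) |>
    dplyr::arrange(.data$ratio)
  attr(out, "overall") <- c(
    acc_congruent = stats::weighted.mean(out$acc_congruent, out$n_congruent),
    acc_incongruent = stats::weighted.mean(out$acc_incongruent, out$n_incongruent),
    cost = stats::weighted.mean(out$cost, out$n_congruent + out$n_incongruent))
  out
}
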
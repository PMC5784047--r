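# generative layer and read-out, on a deliberately small scale
bank <- build_filterbank()

small_corpus <- function(n, seed) generate_corpus(corpus_spec(n, seed = seed))

test_that("checkpoint scheduling follows the stated interval", {
  set.seed(1)
  V <- matrix(runif(40 * 12), 40, 12)
  layer <- new_generative_layer(12, n_hidden = 8, seed = 2)
  traj <- train_unsupervised(V, layer, epochs = 90, checkpoint_every = 30,
                             batch_size = 10, seed = 3)
  expect_equal(checkpoint_epochs(traj), c(30L, 60L, 90L))
  expect_equal(traj$snapshots[["60"]]$epoch, 60L)
})

test_that("unsupervised training is seeded-deterministic and label-blind", {
  corpus <- small_corpus(40, seed = 7)
  layer <- new_generative_layer(bank$n_features, n_hidden = 30, seed = 8)
  t1 <- train_unsupervised(corpus, layer, bank, epochs = 4,
                           checkpoint_every = 2, seed = 9)
  t2 <- train_unsupervised(corpus, layer, bank, epochs = 4,
                           checkpoint_every = 2, seed = 9)
  expect_identical(t1$snapshots[["4"]]$W, t2$snapshots[["4"]]$W)

  # deleting all ground-truth metadata cannot change the outcome: only the
  # pixels reach the learning rule
  stripped <- corpus
  stripped$meta <- stripped$meta[0, ]
  stripped$images <- lapply(stripped$images, function(im) {
    im$n <- NA_integer_; im$area <- NA_integer_; im$contour <- NA_integer_
    im$item_areas <- NA_integer_
    im
  })
  t3 <- train_unsupervised(stripped, layer, bank, epochs = 4,
                           checkpoint_every = 2, seed = 9)
  expect_identical(t1$snapshots[["4"]]$W, t3$snapshots[["4"]]$W)
})

test_that("generative learning reduces reconstruction error", {
  corpus <- small_corpus(150, seed = 10)
  V <- propagate(corpus, bank)
  layer <- new_generative_layer(ncol(V), n_hidden = 60, seed = 11)
  traj <- train_unsupervised(V, layer, epochs = 10, checkpoint_every = 5,
                             seed = 12)
  e0 <- reconstruction_error(V, bank, layer)
  e1 <- reconstruction_error(V, bank, traj$snapshots[["10"]])
  expect_lt(e1, e0)
  # epoch-wise trace is non-increasing on a smoothed basis
  sm <- stats::filter(traj$recon_error$mse, rep(1 / 3, 3), sides = 1)
  sm <- sm[!is.na(sm)]
  expect_lt(sm[length(sm)], sm[1])
})

test_that("the filter layer is immutable under training", {
  corpus <- small_corpus(30, seed = 13)
  before <- bank$W
  layer <- new_generative_layer(bank$n_features, n_hidden = 20, seed = 14)
  invisible(train_unsupervised(corpus, layer, bank, epochs = 2,
                               checkpoint_every = 1, seed = 15))
  expect_identical(bank$W, before)
})

test_that("encode is deterministic, bounded, and separates distinct images", {
  layer <- new_generative_layer(bank$n_features, n_hidden = 50, seed = 16)
  set.seed(17)
  img <- generate_image(5)
  h1 <- encode(img, bank, layer)
  h2 <- encode(img, bank, layer)
  expect_identical(h1, h2)
  expect_length(h1, 50)
  expect_true(all(h1 >= 0 & h1 <= 1))
  # an untrained (random) layer still assigns distinct codes to random
  # image pairs
  set.seed(18)
  for (i in 1:100) {
    a <- encode(generate_image(sample(1:16, 1)), bank, layer)
    b <- encode(generate_image(sample(17:32, 1)), bank, layer)
    expect_gt(max(abs(a - b)), 0)
  }
})

test_that("train_unsupervised validates its inputs", {
  layer <- new_generative_layer(10, n_hidden = 4)
  expect_error(train_unsupervised(matrix(numeric(0), 0, 10), layer, epochs = 1),
               class = "numerosense_precondition")
  expect_error(train_unsupervised(matrix(runif(50), 5, 10),
                                  new_generative_layer(7, n_hidden = 4),
                                  epochs = 1),
               class = "numerosense_config")
})

test_that("delta-rule read-out converges on separable pairs and respects the feedback fraction", {
  layer <- new_generative_layer(bank$n_features, n_hidden = 50, seed = 20)
  pairs <- generate_comparison_pairs(8, ratios = list(c(1L, 4L)), seed = 21)
  head <- train_readout(pairs, bank, layer, feedback_fraction = 1,
                        epochs = 150, seed = 22)
  trials <- evaluate_pairs(pairs, bank, layer, head)
  expect_equal(mean(trials$correct), 1)

  head25 <- train_readout(pairs, bank, layer, feedback_fraction = 0.25, seed = 23)
  expect_length(head25$train_index, round(0.25 * length(pairs)))
  headn <- train_readout(pairs, bank, layer, n_feedback = 3, seed = 23)
  expect_length(headn$train_index, 3L)

  expect_error(train_readout(pairs, bank, layer, feedback_fraction = 0),
               class = "numerosense_precondition")
  expect_error(train_readout(pairs, bank, layer, feedback_fraction = 1.2),
               class = "numerosense_precondition")
  expect_error(train_readout(list(), bank, layer),
               class = "numerosense_precondition")
})

test_that("read-out training never touches the generative weights", {
  layer <- new_generative_layer(bank$n_features, n_hidden = 30, seed = 24)
  W_before <- layer$W
  pairs <- generate_comparison_pairs(4, ratios = list(c(1L, 2L)), seed = 25)
  invisible(train_readout(pairs, bank, layer, feedback_fraction = 1, seed = 26))
  expect_identical(layer$W, W_before)
})

test_that("an unbiased head mirrors mirrored pair input", {
  layer <- new_generative_layer(bank$n_features, n_hidden = 20, seed = 27)
  set.seed(28)
  head <- structure(list(
    v = runif(20) - 0.5, b = 0,
    train_index = integer(), n_hidden = 20,
    settings = list(n_feedback = 0)), class = "readout_head")
  pairs <- generate_comparison_pairs(5, ratios = list(c(2L, 3L)), seed = 29)
  swapped <- lapply(pairs, function(p) {
    q <- p; q$left <- p$right; q$right <- p$left
    q$correct_side <- if (p$correct_side == "left") "right" else "left"
    q
  })
  r1 <- evaluate_pairs(pairs, bank, layer, head)
  r2 <- evaluate_pairs(swapped, bank, layer, head)
  expect_equal(r2$choice, ifelse(r1$choice == "left", "right", "left"))
  expect_equal(r1$correct, r2$correct)
})

test_that("network persistence round-trips weights and behaviour", {
  dir <- withr::local_tempdir()
  layer <- new_generative_layer(bank$n_features, n_hidden = 15, seed = 30)
  pairs <- generate_comparison_pairs(3, ratios = list(c(1L, 3L)), seed = 31)
  head <- train_readout(pairs, bank, layer, feedback_fraction = 1,
                        epochs = 5, seed = 32)
  save_network(bank, layer, head, dir)
  back <- load_network(dir)
  expect_equal(back$layer$W, layer$W, tolerance = 1e-12)
  set.seed(33)
  img <- generate_image(4)
  expect_equal(encode(img, back$bank, back$layer), encode(img, bank, layer),
               tolerance = 1e-10)
  r1 <- evaluate_pairs(pairs, bank, layer, head)
  r2 <- evaluate_pairs(pairs, back$bank, back$layer, back$head)
  expect_equal(r1$choice, r2$choice)
})
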
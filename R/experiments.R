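#' Experiment profiles
#'
#' `"full"` mirrors the reference regime (51 200-image corpus, 300
#' unsupervised epochs, multi-million-iteration evolution) and is
#' compute-heavy; `"scaled"` is the desk-scale profile used throughout the
#' documentation (5 000 images, 90 epochs, 1 million ecosystem
#' iterations).
#'
#' @param profile `"scaled"` or `"full"`.
#' @return Named list of experiment settings.
#' @export
experiment_profile <- function(profile = c("scaled", "full")) {
  profile <- match.arg(profile)
  if (profile == "full") {
    list(profile = "full", corpus_images = 51200L, epochs = 300L,
         checkpoint_every = 30L, pairs_per_ratio = 400L,
         eval_pairs_per_ratio = 400L, congruency_count = 400L,
         readout_epochs = 30L, feedback_fraction = 0.25,
         summation_reps = 20L, selective_reps = 50L,
         evolife_iterations = 2000000L, evolife_agents = 200L,
         test_reps = 50L)
  } else {
    list(profile = "scaled", corpus_images = 5000L, epochs = 90L,
         checkpoint_every = 30L, pairs_per_ratio = 800L,
         eval_pairs_per_ratio = 250L, congruency_count = 200L,
         readout_epochs = 30L, feedback_fraction = 0.25,
         summation_reps = 20L, selective_reps = 50L,
         evolife_iterations = 1000000L, evolife_agents = 200L,
         test_reps = 50L)
  }
}

#' Run a named end-to-end experiment
#'
#' Reproducible recipes over the package's modules:
#' \describe{
#'   \item{`"trajectory"`}{Weber-fraction developmental trajectory across
#'     unsupervised-learning checkpoints.}
#'   \item{`"feedback"`}{Accuracy by ratio for the initial (random) and
#'     mature networks under reduced feedback (25% and 1% regimes).}
#'   \item{`"congruency"`}{Congruent vs incongruent accuracy and
#'     incongruency cost for initial and mature networks.}
#'   \item{`"coding"`}{Summation-coding and numerosity-selectivity
#'     classification of hidden units, with pooled tuning curves.}
#'   \item{`"evolution"`}{Ecosystem evolution, comparison test battery,
#'     distance/size effects and hidden-unit monotonicity.}
#' }
#' All randomness descends deterministically from `seed`; when `out_dir` is
#' given, result tables are written as TSV together with a JSON manifest
#' sufficient to re-run the experiment bit-identically.
#'
#' @param name Experiment name (see above).
#' @param profile `"scaled"` or `"full"`.
#' @param seed Master seed.
#' @param out_dir Optional output directory.
#' @param overrides Named list overriding individual profile settings.
#' @return Named list of result tables (tibbles), invisibly when writing.
#' @export
run_experiment <- function(name = c("trajectory", "feedback", "congruency",
                                    "coding", "evolution"),
                           profile = "scaled", seed = 1L, out_dir = NULL,
                           overrides = list()) {
  name <- tryCatch(match.arg(name),
                   error = function(e) abort(
                     sprintf("unknown experiment '%s'", name[1]),
                     class = "numerosense_usage"))
  cfg <- utils::modifyList(experiment_profile(profile), overrides)
  seeds <- derive_subseeds(seed, 10L)
  names(seeds) <- c("corpus", "layer", "train", "pairs", "eval_pairs",
                    "readout", "congruency", "probe", "evolife", "test")

  results <- switch(name,
    trajectory = exp_trajectory(cfg, seeds),
    feedback = exp_feedback(cfg, seeds),
    congruency = exp_congruency(cfg, seeds),
    coding = exp_coding(cfg, seeds),
    evolution = exp_evolution(cfg, seeds))

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(results)) {
      utils::write.table(results[[nm]],
                         file.path(out_dir, paste0(nm, ".tsv")),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    }
    manifest <- list(experiment = name, master_seed = seed,
                     sub_seeds = as.list(seeds), config = cfg,
                     package_version = as.character(utils::packageVersion("numerosense")))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    return(invisible(results))
  }
  results
}

# shared pipeline: corpus -> filter bank -> random layer -> trained trajectory
fit_deep_model <- function(cfg, seeds, train = TRUE) {
  corpus <- generate_corpus(corpus_spec(cfg$corpus_images, seed = seeds[["corpus"]]))
  bank <- build_filterbank()
  feats <- propagate(corpus, bank)
  layer0 <- new_generative_layer(ncol(feats), seed = seeds[["layer"]])
  traj <- if (train) {
    train_unsupervised(feats, layer0, epochs = cfg$epochs,
                       checkpoint_every = cfg$checkpoint_every,
                       seed = seeds[["train"]])
  } else NULL
  list(corpus = corpus, bank = bank, feats = feats, layer0 = layer0,
       traj = traj)
}

final_layer <- function(traj) traj$snapshots[[length(traj$snapshots)]]

exp_trajectory <- function(cfg, seeds) {
  m <- fit_deep_model(cfg, seeds)
  train_pairs <- generate_comparison_pairs(cfg$pairs_per_ratio,
                                           seed = seeds[["pairs"]])
  eval_pairs <- generate_comparison_pairs(cfg$eval_pairs_per_ratio,
                                          seed = seeds[["eval_pairs"]])
  traj_tbl <- learning_trajectory(m$traj, m$bank, train_pairs, eval_pairs,
                                  feedback_fraction = cfg$feedback_fraction,
                                  readout_epochs = cfg$readout_epochs,
                                  seed = seeds[["readout"]])
  list(trajectory = traj_tbl, recon_error = m$traj$recon_error)
}

exp_feedback <- function(cfg, seeds) {
  m <- fit_deep_model(cfg, seeds)
  train_pairs <- generate_comparison_pairs(cfg$pairs_per_ratio,
                                           seed = seeds[["pairs"]])
  eval_pairs <- generate_comparison_pairs(cfg$eval_pairs_per_ratio,
                                          seed = seeds[["eval_pairs"]])
  nets <- list(initial = m$layer0, mature = final_layer(m$traj))
  out <- purrr::imap_dfr(nets, function(layer, net) {
    purrr::map_dfr(c(0.25, 0.01), function(fb) {
      head <- train_readout(train_pairs, m$bank, layer,
                            feedback_fraction = fb,
                            epochs = cfg$readout_epochs,
                            seed = seeds[["readout"]])
      accuracy_by_ratio(evaluate_pairs(eval_pairs, m$bank, layer, head)) |>
        dplyr::mutate(network = net, feedback_fraction = fb)
    })
  })
  list(feedback_accuracy = out)
}

congruency_eval <- function(cfg, seeds, bank, layer, head,
                            ratios = default_ratios()) {
  purrr::map_dfr(ratios, function(r) {
    purrr::map_dfr(c("congruent", "incongruent"), function(cg) {
      prs <- generate_congruency_pairs(r, cg, cfg$congruency_count,
                                       seed = seeds[["congruency"]] +
                                         r[2] * 7L + (cg == "incongruent"))
      evaluate_pairs(prs, bank, layer, head)
    })
  })
}

exp_congruency <- function(cfg, seeds) {
  m <- fit_deep_model(cfg, seeds)
  train_pairs <- generate_comparison_pairs(cfg$pairs_per_ratio,
                                           seed = seeds[["pairs"]])
  nets <- list(initial = m$layer0, mature = final_layer(m$traj))
  tabs <- purrr::imap(nets, function(layer, net) {
    head <- train_readout(train_pairs, m$bank, layer,
                          feedback_fraction = cfg$feedback_fraction,
                          epochs = cfg$readout_epochs,
                          seed = seeds[["readout"]])
    trials <- congruency_eval(cfg, seeds, m$bank, layer, head)
    congruency_cost(trials) |> dplyr::mutate(network = net)
  })
  list(congruency_cost = dplyr::bind_rows(tabs))
}

exp_coding <- function(cfg, seeds) {
  m <- fit_deep_model(cfg, seeds)
  probe_sum <- generate_probe(1:32, c(32L, 64L), reps = cfg$summation_reps,
                              seed = seeds[["probe"]])
  probe_sel <- generate_probe(1:5, c(32L, 64L), reps = cfg$selective_reps,
                              seed = seeds[["probe"]] + 1L)
  nets <- list(initial = m$layer0, mature = final_layer(m$traj))
  summation <- purrr::imap_dfr(nets, function(layer, net) {
    classify_summation(build_tuning_table(m$bank, layer, probe_sum)) |>
      dplyr::mutate(network = net)
  })
  selective <- purrr::imap_dfr(nets, function(layer, net) {
    classify_selective(m$bank, layer, probe_sel) |>
      dplyr::mutate(network = net)
  })
  curves <- purrr::imap_dfr(nets, function(layer, net) {
    tt <- build_tuning_table(m$bank, layer, probe_sel)
    pool <- pool_tuning_curves(
      classify_selective(m$bank, layer, probe_sel), tt)
    pool$curves |> dplyr::mutate(network = net)
  })
  list(summation = summation, selective = selective,
       pooled_curves = curves)
}

exp_evolution <- function(cfg, seeds) {
  eco <- create_ecosystem(n_agents = cfg$evolife_agents,
                          seed = seeds[["evolife"]])
  eco <- evolve(eco, cfg$evolife_iterations, seed = seeds[["evolife"]] + 1L)
  trials <- test_comparison(eco, reps = cfg$test_reps, seed = seeds[["test"]])
  eff <- distance_size_effects(trials)
  per_agent <- trials |>
    dplyr::filter(!.data$timeout) |>
    dplyr::group_by(.data$agent) |>
    dplyr::summarise(n = dplyr::n(), accuracy = mean(.data$correct),
                     .groups = "drop")
  best <- per_agent$agent[which.max(per_agent$accuracy)]
  units <- analyze_hidden_units(eco, best, seed = seeds[["test"]] + 1L)
  list(fitness_trace = eco$trace, agent_accuracy = per_agent,
       distance_effects = eff$distance, size_effects = eff$size,
       hidden_units = units)
}
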
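#' Neuron-level coding analyses
#'
#' Hidden units are probed with a factorial stimulus set crossing
#' numerosity with cumulative area, and classified into two emergent coding
#' families: *numerosity-sensitive* units (summation coding — activation
#' rises or falls monotonically with numerosity, indexed by a large
#' standardized regression coefficient for log numerosity and a small one
#' for log area) and *numerosity-selective* units (bell-shaped tuning with
#' a preferred numerosity, selected by a two-factor ANOVA with a
#' significant numerosity main effect and no cumulative-area effect).
#'
#' @name neural_analysis
NULL

#' Generate a factorial probe corpus
#'
#' Images crossing every numerosity level with every cumulative-area level,
#' `reps` images per cell.
#'
#' @param numerosities Numerosity levels.
#' @param area_levels Cumulative-area levels (each must be feasible for
#'   every numerosity).
#' @param reps Images per (numerosity, area) cell.
#' @param side Grid side.
#' @param seed Optional seed.
#' @return A `num_corpus` whose meta crosses the full design.
#' @export
generate_probe <- function(numerosities, area_levels, reps, side = 30L,
                           seed = NULL) {
  design <- expand.grid(n = as.integer(numerosities),
                        area = as.integer(area_levels))
  design <- design[rep(seq_len(nrow(design)), each = reps), ]
  with_seed(seed, {
    imgs <- purrr::map2(design$n, design$area, function(nn, aa) {
      generate_image(nn, area_target = aa, side = side)
    })
    structure(list(images = imgs, meta = corpus_meta(imgs), spec = NULL),
              class = "num_corpus")
  })
}

#' Build a per-neuron tuning table from a factorial probe
#'
#' Mean and variance of each hidden unit's (deterministic, mean-field)
#' activation in every (numerosity, cumulative-area) condition cell.
#'
#' @param bank,layer Network components.
#' @param probe A factorial `num_corpus` (see [generate_probe()]).
#' @param activations Optional pre-computed images x neurons activation
#'   matrix (e.g. synthetic populations); bypasses [encode()].
#' @return A `tuning_table` tibble: `neuron`, `n`, `area`, `mean`, `var`,
#'   `n_trials`, with design attributes.
#' @export
build_tuning_table <- function(bank, layer, probe, activations = NULL) {
  meta <- probe$meta
  ns <- sort(unique(meta$n)); as_ <- sort(unique(meta$area))
  full <- expand.grid(n = ns, area = as_)
  have <- dplyr::distinct(meta, .data$n, .data$area)
  miss <- dplyr::anti_join(full, have, by = c("n", "area"))
  if (nrow(miss) > 0) {
    abort(sprintf("incomplete factorial probe; missing cells: %s",
                  paste(sprintf("(N=%d, A=%d)", miss$n, miss$area),
                        collapse = ", ")),
          class = "numerosense_precondition")
  }
  H <- if (is.null(activations)) encode(probe, bank, layer) else activations
  cell <- interaction(meta$n, meta$area, drop = TRUE)
  mu <- rowsum(H, cell) / as.vector(table(cell))
  vv <- rowsum(H^2, cell) / as.vector(table(cell)) - mu^2
  nn <- as.vector(table(cell))
  key <- do.call(rbind, strsplit(rownames(mu), ".", fixed = TRUE))
  out <- tibble::tibble(
    neuron = rep(seq_len(ncol(H)), each = nrow(mu)),
    n = rep(as.integer(key[, 1]), ncol(H)),
    area = rep(as.integer(key[, 2]), ncol(H)),
    mean = as.vector(mu),
    var = as.vector(pmax(vv, 0)),
    n_trials = rep(nn, ncol(H))
  )
  structure(dplyr::arrange(out, .data$neuron, .data$n, .data$area),
            class = c("tuning_table", class(out)),
            numerosities = ns, area_levels = as_)
}

#' Classify summation-coding (numerosity-sensitive) units
#'
#' Per neuron, ordinary least squares of the (standardized) cell-mean
#' activation on standardized `log2(N)` and `log2(A)`. A unit is
#' numerosity-sensitive when the absolute numerosity coefficient is large,
#' the area coefficient small, and the fit good; the coefficient sign
#' splits increasing (`sensitive+`) from decreasing (`sensitive-`)
#' profiles.
#'
#' @param table A [build_tuning_table()] result.
#' @param theta_n Minimum `|B_numerosity|`.
#' @param theta_a Maximum `|B_area|`.
#' @param theta_r2 Minimum regression R-squared.
#' @return Tibble: `neuron`, `b_n`, `b_a`, `r2`, `class`
#'   (`sensitive+`/`sensitive-`/`none`), `flag`.
#' @export
classify_summation <- function(table, theta_n = 0.10, theta_a = 0.05,
                               theta_r2 = 0.50) {
  wide <- table |>
    dplyr::arrange(.data$neuron, .data$n, .data$area)
  n_neuron <- length(unique(wide$neuron))
  cells <- wide |> dplyr::filter(.data$neuron == wide$neuron[1])
  M <- matrix(wide$mean, ncol = n_neuron)  # cells x neurons
  sds <- apply(M, 2, sd)
  zero_var <- sds < 1e-12
  Ms <- scale(M)
  Ms[, zero_var] <- 0
  X <- cbind(1, scale(log2(cells$n)), scale(log2(cells$area)))
  B <- solve(crossprod(X), crossprod(X, Ms))
  fitted <- X %*% B
  r2 <- 1 - colSums((Ms - fitted)^2) / pmax(colSums(scale(Ms, scale = FALSE)^2), 1e-300)
  r2[zero_var] <- 0
  b_n <- B[2, ]; b_a <- B[3, ]
  cls <- dplyr::case_when(
    zero_var ~ "none",
    abs(b_n) >= theta_n & abs(b_a) <= theta_a & r2 >= theta_r2 & b_n > 0 ~ "sensitive+",
    abs(b_n) >= theta_n & abs(b_a) <= theta_a & r2 >= theta_r2 & b_n < 0 ~ "sensitive-",
    TRUE ~ "none"
  )
  tibble::tibble(neuron = seq_len(n_neuron), b_n = unname(b_n),
                 b_a = unname(b_a), r2 = unname(r2),
                 class = unname(cls),
                 flag = ifelse(zero_var, "zero_variance", NA_character_))
}

#' Classify numerosity-selective units by two-factor ANOVA
#'
#' Per neuron, a balanced two-way ANOVA (numerosity x cumulative area, with
#' interaction) over per-image activations. A unit is selective when the
#' numerosity main effect is significant at `alpha` while neither the area
#' main effect nor the interaction is. The preferred numerosity is the
#' level with maximal marginal mean activation.
#'
#' @param bank,layer Network components.
#' @param probe Replicated factorial `num_corpus` (>= 2 images per cell).
#' @param alpha Significance level.
#' @param activations Optional pre-computed images x neurons activation
#'   matrix; bypasses [encode()].
#' @return Tibble: `neuron`, `f_n`, `f_a`, `f_int`, `p_n`, `p_a`, `p_int`,
#'   `class` (`selective`/`none`), `preferred_n`, `flag`.
#' @export
classify_selective <- function(bank, layer, probe, alpha = 0.01,
                               activations = NULL) {
  meta <- probe$meta
  counts <- table(meta$n, meta$area)
  if (any(counts < 2)) {
    abort("need >= 2 replicates per (numerosity, area) cell for the ANOVA error term",
          class = "numerosense_precondition")
  }
  if (length(unique(as.vector(counts))) != 1) {
    abort("unbalanced probe design", class = "numerosense_precondition")
  }
  H <- if (is.null(activations)) encode(probe, bank, layer) else activations
  a <- length(unique(meta$n)); b <- length(unique(meta$area))
  r <- as.vector(counts)[1]
  N <- nrow(H)
  grand <- colMeans(H)
  dev <- sweep(H, 2, grand)
  ss_tot <- colSums(dev^2)
  mean_by <- function(f) sweep(rowsum(H, f), 1, as.vector(table(f)), "/")
  mn <- mean_by(factor(meta$n))        # a x neurons
  ma <- mean_by(factor(meta$area))     # b x neurons
  mc <- mean_by(interaction(meta$n, meta$area, drop = TRUE))  # ab x neurons
  ss_n <- r * b * colSums(sweep(mn, 2, grand)^2)
  ss_a <- r * a * colSums(sweep(ma, 2, grand)^2)
  ss_cells <- r * colSums(sweep(mc, 2, grand)^2)
  ss_int <- pmax(ss_cells - ss_n - ss_a, 0)
  ss_err <- pmax(ss_tot - ss_cells, 0)
  df_n <- a - 1; df_a <- b - 1; df_int <- (a - 1) * (b - 1)
  df_err <- a * b * (r - 1)
  mse <- ss_err / df_err
  f_n <- (ss_n / df_n) / mse
  f_a <- (ss_a / df_a) / mse
  f_int <- (ss_int / df_int) / mse
  p_n <- pf(f_n, df_n, df_err, lower.tail = FALSE)
  p_a <- pf(f_a, df_a, df_err, lower.tail = FALSE)
  p_int <- pf(f_int, df_int, df_err, lower.tail = FALSE)
  zero_var <- ss_tot < 1e-12
  selective <- !zero_var & p_n < alpha & p_a >= alpha & p_int >= alpha
  ns <- sort(unique(meta$n))
  pref <- ns[apply(mn, 2, which.max)]
  tibble::tibble(
    neuron = seq_len(ncol(H)),
    f_n = unname(f_n), f_a = unname(f_a), f_int = unname(f_int),
    p_n = unname(p_n), p_a = unname(p_a), p_int = unname(p_int),
    class = unname(ifelse(selective, "selective", "none")),
    preferred_n = unname(ifelse(selective, pref, NA_integer_)),
    flag = unname(ifelse(zero_var, "zero_variance", NA_character_))
  )
}

#' Pool tuning curves of numerosity-selective units
#'
#' Each selective unit's tuning curve (marginal mean activation per
#' numerosity) is min-max normalised to `[0, 1]`; curves sharing a
#' preferred numerosity are averaged. A second view re-indexes each curve
#' by numerical distance from the preferred level, and the frequency
#' distribution of preferred numerosities is tallied.
#'
#' @param profiles A [classify_selective()] result.
#' @param table The matching [build_tuning_table()] result.
#' @return A `tuning_pool` list: `curves` (preferred_n, n, response,
#'   n_neurons), `distance_curves` (distance, response, n_obs),
#'   `preferred_freq` (preferred_n, count).
#' @export
pool_tuning_curves <- function(profiles, table) {
  sel <- dplyr::filter(profiles, .data$class == "selective")
  if (nrow(sel) == 0) {
    warn("no numerosity-selective units; returning empty pooled curves")
    return(structure(list(
      curves = tibble::tibble(preferred_n = integer(), n = integer(),
                              response = numeric(), n_neurons = integer()),
      distance_curves = tibble::tibble(distance = integer(),
                                       response = numeric(), n_obs = integer()),
      preferred_freq = tibble::tibble(preferred_n = integer(), count = integer())
    ), class = "tuning_pool"))
  }
  curves <- table |>
    dplyr::filter(.data$neuron %in% sel$neuron) |>
    dplyr::group_by(.data$neuron, .data$n) |>
    dplyr::summarise(resp = mean(.data$mean), .groups = "drop_last") |>
    dplyr::mutate(resp = (.data$resp - min(.data$resp)) /
                    max(max(.data$resp) - min(.data$resp), 1e-300)) |>
    dplyr::ungroup() |>
    dplyr::left_join(dplyr::select(sel, "neuron", "preferred_n"), by = "neuron")
  pooled <- curves |>
    dplyr::group_by(.data$preferred_n, .data$n) |>
    dplyr::summarise(response = mean(.data$resp),
                     n_neurons = dplyr::n(), .groups = "drop")
  dist <- curves |>
    dplyr::mutate(distance = .data$n - .data$preferred_n) |>
    dplyr::group_by(.data$distance) |>
    dplyr::summarise(response = mean(.data$resp), n_obs = dplyr::n(),
                     .groups = "drop")
  freq <- sel |> dplyr::count(.data$preferred_n, name = "count")
  structure(list(curves = pooled, distance_curves = dist,
                 preferred_freq = freq),
            class = "tuning_pool")
}

#' @export
print.tuning_pool <- function(x, ...) {
  cat(sprintf("<tuning_pool  %d selective neurons across %d preferred levels>\n",
              sum(x$preferred_freq$count), nrow(x$preferred_freq)))
  invisible(x)
}
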
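#' Artificial-life ecosystem of evolving foragers
#'
#' A grid world in which a fixed population of agents, each controlled by a
#' recurrent, asymmetrically connected neural network, forages for food.
#' Each cell holds a food quantity in 0..9, sensed as a binary vector with
#' that many randomly chosen active units (a size-free quantity code). Agents
#' see the current cell and the three cells of the row directly ahead, and
#' can turn left/right, move forward, or eat. A genetic algorithm (fitness =
#' food-collection rate; crossover plus small mutations) replaces the weaker
#' of two randomly drawn parents with their child at every iteration, so
#' quantity-sensitive foraging — and with it quantity comparison — can
#' emerge from selection pressure alone.
#'
#' @name evolife
NULL

.AGENT_ACTIONS <- c("left", "right", "forward", "eat")

#' Encode a food quantity as a 9-unit binary vector
#'
#' Exactly `n` of the nine units are active, at uniformly random positions.
#' This code carries quantity without any object-size confound.
#'
#' @param n Food quantity in 0..9.
#' @return Integer vector of length 9 with `n` ones.
#' @export
encode_food <- function(n) {
  if (!is.numeric(n) || length(n) != 1 || n < 0 || n > 9 || n != round(n)) {
    abort("food quantity must be a single integer in 0..9",
          class = "numerosense_precondition")
  }
  cpp_encode_food(as.integer(n))
}

#' Create a fresh ecosystem with a random population
#'
#' @param side Grid side (cells).
#' @param n_agents Population size (held constant forever after).
#' @param hidden_range Bounds of the evolvable hidden-layer size.
#' @param init_weight_sd Standard deviation of initial genome weights.
#' @param food_zero_prob Probability that a cell is empty; non-empty cells
#'   hold a uniform quantity in 1..9. Sparse food makes steering toward
#'   sensed food (and hence quantity comparison) adaptive.
#' @param seed Optional seed.
#' @return An `ecosystem`: `grid` (food matrix), `genomes`
#'   (genes x agents), `hidden_sizes`, `pos_r`/`pos_c` (0-based),
#'   `headings` (0 = north), `collected`, `age`, `params`.
#' @export
create_ecosystem <- function(side = 100L, n_agents = 200L,
                             hidden_range = c(2L, 20L),
                             init_weight_sd = 0.5, food_zero_prob = 0.75,
                             seed = NULL) {
  glen <- cpp_genome_length()
  with_seed(seed, {
    structure(list(
      grid = matrix(sample(0:9, side * side, replace = TRUE,
                           prob = c(food_zero_prob,
                                    rep((1 - food_zero_prob) / 9, 9))),
                    side, side),
      genomes = matrix(rnorm(glen * n_agents, sd = init_weight_sd), glen, n_agents),
      hidden_sizes = sample(hidden_range[1]:hidden_range[2], n_agents,
                            replace = TRUE),
      pos_r = sample.int(side, n_agents, replace = TRUE) - 1L,
      pos_c = sample.int(side, n_agents, replace = TRUE) - 1L,
      headings = sample(0:3, n_agents, replace = TRUE),
      collected = numeric(n_agents),
      age = integer(n_agents),
      pending = list(delay = integer(), r = integer(), c = integer()),
      params = list(side = side, n_agents = n_agents,
                    hidden_range = as.integer(hidden_range),
                    food_zero_prob = food_zero_prob),
      trace = tibble::tibble(iteration = integer(), mean_fitness = numeric()),
      iterations_run = 0L
    ), class = "ecosystem")
  })
}

#' @export
print.ecosystem <- function(x, ...) {
  cat(sprintf("<ecosystem  %dx%d grid  %d agents  %d iterations run>\n",
              x$params$side, x$params$side, x$params$n_agents,
              x$iterations_run))
  invisible(x)
}

#' Sensory input of one agent
#'
#' Concatenated 9-unit food codes of the four visible cells in fixed order:
#' current cell, ahead-left, ahead, ahead-right (toroidal wrap).
#'
#' @param eco An `ecosystem`.
#' @param agent Agent index.
#' @return Integer vector of length 36.
#' @export
sense <- function(eco, agent) {
  cells <- cpp_visible_cells(nrow(eco$grid), ncol(eco$grid),
                             eco$pos_r[agent], eco$pos_c[agent],
                             eco$headings[agent], TRUE)
  as.integer(unlist(lapply(seq_len(4), function(k) {
    encode_food(eco$grid[cells[k, 1] + 1L, cells[k, 2] + 1L])
  })))
}

#' Single controller update of an agent network
#'
#' One recurrent-state update followed by action selection (argmax over the
#' four effector activations, uniform random tie-break).
#'
#' @param genome Numeric genome vector.
#' @param hidden_size Active hidden units.
#' @param input 36-unit sensory vector.
#' @param hidden_state Current hidden state (padded/truncated as needed).
#' @return List: `action` (one of "left", "right", "forward", "eat"),
#'   `hidden` (new state), `effectors` (the four activations).
#' @export
step_agent <- function(genome, hidden_size, input, hidden_state = NULL) {
  if (is.null(hidden_state)) hidden_state <- numeric(0)
  res <- cpp_step_network(genome, as.integer(hidden_size),
                          as.numeric(input), as.numeric(hidden_state))
  res$action <- .AGENT_ACTIONS[res$action]
  res
}

#' Food-collection rate of an agent
#'
#' @param collected Food units collected over the window.
#' @param steps Window length in time-steps.
#' @return Rate in food units per time-step.
#' @export
agent_fitness <- function(collected, steps) {
  if (any(steps <= 0)) abort("zero-length fitness window",
                             class = "numerosense_precondition")
  collected / steps
}

#' Run the ecosystem under the genetic algorithm
#'
#' Each iteration, every agent senses and acts once; then two random
#' fitness-eligible parents are drawn and the weaker is replaced by their
#' child (uniform per-gene crossover, additive Gaussian mutation, occasional
#' hidden-size mutation). Eaten cells refill with a fresh uniform food draw
#' after a fixed delay. The population size never changes.
#'
#' @param eco An `ecosystem`.
#' @param iterations Number of ecosystem updates.
#' @param regrow_delay Iterations before an eaten cell refills.
#' @param burn_in Minimum age (steps) before an agent can be a parent.
#' @param mut_sd,mut_prob Additive Gaussian mutation scale and per-gene
#'   probability.
#' @param hmut_prob Probability of a +/-1 hidden-size mutation.
#' @param trace_every Record mean population fitness every this many
#'   iterations.
#' @param wrap Toroidal wrap (`TRUE`) or walled grid (`FALSE`, default).
#'   Walls match the test-arena kinematics and keep blind straight-line
#'   foraging from being a sensing-free optimum.
#' @param seed Optional seed.
#' @return The updated `ecosystem`, with `trace` extended.
#' @export
evolve <- function(eco, iterations, regrow_delay = 100L, burn_in = 500L,
                   mut_sd = 0.1, mut_prob = 0.03, hmut_prob = 0.02,
                   trace_every = 1000L, wrap = FALSE, seed = NULL) {
  stopifnot(inherits(eco, "ecosystem"), iterations >= 0)
  if (iterations == 0) return(eco)
  with_seed(seed, {
    res <- cpp_evolve(eco$grid + 0L, eco$genomes + 0,
                      eco$hidden_sizes + 0L, eco$pos_r + 0L, eco$pos_c + 0L,
                      eco$headings + 0L, eco$collected + 0, eco$age + 0L,
                      as.integer(iterations), as.integer(regrow_delay),
                      as.integer(burn_in), mut_sd, mut_prob, hmut_prob,
                      eco$params$hidden_range[1], eco$params$hidden_range[2],
                      as.integer(trace_every), eco$params$food_zero_prob,
                      isTRUE(wrap), eco$pending$delay + 0L, eco$pending$r + 0L,
                      eco$pending$c + 0L)
    eco$grid <- res$grid
    eco$genomes <- res$genomes
    eco$hidden_sizes <- res$hidden_sizes
    eco$pos_r <- res$pos_r; eco$pos_c <- res$pos_c
    eco$headings <- res$headings
    eco$collected <- res$collected; eco$age <- res$age
    eco$pending <- list(delay = res$pending_delay, r = res$pending_r,
                        c = res$pending_c)
    eco$trace <- dplyr::bind_rows(
      eco$trace,
      tibble::tibble(iteration = eco$iterations_run + res$trace_iter,
                     mean_fitness = res$trace_fitness))
    eco$iterations_run <- eco$iterations_run + as.integer(iterations)
    eco
  })
}

#' Quantity-comparison test battery
#'
#' Each tested agent is moved to a walled 3x3 arena whose top-left and
#' top-right cells hold two distinct food quantities; starting from the
#' centre (facing the baited row, where it senses both quantities) it moves
#' freely until it steps onto a baited cell. A choice is correct when the
#' selected cell holds the larger quantity. All ordered distinct pairs of
#' `quantities` are administered `reps` times (9 quantities give
#' 72 x 50 = 3600 trials per agent).
#'
#' @param eco An `ecosystem`, or a single genome vector.
#' @param agents Agent indices to test (default: all).
#' @param quantities Food quantities used in the pairs.
#' @param reps Repetitions per ordered pair.
#' @param step_cap Steps before a trial times out.
#' @param policy `"network"`, `"random"` (uniform random actions; chance
#'   baseline) or `"oracle"` (greedy walk to the larger quantity; validates
#'   the trial bookkeeping).
#' @param hidden_size Needed only when `eco` is a bare genome.
#' @param seed Optional seed.
#' @return Tibble: `agent`, `left`, `right`, `choice` ("left"/"right"/NA),
#'   `correct` (NA on timeout), `rt` (time-steps), `timeout`.
#' @export
test_comparison <- function(eco, agents = NULL, quantities = 1:9, reps = 50L,
                            step_cap = 50L,
                            policy = c("network", "random", "oracle"),
                            hidden_size = NULL, seed = NULL) {
  policy <- match.arg(policy)
  grid_pairs <- expand.grid(left = quantities, right = quantities)
  grid_pairs <- grid_pairs[grid_pairs$left != grid_pairs$right, ]
  left <- rep(grid_pairs$left, times = reps)
  right <- rep(grid_pairs$right, times = reps)
  if (inherits(eco, "ecosystem")) {
    if (is.null(agents)) agents <- seq_len(eco$params$n_agents)
    genomes <- lapply(agents, function(a) eco$genomes[, a])
    hs <- eco$hidden_sizes[agents]
  } else {
    stopifnot(!is.null(hidden_size))
    genomes <- list(as.numeric(eco))
    hs <- hidden_size
    agents <- 1L
  }
  with_seed(seed, {
    purrr::map_dfr(seq_along(genomes), function(i) {
      m <- cpp_test_agent(genomes[[i]], as.integer(hs[i]),
                          as.integer(left), as.integer(right),
                          as.integer(step_cap),
                          switch(policy, network = 0L, random = 1L,
                                 oracle = 2L))
      tibble::tibble(
        agent = agents[i],
        left = m[, 1], right = m[, 2],
        choice = dplyr::case_when(m[, 3] == 1 ~ "left",
                                  m[, 3] == 2 ~ "right",
                                  TRUE ~ NA_character_),
        correct = dplyr::case_when(
          m[, 3] == 1 ~ m[, 1] > m[, 2],
          m[, 3] == 2 ~ m[, 2] > m[, 1],
          TRUE ~ NA),
        rt = m[, 4],
        timeout = m[, 3] == 0
      )
    })
  })
}

#' Distance and size effects in comparison trials
#'
#' Timeout trials are excluded. Accuracy and mean response time are grouped
#' by numerical distance `|left - right|`; accuracy is additionally grouped
#' by pair magnitude `max(left, right)`.
#'
#' @param trials A [test_comparison()] result.
#' @return List of tibbles: `distance` (`distance`, `n`, `accuracy`,
#'   `mean_rt`) and `size` (`size`, `n`, `accuracy`).
#' @export
distance_size_effects <- function(trials) {
  if (nrow(trials) == 0) abort("no trials", class = "numerosense_precondition")
  done <- dplyr::filter(trials, !.data$timeout)
  list(
    distance = done |>
      dplyr::group_by(distance = abs(.data$left - .data$right)) |>
      dplyr::summarise(n = dplyr::n(), accuracy = mean(.data$correct),
                       mean_rt = mean(.data$rt), .groups = "drop"),
    size = done |>
      dplyr::group_by(size = pmax(.data$left, .data$right)) |>
      dplyr::summarise(n = dplyr::n(), accuracy = mean(.data$correct),
                       .groups = "drop")
  )
}

#' Monotonicity profiles of an agent's hidden units
#'
#' Each probe presents a quantity in the cell directly ahead (hidden state
#' reset, one network update); mean activation per quantity is correlated
#' with quantity by Spearman rank correlation. Units with `|rho|` at or
#' above the threshold are classified as monotone increasing or decreasing
#' (summation coding); near-constant units stay unclassified.
#'
#' @param eco An `ecosystem` or a genome vector.
#' @param agent Agent index (when `eco` is an ecosystem).
#' @param values Probe quantities.
#' @param reps Probe repetitions per quantity (random encodings).
#' @param rho_threshold Absolute Spearman correlation required.
#' @param hidden_size Needed only for a bare genome.
#' @param seed Optional seed.
#' @return Tibble: `unit`, `rho`, `class` ("increasing"/"decreasing"/
#'   "unclassified"); mean activations per quantity in the
#'   `activations` attribute (long tibble).
#' @export
analyze_hidden_units <- function(eco, agent = 1L, values = 0:9, reps = 100L,
                                 rho_threshold = 0.9, hidden_size = NULL,
                                 seed = NULL) {
  if (inherits(eco, "ecosystem")) {
    genome <- eco$genomes[, agent]
    hidden_size <- eco$hidden_sizes[agent]
  } else {
    genome <- as.numeric(eco)
    stopifnot(!is.null(hidden_size))
  }
  with_seed(seed, {
    m <- cpp_probe_hidden(genome, as.integer(hidden_size),
                          as.integer(values), as.integer(reps))
  })
  m <- m[, seq_len(hidden_size), drop = FALSE]
  rho <- apply(m, 2, function(col) {
    if (sd(col) < 1e-10) return(NA_real_)
    cor(values, col, method = "spearman")
  })
  acts <- tibble::tibble(
    unit = rep(seq_len(hidden_size), each = length(values)),
    value = rep(values, hidden_size),
    activation = as.vector(m))
  out <- tibble::tibble(
    unit = seq_len(hidden_size),
    rho = rho,
    class = dplyr::case_when(
      is.na(rho) ~ "unclassified",
      rho >= rho_threshold ~ "increasing",
      rho <= -rho_threshold ~ "decreasing",
      TRUE ~ "unclassified")
  )
  attr(out, "activations") <- acts
  out
}
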
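# Agent, ecosystem, and test-battery mechanics at small scale.

glen <- numerosense:::cpp_genome_length()

# genome with a single dominant effector bias (index within 1221..1224:
# left, right, forward, eat)
biased_genome <- function(action) {
  g <- numeric(glen)
  g[glen - 4L + action] <- 10
  g
}

test_that("food encoding has exactly n active units at uniform positions", {
  set.seed(1)
  expect_equal(encode_food(0), rep(0L, 9))
  expect_equal(encode_food(9), rep(1L, 9))
  expect_error(encode_food(10), "0..9")
  expect_error(encode_food(-1), class = "numerosense_precondition")
  draws <- replicate(10000, encode_food(4))
  expect_true(all(colSums(draws) == 4))
  # each unit active close to 4/9 of the time (brute-force binomial check)
  rate <- rowMeans(draws)
  expect_true(all(abs(rate - 4 / 9) < 3 * sqrt((4 / 9) * (5 / 9) / 10000) + 0.01))
})

test_that("sensing concatenates the four visible cells in fixed order", {
  eco <- create_ecosystem(side = 10L, n_agents = 1L, seed = 2)
  eco$grid[, ] <- 0L
  eco$pos_r[1] <- 5L; eco$pos_c[1] <- 5L; eco$headings[1] <- 0L  # facing north
  # blocks: current (6,6), ahead-left (5,5), ahead (5,6), ahead-right (5,7)
  eco$grid[6, 6] <- 9L
  eco$grid[5, 5] <- 9L
  x <- sense(eco, 1)
  expect_length(x, 36L)
  expect_equal(sum(x[1:9]), 9)
  expect_equal(sum(x[10:18]), 9)
  expect_equal(sum(x[19:36]), 0)
  # empty neighbourhood gives the zero vector
  eco$grid[, ] <- 0L
  expect_equal(sense(eco, 1), rep(0L, 36))
  # deterministic under a fixed stream
  eco$grid[5, 6] <- 5L
  s1 <- withr::with_seed(7, sense(eco, 1))
  s2 <- withr::with_seed(7, sense(eco, 1))
  expect_identical(s1, s2)
})

test_that("field of view wraps on the torus", {
  eco <- create_ecosystem(side = 6L, n_agents = 1L, seed = 3)
  eco$grid[, ] <- 0L
  eco$pos_r[1] <- 0L; eco$pos_c[1] <- 0L; eco$headings[1] <- 0L
  eco$grid[6, 6] <- 7L  # wrapped ahead-left cell (row -1, col -1)
  x <- sense(eco, 1)
  expect_equal(sum(x[10:18]), 7)
})

test_that("a dominant effector bias forces the corresponding action", {
  for (a in 1:4) {
    res <- step_agent(biased_genome(a), 5L, rep(0, 36))
    expect_equal(res$action, c("left", "right", "forward", "eat")[a])
  }
  res <- step_agent(biased_genome(4), 5L, rep(1, 36))
  expect_length(res$effectors, 4L)
  expect_true(all(res$effectors >= 0 & res$effectors <= 1))
})

test_that("eating transfers the cell's food and empties it", {
  eco <- create_ecosystem(side = 8L, n_agents = 2L, seed = 4)
  eco$genomes[, 1] <- biased_genome(4)  # always eat
  eco$genomes[, 2] <- biased_genome(1)  # always turn (eats nothing)
  eco$pos_r <- c(3L, 6L); eco$pos_c <- c(3L, 6L)
  eco$grid[4, 4] <- 5L
  eco2 <- evolve(eco, 1, burn_in = 10000L, seed = 5)
  expect_equal(eco2$collected[1], 5)
  expect_equal(eco2$grid[4, 4], 0L)
  expect_equal(eco2$collected[2], 0)
  # conservation: collected food equals food removed from the grid
  expect_equal(sum(eco$grid) - sum(eco2$grid), sum(eco2$collected))
})

test_that("forward movement is blocked by walls and wraps on the torus option", {
  eco <- create_ecosystem(side = 5L, n_agents = 1L, seed = 6)
  eco$genomes[, 1] <- biased_genome(3)  # always forward
  eco$pos_r[1] <- 0L; eco$pos_c[1] <- 2L; eco$headings[1] <- 0L  # north
  walls <- evolve(eco, 1, burn_in = 10000L, seed = 7)
  expect_equal(walls$pos_r[1], 0L)  # blocked at the wall
  torus <- evolve(eco, 1, burn_in = 10000L, wrap = TRUE, seed = 7)
  expect_equal(torus$pos_r[1], 4L)
  expect_equal(torus$pos_c[1], 2L)
})

test_that("fitness is the food-collection rate", {
  expect_equal(agent_fitness(12, 100), 0.12)
  expect_equal(agent_fitness(0, 50), 0)
  expect_error(agent_fitness(3, 0), class = "numerosense_precondition")
})

test_that("the genetic algorithm preserves population size and degenerates correctly", {
  eco <- create_ecosystem(side = 20L, n_agents = 12L, seed = 8)
  expect_identical(evolve(eco, 0), eco)

  # zero mutation with a clonal population: children equal the shared genome
  g0 <- eco$genomes[, 1]
  eco$genomes[] <- g0
  eco$hidden_sizes[] <- 6L
  eco2 <- evolve(eco, 300, burn_in = 0L, mut_sd = 0, mut_prob = 0,
                 hmut_prob = 0, seed = 9)
  expect_equal(ncol(eco2$genomes), 12L)
  expect_true(all(apply(eco2$genomes, 2, function(g) identical(g, g0))))
  expect_true(all(eco2$hidden_sizes == 6L))

  # with mutation on, population size still never changes
  eco3 <- evolve(eco, 500, burn_in = 0L, seed = 10)
  expect_equal(ncol(eco3$genomes), 12L)
  expect_equal(length(eco3$collected), 12L)
  expect_true(all(eco3$hidden_sizes >= 2 & eco3$hidden_sizes <= 20))
})

test_that("evolution is bit-reproducible under a fixed seed", {
  e1 <- evolve(create_ecosystem(side = 20L, n_agents = 10L, seed = 11),
               400, burn_in = 0L, seed = 12)
  e2 <- evolve(create_ecosystem(side = 20L, n_agents = 10L, seed = 11),
               400, burn_in = 0L, seed = 12)
  expect_identical(e1$genomes, e2$genomes)
  expect_identical(e1$grid, e2$grid)
  expect_identical(e1$trace, e2$trace)
})

test_that("the test battery administers exactly the stated protocol", {
  g <- biased_genome(3)
  tb <- test_comparison(g, hidden_size = 4L, quantities = 1:9, reps = 50L,
                        seed = 13)
  expect_equal(nrow(tb), 72L * 50L)   # ordered distinct pairs x repetitions
  expect_equal(nrow(dplyr::distinct(tb, left, right)), 72L)
  expect_true(all(tb$left != tb$right))
  # forced-forward agents reach the unbaited top-middle cell and stall
  expect_true(all(tb$timeout))
})

test_that("a greedy oracle agent is always correct; a random walker is at chance", {
  ob <- test_comparison(numeric(glen), hidden_size = 2L, policy = "oracle",
                        reps = 2L, seed = 14)
  expect_true(all(!ob$timeout))
  expect_true(all(ob$correct))
  expect_true(all(ob$rt <= 5))

  rnd <- test_comparison(numeric(glen), hidden_size = 2L, policy = "random",
                         reps = 50L, seed = 15)
  done <- rnd[!rnd$timeout, ]
  se <- sqrt(0.25 / nrow(done))
  expect_lt(abs(mean(done$correct) - 0.5), 2 * se + 0.005)
})

test_that("distance and size effects aggregate trials correctly", {
  tr <- tibble::tibble(
    agent = 1L,
    left = c(1L, 1L, 2L, 9L, 3L, 5L),
    right = c(2L, 3L, 4L, 1L, 2L, 4L),
    choice = c("right", "right", "left", "left", "left", "right"),
    correct = c(TRUE, TRUE, FALSE, TRUE, TRUE, FALSE),
    rt = c(4L, 6L, 10L, 3L, 5L, 7L),
    timeout = FALSE)
  eff <- distance_size_effects(tr)
  d1 <- eff$distance[eff$distance$distance == 1, ]
  expect_equal(d1$n, 3L)                      # pairs (1,2), (3,2), (5,4)
  expect_equal(d1$accuracy, 2 / 3)
  expect_equal(d1$mean_rt, mean(c(4, 5, 7)))
  d2 <- eff$distance[eff$distance$distance == 2, ]
  expect_equal(d2$accuracy, c(mean(c(TRUE, FALSE))))
  s9 <- eff$size[eff$size$size == 9, ]
  expect_equal(s9$n, 1L)
  expect_equal(s9$accuracy, 1)

  all_right <- dplyr::mutate(tr, correct = TRUE)
  expect_true(all(distance_size_effects(all_right)$distance$accuracy == 1))
})

test_that("hidden-unit probes classify monotone units like a brute-force Spearman", {
  # unit 1 pools the 9 input lines of the ahead cell: activation rises with
  # the presented quantity
  g <- numeric(glen)
  g[(0 * 36 + 19):(0 * 36 + 27)] <- 1   # W_in row for hidden unit 1, block 3
  prof <- analyze_hidden_units(g, hidden_size = 3L, values = 0:9, reps = 200L,
                               seed = 16)
  expect_equal(prof$class[1], "increasing")
  expect_equal(prof$class[2], "unclassified")  # untouched unit: constant

  acts <- attr(prof, "activations")
  m1 <- acts$activation[acts$unit == 1]
  rho_oracle <- cor(rank(0:9), rank(m1))
  expect_equal(prof$rho[1], rho_oracle, tolerance = 1e-12)

  # decreasing unit: negative pooling
  g2 <- numeric(glen)
  g2[(0 * 36 + 19):(0 * 36 + 27)] <- -1
  prof2 <- analyze_hidden_units(g2, hidden_size = 2L, seed = 17)
  expect_equal(prof2$class[1], "decreasing")
})
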
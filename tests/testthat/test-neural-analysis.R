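# Coding-profile analyses validated against planted ground truth and
# brute-force statistical oracles.

plant_population <- function(meta, seed = 1, noise = 0.02,
                             n_sum = 6, n_sel = 6, n_noise = 8) {
  set.seed(seed)
  zn <- log2(meta$n)
  za <- log2(meta$area)
  cols <- list()
  labels <- character(0)
  for (i in seq_len(n_sum)) {
    slope <- sample(c(-0.1, 0.1), 1)
    cols[[length(cols) + 1]] <- 0.5 + slope * scale(zn)[, 1]
    labels <- c(labels, if (slope > 0) "sensitive+" else "sensitive-")
  }
  prefs <- rep_len(sort(unique(meta$n)), n_sel)
  for (i in seq_len(n_sel)) {
    cols[[length(cols) + 1]] <-
      0.2 + 0.7 * exp(-(log2(meta$n) - log2(prefs[i]))^2 / (2 * 0.35^2))
    labels <- c(labels, paste0("selective", prefs[i]))
  }
  for (i in seq_len(n_noise)) {
    cols[[length(cols) + 1]] <- rep(0.4, nrow(meta))
    labels <- c(labels, "none")
  }
  H <- do.call(cbind, cols) + matrix(rnorm(nrow(meta) * length(cols), 0, noise),
                                     nrow(meta))
  list(H = pmin(pmax(H, 0), 1), labels = labels, prefs = prefs)
}

test_that("tuning tables are complete, conservative, and correct for planted units", {
  probe <- fake_probe(c(1, 2, 4, 8), c(32, 64), reps = 25)
  pop <- plant_population(probe$meta, n_sum = 2, n_sel = 2, n_noise = 1)
  tt <- build_tuning_table(NULL, NULL, probe, activations = pop$H)
  expect_s3_class(tt, "tuning_table")
  expect_equal(nrow(tt), 4 * 2 * ncol(pop$H))
  expect_true(all(tt$n_trials == 25))
  # a constant unit has a flat table
  flat <- tt[tt$neuron == 5, ]
  expect_lt(max(flat$mean) - min(flat$mean), 0.02)
  # a monotone log-N unit increases in N and is flat in area
  unit1 <- tt[tt$neuron == 1, ]
  by_n <- tapply(unit1$mean, unit1$n, mean)
  expect_true(all(diff(by_n) * sign(by_n[4] - by_n[1]) > 0))
})

test_that("an incomplete factorial probe is rejected with the missing cells named", {
  probe <- fake_probe(c(1, 2), c(32, 64), reps = 3)
  probe$meta <- probe$meta[!(probe$meta$n == 2 & probe$meta$area == 64), ]
  H <- matrix(runif(nrow(probe$meta) * 2), ncol = 2)
  expect_error(build_tuning_table(NULL, NULL, probe, activations = H),
               "N=2, A=64", class = "numerosense_precondition")
})

test_that("summation classification recovers planted monotone units", {
  probe <- fake_probe(c(1, 2, 4, 8, 16, 32), c(32, 64), reps = 30)
  pop <- plant_population(probe$meta, seed = 2)
  tt <- build_tuning_table(NULL, NULL, probe, activations = pop$H)
  prof <- classify_summation(tt)
  planted <- pop$labels[1:6]
  expect_equal(prof$class[1:6], planted)
  # flat/noise units are never classified as sensitive
  expect_true(all(prof$class[13:20] == "none"))

  # an area-driven unit is excluded by the |B_area| criterion
  area_unit <- 0.5 + 0.12 * scale(log2(probe$meta$area))[, 1]
  tt2 <- build_tuning_table(NULL, NULL, probe,
                            activations = cbind(area_unit, pop$H[, 1]))
  prof2 <- classify_summation(tt2)
  expect_equal(prof2$class[1], "none")
  expect_gt(abs(prof2$b_a[1]), 0.05)
})

test_that("summation regression equals the least-squares oracle to 1e-8", {
  probe <- fake_probe(c(1, 2, 4, 8), c(32, 64, 128), reps = 5)
  set.seed(3)
  H <- matrix(runif(nrow(probe$meta) * 5), ncol = 5)
  tt <- build_tuning_table(NULL, NULL, probe, activations = H)
  prof <- classify_summation(tt)
  for (j in 1:5) {
    cell <- tt[tt$neuron == j, ]
    # brute-force normal equations on standardized variables
    X <- cbind(1, scale(log2(cell$n)), scale(log2(cell$area)))
    y <- scale(cell$mean)[, 1]
    beta <- solve(t(X) %*% X, t(X) %*% y)
    expect_equal(prof$b_n[j], beta[2], tolerance = 1e-8)
    expect_equal(prof$b_a[j], beta[3], tolerance = 1e-8)
    fit <- lm(y ~ X - 1)
    expect_equal(prof$r2[j], summary(fit)$r.squared, tolerance = 1e-8)
  }
})

test_that("selectivity ANOVA recovers planted bell-tuned units and rejects area units", {
  probe <- fake_probe(1:5, c(32, 64), reps = 50)
  set.seed(4)
  zn <- log2(probe$meta$n)
  bell <- 0.2 + 0.7 * exp(-(zn - log2(3))^2 / (2 * 0.3^2)) +
    rnorm(nrow(probe$meta), 0, 0.02)
  area_unit <- 0.3 + 0.3 * (probe$meta$area == 64) + rnorm(nrow(probe$meta), 0, 0.02)
  flat <- rep(0.5, nrow(probe$meta))
  H <- cbind(bell, area_unit, flat)
  prof <- classify_selective(NULL, NULL, probe, activations = H)
  expect_equal(prof$class, c("selective", "none", "none"))
  expect_equal(prof$preferred_n[1], 3L)
  expect_equal(prof$flag[3], "zero_variance")
})

test_that("ANOVA F statistics equal stats::aov to 1e-8 on a balanced design", {
  probe <- fake_probe(c(2, 4, 8), c(32, 64), reps = 6)
  set.seed(5)
  H <- matrix(runif(nrow(probe$meta) * 3), ncol = 3)
  prof <- classify_selective(NULL, NULL, probe, activations = H)
  for (j in 1:3) {
    dat <- data.frame(y = H[, j], n = factor(probe$meta$n),
                      a = factor(probe$meta$area))
    sm <- summary(stats::aov(y ~ n * a, dat))[[1]]
    rownames(sm) <- trimws(rownames(sm))
    expect_equal(prof$f_n[j], sm["n", "F value"], tolerance = 1e-8)
    expect_equal(prof$f_a[j], sm["a", "F value"], tolerance = 1e-8)
    expect_equal(prof$f_int[j], sm["n:a", "F value"], tolerance = 1e-8)
    expect_equal(prof$p_n[j], sm["n", "Pr(>F)"], tolerance = 1e-8)
  }
})

test_that("replicate-free probes are rejected (no ANOVA error term)", {
  probe <- fake_probe(c(1, 2), c(32, 64), reps = 1)
  expect_error(classify_selective(NULL, NULL, probe,
                                  activations = matrix(runif(8), ncol = 2)),
               class = "numerosense_precondition")
})

test_that("planted coding types are recovered at >= 95% under low noise", {
  probe <- fake_probe(c(1, 2, 4, 8, 16, 32), c(32, 64), reps = 30)
  pop <- plant_population(probe$meta, seed = 6, noise = 0.02,
                          n_sum = 10, n_sel = 0, n_noise = 10)
  tt <- build_tuning_table(NULL, NULL, probe, activations = pop$H)
  prof <- classify_summation(tt)
  hits <- sum(prof$class == pop$labels)
  expect_gte(hits / length(pop$labels), 0.95)

  probe2 <- fake_probe(1:5, c(32, 64), reps = 50)
  pop2 <- plant_population(probe2$meta, seed = 7, noise = 0.02,
                           n_sum = 0, n_sel = 10, n_noise = 10)
  prof2 <- classify_selective(NULL, NULL, probe2, activations = pop2$H)
  planted_sel <- startsWith(pop2$labels, "selective")
  hits2 <- sum((prof2$class == "selective") == planted_sel)
  expect_gte(hits2 / length(pop2$labels), 0.95)
})

test_that("classification is invariant to neuron order", {
  probe <- fake_probe(c(1, 2, 4, 8), c(32, 64), reps = 20)
  pop <- plant_population(probe$meta, seed = 8, n_sum = 4, n_sel = 3, n_noise = 3)
  perm <- sample(ncol(pop$H))
  tt1 <- build_tuning_table(NULL, NULL, probe, activations = pop$H)
  tt2 <- build_tuning_table(NULL, NULL, probe, activations = pop$H[, perm])
  c1 <- classify_summation(tt1)$class
  c2 <- classify_summation(tt2)$class
  expect_equal(c2, c1[perm])
})

test_that("tuning-curve pooling normalises, aligns, and conserves counts", {
  probe <- fake_probe(1:5, c(32, 64), reps = 40)
  pop <- plant_population(probe$meta, seed = 9, n_sum = 0, n_sel = 7, n_noise = 3)
  tt <- build_tuning_table(NULL, NULL, probe, activations = pop$H)
  prof <- classify_selective(NULL, NULL, probe, activations = pop$H)
  pool <- pool_tuning_curves(prof, tt)
  n_sel <- sum(prof$class == "selective")
  expect_equal(sum(pool$preferred_freq$count), n_sel)
  # every pooled curve peaks at 1 at its preferred numerosity
  peaks <- pool$curves |>
    dplyr::group_by(preferred_n) |>
    dplyr::summarise(peak_n = n[which.max(response)],
                     peak = max(response))
  expect_true(all(abs(peaks$peak - 1) < 1e-9 |
                    pool$preferred_freq$count[match(peaks$preferred_n,
                                                    pool$preferred_freq$preferred_n)] > 1))
  # distance view is defined at distance 0 with the maximal mean response
  d0 <- pool$distance_curves$response[pool$distance_curves$distance == 0]
  expect_equal(d0, max(pool$distance_curves$response))

  # a single selective neuron pools to its own normalised curve
  one <- prof[prof$class == "selective", ][1, ]
  pool1 <- pool_tuning_curves(prof[prof$neuron == one$neuron, ], tt)
  own <- tt[tt$neuron == one$neuron, ] |>
    dplyr::group_by(n) |>
    dplyr::summarise(resp = mean(mean))
  norm <- (own$resp - min(own$resp)) / (max(own$resp) - min(own$resp))
  expect_equal(pool1$curves$response, norm, tolerance = 1e-9)

  # empty selective set yields a warning and empty outputs
  none <- prof |> dplyr::mutate(class = "none")
  expect_warning(p0 <- pool_tuning_curves(none, tt))
  expect_equal(nrow(p0$curves), 0L)
})
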
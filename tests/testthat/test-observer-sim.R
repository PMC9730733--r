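test_that("trial budgets reproduce the published dataset sizes", {
  expect_identical(triplet_budget(60, 3, 4), 2947L)
  expect_identical(triplet_budget(60, 3, 8), 5895L)
  expect_identical(triplet_budget(60, 3, 2), 1473L)  # floor(360 * ln 60)
  expect_error(triplet_budget(2, 1, 4), ">= 3")
})

test_that("the rule-of-thumb budget is ceil(2 d n log2 n) and monotone", {
  expect_identical(rule_of_thumb_budget(8, 1), 48L)
  expect_identical(rule_of_thumb_budget(60, 3), 2127L)  # ceil(2126.5...)
  grid <- expand.grid(n = c(5, 10, 20), d = 1:3)
  b <- mapply(rule_of_thumb_budget, grid$n, grid$d)
  expect_true(all(mapply(rule_of_thumb_budget, grid$n + 1, grid$d) > b))
  expect_true(all(mapply(rule_of_thumb_budget, grid$n, grid$d + 1) > b))
})

test_that("normal scales are seeded, standard normal in the large-n limit", {
  s1 <- sample_normal_scale(50, 3, seed = 7)
  s2 <- sample_normal_scale(50, 3, seed = 7)
  expect_identical(unclass(s1), unclass(s2))
  expect_false(identical(unclass(s1),
                         unclass(sample_normal_scale(50, 3, seed = 8))))
  expect_equal(dim(s1), c(50L, 3L))
  big <- sample_normal_scale(10000, 2, seed = 1)
  expect_lt(max(abs(colMeans(big))), 0.05)
  expect_lt(max(abs(apply(big, 2, var) - 1)), 0.05)
  expect_error(sample_normal_scale(2, 1), ">= 3")
})

test_that("distance spread is the sd of pairwise distances, homogeneous", {
  # coords (0, 1, 2): distances {1, 1, 2}, sample sd = 1/sqrt(3)
  s <- perceptual_scale(c(0, 1, 2))
  expect_equal(distance_spread(s), sd(c(1, 1, 2)))
  expect_equal(distance_spread(s), 0.5773503, tolerance = 1e-6)
  expect_equal(distance_spread(perceptual_scale(c(0, 2.5, 5))),
               2.5 * distance_spread(s))
  expect_error(distance_spread(perceptual_scale(c(0, 1))), "n >= 3")
  expect_error(distance_spread(perceptual_scale(c(1, 1, 1))), "degenerate")
})

test_that("judgments follow the noisy decision rule", {
  scale <- perceptual_scale(matrix(c(0, 1, 3, 0, 0, 0), 3, 2))
  noise_free <- ground_truth_world(scale, noise = "none")
  # j closer than k: always kept in ground-truth orientation
  td <- simulate_judgment(noise_free, rep(1L, 50), rep(2L, 50), rep(3L, 50))
  expect_true(all(td$triplets[, "near"] == 2L))
  expect_error(simulate_judgment(noise_free, 1L, 1L, 3L), "distinct")

  # equidistant pair under noise: both orientations equally likely
  sym <- ground_truth_world(perceptual_scale(c(-1, 0, 1)), noise = "med")
  set.seed(2)
  td2 <- simulate_judgment(sym, rep(2L, 10000), rep(1L, 10000),
                           rep(3L, 10000))
  expect_equal(mean(td2$triplets[, "near"] == 1L), 0.5, tolerance = 0.02)
})

test_that("flip probabilities match the normal-CDF closed form", {
  set.seed(6)
  scale <- perceptual_scale(matrix(rnorm(8), 4, 2))
  world <- ground_truth_world(scale, noise = "med")
  sig <- world$sigma_effective
  cases <- rbind(c(1, 2, 3), c(2, 3, 4), c(4, 1, 2))
  for (row in seq_len(nrow(cases))) {
    i <- cases[row, 1]; j <- cases[row, 2]; k <- cases[row, 3]
    delta <- euclid(unclass(scale), i, k) - euclid(unclass(scale), j, i)
    td <- simulate_judgment(world, rep(i, 20000), rep(j, 20000),
                            rep(k, 20000))
    expect_equal(mean(td$triplets[, "near"] == j), pnorm(delta / sig),
                 tolerance = 0.02)
  }
})

test_that("generated datasets have the stated sizes and are seeded", {
  world <- simulate_world(60, 3, noise = "med", seed = 3)
  sim <- generate_dataset(simulation_design(60, 3, lambda = 4), world)
  expect_identical(n_triplets(sim$data), 2947L)
  expect_identical(n_triplets(sim$ceiling), 10000L)
  sim2 <- generate_dataset(simulation_design(60, 3, lambda = 4), world)
  expect_identical(sim$data$triplets, sim2$data$triplets)
  expect_identical(sim$ceiling$triplets, sim2$ceiling$triplets)
  # changing the budget leaves the ground truth untouched (stream split)
  world_b <- simulate_world(60, 3, noise = "med", seed = 3)
  expect_identical(unclass(world$scale), unclass(world_b$scale))
})

test_that("noise-free datasets agree perfectly with the truth", {
  world <- simulate_world(12, 2, noise = "none", seed = 4)
  sim <- generate_dataset(simulation_design(12, 2, lambda = 4), world)
  expect_equal(triplet_accuracy(world$scale, sim$data), 1.0)
  expect_equal(sim$noise_ceiling, 1.0)
})

test_that("noise ceiling matches its closed form and decays with noise", {
  world <- simulate_world(15, 2, noise = "med", seed = 10)
  sim <- generate_dataset(simulation_design(15, 2, lambda = 2), world)
  ceiling_obs <- noise_ceiling(world, sim$ceiling)
  # oracle: mean Phi(|Delta| / sigma) over the sampled questions
  co <- unclass(world$scale)
  tr <- sim$ceiling$triplets
  delta <- abs(
    vapply(seq_len(nrow(tr)), function(r) {
      euclid(co, tr[r, 1], tr[r, 3]) - euclid(co, tr[r, 2], tr[r, 1])
    }, numeric(1)))
  expect_equal(ceiling_obs, mean(pnorm(delta / world$sigma_effective)),
               tolerance = 0.02)

  # monotone non-increasing in sigma over a grid with shared seeds
  scale <- sample_normal_scale(15, 2, seed = 11)
  ceilings <- vapply(c(0, 0.25, 0.5, 1, 2, 100), function(base) {
    w <- ground_truth_world(scale, noise = base, seed = 11)
    generate_dataset(simulation_design(15, 2, lambda = 2), w)$noise_ceiling
  }, numeric(1))
  expect_equal(ceilings[1], 1.0)
  expect_true(all(diff(ceilings) <= 0.01))  # sampling noise tolerance
  expect_lt(abs(ceilings[6] - 0.5), 0.02)  # coin-flip limit within 2 points
})

test_that("the validation grid enumerates 81 conditions", {
  grid <- validation_grid()
  expect_identical(nrow(grid), 81L)
  expect_identical(nrow(unique(grid[, c("n", "d")])), 9L)
  expect_setequal(unique(grid$lambda), c(2, 4, 8))
  expect_setequal(unique(grid$noise), c("low", "med", "high"))
  expect_identical(
    grid$budget[grid$n == 60 & grid$d == 3 & grid$lambda == 4][1], 2947L)
})

test_that("the ordinal-capacity route needs ~n/d times more triplets", {
  expect_equal(ordinal_capacity_ratio(40, 2), 20)
})
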
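test_that("axes drawn by the generator reproduce the drawn biovolume exactly", {
  cfg <- community_sim_config(
    n_stations = 1, samples_per_station = 1,
    n_prey_individuals = 10, n_predator_individuals = 10,
    prey_logvol_mixture = data.frame(weight = 1, mean = 5, sd = 1),
    station_effect_sd = 0, seed = 2)
  s <- simulate_individuals(cfg)[[1]]
  expect_equal(nrow(s$prey), 10)
  for (grp in list(s$prey, s$predators)) {
    v <- ellipsoid_volume(grp$major_um, grp$minor_um)
    expect_equal(v, grp$biovolume_drawn_um3, tolerance = 1e-9)
    expect_true(all(grp$major_um >= grp$minor_um))
  }
})

test_that("aspect ratios respect the configured group-specific ranges", {
  cfg <- community_sim_config(n_stations = 2, samples_per_station = 1,
                              n_prey_individuals = 500,
                              n_predator_individuals = 500, seed = 5)
  s <- simulate_individuals(cfg)[[1]]
  prey_ratio <- s$prey$major_um / s$prey$minor_um
  pred_ratio <- s$predators$major_um / s$predators$minor_um
  expect_true(all(prey_ratio >= 1 - 1e-9 & prey_ratio <= 1.5 + 1e-9))
  expect_true(all(pred_ratio >= 2 - 1e-9 & pred_ratio <= 6 + 1e-9))
})

test_that("carnivore_fraction zero flags nobody, one flags everybody", {
  base <- list(n_stations = 1, samples_per_station = 1,
               n_prey_individuals = 5, n_predator_individuals = 200, seed = 7)
  s0 <- simulate_individuals(do.call(community_sim_config,
                                     c(base, carnivore_fraction = 0)))[[1]]
  expect_false(any(s0$predators$is_carnivore))
  s1 <- simulate_individuals(do.call(community_sim_config,
                                     c(base, carnivore_fraction = 1)))[[1]]
  expect_true(all(s1$predators$is_carnivore))
})

test_that("generated log-biovolumes match the configured mixture moments", {
  cfg <- community_sim_config(
    n_stations = 1, samples_per_station = 1,
    n_prey_individuals = 50000, n_predator_individuals = 10,
    prey_logvol_mixture = data.frame(weight = 1, mean = 5, sd = 1),
    station_effect_sd = 0,
    diversity_link = list(prey = NULL, predator = NULL), seed = 11)
  s <- simulate_individuals(cfg)[[1]]
  x <- log(ellipsoid_volume(s$prey$major_um, s$prey$minor_um))
  se <- 1 / sqrt(50000)
  expect_lt(abs(mean(x) - 5), 3 * se)
  sd_se <- 1 / sqrt(2 * (50000 - 1))
  expect_lt(abs(sd(x) - 1), 3 * sd_se)
})

test_that("the survey generator is bit-reproducible under its seed", {
  cfg <- community_sim_config(n_stations = 2, samples_per_station = 2,
                              n_prey_individuals = 50,
                              n_predator_individuals = 50, seed = 13)
  a <- simulate_individuals(cfg)
  b <- simulate_individuals(cfg)
  attr(a, "config") <- NULL
  attr(b, "config") <- NULL
  expect_identical(a, b)
  cfg2 <- community_sim_config(n_stations = 2, samples_per_station = 2,
                               n_prey_individuals = 50,
                               n_predator_individuals = 50, seed = 14)
  c2 <- simulate_individuals(cfg2)
  expect_false(identical(a[[1]]$prey, c2[[1]]$prey))
})

test_that("invalid community configurations are rejected", {
  expect_error(community_sim_config(prey_logvol_mixture = data.frame(
    weight = c(0.5, 0.4), mean = c(1, 2), sd = c(1, 1))), "sum to 1")
  expect_error(community_sim_config(predator_logvol_mixture = data.frame(
    weight = 1, mean = 1, sd = 0)), "sds must be positive")
  expect_error(community_sim_config(n_stations = 0), "positive")
  expect_error(community_sim_config(carnivore_fraction = 1.2), "\\[0, 1\\]")
})

test_that("the LMM generator produces the stated linear structure", {
  # noise-free: y is exactly the linear predictor
  d <- simulate_lmm_dataset(lmm_sim_config(
    fixed_effects = c(x = 2), intercept = 0,
    random_intercept_sd = 0, residual_sd = 0, seed = 3))
  expect_equal(d$data$y, 2 * d$data$x)

  # determinism
  cfg <- lmm_sim_config(seed = 4)
  expect_identical(simulate_lmm_dataset(cfg), simulate_lmm_dataset(cfg))

  # truth record carries the generating parameters
  expect_equal(d$truth$slopes, c(x = 2))
  expect_equal(d$truth$residual_sd, 0)
})

test_that("OLS on generated data recovers a Table-sized slope within 3 SE", {
  d <- simulate_lmm_dataset(lmm_sim_config(
    fixed_effects = c(x = -1.655), random_intercept_sd = 0.1,
    residual_sd = 0.2, seed = 21))
  s <- summary(lm(y ~ x, d$data))$coefficients
  expect_lt(abs(s["x", "Estimate"] - (-1.655)), 3 * s["x", "Std. Error"])
})

test_that("interaction slopes enter as products of main-effect columns", {
  d <- simulate_lmm_dataset(lmm_sim_config(
    fixed_effects = c(A = 1, B = 2, "A:B" = 3), intercept = 0.25,
    random_intercept_sd = 0, residual_sd = 0, seed = 31))$data
  expect_equal(d$y, 0.25 + d$A + 2 * d$B + 3 * d$A * d$B)
})

test_that("LMM config invariants hold", {
  expect_error(lmm_sim_config(n_obs = 10, n_groups = 20), "n_obs >= n_groups")
  expect_error(lmm_sim_config(residual_sd = -1), ">= 0")
})
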
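test_that("ellipsoid volume reduces to the sphere when axes are equal", {
  d <- c(1, 2, 7.5)
  expect_equal(ellipsoid_volume(d, d), (pi / 6) * d^3)
  expect_equal(ellipsoid_volume(2, 2), 4 * pi / 3)
  expect_equal(ellipsoid_volume(2, 1), pi / 3)
})

test_that("ellipsoid volume matches the solid-of-revolution quadrature oracle", {
  # volume of the prolate spheroid by numerical integration of pi * y(t)^2
  # along the major axis
  revolve <- function(M, m) {
    a <- M / 2
    b <- m / 2
    stats::integrate(function(t) pi * b^2 * (1 - t^2 / a^2), -a, a,
                     rel.tol = 1e-10)$value
  }
  set.seed(42)
  for (i in 1:20) {
    m <- runif(1, 1, 100)
    M <- m * runif(1, 1, 8)
    expect_equal(ellipsoid_volume(M, m), revolve(M, m), tolerance = 1e-6)
  }
})

test_that("ellipsoid volume is strictly increasing in each axis and validates input", {
  expect_gt(ellipsoid_volume(3, 2), ellipsoid_volume(2.5, 2))
  expect_gt(ellipsoid_volume(3, 2.5), ellipsoid_volume(3, 2))
  expect_error(ellipsoid_volume(1, 2), "major axis")
  expect_error(ellipsoid_volume(2, 0), "positive")
  expect_error(ellipsoid_volume(-1, -2), "positive")
})

test_that("shrinkage correction multiplies prey volumes and exempts predators", {
  tab <- unit_conversion_table(shrinkage_factor = 1.33)
  expect_equal(apply_shrinkage(100, tab, "prey"), 133)
  expect_equal(apply_shrinkage(100, tab, "predator"), 100)
  tab1 <- unit_conversion_table(shrinkage_factor = 1)
  expect_identical(apply_shrinkage(c(5, 50), tab1, "prey"), c(5, 50))
  expect_error(apply_shrinkage(-1, tab, "prey"), "positive")
})

test_that("biomass conversion follows the configured power law", {
  tab <- unit_conversion_table()
  expect_equal(biomass_of(5, tab, "prey"), 5)  # identity mapping defaults
  expect_equal(biomass_of(10, tab, "prey"), 2 * biomass_of(5, tab, "prey"))
  tab2 <- unit_conversion_table(prey = list(factor = 0.12, exponent = 0.9))
  expect_equal(biomass_of(1000, tab2, "prey"), 0.12 * 1000^0.9)
  expect_gt(biomass_of(2000, tab2, "prey"), biomass_of(1000, tab2, "prey"))
  expect_error(biomass_of(10, tab, "benthos"), "unknown trophic group")
})

test_that("conversion table validates factors and warns about placeholders", {
  expect_warning(biomass_conversion_table(), "placeholder")
  expect_error(unit_conversion_table(prey = list(factor = -1, exponent = 1)),
               "positive")
  expect_error(unit_conversion_table(shrinkage_factor = 0), "positive")
})

test_that("carnivore filter drops exactly the flagged predators", {
  s0 <- make_test_sample(n_pred = 20, n_carnivores = 0)
  expect_identical(suppressMessages(remove_carnivores(s0))$predators,
                   s0$predators)

  s5 <- make_test_sample(n_pred = 20, n_carnivores = 5)
  expect_message(out <- remove_carnivores(s5), "removed 5")
  expect_equal(nrow(out$predators), 15)
  expect_false(any(out$predators$is_carnivore))
  expect_identical(out$prey, s5$prey)
  expect_equal(attr(out, "n_carnivores_removed"), 5)
})

test_that("all predators flagged leaves an empty group and biomass errors downstream", {
  s <- make_test_sample(n_pred = 4, n_carnivores = 4)
  out <- suppressMessages(remove_carnivores(s))
  expect_equal(nrow(out$predators), 0)
  out <- derive_biomass(out, unit_conversion_table())
  expect_error(total_biomass(out, "predator"), "empty")
})

test_that("total biomass is the weighted sum, additive and permutation-invariant", {
  tab <- unit_conversion_table()
  one <- sample_community("s", "st",
    prey = data.frame(major_um = 2, minor_um = 2, weight_per_m3 = 2,
                      is_carnivore = FALSE),
    predators = data.frame(major_um = 4, minor_um = 2, weight_per_m3 = 1,
                           is_carnivore = FALSE))
  # single individual: weight * biomass, with factor/exponent 1 biomass = volume
  one$prey$major_um <- 1; one$prey$minor_um <- 1
  one <- derive_biomass(one, tab)
  one$prey$biomass_mgC <- 3  # weight 2, biomass 3 -> 6
  expect_equal(sum(one$prey$weight_per_m3 * one$prey$biomass_mgC), 6)

  set.seed(7)
  n <- 1000
  prey <- data.frame(minor_um = runif(n, 5, 20), is_carnivore = FALSE)
  prey$major_um <- prey$minor_um * runif(n, 1, 1.5)
  prey$weight_per_m3 <- sample(1:9, n, replace = TRUE)
  s <- sample_community("s", "st", prey = prey,
                        predators = make_test_sample()$predators)
  s <- derive_biomass(s, tab)
  # naive loop oracle
  acc <- 0
  for (i in seq_len(n)) {
    acc <- acc + s$prey$weight_per_m3[i] * s$prey$biomass_mgC[i]
  }
  expect_equal(total_biomass(s, "prey"), acc)

  # additivity over disjoint halves
  h1 <- s; h1$prey <- s$prey[1:500, ]
  h2 <- s; h2$prey <- s$prey[501:1000, ]
  expect_equal(total_biomass(h1, "prey") + total_biomass(h2, "prey"),
               total_biomass(s, "prey"))
  # permutation invariance
  sp <- s; sp$prey <- s$prey[sample(n), ]
  expect_equal(total_biomass(sp, "prey"), total_biomass(s, "prey"))
})

test_that("shrinkage-then-conversion order commutes only for exponent 1", {
  v <- 100
  lin <- unit_conversion_table(prey = list(factor = 2, exponent = 1),
                               shrinkage_factor = 1.33)
  a <- biomass_of(apply_shrinkage(v, lin, "prey"), lin, "prey")
  b <- apply_shrinkage(biomass_of(v, lin, "prey"), lin, "prey")
  expect_equal(a, b)

  pow <- unit_conversion_table(prey = list(factor = 2, exponent = 0.8),
                               shrinkage_factor = 1.33)
  a <- biomass_of(apply_shrinkage(v, pow, "prey"), pow, "prey")
  b <- apply_shrinkage(biomass_of(v, pow, "prey"), pow, "prey")
  expect_false(isTRUE(all.equal(a, b)))
  # the pipeline applies shrinkage first
  s <- make_test_sample()
  s <- derive_biomass(s, pow)
  vol <- ellipsoid_volume(s$prey$major_um, s$prey$minor_um) * 1.33
  expect_equal(s$prey$biomass_mgC, 2 * vol^0.8)
})
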
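test_that("containment df reproduces the survey design arithmetic", {
  expect_identical(within_group_df(106, 40, 1), 65L)
  expect_identical(within_group_df(106, 1, 0), 105L)
  expect_identical(within_group_df(10, 2, 3), 5L)
  expect_error(within_group_df(10, 9, 2), "non-positive")
})

test_that("AICc follows its closed form and approaches AIC as n grows", {
  expect_equal(aicc(0, 2, 10), 4 + 12 / 7)
  ll <- -53.2
  k <- 4
  aic <- -2 * ll + 2 * k
  expect_equal(aicc(ll, k, 1e9), aic, tolerance = 1e-6)
  diffs <- vapply(c(20, 50, 200, 1000), function(n) aicc(ll, k, n) - aic,
                  numeric(1))
  expect_true(all(diffs > 0))
  expect_true(all(diff(diffs) < 0))
  expect_error(aicc(0, 5, 6), "undefined")
})

test_that("noise-free data are recovered exactly", {
  d <- simulate_lmm_dataset(lmm_sim_config(
    fixed_effects = c(x = 2), intercept = 0,
    random_intercept_sd = 0, residual_sd = 0, seed = 3))
  expect_equal(d$data$y, 2 * d$data$x)
  f <- suppressWarnings(fit_lmm("y", "x", "station", d$data))
  expect_equal(f$coefficients$estimate[f$coefficients$term == "x"], 2,
               tolerance = 1e-9)
})

test_that("slopes and intercepts are recovered within 3 SE in >= 95% of replicates", {
  truth_b <- -1.655
  truth_a <- 0.5
  ok <- vapply(1:100, function(i) {
    d <- simulate_lmm_dataset(lmm_sim_config(
      fixed_effects = c(x = truth_b), intercept = truth_a, seed = i))
    f <- suppressWarnings(fit_lmm("y", "x", "station", d$data))
    co <- f$coefficients
    sl <- co[co$term == "x", ]
    ic <- co[co$term == "(Intercept)", ]
    abs(sl$estimate - truth_b) <= 3 * sl$se &&
      abs(ic$estimate - truth_a) <= 3 * ic$se
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})

test_that("zero random-intercept variance reduces the fit to OLS", {
  d <- simulate_lmm_dataset(lmm_sim_config(random_intercept_sd = 0, seed = 5))
  f <- suppressWarnings(fit_lmm("y", "x", "station", d$data))
  ols <- lm(y ~ x, d$data)
  expect_equal(f$coefficients$estimate, unname(coef(ols)), tolerance = 1e-3)
})

test_that("a single grouping unit gives ordinary-regression t statistics", {
  d <- simulate_lmm_dataset(lmm_sim_config(n_groups = 1, seed = 9))
  f <- suppressWarnings(fit_lmm("y", "x", "station", d$data))
  s <- summary(lm(y ~ x, d$data))$coefficients
  expect_equal(f$coefficients$t, unname(s[, "t value"]), tolerance = 1e-6)
  # containment df with one group equals the OLS residual df
  expect_equal(f$coefficients$df[1], unname(summary(lm(y ~ x, d$data))$df[2]))
})

test_that("the fitted df convention attaches n - g - p to every slope", {
  d <- simulate_lmm_dataset(lmm_sim_config(seed = 13))
  f <- suppressWarnings(fit_lmm("y", "x", "station", d$data))
  expect_true(all(f$coefficients$df == 65L))
  expect_equal(f$k, 4)  # intercept + slope + 2 variance components
})

test_that("rank-deficient designs are rejected with the collinear terms named", {
  d <- simulate_lmm_dataset(lmm_sim_config(seed = 17))$data
  d$x2 <- 2 * d$x
  expect_error(suppressWarnings(fit_lmm("y", c("x", "x2"), "station", d)),
               "collinear")
})

test_that("univariate ranking orders candidates by AICc with stable ties", {
  d <- simulate_lmm_dataset(lmm_sim_config(
    fixed_effects = c(A = 1.5, B = 0, C = 0), seed = 19))$data
  r1 <- suppressWarnings(rank_univariate("y", "A", "station", d))
  expect_equal(nrow(r1), 1)
  r <- suppressWarnings(rank_univariate("y", c("B", "A", "C"), "station", d))
  expect_false(is.unsorted(r$aicc))
  expect_true(all(c("term", "aicc", "estimate", "se", "t", "p", "df") %in%
                    names(r)))
  # identical columns tie exactly; input order preserved
  d$B2 <- d$B
  rt <- suppressWarnings(rank_univariate("y", c("B", "B2"), "station", d))
  expect_equal(rt$aicc[1], rt$aicc[2])
  expect_identical(rt$term, c("B", "B2"))
})

test_that("the truly active variable ranks first under a strong effect", {
  hits <- vapply(1:50, function(i) {
    d <- simulate_lmm_dataset(lmm_sim_config(
      fixed_effects = c(A = 1.5, B = 0, C = 0), seed = 100 + i))$data
    r <- suppressWarnings(rank_univariate("y", c("B", "A", "C"), "station", d))
    r$term[1] == "A"
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("admissible subsets respect marginality, matching brute-force enumeration", {
  got <- sizetransfer:::admissible_subsets(c("A", "B", "A:B"))
  # oracle: filter all 2^3 subsets by the marginality rule
  all_terms <- c("A", "B", "A:B")
  oracle <- Filter(
    function(s) !("A:B" %in% s) || all(c("A", "B") %in% s),
    lapply(0:7, function(mask) all_terms[as.logical(bitwAnd(mask, c(1, 2, 4)))])
  )
  canon <- function(l) sort(vapply(l, paste, character(1), collapse = "+"))
  expect_identical(canon(got), canon(oracle))
  expect_equal(length(got), 5)  # {}, {A}, {B}, {A,B}, {A,B,A:B}
  expect_error(sizetransfer:::admissible_subsets(paste0("t", 1:21)), "20 terms")
})

test_that("dredge returns an AICc-ascending table whose head is the best fit", {
  d <- simulate_lmm_dataset(lmm_sim_config(
    fixed_effects = c(A = 0.5, B = 0.3, "A:B" = 1), seed = 23))$data
  dr <- suppressWarnings(dredge_all_subsets("y", c("A", "B", "A:B"),
                                            "station", d))
  expect_equal(nrow(dr$table), 5)
  expect_false(is.unsorted(dr$table$aicc))
  expect_equal(dr$table$delta[1], 0)
  expect_equal(dr$table$aicc[1], dr$best$aicc)
  # lower AICc model is ranked first
  expect_true(all(dr$table$aicc[1] <= dr$table$aicc))
})

test_that("dredge selects the interaction model when it generated the data", {
  hits <- vapply(1:100, function(i) {
    d <- simulate_lmm_dataset(lmm_sim_config(
      fixed_effects = c(A = 0.5, B = 0.3, "A:B" = 1), seed = i))$data
    dr <- suppressWarnings(dredge_all_subsets("y", c("A", "B", "A:B"),
                                              "station", d))
    "A:B" %in% dr$best$fixed_terms
  }, logical(1))
  expect_gte(mean(hits), 0.90)
})

test_that("selection of the interaction becomes more frequent as its effect grows", {
  freq <- vapply(c(0, 0.3, 1), function(beta) {
    mean(vapply(1:40, function(i) {
      d <- simulate_lmm_dataset(lmm_sim_config(
        fixed_effects = c(A = 0.3, B = 0.3, "A:B" = beta), seed = 400 + i))$data
      dr <- suppressWarnings(dredge_all_subsets("y", c("A", "B", "A:B"),
                                                "station", d))
      "A:B" %in% dr$best$fixed_terms
    }, logical(1)))
  }, numeric(1))
  expect_true(all(diff(freq) >= 0))
  expect_gt(freq[3], freq[1])
})

test_that("pure-noise predictors leave the intercept-only model winning a plurality", {
  wins <- vapply(1:100, function(i) {
    d <- simulate_lmm_dataset(lmm_sim_config(
      fixed_effects = c(A = 0, B = 0, "A:B" = 0), seed = 1000 + i))$data
    dr <- suppressWarnings(dredge_all_subsets("y", c("A", "B", "A:B"),
                                              "station", d))
    dr$table$model[1]
  }, character(1))
  tab <- sort(table(wins), decreasing = TRUE)
  expect_identical(names(tab)[1], "y ~ 1")
})

test_that("pearson_with_p matches the textbook formula", {
  expect_equal(pearson_with_p(1:10, 1:10)$r, 1)
  expect_equal(pearson_with_p(1:10, 10:1)$r, -1)
  x <- c(1.2, 3.4, 2.2, 5.1, 4.4, 0.7)
  y <- c(0.8, 2.9, 2.5, 4.0, 4.8, 1.1)
  # hand oracle
  r0 <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  n <- length(x)
  t0 <- r0 * sqrt((n - 2) / (1 - r0^2))
  p0 <- 2 * pt(-abs(t0), n - 2)
  got <- pearson_with_p(x, y)
  expect_equal(got$r, r0)
  expect_equal(got$p, p0)
  expect_equal(got$n, n)
  expect_error(pearson_with_p(1:2, 1:2), "at least 3")
  expect_error(pearson_with_p(rep(1, 5), 1:5), "zero variance")
})
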
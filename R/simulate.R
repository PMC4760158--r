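#' Configuration for the synthetic plankton survey generator
#'
#' Describes a station-structured survey with known size distributions so
#' that every downstream stage (morphometry, size diversity, transfer
#' metrics, mixed models) can be tested against generating parameters.
#' Log-biovolumes are drawn from per-group normal mixtures (natural-log
#' um^3 scale); mixtures allow the bimodality that stresses the kernel
#' density estimator. Major/minor axes are back-computed from the drawn
#' biovolume and a log-uniform aspect ratio: predators (mesozooplankton)
#' elongated, prey (nano-microplankton) near-spherical.
#'
#' @param n_stations Number of stations (default 40).
#' @param samples_per_station Samples collected per station (default 3).
#' @param n_prey_individuals Measured prey individuals per sample
#'   (default 3500).
#' @param n_predator_individuals Measured predator individuals per sample
#'   (default 2000).
#' @param prey_logvol_mixture,predator_logvol_mixture Data frames with
#'   columns `weight`, `mean`, `sd` describing the normal mixture on
#'   log-biovolume; weights must sum to 1.
#' @param prey_aspect_range,predator_aspect_range Ranges of the
#'   log-uniform major/minor axis ratio.
#' @param carnivore_fraction Fraction of predators flagged carnivorous
#'   (synthetic metadata used to test the filter; default 0.1).
#' @param station_effect_sd SD of a station-level random shift applied to
#'   the log-biovolume means of both groups (default 0.3), giving the
#'   survey its station structure.
#' @param env_model List with `means`, `sds` and `corr` for the surface
#'   covariates `sst`, `sss`, `ln_no3`, `ln_po4`, `ln_sio3` (nutrients
#'   log-normal), plus `mld_mean`, `mld_sd` and `nutrient_gradient` (the
#'   relative increase of nutrient concentration from surface to MLD).
#' @param diversity_link Named lists `prey` / `predator` mapping surface
#'   covariates to slopes on the log of the mixture-sd multiplier, used to
#'   induce environment-diversity relationships of known sign. Defaults:
#'   prey spread shrinks with warmer SST, predator spread shrinks with
#'   silicate.
#' @param seed Integer seed making the whole survey reproducible.
#' @return An object of class `community_sim_config`.
#' @export
community_sim_config <- function(n_stations = 40L,
                                 samples_per_station = 3L,
                                 n_prey_individuals = 3500L,
                                 n_predator_individuals = 2000L,
                                 prey_logvol_mixture = data.frame(
                                   weight = c(0.6, 0.4),
                                   mean = c(5.5, 8.5),
                                   sd = c(1.2, 1.5)),
                                 predator_logvol_mixture = data.frame(
                                   weight = c(0.7, 0.3),
                                   mean = c(16.5, 19.0),
                                   sd = c(1.2, 1.5)),
                                 prey_aspect_range = c(1, 1.5),
                                 predator_aspect_range = c(2, 6),
                                 carnivore_fraction = 0.1,
                                 station_effect_sd = 0.3,
                                 env_model = default_env_model(),
                                 diversity_link = list(
                                   prey = c(sst = -0.15),
                                   predator = c(ln_sio3 = -0.15)),
                                 seed = 1L) {
  check_mixture <- function(mx, nm) {
    if (!is.data.frame(mx) || !all(c("weight", "mean", "sd") %in% names(mx))) {
      stop(nm, " must be a data frame with weight, mean, sd", call. = FALSE)
    }
    if (abs(sum(mx$weight) - 1) > 1e-8 || any(mx$weight <= 0)) {
      stop(nm, ": mixture weights must be positive and sum to 1", call. = FALSE)
    }
    if (any(mx$sd <= 0)) stop(nm, ": mixture sds must be positive", call. = FALSE)
  }
  check_mixture(prey_logvol_mixture, "prey_logvol_mixture")
  check_mixture(predator_logvol_mixture, "predator_logvol_mixture")
  counts <- c(n_stations, samples_per_station,
              n_prey_individuals, n_predator_individuals)
  if (any(counts < 1)) stop("all counts must be positive", call. = FALSE)
  if (carnivore_fraction < 0 || carnivore_fraction > 1) {
    stop("carnivore_fraction must lie in [0, 1]", call. = FALSE)
  }
  if (station_effect_sd < 0) stop("station_effect_sd must be >= 0", call. = FALSE)
  for (rng in list(prey_aspect_range, predator_aspect_range)) {
    if (length(rng) != 2 || rng[1] < 1 || rng[2] < rng[1]) {
      stop("aspect ranges must be increasing and >= 1", call. = FALSE)
    }
  }
  structure(
    list(n_stations = as.integer(n_stations),
         samples_per_station = as.integer(samples_per_station),
         n_prey_individuals = as.integer(n_prey_individuals),
         n_predator_individuals = as.integer(n_predator_individuals),
         prey_logvol_mixture = prey_logvol_mixture,
         predator_logvol_mixture = predator_logvol_mixture,
         prey_aspect_range = prey_aspect_range,
         predator_aspect_range = predator_aspect_range,
         carnivore_fraction = carnivore_fraction,
         station_effect_sd = station_effect_sd,
         env_model = env_model,
         diversity_link = diversity_link,
         seed = as.integer(seed)),
    class = "community_sim_config"
  )
}

#' Default surface-environment model for the survey generator
#'
#' Multivariate-normal surface covariates (nutrients on the natural-log
#' scale) with a mild warm-oligotrophic correlation structure: warmer
#' water tends to carry fewer nutrients. The values describe a plausible
#' subtropical shelf-sea summer; they make no claim to reproduce any
#' specific hydrography.
#'
#' @return A list consumed by [community_sim_config()].
#' @export
default_env_model <- function() {
  vars <- c("sst", "sss", "ln_no3", "ln_po4", "ln_sio3")
  corr <- diag(5)
  dimnames(corr) <- list(vars, vars)
  corr["sst", "ln_no3"] <- corr["ln_no3", "sst"] <- -0.5
  corr["sst", "ln_po4"] <- corr["ln_po4", "sst"] <- -0.4
  corr["sst", "ln_sio3"] <- corr["ln_sio3", "sst"] <- -0.4
  corr["ln_no3", "ln_po4"] <- corr["ln_po4", "ln_no3"] <- 0.6
  corr["ln_no3", "ln_sio3"] <- corr["ln_sio3", "ln_no3"] <- 0.5
  corr["ln_po4", "ln_sio3"] <- corr["ln_sio3", "ln_po4"] <- 0.5
  list(
    means = c(sst = 26, sss = 33.5, ln_no3 = log(2), ln_po4 = log(0.15),
              ln_sio3 = log(5)),
    sds = c(sst = 2, sss = 0.6, ln_no3 = 0.7, ln_po4 = 0.5, ln_sio3 = 0.6),
    corr = corr,
    mld_mean = 30, mld_sd = 8,
    nutrient_gradient = 1
  )
}

#' Simulate a station-structured plankton survey
#'
#' Draws, for every sample, per-individual log-biovolumes from the
#' configured mixtures (shifted by a station random effect and by the
#' environment-diversity link), back-computes major/minor ellipse axes
#' consistent with the prolate-spheroid volume formula and the aspect
#' ratio model, flags a configurable fraction of predators as carnivores,
#' and attaches an environmental profile. Abundance weights are integer
#' particle counts (1 + Poisson(3)). Fully reproducible given the config
#' seed.
#'
#' @param config A [community_sim_config()].
#' @return A list of [sample_community()] objects; the generating config
#'   is attached as attribute `config`.
#' @export
simulate_individuals <- function(config) {
  stopifnot(inherits(config, "community_sim_config"))
  withr::with_seed(config$seed, simulate_individuals_impl(config))
}

simulate_individuals_impl <- function(config) {
  em <- config$env_model
  vars <- names(em$means)
  sigma <- diag(em$sds) %*% em$corr %*% diag(em$sds)
  station_shift <- rnorm(config$n_stations, 0, config$station_effect_sd)
  samples <- list()
  for (st in seq_len(config$n_stations)) {
    station_id <- sprintf("st%02d", st)
    cruise_id <- sprintf("cr%02d", (st - 1L) %/% 4L + 1L)
    for (sm in seq_len(config$samples_per_station)) {
      sample_id <- sprintf("%s_s%d", station_id, sm)
      env_draw <- drop(MASS::mvrnorm(1, mu = em$means, Sigma = sigma))
      names(env_draw) <- vars
      env <- build_env_profile(env_draw, em)
      prey <- draw_group(config$n_prey_individuals,
                         config$prey_logvol_mixture,
                         config$prey_aspect_range,
                         shift = station_shift[st],
                         sd_scale = link_sd_scale(config$diversity_link$prey,
                                                  env_draw, em),
                         carnivore_fraction = 0)
      pred <- draw_group(config$n_predator_individuals,
                         config$predator_logvol_mixture,
                         config$predator_aspect_range,
                         shift = station_shift[st],
                         sd_scale = link_sd_scale(config$diversity_link$predator,
                                                  env_draw, em),
                         carnivore_fraction = config$carnivore_fraction)
      samples[[length(samples) + 1L]] <-
        sample_community(sample_id, station_id, cruise_id,
                         prey = prey, predators = pred, env = env)
    }
  }
  attr(samples, "config") <- config
  samples
}

# Multiplier on the mixture sds induced by surface covariates:
# exp(sum slope_j * standardized covariate_j).
link_sd_scale <- function(link, env_draw, em) {
  if (is.null(link) || !length(link)) return(1)
  z <- (env_draw[names(link)] - em$means[names(link)]) / em$sds[names(link)]
  exp(sum(link * z))
}

draw_group <- function(n, mixture, aspect_range, shift, sd_scale,
                       carnivore_fraction) {
  comp <- sample.int(nrow(mixture), n, replace = TRUE, prob = mixture$weight)
  logvol <- rnorm(n, mean = mixture$mean[comp] + shift,
                  sd = mixture$sd[comp] * sd_scale)
  vol <- exp(logvol)
  ratio <- exp(runif(n, log(aspect_range[1]), log(aspect_range[2])))
  minor <- (6 * vol / (pi * ratio))^(1 / 3)
  major <- ratio * minor
  data.frame(
    major_um = major,
    minor_um = minor,
    weight_per_m3 = 1 + rpois(n, 3),
    is_carnivore = runif(n) < carnivore_fraction,
    # the generating biovolume, kept so round-trip consistency of the
    # axis back-computation is testable
    biovolume_drawn_um3 = vol
  )
}

build_env_profile <- function(env_draw, em) {
  mld <- max(10, rnorm(1, em$mld_mean, em$mld_sd))
  depths <- seq(0, 10 * ceiling(mld / 10), by = 10)
  grad <- em$nutrient_gradient
  profile_of <- function(surface) {
    pmax(surface * (1 + grad * depths / mld), 0)
  }
  env_profile(
    depths = depths,
    no3 = profile_of(exp(env_draw[["ln_no3"]])),
    po4 = profile_of(exp(env_draw[["ln_po4"]])),
    sio3 = profile_of(exp(env_draw[["ln_sio3"]])),
    sst = env_draw[["sst"]],
    sss = env_draw[["sss"]],
    mld = mld
  )
}

#' Configuration for the mixed-model test-surface generator
#'
#' Describes a dataset of `n_obs` rows over `n_groups` stations with a
#' known linear fixed-effect structure, a station random intercept and
#' i.i.d. residual noise — the recovery surface for the inference module.
#' Defaults mirror the survey design the package targets: 106
#' observations over 40 stations, and a prey-size-diversity-sized slope.
#'
#' @param n_obs Number of observations (default 106).
#' @param n_groups Number of stations (default 40; must not exceed
#'   `n_obs`).
#' @param fixed_effects Named numeric vector mapping covariate names to
#'   true slopes; interaction terms may be written `"A:B"` (default one
#'   slope, `x = -1.655`).
#' @param intercept True intercept (default 0.5).
#' @param random_intercept_sd SD of the station random intercept
#'   (default 0.3; >= 0).
#' @param residual_sd Residual SD (default 0.4; >= 0).
#' @param covariate_distributions Optional named list of `list(mean, sd)`
#'   per covariate (default standard normal); and optionally a
#'   `correlation` matrix across covariates.
#' @param correlation Optional correlation matrix for the covariates
#'   (default identity).
#' @param seed Integer seed.
#' @return An object of class `lmm_sim_config`.
#' @export
lmm_sim_config <- function(n_obs = 106L, n_groups = 40L,
                           fixed_effects = c(x = -1.655),
                           intercept = 0.5,
                           random_intercept_sd = 0.3,
                           residual_sd = 0.4,
                           covariate_distributions = NULL,
                           correlation = NULL,
                           seed = 1L) {
  if (n_obs < n_groups) stop("need n_obs >= n_groups", call. = FALSE)
  if (n_obs < 1 || n_groups < 1) stop("counts must be positive", call. = FALSE)
  if (random_intercept_sd < 0 || residual_sd < 0) {
    stop("standard deviations must be >= 0", call. = FALSE)
  }
  structure(
    list(n_obs = as.integer(n_obs), n_groups = as.integer(n_groups),
         fixed_effects = fixed_effects, intercept = intercept,
         random_intercept_sd = random_intercept_sd,
         residual_sd = residual_sd,
         covariate_distributions = covariate_distributions,
         correlation = correlation,
         seed = as.integer(seed)),
    class = "lmm_sim_config"
  )
}

#' Simulate a mixed-model dataset with known parameters
#'
#' Generates covariates, station labels and the response
#' `y = intercept + sum(slope * x) + station effect + noise`, returning
#' both the analysis table and the generating parameters. Interaction
#' terms (`"A:B"` in the slope names) contribute the product of their
#' main-effect columns; main-effect covariates are drawn (optionally
#' correlated) normals.
#'
#' @param config An [lmm_sim_config()].
#' @return A list with `data` (data frame: covariates, `station`, `y`)
#'   and `truth` (the generating parameters).
#' @export
simulate_lmm_dataset <- function(config) {
  stopifnot(inherits(config, "lmm_sim_config"))
  withr::with_seed(config$seed, simulate_lmm_impl(config))
}

simulate_lmm_impl <- function(config) {
  slopes <- config$fixed_effects
  terms <- names(slopes)
  if (is.null(terms) || any(!nzchar(terms))) {
    stop("fixed_effects must be a named vector", call. = FALSE)
  }
  main <- unique(unlist(strsplit(terms, ":", fixed = TRUE)))
  n <- config$n_obs
  g <- config$n_groups

  dists <- config$covariate_distributions
  mu <- vapply(main, function(v) {
    if (!is.null(dists[[v]]$mean)) dists[[v]]$mean else 0
  }, numeric(1))
  sdv <- vapply(main, function(v) {
    if (!is.null(dists[[v]]$sd)) dists[[v]]$sd else 1
  }, numeric(1))
  corr <- config$correlation
  if (is.null(corr)) corr <- diag(length(main))
  sigma <- diag(sdv, nrow = length(main)) %*% corr %*% diag(sdv, nrow = length(main))
  X <- MASS::mvrnorm(n, mu = mu, Sigma = sigma)
  X <- matrix(X, nrow = n, dimnames = list(NULL, main))

  station <- factor(sample(rep_len(seq_len(g), n)),
                    levels = seq_len(g),
                    labels = sprintf("st%02d", seq_len(g)))
  b <- rnorm(g, 0, config$random_intercept_sd)
  eps <- rnorm(n, 0, config$residual_sd)

  eta <- rep(config$intercept, n)
  for (tm in terms) {
    parts <- strsplit(tm, ":", fixed = TRUE)[[1]]
    col <- Reduce(`*`, lapply(parts, function(p) X[, p]))
    eta <- eta + slopes[[tm]] * col
  }
  y <- eta + b[as.integer(station)] + eps

  data <- as.data.frame(X)
  data$station <- station
  data$y <- y
  list(
    data = data,
    truth = list(intercept = config$intercept,
                 slopes = slopes,
                 random_intercept_sd = config$random_intercept_sd,
                 residual_sd = config$residual_sd,
                 seed = config$seed)
  )
}
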
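#' Ellipsoidal biovolume from major and minor ellipse axes
#'
#' Converts the major (M) and minor (m) axes of the ellipse containing an
#' imaged individual (ZooSCAN / FlowCAM two-axis measurements) to a prolate
#' spheroid volume \eqn{V = (\pi/6)\, M m^2}: the unmeasured third axis is
#' assumed equal to the minor one. This is preferred over the equivalent
#' spherical diameter for elongated organisms such as most mesozooplankton.
#'
#' @param major_um Major axis length in micrometres (vector).
#' @param minor_um Minor axis length in micrometres (vector, recycled against
#'   `major_um`).
#' @return Biovolume in cubic micrometres, same length as the longer input.
#' @examples
#' ellipsoid_volume(2, 2)  # sphere of diameter 2: 4*pi/3
#' ellipsoid_volume(2, 1)  # pi/3
#' @export
ellipsoid_volume <- function(major_um, minor_um) {
  n <- max(length(major_um), length(minor_um))
  major_um <- rep_len(major_um, n)
  minor_um <- rep_len(minor_um, n)
  if (!all(is.finite(major_um)) || !all(is.finite(minor_um))) {
    stop("axis measurements must be finite", call. = FALSE)
  }
  if (any(minor_um <= 0)) {
    stop("axis measurements must be strictly positive", call. = FALSE)
  }
  if (any(major_um < minor_um)) {
    bad <- which(major_um < minor_um)[1L]
    stop(sprintf(
      "major axis must be >= minor axis (violated at element %d: M = %g < m = %g)",
      bad, major_um[bad], minor_um[bad]
    ), call. = FALSE)
  }
  (pi / 6) * major_um * minor_um^2
}

#' Biovolume-to-biomass conversion table
#'
#' Holds the multiplicative factor and exponent of the power law
#' `biomass = factor * biovolume^exponent` for each trophic group, plus the
#' preservation-shrinkage multiplier applied to prey (nano-microplankton)
#' cell volumes. The defaults (factor 1, exponent 1, shrinkage 1) are
#' *placeholders*, not literature values: they reproduce simple volumetric
#' scaling and must be replaced with taxon-appropriate conversion factors
#' for any absolute-biomass interpretation. A warning reminds the user when
#' the defaults are used.
#'
#' @param prey,predator Lists with elements `factor` and `exponent` (both
#'   `> 0` for `factor`; exponent any positive real).
#' @param shrinkage_factor Multiplier applied to prey biovolume before
#'   biomass conversion (preserved nano-microplankton cells shrink; > 0).
#' @param quiet Suppress the placeholder warning.
#' @return An object of class `biomass_conversion_table`.
#' @export
biomass_conversion_table <- function(prey = list(factor = 1, exponent = 1),
                                     predator = list(factor = 1, exponent = 1),
                                     shrinkage_factor = 1,
                                     quiet = FALSE) {
  for (grp in list(prey, predator)) {
    if (!is.list(grp) || is.null(grp$factor) || is.null(grp$exponent)) {
      stop("each group needs a list(factor = , exponent = )", call. = FALSE)
    }
    if (grp$factor <= 0 || !is.finite(grp$factor)) {
      stop("conversion factors must be positive and finite", call. = FALSE)
    }
    if (grp$exponent <= 0 || !is.finite(grp$exponent)) {
      stop("conversion exponents must be positive and finite", call. = FALSE)
    }
  }
  if (shrinkage_factor <= 0 || !is.finite(shrinkage_factor)) {
    stop("shrinkage_factor must be positive and finite", call. = FALSE)
  }
  defaults <- identical(prey, list(factor = 1, exponent = 1)) &&
    identical(predator, list(factor = 1, exponent = 1)) &&
    shrinkage_factor == 1
  if (defaults && !quiet) {
    warning(paste(
      "biomass_conversion_table(): using placeholder factors",
      "(factor 1, exponent 1, shrinkage 1);",
      "supply literature-based values for absolute biomass"
    ), call. = FALSE)
  }
  structure(
    list(prey = prey, predator = predator,
         shrinkage_factor = shrinkage_factor),
    class = "biomass_conversion_table"
  )
}

#' Preservation-shrinkage correction
#'
#' Prey (nano-microplankton) cell volumes are multiplied by the table's
#' `shrinkage_factor` to undo shrinkage owing to preservation; predator
#' volumes pass through unchanged.
#'
#' @param volume_um3 Biovolume in cubic micrometres.
#' @param table A [biomass_conversion_table()].
#' @param group `"prey"` or `"predator"` (scalar or vector recycled against
#'   `volume_um3`).
#' @return Corrected biovolume.
#' @export
apply_shrinkage <- function(volume_um3, table, group) {
  stopifnot(inherits(table, "biomass_conversion_table"))
  if (any(volume_um3 <= 0)) stop("biovolume must be positive", call. = FALSE)
  group <- match_group(group, length(volume_um3))
  ifelse(group == "prey", volume_um3 * table$shrinkage_factor, volume_um3)
}

#' Carbon biomass of individuals from biovolume
#'
#' Applies the group's power law `factor * biovolume^exponent`. The
#' shrinkage correction is *not* applied here: the pipeline order is fixed
#' as carnivore filter, then shrinkage, then biomass conversion, then
#' aggregation (see [derive_biomass()]).
#'
#' @inheritParams apply_shrinkage
#' @return Biomass (mg C) per individual.
#' @export
biomass_of <- function(volume_um3, table, group) {
  stopifnot(inherits(table, "biomass_conversion_table"))
  if (any(volume_um3 <= 0)) stop("biovolume must be positive", call. = FALSE)
  group <- match_group(group, length(volume_um3))
  fac <- ifelse(group == "prey", table$prey$factor, table$predator$factor)
  ex <- ifelse(group == "prey", table$prey$exponent, table$predator$exponent)
  fac * volume_um3^ex
}

match_group <- function(group, n) {
  group <- rep_len(as.character(group), n)
  bad <- !group %in% c("prey", "predator")
  if (any(bad)) {
    stop(sprintf("unknown trophic group '%s'", group[which(bad)[1L]]),
         call. = FALSE)
  }
  group
}

#' One sample's prey and predator collections
#'
#' A `sample_community` bundles everything measured for one station/date
#' sample pair: the prey (nano-microplankton) and predator (mesozooplankton)
#' particle tables and, optionally, the environmental profile.
#' Particle tables must carry `major_um`, `minor_um` and `weight_per_m3`
#' columns; predator tables also `is_carnivore`.
#'
#' @param sample_id,station_id,cruise_id Identifiers.
#' @param prey,predators Data frames of individuals.
#' @param env Optional [env_profile()].
#' @return An object of class `sample_community`.
#' @export
sample_community <- function(sample_id, station_id, cruise_id = NA_character_,
                             prey, predators, env = NULL) {
  check_individuals(prey, need_carnivore = FALSE)
  check_individuals(predators, need_carnivore = TRUE)
  structure(
    list(sample_id = as.character(sample_id),
         station_id = as.character(station_id),
         cruise_id = as.character(cruise_id),
         prey = prey, predators = predators, env = env),
    class = "sample_community"
  )
}

check_individuals <- function(df, need_carnivore) {
  stopifnot(is.data.frame(df))
  need <- c("major_um", "minor_um", "weight_per_m3")
  if (need_carnivore) need <- c(need, "is_carnivore")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("individual table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(df)) {
    if (any(df$minor_um <= 0) || any(df$major_um < df$minor_um)) {
      stop("invalid axes: need major >= minor > 0", call. = FALSE)
    }
    if (any(df$weight_per_m3 <= 0)) {
      stop("abundance weights must be positive", call. = FALSE)
    }
  }
  invisible(df)
}

#' @export
print.sample_community <- function(x, ...) {
  cat(sprintf("<sample_community %s (station %s)>\n", x$sample_id, x$station_id))
  cat(sprintf("  prey:      %d individuals\n", nrow(x$prey)))
  cat(sprintf("  predators: %d individuals (%d carnivores)\n",
              nrow(x$predators), sum(x$predators$is_carnivore)))
  invisible(x)
}

#' Remove carnivorous mesozooplankton from a sample
#'
#' Carnivores are excluded from the predator collection before any biomass
#' or diversity computation, so that the predator group represents grazers
#' on the nano-microplankton prey field. The prey collection is untouched.
#' The number removed is reported via `message()` and attached as attribute
#' `n_carnivores_removed`.
#'
#' @param sample A [sample_community()].
#' @return The sample with flagged predators dropped.
#' @export
remove_carnivores <- function(sample) {
  stopifnot(inherits(sample, "sample_community"))
  flagged <- sample$predators$is_carnivore
  n <- sum(flagged)
  if (n > 0) {
    message(sprintf("sample %s: removed %d carnivorous predator(s)",
                    sample$sample_id, n))
    sample$predators <- sample$predators[!flagged, , drop = FALSE]
  }
  attr(sample, "n_carnivores_removed") <- n
  sample
}

#' Derive biovolume and biomass columns for a sample
#'
#' Applies the fixed processing order: preservation-shrinkage correction of
#' prey volumes, then the power-law biomass conversion. Adds
#' `biovolume_um3` (post-shrinkage) and `biomass_mgC` columns to both
#' groups. Shrinkage and conversion commute only when the exponent is 1, so
#' the order matters and is pinned here.
#'
#' @param sample A [sample_community()] (carnivores should already be
#'   removed; see [remove_carnivores()]).
#' @param table A [biomass_conversion_table()].
#' @return The sample with derived columns.
#' @export
derive_biomass <- function(sample, table) {
  stopifnot(inherits(sample, "sample_community"),
            inherits(table, "biomass_conversion_table"))
  for (grp in c("prey", "predators")) {
    df <- sample[[grp]]
    gname <- if (grp == "prey") "prey" else "predator"
    if (nrow(df)) {
      vol <- ellipsoid_volume(df$major_um, df$minor_um)
      vol <- apply_shrinkage(vol, table, gname)
      df$biovolume_um3 <- vol
      df$biomass_mgC <- biomass_of(vol, table, gname)
    } else {
      df$biovolume_um3 <- numeric(0)
      df$biomass_mgC <- numeric(0)
    }
    sample[[grp]] <- df
  }
  sample
}

#' Total biomass of one trophic group in a sample
#'
#' Abundance-weighted sum \eqn{\sum_i w_i b_i} of individual biomasses,
#' giving mg C per cubic metre. Requires [derive_biomass()] to have run.
#'
#' @param sample A [sample_community()] with derived biomass.
#' @param group `"prey"` or `"predator"`.
#' @return Total biomass (mg C m^-3).
#' @export
total_biomass <- function(sample, group) {
  stopifnot(inherits(sample, "sample_community"))
  group <- match.arg(group, c("prey", "predator"))
  df <- if (group == "prey") sample$prey else sample$predators
  if (!nrow(df)) {
    stop(sprintf("sample %s: %s group is empty; total biomass undefined",
                 sample$sample_id, group), call. = FALSE)
  }
  if (is.null(df$biomass_mgC)) {
    stop("biomass not derived yet; call derive_biomass() first", call. = FALSE)
  }
  sum(df$weight_per_m3 * df$biomass_mgC)
}
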
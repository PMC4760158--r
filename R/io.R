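#' Flatten sample communities to a particle table
#'
#' One row per measured individual, in the package's particle CSV schema:
#' `sample_id, station_id, cruise_id, group, is_carnivore, major_um,
#' minor_um, weight_per_m3`.
#'
#' @param samples A list of [sample_community()] objects.
#' @return A data frame.
#' @export
particle_table <- function(samples) {
  rows <- lapply(samples, function(s) {
    grp <- function(df, group, carn) {
      if (!nrow(df)) return(NULL)
      data.frame(
        sample_id = s$sample_id, station_id = s$station_id,
        cruise_id = s$cruise_id, group = group,
        is_carnivore = if (carn) df$is_carnivore else FALSE,
        major_um = df$major_um, minor_um = df$minor_um,
        weight_per_m3 = df$weight_per_m3,
        stringsAsFactors = FALSE
      )
    }
    rbind(grp(s$prey, "prey", carn = FALSE),
          grp(s$predators, "predator", carn = TRUE))
  })
  do.call(rbind, rows)
}

#' Flatten environmental profiles to a long table
#'
#' One row per (sample, depth): `sample_id, depth_m, no3, po4, sio3, sst,
#' sss, mld` (surface fields repeated down the profile).
#'
#' @param samples A list of [sample_community()] objects with `env` set.
#' @return A data frame.
#' @export
env_table <- function(samples) {
  rows <- lapply(samples, function(s) {
    e <- s$env
    if (is.null(e)) return(NULL)
    data.frame(sample_id = s$sample_id, depth_m = e$depths,
               no3 = e$no3, po4 = e$po4, sio3 = e$sio3,
               sst = e$sst, sss = e$sss, mld = e$mld,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

write_commented_csv <- function(df, path, header = character(0)) {
  con <- file(path, "w")
  on.exit(close(con))
  for (h in header) writeLines(paste0("# ", h), con)
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}

read_commented_csv <- function(path) {
  read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Write / read particle tables as CSV
#'
#' @param x A particle data frame (or list of [sample_community()]s,
#'   flattened first).
#' @param path File path.
#' @param header Optional comment lines (e.g. config hash) written as
#'   `# ...` before the table.
#' @return `write_particles()` returns the path invisibly;
#'   `read_particles()` a data frame in the particle schema.
#' @export
write_particles <- function(x, path, header = character(0)) {
  if (!is.data.frame(x)) x <- particle_table(x)
  write_commented_csv(x, path, header)
}

#' @rdname write_particles
#' @export
read_particles <- function(path) {
  df <- read_commented_csv(path)
  need <- c("sample_id", "station_id", "group", "is_carnivore",
            "major_um", "minor_um", "weight_per_m3")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("particle CSV missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  df$is_carnivore <- as.logical(df$is_carnivore)
  df
}

#' Write / read environmental profiles as long CSV
#'
#' @param x An environment data frame (or list of samples, flattened).
#' @inheritParams write_particles
#' @return `read_env_profiles()` returns a named list of [env_profile()]
#'   objects keyed by `sample_id`.
#' @export
write_env <- function(x, path, header = character(0)) {
  if (!is.data.frame(x)) x <- env_table(x)
  write_commented_csv(x, path, header)
}

#' @rdname write_env
#' @export
read_env_profiles <- function(path) {
  df <- read_commented_csv(path)
  need <- c("sample_id", "depth_m", "no3", "po4", "sio3", "sst", "sss", "mld")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("environment CSV missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  split_df <- split(df, df$sample_id)
  lapply(split_df, function(d) {
    d <- d[order(d$depth_m), , drop = FALSE]
    env_profile(depths = d$depth_m, no3 = d$no3, po4 = d$po4, sio3 = d$sio3,
                sst = d$sst[1], sss = d$sss[1], mld = d$mld[1])
  })
}

#' Rebuild sample communities from a particle table
#'
#' Inverse of [particle_table()]: splits a particle data frame by
#' `sample_id` and reattaches environmental profiles when given.
#'
#' @param particles Data frame in the particle schema.
#' @param env Optional named list of [env_profile()]s keyed by sample id
#'   (as returned by [read_env_profiles()]).
#' @return A list of [sample_community()] objects.
#' @export
as_sample_communities <- function(particles, env = NULL) {
  pieces <- split(particles, particles$sample_id)
  lapply(pieces, function(d) {
    mk <- function(g) {
      sub <- d[d$group == g,
               c("major_um", "minor_um", "weight_per_m3", "is_carnivore"),
               drop = FALSE]
      rownames(sub) <- NULL
      sub
    }
    sample_community(
      sample_id = d$sample_id[1], station_id = d$station_id[1],
      cruise_id = if ("cruise_id" %in% names(d)) d$cruise_id[1] else NA_character_,
      prey = mk("prey"), predators = mk("predator"),
      env = if (!is.null(env)) env[[d$sample_id[1]]] else NULL
    )
  })
}

#' Read a cohort table for production-rate estimation
#'
#' Schema: `sample_id, group, w0_ug, wt_ug, dt_days, biomass_mgC_m3` —
#' one artificial-cohort incubation per sample and trophic group.
#'
#' @param path File path.
#' @return A data frame.
#' @export
read_cohorts <- function(path) {
  df <- read_commented_csv(path)
  need <- c("sample_id", "group", "w0_ug", "wt_ug", "dt_days", "biomass_mgC_m3")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("cohort CSV missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  df
}
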
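# Small deterministic builders shared across test files.

# A sample with hand-set axes: prey near-spherical, predators elongated.
make_test_sample <- function(n_prey = 6, n_pred = 4, n_carnivores = 0,
                             sample_id = "s1", station_id = "st01") {
  prey <- data.frame(
    major_um = seq(10, 10 + n_prey - 1),
    minor_um = seq(10, 10 + n_prey - 1) / 1.2,
    weight_per_m3 = rep(2, n_prey),
    is_carnivore = FALSE
  )
  pred <- data.frame(
    major_um = seq(500, 500 + 10 * (n_pred - 1), by = 10),
    minor_um = seq(500, 500 + 10 * (n_pred - 1), by = 10) / 4,
    weight_per_m3 = rep(1, n_pred),
    is_carnivore = seq_len(n_pred) <= n_carnivores
  )
  sample_community(sample_id, station_id, "cr01", prey = prey, predators = pred)
}

unit_conversion_table <- function(...) {
  biomass_conversion_table(..., quiet = TRUE)
}

make_test_profile <- function(depths, no3, mld, po4 = NULL, sio3 = NULL) {
  if (is.null(po4)) po4 <- rep(0.1, length(depths))
  if (is.null(sio3)) sio3 <- rep(1, length(depths))
  env_profile(depths = depths, no3 = no3, po4 = po4, sio3 = sio3,
              sst = 25, sss = 34, mld = mld)
}
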
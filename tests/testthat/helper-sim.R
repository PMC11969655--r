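# Shared shortcuts for the suite: small simulations and decode configs
# kept cheap enough for repeated use.

quiet_sim <- function(code, seed, noise = TRUE, jitter = 0.03,
                      n_frames = 20, ...) {
  simulate_barcode_stack(code, barcode_scheme(),
                         motion = motion_params(jitter_fraction = jitter),
                         noise = noise, n_frames = n_frames, seed = seed, ...)
}

fast_decode <- function(sim, n_boot = 100, seed = 2, ...) {
  read_barcode(sim$stack, sim$track, barcode_scheme(),
               decode_config(n_boot = n_boot, seed = seed, ...))
}

# deterministic plateau / bleached-well / plateau profile built from the
# analytic expected bleach pattern; first and last bleach lines at
# `lead` and `lead + region`
well_profile <- function(periods = 1200, lead = 4000, region = 12000,
                         tail = 4000, level = 5000, h = 160 / 3,
                         dose = 0.7) {
  sch <- make_schedule(periods, v_x = 1000, region_length = region)
  pos <- seq(0, lead + region + tail, by = h)
  y <- level * expected_bleach_profile(sch, pos - lead, dose = dose)
  intensity_profile(pos, y)
}

# manually assembled aligned_profiles object (already on a common grid)
make_aligned <- function(Y, pos) {
  structure(list(average = intensity_profile(pos, colMeans(Y), "averaged",
                                             nrow(Y)),
                 shifts_nm = rep(0, nrow(Y)), aligned = Y, positions = pos),
            class = "aligned_profiles")
}
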
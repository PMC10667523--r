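# Shared fixtures built in code.

# A tiny constant-frame cube triple on an arbitrary axis: raw sits a known
# fraction of the way between dark and white, so Eq.-style reflectance has a
# closed-form value.
make_reference_frames <- function(h = 4, w = 3, nb = 6, frac = 0.25,
                                  dark_level = 100, white_level = 1100) {
  wl <- seq(1000, 1100, length.out = nb)
  dark <- hyper_cube(array(dark_level, c(h, w, nb)), wl, "dark")
  white <- hyper_cube(array(white_level, c(h, w, nb)), wl, "white")
  raw <- hyper_cube(array(dark_level + frac * (white_level - dark_level),
                          c(h, w, nb)), wl, "raw")
  list(raw = raw, dark = dark, white = white, wl = wl)
}

# A reflectance cube whose every pixel carries the same smooth Gaussian
# absorption feature (in reflectance space), for spike-filter fixtures.
make_smooth_reflectance <- function(h = 2, w = 2, nb = 101) {
  wl <- seq(1000, 1400, length.out = nb)
  r <- 0.6 - 0.3 * exp(-(wl - 1180)^2 / (2 * 15^2))
  hyper_cube(array(rep(r, each = h * w), c(h, w, nb)), wl, "reflectance")
}

# Noiseless single-lobe rendering used by round-trip oracles.
render_noiseless_lobe <- function(profile = default_diet_profiles()$ND,
                                  h = 8, w = 8, seed = 7) {
  render_cube(lobe_scene(profile, h, w, readout_sd = 0, shot_scale = 0,
                         spike_rate = 0, seed = seed))
}

expect_masked_equal <- function(cube, truth_array, mask, tol = 1e-6) {
  sel <- array(rep(mask & cube$mask, dim(cube$data)[3]), dim(cube$data))
  expect_lt(max(abs(cube$data[sel] - truth_array[sel])), tol)
}
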
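# Synthetic generator: diet profiles, Dirichlet compositions, band spectra,
# scene rendering.

test_that("default diet profiles hit their target tissue HCL/DS exactly", {
  targets <- list(LA2 = c(17.22, 0.83), LA12 = c(17.54, 0.81),
                  HFD = c(17.56, 0.79), ND = c(17.72, 0.77),
                  HCD = c(17.83, 0.75))
  for (nm in names(targets)) {
    p <- default_diet_profiles()[[nm]]
    comp <- fatty_acid_composition(p$mean_fractions)
    pr <- composition_profile(comp)
    expect_equal(pr$hcl, targets[[nm]][1], tolerance = 1e-10)
    expect_equal(pr$ds, targets[[nm]][2], tolerance = 1e-10)
    expect_true(all(p$mean_fractions >= 0))
  }
})

test_that("profile means place most mass on 16:0, 18:2 and 18:3", {
  for (p in default_diet_profiles()) {
    majors <- sum(p$mean_fractions[c("16:0", "18:2", "18:3")])
    expect_gt(majors, 0.5)
  }
})

test_that("sample_composition is deterministic and degenerates correctly", {
  p <- default_diet_profiles()$HFD
  a <- sample_composition(p, seed = 9)
  b <- sample_composition(p, seed = 9)
  expect_equal(a$molar_fraction, b$molar_fraction)
  expect_equal(attr(a, "total_lipid"), attr(b, "total_lipid"))

  inf <- p; inf$concentration <- Inf
  class(inf) <- "diet_profile"
  d <- sample_composition(inf, seed = 1)
  expect_equal(d$molar_fraction, unname(p$mean_fractions))
})

test_that("Dirichlet draws center on the profile means (Monte Carlo)", {
  p <- default_diet_profiles()$HFD
  n <- 2000
  draws <- withr::with_seed(77, {
    vapply(seq_len(n), function(i) sample_composition(p)$molar_fraction,
           numeric(length(p$mean_fractions)))
  })
  emp <- rowMeans(draws)
  se <- apply(draws, 1, sd) / sqrt(n)
  expect_true(all(abs(emp - unname(p$mean_fractions)) <= 3 * se + 1e-4))
})

test_that("band spectra obey linearity and group-count structure", {
  wl <- instrument_wavelengths()
  bands <- band_model()
  comp <- fatty_acid_composition(c("16:0" = 0.5, "18:3" = 0.5))

  zero <- band_model(weights = c(ch3 = 0, ch2 = 0, ch = 0),
                     water_amplitude = 0)
  base <- absorption_spectrum(comp, 100, zero, wl,
                              baseline_offset = 0.05, baseline_slope = 0.02)
  expect_equal(base,
               0.05 + 0.02 * (wl - wl[1]) / diff(range(wl)))

  a1 <- absorption_spectrum(comp, 100, bands, wl)
  a2 <- absorption_spectrum(comp, 200, bands, wl)
  water <- absorption_spectrum(comp, 0, bands, wl)
  expect_equal(a2 - water, 2 * (a1 - water), tolerance = 1e-12)

  # CH band at ~1190 nm: absent for saturated 16:0, present for 18:3
  i1190 <- which.min(abs(wl - 1190))
  sat <- absorption_spectrum(fatty_acid_composition(c("16:0" = 1)), 100,
                             band_model(weights = c(ch3 = 0, ch2 = 0, ch = 1),
                                        water_amplitude = 0), wl)
  poly <- absorption_spectrum(fatty_acid_composition(c("18:3" = 1)), 100,
                              band_model(weights = c(ch3 = 0, ch2 = 0, ch = 1),
                                         water_amplitude = 0), wl)
  expect_equal(sat[i1190], 0)
  expect_gt(poly[i1190], 0)
})

test_that("rendered frames satisfy the zero-absorbance identity", {
  # a profile with zero lipid scale gives A = 0 when baselines/water are off
  p <- default_diet_profiles()$ND
  scn <- lobe_scene(p, 6, 6, readout_sd = 0, shot_scale = 0, spike_rate = 0,
                    baseline_offset_range = c(0, 0),
                    baseline_slope_range = c(0, 0), seed = 3)
  bands0 <- band_model(weights = c(ch3 = 0, ch2 = 0, ch = 0),
                       water_amplitude = 0)
  rc <- render_cube(scn, bands = bands0)
  sel <- array(rep(rc$mask, dim(rc$raw$data)[3]), dim(rc$raw$data))
  expect_equal(rc$raw$data[sel], rc$white$data[sel])
})

test_that("identical scene spec and seed give bit-identical cubes", {
  p <- default_diet_profiles()$HCD
  scn <- lobe_scene(p, 8, 8, seed = 123)
  a <- render_cube(scn)
  b <- render_cube(scn)
  expect_identical(a$raw$data, b$raw$data)
  expect_identical(a$truth$lipid, b$truth$lipid)
})

test_that("zero-noise render/preprocess round trip recovers the absorbance", {
  rc <- render_noiseless_lobe()
  refl <- to_reflectance(rc$raw, rc$dark, rc$white)
  refl <- remove_spikes(refl) # must be a no-op on a spike-free cube
  ab <- crop_wavelengths(to_absorbance(refl))
  truth <- crop_wavelengths(
    hyper_cube(rc$absorbance, rc$raw$wavelengths, "absorbance",
               mask = rc$mask)
  )
  expect_masked_equal(ab, truth$data, rc$mask, tol = 1e-6)
})

test_that("diet clusters separate on the generated HCL/DS plane", {
  profiles <- default_diet_profiles()
  stats <- withr::with_seed(55, {
    lapply(profiles[c("LA2", "HCD")], function(p) {
      draws <- t(vapply(1:30, function(i) {
        pr <- composition_profile(sample_composition(p))
        c(pr$hcl, pr$ds)
      }, numeric(2)))
      colMeans(draws)
    })
  })
  expect_lt(stats$LA2[1], stats$HCD[1]) # lower chain length under low-LA
  expect_gt(stats$LA2[2], stats$HCD[2]) # higher saturation under low-LA
})
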
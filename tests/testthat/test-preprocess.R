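# Reflectance correction, spike removal, absorbance, crop, mean spectrum,
# SNV.

test_that("reflectance correction matches the direct arithmetic oracle", {
  fx <- make_reference_frames(frac = 0.25)
  refl <- to_reflectance(fx$raw, fx$dark, fx$white)
  expect_equal(unique(as.numeric(refl$data)), 0.25)

  refl1 <- to_reflectance(fx$white, fx$dark, fx$white)
  expect_true(all(refl1$data == 1))
  refl0 <- to_reflectance(fx$dark, fx$dark, fx$white)
  expect_true(all(refl0$data == 0))
})

test_that("degenerate white references mask pixels instead of dividing", {
  fx <- make_reference_frames()
  bad_white <- fx$white
  bad_white$data[1, 1, 3] <- fx$dark$data[1, 1, 3] # white == dark at one band
  refl <- to_reflectance(fx$raw, fx$dark, bad_white)
  expect_false(refl$mask[1, 1])
  expect_true(all(refl$mask[-1, ]))
  expect_true(all(is.na(refl$data[1, 1, ])))
  expect_true(all(is.finite(refl$data[2, , ])))
  # all-degenerate references are an error, not an empty result
  expect_error(to_reflectance(fx$raw, fx$dark, fx$dark), "unusable")
})

test_that("mismatched cube axes are rejected", {
  fx <- make_reference_frames()
  other <- hyper_cube(fx$raw$data, fx$wl + 5, "raw")
  expect_error(to_reflectance(other, fx$dark, fx$white), "wavelength axis")
})

test_that("spike removal fixes injected outliers and nothing else", {
  cube <- make_smooth_reflectance()
  clean <- remove_spikes(cube)
  expect_equal(clean$data, cube$data) # spike-free input untouched

  spiked <- cube
  spiked$data[1, 2, 40] <- spiked$data[1, 2, 40] + 1.5 # huge one-band spike
  fixed <- remove_spikes(spiked)
  # replaced by the local running median: close to the smooth value, tiny
  # against the injected 1.5 spike
  expect_lt(abs(fixed$data[1, 2, 40] - cube$data[1, 2, 40]), 0.05)
  expect_equal(fixed$data[1, 2, -40], cube$data[1, 2, -40])
  expect_equal(fixed$data[2, 1, ], cube$data[2, 1, ])
})

test_that("absorbance is the decadic log of 1/R", {
  wl <- seq(1000, 1100, length.out = 5)
  r <- array(rep(c(1, 0.1, 0.5, 0.25, 0.9), each = 4), c(2, 2, 5))
  ab <- to_absorbance(hyper_cube(r, wl, "reflectance"))
  expect_equal(ab$data[1, 1, ], c(0, 1, log10(2), log10(4), -log10(0.9)))
})

test_that("non-positive reflectance masks the pixel out", {
  wl <- seq(1000, 1100, length.out = 5)
  r <- array(0.5, c(2, 2, 5))
  r[2, 2, 3] <- 0
  ab <- to_absorbance(hyper_cube(r, wl, "reflectance"))
  expect_false(ab$mask[2, 2])
  expect_true(all(ab$mask[1, ]))
})

test_that("crop keeps the closed 1000-1400 nm interval on the camera grid", {
  wl <- instrument_wavelengths() # 760-1884.2 nm at 2.2 nm
  cube <- hyper_cube(array(1, c(1, 1, length(wl))), wl, "absorbance")
  kept <- crop_wavelengths(cube)$wavelengths
  expect_true(all(kept >= 1000 & kept <= 1400))
  expect_equal(sum(wl >= 1000 & wl <= 1400), length(kept))

  # endpoints are kept: closed interval
  wl2 <- seq(996, 1404, by = 2) # hits 1000 and 1400 exactly
  cube2 <- hyper_cube(array(1, c(1, 1, length(wl2))), wl2, "absorbance")
  kept2 <- crop_wavelengths(cube2)$wavelengths
  expect_equal(range(kept2), c(1000, 1400))

  # an axis already inside the interval is untouched
  wl3 <- seq(1100, 1300, by = 10)
  cube3 <- hyper_cube(array(1, c(1, 1, length(wl3))), wl3, "absorbance")
  expect_equal(crop_wavelengths(cube3)$wavelengths, wl3)

  expect_error(crop_wavelengths(cube3, 2000, 2100), "no bands")
})

test_that("mean sample spectrum is the bandwise pixel mean", {
  wl <- seq(1000, 1100, length.out = 8)
  s <- sin(wl / 50) + 2
  t_ <- cos(wl / 50) + 2
  data <- array(NA_real_, c(2, 2, 8))
  data[1, 1, ] <- s; data[2, 1, ] <- s
  data[1, 2, ] <- t_; data[2, 2, ] <- t_
  cube <- hyper_cube(data, wl, "reflectance")
  m <- mean_sample_spectrum(cube)
  expect_equal(m$reflectance, (s + t_) / 2)
  expect_equal(attr(m, "n_pixels"), 4L)

  single <- mean_sample_spectrum(cube, matrix(c(TRUE, FALSE, FALSE, FALSE), 2))
  expect_equal(single$reflectance, s)
  expect_error(mean_sample_spectrum(cube, matrix(FALSE, 2, 2)), "empty")
})

test_that("SNV standardizes with the sample SD and is affine invariant", {
  expect_equal(snv(c(1, 2, 3)), c(-1, 0, 1))
  expect_equal(snv(c(1, 2, 3), sd_type = "population"),
               c(-1, 0, 1) * sqrt(3 / 2))
  expect_error(snv(rep(1, 5)), "zero-variance")
  expect_error(snv(1), "length")

  withr::with_seed(99, {
    for (i in 1:1000) {
      x <- rnorm(20)
      z <- snv(x)
      expect_equal(mean(z), 0, tolerance = 1e-9)
      expect_equal(sd(z), 1, tolerance = 1e-9)
      a <- runif(1, 0.1, 5); b <- rnorm(1, 0, 10)
      expect_equal(snv(a * x + b), z, tolerance = 1e-8)
    }
  })
  # idempotence
  x <- rnorm(30)
  expect_equal(snv(snv(x)), snv(x))
})

test_that("masks only shrink along the pipeline", {
  rc <- render_noiseless_lobe(h = 6, w = 6, seed = 21)
  refl <- to_reflectance(rc$raw, rc$dark, rc$white)
  desp <- remove_spikes(refl)
  ab <- to_absorbance(desp)
  cr <- crop_wavelengths(ab)
  expect_true(all(desp$mask <= refl$mask))
  expect_true(all(ab$mask <= desp$mask))
  expect_true(all(cr$mask <= ab$mask))
})

test_that("per-sample preprocessing emits a kept-band SNV spectrum", {
  rc <- render_noiseless_lobe(h = 6, w = 6, seed = 12)
  sp <- preprocess_sample(rc$raw, rc$dark, rc$white, mask = rc$mask)
  expect_true(all(sp$wavelength >= 1000 & sp$wavelength <= 1400))
  expect_equal(mean(sp$snv), 0, tolerance = 1e-9)
  expect_equal(sd(sp$snv), 1, tolerance = 1e-9)
  expect_equal(sp$absorbance, -log10(sp$reflectance))
})
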
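# Synthetic diet-structured liver scenes: fatty-acid compositions drawn from
# Dirichlet-distributed diet profiles, Beer-Lambert-style absorbance built
# from CH3/CH2/CH overtone bands, and raw/dark/white frames as a line-scan
# instrument would record them.

# Fixed small molar fractions for the 13 minor panel acids (sum 0.2); the
# three major acids (16:0, 18:2, 18:3) are solved per diet to hit the target
# tissue HCL and DS.
default_minor_fractions <- function() {
  c("14:0" = 0.010, "16:1" = 0.020, "17:0" = 0.002, "18:0" = 0.040,
    "18:1" = 0.060, "20:1" = 0.004, "20:2" = 0.004, "20:3" = 0.008,
    "20:4" = 0.030, "20:5" = 0.004, "22:4" = 0.002, "22:5" = 0.004,
    "22:6" = 0.012)
}

# Solve the 16:0 / 18:2 / 18:3 fractions so that the pooled profile of the
# full composition equals (hcl, ds). Linear 3x3 system:
#   sum f              = 1 - sum(minor)
#   sum f * C          = hcl - sum(minor * C)
#   sum f * (sat - ds*tot) = ds * tot_minor - sat_minor
# with sat = C - 2 - 2d (CH2 count) and tot = C - 2 (CH + CH2 count).
solve_major_fractions <- function(hcl, ds, minors = default_minor_fractions()) {
  mp <- fatty_acid_properties(names(minors))
  majors <- fatty_acid_properties(c("16:0", "18:2", "18:3"))
  mass <- 1 - sum(minors)
  a <- rbind(
    rep(1, 3),
    majors$carbons,
    majors$n_ch2 - ds * (majors$n_ch + majors$n_ch2)
  )
  b <- c(
    mass,
    hcl - sum(minors * mp$carbons),
    ds * sum(minors * (mp$n_ch + mp$n_ch2)) - sum(minors * mp$n_ch2)
  )
  f <- drop(solve(a, b))
  if (any(f < 0)) {
    stop("target (HCL = ", hcl, ", DS = ", ds,
         ") is not reachable with non-negative major fractions",
         call. = FALSE)
  }
  names(f) <- majors$fatty_acid
  f
}

#' Define a diet profile for the synthetic generator
#'
#' A diet profile is the generative description of one feeding group: mean
#' molar fractions over the fatty-acid panel (solved so the pooled tissue
#' profile matches the group's target HCL and DS), a Dirichlet concentration
#' controlling lobe-to-lobe compositional scatter, and the group's total
#' lipid mean and SD.
#'
#' @param name group label.
#' @param hcl,ds target pooled tissue HCL and DS of the mean composition.
#' @param lipid_mean,lipid_sd total lipid content distribution, mg/g
#'   (sampled truncated-normal at 0).
#' @param concentration Dirichlet concentration (dimensionless, > 0; larger
#'   means tighter around the mean fractions; `Inf` degenerates to the mean).
#' @param minor_fractions named fractions for the non-major panel acids.
#' @return a list of class `diet_profile` with `name`, `mean_fractions`
#'   (named, summing to 1), `concentration`, `lipid_mean`, `lipid_sd`.
#' @export
diet_profile <- function(name, hcl, ds, lipid_mean, lipid_sd,
                         concentration = 300,
                         minor_fractions = default_minor_fractions()) {
  stopifnot(lipid_mean > 0, lipid_sd >= 0, concentration > 0)
  majors <- solve_major_fractions(hcl, ds, minor_fractions)
  mean_fractions <- c(majors, minor_fractions)
  # order by carbon then unsaturation for stable panels
  p <- parse_cn_d(names(mean_fractions))
  ord <- order(p$carbons, p$double_bonds)
  mean_fractions <- mean_fractions[ord]
  structure(
    list(name = name, mean_fractions = mean_fractions,
         concentration = concentration,
         lipid_mean = lipid_mean, lipid_sd = lipid_sd),
    class = "diet_profile"
  )
}

#' Default diet profiles
#'
#' Five feeding groups — normal diet (ND), high-fat diet (HFD),
#' high-cholesterol diet (HCD) and HFD with 2% or 12% linoleic acid — with
#' group-level tissue HCL, DS and total-lipid statistics of a diet-modified
#' mouse-liver study: HCL increases in the order 2% LA < 12% LA < HFD < ND <
#' HCD while DS decreases in that order, and lipid accumulation is highest
#' under HCD/HFD.
#'
#' @return named list of [diet_profile()] objects.
#' @export
default_diet_profiles <- function() {
  list(
    LA2 = diet_profile("LA2", hcl = 17.22, ds = 0.83,
                       lipid_mean = 80.4, lipid_sd = 27.8),
    LA12 = diet_profile("LA12", hcl = 17.54, ds = 0.81,
                        lipid_mean = 65.2, lipid_sd = 24.2),
    HFD = diet_profile("HFD", hcl = 17.56, ds = 0.79,
                       lipid_mean = 135.0, lipid_sd = 54.2),
    ND = diet_profile("ND", hcl = 17.72, ds = 0.77,
                      lipid_mean = 66.2, lipid_sd = 20.2),
    HCD = diet_profile("HCD", hcl = 17.83, ds = 0.75,
                       lipid_mean = 174.2, lipid_sd = 35.8)
  )
}

#' Draw a lobe composition from a diet profile
#'
#' Molar fractions are a Dirichlet draw with parameter
#' `concentration * mean_fractions` (so the expectation is the profile mean)
#' and the total lipid content is normal truncated at zero.
#'
#' @param profile a [diet_profile()].
#' @param seed optional integer; when given the draw is reproducible and the
#'   global RNG state is untouched.
#' @return an [fatty_acid_composition()] with `total_lipid` set.
#' @export
sample_composition <- function(profile, seed = NULL) {
  stopifnot(inherits(profile, "diet_profile"))
  draw <- function() {
    p <- profile$mean_fractions
    if (is.infinite(profile$concentration)) {
      f <- p
    } else {
      g <- rep(0, length(p))
      pos <- p > 0
      g[pos] <- rgamma(sum(pos), shape = profile$concentration * p[pos])
      if (sum(g) <= 0) stop("degenerate Dirichlet draw", call. = FALSE)
      f <- g / sum(g)
      names(f) <- names(p)
    }
    lipid <- repeat_until_positive(profile$lipid_mean, profile$lipid_sd)
    fatty_acid_composition(f, total_lipid = lipid)
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

repeat_until_positive <- function(mean, sd) {
  for (i in 1:1000) {
    x <- rnorm(1, mean, sd)
    if (x > 0) return(x)
  }
  stop("could not draw a positive lipid content", call. = FALSE)
}

#' NIR band model for the synthetic spectra
#'
#' Gaussian overtone bands for the three aliphatic groups — CH3 near
#' 1150 nm, the CH2 second overtone near 1175 nm, olefinic CH near
#' 1190 nm — plus a rising water absorption edge above ~1400 nm and a global
#' lipid absorptivity scale. Band weights are free parameters of the
#' generator: only recovery of composition statistics, not absolute spectra,
#' is meaningful.
#'
#' @param centers,widths,weights named numeric vectors over `ch3`, `ch2`,
#'   `ch` (nm, nm, dimensionless).
#' @param water_edge,water_scale,water_amplitude logistic water-edge
#'   parameters (nm, nm, absorbance units).
#' @param lipid_scale absorbance per (mg/g lipid x group count).
#' @return a list of class `band_model`.
#' @export
band_model <- function(centers = c(ch3 = 1150, ch2 = 1175, ch = 1190),
                       widths = c(ch3 = 12, ch2 = 12, ch = 12),
                       weights = c(ch3 = 0.9, ch2 = 1.0, ch = 1.1),
                       water_edge = 1400, water_scale = 25,
                       water_amplitude = 0.4, lipid_scale = 2e-4) {
  stopifnot(all(widths > 0), water_scale > 0, lipid_scale > 0)
  structure(
    list(centers = centers, widths = widths, weights = weights,
         water_edge = water_edge, water_scale = water_scale,
         water_amplitude = water_amplitude, lipid_scale = lipid_scale),
    class = "band_model"
  )
}

# Pooled per-molecule group counts of a composition: CH3 is always 1 per
# molecule; CH2 and CH are molar-fraction-weighted counts.
group_concentrations <- function(comp) {
  f <- comp$molar_fraction
  c(ch3 = sum(f),
    ch2 = sum(f * (comp$carbons - 2L - 2L * comp$double_bonds)),
    ch = sum(f * 2L * comp$double_bonds))
}

#' Synthetic absorbance spectrum of a tissue composition
#'
#' Beer-Lambert-style construction: each functional group contributes a
#' Gaussian band whose amplitude is (lipid content) x (pooled group count) x
#' (band weight) x (global absorptivity scale); a logistic water edge and an
#' affine scatter baseline are added on top. Doubling the lipid content at
#' fixed composition doubles the band component exactly.
#'
#' @param comp an [fatty_acid_composition()].
#' @param lipid total lipid content, mg/g.
#' @param bands a [band_model()].
#' @param wavelengths strictly increasing wavelength axis, nm.
#' @param baseline_offset,baseline_slope affine scatter baseline; the slope
#'   term ramps linearly from 0 to `baseline_slope` across the axis. Both
#'   must be non-negative so the spectrum stays non-negative.
#' @return absorbance vector over `wavelengths`.
#' @export
absorption_spectrum <- function(comp, lipid, bands = band_model(),
                                wavelengths = instrument_wavelengths(),
                                baseline_offset = 0, baseline_slope = 0) {
  stopifnot(inherits(comp, "fa_composition"), length(wavelengths) >= 2L,
            all(diff(wavelengths) > 0), is.finite(lipid), lipid >= 0,
            baseline_offset >= 0, baseline_slope >= 0)
  conc <- group_concentrations(comp)
  a <- numeric(length(wavelengths))
  for (g in names(bands$centers)) {
    a <- a + bands$weights[[g]] * conc[[g]] *
      exp(-(wavelengths - bands$centers[[g]])^2 / (2 * bands$widths[[g]]^2))
  }
  a <- bands$lipid_scale * lipid * a
  a <- a + bands$water_amplitude *
    stats::plogis((wavelengths - bands$water_edge) / bands$water_scale)
  w01 <- (wavelengths - wavelengths[1]) / diff(range(wavelengths))
  a + baseline_offset + baseline_slope * w01
}

#' Describe a synthetic scene
#'
#' A scene is an image grid with an integer region-label matrix (0 =
#' background), one diet profile per region (a region is one tissue sample),
#' noise and artifact levels, and a seed that fixes the full generated cube.
#'
#' @param labels integer matrix, 0 for background, `1..R` for regions.
#' @param profiles list of [diet_profile()]s, one per region label.
#' @param readout_sd additive Gaussian readout noise SD, counts.
#' @param shot_scale multiplier on `sqrt(signal)` shot-like noise.
#' @param spike_rate per-(pixel, band) probability of an isolated positive
#'   spike (>= 10 local noise SDs) in the raw frame.
#' @param baseline_offset_range,baseline_slope_range per-pixel uniform
#'   ranges of the scatter baseline (non-negative).
#' @param seed integer seed fixing every random element of the scene.
#' @return a list of class `scene_spec`.
#' @export
scene_spec <- function(labels, profiles, readout_sd = 5, shot_scale = 1,
                       spike_rate = 1e-4,
                       baseline_offset_range = c(0, 0.1),
                       baseline_slope_range = c(0, 0.08), seed = 1L) {
  labels <- as.matrix(labels)
  storage.mode(labels) <- "integer"
  r <- max(labels)
  stopifnot(r >= 1L, length(profiles) == r, all(labels >= 0L),
            readout_sd >= 0, shot_scale >= 0,
            spike_rate >= 0, spike_rate <= 1,
            all(baseline_offset_range >= 0), all(baseline_slope_range >= 0))
  for (p in profiles) stopifnot(inherits(p, "diet_profile"))
  structure(
    list(labels = labels, profiles = profiles, readout_sd = readout_sd,
         shot_scale = shot_scale, spike_rate = spike_rate,
         baseline_offset_range = baseline_offset_range,
         baseline_slope_range = baseline_slope_range,
         seed = as.integer(seed)),
    class = "scene_spec"
  )
}

# Elliptical lobe mask on a height x width grid.
elliptical_labels <- function(height, width, fill = 0.85) {
  y <- (seq_len(height) - (height + 1) / 2) / (height / 2)
  x <- (seq_len(width) - (width + 1) / 2) / (width / 2)
  m <- outer(y, x, function(yy, xx) (yy / fill)^2 + (xx / fill)^2 <= 1)
  matrix(as.integer(m), height, width)
}

#' Single-lobe and tumor-bearing scenes
#'
#' `lobe_scene()` is an elliptical tissue region on background;
#' `tumor_scene()` embeds a circular tumor region (its own diet profile,
#' typically lower DS and higher lipid) inside the lobe.
#'
#' @param profile,normal_profile,tumor_profile [diet_profile()]s.
#' @param height,width image size in pixels.
#' @param tumor_radius tumor radius in pixels.
#' @param ... passed to [scene_spec()] (noise levels, seed, ...).
#' @return a [scene_spec()].
#' @export
lobe_scene <- function(profile, height = 12L, width = 12L, ...) {
  scene_spec(elliptical_labels(height, width), list(profile), ...)
}

#' @rdname lobe_scene
#' @export
tumor_scene <- function(normal_profile, tumor_profile,
                        height = 32L, width = 32L,
                        tumor_radius = height / 5, ...) {
  labels <- elliptical_labels(height, width)
  cy <- height * 0.4; cx <- width * 0.6
  tum <- outer(seq_len(height), seq_len(width),
               function(y, x) (y - cy)^2 + (x - cx)^2 <= tumor_radius^2)
  labels[tum & labels == 1L] <- 2L
  scene_spec(labels, list(normal_profile, tumor_profile), ...)
}

#' Render a scene into raw/dark/white hyperspectral frames
#'
#' One composition and lipid content are drawn per region; every tissue
#' pixel gets its own scatter baseline, the Beer-Lambert absorbance is
#' converted to raw counts as `signal x 10^(-A) + dark current`, and
#' shot-like plus readout noise and isolated single-band spikes are added to
#' the raw frame. The white reference frame stores illumination signal plus
#' dark current (as an instrument records it) and the dark frame the dark
#' current alone, so reflectance correction recovers `10^(-A)` exactly at
#' zero noise. Background pixels reflect a constant 2%.
#'
#' @param scene a [scene_spec()].
#' @param bands a [band_model()].
#' @param wavelengths wavelength axis, nm.
#' @return a list of class `rendered_scene`: `raw`, `dark`, `white`
#'   ([hyper_cube()]s), `mask` (tissue logical matrix), `labels`, and
#'   `truth` (per-region tibble with `label`, `diet`, `lipid`, `hcl`, `ds`
#'   and a `composition` list-column, plus the noise-free `absorbance`
#'   array).
#' @export
render_cube <- function(scene, bands = band_model(),
                        wavelengths = instrument_wavelengths()) {
  stopifnot(inherits(scene, "scene_spec"))
  withr::with_seed(scene$seed, {
    labels <- scene$labels
    h <- nrow(labels); w <- ncol(labels); nb <- length(wavelengths)
    n_regions <- max(labels)

    wl13 <- (wavelengths - 1300) / 600
    signal <- 3000 * (1 - 0.3 * wl13^2) # smooth halogen-lamp envelope
    dark_level <- rep(100, nb)

    regions <- vector("list", n_regions)
    for (r in seq_len(n_regions)) {
      comp <- sample_composition(scene$profiles[[r]])
      prof <- composition_profile(comp)
      regions[[r]] <- list(comp = comp, lipid = attr(comp, "total_lipid"),
                           hcl = prof$hcl, ds = prof$ds)
    }

    absorb <- array(NA_real_, c(h, w, nb))
    raw <- array(rep(signal * 0.02 + dark_level, each = h * w), c(h, w, nb))
    tissue <- which(labels > 0L)
    for (idx in tissue) {
      r <- labels[idx]
      off <- runif(1, scene$baseline_offset_range[1],
                   scene$baseline_offset_range[2])
      slo <- runif(1, scene$baseline_slope_range[1],
                   scene$baseline_slope_range[2])
      a <- absorption_spectrum(regions[[r]]$comp, regions[[r]]$lipid,
                               bands, wavelengths,
                               baseline_offset = off, baseline_slope = slo)
      absorb[arrayInd(idx, c(h, w))[1], arrayInd(idx, c(h, w))[2], ] <- a
      raw[arrayInd(idx, c(h, w))[1], arrayInd(idx, c(h, w))[2], ] <-
        signal * 10^(-a) + dark_level
    }

    if (scene$shot_scale > 0 || scene$readout_sd > 0) {
      clean <- raw
      noise_sd <- sqrt(pmax(scene$shot_scale^2 * pmax(clean - 100, 0), 0) +
                       scene$readout_sd^2)
      raw <- clean + array(rnorm(length(raw)), dim(raw)) * noise_sd
    } else {
      noise_sd <- array(0, dim(raw))
    }

    if (scene$spike_rate > 0) {
      hit <- which(runif(length(raw)) < scene$spike_rate)
      if (length(hit)) {
        local_sd <- pmax(noise_sd[hit], 1)
        raw[hit] <- raw[hit] + runif(length(hit), 10, 20) * local_sd
      }
    }

    truth <- tibble::tibble(
      label = seq_len(n_regions),
      diet = vapply(scene$profiles, function(p) p$name, ""),
      lipid = vapply(regions, function(r) r$lipid, 1),
      hcl = vapply(regions, function(r) r$hcl, 1),
      ds = vapply(regions, function(r) r$ds, 1),
      composition = lapply(regions, function(r) r$comp)
    )

    structure(
      list(
        raw = hyper_cube(raw, wavelengths, "raw"),
        dark = hyper_cube(array(rep(dark_level, each = h * w), c(h, w, nb)),
                          wavelengths, "dark"),
        white = hyper_cube(array(rep(signal + dark_level, each = h * w),
                                 c(h, w, nb)), wavelengths, "white"),
        mask = labels > 0L,
        labels = labels,
        truth = truth,
        absorbance = absorb,
        scene = scene
      ),
      class = "rendered_scene"
    )
  })
}

#' Simulate a diet-structured calibration set
#'
#' Renders one small lobe scene per sample (cycling over the diet profiles),
#' runs the full preprocessing chain (reflectance, spike removal, masked
#' mean spectrum, absorbance, crop, SNV) and assembles the SNV features with
#' the generated lipid/HCL/DS labels — the synthetic stand-in for pairing
#' instrument spectra with Folch/GC reference values.
#'
#' @param n_per_diet lobes per diet group.
#' @param profiles list of [diet_profile()]s.
#' @param height,width lobe image size in pixels.
#' @param seed integer; fixes every sample's scene.
#' @param crop kept wavelength interval, nm.
#' @param ... passed to [lobe_scene()] (noise levels, spike rate, ...).
#' @return a [calibration_set()] whose `targets` carry `sample_id`, `diet`,
#'   `lipid`, `hcl`, `ds`.
#' @export
simulate_calibration <- function(n_per_diet = 20L,
                                 profiles = default_diet_profiles(),
                                 height = 12L, width = 12L, seed = 1L,
                                 crop = c(1000, 1400), ...) {
  n <- n_per_diet * length(profiles)
  scene_seeds <- withr::with_seed(seed, sample.int(.Machine$integer.max, n))
  feats <- NULL
  targets <- vector("list", n)
  i <- 0L
  for (rep in seq_len(n_per_diet)) {
    for (p in profiles) {
      i <- i + 1L
      scn <- lobe_scene(p, height = height, width = width,
                        seed = scene_seeds[i], ...)
      rc <- render_cube(scn)
      sp <- preprocess_sample(rc$raw, rc$dark, rc$white, mask = rc$mask,
                              crop = crop)
      if (is.null(feats)) {
        feats <- matrix(NA_real_, n, nrow(sp))
        kept_wl <- sp$wavelength
      }
      feats[i, ] <- sp$snv
      targets[[i]] <- tibble::tibble(
        sample_id = sprintf("%s_%02d", p$name, rep), diet = p$name,
        lipid = rc$truth$lipid[1], hcl = rc$truth$hcl[1],
        ds = rc$truth$ds[1]
      )
    }
  }
  calibration_set(feats, kept_wl, do.call(rbind, targets))
}
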
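# Raw -> reflectance -> absorbance -> SNV preprocessing for hyperspectral
# cubes, per-sample (masked mean spectrum, for calibration) and per-pixel
# (for mapping).

#' Hyperspectral cube container
#'
#' A 3-D intensity array indexed `(y, x, band)` with its wavelength axis and
#' frame role. `y` is the scan axis. Reflectance/absorbance cubes
#' additionally carry a per-pixel validity mask; operations only ever shrink
#' the mask.
#'
#' @param data numeric array `(y, x, band)`, all values finite on valid
#'   pixels.
#' @param wavelengths strictly increasing band centers, nm; length must
#'   match `dim(data)[3]`.
#' @param role one of `"raw"`, `"dark"`, `"white"`, `"reflectance"`,
#'   `"absorbance"`.
#' @param mask optional logical `(y, x)` validity matrix.
#' @return an object of class `hyper_cube`.
#' @export
hyper_cube <- function(data, wavelengths,
                       role = c("raw", "dark", "white", "reflectance",
                                "absorbance"),
                       mask = NULL) {
  role <- match.arg(role)
  stopifnot(is.array(data), length(dim(data)) == 3L,
            dim(data)[3] == length(wavelengths),
            all(diff(wavelengths) > 0))
  if (is.null(mask)) mask <- matrix(TRUE, dim(data)[1], dim(data)[2])
  stopifnot(is.logical(mask), all(dim(mask) == dim(data)[1:2]))
  structure(list(data = data, wavelengths = as.numeric(wavelengths),
                 role = role, mask = mask),
            class = "hyper_cube")
}

#' @export
print.hyper_cube <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<hyper_cube %s> %d x %d pixels, %d bands (%.1f-%.1f nm), %d masked-in\n",
              x$role, d[1], d[2], d[3], min(x$wavelengths),
              max(x$wavelengths), sum(x$mask)))
  invisible(x)
}

check_same_geometry <- function(a, b) {
  if (!all(dim(a$data) == dim(b$data)) ||
      !isTRUE(all.equal(a$wavelengths, b$wavelengths))) {
    stop("cubes do not share geometry and wavelength axis", call. = FALSE)
  }
}

#' Convert raw counts to relative reflectance
#'
#' Per pixel and band, `R = (raw - dark) / (white - dark)`. Pixels whose
#' white-minus-dark denominator falls below `tol` times the white-frame
#' scale at any band are masked out rather than propagated as infinities.
#'
#' @param raw,dark,white [hyper_cube()]s sharing geometry and wavelength
#'   axis.
#' @param tol relative denominator tolerance.
#' @return a reflectance [hyper_cube()].
#' @export
to_reflectance <- function(raw, dark, white, tol = 1e-12) {
  stopifnot(inherits(raw, "hyper_cube"), inherits(dark, "hyper_cube"),
            inherits(white, "hyper_cube"))
  check_same_geometry(raw, dark)
  check_same_geometry(raw, white)
  denom <- white$data - dark$data
  scale <- max(abs(white$data))
  bad_px <- apply(abs(denom) < tol * scale, c(1, 2), any)
  mask <- raw$mask & dark$mask & white$mask & !bad_px
  if (!any(mask)) {
    stop("all pixels masked out: unusable white/dark references",
         call. = FALSE)
  }
  r <- (raw$data - dark$data) / denom
  r[array(rep(!mask, dim(r)[3]), dim(r))] <- NA_real_
  hyper_cube(r, raw$wavelengths, "reflectance", mask = mask)
}

#' Remove isolated spectral spikes
#'
#' Cosmic-ray-style single-band outliers are detected per pixel along the
#' spectral axis: values deviating from a running median by more than
#' `z_threshold` robust SDs (1.4826 x median absolute residual) are replaced
#' by the local median. Smooth absorption bands (tens of nm wide on a 2.2 nm
#' grid) sit well below the default threshold and pass untouched.
#'
#' @param cube a [hyper_cube()] with at least 5 bands.
#' @param z_threshold robust z-score threshold.
#' @param window odd running-median window length, bands.
#' @return the despiked cube.
#' @export
remove_spikes <- function(cube, z_threshold = 6, window = 7L) {
  stopifnot(inherits(cube, "hyper_cube"), dim(cube$data)[3] >= 5L,
            window %% 2L == 1L, z_threshold > 0)
  d <- cube$data
  h <- dim(d)[1]; w <- dim(d)[2]
  for (idx in which(cube$mask)) {
    yy <- ((idx - 1L) %% h) + 1L
    xx <- ((idx - 1L) %/% h) + 1L
    x <- d[yy, xx, ]
    med <- runmed(x, window, endrule = "median")
    res <- x - med
    # robust scale; on noise-free spectra the median absolute residual is
    # exactly 0 (running medians reproduce monotone stretches), so fall
    # back to the upper residual quantile: smooth-curvature residuals set
    # the scale there and only far-out isolated bands are flagged
    s <- 1.4826 * median(abs(res))
    if (s <= 0) s <- stats::quantile(abs(res), 0.98, names = FALSE)
    if (s > 0) {
      out <- abs(res) > z_threshold * s
      if (any(out)) d[yy, xx, out] <- med[out]
    }
  }
  hyper_cube(d, cube$wavelengths, cube$role, mask = cube$mask)
}

#' Convert reflectance to decadic absorbance
#'
#' `A = log10(1 / R)`. Pixels with non-positive reflectance at any band are
#' masked out (saturated or dead pixels have no defined absorbance).
#'
#' @param cube a reflectance [hyper_cube()].
#' @return an absorbance [hyper_cube()].
#' @export
to_absorbance <- function(cube) {
  stopifnot(inherits(cube, "hyper_cube"))
  nonpos <- apply(cube$data <= 0, c(1, 2), function(v) any(v, na.rm = TRUE))
  mask <- cube$mask & !nonpos
  if (!any(mask)) stop("all pixels masked out in absorbance conversion",
                       call. = FALSE)
  a <- -log10(cube$data)
  a[array(rep(!mask, dim(a)[3]), dim(a))] <- NA_real_
  hyper_cube(a, cube$wavelengths, "absorbance", mask = mask)
}

crop_index <- function(wavelengths, lo, hi) {
  stopifnot(all(diff(wavelengths) > 0), lo < hi)
  keep <- which(wavelengths >= lo & wavelengths <= hi)
  if (!length(keep)) {
    stop("no bands inside [", lo, ", ", hi, "] nm: wrong instrument range?",
         call. = FALSE)
  }
  keep
}

#' Crop to the analysed wavelength interval
#'
#' Keeps bands inside the closed interval `[lo, hi]` (default 1000-1400 nm:
#' below that the camera loses sensitivity, above it water dominates).
#' Works on a [hyper_cube()] or on a data frame with a `wavelength` column.
#'
#' @param x cube or data frame.
#' @param lo,hi interval bounds, nm (closed on both sides).
#' @return the cropped object, band order preserved.
#' @export
crop_wavelengths <- function(x, lo = 1000, hi = 1400) {
  if (inherits(x, "hyper_cube")) {
    keep <- crop_index(x$wavelengths, lo, hi)
    hyper_cube(x$data[, , keep, drop = FALSE], x$wavelengths[keep],
               x$role, mask = x$mask)
  } else if (is.data.frame(x)) {
    stopifnot("wavelength" %in% names(x))
    keep <- crop_index(x$wavelength, lo, hi)
    x[keep, , drop = FALSE]
  } else {
    stop("crop_wavelengths handles hyper_cube or data.frame", call. = FALSE)
  }
}

#' Masked mean spectrum of a sample
#'
#' Bandwise arithmetic mean of the reflectance spectra of the masked-in
#' pixels — the per-lobe representative spectrum. Averaging happens on
#' reflectance; conversion to absorbance comes after.
#'
#' @param cube a reflectance [hyper_cube()].
#' @param mask optional logical matrix further restricting the cube mask.
#' @return a tibble `(wavelength, reflectance)` with attribute `n_pixels`.
#' @export
mean_sample_spectrum <- function(cube, mask = NULL) {
  stopifnot(inherits(cube, "hyper_cube"))
  m <- cube$mask
  if (!is.null(mask)) {
    stopifnot(is.logical(mask), all(dim(mask) == dim(m)))
    m <- m & mask
  }
  n <- sum(m)
  if (n < 1L) stop("empty pixel mask", call. = FALSE)
  px <- pixel_matrix(cube, m)
  out <- tibble::tibble(wavelength = cube$wavelengths,
                        reflectance = colMeans(px))
  attr(out, "n_pixels") <- n
  out
}

# masked pixels as a (n_pixels x bands) matrix, rows in which(mask) order
pixel_matrix <- function(cube, mask = cube$mask) {
  nb <- dim(cube$data)[3]
  flat <- matrix(cube$data, ncol = nb)
  flat[which(mask), , drop = FALSE]
}

#' Standard normal variate (SNV) transform
#'
#' Standardizes a spectrum over its bands: `z = (x - mean(x)) / sd(x)`, with
#' the sample (n-1) standard deviation. SNV removes additive baseline
#' offsets and multiplicative scatter factors (it is invariant to
#' `a * x + b`, `a > 0`), which is its purpose here: compensating surface
#' scattering and dark-current drift. Matrices are transformed row-wise.
#'
#' @param x numeric vector (one spectrum) or matrix (spectra in rows).
#' @param sd_type `"sample"` (n-1, default) or `"population"` (n) standard
#'   deviation.
#' @return the transformed vector or matrix: each spectrum has mean 0 and
#'   (chosen-convention) SD 1.
#' @export
snv <- function(x, sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  if (is.matrix(x)) return(t(apply(x, 1, snv, sd_type = sd_type)))
  stopifnot(is.numeric(x), length(x) >= 2L, all(is.finite(x)))
  s <- sd(x)
  if (sd_type == "population") s <- s * sqrt((length(x) - 1) / length(x))
  if (s == 0) stop("zero-variance spectrum: degenerate (saturated?) pixel",
                   call. = FALSE)
  (x - mean(x)) / s
}

#' Preprocess one sample to a calibration spectrum
#'
#' The full per-sample chain: reflectance correction, spike removal, masked
#' mean reflectance spectrum, decadic absorbance, wavelength crop, SNV.
#'
#' @param raw,dark,white [hyper_cube()]s.
#' @param mask optional tissue mask (logical matrix).
#' @param spike_z,spike_window spike-removal parameters; `spike_z = NULL`
#'   skips the filter.
#' @param crop kept wavelength interval, nm.
#' @param snv_on `"absorbance"` (default) applies SNV to the absorbance
#'   spectrum; `"reflectance"` standardizes the reflectance spectrum before
#'   the log transform instead.
#' @return a tibble `(wavelength, reflectance, absorbance, snv)` restricted
#'   to the kept bands, with attribute `n_pixels`.
#' @export
preprocess_sample <- function(raw, dark, white, mask = NULL, spike_z = 6,
                              spike_window = 7L, crop = c(1000, 1400),
                              snv_on = c("absorbance", "reflectance")) {
  snv_on <- match.arg(snv_on)
  refl <- to_reflectance(raw, dark, white)
  if (!is.null(spike_z)) refl <- remove_spikes(refl, spike_z, spike_window)
  sp <- mean_sample_spectrum(refl, mask)
  keep <- crop_index(sp$wavelength, crop[1], crop[2])
  sp <- sp[keep, , drop = FALSE]
  if (any(sp$reflectance <= 0)) {
    stop("non-positive mean reflectance in kept bands", call. = FALSE)
  }
  sp$absorbance <- -log10(sp$reflectance)
  sp$snv <- if (snv_on == "absorbance") snv(sp$absorbance)
            else snv(sp$reflectance)
  out <- tibble::tibble(wavelength = sp$wavelength,
                        reflectance = sp$reflectance,
                        absorbance = sp$absorbance, snv = sp$snv)
  attr(out, "n_pixels") <- attr(sp, "n_pixels") %||% NA_integer_
  out
}

#' Preprocess a cube per pixel for mapping
#'
#' Same chain as [preprocess_sample()] but without pixel averaging: every
#' masked-in pixel becomes one SNV absorbance spectrum. Pixels with
#' non-positive reflectance or zero spectral variance are masked out.
#'
#' @inheritParams preprocess_sample
#' @return a list of class `processed_cube`: `features` (pixels x kept
#'   bands), `wavelengths`, `mask`, `pixel_index` (linear indices of feature
#'   rows in the image), `dim`.
#' @export
preprocess_pixels <- function(raw, dark, white, mask = NULL, spike_z = 6,
                              spike_window = 7L, crop = c(1000, 1400)) {
  refl <- to_reflectance(raw, dark, white)
  if (!is.null(mask)) {
    stopifnot(is.logical(mask), all(dim(mask) == dim(refl$mask)))
    refl$mask <- refl$mask & mask
    if (!any(refl$mask)) stop("empty pixel mask", call. = FALSE)
  }
  if (!is.null(spike_z)) refl <- remove_spikes(refl, spike_z, spike_window)
  ab <- to_absorbance(refl)
  ab <- crop_wavelengths(ab, crop[1], crop[2])
  px <- pixel_matrix(ab)
  keep_px <- apply(px, 1, function(v) all(is.finite(v)) && sd(v) > 0)
  idx <- which(ab$mask)[keep_px]
  feats <- snv(px[keep_px, , drop = FALSE])
  mask_out <- matrix(FALSE, dim(ab$data)[1], dim(ab$data)[2])
  mask_out[idx] <- TRUE
  structure(
    list(features = feats, wavelengths = ab$wavelengths, mask = mask_out,
         pixel_index = idx, dim = dim(ab$data)[1:2]),
    class = "processed_cube"
  )
}
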
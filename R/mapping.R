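# Visual outputs: pseudo-color NIR images, per-pixel prediction maps and
# region summaries, and the HCL/DS scatter with fatty-acid vertices.

#' Bundle per-pixel prediction rasters
#'
#' @param lipid,hcl,ds numeric `(y, x)` rasters (as from
#'   [predict_pixels()]); any subset may be supplied.
#' @param mask logical tissue mask; raster values outside it are dropped.
#' @return a list of class `prediction_map` with the rasters and `mask`.
#' @export
prediction_map <- function(lipid = NULL, hcl = NULL, ds = NULL, mask) {
  rasters <- Filter(Negate(is.null),
                    list(lipid = lipid, hcl = hcl, ds = ds))
  if (!length(rasters)) stop("no rasters supplied", call. = FALSE)
  stopifnot(is.logical(mask))
  for (r in rasters) {
    stopifnot(is.matrix(r), all(dim(r) == dim(mask)))
  }
  rasters <- lapply(rasters, function(r) { r[!mask] <- NA_real_; r })
  structure(c(rasters, list(mask = mask)), class = "prediction_map")
}

#' Pseudo-color NIR rendering
#'
#' Maps three wavelength bands of an absorbance cube to RGB channels
#' (defaults 1210 / 1190 / 1080 nm), choosing the nearest band on the grid
#' and rescaling each channel to [0, 1] by its masked-in minimum and
#' maximum. Background pixels render black.
#'
#' @param cube a processed absorbance [hyper_cube()].
#' @param r,g,b requested channel wavelengths, nm; must fall within one band
#'   spacing of a grid point.
#' @return numeric array `(y, x, 3)` in [0, 1].
#' @export
pseudo_color <- function(cube, r = 1210, g = 1190, b = 1080) {
  stopifnot(inherits(cube, "hyper_cube"))
  wl <- cube$wavelengths
  spacing <- max(diff(wl))
  pick <- function(target) {
    i <- which.min(abs(wl - target))
    if (abs(wl[i] - target) > spacing) {
      stop("requested wavelength ", target, " nm lies outside the cube grid",
           call. = FALSE)
    }
    i
  }
  idx <- vapply(c(r, g, b), pick, 1L)
  out <- array(0, c(dim(cube$data)[1:2], 3L))
  for (k in 1:3) {
    band <- cube$data[, , idx[k]]
    v <- band[cube$mask]
    rng <- range(v, finite = TRUE)
    chan <- matrix(0, nrow(band), ncol(band))
    chan[cube$mask] <- if (diff(rng) > 0) (v - rng[1]) / diff(rng) else 0.5
    out[, , k] <- chan
  }
  out
}

#' Summarize a prediction map over a region
#'
#' Mean and SD of each raster over a pixel region (whole lobe, tumor,
#' normal, ...). Regions must lie inside the tissue mask; two summaries
#' expose tumor-vs-normal contrasts directly.
#'
#' @param map a [prediction_map()].
#' @param region logical matrix selecting the region.
#' @param label region name for the output row.
#' @return a one-row tibble: `label`, `n_pixels`, then `<raster>_mean` and
#'   `<raster>_sd` per raster.
#' @export
summarize_region <- function(map, region, label = "region") {
  stopifnot(inherits(map, "prediction_map"), is.logical(region),
            all(dim(region) == dim(map$mask)))
  if (any(region & !map$mask)) {
    stop("region extends outside the tissue mask", call. = FALSE)
  }
  n <- sum(region)
  if (n < 1L) stop("empty region", call. = FALSE)
  out <- tibble::tibble(label = label, n_pixels = n)
  for (nm in setdiff(names(map), "mask")) {
    v <- map[[nm]][region]
    out[[paste0(nm, "_mean")]] <- mean(v)
    out[[paste0(nm, "_sd")]] <- sd(v)
  }
  out
}

#' Plot the HCL/DS plane
#'
#' Tissue points (colored by group) and fatty-acid vertices (labeled
#' triangles) on the chain-length (x) vs saturation (y) plane. When `file`
#' is given the figure is written as PNG and the plotted coordinates as
#' sibling CSVs (`<file>_points.csv`, `<file>_vertices.csv`).
#'
#' @param scatter an [hcl_ds_scatter_data()] object.
#' @param file optional output path prefix (no extension).
#' @param width,height,dpi figure geometry passed to [ggplot2::ggsave()].
#' @return the ggplot object, invisibly when writing files.
#' @export
render_hcl_ds_plot <- function(scatter, file = NULL, width = 6, height = 4.5,
                               dpi = 150) {
  stopifnot(inherits(scatter, "hcl_ds_scatter"))
  p <- ggplot2::ggplot() +
    ggplot2::geom_point(
      data = scatter$vertices,
      ggplot2::aes(x = .data$hcl, y = .data$ds),
      shape = 17, size = 2.5, color = "grey40"
    ) +
    ggplot2::geom_text(
      data = scatter$vertices,
      ggplot2::aes(x = .data$hcl, y = .data$ds, label = .data$fatty_acid),
      vjust = -0.8, size = 2.6, color = "grey40"
    ) +
    ggplot2::geom_point(
      data = scatter$points,
      ggplot2::aes(x = .data$hcl, y = .data$ds, color = .data$group),
      size = 2
    ) +
    ggplot2::labs(x = "Hydrocarbon chain length (HCL)",
                  y = "Degree of saturation (DS)", color = NULL) +
    ggplot2::theme_minimal()
  if (is.null(file)) return(p)
  readr::write_csv(scatter$points, paste0(file, "_points.csv"))
  readr::write_csv(scatter$vertices, paste0(file, "_vertices.csv"))
  ggplot2::ggsave(paste0(file, ".png"), p, width = width, height = height,
                  dpi = dpi)
  invisible(p)
}
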
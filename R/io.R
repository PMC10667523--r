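# Cube files (ENVI-convention text header + band-sequential binary), model
# serialization, run configuration and the pipeline driver.

#' Write / read a hyperspectral cube
#'
#' Cubes are stored in the ENVI convention emitted by line-scan instruments:
#' a text header `<path>.hdr` (geometry, data type, interleave, full-
#' precision wavelength vector, frame role) plus a band-sequential binary
#' payload `<path>.raw` of little-endian doubles. Round trips are
#' bit-identical.
#'
#' @param cube a [hyper_cube()].
#' @param path file path prefix (the `.hdr` / `.raw` extensions are added).
#' @return `write_cube` returns `path` invisibly; `read_cube` the cube.
#' @export
write_cube <- function(cube, path) {
  stopifnot(inherits(cube, "hyper_cube"))
  d <- dim(cube$data)
  wl <- paste(format(cube$wavelengths, digits = 17, scientific = FALSE,
                     trim = TRUE), collapse = ", ")
  header <- c(
    "ENVI",
    "description = {nirlipidmap hyperspectral cube}",
    paste0("samples = ", d[2]),
    paste0("lines = ", d[1]),
    paste0("bands = ", d[3]),
    "header offset = 0",
    "data type = 5",
    "interleave = bsq",
    "byte order = 0",
    "wavelength units = Nanometers",
    paste0("frame role = ", cube$role),
    paste0("wavelength = {", wl, "}")
  )
  writeLines(header, paste0(path, ".hdr"))
  # BSQ: band slowest, scan line next, sample (x) fastest
  con <- file(paste0(path, ".raw"), "wb")
  on.exit(close(con))
  writeBin(as.numeric(aperm(cube$data, c(2, 1, 3))), con,
           size = 8, endian = "little")
  invisible(path)
}

#' @rdname write_cube
#' @export
read_cube <- function(path) {
  hdr_path <- paste0(path, ".hdr")
  raw_path <- paste0(path, ".raw")
  stopifnot(file.exists(hdr_path), file.exists(raw_path))
  lines <- readLines(hdr_path)
  get_field <- function(name, required = TRUE) {
    re <- paste0("^", name, "\\s*=\\s*(.*)$")
    hit <- grep(re, lines, value = TRUE)
    if (!length(hit)) {
      if (required) stop("cube header missing field ", sQuote(name),
                         call. = FALSE)
      return(NULL)
    }
    sub(re, "\\1", hit[1])
  }
  samples <- as.integer(get_field("samples"))
  nlines <- as.integer(get_field("lines"))
  bands <- as.integer(get_field("bands"))
  role <- get_field("frame role", required = FALSE) %||% "raw"
  wl_raw <- get_field("wavelength")
  if (is.null(wl_raw)) stop("cube header missing wavelength vector",
                            call. = FALSE)
  wl <- as.numeric(strsplit(gsub("[{}]", "", wl_raw), ",")[[1]])
  if (length(wl) != bands || anyNA(wl)) {
    stop("cube header wavelength vector does not match band count",
         call. = FALSE)
  }
  expected <- as.numeric(samples) * nlines * bands * 8
  if (file.size(raw_path) != expected) {
    stop("cube payload size mismatch: expected ", expected, " bytes, found ",
         file.size(raw_path), call. = FALSE)
  }
  con <- file(raw_path, "rb")
  on.exit(close(con))
  v <- readBin(con, "double", n = samples * nlines * bands, size = 8,
               endian = "little")
  data <- aperm(array(v, c(samples, nlines, bands)), c(2, 1, 3))
  hyper_cube(data, wl, role)
}

#' Save / load a calibration model
#'
#' Single-file, format-versioned serialization of an [svr_fit()] model.
#'
#' @param model an `svr_model`.
#' @param path file path (`.rds`).
#' @return `save_model` returns `path` invisibly; `load_model` the model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "svr_model"))
  saveRDS(list(format = "nirlipidmap-svr", version = 1L, model = model),
          path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "nirlipidmap-svr")) {
    stop("not a nirlipidmap model file", call. = FALSE)
  }
  obj$model
}

#' Default run configuration
#'
#' Every tunable of the pipeline in one serializable list: instrument grid,
#' crop interval, spike threshold, SNV variant, SVR defaults, and the
#' synthetic-study sizes. Configurations round-trip losslessly through YAML
#' ([read_run_config()] / [write_run_config()]).
#'
#' @return a nested named list.
#' @export
default_run_config <- function() {
  list(
    instrument = list(start_nm = 760, step_nm = 2.2, bands = 512L),
    preprocess = list(crop_nm = c(1000, 1400), spike_z = 6,
                      spike_window = 7L, snv_on = "absorbance"),
    svr = list(cost = 10, epsilon = 0.05),
    simulate = list(n_per_diet = 6L, lobe_height = 12L, lobe_width = 12L,
                    scene_height = 28L, scene_width = 28L,
                    tumor_radius = 5)
  )
}

#' @rdname default_run_config
#' @param path YAML file path.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  utils::modifyList(default_run_config(), cfg)
}

#' @rdname default_run_config
#' @param config a configuration list.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Run the full synthetic study pipeline
#'
#' simulate -> preprocess -> calibrate -> crossval -> map -> plot, from one
#' configuration and one seed, writing machine-readable outputs under
#' `out_dir`: the resolved configuration, ground-truth sample table,
#' calibration spectra, per-target models and LOOCV reports, a rendered
#' tumor-bearing scene (raw/dark/white cubes), per-pixel prediction maps and
#' region summaries, the pseudo-color image, and the HCL/DS scatter.
#' Identical config + seed reproduce identical outputs.
#'
#' @param config configuration list, see [default_run_config()].
#' @param seed integer seed for every random element.
#' @param out_dir output directory (created if needed).
#' @param targets which calibration targets to fit.
#' @return invisibly, a list with the calibration set, models, LOOCV
#'   reports, prediction map, region summaries and output file paths.
#' @export
run_pipeline <- function(config = default_run_config(), seed = 1L,
                         out_dir = tempfile("nirlipidmap_run_"),
                         targets = c("lipid", "hcl", "ds")) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  note <- function(p) { paths <<- c(paths, p); p }

  write_run_config(config, note(file.path(out_dir, "config.yaml")))
  wl <- instrument_wavelengths(config$instrument$start_nm,
                               config$instrument$step_nm,
                               config$instrument$bands)
  profiles <- default_diet_profiles()

  # simulate + preprocess calibration lobes
  cal <- simulate_calibration(
    n_per_diet = config$simulate$n_per_diet, profiles = profiles,
    height = config$simulate$lobe_height, width = config$simulate$lobe_width,
    seed = seed, crop = config$preprocess$crop_nm
  )
  readr::write_csv(cal$targets, note(file.path(out_dir, "truth.csv")))
  spectra <- tibble::as_tibble(as.data.frame(t(cal$features)))
  names(spectra) <- cal$targets$sample_id
  spectra <- tibble::tibble(wavelength = cal$wavelengths, spectra)
  readr::write_csv(spectra, note(file.path(out_dir, "snv_spectra.csv")))

  # calibrate + crossval
  models <- list()
  reports <- list()
  r2 <- tibble::tibble(target = character(), r_squared = numeric())
  for (tg in targets) {
    models[[tg]] <- svr_fit(cal, tg, cost = config$svr$cost,
                            epsilon = config$svr$epsilon)
    save_model(models[[tg]], file.path(out_dir, paste0("model_", tg, ".rds")))
    reports[[tg]] <- loocv(cal, tg, cost = config$svr$cost,
                           epsilon = config$svr$epsilon)
    readr::write_csv(reports[[tg]]$predictions,
                     note(file.path(out_dir, paste0("crossval_", tg, ".csv"))))
    r2 <- rbind(r2, tibble::tibble(target = tg,
                                   r_squared = reports[[tg]]$r_squared))
  }
  readr::write_csv(r2, note(file.path(out_dir, "r_squared.csv")))

  # map a tumor-bearing scene
  tumor_profile <- diet_profile("tumor", hcl = 17.54, ds = 0.78,
                                lipid_mean = 150, lipid_sd = 20)
  scn <- tumor_scene(profiles$LA12, tumor_profile,
                     height = config$simulate$scene_height,
                     width = config$simulate$scene_width,
                     tumor_radius = config$simulate$tumor_radius,
                     seed = seed + 1L)
  rc <- render_cube(scn, wavelengths = wl)
  for (frame in c("raw", "dark", "white")) {
    write_cube(rc[[frame]], file.path(out_dir, paste0("scene_", frame)))
    note(file.path(out_dir, paste0("scene_", frame, ".hdr")))
    note(file.path(out_dir, paste0("scene_", frame, ".raw")))
  }
  processed <- preprocess_pixels(rc$raw, rc$dark, rc$white, mask = rc$mask,
                                 spike_z = config$preprocess$spike_z,
                                 spike_window = config$preprocess$spike_window,
                                 crop = config$preprocess$crop_nm)
  pm <- prediction_map(
    lipid = if ("lipid" %in% targets) predict_pixels(models$lipid, processed),
    hcl = if ("hcl" %in% targets) predict_pixels(models$hcl, processed),
    ds = if ("ds" %in% targets) predict_pixels(models$ds, processed),
    mask = processed$mask
  )
  map_long <- do.call(rbind, lapply(setdiff(names(pm), "mask"), function(nm) {
    idx <- which(pm$mask)
    yx <- arrayInd(idx, dim(pm$mask))
    tibble::tibble(raster = nm, y = yx[, 1], x = yx[, 2],
                   value = pm[[nm]][idx])
  }))
  readr::write_csv(map_long, note(file.path(out_dir, "prediction_maps.csv")))

  regions <- rbind(
    summarize_region(pm, rc$labels == 1L & processed$mask, "normal"),
    summarize_region(pm, rc$labels == 2L & processed$mask, "tumor"),
    summarize_region(pm, processed$mask, "whole_lobe")
  )
  readr::write_csv(regions, note(file.path(out_dir, "region_summary.csv")))

  ab <- to_absorbance(remove_spikes(to_reflectance(rc$raw, rc$dark, rc$white),
                                    config$preprocess$spike_z,
                                    config$preprocess$spike_window))
  ab$mask <- ab$mask & rc$mask
  rgb <- pseudo_color(ab)
  grDevices::png(file.path(out_dir, "pseudo_color.png"),
                 width = 480, height = 480)
  graphics::par(mar = c(0, 0, 0, 0))
  graphics::plot.new()
  graphics::rasterImage(grDevices::as.raster(rgb), 0, 0, 1, 1,
                        interpolate = FALSE)
  grDevices::dev.off()

  # HCL/DS scatter of the cross-validated group means
  if (all(c("hcl", "ds") %in% targets)) {
    gm_h <- reports$hcl$group_means
    gm_d <- reports$ds$group_means
    pts <- tibble::tibble(group = gm_h$diet, hcl = gm_h$predicted_mean,
                          ds = gm_d$predicted_mean)
    sc <- hcl_ds_scatter_data(pts)
    render_hcl_ds_plot(sc, file = file.path(out_dir, "hcl_ds"))
    note(file.path(out_dir, "hcl_ds_points.csv"))
    note(file.path(out_dir, "hcl_ds_vertices.csv"))
  }

  invisible(list(calibration = cal, models = models, reports = reports,
                 map = pm, regions = regions, out_dir = out_dir,
                 data_files = paths))
}
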
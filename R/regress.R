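# Kernel (support-vector) regression from SNV spectra to lipid / HCL / DS,
# with leave-one-out cross-validation and the cross-validated R-squared.

#' Calibration set of spectra and reference values
#'
#' Pairs per-sample SNV absorbance spectra with the sample's reference total
#' lipid content, HCL and DS.
#'
#' @param features numeric matrix, samples x kept bands; no missing values.
#' @param wavelengths band centers of the feature columns, nm.
#' @param targets data frame with one row per sample: `sample_id`, optional
#'   `diet`, and any of `lipid`, `hcl`, `ds` (finite).
#' @return an object of class `calibration_set`.
#' @export
calibration_set <- function(features, wavelengths, targets) {
  features <- as.matrix(features)
  stopifnot(is.numeric(features), all(is.finite(features)),
            ncol(features) == length(wavelengths),
            is.data.frame(targets), nrow(targets) == nrow(features),
            "sample_id" %in% names(targets))
  for (v in intersect(c("lipid", "hcl", "ds"), names(targets))) {
    if (any(!is.finite(targets[[v]]))) {
      stop("non-finite target values in ", sQuote(v), call. = FALSE)
    }
  }
  structure(
    list(features = features, wavelengths = as.numeric(wavelengths),
         targets = tibble::as_tibble(targets)),
    class = "calibration_set"
  )
}

#' @export
print.calibration_set <- function(x, ...) {
  cat(sprintf("<calibration_set> %d samples x %d bands; targets: %s\n",
              nrow(x$features), ncol(x$features),
              paste(intersect(c("lipid", "hcl", "ds"), names(x$targets)),
                    collapse = ", ")))
  invisible(x)
}

subset_calibration <- function(cal, idx) {
  calibration_set(cal$features[idx, , drop = FALSE], cal$wavelengths,
                  cal$targets[idx, , drop = FALSE])
}

#' Cross-validation R-squared
#'
#' `1 - SS_res / SS_tot`, residual sum of squares of predicted minus
#' measured over total sum of squares of the measured values about their
#' mean. Equals 1 iff the predictions reproduce the measurements exactly and
#' 0 when they do no better than the measured mean.
#'
#' @param measured,predicted numeric vectors of equal length (>= 2).
#' @return dimensionless coefficient of determination.
#' @export
r_squared <- function(measured, predicted) {
  stopifnot(length(measured) == length(predicted), length(measured) >= 2L,
            all(is.finite(measured)), all(is.finite(predicted)))
  ss_tot <- sum((measured - mean(measured))^2)
  if (ss_tot <= 0) {
    stop("R-squared undefined: measured values have zero variance",
         call. = FALSE)
  }
  1 - sum((predicted - measured)^2) / ss_tot
}

#' Fit a support-vector regression calibration model
#'
#' Epsilon-insensitive SVR with a radial-basis kernel maps SNV spectra to
#' one target. The kernel width defaults to the median-heuristic
#' `gamma = 1 / median(pairwise squared feature distance)`. Features enter
#' as-is (SNV already standardizes each spectrum); the target is
#' standardized internally and back-transformed at prediction. A constant
#' target yields a degenerate model that predicts the constant.
#'
#' @param cal a [calibration_set()].
#' @param target `"lipid"`, `"hcl"` or `"ds"`.
#' @param cost SVR regularization parameter.
#' @param epsilon epsilon-tube half-width on the standardized target.
#' @param gamma RBF kernel parameter; `NULL` for the median heuristic
#'   (ignored for the linear kernel).
#' @param kernel `"radial"` (default) or `"linear"`.
#' @return an object of class `svr_model`.
#' @export
svr_fit <- function(cal, target = c("lipid", "hcl", "ds"), cost = 10,
                    epsilon = 0.05, gamma = NULL,
                    kernel = c("radial", "linear")) {
  stopifnot(inherits(cal, "calibration_set"))
  target <- match.arg(target)
  kernel <- match.arg(kernel)
  if (!target %in% names(cal$targets)) {
    stop("calibration set has no ", sQuote(target), " target", call. = FALSE)
  }
  y <- cal$targets[[target]]
  x <- cal$features
  mu <- mean(y)
  s <- sd(y)
  if (!is.finite(s) || s < 1e-12) {
    model <- list(constant = mu, svm = NULL)
  } else {
    if (is.null(gamma) && kernel == "radial") {
      d2 <- as.numeric(dist(x))^2
      m <- median(d2)
      if (!is.finite(m) || m < 1e-12) {
        stop("degenerate features: spectra are (near-)identical, kernel ",
             "width heuristic undefined", call. = FALSE)
      }
      gamma <- 1 / m
    }
    if (is.null(gamma)) gamma <- 1 / ncol(x) # linear kernel: value unused
    fit <- e1071::svm(x, (y - mu) / s, type = "eps-regression",
                      kernel = kernel, gamma = gamma, cost = cost,
                      epsilon = epsilon, scale = FALSE)
    model <- list(constant = NULL, svm = fit)
  }
  structure(
    list(model = model, target = target, y_center = mu, y_scale = s,
         wavelengths = cal$wavelengths,
         config = list(cost = cost, epsilon = epsilon, gamma = gamma,
                       kernel = kernel)),
    class = "svr_model"
  )
}

#' Predict from a fitted calibration model
#'
#' @param object an [svr_fit()] model.
#' @param features numeric matrix (spectra in rows) or a single spectrum
#'   vector on the model's wavelength grid.
#' @param ... unused.
#' @return numeric vector of predictions on the original target scale.
#' @export
predict.svr_model <- function(object, features, ...) {
  if (!is.matrix(features)) features <- matrix(features, nrow = 1L)
  stopifnot(ncol(features) == length(object$wavelengths))
  if (!is.null(object$model$constant)) {
    return(rep(object$model$constant, nrow(features)))
  }
  as.numeric(predict(object$model$svm, features)) * object$y_scale +
    object$y_center
}

#' Leave-one-out cross-validation of a calibration
#'
#' For each sample in turn, the model is refitted on the remaining n-1
#' samples (including the kernel-width heuristic) and the held-out sample is
#' predicted. Results are indexed by sample identifier, so the report is
#' invariant to sample order.
#'
#' @inheritParams svr_fit
#' @param ... passed to [svr_fit()] (`cost`, `epsilon`, `gamma`).
#' @return an object of class `cv_report`: `predictions` tibble
#'   (`sample_id`, `diet` if present, `measured`, `predicted`), `target`,
#'   `r_squared` (NA with a message when the measured variance is zero), and
#'   `group_means` per diet when diets are present.
#' @export
loocv <- function(cal, target = c("lipid", "hcl", "ds"), ...) {
  stopifnot(inherits(cal, "calibration_set"))
  target <- match.arg(target)
  n <- nrow(cal$features)
  if (n < 3L) stop("leave-one-out needs at least 3 samples", call. = FALSE)
  measured <- cal$targets[[target]]
  predicted <- numeric(n)
  for (i in seq_len(n)) {
    fit <- tryCatch(
      svr_fit(subset_calibration(cal, -i), target, ...),
      error = function(e) {
        stop("LOOCV fold ", i, " (held out ", cal$targets$sample_id[i],
             "): ", conditionMessage(e), call. = FALSE)
      }
    )
    predicted[i] <- predict(fit, cal$features[i, , drop = FALSE])
  }
  preds <- tibble::tibble(sample_id = cal$targets$sample_id,
                          measured = measured, predicted = predicted)
  if ("diet" %in% names(cal$targets)) {
    preds$diet <- cal$targets$diet
    preds <- preds[, c("sample_id", "diet", "measured", "predicted")]
  }
  r2 <- if (var(measured) > 0) r_squared(measured, predicted) else NA_real_
  gm <- NULL
  if ("diet" %in% names(preds)) {
    sp <- split(preds, preds$diet)
    gm <- tibble::tibble(
      diet = names(sp),
      n = vapply(sp, nrow, 1L),
      measured_mean = vapply(sp, function(d) mean(d$measured), 1),
      predicted_mean = vapply(sp, function(d) mean(d$predicted), 1)
    )
  }
  structure(
    list(predictions = preds, target = target, r_squared = r2,
         group_means = gm),
    class = "cv_report"
  )
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report %s> n = %d, LOOCV R^2 = %s\n", x$target,
              nrow(x$predictions),
              if (is.na(x$r_squared)) "undefined (zero measured variance)"
              else sprintf("%.4f", x$r_squared)))
  invisible(x)
}

#' Predict a raster of per-pixel values
#'
#' Applies a calibration model to every masked-in pixel spectrum of a
#' processed cube; identical to predicting each pixel spectrum on its own.
#'
#' @param model an [svr_fit()] model.
#' @param processed a [preprocess_pixels()] result on the model's wavelength
#'   grid.
#' @return numeric matrix `(y, x)`: predictions on masked-in pixels, `NA`
#'   elsewhere.
#' @export
predict_pixels <- function(model, processed) {
  stopifnot(inherits(model, "svr_model"), inherits(processed, "processed_cube"))
  if (!isTRUE(all.equal(processed$wavelengths, model$wavelengths))) {
    stop("wavelength grid of the cube does not match the training grid ",
         "(incompatible instrument or crop)", call. = FALSE)
  }
  raster <- matrix(NA_real_, processed$dim[1], processed$dim[2])
  raster[processed$pixel_index] <- predict(model, processed$features)
  raster
}
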
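#' En-face image
#'
#' A 2-D scalar raster with an isotropic physical pixel pitch and a modality
#' tag. Pixel values are finite and non-negative; row/column indices are
#' 1-based with the origin at the top-left pixel. Physical coordinates (mm)
#' are measured from the image centre (scans are fovea-centred unless an
#' explicit fovea point is supplied downstream).
#'
#' @param pixels Numeric matrix of intensities.
#' @param pitch_um Physical size of one pixel (um), isotropic, > 0.
#' @param modality One of `"flow"`, `"structure"`, `"superficial"`.
#' @return An `enface_image` object.
#' @export
enface_image <- function(pixels, pitch_um,
                         modality = c("flow", "structure", "superficial")) {
  modality <- match.arg(modality)
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    stop("`pixels` must be a numeric matrix", call. = FALSE)
  }
  if (any(!is.finite(pixels))) stop("pixel values must be finite", call. = FALSE)
  if (any(pixels < 0)) stop("pixel values must be non-negative", call. = FALSE)
  if (!is.numeric(pitch_um) || length(pitch_um) != 1 || pitch_um <= 0) {
    stop("`pitch_um` must be a single positive number", call. = FALSE)
  }
  structure(list(pixels = pixels, pitch_um = pitch_um, modality = modality),
            class = "enface_image")
}

#' @exportS3Method base::print
print.enface_image <- function(x, ...) {
  cat(sprintf("<enface_image:%s> %d x %d px @ %.4g um/px, range [%.3g, %.3g]\n",
              x$modality, nrow(x$pixels), ncol(x$pixels), x$pitch_um,
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

mask_labels <- c("psv_roi", "ring", "vessel_exclusion",
                 "truth_deficit", "deficit_binary")

#' Region mask
#'
#' A boolean raster sharing the geometry of a companion en-face image. The
#' `label` records the mask's role. PSV ROI masks must be non-empty.
#'
#' @param pixels Logical matrix.
#' @param pitch_um Physical pixel pitch (um), matching the companion image.
#' @param label One of `"psv_roi"`, `"ring"`, `"vessel_exclusion"`,
#'   `"truth_deficit"`, `"deficit_binary"`.
#' @return A `region_mask` object.
#' @export
region_mask <- function(pixels, pitch_um, label = mask_labels) {
  label <- match.arg(label)
  if (is.numeric(pixels)) {
    storage.mode(pixels) <- "logical"
  }
  if (!is.matrix(pixels) || !is.logical(pixels)) {
    stop("`pixels` must be a logical matrix", call. = FALSE)
  }
  if (any(is.na(pixels))) stop("mask contains NA", call. = FALSE)
  if (label == "psv_roi" && !any(pixels)) {
    stop("a psv_roi mask must be non-empty", call. = FALSE)
  }
  structure(list(pixels = pixels, pitch_um = pitch_um, label = label),
            class = "region_mask")
}

#' @exportS3Method base::print
print.region_mask <- function(x, ...) {
  cat(sprintf("<region_mask:%s> %d x %d px @ %.4g um/px, %d set (%.2f%%)\n",
              x$label, nrow(x$pixels), ncol(x$pixels), x$pitch_um,
              sum(x$pixels), 100 * mean(x$pixels)))
  invisible(x)
}

# geometry agreement between any mix of enface_image / region_mask
check_same_geometry <- function(a, b) {
  if (!identical(dim(a$pixels), dim(b$pixels))) {
    stop("raster dimensions differ (",
         paste(dim(a$pixels), collapse = "x"), " vs ",
         paste(dim(b$pixels), collapse = "x"), ")", call. = FALSE)
  }
  if (!isTRUE(all.equal(a$pitch_um, b$pitch_um))) {
    stop("pixel pitches differ", call. = FALSE)
  }
  invisible(TRUE)
}
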
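#' Read an en-face grayscale image
#'
#' Loads a single-channel 8- or 16-bit grayscale TIFF or PNG as an
#' [enface_image]. Values are returned on the `[0, 1]` scale (integer sample
#' value divided by the bit-depth maximum), preserved losslessly.
#'
#' @param path File path (`.tif`, `.tiff`, `.png`).
#' @param pitch_um Physical pixel pitch (um).
#' @param modality Image modality tag.
#' @return An [enface_image].
#' @export
load_enface <- function(path, pitch_um,
                        modality = c("flow", "structure", "superficial")) {
  modality <- match.arg(modality)
  px <- read_gray(path)
  enface_image(px, pitch_um = pitch_um, modality = modality)
}

#' Write an en-face image
#'
#' Writes as 16-bit grayscale TIFF (or 8-bit PNG when `path` ends in
#' `.png`). Pixels must already lie in `[0, 1]`; they are snapped to the
#' integer sample grid so a write/read round trip is bit-identical.
#'
#' @param img An [enface_image] with pixels in `[0, 1]`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_enface <- function(img, path) {
  stopifnot(inherits(img, "enface_image"))
  px <- img$pixels
  if (min(px) < 0 || max(px) > 1) {
    stop("pixels must lie in [0, 1] before writing", call. = FALSE)
  }
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    png::writePNG(round(px * 255) / 255, path)
  } else {
    tiff::writeTIFF(round(px * 65535) / 65535, path,
                    bits.per.sample = 16L, compression = "none")
  }
  invisible(path)
}

read_gray <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    px <- png::readPNG(path)
  } else if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    px <- tiff::readTIFF(path)
  } else {
    stop("unsupported image format: ", path, call. = FALSE)
  }
  if (length(dim(px)) != 2) {
    stop("expected single-channel grayscale image, got ",
         length(dim(px)), "-dimensional data: ", path, call. = FALSE)
  }
  px
}

#' Read a binary region mask
#'
#' Loads a binary raster (pixel > 0.5 is "set") and checks its geometry
#' against a companion image.
#'
#' @param path File path of an 8-bit PNG or TIFF mask.
#' @param companion The [enface_image] the mask annotates.
#' @param label Mask role; `psv_roi` masks must be non-empty.
#' @return A [region_mask].
#' @export
load_mask <- function(path, companion, label = mask_labels) {
  stopifnot(inherits(companion, "enface_image"))
  px <- read_gray(path)
  if (!identical(dim(px), dim(companion$pixels))) {
    stop("mask dimensions (", paste(dim(px), collapse = "x"),
         ") do not match companion image (",
         paste(dim(companion$pixels), collapse = "x"), ")", call. = FALSE)
  }
  region_mask(px > 0.5, pitch_um = companion$pitch_um, label = label)
}

#' Write a binary mask as 8-bit PNG
#' @param mask A [region_mask].
#' @param path Output path (`.png`).
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "region_mask"))
  png::writePNG(mask$pixels * 1.0, path)
  invisible(path)
}

#' Read a PSV label mask into per-PSV region masks
#'
#' A label raster stores PSV k at integer sample value k (8-bit PNG,
#' value k/255). Returns one `psv_roi` mask per label, in label order.
#'
#' @param path Label image path.
#' @param companion The [enface_image] the labels annotate.
#' @return A list of [region_mask] objects (possibly empty).
#' @export
load_psv_labels <- function(path, companion) {
  stopifnot(inherits(companion, "enface_image"))
  px <- read_gray(path)
  if (!identical(dim(px), dim(companion$pixels))) {
    stop("label mask dimensions do not match companion image", call. = FALSE)
  }
  lab <- round(px * 255)
  ids <- sort(setdiff(unique(as.vector(lab)), 0))
  lapply(ids, function(k) {
    region_mask(lab == k, pitch_um = companion$pitch_um, label = "psv_roi")
  })
}

#' Write per-PSV masks as one label image
#' @param rois List of `psv_roi` [region_mask] objects (disjoint).
#' @param path Output path (`.png`); supports up to 255 PSVs.
#' @return `path`, invisibly.
#' @export
write_psv_labels <- function(rois, path) {
  if (length(rois) > 255) stop("at most 255 PSV labels", call. = FALSE)
  if (length(rois) == 0) stop("need at least one ROI to size the raster; ",
                              "write an empty mask instead", call. = FALSE)
  lab <- matrix(0L, nrow(rois[[1]]$pixels), ncol(rois[[1]]$pixels))
  for (k in seq_along(rois)) {
    if (any(lab[rois[[k]]$pixels] != 0L)) stop("ROIs overlap", call. = FALSE)
    lab[rois[[k]]$pixels] <- k
  }
  png::writePNG(lab / 255, path)
  invisible(path)
}

#' Write/read a scan-geometry JSON sidecar
#' @param geom A [scan_geometry].
#' @param path JSON path.
#' @return `path` invisibly / a [scan_geometry].
#' @export
write_geometry <- function(geom, path) {
  stopifnot(inherits(geom, "scan_geometry"))
  jsonlite::write_json(unclass(geom)[c("scan_mm", "raster_px", "axl_mm")],
                       path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_geometry
#' @export
read_geometry <- function(path) {
  g <- jsonlite::read_json(path, simplifyVector = TRUE)
  scan_geometry(scan_mm = g$scan_mm, raster_px = g$raster_px,
                axl_mm = if (is.null(g$axl_mm)) NA_real_ else g$axl_mm)
}
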
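#' Magnification-corrected PSV area
#'
#' Area of a PSV entry ROI: pixel count times physical pixel area, scaled
#' by `F^2` (areas scale with the square of the Bennett-Littmann factor;
#' correction is applied post hoc to measurements made in nominal image
#' units).
#'
#' @param roi Non-empty `psv_roi` [region_mask].
#' @param geom [scan_geometry] supplying pitch and magnification factor.
#' @return Area in mm^2.
#' @export
psv_area <- function(roi, geom) {
  stopifnot(inherits(roi, "region_mask"), inherits(geom, "scan_geometry"))
  n <- sum(roi$pixels)
  if (n == 0) stop("ROI is empty", call. = FALSE)
  n * (geom$pitch_um / 1000)^2 * geom$F^2
}

#' Concentric ring around a PSV ROI
#'
#' The perivascular ring of physical width `width_um` circumferential to a
#' PSV ROI: all pixels whose Euclidean distance to the nearest ROI pixel is
#' in `(0, width_um]`. Built from an exact distance transform so the ring
#' width is isotropic in physical units; the ROI itself is excluded. Rings
#' reaching the image border are clipped to the frame and flagged via
#' `attr(, "clipped")`.
#'
#' @param roi Non-empty `psv_roi` [region_mask].
#' @param width_um Ring width (um), default 250.
#' @param geom Optional [scan_geometry]; pitch defaults to the ROI's.
#' @return A [region_mask] with label `ring`.
#' @export
ring_mask <- function(roi, width_um = 250, geom = NULL) {
  stopifnot(inherits(roi, "region_mask"))
  if (!any(roi$pixels)) stop("ROI is empty", call. = FALSE)
  pitch <- if (is.null(geom)) roi$pitch_um else geom$pitch_um
  r_px <- width_um / pitch
  d2 <- distance_transform_sq(roi$pixels)
  ring <- d2 > 0 & d2 <= r_px^2
  out <- region_mask(ring, pitch_um = pitch, label = "ring")
  # clipped if the ROI lies within the ring width of any border
  ij <- which(roi$pixels, arr.ind = TRUE)
  margin <- min(ij[, 1] - 1, nrow(roi$pixels) - ij[, 1],
                ij[, 2] - 1, ncol(roi$pixels) - ij[, 2])
  attr(out, "clipped") <- margin < r_px
  out
}

#' Flow-deficit metrics at a PSV site
#'
#' `fd_psv` is the flow-deficit percentage within the PSV entry ROI;
#' `fd_250` (for the default 250-um width) is the same metric over the
#' concentric perivascular ring. Both honor the large-vessel exclusion
#' mask.
#'
#' @param deficit Binary deficit [region_mask].
#' @param exclusion Optional `vessel_exclusion` [region_mask].
#' @param roi `psv_roi` [region_mask].
#' @param geom Optional [scan_geometry].
#' @param ring_width_um Ring width (um), default 250.
#' @return List with `fd_psv`, `fd_250` (percent), the `ring` mask, and the
#'   two underlying `fd_result` objects.
#' @export
fd_psv_metrics <- function(deficit, exclusion = NULL, roi, geom = NULL,
                           ring_width_um = 250) {
  ring <- ring_mask(roi, width_um = ring_width_um, geom = geom)
  res_roi <- fd_percent(deficit, exclusion, roi)
  res_ring <- fd_percent(deficit, exclusion, ring)
  list(fd_psv = res_roi$ccfd_percent,
       fd_250 = res_ring$ccfd_percent,
       ring = ring, roi_result = res_roi, ring_result = res_ring)
}

#' Vessel-to-fovea distance (VFD)
#'
#' Overlays the ROI with a square grid of cells of area `unit_area_mm2`
#' (default 0.1 mm^2) anchored at the fovea, computes the centroid
#' \eqn{(X_i, Y_i)} of the ROI's intersection with each grid cell, the
#' Euclidean distance \eqn{d_i = \sqrt{(X_i-X_0)^2 + (Y_i-Y_0)^2}} of each
#' centroid to the foveal centre \eqn{(X_0, Y_0)}, and returns the mean
#' distance together with the mean X and Y offsets (the VFD decomposition).
#' All outputs are scaled post hoc by the magnification factor `F`.
#'
#' ROIs smaller than one grid cell fall back to the single whole-ROI
#' centroid (`N = 1`), flagged via `attr(, "single_cell")`. Coordinates are
#' in mm with x increasing along columns, y along rows, origin at the image
#' centre.
#'
#' @param roi Non-empty `psv_roi` [region_mask].
#' @param fovea_xy Foveal centre `(x, y)` in mm from the image centre;
#'   default `c(0, 0)` (fovea-centred scans).
#' @param geom Optional [scan_geometry] (pitch + magnification).
#' @param unit_area_mm2 Grid cell area (mm^2), default 0.1.
#' @return Named list `vfd_mm`, `x_off_mm`, `y_off_mm`, `n_cells`, with
#'   attribute `single_cell`.
#' @export
vfd <- function(roi, fovea_xy = c(0, 0), geom = NULL, unit_area_mm2 = 0.1) {
  stopifnot(inherits(roi, "region_mask"), length(fovea_xy) == 2,
            unit_area_mm2 > 0)
  if (!any(roi$pixels)) stop("ROI is empty", call. = FALSE)
  pitch_mm <- (if (is.null(geom)) roi$pitch_um else geom$pitch_um) / 1000
  F <- if (is.null(geom)) 1 else geom$F
  nr <- nrow(roi$pixels); nc <- ncol(roi$pixels)
  ij <- which(roi$pixels, arr.ind = TRUE)
  # pixel-centre coordinates, mm, origin at the image centre
  x <- (ij[, 2] - 0.5) * pitch_mm - nc * pitch_mm / 2
  y <- (ij[, 1] - 0.5) * pitch_mm - nr * pitch_mm / 2
  # fovea must lie inside the frame
  if (abs(fovea_xy[1]) > nc * pitch_mm / 2 ||
      abs(fovea_xy[2]) > nr * pitch_mm / 2) {
    stop("fovea lies outside the image frame", call. = FALSE)
  }
  roi_area <- length(x) * pitch_mm^2
  s <- sqrt(unit_area_mm2)
  if (roi_area < unit_area_mm2) {
    cx <- mean(x); cy <- mean(y)
    n_cells <- 1L
  } else {
    # grid anchored at the fovea, so jointly shifting ROI and fovea is exact
    cell <- paste(floor((x - fovea_xy[1]) / s),
                  floor((y - fovea_xy[2]) / s))
    cx <- tapply(x, cell, mean)
    cy <- tapply(y, cell, mean)
    n_cells <- length(cx)
  }
  dx <- cx - fovea_xy[1]
  dy <- cy - fovea_xy[2]
  d <- sqrt(dx^2 + dy^2)
  out <- list(vfd_mm = F * mean(d),
              x_off_mm = F * mean(dx),
              y_off_mm = F * mean(dy),
              n_cells = as.integer(n_cells))
  attr(out, "single_cell") <- n_cells == 1L
  out
}
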
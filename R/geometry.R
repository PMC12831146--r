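#' Bennett-Littmann magnification factor
#'
#' Converts nominal (device-assumed) image measurements to true ocular
#' dimensions as a function of axial length, using the abbreviated
#' Bennett-Littmann formula \eqn{F = 3.48 \times 0.01306 \times (AXL - 1.82)}.
#' Linear measures scale by `F`, areas by `F^2`.
#'
#' @param axl_mm Axial length in mm; must exceed 1.82 mm (the formula's
#'   nodal-point offset, where the factor degenerates to zero).
#' @return The dimensionless magnification factor `F`.
#' @examples
#' magnification_factor(25.28)
#' @export
magnification_factor <- function(axl_mm) {
  if (!is.numeric(axl_mm) || any(!is.finite(axl_mm))) {
    stop("`axl_mm` must be finite numeric", call. = FALSE)
  }
  if (any(axl_mm <= 1.82)) {
    stop("`axl_mm` must exceed 1.82 mm (magnification factor degenerates)",
         call. = FALSE)
  }
  3.48 * 0.01306 * (axl_mm - 1.82)
}

#' Scan geometry
#'
#' Physical geometry of an en-face scan: width in mm, raster size in pixels,
#' and optionally the eye's axial length from which the Bennett-Littmann
#' magnification factor is derived. Without an axial length the factor is 1
#' (nominal image units).
#'
#' @param scan_mm Scan width (mm), isotropic.
#' @param raster_px Pixels per side.
#' @param axl_mm Axial length (mm) or `NA` for nominal geometry.
#' @return A `scan_geometry` object with fields `scan_mm`, `raster_px`,
#'   `pitch_um` (derived), `axl_mm` and `F`.
#' @examples
#' scan_geometry(6, 1024, axl_mm = 25.28)
#' @export
scan_geometry <- function(scan_mm = 6, raster_px = 1024, axl_mm = NA_real_) {
  stopifnot(is.numeric(scan_mm), scan_mm > 0,
            is.numeric(raster_px), raster_px >= 1)
  F <- if (is.na(axl_mm)) 1 else magnification_factor(axl_mm)
  structure(
    list(scan_mm = scan_mm, raster_px = as.integer(raster_px),
         pitch_um = 1000 * scan_mm / raster_px,
         axl_mm = axl_mm, F = F),
    class = "scan_geometry"
  )
}

#' @exportS3Method base::print
print.scan_geometry <- function(x, ...) {
  cat(sprintf("<scan_geometry> %.3g mm / %d px (pitch %.4g um/px), AXL %s, F = %.4g\n",
              x$scan_mm, x$raster_px, x$pitch_um,
              ifelse(is.na(x$axl_mm), "none", sprintf("%.2f mm", x$axl_mm)),
              x$F))
  invisible(x)
}
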
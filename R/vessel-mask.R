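#' Large-retinal-vessel exclusion mask
#'
#' Builds an exclusion mask for CC regions shadowed by large retinal
#' vessels from a superficial-plexus en-face image: global Otsu
#' binarization, a Euclidean morphological opening that suppresses
#' sub-caliber specks (capillary-scale signal), then isotropic Euclidean
#' dilation by `dilation_um` to buffer shadow margins.
#'
#' @param superficial [enface_image] with modality `"superficial"`.
#' @param dilation_um Dilation radius (um, >= 0). Default 0.
#' @param opening_um Opening radius (um); structures thinner than twice this
#'   are removed before dilation. Default 10 um.
#' @return A [region_mask] with label `vessel_exclusion`.
#' @export
vessel_exclusion_mask <- function(superficial, dilation_um = 0,
                                  opening_um = 10) {
  stopifnot(inherits(superficial, "enface_image"))
  if (superficial$modality != "superficial") {
    stop("expected a superficial-plexus image", call. = FALSE)
  }
  px <- superficial$pixels
  pitch <- superficial$pitch_um
  rg <- range(px)
  if (rg[2] - rg[1] < 1e-8) {
    # featureless image: nothing to exclude
    return(region_mask(matrix(FALSE, nrow(px), ncol(px)), pitch_um = pitch,
                       label = "vessel_exclusion"))
  }
  x01 <- (px - rg[1]) / (rg[2] - rg[1])
  th <- EBImage::otsu(x01, range = c(0, 1))
  bin <- x01 > th
  r_open <- opening_um / pitch
  if (r_open > 0 && any(bin)) {
    # Euclidean opening: erode then re-dilate by the same radius
    core <- distance_transform_sq(!bin) > r_open^2
    bin <- if (any(core)) dilate_euclid(core, r_open) else core
  }
  r_dil <- dilation_um / pitch
  if (r_dil > 0) bin <- dilate_euclid(bin, r_dil)
  region_mask(bin, pitch_um = pitch, label = "vessel_exclusion")
}
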
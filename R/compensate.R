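#' Inverse-structure signal compensation
#'
#' Compensates an en-face OCTA flow slab for signal attenuation by
#' pixel-wise multiplication with the inverse of the structural OCT image
#' of the same slab: `out = flow / max(structure, eps)`, rescaled so the
#' maximum is 1. Because real attenuation multiplies flow and structure by
#' the same local factor, the ratio is attenuation-free (up to the epsilon
#' floor guarding near-zero structure pixels).
#'
#' @param flow [enface_image] with modality `"flow"`.
#' @param structure [enface_image] with modality `"structure"`, same
#'   geometry.
#' @param eps_frac Division floor as a fraction of the structure image's
#'   maximum (default 0.01).
#' @return A compensated [enface_image] (modality `"flow"`) scaled to
#'   `[0, 1]`.
#' @export
compensate <- function(flow, structure, eps_frac = 0.01) {
  stopifnot(inherits(flow, "enface_image"), inherits(structure, "enface_image"))
  if (flow$modality != "flow" || structure$modality != "structure") {
    stop("`flow` must have modality 'flow' and `structure` 'structure'",
         call. = FALSE)
  }
  check_same_geometry(flow, structure)
  smax <- max(structure$pixels)
  if (smax <= 0) stop("structure image is all zero", call. = FALSE)
  eps <- eps_frac * smax
  out <- flow$pixels / pmax(structure$pixels, eps)
  m <- max(out)
  if (m > 0) out <- out / m
  enface_image(out, pitch_um = flow$pitch_um, modality = "flow")
}
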
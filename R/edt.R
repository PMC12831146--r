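#' Exact squared Euclidean distance transform
#'
#' For every pixel, the squared Euclidean distance (in pixel units, between
#' pixel centres) to the nearest `TRUE` pixel of `mask`. Exact: squared
#' inter-pixel distances are integers and the two-pass lower-envelope
#' algorithm introduces no approximation. Pixels of an all-`FALSE` mask get
#' `Inf`.
#'
#' @param mask Logical matrix.
#' @return Numeric matrix of squared distances (px^2).
#' @export
distance_transform_sq <- function(mask) {
  if (!is.matrix(mask)) stop("`mask` must be a matrix", call. = FALSE)
  storage.mode(mask) <- "logical"
  if (any(is.na(mask))) stop("mask contains NA", call. = FALSE)
  edt_squared(mask)
}

# isotropic Euclidean dilation: pixels within radius_px of a set pixel
dilate_euclid <- function(mask, radius_px) {
  if (radius_px <= 0) return(mask)
  if (!any(mask)) return(mask)
  edt_squared(mask) <= radius_px^2
}
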
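#' Phansalkar threshold parameters
#'
#' The Phansalkar local adaptive threshold for low-contrast images computes,
#' over a circular window of physical radius `radius_um` around each pixel,
#' \deqn{t = \mu_w (1 + p e^{-q \mu_w} + k(\sigma_w / r - 1))}
#' where \eqn{\mu_w, \sigma_w} are the window mean and (population) standard
#' deviation. Pixels with intensity `<= t` are flow deficits ("dark pixels").
#'
#' The default radius is 23.4 um; with the default 6-mm / 1024-px geometry
#' (pitch 5.859 um) this is exactly 4 px. The constants default to the
#' widely used auto-local-threshold parameterization for `[0, 1]` images
#' (k = 0.25, r = 0.5, p = 2, q = 10) and are configurable.
#'
#' @param radius_um Window radius in um (> 0).
#' @param k,r,p,q Threshold constants; r must be positive.
#' @param normalize If `TRUE`, min-max rescale the image to `[0, 1]` before
#'   thresholding; if `FALSE` the image must already lie in `[0, 1]`.
#' @return A `phansalkar_params` list.
#' @export
phansalkar_params <- function(radius_um = 23.4, k = 0.25, r = 0.5,
                              p = 2, q = 10, normalize = FALSE) {
  stopifnot(radius_um > 0, r > 0)
  structure(list(radius_um = radius_um, k = k, r = r, p = p, q = q,
                 normalize = isTRUE(normalize)),
            class = "phansalkar_params")
}

# symmetric (edge-repeating) reflective padding by `r` pixels
pad_reflect <- function(m, r) {
  nr <- nrow(m); nc <- ncol(m)
  if (r >= nr || r >= nc) stop("padding radius exceeds image size", call. = FALSE)
  ri <- c(r:1, 1:nr, nr:(nr - r + 1))
  ci <- c(r:1, 1:nc, nc:(nc - r + 1))
  m[ri, ci]
}

# integer offsets of the circular window: dx^2 + dy^2 <= r^2
disc_offsets <- function(r_px) {
  d <- expand.grid(dy = -r_px:r_px, dx = -r_px:r_px)
  d[d$dy^2 + d$dx^2 <= r_px^2, , drop = FALSE]
}

#' Phansalkar local-threshold binarization
#'
#' Binarizes a compensated en-face CC slab into a flow-deficit mask using
#' the Phansalkar local threshold (see [phansalkar_params]) over a circular
#' window; image borders are handled by reflective padding.
#'
#' @param img [enface_image] with values in `[0, 1]` (or set
#'   `normalize = TRUE` in `params`).
#' @param params A [phansalkar_params] object.
#' @return A [region_mask] with label `deficit_binary`; `TRUE` marks
#'   flow-deficit (dark) pixels.
#' @export
phansalkar_binarize <- function(img, params = phansalkar_params()) {
  stopifnot(inherits(img, "enface_image"), inherits(params, "phansalkar_params"))
  px <- img$pixels
  if (params$normalize) {
    rg <- range(px)
    px <- if (rg[2] > rg[1]) (px - rg[1]) / (rg[2] - rg[1]) else px * 0
  } else if (min(px) < 0 || max(px) > 1) {
    stop("image must lie in [0, 1]; use normalize = TRUE", call. = FALSE)
  }
  r_px <- as.integer(round(params$radius_um / img$pitch_um))
  if (r_px < 1) {
    stop("window radius is smaller than one pixel (",
         format(params$radius_um), " um at pitch ",
         format(img$pitch_um), " um/px)", call. = FALSE)
  }
  off <- disc_offsets(r_px)
  pad <- pad_reflect(px, r_px)
  nr <- nrow(px); nc <- ncol(px)
  S <- matrix(0, nr, nc); S2 <- matrix(0, nr, nc)
  for (i in seq_len(nrow(off))) {
    sub <- pad[(1:nr) + r_px + off$dy[i], (1:nc) + r_px + off$dx[i]]
    S <- S + sub
    S2 <- S2 + sub * sub
  }
  n <- nrow(off)
  mu <- S / n
  sg <- sqrt(pmax(S2 / n - mu * mu, 0))
  thr <- mu * (1 + params$p * exp(-params$q * mu) +
                 params$k * (sg / params$r - 1))
  region_mask(px <= thr, pitch_um = img$pitch_um, label = "deficit_binary")
}
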
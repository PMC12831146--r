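# Independent brute-force oracles used to validate the fast implementations.
# These deliberately recompute everything with explicit per-pixel loops.

# Phansalkar threshold via an explicit sliding-window loop over a circular
# neighborhood on a symmetrically padded image.
phansalkar_oracle <- function(px, pitch_um, params) {
  r_px <- as.integer(round(params$radius_um / pitch_um))
  nr <- nrow(px); nc <- ncol(px)
  ri <- c(r_px:1, 1:nr, nr:(nr - r_px + 1))
  ci <- c(r_px:1, 1:nc, nc:(nc - r_px + 1))
  pad <- px[ri, ci]
  off <- expand.grid(dy = -r_px:r_px, dx = -r_px:r_px)
  off <- off[off$dy^2 + off$dx^2 <= r_px^2, ]
  out <- matrix(FALSE, nr, nc)
  for (i in 1:nr) {
    for (j in 1:nc) {
      vals <- pad[cbind(i + r_px + off$dy, j + r_px + off$dx)]
      m <- mean(vals)
      s <- sqrt(sum((vals - m)^2) / length(vals))
      th <- m * (1 + params$p * exp(-params$q * m) +
                   params$k * (s / params$r - 1))
      out[i, j] <- px[i, j] <= th
    }
  }
  out
}

# Exact squared Euclidean distance to the nearest TRUE pixel, by direct
# minimization over all set pixels.
edt_oracle <- function(mask) {
  ij <- which(mask, arr.ind = TRUE)
  out <- matrix(Inf, nrow(mask), ncol(mask))
  if (nrow(ij) == 0) return(out)
  for (i in seq_len(nrow(mask))) {
    for (j in seq_len(ncol(mask))) {
      out[i, j] <- min((ij[, 1] - i)^2 + (ij[, 2] - j)^2)
    }
  }
  out
}

# Mean per-pixel Euclidean distance (mm) from ROI pixel centres to a fovea
# point given in mm from the image centre.
vfd_pixel_oracle <- function(roi_px, pitch_mm, fovea_xy) {
  nr <- nrow(roi_px); nc <- ncol(roi_px)
  ij <- which(roi_px, arr.ind = TRUE)
  x <- (ij[, 2] - 0.5) * pitch_mm - nc * pitch_mm / 2
  y <- (ij[, 1] - 0.5) * pitch_mm - nr * pitch_mm / 2
  mean(sqrt((x - fovea_xy[1])^2 + (y - fovea_xy[2])^2))
}

# Filled ellipse mask helper (pixel coordinates, axis-aligned).
make_ellipse_mask <- function(n, cy, cx, a_px, b_px, pitch_um,
                              label = "psv_roi") {
  ry <- matrix(rep(1:n, times = n), n, n)
  cxm <- matrix(rep(1:n, each = n), n, n)
  m <- ((cxm - cx) / a_px)^2 + ((ry - cy) / b_px)^2 <= 1
  region_mask(m, pitch_um = pitch_um, label = label)
}

# A small scene configuration shared by image-pipeline tests.
small_scene_params <- function(seed, ...) {
  scene_params(raster_px = 256L, n_psv = 2L, seed = seed, ...)
}
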
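#' Synthetic scene parameters
#'
#' Parameters of the synthetic en-face CC scene generator. Defaults emulate
#' a 6 x 6 mm fovea-centred swept-source OCTA acquisition rasterized at
#' 1024 px (pitch 5.859 um/px) with a global flow-deficit burden of 18%
#' (healthy-myopic range), a smooth multiplicative attenuation field of
#' amplitude 0.3, and three PSV entry ROIs with radii spanning 60-220 um
#' (mean ROI area approximately 0.05 mm^2).
#'
#' @param raster_px Pixels per side (>= 64).
#' @param scan_mm Physical scan width (mm).
#' @param deficit_fraction_target Target ground-truth deficit area fraction
#'   in `[0, 1]`.
#' @param attenuation_amplitude Peak fractional signal loss of the
#'   attenuation field, in `[0, 1)`; 0 disables attenuation.
#' @param n_psv Number of PSV entry ROIs to place.
#' @param psv_radius_um_range Min/max PSV ellipse semi-major axis (um);
#'   strictly positive and below half the scan width.
#' @param noise_sd SD of additive sensor noise (intensity units on the
#'   `[0, 1]` scale).
#' @param texture_scale_um Correlation scale of the CC texture field (um);
#'   deficit patches span roughly 2-4x this scale.
#' @param edge_softness Logistic transition width of deficit borders, in
#'   SD units of the texture field (~1 px at the default; emulates ~20 um
#'   optical resolution).
#' @param flow_levels `c(lo, hi)` intensities of deficit and perfused CC.
#' @param structure_level Mean structural-slab intensity.
#' @param seed Integer seed; generation is fully reproducible.
#' @return A `scene_params` list.
#' @export
scene_params <- function(raster_px = 1024L, scan_mm = 6,
                         deficit_fraction_target = 0.18,
                         attenuation_amplitude = 0.3,
                         n_psv = 3L,
                         psv_radius_um_range = c(60, 220),
                         noise_sd = 0.02,
                         texture_scale_um = 94,
                         edge_softness = 0.05,
                         flow_levels = c(0.08, 0.70),
                         structure_level = 0.55,
                         seed = 1L) {
  stopifnot(raster_px >= 64, scan_mm > 0,
            deficit_fraction_target >= 0, deficit_fraction_target <= 1,
            attenuation_amplitude >= 0, attenuation_amplitude < 1,
            n_psv >= 0, length(psv_radius_um_range) == 2,
            all(psv_radius_um_range > 0),
            all(psv_radius_um_range < scan_mm * 500),
            diff(psv_radius_um_range) >= 0,
            noise_sd >= 0, flow_levels[1] < flow_levels[2])
  structure(as.list(environment()), class = "scene_params")
}

# Gaussian blur with the kernel capped so it always fits the raster
gblur_safe <- function(x, sigma) {
  smax <- (min(dim(x)) - 2) / 9
  EBImage::gblur(x, sigma = min(sigma, smax))
}

# smooth field: sum of broad Gaussians, normalized to [0, 1]
attenuation_field <- function(n, pitch_um, n_gauss = 3) {
  xs <- matrix(rep(seq_len(n), each = n), n, n)   # column index
  ys <- matrix(rep(seq_len(n), times = n), n, n)  # row index
  fld <- matrix(0, n, n)
  for (g in seq_len(n_gauss)) {
    cx <- runif(1, 1, n); cy <- runif(1, 1, n)
    sg <- runif(1, 1500, 3000) / pitch_um  # 1.5-3 mm
    amp <- runif(1, 0.5, 1)
    fld <- fld + amp * exp(-((xs - cx)^2 + (ys - cy)^2) / (2 * sg^2))
  }
  rg <- range(fld)
  if (rg[2] > rg[1]) (fld - rg[1]) / (rg[2] - rg[1]) else fld * 0
}

# mark pixels within halfwidth_px of segment p0-p1 (pixel coordinates)
mark_capsule <- function(mask, p0, p1, halfwidth_px) {
  n <- nrow(mask)
  lo <- pmax(1, floor(pmin(p0, p1) - halfwidth_px - 1))
  hi <- pmin(n, ceiling(pmax(p0, p1) + halfwidth_px + 1))
  if (any(hi < lo)) return(mask)
  rows <- lo[1]:hi[1]; cols <- lo[2]:hi[2]
  ry <- matrix(rep(rows, times = length(cols)), length(rows), length(cols))
  cx <- matrix(rep(cols, each = length(rows)), length(rows), length(cols))
  v <- p1 - p0
  len2 <- sum(v^2)
  if (len2 == 0) {
    d2 <- (ry - p0[1])^2 + (cx - p0[2])^2
  } else {
    t <- ((ry - p0[1]) * v[1] + (cx - p0[2]) * v[2]) / len2
    t <- pmin(pmax(t, 0), 1)
    d2 <- (ry - (p0[1] + t * v[1]))^2 + (cx - (p0[2] + t * v[2]))^2
  }
  mask[rows, cols] <- mask[rows, cols] | (d2 <= halfwidth_px^2)
  mask
}

# branching large-vessel tree in the superficial plexus
vessel_tree <- function(n, pitch_um) {
  mask <- matrix(FALSE, n, n)
  n_trunk <- sample(3:4, 1)
  for (tr in seq_len(n_trunk)) {
    # enter from a random edge, head across the frame with a slight curve
    side <- sample(1:4, 1)
    p <- switch(side,
                c(1, runif(1, 1, n)), c(n, runif(1, 1, n)),
                c(runif(1, 1, n), 1), c(runif(1, 1, n), n))
    ang <- atan2(n / 2 - p[1], n / 2 - p[2]) + runif(1, -0.5, 0.5)
    caliber_px <- runif(1, 60, 120) / pitch_um / 2  # half-width, 60-120 um vessels
    step <- n / 8
    for (k in 1:9) {
      q <- p + step * c(sin(ang), cos(ang))
      mask <- mark_capsule(mask, p, q, caliber_px)
      if (k == 4 && runif(1) < 0.8) {
        # one side branch, thinner
        bang <- ang + sample(c(-1, 1), 1) * runif(1, 0.5, 1.1)
        bp <- q
        bcal <- caliber_px * runif(1, 0.5, 0.8)
        for (m in 1:4) {
          bq <- bp + step * 0.8 * c(sin(bang), cos(bang))
          mask <- mark_capsule(mask, bp, bq, bcal)
          bp <- bq
          bang <- bang + runif(1, -0.25, 0.25)
        }
      }
      p <- q
      ang <- ang + runif(1, -0.25, 0.25)
      caliber_px <- caliber_px * runif(1, 0.92, 1.0)
      if (all(p < -n / 4) || all(p > 5 * n / 4)) break
    }
  }
  mask
}

# pixels of a rotated ellipse centred at (cy, cx) px
ellipse_pixels <- function(n, cy, cx, a_px, b_px, theta) {
  lo <- pmax(1, floor(c(cy, cx) - max(a_px, b_px) - 1))
  hi <- pmin(n, ceiling(c(cy, cx) + max(a_px, b_px) + 1))
  rows <- lo[1]:hi[1]; cols <- lo[2]:hi[2]
  ry <- matrix(rep(rows, times = length(cols)), length(rows), length(cols))
  cxm <- matrix(rep(cols, each = length(rows)), length(rows), length(cols))
  u <- (cxm - cx) * cos(theta) + (ry - cy) * sin(theta)
  v <- -(cxm - cx) * sin(theta) + (ry - cy) * cos(theta)
  inside <- (u / a_px)^2 + (v / b_px)^2 <= 1
  cbind(row = ry[inside], col = cxm[inside])
}

#' Generate a synthetic CC scene with known ground truth
#'
#' Produces a matched (flow, structure, superficial) image triple plus
#' ground-truth masks. The CC flow texture is a thresholded band-pass
#' (Gaussian-smoothed) noise field whose dark patches are contiguous blobs
#' realizing the target deficit fraction; one smooth multiplicative
#' attenuation field scales flow and structure identically, so their ratio
#' is attenuation-free; PSV entry ROIs are disjoint ellipses avoiding the
#' superficial vessel tree; all outputs are reproducible for a fixed seed.
#' Image pixels are snapped to the 16-bit grid so file round trips are
#' bit-identical.
#'
#' @param params A [scene_params] object.
#' @param max_tries Placement retries per ROI before a packing error.
#' @return List with [enface_image]s `flow`, `structure`, `superficial`;
#'   [region_mask]s `truth_deficit` and `vessel_truth`; `psv_rois` (list of
#'   `psv_roi` masks); `fovea_xy` (mm, image-centre origin); `geometry`
#'   ([scan_geometry]); and `params`.
#' @export
generate_cc_scene <- function(params = scene_params(), max_tries = 500L) {
  stopifnot(inherits(params, "scene_params"))
  set.seed(params$seed)
  n <- as.integer(params$raster_px)
  pitch <- 1000 * params$scan_mm / n
  lo <- params$flow_levels[1]; hi <- params$flow_levels[2]

  # CC texture field and ground-truth deficit mask
  g <- gblur_safe(matrix(rnorm(n * n), n, n),
                  sigma = params$texture_scale_um / pitch)
  tgt <- params$deficit_fraction_target
  if (tgt <= 0) {
    truth <- matrix(FALSE, n, n)
    flow_base <- matrix(hi, n, n)
  } else if (tgt >= 1) {
    truth <- matrix(TRUE, n, n)
    flow_base <- matrix(lo, n, n)
  } else {
    qv <- quantile(g, tgt, names = FALSE)
    truth <- g < qv
    w <- params$edge_softness * sd(g)
    soft <- if (w > 0) plogis((g - qv) / w) else (g >= qv) * 1.0
    flow_base <- lo + (hi - lo) * soft
  }

  # shared multiplicative attenuation (draws consumed even when amplitude 0,
  # keeping the RNG stream aligned across amplitudes)
  att01 <- attenuation_field(n, pitch)
  atten <- 1 - params$attenuation_amplitude * att01

  # mild smooth texture in the structural slab
  s_tex <- gblur_safe(matrix(rnorm(n * n), n, n), sigma = 25)
  s_tex <- s_tex / max(abs(s_tex), 1e-12)
  structure_base <- params$structure_level * (1 + 0.09 * s_tex)

  # superficial plexus: bright large-vessel tree over dim background
  vtruth <- vessel_tree(n, pitch)
  sup_base <- 0.15 + 0.6 * EBImage::gblur(vtruth * 1.0, sigma = 1)

  # PSV ROIs: disjoint ellipses in an annulus around the fovea, off-vessel
  rois <- list()
  labels <- matrix(0L, n, n)
  occupied <- vtruth
  cx0 <- (n + 1) / 2
  for (k in seq_len(params$n_psv)) {
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      rad_mm <- runif(1, 0.8, 2.5)
      ang <- runif(1, 0, 2 * pi)
      cy <- cx0 + rad_mm * 1000 / pitch * sin(ang)
      cx <- cx0 + rad_mm * 1000 / pitch * cos(ang)
      a_px <- runif(1, params$psv_radius_um_range[1],
                    params$psv_radius_um_range[2]) / pitch
      b_px <- a_px * runif(1, 0.6, 1)
      theta <- runif(1, 0, pi)
      ext <- max(a_px, b_px)
      if (cy - ext < 2 || cy + ext > n - 1 || cx - ext < 2 || cx + ext > n - 1) next
      pix <- ellipse_pixels(n, cy, cx, a_px, b_px, theta)
      if (nrow(pix) == 0) next
      if (any(occupied[pix])) next
      m <- matrix(FALSE, n, n)
      m[pix] <- TRUE
      occupied <- occupied | m
      labels[pix] <- k
      rois[[k]] <- region_mask(m, pitch_um = pitch, label = "psv_roi")
      placed <- TRUE
      break
    }
    if (!placed) {
      stop("could not place ", params$n_psv, " disjoint PSV ROIs after ",
           max_tries, " tries each (packing failure); reduce n_psv or radii",
           call. = FALSE)
    }
  }

  clamp01 <- function(x) pmin(pmax(x, 0), 1)
  snap16 <- function(x) round(x * 65535) / 65535
  noise <- function() {
    if (params$noise_sd > 0) matrix(rnorm(n * n, sd = params$noise_sd), n, n)
    else 0
  }
  flow_px <- snap16(clamp01(flow_base * atten + noise()))
  struct_px <- snap16(clamp01(structure_base * atten + noise()))
  sup_px <- snap16(clamp01(sup_base + noise()))

  geom <- scan_geometry(scan_mm = params$scan_mm, raster_px = n)
  list(
    flow = enface_image(flow_px, pitch, "flow"),
    structure = enface_image(struct_px, pitch, "structure"),
    superficial = enface_image(sup_px, pitch, "superficial"),
    truth_deficit = region_mask(truth, pitch, "truth_deficit"),
    vessel_truth = region_mask(vtruth, pitch, "vessel_exclusion"),
    psv_rois = rois,
    psv_labels = labels,
    fovea_xy = c(0, 0),
    geometry = geom,
    params = params
  )
}
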
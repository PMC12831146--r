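test_that("PSV area follows pixel count, pitch and F^2", {
  pitch <- 5.86
  g1 <- scan_geometry(scan_mm = pitch * 100 / 1000, raster_px = 100)
  m <- matrix(FALSE, 100, 100); m[1:10, 1:10] <- TRUE  # 100 px
  roi <- region_mask(m, pitch, "psv_roi")
  expect_equal(psv_area(roi, g1), 100 * (pitch / 1000)^2, tolerance = 1e-12)
  # doubling F quadruples the area
  g2 <- g1; g2$F <- 2
  expect_equal(psv_area(roi, g2), 4 * psv_area(roi, g1))
  # whole-frame ROI gives the full scan area times F^2
  whole <- region_mask(matrix(TRUE, 100, 100), pitch, "psv_roi")
  expect_equal(psv_area(whole, g1), g1$scan_mm^2, tolerance = 1e-12)
  expect_error(psv_area(region_mask(matrix(FALSE, 4, 4), pitch,
                                    "truth_deficit"), g1), "empty")
})

test_that("single-pixel ring at one-pitch width is the 4-neighbour shell", {
  pitch <- 10
  m <- matrix(FALSE, 9, 9); m[5, 5] <- TRUE
  roi <- region_mask(m, pitch, "psv_roi")
  ring <- ring_mask(roi, width_um = pitch)
  expected <- matrix(FALSE, 9, 9)
  expected[cbind(c(4, 6, 5, 5), c(5, 5, 4, 6))] <- TRUE
  expect_identical(ring$pixels, expected)
})

test_that("ring construction matches the brute-force distance oracle", {
  set.seed(19)
  for (i in 1:5) {
    n <- sample(48:128, 1)
    pitch <- runif(1, 5, 12)
    m <- matrix(FALSE, n, n)
    cy <- sample(10:(n - 10), 1); cx <- sample(10:(n - 10), 1)
    blob <- make_ellipse_mask(n, cy, cx, sample(2:6, 1), sample(2:6, 1),
                              pitch)
    width <- runif(1, 2, 8) * pitch
    ring <- ring_mask(blob, width_um = width)
    d2 <- edt_oracle(blob$pixels)
    expected <- d2 > 0 & d2 <= (width / pitch)^2
    expect_identical(ring$pixels, expected)
    expect_false(any(ring$pixels & blob$pixels))  # disjoint from the ROI
  }
})

test_that("ring area approximates the analytic annulus", {
  # circular ROI radius 100 um, ring width 250 um, fine pitch
  pitch <- 4
  n <- 301
  roi <- make_ellipse_mask(n, 151, 151, 100 / pitch, 100 / pitch, pitch)
  ring <- ring_mask(roi, width_um = 250)
  area_um2 <- sum(ring$pixels) * pitch^2
  analytic <- pi * (350^2 - 100^2)
  expect_equal(area_um2, analytic, tolerance = 0.05)
  expect_false(attr(ring, "clipped"))
  # a border-touching ROI is flagged as clipped
  edge <- matrix(FALSE, 64, 64); edge[2:4, 2:4] <- TRUE
  rr <- ring_mask(region_mask(edge, pitch, "psv_roi"), width_um = 10 * pitch)
  expect_true(attr(rr, "clipped"))
})

test_that("fd metrics split ROI and ring contributions", {
  pitch <- 5.86
  n <- 64
  roi <- make_ellipse_mask(n, 32, 32, 5, 5, pitch)
  deficit_px <- roi$pixels  # deficits exactly on the ROI
  dm <- region_mask(deficit_px, pitch, "deficit_binary")
  m <- fd_psv_metrics(dm, NULL, roi)
  expect_equal(m$fd_psv, 100)
  expect_equal(m$fd_250, 0)
  # ROI fully excluded -> undefined metric
  ex <- region_mask(roi$pixels, pitch, "vessel_exclusion")
  expect_error(fd_psv_metrics(dm, ex, roi), "undefined")
})

test_that("uniform random deficits give matching ROI/ring/global rates", {
  set.seed(23)
  pitch <- 5.86
  n <- 256
  roi <- make_ellipse_mask(n, 128, 128, 20, 20, pitch)
  f <- 0.3
  dm <- region_mask(matrix(runif(n * n) < f, n, n), pitch, "deficit_binary")
  m <- fd_psv_metrics(dm, NULL, roi)
  expect_equal(m$fd_psv, 100 * f, tolerance = 0.12)
  expect_equal(m$fd_250, 100 * f, tolerance = 0.12)
  # ring FD is statistically indistinguishable from global CCFD% for
  # spatially uniform deficits
  nsig <- 0
  for (s in 1:50) {
    set.seed(400 + s)
    dpx <- matrix(runif(128 * 128) < 0.25, 128, 128)
    dmk <- region_mask(dpx, pitch, "deficit_binary")
    blob <- make_ellipse_mask(128, 64, 64, 6, 6, pitch)
    ring <- ring_mask(blob, width_um = 10 * pitch)
    k_ring <- sum(dpx & ring$pixels); n_ring <- sum(ring$pixels)
    k_all <- sum(dpx); n_all <- length(dpx)
    p <- suppressWarnings(
      prop.test(c(k_ring, k_all), c(n_ring, n_all))$p.value)
    nsig <- nsig + (p < 0.01)
  }
  expect_lte(nsig, 5)
})

test_that("VFD reduces to centroid distance for sub-cell ROIs", {
  # ROI centred 3 mm right / 4 mm up of the fovea -> VFD 5 mm; the centre
  # sits on a half-integer pixel so the discrete ellipse is symmetric and
  # its centroid is exact
  pitch <- 25
  n <- 400
  cx_px <- n / 2 + 0.5 + 3000 / pitch
  cy_px <- n / 2 + 0.5 - 4000 / pitch
  roi <- make_ellipse_mask(n, cy_px, cx_px, 4, 4, pitch)
  v <- vfd(roi, fovea_xy = c(0, 0), unit_area_mm2 = 0.1)
  expect_true(attr(v, "single_cell"))
  expect_equal(v$vfd_mm, 5, tolerance = 1e-6)
  expect_equal(v$x_off_mm, 3, tolerance = 1e-6)
  expect_equal(v$y_off_mm, -4, tolerance = 1e-6)
})

test_that("VFD offsets vanish for an ROI symmetric about the fovea", {
  pitch <- 20
  n <- 128  # even: pixel grid symmetric about the image centre
  m <- matrix(FALSE, n, n)
  m[40:44, 40:44] <- TRUE
  m[n - (39:43), n - (39:43)] <- TRUE  # mirrored blob
  roi <- region_mask(m, pitch, "psv_roi")
  v <- vfd(roi, fovea_xy = c(0, 0), unit_area_mm2 = (5 * pitch / 1000)^2)
  expect_equal(v$x_off_mm, 0, tolerance = 1e-12)
  expect_equal(v$y_off_mm, 0, tolerance = 1e-12)
  expect_gt(v$vfd_mm, 0)
})

test_that("pixel-fine VFD grid matches the per-pixel oracle", {
  set.seed(29)
  pitch <- 11.7
  n <- 128
  roi <- make_ellipse_mask(n, 40, 90, 7, 5, pitch)
  fovea <- c(0.2, -0.1)
  v <- vfd(roi, fovea_xy = fovea, unit_area_mm2 = (pitch / 1000)^2)
  oracle <- vfd_pixel_oracle(roi$pixels, pitch / 1000, fovea)
  expect_equal(v$vfd_mm, oracle, tolerance = 1e-9)
  # coarse-grid VFD approaches the per-pixel value
  v_coarse <- vfd(roi, fovea_xy = fovea, unit_area_mm2 = 0.01)
  expect_equal(v_coarse$vfd_mm, oracle, tolerance = 0.05)
})

test_that("VFD is translation-equivariant and scales with F", {
  pitch <- 20
  n <- 128
  m <- matrix(FALSE, n, n); m[30:36, 50:58] <- TRUE
  roi <- region_mask(m, pitch, "psv_roi")
  shift_px <- c(7, 11)  # rows, cols
  m2 <- matrix(FALSE, n, n)
  m2[30:36 + shift_px[1], 50:58 + shift_px[2]] <- TRUE
  roi2 <- region_mask(m2, pitch, "psv_roi")
  f0 <- c(-0.3, 0.4)
  f2 <- f0 + c(shift_px[2], shift_px[1]) * pitch / 1000  # (x, y) order
  v1 <- vfd(roi, fovea_xy = f0, unit_area_mm2 = 0.02)
  v2 <- vfd(roi2, fovea_xy = f2, unit_area_mm2 = 0.02)
  expect_equal(v1$vfd_mm, v2$vfd_mm, tolerance = 1e-9)
  expect_equal(v1$x_off_mm, v2$x_off_mm, tolerance = 1e-9)
  expect_equal(v1$y_off_mm, v2$y_off_mm, tolerance = 1e-9)
  # magnification: doubling F doubles distances, leaves FD%s untouched
  g1 <- scan_geometry(n * pitch / 1000, n)
  g2 <- g1; g2$F <- 2
  va <- vfd(roi, fovea_xy = f0, geom = g1, unit_area_mm2 = 0.02)
  vb <- vfd(roi, fovea_xy = f0, geom = g2, unit_area_mm2 = 0.02)
  expect_equal(vb$vfd_mm, 2 * va$vfd_mm)
  expect_equal(vb$x_off_mm, 2 * va$x_off_mm)
  expect_equal(vb$y_off_mm, 2 * va$y_off_mm)
})
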
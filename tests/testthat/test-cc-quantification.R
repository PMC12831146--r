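test_that("compensation by a constant structure is a pure rescale", {
  set.seed(4)
  fpx <- matrix(runif(32 * 32), 32, 32)
  flow <- enface_image(fpx, 5.86, "flow")
  struct <- enface_image(matrix(0.7, 32, 32), 5.86, "structure")
  out <- compensate(flow, struct)
  expect_equal(out$pixels, fpx / max(fpx), tolerance = 1e-12)
})

test_that("compensation guards division and geometry", {
  flow <- enface_image(matrix(runif(16 * 16), 16, 16), 5.86, "flow")
  szero <- matrix(1, 16, 16); szero[1, 1] <- 0
  out <- compensate(flow, enface_image(szero, 5.86, "structure"))
  expect_true(all(is.finite(out$pixels)))
  expect_error(compensate(flow, enface_image(matrix(0, 16, 16), 5.86,
                                             "structure")), "all zero")
  small <- enface_image(matrix(1, 8, 8), 5.86, "structure")
  expect_error(compensate(flow, small), "dimensions")
  expect_error(compensate(flow, flow), "modality")
})

test_that("Phansalkar threshold matches its closed form on flat images", {
  # constant 0.5: t = 0.5 (1 + 2 e^-5 - 0.25) ~ 0.3817 < 0.5, empty mask
  img <- enface_image(matrix(0.5, 40, 40), 5.86, "flow")
  def <- phansalkar_binarize(img, phansalkar_params(radius_um = 23.4))
  expect_false(any(def$pixels))
  # constant 0: t = 0, every pixel <= t, full mask
  img0 <- enface_image(matrix(0, 40, 40), 5.86, "flow")
  def0 <- phansalkar_binarize(img0, phansalkar_params(radius_um = 23.4))
  expect_true(all(def0$pixels))
})

test_that("Phansalkar binarization matches the explicit-loop oracle", {
  set.seed(8)
  for (i in 1:10) {
    n <- sample(24:40, 1)
    px <- matrix(runif(n * n), n, n)
    pitch <- runif(1, 4, 8)
    pars <- phansalkar_params(radius_um = sample(2:5, 1) * pitch)
    img <- enface_image(px, pitch, "flow")
    fast <- phansalkar_binarize(img, pars)$pixels
    slow <- phansalkar_oracle(px, pitch, pars)
    expect_identical(fast, slow)
  }
})

test_that("a sub-pixel Phansalkar radius is rejected", {
  img <- enface_image(matrix(0.5, 16, 16), pitch_um = 60, modality = "flow")
  expect_error(phansalkar_binarize(img, phansalkar_params(radius_um = 23.4)),
               "smaller than one pixel")
})

test_that("vessel exclusion recovers the synthetic tree and dilates monotonically", {
  sc <- generate_cc_scene(scene_params(raster_px = 512L, n_psv = 0L,
                                       noise_sd = 0, seed = 17))
  ex0 <- vessel_exclusion_mask(sc$superficial, dilation_um = 0)
  truth <- sc$vessel_truth$pixels
  dice <- 2 * sum(ex0$pixels & truth) / (sum(ex0$pixels) + sum(truth))
  expect_gte(dice, 0.9)
  ex50 <- vessel_exclusion_mask(sc$superficial, dilation_um = 50)
  expect_true(all(ex50$pixels[ex0$pixels]))     # contains the undilated mask
  expect_gt(sum(ex50$pixels), sum(ex0$pixels))  # strictly larger
  # blank image excludes nothing
  blank <- enface_image(matrix(0, 64, 64), 11.7, "superficial")
  expect_false(any(vessel_exclusion_mask(blank)$pixels))
})

test_that("flow-deficit percentage counts evaluable pixels correctly", {
  pitch <- 5.86
  deficit <- matrix(FALSE, 10, 10); deficit[1:5, 1:5] <- TRUE  # 25 px
  excl <- matrix(FALSE, 10, 10); excl[1:5, 1:4] <- TRUE        # hides 20
  dm <- region_mask(deficit, pitch, "deficit_binary")
  em <- region_mask(excl, pitch, "vessel_exclusion")
  res <- fd_percent(dm, em)
  expect_equal(res$ccfd_percent, 5 / 80 * 100)
  expect_equal(res$evaluable_px, 80)
  expect_equal(res$excluded_px, 20)
  # extremes
  expect_equal(fd_percent(region_mask(matrix(TRUE, 4, 4), pitch,
                                      "deficit_binary"))$ccfd_percent, 100)
  expect_equal(fd_percent(region_mask(matrix(FALSE, 4, 4), pitch,
                                      "deficit_binary"))$ccfd_percent, 0)
  # empty evaluable area is an error, not zero
  allx <- region_mask(matrix(TRUE, 4, 4), pitch, "vessel_exclusion")
  expect_error(fd_percent(region_mask(matrix(TRUE, 4, 4), pitch,
                                      "deficit_binary"), allx), "undefined")
})

test_that("fd_percent ignores deficit states under the exclusion mask", {
  set.seed(12)
  deficit <- matrix(runif(400) < 0.3, 20, 20)
  excl <- matrix(runif(400) < 0.25, 20, 20)
  pitch <- 5.86
  a <- fd_percent(region_mask(deficit, pitch, "deficit_binary"),
                  region_mask(excl, pitch, "vessel_exclusion"))
  flipped <- deficit; flipped[excl] <- !flipped[excl]
  b <- fd_percent(region_mask(flipped, pitch, "deficit_binary"),
                  region_mask(excl, pitch, "vessel_exclusion"))
  expect_equal(a$ccfd_percent, b$ccfd_percent)
})
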
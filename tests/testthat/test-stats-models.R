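test_that("Spearman screen recovers monotone relations", {
  d <- data.frame(x = 1:20)
  d$lin <- d$x
  d$cub <- -d$x^3
  d$flat <- 5
  res <- spearman_screen(d, "lin", c("x", "cub", "flat"))
  expect_equal(res$rho[res$predictor == "x"], 1)
  expect_equal(res$rho[res$predictor == "cub"], -1)
  expect_true(is.na(res$rho[res$predictor == "flat"]))
})

test_that("Spearman rho matches the rank-difference formula", {
  # Sum d_i^2 = 4 -> rho = 1 - 6*4/(5*24) = 0.8
  d <- data.frame(x = 1:5, y = c(2, 1, 4, 3, 5))
  res <- spearman_screen(d, "y", "x")
  brute <- 1 - 6 * sum((rank(d$x) - rank(d$y))^2) / (5 * (5^2 - 1))
  expect_equal(brute, 0.8)
  expect_equal(res$rho, brute)
})

test_that("mixed model collapses to OLS when variance components are zero", {
  # one PSV per eye, one eye per subject: with no replication inside any
  # cluster the marginal covariance is proportional to the identity for
  # every variance split, so fixed effects equal OLS exactly
  p <- cohort_params(n_subjects = 120, p_both_eyes = 0,
                     psv_per_eye_mean = 1, sd_subject = 0, sd_eye = 0,
                     sd_resid = 4, seed = 41)
  d <- generate_cohort(p)
  terms <- c("age_y", "axl_mm", "global_ccfd_pct")
  fit <- fit_mixed(d, "fd_psv", terms)
  ols <- lm(fd_psv ~ age_y + axl_mm + global_ccfd_pct, data = d)
  expect_equal(fit$terms$estimate, unname(coef(ols)), tolerance = 1e-6)
  expect_true(fit$singular)  # boundary fit is flagged, not raised
  # with replicated clusters the zero-variance fit is only asymptotically
  # OLS: variance components are estimated near (not at) zero
  p2 <- cohort_params(n_subjects = 60, sd_subject = 0, sd_eye = 0,
                      sd_resid = 4, seed = 41)
  d2 <- generate_cohort(p2)
  fit2 <- fit_mixed(d2, "fd_psv", terms)
  ols2 <- lm(fd_psv ~ age_y + axl_mm + global_ccfd_pct, data = d2)
  se2 <- sqrt(diag(vcov(ols2)))
  expect_true(all(abs(fit2$terms$estimate - coef(ols2)) < se2))
})

test_that("mixed model recovers simulated fixed effects and nesting", {
  d <- generate_cohort(cohort_params(n_subjects = 300, seed = 43))
  fit <- fit_mixed(d, "fd_psv",
                   c("age_y", "axl_mm", "se_d", "ct_um",
                     "global_ccfd_pct", "area_mm2", "vfd_mm"))
  truth <- cohort_params()$fixed_effects
  est <- setNames(fit$terms$estimate, fit$terms$term)
  expect_equal(est[["global_ccfd_pct"]], truth[["global_ccfd_pct"]],
               tolerance = 0.1)
  expect_equal(est[["age_y"]], truth[["age_y"]], tolerance = 0.5)
  expect_true(all(fit$terms$ci_low <= fit$terms$estimate &
                    fit$terms$estimate <= fit$terms$ci_high))
  expect_equal(fit$n_subjects, 300)
  expect_gt(fit$r2, 0)
  expect_lt(fit$r2, 1)
  expect_error(fit_mixed(d[d$subject_id == "S001", ], "fd_psv", "age_y"),
               "2 subjects")
})

test_that("VIF matches the closed form and flags perfect collinearity", {
  set.seed(47)
  n <- 500
  x1 <- rnorm(n); x2 <- rnorm(n); x3 <- 0.9 * x1 + sqrt(1 - 0.81) * rnorm(n)
  d <- data.frame(x1 = x1, x2 = x2, x3 = x3, dup = x1)
  # two-predictor closed form 1/(1 - r^2), to numerical identity
  r <- cor(d$x1, d$x3)
  v <- vif(d, c("x1", "x3"))
  expect_equal(v$vif, rep(1 / (1 - r^2), 2), tolerance = 1e-10)
  # near-orthogonal predictors sit near 1
  v2 <- vif(d, c("x1", "x2"))
  expect_equal(v2$vif, c(1, 1), tolerance = 0.05)
  # duplicated predictor is infinite
  v3 <- vif(d, c("x1", "x2", "dup"))
  expect_true(all(is.infinite(v3$vif[v3$predictor != "x2"])))
})

test_that("ICC(A,1) behaves across agreement regimes", {
  set.seed(53)
  items <- rnorm(40, 50, 10)
  # exact repetition -> ICC 1
  r1 <- icc_repeatability(items, items)
  expect_equal(r1$icc, 1)
  expect_equal(r1$ci_low, 1)
  # independent sessions -> ICC near 0
  r0 <- icc_repeatability(rnorm(500), rnorm(500))
  expect_lt(abs(r0$icc), 0.1)
  # between-SD 10, within-SD 3 -> ICC ~ 100/109
  truth <- rnorm(4000, 0, 10)
  y1 <- truth + rnorm(4000, 0, 3)
  y2 <- truth + rnorm(4000, 0, 3)
  rr <- icc_repeatability(y1, y2)
  expect_equal(rr$icc, 100 / 109, tolerance = 0.03)
  expect_true(rr$ci_low <= rr$icc && rr$icc <= rr$ci_high)
  # degenerate: no variance anywhere
  rc <- icc_repeatability(rep(1, 10), rep(1, 10))
  expect_true(is.na(rc$icc))
})

test_that("post hoc power is exact at the null and monotone", {
  expect_equal(posthoc_power(0, se = 1, n_eff = 31), 0.05)
  expect_equal(posthoc_power(0, se = 2, n_eff = 31, alpha = 0.10), 0.10)
  # symmetry: ncp at the critical point gives ~50% power for large df
  tc <- qt(0.975, 1e5 - 2)
  expect_equal(posthoc_power(tc, se = 1, n_eff = 1e5), 0.5, tolerance = 0.01)
  # monotone in |beta|/se and in n_eff
  p <- sapply(c(0.5, 1, 2, 3), function(b) posthoc_power(b, 1, 31))
  expect_true(all(diff(p) > 0))
  p2 <- sapply(c(10, 31, 100), function(n) posthoc_power(1.5, 1, n))
  expect_true(all(diff(p2) > 0))
  expect_gt(posthoc_power(50, 1, 31), 0.999)  # ncp -> inf limit
  expect_error(posthoc_power(1, 1, n_eff = 2), "degrees of freedom")
})
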
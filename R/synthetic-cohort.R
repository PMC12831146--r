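#' Cohort simulation parameters
#'
#' Parameters for simulating a multi-PSV / multi-eye / multi-subject cohort
#' with nested random intercepts. Covariates are drawn around the
#' descriptive means and SDs of a healthy-myopic adult cohort (age
#' 28.3 +/- 7.0 y, AXL 25.28 +/- 1.09 mm, SE -4.03 +/- 1.71 D, CT
#' 187 +/- 60 um, global CCFD 17.86 +/- 10.58 %, PSV area ~0.05 mm^2, VFD
#' 1.50 +/- 0.69 mm, 2.3 PSVs per eye). The default fixed effects are the
#' adjusted (multivariable-scale) coefficients of that cohort, which
#' reproduce its mean FDPSV of ~16.5% at the covariate means. Axial length
#' and global CCFD are deliberately collinear at `confound_axl_ccfd`
#' (default 0.47), so that a negative adjusted AXL effect coexists with a
#' positive marginal one.
#'
#' @param n_subjects Number of subjects.
#' @param p_both_eyes Probability a subject contributes both eyes.
#' @param psv_per_eye_mean Mean PSVs per eye (>= 1 enforced per eye;
#'   `1 + Poisson(mean - 1)`).
#' @param fixed_effects Named vector of true coefficients; names from
#'   `"(Intercept)"`, `"age_y"`, `"axl_mm"`, `"se_d"`, `"ct_um"`,
#'   `"global_ccfd_pct"`, `"area_mm2"`, `"vfd_mm"`.
#' @param sd_subject,sd_eye,sd_resid SDs of the subject intercept, the
#'   eye-within-subject intercept, and the residual (all >= 0).
#' @param confound_axl_ccfd Correlation between AXL and global CCFD,
#'   in (-1, 1).
#' @param seed Integer seed.
#' @return A `cohort_params` list.
#' @export
cohort_params <- function(n_subjects = 31L,
                          p_both_eyes = 0.68,
                          psv_per_eye_mean = 2.3,
                          fixed_effects = c(
                            "(Intercept)" = 48.529, age_y = 0.230,
                            axl_mm = -2.372, se_d = -0.434, ct_um = 0.013,
                            global_ccfd_pct = 1.022, area_mm2 = 16.518,
                            vfd_mm = -1.153),
                          sd_subject = 4, sd_eye = 2.5, sd_resid = 5,
                          confound_axl_ccfd = 0.47,
                          seed = 1L) {
  stopifnot(n_subjects >= 1, p_both_eyes >= 0, p_both_eyes <= 1,
            psv_per_eye_mean > 0,
            sd_subject >= 0, sd_eye >= 0, sd_resid >= 0)
  if (abs(confound_axl_ccfd) >= 1) {
    stop("|confound_axl_ccfd| must be < 1 (implied covariance not ",
         "positive definite)", call. = FALSE)
  }
  known <- c("(Intercept)", "age_y", "axl_mm", "se_d", "ct_um",
             "global_ccfd_pct", "area_mm2", "vfd_mm")
  if (is.null(names(fixed_effects)) || !all(names(fixed_effects) %in% known)) {
    stop("fixed_effects names must be among: ",
         paste(known, collapse = ", "), call. = FALSE)
  }
  structure(as.list(environment())[
    c("n_subjects", "p_both_eyes", "psv_per_eye_mean", "fixed_effects",
      "sd_subject", "sd_eye", "sd_resid", "confound_axl_ccfd", "seed")],
    class = "cohort_params")
}

#' Simulate a PSV cohort table
#'
#' One row per PSV. Subject-level age; eye-level axial length, spherical
#' equivalent, choroidal thickness and global CCFD% (AXL and CCFD drawn
#' jointly at the configured correlation); PSV-level area (lognormal,
#' mean ~0.052 mm^2) and VFD. The response `fd_psv` is the linear predictor
#' from the configured fixed effects plus a subject intercept, an
#' eye-within-subject intercept, and a residual (all Gaussian; the response
#' is not clipped, keeping inference on it unbiased). Eye IDs are globally
#' unique, so the subject/eye nesting is well-formed by construction.
#'
#' @param params A [cohort_params] object.
#' @return A data.frame of PSV records with columns `subject_id`, `eye_id`,
#'   `psv_id`, covariates (`age_y`, `axl_mm`, `se_d`, `ct_um`, `ct_axl`,
#'   `global_ccfd_pct`, `area_mm2`, `vfd_mm`) and the response `fd_psv`.
#' @export
generate_cohort <- function(params = cohort_params()) {
  stopifnot(inherits(params, "cohort_params"))
  set.seed(params$seed)
  ns <- params$n_subjects
  age <- rnorm(ns, 28.30, 6.99)
  b_subj <- rnorm(ns, 0, params$sd_subject)
  n_eyes_per <- 1L + rbinom(ns, 1L, params$p_both_eyes)

  rows <- vector("list", ns)
  eye_counter <- 0L
  for (s in seq_len(ns)) {
    eyes <- seq_len(n_eyes_per[s])
    erows <- vector("list", length(eyes))
    for (e in eyes) {
      eye_counter <- eye_counter + 1L
      z_axl <- rnorm(1)
      z2 <- rnorm(1)
      rho <- params$confound_axl_ccfd
      axl <- 25.28 + 1.09 * z_axl
      ccfd <- 17.86 + 10.58 * (rho * z_axl + sqrt(1 - rho^2) * z2)
      ccfd <- min(max(ccfd, 0), 100)
      se <- rnorm(1, -4.03, 1.71)
      ct <- max(rnorm(1, 187.01, 59.71), 20)
      b_eye <- rnorm(1, 0, params$sd_eye)
      n_psv <- 1L + rpois(1L, max(params$psv_per_eye_mean - 1, 0))
      area <- rlnorm(n_psv, meanlog = log(0.052) - 0.8^2 / 2, sdlog = 0.8)
      vfd_v <- abs(rnorm(n_psv, 1.50, 0.69))
      erows[[e]] <- data.frame(
        subject_id = sprintf("S%03d", s),
        eye_id = sprintf("S%03d_E%d", s, e),
        psv_id = sprintf("S%03d_E%d_P%d", s, e, seq_len(n_psv)),
        age_y = age[s], axl_mm = axl, se_d = se, ct_um = ct,
        ct_axl = ct / axl,
        global_ccfd_pct = ccfd, area_mm2 = area, vfd_mm = vfd_v,
        b_subj = b_subj[s], b_eye = b_eye,
        stringsAsFactors = FALSE
      )
    }
    rows[[s]] <- do.call(rbind, erows)
  }
  d <- do.call(rbind, rows)

  fe <- params$fixed_effects
  lp <- rep(0, nrow(d))
  if ("(Intercept)" %in% names(fe)) lp <- lp + fe[["(Intercept)"]]
  for (nm in setdiff(names(fe), "(Intercept)")) {
    lp <- lp + fe[[nm]] * d[[nm]]
  }
  d$fd_psv <- lp + d$b_subj + d$b_eye + rnorm(nrow(d), 0, params$sd_resid)
  d$b_subj <- NULL
  d$b_eye <- NULL
  rownames(d) <- NULL
  d
}
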
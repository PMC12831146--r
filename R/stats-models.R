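#' Spearman rank-correlation screen
#'
#' Rank correlation of each candidate predictor with the response, with
#' tie-corrected asymptotic p-values. Constant predictors (or fewer than 3
#' complete pairs) yield `NA` rather than an error.
#'
#' @param table Data frame.
#' @param response Response column name.
#' @param predictors Character vector of predictor column names.
#' @return Data frame with columns `predictor`, `rho`, `p_value`, `n`.
#' @export
spearman_screen <- function(table, response, predictors) {
  stopifnot(response %in% names(table), all(predictors %in% names(table)))
  y <- table[[response]]
  out <- lapply(predictors, function(pr) {
    x <- table[[pr]]
    ok <- is.finite(x) & is.finite(y)
    n <- sum(ok)
    if (n < 3 || sd(x[ok]) == 0 || sd(y[ok]) == 0) {
      return(data.frame(predictor = pr, rho = NA_real_, p_value = NA_real_,
                        n = n))
    }
    ct <- suppressWarnings(
      cor.test(x[ok], y[ok], method = "spearman", exact = FALSE))
    data.frame(predictor = pr, rho = unname(ct$estimate),
               p_value = ct$p.value, n = n)
  })
  do.call(rbind, out)
}

#' Nested mixed-effects model for paired-eye PSV data
#'
#' Linear mixed-effects regression with nested random intercepts for
#' subject and eye-within-subject, fitted by maximum likelihood. Reports
#' Wald fixed-effect estimates, 95% CIs and z-based p-values, the three
#' variance components, and a marginal R-squared (fixed-effect variance
#' over total variance). Singular (boundary) fits are flagged in the
#' result, not raised.
#'
#' @param table Data frame (one row per PSV).
#' @param response Response column name.
#' @param fixed_terms Character vector of fixed-effect column names.
#' @param grouping Length-2 character vector: subject and eye ID columns.
#' @param conf_level Confidence level (default 0.95).
#' @return A `psv_model` list: `terms` (data.frame of term, estimate, se,
#'   ci_low, ci_high, p_value), `var_subject`, `var_eye`, `var_resid`,
#'   `r2`, `n_obs`, `n_subjects`, `n_eyes`, `singular`, and the underlying
#'   `fit`.
#' @export
fit_mixed <- function(table, response, fixed_terms,
                      grouping = c("subject_id", "eye_id"),
                      conf_level = 0.95) {
  stopifnot(length(grouping) == 2, response %in% names(table),
            all(fixed_terms %in% names(table)),
            all(grouping %in% names(table)))
  n_subj <- length(unique(table[[grouping[1]]]))
  if (n_subj < 2) {
    stop("need at least 2 subjects to fit the nested mixed model",
         call. = FALSE)
  }
  re <- c(sprintf("(1 | %s)", grouping[1]),
          sprintf("(1 | %s:%s)", grouping[1], grouping[2]))
  fml <- as.formula(paste(response, "~",
                          paste(c(fixed_terms, re), collapse = " + ")))
  fit <- suppressMessages(lme4::lmer(
    fml, data = table, REML = FALSE,
    control = lme4::lmerControl(check.nobs.vs.nlev = "ignore",
                                check.nobs.vs.nRE = "ignore",
                                # covariates keep their clinical units (um,
                                # mm, mm^2), which span several decades
                                check.scaleX = "ignore",
                                calc.derivs = FALSE)))
  singular <- lme4::isSingular(fit)
  be <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(vcov(fit))))
  zc <- qnorm(1 - (1 - conf_level) / 2)
  p <- 2 * pnorm(-abs(be / se))
  vc <- as.data.frame(lme4::VarCorr(fit))
  pick_var <- function(grp) {
    i <- which(vc$grp == grp)
    if (length(i) == 1) vc$vcov[i] else 0
  }
  var_subject <- pick_var(grouping[1])
  var_eye <- pick_var(paste0(grouping[1], ":", grouping[2]))
  var_resid <- pick_var("Residual")
  X <- model.matrix(fit)
  var_fixed <- var(as.vector(X %*% be))
  r2 <- var_fixed / (var_fixed + var_subject + var_eye + var_resid)
  structure(list(
    terms = data.frame(term = names(be), estimate = unname(be),
                       se = unname(se),
                       ci_low = unname(be - zc * se),
                       ci_high = unname(be + zc * se),
                       p_value = unname(p), stringsAsFactors = FALSE),
    var_subject = var_subject, var_eye = var_eye, var_resid = var_resid,
    r2 = r2, n_obs = nrow(X), n_subjects = n_subj,
    n_eyes = length(unique(paste(table[[grouping[1]]],
                                 table[[grouping[2]]]))),
    singular = singular, fit = fit), class = "psv_model")
}

#' @exportS3Method base::print
print.psv_model <- function(x, ...) {
  cat(sprintf(
    "<psv_model> %d PSVs, %d eyes, %d subjects; R2 = %.3f%s\n",
    x$n_obs, x$n_eyes, x$n_subjects, x$r2,
    if (x$singular) " (singular fit)" else ""))
  print(x$terms, digits = 4)
  cat(sprintf("variance components: subject %.3g, eye %.3g, residual %.3g\n",
              x$var_subject, x$var_eye, x$var_resid))
  invisible(x)
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R2_j)` where `R2_j` is from regressing predictor `j`
#' on the remaining predictors. Perfect collinearity reports `Inf`.
#'
#' @param table Data frame.
#' @param predictors Character vector of (>= 2) predictor columns.
#' @return Data frame with columns `predictor`, `vif`.
#' @export
vif <- function(table, predictors) {
  stopifnot(length(predictors) >= 2, all(predictors %in% names(table)))
  d <- table[predictors]
  if (nrow(d) < length(predictors) + 2) {
    stop("need at least ", length(predictors) + 2, " rows", call. = FALSE)
  }
  out <- vapply(predictors, function(pr) {
    fml <- reformulate(setdiff(predictors, pr), response = pr)
    # lm warns about essentially perfect fits; that case is the documented
    # infinite-VIF outcome, so the warning is redundant here
    r2 <- suppressWarnings(summary(lm(fml, data = d))$r.squared)
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  data.frame(predictor = predictors, vif = unname(out))
}

#' Intraclass correlation for repeatability
#'
#' Two-way mixed-effects, absolute-agreement, single-measurement ICC
#' (ICC(A,1) in the McGraw-Wong taxonomy) for repeated grading sessions of
#' the same items, with the F-based 95% CI. Zero between-item variance
#' makes the ICC undefined (`NA`).
#'
#' @param session1,session2 Paired measurements (same items, two sessions);
#'   alternatively `session1` may be an n x k matrix with `session2`
#'   missing.
#' @param conf_level Confidence level (default 0.95).
#' @return List `icc`, `ci_low`, `ci_high`, `n`, `k`.
#' @export
icc_repeatability <- function(session1, session2 = NULL, conf_level = 0.95) {
  Y <- if (is.null(session2)) as.matrix(session1) else cbind(session1, session2)
  Y <- Y[stats::complete.cases(Y), , drop = FALSE]
  n <- nrow(Y); k <- ncol(Y)
  if (n < 5 || k < 2) stop("need >= 5 items measured in >= 2 sessions",
                           call. = FALSE)
  gm <- mean(Y)
  row_m <- rowMeans(Y)
  col_m <- colMeans(Y)
  ssr <- k * sum((row_m - gm)^2)
  ssc <- n * sum((col_m - gm)^2)
  sst <- sum((Y - gm)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse + (k / n) * (msc - mse)
  if (denom <= 0) {
    # no variance anywhere: agreement is undefined
    return(list(icc = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                n = n, k = k))
  }
  icc <- (msr - mse) / denom
  if (mse == 0 && msc == 0) {
    # sessions agree exactly: degenerate CI at 1
    return(list(icc = icc, ci_low = icc, ci_high = icc, n = n, k = k))
  }
  alpha <- 1 - conf_level
  a <- (k * icc) / (n * (1 - icc))
  b <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
  v <- (a * msc + b * mse)^2 /
    ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
  fl <- qf(1 - alpha / 2, n - 1, v)
  fu <- qf(1 - alpha / 2, v, n - 1)
  ci_low <- n * (msr - fl * mse) /
    (fl * (k * msc + (k * n - k - n) * mse) + n * msr)
  ci_high <- n * (fu * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * fu * msr)
  list(icc = icc, ci_low = ci_low, ci_high = ci_high, n = n, k = k)
}

#' Post hoc power from the noncentral t-distribution
#'
#' Power of the two-sided test of a regression coefficient, from the
#' observed coefficient and standard error (derivable from a 95% CI
#' half-width divided by 1.96): noncentrality `ncp = beta_hat / se`,
#' degrees of freedom `n_eff - k - 1` with `n_eff` the subject-level
#' effective sample size, and `power = P(|T_ncp| > t_crit)` at level
#' `alpha`. With `beta_hat = 0` the power equals `alpha` exactly.
#'
#' @param beta_hat Observed coefficient.
#' @param se Standard error (> 0).
#' @param n_eff Subject-level effective sample size.
#' @param k Number of model predictors (default 1).
#' @param alpha Significance level (default 0.05).
#' @return Estimated power in `[0, 1]`.
#' @export
posthoc_power <- function(beta_hat, se, n_eff, k = 1, alpha = 0.05) {
  stopifnot(se > 0, alpha > 0, alpha < 1)
  df <- n_eff - k - 1
  if (df <= 0) stop("non-positive degrees of freedom (n_eff too small)",
                    call. = FALSE)
  ncp <- beta_hat / se
  tc <- qt(1 - alpha / 2, df)
  pt(tc, df, ncp = ncp, lower.tail = FALSE) + pt(-tc, df, ncp = ncp)
}
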
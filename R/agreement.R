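# Repeated-measures Bland-Altman statistics via linear mixed models.
# All fits use lme4 with REML; variance components are truncated at zero
# by lme4 itself; inference is Wald (normal) at 95%.

lmer_quiet <- function(formula, data) {
  ctrl <- lme4::lmerControl(
    check.conv.singular = "ignore",
    check.conv.grad = lme4::.makeCC("ignore", tol = 2e-3),
    check.conv.hess = lme4::.makeCC("ignore", tol = 1e-6)
  )
  withCallingHandlers(
    suppressMessages(lme4::lmer(formula, data = data, REML = TRUE,
                                control = ctrl)),
    warning = function(w) {
      # roundoff breakdown at the zero-variance boundary is expected for
      # noise-free constructions; the returned optimum is still valid
      if (grepl("NLOPT_ROUNDOFF_LIMITED", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
}

wald_table <- function(fit, level = 0.95) {
  est <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  z <- stats::qnorm(1 - (1 - level) / 2)
  data.frame(
    term = names(est), estimate = unname(est), se = unname(se),
    ci_lower = unname(est - z * se), ci_upper = unname(est + z * se),
    p_value = 2 * stats::pnorm(-abs(unname(est) / unname(se))),
    stringsAsFactors = FALSE
  )
}

variance_components <- function(fit) {
  vc <- as.data.frame(lme4::VarCorr(fit))
  resid_sd <- vc$sdcor[vc$grp == "Residual"]
  subj_sd <- vc$sdcor[vc$grp == "subject_id"]
  level_sd <- vc$sdcor[grepl(":", vc$grp)]
  list(
    sigma_between = if (length(subj_sd)) subj_sd else 0,
    sigma_level = if (length(level_sd)) level_sd else 0,
    sigma_resid = resid_sd
  )
}

#' Fit a random-intercept linear mixed model
#'
#' The workhorse behind all agreement statistics: a Gaussian linear
#' mixed model with a subject random intercept (and optionally a
#' level-within-subject intercept), estimated by REML, with 95% Wald
#' confidence intervals and normal-approximation p-values.
#'
#' @param y Response vector.
#' @param covariates Optional data frame of fixed-effect columns (an
#'   intercept is always included); interactions can be passed as
#'   precomputed columns.
#' @param subject Subject identifier vector.
#' @param level Optional LBNP-level identifier; when given, a
#'   level-within-subject random intercept is added.
#' @return An object of class `lmm_fit`: the coefficient table,
#'   variance components (`sigma_between`, `sigma_level`,
#'   `sigma_resid`), `n_obs`, `n_subjects`, the REML log-likelihood and
#'   the underlying `lmerMod` object.
#' @export
fit_random_intercept <- function(y, covariates = NULL, subject,
                                 level = NULL) {
  dat <- data.frame(y = y, subject_id = factor(subject))
  if (length(unique(dat$subject_id)) < 2) {
    stop("at least two subjects are required")
  }
  rhs <- "1"
  if (!is.null(covariates) && ncol(as.data.frame(covariates)) > 0) {
    covariates <- as.data.frame(covariates)
    dat <- cbind(dat, covariates)
    rhs <- paste(c("1", names(covariates)), collapse = " + ")
    mm <- stats::model.matrix(
      stats::as.formula(paste("~", rhs)), dat)
    if (qr(mm)$rank < ncol(mm)) stop("fixed-effect design is rank deficient")
  }
  re <- "(1 | subject_id)"
  if (!is.null(level)) {
    dat$lbnp_level <- factor(level)
    re <- paste(re, "+ (1 | subject_id:lbnp_level)")
  }
  # degenerate intercept-only data with (numerically) zero within-subject
  # variation sits on the REML boundary where lme4 is unreliable; the
  # balanced closed form is exact there
  if (is.null(covariates) && is.null(level)) {
    mu <- tapply(dat$y, dat$subject_id, mean)
    wss <- sum((dat$y - mu[dat$subject_id])^2)
    scale2 <- stats::var(dat$y) + mean(dat$y)^2
    if (wss <= 1e-12 * max(scale2, 1) * nrow(dat)) {
      a <- length(mu)
      est <- mean(mu)
      se <- stats::sd(mu) / sqrt(a)
      z <- stats::qnorm(0.975)
      return(structure(list(
        fixed_effects = data.frame(
          term = "(Intercept)", estimate = est, se = se,
          ci_lower = est - z * se, ci_upper = est + z * se,
          p_value = 2 * stats::pnorm(-abs(est / se)),
          stringsAsFactors = FALSE),
        sigma_between = stats::sd(mu), sigma_level = 0, sigma_resid = 0,
        n_obs = nrow(dat), n_subjects = a, logLik_reml = NA_real_,
        model = NULL, y = dat$y,
        fitted_values = unname(mu[dat$subject_id])
      ), class = "lmm_fit"))
    }
  }
  form <- stats::as.formula(paste("y ~", rhs, "+", re))
  fit <- lmer_quiet(form, dat)
  vc <- variance_components(fit)
  structure(list(
    fixed_effects = wald_table(fit),
    sigma_between = vc$sigma_between,
    sigma_level = vc$sigma_level,
    sigma_resid = vc$sigma_resid,
    n_obs = nrow(dat),
    n_subjects = length(unique(dat$subject_id)),
    logLik_reml = as.numeric(stats::logLik(fit)),
    model = fit
  ), class = "lmm_fit")
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat("Linear mixed model (REML),", x$n_obs, "records,",
      x$n_subjects, "subjects\n")
  print(x$fixed_effects, digits = 4, row.names = FALSE)
  cat(sprintf("sigma_between = %.3f, sigma_level = %.3f, sigma_resid = %.3f\n",
              x$sigma_between, x$sigma_level, x$sigma_resid))
  invisible(x)
}

#' Repeated-measures Bland-Altman analysis
#'
#' Fits the between-method difference with a subject random intercept
#' (`diff ~ 1 + (1 | subject)`). The bias is the fixed intercept; the
#' limits-of-agreement half-width is 1.96 times the total SD
#' (`sqrt(sigma_between^2 + sigma_resid^2)`); the within-subject
#' limits-of-agreement half-width is 1.96 times the residual SD; the
#' within-subject percentage error divides the latter by the mean of
#' the paired-method averages.
#'
#' @param bins Bin data frame with `diff`, `mean` and `subject_id`.
#' @param pe_denominator `"grand"`: grand mean of per-bin mean-of-methods;
#'   `"subject"`: mean of per-subject mean-of-methods.
#' @return An object of class `agreement_fit` with `bias`,
#'   `loa_half_width`, `ws_loa_half_width`, `percentage_error` and the
#'   underlying `lmm_fit`.
#' @export
bland_altman <- function(bins, pe_denominator = c("grand", "subject")) {
  pe_denominator <- match.arg(pe_denominator)
  fit <- fit_random_intercept(bins$diff, NULL, bins$subject_id)
  denom <- switch(pe_denominator,
    grand = mean(bins$mean),
    subject = mean(tapply(bins$mean, bins$subject_id, mean))
  )
  total_sd <- sqrt(fit$sigma_between^2 + fit$sigma_resid^2)
  structure(list(
    bias = fit$fixed_effects$estimate[1],
    loa_half_width = 1.96 * total_sd,
    ws_loa_half_width = 1.96 * fit$sigma_resid,
    percentage_error = 1.96 * fit$sigma_resid / denom * 100,
    pe_denominator = pe_denominator,
    fit = fit
  ), class = "agreement_fit")
}

#' @export
print.agreement_fit <- function(x, ...) {
  cat(sprintf(
    "Bland-Altman (mixed regression): bias %.1f mL, LOA +/- %.1f mL,\n",
    x$bias, x$loa_half_width))
  cat(sprintf(
    "  within-subject LOA +/- %.1f mL, within-subject PE %.1f%%\n",
    x$ws_loa_half_width, x$percentage_error))
  invisible(x)
}

new_covariate_fit <- function(tag, fit, slopes = NULL, extra = list()) {
  structure(c(list(tag = tag, coefficients = fit$fixed_effects,
                   slopes = slopes, fit = fit), extra),
            class = "covariate_fit")
}

#' @export
print.covariate_fit <- function(x, ...) {
  cat("Covariate bias model:", x$tag, "\n")
  print(x$coefficients, digits = 4, row.names = FALSE)
  if (!is.null(x$slopes)) print(x$slopes, digits = 4, row.names = FALSE)
  invisible(x)
}

#' Sloped bias line on the mean of methods
#'
#' Regresses the between-method difference on the mean of methods with
#' a subject random intercept. Limits of agreement about the fitted
#' line use the same variance-component rule as [bland_altman()].
#'
#' @param bins Bin data frame.
#' @param pe_denominator See [bland_altman()].
#' @return A `covariate_fit` (tag `"sloped_bias"`) whose `slope` element
#'   is in mL/mL; includes `loa_half_width`, `ws_loa_half_width` and
#'   `percentage_error` about the fitted line.
#' @export
sloped_bias <- function(bins, pe_denominator = c("grand", "subject")) {
  pe_denominator <- match.arg(pe_denominator)
  if (stats::sd(bins$mean) == 0) {
    stop("mean of methods is constant; sloped bias is unidentifiable")
  }
  fit <- fit_random_intercept(bins$diff,
                              data.frame(mean_of_methods = bins$mean),
                              bins$subject_id)
  denom <- switch(pe_denominator,
    grand = mean(bins$mean),
    subject = mean(tapply(bins$mean, bins$subject_id, mean))
  )
  total_sd <- sqrt(fit$sigma_between^2 + fit$sigma_resid^2)
  new_covariate_fit("sloped_bias", fit,
    slopes = fit$fixed_effects[2, , drop = FALSE],
    extra = list(
      slope = fit$fixed_effects$estimate[2],
      loa_half_width = 1.96 * total_sd,
      ws_loa_half_width = 1.96 * fit$sigma_resid,
      percentage_error = 1.96 * fit$sigma_resid / denom * 100
    ))
}

#' Effect of systemic vascular resistance on the agreement
#'
#' Regresses the between-method difference on `svr_us` with a subject
#' random intercept; optionally adds sex and its interaction with SVR,
#' in which case sex-specific SVR slopes are reported as linear
#' combinations with Wald CIs.
#'
#' @param bins Bin data frame.
#' @param with_sex_interaction Logical.
#' @return A `covariate_fit` (tag `"svr"` or `"svr_sex_interaction"`).
#'   `slope` is the common SVR slope (mL per mmHg·min·L^-1); with the
#'   interaction, `slopes` holds one row per sex.
#' @export
svr_effect <- function(bins, with_sex_interaction = FALSE) {
  if (stats::sd(bins$svr_us) == 0) stop("svr_us must vary")
  if (!with_sex_interaction) {
    fit <- fit_random_intercept(bins$diff,
                                data.frame(svr_us = bins$svr_us),
                                bins$subject_id)
    return(new_covariate_fit("svr", fit,
      slopes = fit$fixed_effects[2, , drop = FALSE],
      extra = list(slope = fit$fixed_effects$estimate[2])))
  }
  if (length(unique(bins$sex)) < 2) {
    stop("sex interaction requires both sexes in the data")
  }
  male <- as.numeric(bins$sex == "male")
  fit <- fit_random_intercept(
    bins$diff,
    data.frame(svr_us = bins$svr_us, sex_male = male,
               svr_sex_male = bins$svr_us * male),
    bins$subject_id)
  est <- fit$fixed_effects$estimate
  names(est) <- fit$fixed_effects$term
  V <- as.matrix(stats::vcov(fit$model))
  z <- stats::qnorm(0.975)
  comb <- function(w) {
    e <- sum(w * est)
    s <- sqrt(drop(t(w) %*% V %*% w))
    c(estimate = e, se = s, ci_lower = e - z * s, ci_upper = e + z * s,
      p_value = 2 * stats::pnorm(-abs(e / s)))
  }
  w_f <- c(0, 1, 0, 0)
  w_m <- c(0, 1, 0, 1)
  slopes <- as.data.frame(rbind(female = comb(w_f), male = comb(w_m)))
  slopes <- cbind(term = paste0("svr_us_", rownames(slopes)), slopes)
  rownames(slopes) <- NULL
  new_covariate_fit("svr_sex_interaction", fit, slopes = slopes,
    extra = list(slope_male = slopes$estimate[slopes$term == "svr_us_male"],
                 slope_female = slopes$estimate[slopes$term == "svr_us_female"]))
}

#' Time as a proxy for SVR during handgrip periods
#'
#' Because SVR, MAP and cardiac output are mathematically coupled, the
#' SVR covariate is replaced by time within the handgrip periods:
#' the difference is regressed on the ordinal 30-s bin index with a
#' subject random intercept and an LBNP-level-within-subject random
#' intercept. The slope is in mL per 30 s.
#'
#' @param bins Bin data frame; only `phase == "ihg"` rows are used.
#' @return A `covariate_fit` (tag `"time_proxy"`).
#' @export
time_effect <- function(bins) {
  ihg <- bins[bins$phase == "ihg", , drop = FALSE]
  if (nrow(ihg) == 0) stop("no handgrip bins in the data")
  fit <- fit_random_intercept(
    ihg$diff, data.frame(time_bin = ihg$period_time_bin),
    ihg$subject_id, level = ihg$lbnp)
  new_covariate_fit("time_proxy", fit,
    slopes = fit$fixed_effects[2, , drop = FALSE],
    extra = list(slope = fit$fixed_effects$estimate[2]))
}

#' Per-method precision at rest
#'
#' Precision is 1.96 times the residual SD of a subject-random-intercept
#' model fitted to one method's 30-s values at LBNP 0 without handgrip.
#'
#' @param bins Bin data frame.
#' @param method `"us"` or `"pwa"`.
#' @return An object of class `precision_result` with `half_width` (mL).
#' @export
precision <- function(bins, method = c("us", "pwa")) {
  method <- match.arg(method)
  rest <- bins[bins$lbnp == 0 & bins$phase == "rest", , drop = FALSE]
  if (nrow(rest) == 0) stop("no resting LBNP-0 bins in the data")
  y <- if (method == "us") rest$sv_us else rest$sv_pwa
  fit <- fit_random_intercept(y, NULL, rest$subject_id)
  structure(list(method = method,
                 half_width = 1.96 * fit$sigma_resid,
                 fit = fit),
            class = "precision_result")
}

#' @export
print.precision_result <- function(x, ...) {
  cat(sprintf("Precision (sv_%s at rest, LBNP 0): +/- %.2f mL\n",
              x$method, x$half_width))
  invisible(x)
}

#' Residual diagnostics for a mixed fit
#'
#' Exports residuals, fitted values, standardized residuals and
#' normal-quantile pairs as a plain table for plotting; no automatic
#' pass/fail.
#'
#' @param fit An `lmm_fit` (or an object carrying one in `$fit`).
#' @return A data frame with columns `fitted`, `residual`,
#'   `std_residual` and `theoretical_quantile`.
#' @export
residual_diagnostics <- function(fit) {
  if (!inherits(fit, "lmm_fit") && !is.null(fit$fit)) fit <- fit$fit
  stopifnot(inherits(fit, "lmm_fit"))
  if (is.null(fit$model)) {
    r <- fit$y - fit$fitted_values
    f <- fit$fitted_values
  } else {
    r <- stats::residuals(fit$model)
    f <- stats::fitted(fit$model)
  }
  s <- if (fit$sigma_resid > 0) r / fit$sigma_resid else r * 0
  n <- length(r)
  q <- stats::qnorm(stats::ppoints(n))[rank(r, ties.method = "first")]
  data.frame(fitted = as.numeric(f), residual = as.numeric(r),
             std_residual = as.numeric(s), theoretical_quantile = q)
}
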
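#!/usr/bin/env Rscript
# Solves the calibrated defaults of trajectory_params() and
# discrepancy_params(). The defaults are defined by recovery properties:
# the fitted agreement models at the parameter-recovery scale must
# reproduce the reference estimates of the motivating method-comparison
# study:
#   bias 27.0 mL, LOA +/-30.1 mL, within-subject LOA +/-11.1 mL,
#   mean-of-methods slope -0.15 mL/mL, time-during-IHG slope
#   0.58 mL/30 s, per-method rest precision +/-3.7 mL
# (the SVR slope 0.60 is recovered by construction and only monitored).
# Unknowns: beat_noise_sd, map_ihg_boost, sv_drop_per_level,
# sigma_within_slope, sigma_between, delta0. Damped fixed-point /
# secant iteration over pilot simulations. Run from the repository root
# with the package installed; paste the printed constants into
# R/config.R.

suppressMessages(library(svagree))

pilot <- function(pars, seeds, n = 400) {
  res <- lapply(seeds, function(s) {
    traj <- trajectory_params(sv_drop_per_level = pars$d,
                              map_ihg_boost = pars$B,
                              beat_noise_sd = pars$sw,
                              bin_noise_sd_pwa = pars$sv)
    disc <- discrepancy_params(delta0 = pars$delta0,
                               sigma_between = pars$sb,
                               sigma_within_slope = pars$kappa)
    rc <- run_config(seed = s, n_subjects = n, traj = traj, disc = disc)
    cohort <- simulate_study(rc, write = FALSE)
    bins <- preprocess_study(rc, cohort, write = FALSE)
    ab <- analysis_bins(bins)
    ba <- bland_altman(ab)
    c(bias = ba$bias,
      resid = ba$fit$sigma_resid,
      btw = ba$fit$sigma_between,
      mean_slope = sloped_bias(ab)$slope,
      svr_slope = svr_effect(ab)$slope,
      time_slope = time_effect(ab)$slope,
      prec_us_resid = precision(bins, "us")$fit$sigma_resid,
      prec_pwa_resid = precision(bins, "pwa")$fit$sigma_resid,
      pe = ba$percentage_error)
  })
  rowMeans(do.call(cbind, res))
}

target <- list(bias = 27.0, resid = 11.1 / 1.96,
               btw = sqrt((30.1 / 1.96)^2 - (11.1 / 1.96)^2),
               mean_slope = -0.15, time_slope = 0.58,
               prec_resid = 3.7 / 1.96)

pars <- list(d = 12.5, B = 15, sw = 10.3, kappa = 0.95,
             sb = 14.3, delta0 = 24.4, sv = 0.9)
prev <- NULL

n_iter <- as.integer(Sys.getenv("CAL_ITER", "7"))
for (it in seq_len(n_iter)) {
  seeds <- 1000 * it + seq_len(ifelse(it < n_iter, 6, 12))
  m <- pilot(pars, seeds)
  cat(sprintf(
    "iter %d: bias %.2f resid %.3f btw %.3f mslope %.4f svr %.4f tslope %.4f prec %.3f/%.3f pe %.2f\n",
    it, m["bias"], m["resid"], m["btw"], m["mean_slope"], m["svr_slope"],
    m["time_slope"], 1.96 * m["prec_us_resid"], 1.96 * m["prec_pwa_resid"],
    m["pe"]))
  new <- pars
  new$sw <- pars$sw * target$prec_resid / m[["prec_us_resid"]]
  # PWA-side independent bin noise compensates the discrepancy's partial
  # cancellation of the shared physiological variability at rest
  new$sv <- sqrt(max(pars$sv^2 + target$prec_resid^2 -
                       m[["prec_pwa_resid"]]^2, 0))
  new$B <- pars$B * (target$time_slope / m[["time_slope"]])^0.8
  # mean-slope vs sv_drop: damped secant (slope can cross zero)
  sens <- if (!is.null(prev) && abs(pars$d - prev$d) > 0.05) {
    (m[["mean_slope"]] - prev$m[["mean_slope"]]) / (pars$d - prev$d)
  } else {
    -0.035
  }
  if (!is.finite(sens) || sens > -0.01) sens <- -0.035
  new$d <- pars$d + 0.6 * (target$mean_slope - m[["mean_slope"]]) / sens
  new$d <- min(max(new$d, 9), 15.5)
  # residual variance is ~linear in kappa^2: secant on the pair
  sens_k <- if (!is.null(prev) && abs(pars$kappa^2 - prev$kappa^2) > 0.01) {
    (m[["resid"]]^2 - prev$m[["resid"]]^2) / (pars$kappa^2 - prev$kappa^2)
  } else {
    30
  }
  if (!is.finite(sens_k) || sens_k < 5 || sens_k > 200) sens_k <- 30
  new$kappa <- sqrt(max(pars$kappa^2 +
                          0.8 * (target$resid^2 - m[["resid"]]^2) / sens_k,
                        0.01))
  new$sb <- sqrt(max(pars$sb^2 + target$btw^2 - m[["btw"]]^2, 1))
  new$delta0 <- pars$delta0 + (target$bias - m[["bias"]])
  prev <- list(d = pars$d, kappa = pars$kappa, m = m)
  pars <- new
  cat(sprintf(
    "  -> d %.3f B %.3f sw %.4f sv %.4f kappa %.4f sb %.3f delta0 %.3f\n",
    pars$d, pars$B, pars$sw, pars$sv, pars$kappa, pars$sb, pars$delta0))
}

cat("\nFinal constants:\n")
cat(sprintf("  sv_drop_per_level  = %.3f\n", pars$d))
cat(sprintf("  map_ihg_boost      = %.3f\n", pars$B))
cat(sprintf("  beat_noise_sd      = %.4f\n", pars$sw))
cat(sprintf("  bin_noise_sd_pwa   = %.4f\n", pars$sv))
cat(sprintf("  sigma_within_slope = %.4f\n", pars$kappa))
cat(sprintf("  sigma_between      = %.3f\n", pars$sb))
cat(sprintf("  delta0             = %.3f\n", pars$delta0))
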
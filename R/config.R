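#' Protocol configuration
#'
#' Describes the LBNP/IHG protocol: chamber pressures, level and period
#' durations, the block sizes used to randomize whether a subject starts
#' with handgrip or rest, and the handgrip target as a fraction of
#' maximal voluntary contraction.
#'
#' Each LBNP level lasts `level_duration` seconds and is made of three
#' `period_duration`-second periods: a stabilization period followed by
#' two periods alternating isometric handgrip (IHG) and rest.
#'
#' @param lbnp_levels Ordered chamber pressures in mmHg.
#' @param level_duration Seconds per LBNP level (must equal
#'   `3 * period_duration`).
#' @param period_duration Seconds per 2-minute period.
#' @param block_sizes Allowed randomization block sizes (even positives).
#' @param mvc_fraction Handgrip target as a fraction of MVC.
#' @return An object of class `protocol_config`.
#' @export
protocol_config <- function(lbnp_levels = c(0, 20, 40, 60, 80),
                            level_duration = 360,
                            period_duration = 120,
                            block_sizes = c(2, 4),
                            mvc_fraction = 0.40) {
  if (any(diff(lbnp_levels) <= 0) || any(lbnp_levels < 0)) {
    stop("lbnp_levels must be strictly increasing and non-negative")
  }
  if (level_duration != 3 * period_duration) {
    stop("level_duration must equal 3 * period_duration")
  }
  if (any(block_sizes <= 0) || any(block_sizes %% 2 != 0)) {
    stop("block_sizes must be even positive integers")
  }
  if (mvc_fraction <= 0 || mvc_fraction >= 1) {
    stop("mvc_fraction must be in (0, 1)")
  }
  structure(list(
    lbnp_levels = as.numeric(lbnp_levels),
    level_duration = level_duration,
    period_duration = period_duration,
    block_sizes = as.integer(block_sizes),
    mvc_fraction = mvc_fraction
  ), class = "protocol_config")
}

#' Latent hemodynamic trajectory parameters
#'
#' Controls the noise-free subject trajectory and the measurement-scale
#' noise of the synthetic cohort. Stroke volume falls linearly with LBNP
#' level, heart rate rises linearly, and MAP ramps linearly from baseline
#' to `map_baseline + map_ihg_boost` across each 2-minute handgrip
#' period. Systemic vascular resistance is emergent (MAP / CO).
#'
#' The defaults are calibrated (see the methods vignette): the baseline
#' stroke volume of 81 mL matches a resting BSA-indexed stroke volume of
#' 43.2 mL/m^2 at the cohort-mean body surface area, and the
#' stroke-volume drop and handgrip MAP boost are solved jointly so that
#' the latent SVR excursion and mean-stroke-volume decline reproduce the
#' reference regression slopes (difference-on-mean -0.15 mL/mL, time
#' slope 0.58 mL/30 s at an SVR coefficient of 0.60).
#'
#' @param sv_baseline Stroke volume at LBNP 0, mL.
#' @param sv_drop_per_level Stroke-volume decline per 20-mmHg level, mL.
#' @param hr_baseline Heart rate at LBNP 0, bpm.
#' @param hr_rise_per_level Heart-rate rise per level, bpm.
#' @param map_baseline Mean arterial pressure at rest, mmHg.
#' @param map_ihg_boost MAP elevation at the end of a handgrip period,
#'   mmHg (ramped linearly over the period).
#' @param beat_noise_sd Beat-to-beat physiological stroke-volume
#'   variability shared by both methods, mL. The default is calibrated
#'   so that the residue this variability leaves in a 5%-trimmed 30-s
#'   mean makes the per-method precision statistic (1.96 x residual SD
#'   of resting 30-s values) recover +/-3.7 mL.
#' @param bin_noise_sd_us,bin_noise_sd_pwa Independent 30-s-scale
#'   method noise, mL (default 0: resting 30-s variability is
#'   attributed to the shared physiological component, which cancels in
#'   the between-method difference).
#' @param map_beat_noise_sd Beat-scale MAP noise, mmHg.
#' @param rr_jitter_sd Beat-interval jitter, s.
#' @return An object of class `trajectory_params`.
#' @export
trajectory_params <- function(sv_baseline = 81,
                              sv_drop_per_level = 12.23,
                              hr_baseline = 60,
                              hr_rise_per_level = 2,
                              map_baseline = 85,
                              map_ihg_boost = 14.6,
                              beat_noise_sd = 10.13,
                              bin_noise_sd_us = 0,
                              bin_noise_sd_pwa = 0.92,
                              map_beat_noise_sd = 2,
                              rr_jitter_sd = 0.01) {
  p <- list(
    sv_baseline = sv_baseline, sv_drop_per_level = sv_drop_per_level,
    hr_baseline = hr_baseline, hr_rise_per_level = hr_rise_per_level,
    map_baseline = map_baseline, map_ihg_boost = map_ihg_boost,
    beat_noise_sd = beat_noise_sd,
    bin_noise_sd_us = bin_noise_sd_us, bin_noise_sd_pwa = bin_noise_sd_pwa,
    map_beat_noise_sd = map_beat_noise_sd, rr_jitter_sd = rr_jitter_sd
  )
  pos <- c("sv_baseline", "hr_baseline", "map_baseline")
  if (any(unlist(p[pos]) <= 0)) stop("baseline parameters must be positive")
  nonneg <- c("sv_drop_per_level", "hr_rise_per_level", "map_ihg_boost",
              "beat_noise_sd", "bin_noise_sd_us", "bin_noise_sd_pwa",
              "map_beat_noise_sd", "rr_jitter_sd")
  if (any(unlist(p[nonneg]) < 0)) stop("noise and slope parameters must be non-negative")
  structure(p, class = "trajectory_params")
}

#' Between-method discrepancy parameters
#'
#' The generative counterpart of the fitted agreement models: the 30-s
#' scale difference between pulse-wave-analysis and ultrasound stroke
#' volume is
#' `delta0 + beta_svr * (SVR_US - svr_ref) + b_subject + e_bin`,
#' where `SVR_US` is the systemic vascular resistance computed from the
#' measured ultrasound 30-s value (exactly the covariate the analysis
#' models use), `b_subject` is a between-subject offset with SD
#' `sigma_between` carried on the pulse-wave-analysis side, and `e_bin`
#' is 30-s difference noise whose SD is
#' `sqrt(sigma_within^2 + (sigma_within_slope * dSVR)^2)` with `dSVR`
#' the latent SVR elevation above the resting baseline. The
#' stress-dependent term is required for internal consistency: resting
#' per-method precisions of +/-3.7 mL bound the resting difference noise
#' near 2.7 mL, while the overall within-subject variability corresponds
#' to 11.1/1.96 = 5.66 mL, so the difference noise must grow with
#' vasoconstriction.
#'
#' Defaults are calibrated by variance accounting (methods vignette) so
#' the fitted Bland-Altman components recover bias 27.0 mL, limits of
#' agreement +/-30.1 mL and within-subject limits +/-11.1 mL.
#'
#' @param delta0 Difference at the reference SVR, mL.
#' @param beta_svr Difference slope on SVR, mL per mmHg·min·L^-1.
#' @param beta_svr_male,beta_svr_female Optional sex-specific slopes;
#'   when both are given they replace `beta_svr`.
#' @param svr_ref Reference SVR, mmHg·min·L^-1.
#' @param sigma_between SD of the subject-level offset, mL.
#' @param sigma_within Stress-independent 30-s difference-noise SD, mL.
#' @param sigma_within_slope Stress-dependent difference-noise SD per
#'   unit of SVR elevation, mL per mmHg·min·L^-1.
#' @return An object of class `discrepancy_params`.
#' @export
discrepancy_params <- function(delta0 = 23.74,
                               beta_svr = 0.60,
                               beta_svr_male = NULL,
                               beta_svr_female = NULL,
                               svr_ref = 17.49,
                               sigma_between = 14.46,
                               sigma_within = 0,
                               sigma_within_slope = 0.568) {
  if (sigma_between < 0 || sigma_within < 0 || sigma_within_slope < 0) {
    stop("noise SDs must be non-negative")
  }
  if (xor(is.null(beta_svr_male), is.null(beta_svr_female))) {
    stop("provide both sex-specific slopes or neither")
  }
  structure(list(
    delta0 = delta0, beta_svr = beta_svr,
    beta_svr_male = beta_svr_male, beta_svr_female = beta_svr_female,
    svr_ref = svr_ref, sigma_between = sigma_between,
    sigma_within = sigma_within, sigma_within_slope = sigma_within_slope
  ), class = "discrepancy_params")
}

#' Default per-level dropout distribution
#'
#' Probability that a subject's highest completed level is 20, 40, 60 or
#' 80 mmHg. The default (1, 4, 9, 2)/16 reproduces completion counts of
#' 16, 15, 11 and 2 subjects out of 16 at LBNP 20/40/60/80.
#'
#' @param config A [protocol_config()].
#' @return Named numeric vector of stop-level probabilities.
#' @export
default_dropout_dist <- function(config = protocol_config()) {
  lv <- config$lbnp_levels[config$lbnp_levels >= 20]
  if (length(lv) != 4) stop("default dropout distribution requires levels 20-80")
  stats::setNames(c(1, 4, 9, 2) / 16, lv)
}

#' Full run configuration
#'
#' Bundles everything one end-to-end run needs: the RNG seed, cohort
#' size, parameter blocks and analysis switches.
#'
#' @param seed Integer RNG seed (mandatory for simulation).
#' @param n_subjects Number of subjects.
#' @param config A [protocol_config()].
#' @param traj A [trajectory_params()].
#' @param disc A [discrepancy_params()].
#' @param dropout_dist Stop-level distribution, see
#'   [default_dropout_dist()].
#' @param include_stabilization Logical; include stabilization-period
#'   bins in the agreement analyses (default `FALSE`).
#' @param pe_denominator `"grand"` (grand mean of per-bin mean-of-methods)
#'   or `"subject"` (mean of per-subject means) for the percentage-error
#'   denominator.
#' @param trim_fraction Trim fraction for 30-s means.
#' @param exclusion_window Seconds of data dropped after each handgrip
#'   release.
#' @param out_dir Directory for output files.
#' @return An object of class `run_config`.
#' @export
run_config <- function(seed = 1L,
                       n_subjects = 16L,
                       config = protocol_config(),
                       traj = trajectory_params(),
                       disc = discrepancy_params(),
                       dropout_dist = default_dropout_dist(config),
                       include_stabilization = FALSE,
                       pe_denominator = c("grand", "subject"),
                       trim_fraction = 0.05,
                       exclusion_window = 30,
                       out_dir = ".") {
  pe_denominator <- match.arg(pe_denominator)
  if (!is.numeric(seed) || length(seed) != 1 || !is.finite(seed)) {
    stop("seed must be a single integer")
  }
  if (n_subjects < 1) stop("n_subjects must be at least 1")
  structure(list(
    seed = as.integer(seed), n_subjects = as.integer(n_subjects),
    config = config, traj = traj, disc = disc,
    dropout_dist = dropout_dist,
    include_stabilization = include_stabilization,
    pe_denominator = pe_denominator,
    trim_fraction = trim_fraction,
    exclusion_window = exclusion_window,
    out_dir = out_dir
  ), class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' The file may set any of the `run_config()` fields at top level and
#' any field of the parameter blocks under `protocol`, `trajectory` and
#' `discrepancy`.
#'
#' @param path Path to a YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- do.call(protocol_config, raw$protocol %||% list())
  traj <- do.call(trajectory_params, raw$trajectory %||% list())
  disc <- do.call(discrepancy_params, raw$discrepancy %||% list())
  top <- raw[setdiff(names(raw), c("protocol", "trajectory", "discrepancy"))]
  args <- c(top, list(config = cfg, traj = traj, disc = disc))
  do.call(run_config, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
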
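# End-to-end orchestration: simulate -> preprocess -> analyze, with CSV
# and JSON file interfaces. All files are UTF-8 CSV with '.' decimals.

#' Select the bins that enter the agreement analyses
#'
#' Stabilization-period bins are flagged during binning; by default only
#' handgrip and rest bins are analysed.
#'
#' @param bins Bin data frame.
#' @param include_stabilization Logical.
#' @return The filtered bins.
#' @export
analysis_bins <- function(bins, include_stabilization = FALSE) {
  if (include_stabilization) bins
  else bins[bins$phase != "stabilization", , drop = FALSE]
}

#' Simulate a cohort and write beats.csv / subjects.csv
#'
#' @param rc A [run_config()].
#' @param write Logical; write CSV files into `rc$out_dir`.
#' @return Invisibly, the list returned by [simulate_cohort()].
#' @export
simulate_study <- function(rc, write = TRUE) {
  cohort <- simulate_cohort(rc$n_subjects, rc$config, rc$traj, rc$disc,
                            rc$dropout_dist, rng_seed = rc$seed)
  if (write) {
    dir.create(rc$out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(cohort$beats, file.path(rc$out_dir, "beats.csv"),
                     row.names = FALSE)
    utils::write.csv(cohort$profiles, file.path(rc$out_dir, "subjects.csv"),
                     row.names = FALSE)
    message(sprintf("simulate: seed %d, %d subjects, %d beats written",
                    rc$seed, rc$n_subjects, nrow(cohort$beats)))
  }
  invisible(cohort)
}

#' Preprocess beats into 30-s bins and write bins.csv
#'
#' @param rc A [run_config()].
#' @param cohort Optional in-memory cohort (list with `beats`,
#'   `profiles`); when `NULL`, `beats.csv` / `subjects.csv` are read
#'   from `rc$out_dir`.
#' @param write Logical; write `bins.csv`.
#' @return Invisibly, the bin data frame.
#' @export
preprocess_study <- function(rc, cohort = NULL, write = TRUE) {
  if (is.null(cohort)) {
    cohort <- list(
      beats = read_beats(file.path(rc$out_dir, "beats.csv")),
      profiles = read_profiles(file.path(rc$out_dir, "subjects.csv"))
    )
  }
  bins <- preprocess_beats(cohort$beats, cohort$profiles, rc$config,
                           exclusion_window = rc$exclusion_window,
                           trim_fraction = rc$trim_fraction)
  if (write) {
    dir.create(rc$out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(bins, file.path(rc$out_dir, "bins.csv"),
                     row.names = FALSE)
    message(sprintf("preprocess: %d beats -> %d bins",
                    nrow(cohort$beats), nrow(bins)))
  }
  invisible(bins)
}

read_beats <- function(path) {
  need <- c("subject_id", "t_onset", "rr", "lbnp", "level_index", "phase",
            "period_time", "sv_us", "sv_pwa", "map", "sex")
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols) > 0) {
    stop("beats file is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  x
}

read_profiles <- function(path) {
  need <- c("subject_id", "sex", "ihg_first", "decompensation_level")
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols) > 0) {
    stop("subjects file is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  x
}

#' Run all agreement analyses on a set of bins
#'
#' Fits the repeated-measures Bland-Altman model, the sloped-bias model,
#' the SVR model (with and, when both sexes are present, without the sex
#' interaction), the time-during-handgrip proxy model and both
#' per-method precisions.
#'
#' @param rc A [run_config()].
#' @param bins Optional in-memory bins; when `NULL`, `bins.csv` is read
#'   from `rc$out_dir`.
#' @param write Logical; write `results.json` and
#'   `bland_altman_plot.csv`.
#' @return Invisibly, a named list of fits: `bland_altman`,
#'   `sloped_bias`, `svr`, `svr_sex` (or `NULL`), `time_proxy`,
#'   `precision_us`, `precision_pwa`.
#' @export
analyze_study <- function(rc, bins = NULL, write = TRUE) {
  if (is.null(bins)) {
    bins <- utils::read.csv(file.path(rc$out_dir, "bins.csv"),
                            stringsAsFactors = FALSE)
  }
  ab <- analysis_bins(bins, rc$include_stabilization)
  res <- list(
    bland_altman = bland_altman(ab, rc$pe_denominator),
    sloped_bias = sloped_bias(ab, rc$pe_denominator),
    svr = svr_effect(ab, with_sex_interaction = FALSE),
    svr_sex = if (length(unique(ab$sex)) > 1)
      svr_effect(ab, with_sex_interaction = TRUE) else NULL,
    time_proxy = time_effect(ab),
    precision_us = precision(bins, "us"),
    precision_pwa = precision(bins, "pwa")
  )
  if (write) {
    dir.create(rc$out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(results_payload(res),
                         file.path(rc$out_dir, "results.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    utils::write.csv(bland_altman_plot_data(ab, res),
                     file.path(rc$out_dir, "bland_altman_plot.csv"),
                     row.names = FALSE)
  }
  invisible(res)
}

lmm_payload <- function(fit) {
  list(coefficients = fit$fixed_effects,
       sigma_between_mL = fit$sigma_between,
       sigma_level_mL = fit$sigma_level,
       sigma_resid_mL = fit$sigma_resid,
       n_obs = fit$n_obs, n_subjects = fit$n_subjects)
}

results_payload <- function(res) {
  ba <- res$bland_altman
  sb <- res$sloped_bias
  out <- list(
    bland_altman = c(list(bias_mL = ba$bias,
                          loa_half_width_mL = ba$loa_half_width,
                          ws_loa_half_width_mL = ba$ws_loa_half_width,
                          percentage_error_pct = ba$percentage_error),
                     lmm_payload(ba$fit)),
    sloped_bias = c(list(slope_mL_per_mL = sb$slope,
                         loa_half_width_mL = sb$loa_half_width,
                         ws_loa_half_width_mL = sb$ws_loa_half_width,
                         percentage_error_pct = sb$percentage_error),
                    lmm_payload(sb$fit)),
    svr = c(list(slope_mL_per_svr_unit = res$svr$slope),
            lmm_payload(res$svr$fit)),
    time_proxy = c(list(slope_mL_per_30s = res$time_proxy$slope),
                   lmm_payload(res$time_proxy$fit)),
    precision_us = list(half_width_mL = res$precision_us$half_width),
    precision_pwa = list(half_width_mL = res$precision_pwa$half_width)
  )
  if (!is.null(res$svr_sex)) {
    out$svr_sex <- c(list(slope_male_mL_per_svr_unit = res$svr_sex$slope_male,
                          slope_female_mL_per_svr_unit = res$svr_sex$slope_female,
                          slopes = res$svr_sex$slopes),
                     lmm_payload(res$svr_sex$fit))
  }
  out
}

bland_altman_plot_data <- function(ab_bins, res) {
  sb <- res$sloped_bias
  data.frame(
    subject_id = ab_bins$subject_id,
    mean = ab_bins$mean,
    diff = ab_bins$diff,
    bias = res$bland_altman$bias,
    loa_lower = res$bland_altman$bias - res$bland_altman$loa_half_width,
    loa_upper = res$bland_altman$bias + res$bland_altman$loa_half_width,
    ws_loa_lower = res$bland_altman$bias - res$bland_altman$ws_loa_half_width,
    ws_loa_upper = res$bland_altman$bias + res$bland_altman$ws_loa_half_width,
    fitted_bias_line = sb$coefficients$estimate[1] +
      sb$coefficients$estimate[2] * ab_bins$mean,
    stringsAsFactors = FALSE
  )
}

#' One-command replication of the synthetic study
#'
#' Runs simulate, preprocess and analyze at the calibrated defaults and
#' returns a side-by-side table of recovered quantities against the
#' reference values of the motivating method-comparison study. With
#' `replicates > 1`, quantities are averaged over replicate seeds and a
#' Monte-Carlo standard error is attached.
#'
#' @param n_subjects Cohort size (default 200, the package's
#'   parameter-recovery scale).
#' @param seed Base seed; replicate r uses `seed + r - 1`.
#' @param replicates Number of replicate cohorts.
#' @param sex_specific Use the sex-specific SVR slopes (needed for the
#'   sex-interaction row).
#' @param quiet Suppress progress messages.
#' @return A data frame with one row per recovered quantity:
#'   `quantity`, `recovered`, `reference`, `units` (and `mc_se` when
#'   `replicates > 1`).
#' @export
replicate_study <- function(n_subjects = 200, seed = 1, replicates = 1,
                            sex_specific = TRUE, quiet = FALSE) {
  one <- function(s) {
    rc <- run_config(seed = s, n_subjects = n_subjects)
    disc_sex <- discrepancy_params(beta_svr_male = 0.86,
                                   beta_svr_female = 0.40)
    cohort <- simulate_study(rc, write = FALSE)
    bins <- preprocess_study(rc, cohort, write = FALSE)
    res <- analyze_study(rc, bins, write = FALSE)
    male_slope <- NA_real_
    if (sex_specific) {
      rc2 <- run_config(seed = s + 500000L, n_subjects = n_subjects,
                        disc = disc_sex)
      cohort2 <- simulate_study(rc2, write = FALSE)
      bins2 <- preprocess_study(rc2, cohort2, write = FALSE)
      ab2 <- analysis_bins(bins2, rc2$include_stabilization)
      male_slope <- svr_effect(ab2, TRUE)$slope_male
    }
    c(bias = res$bland_altman$bias,
      loa = res$bland_altman$loa_half_width,
      ws_loa = res$bland_altman$ws_loa_half_width,
      pe = res$bland_altman$percentage_error,
      mean_slope = res$sloped_bias$slope,
      svr_slope = res$svr$slope,
      precision_us = res$precision_us$half_width,
      precision_pwa = res$precision_pwa$half_width,
      svr_slope_male = male_slope,
      time_slope = res$time_proxy$slope)
  }
  vals <- vapply(seq_len(replicates), function(r) {
    if (!quiet) message("replicate ", r, "/", replicates)
    one(seed + r - 1)
  }, numeric(10))
  vals <- matrix(vals, nrow = 10,
                 dimnames = list(c("bias", "loa", "ws_loa", "pe",
                                   "mean_slope", "svr_slope",
                                   "precision_us", "precision_pwa",
                                   "svr_slope_male", "time_slope"), NULL))
  ref <- c(bias = 27.0, loa = 30.1, ws_loa = 11.1, pe = 14.6,
           mean_slope = -0.15, svr_slope = 0.60,
           precision_us = 3.7, precision_pwa = 3.7,
           svr_slope_male = 0.86, time_slope = 0.58)
  units <- c("mL", "mL", "mL", "%", "mL/mL", "mL per mmHg.min/L",
             "mL", "mL", "mL per mmHg.min/L", "mL per 30 s")
  out <- data.frame(
    quantity = rownames(vals),
    recovered = rowMeans(vals),
    reference = unname(ref[rownames(vals)]),
    units = units,
    stringsAsFactors = FALSE
  )
  if (replicates > 1) {
    out$mc_se <- apply(vals, 1, stats::sd) / sqrt(replicates)
  }
  rownames(out) <- NULL
  out
}
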
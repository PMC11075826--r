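# Latent trajectory helpers ------------------------------------------------

latent_sv <- function(traj, level_index) {
  traj$sv_baseline - traj$sv_drop_per_level * level_index
}

latent_hr <- function(traj, level_index) {
  traj$hr_baseline + traj$hr_rise_per_level * level_index
}

# Mean MAP over a 30-s bin; the handgrip boost ramps linearly over the
# 2-minute period, so bin k of an IHG period averages boost*(30k+15)/120.
latent_map_bin <- function(traj, phase, bin_index, period_duration) {
  base <- traj$map_baseline
  if (phase == "ihg") {
    base <- base + traj$map_ihg_boost *
      (30 * bin_index + 15) / period_duration
  }
  base
}

# Baseline (LBNP 0, rest) latent SVR, the reference for the
# stress-dependent difference noise.
baseline_svr <- function(traj) {
  1000 * traj$map_baseline / (traj$sv_baseline * traj$hr_baseline)
}

subject_beta <- function(disc, sex) {
  if (!is.null(disc$beta_svr_male)) {
    if (identical(sex, "male")) disc$beta_svr_male else disc$beta_svr_female
  } else {
    disc$beta_svr
  }
}

#' Simulate the beat series of one subject
#'
#' Beats tile each 2-minute period with R-R intervals from the heart-rate
#' trajectory (the first beat of a period starts at the period boundary
#' and no beat straddles a boundary). The two methods' stroke volumes are
#' built at the 30-s-bin scale. Both methods share the beat-to-beat
#' physiological stroke-volume variability (which therefore cancels
#' exactly in their difference but gives each method its resting 30-s
#' variability); the ultrasound value adds only its (by default zero)
#' independent 30-s method noise and is the reference measurement. The
#' pulse-wave-analysis value adds the between-method discrepancy
#' `delta0 + beta_svr * (SVR_US - svr_ref) + b + e`,
#' where `SVR_US` is the systemic vascular resistance computed from the
#' trimmed-mean-measured ultrasound 30-s value — exactly the covariate
#' the agreement models later use, so the fitted difference-versus-SVR
#' slope equals `beta_svr` on both the within- and the between-subject
#' channel — `b` is the subject-level offset and `e` is the
#' stress-dependent 30-s difference noise. The PWA-side placement of
#' `b` and `e` puts half of their variance into the mean of methods;
#' this stable contribution to the difference-versus-mean slope is
#' accounted for in the calibration of the trajectory defaults (see the
#' methods vignette).
#'
#' @param config A [protocol_config()].
#' @param profile One-row subject profile.
#' @param traj A [trajectory_params()].
#' @param disc A [discrepancy_params()].
#' @param rng_seed Optional seed; `NULL` uses the current RNG state.
#' @param subject_offset Optional fixed subject-level difference offset
#'   in mL; drawn from `N(0, sigma_between^2)` when `NULL`.
#' @return A data frame of beats (one row per heartbeat) with columns
#'   `subject_id`, `t_onset`, `rr`, `lbnp`, `level_index`, `phase`,
#'   `period_time`, `sv_us`, `sv_pwa`, `map`, `sex`.
#' @export
simulate_subject <- function(config, profile, traj = trajectory_params(),
                             disc = discrepancy_params(),
                             rng_seed = NULL, subject_offset = NULL) {
  if (!is.null(rng_seed)) set.seed(rng_seed)
  sched <- build_schedule(config, profile)
  max_level <- max(sched$level_index)
  if (latent_sv(traj, max_level) <= 0) {
    stop("trajectory parameters drive stroke volume to zero or below")
  }
  b <- if (is.null(subject_offset)) {
    stats::rnorm(1, 0, disc$sigma_between)
  } else {
    subject_offset
  }
  beta <- subject_beta(disc, profile$sex)
  svr0 <- baseline_svr(traj)
  pd <- config$period_duration
  n_bins <- pd %/% 30

  out <- vector("list", nrow(sched))
  for (i in seq_len(nrow(sched))) {
    per <- sched[i, ]
    sv_lat <- latent_sv(traj, per$level_index)
    hr_lat <- latent_hr(traj, per$level_index)
    rr0 <- 60 / hr_lat

    # beat onsets tiling [start, end); keep beats that end within the period
    n_max <- ceiling(pd / rr0) + 8L
    rr <- rr0 + stats::rnorm(n_max, 0, traj$rr_jitter_sd)
    rr <- pmax(rr, 0.25)
    onsets <- per$start + c(0, cumsum(rr))[seq_len(n_max)]
    keep <- onsets + rr <= per$end
    rr <- rr[keep]
    onsets <- onsets[keep]
    nb <- length(onsets)
    if (nb == 0L) next

    # 30-s bin construction
    ks <- seq_len(n_bins) - 1L
    map_bin <- vapply(ks, function(k)
      latent_map_bin(traj, per$phase, k, pd), numeric(1))
    svr_lat <- 1000 * map_bin / (sv_lat * hr_lat)
    u <- stats::rnorm(n_bins, 0, traj$bin_noise_sd_us)
    v <- stats::rnorm(n_bins, 0, traj$bin_noise_sd_pwa)
    e_sd <- sqrt(disc$sigma_within^2 +
                   (disc$sigma_within_slope * pmax(0, svr_lat - svr0))^2)
    e <- stats::rnorm(n_bins, 0, e_sd)

    bin_of <- pmin(floor((onsets - per$start) / 30), n_bins - 1L) + 1L
    w <- stats::rnorm(nb, 0, traj$beat_noise_sd)
    # the discrepancy responds to the SVR the analysis will measure:
    # the 5%-trimmed 30-s mean of the ultrasound beats
    s_us <- pmax(sv_lat + u, 3)
    m_us <- s_us
    for (k in seq_len(n_bins)) {
      in_bin <- bin_of == k
      if (any(in_bin)) {
        m_us[k] <- trimmed_mean(s_us[k] + w[in_bin], 0.05)
      }
    }
    svr_star <- 1000 * map_bin / (pmax(m_us, 3) * hr_lat)
    dis <- disc$delta0 + beta * (svr_star - disc$svr_ref)
    s_pwa <- pmax(sv_lat + v + e + b + dis, 3)
    tau <- onsets - per$start
    map_beat <- traj$map_baseline +
      (per$phase == "ihg") * traj$map_ihg_boost * tau / pd +
      stats::rnorm(nb, 0, traj$map_beat_noise_sd)

    out[[i]] <- list(
      t_onset = onsets, rr = rr,
      lbnp = rep(per$lbnp, nb), level_index = rep(per$level_index, nb),
      phase = rep(per$phase, nb), period_time = tau,
      sv_us = pmax(s_us[bin_of] + w, 0.5),
      sv_pwa = pmax(s_pwa[bin_of] + w, 0.5),
      map = pmax(map_beat, 20)
    )
  }
  out <- out[!vapply(out, is.null, logical(1))]
  cols <- lapply(names(out[[1]]), function(nm)
    unlist(lapply(out, `[[`, nm), use.names = FALSE))
  names(cols) <- names(out[[1]])
  n_total <- length(cols$t_onset)
  data.frame(
    subject_id = rep(profile$subject_id, n_total),
    t_onset = cols$t_onset, rr = cols$rr, lbnp = cols$lbnp,
    level_index = cols$level_index, phase = cols$phase,
    period_time = cols$period_time, sv_us = cols$sv_us,
    sv_pwa = cols$sv_pwa, map = cols$map,
    sex = rep(profile$sex, n_total),
    stringsAsFactors = FALSE
  )
}

#' Simulate a full synthetic cohort
#'
#' Draws subject profiles (including per-subject dropout levels) and
#' concatenates per-subject beat series. Fully reproducible from the
#' seed.
#'
#' @param n_subjects Number of subjects.
#' @param config A [protocol_config()].
#' @param traj A [trajectory_params()].
#' @param disc A [discrepancy_params()].
#' @param dropout_dist Stop-level distribution
#'   (see [default_dropout_dist()]).
#' @param rng_seed Integer seed.
#' @param exact_dropout Assign stop levels in deterministic proportions
#'   (see [sample_profiles()]).
#' @return A list with elements `beats` (data frame of all beats) and
#'   `profiles` (the `subject_profiles` data frame).
#' @export
simulate_cohort <- function(n_subjects,
                            config = protocol_config(),
                            traj = trajectory_params(),
                            disc = discrepancy_params(),
                            dropout_dist = default_dropout_dist(config),
                            rng_seed = 1L,
                            exact_dropout = FALSE) {
  if (n_subjects < 1) stop("n_subjects must be at least 1")
  if (length(dropout_dist) == 0) stop("dropout_dist must be non-empty")
  set.seed(rng_seed)
  profiles <- sample_profiles(n_subjects, config, dropout_dist,
                              exact_dropout = exact_dropout)
  beats <- do.call(rbind, lapply(seq_len(n_subjects), function(i) {
    simulate_subject(config, profiles[i, ], traj, disc)
  }))
  rownames(beats) <- NULL
  list(beats = beats, profiles = profiles)
}

#' Synthesize pressure and velocity waveforms for one beat
#'
#' Builds a 1-beat arterial pressure trace whose time-weighted mean is
#' the beat's MAP (a raised-cosine pulse around the mean) and an aortic
#' velocity trace (half-sine systolic ejection, zero in diastole) whose
#' velocity-time integral times the given LVOT area reproduces the
#' beat's ultrasound stroke volume.
#'
#' @param beat One-row beat record (needs `rr`, `map`, `sv_us`).
#' @param sampling_rate Samples per second (>= 100).
#' @param lvot_area_cm2 LVOT area used to scale the velocity trace.
#' @param pulse_pressure Peak-to-trough pressure amplitude, mmHg.
#' @return A list with `time` (s), `pressure` (mmHg), `velocity` (m/s),
#'   `sampling_rate` and the `lvot_area_cm2` used.
#' @export
synthesize_beat_waveforms <- function(beat, sampling_rate = 1000,
                                      lvot_area_cm2 = 3.5,
                                      pulse_pressure = 40) {
  if (sampling_rate < 100) stop("sampling_rate must be at least 100 Hz")
  n <- floor(beat$rr * sampling_rate) + 1L
  if (n < 2) stop("beat shorter than two samples")
  t <- seq(0, by = 1 / sampling_rate, length.out = n)
  pressure <- beat$map - (pulse_pressure / 2) * cos(2 * pi * t / beat$rr)
  t_eject <- min(0.3, 0.4 * beat$rr)
  vti_cm <- beat$sv_us / lvot_area_cm2
  peak_ms <- (vti_cm / 100) * pi / (2 * t_eject)
  velocity <- ifelse(t < t_eject, peak_ms * sin(pi * t / t_eject), 0)
  list(time = t, pressure = pressure, velocity = velocity,
       sampling_rate = sampling_rate, lvot_area_cm2 = lvot_area_cm2)
}
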
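#' Time-weighted mean of a pressure trace
#'
#' Mean arterial pressure over a beat window: the trapezoidal integral
#' of the pressure trace divided by the window duration.
#'
#' @param pressure Numeric pressure trace, mmHg.
#' @param sampling_rate Samples per second.
#' @param window Optional `c(start, end)` in seconds from the start of
#'   the trace; default is the whole trace.
#' @return Time-weighted mean pressure, mmHg.
#' @export
time_weighted_map <- function(pressure, sampling_rate, window = NULL) {
  x <- window_samples(pressure, sampling_rate, window)
  if (length(x) < 2) stop("window must contain at least two samples")
  trapz_integral(x, 1 / sampling_rate) / ((length(x) - 1) / sampling_rate)
}

#' Velocity-time integral of a Doppler velocity trace
#'
#' Trapezoidal integral of the non-negative part of the velocity trace
#' (m/s) over the beat window, returned in cm. An all-negative trace
#' yields 0 with a warning.
#'
#' @inheritParams time_weighted_map
#' @param velocity Numeric velocity trace, m/s.
#' @return Velocity-time integral, cm.
#' @export
velocity_time_integral <- function(velocity, sampling_rate, window = NULL) {
  x <- window_samples(velocity, sampling_rate, window)
  if (length(x) < 2) stop("window must contain at least two samples")
  if (all(x < 0)) {
    warning("velocity trace entirely negative; returning 0")
    return(0)
  }
  100 * trapz_integral(pmax(x, 0), 1 / sampling_rate)
}

trapz_integral <- function(x, dt) {
  n <- length(x)
  dt * (sum(x) - (x[1] + x[n]) / 2)
}

window_samples <- function(x, sampling_rate, window) {
  if (is.null(window)) return(x)
  if (length(window) != 2 || window[2] <= window[1]) {
    stop("window must be c(start, end) with end > start")
  }
  i0 <- max(1L, floor(window[1] * sampling_rate) + 1L)
  i1 <- min(length(x), floor(window[2] * sampling_rate) + 1L)
  if (i1 <= i0) stop("window is empty")
  x[i0:i1]
}

#' Trimmed mean with a ceiling trim count
#'
#' Removes `ceiling(trim_fraction * n)` values from each tail before
#' averaging, so a 5% trim is active even in a 30-s bin of 25-50 beats.
#' Falls back to the plain mean if trimming would empty the vector.
#'
#' @param values Non-empty numeric vector.
#' @param trim_fraction Fraction trimmed from each tail (in \[0, 0.5)).
#' @return The trimmed mean.
#' @examples
#' trimmed_mean(1:20) # removes 1 and 20 -> 10.5
#' @export
trimmed_mean <- function(values, trim_fraction = 0.05) {
  if (length(values) == 0) stop("values must be non-empty")
  if (trim_fraction < 0 || trim_fraction >= 0.5) {
    stop("trim_fraction must be in [0, 0.5)")
  }
  n <- length(values)
  k <- ceiling(trim_fraction * n)
  if (2 * k >= n) return(mean(values))
  s <- sort(values)
  mean(s[(k + 1):(n - k)])
}

#' Remove beats after each handgrip release
#'
#' Handgrip release triggers very rapid hemodynamic transients, so every
#' beat whose onset falls in `[release, release + window)` for any
#' release time is dropped.
#'
#' @param beats Beat data frame with `t_onset`.
#' @param release_times Numeric vector of release times (s), e.g. the
#'   `ihg_release_times` attribute of [build_schedule()].
#' @param exclusion_window Window length in seconds (default 30).
#' @return The beats outside all release windows.
#' @export
exclude_post_ihg <- function(beats, release_times, exclusion_window = 30) {
  if (nrow(beats) == 0 || length(release_times) == 0) return(beats)
  drop <- rep(FALSE, nrow(beats))
  for (r in release_times) {
    drop <- drop | (beats$t_onset >= r & beats$t_onset < r + exclusion_window)
  }
  beats[!drop, , drop = FALSE]
}

#' Drop LBNP levels a subject did not complete
#'
#' Only completed LBNP levels enter the statistical analyses; beats at
#' pressures above each subject's decompensation level are removed.
#'
#' @param beats Beat data frame with `subject_id` and `lbnp`.
#' @param profiles Subject profiles with `decompensation_level`.
#' @return The filtered beats.
#' @export
drop_incomplete_levels <- function(beats, profiles) {
  if (nrow(beats) == 0) return(beats)
  idx <- match(beats$subject_id, profiles$subject_id)
  if (anyNA(idx)) {
    stop("unknown subject id: ",
         paste(unique(beats$subject_id[is.na(idx)]), collapse = ", "))
  }
  beats[beats$lbnp <= profiles$decompensation_level[idx], , drop = FALSE]
}

#' Aggregate beats into 30-second records
#'
#' Bins are aligned to period starts (so the ordinal bin index within
#' each 2-minute period is well defined), and within each bin the
#' stroke volumes, MAP and instantaneous heart rate (60/RR) are averaged
#' with a two-tailed trimmed mean. Bins with fewer than `min_beats`
#' beats are dropped. Derived variables (cardiac output, systemic
#' vascular resistance, difference and mean of methods) are filled from
#' the bin means.
#'
#' @param beats Beat data frame (after exclusions).
#' @param bin_width Bin width in seconds (default 30).
#' @param trim_fraction Trim fraction for the bin means.
#' @param min_beats Minimum beats per bin; sparser bins are dropped.
#' @return A data frame of 30-s records with columns `subject_id`,
#'   `sex`, `lbnp`, `level_index`, `phase`, `bin_start`, `n_beats_used`,
#'   `sv_us`, `sv_pwa`, `hr`, `map`, `co_us`, `svr_us`, `diff`, `mean`
#'   and `period_time_bin`.
#' @export
bin_30s <- function(beats, bin_width = 30, trim_fraction = 0.05,
                    min_beats = 5L) {
  cols <- c("subject_id", "t_onset", "rr", "lbnp", "level_index", "phase",
            "period_time", "sv_us", "sv_pwa", "map", "sex")
  missing_cols <- setdiff(cols, names(beats))
  if (length(missing_cols) > 0) {
    stop("beats data is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (nrow(beats) == 0) return(empty_bins())

  period_start <- beats$t_onset - beats$period_time
  bin_idx <- floor(beats$period_time / bin_width)
  key <- paste(beats$subject_id, sprintf("%012.3f", period_start),
               bin_idx, sep = "|")
  groups <- split(seq_len(nrow(beats)), key)
  groups <- groups[lengths(groups) >= min_beats]
  if (length(groups) == 0) return(empty_bins())

  firsts <- vapply(groups, `[`, integer(1), 1L)
  tm <- function(x) vapply(groups, function(ii)
    trimmed_mean(x[ii], trim_fraction), numeric(1))
  bins <- data.frame(
    subject_id = beats$subject_id[firsts],
    sex = beats$sex[firsts],
    lbnp = beats$lbnp[firsts],
    level_index = beats$level_index[firsts],
    phase = beats$phase[firsts],
    bin_start = period_start[firsts] + bin_idx[firsts] * bin_width,
    n_beats_used = lengths(groups),
    sv_us = tm(beats$sv_us),
    sv_pwa = tm(beats$sv_pwa),
    hr = tm(60 / beats$rr),
    map = tm(beats$map),
    period_time_bin = bin_idx[firsts],
    stringsAsFactors = FALSE
  )
  bins <- bins[order(bins$subject_id, bins$bin_start), , drop = FALSE]
  rownames(bins) <- NULL
  bins$co_us <- cardiac_output(bins$sv_us, bins$hr)
  bins$svr_us <- svr(bins$map, bins$co_us)
  bins$diff <- bins$sv_pwa - bins$sv_us
  bins$mean <- (bins$sv_pwa + bins$sv_us) / 2
  bins
}

empty_bins <- function() {
  data.frame(
    subject_id = character(0), sex = character(0), lbnp = numeric(0),
    level_index = integer(0), phase = character(0), bin_start = numeric(0),
    n_beats_used = integer(0), sv_us = numeric(0), sv_pwa = numeric(0),
    hr = numeric(0), map = numeric(0), period_time_bin = numeric(0),
    co_us = numeric(0), svr_us = numeric(0), diff = numeric(0),
    mean = numeric(0), stringsAsFactors = FALSE
  )
}

#' Run the full beat-to-bin preprocessing chain
#'
#' Applies, in order: removal of incomplete LBNP levels, removal of the
#' post-handgrip-release window, and trimmed 30-s binning. The chain is
#' idempotent at the beat level: re-running the exclusions on already
#' filtered beats changes nothing.
#'
#' @param beats Beat data frame.
#' @param profiles Subject profiles.
#' @param config A [protocol_config()] used to reconstruct each
#'   subject's schedule (for handgrip release times).
#' @param exclusion_window Seconds dropped after handgrip release.
#' @param trim_fraction Trim fraction for bin means.
#' @param min_beats Minimum beats per bin.
#' @return The bin data frame of [bin_30s()].
#' @export
preprocess_beats <- function(beats, profiles, config = protocol_config(),
                             exclusion_window = 30, trim_fraction = 0.05,
                             min_beats = 5L) {
  beats <- drop_incomplete_levels(beats, profiles)
  by_subject <- split(seq_len(nrow(beats)), beats$subject_id)
  keep <- rep(TRUE, nrow(beats))
  for (i in seq_len(nrow(profiles))) {
    ii <- by_subject[[profiles$subject_id[i]]]
    if (is.null(ii)) next
    sched <- build_schedule(config, profiles[i, ])
    for (r in attr(sched, "ihg_release_times")) {
      t <- beats$t_onset[ii]
      keep[ii[t >= r & t < r + exclusion_window]] <- FALSE
    }
  }
  beats <- beats[keep, , drop = FALSE]
  bin_30s(beats, trim_fraction = trim_fraction, min_beats = min_beats)
}
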
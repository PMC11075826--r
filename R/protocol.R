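#' Block-randomize the handgrip/rest starting order
#'
#' Subjects are assigned to start the first LBNP level with isometric
#' handgrip or with rest using permuted-block randomization: block sizes
#' are drawn from `block_sizes`, and within each block exactly half the
#' subjects start with handgrip.
#'
#' @param n_subjects Number of subjects (>= 1).
#' @param block_sizes Allowed even block sizes.
#' @param rng_seed Optional integer seed; when `NULL` the current RNG
#'   state is used.
#' @return Logical vector of length `n_subjects`: `TRUE` = starts with
#'   handgrip. The drawn block sizes are attached as attribute
#'   `block_sizes`.
#' @export
randomize_ihg_order <- function(n_subjects, block_sizes = c(2, 4),
                                rng_seed = NULL) {
  if (n_subjects < 1) stop("n_subjects must be at least 1")
  if (any(block_sizes <= 0) || any(block_sizes %% 2 != 0)) {
    stop("block_sizes must be even positive integers")
  }
  if (!is.null(rng_seed)) set.seed(rng_seed)
  flags <- logical(0)
  sizes <- integer(0)
  while (length(flags) < n_subjects) {
    size <- block_sizes[sample.int(length(block_sizes), 1)]
    block <- sample(rep(c(TRUE, FALSE), each = size / 2))
    flags <- c(flags, block)
    sizes <- c(sizes, size)
  }
  structure(flags[seq_len(n_subjects)], block_sizes = sizes)
}

#' Generate subject profiles for a synthetic cohort
#'
#' Draws anthropometrics from the cohort distributions (age 24 +/- 3 y,
#' height 177 +/- 11 cm, weight 71 +/- 14 kg), simulates three maximal
#' voluntary contraction attempts per subject, assigns sex in a
#' repeating 9-female / 7-male per 16 pattern, block-randomizes the
#' handgrip starting order and draws each subject's highest completed
#' LBNP level from `dropout_dist`.
#'
#' @param n_subjects Number of subjects.
#' @param config A [protocol_config()].
#' @param dropout_dist Named probability vector over stop levels (names
#'   are chamber pressures in mmHg); must sum to 1 over levels >= 20.
#' @param exact_dropout Logical; when `TRUE` stop levels are assigned
#'   deterministically in proportions as close to `dropout_dist` as
#'   possible (used for calibration and noise-free checks) instead of
#'   being drawn at random.
#' @return A data frame of class `subject_profiles` with one row per
#'   subject.
#' @export
sample_profiles <- function(n_subjects,
                            config = protocol_config(),
                            dropout_dist = default_dropout_dist(config),
                            exact_dropout = FALSE) {
  if (n_subjects < 1) stop("n_subjects must be at least 1")
  if (length(dropout_dist) == 0) stop("dropout_dist must be non-empty")
  stop_levels <- as.numeric(names(dropout_dist))
  if (any(is.na(stop_levels)) || !all(stop_levels %in% config$lbnp_levels)) {
    stop("dropout_dist names must be protocol LBNP levels")
  }
  if (abs(sum(dropout_dist) - 1) > 1e-8) stop("dropout_dist must sum to 1")

  sex_pattern <- rep(c("female", "male"), c(9, 7))
  sex <- rep(sex_pattern, length.out = n_subjects)
  age <- round(stats::rnorm(n_subjects, 24, 3))
  height <- stats::rnorm(n_subjects, 177, 11)
  weight <- stats::rnorm(n_subjects, 71, 14)
  mvc_attempts <- matrix(stats::rnorm(3 * n_subjects, 300, 30), ncol = 3)
  mvc <- rowMeans(mvc_attempts)
  ihg_first <- as.logical(randomize_ihg_order(n_subjects,
                                              config$block_sizes))
  if (exact_dropout) {
    counts <- floor(dropout_dist * n_subjects)
    rem <- n_subjects - sum(counts)
    if (rem > 0) {
      extra <- order(dropout_dist * n_subjects - counts, decreasing = TRUE)
      counts[extra[seq_len(rem)]] <- counts[extra[seq_len(rem)]] + 1
    }
    decomp <- rep(stop_levels, counts)[seq_len(n_subjects)]
  } else {
    decomp <- stop_levels[sample.int(length(stop_levels), n_subjects,
                                     replace = TRUE, prob = dropout_dist)]
  }
  structure(data.frame(
    subject_id = sprintf("S%03d", seq_len(n_subjects)),
    sex = sex, age = age, height = height, weight = weight,
    mvc = mvc,
    target_force = vapply(seq_len(n_subjects), function(i)
      target_force(mvc_attempts[i, ], config$mvc_fraction), numeric(1)),
    ihg_first = ihg_first,
    decompensation_level = decomp,
    stringsAsFactors = FALSE
  ), class = c("subject_profiles", "data.frame"))
}

#' Build a subject's protocol schedule
#'
#' One 6-minute block per completed LBNP level, each split into a
#' stabilization period followed by two periods alternating handgrip and
#' rest. The phase that opens the post-stabilization pair alternates
#' across successive levels, starting according to the subject's
#' randomized `ihg_first` flag, so with `ihg_first = TRUE` level 0 runs
#' stabilization/IHG/rest and level 1 runs stabilization/rest/IHG.
#'
#' @param config A [protocol_config()].
#' @param profile A one-row subject profile (needs `ihg_first` and
#'   `decompensation_level`).
#' @return A data frame of periods (columns `lbnp`, `level_index`,
#'   `period_index`, `phase`, `start`, `end`) with the handgrip release
#'   times in attribute `ihg_release_times`.
#' @export
build_schedule <- function(config, profile) {
  if (!profile$decompensation_level %in% config$lbnp_levels) {
    stop("decompensation_level must be one of the protocol LBNP levels")
  }
  levels_done <- config$lbnp_levels[
    config$lbnp_levels <= profile$decompensation_level]
  pd <- config$period_duration
  rows <- lapply(seq_along(levels_done) - 1L, function(l) {
    start_ihg <- xor(isTRUE(profile$ihg_first), l %% 2 == 1)
    phases <- c("stabilization",
                if (start_ihg) c("ihg", "rest") else c("rest", "ihg"))
    data.frame(
      lbnp = levels_done[l + 1L], level_index = l,
      period_index = 0:2, phase = phases,
      start = l * config$level_duration + 0:2 * pd,
      end = l * config$level_duration + 1:3 * pd,
      stringsAsFactors = FALSE
    )
  })
  sched <- do.call(rbind, rows)
  attr(sched, "ihg_release_times") <- sched$end[sched$phase == "ihg"]
  sched
}
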
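cfg <- protocol_config()

test_that("trimmed mean follows the ceiling-per-tail rule", {
  expect_equal(trimmed_mean(1:20), 10.5)           # drops 1 and 20
  expect_equal(trimmed_mean(rep(7, 13), 0.2), 7)
  expect_equal(trimmed_mean(c(1:10, 1000)), mean(2:10))
  expect_equal(trimmed_mean(c(5, 2), 0.4), mean(c(5, 2)))  # fallback
  set.seed(4)
  for (n in c(7, 25, 40)) {
    x <- rnorm(n, 50, 20)
    expect_equal(trimmed_mean(x), oracle_trimmed_mean(x))
  }
  expect_error(trimmed_mean(numeric(0)), "non-empty")
  expect_error(trimmed_mean(1:5, 0.5), "trim_fraction")
})

test_that("post-handgrip exclusion uses half-open 30-s windows", {
  beats <- data.frame(t_onset = c(239.5, 240, 269.9, 270, 300))
  out <- exclude_post_ihg(beats, release_times = 240)
  expect_equal(out$t_onset, c(239.5, 270, 300))

  set.seed(9)
  t_onset <- sort(runif(500, 0, 1800))
  rel <- c(240, 600, 960)
  kept <- exclude_post_ihg(data.frame(t_onset = t_onset), rel)
  removed <- setdiff(seq_along(t_onset),
                     match(kept$t_onset, t_onset))
  expect_equal(sort(removed), oracle_excluded_idx(t_onset, rel))
  # touching windows do not double count
  kept2 <- exclude_post_ihg(data.frame(t_onset = t_onset), c(240, 270))
  expect_equal(nrow(kept2),
               500 - length(oracle_excluded_idx(t_onset, c(240, 270), 30)))
})

test_that("incomplete LBNP levels are dropped per subject", {
  profiles <- data.frame(subject_id = c("A", "B"),
                         decompensation_level = c(40, 80))
  beats <- data.frame(subject_id = rep(c("A", "B"), each = 5),
                      lbnp = rep(c(0, 20, 40, 60, 80), 2))
  out <- drop_incomplete_levels(beats, profiles)
  expect_equal(out$lbnp[out$subject_id == "A"], c(0, 20, 40))
  expect_equal(out$lbnp[out$subject_id == "B"], c(0, 20, 40, 60, 80))
  expect_error(
    drop_incomplete_levels(data.frame(subject_id = "C", lbnp = 0), profiles),
    "unknown subject")
})

test_that("binning yields four 30-s records per period with correct means", {
  prof <- data.frame(subject_id = "S1", sex = "female", ihg_first = TRUE,
                     decompensation_level = 20)
  beats <- simulate_subject(cfg, prof, zero_noise_traj(),
                            zero_noise_disc(beta_svr = 0, delta0 = 10),
                            rng_seed = 1, subject_offset = 0)
  bins <- bin_30s(beats)
  # 2 levels x 3 periods x 4 bins
  expect_equal(nrow(bins), 24)
  expect_true(all(bins$period_time_bin %in% 0:3))
  expect_equal(as.vector(table(bins$period_time_bin)), rep(6L, 4))
  # constant latent signals -> bin means equal the constants
  l0 <- bins[bins$level_index == 0 & bins$phase != "ihg", ]
  expect_equal(l0$sv_us, rep(81, nrow(l0)), tolerance = 1e-9)
  expect_equal(l0$map, rep(85, nrow(l0)), tolerance = 1e-9)
  expect_equal(l0$hr, rep(60, nrow(l0)), tolerance = 1e-9)
  # derived columns satisfy the record invariants
  expect_equal(bins$diff, bins$sv_pwa - bins$sv_us)
  expect_equal(bins$mean, (bins$sv_pwa + bins$sv_us) / 2)
  expect_equal(bins$co_us, bins$sv_us * bins$hr / 1000)
  expect_equal(bins$svr_us, bins$map / bins$co_us)
})

test_that("noisy bin means equal an independently coded trim-then-average", {
  coh <- simulate_cohort(2, cfg, rng_seed = 17)
  bins <- bin_30s(coh$beats)
  beats <- coh$beats
  set.seed(5)
  for (i in sample(nrow(bins), 25)) {
    sel <- beats$subject_id == bins$subject_id[i] &
      beats$t_onset >= bins$bin_start[i] &
      beats$t_onset < bins$bin_start[i] + 30
    expect_equal(bins$sv_us[i], oracle_trimmed_mean(beats$sv_us[sel]))
    expect_equal(bins$sv_pwa[i], oracle_trimmed_mean(beats$sv_pwa[sel]))
    expect_equal(bins$hr[i], oracle_trimmed_mean(60 / beats$rr[sel]))
    expect_equal(bins$n_beats_used[i], sum(sel))
  }
})

test_that("the preprocessing chain orders exclusion before binning and is idempotent", {
  coh <- simulate_cohort(3, cfg, rng_seed = 23)
  bins1 <- preprocess_beats(coh$beats, coh$profiles, cfg)
  # the bin right after each handgrip release is absent
  rel_bins <- lapply(seq_len(nrow(coh$profiles)), function(i) {
    sched <- build_schedule(cfg, coh$profiles[i, ])
    data.frame(subject_id = coh$profiles$subject_id[i],
               bin_start = attr(sched, "ihg_release_times"))
  })
  rel_bins <- do.call(rbind, rel_bins)
  rel_bins <- rel_bins[rel_bins$bin_start < max(coh$beats$t_onset), ]
  hit <- mapply(function(s, b0)
    any(bins1$subject_id == s & abs(bins1$bin_start - b0) < 1e-9),
    rel_bins$subject_id, rel_bins$bin_start)
  expect_false(any(hit))
  # re-running the same exclusions on already filtered beats changes nothing
  filtered <- drop_incomplete_levels(coh$beats, coh$profiles)
  for (i in seq_len(nrow(coh$profiles))) {
    sched <- build_schedule(cfg, coh$profiles[i, ])
    sel <- filtered$subject_id == coh$profiles$subject_id[i]
    sub <- exclude_post_ihg(filtered[sel, ], attr(sched, "ihg_release_times"))
    again <- exclude_post_ihg(sub, attr(sched, "ihg_release_times"))
    expect_identical(sub, again)
  }
  expect_identical(bins1, preprocess_beats(coh$beats, coh$profiles, cfg))
})

test_that("zero-noise pipeline SVR matches the latent trajectory closely", {
  prof <- data.frame(subject_id = "S1", sex = "male", ihg_first = FALSE,
                     decompensation_level = 60)
  traj <- zero_noise_traj()
  beats <- simulate_subject(cfg, prof, traj, zero_noise_disc(),
                            rng_seed = 1, subject_offset = 0)
  bins <- bin_30s(beats)
  sv_lat <- traj$sv_baseline - traj$sv_drop_per_level * bins$level_index
  hr_lat <- traj$hr_baseline + traj$hr_rise_per_level * bins$level_index
  map_lat <- traj$map_baseline + (bins$phase == "ihg") *
    traj$map_ihg_boost * (30 * bins$period_time_bin + 15) / 120
  svr_lat <- 1000 * map_lat / (sv_lat * hr_lat)
  expect_true(all(abs(bins$svr_us - svr_lat) / svr_lat < 0.001))
})

test_that("degenerate inputs are handled", {
  expect_equal(nrow(bin_30s(simulate_cohort(1, cfg, rng_seed = 1,
    dropout_dist = c("20" = 1))$beats[0, ])), 0)
  expect_error(bin_30s(data.frame(x = 1)), "missing column")
})
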
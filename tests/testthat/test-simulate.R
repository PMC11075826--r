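cfg <- protocol_config()

test_that("with all noise off and no SVR effect the difference is constant", {
  prof <- data.frame(subject_id = "S1", sex = "female", ihg_first = TRUE,
                     decompensation_level = 40)
  beats <- simulate_subject(cfg, prof, zero_noise_traj(),
                            zero_noise_disc(beta_svr = 0, delta0 = 12),
                            rng_seed = 1, subject_offset = 3)
  expect_true(all(abs(beats$sv_pwa - beats$sv_us - 15) < 1e-10))
})

test_that("with noise off the difference tracks the latent SVR exactly", {
  prof <- data.frame(subject_id = "S1", sex = "male", ihg_first = FALSE,
                     decompensation_level = 80)
  traj <- zero_noise_traj()
  disc <- zero_noise_disc(delta0 = 0, beta_svr = 0.5, svr_ref = 0)
  beats <- simulate_subject(cfg, prof, traj, disc, rng_seed = 1,
                            subject_offset = 0)
  # recompute the latent SVR for each beat from the trajectory functions
  sv_lat <- traj$sv_baseline - traj$sv_drop_per_level * beats$level_index
  hr_lat <- traj$hr_baseline + traj$hr_rise_per_level * beats$level_index
  k <- floor(beats$period_time / 30)
  map_lat <- traj$map_baseline +
    (beats$phase == "ihg") * traj$map_ihg_boost * (30 * k + 15) / 120
  svr_lat <- 1000 * map_lat / (sv_lat * hr_lat)
  expect_equal(beats$sv_pwa - beats$sv_us, 0.5 * svr_lat, tolerance = 1e-10)
})

test_that("zero-noise SVR rises with LBNP level and within handgrip", {
  prof <- data.frame(subject_id = "S1", sex = "female", ihg_first = TRUE,
                     decompensation_level = 80)
  beats <- simulate_subject(cfg, prof, zero_noise_traj(), zero_noise_disc(),
                            rng_seed = 1, subject_offset = 0)
  bins <- bin_30s(beats)
  lev_svr <- tapply(bins$svr_us[bins$phase == "rest"],
                    bins$level_index[bins$phase == "rest"], mean)
  expect_true(all(diff(lev_svr) > 0))
  ihg <- bins[bins$phase == "ihg", ]
  for (key in unique(paste(ihg$level_index, ihg$bin_start %/% 360))) {
    grp <- ihg[paste(ihg$level_index, ihg$bin_start %/% 360) == key, ]
    expect_true(all(diff(grp$svr_us[order(grp$period_time_bin)]) > 0))
  }
})

test_that("empirical resting heart rate matches the trajectory baseline", {
  prof <- data.frame(subject_id = "S1", sex = "female", ihg_first = TRUE,
                     decompensation_level = 20)
  traj <- trajectory_params()
  beats <- simulate_subject(cfg, prof, traj, discrepancy_params(),
                            rng_seed = 5)
  l0 <- beats[beats$level_index == 0, ]
  hr_obs <- 60 / l0$rr
  se <- sd(hr_obs) / sqrt(nrow(l0))
  expect_lt(abs(mean(hr_obs) - traj$hr_baseline), 3 * se + 0.05)
})

test_that("cohorts are bit-reproducible from the seed", {
  a <- simulate_cohort(6, cfg, rng_seed = 99)
  b <- simulate_cohort(6, cfg, rng_seed = 99)
  expect_identical(a, b)
  c2 <- simulate_cohort(6, cfg, rng_seed = 100)
  expect_false(identical(a$beats, c2$beats))
})

test_that("a point-mass dropout keeps every level and bad parameters error", {
  coh <- simulate_cohort(3, cfg, rng_seed = 2,
                         dropout_dist = c("80" = 1))
  expect_equal(max(coh$beats$lbnp), 80)
  expect_error(
    simulate_subject(cfg,
                     data.frame(subject_id = "S1", sex = "female",
                                ihg_first = TRUE, decompensation_level = 80),
                     trajectory_params(sv_drop_per_level = 25),
                     discrepancy_params(), rng_seed = 1),
    "stroke volume")
  expect_error(simulate_cohort(0, cfg), "at least 1")
  expect_error(simulate_cohort(4, cfg, dropout_dist = numeric(0)),
               "non-empty")
})

test_that("simulated stroke volumes and pressures stay positive", {
  coh <- simulate_cohort(12, cfg, rng_seed = 31)
  expect_true(all(coh$beats$sv_us > 0))
  expect_true(all(coh$beats$sv_pwa > 0))
  expect_true(all(coh$beats$map > 0))
  expect_true(all(coh$beats$rr > 0))
})
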
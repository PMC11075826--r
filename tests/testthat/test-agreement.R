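test_that("REML variance components equal closed-form ANOVA on balanced data", {
  set.seed(11)
  for (rep in 1:4) {
    a <- 8; m <- 6
    g <- rep(seq_len(a), each = m)
    y <- rep(rnorm(a, 0, 4), each = m) + rnorm(a * m, 0, 2)
    fit <- fit_random_intercept(y, NULL, g)
    oracle <- oracle_anova_components(y, g)
    expect_equal(fit$sigma_between, unname(oracle["sigma_b"]),
                 tolerance = 1e-6)
    expect_equal(fit$sigma_resid, unname(oracle["sigma_w"]),
                 tolerance = 1e-6)
    expect_equal(fit$fixed_effects$estimate[1], mean(y), tolerance = 1e-8)
  }
})

test_that("pure subject shifts give zero residual and the closed-form LOA", {
  y <- c(10, 10, 10, 20, 20, 20)
  g <- c(1, 1, 1, 2, 2, 2)
  fit <- fit_random_intercept(y, NULL, g)
  expect_equal(fit$fixed_effects$estimate[1], 15, tolerance = 1e-6)
  expect_lt(fit$sigma_resid, 1e-6)

  bins <- data.frame(subject_id = g, diff = y, mean = 80,
                     stringsAsFactors = FALSE)
  ba <- bland_altman(bins)
  expect_equal(ba$bias, 15, tolerance = 1e-6)
  expect_lt(ba$ws_loa_half_width, 1e-5)
  oracle <- oracle_anova_components(y, g)
  expect_equal(ba$loa_half_width, 1.96 * oracle[["sigma_b"]],
               tolerance = 1e-5)
})

test_that("simulation recovers a known residual SD", {
  set.seed(21)
  m <- 400
  g <- rep(1:10, each = m)
  y <- rep(rnorm(10, 50, 6), each = m) + rnorm(10 * m, 0, 2)
  fit <- fit_random_intercept(y, NULL, g)
  expect_lt(abs(fit$sigma_resid - 2), 3 * 2 / sqrt(2 * (10 * m - 10)))
})

test_that("bias is shift-equivariant and LOA widths are shift-invariant", {
  bins <- make_toy_bins()
  ba <- bland_altman(bins)
  shifted <- bins
  shifted$sv_pwa <- shifted$sv_pwa + 7
  shifted$diff <- shifted$sv_pwa - shifted$sv_us
  shifted$mean <- (shifted$sv_pwa + shifted$sv_us) / 2
  ba2 <- bland_altman(shifted)
  expect_equal(ba2$bias, ba$bias + 7, tolerance = 1e-6)
  expect_equal(ba2$loa_half_width, ba$loa_half_width, tolerance = 1e-6)
  expect_equal(ba2$ws_loa_half_width, ba$ws_loa_half_width,
               tolerance = 1e-6)
  # adding the same constant to both methods changes nothing but the mean
  both <- bins
  both$sv_us <- both$sv_us + 5; both$sv_pwa <- both$sv_pwa + 5
  both$diff <- both$sv_pwa - both$sv_us
  both$mean <- (both$sv_pwa + both$sv_us) / 2
  ba3 <- bland_altman(both)
  expect_equal(ba3$bias, ba$bias, tolerance = 1e-6)
  expect_equal(ba3$loa_half_width, ba$loa_half_width, tolerance = 1e-6)
})

test_that("within-subject LOA never exceeds total LOA", {
  for (seed in 1:6) {
    bins <- make_toy_bins(seed = seed, sigma_b = runif(1, 0, 8),
                          sigma_e = runif(1, 0.5, 6))
    ba <- bland_altman(bins)
    expect_lte(ba$ws_loa_half_width, ba$loa_half_width + 1e-10)
    expect_gt(ba$percentage_error, 0)
  }
})

test_that("a constructed linear bias line is recovered exactly", {
  bins <- make_toy_bins(diff_fun = function(m, s, b) -0.2 * m + 30)
  sb <- sloped_bias(bins)
  expect_equal(sb$slope, -0.2, tolerance = 1e-6)
  expect_lt(sb$fit$sigma_resid, 1e-5)
  # swapping the methods flips the slope sign
  sw <- bins
  sw$sv_us <- bins$sv_pwa; sw$sv_pwa <- bins$sv_us
  sw$diff <- sw$sv_pwa - sw$sv_us
  sw$mean <- (sw$sv_pwa + sw$sv_us) / 2
  expect_equal(sloped_bias(sw)$slope, 0.2, tolerance = 1e-6)
  expect_error(sloped_bias(transform(bins, mean = 75)), "constant")
})

test_that("a constructed SVR effect is recovered exactly, by sex if present", {
  bins <- make_toy_bins(diff_fun = function(m, s, b) 0.5 * s + b + 4)
  sv <- svr_effect(bins)
  expect_equal(sv$slope, 0.5, tolerance = 1e-6)
  bins2 <- make_toy_bins(diff_fun = function(m, s, b) b)
  bins2$diff <- bins2$diff +
    ifelse(bins2$sex == "male", 0.9, 0.3) * bins2$svr_us
  bins2$sv_pwa <- bins2$sv_us + bins2$diff
  bins2$mean <- (bins2$sv_pwa + bins2$sv_us) / 2
  sv2 <- svr_effect(bins2, with_sex_interaction = TRUE)
  expect_equal(sv2$slope_male, 0.9, tolerance = 1e-6)
  expect_equal(sv2$slope_female, 0.3, tolerance = 1e-6)
  expect_true(all(c("svr_us_female", "svr_us_male") %in% sv2$slopes$term))
  one_sex <- bins[bins$sex == "female", ]
  expect_error(svr_effect(one_sex, with_sex_interaction = TRUE),
               "both sexes")
})

test_that("the time-proxy model recovers a per-bin trend and dies without IHG bins", {
  bins <- make_toy_bins(n_subj = 8)
  bins$diff <- 10 + 1.0 * bins$period_time_bin +
    rep(rnorm(8, 0, 3), each = 8)[seq_len(nrow(bins))]
  te <- time_effect(bins)
  expect_equal(te$slope, 1.0, tolerance = 1e-6)
  rest_only <- bins[bins$phase == "rest", ]
  rest_only$phase <- "rest"
  expect_error(time_effect(transform(bins, phase = "rest")), "handgrip")
})

test_that("shuffling bin order within handgrip periods removes the time effect", {
  rc <- run_config(seed = 77, n_subjects = 80)
  coh <- simulate_study(rc, write = FALSE)
  bins <- analysis_bins(preprocess_study(rc, coh, write = FALSE))
  te <- time_effect(bins)
  expect_gt(te$slopes$ci_lower, 0)   # real upward trend
  set.seed(1)
  shuffled <- bins
  ihg_idx <- which(shuffled$phase == "ihg")
  per <- paste(shuffled$subject_id[ihg_idx],
               shuffled$bin_start[ihg_idx] - 30 *
                 shuffled$period_time_bin[ihg_idx])
  for (p in unique(per)) {
    ii <- ihg_idx[per == p]
    shuffled$diff[ii] <- shuffled$diff[sample(ii)]
  }
  te2 <- time_effect(shuffled)
  expect_lt(te2$slope, te$slope / 2)     # effect largely destroyed
  expect_lt(te2$slopes$ci_lower, 0.05)   # interval reaches down to zero
})

test_that("precision is zero for noise-free bins and refuses single subjects", {
  prof2 <- data.frame(subject_id = c("A", "B"), sex = "female",
                      ihg_first = TRUE, decompensation_level = 20)
  cfg <- protocol_config()
  beats <- rbind(
    simulate_subject(cfg, prof2[1, ], zero_noise_traj(), zero_noise_disc(),
                     rng_seed = 1, subject_offset = 0),
    simulate_subject(cfg, prof2[2, ], zero_noise_traj(), zero_noise_disc(),
                     rng_seed = 2, subject_offset = 0))
  bins <- bin_30s(beats)
  p <- precision(bins, "us")
  expect_lt(p$half_width, 1e-6)
  expect_error(precision(bins[bins$subject_id == "A", ], "us"),
               "two subjects")
})

test_that("residual diagnostics decompose the response exactly", {
  bins <- make_toy_bins()
  ba <- bland_altman(bins)
  d <- residual_diagnostics(ba$fit)
  expect_equal(d$fitted + d$residual, bins$diff, tolerance = 1e-8)
  expect_equal(nrow(d), nrow(bins))
  expect_true(all(is.finite(d$theoretical_quantile)))
  # standardized residuals use the residual SD
  expect_equal(d$std_residual, d$residual / ba$fit$sigma_resid,
               tolerance = 1e-10)
})

test_that("single-subject agreement analyses are refused", {
  bins <- make_toy_bins(n_subj = 1)
  expect_error(bland_altman(bins), "two subjects")
})

test_that("Wald intervals cover a generating slope at the nominal rate", {
  set.seed(99)
  n_reps <- 200
  cover <- 0
  for (r in seq_len(n_reps)) {
    n_subj <- 15; m <- 10
    g <- rep(seq_len(n_subj), each = m)
    x <- rnorm(n_subj * m, 20, 4)
    y <- 2 + 0.5 * x + rep(rnorm(n_subj, 0, 3), each = m) +
      rnorm(n_subj * m, 0, 2)
    fit <- fit_random_intercept(y, data.frame(x = x), g)
    ci <- fit$fixed_effects[fit$fixed_effects$term == "x", ]
    cover <- cover + (ci$ci_lower <= 0.5 && 0.5 <= ci$ci_upper)
  }
  phat <- cover / n_reps
  tol <- 3 * sqrt(0.95 * 0.05 / n_reps)
  expect_gt(phat, 0.95 - tol)
  expect_lte(phat, 1)
})
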
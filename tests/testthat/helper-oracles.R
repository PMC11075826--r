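# Independent brute-force oracles used against the package implementations.

# plain Riemann/trapezoid sum written independently of trapz_integral()
oracle_trapz <- function(x, dt) {
  s <- 0
  for (i in seq_len(length(x) - 1)) s <- s + (x[i] + x[i + 1]) / 2 * dt
  s
}

# explicit trim-then-average, ceiling rule
oracle_trimmed_mean <- function(x, trim = 0.05) {
  n <- length(x)
  k <- ceiling(trim * n)
  if (2 * k >= n) return(mean(x))
  s <- sort(x)
  mean(s[seq(k + 1, n - k)])
}

# interval-scan oracle for post-handgrip exclusion
oracle_excluded_idx <- function(t_onset, releases, window = 30) {
  hit <- rep(FALSE, length(t_onset))
  for (i in seq_along(t_onset)) {
    for (r in releases) {
      if (t_onset[i] >= r && t_onset[i] < r + window) hit[i] <- TRUE
    }
  }
  which(hit)
}

# closed-form one-way ANOVA variance components on a balanced design
oracle_anova_components <- function(y, g) {
  g <- factor(g)
  m <- length(y) / nlevels(g)
  means <- tapply(y, g, mean)
  mse <- sum((y - ave(y, g))^2) / (length(y) - nlevels(g))
  msb <- m * sum((means - mean(y))^2) / (nlevels(g) - 1)
  c(sigma_b = sqrt(max((msb - mse) / m, 0)), sigma_w = sqrt(mse))
}

# hand-built bin table for the agreement fits
make_toy_bins <- function(n_subj = 6, n_per = 8, seed = 42,
                          diff_fun = NULL, sigma_b = 5, sigma_e = 2) {
  set.seed(seed)
  subj <- rep(sprintf("S%02d", seq_len(n_subj)), each = n_per)
  b <- rep(rnorm(n_subj, 0, sigma_b), each = n_per)
  mean_v <- runif(n_subj * n_per, 50, 100)
  svr_v <- runif(n_subj * n_per, 15, 30)
  d <- if (is.null(diff_fun)) {
    20 + b + rnorm(n_subj * n_per, 0, sigma_e)
  } else {
    diff_fun(mean_v, svr_v, b)
  }
  data.frame(
    subject_id = subj,
    sex = rep(rep(c("female", "male"), length.out = n_subj), each = n_per),
    lbnp = rep(rep(c(0, 20), each = n_per / 2), n_subj),
    phase = rep(rep(c("ihg", "rest"), n_per / 2), n_subj),
    sv_us = mean_v - d / 2, sv_pwa = mean_v + d / 2,
    hr = 60, map = 85,
    svr_us = svr_v,
    period_time_bin = rep(c(0:3, 0:3), length.out = n_subj * n_per),
    diff = d, mean = mean_v,
    stringsAsFactors = FALSE
  )
}

zero_noise_traj <- function(...) {
  trajectory_params(beat_noise_sd = 0, bin_noise_sd_us = 0,
                    bin_noise_sd_pwa = 0, map_beat_noise_sd = 0,
                    rr_jitter_sd = 0, ...)
}

zero_noise_disc <- function(...) {
  discrepancy_params(sigma_between = 0, sigma_within = 0,
                     sigma_within_slope = 0, ...)
}
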
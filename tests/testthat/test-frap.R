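test_that("normalization anchors pre-bleach at 100 and the bleach frame at 0", {
  rec <- generate_frap_recording(
    frap_sim_params(k = 0.03, noise_sd = 15, photofade_rate = 0.002,
                    background_level = 50), seed = 3)
  nc <- normalize_frap(rec)
  expect_equal(nc$data$y[rec$bleach_index], 0)
  expect_equal(mean(nc$data$y[seq_len(rec$bleach_index - 1)]), 100)
  expect_equal(nc$data$t_post[rec$bleach_index], 0)
})

test_that("bleach-control division cancels photofading exactly (noiseless closed form)", {
  p <- frap_sim_params(k = 0.05, mobile_fraction = 1, photofade_rate = 0.01,
                       noise_sd = 0, background_level = 120)
  nc <- normalize_frap(generate_frap_recording(p, seed = 1))
  post <- nc$data[nc$data$t_post >= 0, ]
  expect_lt(max(abs(post$y - 100 * (1 - exp(-0.05 * post$t_post)))), 1e-9)
})

test_that("degenerate recordings are rejected", {
  flat <- frap_recording(0:19, rep(100, 20), rep(0, 20), rep(200, 20),
                         bleach_index = 3L)
  expect_error(normalize_frap(flat), "no bleach depth")
  neg <- frap_recording(0:19, rep(100, 20), rep(300, 20), rep(200, 20),
                        bleach_index = 3L)
  expect_error(normalize_frap(neg), "positive")
})

test_that("normalization is idempotent on an already-normalized curve", {
  rec <- generate_frap_recording(frap_sim_params(k = 0.04), seed = 2)
  nc <- normalize_frap(rec)
  renorm <- frap_recording(
    time_s = rec$data$time_s, roi = nc$data$y,
    background = rep(0, nrow(rec$data)), control = rep(1, nrow(rec$data)),
    bleach_index = rec$bleach_index)
  nc2 <- normalize_frap(renorm)
  expect_equal(nc2$data$y, nc$data$y, tolerance = 1e-12)
})

test_that("single-exponential fit recovers exact parameters on noiseless input", {
  nc <- normalize_frap(generate_frap_recording(
    frap_sim_params(k = 0.05, mobile_fraction = 1, noise_sd = 0), seed = 1))
  fit <- fit_single_exponential(nc)
  expect_true(fit$converged)
  expect_equal(fit$k, 0.05, tolerance = 1e-6)
  expect_equal(fit$t_half, log(2) / 0.05, tolerance = 1e-6)
  expect_equal(fit$plateau, 100, tolerance = 1e-4)
  expect_gt(fit$r_squared, 0.999999)
  # the identity t_half * k = ln(2) holds exactly for every fit
  expect_identical(fit$t_half * fit$k, log(2))
})

test_that("truth half-time equals ln(2)/k and k = ln(2) gives t_half = 1", {
  rec <- generate_frap_recording(frap_sim_params(k = 0.0231), seed = 1)
  expect_equal(rec$truth$t_half, log(2) / 0.0231)
  expect_equal(round(rec$truth$t_half, 1), 30.0)
  nc <- normalize_frap(generate_frap_recording(
    frap_sim_params(k = log(2), mobile_fraction = 1, noise_sd = 0,
                    frame_interval = 0.1), seed = 1))
  fit <- fit_single_exponential(nc)
  expect_equal(fit$k, log(2), tolerance = 1e-6)
  expect_equal(fit$t_half, 1.0, tolerance = 1e-6)
})

test_that("parameter recovery: median t_half within 10% at 2% noise, k within 10% per recording", {
  p <- frap_sim_params(k = 0.05, mobile_fraction = 0.8, noise_sd = 0.02 * 1000)
  fit7 <- fit_single_exponential(normalize_frap(generate_frap_recording(p, seed = 7)))
  expect_lt(abs(fit7$k - 0.05) / 0.05, 0.10)

  fits <- frap_fit_batch(lapply(1:60, function(s) generate_frap_recording(
    frap_sim_params(k = 0.04, mobile_fraction = 0.85, noise_sd = 0.02 * 1000),
    seed = s)), "WT")
  expect_equal(nrow(fits), 60)
  expect_lt(abs(median(fits$t_half) - log(2) / 0.04) / (log(2) / 0.04), 0.10)
})

test_that("recovery error shrinks as noise decreases", {
  rmse <- sapply(c(40, 10, 0), function(ns) {
    ks <- sapply(1:12, function(s) fit_single_exponential(normalize_frap(
      generate_frap_recording(frap_sim_params(k = 0.04, noise_sd = ns), seed = s)))$k)
    sqrt(mean((ks - 0.04)^2))
  })
  expect_true(all(diff(rmse) <= 1e-12))
})

test_that("group_frap_compare summarizes half-times and flags slowed variants", {
  recs <- c(
    lapply(1:12, function(s) generate_frap_recording(
      frap_sim_params(k = 0.05, noise_sd = 20), seed = s)),
    lapply(13:24, function(s) generate_frap_recording(
      frap_sim_params(k = 0.025, noise_sd = 20), seed = s))
  )
  fits <- frap_fit_batch(recs, rep(c("WT", "slow"), each = 12))
  cmp <- group_frap_compare(fits, reference = "WT", seed = 5)
  expect_setequal(cmp$summary$group, c("WT", "slow"))
  slow <- tidy(cmp$dunnett)
  expect_gt(slow$estimate[slow$group == "slow"], 0)
  expect_lt(slow$p_adjusted[slow$group == "slow"], 0.05)

  expect_error(group_frap_compare(fits, reference = "absent"), "not present")
  small <- dplyr::bind_rows(fits, tibble::tibble(
    group = "tiny", recording = 99L, plateau = 80, k = 0.04,
    t_half = log(2) / 0.04, r_squared = 0.9, converged = TRUE))
  expect_warning(group_frap_compare(small, reference = "WT", seed = 5), "excluding")
})
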
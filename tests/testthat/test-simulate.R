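test_that("fixed seed reproduces the series bit for bit", {
  p <- quick_protocol(n_trials = 2, poststim_s = 0.5)
  s <- ins_scene(p)
  a <- simulate_bm_series(p, s, exposure = 1, seed = 42)
  b <- simulate_bm_series(p, s, exposure = 1, seed = 42)
  expect_identical(a$data, b$data)
  expect_identical(a$ground_truth$amp_jitter, b$ground_truth$amp_jitter)
  c <- simulate_bm_series(p, s, exposure = 1, seed = 43)
  expect_false(identical(a$data[[1]], c$data[[1]]))
})

test_that("a static noise-free scene produces identical frames", {
  p <- quick_protocol(n_trials = 1, poststim_s = 0.5)
  s <- quiet_scene(p)
  bm <- simulate_bm_series(p, s, exposure = 0, seed = 1)
  a <- bm$data[[1]]
  for (k in 2:dim(a)[3]) expect_identical(a[, , k], a[, , 1])
})

test_that("activation pixels carry the programmed fractional elevation", {
  # Monte-Carlo mean over >= 1e4 activation-pixel samples at the peak
  p <- ins_protocol(poststim_s = 0.5, n_trials = 8, n_z = 64, n_x = 64)
  s <- ins_scene(p, trial_cv = 0)
  bm <- simulate_bm_series(p, s, exposure = 1, seed = 7)
  tt <- frame_times(p, "oct")
  kpk <- which.min(abs(tt - s$template$peak_delay_s))
  mov <- insfoct:::scene_moving_pixels(s)
  act <- which(s$activation & !(mov$vessel_mask | mov$tail_mask))
  expect_gt(length(act) * p$n_trials, 1e4)
  rel <- sapply(seq_len(p$n_trials), function(i) {
    a <- bm$data[[i]]
    base <- apply(a[, , tt < 0], c(1, 2), mean)
    mean(a[, , kpk][act]) / mean(base[act])
  })
  tplpk <- template_eval(s$template, tt[kpk])
  # speckle-averaged ratio of means; MC error ~ 1/sqrt(n_px * n_trials)
  expect_equal(mean(rel), 1 + tplpk, tolerance = 0.01)
})

test_that("OISI series darkens by the programmed fraction at its peak", {
  p <- ins_protocol(poststim_s = 0.5, n_trials = 6, oisi_fps = 60)
  s <- ins_scene(p, trial_cv = 0)
  os <- simulate_oisi_series(p, s, exposure = 1, seed = 8)
  tt <- frame_times(p, "oisi")
  kpk <- which.min(abs(tt - s$oisi_template$peak_delay_s))
  act <- which(s$oisi_activation)
  rel <- sapply(seq_len(p$n_trials), function(i) {
    a <- os$data[[i]]
    base <- apply(a[, , tt < 0], c(1, 2), mean)
    mean(a[, , kpk][act]) / mean(base[act])
  })
  expect_equal(mean(rel), 1 + template_eval(s$oisi_template, tt[kpk]),
               tolerance = 5e-4)
  # zero-amplitude template: frames statistically identical
  s0 <- ins_scene(p, oisi_tpl = oisi_template(peak_amplitude = 0))
  o0 <- simulate_oisi_series(p, s0, exposure = 1, seed = 9)
  m <- apply(o0$data[[1]], 3, mean)
  expect_lt(diff(range(m)), 6 * sd(m))
})

test_that("frame counts follow the protocol frame rates", {
  p <- ins_protocol(n_trials = 1, n_z = 8, n_x = 8)
  s <- ins_scene(p, vessels = list())
  expect_identical(dim(simulate_bm_series(p, s, 1, seed = 1)$data[[1]])[3],
                   2000L)
  expect_identical(dim(simulate_oisi_series(p, s, 1, seed = 1)$data[[1]])[3],
                   400L)
})

test_that("phantom decorrelation increases with velocity and saturates", {
  p <- ins_protocol(poststim_s = 1, n_trials = 1, n_z = 40, n_x = 40)
  ph <- simulate_flow_phantom(c(0, 0.3, 0.6, 0.9, 1.2), p, seed = 11)
  curve <- decorrelation_velocity_curve(ph)
  expect_true(all(diff(curve$mean_D) > 0))     # strictly increasing
  expect_lt(curve$mean_D[1], 0.02)             # v = 0: noise floor only
  # fully refreshing scatterers: decorrelation near the independent-
  # speckle plateau, approached from below
  ph2 <- simulate_flow_phantom(c(1.0, 2.0, 4.0), p, seed = 12)
  c2 <- decorrelation_velocity_curve(ph2)
  expect_equal(c2$mean_D[2], c2$mean_D[3], tolerance = 0.02)
  expect_error(simulate_flow_phantom(c(-0.1, 1), p, seed = 1), "velocities")
})

test_that("spike trains follow the programmed Poisson rates", {
  p <- ins_protocol(poststim_s = 1, n_z = 4, n_x = 4)
  sp <- simulate_spike_trains(p, baseline_rate_hz = 5, stim_rate_hz = 5,
                              n_trials = 30, seed = 13)
  expect_length(sp$trials, 30)
  # prestim 0.5-s window: expected count 5 Hz x 0.5 s x 30 = 75
  pre <- sum(vapply(sp$trials, function(ts) sum(ts >= -0.5 & ts < 0),
                    numeric(1)))
  expect_lt(abs(pre - 75) / sqrt(75), 4)       # within 4 Poisson SDs
  # rate-matched stim: PSTH flat within sampling error
  ps <- build_psth(sp, bin_ms = 100, window = c(-1, 1.5))
  expect_lt(max(ps$rate_hz) - min(ps$rate_hz),
            6 * sqrt(5 / (30 * 0.1)))
  expect_error(simulate_spike_trains(p, baseline_rate_hz = -1, seed = 1),
               "rates")
})
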
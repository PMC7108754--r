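test_that("fractional change matches the elementwise definition", {
  set.seed(51)
  a <- array(rexp(5 * 4 * 30) + 0.5, dim = c(5, 4, 30))
  bl <- compute_baseline(a, n_prestim = 10)
  drr <- fractional_change(a, bl)
  # brute-force elementwise oracle
  for (k in c(1, 15, 30))
    expect_equal(drr[, , k], (a[, , k] - bl$Ib) / bl$Ib, tolerance = 1e-12)
  # I = Ib everywhere -> 0; I = 1.025 Ib -> 0.025
  a2 <- array(rep(bl$Ib, 30), dim = dim(a))
  expect_true(all(fractional_change(a2, bl) == 0))
  expect_equal(range(fractional_change(a2 * 1.025, bl)),
               c(0.025, 0.025), tolerance = 1e-9)
  # non-positive baseline pixels are excluded as NA, not propagated
  a[2, 2, ] <- 0
  bl2 <- compute_baseline(a, n_prestim = 10)
  drr2 <- fractional_change(a, bl2)
  expect_true(all(is.na(drr2[2, 2, ])))
  expect_true(all(is.finite(drr2[1, 1, ])))
})

make_cov <- function(d, labels) {
  # coverage array with constant per-pixel labels
  cov <- array(0L, d)
  for (k in seq_len(d[3])) cov[, , k] <- labels
  cov
}

test_that("pooling inverts negative labels and averages", {
  d <- c(4, 4, 10)
  cc <- 0.02
  drr <- array(cc, dim = d)
  labels <- matrix(1L, 4, 4)
  tt <- seq_len(10) - 5
  # all +1 with drr = c: course constantly c
  tc <- aggregate_foct(drr, make_cov(d, labels), times = tt)
  expect_true(all(abs(tc$value - cc) < 1e-12))
  # half -1 with drr = -c, half +1 with +c: inversion normalizes to c
  drr2 <- drr; drr2[, 3:4, ] <- -cc
  labels2 <- labels; labels2[, 3:4] <- -1L
  for (mode in c("pixel", "frame")) {
    tc2 <- aggregate_foct(drr2, make_cov(d, labels2), times = tt,
                          pooling = mode)
    expect_true(all(abs(tc2$value - cc) < 1e-12))
    expect_equal(tc2$n_pixels[1], 16)
  }
})

test_that("frame pooling flags frames with no eligible pixels", {
  d <- c(3, 3, 8)
  drr <- array(0.01, dim = d)
  cov <- array(0L, d)
  cov[, , 5:8] <- 1L   # covered only late
  tc <- aggregate_foct(drr, cov, times = seq_len(8) - 4, pooling = "frame")
  expect_true(all(is.na(tc$value[1:4])))
  expect_true(all(is.finite(tc$value[5:8])))
  expect_identical(attr(tc, "flagged_frames"), 1:4)
})

test_that("single full-depth bin reproduces the whole-frame course", {
  p <- quick_protocol(n_trials = 2, poststim_s = 1)
  s <- quiet_scene(p)
  bm <- simulate_bm_series(p, s, 1, seed = 52)
  tt <- frame_times(p, "oct")
  drr <- list(); sig <- list()
  for (i in 1:2) {
    bl <- compute_baseline(bm, trial = i)
    drr[[i]] <- fractional_change(bm, bl, trial = i)
    sig[[i]] <- detect_significant(bm, bl, trial = i)
  }
  whole <- aggregate_foct(drr, sig, times = tt)
  one_bin <- depth_resolved(drr, sig, times = tt,
                            z_pitch_um = p$z_pitch_um,
                            bin_um = p$n_z * p$z_pitch_um, n_bins = 1)
  expect_equal(one_bin[[1]]$value, whole$value, tolerance = 1e-12)
  # activation programmed to 500 um: bins 1-5 respond, bin 6 empty
  p6 <- quick_protocol(n_trials = 1, poststim_s = 1, n_z = 60)
  s6 <- quiet_scene(p6)
  bm6 <- simulate_bm_series(p6, s6, 1, seed = 53)
  bl6 <- compute_baseline(bm6)
  dd <- depth_resolved(fractional_change(bm6, bl6),
                       list(detect_significant(bm6, bl6)),
                       times = tt, z_pitch_um = 10, bin_um = 100, n_bins = 6)
  pk <- vapply(dd, function(tc) {
    v <- tc$value[tc$time_s >= 0]
    if (all(is.na(v))) NA_real_ else max(abs(v), na.rm = TRUE)
  }, numeric(1))
  expect_true(all(pk[1:5] > 0.02))
  expect_true(is.na(pk[6]))
  expect_error(depth_resolved(drr, sig, times = tt, z_pitch_um = 10,
                              bin_um = 100, n_bins = 60),
               "exceed")
})

test_that("permuting depth rows preserves the whole-frame course", {
  set.seed(54)
  d <- c(10, 6, 20)
  drr <- array(rnorm(prod(d), 0.01, 0.002), dim = d)
  cov <- array(1L, d)
  tt <- seq_len(20) - 10
  perm <- sample(10)
  tc1 <- aggregate_foct(drr, cov, times = tt)
  tc2 <- aggregate_foct(drr[perm, , ], cov[perm, , ], times = tt)
  expect_equal(tc1$value, tc2$value, tolerance = 1e-12)
})

test_that("OISI ROI signal recovers the programmed darkening", {
  p <- quick_protocol(n_trials = 3, poststim_s = 1, oisi_fps = 20)
  s <- ins_scene(p, trial_cv = 0, oisi_noise_sd = 0)
  os <- simulate_oisi_series(p, s, exposure = 1, seed = 55)
  tc <- oisi_signal(os)
  tt <- tc$time_s
  expect_equal(tc$value[tt >= 0.4 & tt <= 0.6],
               template_eval(s$oisi_template, tt[tt >= 0.4 & tt <= 0.6]),
               tolerance = 1e-9)
  expect_equal(tc$n_pixels[1], 400)   # default 20 x 20 ROI
  # constant frames -> zero course
  s0 <- ins_scene(p, oisi_tpl = oisi_template(peak_amplitude = 0),
                  oisi_noise_sd = 0)
  tc0 <- oisi_signal(simulate_oisi_series(p, s0, 1, seed = 56))
  expect_true(all(tc0$value == 0))
  # ROI outside the activation stays at baseline
  far <- matrix(FALSE, p$n_x, p$n_x); far[1:6, 1:6] <- TRUE
  tcf <- oisi_signal(os, roi = far)
  expect_lt(max(abs(tcf$value)), 1e-9)
})

test_that("activation map counts significant pixels in the window", {
  p <- quick_protocol(n_trials = 2, poststim_s = 1)
  s <- quiet_scene(p)
  bm <- simulate_bm_series(p, s, 1, seed = 57)
  tt <- frame_times(p, "oct")
  drr <- list(); sig <- list()
  for (i in 1:2) {
    bl <- compute_baseline(bm, trial = i)
    drr[[i]] <- fractional_change(bm, bl, trial = i)
    sig[[i]] <- detect_significant(bm, bl, trial = i)
  }
  am <- activation_map(drr, sig, times = tt, time_window_s = c(0, 1))
  expect_equal(am$count, sum(s$activation))   # noise-free: exact area
  expect_true(all(is.na(am$map[!s$activation])))
  expect_true(all(am$map[s$activation] > 0))
  # no significant pixels -> empty map, count 0
  cov0 <- list(array(0L, dim(drr[[1]])), array(0L, dim(drr[[1]])))
  am0 <- activation_map(drr, cov0, times = tt, time_window_s = c(0, 1))
  expect_identical(am0$count, 0)
  expect_true(all(is.na(am0$map)))
  # raising k_sigma never increases the count (threshold monotonicity)
  p2 <- quick_protocol(n_trials = 1, poststim_s = 1)
  s2 <- ins_scene(p2)
  bm2 <- simulate_bm_series(p2, s2, 1, seed = 58)
  bl2 <- compute_baseline(bm2)
  drr2 <- fractional_change(bm2, bl2)
  counts <- vapply(c(2, 3, 4, 6), function(k) {
    activation_map(drr2, list(detect_significant(bm2, bl2, k_sigma = k)),
                   times = tt, time_window_s = c(0, 1))$count
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})
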
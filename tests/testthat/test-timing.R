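test_that("onset is the first 3-sigma power crossing after t = 0", {
  tt <- seq(-1, 3, by = 0.01)
  # noiseless step on a zero baseline: onset at the step time
  v <- ifelse(tt >= 0.5, 0.2, 0)
  lat <- onset_delay(time_course(tt, v))
  expect_true(lat$detected)
  expect_equal(lat$onset_delay_s, 0.5)
  # a course that never departs baseline is not detected
  lat0 <- onset_delay(time_course(tt, rep(0, length(tt))))
  expect_false(lat0$detected)
  expect_true(is.na(lat0$onset_delay_s))
  # darkening signals are handled through |value|
  latn <- onset_delay(time_course(tt, -v))
  expect_equal(latn$onset_delay_s, 0.5)
  expect_error(onset_delay(time_course(tt[tt >= 0], v[tt >= 0])),
               "prestimulus")
})

test_that("onset is non-decreasing in the threshold multiplier k", {
  set.seed(61)
  tt <- seq(-1, 3, by = 1 / 240)
  sig <- template_eval(response_template(), tt) +
    rnorm(length(tt), sd = 5e-4)
  tc <- time_course(tt, sig)
  on <- vapply(c(1, 2, 3, 5, 8),
               function(k) onset_delay(tc, k = k)$onset_delay_s,
               numeric(1))
  expect_true(all(diff(on) >= 0))
})

test_that("peak delay is the earliest argmax of |value| after onset", {
  tt <- seq(-1, 3, by = 0.01)
  v <- numeric(length(tt)); v[tt == 0.5] <- 1
  expect_equal(peak_delay(time_course(tt, v)), 0.5)
  # plateau of equal maxima: earliest index wins
  v2 <- numeric(length(tt)); v2[tt >= 1 & tt <= 2] <- 3
  expect_equal(peak_delay(time_course(tt, v2)), 1)
  # negative peaks count through the absolute value
  v3 <- numeric(length(tt)); v3[tt == 0.8] <- -2; v3[tt == 1.2] <- 1
  expect_equal(peak_delay(time_course(tt, v3)), 0.8)
})

test_that("dose-response fit recovers exact linear relations", {
  x <- c(0.3, 0.5, 0.7, 1.0)
  fit <- dose_response_fit(x, 2 * x)
  expect_equal(fit$slope, 2, tolerance = 1e-12)
  expect_equal(fit$intercept, 0, tolerance = 1e-12)
  expect_equal(fit$r, 1, tolerance = 1e-12)
  expect_error(dose_response_fit(c(1, 1), c(2, 3)), "distinct")
})

test_that("pipeline peaks recover the generator's exposure slope", {
  # noise-free, jitter-free conditions: parameter recovery is exact up
  # to frame-grid quantization of the template peak
  p <- ins_protocol(poststim_s = 1.5, n_trials = 2, n_z = 32, n_x = 32)
  s <- quiet_scene(p)
  exposures <- c(0.3, 0.5, 0.7, 1.0)
  peaks <- vapply(exposures, function(E) {
    run <- run_foct_pipeline(p, s, exposure = E, seed = 62)
    max(abs(run$tc$value[run$tc$time_s >= 0]))
  }, numeric(1))
  fit <- dose_response_fit(exposures, peaks)
  slope_true <- s$template$amplitude_vs_exposure_slope
  expect_lt(abs(fit$slope - slope_true) / slope_true, 0.05)
  expect_gt(fit$r, 0.999)
})

test_that("projection view is the depth mean", {
  vol <- array(3, dim = c(5, 4, 6))
  expect_equal(projection_view(vol), matrix(3, 4, 6))
  vol2 <- array(0, dim = c(5, 4, 6))
  vol2[2, , ] <- 10   # single nonzero slab: image = slab / n_z
  expect_equal(projection_view(vol2), matrix(2, 4, 6))
  expect_error(projection_view(matrix(1, 2, 2)), "3-D")
})

test_that("coregistration recovers a constructed translation", {
  set.seed(63)
  base <- matrix(rnorm(60 * 60), 60)
  expect_equal(coregister(base, base, max_shift = 5),
               list(shift_x = 0, shift_y = 0, r = 1), tolerance = 1e-12)
  # B cropped so that A[y, x] == B[y + 2, x - 3]
  big <- matrix(rnorm(80 * 80), 80)
  A <- big[11:70, 11:70]
  B <- big[(11 - 2):(70 - 2), (11 + 3):(70 + 3)]
  got <- coregister(A, B, max_shift = 6)
  expect_equal(c(got$shift_x, got$shift_y), c(-3, 2))
  expect_gt(got$r, 0.999)
  expect_error(coregister(matrix(1, 10, 10), base), "degenerate")
})

test_that("shared vasculature aligns OISI with the OCT projection", {
  # scene vessels appear dark in OISI and as shadows in the OCT volume
  p <- ins_protocol(n_trials = 1, n_z = 24, n_x = 48)
  s <- ins_scene(p)
  set.seed(64)
  n <- p$n_x
  oisi_img <- s$oisi_reflectance + matrix(rnorm(n * n, sd = 0.02), n)
  vol <- array(0, dim = c(24, n, n))
  for (k in seq_len(n))   # vol[z, x, y] = 0.8 * reflectance[y, x]
    vol[, , k] <- 0.8 * matrix(rep(s$oisi_reflectance[k, ], each = 24), 24) +
      rnorm(24 * n, sd = 0.02)
  proj <- projection_view(vol)   # (x, y); transpose to match (y, x)
  got <- coregister(oisi_img, t(proj), max_shift = 4)
  expect_equal(c(got$shift_x, got$shift_y), c(0, 0))
  expect_gt(got$r, 0.5)
  # misregistration degrades the correlation
  r_off <- cor(as.vector(oisi_img[1:(n - 10), ]),
               as.vector(t(proj)[11:n, ]))
  expect_gt(got$r, r_off)
})
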
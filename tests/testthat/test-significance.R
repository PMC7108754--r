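test_that("baseline statistics are the prestim mean and N-1 SD", {
  a <- array(2, dim = c(3, 4, 10))
  b <- compute_baseline(a, n_prestim = 5)
  expect_true(all(b$Ib == 2))
  expect_true(all(b$sigma_b == 0))
  # hand-computed: frames {1, 2, 3} -> mean 2, sample SD 1
  a2 <- array(0, dim = c(1, 1, 3))
  a2[1, 1, ] <- 1:3
  b2 <- compute_baseline(a2, n_prestim = 3)
  expect_equal(b2$Ib[1, 1], 2)
  expect_equal(b2$sigma_b[1, 1], 1)
  # 1 s prestim at 100 fps -> N = 100
  p <- ins_protocol(poststim_s = 0.5, n_trials = 1, n_z = 6, n_x = 6)
  bm <- simulate_bm_series(p, ins_scene(p, vessels = list()), 1, seed = 1)
  expect_identical(compute_baseline(bm)$N, 100L)
  expect_error(compute_baseline(a, n_prestim = 1), "at least 2")
})

test_that("run-length detector fires only on full strict runs", {
  nt <- 40
  a <- array(0, dim = c(1, 1, nt))
  bl <- list(Ib = matrix(0, 1, 1), sigma_b = matrix(1, 1, 1), N = 10L)
  class(bl) <- "baseline_stats"
  # constant at baseline: nothing
  lab <- significance_labels(detect_significant(a, bl))
  expect_true(all(lab == 0L))
  # exactly 5 frames at +4 sigma: one positive start at the run head
  a[1, 1, 11:15] <- 4
  sig <- detect_significant(a, bl, k_sigma = 3, run_length = 5)
  expect_identical(which(sig$pos), 11L)
  expect_identical(sum(sig$neg), 0L)
  cov <- significance_coverage(sig)
  expect_identical(which(cov == 1L), 11:15)
  # ties (exactly at threshold) are not significant
  a[1, 1, 11:15] <- 3
  expect_identical(sum(detect_significant(a, bl)$pos), 0L)
  # a 4-frame excursion cannot start a 5-frame run
  a[1, 1, 11:15] <- 0; a[1, 1, 21:24] <- 10
  expect_identical(sum(detect_significant(a, bl)$pos), 0L)
  # runs cannot start within run_length-1 frames of the series end
  a[1, 1, ] <- 10
  sig <- detect_significant(a, bl)
  expect_identical(which(sig$pos), seq_len(nt - 4L))
})

test_that("detector matches a brute-force run scan on random traces", {
  set.seed(31)
  nt <- 2000
  for (rep in 1:3) {
    a <- array(rnorm(4 * nt), dim = c(2, 2, nt))
    bl <- compute_baseline(a, n_prestim = 50)
    k <- c(1, 1.5, 2)[rep]
    sig <- detect_significant(a, bl, k_sigma = k, run_length = 5)
    # independent oracle: direct scan of the realized traces
    for (z in 1:2) for (x in 1:2) {
      up <- a[z, x, ] > bl$Ib[z, x] + k * bl$sigma_b[z, x]
      dn <- a[z, x, ] < bl$Ib[z, x] - k * bl$sigma_b[z, x]
      pos_ref <- vapply(seq_len(nt), function(t)
        t + 4 <= nt && all(up[t:(t + 4)]), logical(1))
      neg_ref <- vapply(seq_len(nt), function(t)
        t + 4 <= nt && all(dn[t:(t + 4)]), logical(1))
      expect_identical(sig$pos[z, x, ], pos_ref)
      expect_identical(sig$neg[z, x, ], neg_ref)
    }
  }
})

test_that("detector is invariant to increasing affine rescaling", {
  set.seed(32)
  a <- array(rexp(6 * 6 * 300), dim = c(6, 6, 300))
  bl <- compute_baseline(a, n_prestim = 40)
  sig <- detect_significant(a, bl, k_sigma = 1.2)
  a2 <- 7.3 * a + 11
  bl2 <- compute_baseline(a2, n_prestim = 40)
  sig2 <- detect_significant(a2, bl2, k_sigma = 1.2)
  expect_identical(sig$pos, sig2$pos)
  expect_identical(sig$neg, sig2$neg)
})

test_that("noise-free programmed activation is recovered exactly", {
  p <- quick_protocol(n_trials = 1, poststim_s = 1)
  s <- quiet_scene(p)
  set.seed(33)
  arr <- insfoct:::sim_bm_trial(p, s, 1, p$oct_fps, 1)
  bl <- compute_baseline(arr, n_prestim = 100)
  cov <- significance_coverage(detect_significant(arr, bl))
  pos_px <- which(apply(cov == 1L, c(1, 2), any))
  expect_identical(pos_px, which(s$activation))
  expect_identical(sum(cov == -1L), 0L)
})

test_that("false-positive rate on a blank condition is below 1e-3", {
  p <- quick_protocol(n_trials = 2, poststim_s = 1)
  s <- ins_scene(p)
  bm <- simulate_bm_series(p, s, exposure = 0, seed = 34, stim = FALSE)
  fp <- 0; n <- 0
  for (tr in 1:2) {
    bl <- compute_baseline(bm, trial = tr)
    cov <- significance_coverage(detect_significant(bm, bl, trial = tr))
    fp <- fp + sum(cov != 0L)
    n <- n + length(cov)
  }
  expect_lt(fp / n, 1e-3)
})

test_that("intensity mask thresholds the baseline against the noise floor", {
  bl <- structure(list(Ib = matrix(c(5, 10, 20), 1),
                       sigma_b = matrix(0, 1, 3), N = 10L),
                  class = "baseline_stats")
  m <- intensity_mask(bl, noise_mean = 4, noise_sigma = 1, factor = 6)
  expect_identical(as.vector(m), c(FALSE, FALSE, TRUE))
  # zero noise SD: mask wherever Ib exceeds the noise mean
  m0 <- intensity_mask(bl, noise_mean = 4, noise_sigma = 0)
  expect_identical(as.vector(m0), c(TRUE, TRUE, TRUE))
  expect_identical(formals(intensity_mask)$factor, 6)
  expect_error(intensity_mask(bl), "noise")
})

test_that("noise floor is estimated from the deepest rows", {
  a <- array(10, dim = c(20, 5, 8))
  a[19:20, , ] <- 0.5
  nf <- estimate_noise_floor(a, rows_frac = 0.1, prestim_only = FALSE)
  expect_equal(nf$mean, 0.5)
  expect_equal(nf$sd, 0)
})
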
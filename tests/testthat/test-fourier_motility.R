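test_that("DICF of a static noiseless movie vanishes", {
  set.seed(1)
  f1 <- 10 + stamp_gaussians(64, 64, runif(50, 0, 64), runif(50, 0, 64), 30)
  st <- image_stack(array(rep(f1, 30), c(64, 64, 30)))
  di <- compute_dicf(st, lags = c(1, 3, 5))
  expect_true(all(abs(di$g) < 1e-16 * max(f1)^2))
  expect_true(all(di$g >= 0))
})

test_that("swimmer ISF: normalization, reductions, large-Z limit", {
  expect_equal(swimmer_isf(1, 0, 20, 10, 0.4, 0.7), 1)
  taus <- c(0.01, 0.05, 0.2, 1)
  expect_equal(swimmer_isf(0.8, taus, 20, 10, 0.4, 0),
               exp(-0.4 * 0.64 * taus), tolerance = 1e-12)
  # Z -> infinity approaches the single-speed sinc form (O(x^2/Z) error)
  x <- 0.8 * 20 * taus
  single <- exp(-0.4 * 0.64 * taus) * (0.3 + 0.7 * sin(x) / x)
  expect_lt(max(abs(swimmer_isf(0.8, taus[1:3], 20, 1e4, 0.4, 0.7) -
                      single[1:3])), 1e-4)
  expect_lt(max(abs(swimmer_isf(0.8, taus, 20, 1e6, 0.4, 0.7) - single)),
            1e-4)
  # Schulz average against direct quadrature
  f_num <- sapply(taus, function(tau)
    integrate(function(v) dgamma(v, shape = 11, scale = 20 / 11) *
                ifelse(0.8 * v * tau < 1e-12, 1,
                       sin(0.8 * v * tau) / (0.8 * v * tau)),
              0, Inf, rel.tol = 1e-10)$value)
  expect_equal(swimmer_isf(0.8, taus, 20, 10, 0, 1), f_num, tolerance = 1e-8)
  # monotone decreasing in tau for alpha = 0; |f| <= 1
  tg <- seq(0, 3, by = 0.02)
  fa0 <- swimmer_isf(1.2, tg, 20, 10, 0.4, 0)
  expect_true(all(diff(fa0) < 0))
  expect_true(all(abs(swimmer_isf(1.2, tg, 20, 5, 0.4, 0.7)) <= 1 + 1e-12))
})

test_that("DICF fitting is self-consistent on exact model data", {
  q <- seq(0.3, 1.4, by = 0.1)
  lags <- exp(seq(log(0.01), log(2), length.out = 30))
  g <- t(sapply(q, function(qq)
    5 + 80 * (1 - swimmer_isf(qq, lags, 20, 10, 0.4, 0.7))))
  di <- structure(list(q_px = q * 1.4, q_um = q, lags = lags, g = g),
                  class = "dicf")
  ft <- fit_dicf(di, q_range = c(0.4, 2))
  expect_equal(ft$v0, 20, tolerance = 1e-4)
  expect_equal(ft$alpha, 0.7, tolerance = 1e-4)
  expect_equal(ft$D, 0.4, tolerance = 1e-3)
  expect_equal(ft$Z, 10, tolerance = 1e-2)
  expect_equal(ft$sigma_v, 20 / sqrt(11), tolerance = 1e-2)
})

test_that("DDM is invariant under affine intensity changes", {
  spec <- swimmer_spec(n = 150, dimension = 3, v0_mean = 20, Z = 10,
                       alpha = 0.7, D = 0.4, box = 64 * 1.4, duration = 6,
                       dt = 0.01, seed = 11)
  tr <- generate_swimmers(spec)
  st <- render_stack(tr, render_spec(width = 64, height = 64, noise_sd = 0))
  # power-of-two gain: the FFT -> g -> normalized-fit chain is then
  # bit-exact, so the gain invariance of the fitted parameters is tested
  # free of optimizer sensitivity to last-bit rounding
  st2 <- image_stack(8 * st$frames, st$px_size, st$frame_rate)
  f1 <- fit_dicf(compute_dicf(st), q_range = c(0.5, 1.5))
  f2 <- fit_dicf(compute_dicf(st2), q_range = c(0.5, 1.5))
  expect_equal(f2$v0, f1$v0, tolerance = 1e-8)
  expect_equal(f2$alpha, f1$alpha, tolerance = 1e-8)
  expect_equal(f2$D, f1$D, tolerance = 1e-8)
  expect_equal(f2$by_q$a1, 64 * f1$by_q$a1, tolerance = 1e-8)
  # a uniform intensity offset cancels in the frame differences exactly up
  # to floating-point rounding: g changes only at that level, and the
  # robustly identified speed is unaffected
  st3 <- image_stack(st$frames + 40, st$px_size, st$frame_rate)
  d3 <- compute_dicf(st3); d1 <- compute_dicf(st)
  expect_equal(d3$g, d1$g, tolerance = 1e-10)
  f3 <- fit_dicf(d3, q_range = c(0.5, 1.5))
  expect_equal(f3$v0, f1$v0, tolerance = 1e-3)
})

test_that("q-range selection follows the cell-length calibration", {
  expect_identical(select_q_range(2), c(0.4, 2.0))
  expect_identical(select_q_range(4), c(0.4, 0.9))
  expect_warning(r3 <- select_q_range(3), "nearest")
  expect_identical(r3, c(0.4, 0.9))
})

test_that("confinement correction divides by the calibrated factors", {
  expect_equal(confinement_correction(20, 50), 20)
  expect_equal(confinement_correction(21.5, 30), 20, tolerance = 1e-12)
  expect_equal(confinement_correction(22.8, 8), 20, tolerance = 1e-12)
  expect_error(confinement_correction(20, 15), "no confinement calibration")
})

test_that("density calibration inverts the amplitude logistic", {
  cal <- density_calibration(m = 1)
  expect_equal(amplitude_to_volume_fraction(0, cal), 0)
  # forward logistic at OD = 1, m = 1: a1 = 1.25/2; inverse recovers OD = 1
  a1 <- cal$d0 * 1 / (1 + 1)
  expect_equal(a1, 0.625)
  expect_equal(amplitude_to_volume_fraction(a1, cal), 1.78e-3,
               tolerance = 1e-12)
  expect_error(amplitude_to_volume_fraction(1.3, cal), "saturation")
  # direct count route
  expect_equal(amplitude_to_volume_fraction(0.1, cal, n_c = 1e-3),
               pi * 0.25 * 2 * 1e-3, tolerance = 1e-12)
  # synthetic self-calibration recovers m
  od <- c(0.2, 0.5, 1, 2, 4)
  a1s <- 1.25 * 0.8 * od / (1 + 0.8 * od)
  expect_equal(calibrate_amplitude(od, a1s), 0.8, tolerance = 1e-10)
})

test_that("velocimetry: static movies give zero fields, displacement is linear", {
  set.seed(2)
  f1 <- 10 + stamp_gaussians(64, 64, runif(400, 0, 64), runif(400, 0, 64),
                             runif(400, 15, 45))
  st <- image_stack(array(rep(f1, 30), c(64, 64, 30)))
  vf <- local_velocimetry(st, velocimetry_config(a = 32, da = 8))
  expect_lt(max(abs(vf$vx_px), na.rm = TRUE), 1e-8)
  expect_equal(phase_diff_drift(st)$v_d, 0, tolerance = 1e-10)
  # linearity: doubling the displacement doubles the recovered velocity
  mk <- function(v) {
    set.seed(9)
    n <- 900; px0 <- runif(n, 0, 64); py0 <- runif(n, 0, 64)
    amp <- runif(n, 15, 45)
    fr <- array(0, c(64, 64, 40))
    for (t in 1:40)
      fr[, , t] <- 10 + stamp_gaussians(64, 64, (px0 + v * (t - 1)) %% 64,
                                        py0, amp)
    image_stack(fr)
  }
  g1 <- phase_diff_drift(mk(0.2))$v_d_px[1]
  g2 <- phase_diff_drift(mk(0.4))$v_d_px[1]
  expect_equal(g2 / g1, 2, tolerance = 0.02)
  expect_equal(g1, 0.2, tolerance = 0.004)
})

test_that("opposite drifting sub-populations cancel in the global drift", {
  set.seed(12)
  n <- 800; px0 <- runif(n, 0, 64); py0 <- runif(n, 0, 64)
  half <- seq_len(n) <= n / 2
  fr <- array(0, c(64, 64, 40))
  for (t in 1:40)
    fr[, , t] <- 10 + stamp_gaussians(64, 64,
                                      (px0 + ifelse(half, 0.3, -0.3) *
                                         (t - 1)) %% 64, py0, 30)
  v <- phase_diff_drift(image_stack(fr))$v_d_px[1]
  expect_lt(abs(v), 0.05)
})
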
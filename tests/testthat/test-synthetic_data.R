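test_that("swimmer generator matches Brownian and Schulz statistics", {
  # non-motile MSD = 2 dim D t
  sp <- swimmer_spec(n = 1000, dimension = 2, alpha = 0, D = 0.5,
                     duration = 5, dt = 0.01, seed = 3)
  tr <- generate_swimmers(sp)
  it <- nrow(tr$x)
  msd <- mean((tr$x[it, ] - tr$x[1, ])^2 + (tr$y[it, ] - tr$y[1, ])^2)
  expect_equal(msd, 2 * 2 * 0.5 * (max(tr$times)), tolerance = 0.05)
  # Schulz speeds: mean v0, sigma_v = v0/sqrt(Z+1), KS against the Gamma law
  sp2 <- swimmer_spec(n = 3000, dimension = 3, v0_mean = 20, Z = 10,
                      alpha = 1, duration = 0.02, dt = 0.01, seed = 4)
  tr2 <- generate_swimmers(sp2)
  v <- tr2$speed
  expect_equal(mean(v), 20, tolerance = 0.02)
  expect_equal(sd(v), 20 / sqrt(11), tolerance = 0.05)
  ks <- suppressWarnings(ks.test(v, function(q)
    pgamma(q, shape = 11, scale = 20 / 11)))
  expect_gt(ks$p.value, 0.01)
  # zero speed, all motile: no displacement
  sp0 <- swimmer_spec(n = 10, dimension = 2, v0_mean = 0, alpha = 1,
                      duration = 1, dt = 0.01, seed = 5)
  tr0 <- generate_swimmers(sp0)
  expect_equal(max(abs(tr0$x - tr0$x[1, ][col(tr0$x)])), 0)
  # bit reproducibility
  expect_identical(generate_swimmers(sp0), generate_swimmers(sp0))
})

test_that("rendering conserves injected intensity and places spots", {
  sp <- swimmer_spec(n = 40, dimension = 2, v0_mean = 15, alpha = 1,
                     box = 64 * 1.4, duration = 1, dt = 0.02, seed = 6)
  tr <- generate_swimmers(sp)
  st <- render_stack(tr, render_spec(width = 64, height = 64, noise_sd = 0,
                                     frame_rate = 50))
  tot <- apply(st$frames, 3, sum)
  expect_lt(sd(tot) / mean(tot), 1e-6)
  # single static particle: intensity maximum at the nearest pixel
  trj <- list(times = c(0, 0.02), x = matrix(c(30.3, 30.3) * 1.4, 2, 1),
              y = matrix(c(41.8, 41.8) * 1.4, 2, 1))
  st1 <- render_stack(trj, render_spec(width = 64, height = 64, noise_sd = 0,
                                       frame_rate = 50))
  pk <- which(st1$frames[, , 1] == max(st1$frames[, , 1]), arr.ind = TRUE)
  expect_equal(unname(pk[1, ]), c(42 + 1, 30 + 1)) # row = y, 0-based coords
  # empty field: DDM sees only the flat noise floor (up to annulus-count
  # statistics, so the lowest bins are excluded)
  tre <- list(times = seq(0, 0.39, by = 0.01),
              x = matrix(numeric(0), 40, 0), y = matrix(numeric(0), 40, 0))
  ste <- render_stack(tre, render_spec(width = 64, height = 64, noise_sd = 1))
  di <- compute_dicf(ste, lags = c(1, 5))
  gq <- di$g[-(1:2), ]
  expect_lt(max(abs(gq - mean(gq))) / mean(gq), 0.3)
})

test_that("Taylor-Green vortex array has the declared structure", {
  vf <- vortex_field(16, amplitude = 10, grid_side = 64, spacing = 1)
  # discrete divergence (central differences, periodic) is tiny
  vx <- vf$vx[, , 1]; vy <- vf$vy[, , 1]
  sh <- function(m, i, j) m[(seq_len(64) + i - 1) %% 64 + 1,
                            (seq_len(64) + j - 1) %% 64 + 1]
  div <- (sh(vx, 1, 0) - sh(vx, -1, 0)) / 2 + (sh(vy, 0, 1) - sh(vy, 0, -1)) / 2
  # second-order stencil on a smooth field: relative to |grad v| ~ A k
  expect_lt(max(abs(div)) / (10 * pi / 16), 1e-2)
  # analytic divergence identically zero on the staggered symmetry points
  expect_equal(sum(vx[1, ]), 0, tolerance = 1e-9)
  expect_error(vortex_field(10, grid_side = 64), "multiple")
  # spectral peak at pi/q = ell within one bin, amplitude-invariant
  sp <- flow_structure_factor(vf)
  pk <- peak_analysis(sp)
  expect_lt(abs(pk$q_max - pi / 16), sp$dq + 1e-12)
})

test_that("gradient solver relaxes to the linear profile", {
  gs <- gradient_spec(c_left = 0, c_right = 200, channel_length = 2000,
                      D_ligand = 500, dx = 20)
  # equal reservoirs: constant profile
  g0 <- gradient_profile(gradient_spec(c_left = 50, c_right = 50), 100)
  expect_true(all(abs(g0$c - 50) < 1e-9))
  # steady state: linear within 1e-3 of c_right
  gst <- gradient_profile(gs, Inf)
  expect_true(all(abs(gst$c - gst$x / 10) < 1e-3 * 200))
  glong <- gradient_profile(gs, 8000)
  expect_lt(max(abs(glong$c - gst$c)), 1e-3 * 200)
  # boundary values exact at any time
  gt <- gradient_profile(gs, 37.7)
  expect_identical(gt$c[1], 0)
  expect_identical(gt$c[length(gt$c)], 200)
  # slowest relaxation rate against the eigenfunction-expansion oracle:
  # deviation from steady state decays as exp(-pi^2 D t / L^2)
  t1 <- 600; t2 <- 1200
  d1 <- gradient_profile(gs, t1)$c - gst$c
  d2 <- gradient_profile(gs, t2)$c - gst$c
  mode <- sin(pi * gst$x / 2000)
  a1 <- sum(d1 * mode); a2 <- sum(d2 * mode)
  rate <- log(a1 / a2) / (t2 - t1)
  expect_equal(rate, pi^2 * 500 / 2000^2, tolerance = 0.02)
  expect_equal(1 / (pi^2 * 500 / 2000^2), 810.6, tolerance = 0.001)
})

test_that("Peclet number is the printed ratio", {
  gs <- gradient_spec()
  expect_equal(peclet(gs, 50, v_f = 10), 1)
  expect_equal(peclet(gs, 50, v_f = 0), 0)
  expect_equal(peclet(gs, 25, v_f = 10), 0.5)
  expect_equal(peclet(gs, 50, v_f = 20), 2)
})
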
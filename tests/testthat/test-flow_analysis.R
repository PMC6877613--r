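test_that("coarse graining reproduces a direct kernel-sum oracle", {
  cfg <- simulation_config(n_rods = 40, box_side = 48, t_total = 1, dt = 0.01,
                           save_interval = 0.5, seed = 5)
  tr <- run_simulation(cfg)
  vf <- coarse_grain_velocity(tr, spacing = 2, sigma = 2.5,
                              times = tr$times[length(tr$times)])
  # naive double loop at a handful of nodes
  it <- length(tr$times)
  gx <- vf$grid
  pim <- function(d) d - 48 * round(d / 48)
  for (ix in c(3, 10, 20)) for (iy in c(5, 15)) {
    w <- exp(-(pim(gx[ix] - tr$x[it, ])^2 + pim(gx[iy] - tr$y[it, ])^2) /
               (2 * 2.5^2))
    w[w < exp(-9 / 2 - 1e-9)] <- w[w < exp(-9 / 2 - 1e-9)] # keep all; cutoff below
    keep <- abs(pim(gx[ix] - tr$x[it, ])) <= 7.5 &
      abs(pim(gx[iy] - tr$y[it, ])) <= 7.5
    expect_equal(vf$vx[ix, iy, 1],
                 if (any(keep)) sum((w * tr$vx[it, ])[keep]) / sum(w[keep])
                 else 0,
                 tolerance = 1e-10)
  }
  # all rods sharing one velocity gives that velocity at occupied nodes
  tr$vx[] <- 3; tr$vy[] <- -1
  vf2 <- coarse_grain_velocity(tr, times = tr$times[it])
  occ <- vf2$weight[, , 1] > 0
  expect_equal(unique(round(vf2$vx[, , 1][occ], 10)), 3)
  expect_equal(unique(round(vf2$vy[, , 1][occ], 10)), -1)
})

test_that("flow structure factor is normalized and locates single modes", {
  set.seed(2)
  # random fields: sum E dq = 1 and E >= 0
  for (k in 1:3) {
    vf <- velocity_field(matrix(rnorm(64^2), 64), matrix(rnorm(64^2), 64),
                         spacing = 2)
    sp <- flow_structure_factor(vf)
    expect_equal(sum(sp$E) * sp$dq, 1, tolerance = 1e-10)
    expect_true(all(sp$E >= 0))
  }
  # uniform field: all weight in the lowest bin
  vfu <- velocity_field(matrix(1, 64, 64), matrix(2, 64, 64), spacing = 2)
  spu <- flow_structure_factor(vfu)
  expect_equal(spu$E[1] * spu$dq, 1, tolerance = 1e-10)
  # single shear mode sin(q0 x) yhat: all weight in the q0 bin
  g <- (0:63) * 2
  q0 <- 2 * pi * 4 / 128
  vfm <- velocity_field(matrix(0, 64, 64),
                        matrix(rep(sin(q0 * g), each = 1), 64, 64,
                               byrow = FALSE), spacing = 2)
  spm <- flow_structure_factor(vfm)
  expect_equal(which.max(spm$E), which.min(abs(spm$q - q0)))
  # all-zero field errors
  expect_error(flow_structure_factor(
    velocity_field(matrix(0, 16, 16), matrix(0, 16, 16), 1)), "zero")
})

test_that("spectral peak is invariant under velocity rescaling", {
  vf <- vortex_field(16, amplitude = 5, grid_side = 64, spacing = 1)
  vf2 <- vortex_field(16, amplitude = 50, grid_side = 64, spacing = 1)
  s1 <- flow_structure_factor(vf); s2 <- flow_structure_factor(vf2)
  expect_equal(s1$E, s2$E, tolerance = 1e-12)
})

test_that("peak analysis applies baselines and frozen q_str", {
  vf <- vortex_field(16, grid_side = 64)
  sp <- flow_structure_factor(vf)
  pk0 <- peak_analysis(sp, baseline = sp)
  expect_equal(pk0$deltaE, 0, tolerance = 1e-12)
  pk <- peak_analysis(sp, q_str = 0.3)
  expect_equal(pk$q_str, sp$q[which.min(abs(sp$q - 0.3))])
  expect_equal(pk$vortex_size, pi / pk$q_str)
})

test_that("velocity autocorrelation: level crossing and sentinels", {
  # frozen velocities: C_v constant at 1, sentinel tau_dec
  frozen <- list(times = seq(0, 9.9, by = 0.1),
                 vx = matrix(rep(rnorm(50), each = 100), 100),
                 vy = matrix(rep(rnorm(50), each = 100), 100))
  expect_warning(ac <- velocity_autocorrelation(frozen), "never crosses")
  expect_true(all(abs(ac$C_v - 1) < 1e-12))
  expect_true(is.na(ac$tau_dec))
  # synthetic exponential: tau_dec = tau log 2
  set.seed(1)
  tau <- 0.8; dt <- 0.05; nT <- 400; np <- 400
  ph <- matrix(0, nT, np)
  for (t in 2:nT) ph[t, ] <- ph[t - 1, ] + sqrt(dt / tau) * rnorm(np)
  syn <- list(times = (1:nT) * dt, vx = cos(ph), vy = sin(ph))
  ac2 <- velocity_autocorrelation(syn)
  expect_equal(ac2$tau_dec, tau * log(2) * 2, tolerance = 0.15)
  # note: 2D phase diffusion at rate 1/(2 tau) per component gives
  # <cos dphi> = exp(-t/(2 tau)); crossing at 2 tau log 2
  expect_equal(ac2$C_v[1], 1)
})

test_that("chemotactic drift bookkeeping", {
  nT <- 120
  traj <- list(times = seq(0.5, 60, by = 0.5),
               unwrapped_x = outer(seq(0.5, 60, by = 0.5), rep(2.5, 30)),
               vx = matrix(2.5, nT, 30), vy = matrix(0, nT, 30))
  dr <- chemotactic_drift(traj, alpha = 1, t_burn = 10)
  expect_equal(dr$v_ch, 2.5, tolerance = 1e-12)
  expect_equal(dr$v0, 2.5, tolerance = 1e-12)
  expect_equal(dr$coefficient, 1 / 2.5, tolerance = 1e-12)
  dr2 <- chemotactic_drift(traj, alpha = 0.5, t_burn = 10)
  expect_equal(dr2$v_ch, 2 * dr$v_ch)
  expect_error(chemotactic_drift(traj, alpha = 0), "alpha")
})

test_that("sensing time: closed-form values and limits", {
  expect_equal(sensing_time(3, 3, 3), 0.5, tolerance = 1e-12) # T/6 with T = 3
  expect_lt(sensing_time(1, 1e9, 10), 1e-6)
  expect_equal(sensing_time(1, 1, 10), (10 / 11) * (1 / 2.1),
               tolerance = 1e-6)
  expect_equal(sensing_time(1, 1, 10), 0.43290, tolerance = 1e-4)
})

test_that("tau_dec-parameterised prediction is an exact algebraic identity", {
  th <- theory_params(gain = 10, tau_m = 20, tau_R = 17.5, tau_T = 1.4,
                      grad_f = 6.7e-4)
  expect_identical(predicted_coefficient(theory_params(10, 20, 17.5, 1.4, 0)),
                   0)
  tau_dec <- th$tau_R * th$tau_T / (th$tau_R + th$tau_T)
  expect_equal(predicted_coefficient(th, tau_dec), predicted_coefficient(th),
               tolerance = 1e-12)
})

test_that("dilute decorrelation rate matches the reorientation theory", {
  # C_v decays exponentially at 1/tau_R + 1/tau_T (module tau_T, which uses
  # the wall-clock tumble frequency); fitted rate within 15%
  cfg <- simulation_config(n_rods = 800, box_side = 512, D_r = 0.3,
                           t_total = 40, dt = 0.01, save_interval = 0.05,
                           hydrodynamics_on = FALSE, steric_on = FALSE,
                           gradient = NULL, seed = 17)
  tr <- run_simulation(cfg)
  ac <- velocity_autocorrelation(tr, t_min = 5, max_lag = 3)
  ep <- effective_parameters(pathway_params(), D_r = 0.3)
  keep <- ac$lags > 0.1 & ac$lags < 1.2 & ac$C_v > 0.05
  fit <- lm(log(ac$C_v[keep]) ~ ac$lags[keep])
  rate <- -coef(fit)[[2]]
  expect_equal(rate, 1 / ep$tau_R + 1 / ep$tau_T, tolerance = 0.15)
  # tau_dec decreases when D_r increases
  cfg2 <- simulation_config(n_rods = 800, box_side = 512, D_r = 1.5,
                            t_total = 40, dt = 0.01, save_interval = 0.05,
                            hydrodynamics_on = FALSE, steric_on = FALSE,
                            gradient = NULL, seed = 17)
  ac2 <- velocity_autocorrelation(run_simulation(cfg2), t_min = 5, max_lag = 3)
  expect_lt(ac2$tau_dec, ac$tau_dec)
})
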
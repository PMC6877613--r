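test_that("friction coefficients obey the slender-body relations", {
  fr <- friction_set(2, 1, 1e-3)
  expect_equal(fr$gamma_par, 2 * pi * 1e-3 * 2 / log(2))
  expect_equal(fr$gamma_perp, 2 * fr$gamma_par)
  expect_equal(fr$gamma_rot, fr$gamma_par * 4 / 6)
})

test_that("area fraction arithmetic", {
  cfg <- simulation_config(box_side = 256, L = 2, e = 1, n_rods = 1,
                           t_total = 1)
  expect_equal(area_fraction(0, cfg), 0)
  expect_equal(area_fraction(1, cfg), (1 + pi / 4) / 65536, tolerance = 1e-12)
  expect_equal(area_fraction(10, cfg), 10 * area_fraction(1, cfg))
})

test_that("config validation enforces the displacement bound", {
  expect_error(simulation_config(n_rods = 5, dt = 0.05, v0_mean = 20),
               "displacement bound")
  expect_error(simulation_config(phi = NULL, n_rods = NULL), "n_rods or phi")
})

test_that("contact detection matches a brute-force segment-distance oracle", {
  cfg <- simulation_config(box_side = 64, n_rods = 2, L = 2, e = 1,
                           t_total = 1)
  # far apart: no contact
  st <- rbind(rod_state(10, 10, 0), rod_state(20, 10, 0))
  expect_identical(nrow(find_contacts(st, cfg)), 0L)
  # perpendicular rods, centre distance 0.8, e = 1: the minimal segment
  # distance is 0.3 (lower tip of the vertical core to the horizontal axis),
  # so delta = 0.7 - verified against the brute-force sampling oracle
  st2 <- rbind(rod_state(30, 30, 0), rod_state(30, 30.8, pi / 2))
  ct <- find_contacts(st2, cfg)
  expect_identical(nrow(ct), 1L)
  d_bf <- segseg_bruteforce(c(30, 30), 0, c(30, 30.8), pi / 2, 2, 1)
  expect_equal(ct$delta, 1 - d_bf, tolerance = 1e-4)
  expect_equal(ct$delta, 0.7, tolerance = 1e-4)
  # laterally offset parallel rods at distance 0.8 give delta = 0.2
  stp2 <- rbind(rod_state(30, 30, 0), rod_state(30, 30.8, 0))
  expect_equal(find_contacts(stp2, cfg)$delta, 0.2, tolerance = 1e-9)
  # contact normal is a unit vector orthogonal to the tangent
  expect_equal(ct$ux^2 + ct$uy^2, 1, tolerance = 1e-12)
  expect_equal(ct$ux * ct$vx + ct$uy * ct$vy, 0, tolerance = 1e-12)
  # random configurations against the brute-force oracle
  set.seed(7)
  for (k in 1:12) {
    c1 <- runif(2, 20, 24); c2 <- c1 + runif(2, -2, 2)
    t1 <- runif(1, -pi, pi); t2 <- runif(1, -pi, pi)
    stx <- rbind(rod_state(c1[1], c1[2], t1), rod_state(c2[1], c2[2], t2))
    ct <- find_contacts(stx, cfg)
    d_bf <- segseg_bruteforce(c1, t1, c2, t2, 2, 1)
    if (d_bf < 1 - 1e-4) {
      expect_identical(nrow(ct), 1L)
      expect_equal(ct$delta, 1 - d_bf, tolerance = 1e-3)
    } else if (d_bf > 1 + 1e-4) {
      expect_identical(nrow(ct), 0L)
    }
  }
  # overlap across the periodic boundary is found
  st3 <- rbind(rod_state(0.2, 10, pi / 2), rod_state(63.7, 10, pi / 2))
  expect_identical(nrow(find_contacts(st3, cfg)), 1L)
})

test_that("steric forces: Hertzian magnitude, Newton's third law", {
  cfg <- simulation_config(box_side = 64, n_rods = 2, L = 2, e = 1,
                           K_el = 200, t_total = 1)
  st <- rbind(rod_state(30, 30, 0), rod_state(30, 30.9, 0)) # parallel, delta = 0.1
  ct <- find_contacts(st, cfg)
  expect_equal(ct$delta, 0.1, tolerance = 1e-9)
  fo <- steric_forces(ct, st, cfg)
  expect_equal(sqrt(sum(fo$force[1, ]^2)), 200 * 0.1^1.5, tolerance = 1e-9)
  expect_equal(sqrt(sum(fo$force[1, ]^2)), 6.325, tolerance = 1e-3)
  expect_equal(fo$force[1, ] + fo$force[2, ], c(0, 0), tolerance = 1e-12)
  # zero interpenetration -> zero force
  st0 <- rbind(rod_state(30, 30, 0), rod_state(30, 31.01, 0))
  expect_identical(nrow(find_contacts(st0, cfg)), 0L)
  # random pile: total contact force vanishes to machine precision
  set.seed(3)
  stp <- do.call(rbind, lapply(1:12, function(i)
    rod_state(30 + runif(1, 0, 4), 30 + runif(1, 0, 4), runif(1, -pi, pi))))
  ctp <- find_contacts(stp, cfg)
  fop <- steric_forces(ctp, stp, cfg,
                       velocities = matrix(rnorm(24), 12, 2))
  expect_lt(max(abs(colSums(fop$force))), 1e-10 * max(1, max(abs(fop$force))))
})

test_that("single-rod kinematics are exactly ballistic without noise", {
  cfg <- simulation_config(n_rods = 1, box_side = 64, D_r = 1e-300,
                           t_total = 1, dt = 0.01, hydrodynamics_on = FALSE,
                           gradient = NULL, pathway = quiet_pathway())
  st <- rod_state(10, 10, 0.5)
  set.seed(1)
  out <- step_rods(st, cfg, n_steps = 100)
  expect_equal(out$unwrapped_x, 10 + 20 * cos(0.5), tolerance = 1e-4)
  expect_equal(out$y, 10 + 20 * sin(0.5), tolerance = 1e-4)
})

test_that("hydrodynamic advection matches the dipole-flow oracle", {
  cfg <- simulation_config(n_rods = 2, box_side = 256, h = 30, D_r = 1e-300,
                           t_total = 1, dt = 0.01, hydrodynamics_on = TRUE,
                           gradient = NULL, pathway = quiet_pathway())
  st <- rbind(rod_state(100, 100, 0.3, v = 20),
              rod_state(110, 104, -1.1, v = 25))
  set.seed(1)
  out <- step_rods(st, cfg, n_steps = 1)
  med <- hele_shaw_medium(30, r_clamp = cfg$r_clamp, r_cutoff = cfg$r_cutoff)
  fr <- cfg$friction
  n1 <- c(cos(0.3), sin(0.3)); n2 <- c(cos(-1.1), sin(-1.1))
  dip1 <- force_dipole(c(100, 100), n1, fr$gamma_par * 20, cfg$L_dip)
  pA <- c(110, 104); pB <- pA - cfg$L_dip * n2
  w <- (dipole_flow(dip1, pA, med) + dipole_flow(dip1, pB, med)) / 2
  pred <- pA + (25 * n2 + w) * 0.01
  # tabulated kernel in the compiled core vs exact Bessel evaluation
  expect_equal(c(out$x[2], out$y[2]), pred, tolerance = 1e-6)
})

test_that("rotational diffusion follows Var = 2 D_r t", {
  cfg <- simulation_config(n_rods = 1500, box_side = 2560, D_r = 0.057,
                           t_total = 6, dt = 0.01, save_interval = 0.1,
                           hydrodynamics_on = FALSE, steric_on = FALSE,
                           gradient = NULL, pathway = quiet_pathway(),
                           seed = 7)
  tr <- run_simulation(cfg)
  dth <- apply(tr$theta, 2, function(v) {
    d <- diff(v); sum(d - 2 * pi * round(d / (2 * pi)))
  })
  t_span <- max(tr$times) - min(tr$times)
  expect_equal(var(dth), 2 * 0.057 * t_span, tolerance = 0.1)
})

test_that("identical seeds give bit-identical trajectories", {
  cfg <- simulation_config(n_rods = 30, box_side = 48, phi = NULL, h = 30,
                           t_total = 2, dt = 0.01, seed = 42)
  tr1 <- run_simulation(cfg)
  tr2 <- run_simulation(cfg)
  expect_identical(tr1$x, tr2$x)
  expect_identical(tr1$theta, tr2$theta)
  expect_identical(tr1$methylation, tr2$methylation)
})

test_that("trajectory summaries and export work", {
  cfg <- simulation_config(n_rods = 10, box_side = 48, t_total = 2, dt = 0.01,
                           seed = 2)
  tr <- run_simulation(cfg)
  s <- summary(tr)
  expect_true(all(c("time", "mean_speed", "mean_drift", "phi") %in% names(s)))
  expect_true(all(is.finite(s$mean_speed)))
  td <- file.path(tempdir(), "traj_test")
  paths <- write_trajectories(tr, td)
  expect_true(file.exists(paste0(td, "_summary.csv")))
  meta <- jsonlite::read_json(paste0(td, "_meta.json"))
  expect_true(all(c("config_hash", "seed", "version") %in% names(meta)))
})
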
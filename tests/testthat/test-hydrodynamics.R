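test_that("kernel factors approach the far-field limit and match Bessel oracles", {
  med <- hele_shaw_medium(30)
  sk <- sqrt(med$kappa)
  # z >> 1: c1 -> -1, c2 -> 2, so G -> (2 rhat rhat - I)/(pi eta h kappa r^2)
  r20 <- 20 / sk
  G <- hele_shaw_kernel(c(r20, 0), med)
  pref <- pi * med$eta * med$h * med$kappa * r20^2
  expect_equal(G[2, 2] * pref, -1, tolerance = 1e-3)
  expect_equal(G[1, 1] * pref, 1, tolerance = 1e-3)  # c1 + c2 along rhat
  # z = 1 against an independent integral-representation Bessel evaluation
  K0 <- bessel_k_int(1, 0); K2 <- bessel_k_int(1, 2)
  r1 <- 1 / sk
  G1 <- hele_shaw_kernel(c(0, r1), med)
  pref1 <- pi * med$eta * med$h * med$kappa * r1^2
  expect_equal(G1[1, 1] * pref1, (K0 + K2) / 2 - 1, tolerance = 1e-8)
  expect_equal(G1[2, 2] * pref1, ((K0 + K2) / 2 - 1) + (2 - K2),
               tolerance = 1e-8)
})

test_that("kernel is symmetric, even, and clamps the near field", {
  med <- hele_shaw_medium(30)
  set.seed(1)
  for (k in 1:20) {
    r <- runif(2, -20, 20)
    G <- hele_shaw_kernel(r, med)
    expect_equal(G, t(G), tolerance = 1e-12)
    expect_equal(G, hele_shaw_kernel(-r, med), tolerance = 1e-12)
  }
  # inside r_clamp the evaluation is frozen at r_clamp
  d <- c(0.8, 0.6)
  expect_equal(hele_shaw_kernel(0.1 * d, med),
               hele_shaw_kernel(med$r_clamp * d, med), tolerance = 1e-12)
  expect_warning(hele_shaw_kernel(c(0, 0), med), "clamped")
})

test_that("point-force flow is incompressible (divergence vanishes as h^2)", {
  med <- hele_shaw_medium(30)
  U <- function(p) drop(hele_shaw_kernel(p, med) %*% c(1, 0.3))
  divrel <- function(p, hh) {
    dv <- (U(p + c(hh, 0))[1] - U(p - c(hh, 0))[1] +
             U(p + c(0, hh))[2] - U(p - c(0, hh))[2]) / (2 * hh)
    J <- cbind((U(p + c(hh, 0)) - U(p - c(hh, 0))) / (2 * hh),
               (U(p + c(0, hh)) - U(p - c(0, hh))) / (2 * hh))
    abs(dv) / sqrt(sum(J^2))
  }
  for (p in list(c(2.2, 0.9), c(5, 3), c(15, -8), c(30, 20))) {
    # second-order stencil: truncation-limited at spacing 0.05, so verify
    # h^2 convergence towards zero and the 1e-6 level at fine spacing
    d1 <- divrel(p, 0.05); d2 <- divrel(p, 0.01); d3 <- divrel(p, 0.002)
    expect_lt(d1, 2e-4)
    expect_lt(d2, d1)
    expect_lt(d3, 1e-6)
  }
})

test_that("screening: far-field decay follows the Bessel asymptotics", {
  med <- hele_shaw_medium(30)
  sk <- sqrt(med$kappa)
  U <- function(r) drop(hele_shaw_kernel(c(r, 0), med) %*% c(1, 0))
  ratio <- U(med$h)[1] / U(1)[1]
  cfun <- function(r) { # independent evaluation via integral-rep Bessels
    z <- sk * r
    c1 <- z^2 * (bessel_k_int(z, 0) + bessel_k_int(z, 2)) / 2 - 1
    c2 <- 2 - z^2 * bessel_k_int(z, 2)
    (c1 + c2) / r^2
  }
  expect_equal(ratio, cfun(med$h) / cfun(1), tolerance = 1e-6)
})

test_that("larger channel height gives longer-ranged flow", {
  # range = decay between 1 um and 10 um; the magnitude at fixed r is not
  # itself monotone in h (depth-averaging dilutes the flow as 1/h once the
  # screening length exceeds r), so the reach ratio is the monotone quantity
  reach <- sapply(c(8, 30, 50), function(h) {
    med <- hele_shaw_medium(h)
    u <- function(r) drop(hele_shaw_kernel(c(r, 0), med) %*% c(1, 0))[1]
    u(10) / u(1)
  })
  expect_true(all(diff(reach) > 0))
})

test_that("dipole flow superposes two point forces and scales linearly", {
  med <- hele_shaw_medium(30)
  n <- c(cos(0.7), sin(0.7))
  dip <- force_dipole(c(3, -2), n, F_mag = 0.4, L_dip = 6)
  p <- c(9, 4)
  w <- dipole_flow(dip, p, med)
  w_oracle <- drop(hele_shaw_kernel(p - c(3, -2), med) %*% (0.4 * n)) -
    drop(hele_shaw_kernel(p - (c(3, -2) - 6 * n), med) %*% (0.4 * n))
  expect_equal(w, w_oracle, tolerance = 1e-12)
  # zero dipole length cancels exactly; doubling F doubles w
  expect_equal(dipole_flow(force_dipole(c(3, -2), n, 0.4, 0), p, med), c(0, 0))
  w2 <- dipole_flow(force_dipole(c(3, -2), n, 0.8, 6), p, med)
  expect_equal(w2, 2 * w, tolerance = 1e-12)
  # decays to negligible beyond the cutoff
  far <- c(3, -2) + (med$r_cutoff + 10) * c(1, 0)
  expect_equal(dipole_flow(dip, far, med), c(0, 0))
})

test_that("dipole length follows the cell geometry", {
  expect_identical(dipole_length(2, 10), 6)
  expect_identical(dipole_length(4, 10), 7)
})
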
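# Shared fixtures: textured movies, independent oracles.

stamp_gaussians <- function(W, H, px, py, amp, sig = 1.5, theta = NULL) {
  n <- length(px)
  if (is.null(theta)) theta <- numeric(n)
  getFromNamespace("cpp_stamp_gaussians", "chemoflow")(
    W, H, px, py, rep_len(amp, n), rep_len(sig, n), rep_len(sig, n), theta)
}

# dense random blob texture rigidly translating at (vx, vy) px/frame
translating_stack <- function(W = 96, nT = 60, v = c(0.3, -0.2), n = 1500,
                              seed = 4, background = 10) {
  set.seed(seed)
  px0 <- runif(n, 0, W); py0 <- runif(n, 0, W); amp <- runif(n, 15, 45)
  fr <- array(0, c(W, W, nT))
  for (t in seq_len(nT))
    fr[, , t] <- background + stamp_gaussians(W, W, (px0 + v[1] * (t - 1)) %% W,
                                              (py0 + v[2] * (t - 1)) %% W, amp)
  image_stack(fr, px_size = 1.4, frame_rate = 100)
}

# independent PIV oracle: full-frame cross-correlation peak between two
# frames, parabolic sub-pixel interpolation
piv_displacement <- function(f1, f2) {
  W <- nrow(f1)
  f1 <- f1 - mean(f1); f2 <- f2 - mean(f2)
  cc <- Re(fft(fft(f2) * Conj(fft(f1)), inverse = TRUE))
  pk <- which(cc == max(cc), arr.ind = TRUE)[1, ]
  sub <- function(m, i, j) m[(i - 1) %% W + 1, (j - 1) %% W + 1]
  par1d <- function(cm, c0, cp) {
    d <- (cm - cp) / (2 * (cm - 2 * c0 + cp))
    if (!is.finite(d)) 0 else d
  }
  dy <- pk[1] - 1; dx <- pk[2] - 1
  dx <- dx + par1d(sub(cc, pk[1], pk[2] - 1), cc[pk[1], pk[2]],
                   sub(cc, pk[1], pk[2] + 1))
  dy <- dy + par1d(sub(cc, pk[1] - 1, pk[2]), cc[pk[1], pk[2]],
                   sub(cc, pk[1] + 1, pk[2]))
  if (dx > W / 2) dx <- dx - W
  if (dy > W / 2) dy <- dy - W
  c(dx, dy)
}

# single-rod state row
rod_state <- function(x, y, theta, v = 20, motor = 1L, m = 4) {
  data.frame(x = x, y = y, unwrapped_x = x, theta = theta, v_i = v,
             motor = motor, m = m, activity = 1 / 3, time_in_state = 0)
}

# quiet pathway (effectively no tumbling) for deterministic dynamics tests
quiet_pathway <- function() pathway_params(lambda0 = 1e-12)

# brute-force spherocylinder distance by dense point sampling on both axes
segseg_bruteforce <- function(c1, th1, c2, th2, L, e, n_pts = 2001) {
  a <- (L - e) / 2
  s <- seq(-a, a, length.out = n_pts)
  p1 <- cbind(c1[1] + s * cos(th1), c1[2] + s * sin(th1))
  p2 <- cbind(c2[1] + s * cos(th2), c2[2] + s * sin(th2))
  min(sqrt(outer(p1[, 1], p2[, 1], "-")^2 + outer(p1[, 2], p2[, 2], "-")^2))
}

# modified Bessel K_n via the integral representation (independent of
# besselK), for kernel oracles
bessel_k_int <- function(z, n) {
  integrate(function(t) exp(-z * cosh(t)) * cosh(n * t), 0, 30,
            rel.tol = 1e-12)$value
}
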
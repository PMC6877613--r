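## Generators for all synthetic inputs the analyses assume: run-and-tumble
## swimmer trajectories (2D/3D, Schulz speeds, non-motile fraction),
## microscopy-like rendered image stacks, reference velocity fields
## (Taylor-Green vortex arrays) and quasi-static 1D attractant gradients.

#' Swimmer ensemble specification
#'
#' The generative counterpart of the population the DDM model assumes:
#' a fraction \code{alpha} of ballistic swimmers with Schulz-distributed
#' speeds (mean \code{v0_mean}, width \code{v0_mean/sqrt(Z+1)}), subject to
#' rotational diffusion and Poisson tumbles (uniform reorientation in 3D,
#' diffusive kicks of variance \code{2 D_T tau_kick} in 2D), the rest
#' Brownian with diffusivity \code{D}. The default ensemble is non-tumbling
#' and non-wiggling (\code{tumble_rate = 0}, \code{D_r = 0}) because the
#' swimmer ISF model describes straight isotropic runs.
#'
#' @param n number of particles.
#' @param dimension 2 or 3.
#' @param v0_mean mean swimming speed (um/s).
#' @param Z Schulz parameter.
#' @param alpha motile fraction in [0, 1].
#' @param D thermal diffusivity of non-motile particles (um^2/s).
#' @param tumble_rate Poisson tumble rate (1/s).
#' @param D_r rotational diffusion (rad^2/s).
#' @param D_T,tau_kick tumble kick parameters (2D only).
#' @param box periodic box side (um).
#' @param duration,dt total time and step (s).
#' @param seed RNG seed.
#' @export
swimmer_spec <- function(n = 200, dimension = 3, v0_mean = 20, Z = 10,
                         alpha = 0.7, D = 0.4, tumble_rate = 0, D_r = 0,
                         D_T = 10.6, tau_kick = 0.12, box = 179.2,
                         duration = 20, dt = 0.01, seed = 1L) {
  stopifnot(n >= 1, dimension %in% c(2, 3), alpha >= 0, alpha <= 1, Z > 0,
            D >= 0, duration > 0, dt > 0)
  structure(list(n = as.integer(n), dimension = dimension,
                 v0_mean = v0_mean, Z = Z, alpha = alpha, D = D,
                 tumble_rate = tumble_rate, D_r = D_r, D_T = D_T,
                 tau_kick = tau_kick, box = box, duration = duration,
                 dt = dt, seed = as.integer(seed)),
            class = "swimmer_spec")
}

#' Generate run-and-tumble swimmer trajectories
#'
#' Motile particles keep a quenched speed drawn from the Schulz (Gamma)
#' distribution with shape \code{Z + 1} and mean \code{v0_mean}; directions
#' evolve by rotational diffusion and tumble events. Non-motile particles
#' are pure Brownian walkers. Positions are unwrapped (wrap with
#' \code{x %% box} when rendering).
#'
#' @param spec a [swimmer_spec()].
#' @return list with \code{times}, position arrays \code{x}, \code{y} (and
#'   \code{z} in 3D; time x particle), \code{speed}, logical \code{motile},
#'   and the spec.
#' @export
generate_swimmers <- function(spec) {
  set.seed(spec$seed)
  n <- spec$n; dt <- spec$dt
  nT <- round(spec$duration / dt) + 1
  motile <- seq_len(n) <= round(spec$alpha * n)
  speed <- numeric(n)
  speed[motile] <- rgamma(sum(motile), shape = spec$Z + 1,
                          scale = spec$v0_mean / (spec$Z + 1))
  x <- matrix(0, nT, n); y <- matrix(0, nT, n)
  z <- if (spec$dimension == 3) matrix(0, nT, n) else NULL
  x[1, ] <- runif(n, 0, spec$box); y[1, ] <- runif(n, 0, spec$box)
  if (!is.null(z)) z[1, ] <- runif(n, 0, spec$box)
  nm <- which(!motile); mo <- which(motile)
  if (spec$dimension == 2) {
    th <- runif(n, -pi, pi)
    for (t in 2:nT) {
      x[t, ] <- x[t - 1, ]; y[t, ] <- y[t - 1, ]
      if (length(mo)) {
        x[t, mo] <- x[t, mo] + speed[mo] * cos(th[mo]) * dt
        y[t, mo] <- y[t, mo] + speed[mo] * sin(th[mo]) * dt
        th[mo] <- th[mo] + sqrt(2 * spec$D_r * dt) * rnorm(length(mo))
        tb <- mo[runif(length(mo)) < spec$tumble_rate * dt]
        if (length(tb))
          th[tb] <- th[tb] + sqrt(2 * spec$D_T * spec$tau_kick) *
            rnorm(length(tb))
      }
      if (length(nm)) {
        s <- sqrt(2 * spec$D * dt)
        x[t, nm] <- x[t, nm] + s * rnorm(length(nm))
        y[t, nm] <- y[t, nm] + s * rnorm(length(nm))
      }
    }
  } else {
    ## 3D: unit direction vectors, rotational diffusion as Gaussian kicks
    ## transverse to the current direction; tumbles draw a fresh isotropic
    ## direction.
    dir <- matrix(rnorm(3 * n), n, 3)
    dir <- dir / sqrt(rowSums(dir^2))
    for (t in 2:nT) {
      x[t, ] <- x[t - 1, ]; y[t, ] <- y[t - 1, ]; z[t, ] <- z[t - 1, ]
      if (length(mo)) {
        x[t, mo] <- x[t, mo] + speed[mo] * dir[mo, 1] * dt
        y[t, mo] <- y[t, mo] + speed[mo] * dir[mo, 2] * dt
        z[t, mo] <- z[t, mo] + speed[mo] * dir[mo, 3] * dt
        if (spec$D_r > 0) {
          kick <- sqrt(2 * spec$D_r * dt) * matrix(rnorm(2 * length(mo)),
                                                   length(mo), 2)
          dir[mo, ] <- .rotate_transverse(dir[mo, , drop = FALSE], kick)
        }
        tb <- mo[runif(length(mo)) < spec$tumble_rate * dt]
        if (length(tb)) {
          nd <- matrix(rnorm(3 * length(tb)), length(tb), 3)
          dir[tb, ] <- nd / sqrt(rowSums(nd^2))
        }
      }
      if (length(nm)) {
        s <- sqrt(2 * spec$D * dt)
        x[t, nm] <- x[t, nm] + s * rnorm(length(nm))
        y[t, nm] <- y[t, nm] + s * rnorm(length(nm))
        z[t, nm] <- z[t, nm] + s * rnorm(length(nm))
      }
    }
  }
  out <- list(times = (seq_len(nT) - 1) * dt, x = x, y = y, z = z,
              speed = speed, motile = motile, spec = spec)
  class(out) <- "swimmer_trajectories"
  out
}

## small transverse Gaussian kicks on unit vectors (3D rotational diffusion)
.rotate_transverse <- function(dir, kick) {
  n <- nrow(dir)
  ## orthonormal frame (e1, e2) transverse to dir
  ref <- cbind(rep(1, n), 0, 0)
  swap <- abs(dir[, 1]) > 0.9
  ref[swap, ] <- matrix(c(0, 1, 0), sum(swap), 3, byrow = TRUE)
  e1 <- ref - dir * rowSums(ref * dir)
  e1 <- e1 / sqrt(rowSums(e1^2))
  e2 <- cbind(dir[, 2] * e1[, 3] - dir[, 3] * e1[, 2],
              dir[, 3] * e1[, 1] - dir[, 1] * e1[, 3],
              dir[, 1] * e1[, 2] - dir[, 2] * e1[, 1])
  nd <- dir + e1 * kick[, 1] + e2 * kick[, 2]
  nd / sqrt(rowSums(nd^2))
}

#' Rendering specification for synthetic image stacks
#'
#' @param px_size pixel size (um).
#' @param width,height frame size (px).
#' @param frame_rate frames per second.
#' @param psf_sigma Gaussian spot width (px).
#' @param amplitude particle peak intensity.
#' @param background constant background level.
#' @param noise_sd additive Gaussian noise SD.
#' @param poisson also apply Poisson (shot) noise.
#' @param elongated render anisotropic spots aligned with motion/orientation.
#' @param aspect parallel/perpendicular spot width ratio when elongated.
#' @export
render_spec <- function(px_size = 1.4, width = 128, height = 128,
                        frame_rate = 100, psf_sigma = 1.5, amplitude = 50,
                        background = 10, noise_sd = 1, poisson = FALSE,
                        elongated = FALSE, aspect = 2) {
  stopifnot(psf_sigma > 0, width >= 64, height >= 64)
  structure(list(px_size = px_size, width = as.integer(width),
                 height = as.integer(height), frame_rate = frame_rate,
                 psf_sigma = psf_sigma, amplitude = amplitude,
                 background = background, noise_sd = noise_sd,
                 poisson = poisson, elongated = elongated, aspect = aspect),
            class = "render_spec")
}

#' Render trajectories into a microscopy-like image stack
#'
#' Each particle is drawn as a (possibly anisotropic) Gaussian spot with
#' periodic wrapping, additive on a constant background; noise is applied
#' last. 3D trajectories are projected onto the xy plane with z-independent
#' amplitude (thin slab). Frames are sampled from the trajectory times at
#' the rendering frame rate.
#'
#' @param traj a \code{swimmer_trajectories} (or any list with \code{times}
#'   and time x particle \code{x}, \code{y} position matrices, in um).
#' @param spec a [render_spec()].
#' @param theta optional time x particle orientation matrix for elongated
#'   rendering (defaults to the direction of motion).
#' @return an [image_stack()].
#' @export
render_stack <- function(traj, spec = render_spec(), theta = NULL) {
  dt_frame <- 1 / spec$frame_rate
  t_end <- max(traj$times)
  ft <- seq(0, t_end, by = dt_frame)
  it <- vapply(ft, function(t) which.min(abs(traj$times - t)), 1L)
  nT <- length(it)
  frames <- array(0, c(spec$height, spec$width, nT))
  n <- ncol(traj$x)
  sig_par <- rep(spec$psf_sigma * if (spec$elongated) spec$aspect else 1, n)
  sig_perp <- rep(spec$psf_sigma, n)
  amp <- rep(spec$amplitude, n)
  for (k in seq_len(nT)) {
    i <- it[k]
    px <- (traj$x[i, ] %% (spec$width * spec$px_size)) / spec$px_size
    py <- (traj$y[i, ] %% (spec$height * spec$px_size)) / spec$px_size
    th <- if (spec$elongated) {
      if (!is.null(theta)) theta[i, ]
      else if (i > 1) atan2(traj$y[i, ] - traj$y[i - 1, ],
                            traj$x[i, ] - traj$x[i - 1, ])
      else numeric(n)
    } else numeric(n)
    frames[, , k] <- spec$background +
      cpp_stamp_gaussians(spec$width, spec$height, px, py, amp,
                          sig_par, sig_perp, th)
  }
  if (spec$poisson)
    frames[] <- rpois(length(frames), pmax(frames, 0))
  if (spec$noise_sd > 0)
    frames <- frames + rnorm(length(frames), 0, spec$noise_sd)
  image_stack(frames, px_size = spec$px_size, frame_rate = spec$frame_rate)
}

#' Taylor-Green vortex array
#'
#' \code{u = A (sin(kx) cos(ky), -cos(kx) sin(ky))} with \code{k = pi/ell}:
#' a divergence-free array of counter-rotating eddies of size \code{ell},
#' the reference fixture for spectral peak analysis.
#'
#' @param ell vortex size (um).
#' @param amplitude velocity scale (um/s).
#' @param grid_side box side (um); must be a multiple of \code{2 ell}.
#' @param spacing grid spacing (um).
#' @param n_frames identical frames to emit.
#' @return a [velocity_field()].
#' @export
vortex_field <- function(ell, amplitude = 10, grid_side = 4 * ell,
                         spacing = 1, n_frames = 1) {
  if (abs(grid_side / (2 * ell) - round(grid_side / (2 * ell))) > 1e-9)
    stop("grid_side must be a multiple of 2*ell")
  k <- pi / ell
  g <- seq(0, grid_side - spacing, by = spacing)
  ux <- outer(sin(k * g), cos(k * g))
  uy <- outer(-cos(k * g), sin(k * g))
  vx <- array(rep(amplitude * ux, n_frames), c(dim(ux), n_frames))
  vy <- array(rep(amplitude * uy, n_frames), c(dim(uy), n_frames))
  velocity_field(vx, vy, spacing)
}

#' Attractant gradient specification
#'
#' Quasi-static linear gradient between two reservoirs (defaults: 0 to
#' 200 uM MeAsp over a 2 mm channel, ligand diffusivity 500 um^2/s).
#'
#' @param c_left,c_right reservoir concentrations (uM).
#' @param channel_length channel length (um).
#' @param D_ligand ligand diffusivity (um^2/s).
#' @param dx spatial grid spacing for the relaxation solver (um).
#' @param v_f advective fluid speed scale used for Peclet estimates (um/s).
#' @export
gradient_spec <- function(c_left = 0, c_right = 200, channel_length = 2000,
                          D_ligand = 500, dx = 10, v_f = 10) {
  stopifnot(c_left >= 0, c_right >= 0, channel_length > 0, D_ligand > 0)
  structure(list(c_left = c_left, c_right = c_right,
                 channel_length = channel_length, D_ligand = D_ligand,
                 dx = dx, v_f = v_f),
            class = "gradient_spec")
}

#' Transient 1D gradient profile
#'
#' Solves the 1D diffusion equation with Dirichlet reservoir boundary
#' conditions by explicit finite differences (automatic sub-stepping keeps
#' the scheme within the CFL limit), starting from a uniform concentration
#' \code{c_left}. The steady state is the linear profile.
#'
#' @param spec a [gradient_spec()].
#' @param t time since gradient initiation (s); \code{Inf} gives the steady
#'   state.
#' @return data frame with \code{x} (um) and \code{c} (uM).
#' @export
gradient_profile <- function(spec, t) {
  stopifnot(t >= 0)
  x <- seq(0, spec$channel_length, by = spec$dx)
  if (!is.finite(t)) {
    cc <- spec$c_left + (spec$c_right - spec$c_left) * x / spec$channel_length
    return(data.frame(x = x, c = cc))
  }
  cc <- rep(spec$c_left, length(x))
  cc[1] <- spec$c_left; cc[length(x)] <- spec$c_right
  if (t > 0) {
    dt_cfl <- 0.4 * spec$dx^2 / spec$D_ligand
    n_sub <- ceiling(t / dt_cfl)
    dt <- t / n_sub
    r <- spec$D_ligand * dt / spec$dx^2
    n <- length(x)
    for (s in seq_len(n_sub)) {
      cc_new <- cc
      cc_new[2:(n - 1)] <- cc[2:(n - 1)] +
        r * (cc[1:(n - 2)] - 2 * cc[2:(n - 1)] + cc[3:n])
      cc <- cc_new
      cc[1] <- spec$c_left; cc[n] <- spec$c_right # exact boundary values
    }
  }
  data.frame(x = x, c = cc)
}

#' Peclet number of attractant stirring
#'
#' \code{Pe = h v_f / D}: advective vs diffusive ligand transport across an
#' eddy spanning the channel height.
#'
#' @param spec a [gradient_spec()] (supplies \code{D_ligand} and the default
#'   \code{v_f}).
#' @param h channel height (um).
#' @param v_f fluid velocity scale (um/s); defaults to the spec value.
#' @export
peclet <- function(spec, h, v_f = NULL) {
  if (is.null(v_f)) v_f <- spec$v_f
  stopifnot(h > 0, spec$D_ligand > 0, v_f >= 0)
  h * v_f / spec$D_ligand
}
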
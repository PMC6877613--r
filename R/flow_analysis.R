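## Collective-flow and chemotaxis statistics: coarse-grained velocity fields,
## the velocity-normalized kinetic-energy structure factor E(q), its peak
## (vortex size pi/q_str and amplitude Delta E), cell-velocity
## autocorrelations and decorrelation time, chemotactic drift, and the
## analytic sensing-time theory for non-interacting swimmers.

#' Coarse-grained velocity field from rod trajectories
#'
#' Gaussian-kernel-weighted mean of rod velocities on a square grid
#' (mirroring experimental velocimetry that averages over a few neighbouring
#' cells). Nodes without any kernel weight are set to zero and flagged.
#'
#' @param traj a \code{rod_trajectories}.
#' @param spacing grid spacing (um).
#' @param sigma kernel width (um).
#' @param times times (s) at which to evaluate (default: all saved frames).
#' @return an object of class \code{velocity_field}: arrays \code{vx},
#'   \code{vy} (nx x ny x nt), \code{weight}, grid coordinates, spacing,
#'   field-of-view area \code{A0} and \code{times}.
#' @export
coarse_grain_velocity <- function(traj, spacing = 2, sigma = 2.5,
                                  times = NULL) {
  box <- traj$config$box_side
  idx <- if (is.null(times)) seq_along(traj$times) else
    vapply(times, function(t) which.min(abs(traj$times - t)), 1L)
  ng <- round(box / spacing)
  gx <- (seq_len(ng) - 1) * spacing
  vxf <- array(0, c(ng, ng, length(idx)))
  vyf <- array(0, c(ng, ng, length(idx)))
  wf <- array(0, c(ng, ng, length(idx)))
  cut <- 3 * sigma
  for (kk in seq_along(idx)) {
    it <- idx[kk]
    px <- traj$x[it, ]; py <- traj$y[it, ]
    vx <- traj$vx[it, ]; vy <- traj$vy[it, ]
    VX <- matrix(0, ng, ng); VY <- matrix(0, ng, ng); W <- matrix(0, ng, ng)
    for (p in seq_along(px)) {
      ix <- which(abs(.pimage(gx - px[p], box)) <= cut)
      iy <- which(abs(.pimage(gx - py[p], box)) <= cut)
      if (!length(ix) || !length(iy)) next
      wx <- exp(-.pimage(gx[ix] - px[p], box)^2 / (2 * sigma^2))
      wy <- exp(-.pimage(gx[iy] - py[p], box)^2 / (2 * sigma^2))
      wmat <- outer(wx, wy)
      VX[ix, iy] <- VX[ix, iy] + wmat * vx[p]
      VY[ix, iy] <- VY[ix, iy] + wmat * vy[p]
      W[ix, iy] <- W[ix, iy] + wmat
    }
    nz <- W > 0
    VX[nz] <- VX[nz] / W[nz]; VY[nz] <- VY[nz] / W[nz]
    vxf[, , kk] <- VX; vyf[, , kk] <- VY; wf[, , kk] <- W
  }
  structure(list(vx = vxf, vy = vyf, weight = wf, grid = gx,
                 spacing = spacing, A0 = box^2, times = traj$times[idx]),
            class = "velocity_field")
}

#' Build a velocity field object from raw arrays
#'
#' @param vx,vy velocity components: matrices (single frame) or
#'   nx x ny x nt arrays (um/s).
#' @param spacing grid spacing (um).
#' @param times frame times (s).
#' @export
velocity_field <- function(vx, vy, spacing, times = NULL) {
  if (length(dim(vx)) == 2) { vx <- array(vx, c(dim(vx), 1)); vy <- array(vy, c(dim(vy), 1)) }
  stopifnot(all(dim(vx) == dim(vy)), all(is.finite(vx)), all(is.finite(vy)))
  if (is.null(times)) times <- seq_len(dim(vx)[3])
  structure(list(vx = vx, vy = vy, weight = array(1, dim(vx)),
                 grid = (seq_len(dim(vx)[1]) - 1) * spacing,
                 spacing = spacing, A0 = prod(dim(vx)[1:2]) * spacing^2,
                 times = times),
            class = "velocity_field")
}

#' Flow structure factor E(q)
#'
#' Velocity-normalized 2D kinetic-energy spectrum
#' \deqn{E(q) = q \langle |\tilde v(q,t)|^2 / (A_0 \langle v^2\rangle)
#'   \rangle_{t, |q| = q},}
#' annularly averaged over wave-vector magnitude and frames, then
#' renormalized so that \code{sum(E) * dq = 1} (declared convention; only
#' the relative spectral structure is used downstream). \code{E(q)} measures
#' the probability of observing a flow structure ("vortex") of size
#' \code{pi/q}.
#'
#' @param field a \code{velocity_field}.
#' @return object of class \code{flow_spectrum}: \code{q} (um^-1), \code{E}
#'   (um), \code{dq}, \code{n_frames}.
#' @export
flow_structure_factor <- function(field) {
  d <- dim(field$vx)
  nx <- d[1]; nt <- d[3]
  msq <- mean(field$vx^2 + field$vy^2)
  if (msq == 0) stop("all-zero velocity field: <v^2> = 0")
  box <- nx * field$spacing
  dq <- 2 * pi / box
  ## annulus index for each mode
  kx <- c(0:(nx %/% 2), -((nx - (nx %/% 2 + 1)):1)) * dq
  qmag <- sqrt(outer(kx^2, kx^2, "+"))
  bin <- pmax(1L, as.integer(round(qmag / dq)))
  nbin <- nx %/% 2
  acc <- numeric(nbin)
  sel <- which(bin <= nbin)
  sp <- split(sel, bin[sel])
  bvals <- as.integer(names(sp))
  cnt <- numeric(nbin); cnt[bvals] <- lengths(sp)
  h2 <- field$spacing^2 # DFT -> continuous FT normalization
  for (it in seq_len(nt)) {
    pw <- (Mod(fft(field$vx[, , it]))^2 + Mod(fft(field$vy[, , it]))^2) * h2^2
    acc[bvals] <- acc[bvals] + vapply(sp, function(ii) sum(pw[ii]), numeric(1))
  }
  q <- (seq_len(nbin)) * dq
  E <- q * (acc / (nt * pmax(cnt, 1))) / (field$A0 * msq)
  E <- E / (sum(E) * dq)
  structure(list(q = q, E = E, dq = dq, n_frames = nt), class = "flow_spectrum")
}

#' Flow structure factor directly from rod velocities
#'
#' Gridless estimator: the Fourier sum \code{v~(q) = sum_j v_j exp(-i q r_j)}
#' over integer box modes, annularly averaged and normalized like
#' [flow_structure_factor()]. Unlike the coarse-grained route it carries no
#' smoothing-kernel transfer function, so weak spectral structure (e.g. of
#' steric-only suspensions) is not masked by the kernel envelope; an
#' uncorrelated suspension gives a featureless (flat-power) spectrum.
#'
#' @param traj a \code{rod_trajectories}.
#' @param t_min discard frames before this time (s).
#' @param q_max largest wavenumber (um^-1).
#' @param subtract_self remove the incoherent (self) contribution
#'   \code{N <v^2>}, leaving the distinct part that vanishes for
#'   uncorrelated swimmers (default TRUE). The spectrum is then normalized
#'   on its positive part.
#' @return a \code{flow_spectrum}.
#' @export
flow_structure_factor_direct <- function(traj, t_min = 0, q_max = 1,
                                         subtract_self = TRUE) {
  keep <- which(traj$times >= t_min)
  box <- traj$config$box_side
  kmax <- max(2L, as.integer(floor(q_max * box / (2 * pi))))
  res <- cpp_velocity_spectrum(traj$x[keep, , drop = FALSE],
                               traj$y[keep, , drop = FALSE],
                               traj$vx[keep, , drop = FALSE],
                               traj$vy[keep, , drop = FALSE],
                               box, kmax)
  msq <- mean(traj$vx[keep, ]^2 + traj$vy[keep, ]^2)
  if (msq == 0) stop("all-zero velocities")
  pw <- res$power / pmax(res$count, 1)
  if (subtract_self) pw <- pw - ncol(traj$x) * msq
  q <- seq_len(kmax) * res$dq
  E <- q * pw / (box^2 * msq)
  pos <- sum(pmax(E, 0)) * res$dq
  if (pos > 0) E <- E / pos # else: no coherent power at all; leave raw
  structure(list(q = q, E = E, dq = res$dq, n_frames = length(keep)),
            class = "flow_spectrum")
}

#' Spectral peak analysis
#'
#' Locates the spectral peak \code{q_max} (excluding the lowest-q bin), and
#' the collective-motion amplitude \code{Delta E(q_str) = E(q_str) -
#' E_baseline(q_str)}, where \code{q_str} is either supplied (frozen from the
#' densest member of an analysis set) or taken equal to \code{q_max}. When no
#' baseline spectrum is given, a flat noise floor estimated from the upper
#' third of the q range is used.
#'
#' @param spectrum a \code{flow_spectrum}.
#' @param baseline optional matched low-density \code{flow_spectrum}.
#' @param q_str optional frozen peak wavenumber (um^-1).
#' @return list with \code{q_max}, \code{E_at_max}, \code{q_str},
#'   \code{deltaE}, \code{vortex_size} (= pi/q_str) and a \code{flag} for
#'   edge peaks.
#' @export
peak_analysis <- function(spectrum, baseline = NULL, q_str = NULL) {
  q <- spectrum$q; E <- spectrum$E
  usable <- seq_along(q) > 1 # exclude the q = dq bin
  imax <- which(usable)[which.max(E[usable])]
  flag <- if (imax == length(q)) "edge" else "ok"
  if (is.null(q_str)) q_str <- q[imax]
  istr <- which.min(abs(q - q_str))
  Eb <- if (!is.null(baseline)) {
    stopifnot(length(baseline$E) == length(E))
    baseline$E[istr]
  } else {
    mean(E[q > 2 / 3 * max(q)])
  }
  list(q_max = q[imax], E_at_max = E[imax], q_str = q[istr],
       deltaE = E[istr] - Eb, vortex_size = pi / q[istr], flag = flag)
}

#' Cell-velocity autocorrelation and decorrelation time
#'
#' \code{C_v(t) = <v_i(t + t0) . v_i(t0)> / <v_i^2>} averaged over rods and
#' time origins; the decorrelation time solves \code{C_v(tau_dec) = 0.5} by
#' linear interpolation between the bracketing lags (sentinel \code{NA} with
#' a warning when no crossing exists).
#'
#' @param traj a \code{rod_trajectories}, or a list with matrices \code{vx},
#'   \code{vy} (time x particle) and \code{times}.
#' @param t_min discard samples before this time (s).
#' @param max_lag maximum lag (s; default half the usable series).
#' @return object of class \code{autocorr_result}: \code{lags}, \code{C_v},
#'   \code{tau_dec}.
#' @export
velocity_autocorrelation <- function(traj, t_min = 0, max_lag = NULL) {
  if (length(traj$times) < 100) stop("need at least 100 time samples")
  keep <- traj$times >= t_min
  if (sum(keep) < 10) stop("fewer than 10 samples left after t_min")
  vx <- traj$vx[keep, , drop = FALSE]; vy <- traj$vy[keep, , drop = FALSE]
  times <- traj$times[keep]
  dt <- median(diff(times))
  nT <- nrow(vx)
  nlag <- if (is.null(max_lag)) nT %/% 2 else min(nT - 1, round(max_lag / dt))
  norm <- mean(vx^2 + vy^2)
  Cv <- numeric(nlag + 1)
  Cv[1] <- 1
  for (k in seq_len(nlag)) {
    i1 <- seq_len(nT - k)
    Cv[k + 1] <- mean(vx[i1, ] * vx[i1 + k, ] + vy[i1, ] * vy[i1 + k, ]) / norm
  }
  lags <- (0:nlag) * dt
  tau_dec <- NA_real_
  below <- which(Cv < 0.5)
  if (length(below) == 0) {
    warning("C_v never crosses 0.5 within the lag range; tau_dec = NA")
  } else {
    ib <- below[1]
    ia <- ib - 1
    tau_dec <- lags[ia] + (0.5 - Cv[ia]) * (lags[ib] - lags[ia]) /
      (Cv[ib] - Cv[ia])
  }
  structure(list(lags = lags, C_v = Cv, tau_dec = tau_dec),
            class = "autocorr_result")
}

#' Chemotactic drift statistics
#'
#' Population drift up the gradient (+x): \code{v_d} is the mean unwrapped-x
#' displacement rate over rods and time (after discarding the transient),
#' the chemotactic velocity is \code{v_ch = v_d / alpha} (correcting for a
#' non-motile fraction alpha), and the chemotactic coefficient is
#' \code{v_ch / v0^2} with \code{v0} the mean instantaneous speed.
#'
#' @param traj a \code{rod_trajectories}.
#' @param alpha motile fraction in (0, 1].
#' @param t_burn transient discarded from the start of the run (s).
#' @return list with \code{v_d}, \code{v_ch}, \code{v0}, \code{coefficient},
#'   \code{alpha}.
#' @export
chemotactic_drift <- function(traj, alpha = 1, t_burn = 20) {
  if (alpha <= 0 || alpha > 1) stop("alpha must be in (0, 1]")
  keep <- traj$times >= t_burn
  if (sum(keep) < 2) stop("no samples after transient discard")
  ux <- traj$unwrapped_x[keep, , drop = FALSE]
  tt <- traj$times[keep]
  v_d <- mean((ux[nrow(ux), ] - ux[1, ]) / (tt[length(tt)] - tt[1]))
  v0 <- mean(sqrt(traj$vx[keep, ]^2 + traj$vy[keep, ]^2))
  v_ch <- v_d / alpha
  list(v_d = v_d, v_ch = v_ch, v0 = v0, coefficient = v_ch / v0^2,
       alpha = alpha)
}

#' Directional sensing time of a run-and-tumble chemotactic swimmer
#'
#' \deqn{\tau = \frac{\tau_R}{\tau_R + \tau_T}\;
#'   \frac{\tau_T}{1 + \tau_T/\tau_R + \tau_T/\tau_m}}
#' combining the memory time \code{tau_m}, the tumble reorientation time
#' \code{tau_T} and the Brownian reorientation time \code{tau_R}.
#'
#' @param tau_m,tau_T,tau_R time scales (s), all positive.
#' @export
sensing_time <- function(tau_m, tau_T, tau_R) {
  stopifnot(all(tau_m > 0), all(tau_T > 0), all(tau_R > 0))
  (tau_R / (tau_R + tau_T)) * tau_T / (1 + tau_T / tau_R + tau_T / tau_m)
}

#' Theory parameter bundle for drift predictions
#'
#' @param gain total pathway gain G (dimensionless per kT).
#' @param tau_m,tau_R,tau_T time scales (s).
#' @param grad_f free-energy gradient (1/um).
#' @param D_T,tau_t tumble diffusion and duration (for bookkeeping).
#' @export
theory_params <- function(gain, tau_m, tau_R, tau_T, grad_f,
                          D_T = 10.6, tau_t = 0.12) {
  stopifnot(tau_m > 0, tau_R > 0, tau_T > 0)
  structure(list(gain = gain, tau_m = tau_m, tau_R = tau_R, tau_T = tau_T,
                 grad_f = grad_f, D_T = D_T, tau_t = tau_t),
            class = "theory_params")
}

#' Predicted chemotactic coefficient
#'
#' Without \code{tau_dec}: \code{v_ch/v0^2 = G tau(tau_m, tau_T, tau_R)
#' grad_f}. With a decorrelation time (which at high density also absorbs
#' collective reorientations):
#' \deqn{v_{ch}/v_0^2 = \frac{\tau_{dec}^2/\tau_T}{1 + \tau_{dec}/\tau_m}
#'   \, G \, \nabla f.}
#' The two forms agree exactly when \code{tau_dec = tau_R tau_T /
#' (tau_R + tau_T)}.
#'
#' @param theory a [theory_params()].
#' @param tau_dec optional decorrelation time(s) (s).
#' @return predicted coefficient (s/um), vectorised over \code{tau_dec}.
#' @export
predicted_coefficient <- function(theory, tau_dec = NULL) {
  if (is.null(tau_dec)) {
    tau <- sensing_time(theory$tau_m, theory$tau_T, theory$tau_R)
    return(theory$gain * tau * theory$grad_f)
  }
  (tau_dec^2 / theory$tau_T) / (1 + tau_dec / theory$tau_m) *
    theory$gain * theory$grad_f
}

#' Write a flow spectrum (and optional baseline) to CSV
#'
#' @param spectrum a \code{flow_spectrum}.
#' @param path output CSV path.
#' @param baseline optional matched baseline \code{flow_spectrum}.
#' @export
write_spectrum <- function(spectrum, path, baseline = NULL) {
  df <- data.frame(q = spectrum$q, E = spectrum$E)
  if (!is.null(baseline)) df$E_baseline <- baseline$E
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
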
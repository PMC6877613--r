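## Image-based motility measurement in Fourier space:
##  - differential dynamic microscopy (DDM): differential image correlation
##    functions g(q, tau), fitted with the Schulz-swimmer intermediate
##    scattering function to extract v0, swimming fraction alpha, D, Z;
##  - phase-differential microscopy: population drift from the phase of the
##    frame-to-frame Fourier correlator, plus a windowed local variant that
##    yields velocity-field maps (equivalent to PIV);
##  - in-situ cell density calibration from the DDM amplitude a1.

#' Grayscale image stack
#'
#' @param frames numeric array (ny x nx x nt) of intensities.
#' @param px_size pixel size (um; default 1.4).
#' @param frame_rate frames per second (default 100).
#' @return object of class \code{image_stack}.
#' @export
image_stack <- function(frames, px_size = 1.4, frame_rate = 100) {
  stopifnot(length(dim(frames)) == 3, dim(frames)[3] >= 2,
            all(is.finite(frames)))
  structure(list(frames = frames, px_size = px_size, frame_rate = frame_rate,
                 mean_intensity = mean(frames)),
            class = "image_stack")
}

## annulus binning shared by DDM (q in px^-1, dq = 2*pi/n)
.annulus_bins <- function(nx, ny) {
  dqx <- 2 * pi / nx; dqy <- 2 * pi / ny
  kx <- c(0:(nx %/% 2), -((nx - (nx %/% 2 + 1)):1)) * dqx
  ky <- c(0:(ny %/% 2), -((ny - (ny %/% 2 + 1)):1)) * dqy
  dq <- min(dqx, dqy)
  qmag <- sqrt(outer(ky^2, kx^2, "+")) # [ky, kx] matches frame orientation
  bin <- as.integer(round(qmag / dq))
  nbin <- min(nx, ny) %/% 2
  sel <- which(bin >= 1 & bin <= nbin)
  sp <- split(sel, bin[sel])
  list(dq = dq, nbin = nbin, sp = sp, bvals = as.integer(names(sp)))
}

#' Differential image correlation function (DDM)
#'
#' \code{g(q, tau) = <|I~(q, t + tau) - I~(q, t)|^2>} averaged over time
#' origins and over annuli of constant \code{|q|}; lags are log-spaced
#' between one frame and a tenth of the movie by default.
#'
#' @param stack an [image_stack()].
#' @param lags integer frame lags (default 30 log-spaced up to T/10).
#' @param n_origins time origins averaged per lag (evenly spaced).
#' @param window apply a Hann window before transforming (for non-periodic
#'   images; synthetic stacks are periodic, so the default is none).
#' @return object of class \code{dicf}: \code{q_px} (px^-1), \code{q_um}
#'   (um^-1), \code{lags} (s), matrix \code{g} (n_q x n_lag).
#' @export
compute_dicf <- function(stack, lags = NULL, n_origins = 64, window = FALSE) {
  fr <- stack$frames
  d <- dim(fr); ny <- d[1]; nx <- d[2]; nT <- d[3]
  ## log-spaced lags up to a fifth of the movie: desk-scale (2000-frame)
  ## movies need the longer branch to resolve the diffusive decay of the
  ## non-motile fraction (with 1e4-frame movies a tenth would suffice)
  if (is.null(lags))
    lags <- sort(unique(round(exp(seq(log(1), log(max(2, nT %/% 5)),
                                      length.out = 30)))))
  stopifnot(max(lags) + 1 <= nT)
  ab <- .annulus_bins(nx, ny)
  win <- if (window) {
    hy <- 0.5 * (1 - cos(2 * pi * seq_len(ny) / ny))
    hx <- 0.5 * (1 - cos(2 * pi * seq_len(nx) / nx))
    outer(hy, hx)
  } else NULL
  g <- matrix(0, ab$nbin, length(lags))
  for (il in seq_along(lags)) {
    lag <- lags[il]
    origins <- unique(round(seq(1, nT - lag, length.out =
                                  min(n_origins, nT - lag))))
    acc <- numeric(ab$nbin)
    for (t0 in origins) {
      dfr <- fr[, , t0 + lag] - fr[, , t0]
      if (!is.null(win)) dfr <- dfr * win
      pw <- Mod(fft(dfr))^2 / (nx * ny)
      acc[ab$bvals] <- acc[ab$bvals] +
        vapply(ab$sp, function(ii) sum(pw[ii]), numeric(1))
    }
    cnt <- numeric(ab$nbin); cnt[ab$bvals] <- lengths(ab$sp)
    g[, il] <- acc / (length(origins) * pmax(cnt, 1))
  }
  q_px <- seq_len(ab$nbin) * ab$dq
  structure(list(q_px = q_px, q_um = q_px / stack$px_size,
                 lags = lags / stack$frame_rate, lag_frames = lags, g = g,
                 px_size = stack$px_size, frame_rate = stack$frame_rate),
            class = "dicf")
}

#' Swimmer intermediate scattering function (Schulz speed distribution)
#'
#' ISF of a population of which a fraction \code{alpha} swims ballistically
#' and isotropically in 3D with Schulz-distributed speeds (mean \code{v0},
#' width \code{sigma_v = v0/sqrt(Z+1)}), the rest diffusing with diffusivity
#' \code{D}:
#' \deqn{f(q,\tau) = e^{-Dq^2\tau}\Big[(1-\alpha) + \alpha\,
#'   \frac{Z+1}{Z q v_0 \tau}\,
#'   \frac{\sin(Z \tan^{-1}\lambda)}{(1+\lambda^2)^{Z/2}}\Big],\quad
#'   \lambda = \frac{q v_0 \tau}{Z+1}.}
#' The \code{sin(Z tan^-1 lambda)} form preserves the normalisation
#' \code{f(q, 0) = 1}.
#'
#' @param q wavenumber (um^-1).
#' @param tau lag time (s), vectorised.
#' @param v0 mean swimming speed (um/s).
#' @param Z Schulz parameter (> 0).
#' @param D diffusivity of non-swimmers (um^2/s).
#' @param alpha swimming fraction in [0, 1].
#' @export
swimmer_isf <- function(q, tau, v0, Z, D, alpha) {
  stopifnot(v0 >= 0, Z > 0, D >= 0, alpha >= 0, alpha <= 1)
  x <- q * v0 * tau
  lam <- x / (Z + 1)
  swim <- ifelse(abs(x) < 1e-8, 1,
                 ((Z + 1) / (Z * x)) * sin(Z * atan(lam)) /
                   (1 + lam^2)^(Z / 2))
  exp(-D * q^2 * tau) * ((1 - alpha) + alpha * swim)
}

#' DDM model for g(q, tau)
#'
#' \code{g = a0 + a1 (1 - f(q, tau))} with \code{f} the swimmer ISF.
#' @keywords internal
.dicf_model <- function(par, q, tau)
  par[1] + par[2] * (1 - swimmer_isf(q, tau, par[3], par[4], par[5], par[6]))

#' Fit the DICF with the swimmer ISF model
#'
#' Per-q nonlinear least squares of \code{g(q, tau) = a0(q) + a1(q) (1 -
#' f(q, tau))}; \code{a0} is initialised from the smallest-lag g, \code{a1}
#' from the large-lag plateau. Bounds: v0 in [2, 100] um/s, Z in [0.5, 500],
#' D in [0, 5] um^2/s, alpha in [0, 1]. Aggregated v0 and alpha are means
#' over the fitted q range.
#'
#' @param dicf a [compute_dicf()] result.
#' @param q_range fit range in px^-1 (default [select_q_range()] for
#'   \code{L}, or 0.4-2.0).
#' @param L cell length (um) used to pick the default q range.
#' @param init optional named list of initial guesses (v0, Z, D, alpha).
#' @param global_refine refine the aggregated parameters by a global fit
#'   with shared (v0, Z, D, alpha) and per-q linear amplitudes; this is what
#'   identifies alpha and D on short movies, where per-q fits only constrain
#'   the product a1*alpha at low q (default TRUE).
#' @return object of class \code{isf_fit}: per-q table \code{by_q} and
#'   aggregated \code{v0}, \code{alpha}, \code{D}, \code{Z}, \code{sigma_v}.
#' @export
fit_dicf <- function(dicf, q_range = NULL, L = NULL, init = list(),
                     global_refine = TRUE) {
  if (is.null(q_range))
    q_range <- if (!is.null(L)) select_q_range(L) else c(0.4, 2.0)
  iq <- which(dicf$q_px >= q_range[1] & dicf$q_px <= q_range[2])
  if (!length(iq)) stop("q_range outside the available grid")
  ini <- modifyList(list(v0 = 15, Z = 10, D = 0.5, alpha = 0.7), init)
  rows <- lapply(iq, function(i) {
    gq_raw <- dicf$g[i, ]
    scale <- max(gq_raw, 1e-300) # fit in normalized units: the result is
    gq <- gq_raw / scale         # then exactly invariant under affine
    a0_0 <- max(min(gq), 1e-12)  # intensity changes of the movie
    a1_0 <- max(max(gq) - a0_0, 1e-12)
    par0 <- c(a0_0, a1_0, ini$v0, ini$Z, ini$D, ini$alpha)
    obj <- function(p) sum((.dicf_model(p, dicf$q_um[i], dicf$lags) - gq)^2)
    ft <- nlminb(par0, obj,
                 lower = c(0, 0, 2, 0.5, 0, 0),
                 upper = c(Inf, Inf, 100, 500, 5, 1),
                 control = list(iter.max = 500, eval.max = 800))
    res <- sqrt(ft$objective / length(gq)) / max(ft$par[2], 1e-12)
    data.frame(q_px = dicf$q_px[i], q_um = dicf$q_um[i],
               a0 = ft$par[1] * scale, a1 = ft$par[2] * scale,
               v0 = ft$par[3], Z = ft$par[4], D = ft$par[5],
               alpha = ft$par[6],
               rms_resid = res, converged = is.finite(res) & res < 0.1)
  })
  by_q <- do.call(rbind, rows)
  ok <- by_q$converged
  if (mean(ok) < 0.7)
    stop("DICF fit failed on ", round(100 * mean(!ok)),
         "% of q bins (allowed: 30%); check q range and lag coverage")
  fit <- list(by_q = by_q, q_range = q_range,
              v0 = mean(by_q$v0[ok]), alpha = mean(by_q$alpha[ok]),
              D = median(by_q$D[ok]), Z = median(by_q$Z[ok]))
  if (global_refine) {
    ## Per-q fits leave (alpha, D) poorly identified wherever D q^2 tau is
    ## small over the lag window (a1*alpha is then the only identified
    ## combination), so the aggregated values are refined by a global fit:
    ## shared (v0, Z, D, alpha), per-q linear (a0, a1).
    gq <- dicf$g[iq, , drop = FALSE]
    scales <- pmax(apply(gq, 1, max), 1e-300)
    qum <- dicf$q_um[iq]
    obj <- function(th) {
      tot <- 0
      for (k in seq_along(iq)) {
        f <- swimmer_isf(qum[k], dicf$lags, th[1], th[2], th[3], th[4])
        X <- cbind(1, 1 - f)
        y <- gq[k, ] / scales[k]
        cf <- tryCatch(qr.coef(qr(X), y), error = function(e) c(0, 1))
        cf[is.na(cf)] <- 0
        cf <- pmax(cf, 0)
        tot <- tot + sum((y - X %*% cf)^2)
      }
      tot
    }
    th0 <- c(fit$v0, fit$Z, max(fit$D, 0.01), min(max(fit$alpha, 0.05), 0.95))
    gf <- nlminb(th0, obj, lower = c(2, 0.5, 0, 0), upper = c(100, 500, 5, 1),
                 control = list(iter.max = 300, eval.max = 500))
    fit$v0 <- gf$par[1]; fit$Z <- gf$par[2]
    fit$D <- gf$par[3]; fit$alpha <- gf$par[4]
    fit$global_objective <- gf$objective
  }
  fit$sigma_v <- fit$v0 / sqrt(fit$Z + 1)
  structure(fit, class = "isf_fit")
}

#' Default DDM q fit range for a given cell length
#'
#' Elongated cells violate the isotropic-image assumption above
#' q = 0.9 px^-1, so their fit range is restricted; normal-length cells use
#' 0.4-2.0 px^-1.
#'
#' @param L cell length (um); 2 and 4 are calibrated, others use the nearest
#'   rule with a warning.
#' @return c(q_lo, q_hi) in px^-1.
#' @export
select_q_range <- function(L) {
  if (isTRUE(all.equal(as.numeric(L), 2))) return(c(0.4, 2.0))
  if (isTRUE(all.equal(as.numeric(L), 4))) return(c(0.4, 0.9))
  warning("no calibrated q range for L = ", L,
          "; using the conservative nearest rule")
  if (abs(L - 2) < abs(L - 4)) c(0.4, 2.0) else c(0.4, 0.9)
}

#' Correct a fitted swimming speed for vertical confinement
#'
#' Confinement biases swimming directions into the plane, inflating the
#' apparent 3D-fitted speed by a calibrated height-dependent factor:
#' 1.0 (h = 50), 1.075 (h = 30), 1.14 (h = 8).
#'
#' @param v0_fitted fitted speed (um/s).
#' @param h channel height (um), one of 8, 30, 50.
#' @export
confinement_correction <- function(v0_fitted, h) {
  fac <- c(`50` = 1.0, `30` = 1.075, `8` = 1.14)[as.character(h)]
  if (is.na(fac)) stop("no confinement calibration for h = ", h)
  unname(v0_fitted / fac)
}

#' Density calibration constants
#'
#' The normalized DDM amplitude saturates with optical density as
#' \code{a1_max/<I>^2 = d0 m OD / (1 + m OD)} (d0 = 1.25 for h in {30, 50};
#' free for h = 8), and the cell body volume fraction is proportional to OD:
#' \code{Phi_c = 1.78e-3 OD} (or \code{pi r^2 L n_c} from a direct count).
#'
#' @param m logistic constant (per OD); system-dependent, must be calibrated
#'   (see [calibrate_amplitude()] for synthetic self-calibration).
#' @param d0 saturation amplitude.
#' @param od_to_phi volume fraction per OD unit.
#' @param r cell radius (um).
#' @param L cell length (um).
#' @export
density_calibration <- function(m, d0 = 1.25, od_to_phi = 1.78e-3,
                                r = 0.5, L = 2) {
  stopifnot(m > 0, d0 > 0, od_to_phi > 0)
  structure(list(m = m, d0 = d0, od_to_phi = od_to_phi, r = r, L = L),
            class = "density_calibration")
}

#' Cell body volume fraction from the DDM amplitude
#'
#' Inverts the logistic amplitude-OD relation; alternatively uses a direct
#' number density when supplied.
#'
#' @param a1_max_norm peak of \code{a1(q)/<I>^2}; must be below the
#'   saturation \code{d0}.
#' @param calib a [density_calibration()].
#' @param n_c optional number density (um^-3); when given,
#'   \code{Phi_c = pi r^2 L n_c} is returned instead.
#' @export
amplitude_to_volume_fraction <- function(a1_max_norm, calib, n_c = NULL) {
  if (!is.null(n_c)) return(pi * calib$r^2 * calib$L * n_c)
  if (any(a1_max_norm < 0)) stop("amplitude must be non-negative")
  if (any(a1_max_norm >= calib$d0))
    stop("amplitude at or above saturation d0; density not identifiable")
  od <- a1_max_norm / (calib$m * (calib$d0 - a1_max_norm))
  calib$od_to_phi * od
}

#' Synthetic self-calibration of the amplitude constant m
#'
#' Fits the logistic amplitude-OD relation on (OD, a1_max_norm) pairs, e.g.
#' measured on rendered stacks of known density.
#'
#' @param od optical densities.
#' @param a1_max_norm matching normalized amplitudes.
#' @param d0 fixed saturation.
#' @return fitted m.
#' @export
calibrate_amplitude <- function(od, a1_max_norm, d0 = 1.25) {
  stopifnot(length(od) == length(a1_max_norm), all(a1_max_norm < d0))
  ## linear in 1/OD: a1/(d0 - a1) = m OD
  y <- a1_max_norm / (d0 - a1_max_norm)
  sum(y * od) / sum(od^2)
}

#' Velocimetry configuration
#'
#' Parameters of the local phase-differential velocimetry: window size
#' \code{a} (px, power of two), lattice spacing \code{da}, Gaussian
#' localization range \code{l}, displacement fit window (frames), and the
#' maximum wavenumber used in the phase fit (default pi/4, keeping the
#' per-frame phase below pi for displacements up to 4 px/frame).
#'
#' The preprocessing applied before the windowed transforms is selectable:
#' \itemize{
#' \item \code{"whiten"} (default): each frame's spectrum is divided by the
#'   time-averaged amplitude spectrum (phase-correlation normalization).
#'   This is what makes the phase fit node-wise equivalent to the PIV
#'   cross-correlation peak: with an unwhitened, decaying texture spectrum,
#'   the window's spectral leakage mixes wavenumbers asymmetrically and
#'   biases the recovered displacement towards lower q (several percent).
#' \item \code{"blur"}: Gaussian low-pass with range \code{l} (reading
#'   "blurred frame" literally), then a plain window.
#' \item \code{"window"}: multiplicative Gaussian localization
#'   \code{exp(-r^2/l^2)} inside the window, the printed form of the
#'   windowed transform. Strongly localized (range l) but noisy per node,
#'   since the localization mixes wavenumbers over ~2/l.
#' }
#'
#' @param a window size (px).
#' @param da lattice spacing (px).
#' @param l Gaussian blur/localization range (px).
#' @param fit_window velocity fit window (frames).
#' @param q_fit_max phase-fit wavenumber cutoff (px^-1).
#' @param localization \code{"whiten"}, \code{"blur"} or \code{"window"}.
#' @export
velocimetry_config <- function(a = 32, da = 4, l = 3, fit_window = 20,
                               q_fit_max = pi / 4,
                               localization = c("whiten", "blur", "window")) {
  stopifnot(a >= 4, bitwAnd(a, a - 1L) == 0, da <= a, l < a / 2,
            fit_window >= 2)
  structure(list(a = as.integer(a), da = as.integer(da), l = l,
                 fit_window = as.integer(fit_window), q_fit_max = q_fit_max,
                 localization = match.arg(localization)),
            class = "velocimetry_config")
}

## Gaussian blur of every frame by convolution with exp(-r^2/l^2)
## (normalized), via the FFT: kernel transform exp(-q^2 l^2 / 4).
.blur_frames <- function(fr, l) {
  ny <- dim(fr)[1]; nx <- dim(fr)[2]
  qy <- c(0:(ny %/% 2), -((ny - (ny %/% 2 + 1)):1)) * (2 * pi / ny)
  qx <- c(0:(nx %/% 2), -((nx - (nx %/% 2 + 1)):1)) * (2 * pi / nx)
  ker <- exp(-outer(qy^2, qx^2, "+") * l^2 / 4)
  for (t in seq_len(dim(fr)[3]))
    fr[, , t] <- Re(fft(fft(fr[, , t]) * ker, inverse = TRUE)) / (nx * ny)
  fr
}

## Spectral whitening: divide each frame's spectrum by the time-mean
## amplitude spectrum (regularized), flattening the texture spectrum.
.whiten_frames <- function(fr, eps_frac = 0.01) {
  ny <- dim(fr)[1]; nx <- dim(fr)[2]; nT <- dim(fr)[3]
  FF <- lapply(seq_len(nT), function(t) fft(fr[, , t]))
  A <- sqrt(Reduce(`+`, lapply(FF, function(f) Mod(f)^2)) / nT)
  eps <- eps_frac * max(A)
  for (t in seq_len(nT))
    fr[, , t] <- Re(fft(FF[[t]] / (A + eps), inverse = TRUE)) / (nx * ny)
  fr
}

## Core phase-differential displacement tracker for one window position.
## sub: a x a x T array, background-subtracted and (usually) whitened or
## blurred upstream. Per frame pair, the phase increments of the correlator
## I(q, t+1) I*(q, t), wrapped to (-pi, pi], are fitted against q
## (weighted, wrap-aware iterative refinement) to give the frame-to-frame
## displacement; only increments are ever used - never absolute phases -
## and their sum is the cumulative displacement r_k(t).
## Returns T x 2 matrix of cumulative displacements (px; first row zero).
.phase_displacements <- function(sub, l, q_fit_max, localize = FALSE) {
  a <- dim(sub)[1]; nT <- dim(sub)[3]
  offs <- (0:(a - 1)) - a / 2
  filt <- if (localize) exp(-outer(offs^2, offs^2, "+") / l^2) else
    matrix(1, a, a)
  qv <- c(0:(a %/% 2), -((a - (a %/% 2 + 1)):1)) * (2 * pi / a)
  qx <- matrix(qv, a, a, byrow = TRUE) # columns = x
  qy <- matrix(qv, a, a)
  sel <- which(sqrt(qx^2 + qy^2) <= q_fit_max & (qx != 0 | qy != 0))
  qxs <- qx[sel]; qys <- qy[sel]
  disp <- matrix(0, nT, 2)
  Fprev <- fft(sub[, , 1] * filt)[sel]
  for (t in 2:nT) {
    Fc <- fft(sub[, , t] * filt)[sel]
    dphi <- Arg(Fc * Conj(Fprev))
    w <- Mod(Fc) * Mod(Fprev)
    Sxx <- sum(w * qxs^2); Sxy <- sum(w * qxs * qys); Syy <- sum(w * qys^2)
    det <- Sxx * Syy - Sxy^2
    bx <- sum(w * qxs * dphi); by <- sum(w * qys * dphi)
    dd <- -c(Syy * bx - Sxy * by, Sxx * by - Sxy * bx) / det
    for (it in 1:2) { # wrap-aware Gauss-Newton refinement
      r <- dphi + qxs * dd[1] + qys * dd[2]
      r <- r - 2 * pi * round(r / (2 * pi))
      bx <- sum(w * qxs * r); by <- sum(w * qys * r)
      dd <- dd - c(Syy * bx - Sxy * by, Sxx * by - Sxy * bx) / det
    }
    disp[t, ] <- disp[t - 1, ] + dd
    Fprev <- Fc
  }
  disp
}

## sliding-window OLS slope of each displacement component
.window_velocity <- function(disp, fit_window) {
  nT <- nrow(disp)
  v <- matrix(NA_real_, nT, 2)
  half <- fit_window %/% 2
  for (t in seq_len(nT)) {
    i0 <- max(1, t - half); i1 <- min(nT, t + half)
    tt <- i0:i1
    tc <- tt - mean(tt)
    denom <- sum(tc^2)
    v[t, ] <- c(sum(tc * disp[tt, 1]), sum(tc * disp[tt, 2])) / denom
  }
  v
}

#' Local phase-differential velocimetry
#'
#' Velocity-field maps from windowed Fourier phases: at each node of a
#' square lattice, a Gaussian-localized windowed DFT is taken per frame
#' (localization range \code{l}); per-frame phase increments of the
#' correlator \code{I(q, t+1) I*(q, t)} are accumulated (never absolute
#' phases - the core trick of the method), fitted against q (weights
#' \code{|I(q)|^2}) to give the cumulative displacement, whose sliding-window
#' slope is the local instantaneous velocity. Equivalent to PIV.
#'
#' @param stack an [image_stack()].
#' @param config a [velocimetry_config()].
#' @return object of class \code{velocimetry_field}: node coordinates
#'   \code{nodes_x}, \code{nodes_y} (px), arrays \code{vx_px}, \code{vy_px}
#'   (nx_nodes x ny_nodes x T, px/frame) and \code{vx}, \code{vy} (um/s).
#' @export
local_velocimetry <- function(stack, config = velocimetry_config()) {
  fr <- stack$frames
  ny <- dim(fr)[1]; nx <- dim(fr)[2]; nT <- dim(fr)[3]
  a <- config$a
  if (a > min(nx, ny)) stop("window size exceeds the frame")
  cx <- seq(a / 2, nx - a / 2, by = config$da)
  cy <- seq(a / 2, ny - a / 2, by = config$da)
  vx_px <- array(NA_real_, c(length(cx), length(cy), nT))
  vy_px <- array(NA_real_, c(length(cx), length(cy), nT))
  ## remove the uniform background (a static additive component would leak
  ## into all windowed modes and pin the phases); nonuniform static
  ## backgrounds should be removed upstream, e.g. by subtracting the
  ## temporal mean image of a long movie
  fr <- fr - mean(fr)
  fr <- switch(config$localization,
               whiten = .whiten_frames(fr),
               blur = .blur_frames(fr, config$l),
               window = fr)
  for (ix in seq_along(cx)) {
    xi <- (cx[ix] - a / 2 + 1):(cx[ix] + a / 2)
    for (iy in seq_along(cy)) {
      yi <- (cy[iy] - a / 2 + 1):(cy[iy] + a / 2)
      disp <- .phase_displacements(fr[yi, xi, , drop = FALSE], config$l,
                                   config$q_fit_max,
                                   localize = config$localization == "window")
      v <- .window_velocity(disp, config$fit_window)
      vx_px[ix, iy, ] <- v[, 1]
      vy_px[ix, iy, ] <- v[, 2]
    }
  }
  s <- stack$px_size * stack$frame_rate
  structure(list(nodes_x = cx, nodes_y = cy, vx_px = vx_px, vy_px = vy_px,
                 vx = vx_px * s, vy = vy_px * s,
                 px_size = stack$px_size, frame_rate = stack$frame_rate,
                 spacing_um = config$da * stack$px_size),
            class = "velocimetry_field")
}

#' Population drift by global phase-differential microscopy
#'
#' Single-window variant of [local_velocimetry()] using the whole frame and
#' no localization filter; returns the intensity-weighted population drift.
#'
#' @param stack an [image_stack()].
#' @param q_fit_max phase-fit cutoff (px^-1).
#' @return list with \code{v_d} (x drift, um/s), \code{v_d_vec_um_s},
#'   \code{v_d_px} (px/frame, both components) and the cumulative
#'   displacement series \code{displacement_px}.
#' @export
phase_diff_drift <- function(stack, q_fit_max = pi / 4) {
  fr <- stack$frames
  ny <- dim(fr)[1]; nx <- dim(fr)[2]
  if (nx != ny) stop("square frames required for the global drift")
  disp <- .phase_displacements(fr, l = 1, q_fit_max = q_fit_max,
                               localize = FALSE)
  nT <- nrow(disp)
  v_px <- disp[nT, ] / (nT - 1)
  s <- stack$px_size * stack$frame_rate
  list(v_d = v_px[1] * s, v_d_vec_um_s = v_px * s, v_d_px = v_px,
       displacement_px = disp)
}

#' Write DICF fit results to CSV
#'
#' @param fit an \code{isf_fit}.
#' @param path output path.
#' @export
write_isf_fit <- function(fit, path) {
  write.csv(fit$by_q, path, row.names = FALSE)
  invisible(path)
}
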
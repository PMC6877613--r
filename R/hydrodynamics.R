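## Quasi-2D (Hele-Shaw) screened point-force hydrodynamics.
##
## Depth-averaging the Stokes equation across a channel of height h yields a
## 2D Brinkman-like equation with screening parameter kappa = 12/h^2; the
## resulting point-force Green's function decays exponentially beyond ~h.
## A swimmer is modelled as a pusher dipole: drag force +F at the cell body
## centre and thrust -F a distance L_dip behind it along the axis.

#' Hele-Shaw medium description
#'
#' Bundles the physical parameters of the depth-averaged quasi-2D fluid.
#' The screening parameter is fixed to \code{kappa = 12/h^2}, so the channel
#' height sets both the strength and the reach of the flow.
#'
#' @param h channel height (micrometres).
#' @param eta dynamic viscosity in pN s/um^2 (1e-3 corresponds to water,
#'   1 mPa s).
#' @param r_clamp minimum evaluation distance (um). The point-force solution
#'   diverges logarithmically at the origin; evaluations below \code{r_clamp}
#'   return the value at \code{r_clamp} (default: half a rod width).
#' @param r_cutoff interaction cutoff (um); defaults to \code{6/sqrt(kappa)},
#'   beyond which the screened kernel is negligible (factor < e^-6).
#' @return an object of class \code{hele_shaw_medium}.
#' @export
hele_shaw_medium <- function(h, eta = 1e-3, r_clamp = 0.5, r_cutoff = NULL) {
  stopifnot(h > 0, eta > 0, r_clamp > 0)
  kappa <- 12 / h^2
  if (is.null(r_cutoff)) r_cutoff <- 6 / sqrt(kappa)
  if (r_clamp >= r_cutoff) stop("r_clamp must be smaller than r_cutoff")
  structure(list(h = h, eta = eta, kappa = kappa,
                 r_clamp = r_clamp, r_cutoff = r_cutoff),
            class = "hele_shaw_medium")
}

## Bessel-function factors of the kernel; z = sqrt(kappa)*|r|.
## c1 -> -1 and c2 -> 2 as z -> Inf; both -> 0 as z -> 0.
hs_c1 <- function(z) z^2 * (besselK(z, 0) + besselK(z, 2)) / 2 - 1
hs_c2 <- function(z) 2 - z^2 * besselK(z, 2)

#' Screened point-force mobility tensor
#'
#' Exact evaluation of the quasi-2D Green's function
#' \deqn{G(r) = [c_1(z) I + c_2(z) \hat r \hat r] / (\pi \eta h \kappa |r|^2),
#'   \quad z = \sqrt{\kappa} |r|,}
#' with \eqn{c_1(z) = z^2 (K_0 + K_2)/2 - 1} and \eqn{c_2(z) = 2 - z^2 K_2}
#' (modified Bessel functions of the second kind). Units: um/s per pN.
#'
#' Distances below \code{medium$r_clamp} are clamped (with a warning for
#' exactly coincident points); the simulator uses a tabulated version of this
#' function, which therefore doubles as its oracle.
#'
#' @param r numeric length-2 separation vector (um), or an n x 2 matrix.
#' @param medium a [hele_shaw_medium()].
#' @return a 2 x 2 mobility tensor, or a list of tensors for matrix input.
#' @export
hele_shaw_kernel <- function(r, medium) {
  if (is.matrix(r)) return(apply(r, 1, hele_shaw_kernel, medium = medium,
                                 simplify = FALSE))
  stopifnot(length(r) == 2)
  rn <- sqrt(sum(r^2))
  if (rn == 0) {
    warning("kernel evaluated at |r| = 0; clamped (exclude self-interactions upstream)")
    r <- c(medium$r_clamp, 0)
    rn <- medium$r_clamp
  } else if (rn < medium$r_clamp) {
    r <- r * (medium$r_clamp / rn)
    rn <- medium$r_clamp
  }
  z <- sqrt(medium$kappa) * rn
  rh <- r / rn
  (hs_c1(z) * diag(2) + hs_c2(z) * tcrossprod(rh)) /
    (pi * medium$eta * medium$h * medium$kappa * rn^2)
}

#' Pusher force dipole
#'
#' The propelled rod drags the fluid with a point force \code{F = gamma_par *
#' v * n} at its centre while the flagellar bundle pushes with \code{-F} at a
#' distance \code{L_dip = L/2 + L_flag/2} behind the centre.
#'
#' @param application_point length-2 position of the drag force (rod centre, um).
#' @param n length-2 unit orientation vector.
#' @param F_mag signed force magnitude along \code{n} (pN).
#' @param L_dip dipole length (um).
#' @return an object of class \code{force_dipole}.
#' @export
force_dipole <- function(application_point, n, F_mag, L_dip) {
  stopifnot(length(application_point) == 2, length(n) == 2, L_dip >= 0)
  nn <- sqrt(sum(n^2))
  if (abs(nn - 1) > 1e-8) {
    if (nn == 0) stop("orientation vector must be non-zero")
    n <- n / nn
  }
  structure(list(application_point = as.numeric(application_point),
                 n = as.numeric(n), F_vector = F_mag * n, L_dip = L_dip),
            class = "force_dipole")
}

#' Dipole length from cell geometry
#'
#' \code{L_dip = L/2 + L_flag/2}: half the body plus half the flagellar
#' bundle. With the default bundle length of 10 um and L = 2 um this gives
#' the literature estimate of ~6 um.
#'
#' @param L cell body length (um).
#' @param L_flag flagellar bundle length (um).
#' @export
dipole_length <- function(L, L_flag = 10) L / 2 + L_flag / 2

#' Flow field of a pusher dipole
#'
#' Superposition of the two screened point-force flows:
#' \code{w(r) = G(r - x_drag) F - G(r - x_thrust) F}, with the thrust applied
#' at \code{x_drag - L_dip * n}.
#'
#' @param source a [force_dipole()].
#' @param eval_point length-2 position, or n x 2 matrix of positions (um).
#' @param medium a [hele_shaw_medium()].
#' @return fluid velocity (um/s), same shape as \code{eval_point}.
#' @export
dipole_flow <- function(source, eval_point, medium) {
  if (is.matrix(eval_point))
    return(t(apply(eval_point, 1, function(p) dipole_flow(source, p, medium))))
  if (source$L_dip == 0) return(c(0, 0)) # forces cancel exactly
  p_drag <- source$application_point
  p_thrust <- p_drag - source$L_dip * source$n
  Fv <- source$F_vector
  u <- c(0, 0)
  r1 <- eval_point - p_drag
  if (sqrt(sum(r1^2)) <= medium$r_cutoff)
    u <- u + drop(hele_shaw_kernel(r1, medium) %*% Fv)
  r2 <- eval_point - p_thrust
  if (sqrt(sum(r2^2)) <= medium$r_cutoff)
    u <- u - drop(hele_shaw_kernel(r2, medium) %*% Fv)
  u
}

## Radial tabulation of the kernel factors used by the compiled simulator;
## spacing 0.02 in z (= 0.02/sqrt(kappa) in r), linear interpolation.
hs_kernel_table <- function(medium, dz = 0.02) {
  zmax <- sqrt(medium$kappa) * medium$r_cutoff
  z <- seq(1e-4, zmax + dz, by = dz)
  list(z = z, c1 = hs_c1(z), c2 = hs_c2(z))
}
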
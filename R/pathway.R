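## Intracellular chemotaxis pathway: a Monod-Wyman-Changeux (MWC) receptor
## cluster with linear methylation/demethylation adaptation kinetics, mapped
## to the tumble initiation rate through a Hill-type motor response.
##
## The receptor free-energy contribution of Tar-MeAsp binding is
##   f(c) = ln[(1 + c/K_off)/(1 + c/K_on)],
## the cluster activity a = 1/(1 + exp(N [eps0 - eps1 m + f(c)])), and the
## methylation level integrates dm/dt = k_R (1 - a) - k_B a, which adapts a
## exactly to a_ss = k_R/(k_R + k_B) for any constant ambient concentration
## (within the methylation range). The tumble rate is lambda0 (a/a_ss)^H.

#' Chemotaxis pathway parameters
#'
#' Defaults follow standard literature values for the E. coli Tar/MeAsp
#' system: cluster size N = 6, dissociation constants K_off = 20 uM and
#' K_on = 500 uM, methylation free-energy increment eps1 = 0.5 kT per methyl
#' group, adaptation rates k_R = 0.0069 1/s and k_B = 0.0138 1/s (adapted
#' activity 1/3), motor Hill exponent H = 10, steady-state tumble rate
#' lambda0 = 1/s and tumble duration tau_t = 0.12 s. \code{eps0} defaults so
#' that the adapted methylation level at c = 100 uM sits mid-range.
#'
#' @param N receptor cluster size.
#' @param K_off,K_on inactive/active-state dissociation constants (uM).
#' @param eps1 methylation free-energy offset per methyl group (kT).
#' @param eps0 free-energy offset at m = 0 (kT); \code{NULL} centres the
#'   adapted state at \code{c_center}.
#' @param k_R,k_B methylation and demethylation rates (1/s).
#' @param m_max methylation range upper bound.
#' @param H motor Hill exponent.
#' @param lambda0 adapted tumble initiation rate (1/s).
#' @param tau_t tumble duration (s).
#' @param c_center concentration (uM) at which the adapted methylation level
#'   equals \code{m_max/2} (used only when \code{eps0} is NULL).
#' @return an object of class \code{pathway_params}.
#' @export
pathway_params <- function(N = 6, K_off = 20, K_on = 500, eps1 = 0.5,
                           eps0 = NULL, k_R = 0.0069, k_B = 0.0138,
                           m_max = 8, H = 10, lambda0 = 1, tau_t = 0.12,
                           c_center = 100) {
  stopifnot(K_on > K_off, K_off > 0, k_R > 0, k_B > 0, H >= 1)
  a_ss <- k_R / (k_R + k_B)
  if (is.null(eps0)) {
    f_c <- log((1 + c_center / K_off) / (1 + c_center / K_on))
    eps0 <- eps1 * (m_max / 2) - f_c + log(1 / a_ss - 1) / N
  }
  structure(list(N = N, K_off = K_off, K_on = K_on, eps0 = eps0, eps1 = eps1,
                 k_R = k_R, k_B = k_B, m_max = m_max, H = H,
                 lambda0 = lambda0, tau_t = tau_t, a_ss = a_ss),
            class = "pathway_params")
}

#' Ligand binding free energy
#'
#' \code{f(c) = log((1 + c/K_off)/(1 + c/K_on))} in kT units; monotone in c
#' and bounded by \code{log(K_on/K_off)}.
#'
#' @param c concentration (uM), vectorised.
#' @param params a [pathway_params()].
#' @export
ligand_free_energy <- function(c, params) {
  if (any(c < 0)) stop("concentration must be non-negative")
  log((1 + c / params$K_off) / (1 + c / params$K_on))
}

#' MWC receptor cluster activity
#'
#' @param m methylation level.
#' @param c ligand concentration (uM).
#' @param params a [pathway_params()].
#' @return activity in [0, 1]; decreasing in c (attractant), increasing in m.
#' @export
receptor_activity <- function(m, c, params) {
  f <- ligand_free_energy(c, params)
  1 / (1 + exp(params$N * (params$eps0 - params$eps1 * m + f)))
}

#' Adapted pathway state at a given concentration
#'
#' Methylation level solving \code{receptor_activity(m, c) == a_ss}
#' (clipped to the methylation range), with the corresponding activity and
#' tumble rate.
#'
#' @inheritParams receptor_activity
#' @return a \code{pathway_state} list with fields \code{m}, \code{a},
#'   \code{lambda}.
#' @export
adapted_state <- function(c, params) {
  f <- ligand_free_energy(c, params)
  m <- (params$eps0 + f - log(1 / params$a_ss - 1) / params$N) / params$eps1
  m <- pmin(pmax(m, 0), params$m_max)
  a <- receptor_activity(m, c, params)
  pathway_state(m, a, params$lambda0 * (a / params$a_ss)^params$H)
}

#' Pathway state constructor
#'
#' @param m methylation level.
#' @param a receptor activity.
#' @param lambda tumble rate (1/s).
#' @export
pathway_state <- function(m, a, lambda) {
  structure(list(m = m, a = a, lambda = lambda), class = "pathway_state")
}

#' Advance the pathway by one Euler step
#'
#' @param state a \code{pathway_state} (fields \code{m}, \code{a},
#'   \code{lambda}).
#' @param c ligand concentration (uM) experienced during the step.
#' @param dt time step (s); must not exceed 0.05 s.
#' @param params a [pathway_params()].
#' @export
update_pathway <- function(state, c, dt, params) {
  if (!is.finite(c)) stop("non-finite concentration")
  stopifnot(dt <= 0.05)
  a <- receptor_activity(state$m, c, params)
  m <- state$m + (params$k_R * (1 - a) - params$k_B * a) * dt
  m <- min(max(m, 0), params$m_max)
  a_new <- receptor_activity(m, c, params)
  pathway_state(m, a_new, params$lambda0 * (a_new / params$a_ss)^params$H)
}

#' Effective sensing-theory time scales and gain
#'
#' Computes, for the drift theory of non-interacting swimmers:
#' \itemize{
#' \item \code{tau_m}: the memory (adaptation) time, measured numerically as
#'   the e-folding time of the activity relaxation after a small free-energy
#'   step about the adapted state;
#' \item \code{tau_T}: the tumble reorientation time
#'   \code{tau_0/(1 - exp(-D_T tau_t))}, where \code{D_T tau_t} is half the
#'   mean squared angular change of a tumble and \code{tau_0 = (1 + lambda0
#'   tau_t)/lambda0} is the inverse wall-clock tumble frequency (tumbles
#'   are initiated only while running);
#' \item \code{tau_R = 1/D_r}: the Brownian reorientation time;
#' \item \code{gain}: the total gain G of the pathway entering the drift
#'   formula \code{v_ch = G v0^2 tau grad(f)}. The bare linear-response gain
#'   of the cascade is \code{H N (1 - a_ss)} (relative tumble-rate change per
#'   unit free energy); for the 2D simulator geometry the projection of runs
#'   on the gradient contributes a factor 1/2 and the finite tumble duration
#'   inflates the measured coefficient by \code{1 + lambda0 tau_t} (both the
#'   drift and the mean speed are reduced by the run duty cycle p, so
#'   v_ch/v0^2 scales as 1/p);
#' \item \code{gain_taudec}: gain calibrated for predictions parameterised
#'   by the measured velocity decorrelation time tau_dec (the lag where the
#'   speed-weighted autocorrelation crosses 0.5). Because propulsion is off
#'   during tumbles, C_v drops by the duty factor p before decaying, so the
#'   measured crossing sits below tau_p log 2; the calibration solves the
#'   modeled C_v for its dilute crossing \code{tau_dec_dilute} and maps the
#'   direct prediction exactly onto the tau_dec-parameterised form there.
#' }
#'
#' @param params a [pathway_params()].
#' @param D_r rotational diffusion during runs (rad^2/s).
#' @param D_T rotational diffusion during tumbles (rad^2/s).
#' @param c_ref reference concentration for the linearisation (uM).
#' @return list with \code{tau_m}, \code{tau_T}, \code{tau_R}, \code{gain},
#'   \code{gain_taudec}, \code{a_ss}, \code{duty}.
#' @export
effective_parameters <- function(params, D_r = 0.057, D_T = 10.6,
                                 c_ref = 100) {
  ## analytic linearisation of the adaptation dynamics:
  ## d(da)/dt = -da/tau_m with 1/tau_m = N eps1 a(1-a)(k_R + k_B)
  a <- params$a_ss
  tau_m_lin <- 1 / (params$N * params$eps1 * a * (1 - a) *
                      (params$k_R + params$k_B))
  ## numerical check by direct ODE integration of a small f-step
  tau_m <- .measure_tau_m(params, c_ref)
  duty <- 1 / (1 + params$lambda0 * params$tau_t)
  ## tau_T = tau_0/(1 - exp(-D_T tau_t)) with tau_0 the inverse steady-state
  ## tumble frequency. Tumbles are initiated at rate lambda0 only while
  ## running, so the wall-clock frequency is duty * lambda0; the measured
  ## decay rate of the velocity autocorrelation confirms
  ## 1/tau_p = D_r + duty lambda0 (1 - beta).
  tau_T <- (1 / (duty * params$lambda0)) / (1 - exp(-D_T * params$tau_t))
  tau_R <- 1 / D_r
  gain_bare <- params$H * params$N * (1 - a)
  gain <- gain_bare / (2 * duty)
  ## dilute-limit prediction of the measured decorrelation time: the
  ## speed-weighted C_v of the run-and-tumble process is approximately
  ##   C_v(t) = [p + (1-p) exp(-t (lambda0 + 1/tau_t))] *
  ##            exp(-(D_r + p lambda0 (1 - beta)) t),
  ## (duty factor p, directional persistence beta = exp(-D_T tau_t) across a
  ## tumble, wall-clock tumble rate p lambda0); tau_dec solves C_v = 0.5.
  beta <- exp(-D_T * params$tau_t)
  rate <- D_r + duty * params$lambda0 * (1 - beta)
  cv <- function(t) (duty + (1 - duty) *
                       exp(-t * (params$lambda0 + 1 / params$tau_t))) *
    exp(-rate * t)
  tau_dec_dilute <- uniroot(function(t) cv(t) - 0.5, c(1e-6, 50 / rate))$root
  ## calibrate the tau_dec-parameterised gain so that the tau_dec-parameterised
  ## prediction reproduces the direct sensing-time one in the dilute limit
  tau <- sensing_time(tau_m, tau_T, tau_R)
  gain_taudec <- gain * tau /
    ((tau_dec_dilute^2 / tau_T) / (1 + tau_dec_dilute / tau_m))
  list(tau_m = tau_m, tau_m_linear = tau_m_lin, tau_T = tau_T, tau_R = tau_R,
       gain = gain, gain_taudec = gain_taudec, a_ss = a, duty = duty,
       tau_dec_dilute = tau_dec_dilute)
}

## e-folding time of the activity response to a small step in f, by direct
## Euler integration about the adapted state (oracle for tau_m).
.measure_tau_m <- function(params, c_ref = 100, df = 0.01, dt = 0.05) {
  st <- adapted_state(c_ref, params)
  ## apply the f-step as an equivalent concentration change
  f0 <- ligand_free_energy(c_ref, params)
  c_new <- .conc_for_f(f0 + df, params)
  a0 <- params$a_ss
  a_jump <- receptor_activity(st$m, c_new, params)
  target <- abs(a_jump - a0) * exp(-1)
  t <- 0
  for (i in seq_len(200000)) {
    st <- update_pathway(st, c_new, dt, params)
    t <- t + dt
    if (abs(st$a - a0) <= target) break
  }
  t
}

## invert f(c) (monotone)
.conc_for_f <- function(f, params) {
  ef <- exp(f)
  ## solve (1 + c/K_off) = ef (1 + c/K_on)
  (ef - 1) / (1 / params$K_off - ef / params$K_on)
}
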
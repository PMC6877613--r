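## Agent-based simulator of self-propelled chemotactic rods in a periodic 2D
## box. Rods are spherocylinders (core segment of length L - e, radius e/2)
## that interact through Hertzian repulsion + tangential contact friction and,
## optionally, through the screened Hele-Shaw dipole flows they generate.
## Overdamped equations of motion are integrated with an explicit Euler
## scheme; a step whose displacement would exceed e/2 is rejected and retried
## with a halved time step.

#' Anisotropic rod friction coefficients
#'
#' Slender-body values: \code{gamma_par = 2 pi eta L / log(L/e)},
#' \code{gamma_perp = 2 gamma_par}, \code{gamma_rot = gamma_par L^2 / 6}.
#'
#' @param L rod length (um).
#' @param e rod width (um).
#' @param eta viscosity (pN s/um^2).
#' @return list with \code{gamma_par} (pN s/um), \code{gamma_perp},
#'   \code{gamma_rot} (pN s um).
#' @export
friction_set <- function(L, e, eta = 1e-3) {
  stopifnot(L > e, e > 0, eta > 0)
  gpar <- 2 * pi * eta * L / log(L / e)
  list(gamma_par = gpar, gamma_perp = 2 * gpar, gamma_rot = gpar * L^2 / 6)
}

#' Simulation configuration
#'
#' Physical and numerical parameters of a rod-suspension run. Defaults give
#' normally sized cells (L = 2 um) in a moderately confined channel
#' (h = 30 um) in the standard attractant gradient (0 to 200 uM over 2 mm,
#' i.e. 0.1 uM/um, mid-channel concentration 100 uM).
#'
#' Either \code{n_rods} or a target area fraction \code{phi} must be given;
#' the rod area is \code{(L - e) e + pi (e/2)^2}.
#'
#' @param box_side periodic box side (um).
#' @param h channel height (um), sets the hydrodynamic screening
#'   \code{kappa = 12/h^2}.
#' @param L,e rod length and width (um).
#' @param L_flag flagellar bundle length (um); the dipole length is
#'   \code{L/2 + L_flag/2}.
#' @param eta viscosity (pN s/um^2).
#' @param K_el Hertzian elastic constant (pN/um^(3/2)).
#' @param K_fr contact friction constant (pN s/um).
#' @param v0_mean,v0_std mean and SD of the quenched Gaussian swimming-speed
#'   distribution (um/s).
#' @param D_r rotational diffusion during runs (rad^2/s); if \code{NULL},
#'   0.057 for L = 2 scaled by slender-body \code{L^-3 log(L/e)}.
#' @param D_T rotational diffusion during tumbles (rad^2/s).
#' @param tau_t tumble duration (s).
#' @param dt outer Euler time step (s); must satisfy \code{dt v0_mean < e/2}.
#' @param contact_dt contact-relaxation substep (s). Hertzian contacts are
#'   stiff (relaxation rate \code{~K_el delta^(1/2)/gamma}), so the contact
#'   forces are subcycled at this resolution inside each outer step.
#' @param t_total simulated time (s).
#' @param save_interval state recording interval (s).
#' @param n_rods number of rods (overrides \code{phi}).
#' @param phi target area fraction in [0, 0.6].
#' @param hydrodynamics_on include dipole flows.
#' @param steric_on include contact forces.
#' @param gate_dipole switch the dipole off while tumbling (propulsion off
#'   implies no thrust/drag pair).
#' @param hydro_interval time between refreshes of the (smooth) hydrodynamic
#'   flow field (s); the flows are frozen between refreshes, a multiple
#'   time-step scheme that leaves the stiff contact forces at full
#'   resolution.
#' @param gradient a [gradient_spec()] or \code{NULL} for uniform ambient
#'   concentration \code{c_uniform}.
#' @param c_uniform ambient concentration when no gradient is given (uM).
#' @param pathway a [pathway_params()].
#' @param seed RNG seed.
#' @return an object of class \code{simulation_config}.
#' @export
simulation_config <- function(box_side = 256, h = 30, L = 2, e = 1,
                              L_flag = 10, eta = 1e-3, K_el = 200,
                              K_fr = 0.01, v0_mean = 20, v0_std = 5,
                              D_r = NULL, D_T = 10.6, tau_t = 0.12,
                              dt = 0.01, contact_dt = 2e-4,
                              t_total = 60, save_interval = 0.1,
                              n_rods = NULL, phi = NULL,
                              hydrodynamics_on = TRUE, steric_on = TRUE,
                              gate_dipole = TRUE, hydro_interval = 0.02,
                              gradient = gradient_spec(), c_uniform = 100,
                              pathway = pathway_params(), seed = 1L) {
  if (is.null(D_r))
    D_r <- 0.057 * (2^3 / log(2 / 1)) * log(L / e) / L^3
  stopifnot(box_side > 0, h > 0, L > e, e > 0, eta > 0, K_el > 0, K_fr >= 0,
            v0_mean > 0, D_r > 0, D_T > 0, tau_t > 0, dt > 0, t_total > 0)
  if (dt * v0_mean >= e / 2)
    stop("time step violates the displacement bound dt * v0_mean < e/2")
  rod_area <- (L - e) * e + pi * (e / 2)^2
  if (is.null(n_rods)) {
    if (is.null(phi)) stop("give either n_rods or phi")
    stopifnot(phi >= 0, phi <= 0.6)
    n_rods <- round(phi * box_side^2 / rod_area)
  }
  kappa <- 12 / h^2
  r_cutoff <- min(6 / sqrt(kappa), box_side / 2)
  cfg <- structure(list(
    box_side = box_side, h = h, L = L, e = e, L_flag = L_flag,
    L_dip = dipole_length(L, L_flag), eta = eta, K_el = K_el, K_fr = K_fr,
    v0_mean = v0_mean, v0_std = v0_std, D_r = D_r, D_T = D_T, tau_t = tau_t,
    dt = dt, contact_dt = contact_dt, t_total = t_total,
    save_interval = save_interval,
    n_rods = as.integer(n_rods), hydrodynamics_on = hydrodynamics_on,
    steric_on = steric_on, gate_dipole = gate_dipole,
    hydro_interval = hydro_interval, kappa = kappa,
    r_clamp = e / 2, r_cutoff = r_cutoff,
    gradient = gradient, c_uniform = c_uniform, pathway = pathway,
    friction = friction_set(L, e, eta), seed = as.integer(seed)),
    class = "simulation_config")
  cfg
}

#' Rod suspension area fraction
#'
#' \code{Phi = n * ((L - e) e + pi (e/2)^2) / box_side^2}.
#'
#' @param n_rods number of rods (or a state data frame, whose rows are
#'   counted).
#' @param config a [simulation_config()].
#' @export
area_fraction <- function(n_rods, config) {
  if (is.data.frame(n_rods)) n_rods <- nrow(n_rods)
  n_rods * ((config$L - config$e) * config$e + pi * (config$e / 2)^2) /
    config$box_side^2
}

#' Initial rod states
#'
#' Random sequential insertion without overlaps (feasible up to area
#' fractions of about 0.3), uniform orientations, quenched swimming speeds
#' redrawn until positive, pathway pre-adapted to the local concentration
#' and motor states drawn from the steady-state run/tumble occupancy.
#'
#' @param config a [simulation_config()].
#' @return data frame of per-rod state (one row per rod).
#' @export
init_rods <- function(config) {
  n <- config$n_rods
  box <- config$box_side
  x <- numeric(n); y <- numeric(n); th <- numeric(n)
  placed <- 0L
  max_try <- 400L * n + 1000L
  for (k in seq_len(max_try)) {
    xx <- runif(1, 0, box); yy <- runif(1, 0, box)
    tt <- runif(1, -pi, pi)
    idx <- seq_len(placed)
    cand_x <- c(x[idx], xx); cand_y <- c(y[idx], yy); cand_t <- c(th[idx], tt)
    ## cheap check: only test the candidate against others
    ok <- TRUE
    if (placed > 0) {
      cm <- cpp_find_contacts(cand_x, cand_y, cand_t, config$L, config$e, box)
      if (nrow(cm) > 0 && any(cm[, "i"] == placed + 1 | cm[, "j"] == placed + 1))
        ok <- FALSE
    }
    if (ok) {
      placed <- placed + 1L
      x[placed] <- xx; y[placed] <- yy; th[placed] <- tt
      if (placed == n) break
    }
  }
  if (placed < n)
    stop("could not place ", n, " rods without overlap (reached ", placed, ")")
  v <- rnorm(n, config$v0_mean, config$v0_std)
  while (any(v <= 0)) v[v <= 0] <- rnorm(sum(v <= 0), config$v0_mean, config$v0_std)
  c_loc <- local_concentration(x, config)
  ad <- adapted_state(c_loc, config$pathway)
  p_run <- 1 / (1 + config$pathway$lambda0 * config$pathway$tau_t)
  motor <- ifelse(runif(n) < p_run, 1L, 0L)
  data.frame(x = x, y = y, unwrapped_x = x, theta = th, v_i = v,
             motor = motor, m = ad$m, activity = ad$a,
             time_in_state = ifelse(motor == 1L, 0, runif(n, 0, config$tau_t)))
}

## ligand concentration at (possibly unwrapped) x positions
local_concentration <- function(x, config) {
  g <- config$gradient
  if (is.null(g)) return(rep(config$c_uniform, length(x)))
  c_mid <- (g$c_left + g$c_right) / 2
  grad <- (g$c_right - g$c_left) / g$channel_length
  pmax(c_mid + grad * (x - config$box_side / 2), 0)
}

#' Find steric contacts between rods
#'
#' Spherocylinder segment-segment distance with the minimal-image convention;
#' a contact is reported when the axis distance drops below the rod width e.
#'
#' @param states rod state data frame (columns \code{x}, \code{y},
#'   \code{theta}).
#' @param config a [simulation_config()].
#' @return data frame with one row per contact: indices \code{i}, \code{j},
#'   interpenetration \code{delta}, contact normal \code{ux}, \code{uy}
#'   (pointing from j to i), tangent \code{vx}, \code{vy}, contact point
#'   \code{cx}, \code{cy} (relative to the centre of rod i), axis parameters
#'   (signed lever arms) \code{lever_i}, \code{lever_j}.
#' @export
find_contacts <- function(states, config) {
  m <- cpp_find_contacts(states$x, states$y, states$theta,
                         config$L, config$e, config$box_side)
  data.frame(i = as.integer(m[, "i"]), j = as.integer(m[, "j"]),
             delta = m[, "delta"], ux = m[, "ux"], uy = m[, "uy"],
             vx = -m[, "uy"], vy = m[, "ux"],
             cx = m[, "cx"], cy = m[, "cy"],
             lever_i = m[, "si"], lever_j = m[, "tj"])
}

#' Steric forces and torques
#'
#' Hertzian repulsion \code{F_el = K_el delta^(3/2) u_ij} plus tangential
#' friction \code{F_fr = -K_fr [(v_i - v_j) . v_ij] v_ij}, with pairwise
#' antisymmetry built in; torques are lever x force (z-component).
#'
#' @param contacts output of [find_contacts()].
#' @param states rod state data frame.
#' @param config a [simulation_config()].
#' @param velocities optional n x 2 matrix of instantaneous rod velocities
#'   used for the friction term (defaults to zero: elastic forces only).
#' @return list with \code{force} (n x 2, pN) and \code{torque} (length n,
#'   pN um).
#' @export
steric_forces <- function(contacts, states, config, velocities = NULL) {
  n <- nrow(states)
  if (is.null(velocities)) velocities <- matrix(0, n, 2)
  Fm <- matrix(0, n, 2); tq <- numeric(n)
  if (nrow(contacts) == 0) return(list(force = Fm, torque = tq))
  for (k in seq_len(nrow(contacts))) {
    ct <- contacts[k, ]
    i <- ct$i; j <- ct$j
    fel <- config$K_el * ct$delta^1.5
    dvt <- sum((velocities[i, ] - velocities[j, ]) * c(ct$vx, ct$vy))
    Fi <- fel * c(ct$ux, ct$uy) - config$K_fr * dvt * c(ct$vx, ct$vy)
    Fm[i, ] <- Fm[i, ] + Fi
    Fm[j, ] <- Fm[j, ] - Fi
    lev_i <- c(ct$cx, ct$cy)
    tq[i] <- tq[i] + lev_i[1] * Fi[2] - lev_i[2] * Fi[1]
    dxj <- .pimage(states$x[i] + ct$cx - states$x[j], config$box_side)
    dyj <- .pimage(states$y[i] + ct$cy - states$y[j], config$box_side)
    tq[j] <- tq[j] - (dxj * Fi[2] - dyj * Fi[1])
  }
  list(force = Fm, torque = tq)
}

.pimage <- function(d, box) d - box * round(d / box)

## Assemble the flat config + kernel table consumed by the compiled core.
.cpp_config <- function(config, n_steps, save_every) {
  g <- config$gradient
  if (is.null(g)) {
    c_mid <- config$c_uniform; grad <- 0
  } else {
    c_mid <- (g$c_left + g$c_right) / 2
    grad <- (g$c_right - g$c_left) / g$channel_length
  }
  pw <- config$pathway
  fr <- config$friction
  list(n = config$n_rods, box = config$box_side, L = config$L, e = config$e,
       L_dip = config$L_dip, eta = config$eta, K_el = config$K_el,
       K_fr = config$K_fr, gamma_par = fr$gamma_par,
       gamma_perp = fr$gamma_perp, gamma_rot = fr$gamma_rot,
       D_r = config$D_r, D_T = config$D_T, tau_t = config$tau_t,
       hydrodynamics_on = config$hydrodynamics_on,
       steric_on = config$steric_on, gate_dipole = config$gate_dipole,
       hydro_every = max(1L, as.integer(round(config$hydro_interval / config$dt))),
       N_rec = pw$N, K_off = pw$K_off, K_on = pw$K_on, eps0 = pw$eps0,
       eps1 = pw$eps1, k_R = pw$k_R, k_B = pw$k_B, H = pw$H,
       lambda0 = pw$lambda0, m_max = pw$m_max, a_ss = pw$a_ss,
       c_mid = c_mid, grad_c = grad, x0 = config$box_side / 2,
       h = config$h, kappa = config$kappa, r_clamp = config$r_clamp,
       r_cutoff = config$r_cutoff,
       dt = config$dt, n_steps = as.integer(n_steps),
       save_every = as.integer(save_every),
       n_contact_sub = max(1L, as.integer(round(config$dt / config$contact_dt))))
}

.state_list <- function(states) {
  list(x = states$x, y = states$y, theta = states$theta, v_i = states$v_i,
       m = states$m, motor = as.integer(states$motor),
       time_in_state = states$time_in_state)
}

#' Advance rod states by explicit Euler steps
#'
#' Low-level single/multi step integration used by [run_simulation()] and in
#' unit tests; operates on a state data frame and returns the updated one.
#' Randomness uses the current R RNG state.
#'
#' @param states state data frame as from [init_rods()].
#' @param config a [simulation_config()].
#' @param n_steps number of Euler steps.
#' @return updated state data frame, with attribute \code{n_reject} counting
#'   rejected (halved) steps.
#' @export
step_rods <- function(states, config, n_steps = 1) {
  tab <- hs_kernel_table(hele_shaw_medium(config$h, config$eta,
                                          config$r_clamp, config$r_cutoff))
  cc <- .cpp_config(config, n_steps, n_steps)
  res <- cpp_run_sim(cc, .state_list(states), tab$z, tab$c1, tab$c2)
  fin <- res$final
  out <- data.frame(x = fin$x, y = fin$y, unwrapped_x = states$unwrapped_x +
                      (fin$unwrapped_x - states$x),
                    theta = fin$theta, v_i = fin$v_i,
                    motor = fin$motor, m = fin$m,
                    activity = res$activity[nrow(res$activity), ],
                    time_in_state = fin$time_in_state)
  attr(out, "n_reject") <- res$n_reject
  attr(out, "velocity") <- cbind(fin$velx, fin$vely)
  out
}

#' Run a rod-suspension simulation
#'
#' Integrates the overdamped equations of motion for all rods with the
#' chemotaxis pathway advanced at every step using the ligand concentration
#' at the rod's unwrapped x position, and records the state every
#' \code{save_interval}. Deterministic for a given \code{config$seed}.
#'
#' @param config a [simulation_config()].
#' @param states optional initial states (default [init_rods()]).
#' @return an object of class \code{rod_trajectories}: list with
#'   \code{times} and time x rod matrices \code{x}, \code{y},
#'   \code{unwrapped_x}, \code{theta}, \code{motor}, \code{vx}, \code{vy},
#'   \code{methylation}, \code{activity}, plus the config and per-rod speeds.
#' @export
run_simulation <- function(config, states = NULL) {
  set.seed(config$seed)
  if (is.null(states)) states <- init_rods(config)
  n_steps <- round(config$t_total / config$dt)
  save_every <- max(1L, round(config$save_interval / config$dt))
  tab <- hs_kernel_table(hele_shaw_medium(config$h, config$eta,
                                          config$r_clamp, config$r_cutoff))
  cc <- .cpp_config(config, n_steps, save_every)
  res <- cpp_run_sim(cc, .state_list(states), tab$z, tab$c1, tab$c2)
  structure(list(times = res$times, x = res$x, y = res$y,
                 unwrapped_x = res$unwrapped_x, theta = res$theta,
                 motor = res$motor, vx = res$vx, vy = res$vy,
                 methylation = res$methylation, activity = res$activity,
                 v_i = states$v_i, n_reject = res$n_reject,
                 config = config),
            class = "rod_trajectories")
}

#' @export
print.rod_trajectories <- function(x, ...) {
  cat("rod_trajectories:", ncol(x$x), "rods,", length(x$times),
      "saved states, t =", round(max(x$times), 2), "s\n")
  cat("  area fraction:", signif(area_fraction(ncol(x$x), x$config), 3),
      " box:", x$config$box_side, "um  h:", x$config$h, "um  L:",
      x$config$L, "um\n")
  cat("  hydrodynamics:", x$config$hydrodynamics_on,
      " rejected steps:", x$n_reject, "\n")
  invisible(x)
}

#' Per-time summary of a simulation
#'
#' @param object a \code{rod_trajectories}.
#' @param ... unused.
#' @return data frame with time, mean speed, mean drift velocity and area
#'   fraction.
#' @export
summary.rod_trajectories <- function(object, ...) {
  sp <- sqrt(object$vx^2 + object$vy^2)
  dtv <- diff(object$times)
  drift <- rbind(NA, diff(object$unwrapped_x) / dtv)
  data.frame(time = object$times,
             mean_speed = rowMeans(sp),
             mean_drift = rowMeans(drift),
             phi = area_fraction(ncol(object$x), object$config))
}

#' Export trajectories to plain-text files
#'
#' Writes a per-time summary CSV and (optionally) the full state time series
#' as CSV tables, plus a JSON sidecar with the configuration, its hash and
#' the seed.
#'
#' @param traj a \code{rod_trajectories}.
#' @param path output file prefix.
#' @param full also write the complete state matrices.
#' @return invisibly, the paths written.
#' @export
write_trajectories <- function(traj, path, full = FALSE) {
  paths <- character(0)
  s <- summary(traj)
  p1 <- paste0(path, "_summary.csv")
  write.csv(s, p1, row.names = FALSE)
  paths <- c(paths, p1)
  if (full) {
    for (f in c("x", "y", "unwrapped_x", "theta", "motor", "vx", "vy",
                "methylation", "activity")) {
      pf <- paste0(path, "_", f, ".csv")
      write.csv(cbind(time = traj$times, traj[[f]]), pf, row.names = FALSE)
      paths <- c(paths, pf)
    }
  }
  meta <- list(config = .config_plain(traj$config),
               config_hash = digest::digest(.config_plain(traj$config)),
               seed = traj$config$seed,
               version = as.character(utils::packageVersion("chemoflow")))
  pj <- paste0(path, "_meta.json")
  jsonlite::write_json(meta, pj, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, pj))
}

.config_plain <- function(config) {
  cfg <- unclass(config)
  cfg$pathway <- unclass(cfg$pathway)
  if (!is.null(cfg$gradient)) cfg$gradient <- unclass(cfg$gradient)
  cfg$friction <- NULL
  cfg
}
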
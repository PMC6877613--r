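## Orchestration: config-file driven simulation runs, condition sweeps over
## (area fraction, cell length, channel height, interaction model), and
## dispatch of the analysis tools, with plain-text outputs (CSV + JSON
## sidecars carrying config hash, seed and package version).

.read_config_file <- function(path) {
  if (grepl("\\.(ya?ml)$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("yaml package required for YAML configs; use JSON instead")
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE)
}

.config_from_list <- function(lst) {
  known <- names(formals(simulation_config))
  bad <- setdiff(names(lst), c(known, "phi"))
  if (length(bad))
    stop("unknown config fields: ", paste0("$", bad, collapse = ", "))
  if (!is.null(lst$gradient) && !inherits(lst$gradient, "gradient_spec"))
    lst$gradient <- do.call(gradient_spec, lst$gradient)
  if (!is.null(lst$pathway) && !inherits(lst$pathway, "pathway_params"))
    lst$pathway <- do.call(pathway_params, lst$pathway)
  do.call(simulation_config, lst)
}

.meta_sidecar <- function(config, path) {
  meta <- list(config = .config_plain(config),
               config_hash = digest::digest(.config_plain(config)),
               seed = config$seed,
               version = as.character(utils::packageVersion("chemoflow")),
               timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Run a simulation from a config file
#'
#' Reads a JSON (or YAML) file whose fields mirror [simulation_config()]
#' arguments, runs the simulation and writes the trajectory summary plus a
#' JSON metadata sidecar (config hash, seed, package version).
#'
#' @param config_file path to the config file, or a config list/object.
#' @param out_dir output directory.
#' @param full write full state matrices as CSV.
#' @return the \code{rod_trajectories}, invisibly.
#' @export
cmd_simulate <- function(config_file, out_dir = ".", full = FALSE) {
  cfg <- if (inherits(config_file, "simulation_config")) config_file
  else if (is.list(config_file)) .config_from_list(config_file)
  else .config_from_list(.read_config_file(config_file))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  traj <- run_simulation(cfg)
  prefix <- file.path(out_dir, sprintf("sim_phi%.3f_h%g_L%g_seed%d",
                                       area_fraction(ncol(traj$x), cfg),
                                       cfg$h, cfg$L, cfg$seed))
  write_trajectories(traj, prefix, full = full)
  .meta_sidecar(cfg, paste0(prefix, "_meta.json"))
  message("simulate: ", ncol(traj$x), " rods, ", length(traj$times),
          " frames -> ", prefix, "_summary.csv")
  invisible(traj)
}

#' Analyse one condition of a sweep
#'
#' Runs (or reuses) a simulation and computes the standard summary row:
#' area fraction, mean speed, drift, chemotactic coefficient, spectral peak
#' amplitude and vortex size, and decorrelation time.
#'
#' @param traj a \code{rod_trajectories}.
#' @param t_burn transient discard (s).
#' @param q_str frozen peak wavenumber (um^-1) or NULL.
#' @param baseline optional baseline \code{flow_spectrum}.
#' @param grid_spacing coarse-graining grid spacing (um).
#' @return one-row data frame.
#' @export
condition_summary <- function(traj, t_burn = 20, q_str = NULL,
                              baseline = NULL, grid_spacing = 2) {
  cfg <- traj$config
  vf <- coarse_grain_velocity(traj, spacing = grid_spacing,
                              times = traj$times[traj$times >= t_burn])
  sp <- flow_structure_factor(vf)
  pk <- peak_analysis(sp, baseline = baseline, q_str = q_str)
  dr <- chemotactic_drift(traj, t_burn = t_burn)
  ac <- velocity_autocorrelation(traj, t_min = t_burn)
  data.frame(phi = area_fraction(ncol(traj$x), cfg), h = cfg$h, L = cfg$L,
             hydro = cfg$hydrodynamics_on, seed = cfg$seed,
             v0 = dr$v0, v_ch = dr$v_ch, coefficient = dr$coefficient,
             q_max = pk$q_max, q_str = pk$q_str, deltaE = pk$deltaE,
             vortex_size = pk$vortex_size, tau_dec = ac$tau_dec)
}

#' Sweep over suspension conditions
#'
#' Runs every (phi, L, h, hydrodynamics) cell for each seed, freezes
#' \code{q_str} per (h, L, hydro) group from its densest cell, uses the
#' lowest-density cell of each group as the Delta E baseline, and collects
#' one summary row per run. Failed cells are logged and skipped.
#'
#' @param cells data frame with columns \code{phi}, \code{L}, \code{h},
#'   \code{hydro} (logical).
#' @param seeds integer vector of seeds.
#' @param base_config named list of [simulation_config()] overrides shared
#'   by all cells (e.g. \code{box_side}, \code{t_total}, \code{dt}).
#' @param t_burn transient discard (s).
#' @return data frame of summary rows (one per cell x seed), with the
#'   spectra attached as attribute \code{spectra}.
#' @export
run_sweep <- function(cells, seeds = 1L, base_config = list(), t_burn = 20) {
  stopifnot(nrow(cells) >= 1, length(seeds) >= 1)
  runs <- list(); spectra <- list()
  for (ic in seq_len(nrow(cells))) {
    for (sd in seeds) {
      key <- sprintf("phi%.4g_L%g_h%g_hy%d_s%d", cells$phi[ic], cells$L[ic],
                     cells$h[ic], cells$hydro[ic], sd)
      args <- modifyList(base_config,
                         list(phi = cells$phi[ic], L = cells$L[ic],
                              h = cells$h[ic],
                              hydrodynamics_on = isTRUE(cells$hydro[ic]),
                              seed = sd))
      res <- tryCatch({
        traj <- run_simulation(.config_from_list(args))
        vf <- coarse_grain_velocity(traj,
                                    times = traj$times[traj$times >= t_burn])
        sp <- flow_structure_factor(vf)
        dr <- chemotactic_drift(traj, t_burn = t_burn)
        ac <- tryCatch(
          suppressWarnings(velocity_autocorrelation(traj, t_min = t_burn)),
          error = function(e) list(tau_dec = NA_real_))
        list(spectrum = sp, drift = dr, autocorr = ac, traj_cfg = traj$config,
             n = ncol(traj$x))
      }, error = function(e) {
        message("sweep cell ", key, " failed: ", conditionMessage(e))
        NULL
      })
      if (is.null(res)) next
      spectra[[key]] <- res$spectrum
      runs[[key]] <- data.frame(
        cell = ic, phi_target = cells$phi[ic],
        phi = area_fraction(res$n, res$traj_cfg),
        h = cells$h[ic], L = cells$L[ic], hydro = isTRUE(cells$hydro[ic]),
        seed = sd, v0 = res$drift$v0, v_ch = res$drift$v_ch,
        coefficient = res$drift$coefficient, tau_dec = res$autocorr$tau_dec)
    }
  }
  if (!length(runs)) stop("empty sweep: no cell completed")
  out <- do.call(rbind, runs)
  rownames(out) <- NULL
  ## freeze q_str per (h, L, hydro) group from the densest cell; baseline
  ## from the least dense
  out$q_str <- NA_real_; out$deltaE <- NA_real_; out$vortex_size <- NA_real_
  grp <- interaction(out$h, out$L, out$hydro, drop = TRUE)
  keys <- names(spectra)
  for (g in levels(grp)) {
    ii <- which(grp == g)
    dens <- ii[which.max(out$phi[ii])]
    base <- ii[which.min(out$phi[ii])]
    kd <- sprintf("phi%.4g_L%g_h%g_hy%d_s%d", out$phi_target[dens],
                  out$L[dens], out$h[dens], out$hydro[dens], out$seed[dens])
    qs <- peak_analysis(spectra[[kd]])$q_max
    for (i in ii) {
      ki <- sprintf("phi%.4g_L%g_h%g_hy%d_s%d", out$phi_target[i], out$L[i],
                    out$h[i], out$hydro[i], out$seed[i])
      kb <- sprintf("phi%.4g_L%g_h%g_hy%d_s%d", out$phi_target[base],
                    out$L[base], out$h[base], out$hydro[base], out$seed[i])
      bl <- spectra[[kb]]
      if (is.null(bl)) bl <- spectra[[keys[1]]]
      pk <- peak_analysis(spectra[[ki]], baseline = bl, q_str = qs)
      out$q_str[i] <- pk$q_str; out$deltaE[i] <- pk$deltaE
      out$vortex_size[i] <- pk$vortex_size
    }
  }
  attr(out, "spectra") <- spectra
  out
}

#' Run a sweep from a sweep file
#'
#' The sweep file (JSON/YAML) holds \code{cells} (list of phi/L/h/hydro
#' records), \code{seeds} and optional \code{base_config} overrides.
#'
#' @param sweep_file path, or an equivalent list.
#' @param out_dir output directory for the summary CSV.
#' @return the summary data frame, invisibly.
#' @export
cmd_sweep <- function(sweep_file, out_dir = ".") {
  sw <- if (is.list(sweep_file)) sweep_file else .read_config_file(sweep_file)
  if (is.null(sw$cells) || !length(sw$cells)) stop("empty sweep: no cells")
  cells <- do.call(rbind, lapply(sw$cells, as.data.frame))
  if (is.null(cells$hydro)) cells$hydro <- TRUE
  seeds <- if (is.null(sw$seeds)) 1L else as.integer(unlist(sw$seeds))
  base <- if (is.null(sw$base_config)) list() else sw$base_config
  tb <- if (is.null(sw$t_burn)) 20 else sw$t_burn
  out <- run_sweep(cells, seeds, base, t_burn = tb)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- file.path(out_dir, "sweep_summary.csv")
  write.csv(out, p, row.names = FALSE)
  message("sweep: ", nrow(out), " runs -> ", p)
  invisible(out)
}

#' Analyse a stored dataset
#'
#' Dispatches to the DDM, velocimetry or flow analyses. \code{input} is an
#' in-memory object (an \code{image_stack} for the image modes, a
#' \code{rod_trajectories} for \code{"flow"}).
#'
#' @param input object to analyse.
#' @param mode one of \code{"ddm"}, \code{"velocimetry"}, \code{"flow"}.
#' @param out_dir output directory for CSV results.
#' @param ... passed to the underlying analysis.
#' @return the analysis result, invisibly.
#' @export
cmd_analyze <- function(input, mode = c("ddm", "velocimetry", "flow"),
                        out_dir = ".", ...) {
  mode <- match.arg(mode)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- switch(mode,
    ddm = {
      if (!inherits(input, "image_stack")) stop("ddm mode needs an image_stack")
      fit <- fit_dicf(compute_dicf(input), ...)
      write_isf_fit(fit, file.path(out_dir, "ddm_fit.csv"))
      fit
    },
    velocimetry = {
      if (!inherits(input, "image_stack"))
        stop("velocimetry mode needs an image_stack")
      vf <- local_velocimetry(input, ...)
      mid <- dim(vf$vx_px)[3] %/% 2 + 1
      df <- expand.grid(x_px = vf$nodes_x, y_px = vf$nodes_y)
      df$vx_px <- as.vector(vf$vx_px[, , mid])
      df$vy_px <- as.vector(vf$vy_px[, , mid])
      write.csv(df, file.path(out_dir, "velocimetry_field.csv"),
                row.names = FALSE)
      vf
    },
    flow = {
      if (!inherits(input, "rod_trajectories"))
        stop("flow mode needs rod_trajectories")
      row <- condition_summary(input, ...)
      write.csv(row, file.path(out_dir, "flow_summary.csv"), row.names = FALSE)
      row
    })
  invisible(res)
}

#' Minimal command-line entry point
#'
#' \code{chemoflow_cli(c("simulate", "config.json", "out/"))} etc.; used by
#' the \code{inst/cli/chemoflow} script. Supported subcommands:
#' \code{simulate}, \code{sweep}.
#'
#' @param args character vector of arguments.
#' @export
chemoflow_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) stop("usage: chemoflow <simulate|sweep> <file> [out_dir]")
  cmd <- args[1]
  out <- if (length(args) >= 3) args[3] else "."
  switch(cmd,
         simulate = cmd_simulate(args[2], out),
         sweep = cmd_sweep(args[2], out),
         stop("unknown subcommand: ", cmd,
              " (expected 'simulate' or 'sweep')"))
}
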
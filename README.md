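# chemoflow

Chemotaxis and collective motion in dense bacterial suspensions: an
agent-based simulator of quasi-2D suspensions of chemotactic, self-propelled
rods (E. coli-like), plus the Fourier image and flow analyses used to
quantify swimming, collective flows, and chemotactic drift at any cell
density.

## The scientific problem

Swimming bacteria at high density self-organize into swirling collective
motion. Chemotaxis, however, relies on temporal comparisons made while a
cell holds its course: anything that randomizes swimming direction faster
degrades gradient sensing. This package provides the computational
machinery to study that tension:

* **Simulation** — rods with quenched speeds $v_i$, run-and-tumble motor
  dynamics driven by an MWC receptor/methylation pathway
  ($\lambda = \lambda_0 (a/a_{ss})^H$, exact adaptation via
  $\dot m = k_R(1-a) - k_B a$), Hertzian steric contacts
  ($F = K_{el}\,\delta^{3/2}$ plus tangential friction), and screened
  quasi-2D hydrodynamics: each swimmer is a pusher force dipole whose
  point-force flow is
  $G(r) = [c_1(z) I + c_2(z)\hat r\hat r]/(\pi\eta h \kappa r^2)$,
  $z = \sqrt{\kappa} r$, $\kappa = 12/h^2$ — the channel height $h$ sets
  the reach of the interaction.
* **Measurement** — differential dynamic microscopy (DDM) with the Schulz
  swimmer ISF (mean speed $v_0$, swimming fraction $\alpha$, diffusivity
  $D$); global and local phase-differential velocimetry (drift and velocity
  maps from Fourier phase increments, PIV-equivalent); the flow structure
  factor $E(q) = q\langle|\tilde v|^2/(A_0\langle v^2\rangle)\rangle$ whose
  peak gives the vortex size $\pi/q_{str}$ and amplitude
  $\Delta E(q_{str})$; velocity autocorrelations and the decorrelation time
  $\tau_{dec}$ ($C_v(\tau_{dec}) = 1/2$); chemotactic drift
  $v_{ch} = v_d/\alpha$ and coefficient $v_{ch}/v_0^2$, with the
  non-interacting theory
  $v_{ch}/v_0^2 = G\,\tau(\tau_m,\tau_T,\tau_R)\,\nabla f(c)$ and its
  $\tau_{dec}$-parameterised form.
* **Synthetic data** — run-and-tumble/Brownian trajectory ensembles with
  Schulz speeds, microscopy-like rendered image stacks (1.4 um/px, 100
  fps), Taylor-Green vortex arrays, and quasi-static 1D attractant
  gradients (0-200 uM MeAsp over 2 mm, D = 500 um^2/s).

## A worked example

Moderate density (area fraction 0.1), normal cells (L = 2 um), channel
height 30 um, in the standard gradient:

```r
library(chemoflow)
cfg <- simulation_config(box_side = 96, phi = 0.1, h = 30, L = 2,
                         dt = 0.01, t_total = 30, save_interval = 0.25,
                         hydro_interval = 0.05, seed = 1)
traj <- run_simulation(cfg)            # 516 rods, ~15 s on one core
vf  <- coarse_grain_velocity(traj, times = traj$times[traj$times >= 15])
pk  <- peak_analysis(flow_structure_factor(vf))
dr  <- chemotactic_drift(traj, t_burn = 15)
ac  <- velocity_autocorrelation(traj, t_min = 15)
c(vortex_um = pk$vortex_size, v0 = dr$v0,
  coeff = dr$coefficient, tau_dec = ac$tau_dec)
#> vortex_um          v0       coeff     tau_dec
#>  16.00000    17.02895  0.00416927   0.4685843
```

Read: the collective flow concentrates at eddies of ~16 um (set by the
channel height, not the cell length); the chemotactic coefficient
0.0042 s/um is already ~3.5-fold below its dilute value (~0.015 at area
fraction 0.01, same protocol) because collective reorientations have pushed
the velocity decorrelation time down to 0.47 s — the mechanism by which
collective motion suppresses chemotaxis.

At the dilute end, the theory closes quantitatively: `effective_parameters()`
computes $\tau_m$, $\tau_T$, $\tau_R$ and the total gain from the pathway
constants (not from fits), and `predicted_coefficient()` reproduces the
measured dilute coefficient as a function of the measured $\tau_{dec}$
(see `tests/testthat/test-acceptance.R`, criterion 8).

## Layout

| module | contents |
|---|---|
| `R/hydrodynamics.R` | screened Hele-Shaw kernel, pusher dipoles |
| `R/rod_dynamics.R` | rod suspension simulator (Rcpp core in `src/`) |
| `R/pathway.R` | MWC chemotaxis pathway, sensing-theory parameters |
| `R/flow_analysis.R` | E(q), peaks, autocorrelation, drift, theory |
| `R/fourier_motility.R` | DDM, ISF fits, phase-differential velocimetry |
| `R/synthetic_data.R` | swimmers, renderer, vortex arrays, gradients |
| `R/pipeline.R` | config-driven runs, sweeps, CLI (`inst/cli/chemoflow`) |

The methods vignette (`vignettes/chemoflow-methods.Rmd`) documents the
model, parameter defaults and units, numerical choices, and what the
synthetic-data tests do and do not establish.
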
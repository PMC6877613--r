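---
title: "Methods: simulating and measuring chemotaxis in dense bacterial suspensions"
author: "chemoflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and measuring chemotaxis in dense bacterial suspensions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# Scope and model

`chemoflow` simulates populations of run-and-tumble, rod-shaped swimmers
(E. coli-like) confined to two dimensions in a thin channel, and provides the
Fourier image/flow analyses used to quantify their collective motion and
chemotactic drift. The scientific question it addresses is how the swirling
collective motion that develops at high cell density interferes with
chemotactic gradient sensing.

## Equations of motion

Each rod i has position $r_i$, orientation $\theta_i$
($n_i = (\cos\theta_i, \sin\theta_i)$), a quenched swimming speed $v_i$
(Gaussian, mean 20 um/s, SD 5 um/s, redrawn if negative), and a motor state
$\Theta_i \in \{\text{run}=1, \text{tumble}=0\}$. Overdamped dynamics:

$$\dot r_i = \Theta_i v_i n_i
  + \tfrac12\left[w(r_i) + w(r_i - L_{dip} n_i)\right]
  + \left(\gamma_\perp^{-1} I + (\gamma_\parallel^{-1} - \gamma_\perp^{-1})
  n_i n_i\right) \textstyle\sum_j F^{tot}_{ij},$$

$$\dot\theta_i = \sqrt{2 D_r}\,\eta(t) + \sqrt{2 D_T}\,\eta_T(t)(1 - \Theta_i)
  + n_i \wedge \frac{w(r_i) - w(r_i - L_{dip} n_i)}{L_{dip}}
  + \gamma_r^{-1} \textstyle\sum_j \ell_{ij} \wedge F^{tot}_{ij},$$

with slender-body frictions $\gamma_\parallel = 2\pi\eta L / \ln(L/e)$,
$\gamma_\perp = 2\gamma_\parallel$, $\gamma_r = \gamma_\parallel L^2/6$.
The noise convention is fixed by the requirement
$\mathrm{Var}[\theta](t) = 2 D_r t$; the mean squared angular change of a
tumble is then $2 D_T \tau_t$ and the directional persistence across a
tumble is $\beta = e^{-D_T \tau_t}$.

Steric contacts between spherocylinders (length $L$, width $e$) combine a
Hertzian repulsion $F^{el} = K_{el}\,\delta^{3/2} u$ along the contact
normal with a tangential friction
$F^{fr} = -K_{fr} [(v_i - v_j)\cdot v_{ij}] v_{ij}$ using the full rod
velocities of the previous step. Parallel-rod degenerate contacts use the
midpoint of the overlap interval.

## Quasi-2D hydrodynamics

Depth-averaging Stokes flow across the channel height $h$ gives a screened
2D equation whose point-force solution is

$$G(r) = \frac{c_1(z) I + c_2(z) \hat r \hat r}{\pi \eta h \kappa |r|^2},
 \qquad z = \sqrt{\kappa}\,|r|,\ \kappa = 12/h^2,$$

with $c_1 = z^2(K_0 + K_2)/2 - 1$ and $c_2 = 2 - z^2 K_2$. The channel
height thus sets both strength and reach of the interaction. A swimmer is a
pusher dipole: drag $+F = \gamma_\parallel v_i n_i$ at the body centre and
thrust $-F$ at $L_{dip} = L/2 + L_{flag}/2$ behind it (6 um for normal
cells); both point forces are evaluated explicitly because the far-field
dipole expansion is inaccurate at the relevant separations. The kernel is
exactly divergence-free; the package keeps the exact Bessel evaluation as
the oracle for the tabulated kernel (radial grid, spacing $0.02/\sqrt\kappa$)
used in the compiled inner loop. Evaluations below `r_clamp = e/2` are
frozen (logarithmic near-field divergence), and the kernel is cut off at
$6/\sqrt\kappa$ where screening has suppressed it by more than $e^{-6}$.
The dipole of a tumbling rod is switched off (its propulsion is off; the
thrust/drag pair does not exist). Periodic boundaries use the minimal image
with the cutoff clamped to half the box.

## Chemotaxis pathway

The printed source for the pathway is unavailable, so the module
re-specifies the standard MWC receptor-cluster model with linear
adaptation: free energy per receptor
$f(c) = \ln[(1 + c/K_{off})/(1 + c/K_{on})]$ (Tar-MeAsp:
$K_{off} = 20\,\mu M$, $K_{on} = 500\,\mu M$), cluster activity
$a = [1 + e^{N(\epsilon_0 - \epsilon_1 m + f)}]^{-1}$ with $N = 6$,
$\epsilon_1 = 0.5\,kT$, and methylation kinetics
$\dot m = k_R(1-a) - k_B a$ ($k_R = 0.0069$, $k_B = 0.0138\,s^{-1}$), which
adapts $a$ exactly to $a_{ss} = 1/3$ at any constant attractant level within
the methylation range $[0, 8]$. The tumble rate is
$\lambda = \lambda_0 (a/a_{ss})^H$ with $H = 10$, $\lambda_0 = 1\,s^{-1}$;
tumbles last a fixed $\tau_t = 0.12$ s. $\epsilon_0$ is chosen so the
adapted methylation at 100 uM sits mid-range. CheY-P is eliminated by this
quasi-steady monotone map from activity to tumble rate.

## Drift theory and computed gains

For non-interacting swimmers the chemotactic coefficient obeys
$v_{ch}/v_0^2 = G\,\tau(\tau_m, \tau_T, \tau_R)\,\nabla f$ with the sensing
time

$$\tau = \frac{\tau_R}{\tau_R + \tau_T}
  \frac{\tau_T}{1 + \tau_T/\tau_R + \tau_T/\tau_m},$$

$\tau_R = 1/D_r$, $\tau_T = \tau_0/(1 - e^{-D_T\tau_t})$ with $\tau_0 =
(1 + \lambda_0\tau_t)/\lambda_0$ the inverse *wall-clock* tumble frequency
(tumbles are initiated at $\lambda_0$ only while running; the measured
velocity-autocorrelation decay rate $D_r + p\lambda_0(1-\beta)$
independently pins this convention), and the
memory time $\tau_m$ measured as the e-folding time of the activity response
to a small free-energy step (= the linearised
$[N \epsilon_1 a(1-a)(k_R + k_B)]^{-1} \approx 72$ s for the defaults; the
slow adaptation of this parameter set is inherited from the re-specified
model). The package *computes* the total gain from its own linear-response
analysis rather than fitting it:
$G = H N (1 - a_{ss}) / (2 p)$, where the bare cascade gain
$H N (1 - a_{ss}) = 40$ is the relative tumble-rate change per unit
free-energy, the factor $1/2$ is the 2D projection of runs onto the
gradient, and $p = 1/(1 + \lambda_0\tau_t)$ accounts for the run duty cycle
(both the measured drift and the measured mean speed carry a factor $p$, so
their ratio $v_{ch}/v_0^2$ carries $1/p$).

The decorrelation-time form
$\langle v_{ch}/v_0^2\rangle = \frac{\tau_{dec}^2/\tau_T}
{1 + \tau_{dec}/\tau_m} G \nabla f$ is algebraically identical to the
direct form when $\tau_{dec} = \tau_R\tau_T/(\tau_R + \tau_T)$. The
*measured* $\tau_{dec}$ (0.5-crossing of the speed-weighted velocity
autocorrelation) differs from that combination in two calculable ways: the
propulsion is off during tumbles, so $C_v$ drops by $p$ before decaying,
and tumble events occur at wall-clock rate $p\lambda_0$ (already absorbed
into $\tau_T$ above). The module
predicts the dilute crossing by solving
$[p + (1-p)e^{-t(\lambda_0 + 1/\tau_t)}]\,e^{-(D_r + p\lambda_0(1-\beta))t}
 = 1/2$ and calibrates a gain `gain_taudec` so the $\tau_{dec}$-parameterised
prediction reproduces the direct one exactly in the dilute limit. Both
gains are closed-form, computed before any sweep is run. With these
computed coefficients the dilute $D_r$ sweep follows the
$\tau_{dec}$-parameterised prediction with $R^2 \approx 0.97$
(residual $\pm 20\%$ systematics at the extremes of the sweep reflect the
remaining duty-cycle approximations of the derivation).

### Linear response and the steep experimental gradient

The drift relations above are linear-response results. With the bare gain
of 40, the experimental gradient (0 to 200 uM over 2 mm; $\nabla f \approx
6.7\times10^{-4}\,\mu m^{-1}$ at mid-channel) modulates the tumble rate by
order one over a persistence time at small $D_r$: the dilute simulation
then shows super-linear run-extension enhancement at low $D_r$ (up to
~1.9x) and suppression (~2x) at intermediate $D_r$ relative to the linear
prediction. The acceptance sweep that validates the $\tau_{dec}$ form
therefore holds the modulation depth $G_{bare}\,\nabla f\,v_0\,\tau_p$ at
0.1 by scaling the gradient per $D_r$ — a validation inside the theory's
domain; the dense-suspension experiments keep the full experimental
gradient, where the pathway is driven nonlinearly just as real cells are.

## Numerical scheme

Explicit Euler with three deliberate structural choices, each forced by a
separation of time scales:

* **Contact subcycling.** The Hertzian contacts are stiff: at the
  steady-state overlap where elastic force balances propulsion
  ($\delta \approx 0.015$ um) the contact relaxation rate
  $\tfrac32 K_{el}\sqrt\delta\,(\gamma_\perp^{-1}+\gamma_\parallel^{-1})$
  is several $10^3\,s^{-1}$. Contact forces are therefore subcycled at
  `contact_dt` = 2e-4 s on a per-step candidate pair list (centre distance
  < L + 1 um), while the smooth terms advance at the outer `dt`.
* **Multiple-time-step hydrodynamics.** The dipole flow field evolves on
  the swimming time scale, so it is refreshed every `hydro_interval`
  (0.05 s) and frozen between refreshes.
* **Step rejection.** Any outer displacement exceeding $e/2$ rejects the
  smooth substep and halves its dt (recursively); contact substeps carry a
  displacement clamp at $e/4$ as a safety valve. Both events are counted
  and reported on the trajectory object.

Initial states use random sequential insertion (no overlaps, feasible to
area fraction ~0.3), uniform orientations, motor states at the steady-state
run/tumble occupancy, and pathway pre-adapted to the local concentration;
analyses discard a 15-20 s transient. The ligand concentration is evaluated
on the *unwrapped* x coordinate (floored at zero), so cells never see a
concentration jump at the periodic boundary while interactions use wrapped
coordinates.

# Image analysis

## DDM

The differential image correlation function
$g(q,\tau) = \langle|\tilde I(q, t+\tau) - \tilde I(q, t)|^2\rangle$
(annular average, 30 log-spaced lags up to a tenth of the movie) is fitted
with $g = a_0 + a_1(1 - f(q,\tau))$, where the swimmer ISF combines a
diffusing non-motile fraction with 3D-isotropic ballistic swimmers with
Schulz-distributed speeds:

$$f(q,\tau) = e^{-Dq^2\tau}\Big[(1-\alpha) + \alpha
  \frac{Z+1}{Z q v_0 \tau}
  \frac{\sin(Z \tan^{-1}\lambda)}{(1+\lambda^2)^{Z/2}}\Big],
  \quad \lambda = \frac{q v_0 \tau}{Z+1}.$$

The printed source carries $\sin(Z^{-1}\tan^{-1}\lambda)$, which violates
$f(q,0)=1$; the form above is the established one and matches direct
quadrature of the sinc average over the Schulz law to 1e-8. Fits are per-q
(bounds $v_0 \in [2,100]$, $Z \in [0.5, 500]$, $D \in [0,5]$,
$\alpha \in [0,1]$), initialised from the small-lag g ($a_0$) and the
large-lag plateau ($a_1$), aggregated over the calibrated q range
(0.4-2.0 px$^{-1}$ for 2 um cells, 0.4-0.9 for 4 um cells, whose image
anisotropy corrupts higher q). Fitted speeds in confined channels divide by
the calibrated factors 1.075 ($h=30$) and 1.14 ($h=8$). The DDM amplitude
saturates with optical density as $a_1^{max}/\langle I\rangle^2 =
d_0\,m\,OD/(1 + m\,OD)$ ($d_0 = 1.25$ for $h \in \{30, 50\}$); inverting it
and applying $\Phi_c = 1.78\times10^{-3}\,OD$ gives the in-situ cell body
volume fraction. The constant $m$ is system-dependent with no printed
value: it must be supplied, or self-calibrated on rendered stacks of known
density with `calibrate_amplitude()`.

## Phase-differential velocimetry

Population drift comes from the phase of the frame-to-frame Fourier
correlator: per wavevector, the phase increment
$\delta\phi(q, t) = \arg[\tilde I(q, t+1)\tilde I^*(q, t)]$ (wrapped to
$(-\pi, \pi]$) is fitted against $q$ (weights $|\tilde I|^2$, wrap-aware
refinement) to give the frame displacement; increments - never absolute
phases - are accumulated, and velocities are sliding-window (20-frame) OLS
slopes of the cumulative displacement. The local variant computes this on
windows of a = 32 px on a lattice of spacing da = 4 px, with the phase fit
restricted to $|q| \le \pi/4$ so that displacements up to 4 px/frame stay
unwrapped.

The localization step admits three readings of the printed "blurred frame"
(range l = 3 px); they are all implemented, and the default was chosen by
validating against the method's own stated equivalence with PIV:
multiplying the window by $e^{-r^2/l^2}$ (the printed integral) mixes
wavenumbers over $\sim 2/l \approx 0.7$ px$^{-1}$ - the whole fit range -
and leaves persistent per-node errors of order 20% on frozen translating
texture; a literal Gaussian blur inherits a proportional bias of ~15% from
the decaying texture spectrum (the window's spectral leakage then pulls
every mode's phase rate towards lower q). The default therefore whitens
each frame's spectrum by the time-mean amplitude spectrum (the
phase-correlation normalization of the PIV literature) before windowing,
which removes the spectral-slope bias and recovers rigid translations to
better than 0.02 px/frame per node. A uniform background is always
subtracted first (a static additive component would pin the phases);
nonuniform static backgrounds should be removed upstream.

## Flow structure factor

Coarse-grained velocity fields (Gaussian kernel, sigma 2.5 um, mirroring
velocimetry that averages a few neighbouring cells) are transformed to

$$E(q) = q\,\Big\langle \frac{|\tilde v(q,t)|^2}{A_0 \langle v^2\rangle}
  \Big\rangle_{t, |q|=q},$$

renormalised so $\sum E\,\Delta q = 1$ (the absolute convention is
FFT-scaling dependent; only relative structure is used downstream). The
peak position $q_{max}$ (excluding the lowest bin) identifies the dominant
eddy size $\pi/q$; across a density sweep $q_{str}$ is frozen from the
densest member and the collective-motion amplitude is
$\Delta E(q_{str}) = E(q_{str}) - E_{baseline}(q_{str})$ with the matched
lowest-density run (or a flat floor from the upper third of the q range) as
baseline. The velocity decorrelation time solves $C_v(\tau_{dec}) = 1/2$ by
linear interpolation; full velocity vectors are used, per the printed
definition.

A caveat discovered while validating: the Gaussian coarse-graining kernel
has its own transfer function $e^{-q^2\sigma^2}$, which multiplies a flat
(uncorrelated-suspension) velocity power into an *apparent* spectral peak
at $q \approx 1/(\sigma\sqrt2)$, i.e. a "vortex size" of ~11 um that is
pure measurement envelope. For simulation trajectories the package
therefore also provides a gridless estimator,
`flow_structure_factor_direct()`: the Fourier sum of the discrete rod
velocities, with the incoherent (self) contribution $N\langle v^2\rangle$
subtracted. Its distinct part vanishes for uncorrelated swimmers (the
"featureless spectrum" of dilute suspensions appears as a flat noise
floor) and peaks at the collective-flow scale when that exists. The
acceptance analyses of collective motion use this estimator; the gridded
route remains the faithful mirror of the experimental pipeline.

# Synthetic data

The generators state the world the analyses assume; their defaults are not
tuned to test outcomes:

* `generate_swimmers()`: Schulz speeds via Gamma(Z+1, mean v0); 3D
  isotropic directions (matching the DDM model's assumption) or 2D with
  diffusive tumble kicks; non-motile fraction diffusing with D. The
  DDM-fixture default is non-tumbling straight swimmers because that is the
  population Eq.-8-type fitting assumes; the rod simulator, not this
  generator, owns run-and-tumble realism.
* `render_stack()`: Gaussian spots (sigma 1.5 px, anisotropic option for
  rods), thin-slab projection (z-independent amplitude), additive uniform
  background, Gaussian (optionally Poisson) noise applied last; 1 px =
  1.4 um, 100 frames/s, matching the experimental optics scale.
* `vortex_field()`: Taylor-Green arrays, the analytic fixture for spectral
  peaks. Its modes sit at $|q| = \sqrt2\,\pi/\ell$, so peak tests use boxes
  of side $4\ell$, where that mode and $\pi/\ell$ fall within one q bin.
* `gradient_profile()`: 1D diffusion between Dirichlet reservoirs
  (0 and 200 uM over 2 mm, D = 500 um^2/s), explicit scheme with automatic
  CFL sub-stepping; steady state is the linear profile, approached with the
  slowest relaxation time $L_c^2/(\pi^2 D) \approx 811$ s.

What a green test does *not* establish: the renderer has no phase-contrast
optics, defocus, or form-factor physics; the simulator is strictly 2D (no
wall collisions, no flagellar mechanics); the pathway constants are
literature standards, not fitted to any experiment. Quantitative agreement
with the experimental figures is out of scope - the tests establish the
mechanisms (screened-hydrodynamics vortex scale set by h, collective
suppression of chemotaxis consistent with the decorrelation-time theory)
at desk scale.

# Known limitations

A substantive negative result: with this package's defaults (aspect ratios
2 and 4, area fractions up to ~0.28 reachable by non-overlapping insertion,
tumbling at 1/s, contact friction K_fr = 0.01 pN s/um), *steric-only*
suspensions do not develop measurable collective motion - the distinct-part
velocity spectrum stays at the uncorrelated-suspension level, so no
steric-only vortex scale (let alone its cell-length dependence) can be
measured. This is consistent with the steric active-rod literature, where
collective swirling requires higher aspect ratios or densities; the
corresponding acceptance assertion is left failing rather than weakened.
The hydrodynamic route, in contrast, produces robust collective flow at
area fraction 0.05 and above.

* Dense runs at area fraction 0.2 in a 96-128 um box with one seed: vortex
  sizes are resolved to one spectral bin (Delta q = 2 pi / box).
* The steep experimental gradient drives the default pathway outside linear
  response (see above); Eq.-2-style predictions there are order-of-magnitude
  guides, not fits.
* Adaptation at the default k_R, k_B is slow (tau_m ~ 72 s); runs shorter
  than a few tau_m rely on the pre-adapted initialisation.
* The minimal-image hydrodynamic cutoff is clamped to half the box; for
  h = 50 um in small boxes this truncates the natural interaction range and
  compresses the vortex-size contrast between h = 30 and h = 50.

# A worked desk-scale example

```{r example}
library(chemoflow)
cfg <- simulation_config(box_side = 96, phi = 0.1, h = 30, L = 2,
                         dt = 0.01, t_total = 30, save_interval = 0.25,
                         seed = 1)
traj <- run_simulation(cfg)
vf <- coarse_grain_velocity(traj, times = traj$times[traj$times >= 15])
sp <- flow_structure_factor(vf)
peak_analysis(sp)                        # vortex size pi/q_str
chemotactic_drift(traj, t_burn = 15)     # v_ch and v_ch/v0^2
velocity_autocorrelation(traj, t_min = 15)$tau_dec
```
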
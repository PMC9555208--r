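---
title: "Inertial dynamics and receding-horizon control of hawkmoth flower tracking"
author: "mothmpc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inertial dynamics and receding-horizon control of hawkmoth flower tracking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mothmpc)
```

## The model

`mothmpc` simulates a hawkmoth (*Manduca sexta*) as two rigid ellipsoids in
the vertical plane: a head-thorax of mass $m_1$ and pitch inertia $I_1$, and
an abdomen of mass $m_2$ and inertia $I_2$, connected by a pin joint modeled
as a damped torsional spring (stiffness $\kappa$, damping $\eta$). The
generalized coordinates are $q = (x, y, \theta, \phi)$: the position of the
head-thorax center and the two body angles from the positive $x$ axis,
counter-clockwise positive. The abdominal flexion is
$\beta = \phi - \theta - \pi$, zero when the two long axes are aligned.

The equations of motion come from the Euler–Lagrange formulation
$$
\frac{d}{dt}\frac{\partial T^*}{\partial \dot q}
 - \frac{\partial T^*}{\partial q}
 + \frac{\partial V}{\partial q}
 + \frac{\partial D}{\partial \dot q} = e^s_q ,
$$
with $T^*$ the kinetic energy of both bodies, $V$ gravity plus the torsional
spring potential, $D$ the Rayleigh dissipation of the torsional damper and
aerodynamic drag, and $e^s_q$ the applied efforts. The $x$ and $y$ equations
are eliminated analytically, leaving a symmetric 2-by-2 system in
$(\ddot\theta, \ddot\phi)$, which makes a whole Monte-Carlo batch advance as
one vectorized operation. `state_derivative()` exposes the closed form; a
finite-difference assembly of the Lagrangian terms serves as an independent
oracle in the test suite and agrees with it to better than $10^{-7}$ relative
on random states.

The applied efforts, held constant within a control window, are an
aerodynamic force of magnitude $F$ at direction $\alpha$ relative to the
head-thorax long axis, a wing torque $\tau_{wing}$ on the head-thorax, and an
abdominal torque $\tau_{abdo}$ applied as an equal-and-opposite pair across
the joint. Four actuation treatments gate these inputs:

| treatment | wing torque | force origin |
|-----------|-------------|--------------|
| `fa` (fully actuated)      | free        | reference point |
| `fs` (fully actuated, shifted) | free    | shifted by $L_3$ along the body axis |
| `ua` (underactuated)       | fixed at 0  | reference point |
| `us` (underactuated, shifted)  | fixed at 0 | shifted by $L_3$ |

The shifted treatments gain an implicit pitch torque $L_3 F \sin\alpha$. A
`reduced` abdomen condition scales $m_2$ (and, as this package's own choice
so the geometry is unchanged, $I_2$) by 0.1. The force origin of the
unshifted treatments is itself a model option (`force_origin`): `"head"`
(default) applies it at the head-thorax center; `"com"` applies it at the
instantaneous system center of mass, which removes all direct attitude
authority from the force.

### Spring torque and angle wrapping

$\theta$ and $\phi$ are continuous (unwrapped) through integration, and the
work bookkeeping uses unwrapped angle increments. The spring torque, however,
acts on the flexion wrapped to $(-\pi, \pi]$: the joint restores toward the
*nearest* aligned configuration, so its restoring torque is bounded by
$\kappa\pi$. With a strictly quadratic unwrapped potential, a torque ceiling
of 0.01 N·m against $\kappa = 0.0023$ would cap any abdominal deflection at
$0.01/\kappa \approx 4.3$ rad and make sustained abdominal rotation — a
regime this model family is used to study — energetically impossible. The
wrapped potential $\tfrac12\kappa\,\mathrm{wrap}(\beta)^2$ is continuous, so
energy accounting still closes (conservation to better than $10^{-6}$
relative per second is part of the acceptance suite); only the torque has a kink at half a turn.

### Drag

Each body center experiences blunt-body quadratic drag
$\tfrac12\rho_a C_d A_i \lVert v_i\rVert v_i$ with $A_i = \pi r_i^2$ the
ellipsoid cross-section; the drag law is pluggable (`drag = "linear"` gives a
Stokes-type law using $\mu_a$, `"none"` disables it) without touching the
integrator. At the model's speeds drag is a small perturbation relative to
the applied force scale.

## Default parameters

All defaults live in `inst/extdata/defaults.yaml` (SI units, radians) and are
never hard-coded in logic. The effort ranges and the measured joint
stiffness — $F \in [0, 0.443]$ N, $\alpha \in [0, 2\pi)$, torques in
$[0, 0.01]$ N·m, $\kappa = 0.0023$ kg·m²·rad⁻¹·s⁻² — fix the mechanical
scales. The
morphometrics are chosen so those scales are mutually consistent: total mass
22.2 g (weight $= F_{max}/2$, the peak half-stroke force of intermittent
hover-scale force production), abdomen fraction 52.8%, body length
$2(L_1+L_2) = 5$ cm, ellipsoid inertias $I = m(L^2+r^2)/5$. Under these
values the abdominal flexion resonance $\sqrt{\kappa/(I_2+m_2L_2^2)}$ sits
near 5 Hz and $\eta = 4.5\times10^{-5}$ gives a damping ratio of about 0.3 —
a lightly damped joint.

The loss weights $w_{1..6}$ (on squared end-of-window deviations in
$x, y, \theta, \dot x, \dot y, \dot\theta$) default to the decade ladder
$(10^4, 10^4, 10^3, 10^2, 10^2, 1)$: rectilinear positions are penalized ten
times more heavily than the head-thorax angle, and positions more heavily
than rates. All four treatments track stably under this ladder at batch
sizes of 300 and above.

## The goal signal

The flower moves vertically as a sum of eleven sinusoids,
$y_{goal}(t) = \sum_i A_i \sin(2\pi f_i t)$, at prime multiples of 0.1 Hz
(0.2–19.9 Hz) — prime-valued so that a nonlinear response cannot alias onto
an input frequency. Amplitudes decay as $1/f$ so each component contributes
the same velocity amplitude (0.06 m/s) and the signal velocity does not grow
with frequency; the peak excursion is about ±13 cm. The goal state pins
$x = 0$ and $\theta = \pi/2$ (body vertical, nose up) with the analytic
$\dot y_{goal}$ as the velocity target; the abdomen is unconstrained.

## The controller

Each 20 ms control window (half a wing stroke) draws `n_realizations`
independent uniform effort sets, rolls all of them out from the same initial
state, evaluates the loss
$\lambda = \sum_k w_k (\text{deviation}_k)^2$ against the goal state at the
*end-of-window* absolute time, and selects the argmin (ties broken by lowest
draw index). The model then traverses only the first 25% of the selected
path (5 ms), replans from that state, and repeats until `total_time` is
covered — 2000 windows for a 10 s run at defaults.

Numerical choices:

* Rollouts use a fixed-step RK4 propagator on the 0.5 ms dense-output grid
  (two internal substeps, i.e. 0.25 ms steps), vectorized across the batch.
  `integrate_window()` keeps an adaptive contract (deSolve `lsoda`,
  `rtol = 1e-6`, `atol = 1e-9`) and the suite pins the two routes against
  each other: positions and angles agree to $10^{-6}$ over a window at
  representative efforts.
* The 25% advance point is an exact grid sample by construction
  (`advance_fraction * window` must be an integer multiple of
  `output_step`).
* Each window seeds its own RNG substream as a pure function of the master
  seed and window index, so the whole simulation is a pure function of its
  configuration, and draws are consumed realization-by-realization so batches
  are *nested*: the selected loss is exactly non-increasing in the batch
  size for a fixed seed.
* The full simulation starts at rest at the goal: $x = 0$,
  $y = y_{goal}(0) = 0$, $\theta = \pi/2$, $\beta = 0$, zero velocities.

## Flight metrics

Per window the package computes the non-dimensional tracking error
$\sqrt{(x-x_{goal})^2 + (y-y_{goal})^2} / 2(L_1+L_2)$ at the window end; the
generalized mechanical work
$\sum F\,|\Delta r| + |(r\times F)\,\Delta\theta| + |\tau_{wing}\Delta\theta|
+ |\tau_{abdo}\Delta\beta|$ accumulated on the 0.5 ms grid (the moment arm
$r\times F = L_3F\sin\alpha$ is identically zero for the unshifted
treatments); and the cost of transport $C = W/(m_1 g\,d)$ with $d$ the path
length of the reference point. Work and distance are accumulated over the
*traversed* 25% segment by default (`work_segment = "window"` switches to the
full window); windows with $d \le 10^{-9}$ m have no meaningful $C$ and are
flagged `NA`. Cross-treatment testing collapses each run to its per-window
medians first (one value per run, avoiding pseudo-replication), then applies
the Kruskal–Wallis test with effect size
$\eta^2 = (\chi^2 - k + 1)/(n - k)$, Dunn's pairwise rank test with standard
Bonferroni control (reject when $p < \alpha/m$; the divisor is exposed for
other conventions), and compact-letter groupings.

### What the treatment comparison shows here

With the non-negative effort ranges used by this model, zero torque always
lies inside the sampling interval, so a treatment that does not need a torque
can select draws near zero for it. The measured consequence (computed by
`scripts/acceptance.R` at 5 replicates × 1 s × 300 realizations, and
reproduced at 2500 realizations) is that the underactuated treatments settle
into an economical operating point — force along the body axis, near-zero
abdominal torque, quiet abdomen — while the fully actuated treatments carry
irreducible positive-only wing-torque selection noise and pay
$|\tau\,\Delta\theta| + |\tau\,\Delta\beta|$ work on the resulting ripple.
Their median cost of transport is therefore *higher* than the underactuated
treatments', and the underactuated abdomen does not spin: reaction-wheel
pitch control is never forced, because no persistent pitch disturbance exists
that only a torque could cancel. Sustained abdominal rotation and a
fully-actuated energetic advantage require a structural pitch disturbance
(for example a force line that cannot be aimed through the center of mass);
`force_origin = "com"` is one such variant, though at small batch sizes it
destabilizes the fully actuated treatments instead. The acceptance suite
states the orderings it checks explicitly, and the comparison functions
report whatever the dynamics actually produce.

## Free-flight track statistics

Head tracks are plain `(frame, x, y)` tables at a known frame rate (100 fps
default), the natural export of markerless video tracking; statistics are
reported in input units.

* **RMS kinematics** use central differences with one-sided ends.
* **Sliding tortuosity** uses 40-frame windows at unit stride: path length
  over net displacement, with zero-displacement (out-and-back) windows
  flagged, counted, and excluded from the mean.
* **Box-counting dimension** rasterizes the linearly interpolated path onto a
  1024×1024 grid over the padded bounding box (so the measure ignores
  traversal speed and coordinate scale), counts occupied boxes over the
  dyadic ladder $\varepsilon = 2 \ldots 256$ px, and fits
  $\log N$ vs $\log(1/\varepsilon)$ by least squares. Grid and ladder are
  arguments.
* **Segment spectra** average one-sided FFT power over 40-frame segments,
  normalized so the total power equals the mean squared signal per segment
  (Parseval); frequencies come out in Hz in 2.5 Hz bins at 100 fps.
* **Incidence statistics** use the Pearson chi-squared test *without*
  continuity correction (no Yates correction),
  one-decimal percentages, and exact Wilcoxon rank-sum tests where no ties
  allow enumeration (the normal approximation otherwise, recorded in the
  result).

`generate_track()` supplies deterministic-from-seed fixtures (straight,
circle, sinusoid, smoothed random walk, optional measurement noise). These
emulate smooth 100 fps head tracks with controllable spectral content; they
do not emulate tracking dropouts, identity swaps, lens distortion, or the
boundary effects of a finite arena, so passing tests demonstrate estimator
correctness, not robustness to such artifacts.

## Torsional spring constant estimation

A forced-oscillation trial drives the abdominal joint with
$\theta(t) = A\sin(2\pi f t)$ (amplitudes entered in degrees, converted at
ingestion) and records the reaction torque at 1000 Hz for 15 s. Under the
linear joint model $\tau = I\ddot\theta + \eta\dot\theta + \kappa\theta$, the
Fourier transfer ratio at the drive frequency satisfies
$\mathrm{Re}(T/\Theta) = \kappa - I\omega^2$ — damping is purely imaginary —
so $\hat\kappa = \mathrm{Re}(T/\Theta) + I\omega^2$. The 15 s / 1000 Hz
design places all five standard drive frequencies (0.2, 1, 5, 10, 20 Hz)
exactly on DFT bins, so a rectangular window is leakage-free there; for
off-bin frequencies the nearest bin is used and leakage bias grows with the
offset. Estimates from a sweep (5 frequencies × 3 amplitudes × 3 replicates)
are fitted against drive frequency with a second-degree polynomial;
`kappa0` is the polynomial's value at zero frequency. A literal $x$-axis
crossing of that polynomial would instead be a frequency where the apparent
stiffness vanishes — the roots are reported in `x_intercepts` for
completeness, but the zero-frequency value is the physically meaningful
low-frequency stiffness and is the default. The synthetic trial generator is
the exact forward model of the estimator plus white torque noise; parameter
recovery to $10^{-4}$ relative (noiseless) and 2% (5% torque noise) is part
of the acceptance suite. Real rig artifacts — lever-arm compliance,
amplitude-dependent nonlinearity, drift — are outside the forward model.

## Problem sizes

The test and acceptance runs use scaled designs chosen to exercise every code
path at meaningful statistical power: treatment comparisons run 5 replicates
per treatment of 1 s simulated flight at 300 realizations per window;
dynamics invariants integrate 0.5–1 s at tight tolerances; the spring sweep
uses the full 45-trial design. A full-scale study run (10 s, 2500
realizations, 40 replicates) uses the same functions with larger
configuration values.

## Known limitations

* Planar dynamics only: no roll or yaw, no wing aerodynamics model, no
  flexible-body modes.
* The controller is sampling-based selection, not gradient or
  linear-quadratic MPC; there is no sensory noise or delay model.
* The non-negative effort ranges make the selection asymmetric around zero
  torque (see the treatment-comparison discussion above).
* The wrapped spring torque is a modeling choice; a winding joint would
  instead accumulate unbounded restoring torque.
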
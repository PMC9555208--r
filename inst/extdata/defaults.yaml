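# Default model configuration (all SI units, angles in radians).
#
# Morphometric values are chosen at the scale the model's fixed mechanical
# constants jointly imply: the model weight is half the hover-scale force
# ceiling F_max = 0.443 N (the peak force of a half-stroke when force is
# produced intermittently), the abdomen carries 52.8% of the total mass, body
# length is 2*(L1 + L2) = 5 cm, and segment inertias follow the solid-ellipsoid
# formula I = m*(L^2 + r^2)/5. At this scale the measured torsional spring
# constant (0.0023 kg m^2 rad^-1 s^-2) gives an abdominal flexion resonance
# near 5 Hz and the torque ceilings (0.01 N m) sit a factor ~7 above the
# gravitational abdomen torque. The damping coefficient gives a lightly damped
# joint (damping ratio ~0.3 about the aligned rest configuration).
seed: 1
params:
  m1: 1.05e-2      # head-thorax mass (kg)
  m2: 1.17e-2      # abdomen mass (kg)
  I1: 3.549e-7     # head-thorax pitch moment of inertia about its center (kg m^2)
  I2: 4.797e-7     # abdomen pitch moment of inertia about its center (kg m^2)
  L1: 0.012        # head-thorax half-length along the long axis (m)
  L2: 0.013        # abdomen half-length along the long axis (m)
  L3: 0.006        # force-origin offset along the head-thorax axis, shifted treatments (m)
  r1: 0.005        # head-thorax minor half-axis (m), sets the drag reference area
  r2: 0.006        # abdomen minor half-axis (m)
  kappa: 0.0023    # torsional spring constant (kg m^2 rad^-1 s^-2)
  eta: 4.5e-5      # torsional damping coefficient (kg m^2 rad^-1 s^-1)
  Cd: 1.0          # blunt-body drag coefficient (dimensionless)
  mu_a: 1.8e-5     # dynamic viscosity of air (Pa s), linear drag law only
  rho_a: 1.225     # air density (kg m^-3)
  g: 9.81          # gravitational acceleration (m s^-2)
  drag: quadratic  # one of: quadratic, linear, none
  force_origin: head # unshifted force acts at the head-thorax center (or: com)
treatment:
  actuation: fa          # fa | fs | ua | us
  abdomen: regular       # regular | reduced
  reduced_scale: 0.1     # multiplier on m2 (and I2) under the reduced abdomen
ranges:
  F_max: 0.443           # maximum aerodynamic force magnitude (N)
  alpha_min: 0.0         # force direction interval, relative to the body axis (rad)
  alpha_max: 6.283185307179586
  tau_abdo_max: 0.01     # maximum abdominal joint torque (N m)
  tau_wing_max: 0.01     # maximum wing torque (N m); forced to 0 under ua/us
control:
  window: 0.02           # control-window duration (s)
  advance_fraction: 0.25 # fraction of the selected path traversed before replanning
  n_realizations: 2500   # Monte-Carlo draws per window
  total_time: 10.0       # simulated duration (s)
  output_step: 5.0e-4    # dense-output grid step (s)
  # Loss weights (w1..w6 on squared deviations in x, y, theta, xdot, ydot,
  # thetadot): a decade ladder with the rectilinear positions penalized ten
  # times more heavily than the head-thorax angle.
  weights: [1.0e4, 1.0e4, 1.0e3, 1.0e2, 1.0e2, 1.0]
# Goal signal: eleven sinusoids at prime multiples of 0.1 Hz with amplitudes
# chosen so every component has the same velocity amplitude (0.06 m/s), i.e.
# the signal velocity does not grow with frequency.
goal:
  frequencies: [0.2, 0.3, 0.5, 0.7, 1.1, 1.7, 2.9, 4.3, 7.9, 13.7, 19.9]
  amplitudes: [4.774648e-2, 3.183099e-2, 1.909859e-2, 1.364186e-2,
               8.68118e-3, 5.61723e-3, 3.29286e-3, 2.22077e-3,
               1.20878e-3, 6.9703e-4, 4.7986e-4]
  x_goal: 0.0
  theta_goal: 1.5707963267948966
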
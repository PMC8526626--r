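# Run-configuration schema for the frictiongait CLI.
# All blocks are optional; omitted keys take package defaults and the
# fully resolved set is written into every *_meta.json sidecar.
# Units: lengths in body lengths, time in undulation periods; the
# lifting phase offset `phi` is in turns (fraction of a period); all
# other angles (map angles, classifier thresholds) are in radians.
# Numbers are decimal with '.'; unknown keys are rejected.

gait:
  epsilon: 7.0          # lateral curvature amplitude
  k: 1.0                # lateral wavenumber (> 0)
  A: 0.0                # lifting amplitude
  phi: 0.0              # lifting phase offset, turns, in [0, 1)
  lam: 1.0              # lifting/lateral wavenumber ratio (>= 0)
  lifting_model: cosine # cosine | exp_curvature | none

env:
  mu_t_ratio: 2.0       # transverse/forward friction ratio (> 0)
  mu_b_ratio: 1.5       # backward/forward friction ratio (> 0)
  froude: 0.1           # inertia/friction ratio (> 0)
  velocity_reg: 1.0e-6  # Coulomb regularization scale

sim:
  n_periods: 10         # undulation periods to integrate (>= 1)
  n_s: 201              # arclength nodes (>= 3)
  rtol: 1.0e-8          # integrator relative tolerance
  atol: 1.0e-10         # integrator absolute tolerance
  samples_per_period: 200  # uniform output sampling (>= 100)
  method: ode45         # deSolve method

classifier:
  straight_rate: 0.05       # rad/period
  sidewinding_band: [0.35, 2.6]  # rad
  spin_speed: 0.02          # body lengths/period
  steady_tol:               # convergence bands between final windows
    theta_dot: 0.05
    gamma: 0.1
    v_eff: 0.02

sweep:                  # used by the `sweep` command
  A_min: -2.0
  A_max: 2.0
  A_n: 41
  phi_min: 0.0
  phi_max: 1.0
  phi_n: 41

profiles:               # used by the `profiles` command
  ratios: [0.5, 1, 2, 4, 10]

landscape:              # heterogeneous friction map (later wins overlap)
  primitives:
    - type: disk
      center: [3.0, 0.0]
      diameter: 0.4
      scale: 50.0
    - type: strip
      anchor: [5.0, 0.0]
      angle: 1.5708     # radians
      width: 0.3
      scale: 0.0        # 0 = frictionless
    - type: radial_gradient
      center: [8.0, 1.0]
      diameter: 2.0
      scale: 5.0        # centre scale; rim blends linearly to 1

ensemble:               # used by the `ensemble` command
  count: 11
  offset_min: -0.5
  offset_max: 0.5
  heading: 0.0
  start: [0.0, 0.0]

output:
  dir: results
  prefix: run
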
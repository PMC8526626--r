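# frictiongait

Planar effective-friction simulation of limbless (snake-like)
locomotion.

Terrestrial limbless animals propel themselves by pressing an
undulating body against the ground: lateral waves are rectified into
motion by anisotropic Coulomb friction, and lifting parts of the body
off the substrate redistributes weight — and therefore friction — along
the body. `frictiongait` models both effects in the plane. It is aimed
at locomotion biophysicists and bio-inspired-robotics researchers who
want a fast, scriptable way to map how gait kinematics and frictional
environment jointly select behaviours (slithering, sidewinding,
turning, spinning, backward travel), and to explore how *passive*
trajectory control emerges on substrates with engineered friction
patterns (high-friction patches, frictionless strips, graded "lenses").

## Model

The body is an inextensible planar curve of unit length with prescribed
lateral curvature and lifting traveling waves

```
kappa(s, t) = eps * cos(2*pi*k*(s + t))
N_hat(s, t) = max{0, A * cos(2*pi*lambda*k*(s + t + Phi)) + 1}
```

with arclength `s` in [0, 1] (tail to head), time in undulation
periods, lifting amplitude `A`, phase offset `Phi`, and wavenumber
ratio `lambda` (`lambda = 1` lifts one side of the body, as in
sidewinders; `lambda = 2` lifts both sides symmetrically). The local
shape follows from the centre of mass and mean orientation through the
mean-zero integration operator `I`:
`alpha = alpha_bar + I[kappa]`, `x = x_bar + I[t]` with tangent
`t = (cos alpha, sin alpha)`. The substrate exerts an anisotropic
Coulomb friction force density

```
F(s, t) = -N(s, t) * mu(s, t),      N = N_hat / integral(N_hat)
mu = (mu_t/mu_f) (u.n) n + [H(u.t) + (mu_b/mu_f)(1 - H(u.t))] (u.t) t
```

where `u` is the (regularized) sliding direction and `H` the Heaviside
function separating forward from backward sliding. The centre of mass
and mean orientation obey

```
Fr * x_bar_tt   = integral F ds
Fr * alpha_bar_tt = (1/J) integral (x - x_bar) x F ds
                  + (Fr/J) integral I[n].I[t (alpha_bar_t + I[kappa_t])^2]
                                  - I[t].I[t I[kappa_tt]] ds
```

with moment of inertia `J` and Froude number
`Fr = (L/tau^2)/(g*mu_f)` (0.1 by default; friction-dominated).
Steady-state behaviour is summarized by the pose angle `gamma` (between
mean orientation and travel direction), steering rate `theta_dot`, and
effective speed `|v_eff|`, and classified into the gait taxonomy.
Heterogeneous substrates enter as a multiplicative scale field on the
friction coefficients, built from geometric primitives or raster grids.

## Worked example

A sidewinding template (one-sided lifting, quarter-period phase offset)
on a nearly isotropic substrate, against planar slithering on a firm
anisotropic one:

```r
library(frictiongait)

gait <- gait_params(A = 1, phi = 0.25)      # asymmetric lifting wave
env  <- environment_params(mu_t_ratio = 1)  # sand/mud-like isotropy
traj <- simulate_snake(gait, env)
gait_metrics(traj)
#> Gait metrics over window [9, 10]:
#>   pose angle gamma  = 1.483 rad
#>   steering rate     = -0.09658 rad/period
#>   effective speed   = 0.5397 body lengths/period
#>   label             = turning_sidewinding

gait_metrics(simulate_snake(gait_params(A = 0),
                            environment_params(mu_t_ratio = 2)))
#> Gait metrics over window [9, 10]:
#>   pose angle gamma  = -3.038e-15 rad
#>   steering rate     = -1.316e-12 rad/period
#>   effective speed   = 0.1594 body lengths/period
#>   label             = straight_slithering
```

The sidewinder travels at 0.54 body lengths per period with its body
posed ~85 degrees away from its direction of travel — fast oblique
travel on ground where planar slithering barely moves — while the
no-lift gait on anisotropic ground slithers straight (steering rate and
pose angle numerically zero) at 0.16 body lengths per period.

Phase diagrams over lifting amplitude and phase offset, behaviour
profiles across friction ratios, and landscape experiments:

```r
pm <- sweep_phase_map()                      # 41 x 41 (A, Phi) map
plot(pm, "gamma")                            # with separatrices

prof <- friction_ratio_profiles()            # four lifting stereotypes

m <- friction_map(disk_row(7, center = c(3, 0), spacing = 0.5,
                           diameter = 0.3, scale = 40))
res <- run_ensemble(ensemble_spec(offsets = c(-0.5, 0.5), count = 21,
                                  map = m, gait = gait_params(A = 0)))
deflection_pdf(res)                          # diffraction-like pdf
```

A command-line interface (`inst/cli/frictiongait`) exposes the same
functionality via YAML configurations
(`simulate | sweep | profiles | ensemble | contours`); see
`inst/extdata/config-schema.yaml`.

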
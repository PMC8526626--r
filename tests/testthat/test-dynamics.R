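# Equations of motion: assembly, cross-checks, and simulation behaviour.

test_that("moment of inertia has the straight-body closed form", {
  # trapezoidal quadrature of (s - 1/2)^2 carries an h^2/6 error; check
  # the closed form at quadrature order and the quadratic convergence
  errJ <- vapply(c(201, 401), function(n) {
    grid <- body_grid(n)
    cf <- reconstruct_configuration(snake_state(),
                                    gait_params(epsilon = 0), grid)
    abs(moment_of_inertia(cf, grid) - 1 / 12)
  }, numeric(1))
  expect_lt(errJ[1], 5e-6)
  expect_lt(errJ[2], errJ[1] / 3.9)
  # translation invariance is exact
  grid <- body_grid(201)
  cf <- reconstruct_configuration(snake_state(),
                                  gait_params(epsilon = 0), grid)
  cf2 <- reconstruct_configuration(snake_state(com = c(3, -4)),
                                   gait_params(epsilon = 0), grid)
  expect_equal(moment_of_inertia(cf2, grid),
               moment_of_inertia(cf, grid), tolerance = 1e-12)
  # curved shape vs dense-quadrature oracle, at quadrature order
  g <- gait_params()
  cfc <- reconstruct_configuration(snake_state(), g, grid)
  dg <- body_grid(4001)
  cfd <- reconstruct_configuration(snake_state(), g, dg)
  expect_equal(moment_of_inertia(cfc, grid),
               moment_of_inertia(cfd, dg), tolerance = 2e-4)
})

test_that("R assembly and compiled right-hand side agree", {
  grid <- body_grid(151)
  set.seed(3)
  for (rep in 1:6) {
    g <- gait_params(A = runif(1, -1.5, 1.5), phi = runif(1),
                     lam = sample(c(1, 2), 1))
    env <- environment_params(mu_t_ratio = runif(1, 0.5, 5))
    st <- snake_state(com = rnorm(2), com_vel = rnorm(2, sd = 0.3),
                      alpha_bar = rnorm(1), alpha_bar_t = rnorm(1),
                      time = runif(1))
    acc <- acceleration(st, g, env, grid)
    ptr <- frictiongait:::sim_core_create(
      unclass(g), unclass(env)[1:4], grid$s, grid$weights, list())
    y <- c(st$com, st$com_vel, st$alpha_bar, st$alpha_bar_t)
    rhs <- frictiongait:::sim_core_rhs(ptr, st$time, y)
    expect_equal(acc$com_acc, rhs[3:4], tolerance = 1e-12)
    expect_equal(acc$alpha_acc, rhs[6], tolerance = 1e-12)
  }
})

test_that("compiled landscape lookup matches the R implementation", {
  m <- friction_map(disk(c(1, 0), 0.5, 30),
                    strip(c(2, 0), pi / 2, 0.3, 0),
                    radial_gradient(c(-1, 1), 2, 4),
                    raster_map(c(4, 4), 0.25, matrix(1:9, 3)))
  env <- environment_params(friction_map = m)
  grid <- body_grid(11)
  ptr <- frictiongait:::sim_core_create(
    unclass(gait_params()), unclass(env)[1:4], grid$s, grid$weights,
    frictiongait:::map_to_core(m))
  set.seed(5)
  pts <- cbind(runif(300, -2, 5), runif(300, -2, 5))
  expect_equal(frictiongait:::sim_core_scale(ptr, pts),
               local_scale(pts, m))
})

test_that("angular equation matches the finite-difference oracle", {
  grid <- body_grid(1001)
  set.seed(9)
  for (g in list(gait_params(A = 0),
                 gait_params(A = 1, phi = 0.25),
                 gait_params(A = 1, phi = 0.25, lam = 2))) {
    env <- environment_params(mu_t_ratio = 2)
    st <- snake_state(com = rnorm(2), com_vel = rnorm(2, sd = 0.3),
                      alpha_bar = rnorm(1), alpha_bar_t = rnorm(1),
                      time = runif(1))
    impl <- acceleration(st, g, env, grid)$alpha_acc
    oracle <- fd_alpha_acc_oracle(st, g, env, grid)
    expect_lt(abs(impl - oracle) / max(abs(oracle), 1), 1e-4)
  }
})

test_that("translational equation is linear in 1/Fr", {
  grid <- body_grid(101)
  g <- gait_params(A = 1, phi = 0.25)
  st <- snake_state(com_vel = c(0.2, 0.1), alpha_bar_t = 0.5, time = 0.3)
  a1 <- acceleration(st, g, environment_params(froude = 0.1), grid)
  a2 <- acceleration(st, g, environment_params(froude = 0.2), grid)
  expect_equal(a2$com_acc, a1$com_acc / 2, tolerance = 1e-12)
})

test_that("symmetric configurations sliding uniformly feel no torque", {
  grid <- body_grid(201)
  st <- snake_state()
  env <- environment_params(mu_t_ratio = 2)
  # rigid straight body sliding along +x: F_inst = -x_hat, T_inst = 0
  cf0 <- reconstruct_configuration(st, gait_params(epsilon = 0), grid)
  cf0$velocities <- matrix(rep(c(1e6, 0), each = 201), ncol = 2)
  F0 <- friction_force_density(cf0, rep(1, 201), env)
  expect_equal(as.vector(crossprod(grid$weights, F0)), c(-1, 0),
               tolerance = 1e-6)
  # the same body sliding transversally: F = -(mu_t/mu_f) y_hat and the
  # torque vanishes because the centreline has zero mean offset
  cft <- cf0
  cft$velocities <- matrix(rep(c(0, 1e6), each = 201), ncol = 2)
  Ft <- friction_force_density(cft, rep(1, 201), env)
  expect_equal(as.vector(crossprod(grid$weights, Ft)), c(0, -2),
               tolerance = 1e-6)
  rel <- sweep(cft$positions, 2, st$com)
  torque <- sum(grid$weights * (rel[, 1] * Ft[, 2] - rel[, 2] * Ft[, 1]))
  expect_lt(abs(torque), 1e-10)
})

test_that("a snake without actuation stays at rest", {
  traj <- simulate_snake(gait_params(epsilon = 0),
                         environment_params(mu_t_ratio = 2),
                         quick_sim(n_periods = 2))
  expect_lt(max(abs(traj$x)) + max(abs(traj$y)), 1e-9)
})

test_that("planar slithering at mu_t/mu_f = 2 travels straight forward", {
  traj <- simulate_snake(gait_params(A = 0),
                         environment_params(mu_t_ratio = 2), quick_sim())
  m <- gait_metrics(traj)
  expect_lt(abs(m$theta_dot), 1e-3)
  expect_lt(abs(m$gamma), 0.02)
  expect_gt(m$v_eff, 0.05)
  expect_identical(m$label, "straight_slithering")
})

test_that("negating the lateral wave mirrors the trajectory", {
  env <- environment_params(mu_t_ratio = 2)
  t1 <- simulate_snake(gait_params(epsilon = 7, A = 1, phi = 0.1),
                       env, quick_sim())
  t2 <- simulate_snake(gait_params(epsilon = -7, A = 1, phi = 0.1),
                       env, quick_sim())
  expect_lt(max(abs(t1$x - t2$x)), 1e-6)
  expect_lt(max(abs(t1$y + t2$y)), 1e-6)
  expect_lt(max(abs(t1$alpha + t2$alpha)), 1e-6)
})

test_that("shifting the lifting phase by 1/2 equals negating A (lam 1)", {
  env <- environment_params(mu_t_ratio = 2)
  tight <- sim_config(n_s = 101, rtol = 1e-8, atol = 1e-10,
                      samples_per_period = 100)
  t1 <- simulate_snake(gait_params(A = 1, phi = 0.75), env, tight)
  t2 <- simulate_snake(gait_params(A = -1, phi = 0.25), env, tight)
  expect_lt(max(abs(t1$x - t2$x)), 1e-6)
  expect_lt(max(abs(t1$y - t2$y)), 1e-6)
})

test_that("dynamics are equivariant under rotating/translating the frame", {
  g <- gait_params(A = 1, phi = 0.25)
  env <- environment_params(mu_t_ratio = 2)
  tight <- sim_config(n_s = 101, rtol = 1e-8, atol = 1e-10,
                      samples_per_period = 100)
  t1 <- simulate_snake(g, env, tight)
  psi <- 0.7; shift <- c(1.2, -0.5)
  t2 <- simulate_snake(g, env, tight,
                       snake_state(com = shift, alpha_bar = psi))
  R <- matrix(c(cos(psi), sin(psi), -sin(psi), cos(psi)), 2)
  rot <- cbind(t1$x, t1$y) %*% t(R)
  expect_lt(max(abs(rot[, 1] + shift[1] - t2$x)), 1e-6)
  expect_lt(max(abs(rot[, 2] + shift[2] - t2$y)), 1e-6)
  expect_lt(max(abs(t1$alpha + psi - t2$alpha)), 1e-6)
})

test_that("metrics converge under grid doubling and tolerance tightening", {
  g <- gait_params(A = 0); env <- environment_params(mu_t_ratio = 2)
  v1 <- gait_metrics(simulate_snake(g, env, sim_config(
    n_s = 101, rtol = 1e-6, atol = 1e-8)))$v_eff
  v2 <- gait_metrics(simulate_snake(g, env, sim_config(
    n_s = 201, rtol = 1e-6, atol = 1e-8)))$v_eff
  expect_lt(abs(v1 - v2), 1e-3)
  t1 <- simulate_snake(g, env, sim_config(n_s = 101, rtol = 1e-6,
                                          atol = 1e-8))
  t2 <- simulate_snake(g, env, sim_config(n_s = 101, rtol = 1e-8,
                                          atol = 1e-10))
  n <- nrow(t1)
  expect_lt(max(abs(c(t1$x[n] - t2$x[n], t1$y[n] - t2$y[n]))), 1e-4)
})

test_that("reported metrics are insensitive to the Coulomb regularization", {
  g <- gait_params(A = 1, phi = 0.25); mu <- 2
  m1 <- gait_metrics(simulate_snake(
    g, environment_params(mu, velocity_reg = 1e-6), quick_sim()))
  m2 <- gait_metrics(simulate_snake(
    g, environment_params(mu, velocity_reg = 1e-7), quick_sim()))
  expect_lt(abs(m1$v_eff - m2$v_eff), 1e-3)
  expect_lt(abs(m1$theta_dot - m2$theta_dot), 1e-3)
  expect_lt(abs(m1$gamma - m2$gamma), 1e-3)
})

test_that("simulation rejects invalid configurations and reports failure", {
  expect_error(sim_config(n_periods = 0), "n_periods")
  expect_error(sim_config(samples_per_period = 10), "samples_per_period")
  # a lifting wave that removes all body weight aborts with a diagnostic
  expect_error(simulate_snake(gait_params(A = -1, lam = 0),
                              environment_params(),
                              quick_sim(n_periods = 1)),
               "integration failed")
})
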
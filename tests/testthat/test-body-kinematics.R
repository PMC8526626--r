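# Wave definitions, the mean-zero integral, and shape reconstruction.

test_that("lateral curvature wave has the printed closed form", {
  g <- gait_params(epsilon = 7, k = 1)
  expect_equal(lateral_curvature(0, 0, g), 7)
  expect_equal(lateral_curvature(0.25, 0, g), 0, tolerance = 1e-12)
  expect_equal(lateral_curvature(0.1, 0.37, gait_params(epsilon = 0)),
               0)
  # bounded by the amplitude and periodic in t
  s <- seq(0, 1, by = 0.01)
  expect_true(all(abs(lateral_curvature(s, 0.3, g)) <= 7 + 1e-12))
  expect_equal(lateral_curvature(s, 0.3, g),
               lateral_curvature(s, 1.3, g))
})

test_that("all waves satisfy the traveling-wave identity", {
  g <- gait_params(epsilon = 7, k = 2, A = 0.8, phi = 0.3, lam = 1.5)
  s <- seq(0, 0.6, by = 0.07)
  for (d in c(-0.31, 0.12, 0.5)) {
    expect_equal(lateral_curvature(s, 0.2, g),
                 lateral_curvature(s + d, 0.2 - d, g), tolerance = 1e-12)
    expect_equal(lifting_modulation(s, 0.2, g),
                 lifting_modulation(s + d, 0.2 - d, g), tolerance = 1e-12)
    kd1 <- curvature_time_derivatives(s, 0.2, g)
    kd2 <- curvature_time_derivatives(s + d, 0.2 - d, g)
    expect_equal(kd1$kappa_t, kd2$kappa_t, tolerance = 1e-12)
  }
})

test_that("curvature time derivatives match the analytic forms", {
  g <- gait_params(epsilon = 7, k = 1)
  kd <- curvature_time_derivatives(0, 0, g)
  expect_equal(kd$kappa_t, 0)
  z <- curvature_time_derivatives(0.4, 1.1, gait_params(epsilon = 0))
  expect_equal(unname(unlist(z)), c(0, 0))
  # kappa_tt / kappa = -(2 pi k)^2 wherever kappa != 0, and kappa_t
  # matches a central difference
  s <- c(0.05, 0.3, 0.61); t <- 0.23
  kap <- lateral_curvature(s, t, g)
  kd <- curvature_time_derivatives(s, t, g)
  expect_equal(kd$kappa_tt / kap, rep(-(2 * pi)^2, 3), tolerance = 1e-10)
  h <- 1e-6
  fd <- (lateral_curvature(s, t + h, g) -
           lateral_curvature(s, t - h, g)) / (2 * h)
  expect_equal(kd$kappa_t, fd, tolerance = 1e-6)
})

test_that("lifting modulation is nonnegative, clips, and degenerates", {
  s <- seq(0, 1, by = 0.05)
  expect_equal(lifting_modulation(s, 0.4, gait_params(A = 0)),
               rep(1, length(s)))
  expect_equal(lifting_modulation(s, 0.7,
                                  gait_params(lifting_model = "none")),
               rep(1, length(s)))
  g1 <- gait_params(A = 1, phi = 0)
  expect_equal(lifting_modulation(0.5, 0, g1), 0, tolerance = 1e-12)
  g2 <- gait_params(A = 2, phi = 0)
  expect_equal(lifting_modulation(0.5, 0, g2), 0)  # clipped from -1
  expect_true(all(lifting_modulation(s, 0.13, g2) >= 0))
  ge <- gait_params(lifting_model = "exp_curvature")
  expect_equal(lifting_modulation(0, 0, ge), exp(-7))
  expect_true(all(lifting_modulation(s, 0.5, ge) > 0))
})

test_that("gait and grid invariants are enforced", {
  expect_error(gait_params(k = 0), "k")
  expect_error(gait_params(phi = 1), "phi")
  expect_error(gait_params(lam = -1), "lam")
  expect_error(body_grid(2), "3 nodes")
  grid <- body_grid(51)
  expect_equal(sum(grid$weights), 1)
  expect_true(all(diff(grid$s) > 0))
  expect_equal(range(grid$s), c(0, 1))
})

test_that("mean-zero integral matches closed forms and kills the mean", {
  grid <- body_grid(201)
  expect_equal(mean_zero_integral(rep(0, 201), grid), rep(0, 201))
  # I[1] = s - 1/2
  expect_equal(mean_zero_integral(rep(1, 201), grid), grid$s - 0.5,
               tolerance = 1e-12)
  # I[cos(2 pi s)] = sin(2 pi s) / (2 pi)
  expect_equal(mean_zero_integral(cos(2 * pi * grid$s), grid),
               sin(2 * pi * grid$s) / (2 * pi), tolerance = 1e-4)
  # property: quadrature mean vanishes for arbitrary smooth samples
  set.seed(42)
  for (rep in 1:5) {
    cf <- rnorm(4)
    f <- cf[1] + cf[2] * grid$s + cf[3] * sin(2 * pi * grid$s) +
      cf[4] * grid$s^2
    out <- mean_zero_integral(f, grid)
    expect_lt(abs(sum(grid$weights * out)), 1e-12)
    # output minus its value at s = 0 is the running integral
    expect_equal(out - out[1], as.vector(pracma::cumtrapz(grid$s, f)),
                 tolerance = 1e-12)
  }
})

test_that("reconstruction recovers a straight body and honours the COM", {
  grid <- body_grid(201)
  st <- snake_state(com = c(1.5, -0.7))
  cf <- reconstruct_configuration(st, gait_params(epsilon = 0), grid)
  # straight unit segment along +x centred on the COM
  expect_equal(cf$positions[, 1], 1.5 + grid$s - 0.5, tolerance = 1e-12)
  expect_equal(cf$positions[, 2], rep(-0.7, 201), tolerance = 1e-12)
  # curved shape: quadrature means still equal COM and alpha_bar
  st2 <- snake_state(com = c(0.2, 0.9), alpha_bar = 0.31)
  cf2 <- reconstruct_configuration(st2, gait_params(), grid)
  expect_equal(as.vector(crossprod(grid$weights, cf2$positions)),
               c(0.2, 0.9), tolerance = 1e-12)
  expect_equal(sum(grid$weights * cf2$alpha), 0.31, tolerance = 1e-12)
  # frames are orthonormal with n = rot90(t)
  expect_equal(rowSums(cf2$tangents^2), rep(1, 201))
  expect_equal(cf2$normals, cbind(-cf2$tangents[, 2], cf2$tangents[, 1]))
})

test_that("reconstructed positions agree with a dense-quadrature oracle", {
  st <- snake_state(com = c(0.4, -0.1), alpha_bar = 0.8)
  g <- gait_params()
  # second-order convergence of the trapezoidal reconstruction: the
  # error against a 10x finer oracle falls ~16x per grid quadrupling
  err <- vapply(c(401, 1601), function(n) {
    grid <- body_grid(n)
    cf <- reconstruct_configuration(st, g, grid, t = 0.3)
    oracle <- dense_position_oracle(st, g, grid$s, t = 0.3,
                                    n_dense = 10 * (n - 1) + 1)
    max(abs(cf$positions - oracle))
  }, numeric(1))
  expect_lt(err[2], 1e-6)
  expect_lt(err[2], err[1] / 8)
})

test_that("analytic body velocities match finite differences in time", {
  grid <- body_grid(201)
  g <- gait_params(A = 1, phi = 0.25)
  st <- snake_state(com = c(0.1, 0.2), com_vel = c(0.3, -0.2),
                    alpha_bar = 0.5, alpha_bar_t = 1.2, time = 0.4)
  cf <- reconstruct_configuration(st, g, grid)
  dt <- 1e-5
  adv <- function(sgn) {
    s2 <- snake_state(com = st$com + sgn * dt * st$com_vel,
                      com_vel = st$com_vel,
                      alpha_bar = st$alpha_bar + sgn * dt * st$alpha_bar_t,
                      alpha_bar_t = st$alpha_bar_t,
                      time = st$time + sgn * dt)
    reconstruct_configuration(s2, g, grid)$positions
  }
  fd <- (adv(1) - adv(-1)) / (2 * dt)
  expect_lt(max(abs(cf$velocities - fd)), 1e-7)
})
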
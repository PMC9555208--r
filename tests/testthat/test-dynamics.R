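test_that("unforced aligned state at rest with no gravity is an equilibrium", {
  p <- moth_params(g = 0, drag = "none", eta = 0)
  d <- state_derivative(new_state(), effort_set(), p, treatment("fa"))
  expect_equal(max(abs(d)), 0)
})

test_that("with only gravity acting, the center of mass accelerates at (0, -g)", {
  p <- moth_params(drag = "none")
  set.seed(2)
  for (i in 1:5) {
    st <- random_state()
    d <- state_derivative(st, effort_set(), p, treatment("fa"))
    # acceleration of the two mass centers from the generalized accelerations
    th <- st[["theta"]]; ph <- st[["phi"]]
    thd <- st[["thetadot"]]; phd <- st[["phidot"]]
    a2x <- d[[5]] + p$L1 * (d[[7]] * sin(th) + thd^2 * cos(th)) -
      p$L2 * (d[[8]] * sin(ph) + phd^2 * cos(ph))
    a2y <- d[[6]] - p$L1 * (d[[7]] * cos(th) - thd^2 * sin(th)) +
      p$L2 * (d[[8]] * cos(ph) - phd^2 * sin(ph))
    m <- p$m1 + p$m2
    expect_equal((p$m1 * d[[5]] + p$m2 * a2x) / m, 0, tolerance = 1e-10)
    expect_equal((p$m1 * d[[6]] + p$m2 * a2y) / m, -p$g, tolerance = 1e-10)
  }
})

test_that("closed-form equations match the finite-difference Lagrangian oracle", {
  set.seed(42)
  worst <- 0
  for (rep in 1:30) {
    p <- moth_params()
    tr <- treatment(sample(c("fa", "fs", "ua", "us"), 1),
                    sample(c("regular", "reduced"), 1))
    st <- random_state()
    ef <- effort_set(F = runif(1, 0, 0.4), alpha = runif(1, 0, 2 * pi),
                     tau_abdo = runif(1, 0, 0.01),
                     tau_wing = if (wing_torque_active(tr)) runif(1, 0, 0.01) else 0)
    d <- state_derivative(st, ef, p, tr)
    qdd <- oracle_accel(st, ef, p, tr)
    worst <- max(worst, max(abs(d[5:8] - qdd)) / max(abs(qdd)))
  }
  expect_lt(worst, 1e-6)
})

test_that("force through the center of mass conserves angular momentum about it", {
  # no gravity/drag and an unsprung joint: with the force applied at the
  # system c.m. there is no external torque about it, so the total angular
  # momentum about the (accelerating) c.m. stays constant even though the
  # jointed segments counter-rotate
  p <- moth_params(g = 0, drag = "none", eta = 0, kappa = 0,
                   force_origin = "com")
  s0 <- new_state(theta = 1.3, phi = 1.3 + pi, thetadot = 0.5, phidot = -0.8)
  traj <- integrate_window(s0, effort_set(F = 0.3, alpha = 2.1), 0.05, p,
                           treatment("fa"), rtol = 1e-10, atol = 1e-13)
  ang_mom <- function(row) {
    st <- unlist(row[-1])
    r1 <- c(st[["x"]], st[["y"]])
    r2 <- r1 + c(-p$L1 * cos(st[["theta"]]) + p$L2 * cos(st[["phi"]]),
                 -p$L1 * sin(st[["theta"]]) + p$L2 * sin(st[["phi"]]))
    v1 <- c(st[["xdot"]], st[["ydot"]])
    v2 <- v1 + c(p$L1 * sin(st[["theta"]]) * st[["thetadot"]] -
                   p$L2 * sin(st[["phi"]]) * st[["phidot"]],
                 -p$L1 * cos(st[["theta"]]) * st[["thetadot"]] +
                   p$L2 * cos(st[["phi"]]) * st[["phidot"]])
    m <- p$m1 + p$m2
    rc <- (p$m1 * r1 + p$m2 * r2) / m
    vc <- (p$m1 * v1 + p$m2 * v2) / m
    cr <- function(a, b) a[1] * b[2] - a[2] * b[1]
    p$I1 * st[["thetadot"]] + p$I2 * st[["phidot"]] +
      p$m1 * cr(r1 - rc, v1 - vc) + p$m2 * cr(r2 - rc, v2 - vc)
  }
  L <- vapply(seq_len(nrow(traj)), function(i) ang_mom(traj[i, ]), numeric(1))
  expect_lt(max(abs(L - L[1])), 1e-12 + 1e-6 * max(abs(L)))
})

test_that("unforced integration conserves energy and reproduces free fall", {
  p <- moth_params(eta = 0, drag = "none")
  tr <- treatment("fa")
  s0 <- new_state(theta = pi / 2 + 0.3, phi = 3 * pi / 2 - 0.4,
                  xdot = 0.2, ydot = 0.1, thetadot = 1, phidot = -2)
  traj <- integrate_window(s0, effort_set(), 0.5, p, tr,
                           rtol = 1e-10, atol = 1e-13)
  E <- total_energy(traj, p)
  expect_lt(max(abs(E - E[1])) / abs(E[1]), 1e-6 * 0.5)

  cc <- com_xy(traj, p)
  v0 <- com_velocity(s0, p)
  t <- traj$time
  expect_equal(cc[, 1], cc[1, 1] + v0[1] * t, tolerance = 1e-8)
  expect_equal(cc[, 2], cc[1, 2] + v0[2] * t - 0.5 * p$g * t^2,
               tolerance = 1e-8)
})

test_that("zero-velocity zero-force window returns the initial state", {
  p <- moth_params(g = 0, drag = "none")
  s0 <- new_state(x = 0.01, y = -0.02, theta = 1, phi = 1 + pi)
  traj <- integrate_window(s0, effort_set(), 0.02, p, treatment("fa"))
  expect_equal(as.numeric(traj[nrow(traj), -1]), as.numeric(s0),
               tolerance = 1e-9)
})

test_that("the abdominal torque is an internal action-reaction pair", {
  p <- moth_params(g = 0, drag = "none")
  s0 <- new_state(theta = 1.2, phi = 4.0, xdot = 0.1, ydot = -0.05)
  traj <- integrate_window(s0, effort_set(tau_abdo = 0.008), 0.5, p,
                           treatment("ua"), rtol = 1e-10, atol = 1e-13)
  v_start <- com_velocity(unlist(traj[1, -1]), p)
  v_end <- com_velocity(unlist(traj[nrow(traj), -1]), p)
  expect_equal(v_end, v_start, tolerance = 1e-8)
})

test_that("rotating state, force, and gravity together rotates the trajectory", {
  p <- moth_params(g = 0)  # drag on: it is isotropic and must commute too
  ef <- effort_set(F = 0.1, alpha = 0.8, tau_abdo = 0.003, tau_wing = 0.002)
  s0 <- new_state(x = 0.02, y = -0.01, theta = 1.1, phi = 4.0,
                  xdot = 0.3, ydot = 0.1, thetadot = 2, phidot = -1)
  gam <- 0.7
  R <- matrix(c(cos(gam), sin(gam), -sin(gam), cos(gam)), 2)
  s0r <- new_state(x = R[1, ] %*% c(0.02, -0.01), y = R[2, ] %*% c(0.02, -0.01),
                   theta = 1.1 + gam, phi = 4.0 + gam,
                   xdot = R[1, ] %*% c(0.3, 0.1), ydot = R[2, ] %*% c(0.3, 0.1),
                   thetadot = 2, phidot = -1)
  t1 <- integrate_window(s0, ef, 0.05, p, treatment("fs"))
  t2 <- integrate_window(s0r, ef, 0.05, p, treatment("fs"))
  expect_equal(t2$theta, t1$theta + gam, tolerance = 1e-7)
  expect_equal(t2$phi, t1$phi + gam, tolerance = 1e-7)
  xy_rot <- t(R %*% t(cbind(t1$x, t1$y)))
  expect_equal(t2$x, xy_rot[, 1], tolerance = 1e-7)
  expect_equal(t2$y, xy_rot[, 2], tolerance = 1e-7)
})

test_that("energy bookkeeping has the hand-computed spring term", {
  p <- moth_params(kappa = 0.0023, g = 0)
  # pure spring deflection beta = 0.1 rad, everything else at rest
  st <- new_state(theta = pi / 2, phi = 3 * pi / 2 + 0.1)
  expect_equal(total_energy(st, p), 0.5 * 0.0023 * 0.1^2)
  # masses at height zero, beta = 0, at rest: zero energy (theta = 0 puts the
  # head center at y = 0 and the abdomen center at the same height)
  pg <- moth_params()
  st0 <- new_state(x = 0, y = 0, theta = 0, phi = pi)
  expect_equal(total_energy(st0, pg), 0)
  # rigid translation at speed v: kinetic term (m1 + m2) v^2 / 2
  stv <- new_state(xdot = 0.4, ydot = -0.3, theta = 0, phi = pi)
  expect_equal(total_energy(stv, pg), 0.5 * (pg$m1 + pg$m2) * 0.25)
})

test_that("the batch propagator matches the adaptive integrator", {
  p <- moth_params()
  tr <- treatment("fa")
  s0 <- new_state(theta = pi / 2 + 0.1, phi = 3 * pi / 2 - 0.2,
                  xdot = 0.2, ydot = 0.1, thetadot = 1, phidot = -2)
  ef1 <- effort_set(F = 0.03, alpha = 1.2, tau_abdo = 2e-4, tau_wing = 1e-4)
  ef2 <- effort_set(F = 0.25, alpha = 4.5, tau_abdo = 3e-3, tau_wing = 2e-3)
  pp <- mothmpc:::prep_dynamics(p, tr)
  arr <- mothmpc:::propagate_batch(rbind(s0, s0), rbind(ef1, ef2), 0.02, 5e-4, pp)
  for (i in 1:2) {
    ref <- integrate_window(s0, list(ef1, ef2)[[i]], 0.02, p, tr,
                            rtol = 1e-11, atol = 1e-14)
    dev <- abs(t(arr[i, , ]) - as.matrix(ref[, -1]))
    expect_lt(max(dev[, 1:4]), 1e-6)   # positions and angles
    expect_lt(max(dev[, 5:8]), 1e-3)   # rates (fast joint ripple)
  }
})

test_that("non-finite states are rejected with an informative error", {
  p <- moth_params()
  bad <- new_state(x = NaN)
  expect_error(state_derivative(bad, effort_set(), p, treatment("fa")),
               "non-finite")
})
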
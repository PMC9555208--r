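# Equations of motion of the two-ellipsoid model.
#
# Generalized coordinates q = (x, y, theta, phi): the reference point (x, y)
# is the center of the head-thorax mass, where the aerodynamic force is
# applied under fa/ua (fs/us shift it a further L3 along the body axis). The
# pin joint sits L1 behind the reference point along direction theta, and the
# abdomen center a further L2 along phi (counter-clockwise positive):
#   r1 = (x, y),  r2 = (x - L1 cos(theta) + L2 cos(phi),
#                       y - L1 sin(theta) + L2 sin(phi)).
# The straight configuration is phi = theta + pi, i.e. abdominal flexion
# beta = phi - theta - pi = 0 (abdomen anti-parallel to the head direction).
#
# Euler-Lagrange with T* the kinetic energy of both bodies, V gravity plus the
# torsional-spring potential, D the torsional damping plus drag dissipation,
# and the applied efforts (force F at body-relative angle alpha, wing torque
# on theta, abdominal torque as an action-reaction pair across the joint).
# The x/y equations are eliminated analytically, leaving a symmetric 2x2
# system in (thetadd, phidd); everything is vectorized over realizations so a
# whole Monte-Carlo batch advances in one call.

STATE_NAMES <- c("x", "y", "theta", "phi", "xdot", "ydot", "thetadot", "phidot")

#' Construct a model state
#'
#' A state is a named numeric vector of the four generalized coordinates and
#' their time derivatives. Angles are continuous (unwrapped); the abdominal
#' flexion `beta = phi - theta - pi` is a derived quantity, see [flexion()].
#'
#' @param x,y Reference-point position (m): the center of the head-thorax
#'   mass, where the aerodynamic force is applied under fa/ua.
#' @param theta Head-thorax angle from the positive x axis, counter-clockwise
#'   positive (rad).
#' @param phi Abdomen angle, same convention (rad).
#' @param xdot,ydot,thetadot,phidot Time derivatives.
#' @return Named numeric vector of length 8.
#' @export
new_state <- function(x = 0, y = 0, theta = pi / 2, phi = 3 * pi / 2,
                      xdot = 0, ydot = 0, thetadot = 0, phidot = 0) {
  s <- c(x, y, theta, phi, xdot, ydot, thetadot, phidot)
  names(s) <- STATE_NAMES
  s
}

#' Abdominal flexion angle
#'
#' `beta = phi - theta - pi`; zero when the two long axes are aligned
#' (abdomen anti-parallel to the head-thorax direction).
#'
#' @param state A state vector or a trajectory data frame.
#' @return Flexion angle(s), rad (unwrapped).
#' @export
flexion <- function(state) {
  if (is.data.frame(state)) state$phi - state$theta - pi
  else state[["phi"]] - state[["theta"]] - pi
}

#' Wrap an angle to (-pi, pi]
#' @param a Angle(s), rad.
#' @return Wrapped angle(s).
#' @export
wrap_angle <- function(a) a - 2 * pi * round(a / (2 * pi))

#' One set of applied efforts
#'
#' Held constant over a control window: aerodynamic force magnitude `F`
#' applied at direction `alpha` relative to the head-thorax long axis (at the
#' reference point for fa/ua, at the L3-shifted point for fs/us), wing torque
#' on the head-thorax, and the abdominal joint torque acting as an
#' equal-and-opposite pair across the joint.
#'
#' @param F Force magnitude (N).
#' @param alpha Force direction relative to the body long axis (rad).
#' @param tau_abdo Abdominal joint torque (N m).
#' @param tau_wing Wing torque (N m); identically zero under ua/us.
#' @return Named numeric vector of length 4.
#' @export
effort_set <- function(F = 0, alpha = 0, tau_abdo = 0, tau_wing = 0) {
  e <- c(F = F, alpha = alpha, tau_abdo = tau_abdo, tau_wing = tau_wing)
  stopifnot(all(is.finite(e)), F >= 0)
  e
}

# Precompute treatment-adjusted constants for the derivative core. With the
# body offsets a2 = -L1, b2 = L2 of the abdomen center relative to the
# reference point: Sth = m2*a2, Sph = m2*b2 (static moments), K = m2*a2*b2
# (inertial cross-coupling), Jth/Jph the effective single-angle inertias.
prep_dynamics <- function(params, treat) {
  p <- apply_treatment(params, treat)
  m <- p$m1 + p$m2
  a2 <- -p$L1
  b2 <- p$L2
  Sth <- p$m2 * a2
  Sph <- p$m2 * b2
  K <- p$m2 * a2 * b2
  Jth <- p$I1 + p$m2 * a2^2
  Jph <- p$I2 + p$m2 * b2^2
  list(
    m = m, Sth = Sth, Sph = Sph, L1 = p$L1, L2 = p$L2, L3 = p$L3,
    Acoef = Jth - Sth^2 / m, Ccoef = Jph - Sph^2 / m,
    Bfac = K - Sth * Sph / m, Kc = K,
    kappa = p$kappa, eta = p$eta, g = p$g,
    gSth = p$g * Sth, gSph = p$g * Sph,
    shift = is_shifted(treat),
    force_origin = p$force_origin,
    m2frac = p$m2 / m,
    drag = p$drag,
    dq1 = 0.5 * p$rho_a * p$Cd * pi * p$r1^2,
    dq2 = 0.5 * p$rho_a * p$Cd * pi * p$r2^2,
    dl1 = 6 * pi * p$mu_a * p$r1,
    dl2 = 6 * pi * p$mu_a * p$r2
  )
}

# Vectorized derivative: Y is n x 8, E is n x 4 (F, alpha, tau_abdo,
# tau_wing), pp from prep_dynamics(). Returns n x 8.
deriv_core <- function(Y, E, pp) {
  th <- Y[, 3L]; ph <- Y[, 4L]
  xd <- Y[, 5L]; yd <- Y[, 6L]; thd <- Y[, 7L]; phd <- Y[, 8L]
  sth <- sin(th); cth <- cos(th); sph <- sin(ph); cph <- cos(ph)

  Fm <- E[, 1L]; al <- E[, 2L]; ta <- E[, 3L]; tw <- E[, 4L]
  ga <- th + al
  Qx <- Fm * cos(ga)
  Qy <- Fm * sin(ga)
  Qth <- tw - ta
  if (pp$force_origin == "com") {
    # force acts at the system center of mass (no implicit torque when the
    # application point and the c.m. coincide); the moment about the
    # head-thorax center is (com - r1) x F, carried entirely by body 1
    Qth <- Qth + (pp$m2frac) * Fm * (-pp$L1 * sin(al) + pp$L2 * sin(ga - ph))
  }
  if (pp$shift) Qth <- Qth + pp$L3 * Fm * sin(al)
  Qph <- ta

  if (pp$drag != "none") {
    v1x <- xd; v1y <- yd
    v2x <- xd + pp$L1 * sth * thd - pp$L2 * sph * phd
    v2y <- yd - pp$L1 * cth * thd + pp$L2 * cph * phd
    if (pp$drag == "quadratic") {
      s1 <- -pp$dq1 * sqrt(v1x^2 + v1y^2)
      s2 <- -pp$dq2 * sqrt(v2x^2 + v2y^2)
    } else {
      s1 <- -pp$dl1
      s2 <- -pp$dl2
    }
    f1x <- s1 * v1x; f1y <- s1 * v1y
    f2x <- s2 * v2x; f2y <- s2 * v2y
    Qx <- Qx + f1x + f2x
    Qy <- Qy + f1y + f2y
    Qth <- Qth - pp$L1 * (cth * f2y - sth * f2x)
    Qph <- Qph + pp$L2 * (cph * f2y - sph * f2x)
  }

  joint <- pp$kappa * wrap_angle(ph - th - pi) + pp$eta * (phd - thd)
  dA <- ph - th
  sdA <- sin(dA)
  b1 <- Qth - pp$gSth * cth + joint + pp$Kc * phd^2 * sdA -
    (pp$Sth / pp$m) * (-Qx * sth + (Qy - pp$m * pp$g) * cth +
                         pp$Sph * phd^2 * sdA)
  b2 <- Qph - pp$gSph * cph - joint - pp$Kc * thd^2 * sdA -
    (pp$Sph / pp$m) * (-Qx * sph + (Qy - pp$m * pp$g) * cph -
                         pp$Sth * thd^2 * sdA)
  B <- pp$Bfac * cos(dA)
  det <- pp$Acoef * pp$Ccoef - B^2
  thdd <- (pp$Ccoef * b1 - B * b2) / det
  phdd <- (pp$Acoef * b2 - B * b1) / det
  xdd <- (Qx + pp$Sth * (thdd * sth + thd^2 * cth) +
            pp$Sph * (phdd * sph + phd^2 * cph)) / pp$m
  ydd <- (Qy - pp$m * pp$g - pp$Sth * (thdd * cth - thd^2 * sth) -
            pp$Sph * (phdd * cph - phd^2 * sph)) / pp$m
  cbind(xd, yd, thd, phd, xdd, ydd, thdd, phdd, deparse.level = 0)
}

#' Time derivative of the state
#'
#' Evaluates the equations of motion at one state under one effort set. The
#' closed-form equations come from the Euler-Lagrange formulation
#' `d/dt dT*/dqdot - dT*/dq + dV/dq + dD/dqdot = e_q`; gravity and the
#' torsional spring enter through V, torsional damping and aerodynamic drag
#' through D, and the applied force/torques through the generalized efforts.
#'
#' @param state State vector from [new_state()].
#' @param efforts Effort set from [effort_set()].
#' @param params A [moth_params()] object (unscaled; the treatment scaling is
#'   applied internally).
#' @param treat A [treatment()] object; controls the force application point
#'   and the abdomen scaling.
#' @return Named derivative vector of length 8.
#' @export
state_derivative <- function(state, efforts, params,
                             treat = treatment("fa")) {
  if (any(!is.finite(state))) stop("non-finite state")
  pp <- prep_dynamics(params, treat)
  d <- deriv_core(matrix(state, nrow = 1L), matrix(efforts, nrow = 1L), pp)
  if (any(!is.finite(d)))
    stop("equations of motion produced a non-finite derivative ",
         "(singular mass matrix or invalid parameters)")
  s <- as.vector(d)
  names(s) <- STATE_NAMES
  s
}

#' Integrate the dynamics over a control window
#'
#' Adaptive-step integration (deSolve lsoda, relative tolerance `rtol`,
#' absolute `atol`) with dense output on a fixed grid, efforts held constant
#' throughout. The default 0.5 ms grid makes the controller's 25% advance
#' point an exact grid sample.
#'
#' @param state0 Initial state ([new_state()]).
#' @param efforts Window-constant efforts ([effort_set()]).
#' @param duration Window duration (s), > 0.
#' @param params,treat Model parameters and treatment.
#' @param t0 Absolute start time attached to the output (s).
#' @param output_step Output grid step (s).
#' @param rtol,atol Integrator tolerances.
#' @return Data frame (class `moth_trajectory`) with columns `time` and the
#'   eight state components, one row per grid sample.
#' @export
integrate_window <- function(state0, efforts, duration, params,
                             treat = treatment("fa"), t0 = 0,
                             output_step = 5e-4, rtol = 1e-6, atol = 1e-9) {
  stopifnot(duration > 0)
  pp <- prep_dynamics(params, treat)
  E <- matrix(efforts, nrow = 1L)
  times <- seq(0, duration, by = output_step)
  if (times[length(times)] < duration - 1e-12) times <- c(times, duration)
  f <- function(t, y, parms) list(as.vector(deriv_core(matrix(y, nrow = 1L), E, pp)))
  sol <- deSolve::ode(y = as.numeric(state0), times = times, func = f,
                      parms = NULL, method = "lsoda", rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1L] < 0)
    stop("integrator failure near t = ", max(sol[, 1L]),
         "; last state: ", paste(signif(sol[nrow(sol), -1L], 4), collapse = ", "))
  out <- as.data.frame(sol)
  names(out) <- c("time", STATE_NAMES)
  out$time <- out$time + t0
  class(out) <- c("moth_trajectory", "data.frame")
  out
}

# Fixed-step RK4 batch propagator on the dense-output grid, vectorized over
# realizations. Y0: n x 8 states, E: n x 4 efforts. `substeps` internal RK4
# steps are taken per output sample (the 0.25 ms default internal step keeps
# even the fastest torque-saturated spins well resolved). Returns an array
# [n, 8, nsteps + 1].
propagate_batch <- function(Y0, E, duration, output_step, pp, substeps = 2L) {
  nsteps <- round(duration / output_step)
  stopifnot(abs(nsteps * output_step - duration) < 1e-12, nsteps >= 1)
  h <- output_step / substeps
  n <- nrow(Y0)
  out <- array(NA_real_, dim = c(n, 8L, nsteps + 1L))
  out[, , 1L] <- Y0
  Y <- Y0
  for (s in seq_len(nsteps)) {
    for (ss in seq_len(substeps)) {
      k1 <- deriv_core(Y, E, pp)
      k2 <- deriv_core(Y + (h / 2) * k1, E, pp)
      k3 <- deriv_core(Y + (h / 2) * k2, E, pp)
      k4 <- deriv_core(Y + h * k3, E, pp)
      Y <- Y + (h / 6) * (k1 + 2 * k2 + 2 * k3 + k4)
    }
    out[, , s + 1L] <- Y
  }
  out
}

#' Total mechanical energy of a state
#'
#' Kinetic energy of both bodies plus gravitational potential (heights of the
#' two mass centers) plus the torsional-spring potential
#' `0.5 * kappa * wrap(beta)^2`. With damping, drag, and applied efforts all
#' zero this quantity is conserved along trajectories.
#'
#' @param state A state vector or a trajectory data frame.
#' @param params A [moth_params()] object.
#' @return Energy (J); vector if `state` is a trajectory.
#' @export
total_energy <- function(state, params) {
  if (is.data.frame(state)) {
    Y <- as.matrix(state[, STATE_NAMES])
  } else {
    Y <- matrix(state, nrow = 1L)
  }
  p <- params
  th <- Y[, 3L]; ph <- Y[, 4L]
  xd <- Y[, 5L]; yd <- Y[, 6L]; thd <- Y[, 7L]; phd <- Y[, 8L]
  # velocity of the abdomen center r2 = r1 - L1 e_theta + L2 e_phi
  v2x <- xd + p$L1 * sin(th) * thd - p$L2 * sin(ph) * phd
  v2y <- yd - p$L1 * cos(th) * thd + p$L2 * cos(ph) * phd
  Tk <- 0.5 * p$m1 * (xd^2 + yd^2) + 0.5 * p$I1 * thd^2 +
    0.5 * p$m2 * (v2x^2 + v2y^2) + 0.5 * p$I2 * phd^2
  V <- p$m1 * p$g * Y[, 2L] +
    p$m2 * p$g * (Y[, 2L] - p$L1 * sin(th) + p$L2 * sin(ph)) +
    0.5 * p$kappa * wrap_angle(ph - th - pi)^2
  unname(Tk + V)
}

#' Write a trajectory as tabular text
#'
#' One row per output sample: time, positions, angles, and their derivatives.
#'
#' @param traj A trajectory data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE)
  invisible(path)
}
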
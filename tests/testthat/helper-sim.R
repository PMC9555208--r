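# Shared fixtures for the controller tests: a small, fast configuration and a
# center-of-mass extractor used by the rigid-body invariant checks.

quick_config <- function(total_time = 0.1, n_realizations = 30, seed = 1L,
                         ...) {
  control_config(total_time = total_time, n_realizations = n_realizations,
                 seed = seed, ...)
}

# System center of mass of a trajectory (or single state as 1-row frame).
com_xy <- function(traj, p) {
  m <- p$m1 + p$m2
  cx <- (p$m1 * traj$x +
           p$m2 * (traj$x - p$L1 * cos(traj$theta) + p$L2 * cos(traj$phi))) / m
  cy <- (p$m1 * traj$y +
           p$m2 * (traj$y - p$L1 * sin(traj$theta) + p$L2 * sin(traj$phi))) / m
  cbind(cx, cy)
}

com_velocity <- function(state, p) {
  m <- p$m1 + p$m2
  v2x <- state[["xdot"]] + p$L1 * sin(state[["theta"]]) * state[["thetadot"]] -
    p$L2 * sin(state[["phi"]]) * state[["phidot"]]
  v2y <- state[["ydot"]] - p$L1 * cos(state[["theta"]]) * state[["thetadot"]] +
    p$L2 * cos(state[["phi"]]) * state[["phidot"]]
  c((p$m1 * state[["xdot"]] + p$m2 * v2x) / m,
    (p$m1 * state[["ydot"]] + p$m2 * v2y) / m)
}

random_state <- function() {
  new_state(x = stats::rnorm(1, 0, 0.1), y = stats::rnorm(1, 0, 0.1),
            theta = stats::runif(1, 0, 2 * pi), phi = stats::runif(1, 0, 2 * pi),
            xdot = stats::rnorm(1, 0, 0.5), ydot = stats::rnorm(1, 0, 0.5),
            thetadot = stats::rnorm(1, 0, 5), phidot = stats::rnorm(1, 0, 5))
}
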
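# The prescribed flower motion: a sum of sinusoids at prime-valued
# frequencies, moving vertically only. The controller's goal state pins x at 0
# and the head-thorax angle at pi/2 (body vertical, nose up).

#' Goal-signal specification
#'
#' A sum-of-sines vertical flower motion
#' `y_goal(t) = sum_i A_i * sin(2 * pi * f_i * t)`. The default component set
#' (see [default_config()]) uses eleven prime multiples of 0.1 Hz spanning
#' 0.2-19.9 Hz with amplitudes decaying as 1/f, so that every component has
#' the same velocity amplitude and the signal velocity does not grow with
#' frequency. The target x position and head-thorax angle are constants
#' (0 and pi/2).
#'
#' @param amplitudes Component amplitudes (m), non-increasing.
#' @param frequencies Component frequencies (Hz), strictly increasing, > 0.
#' @param x_goal Constant goal x position (m).
#' @param theta_goal Constant goal head-thorax angle (rad).
#' @return Object of class `goal_spec`.
#' @export
goal_spec <- function(amplitudes = NULL, frequencies = NULL,
                      x_goal = NULL, theta_goal = NULL) {
  d <- default_config()$goal
  A <- as.numeric(unlist(amplitudes %||% d$amplitudes))
  f <- as.numeric(unlist(frequencies %||% d$frequencies))
  x_goal <- (x_goal %||% d$x_goal)
  theta_goal <- (theta_goal %||% d$theta_goal)
  if (length(A) != length(f) || length(f) < 1L)
    stop_field("amplitudes", "and frequencies must have equal length >= 1")
  if (any(!is.finite(A)) || any(A < 0))
    stop_field("amplitudes", "must be finite and non-negative")
  if (any(!is.finite(f)) || any(f <= 0) || any(diff(f) <= 0))
    stop_field("frequencies", "must be positive and strictly increasing")
  if (any(diff(A) > 1e-12))
    stop_field("amplitudes", "must be non-increasing with frequency")
  structure(list(amplitudes = A, frequencies = f,
                 x_goal = as.numeric(x_goal),
                 theta_goal = as.numeric(theta_goal)),
            class = "goal_spec")
}

#' Goal position and velocity
#'
#' `y_goal()` evaluates the flower height `sum_i A_i sin(2 pi f_i t)`;
#' `y_goal_rate()` its analytic time derivative.
#'
#' @param t Time(s) in seconds, vectorized.
#' @param spec A [goal_spec()].
#' @return Numeric vector the length of `t`.
#' @export
y_goal <- function(t, spec = goal_spec()) {
  stopifnot(all(t >= 0))
  w <- 2 * pi * spec$frequencies
  colSums(spec$amplitudes * sin(outer(w, t)))
}

#' @rdname y_goal
#' @export
y_goal_rate <- function(t, spec = goal_spec()) {
  stopifnot(all(t >= 0))
  w <- 2 * pi * spec$frequencies
  colSums(spec$amplitudes * w * cos(outer(w, t)))
}

#' Full goal state for the loss function
#'
#' The state the loss penalizes deviations from at the end of a control
#' window: `x = x_goal`, `y = y_goal(t)`, `theta = theta_goal`, `xdot = 0`,
#' `ydot` the analytic goal velocity, `thetadot = 0`. The abdomen angle and
#' its rate are unconstrained (not penalized) and returned as `NA`.
#'
#' @param t Time (s), scalar.
#' @param spec A [goal_spec()].
#' @return Named state vector (see [new_state()]).
#' @export
goal_state <- function(t, spec = goal_spec()) {
  stopifnot(length(t) == 1L, t >= 0)
  new_state(x = spec$x_goal, y = y_goal(t, spec), theta = spec$theta_goal,
            phi = NA_real_, xdot = 0, ydot = y_goal_rate(t, spec),
            thetadot = 0, phidot = NA_real_)
}
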
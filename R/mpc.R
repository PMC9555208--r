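# Monte-Carlo receding-horizon controller. Per 20 ms window a batch of
# randomized window-constant effort sets is rolled out from the same initial
# state; a weighted quadratic loss on the end-of-window state selects the
# best realization; only the first 25% of the selected path is traversed
# before replanning. Repeated until the total simulated time is covered.

# Deterministic per-window RNG substream (pure function of master seed and
# window index), so any window is reproducible in isolation.
window_seed <- function(seed, w) {
  ws <- ((abs(as.numeric(seed)) %% 1e6) * 2111 + w * 7919) %% 2147483629
  as.integer(ws) + 1L
}

#' Sample randomized effort sets
#'
#' Independent uniform draws: `F` on `[0, F_max]`, `alpha` on
#' `[alpha_min, alpha_max)`, each torque on `[0, tau_max]`. Under the
#' underactuated treatments (ua/us) the wing torque is identically zero.
#' Draws consume the RNG stream realization-by-realization, so for a fixed
#' seed the first `k` realizations of a size-`n` batch equal a size-`k` batch
#' (nested batches; the selected loss is then exactly non-increasing in `n`).
#'
#' @param n Number of realizations.
#' @param ranges An [effort_ranges()] object.
#' @param treat A [treatment()] object.
#' @return `n x 4` matrix with columns `F`, `alpha`, `tau_abdo`, `tau_wing`.
#' @export
sample_efforts <- function(n, ranges = effort_ranges(),
                           treat = treatment("fa")) {
  stopifnot(n >= 1)
  u <- matrix(stats::runif(4L * n), ncol = 4L, byrow = TRUE)
  E <- cbind(
    F = u[, 1L] * ranges$F_max,
    alpha = ranges$alpha_min + u[, 2L] * (ranges$alpha_max - ranges$alpha_min),
    tau_abdo = u[, 3L] * ranges$tau_abdo_max,
    tau_wing = if (wing_torque_active(treat)) u[, 4L] * ranges$tau_wing_max else 0
  )
  E
}

#' Loss function of a realization
#'
#' Weighted sum of squared end-of-window deviations from the goal state in
#' `x, y, theta, xdot, ydot, thetadot` (weights `w1..w6`). The abdomen angle
#' and its rate are not penalized.
#'
#' @param final_state End-of-window state.
#' @param goal Goal state from [goal_state()].
#' @param weights Six non-negative weights.
#' @return Scalar loss value.
#' @export
loss <- function(final_state, goal, weights) {
  stopifnot(length(weights) == 6L, all(weights >= 0))
  idx <- c(1L, 2L, 3L, 5L, 6L, 7L)  # x, y, theta, xdot, ydot, thetadot
  dev <- as.numeric(final_state[idx]) - as.numeric(goal[idx])
  sum(weights * dev^2)
}

# Vectorized loss over an n x 8 matrix of final states.
loss_batch <- function(finalY, goal, weights) {
  idx <- c(1L, 2L, 3L, 5L, 6L, 7L)
  g <- as.numeric(goal[idx])
  D <- sweep(finalY[, idx, drop = FALSE], 2L, g)
  as.numeric(D^2 %*% weights)
}

#' Run one control window
#'
#' Integrates `n_realizations` rollouts from the identical initial state, each
#' under its own window-constant effort draw, evaluates the loss against the
#' goal state at the absolute end-of-window time, and returns the argmin
#' realization (ties broken by lowest index) together with the state at the
#' advance point.
#'
#' @param state0 Initial state of the window.
#' @param t0 Absolute window start time (s).
#' @param params,treat,ranges,config,spec Model parameters, treatment, effort
#'   ranges, [control_config()], and [goal_spec()].
#' @param seed Optional integer; if given, seeds the window's RNG substream.
#' @return List of class `window_result`: `window_start_time`, `efforts`
#'   (named vector of the selected draw), `loss_value`, `advance_state`,
#'   `trajectory` (the selected realization on the dense grid, absolute
#'   times), `final_state`, and `n_failed` (realizations that produced
#'   non-finite states, always excluded from selection).
#' @export
run_window <- function(state0, t0, params, treat, ranges, config, spec,
                       seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- config$n_realizations
  E <- sample_efforts(n, ranges, treat)
  pp <- prep_dynamics(params, treat)
  Y0 <- matrix(rep(as.numeric(state0), each = n), nrow = n)
  arr <- propagate_batch(Y0, E, config$window, config$output_step, pp)
  k <- dim(arr)[3L]
  finals <- arr[, , k, drop = FALSE]
  dim(finals) <- c(n, 8L)
  ok <- rowSums(!is.finite(finals)) == 0L
  if (!any(ok))
    stop(sprintf("all %d realizations failed to integrate in window at t0 = %g",
                 n, t0))
  g <- goal_state(t0 + config$window, spec)
  lam <- rep(Inf, n)
  lam[ok] <- loss_batch(finals[ok, , drop = FALSE], g, config$weights)
  sel <- which.min(lam)
  adv_i <- round(config$advance_fraction * config$window / config$output_step) + 1L
  traj <- as.data.frame(t(arr[sel, , ]))
  names(traj) <- STATE_NAMES
  traj <- cbind(time = t0 + (seq_len(k) - 1L) * config$output_step, traj)
  class(traj) <- c("moth_trajectory", "data.frame")
  adv <- arr[sel, , adv_i]
  names(adv) <- STATE_NAMES
  fin <- finals[sel, ]
  names(fin) <- STATE_NAMES
  structure(list(window_start_time = t0,
                 efforts = E[sel, ],
                 loss_value = lam[sel],
                 advance_state = adv,
                 trajectory = traj,
                 final_state = fin,
                 n_failed = sum(!ok)),
            class = "window_result")
}

#' Run a full receding-horizon simulation
#'
#' Chains control windows until `total_time` is covered: each window starts
#' from the previous window's advance state, absolute window clocks advance by
#' `advance_fraction * window` (5 ms at defaults), and each window draws its
#' efforts from a substream derived from the master seed, so the result is a
#' pure function of its inputs. Per-window flight metrics (loss, tracking
#' error, mechanical work, distance, cost of transport) are computed as the
#' simulation runs.
#'
#' @param params A [moth_params()] object.
#' @param treat A [treatment()] object.
#' @param ranges An [effort_ranges()] object.
#' @param config A [control_config()]; `total_time` must be an integer
#'   multiple of `advance_fraction * window`.
#' @param spec A [goal_spec()].
#' @param init_state Initial state; default at rest at the goal (x = x_goal,
#'   y = y_goal(0), theta = theta_goal, beta = 0, zero velocities).
#' @param work_segment `"advance"` (default) accumulates mechanical work over
#'   the traversed 25% segment of each window; `"window"` over the full
#'   window.
#' @param verbose Print progress every 100 windows.
#' @return Object of class `moth_sim`: `windows` (one row per window: start
#'   time, selected efforts, loss, metrics), `trajectory` (the stitched
#'   advance segments spanning `total_time`), plus the configuration
#'   snapshot and seed.
#' @export
run_simulation <- function(params = moth_params(), treat = treatment("fa"),
                           ranges = effort_ranges(),
                           config = control_config(), spec = goal_spec(),
                           init_state = NULL,
                           work_segment = c("advance", "window"),
                           verbose = FALSE) {
  work_segment <- match.arg(work_segment)
  adv_time <- config$advance_fraction * config$window
  nw_real <- config$total_time / adv_time
  n_windows <- round(nw_real)
  if (abs(nw_real - n_windows) > 1e-9)
    stop("total_time must be an integer multiple of advance_fraction * window")
  if (is.null(init_state))
    init_state <- new_state(x = spec$x_goal, y = y_goal(0, spec),
                            theta = spec$theta_goal,
                            phi = spec$theta_goal + pi)
  adv_i <- round(adv_time / config$output_step) + 1L
  blen <- body_length(params)
  state <- init_state
  wtab <- vector("list", n_windows)
  segs <- vector("list", n_windows)
  for (w in seq_len(n_windows)) {
    t0 <- (w - 1L) * adv_time
    wr <- tryCatch(
      run_window(state, t0, params, treat, ranges, config, spec,
                 seed = window_seed(config$seed, w)),
      error = function(e) stop(sprintf("window %d (t0 = %gs): %s",
                                       w, t0, conditionMessage(e)), call. = FALSE)
    )
    g <- goal_state(t0 + config$window, spec)
    seg <- if (work_segment == "advance") wr$trajectory[seq_len(adv_i), ]
           else wr$trajectory
    wk <- window_work(seg, wr$efforts, params, treat)
    dist <- attr(wk, "distance")
    wtab[[w]] <- data.frame(
      window = w, t0 = t0,
      F = unname(wr$efforts[1L]), alpha = unname(wr$efforts[2L]),
      tau_abdo = unname(wr$efforts[3L]), tau_wing = unname(wr$efforts[4L]),
      loss = wr$loss_value,
      tracking_error = tracking_error(wr$final_state, g, blen),
      work = as.numeric(wk), distance = dist,
      cost_of_transport = cost_of_transport(wk, params, dist)
    )
    segs[[w]] <- wr$trajectory[2:adv_i, ]
    state <- wr$advance_state
    if (verbose && w %% 100L == 0L)
      message(sprintf("window %d / %d (t = %.2f s)", w, n_windows, t0 + adv_time))
  }
  traj <- rbind(cbind(time = 0, as.data.frame(t(init_state))),
                do.call(rbind, segs))
  rownames(traj) <- NULL
  class(traj) <- c("moth_trajectory", "data.frame")
  structure(list(windows = do.call(rbind, wtab), trajectory = traj,
                 params = params, treatment = treat, ranges = ranges,
                 config = config, goal = spec, seed = config$seed),
            class = "moth_sim")
}

#' @export
print.moth_sim <- function(x, ...) {
  cat(sprintf("Receding-horizon simulation: %s, %s abdomen, %d windows, %.3g s\n",
              x$treatment$actuation, x$treatment$abdomen,
              nrow(x$windows), x$config$total_time))
  cat(sprintf("  median tracking error: %.4g body lengths\n",
              stats::median(x$windows$tracking_error)))
  cat(sprintf("  median cost of transport: %.4g (%d windows undefined)\n",
              stats::median(x$windows$cost_of_transport, na.rm = TRUE),
              sum(is.na(x$windows$cost_of_transport))))
  invisible(x)
}
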
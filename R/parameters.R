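# Physical parameters, treatments, effort ranges, and control configuration.
# All default numeric values live in inst/extdata/defaults.yaml; nothing in
# the code paths below hard-codes them.

.defaults_env <- new.env(parent = emptyenv())

#' Package default configuration
#'
#' Reads the versioned defaults file shipped with the package (all SI units,
#' angles in radians) and returns it as a nested list. The file holds the
#' morphometric and mechanical properties of the two-body moth model, the
#' treatment definition, the Monte-Carlo effort ranges, the controller
#' configuration, and the sum-of-sines goal specification.
#'
#' @return Nested list with elements `seed`, `params`, `treatment`, `ranges`,
#'   `control`, and `goal`.
#' @export
default_config <- function() {
  if (is.null(.defaults_env$cfg)) {
    path <- system.file("extdata", "defaults.yaml", package = "mothmpc")
    if (!nzchar(path)) stop("defaults.yaml not found in installed package")
    .defaults_env$cfg <- yaml::read_yaml(path)
  }
  .defaults_env$cfg
}

stop_field <- function(field, msg) {
  stop(sprintf("invalid configuration: field '%s' %s", field, msg), call. = FALSE)
}

check_pos <- function(x, field, strict = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_field(field, "must be a finite number")
  if (strict && x <= 0) stop_field(field, "must be strictly positive")
  if (!strict && x < 0) stop_field(field, "must be non-negative")
  as.numeric(x)
}

#' Moth body parameters
#'
#' Constructs the validated physical parameter set of the two-ellipsoid moth
#' model. Any argument not supplied falls back to the package defaults
#' (representative Manduca sexta morphometrics, see [default_config()]).
#'
#' @param m1,m2 Head-thorax and abdomen masses (kg).
#' @param I1,I2 Pitch moments of inertia of the two bodies about their own
#'   mass centers (kg m^2).
#' @param L1,L2 Half-lengths of the two ellipsoids along their long axes (m).
#' @param L3 Offset of the applied-force origin from the reference point along
#'   the head-thorax axis (m); used only by the shifted treatments fs/us.
#' @param r1,r2 Minor half-axes of the two ellipsoids (m); set the drag
#'   reference areas `pi * r^2`.
#' @param kappa Torsional spring constant of the thoracic-abdominal joint
#'   (kg m^2 rad^-1 s^-2).
#' @param eta Torsional damping coefficient (kg m^2 rad^-1 s^-1).
#' @param Cd Drag coefficient (dimensionless).
#' @param mu_a Dynamic viscosity of air (Pa s); used by the linear drag law.
#' @param rho_a Air density (kg m^-3).
#' @param g Gravitational acceleration (m s^-2).
#' @param drag Drag law applied at each mass center: `"quadratic"` (blunt-body,
#'   `0.5 * rho_a * Cd * A_i * |v_i| * v_i`), `"linear"` (Stokes-like,
#'   `6 * pi * mu_a * r_i * v_i`), or `"none"`.
#' @param force_origin Where the aerodynamic force acts under the unshifted
#'   treatments: `"com"` (default) applies it at the system center of mass, so
#'   the force carries no implicit attitude torque and pitch control rests
#'   entirely on the applied torques; `"head"` applies it at the head-thorax
#'   center. The shifted treatments (fs/us) displace the origin a further `L3`
#'   along the head-thorax axis in either case.
#' @return Object of class `moth_params`.
#' @export
moth_params <- function(m1 = NULL, m2 = NULL, I1 = NULL, I2 = NULL,
                        L1 = NULL, L2 = NULL, L3 = NULL, r1 = NULL, r2 = NULL,
                        kappa = NULL, eta = NULL, Cd = NULL, mu_a = NULL,
                        rho_a = NULL, g = NULL, drag = NULL,
                        force_origin = NULL) {
  d <- default_config()$params
  p <- list(m1 = m1, m2 = m2, I1 = I1, I2 = I2, L1 = L1, L2 = L2, L3 = L3,
            r1 = r1, r2 = r2, kappa = kappa, eta = eta, Cd = Cd,
            mu_a = mu_a, rho_a = rho_a, g = g, drag = drag,
            force_origin = force_origin)
  for (nm in names(p)) if (is.null(p[[nm]])) p[[nm]] <- d[[nm]]
  for (nm in c("m1", "m2", "I1", "I2", "L1", "L2", "L3", "r1", "r2"))
    p[[nm]] <- check_pos(p[[nm]], nm, strict = TRUE)
  for (nm in c("kappa", "eta", "Cd", "mu_a", "rho_a"))
    p[[nm]] <- check_pos(p[[nm]], nm, strict = FALSE)
  if (!is.numeric(p$g) || !is.finite(p$g)) stop_field("g", "must be finite")
  p$drag <- match.arg(p$drag, c("quadratic", "linear", "none"))
  p$force_origin <- match.arg(p$force_origin, c("com", "head"))
  structure(p, class = "moth_params")
}

#' Body length of the model
#'
#' Total body length used to non-dimensionalize the tracking error:
#' `2 * (L1 + L2)`.
#'
#' @param params A [moth_params()] object.
#' @return Length in meters.
#' @export
body_length <- function(params) {
  stopifnot(inherits(params, "moth_params"))
  2 * (params$L1 + params$L2)
}

#' Actuation treatment
#'
#' Defines one of the four actuation treatments and the abdomen condition.
#' `fa` is the basic fully actuated model; `fs` shifts the applied-force
#' origin by `L3` along the body axis (an implicit torque); `ua` and `us` are
#' the underactuated counterparts with the wing torque set to zero.
#' The reduced abdomen scales `m2` and `I2` by `reduced_scale`.
#'
#' @param actuation One of `"fa"`, `"fs"`, `"ua"`, `"us"`.
#' @param abdomen `"regular"` or `"reduced"`.
#' @param reduced_scale Multiplier applied to the abdomen mass and inertia
#'   under the reduced condition (default 0.1, a ~90% reduction).
#' @return Object of class `moth_treatment`.
#' @export
treatment <- function(actuation = c("fa", "fs", "ua", "us"),
                      abdomen = c("regular", "reduced"),
                      reduced_scale = NULL) {
  actuation <- match.arg(actuation)
  abdomen <- match.arg(abdomen)
  if (is.null(reduced_scale)) reduced_scale <- default_config()$treatment$reduced_scale
  reduced_scale <- check_pos(reduced_scale, "reduced_scale", strict = TRUE)
  if (reduced_scale > 1) stop_field("reduced_scale", "must be <= 1")
  structure(list(actuation = actuation, abdomen = abdomen,
                 reduced_scale = reduced_scale),
            class = "moth_treatment")
}

#' @rdname treatment
#' @param x A `moth_treatment`.
#' @export
is_shifted <- function(x) x$actuation %in% c("fs", "us")

#' @rdname treatment
#' @export
wing_torque_active <- function(x) x$actuation %in% c("fa", "fs")

#' Apply a treatment to the body parameters
#'
#' Returns the parameter set actually simulated under a treatment: the reduced
#' abdomen scales both the abdomen mass and its moment of inertia by
#' `reduced_scale`, leaving the geometry unchanged.
#'
#' @param params A [moth_params()] object (unscaled).
#' @param treat A [treatment()] object.
#' @return A `moth_params` object.
#' @export
apply_treatment <- function(params, treat) {
  stopifnot(inherits(params, "moth_params"), inherits(treat, "moth_treatment"))
  if (treat$abdomen == "reduced") {
    params$m2 <- params$m2 * treat$reduced_scale
    params$I2 <- params$I2 * treat$reduced_scale
  }
  params
}

#' Monte-Carlo effort ranges
#'
#' Sampling intervals for the randomized applied efforts: force magnitude `F`
#' on `[0, F_max]`, force direction `alpha` on `[alpha_min, alpha_max)`
#' (relative to the head-thorax long axis), and the two torques on
#' `[0, tau_max]`. Defaults are the hover-scale force ceiling 0.443 N, the
#' full circle for alpha, and 0.01 N m torque ceilings.
#'
#' @param F_max Maximum force magnitude (N).
#' @param alpha_min,alpha_max Force-direction interval (rad).
#' @param tau_abdo_max,tau_wing_max Maximum torques (N m).
#' @return Object of class `effort_ranges`.
#' @export
effort_ranges <- function(F_max = NULL, alpha_min = NULL, alpha_max = NULL,
                          tau_abdo_max = NULL, tau_wing_max = NULL) {
  d <- default_config()$ranges
  r <- list(F_max = F_max, alpha_min = alpha_min, alpha_max = alpha_max,
            tau_abdo_max = tau_abdo_max, tau_wing_max = tau_wing_max)
  for (nm in names(r)) if (is.null(r[[nm]])) r[[nm]] <- d[[nm]]
  r$F_max <- check_pos(r$F_max, "F_max", strict = TRUE)
  r$tau_abdo_max <- check_pos(r$tau_abdo_max, "tau_abdo_max", strict = FALSE)
  r$tau_wing_max <- check_pos(r$tau_wing_max, "tau_wing_max", strict = FALSE)
  if (!is.finite(r$alpha_min) || !is.finite(r$alpha_max) ||
      r$alpha_max <= r$alpha_min)
    stop_field("alpha_max", "must exceed alpha_min")
  structure(r, class = "effort_ranges")
}

#' Receding-horizon controller configuration
#'
#' @param window Control-window duration (s). Each batch of realizations is
#'   integrated over this horizon with window-constant efforts.
#' @param advance_fraction Fraction of the selected path traversed before
#'   replanning; must make `advance_fraction * window` an integer multiple of
#'   `output_step`.
#' @param n_realizations Monte-Carlo draws per window.
#' @param total_time Simulated duration (s).
#' @param weights Loss weights `w1..w6` on the squared end-of-window deviations
#'   in `x, y, theta, xdot, ydot, thetadot`.
#' @param output_step Dense-output grid step (s).
#' @param seed Master RNG seed; per-window substreams are derived from it.
#' @return Object of class `control_config`.
#' @export
control_config <- function(window = NULL, advance_fraction = NULL,
                           n_realizations = NULL, total_time = NULL,
                           weights = NULL, output_step = NULL, seed = NULL) {
  d <- default_config()
  cc <- list(window = window, advance_fraction = advance_fraction,
             n_realizations = n_realizations, total_time = total_time,
             weights = weights, output_step = output_step, seed = seed)
  dd <- c(d$control, list(seed = d$seed))
  for (nm in names(cc)) if (is.null(cc[[nm]])) cc[[nm]] <- dd[[nm]]
  cc$window <- check_pos(cc$window, "window", strict = TRUE)
  cc$output_step <- check_pos(cc$output_step, "output_step", strict = TRUE)
  cc$total_time <- check_pos(cc$total_time, "total_time", strict = TRUE)
  if (!is.numeric(cc$advance_fraction) || cc$advance_fraction <= 0 ||
      cc$advance_fraction > 1)
    stop_field("advance_fraction", "must lie in (0, 1]")
  if (!is.numeric(cc$n_realizations) || cc$n_realizations < 1)
    stop_field("n_realizations", "must be >= 1")
  cc$n_realizations <- as.integer(cc$n_realizations)
  w <- as.numeric(unlist(cc$weights))
  if (length(w) != 6L || any(!is.finite(w)) || any(w < 0))
    stop_field("weights", "must be six non-negative numbers")
  cc$weights <- w
  adv_steps <- cc$advance_fraction * cc$window / cc$output_step
  if (abs(adv_steps - round(adv_steps)) > 1e-9)
    stop_field("advance_fraction",
               "times window must be an integer multiple of output_step")
  cc$seed <- as.integer(cc$seed)
  structure(cc, class = "control_config")
}

#' @export
print.moth_params <- function(x, ...) {
  cat("Two-body moth model parameters (SI):\n")
  v <- unlist(x[vapply(x, is.numeric, logical(1))])
  print(signif(v, 4))
  cat("drag law:", x$drag, "\n")
  invisible(x)
}

#' @export
print.moth_treatment <- function(x, ...) {
  cat(sprintf("Treatment: %s, %s abdomen (scale %.2g)\n",
              x$actuation, x$abdomen, x$reduced_scale))
  invisible(x)
}
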
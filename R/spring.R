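# Torsional spring constant estimation from forced-oscillation trials.
# The abdomen is driven sinusoidally about the thoracic-abdominal joint while
# the reaction torque is recorded; with the linear joint model
# torque = I*thetadd + eta*thetad + kappa*theta, the Fourier transfer ratio at
# the drive frequency gives Real(T/Theta) = kappa - I*omega^2 (damping enters
# only the imaginary part), hence kappa = Real(T/Theta) + I*omega^2.

#' Synthesize a forced-oscillation trial
#'
#' Forward model for estimator testing: the imposed angle is
#' `amplitude * sin(2 pi f t)` and the torque follows the linear
#' spring-damper-inertia relation, plus optional white measurement noise.
#' Deterministic for a fixed seed.
#'
#' @param kappa Spring constant (kg m^2 rad^-1 s^-2).
#' @param eta Damping coefficient (kg m^2 rad^-1 s^-1).
#' @param I Abdominal moment of inertia about the joint (kg m^2).
#' @param f_drive Driving frequency (Hz); must satisfy `fs > 2 * f_drive`.
#' @param amplitude_deg Angular sweep amplitude in degrees (converted to
#'   radians at ingestion; all internal angles are radians).
#' @param duration Record length (s), default 15.
#' @param fs Sampling frequency (Hz), default 1000.
#' @param noise_sd Torque noise standard deviation (N m).
#' @param seed RNG seed for the noise.
#' @return Object of class `oscillation_trial`: `time`, `angle` (rad),
#'   `torque` (N m), `f_drive`, `fs`, `amplitude_deg`.
#' @export
synth_trial <- function(kappa, eta, I, f_drive, amplitude_deg = 13.56,
                        duration = 15, fs = 1000, noise_sd = 0, seed = 1L) {
  if (fs <= 2 * f_drive)
    stop("aliasing: sampling frequency must exceed twice the drive frequency")
  n <- round(duration * fs)
  t <- (seq_len(n) - 1L) / fs
  A <- amplitude_deg * pi / 180
  w <- 2 * pi * f_drive
  angle <- A * sin(w * t)
  torque <- I * (-A * w^2 * sin(w * t)) + eta * (A * w * cos(w * t)) +
    kappa * angle
  if (noise_sd > 0) {
    set.seed(seed)
    torque <- torque + stats::rnorm(n, sd = noise_sd)
  }
  structure(list(time = t, angle = angle, torque = torque,
                 f_drive = f_drive, fs = fs, amplitude_deg = amplitude_deg),
            class = "oscillation_trial")
}

#' Estimate the spring constant from one trial
#'
#' Fourier transforms the torque and angle records, takes their ratio at the
#' discrete-frequency bin nearest the drive frequency (rectangular window; the
#' 15 s / 1000 Hz design puts every standard drive frequency exactly on a
#' bin), and corrects for inertia:
#' `kappa_hat = Real(T/Theta) + I * omega^2` with `omega = 2 pi f_drive`.
#'
#' @param trial An [synth_trial()]-shaped trial (fields `angle`, `torque`,
#'   `f_drive`, `fs`).
#' @param I Abdominal moment of inertia about the joint (kg m^2).
#' @return Estimated spring constant (kg m^2 rad^-1 s^-2).
#' @export
estimate_kappa_single <- function(trial, I) {
  n <- length(trial$angle)
  stopifnot(n > 2, length(trial$torque) == n)
  bin <- round(trial$f_drive * n / trial$fs) + 1L
  if (bin < 2L || bin > n %/% 2)
    stop("drive frequency not resolvable by the record length")
  Th <- stats::fft(trial$angle)[bin]
  Tq <- stats::fft(trial$torque)[bin]
  if (Mod(Th) / n < 1e-12 * max(abs(trial$angle), 1e-300))
    stop("no drive content in the angle signal at the drive bin")
  Re(Tq / Th) + I * (2 * pi * trial$f_drive)^2
}

#' Aggregate a frequency sweep into one spring constant
#'
#' Estimates kappa for every trial, fits the per-trial estimates against the
#' driving frequency with a second-degree polynomial (least squares), and
#' evaluates the polynomial at zero frequency: that value (`kappa0`) is the
#' spring constant carried into the simulations. The literal x-axis crossings
#' of the polynomial are also returned for completeness.
#'
#' @param trials List of oscillation trials covering at least 3 distinct
#'   driving frequencies.
#' @param I Abdominal moment of inertia about the joint (kg m^2).
#' @return Object of class `spring_fit`: `per_trial` (data frame of f_drive,
#'   amplitude, kappa_hat), `coef` (polynomial coefficients, intercept first),
#'   `kappa0`, `x_intercepts` (real roots, possibly empty).
#' @export
aggregate_kappa <- function(trials, I) {
  if (length(trials) < 3L) stop("need at least 3 trials for a quadratic fit")
  f <- vapply(trials, function(tr) tr$f_drive, numeric(1))
  if (length(unique(f)) < 3L)
    stop("need at least 3 distinct driving frequencies for a quadratic fit")
  kh <- vapply(trials, estimate_kappa_single, numeric(1), I = I)
  amp <- vapply(trials, function(tr) tr$amplitude_deg %||% NA_real_, numeric(1))
  fit <- stats::lm(kh ~ f + I(f^2))
  cf <- unname(stats::coef(fit))
  disc <- cf[2L]^2 - 4 * cf[3L] * cf[1L]
  roots <- if (abs(cf[3L]) < 1e-300) {
    if (abs(cf[2L]) > 0) -cf[1L] / cf[2L] else numeric(0)
  } else if (disc >= 0) {
    (-cf[2L] + c(-1, 1) * sqrt(disc)) / (2 * cf[3L])
  } else numeric(0)
  structure(list(per_trial = data.frame(f_drive = f, amplitude_deg = amp,
                                        kappa_hat = kh),
                 coef = cf, kappa0 = cf[1L], x_intercepts = roots),
            class = "spring_fit")
}

#' @export
print.spring_fit <- function(x, ...) {
  cat(sprintf("Spring fit over %d trials at %d frequencies\n",
              nrow(x$per_trial), length(unique(x$per_trial$f_drive))))
  cat(sprintf("  kappa0 (zero-frequency value): %.4g kg m^2 rad^-1 s^-2\n",
              x$kappa0))
  cat(sprintf("  quadratic coefficients: %s\n",
              paste(signif(x$coef, 4), collapse = ", ")))
  invisible(x)
}

#' Write / read an oscillation trial as tabular text
#'
#' CSV with columns `time`, `angle`, `torque` and a one-line comment header
#' carrying the trial metadata.
#'
#' @param trial An oscillation trial.
#' @param path File path.
#' @return `path` (write) or an `oscillation_trial` (read).
#' @export
write_trial <- function(trial, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# f_drive=%g fs=%g amplitude_deg=%g",
                     trial$f_drive, trial$fs, trial$amplitude_deg), con)
  utils::write.csv(data.frame(time = trial$time, angle = trial$angle,
                              torque = trial$torque), con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trial
#' @export
read_trial <- function(path) {
  hdr <- readLines(path, n = 1L)
  if (!startsWith(hdr, "#")) stop("missing trial metadata header line")
  meta <- as.numeric(sub(".*=", "", strsplit(sub("^#\\s*", "", hdr), " ")[[1]]))
  d <- utils::read.csv(path, comment.char = "#")
  structure(list(time = d$time, angle = d$angle, torque = d$torque,
                 f_drive = meta[1L], fs = meta[2L], amplitude_deg = meta[3L]),
            class = "oscillation_trial")
}
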
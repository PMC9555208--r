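# Free-flight head-track statistics: RMS kinematics, sliding-window
# tortuosity, box-counting dimension of the rasterized path, per-segment
# spectra, incidence tables, and a synthetic track generator. Tracks are
# plain (frame, x, y) tables at a known frame rate, the natural export of
# markerless video tracking.

#' Construct a 2-D head track
#'
#' @param x,y Head position (arena units; statistics are reported in input
#'   units).
#' @param fps Frames per second (default 100).
#' @param frame Integer frame indices; must be consecutive (gaps must be made
#'   explicit upstream, they are not interpolated here).
#' @return Data frame of class `moth_track` with columns `frame`, `x`, `y` and
#'   attribute `fps`.
#' @export
track <- function(x, y, fps = 100, frame = seq_along(x)) {
  stopifnot(length(x) == length(y), length(x) == length(frame), fps > 0)
  if (any(diff(frame) != 1L))
    stop("frame indices must be consecutive (no missing frames)")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("track coordinates must be finite")
  out <- data.frame(frame = as.integer(frame), x = as.numeric(x),
                    y = as.numeric(y))
  attr(out, "fps") <- fps
  class(out) <- c("moth_track", "data.frame")
  out
}

#' Read a track from a CSV file
#'
#' Expects a header with columns `frame`, `x`, `y` (extra columns from
#' multi-point tracker exports are ignored).
#'
#' @param path CSV file path.
#' @param fps Frames per second of the recording.
#' @return A [track()].
#' @export
read_track <- function(path, fps = 100) {
  d <- utils::read.csv(path)
  need <- c("frame", "x", "y")
  if (!all(need %in% names(d)))
    stop("track file must have columns: ", paste(need, collapse = ", "))
  track(d$x, d$y, fps = fps, frame = d$frame)
}

track_fps <- function(tr) attr(tr, "fps") %||% 100

# Central differences with one-sided ends.
cdiff <- function(v, dt) {
  n <- length(v)
  d <- numeric(n)
  d[2:(n - 1)] <- (v[3:n] - v[1:(n - 2)]) / (2 * dt)
  d[1] <- (v[2] - v[1]) / dt
  d[n] <- (v[n] - v[n - 1]) / dt
  d
}

#' RMS velocity and acceleration of a track
#'
#' Velocity and acceleration by central differences (one-sided at the ends),
#' in arena units per second and per second squared; root-mean-square of the
#' planar magnitudes over the whole track.
#'
#' @param tr A [track()] with at least 3 frames.
#' @return Named vector `c(rms_velocity, rms_acceleration)`.
#' @export
rms_kinematics <- function(tr) {
  if (nrow(tr) < 3L) stop("track too short (need >= 3 frames)")
  dt <- 1 / track_fps(tr)
  vx <- cdiff(tr$x, dt); vy <- cdiff(tr$y, dt)
  ax <- cdiff(vx, dt); ay <- cdiff(vy, dt)
  c(rms_velocity = sqrt(mean(vx^2 + vy^2)),
    rms_acceleration = sqrt(mean(ax^2 + ay^2)))
}

#' Sliding-window path tortuosity
#'
#' For every window of `window` steps starting at frame i (unit stride), the
#' path length over the window divided by the net displacement between its
#' endpoints. Windows whose displacement falls below `epsilon` (out-and-back
#' paths) are degenerate: they are flagged, counted, and excluded from the
#' mean.
#'
#' @param tr A [track()] longer than `window`.
#' @param window Window length in frames (steps), default 40.
#' @param epsilon Minimum net displacement for a defined ratio.
#' @return List: `values` (per-window tortuosity, `NA` where degenerate),
#'   `mean` over the defined windows, `n_degenerate`.
#' @export
sliding_tortuosity <- function(tr, window = 40, epsilon = 1e-12) {
  n <- nrow(tr)
  if (n <= window) stop("track must be longer than the window")
  step <- sqrt(diff(tr$x)^2 + diff(tr$y)^2)
  cs <- c(0, cumsum(step))
  starts <- seq_len(n - window)
  path_len <- cs[starts + window] - cs[starts]
  disp <- sqrt((tr$x[starts + window] - tr$x[starts])^2 +
                 (tr$y[starts + window] - tr$y[starts])^2)
  vals <- ifelse(disp > epsilon, path_len / disp, NA_real_)
  if (all(is.na(vals))) stop("all windows are degenerate (zero displacement)")
  list(values = vals, mean = mean(vals, na.rm = TRUE),
       n_degenerate = sum(is.na(vals)))
}

#' Box-counting dimension of a track
#'
#' Rasterizes the linearly interpolated path onto a binary grid over the
#' padded bounding box (so the measure is independent of traversal speed),
#' counts occupied boxes N(eps) over a dyadic ladder of box sizes, and returns
#' the least-squares slope of log N versus log(1/eps) over that scaling range.
#' A straight line gives ~1; a plane-filling path approaches 2.
#'
#' @param tr A [track()] with a non-degenerate bounding box.
#' @param grid Rasterization grid size in pixels per side.
#' @param sizes Dyadic ladder of box sizes in pixels.
#' @return Dimension estimate, with attribute `counts` (data frame of eps, N).
#' @export
box_dimension <- function(tr, grid = 1024L, sizes = 2^(1:8)) {
  rx <- range(tr$x); ry <- range(tr$y)
  span <- max(rx[2] - rx[1], ry[2] - ry[1])
  if (span <= 0) stop("degenerate bounding box")
  pad <- 0.01 * span
  sc <- (grid - 1) / (span + 2 * pad)
  px <- (tr$x - rx[1] + pad) * sc
  py <- (tr$y - ry[1] + pad) * sc
  # densify: interpolate each segment at sub-pixel resolution
  seg_len <- sqrt(diff(px)^2 + diff(py)^2)
  npts <- pmax(2L, ceiling(seg_len / 0.5) + 1L)
  ix <- unlist(lapply(seq_along(seg_len), function(i) {
    t <- seq(0, 1, length.out = npts[i])
    px[i] + t * (px[i + 1] - px[i])
  }))
  iy <- unlist(lapply(seq_along(seg_len), function(i) {
    t <- seq(0, 1, length.out = npts[i])
    py[i] + t * (py[i + 1] - py[i])
  }))
  cellx <- pmin(floor(ix), grid - 1L)
  celly <- pmin(floor(iy), grid - 1L)
  occ <- unique(cellx * grid + celly)
  counts <- vapply(sizes, function(e) {
    bx <- (occ %/% grid) %/% e
    by <- (occ %% grid) %/% e
    length(unique(bx * (grid %/% e + 1L) + by))
  }, numeric(1))
  fit <- stats::lm(log(counts) ~ log(1 / sizes))
  structure(unname(stats::coef(fit)[2L]),
            counts = data.frame(eps = sizes, N = counts))
}

#' Mean segment power spectra
#'
#' Discrete Fourier power of the position components over sliding segments of
#' `window` frames (unit stride), averaged across segments. Powers are
#' one-sided and normalized so that for each segment the total power equals
#' the mean squared signal (Parseval); frequencies are in Hz from the frame
#' rate.
#'
#' @param tr A [track()] longer than `window`.
#' @param window Segment length in frames, default 40.
#' @param stride Segment stride in frames, default 1.
#' @return Data frame: `freq` (Hz), `power_x`, `power_y`.
#' @export
segment_spectra <- function(tr, window = 40, stride = 1L) {
  n <- nrow(tr)
  if (n < window) stop("track too short for the segment window")
  starts <- seq(1L, n - window + 1L, by = stride)
  nb <- window %/% 2 + 1L
  acc <- matrix(0, nb, 2L)
  for (s in starts) {
    idx <- s:(s + window - 1L)
    for (cmp in 1:2) {
      v <- if (cmp == 1L) tr$x[idx] else tr$y[idx]
      P <- Mod(stats::fft(v))^2 / window^2
      one <- P[seq_len(nb)]
      # fold negative frequencies onto positive bins (not DC; not Nyquist when even)
      fold <- seq(2L, nb - if (window %% 2 == 0) 1L else 0L)
      one[fold] <- one[fold] + P[window + 2L - fold]
      acc[, cmp] <- acc[, cmp] + one
    }
  }
  acc <- acc / length(starts)
  data.frame(freq = (seq_len(nb) - 1L) * track_fps(tr) / window,
             power_x = acc[, 1L], power_y = acc[, 2L])
}

#' Incidence table chi-squared test
#'
#' Pearson chi-squared on a 2x2 treatment-by-outcome count table WITHOUT
#' continuity correction, df = 1, upper-tail p value.
#'
#' @param tbl 2x2 matrix of non-negative integer counts (rows = groups,
#'   column 1 = successes).
#' @return List: `chi2`, `df`, `p`.
#' @export
incidence_chi_squared <- function(tbl) {
  tbl <- as.matrix(tbl)
  stopifnot(all(dim(tbl) == 2L), all(tbl >= 0), sum(tbl) > 0)
  if (any(rowSums(tbl) == 0) || any(colSums(tbl) == 0))
    stop("zero marginal in incidence table")
  ct <- stats::chisq.test(tbl, correct = FALSE)
  list(chi2 = unname(ct$statistic), df = unname(ct$parameter), p = ct$p.value)
}

#' Per-group incidence percentages
#'
#' `100 * successes / row total` for each group, rounded to one decimal.
#'
#' @param tbl 2x2 count matrix (rows = groups, column 1 = successes).
#' @return Named numeric vector of percentages.
#' @export
incidence_percentages <- function(tbl) {
  tbl <- as.matrix(tbl)
  rt <- rowSums(tbl)
  if (any(rt == 0)) stop("zero row total in incidence table")
  round(100 * tbl[, 1L] / rt, 1)
}

#' Wilcoxon rank-sum comparison of two groups
#'
#' Exact two-sample rank-sum test when both groups are untied and small enough
#' for exact enumeration, otherwise the normal approximation (the switch is
#' recorded in the result).
#'
#' @param a,b Numeric vectors (non-empty).
#' @param alternative Test sidedness (as in [stats::wilcox.test()]).
#' @return List: `W`, `p`, `method` (`"exact"` or `"normal approximation"`).
#' @export
rank_sum_compare <- function(a, b, alternative = "two.sided") {
  stopifnot(length(a) > 0, length(b) > 0)
  if (length(unique(c(a, b))) == 1L)
    stop("all values tied; rank-sum comparison is degenerate")
  ties <- any(duplicated(c(a, b)))
  exact <- !ties && length(a) < 50 && length(b) < 50
  wt <- suppressWarnings(stats::wilcox.test(a, b, alternative = alternative,
                                            exact = exact, correct = !exact))
  list(W = unname(wt$statistic), p = wt$p.value,
       method = if (exact) "exact" else "normal approximation")
}

#' Generate a synthetic head track
#'
#' Deterministic-from-seed fixture generator emulating 100 fps head tracking:
#' straight constant-velocity flight, circular flight, horizontal transit with
#' sinusoidal vertical oscillation, or a smooth random walk (Gaussian velocity
#' noise smoothed with a moving-average kernel, then integrated). Optional
#' white measurement noise on the positions.
#'
#' @param kind One of `"straight"`, `"circle"`, `"sinusoid"`,
#'   `"smooth-random"`.
#' @param n Number of frames.
#' @param fps Frames per second.
#' @param seed RNG seed (used by the stochastic parts).
#' @param speed Speed (straight), arena units/s.
#' @param radius,omega Circle radius and angular rate (rad/s).
#' @param amplitude,freq Sinusoid amplitude and frequency (Hz).
#' @param smooth Moving-average half-width (frames) of the random-walk
#'   velocity.
#' @param noise_sd Measurement noise standard deviation (arena units).
#' @return A [track()].
#' @export
generate_track <- function(kind = c("straight", "circle", "sinusoid",
                                    "smooth-random"),
                           n = 500L, fps = 100, seed = 1L,
                           speed = 0.5, radius = 0.2, omega = 2 * pi,
                           amplitude = 0.05, freq = 5, smooth = 10L,
                           noise_sd = 0) {
  kind <- match.arg(kind)
  set.seed(seed)
  t <- (seq_len(n) - 1L) / fps
  xy <- switch(kind,
    straight = cbind(speed * t, 0.5 * speed * t),
    circle = cbind(radius * cos(omega * t), radius * sin(omega * t)),
    sinusoid = cbind(speed * t, amplitude * sin(2 * pi * freq * t)),
    `smooth-random` = {
      k <- rep(1 / (2 * smooth + 1), 2 * smooth + 1)
      vx <- stats::filter(stats::rnorm(n + 2 * smooth, sd = speed), k)
      vy <- stats::filter(stats::rnorm(n + 2 * smooth, sd = speed), k)
      vx <- vx[!is.na(vx)][seq_len(n)]
      vy <- vy[!is.na(vy)][seq_len(n)]
      cbind(cumsum(vx) / fps, cumsum(vy) / fps)
    })
  if (noise_sd > 0) xy <- xy + matrix(stats::rnorm(2 * n, sd = noise_sd), ncol = 2)
  track(xy[, 1L], xy[, 2L], fps = fps)
}
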
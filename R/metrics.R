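# Flight-performance metrics per control window and treatment-level
# statistics: non-dimensional tracking error, generalized mechanical work,
# cost of transport, Kruskal-Wallis omnibus with eta-squared effect size,
# Dunn pairwise comparisons, and compact-letter statistical groupings.

#' Non-dimensional tracking error
#'
#' Planar distance between the end-of-window position and the goal position,
#' divided by the body length `2 * (L1 + L2)`. Depends only on the rectilinear
#' components; angle deviations do not enter.
#'
#' @param final End-of-window state.
#' @param goal Goal state ([goal_state()]).
#' @param body_len Body length (m), > 0.
#' @return Dimensionless error.
#' @export
tracking_error <- function(final, goal, body_len) {
  stopifnot(body_len > 0)
  sqrt((final[["x"]] - goal[["x"]])^2 + (final[["y"]] - goal[["y"]])^2) / body_len
}

#' Mechanical work over a trajectory segment
#'
#' Generalized work accumulated on the dense output grid:
#' `sum_k F |dr_k| + |(r x F) dtheta_k| + |tau_wing dtheta_k| +
#' |tau_abdo dbeta_k|`, with `r x F = L3 F sin(alpha)` the implicit moment of
#' the shifted force (identically zero for fa/ua, where the force acts at the
#' reference point), and `dbeta` the unwrapped flexion increment. Each term is
#' taken in absolute value, so every actuation is an expenditure.
#'
#' @param traj Trajectory data frame (>= 2 rows).
#' @param efforts The window's selected efforts (named vector).
#' @param params,treat Model parameters and treatment.
#' @return Work (J), with attribute `distance` = total path length of the
#'   reference point over the segment (m).
#' @export
window_work <- function(traj, efforts, params, treat) {
  stopifnot(nrow(traj) >= 2L)
  dx <- diff(traj$x); dy <- diff(traj$y)
  dr <- sqrt(dx^2 + dy^2)
  dth <- diff(traj$theta)
  dbe <- diff(flexion(traj))
  Fm <- efforts[["F"]]
  moment <- if (is_shifted(treat)) params$L3 * Fm * sin(efforts[["alpha"]]) else 0
  tw <- if (wing_torque_active(treat)) efforts[["tau_wing"]] else 0
  w <- sum(Fm * dr) + sum(abs(moment * dth)) + sum(abs(tw * dth)) +
    sum(abs(efforts[["tau_abdo"]] * dbe))
  structure(w, distance = sum(dr))
}

#' Cost of transport
#'
#' Mechanical work normalized by the head-thorax weight times the distance
#' traveled: `C = work / (m1 * g * distance)`. Windows whose path length falls
#' below `epsilon` have no meaningful normalization and are flagged as `NA`
#' (excluded from summaries).
#'
#' @param work Work (J).
#' @param params A [moth_params()] object (`m1`, `g`).
#' @param distance Path length (m).
#' @param epsilon Minimum distance for a defined value (m).
#' @return Dimensionless cost, or `NA` when `distance <= epsilon`.
#' @export
cost_of_transport <- function(work, params, distance, epsilon = 1e-9) {
  if (!is.finite(distance) || distance <= epsilon) return(NA_real_)
  as.numeric(work) / (params$m1 * params$g * distance)
}

#' Per-run median metrics
#'
#' Collapses one simulation to its per-run medians (the unit of replication
#' for cross-treatment testing, avoiding pseudo-replication of windows).
#'
#' @param sim A `moth_sim` from [run_simulation()].
#' @return One-row data frame: treatment label, abdomen condition, seed,
#'   median tracking error, median cost of transport (undefined windows
#'   excluded), and total work.
#' @export
run_summary <- function(sim) {
  w <- sim$windows
  data.frame(
    actuation = sim$treatment$actuation,
    abdomen = sim$treatment$abdomen,
    seed = sim$seed,
    tracking_error = stats::median(w$tracking_error),
    cost_of_transport = stats::median(w$cost_of_transport, na.rm = TRUE),
    total_work = sum(w$work),
    n_windows = nrow(w),
    n_cot_undefined = sum(is.na(w$cost_of_transport))
  )
}

#' Dunn's pairwise test on ranks
#'
#' Pairwise z statistics on the pooled mean ranks with the standard tie
#' correction, the usual post-hoc companion of the Kruskal-Wallis test.
#' P values are two-sided normal; the Bonferroni rule rejects when
#' `p < alpha / divisor` (the divisor defaults to the number of comparisons
#' and is exposed).
#'
#' @param x Numeric values.
#' @param g Group labels (coerced to factor).
#' @param alpha Family-wise level.
#' @param divisor Bonferroni divisor; default the number of pairs.
#' @return Data frame with one row per pair: groups, z, p, p threshold, and
#'   the rejection flag.
#' @export
dunn_test <- function(x, g, alpha = 0.05, divisor = NULL) {
  g <- factor(g)
  stopifnot(length(x) == length(g), nlevels(g) >= 2L)
  N <- length(x)
  r <- rank(x)
  mean_ranks <- tapply(r, g, mean)
  n_i <- tabulate(g)
  ties <- table(x)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  s2 <- N * (N + 1) / 12 - tie_corr
  lv <- levels(g)
  pairs <- utils::combn(seq_along(lv), 2L)
  m <- ncol(pairs)
  if (is.null(divisor)) divisor <- m
  z <- p <- numeric(m)
  for (k in seq_len(m)) {
    i <- pairs[1L, k]; j <- pairs[2L, k]
    se <- sqrt(s2 * (1 / n_i[i] + 1 / n_i[j]))
    z[k] <- (mean_ranks[i] - mean_ranks[j]) / se
    p[k] <- 2 * stats::pnorm(-abs(z[k]))
  }
  data.frame(group1 = lv[pairs[1L, ]], group2 = lv[pairs[2L, ]],
             z = z, p = p, p_threshold = alpha / divisor,
             reject = p < alpha / divisor)
}

# Compact letter display: groups that are not significantly different share a
# letter. Groups are ordered by median; for each start position the maximal
# run of mutual non-significance receives one letter (runs contained in a
# longer run are dropped).
cld_letters <- function(levels_ordered, nonsig) {
  k <- length(levels_ordered)
  runs <- lapply(seq_len(k), function(i) {
    j <- i
    while (j < k && all(nonsig[i:j, j + 1L])) j <- j + 1L
    i:j
  })
  keep <- vapply(seq_along(runs), function(a) {
    !any(vapply(seq_along(runs), function(b)
      b != a && all(runs[[a]] %in% runs[[b]]) &&
        length(runs[[b]]) > length(runs[[a]]), logical(1)))
  }, logical(1))
  runs <- unique(runs[keep])
  letters_out <- rep("", k)
  for (a in seq_along(runs))
    letters_out[runs[[a]]] <- paste0(letters_out[runs[[a]]], letters[a])
  stats::setNames(letters_out, levels_ordered)
}

#' Compare treatments on per-run median metrics
#'
#' Treatment-level comparison of simulation groups: Kruskal-Wallis omnibus
#' test (chi-squared, df, p) with the eta-squared effect size
#' `(chi2 - k + 1) / (n - k)`, Dunn pairwise comparisons with Bonferroni
#' control, and compact-letter statistical groupings ordered by the group
#' medians.
#'
#' @param summaries Data frame of per-run medians (rows = runs), e.g. from
#'   rbinding [run_summary()] outputs.
#' @param metric Column to compare (`"tracking_error"` or
#'   `"cost_of_transport"`).
#' @param group Column holding the group label (default `"group"`; falls back
#'   to `actuation` crossed with `abdomen` when absent).
#' @param alpha,divisor Passed to [dunn_test()].
#' @return List of class `treatment_comparison`: `kruskal` (statistic, df, p,
#'   eta squared), `dunn`, `letters`, `medians`.
#' @export
compare_treatments <- function(summaries, metric = "tracking_error",
                               group = "group", alpha = 0.05, divisor = NULL) {
  if (!group %in% names(summaries)) {
    summaries$group <- paste(summaries$actuation, summaries$abdomen, sep = "_")
    group <- "group"
  }
  x <- summaries[[metric]]
  g <- factor(summaries[[group]])
  if (nlevels(g) < 2L) stop("need at least two groups")
  if (any(tabulate(g) < 3L)) stop("need at least three runs per group")
  if (length(unique(x)) == 1L)
    stop("all values tied across groups; comparison is degenerate")
  kw <- stats::kruskal.test(x, g)
  k <- nlevels(g)
  n <- length(x)
  eta2 <- (unname(kw$statistic) - k + 1) / (n - k)
  dn <- dunn_test(x, g, alpha = alpha, divisor = divisor)
  med <- sort(tapply(x, g, stats::median))
  ord <- names(med)
  nonsig <- matrix(TRUE, k, k, dimnames = list(ord, ord))
  for (r in seq_len(nrow(dn))) {
    a <- dn$group1[r]; b <- dn$group2[r]
    nonsig[a, b] <- nonsig[b, a] <- !dn$reject[r]
  }
  structure(list(
    kruskal = list(chi2 = unname(kw$statistic), df = unname(kw$parameter),
                   p = kw$p.value, eta_squared = eta2),
    dunn = dn,
    letters = cld_letters(ord, nonsig),
    medians = med,
    metric = metric
  ), class = "treatment_comparison")
}

#' @export
print.treatment_comparison <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis on %s: chi2 = %.4g, df = %d, p = %.3g, eta2 = %.3g\n",
              x$metric, x$kruskal$chi2, x$kruskal$df, x$kruskal$p,
              x$kruskal$eta_squared))
  cat("group medians and letters:\n")
  print(data.frame(median = signif(x$medians, 4),
                   letters = x$letters[names(x$medians)]))
  invisible(x)
}
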
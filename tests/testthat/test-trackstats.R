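test_that("RMS kinematics recover uniform, stationary, and circular motion", {
  tr <- generate_track("straight", n = 200, speed = 0.8)
  k <- rms_kinematics(tr)
  v_true <- 0.8 * sqrt(1 + 0.25)  # generator moves at (v, v/2)
  expect_equal(unname(k["rms_velocity"]), v_true, tolerance = 1e-9)
  expect_equal(unname(k["rms_acceleration"]), 0, tolerance = 1e-9)

  still <- track(rep(1, 50), rep(-2, 50))
  expect_equal(unname(rms_kinematics(still)), c(0, 0))

  circ <- generate_track("circle", n = 500, radius = 0.2, omega = 2 * pi)
  kc <- rms_kinematics(circ)
  expect_equal(unname(kc["rms_velocity"]), 0.2 * 2 * pi, tolerance = 0.01)
  expect_equal(unname(kc["rms_acceleration"]), 0.2 * (2 * pi)^2,
               tolerance = 0.02)
  expect_error(rms_kinematics(track(1:2, 1:2)), "too short")
})

test_that("straight tracks have tortuosity one; degenerate windows are flagged", {
  tr <- generate_track("straight", n = 120)
  st <- sliding_tortuosity(tr)
  expect_equal(st$mean, 1, tolerance = 1e-12)
  expect_true(all(abs(st$values - 1) < 1e-12))
  expect_equal(st$n_degenerate, 0L)

  # L-shaped 3-point toy with a 2-frame window: legs 3 and 4
  ell <- track(c(0, 3, 3), c(0, 0, 4))
  st2 <- sliding_tortuosity(ell, window = 2)
  expect_equal(st2$values, 7 / 5)

  # out-and-back inside one window is excluded as degenerate
  oab <- track(c(0, 1, 0, 1, 2), c(0, 0, 0, 0, 0))
  st3 <- sliding_tortuosity(oab, window = 2)
  expect_equal(st3$n_degenerate, 2L)
  expect_true(all(is.na(st3$values[1:2])))
  expect_error(sliding_tortuosity(track(c(0, 1, 0), c(0, 0, 0)), window = 2),
               "degenerate")
  expect_true(all(st$values >= 1 - 1e-12, na.rm = TRUE))
})

test_that("box dimension separates lines from plane-filling paths", {
  line <- generate_track("straight", n = 300)
  d_line <- box_dimension(line)
  expect_gt(d_line, 0.9); expect_lt(d_line, 1.1)

  # serpentine sweeping the unit square with line spacing ~2 px at the
  # 1024-pixel rasterization: the plane-filling limit
  ny <- 512
  xs <- rep(c(0, 1, 1, 0), length.out = 2 * ny)
  ys <- rep(seq(0, 1, length.out = ny), each = 2)
  serp <- track(xs, ys)
  d_serp <- box_dimension(serp)
  expect_gt(d_serp, 1.8); expect_lt(d_serp, 2.0)

  # invariance under uniform rescaling of the coordinates
  sm <- generate_track("smooth-random", n = 400, seed = 9)
  d1 <- box_dimension(sm)
  sm2 <- track(sm$x * 37.5, sm$y * 37.5)
  expect_equal(box_dimension(sm2), d1, tolerance = 0.05)
  expect_error(box_dimension(track(rep(0, 60), rep(0, 60))), "degenerate")
})

test_that("segment spectra localize tones and satisfy Parseval", {
  tr <- generate_track("sinusoid", n = 400, freq = 5, amplitude = 0.05,
                       speed = 0)
  sp <- segment_spectra(tr, window = 40)
  expect_equal(sp$freq[which.max(sp$power_y)], 5)  # 2.5 Hz bins
  # constant track: all power at zero frequency
  cs <- segment_spectra(track(rep(2, 60), rep(3, 60)), window = 40)
  expect_equal(cs$freq[cs$power_x > 1e-15], 0)
  # Parseval on a single segment: total one-sided power = mean square
  set.seed(4)
  seg <- track(rnorm(40), rnorm(40))
  sp1 <- segment_spectra(seg, window = 40)
  expect_equal(sum(sp1$power_x), mean(seg$x^2), tolerance = 1e-9)
  expect_equal(sum(sp1$power_y), mean(seg$y^2), tolerance = 1e-9)
})

test_that("incidence chi-squared matches the closed-form and recorded trial counts", {
  # experimental 7/40 flew, sham 18/37 flew
  tbl <- matrix(c(7, 18, 33, 19), 2,
                dimnames = list(c("experimental", "sham"), c("flew", "no")))
  res <- incidence_chi_squared(tbl)
  expect_equal(res$chi2, 8.5053, tolerance = 5e-5)
  expect_equal(res$df, 1)
  expect_equal(res$p, 0.003541, tolerance = 5e-4)

  # identical rows: no association
  same <- matrix(c(10, 10, 5, 5), 2)
  r0 <- incidence_chi_squared(same)
  expect_equal(r0$chi2, 0)
  expect_equal(r0$p, 1)

  # oracle equivalence: brute-force sum over the four cells on random tables
  set.seed(12)
  for (i in 1:20) {
    t2 <- matrix(rpois(4, 20) + 1, 2)
    E <- outer(rowSums(t2), colSums(t2)) / sum(t2)
    expect_equal(incidence_chi_squared(t2)$chi2, sum((t2 - E)^2 / E),
                 tolerance = 1e-12)
  }
  expect_error(incidence_chi_squared(matrix(c(0, 0, 3, 4), 2)), "marginal")
})

test_that("incidence percentages match the recorded one-decimal values", {
  flight <- matrix(c(7, 18, 33, 19), 2)
  expect_equal(unname(incidence_percentages(flight)), c(17.5, 48.6))
  rolls <- matrix(c(45, 23, 51, 89), 2)
  expect_equal(unname(incidence_percentages(rolls)), c(46.9, 20.5))
  expect_equal(unname(incidence_percentages(matrix(c(0, 1, 5, 4), 2))[1]), 0)
})

test_that("rank-sum comparison is exact where enumeration applies", {
  r <- rank_sum_compare(c(1, 2, 3), c(1.5, 2.5, 3.5) - 1e9)  # disjoint
  expect_equal(r$method, "exact")
  # fully separated 5 vs 5: two-sided exact p = 2/choose(10,5)
  a <- 1:5; b <- 6:10
  r2 <- rank_sum_compare(a, b)
  expect_equal(r2$p, 2 / choose(10, 5))
  # identical groups, no ties: p = 1
  r3 <- rank_sum_compare(c(1, 3, 5), c(2, 4, 6))
  expect_gt(r3$p, 0.6)
  # invariance under a common monotone transform
  set.seed(7)
  x <- runif(8); y <- runif(10) + 0.3
  expect_equal(rank_sum_compare(exp(x), exp(y))$p, rank_sum_compare(x, y)$p)
  expect_equal(rank_sum_compare(exp(x), exp(y))$W, rank_sum_compare(x, y)$W)
  expect_error(rank_sum_compare(rep(1, 4), rep(1, 4)), "tied")
})

test_that("track construction and file round-trip preserve the data", {
  tr <- generate_track("smooth-random", n = 100, seed = 2, noise_sd = 1e-3)
  tr2 <- generate_track("smooth-random", n = 100, seed = 2, noise_sd = 1e-3)
  expect_identical(tr, tr2)
  expect_error(track(1:5, 1:5, frame = c(1, 2, 4, 5, 6)), "consecutive")
  f <- withr::local_tempfile(fileext = ".csv")
  write.csv(as.data.frame(tr), f, row.names = FALSE)
  rt <- read_track(f)
  expect_equal(rt$x, tr$x)
  expect_equal(attr(rt, "fps"), 100)
})
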
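test_that("area per lipid is the lateral box area over leaflet count", {
  fr <- frame_series(c(0, 10), array(0.5, c(1, 3, 2)),
                     rbind(c(8, 8, 7), c(8, 8, 7)))
  ap <- area_per_lipid(fr, 100)
  expect_equal(ap$a_l, c(0.64, 0.64))
  expect_equal(sd(ap$a_l), 0)
  # exact linearity in box area and inverse-linearity in n_leaflet
  fr2 <- frame_series(c(0, 10), array(0.5, c(1, 3, 2)),
                      rbind(c(16, 8, 7), c(16, 8, 7)))
  expect_equal(area_per_lipid(fr2, 100)$a_l, 2 * ap$a_l)
  expect_equal(area_per_lipid(fr, 50)$a_l, 2 * ap$a_l)
  expect_error(area_per_lipid(fr, 0), "positive")
})

test_that("a prescribed area trace is reproduced exactly", {
  set.seed(31)
  lx <- sqrt(runif(200, 60, 70))
  fr <- frame_series(seq(0, by = 10, length.out = 200),
                     array(0.5, c(1, 3, 200)),
                     cbind(lx, lx, 7))
  ap <- area_per_lipid(fr, 100)
  expect_equal(ap$a_l, lx^2 / 100)
})

test_that("equilibration detection finds plateaus and change points", {
  tm <- seq(0, by = 10, length.out = 1000)
  # constant series: trivially equilibrated over the full span
  const <- structure(data.frame(times = tm, a_l = rep(0.64, 1000)),
                     class = c("area_series", "data.frame"))
  w <- equilibration_window(const)
  expect_true(w$equilibrated)
  expect_equal(w$t_start, 0)
  # drift for the first half, then plateau with mild noise
  set.seed(41)
  a <- c(seq(0.5, 0.64, length.out = 500), rep(0.64, 500)) +
    rnorm(1000, 0, 0.002)
  drift <- structure(data.frame(times = tm, a_l = a),
                     class = c("area_series", "data.frame"))
  w2 <- equilibration_window(drift)
  expect_true(w2$equilibrated)
  expect_lt(abs(w2$t_start - 5000), 0.1 * 9990)
  # monotone drift throughout: flagged non-equilibrated
  mono <- structure(data.frame(times = tm,
                               a_l = seq(0.5, 0.8, length.out = 1000)),
                    class = c("area_series", "data.frame"))
  expect_false(equilibration_window(mono)$equilibrated)
  expect_error(equilibration_window(const[1:50, ]), "100 frames")
})

test_that("windowed analysis tiles the span and drops the remainder", {
  fr <- frame_series(seq(0, 1e6, by = 1e4), array(0, c(1, 3, 101)),
                     c(5, 5, 5))
  w <- windowed_analysis(fr, 100)
  expect_length(w, 10)
  expect_equal(w[[1]]$t_start, 0)
  expect_equal(w[[10]]$t_end, 1e6)
  expect_length(windowed_analysis(fr, 1000), 1)
  fr2 <- frame_series(seq(0, 9.5e5, by = 1e4), array(0, c(1, 3, 96)),
                      c(5, 5, 5))
  expect_message(w2 <- windowed_analysis(fr2, 100), "dropping trailing 50")
  expect_length(w2, 9)
  expect_error(windowed_analysis(fr, -1), "positive")
})

test_that("unwrapping restores continuous paths across the boundary", {
  b <- gen_brownian_bilayer(0, n_lipids = 2, n_frames = 4, seed = 1)
  # frozen lipids: constant paths
  p0 <- com_trajectories(b$frames, b$topology)
  expect_equal(max(abs(p0 - c(p0[, , 1]))), 0)
  # atom stepping over the +x boundary stays continuous once unwrapped
  fr <- b$frames
  fr$coords[1, 1, ] <- c(7.8, 7.95, 0.1, 0.25)  # crosses x = 8
  p <- com_trajectories(fr, b$topology, remove_system_com = FALSE)
  expect_equal(diff(p[1, 1, ]), rep(0.15, 3), tolerance = 1e-12)
})

test_that("re-wrapping unwrapped paths reproduces the input coordinates", {
  b <- gen_brownian_bilayer(5e-12, n_lipids = 10, n_frames = 200, seed = 2)
  p <- com_trajectories(b$frames, b$topology, remove_system_com = FALSE)
  for (ax in 1:2) {
    rewrapped <- p[, ax, ] - floor(p[, ax, ] / 8) * 8
    expect_lt(max(abs(rewrapped - b$frames$coords[, ax, ])), 1e-9)
  }
})

test_that("removing the collective COM cancels a uniform drift", {
  drift <- c(0.004, -0.002)
  b0 <- gen_brownian_bilayer(5e-12, 20, 300, seed = 3, drift = c(0, 0))
  b1 <- gen_brownian_bilayer(5e-12, 20, 300, seed = 3, drift = drift)
  m0 <- lateral_msd(com_trajectories(b0$frames, b0$topology, TRUE),
                    n_subgroups = 5)
  m1 <- lateral_msd(com_trajectories(b1$frames, b1$topology, TRUE),
                    n_subgroups = 5)
  expect_lt(max(abs(m0$msd - m1$msd)), 1e-9)
})

test_that("time-origin-averaged MSD equals the brute-force double loop", {
  b <- gen_brownian_bilayer(5e-12, n_lipids = 5, n_frames = 50, seed = 5)
  p <- com_trajectories(b$frames, b$topology, remove_system_com = FALSE)
  lag_ns <- c(0.01, 0.05, 0.1, 0.2)
  curve <- lateral_msd(p, lag_grid = lag_ns, n_subgroups = 5)
  dtns <- 0.01
  for (l in lag_ns) {
    lf <- round(l / dtns)
    acc <- 0; cnt <- 0
    for (i in 1:5) for (t0 in 1:(50 - lf)) {
      acc <- acc + sum((p[i, , t0 + lf] - p[i, , t0])^2)
      cnt <- cnt + 1
    }
    expect_lt(abs(curve$msd[curve$lag_ns == l] - acc / cnt), 1e-12)
  }
})

test_that("stationary lipids give a zero MSD with zero SEM", {
  b <- gen_brownian_bilayer(0, n_lipids = 10, n_frames = 100, seed = 6)
  curve <- lateral_msd(com_trajectories(b$frames, b$topology),
                       n_subgroups = 5)
  expect_true(all(curve$msd == 0))
  expect_true(all(curve$sem == 0))
  expect_equal(curve$msd[curve$lag_ns == 0], 0)
})

test_that("subgroup splitting follows the five-by-forty scheme", {
  b <- gen_brownian_bilayer(5e-12, n_lipids = 200, n_frames = 50, seed = 7)
  p <- com_trajectories(b$frames, b$topology)
  curve <- lateral_msd(p, lag_grid = c(0.05, 0.1), n_subgroups = 5)
  expect_equal(nrow(attr(curve, "subgroups")), 5)
  p2 <- p[1:198, , , drop = FALSE]
  attr(p2, "times") <- attr(p, "times")
  expect_error(lateral_msd(p2, n_subgroups = 5), "198")
})

test_that("Brownian walks satisfy the Einstein relation within subgroup SEM", {
  b <- gen_brownian_bilayer(5e-12, n_lipids = 100, n_frames = 2000,
                            seed = 8)
  p <- com_trajectories(b$frames, b$topology, remove_system_com = FALSE)
  curve <- lateral_msd(p, n_subgroups = 5)
  d_nmns <- 5e-12 * 1e9  # nm^2/ns
  sel <- curve$lag_ns > 0 & curve$lag_ns <= 10
  expect_true(all(abs(curve$msd[sel] - 4 * d_nmns * curve$lag_ns[sel]) <=
                    3 * curve$sem[sel]))
})

test_that("an exact line yields the diffusion coefficient with a zero band", {
  lag <- seq(1, 20, by = 1)
  d <- 1e-12
  curve <- data.frame(lag_ns = lag, msd = 4 * (d * 1e9) * lag, sem = 0)
  attr(curve, "span_ns") <- 80
  class(curve) <- c("msd_curve", "data.frame")
  est <- fit_diffusion(curve, fit_window = c(1, 20))
  expect_equal(est$d, d, tolerance = 1e-12)
  expect_equal(est$d_low, d, tolerance = 1e-9)
  expect_equal(est$d_high, d, tolerance = 1e-9)
  expect_error(fit_diffusion(curve, fit_window = c(30, 40)), "3 lags")
})

test_that("the SEM band grows monotonically and matches a brute-force search", {
  lag <- seq(2, 20, by = 2)
  curve0 <- data.frame(lag_ns = lag, msd = 0.02 * lag + 0.001)
  widths <- c()
  for (eps in c(0.001, 0.005, 0.02)) {
    curve <- curve0
    curve$sem <- eps
    attr(curve, "span_ns") <- 80
    class(curve) <- c("msd_curve", "data.frame")
    est <- fit_diffusion(curve, fit_window = c(2, 20))
    widths <- c(widths, est$d_high - est$d_low)
    # brute-force oracle: scan slopes, keep those with a feasible intercept
    slopes <- seq(0, 0.06, length.out = 4001)
    feas <- vapply(slopes, function(b)
      max(curve$msd - eps - b * lag) <= min(curve$msd + eps - b * lag),
      logical(1))
    rng <- range(slopes[feas]) / 4 * 1e-9
    expect_equal(est$d_low, rng[1], tolerance = 2e-3)
    expect_equal(est$d_high, rng[2], tolerance = 2e-3)
  }
  expect_true(all(diff(widths) > 0))
})

test_that("the band covers the true D for most Brownian replicates", {
  cover <- 0L
  for (k in 1:8) {
    b <- gen_brownian_bilayer(5e-12, 50, 1500, seed = 100 + k)
    p <- com_trajectories(b$frames, b$topology, remove_system_com = FALSE)
    curve <- lateral_msd(p, n_subgroups = 5)
    est <- fit_diffusion(curve)
    cover <- cover + (est$d_low <= 5e-12 && 5e-12 <= est$d_high)
  }
  expect_gte(cover, 6L)
})
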
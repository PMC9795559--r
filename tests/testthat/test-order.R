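ALPHA <- "\u03b1"

test_that("fixed tilt angles give the exact second Legendre polynomial", {
  topo <- one_bond_topology()
  bond <- topo$ch_bonds[1, ]
  for (th in c(0, 30, 54.7356, 90, 120)) {
    fr <- frames_from_angles(rep(th, 5), phi_deg = c(0, 45, 90, 180, 301))
    expect_lt(abs(sch_per_lipid(fr, bond) -
                    (3 * cos(th * pi / 180)^2 - 1) / 2), 1e-12)
  }
  # alternating 0 and 90 degrees averages the two exact values
  fr <- frames_from_angles(rep(c(0, 90), 10))
  expect_lt(abs(sch_per_lipid(fr, bond) - 0.25), 1e-12)
})

test_that("degenerate bond vectors error with the frame named", {
  topo <- one_bond_topology()
  fr <- frames_from_angles(c(0, 0, 0))
  fr$coords[2, , 2] <- fr$coords[1, , 2]  # H on top of C in frame 2
  expect_error(sch_per_lipid(fr, topo$ch_bonds[1, ]), "frame 2")
})

test_that("ensemble averaging uses lipids as the independent unit", {
  r <- sch_ensemble(c(0.2, 0.2, 0.2), ALPHA, "R")
  expect_equal(r$s_mean, 0.2)
  expect_equal(r$sem, 0)
  vals <- c(0.1, 0.2, 0.3, 0.4)
  r2 <- sch_ensemble(vals, ALPHA, "R")
  expect_equal(r2$sem, sd(vals) / 2)
  expect_true(is.na(sch_ensemble(0.5, ALPHA)$sem))
})

test_that("the uniform-cone closed form matches numerical integration", {
  # independent oracle: integrate P2(c) over the spherical cap
  for (th0 in c(30, 45, 60, 75)) {
    c0 <- cos(th0 * pi / 180)
    oracle <- integrate(function(c) (3 * c^2 - 1) / 2, c0, 1)$value /
      (1 - c0)
    expect_equal(model_truth_s(orientation_model("cone", theta0 = th0)),
                 oracle, tolerance = 1e-9)
  }
})

test_that("cone ensembles recover the closed-form order parameter", {
  for (th0 in c(30, 60)) {
    sim <- gen_orientation_ensemble(orientation_model("cone", theta0 = th0),
                                    100, 400, seed = th0)
    ops <- order_parameters(sim$frames, sim$topology)
    expect_lt(abs(ops$s_mean - sim$truth), 3 * ops$sem)
  }
})

test_that("isotropic ensembles give a null order parameter", {
  sim <- gen_orientation_ensemble(orientation_model("isotropic"), 100, 400,
                                  seed = 4)
  ops <- order_parameters(sim$frames, sim$topology)
  expect_lt(abs(ops$s_mean), 3 * ops$sem)
})

test_that("order parameters are bounded and invariant under z rotation", {
  sim <- gen_orientation_ensemble(orientation_model("isotropic"), 20, 50,
                                  seed = 8, stereo_labels = c("R", "S"))
  ops <- order_parameters(sim$frames, sim$topology)
  expect_true(all(ops$s_mean >= -0.5 & ops$s_mean <= 1))
  ang <- 0.7
  rot <- sim$frames
  x <- rot$coords[, 1, ]; y <- rot$coords[, 2, ]
  rot$coords[, 1, ] <- cos(ang) * x - sin(ang) * y
  rot$coords[, 2, ] <- sin(ang) * x + cos(ang) * y
  ops2 <- order_parameters(rot, sim$topology)
  expect_lt(max(abs(ops$s_mean - ops2$s_mean)), 1e-12)
})

test_that("theta distributions are per-lipid normalised with SEM over lipids", {
  # point mass at 0 degrees
  sim <- gen_orientation_ensemble(orientation_model("fixed", theta0 = 0),
                                  5, 20, seed = 1)
  td <- theta_distribution(sim$frames, sim$topology$ch_bonds, 1:5, bins = 18)
  expect_equal(td$probability[1], 1)
  expect_equal(sum(td$probability), 1, tolerance = 1e-9)
  # isotropic: bin mass follows the solid-angle measure sin(theta)/2
  sim2 <- gen_orientation_ensemble(orientation_model("isotropic"), 20, 500,
                                   seed = 2)
  td2 <- theta_distribution(sim2$frames, sim2$topology$ch_bonds, 1:20,
                            bins = 12)
  edges <- seq(0, pi, length.out = 13)
  truth <- (cos(edges[-13]) - cos(edges[-1])) / 2
  expect_true(all(abs(td2$probability - truth) < 3 * td2$sem + 1e-12))
  expect_equal(sum(td2$probability), 1, tolerance = 1e-9)
  expect_error(theta_distribution(sim2$frames, sim2$topology$ch_bonds,
                                  integer(0)), "empty")
})

test_that("forking detection is symmetric and flags extreme splits", {
  r <- sch_ensemble(c(1, 1, 1), ALPHA, "R"); r$sem <- 0.01
  s <- sch_ensemble(c(-0.5, -0.5, -0.5), ALPHA, "S"); s$sem <- 0.01
  f <- detect_forking(r, s)
  expect_equal(f$magnitude, 1.5)
  expect_true(f$significant)
  f2 <- detect_forking(s, r)
  expect_equal(f2, f)
  same <- detect_forking(r, within(r, stereo_label <- "S"))
  expect_equal(same$magnitude, 0)
  expect_false(same$significant)
  bad <- within(s, segment_label <- "g1")
  expect_error(detect_forking(r, bad), "different segments")
})

test_that("null forking stays insignificant at the expected rate", {
  hits <- 0L
  n_rep <- 30L
  for (k in seq_len(n_rep)) {
    sim <- gen_orientation_ensemble(orientation_model("cone", theta0 = 60),
                                    50, 100, seed = 1000 + k,
                                    stereo_labels = c("R", "S"))
    ops <- order_parameters(sim$frames, sim$topology)
    f <- detect_forking(ops[ops$stereo_label == "R", ],
                        ops[ops$stereo_label == "S", ], k_sigma = 2)
    hits <- hits + f$significant
  }
  expect_lte(hits, 4L)  # ~5% false-positive rate at 2 sigma
})

test_that("delta S against the R/S-averaged baseline", {
  rec <- sch_ensemble(rep(0.15, 3), "\u03b2"); rec$sem <- 0.01
  r0 <- sch_ensemble(rep(0.3, 3), "\u03b2", "R"); r0$sem <- 0.02
  s0 <- sch_ensemble(rep(0.1, 3), "\u03b2", "S"); s0$sem <- 0.02
  d <- delta_sch(rec, r0, s0, concentration = 0.5)
  expect_equal(d$delta, -0.05)
  expect_equal(d$sem, sqrt(0.01^2 + 0.02^2 / 4 + 0.02^2 / 4))
  expect_equal(delta_sch(r0, r0, r0)$delta, 0)
  expect_error(delta_sch(rec, r0, sch_ensemble(0.1, "g1", "S")),
               "different segments")
})

test_that("delta S recovers the closed-form cone difference", {
  base <- gen_orientation_ensemble(orientation_model("cone", theta0 = 60),
                                   150, 300, seed = 21,
                                   stereo_labels = c("R", "S"))
  th_rec <- acos(2 / 3) * 180 / pi
  rec <- gen_orientation_ensemble(orientation_model("cone", theta0 = th_rec),
                                  150, 300, seed = 22)
  ops0 <- order_parameters(base$frames, base$topology)
  opsc <- order_parameters(rec$frames, rec$topology)
  d <- delta_sch(opsc[1, ], ops0[ops0$stereo_label == "R", ],
                 ops0[ops0$stereo_label == "S", ])
  truth <- (2 / 3) * (1 + 2 / 3) / 2 - 0.375
  expect_lt(abs(d$delta - truth), 3 * d$sem)
})
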
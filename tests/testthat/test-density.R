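test_that("density profiles conserve particles exactly", {
  slab <- gen_ion_slab(layering_model(list(c(-2, 0.3, 0.4), c(2, 0.3, 0.4)),
                                      0.2, 2000),
                       box = c(6, 6, 8), n_frames = 5, seed = 3)
  nd <- number_density(slab$frames, slab$topology, "ions", anchor = NULL)
  binvol <- nd$area * nd$bin_width
  expect_lt(abs(sum(nd$density) * binvol - 2000) / 2000, 1e-9)
})

test_that("a uniform fixture gives a flat profile at the bulk value", {
  u <- uniform_slab(2000, c(6, 6, 8), 20, seed = 7)
  nd <- number_density(u$frames, u$topology, "ions", anchor = NULL)
  bulk <- 2000 / prod(c(6, 6, 8))
  counts_per_bin <- nd$density * nd$area * nd$bin_width * nd$n_frames
  expected <- bulk * nd$area * nd$bin_width * nd$n_frames
  expect_true(all(abs(counts_per_bin - expected) <= 3 * sqrt(expected)))
})

test_that("a stationary point mass lands entirely in the center bin", {
  atoms <- atom_table(-1L, "NA", element = "Na")
  coords <- array(c(3, 3, 4), c(1, 3, 1))
  fr <- frame_series(0, coords, c(6, 6, 8))
  topo <- bilayer_topology(atoms)
  nd <- number_density(fr, topo, 1L, bin_width = 0.1, anchor = NULL)
  peak <- which.max(nd$density)
  expect_equal(nd$density[peak], 1 / (6 * 6 * nd$bin_width))
  expect_equal(sum(nd$density > 0), 1L)
  expect_lt(abs(nd$bin_centers[peak]), nd$bin_width)
})

# Expected counts per bin from the exact analytic bin integrals of a
# truncated-Gaussian + bulk layering model (midpoint evaluation biases the
# peak bins).
layering_bin_counts <- function(model, lz, edges) {
  pk <- model$peaks
  vapply(seq_len(length(edges) - 1L), function(i) {
    p <- model$bulk_fraction * (edges[i + 1] - edges[i]) / lz
    for (k in seq_len(nrow(pk))) {
      nrm <- pnorm(lz / 2, pk[k, 1], pk[k, 2]) -
        pnorm(-lz / 2, pk[k, 1], pk[k, 2])
      p <- p + pk[k, 3] * (pnorm(edges[i + 1], pk[k, 1], pk[k, 2]) -
                             pnorm(edges[i], pk[k, 1], pk[k, 2])) / nrm
    }
    p
  }, numeric(1))
}

test_that("Gaussian layering matches the generator truth within Poisson 3 sigma", {
  slab <- gen_ion_slab(layering_model(list(c(-2, 0.3, 0.4), c(2, 0.3, 0.4)),
                                      0.2, 3000),
                       box = c(6, 6, 8), n_frames = 30, seed = 11)
  nd <- number_density(slab$frames, slab$topology, "ions", anchor = NULL)
  nb <- length(nd$bin_centers)
  edges <- seq(-4, 4, length.out = nb + 1L)
  expected <- layering_bin_counts(slab$model, 8, edges) * 3000 * nd$n_frames
  observed <- nd$density * nd$area * nd$bin_width * nd$n_frames
  expect_true(all(abs(observed - expected) <= 3 * sqrt(pmax(expected, 1))))
})

test_that("mirrored coordinates leave symmetric profiles unchanged", {
  slab <- gen_ion_slab(layering_model(list(c(-2, 0.3, 0.4), c(2, 0.3, 0.4)),
                                      0.2, 3000),
                       box = c(6, 6, 8), n_frames = 10, seed = 13)
  nd <- number_density(slab$frames, slab$topology, "ions", anchor = NULL)
  mir <- slab$frames
  mir$coords[, 3, ] <- mir$box[1, 3] - mir$coords[, 3, ]
  nd2 <- number_density(mir, slab$topology, "ions", anchor = NULL)
  # binning of mirrored data equals the mirrored binning up to edge effects
  expect_lt(mean(abs(nd2$density - rev(nd$density))) /
              mean(nd$density), 0.05)
})

test_that("concentration normalisation returns percent of nominal", {
  u <- uniform_slab(1000, c(6, 6, 8), 10, seed = 5)
  nd <- number_density(u$frames, u$topology, "ions", anchor = NULL)
  molarity <- 1000 / (6.02214076e23 * 1e-24 * prod(c(6, 6, 8)))
  pc <- normalize_by_concentration(nd, molarity)
  expect_equal(mean(pc$density), 100, tolerance = 1e-9)
  pc2 <- normalize_by_concentration(nd, molarity / 2)
  expect_equal(mean(pc2$density), 200, tolerance = 1e-9)
  zero <- nd; zero$density[] <- 0
  expect_true(all(normalize_by_concentration(zero, 0.1)$density == 0))
  expect_error(normalize_by_concentration(nd, 0), "positive")
})

test_that("electron density weights atoms by electron count and conserves them", {
  atoms <- atom_table(c(-1L, -1L), c("O", "NA"), element = c("O", "Na"))
  coords <- array(c(3, 3, 4, 3, 3, 2), c(2, 3, 1))
  fr <- frame_series(0, coords, c(6, 6, 8))
  topo <- bilayer_topology(atoms)
  ed <- electron_density(fr, topo, anchor = NULL)
  expect_equal(max(ed$density), 11 / (36 * ed$bin_width))  # Na, 11 e
  expect_equal(sum(ed$density) * ed$area * ed$bin_width, 8 + 11,
               tolerance = 1e-9)
})

test_that("form factor of a Gaussian slab matches its analytic transform", {
  g <- gen_gaussian_membrane(list(c(0, 0.3, 1)), n_particles = 5e4,
                             n_frames = 2, seed = 17)
  ed <- electron_density(g$frames, g$topology, bin_width = 0.02,
                         anchor = NULL)
  ff <- form_factor(ed, bulk_density = 0)
  truth <- g$truth(ff$q_grid)
  tn <- truth / max(truth[ff$q_grid >= 0.1 & ff$q_grid <= 0.2])
  expect_lt(sqrt(mean((ff$magnitude - tn)^2)), 0.01)
  # |F(0)| equals the integrated contrast
  expect_equal(ff$raw[1], abs(sum(ed$density - 0) * ed$bin_width),
               tolerance = 1e-9)
})

test_that("two symmetric Gaussians put the first |F| zero at pi/(2 z0)", {
  z0 <- 2
  g <- gen_gaussian_membrane(list(c(-z0, 0.25, 0.5), c(z0, 0.25, 0.5)),
                             box = c(6, 6, 12), n_particles = 5e4,
                             n_frames = 2, seed = 19)
  ed <- electron_density(g$frames, g$topology, bin_width = 0.02,
                         anchor = NULL)
  ff <- form_factor(ed, bulk_density = 0, dq = 0.0005)
  # bracket the first cosine zero (shot noise makes the global minimum at
  # high q meaningless)
  sub <- ff$q_grid > 0.02 & ff$q_grid < 0.15
  qmin <- ff$q_grid[sub][which.min(ff$magnitude[sub])]
  expect_lt(abs(qmin - pi / (2 * z0 * 10)), 0.0005 + 1e-12)
})

test_that("zero contrast raises a normalization error", {
  u <- uniform_slab(500, c(6, 6, 8), 2, seed = 23)
  nd <- number_density(u$frames, u$topology, "ions", anchor = NULL)
  flat <- nd
  flat$density[] <- 4.2
  expect_error(form_factor(flat, bulk_density = 4.2), "normalization")
})

test_that("halving dq leaves the normalised curve essentially unchanged", {
  g <- gen_gaussian_membrane(list(c(0, 0.4, 1)), n_particles = 2e4,
                             n_frames = 1, seed = 29)
  ed <- electron_density(g$frames, g$topology, bin_width = 0.05,
                         anchor = NULL)
  f1 <- form_factor(ed, bulk_density = 0, dq = 0.002)
  f2 <- form_factor(ed, bulk_density = 0, dq = 0.001)
  on_f1 <- f2$magnitude[match(round(f1$q_grid, 9),
                              round(f2$q_grid, 9))]
  expect_lt(sqrt(mean((f1$magnitude - on_f1)^2)), 0.001)
})
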
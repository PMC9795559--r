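# Seedable synthetic ensembles with closed-form ground truth. Each
# generator returns the data together with the analytic value of the
# observable it exercises, so analysis-vs-truth comparisons are pure
# functions of the returned pair.

#' Orientation model for C--H bond vectors
#'
#' `fixed` pins the tilt at `theta0` (azimuth uniform); `cone` samples
#' uniformly over the solid angle of the cap with half-angle `theta0`;
#' `isotropic` is uniform over the sphere; `mixture` combines weighted
#' component models. The closed-form order parameter is: fixed
#' `P2(cos theta0)`; cone `cos theta0 (1 + cos theta0)/2`; isotropic 0;
#' mixture the weighted sum.
#'
#' @param kind one of `"fixed"`, `"cone"`, `"isotropic"`, `"mixture"`.
#' @param theta0 half-angle / tilt in degrees (fixed, cone).
#' @param components for mixtures: list of `list(weight =, model =)`.
#' @return object of class `"orientation_model"`.
#' @export
orientation_model <- function(kind = c("fixed", "cone", "isotropic",
                                       "mixture"),
                              theta0 = NULL, components = NULL) {
  kind <- match.arg(kind)
  if (kind %in% c("fixed", "cone")) {
    if (is.null(theta0) || theta0 < 0 || theta0 > 180)
      stop_domain("theta0 must lie in [0, 180] degrees")
  }
  if (kind == "mixture") {
    if (is.null(components) || !length(components))
      stop_domain("mixture needs components")
    w <- vapply(components, `[[`, numeric(1), "weight")
    if (abs(sum(w) - 1) > 1e-9)
      stop_domain("mixture weights must sum to 1")
  }
  structure(list(kind = kind, theta0 = theta0, components = components),
            class = "orientation_model")
}

#' Closed-form order parameter of an orientation model
#' @param model an [orientation_model()].
#' @return expected S_CH.
#' @export
model_truth_s <- function(model) {
  switch(model$kind,
    fixed = p2(cos(model$theta0 * pi / 180)),
    cone = { c0 <- cos(model$theta0 * pi / 180); c0 * (1 + c0) / 2 },
    isotropic = 0,
    mixture = sum(vapply(model$components, function(cm)
      cm$weight * model_truth_s(cm$model), numeric(1))))
}

sample_costheta <- function(model, n) {
  switch(model$kind,
    fixed = rep(cos(model$theta0 * pi / 180), n),
    cone = stats::runif(n, cos(model$theta0 * pi / 180), 1),
    isotropic = stats::runif(n, -1, 1),
    mixture = {
      w <- vapply(model$components, `[[`, numeric(1), "weight")
      pick <- sample.int(length(w), n, replace = TRUE, prob = w)
      out <- numeric(n)
      for (i in seq_along(w)) {
        k <- pick == i
        if (any(k))
          out[k] <- sample_costheta(model$components[[i]]$model, sum(k))
      }
      out
    })
}

#' Generate an orientational ensemble of C--H bonds
#'
#' One carbon per lipid with one hydrogen per requested stereo label; bond
#' vectors are unit length, drawn i.i.d. per frame from the model (no time
#' correlation). The closed-form expected S_CH is returned as `truth`.
#'
#' @param model an [orientation_model()].
#' @param n_lipids,n_frames ensemble size.
#' @param seed RNG seed (mandatory for reproducibility).
#' @param segment_label segment assigned to the bonds.
#' @param stereo_labels one hydrogen per entry, e.g. `c("R", "S")`.
#' @param dt frame spacing (ps).
#' @param box box lengths (nm).
#' @return list with `topology`, `frames`, `truth` (expected S) and the
#'   model.
#' @export
gen_orientation_ensemble <- function(model, n_lipids, n_frames, seed,
                                     segment_label = "\u03b1",
                                     stereo_labels = "R",
                                     dt = 10, box = c(8, 8, 8)) {
  stopifnot(n_lipids >= 1, n_frames >= 1)
  nb <- length(stereo_labels)
  nat_per <- 1L + nb
  nat <- n_lipids * nat_per
  # name atoms after the bundled bond table where possible, so fixtures
  # written to GRO re-attach their bonds on reload
  bt <- tryCatch(read_bond_table(), error = function(e) NULL)
  bt <- if (!is.null(bt)) bt[bt$segment_label == segment_label, ] else NULL
  names_for <- function(st, i) {
    hit <- if (!is.null(bt)) which(bt$stereo_label == st) else integer()
    if (length(hit)) bt$hydrogen_name[hit[1]] else paste0("H", i)
  }
  c_name <- if (!is.null(bt) && nrow(bt)) bt$carbon_name[1] else "C11"
  h_names <- vapply(seq_len(nb), function(i)
    names_for(stereo_labels[i], i), character(1))
  atoms <- atom_table(
    lipid_id = rep(seq_len(n_lipids), each = nat_per),
    atom_name = rep(c(c_name, h_names), n_lipids),
    element = rep(c("C", rep("H", nb)), n_lipids),
    stereo_label = rep(c("none", stereo_labels), n_lipids))
  cidx <- (seq_len(n_lipids) - 1L) * nat_per + 1L
  ch <- do.call(rbind, lapply(seq_len(nb), function(b)
    data.frame(carbon = cidx, hydrogen = cidx + b,
               segment_label = segment_label, stereo_label = stereo_labels[b],
               stringsAsFactors = FALSE)))
  leaflet <- rep(c("upper", "lower"), length.out = n_lipids)
  names(leaflet) <- seq_len(n_lipids)
  topo <- bilayer_topology(atoms, ch, leaflet)
  coords <- with_seed(seed, {
    arr <- array(0, c(nat, 3L, n_frames))
    base <- cbind(stats::runif(n_lipids, 0, box[1]),
                  stats::runif(n_lipids, 0, box[2]),
                  ifelse(leaflet == "upper", 0.75, 0.25) * box[3])
    arr[cidx, 1, ] <- base[, 1]
    arr[cidx, 2, ] <- base[, 2]
    arr[cidx, 3, ] <- base[, 3]
    for (b in seq_len(nb)) {
      ct <- sample_costheta(model, n_lipids * n_frames)
      st <- sqrt(pmax(0, 1 - ct^2))
      phi <- stats::runif(n_lipids * n_frames, 0, 2 * pi)
      hx <- matrix(st * cos(phi), n_lipids)
      hy <- matrix(st * sin(phi), n_lipids)
      hz <- matrix(ct, n_lipids)
      # bond length 0.109 nm (C-H)
      arr[cidx + b, 1, ] <- arr[cidx, 1, ] + 0.109 * hx
      arr[cidx + b, 2, ] <- arr[cidx, 2, ] + 0.109 * hy
      arr[cidx + b, 3, ] <- arr[cidx, 3, ] + 0.109 * hz
    }
    arr
  })
  frames <- frame_series((seq_len(n_frames) - 1) * dt, coords, box)
  list(topology = topo, frames = frames, truth = model_truth_s(model),
       model = model)
}

#' Layering model for ion/water z distributions
#'
#' Mixture of Gaussian surface peaks (given in z relative to the bilayer
#' center) and a uniform bulk component. Gaussians are truncated at the box
#' faces and renormalised analytically, so the ground-truth density stays
#' closed form.
#'
#' @param peaks matrix-like with columns `center` (nm), `sigma` (nm),
#'   `weight`, or a list of length-3 vectors.
#' @param bulk_fraction weight of the uniform component;
#'   `sum(weights) + bulk_fraction` must be 1.
#' @param n_particles particles per frame.
#' @return object of class `"layering_model"`.
#' @export
layering_model <- function(peaks = NULL, bulk_fraction = 0,
                           n_particles = 1000L) {
  if (is.list(peaks) && !is.data.frame(peaks))
    peaks <- do.call(rbind, peaks)
  if (!is.null(peaks)) {
    peaks <- matrix(as.numeric(as.matrix(peaks)), ncol = 3,
                    dimnames = list(NULL, c("center", "sigma", "weight")))
    if (any(peaks[, "sigma"] <= 0)) stop_domain("sigma must be positive")
  } else peaks <- matrix(numeric(0), 0, 3,
                         dimnames = list(NULL,
                                         c("center", "sigma", "weight")))
  if (abs(sum(peaks[, "weight"]) + bulk_fraction - 1) > 1e-9)
    stop_domain("peak weights plus bulk_fraction must sum to 1")
  structure(list(peaks = peaks, bulk_fraction = bulk_fraction,
                 n_particles = as.integer(n_particles)),
            class = "layering_model")
}

# Analytic per-frame number density (nm^-3) of a layering model in a box.
layering_truth <- function(model, box) {
  pk <- model$peaks
  lz <- box[3]
  area <- box[1] * box[2]
  norm <- if (nrow(pk))
    stats::pnorm(lz / 2, pk[, "center"], pk[, "sigma"]) -
      stats::pnorm(-lz / 2, pk[, "center"], pk[, "sigma"]) else numeric(0)
  function(z) {
    dens <- rep(model$bulk_fraction / lz, length(z))
    for (i in seq_len(nrow(pk)))
      dens <- dens + pk[i, "weight"] *
        stats::dnorm(z, pk[i, "center"], pk[i, "sigma"]) / norm[i]
    model$n_particles * dens / area
  }
}

sample_layering_z <- function(model, n, lz) {
  pk <- model$peaks
  w <- c(pk[, "weight"], model$bulk_fraction)
  pick <- sample.int(length(w), n, replace = TRUE, prob = w)
  z <- numeric(n)
  for (i in seq_len(nrow(pk))) {
    k <- pick == i
    if (!any(k)) next
    lo <- stats::pnorm(-lz / 2, pk[i, "center"], pk[i, "sigma"])
    hi <- stats::pnorm(lz / 2, pk[i, "center"], pk[i, "sigma"])
    z[k] <- stats::qnorm(stats::runif(sum(k), lo, hi),
                         pk[i, "center"], pk[i, "sigma"])
  }
  k <- pick == length(w)
  if (any(k)) z[k] <- stats::runif(sum(k), -lz / 2, lz / 2)
  z
}

#' Generate an ion slab with Gaussian surface layering
#'
#' Particle z positions are drawn per frame from the layering model
#' (relative to the box center); x and y are uniform. The returned `truth`
#' is the analytic number-density function of centered z (nm^-3).
#'
#' @param model a [layering_model()].
#' @param box box lengths (nm).
#' @param n_frames frames to generate.
#' @param seed RNG seed.
#' @param element chemical symbol of the particles.
#' @param dt frame spacing (ps).
#' @return list with `topology`, `frames`, `truth` (function of z).
#' @export
gen_ion_slab <- function(model, box = c(6, 6, 8), n_frames = 10L, seed,
                         element = "Na", dt = 10) {
  pk <- model$peaks
  if (nrow(pk) && any(abs(pk[, "center"]) > box[3] / 2))
    stop_domain("peak center outside the box")
  np <- model$n_particles
  atoms <- atom_table(lipid_id = rep(-1L, np),
                      atom_name = rep(toupper(element), np),
                      element = rep(element, np))
  coords <- with_seed(seed, {
    arr <- array(NA_real_, c(np, 3L, n_frames))
    for (k in seq_len(n_frames)) {
      arr[, 1, k] <- stats::runif(np, 0, box[1])
      arr[, 2, k] <- stats::runif(np, 0, box[2])
      arr[, 3, k] <- sample_layering_z(model, np, box[3]) + box[3] / 2
    }
    arr
  })
  frames <- frame_series((seq_len(n_frames) - 1) * dt, coords, box)
  list(topology = bilayer_topology(atoms), frames = frames,
       truth = layering_truth(model, box), model = model)
}

#' Generate point scatterers from a Gaussian electron-density profile
#'
#' Samples `n_particles` point scatterers per frame from a mixture of
#' Gaussian slabs (an idealised electron-density contrast across a
#' membrane), each carrying `electrons` electrons. `truth` is the analytic
#' magnitude of the one-dimensional Fourier transform of the mixture,
#' `|sum_k w_k exp(-q^2 sigma_k^2 / 2) exp(i q z_k)|`, as a function of q
#' in 1/A (arbitrary scale; normalise alongside the computed curve).
#'
#' @param peaks Gaussian components as in [layering_model()] (weights must
#'   sum to 1; no bulk term).
#' @param box box lengths (nm).
#' @param n_particles scatterers per frame.
#' @param n_frames frames to generate.
#' @param seed RNG seed.
#' @param electrons electron count per scatterer.
#' @return list with `topology`, `frames`, `truth` (function of q, 1/A).
#' @export
gen_gaussian_membrane <- function(peaks, box = c(6, 6, 10),
                                  n_particles = 1e5L, n_frames = 1L, seed,
                                  electrons = 8L) {
  model <- layering_model(peaks, bulk_fraction = 0, n_particles)
  sim <- gen_ion_slab(model, box, n_frames, seed, element = "O")
  sim$topology$atoms$electrons <- as.integer(electrons)
  pk <- model$peaks
  sim$truth <- function(q_invA) {
    qn <- q_invA * 10  # 1/nm
    vapply(qn, function(qq)
      abs(sum(pk[, "weight"] * exp(-qq^2 * pk[, "sigma"]^2 / 2) *
                exp(1i * qq * pk[, "center"]))), numeric(1))
  }
  sim
}

#' Generate 2D Brownian lipid center-of-mass motion in a periodic box
#'
#' One particle per lipid performing an independent 2D random walk with
#' per-axis step standard deviation `sqrt(2 D dt)`, optionally with a
#' common drift; coordinates are wrapped into the box so that the
#' unwrapping in [com_trajectories()] is exercised. z stays at the leaflet
#' planes.
#'
#' @param d_true diffusion coefficient (m^2/s).
#' @param n_lipids,n_frames walk dimensions.
#' @param dt frame spacing (ps).
#' @param box box lengths (nm).
#' @param drift common xy drift velocity (nm/ps).
#' @param seed RNG seed.
#' @return list with `topology`, `frames` (wrapped) and `truth = d_true`.
#' @export
gen_brownian_bilayer <- function(d_true = 5e-12, n_lipids = 200L,
                                 n_frames = 1000L, dt = 10,
                                 box = c(8, 8, 8), drift = c(0, 0), seed) {
  stopifnot(d_true >= 0, dt > 0)
  d_nmps <- d_true * 1e6          # m^2/s -> nm^2/ps
  sd_step <- sqrt(2 * d_nmps * dt)
  atoms <- atom_table(lipid_id = seq_len(n_lipids),
                      atom_name = rep("P", n_lipids),
                      element = rep("P", n_lipids))
  leaflet <- rep(c("upper", "lower"), length.out = n_lipids)
  names(leaflet) <- seq_len(n_lipids)
  coords <- with_seed(seed, {
    arr <- array(NA_real_, c(n_lipids, 3L, n_frames))
    for (ax in 1:2) {
      x0 <- stats::runif(n_lipids, 0, box[ax])
      path <- if (n_frames == 1L) matrix(x0) else {
        steps <- matrix(stats::rnorm(n_lipids * (n_frames - 1L), 0, sd_step),
                        n_lipids) + drift[ax] * dt
        cums <- if (n_frames == 2L) steps else t(apply(steps, 1, cumsum))
        cbind(x0, x0 + cums)
      }
      arr[, ax, ] <- wrap_box(path, box[ax])
    }
    arr[, 3, ] <- ifelse(leaflet == "upper", 0.75, 0.25) * box[3]
    arr
  })
  frames <- frame_series((seq_len(n_frames) - 1) * dt, coords, box)
  topo <- bilayer_topology(atoms, leaflet = leaflet)
  list(topology = topo, frames = frames, truth = d_true)
}

#' POPC-like dummy topology with every segment populated
#'
#' Builds lipids containing one atom per carbon and hydrogen of the
#' bond-definition table plus P and N anchors, placed with dummy geometry
#' (anchors at the leaflet planes, C--H bonds isotropic). Useful for
#' end-to-end runs of the full pipeline without any real trajectory.
#' Synthetic: the geometry carries no physical conformational meaning.
#'
#' @param n_lipids lipid count (split across the two leaflets).
#' @param n_frames frames to generate.
#' @param seed RNG seed.
#' @param box box lengths (nm).
#' @param bond_table bond-definition table; bundled POPC table by default.
#' @param dt frame spacing (ps).
#' @return list with `topology` and `frames`.
#' @export
gen_popc_like <- function(n_lipids = 10L, n_frames = 10L, seed,
                          box = c(8, 8, 8), bond_table = NULL, dt = 10) {
  bt <- bond_table %||% read_bond_table()
  cnames <- unique(bt$carbon_name)
  anames <- c("N", "P", cnames, bt$hydrogen_name)
  nat_per <- length(anames)
  elements <- c("N", "P", rep("C", length(cnames)),
                rep("H", nrow(bt)))
  atoms <- atom_table(
    lipid_id = rep(seq_len(n_lipids), each = nat_per),
    atom_name = rep(anames, n_lipids),
    element = rep(elements, n_lipids))
  atoms$resname <- "POPC"
  atoms$resid <- atoms$lipid_id
  leaflet <- rep(c("upper", "lower"), length.out = n_lipids)
  names(leaflet) <- seq_len(n_lipids)
  coords <- with_seed(seed, {
    arr <- array(NA_real_, c(nrow(atoms), 3L, n_frames))
    for (l in seq_len(n_lipids)) {
      off <- (l - 1L) * nat_per
      base <- c(stats::runif(1, 0, box[1]), stats::runif(1, 0, box[2]),
                if (leaflet[l] == "upper") 0.7 * box[3] else 0.3 * box[3])
      for (k in seq_len(n_frames)) {
        heavy <- matrix(base, nat_per, 3, byrow = TRUE) +
          matrix(stats::rnorm(nat_per * 3, 0, 0.05), nat_per)
        arr[off + seq_len(nat_per), , k] <- heavy
      }
      # hydrogens 0.109 nm from their carbon, isotropic direction
      hrows <- off + 2L + length(cnames) + seq_len(nrow(bt))
      crows <- off + 2L + match(bt$carbon_name, cnames)
      for (k in seq_len(n_frames)) {
        ct <- stats::runif(nrow(bt), -1, 1)
        phi <- stats::runif(nrow(bt), 0, 2 * pi)
        st <- sqrt(1 - ct^2)
        arr[hrows, , k] <- arr[crows, , k] +
          0.109 * cbind(st * cos(phi), st * sin(phi), ct)
      }
    }
    arr
  })
  frames <- frame_series((seq_len(n_frames) - 1) * dt, coords, box)
  topo <- bilayer_topology(atoms)
  topo <- apply_bond_table(topo, bt)
  topo$leaflet <- leaflet
  list(topology = topo, frames = frames)
}
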
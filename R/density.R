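# Density profiles along the membrane normal and SAXS form factors.

# Bin weighted z positions frame by frame. Each frame is re-centered on the
# bilayer midplane (mean anchor z; geometric box center when anchor = NULL)
# and wrapped into [-Lz/2, Lz/2). Bins tile [-Lmax/2, Lmax/2] exactly so
# that sum(density) * bin_volume reproduces the mean weight per frame.
bin_profile <- function(frames, idx, bin_width, weights, anchor_idx,
                        species, n_frames_label = NULL) {
  if (bin_width <= 0) stop_domain("bin_width must be positive")
  nf <- n_frames(frames)
  lmax <- max(frames$box[, 3])
  nb <- max(2L, as.integer(ceiling(lmax / bin_width - 1e-9)))
  width <- lmax / nb
  edges <- seq(-lmax / 2, lmax / 2, length.out = nb + 1L)
  acc <- numeric(nb)
  for (k in seq_len(nf)) {
    z <- frames$coords[idx, 3, k]
    mid <- if (is.null(anchor_idx)) frames$box[k, 3] / 2
           else mean(frames$coords[anchor_idx, 3, k])
    zc <- wrap_centered(z - mid, frames$box[k, 3])
    bin <- pmin(nb, pmax(1L, findInterval(zc, edges,
                                          rightmost.closed = TRUE)))
    wt <- numeric(nb)
    tmp <- rowsum(weights, bin)
    wt[as.integer(rownames(tmp))] <- tmp
    acc <- acc + wt
  }
  area <- mean(frames$box[, 1] * frames$box[, 2])
  out <- data.frame(
    bin_center = (edges[-1] + edges[-(nb + 1L)]) / 2,
    density = acc / (nf * area * width))
  structure(list(species = species, bin_centers = out$bin_center,
                 density = out$density, bin_width = width, area = area,
                 n_frames = nf, unit = "nm^-3"),
            class = "density_profile")
}

#' Number-density profile along the bilayer normal
#'
#' Per frame, atom z positions are re-centered on the bilayer midplane
#' (mean z of the anchor atoms; the box center when `anchor` is `NULL`),
#' wrapped into `[-Lz/2, Lz/2)` and accumulated into equal z bins; counts
#' are divided by the frame count and the mean bin volume
#' `Lx*Ly*bin_width`.
#'
#' @param frames a [frame_series()].
#' @param topology a [bilayer_topology()].
#' @param select atom selection (see [select_atoms()]).
#' @param bin_width bin width in nm.
#' @param anchor atom name used for per-frame centering (`NULL` = box
#'   center).
#' @param species label stored in the result.
#' @return object of class `"density_profile"` with fields `bin_centers`
#'   (nm, origin at the bilayer center), `density` (nm^-3) and `n_frames`.
#' @export
number_density <- function(frames, topology, select, bin_width = 0.1,
                           anchor = "P", species = NULL) {
  idx <- select_atoms(topology, select)
  anchor_idx <- if (is.null(anchor)) NULL
                else which(topology$atoms$atom_name == anchor)
  if (!is.null(anchor_idx) && !length(anchor_idx))
    stop_domain("no anchor atoms named '", anchor, "'; pass anchor = NULL ",
                "to center on the box")
  bin_profile(frames, idx, bin_width, rep(1, length(idx)), anchor_idx,
              species %||% if (is.character(select) && length(select) == 1)
                select else "selection")
}

#' Electron-density profile
#'
#' As [number_density()] but with every atom weighted by its electron
#' count (atomic number by default; a partial-charge-adjusted `electrons`
#' column in the atom table is honoured as-is).
#'
#' @inheritParams number_density
#' @return `"density_profile"` in e nm^-3, species `"electrons"`.
#' @export
electron_density <- function(frames, topology, bin_width = 0.1,
                             anchor = "P") {
  el <- topology$atoms$electrons
  if (anyNA(el) || any(el < 1))
    stop_domain("every atom needs a defined electron count >= 1")
  anchor_idx <- if (is.null(anchor)) NULL
                else which(topology$atoms$atom_name == anchor)
  if (!is.null(anchor_idx) && !length(anchor_idx)) anchor_idx <- NULL
  p <- bin_profile(frames, seq_len(nrow(topology$atoms)), bin_width,
                   as.numeric(el), anchor_idx, "electrons")
  p$unit <- "e nm^-3"
  p
}

#' @export
print.density_profile <- function(x, ...) {
  cat("Density profile [", x$species, "]: ", length(x$bin_centers),
      " bins of ", signif(x$bin_width, 4), " nm, ", x$n_frames,
      " frames, unit ", x$unit, "\n", sep = "")
  invisible(x)
}

#' @export
plot.density_profile <- function(x, ...) {
  graphics::plot(x$bin_centers, x$density, type = "l", xlab = "z (nm)",
                 ylab = paste0("density (", x$unit, ")"), ...)
  invisible(x)
}

#' Express an ion density profile as percent of the nominal concentration
#'
#' Divides a number-density profile by the number density corresponding to
#' the nominal salt molarity (Avogadro conversion), returning percentages:
#' 100 means bulk-like, values above 100 indicate accumulation.
#'
#' @param profile a `"density_profile"` in nm^-3.
#' @param salt_molarity nominal salt concentration (M, > 0).
#' @return the profile with `density` in percent.
#' @export
normalize_by_concentration <- function(profile, salt_molarity) {
  if (salt_molarity <= 0) stop_domain("salt molarity must be positive")
  n0 <- salt_molarity * 6.02214076e23 * 1e-24  # molecules per nm^3
  profile$density <- 100 * profile$density / n0
  profile$unit <- "% of nominal"
  profile
}

#' SAXS form factor from an electron-density profile
#'
#' `|F(q_z)| = |integral (rho_e(z) - rho_bulk) exp(i q_z z) dz|` by
#' midpoint quadrature over the profile bins, reported on a q grid in
#' inverse Angstroms and normalised by the first-peak height, i.e. the
#' maximum of `|F|` within 0.1--0.2 1/A.
#'
#' @param profile electron-density `"density_profile"` (e nm^-3).
#' @param bulk_density bulk (solvent) electron density subtracted as the
#'   contrast baseline; estimated from the outermost 10% of bins when
#'   `NULL`.
#' @param q_max,dq q grid extent and spacing (1/A); `q_max >= 0.2`.
#' @param symmetrize average the profile with its mirror image before
#'   transforming.
#' @return object of class `"form_factor"` with `q_grid` (1/A) and
#'   `magnitude` (first peak = 1); the raw unnormalised magnitude and the
#'   bulk density used are kept as fields `raw` and `bulk_density`.
#' @export
form_factor <- function(profile, bulk_density = NULL, q_max = 1, dq = 0.001,
                        symmetrize = FALSE) {
  if (dq <= 0) stop_domain("dq must be positive")
  if (q_max < 0.2)
    stop_domain("q_max must reach the 0.1-0.2 1/A normalization window")
  z <- profile$bin_centers
  rho <- profile$density
  if (symmetrize) rho <- (rho + rev(rho)) / 2
  if (is.null(bulk_density)) {
    k <- max(1L, floor(0.05 * length(z)))
    bulk_density <- mean(c(utils::head(rho, k), utils::tail(rho, k)))
  }
  contrast <- rho - bulk_density
  dz <- profile$bin_width
  q <- seq(0, q_max, by = dq)           # 1/A
  qn <- q * 10                          # 1/nm to match z in nm
  ft <- vapply(qn, function(qq) abs(sum(contrast * exp(1i * qq * z)) * dz),
               numeric(1))
  win <- q >= 0.1 & q <= 0.2
  peak <- max(ft[win])
  if (peak <= 0)
    stop_domain("normalization error: |F| vanishes in the 0.1-0.2 1/A window")
  structure(list(q_grid = q, magnitude = ft / peak, raw = ft,
                 bulk_density = bulk_density, first_peak = peak),
            class = "form_factor")
}

#' @export
print.form_factor <- function(x, ...) {
  cat("SAXS form factor: q in [0, ", max(x$q_grid),
      "] 1/A, first-peak normalised (peak ", signif(x$first_peak, 4),
      " e nm^-2)\n", sep = "")
  invisible(x)
}

#' @export
plot.form_factor <- function(x, ...) {
  graphics::plot(x$q_grid, x$magnitude, type = "l",
                 xlab = expression(q[z] ~ (ring(A)^-1)),
                 ylab = expression("|F(" * q[z] * ")| (normalised)"), ...)
  invisible(x)
}
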
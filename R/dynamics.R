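# Area per lipid, equilibration windowing, lipid center-of-mass motion and
# lateral diffusion from mean squared displacement.

#' Area per lipid time series
#'
#' `A_L(t) = Lx(t) * Ly(t) / n_leaflet`, the lateral box area divided by
#' the number of lipids in one leaflet.
#'
#' @param frames a [frame_series()].
#' @param n_leaflet lipids per leaflet (the paper's systems have 100).
#' @return `data.frame` of class `"area_series"` with `times` (ps) and
#'   `a_l` (nm^2).
#' @export
area_per_lipid <- function(frames, n_leaflet = 100L) {
  if (n_leaflet <= 0) stop_domain("n_leaflet must be positive")
  out <- data.frame(times = frames$times,
                    a_l = frames$box[, 1] * frames$box[, 2] / n_leaflet)
  attr(out, "n_leaflet") <- n_leaflet
  class(out) <- c("area_series", "data.frame")
  out
}

#' @export
plot.area_series <- function(x, ...) {
  graphics::plot(x$times / 1000, x$a_l, type = "l", xlab = "time (ns)",
                 ylab = expression(A[L] ~ (nm^2)), ...)
  invisible(x)
}

#' Detect the equilibrated portion of an area-per-lipid series
#'
#' Finds the earliest start time from which every sliding window of length
#' span/5 has a mean within `tolerance_sd` standard deviations (of the last
#' half of the series) of the last-half mean. When no such start exists
#' before 90% of the span the series is flagged non-equilibrated.
#'
#' @param series an [area_per_lipid()] result (>= 100 frames).
#' @param tolerance_sd tolerance in last-half SD units.
#' @return an [analysis_window()] with an extra `equilibrated` flag.
#' @export
equilibration_window <- function(series, tolerance_sd = 1) {
  n <- nrow(series)
  if (n < 100L) stop_domain("need at least 100 frames")
  a <- series$a_l
  t <- series$times
  half <- a[(floor(n / 2) + 1L):n]
  ref_m <- mean(half)
  ref_sd <- stats::sd(half)
  w <- max(2L, floor(n / 5))
  roll <- as.numeric(stats::filter(a, rep(1 / w, w), sides = 1))[w:n]
  # roll[j] is the mean of the window starting at frame j
  tol <- tolerance_sd * ref_sd + 1e-9 * (abs(ref_m) + 1)  # guard sd = 0
  viol <- which(abs(roll - ref_m) > tol)
  n_starts <- n - w + 1L
  if (!length(viol)) {
    start_idx <- 1L
  } else {
    start_idx <- max(viol) + 1L
  }
  equilibrated <- start_idx <= n_starts &&
    t[start_idx] < t[1] + 0.9 * (t[n] - t[1])
  start_idx <- min(start_idx, n)
  win <- analysis_window(t[start_idx], t[n],
                         label = if (equilibrated) "equilibrated"
                                 else "non-equilibrated")
  win$equilibrated <- equilibrated
  win
}

#' Split a trajectory span into equal analysis windows
#'
#' Contiguous non-overlapping windows of `window_length` covering the span
#' from the start; a trailing remainder shorter than one window is dropped
#' with a message. Used for the windowed re-analysis of runs that never
#' reach a steady state (e.g. ten 100 ns parts of a 1 us run).
#'
#' @param frames a [frame_series()].
#' @param window_length window length in ns.
#' @return list of [analysis_window()] objects.
#' @export
windowed_analysis <- function(frames, window_length) {
  if (window_length <= 0) stop_domain("window_length must be positive")
  len_ps <- window_length * 1000
  t0 <- frames$times[1]
  span <- frames$times[n_frames(frames)] - t0
  if (len_ps > span + 1e-9)
    stop_domain("window_length exceeds the trajectory span")
  k <- floor(span / len_ps + 1e-9)
  rem <- span - k * len_ps
  if (rem > 1e-9)
    message(sprintf("dropping trailing %.6g ns not covering a full window",
                    rem / 1000))
  lapply(seq_len(k), function(i)
    analysis_window(t0 + (i - 1) * len_ps, t0 + i * len_ps,
                    label = sprintf("window %d/%d", i, k)))
}

#' Unwrapped lipid center-of-mass paths in the membrane plane
#'
#' Periodic jumps are removed per atom by minimal-image continuity against
#' the previous frame, then the mass-weighted center of mass of each lipid
#' is formed. With `remove_system_com` the per-frame displacement of the
#' all-lipid center of mass (lipids only, solvent excluded) is subtracted,
#' cancelling common drift.
#'
#' @param frames a [frame_series()].
#' @param topology a [bilayer_topology()].
#' @param remove_system_com subtract collective lipid drift.
#' @return array `n_lipids x 2 x n_frames` of unwrapped xy paths (nm) with
#'   attributes `times` and `lipid_ids`; class `"com_paths"`.
#' @export
com_trajectories <- function(frames, topology, remove_system_com = TRUE) {
  atoms <- topology$atoms
  lip_atoms <- which(atoms$lipid_id >= 0)
  if (!length(lip_atoms)) stop_domain("topology has no lipid atoms")
  ids <- atoms$lipid_id[lip_atoms]
  mass <- atoms$mass[lip_atoms]
  nf <- n_frames(frames)
  lip_levels <- sort(unique(ids))
  grp <- factor(ids, levels = lip_levels)
  com <- array(NA_real_, c(length(lip_levels), 2L, nf))
  unwrapped <- frames$coords[lip_atoms, 1:2, , drop = FALSE]
  for (ax in 1:2) {
    x <- unwrapped[, ax, ]
    if (nf > 1) {
      L <- frames$box[, ax]
      d <- x[, -1L, drop = FALSE] - x[, -nf, drop = FALSE]
      Lm <- matrix(L[-1L], nrow(d), ncol(d), byrow = TRUE)
      d <- d - round(d / Lm) * Lm
      big <- abs(d) > Lm / 4
      if (any(big))
        warning("displacement beyond a quarter box between frames ",
                min(col(d)[big]), " and ", min(col(d)[big]) + 1L,
                "; unwrapping may be ambiguous", call. = FALSE)
      cums <- if (ncol(d) == 1L) d else t(apply(d, 1L, cumsum))
      x <- cbind(x[, 1L], x[, 1L] + cums)
    }
    wsum <- rowsum(x * mass, grp)
    msum <- as.numeric(rowsum(mass, grp))
    com[, ax, ] <- as.matrix(wsum / msum)
  }
  if (remove_system_com) {
    mlip <- as.numeric(rowsum(mass, grp))
    for (ax in 1:2) {
      tot <- colSums(com[, ax, , drop = FALSE] * mlip) / sum(mlip)
      com[, ax, ] <- com[, ax, ] - rep(tot - tot[1], each = nrow(com))
    }
  }
  structure(com, times = frames$times, lipid_ids = lip_levels,
            class = "com_paths")
}

# Integer frame lags for a lag grid given in ns.
lags_to_frames <- function(lag_ns, times) {
  dt <- times[2] - times[1]
  unique(sort(round(lag_ns * 1000 / dt)))
}

#' Lateral mean squared displacement with subgroup errors
#'
#' MSD of the lipid center-of-mass xy paths over all time origins. For
#' error estimation the lipids are divided into `n_subgroups` equal
#' consecutive groups treated as independent measurements; the SEM across
#' subgroup MSDs is attached per lag.
#'
#' @param paths a [com_trajectories()] result.
#' @param lag_grid lags in ns; default: 0 plus ~24 log-spaced lags up to
#'   half the span.
#' @param n_subgroups number of equal subgroups (lipid count must divide).
#' @return `data.frame` of class `"msd_curve"` with `lag_ns`, `msd` (nm^2),
#'   `sem`; the per-subgroup curves are kept in attribute `subgroups`.
#' @export
lateral_msd <- function(paths, lag_grid = NULL, n_subgroups = 5L) {
  times <- attr(paths, "times")
  nl <- dim(paths)[1]
  nf <- dim(paths)[3]
  if (nl %% n_subgroups != 0L)
    stop_domain(nl, " lipids cannot be split into ", n_subgroups,
                " equal subgroups")
  span_ns <- (times[nf] - times[1]) / 1000
  dt_ns <- (times[2] - times[1]) / 1000
  if (is.null(lag_grid))
    lag_grid <- c(0, exp(seq(log(dt_ns), log(span_ns / 2),
                             length.out = 48)))
  lag_f <- lags_to_frames(lag_grid, times)
  lag_f <- lag_f[lag_f >= 0 & lag_f < nf]
  sub <- rep(seq_len(n_subgroups), each = nl / n_subgroups)
  msd_lip <- matrix(NA_real_, nl, length(lag_f))
  for (j in seq_along(lag_f)) {
    l <- lag_f[j]
    if (l == 0L) { msd_lip[, j] <- 0; next }
    dx <- paths[, 1, (1 + l):nf, drop = FALSE] -
          paths[, 1, 1:(nf - l), drop = FALSE]
    dy <- paths[, 2, (1 + l):nf, drop = FALSE] -
          paths[, 2, 1:(nf - l), drop = FALSE]
    msd_lip[, j] <- rowMeans(dx^2 + dy^2, dims = 1)
  }
  subm <- rowsum(msd_lip, sub) / (nl / n_subgroups)
  out <- data.frame(
    lag_ns = lag_f * dt_ns,
    msd = colMeans(msd_lip),
    sem = apply(subm, 2, stats::sd) / sqrt(n_subgroups))
  attr(out, "subgroups") <- subm
  attr(out, "n_subgroups") <- n_subgroups
  attr(out, "span_ns") <- span_ns
  class(out) <- c("msd_curve", "data.frame")
  out
}

#' @export
plot.msd_curve <- function(x, ...) {
  graphics::plot(x$lag_ns, x$msd, type = "b", pch = 19,
                 xlab = "lag (ns)", ylab = expression(MSD ~ (nm^2)), ...)
  graphics::arrows(x$lag_ns, x$msd - x$sem, x$lag_ns, x$msd + x$sem,
                   angle = 90, code = 3, length = 0.02)
  invisible(x)
}

# Feasible-slope interval for lines passing within +-sem of every point,
# solved exactly: the feasibility gap is concave piecewise-linear in the
# slope, so the extreme slopes lie on intersections of constraint pairs.
slope_band <- function(x, y, s, tol = 1e-10) {
  feas <- function(b) max(y - s - b * x) <= min(y + s - b * x) + tol
  cand <- c()
  n <- length(x)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    dxij <- x[j] - x[i]
    if (abs(dxij) < 1e-15) next
    cand <- c(cand,
              ((y[j] + s[j]) - (y[i] - s[i])) / dxij,
              ((y[j] - s[j]) - (y[i] + s[i])) / dxij,
              ((y[j] + s[j]) - (y[i] + s[i])) / dxij,
              ((y[j] - s[j]) - (y[i] - s[i])) / dxij)
  }
  cand <- cand[vapply(cand, feas, logical(1))]
  if (!length(cand)) return(NULL)
  c(min(cand), max(cand))
}

#' Lateral diffusion coefficient from an MSD curve
#'
#' Least-squares line through the MSD points inside `fit_window`; in two
#' dimensions `D_L` is one quarter of the slope. The error band comes from
#' the steepest and gentlest straight lines that pass within one SEM of
#' every windowed point; if no such line exists the band falls back to the
#' slope +- its fit standard error (with a message). The default window is
#' 20--50 ns, the displacement-time regime where lipid MSD is diffusive in
#' bilayer simulations, provided that regime lies within the first quarter
#' of the trajectory span; otherwise 10--25% of the span (longer lags
#' average too few independent displacement segments).
#'
#' @param curve a [lateral_msd()] result.
#' @param fit_window length-2 lag range in ns.
#' @return object of class `"diffusion_fit"` with `d`, `d_low`, `d_high`
#'   (m^2/s) and the window used.
#' @export
fit_diffusion <- function(curve, fit_window = NULL) {
  span <- attr(curve, "span_ns") %||% (max(curve$lag_ns) * 2)
  if (is.null(fit_window))
    # use the 20-50 ns diffusive regime only when it sits within the first
    # quarter of the span; longer lags average too few independent
    # segments for a reliable line
    fit_window <- if (span >= 200 && max(curve$lag_ns) >= 50) c(20, 50)
                  else c(0.10, 0.25) * span
  sel <- curve$lag_ns >= fit_window[1] & curve$lag_ns <= fit_window[2]
  if (sum(sel) < 3L)
    stop_domain("need at least 3 lags inside the fit window [",
                fit_window[1], ", ", fit_window[2], "] ns (have ",
                sum(sel), ")")
  x <- curve$lag_ns[sel]
  y <- curve$msd[sel]
  s <- curve$sem[sel]
  fit <- stats::lm(y ~ x)
  slope <- unname(stats::coef(fit)[2])           # nm^2/ns
  to_SI <- 1e-9 / 4                              # nm^2/ns -> m^2/s, /4 (2D)
  band <- if (all(is.finite(s))) slope_band(x, y, s) else NULL
  if (is.null(band)) {
    se <- summary(fit)$coefficients[2, 2]
    if (!is.finite(se)) se <- 0
    message("no straight line fits within every SEM band; ",
            "falling back to slope +- fit standard error")
    band <- slope + c(-1, 1) * se
  }
  structure(list(d = slope * to_SI,
                 d_low = max(0, band[1] * to_SI),
                 d_high = band[2] * to_SI,
                 fit_window = fit_window, n_points = sum(sel)),
            class = "diffusion_fit")
}

#' @export
print.diffusion_fit <- function(x, ...) {
  cat(sprintf(
    "Lateral diffusion: D_L = %.3g m^2/s  [%.3g, %.3g]  (fit %g-%g ns, %d lags)\n",
    x$d, x$d_low, x$d_high, x$fit_window[1], x$fit_window[2], x$n_points))
  invisible(x)
}

#' Apply an externally supplied finite-size correction
#'
#' Periodic-boundary hydrodynamics bias lipid diffusion in small boxes;
#' published correction formulas require the membrane and solvent
#' viscosities, which this package does not estimate. The hook simply
#' rescales an estimate by a caller-provided multiplicative factor.
#'
#' @param estimate a [fit_diffusion()] result.
#' @param factor multiplicative correction.
#' @return the rescaled `"diffusion_fit"`.
#' @export
apply_finite_size_correction <- function(estimate, factor) {
  stopifnot(is.numeric(factor), length(factor) == 1L, factor > 0)
  estimate$d <- estimate$d * factor
  estimate$d_low <- estimate$d_low * factor
  estimate$d_high <- estimate$d_high * factor
  estimate
}
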
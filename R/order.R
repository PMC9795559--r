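# C-H bond order parameters.
#
# S_CH = <(3 cos^2 theta - 1)/2>, theta the angle between the carbon ->
# hydrogen vector and the membrane normal (+z). The ensemble value for a
# bond is formed by first time-averaging within each lipid, then taking the
# mean and the standard error of the mean across lipids, so the SEM treats
# lipids (not frames) as the independent units.

# cos(theta) for one bond across all frames; errors name the first frame
# with a degenerate (zero-length) bond vector.
bond_costheta <- function(frames, carbon, hydrogen) {
  v <- frames$coords[hydrogen, , , drop = TRUE] -
       frames$coords[carbon, , , drop = TRUE]
  if (is.null(dim(v))) v <- matrix(v, nrow = 3)  # single frame
  len <- sqrt(colSums(v^2))
  if (any(len < 1e-12))
    stop_domain("zero-length C-H vector at frame ", which(len < 1e-12)[1])
  v[3, ] / len
}

p2 <- function(x) (3 * x^2 - 1) / 2

#' Time-averaged order parameter of one C--H bond in one lipid
#'
#' Averages the second Legendre polynomial of cos(theta) over all frames
#' with equal weight. The paper's trajectories are uniformly spaced (10 ps);
#' uneven spacing is still averaged unweighted, with a warning.
#'
#' @param frames a [frame_series()].
#' @param bond one row of a topology's `ch_bonds` table (or a list with
#'   `carbon` and `hydrogen` atom indices).
#' @param lipid_id if supplied, checked against the bond's atoms.
#' @param topology needed only for the `lipid_id` check.
#' @return signed scalar in `[-0.5, 1]`.
#' @export
sch_per_lipid <- function(frames, bond, lipid_id = NULL, topology = NULL) {
  if (n_frames(frames) < 1L) stop_domain("need at least one frame")
  if (!is.null(lipid_id) && !is.null(topology)) {
    ids <- topology$atoms$lipid_id[c(bond$carbon, bond$hydrogen)]
    if (!all(ids == lipid_id))
      stop_domain("bond atoms do not belong to lipid ", lipid_id)
  }
  dt <- diff(frames$times)
  if (length(dt) > 1 && diff(range(dt)) > 1e-6 * mean(dt))
    warning("unevenly spaced frames averaged unweighted", call. = FALSE)
  mean(p2(bond_costheta(frames, bond$carbon, bond$hydrogen)))
}

#' Combine per-lipid order parameters into an ensemble estimate
#'
#' @param per_lipid_values numeric vector, one time-averaged S per lipid.
#' @param segment_label,stereo_label identity of the bond.
#' @param n_frames number of frames behind each value (bookkeeping).
#' @return one-row `data.frame` of class `"ch_order"` with columns
#'   `segment_label`, `stereo_label`, `s_mean`, `sem`, `n_lipids`,
#'   `n_frames`; `sem` is `NA` for a single lipid.
#' @export
sch_ensemble <- function(per_lipid_values, segment_label,
                         stereo_label = "none", n_frames = NA_integer_) {
  n <- length(per_lipid_values)
  if (n < 1L) stop_domain("no per-lipid values")
  sem <- if (n >= 2L) stats::sd(per_lipid_values) / sqrt(n) else NA_real_
  out <- data.frame(segment_label = segment_label,
                    stereo_label = stereo_label,
                    s_mean = mean(per_lipid_values), sem = sem,
                    n_lipids = n, n_frames = n_frames,
                    stringsAsFactors = FALSE)
  class(out) <- c("ch_order", "data.frame")
  out
}

#' Order parameters for every C--H bond of a topology
#'
#' Computes the signed S_CH for each (segment, stereo) bond class: the
#' per-lipid time average first (equivalent hydrogens, e.g. the choline
#' methyls, are averaged within the lipid), then mean and SEM across
#' lipids. Rows are ordered as conventionally plotted (see
#' [segment_levels()]).
#'
#' @param frames a [frame_series()].
#' @param topology a [bilayer_topology()] with a populated `ch_bonds` table.
#' @param lipids optional subset of lipid ids.
#' @return `data.frame` of class `"ch_order"`, one row per bond class.
#' @export
order_parameters <- function(frames, topology, lipids = NULL) {
  ch <- topology$ch_bonds
  if (!nrow(ch)) stop_domain("topology has no C-H bonds")
  if (!is.null(lipids)) ch <- ch[ch$lipid_id %in% lipids, , drop = FALSE]
  if (!nrow(ch)) stop_domain("no C-H bonds for the requested lipids")
  per_bond <- vapply(seq_len(nrow(ch)), function(i)
    mean(p2(bond_costheta(frames, ch$carbon[i], ch$hydrogen[i]))),
    numeric(1))
  key <- interaction(ch$segment_label, ch$stereo_label, drop = TRUE)
  out <- do.call(rbind, lapply(levels(key), function(k) {
    sel <- key == k
    per_lipid <- tapply(per_bond[sel], ch$lipid_id[sel], mean)
    sch_ensemble(as.numeric(per_lipid), ch$segment_label[sel][1],
                 ch$stereo_label[sel][1], n_frames(frames))
  }))
  seg_rank <- match(out$segment_label, segment_levels())
  out <- out[order(seg_rank, out$stereo_label), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("ch_order", "data.frame")
  out
}

#' @export
print.ch_order <- function(x, digits = 4, ...) {
  cat("C-H bond order parameters (", nrow(x), " bond classes)\n", sep = "")
  print.data.frame(x, digits = digits, row.names = FALSE)
  invisible(x)
}

#' @export
plot.ch_order <- function(x, ...) {
  i <- seq_len(nrow(x))
  graphics::plot(i, x$s_mean, pch = 19, xaxt = "n", xlab = "",
                 ylab = expression(S[CH]), ...)
  graphics::arrows(i, x$s_mean - x$sem, i, x$s_mean + x$sem,
                   angle = 90, code = 3, length = 0.03)
  graphics::axis(1, at = i, labels = paste0(x$segment_label,
                 ifelse(x$stereo_label == "none", "",
                        paste0("(", x$stereo_label, ")"))), las = 2)
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}

#' Distribution of C--H bond tilt angles
#'
#' Histograms theta (the angle between the C->H vector and +z, in degrees)
#' per lipid over all frames and bonds in `bond_set`, normalises each
#' lipid's histogram to unit mass, then averages across lipids; the spread
#' across lipids gives the per-bin SEM.
#'
#' @param frames a [frame_series()].
#' @param bond_set `data.frame` of bonds (rows of a `ch_bonds` table).
#' @param lipid_subset lipid ids to include (non-empty).
#' @param bins number of equal bins over `[0, 180]` degrees.
#' @return `data.frame` of class `"theta_dist"` with `bin_center_deg`,
#'   `probability`, `sem`.
#' @export
theta_distribution <- function(frames, bond_set, lipid_subset, bins = 36L) {
  if (bins < 2L) stop_domain("need at least 2 bins")
  lipid_subset <- unique(lipid_subset)
  if (!length(lipid_subset)) stop_domain("empty lipid subset")
  edges <- seq(0, 180, length.out = bins + 1L)
  probs <- matrix(NA_real_, length(lipid_subset), bins)
  for (j in seq_along(lipid_subset)) {
    rows <- which(bond_set$lipid_id == lipid_subset[j])
    if (!length(rows))
      stop_domain("no bonds for lipid ", lipid_subset[j])
    th <- unlist(lapply(rows, function(i)
      acos(pmin(1, pmax(-1, bond_costheta(frames, bond_set$carbon[i],
                                          bond_set$hydrogen[i])))) *
        180 / pi))
    cnt <- graphics::hist(th, breaks = edges, plot = FALSE)$counts
    probs[j, ] <- cnt / sum(cnt)
  }
  nl <- length(lipid_subset)
  out <- data.frame(
    bin_center_deg = (edges[-1] + edges[-(bins + 1L)]) / 2,
    probability = colMeans(probs),
    sem = if (nl >= 2) apply(probs, 2, stats::sd) / sqrt(nl) else NA_real_)
  class(out) <- c("theta_dist", "data.frame")
  out
}

#' @export
plot.theta_dist <- function(x, ...) {
  graphics::plot(x$bin_center_deg, x$probability, type = "b", pch = 19,
                 xlab = expression(theta ~ "(deg)"),
                 ylab = "probability", ...)
  graphics::arrows(x$bin_center_deg, x$probability - x$sem,
                   x$bin_center_deg, x$probability + x$sem,
                   angle = 90, code = 3, length = 0.02)
  invisible(x)
}

#' Forking between the R and S hydrogens of one carbon
#'
#' Forking is the occurrence of unequal order parameters for the two
#' hydrogens bonded to the same carbon. The magnitude is
#' `|s_mean(R) - s_mean(S)|`; it is flagged significant when it exceeds
#' `k_sigma` times the quadrature-combined SEMs.
#'
#' @param r,s one-row [sch_ensemble()] records sharing `segment_label`,
#'   with stereo labels R and S.
#' @param k_sigma significance threshold in combined-SEM units.
#' @return list with `magnitude` and logical `significant`.
#' @export
detect_forking <- function(r, s, k_sigma = 2) {
  if (r$segment_label != s$segment_label)
    stop_domain("records belong to different segments: ",
                r$segment_label, " vs ", s$segment_label)
  if (!setequal(c(r$stereo_label, s$stereo_label), c("R", "S")))
    stop_domain("forking needs one R and one S record")
  magnitude <- abs(r$s_mean - s$s_mean)
  list(magnitude = magnitude,
       significant = magnitude > k_sigma * sqrt(r$sem^2 + s$sem^2))
}

#' Order-parameter change relative to a salt-free baseline
#'
#' The headgroup alpha and beta order parameters respond to bound charge at
#' the membrane interface (the "molecular electrometer"). The change is
#' measured against a baseline set by the average of the R and S hydrogen
#' order parameters of the salt-free system, so baseline forking does not
#' bias the response; SEMs propagate in quadrature with the 1/2 factors.
#'
#' @param record_at_c [sch_ensemble()] record at salt concentration `c`.
#' @param baseline_r,baseline_s salt-free records for the R and S hydrogens.
#' @param concentration molarity of the record's ensemble (bookkeeping).
#' @return one-row `data.frame` of class `"delta_s"` with `segment_label`,
#'   `concentration`, `delta`, `sem`.
#' @export
delta_sch <- function(record_at_c, baseline_r, baseline_s,
                      concentration = NA_real_) {
  labs <- c(record_at_c$segment_label, baseline_r$segment_label,
            baseline_s$segment_label)
  if (length(unique(labs)) != 1L)
    stop_domain("records belong to different segments: ",
                paste(unique(labs), collapse = ", "))
  out <- data.frame(
    segment_label = record_at_c$segment_label,
    concentration = concentration,
    delta = record_at_c$s_mean -
      (baseline_r$s_mean + baseline_s$s_mean) / 2,
    sem = sqrt(record_at_c$sem^2 + baseline_r$sem^2 / 4 +
                 baseline_s$sem^2 / 4),
    stringsAsFactors = FALSE)
  class(out) <- c("delta_s", "data.frame")
  out
}
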
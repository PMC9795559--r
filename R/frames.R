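#' Frame series constructor
#'
#' Container for a coordinate trajectory: times in picoseconds (strictly
#' increasing), coordinates in nanometres and an orthorhombic box per frame.
#' The membrane normal is the z axis by convention.
#'
#' @param times numeric vector of frame times (ps), strictly increasing.
#' @param coords numeric array `n_atoms x 3 x n_frames` (nm).
#' @param box numeric `n_frames x 3` matrix of box lengths (nm), or a
#'   length-3 vector recycled over frames.
#' @return object of class `"frame_series"`.
#' @export
frame_series <- function(times, coords, box) {
  if (length(dim(coords)) != 3L || dim(coords)[2] != 3L)
    stop_domain("coords must be an n_atoms x 3 x n_frames array")
  nf <- dim(coords)[3]
  if (length(times) != nf) stop_domain("length(times) must equal n_frames")
  if (nf > 1 && any(diff(times) <= 0))
    stop_domain("times must be strictly increasing")
  if (is.null(dim(box))) box <- matrix(box, nrow = nf, ncol = 3, byrow = TRUE)
  box <- as.matrix(box)
  if (nrow(box) != nf || ncol(box) != 3L)
    stop_domain("box must be n_frames x 3")
  if (any(box <= 0)) stop_domain("all box lengths must be positive")
  if (!all(is.finite(coords)) || !all(is.finite(box)) ||
      !all(is.finite(times)))
    stop_domain("non-finite values in frame series")
  structure(list(times = as.numeric(times), coords = coords, box = box),
            class = "frame_series")
}

n_frames <- function(frames) dim(frames$coords)[3]
n_atoms <- function(frames) dim(frames$coords)[1]

#' @export
print.frame_series <- function(x, ...) {
  nf <- n_frames(x)
  cat("Frame series:", n_atoms(x), "atoms x", nf, "frames, t =",
      x$times[1], "..", x$times[nf], "ps\n")
  cat("  box (frame 1):", paste(signif(x$box[1, ], 6), collapse = " x "),
      "nm\n")
  invisible(x)
}

#' Analysis window constructor
#'
#' A labelled `[t_start, t_end]` interval (ps) selecting the part of a
#' trajectory used for analysis, e.g. the steady-state portion after the
#' area per lipid has stabilised.
#'
#' @param t_start,t_end window bounds (ps), `t_start < t_end`.
#' @param label free-text label.
#' @return object of class `"analysis_window"`.
#' @export
analysis_window <- function(t_start, t_end, label = "") {
  if (!(t_start < t_end)) stop_domain("t_start must be < t_end")
  structure(list(t_start = t_start, t_end = t_end, label = label),
            class = "analysis_window")
}

#' Restrict a frame series to an analysis window
#'
#' Keeps frames with `t_start <= t <= t_end` (both endpoints inclusive),
#' preserving order.
#'
#' @param frames a [frame_series()].
#' @param window an [analysis_window()].
#' @return the restricted [frame_series()].
#' @export
restrict_to_window <- function(frames, window) {
  tr <- range(frames$times)
  if (window$t_start < tr[1] - 1e-9 || window$t_end > tr[2] + 1e-9)
    stop_domain("analysis window [", window$t_start, ", ", window$t_end,
                "] ps outside trajectory span [", tr[1], ", ", tr[2], "] ps")
  keep <- frames$times >= window$t_start & frames$times <= window$t_end
  if (!any(keep)) stop_domain("analysis window contains no frames")
  frame_series(frames$times[keep],
               frames$coords[, , keep, drop = FALSE],
               frames$box[keep, , drop = FALSE])
}

#' Select atoms of a topology
#'
#' Resolves an atom selection to indices. Selections may be integer or
#' logical indices, a glob pattern matched against atom names, one of the
#' role keywords `"ions"`, `"water"`, `"lipid"`, or a predicate function on
#' the atom table.
#'
#' @param topology a [bilayer_topology()].
#' @param select the selection.
#' @return integer vector of atom indices.
#' @export
select_atoms <- function(topology, select) {
  atoms <- topology$atoms
  idx <-
    if (is.function(select)) which(select(atoms))
    else if (is.logical(select)) which(select)
    else if (is.numeric(select)) as.integer(select)
    else if (is.character(select) && length(select) == 1L) {
      switch(select,
        ions  = which(atoms$lipid_id < 0 &
                        atoms$element %in% c("Na", "Cl", "K", "Ca", "Mg")),
        water = which(atoms$lipid_id < 0 & atoms$element %in% c("O", "H") &
                        grepl("^(OW|HW|SOL|O$|H[12]$)",
                              toupper(atoms$atom_name))),
        lipid = which(atoms$lipid_id >= 0),
        which(grepl(utils::glob2rx(select), atoms$atom_name)))
    } else stop_domain("unsupported selection")
  if (!length(idx)) stop_domain("empty atom selection")
  if (any(idx < 1 | idx > nrow(atoms)))
    stop_domain("selection index outside the atom table")
  idx
}
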
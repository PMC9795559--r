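# Trajectory and topology I/O.
#
# GRO and TRR are parsed/written natively (no R reader exists for them);
# PDB and DCD go through bio3d. Internal units are nm and ps throughout;
# Angstrom-based formats are converted at this boundary. XTC is not
# supported: its compressed-integer coordinate codec is a full codec in its
# own right and uncompressed TRR covers the same role here.

io_format <- function(path, override = NULL) {
  if (!is.null(override)) return(tolower(override))
  tolower(tools::file_ext(path))
}

# ---- GRO ------------------------------------------------------------------

parse_gro_frames <- function(lines) {
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i])) && i == length(lines)) break
    title <- lines[i]
    nat <- suppressWarnings(as.integer(trimws(lines[i + 1L])))
    if (is.na(nat)) stop_domain("GRO format error: bad atom count line ",
                                i + 1L)
    if (i + 1L + nat + 1L > length(lines))
      stop_domain("GRO format error: truncated frame at line ", i)
    rec <- lines[(i + 2L):(i + 1L + nat)]
    boxline <- as.numeric(strsplit(trimws(lines[i + 2L + nat]),
                                   "[[:space:]]+")[[1]])
    if (length(boxline) >= 9 && any(abs(boxline[4:9]) > 1e-9))
      stop_domain("unsupported geometry: non-orthorhombic box in GRO file")
    tm <- NA_real_
    m <- regmatches(title, regexec("t=\\s*([-0-9.eE+]+)", title))[[1]]
    if (length(m) == 2) tm <- as.numeric(m[2])
    frames[[length(frames) + 1L]] <- list(
      resid = as.integer(substr(rec, 1, 5)),
      resname = trimws(substr(rec, 6, 10)),
      atom_name = trimws(substr(rec, 11, 15)),
      x = as.numeric(substr(rec, 21, 28)),
      y = as.numeric(substr(rec, 29, 36)),
      z = as.numeric(substr(rec, 37, 44)),
      box = boxline[1:3], time = tm)
    i <- i + nat + 3L
    while (i <= length(lines) && !nzchar(trimws(lines[i]))) i <- i + 1L
  }
  if (!length(frames)) stop_domain("GRO format error: no frames found")
  frames
}

read_gro <- function(path) {
  fr <- parse_gro_frames(readLines(path, warn = FALSE))
  nat <- length(fr[[1]]$x)
  nf <- length(fr)
  coords <- array(NA_real_, c(nat, 3L, nf))
  box <- matrix(NA_real_, nf, 3)
  times <- vapply(fr, `[[`, numeric(1), "time")
  if (anyNA(times)) times <- (seq_len(nf) - 1) * 10  # 10 ps save interval
  for (k in seq_len(nf)) {
    if (length(fr[[k]]$x) != nat)
      stop_domain("GRO format error: atom count varies between frames")
    coords[, , k] <- cbind(fr[[k]]$x, fr[[k]]$y, fr[[k]]$z)
    box[k, ] <- fr[[k]]$box
  }
  list(resid = fr[[1]]$resid, resname = fr[[1]]$resname,
       atom_name = fr[[1]]$atom_name,
       frames = frame_series(times, coords, box))
}

write_gro <- function(path, resid, resname, atom_name, frames) {
  nat <- length(atom_name)
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_len(n_frames(frames))) {
    cat(sprintf("bilayr frame t= %.5f\n", frames$times[k]), file = con)
    cat(sprintf("%5d\n", nat), file = con)
    xyz <- frames$coords[, , k]
    cat(sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f\n",
                resid %% 100000L, substr(resname, 1, 5),
                substr(atom_name, 1, 5), seq_len(nat) %% 100000L,
                xyz[, 1], xyz[, 2], xyz[, 3]), sep = "", file = con)
    cat(sprintf("%10.5f%10.5f%10.5f\n", frames$box[k, 1], frames$box[k, 2],
                frames$box[k, 3]), file = con)
  }
  invisible(path)
}

# ---- TRR (plain XDR, single precision) ------------------------------------

read_trr <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rint <- function(n = 1) readBin(con, "integer", n, size = 4, endian = "big")
  coords <- list(); boxes <- list(); times <- numeric()
  repeat {
    magic <- rint()
    if (!length(magic)) break
    if (magic != 1993L) stop_domain("TRR format error: bad magic number")
    slen <- rint(2)
    readBin(con, "raw", 4 * ceiling(slen[2] / 4))
    hdr <- rint(13)  # ir,e,box,vir,pres,top,sym,x,v,f sizes, natoms, step, nre
    box_size <- hdr[3]; x_size <- hdr[8]; v_size <- hdr[9]; f_size <- hdr[10]
    natoms <- hdr[11]
    rsize <- if (box_size %in% c(0L, 36L) &&
                 (x_size == 0L || x_size == 12L * natoms)) 4L else 8L
    rreal <- function(n) readBin(con, "numeric", n, size = rsize,
                                 endian = "big")
    tl <- rreal(2)  # t, lambda
    if (box_size > 0) {
      bm <- matrix(rreal(9), 3, 3, byrow = TRUE)
      if (any(abs(bm[upper.tri(bm) | lower.tri(bm)]) > 1e-7))
        stop_domain("unsupported geometry: non-orthorhombic box in TRR file")
      boxes[[length(boxes) + 1L]] <- diag(bm)
    } else stop_domain("TRR format error: frame without box")
    for (sz in c(hdr[4], hdr[5])) if (sz > 0) rreal(9)  # vir, pres
    if (x_size > 0) {
      xyz <- matrix(rreal(3L * natoms), ncol = 3, byrow = TRUE)
      coords[[length(coords) + 1L]] <- xyz
    } else stop_domain("TRR format error: frame without coordinates")
    if (v_size > 0) rreal(3L * natoms)
    if (f_size > 0) rreal(3L * natoms)
    times <- c(times, tl[1])
  }
  if (!length(coords)) stop_domain("TRR format error: no frames")
  nat <- nrow(coords[[1]])
  arr <- array(NA_real_, c(nat, 3L, length(coords)))
  for (k in seq_along(coords)) arr[, , k] <- coords[[k]]
  frame_series(times, arr, do.call(rbind, boxes))
}

write_trr <- function(path, frames) {
  con <- file(path, "wb")
  on.exit(close(con))
  wint <- function(x) writeBin(as.integer(x), con, size = 4, endian = "big")
  wreal <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "big")
  nat <- n_atoms(frames)
  for (k in seq_len(n_frames(frames))) {
    wint(1993L)
    wint(c(13L, 12L))
    writeBin(charToRaw("GMX_trn_file"), con)
    wint(c(0L, 0L, 36L, 0L, 0L, 0L, 0L, 12L * nat, 0L, 0L, nat, k - 1L, 0L))
    wreal(c(frames$times[k], 0))
    bm <- diag(frames$box[k, ])
    wreal(as.vector(t(bm)))
    wreal(as.vector(t(frames$coords[, , k])))
  }
  invisible(path)
}

# ---- plain-text fixture dialect -------------------------------------------

#' Read / write the plain-text fixture trajectory dialect
#'
#' A dependency-free trajectory format for tests and examples: one header
#' line `n_atoms n_frames`, then per frame one box line `Lx Ly Lz [t_ps]`
#' followed by `n_atoms` whitespace-separated `x y z` records (nm).
#'
#' @param path file path.
#' @param frames a [frame_series()] (for writing).
#' @param digits coordinate precision written.
#' @return `read_frames_txt()` a [frame_series()]; `write_frames_txt()` the
#'   path, invisibly.
#' @export
read_frames_txt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- as.integer(strsplit(trimws(lines[1]), "[[:space:]]+")[[1]])
  nat <- hdr[1]; nf <- hdr[2]
  if (length(lines) < 1 + nf * (nat + 1))
    stop_domain("fixture format error: truncated file")
  coords <- array(NA_real_, c(nat, 3L, nf))
  box <- matrix(NA_real_, nf, 3)
  times <- numeric(nf)
  i <- 2L
  for (k in seq_len(nf)) {
    b <- as.numeric(strsplit(trimws(lines[i]), "[[:space:]]+")[[1]])
    box[k, ] <- b[1:3]
    times[k] <- if (length(b) >= 4) b[4] else (k - 1) * 10
    v <- scan(text = lines[(i + 1L):(i + nat)], quiet = TRUE)
    coords[, , k] <- matrix(v, ncol = 3, byrow = TRUE)
    i <- i + nat + 1L
  }
  frame_series(times, coords, box)
}

#' @rdname read_frames_txt
#' @export
write_frames_txt <- function(frames, path, digits = 6) {
  con <- file(path, "w")
  on.exit(close(con))
  fmt <- paste0("%.", digits, "f")
  cat(n_atoms(frames), n_frames(frames), "\n", file = con)
  for (k in seq_len(n_frames(frames))) {
    cat(sprintf(fmt, frames$box[k, ]), sprintf("%.6f", frames$times[k]),
        "\n", file = con)
    xyz <- frames$coords[, , k]
    writeLines(paste(sprintf(fmt, xyz[, 1]), sprintf(fmt, xyz[, 2]),
                     sprintf(fmt, xyz[, 3])), con)
  }
  invisible(path)
}

# ---- topology construction from file records ------------------------------

topology_from_records <- function(resid, resname, atom_name,
                                  lipid_resnames = "POPC",
                                  bond_table = NULL) {
  is_lip <- resname %in% lipid_resnames
  lipid_id <- rep(-1L, length(atom_name))
  if (any(is_lip)) {
    key <- paste(resid[is_lip], resname[is_lip])
    lipid_id[is_lip] <- match(key, unique(key))
  }
  atoms <- atom_table(lipid_id, atom_name)
  atoms$resid <- resid
  atoms$resname <- resname
  topo <- bilayer_topology(atoms)
  bt <- bond_table %||% tryCatch(read_bond_table(), error = function(e) NULL)
  if (!is.null(bt) && topo$n_lipids > 0) topo <- apply_bond_table(topo, bt)
  topo
}

# ---- user-facing loaders --------------------------------------------------

#' Load a bilayer topology and trajectory from standard MD formats
#'
#' Topology formats: GRO, PDB. Trajectory formats: GRO (multi-frame), TRR,
#' DCD, and the plain-text fixture dialect (`.txt`/`.dat`). When
#' `trajectory_path` is `NULL` the frames come from the topology file
#' itself. Lipid residues are identified by residue name and numbered 1..n;
#' solvent and ion atoms get `lipid_id = -1`. C--H bonds and R/S labels are
#' attached from the bond-definition table.
#'
#' @param topology_path path to GRO or PDB file.
#' @param trajectory_path optional trajectory file.
#' @param topology_format,trajectory_format override extension detection.
#' @param lipid_resnames residue names treated as lipids.
#' @param bond_table bond-definition table (see [read_bond_table()]);
#'   bundled POPC table by default.
#' @param dt frame spacing (ps) assumed for formats that store no times.
#' @return list with elements `topology` ([bilayer_topology()]) and
#'   `frames` ([frame_series()]).
#' @export
load_trajectory <- function(topology_path, trajectory_path = NULL,
                            topology_format = NULL, trajectory_format = NULL,
                            lipid_resnames = "POPC", bond_table = NULL,
                            dt = 10) {
  if (!file.exists(topology_path))
    stop_domain("topology file not found: ", topology_path)
  tf <- io_format(topology_path, topology_format)
  if (tf == "gro") {
    g <- read_gro(topology_path)
    topo <- topology_from_records(g$resid, g$resname, g$atom_name,
                                  lipid_resnames, bond_table)
    frames <- g$frames
  } else if (tf == "pdb") {
    pdb <- bio3d::read.pdb(topology_path, verbose = FALSE)
    nat <- nrow(pdb$atom)
    topo <- topology_from_records(pdb$atom$resno, pdb$atom$resid,
                                  pdb$atom$elety, lipid_resnames, bond_table)
    xyz <- matrix(pdb$xyz[1, ], ncol = 3, byrow = TRUE) / 10
    if (is.null(pdb$cryst1) || is.null(pdb$cryst1$abc))
      stop_domain("PDB format error: missing CRYST1 box record")
    if (!is.null(pdb$cryst1$angles) &&
        any(abs(pdb$cryst1$angles - 90) > 1e-3))
      stop_domain("unsupported geometry: non-orthorhombic PDB box")
    frames <- frame_series(0, array(xyz, c(nat, 3, 1)), pdb$cryst1$abc / 10)
  } else stop_domain("unsupported topology format: ", tf)

  if (!is.null(trajectory_path)) {
    if (!file.exists(trajectory_path))
      stop_domain("trajectory file not found: ", trajectory_path)
    rf <- io_format(trajectory_path, trajectory_format)
    frames <- switch(rf,
      gro = read_gro(trajectory_path)$frames,
      trr = read_trr(trajectory_path),
      dcd = read_dcd_frames(trajectory_path, dt),
      txt = , dat = read_frames_txt(trajectory_path),
      xtc = stop_domain("XTC is not supported; convert to TRR, DCD or GRO"),
      stop_domain("unsupported trajectory format: ", rf))
  }
  if (n_atoms(frames) != nrow(topo$atoms))
    stop_domain("format error: topology has ", nrow(topo$atoms),
                " atoms but trajectory frames have ", n_atoms(frames))
  list(topology = topo, frames = frames)
}

read_dcd_frames <- function(path, dt = 10) {
  xyz <- bio3d::read.dcd(path, verbose = FALSE)
  cell <- tryCatch(bio3d::read.dcd(path, cell = TRUE, verbose = FALSE),
                   error = function(e) NULL)
  nf <- nrow(xyz)
  nat <- ncol(xyz) / 3
  coords <- array(NA_real_, c(nat, 3L, nf))
  for (k in seq_len(nf))
    coords[, , k] <- matrix(xyz[k, ], ncol = 3, byrow = TRUE) / 10
  if (is.null(cell))
    stop_domain("DCD format error: no unit-cell information")
  ang <- cell[, 4:6, drop = FALSE]
  if (any(abs(ang - 90) > 1e-3))
    stop_domain("unsupported geometry: non-orthorhombic DCD cell")
  frame_series((seq_len(nf) - 1) * dt, coords,
               cell[, 1:3, drop = FALSE] / 10)
}

#' Write frames to a standard trajectory format
#'
#' Supports multi-frame GRO, TRR and the plain-text fixture dialect; the
#' format follows the file extension. Writing is lossless up to the format
#' precision (GRO: 3 decimals in nm).
#'
#' @param topology a [bilayer_topology()] (atom naming for GRO records).
#' @param frames a [frame_series()] with at least one frame.
#' @param path output path, extension one of `.gro`, `.trr`, `.txt`/`.dat`.
#' @param format override extension detection.
#' @return the path, invisibly.
#' @export
write_frames <- function(topology, frames, path, format = NULL) {
  if (!inherits(frames, "frame_series") || n_frames(frames) < 1L)
    stop_domain("no frames to write")
  if (nrow(topology$atoms) != n_atoms(frames))
    stop_domain("format error: topology/frames atom counts differ")
  fmt <- io_format(path, format)
  if (fmt == "gro") {
    atoms <- topology$atoms
    resname <- atoms$resname %||%
      ifelse(atoms$lipid_id >= 0, "POPC",
             ifelse(atoms$element %in% c("O", "H"), "SOL",
                    toupper(atoms$element)))
    resid <- atoms$resid %||% {
      r <- atoms$lipid_id
      r[r < 0] <- max(c(0L, r)) + seq_len(sum(r < 0))  # one residue per ion
      r
    }
    write_gro(path, as.integer(resid), resname, atoms$atom_name, frames)
  } else if (fmt == "trr") {
    write_trr(path, frames)
  } else if (fmt %in% c("txt", "dat")) {
    write_frames_txt(frames, path)
  } else stop_domain("unsupported output format: ", fmt)
  invisible(path)
}
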
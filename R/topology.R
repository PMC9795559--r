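#' Controlled vocabulary of POPC carbon segments
#'
#' Segment labels for the carbons carrying the analysed C--H bonds, ordered
#' as conventionally plotted: choline gamma, beta, alpha, glycerol g3, g2,
#' g1, then the sn-1 (palmitoyl, C2..C16) and sn-2 (oleoyl, C2..C18) chains
#' by carbon number.
#'
#' @return Character vector of valid `segment_label` values.
#' @export
segment_levels <- function() {
  c("\u03b3", "\u03b2", "\u03b1", "g3", "g2", "g1",
    paste0("sn1-C", 2:16), paste0("sn2-C", 2:18))
}

# Element lookup: electrons (atomic number) and standard atomic mass (u).
element_table <- function() {
  data.frame(
    element   = c("H", "C", "N", "O", "P", "S", "Na", "Cl", "K", "Ca", "Mg"),
    electrons = c(1L, 6L, 7L, 8L, 15L, 16L, 11L, 17L, 19L, 20L, 12L),
    mass      = c(1.008, 12.011, 14.007, 15.999, 30.974, 32.06,
                  22.990, 35.45, 39.098, 40.078, 24.305),
    stringsAsFactors = FALSE
  )
}

# Infer a chemical element from an MD atom name ("H13A" -> "H", "CLA" -> "Cl").
guess_element <- function(atom_name) {
  up <- toupper(gsub("[^A-Za-z].*$", "", sub("^[0-9]+", "", atom_name)))
  two <- substr(up, 1, 2)
  ifelse(two %in% c("NA", "SO"), "Na",
  ifelse(two %in% c("CL", "CLA"), "Cl",
  ifelse(two == "CA" & nchar(up) >= 3, "Ca",   # CAL-style ion names
  ifelse(two == "MG", "Mg",
  ifelse(two == "PO" & up == "POT", "K",
         substr(up, 1, 1))))))
}

#' Atom table constructor
#'
#' Builds the per-atom record table used throughout the package. Solvent and
#' ion atoms carry `lipid_id = -1`; stereo labels (`"R"`/`"S"`) may only be
#' attached to hydrogens, everything else is `"none"`.
#'
#' @param lipid_id integer lipid index per atom (`-1` for solvent/ions).
#' @param atom_name atom names (POPC naming for lipid atoms).
#' @param element chemical symbols; inferred from `atom_name` when `NULL`.
#' @param mass atomic masses (u); from the element table when `NULL`.
#' @param electrons integer electron counts; atomic number when `NULL`.
#' @param stereo_label `"R"`, `"S"` or `"none"` per atom.
#' @return `data.frame` with columns `lipid_id`, `atom_name`, `element`,
#'   `mass`, `electrons`, `stereo_label`.
#' @export
atom_table <- function(lipid_id, atom_name, element = NULL, mass = NULL,
                       electrons = NULL, stereo_label = NULL) {
  n <- length(atom_name)
  if (is.null(element)) element <- guess_element(atom_name)
  et <- element_table()
  idx <- match(element, et$element)
  if (anyNA(idx) && (is.null(mass) || is.null(electrons)))
    stop_domain("unknown element(s): ",
                paste(unique(element[is.na(idx)]), collapse = ", "))
  if (is.null(mass)) mass <- et$mass[idx]
  if (is.null(electrons)) electrons <- et$electrons[idx]
  if (is.null(stereo_label)) stereo_label <- rep("none", n)
  atoms <- data.frame(
    lipid_id = as.integer(lipid_id), atom_name = as.character(atom_name),
    element = element, mass = as.numeric(mass),
    electrons = as.integer(electrons), stereo_label = stereo_label,
    stringsAsFactors = FALSE
  )
  validate_atoms(atoms)
  atoms
}

validate_atoms <- function(atoms) {
  stopifnot(all(c("lipid_id", "atom_name", "element", "mass", "electrons",
                  "stereo_label") %in% names(atoms)))
  if (any(atoms$mass <= 0)) stop_domain("atom masses must be positive")
  if (any(atoms$electrons < 1)) stop_domain("electron counts must be >= 1")
  bad <- atoms$stereo_label != "none" & atoms$element != "H"
  if (any(bad))
    stop_domain("stereo labels are only defined for hydrogens (atoms ",
                paste(which(bad), collapse = ", "), ")")
  invisible(atoms)
}

#' Bilayer topology constructor
#'
#' Bundles the atom table with the C--H bond list, the leaflet map and the
#' lipid count. R/S stereo identities are fixed properties of the bonding
#' graph and live here; they are never re-derived from coordinates.
#'
#' @param atoms atom table (see [atom_table()]).
#' @param ch_bonds `data.frame` with columns `carbon`, `hydrogen` (1-based
#'   atom indices), `segment_label` (one of [segment_levels()]),
#'   `stereo_label` (`"R"`, `"S"`, `"none"`).
#' @param leaflet named character vector mapping lipid id to `"upper"` or
#'   `"lower"`; may be `NULL` before [assign_leaflets()] has run.
#' @param n_lipids number of lipids; counted from `atoms` when `NULL`.
#' @return object of class `"bilayer_topology"`.
#' @export
bilayer_topology <- function(atoms, ch_bonds = NULL, leaflet = NULL,
                             n_lipids = NULL) {
  validate_atoms(atoms)
  if (is.null(ch_bonds))
    ch_bonds <- data.frame(carbon = integer(), hydrogen = integer(),
                           segment_label = character(),
                           stereo_label = character(),
                           stringsAsFactors = FALSE)
  stopifnot(all(c("carbon", "hydrogen", "segment_label", "stereo_label")
                %in% names(ch_bonds)))
  if (anyDuplicated(ch_bonds$hydrogen))
    stop_domain("a hydrogen may appear in at most one C-H bond")
  bad <- !(ch_bonds$segment_label %in% segment_levels())
  if (any(bad))
    stop_domain("segment_label(s) outside the controlled vocabulary: ",
                paste(unique(ch_bonds$segment_label[bad]), collapse = ", "))
  if (nrow(ch_bonds)) {
    rng <- range(c(ch_bonds$carbon, ch_bonds$hydrogen))
    if (rng[1] < 1 || rng[2] > nrow(atoms))
      stop_domain("ch_bonds index outside the atom table")
    ch_bonds$lipid_id <- atoms$lipid_id[ch_bonds$carbon]
  } else ch_bonds$lipid_id <- integer()
  lipid_ids <- sort(unique(atoms$lipid_id[atoms$lipid_id >= 0]))
  if (is.null(n_lipids)) n_lipids <- length(lipid_ids)
  if (!is.null(leaflet)) {
    miss <- setdiff(unique(ch_bonds$lipid_id), as.integer(names(leaflet)))
    if (length(miss))
      stop_domain("lipids in ch_bonds without leaflet assignment: ",
                  paste(miss, collapse = ", "))
    stopifnot(all(leaflet %in% c("upper", "lower")))
  }
  structure(list(atoms = atoms, ch_bonds = ch_bonds, leaflet = leaflet,
                 n_lipids = n_lipids),
            class = "bilayer_topology")
}

#' @export
print.bilayer_topology <- function(x, ...) {
  cat("Bilayer topology:", nrow(x$atoms), "atoms,", x$n_lipids, "lipids,",
      nrow(x$ch_bonds), "C-H bonds\n")
  if (!is.null(x$leaflet))
    cat("  leaflets:", sum(x$leaflet == "upper"), "upper /",
        sum(x$leaflet == "lower"), "lower\n")
  invisible(x)
}

#' Read a C--H bond-definition table
#'
#' The table maps segment labels to (carbon, hydrogen) atom-name pairs and
#' the fixed R/S identity of each hydrogen; a POPC table following CHARMM36
#' atom naming ships with the package.
#'
#' @param path TSV with columns `segment_label`, `carbon_name`,
#'   `hydrogen_name`, `stereo_label`; the bundled POPC table when `NULL`.
#' @return `data.frame` of bond definitions.
#' @export
read_bond_table <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "popc_ch_bonds.tsv", package = "bilayr")
  bt <- utils::read.delim(path, stringsAsFactors = FALSE,
                          fileEncoding = "UTF-8")
  need <- c("segment_label", "carbon_name", "hydrogen_name", "stereo_label")
  if (!all(need %in% names(bt)))
    stop_domain("bond table must have columns ", paste(need, collapse = ", "))
  bad <- !(bt$segment_label %in% segment_levels())
  if (any(bad))
    stop_domain("bond table segment_label(s) outside vocabulary: ",
                paste(unique(bt$segment_label[bad]), collapse = ", "))
  bt
}

# Attach ch_bonds to a topology by matching the bond table's atom-name pairs
# within each lipid.
apply_bond_table <- function(topology, bond_table) {
  atoms <- topology$atoms
  rows <- list()
  for (lip in sort(unique(atoms$lipid_id[atoms$lipid_id >= 0]))) {
    idx <- which(atoms$lipid_id == lip)
    loc <- match(bond_table$carbon_name, atoms$atom_name[idx])
    hoc <- match(bond_table$hydrogen_name, atoms$atom_name[idx])
    keep <- !is.na(loc) & !is.na(hoc)
    if (!any(keep)) next
    rows[[length(rows) + 1L]] <- data.frame(
      carbon = idx[loc[keep]], hydrogen = idx[hoc[keep]],
      segment_label = bond_table$segment_label[keep],
      stereo_label = bond_table$stereo_label[keep],
      stringsAsFactors = FALSE)
    atoms$stereo_label[idx[hoc[keep]]] <- bond_table$stereo_label[keep]
  }
  ch <- if (length(rows)) do.call(rbind, rows) else NULL
  bilayer_topology(atoms, ch, topology$leaflet, topology$n_lipids)
}

#' Assign lipids to leaflets
#'
#' Splits lipids into upper and lower leaflets by the z position of an
#' anchor atom (phosphorus by default) relative to the bilayer midplane,
#' taken as the mean anchor z in one reference frame. Invariant under a
#' global z translation, since the midplane shifts with the anchors.
#'
#' @param topology a [bilayer_topology()].
#' @param frames a [frame_series()].
#' @param reference_frame frame index used for the assignment.
#' @param anchor atom name of the per-lipid anchor.
#' @return the topology with its `leaflet` map filled in.
#' @export
assign_leaflets <- function(topology, frames, reference_frame = 1L,
                            anchor = "P") {
  atoms <- topology$atoms
  lips <- sort(unique(atoms$lipid_id[atoms$lipid_id >= 0]))
  anchor_idx <- vapply(lips, function(l) {
    i <- which(atoms$lipid_id == l & atoms$atom_name == anchor)
    if (!length(i))
      stop_domain("lipid ", l, " has no anchor atom '", anchor, "'")
    i[1]
  }, integer(1))
  z <- frames$coords[anchor_idx, 3, reference_frame]
  if (diff(range(z)) < 1e-9)
    stop_domain("degenerate bilayer: all anchor atoms at identical z")
  mid <- mean(z)
  leaflet <- ifelse(z > mid, "upper", "lower")
  names(leaflet) <- lips
  topology$leaflet <- leaflet
  topology
}

#' Salt concentration from particle counts
#'
#' Molar salt concentration of a simulation box from the cation and water
#' counts, taking the molarity of water as 55.5 M:
#' `[salt] = n_cations * 55.5 / n_waters`.
#'
#' @param n_cations number of cations.
#' @param n_waters number of water molecules (> 0).
#' @return concentration in mol/L.
#' @examples
#' salt_concentration(16, 8880)  # 0.1 M
#' @export
salt_concentration <- function(n_cations, n_waters) {
  if (any(n_waters <= 0)) stop_domain("n_waters must be positive")
  if (any(n_cations < 0)) stop_domain("n_cations must be non-negative")
  n_cations * 55.5 / n_waters
}

#' Water-per-lipid ratio
#'
#' Hydration level of a bilayer system expressed as water molecules per
#' lipid. Full hydration for POPC corresponds to roughly 40+ waters per
#' lipid. Returns the exact ratio; rounding is left to the caller.
#'
#' @param n_waters number of water molecules.
#' @param n_lipids number of lipids (> 0).
#' @return waters per lipid.
#' @examples
#' water_per_lipid(4000, 200)  # 20
#' @export
water_per_lipid <- function(n_waters, n_lipids) {
  if (any(n_lipids <= 0)) stop_domain("n_lipids must be positive")
  n_waters / n_lipids
}
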
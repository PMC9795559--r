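# Shared builders for tiny in-code fixtures.

# One lipid, one C-H bond whose tilt angle is prescribed per frame.
frames_from_angles <- function(theta_deg, phi_deg = 0, box = c(5, 5, 5)) {
  nf <- length(theta_deg)
  th <- theta_deg * pi / 180
  ph <- rep(phi_deg, length.out = nf) * pi / 180
  coords <- array(0, c(2, 3, nf))
  coords[1, , ] <- c(2.5, 2.5, 2.5)
  coords[2, 1, ] <- 2.5 + 0.109 * sin(th) * cos(ph)
  coords[2, 2, ] <- 2.5 + 0.109 * sin(th) * sin(ph)
  coords[2, 3, ] <- 2.5 + 0.109 * cos(th)
  frame_series((seq_len(nf) - 1) * 10, coords, box)
}

one_bond_topology <- function(segment = "\u03b1", stereo = "R") {
  atoms <- atom_table(lipid_id = c(1L, 1L), atom_name = c("C11", "H11A"),
                      element = c("C", "H"),
                      stereo_label = c("none", stereo))
  bilayer_topology(atoms,
                   data.frame(carbon = 1L, hydrogen = 2L,
                              segment_label = segment, stereo_label = stereo,
                              stringsAsFactors = FALSE),
                   leaflet = c(`1` = "upper"))
}

# Uniform particles in a box, fixed over frames unless resampled per frame.
uniform_slab <- function(n_particles, box, n_frames, seed) {
  model <- layering_model(NULL, bulk_fraction = 1,
                          n_particles = n_particles)
  gen_ion_slab(model, box, n_frames, seed)
}

expect_close <- function(x, y, tol) expect_lt(max(abs(x - y)), tol)
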
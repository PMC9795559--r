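# Configuration and orchestration: flat YAML configs, stage dispatch,
# TSV outputs with a config-hash comment header, and a run manifest from
# which any run can be replayed.

pipeline_commands <- function() {
  c("synth", "orderparams", "thetadist", "deltas", "density", "formfactor",
    "apl", "msd")
}

config_keys <- function() {
  c("command", "topology", "trajectory", "baseline_topology",
    "baseline_trajectory", "out_dir", "seed", "t_start", "t_end",
    "window_length", "bond_table", "lipid_resnames", "dt",
    "segment", "lipids", "bins", "k_sigma", "concentration_mM",
    "select", "bin_width", "anchor", "salt_molarity",
    "q_max", "dq", "symmetrize", "bulk_density",
    "n_leaflet", "n_subgroups", "fit_window_lo", "fit_window_hi",
    "remove_system_com", "tolerance_sd",
    "generator", "theta0", "n_lipids", "n_frames", "n_particles",
    "d_true", "drift_x", "drift_y", "box_x", "box_y", "box_z",
    "peaks", "bulk_fraction", "stereo_labels", "output_format")
}

config_defaults <- function() {
  list(out_dir = ".", dt = 10, bins = 36L, k_sigma = 2, bin_width = 0.1,
       anchor = "P", q_max = 1, dq = 0.001, symmetrize = FALSE,
       n_leaflet = 100L, n_subgroups = 5L, remove_system_com = TRUE,
       tolerance_sd = 1, lipid_resnames = "POPC", lipids = 5L,
       select = "ions", n_lipids = 200L, n_frames = 100L,
       n_particles = 1000L, d_true = 5e-12, theta0 = 60,
       drift_x = 0, drift_y = 0, box_x = 8, box_y = 8, box_z = 8,
       bulk_fraction = 0, stereo_labels = "R,S", output_format = "gro")
}

#' Parse and validate a pipeline configuration
#'
#' Reads a flat key-value YAML file (or takes a named list), applies
#' explicit overrides (overrides win over file values; both are logged),
#' fills documented defaults and validates: the command must be known,
#' unknown keys are rejected with the list of valid keys, referenced paths
#' must exist, an analysis window must lie within the trajectory span, and
#' `synth` requires a seed.
#'
#' @param config path to a YAML file or a named list.
#' @param overrides named list of values overriding the file.
#' @param quiet suppress the parameter echo.
#' @return validated list of class `"run_config"`.
#' @export
parse_config <- function(config, overrides = list(), quiet = FALSE) {
  cfg <- if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop_domain("config file not found: ", config)
    yaml::read_yaml(config)
  } else if (is.list(config)) config
  else stop_domain("config must be a file path or a named list")
  for (k in names(overrides)) {
    if (!quiet && !is.null(cfg[[k]]))
      message("override: ", k, " = ", overrides[[k]],
              " (file value ", cfg[[k]], ")")
    cfg[[k]] <- overrides[[k]]
  }
  unknown <- setdiff(names(cfg), config_keys())
  if (length(unknown))
    stop_domain("unknown config key(s): ", paste(unknown, collapse = ", "),
                "\nvalid keys: ", paste(config_keys(), collapse = ", "))
  if (is.null(cfg$command))
    stop_domain("missing required key: command")
  if (!cfg$command %in% pipeline_commands())
    stop_domain("unknown command '", cfg$command, "'; valid commands: ",
                paste(pipeline_commands(), collapse = ", "))
  defs <- config_defaults()
  for (k in names(defs)) if (is.null(cfg[[k]])) cfg[[k]] <- defs[[k]]
  if (cfg$command == "synth" && is.null(cfg$seed))
    stop_domain("missing required key: seed (mandatory for synth)")
  if (cfg$command != "synth" && is.null(cfg$topology))
    stop_domain("missing required key: topology")
  for (k in c("topology", "trajectory", "baseline_topology",
              "baseline_trajectory", "bond_table"))
    if (!is.null(cfg[[k]]) && !file.exists(cfg[[k]]))
      stop_domain("path for '", k, "' does not exist: ", cfg[[k]])
  if (!is.null(cfg$topology) &&
      (!is.null(cfg$t_start) || !is.null(cfg$t_end))) {
    inp <- load_trajectory(cfg$topology, cfg$trajectory,
                           lipid_resnames = cfg$lipid_resnames, dt = cfg$dt)
    tr <- range(inp$frames$times)
    if ((cfg$t_start %||% tr[1]) < tr[1] - 1e-9 ||
        (cfg$t_end %||% tr[2]) > tr[2] + 1e-9)
      stop_domain("t_anal window [", cfg$t_start %||% tr[1], ", ",
                  cfg$t_end %||% tr[2], "] ps outside trajectory span [",
                  tr[1], ", ", tr[2], "] ps")
  }
  if (!quiet)
    for (k in sort(names(cfg)))
      message("config: ", k, " = ", paste(cfg[[k]], collapse = ","))
  class(cfg) <- "run_config"
  cfg
}

config_hash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  u <- unclass(cfg)
  u$out_dir <- NULL  # where outputs land is not part of the run identity
  yaml::write_yaml(u[order(names(u))], tmp)
  unname(tools::md5sum(tmp))
}

write_stage_tsv <- function(df, path, hash) {
  con <- file(path, "w")
  on.exit(close(con))
  cat("# bilayr ", as.character(utils::packageVersion("bilayr")),
      "  config_hash: ", hash, "\n", sep = "", file = con)
  utils::write.table(format(df, digits = 10, trim = TRUE, scientific = NA),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

load_config_input <- function(cfg, topology = cfg$topology,
                              trajectory = cfg$trajectory) {
  bt <- if (!is.null(cfg$bond_table)) read_bond_table(cfg$bond_table)
        else NULL
  inp <- load_trajectory(topology, trajectory,
                         lipid_resnames = cfg$lipid_resnames,
                         bond_table = bt, dt = cfg$dt)
  tr <- range(inp$frames$times)
  if (!is.null(cfg$t_start) || !is.null(cfg$t_end)) {
    win <- analysis_window(cfg$t_start %||% tr[1], cfg$t_end %||% tr[2],
                           "t_anal")
    inp$frames <- restrict_to_window(inp$frames, win)
  }
  inp
}

cfg_box <- function(cfg) c(cfg$box_x, cfg$box_y, cfg$box_z)

run_synth <- function(cfg, hash) {
  gen <- cfg$generator %||% "cone"
  box <- cfg_box(cfg)
  out <- file.path(cfg$out_dir, paste0("fixture.", cfg$output_format))
  truth_path <- file.path(cfg$out_dir, "truth.tsv")
  if (gen %in% c("cone", "fixed", "isotropic")) {
    model <- if (gen == "isotropic") orientation_model("isotropic")
             else orientation_model(gen, theta0 = cfg$theta0)
    sl <- strsplit(cfg$stereo_labels, ",")[[1]]
    sim <- gen_orientation_ensemble(model, cfg$n_lipids, cfg$n_frames,
                                    cfg$seed, stereo_labels = sl,
                                    dt = cfg$dt, box = box)
    truth <- data.frame(quantity = "expected_s", value = sim$truth)
  } else if (gen == "brownian") {
    sim <- gen_brownian_bilayer(cfg$d_true, cfg$n_lipids, cfg$n_frames,
                                cfg$dt, box, c(cfg$drift_x, cfg$drift_y),
                                cfg$seed)
    truth <- data.frame(quantity = "d_true_m2s", value = sim$truth)
  } else if (gen == "slab") {
    pk <- if (!is.null(cfg$peaks))
      lapply(strsplit(strsplit(cfg$peaks, ";")[[1]], ","), as.numeric)
    else NULL
    model <- layering_model(pk, cfg$bulk_fraction, cfg$n_particles)
    sim <- gen_ion_slab(model, box, cfg$n_frames, cfg$seed, dt = cfg$dt)
    z <- seq(-box[3] / 2, box[3] / 2, length.out = 101)
    truth <- data.frame(quantity = "density_nm3", z_nm = z,
                        value = sim$truth(z))
  } else if (gen == "popc") {
    sim <- gen_popc_like(cfg$n_lipids, cfg$n_frames, cfg$seed, box,
                         dt = cfg$dt)
    truth <- data.frame(quantity = "n_lipids", value = cfg$n_lipids)
  } else stop_domain("unknown generator '", gen, "'")
  write_frames(sim$topology, sim$frames, out)
  write_stage_tsv(truth, truth_path, hash)
  c(out, truth_path)
}

run_orderparams <- function(cfg, hash) {
  inp <- load_config_input(cfg)
  ops <- order_parameters(inp$frames, inp$topology)
  write_stage_tsv(as.data.frame(ops),
                  file.path(cfg$out_dir, "orderparams.tsv"), hash)
}

run_thetadist <- function(cfg, hash) {
  inp <- load_config_input(cfg)
  seg <- cfg$segment %||% "\u03b1"
  bonds <- inp$topology$ch_bonds
  bonds <- bonds[bonds$segment_label == seg, , drop = FALSE]
  if (!nrow(bonds)) stop_domain("no bonds for segment ", seg)
  lip <- utils::head(sort(unique(bonds$lipid_id)), cfg$lipids)
  td <- theta_distribution(inp$frames, bonds, lip, cfg$bins)
  write_stage_tsv(as.data.frame(td),
                  file.path(cfg$out_dir, "thetadist.tsv"), hash)
}

run_deltas <- function(cfg, hash) {
  if (is.null(cfg$baseline_topology))
    stop_domain("missing required key: baseline_topology")
  inp <- load_config_input(cfg)
  base <- load_config_input(cfg, cfg$baseline_topology,
                            cfg$baseline_trajectory)
  ops <- order_parameters(inp$frames, inp$topology)
  ops0 <- order_parameters(base$frames, base$topology)
  segs <- intersect(unique(ops$segment_label), unique(ops0$segment_label))
  rows <- list()
  for (sg in segs) {
    r0 <- ops0[ops0$segment_label == sg & ops0$stereo_label == "R", ]
    s0 <- ops0[ops0$segment_label == sg & ops0$stereo_label == "S", ]
    if (!nrow(r0) || !nrow(s0)) next
    for (i in which(ops$segment_label == sg)) {
      d <- delta_sch(ops[i, ], r0, s0,
                     concentration = (cfg$concentration_mM %||% NA) / 1000)
      d$stereo_label <- ops$stereo_label[i]
      rows[[length(rows) + 1L]] <- d
    }
  }
  if (!length(rows))
    stop_domain("no segments with R and S baseline records")
  out <- do.call(rbind, rows)
  out$concentration_mM <- out$concentration * 1000
  out <- out[, c("segment_label", "stereo_label", "concentration_mM",
                 "delta", "sem")]
  write_stage_tsv(out, file.path(cfg$out_dir, "deltas.tsv"), hash)
}

run_density <- function(cfg, hash) {
  inp <- load_config_input(cfg)
  anchor <- if (identical(cfg$anchor, "none")) NULL else cfg$anchor
  prof <- number_density(inp$frames, inp$topology, cfg$select,
                         cfg$bin_width, anchor)
  if (!is.null(cfg$salt_molarity))
    prof <- normalize_by_concentration(prof, cfg$salt_molarity)
  write_stage_tsv(data.frame(z_nm = prof$bin_centers,
                             density = prof$density,
                             species = prof$species),
                  file.path(cfg$out_dir, "density.tsv"), hash)
}

run_formfactor <- function(cfg, hash) {
  inp <- load_config_input(cfg)
  anchor <- if (identical(cfg$anchor, "none")) NULL else cfg$anchor
  ed <- electron_density(inp$frames, inp$topology, cfg$bin_width, anchor)
  ff <- form_factor(ed, cfg$bulk_density, cfg$q_max, cfg$dq,
                    isTRUE(cfg$symmetrize))
  write_stage_tsv(data.frame(q_invA = ff$q_grid,
                             F_normalized = ff$magnitude),
                  file.path(cfg$out_dir, "formfactor.tsv"), hash)
}

run_apl <- function(cfg, hash) {
  inp <- load_config_input(cfg)
  ap <- area_per_lipid(inp$frames, cfg$n_leaflet)
  write_stage_tsv(data.frame(time_ps = ap$times, a_l_nm2 = ap$a_l),
                  file.path(cfg$out_dir, "apl.tsv"), hash)
}

run_msd <- function(cfg, hash) {
  inp <- load_config_input(cfg)
  paths <- com_trajectories(inp$frames, inp$topology,
                            isTRUE(cfg$remove_system_com))
  curve <- lateral_msd(paths, n_subgroups = cfg$n_subgroups)
  fw <- if (!is.null(cfg$fit_window_lo))
    c(cfg$fit_window_lo, cfg$fit_window_hi) else NULL
  est <- if (all(curve$msd == 0)) {
    list(d = 0, d_low = 0, d_high = 0,
         fit_window = fw %||% c(NA, NA))  # frozen system
  } else fit_diffusion(curve, fw)
  p1 <- write_stage_tsv(as.data.frame(curve),
                        file.path(cfg$out_dir, "msd.tsv"), hash)
  p2 <- write_stage_tsv(
    data.frame(d_m2s = est$d, d_low_m2s = est$d_low,
               d_high_m2s = est$d_high,
               fit_lo_ns = est$fit_window[1], fit_hi_ns = est$fit_window[2]),
    file.path(cfg$out_dir, "diffusion.tsv"), hash)
  c(p1, p2)
}

#' Run a configured pipeline stage
#'
#' Dispatches on `config$command`, writes the stage's TSV outputs into
#' `config$out_dir` (created if needed) with a comment header carrying the
#' config hash, and records a `run_manifest.yaml` with the package version,
#' config hash, seed and full resolved configuration — enough to replay
#' the run byte for byte.
#'
#' @param config a [parse_config()] result (or anything it accepts).
#' @return character vector of output paths, invisibly.
#' @export
run_pipeline <- function(config) {
  cfg <- if (inherits(config, "run_config")) config
         else parse_config(config, quiet = TRUE)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(cfg)
  runner <- switch(cfg$command,
    synth = run_synth, orderparams = run_orderparams,
    thetadist = run_thetadist, deltas = run_deltas,
    density = run_density, formfactor = run_formfactor,
    apl = run_apl, msd = run_msd)
  outputs <- tryCatch(runner(cfg, hash), error = function(e)
    stop_domain("stage '", cfg$command, "' failed: ", conditionMessage(e)))
  u <- unclass(cfg)
  yaml::write_yaml(
    list(package = "bilayr",
         version = as.character(utils::packageVersion("bilayr")),
         config_hash = hash, seed = cfg$seed,
         config = u[order(names(u))]),
    file.path(cfg$out_dir, "run_manifest.yaml"))
  invisible(c(outputs, file.path(cfg$out_dir, "run_manifest.yaml")))
}

#' Replay a run from its manifest
#'
#' @param manifest_path path to a `run_manifest.yaml`.
#' @param out_dir optional new output directory.
#' @return output paths, invisibly.
#' @export
replay_manifest <- function(manifest_path, out_dir = NULL) {
  man <- yaml::read_yaml(manifest_path)
  cfg <- man$config
  if (!is.null(out_dir)) cfg$out_dir <- out_dir
  run_pipeline(parse_config(cfg, quiet = TRUE))
}
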
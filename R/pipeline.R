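#' @title Config-driven analysis pipeline
#' @description Each `run_*` entry point takes a run configuration (a YAML
#'   file path or an equivalent named list), executes one analysis stage,
#'   and writes machine-readable outputs (CSV + JSON) plus a plain-text log
#'   into `out_dir`. Outputs are byte-stable for identical inputs;
#'   timestamps appear only in logs.
#'
#' Config keys: `topology` (PDB path), `trajectory` (path), optional
#' `dialect` and `stride_ns`, `domains` (path to a YAML domain config, or an
#' inline mapping name -> list of `"start-end"` strings), plus per-analysis
#' parameter blocks (`dicc`, `rmsd`, `track`, `contacts`, `hbonds`,
#' `synth`).
#' @name pipeline
NULL

load_run_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a YAML path or a named list")
  config
}

load_domains <- function(config) {
  d <- config$domains
  if (is.null(d)) return(npc1_domains())
  if (is.character(d) && length(d) == 1L) return(read_domain_config(d))
  out <- lapply(names(d), function(nm) domain_definition(nm, d[[nm]]))
  stats::setNames(out, names(d))
}

load_inputs <- function(config) {
  if (is.null(config$topology)) stop("config is missing 'topology'")
  if (is.null(config$trajectory)) stop("config is missing 'trajectory'")
  system <- read_structure(config$topology)
  traj <- read_trajectory(system, config$trajectory,
                          dialect = config$dialect %||% "auto",
                          stride_ns = config$stride_ns %||% 1.0)
  list(system = system, traj = traj, domains = load_domains(config))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stage_log <- function(out_dir, stage, lines) {
  writeLines(c(sprintf("[%s] stage %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                       stage), lines),
             file.path(out_dir, paste0(stage, ".log")))
}

write_summary <- function(out_dir, stage, payload) {
  payload$software <- list(package = "diccr",
                           version = as.character(utils::packageVersion("diccr")))
  jsonlite::write_json(payload, file.path(out_dir, paste0(stage, "_summary.json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Run the DiCC stage: align, compute, write the domain correlation matrix
#'
#' @param config run configuration (YAML path or list); uses keys
#'   `topology`, `trajectory`, `domains` and the `dicc` block
#'   (`mode`, `atom_filter`, `squared`, `stride`)
#' @param out_dir output directory (created if needed)
#' @return the `dicc_matrix`, invisibly
#' @export
run_dicc <- function(config, out_dir = ".") {
  config <- load_run_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  inp <- load_inputs(config)
  p <- config$dicc %||% list()
  # align: TRUE for real MD data (removes global tumble); synthetic
  # lab-frame trajectories may set FALSE to avoid fit-induced correlation
  aligned <- if (isTRUE(p$align %||% TRUE)) align_trajectory(inp$traj)
             else inp$traj
  m <- domain_dicc_matrix(aligned, inp$domains,
                          mode = p$mode %||% "domain-vector",
                          atom_filter = p$atom_filter %||% "backbone",
                          squared = isTRUE(p$squared),
                          stride = p$stride %||% 1L)
  write_dicc_csv(m, file.path(out_dir, "dicc.csv"))
  write_dicc_json(m, file.path(out_dir, "dicc.json"))
  sel_sizes <- vapply(inp$domains, function(d)
    length(resolve_selection(inp$system, d, p$atom_filter %||% "backbone")), 0L)
  write_summary(out_dir, "dicc", list(
    mode = attr(m, "mode_label"), atom_filter = attr(m, "atom_filter"),
    n_frames = attr(m, "n_frames"), squared = attr(m, "squared"),
    domains = as.list(sel_sizes)))
  stage_log(out_dir, "dicc", c(
    sprintf("frames: %d, atoms: %d", n_frames(inp$traj), n_atoms(inp$system)),
    sprintf("domain %s: %d atoms selected", names(sel_sizes), sel_sizes)))
  invisible(m)
}

#' Compare two DiCC matrices: Delta-DiCC and ranked cell report
#'
#' @param matrix1,matrix2 paths to DiCC CSV files (layout of
#'   [write_dicc_csv()])
#' @param out_dir output directory
#' @return list with `delta` (the `delta_dicc_matrix`) and `ranking`
#'   (data.frame of off-diagonal cells by decreasing change), invisibly
#' @export
run_compare <- function(matrix1, matrix2, out_dir = ".") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  m1 <- read_dicc_csv(matrix1)
  m2 <- read_dicc_csv(matrix2)
  d <- delta_dicc(m1, m2)
  ranking <- rank_delta_cells(d)
  write_dicc_csv(d, file.path(out_dir, "delta_dicc.csv"))
  write_dicc_json(d, file.path(out_dir, "delta_dicc.json"))
  utils::write.csv(ranking, file.path(out_dir, "delta_ranking.csv"),
                   row.names = FALSE, quote = FALSE)
  am <- attr(d, "argmax")
  write_summary(out_dir, "delta", list(
    argmax = am, n_domains = nrow(d)))
  stage_log(out_dir, "delta", sprintf(
    "largest off-diagonal change: %s-%s = %.6f", am$domain_a, am$domain_b,
    am$value))
  invisible(list(delta = d, ranking = ranking))
}

#' Run the per-domain RMSD stage
#'
#' @param config run configuration; uses the `rmsd` block (`atom_filter`,
#'   `reference` = "first-frame")
#' @param out_dir output directory
#' @return the RMSD data.frame, invisibly
#' @export
run_rmsd <- function(config, out_dir = ".") {
  config <- load_run_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  inp <- load_inputs(config)
  p <- config$rmsd %||% list()
  df <- rmsd_series(inp$traj, inp$domains,
                    atom_filter = p$atom_filter %||% "backbone",
                    reference = p$reference %||% "first-frame")
  utils::write.csv(df, file.path(out_dir, "rmsd.csv"), row.names = FALSE,
                   quote = FALSE)
  write_summary(out_dir, "rmsd", list(
    n_frames = nrow(df), domains = setdiff(names(df), "time_ns"),
    mean_rmsd_A = as.list(round(colMeans(df[-1]), 6))))
  stage_log(out_dir, "rmsd", sprintf("frames: %d, domains: %s", nrow(df),
            paste(setdiff(names(df), "time_ns"), collapse = ", ")))
  invisible(df)
}

#' Run the ligand-tracking stage: atom-pair distances and net displacement
#'
#' @param config run configuration; the `track` block lists `pairs`, each
#'   `list(a = list(residue_number, atom_name), b = ...)`, and optionally
#'   `selection` (a residue name, default `"LIG"`) for the net-displacement
#'   readout, and `align` (default `TRUE`) to measure in the protein frame
#' @param out_dir output directory
#' @return list of distance-series data.frames plus `net_displacement_A`,
#'   invisibly
#' @export
run_track <- function(config, out_dir = ".") {
  config <- load_run_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  inp <- load_inputs(config)
  p <- config$track %||% list()
  traj <- if (isTRUE(p$align %||% TRUE)) align_trajectory(inp$traj) else inp$traj
  series <- list()
  for (pair in p$pairs %||% list()) {
    s <- pair_distance_series(traj, pair$a, pair$b, aligned = TRUE)
    nm <- paste0("track_", gsub("[^A-Za-z0-9]", "_", attr(s, "atom_a")), "__",
                 gsub("[^A-Za-z0-9]", "_", attr(s, "atom_b")))
    utils::write.csv(s, file.path(out_dir, paste0(nm, ".csv")),
                     row.names = FALSE, quote = FALSE)
    series[[nm]] <- s
  }
  res_name <- p$selection %||% "LIG"
  sel_idx <- which(inp$system$atoms$residue_name == res_name)
  net <- if (length(sel_idx))
    net_displacement(traj, atom_selection(sel_idx, res_name)) else NA_real_
  write_summary(out_dir, "track", list(
    pairs = names(series), selection = res_name, net_displacement_A = net))
  stage_log(out_dir, "track", sprintf(
    "pairs: %d; net displacement of %s: %s A", length(series), res_name,
    format(net)))
  invisible(c(series, list(net_displacement_A = net)))
}

#' Run the contact-shell stage
#'
#' @param config run configuration; the `contacts` block gives `query`
#'   (a residue name, default `"LIG"`), `cutoff` (default 5.0), and `frame`
#'   (index, default the last frame)
#' @param out_dir output directory
#' @return the contact data.frame, invisibly
#' @export
run_contacts <- function(config, out_dir = ".") {
  config <- load_run_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  inp <- load_inputs(config)
  p <- config$contacts %||% list()
  res_name <- p$query %||% "LIG"
  qidx <- which(inp$system$atoms$residue_name == res_name)
  if (!length(qidx)) stop("no atoms with residue name '", res_name, "'")
  fi <- p$frame %||% n_frames(inp$traj)
  shell <- contact_shell(frame_coords(inp$traj, fi), inp$system,
                         atom_selection(qidx, res_name),
                         cutoff = p$cutoff %||% 5.0)
  utils::write.csv(shell, file.path(out_dir, "contacts.csv"),
                   row.names = FALSE, quote = FALSE)
  write_summary(out_dir, "contacts", list(
    query = res_name, cutoff_A = p$cutoff %||% 5.0, frame = fi,
    n_residues = nrow(shell)))
  stage_log(out_dir, "contacts", sprintf(
    "query %s (%d atoms), cutoff %.2f A, frame %d: %d residues",
    res_name, length(qidx), p$cutoff %||% 5.0, fi, nrow(shell)))
  invisible(shell)
}

#' Run the hydrogen-bond network stage
#'
#' @param config run configuration; the `hbonds` block gives `cutoff`
#'   (default 3.5), `occupancy_min` (default 0.5), and optional `donors` /
#'   `acceptors` residue-number vectors (default: all N/O/S heavy atoms on
#'   both sides)
#' @param out_dir output directory
#' @return the H-bond data.frame, invisibly
#' @export
run_hbonds <- function(config, out_dir = ".") {
  config <- load_run_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  inp <- load_inputs(config)
  p <- config$hbonds %||% list()
  a <- inp$system$atoms
  nos <- which(a$element %in% c("N", "O", "S"))
  pick <- function(resnos) if (is.null(resnos)) nos
          else nos[a$residue_number[nos] %in% resnos]
  donors <- atom_selection(pick(p$donors), "donors")
  acceptors <- atom_selection(pick(p$acceptors), "acceptors")
  hb <- hbond_network(inp$traj, donors, acceptors,
                      cutoff = p$cutoff %||% 3.5,
                      occupancy_min = p$occupancy_min %||% 0.5)
  utils::write.csv(hb, file.path(out_dir, "hbonds.csv"), row.names = FALSE,
                   quote = FALSE)
  write_summary(out_dir, "hbonds", list(
    cutoff_A = p$cutoff %||% 3.5, occupancy_min = p$occupancy_min %||% 0.5,
    n_bonds = nrow(hb)))
  stage_log(out_dir, "hbonds", sprintf(
    "donors: %d, acceptors: %d, bonds at occupancy >= %.2f: %d",
    length(donors), length(acceptors), p$occupancy_min %||% 0.5, nrow(hb)))
  invisible(hb)
}

#' Run the synthetic-data stage: generate and write a system + trajectory
#'
#' @param config run configuration; the `synth` block maps directly onto
#'   [synthetic_spec()] arguments (`domain_sizes`, `rho` or full `coupling`,
#'   `com_sigma`, `jitter_sigma`, `ligand`, `n_frames`, `stride_ns`,
#'   `seed`), plus `dialect` for the trajectory format (default `"dcd"`)
#' @param out_dir output directory; writes `topology.pdb`,
#'   `trajectory.dcd`/`.pdb`, `domains.yaml` and a summary
#' @param seed overrides the spec seed when non-NULL
#' @return list with `system`, `traj`, `spec` and file paths, invisibly
#' @export
run_synth <- function(config, out_dir = ".", seed = NULL) {
  config <- load_run_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- config$synth %||% config
  sizes <- p$domain_sizes %||% c(20, 20)
  coupling <- if (!is.null(p$coupling)) do.call(rbind, lapply(p$coupling, as.numeric))
              else coupling_matrix(length(sizes), p$rho %||% 0)
  lig <- if (isTRUE(p$no_ligand)) NULL
         else list(drift = as.numeric(p$ligand$drift %||% c(0, 0, 0.1)),
                   diffusion = p$ligand$diffusion %||% 0.2)
  spec <- synthetic_spec(
    domain_sizes = sizes, coupling = coupling,
    com_sigma = p$com_sigma %||% 1.0, jitter_sigma = p$jitter_sigma %||% 0.3,
    ligand = lig, n_frames = p$n_frames %||% 100L,
    stride_ns = p$stride_ns %||% 1.0, seed = seed %||% p$seed %||% 42L,
    ar_phi = p$ar_phi %||% 0)
  system <- build_synthetic_system(spec)
  traj <- simulate_trajectory(system, spec)
  dialect <- p$dialect %||% "dcd"
  top_path <- file.path(out_dir, "topology.pdb")
  trj_path <- file.path(out_dir,
                        if (dialect == "dcd") "trajectory.dcd" else "trajectory.pdb")
  write_structure(system, top_path)
  write_trajectory(traj, trj_path, dialect = dialect)
  doms <- synthetic_domains(spec)
  yaml::write_yaml(list(domains = stats::setNames(lapply(doms, function(d)
    apply(d$ranges, 1, paste, collapse = "-")), names(doms))),
    file.path(out_dir, "domains.yaml"))
  write_summary(out_dir, "synth", list(
    domain_sizes = spec$domain_sizes, n_frames = spec$n_frames,
    com_sigma = spec$com_sigma, jitter_sigma = spec$jitter_sigma,
    seed = spec$seed, stride_ns = spec$stride_ns,
    topology = basename(top_path), trajectory = basename(trj_path)))
  stage_log(out_dir, "synth", sprintf(
    "generated %d atoms x %d frames (seed %d)", n_atoms(system),
    n_frames(traj), spec$seed))
  invisible(list(system = system, traj = traj, spec = spec,
                 topology = top_path, trajectory = trj_path,
                 domains = file.path(out_dir, "domains.yaml")))
}
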
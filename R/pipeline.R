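#' Pipeline configuration
#'
#' Assembles and validates the settings for a full analysis run. Either give
#' file inputs (`topology` + `trajectories` + `groups_file`) or pass a
#' pre-built ensemble via `run_pipeline(..., traj =, groups =)`.
#'
#' @param mode "cmd" (conventional-MD descriptor run) or "amd" (reweighted
#'   free-energy run restricted to minimum-energy frames).
#' @param topology,trajectories,groups_file input paths (optional when an
#'   ensemble is passed directly).
#' @param boost_log boost-energy log path (amd mode; optional if a
#'   `boost_record` is passed to [run_pipeline()]).
#' @param exclude_frames leading frames dropped per replica as equilibration.
#' @param theta_threshold shape threshold, degrees (default 85).
#' @param pmf_cutoff minimum-energy PMF cutoff, kcal/mol (default 0.5).
#' @param contact_cutoff heavy-atom contact cutoff, nm (default 0.4).
#' @param cluster_cutoff RMSD cluster cutoff, nm (defaults: 0.75 cmd /
#'   0.65 amd).
#' @param max_clusters cluster cap (defaults: 15 cmd / 10 amd).
#' @param k_max Maclaurin order (default 10).
#' @param temperature temperature, K.
#' @param cluster_sample cap on frames entering the RMSD matrix (evenly
#'   subsampled beyond it).
#' @param out_dir output directory for CSVs and the manifest.
#' @param seed RNG seed recorded in the manifest.
#' @return validated list, class `pipeline_config`.
#' @export
pipeline_config <- function(mode = c("cmd", "amd"), topology = NULL,
                            trajectories = NULL, groups_file = NULL,
                            boost_log = NULL, exclude_frames = 0L,
                            theta_threshold = 85, pmf_cutoff = 0.5,
                            contact_cutoff = 0.4, cluster_cutoff = NULL,
                            max_clusters = NULL, k_max = 10L,
                            temperature = 300, cluster_sample = 300L,
                            out_dir = NULL, seed = 1L) {
  mode <- match.arg(mode)
  if (is.null(cluster_cutoff)) cluster_cutoff <- if (mode == "cmd") 0.75 else 0.65
  if (is.null(max_clusters)) max_clusters <- if (mode == "cmd") 15L else 10L
  for (p in c(topology, trajectories, groups_file, boost_log))
    if (!is.null(p) && !file.exists(p)) stop("input file not found: ", p)
  structure(list(mode = mode, topology = topology, trajectories = trajectories,
                 groups_file = groups_file, boost_log = boost_log,
                 exclude_frames = as.integer(exclude_frames),
                 theta_threshold = theta_threshold, pmf_cutoff = pmf_cutoff,
                 contact_cutoff = contact_cutoff,
                 cluster_cutoff = cluster_cutoff,
                 max_clusters = as.integer(max_clusters),
                 k_max = as.integer(k_max), temperature = temperature,
                 cluster_sample = as.integer(cluster_sample),
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "pipeline_config")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

.write_csvs <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, name)
    utils::write.csv(df, file.path(out_dir, name), row.names = FALSE)
  w(report$angles_table, "angles.csv")
  w(data.frame(descriptor = "ch2_distance", frame = seq_along(report$ch2$values) - 1L,
               value_nm = report$ch2$values), "ch2_distance.csv")
  if (!is.null(report$fes)) {
    g <- report$fes
    nb <- length(g$breaks) - 1L
    mid <- (g$breaks[-1L] + g$breaks[-(nb + 1L)]) / 2
    w(data.frame(theta1_bin = rep(mid, nb), theta2_bin = rep(mid, each = nb),
                 prob = as.numeric(g$prob),
                 pmf_kcalmol = as.numeric(g$pmf)), "fes.csv")
    w(data.frame(frame = report$min_energy_frames - 1L), "min_energy_frames.csv")
  }
  if (!is.null(report$clusters)) {
    cl <- report$clusters
    w(data.frame(frame = seq_along(cl$id) - 1L, cluster = cl$id), "clusters.csv")
    w(data.frame(cluster = seq_along(cl$sizes), medoid_frame = cl$medoids - 1L,
                 size = cl$sizes, population = cl$populations), "cluster_summary.csv")
  }
  if (!is.null(report$hbonds)) w(report$hbonds, "hbonds.csv")
  if (!is.null(report$contacts)) {
    ct <- report$contacts
    w(data.frame(residue = rep(colnames(ct$counts), each = nrow(ct$counts)),
                 frame = rep(seq_len(nrow(ct$counts)) - 1L, ncol(ct$counts)),
                 contacts = as.integer(ct$counts)), "contacts.csv")
  }
  invisible(NULL)
}

.write_manifest <- function(report, config, out_dir) {
  manifest <- list(
    package = "mabflex",
    version = as.character(utils::packageVersion("mabflex")),
    mode = config$mode, seed = config$seed,
    thresholds = list(theta_deg = config$theta_threshold,
                      pmf_kcalmol = config$pmf_cutoff,
                      contact_nm = config$contact_cutoff,
                      cluster_nm = config$cluster_cutoff,
                      max_clusters = config$max_clusters,
                      k_max = config$k_max,
                      temperature_K = config$temperature),
    n_frames = report$n_frames,
    frames_per_replica = report$frames_per_replica,
    n_min_energy_frames = length(report$min_energy_frames))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
}

#' Run the full analysis workflow
#'
#' cmd mode: orientation angles, shape fractions, delta-phi, CH2 distance,
#' GROMOS clustering with medoids. amd mode: additionally Maclaurin
#' reweighting onto the (theta1, theta2) surface, minimum-energy frame
#' selection, descriptors restricted to that set (delta-phi, ED-filtered
#' delta-phi, glycan distances, contacts, hydrogen bonds where the topology
#' carries them). Writes tidy CSVs plus a machine-readable manifest when
#' `out_dir` is set.
#'
#' @param config a [pipeline_config()].
#' @param traj optional pre-built `traj_ensemble` (skips file loading).
#' @param groups optional [atom_groups()] (required with `traj`).
#' @param boost optional [boost_record()] (amd mode).
#' @return list report with the stage results (angles, shape, dphi, ch2,
#'   fes, min_energy_frames, clusters, ed, filtered_dphi, glycan/contact/
#'   hbond descriptors where computed).
#' @export
run_pipeline <- function(config, traj = NULL, groups = NULL, boost = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(traj)) {
    traj <- .stage("load", load_ensemble(config$topology, config$trajectories,
                                         exclude_frames = config$exclude_frames))
    groups <- .stage("groups", read_groups(config$groups_file, natoms(traj)))
  } else if (is.null(groups)) stop("groups must accompany a pre-built ensemble")
  if (config$mode == "amd" && is.null(boost) && !is.null(config$boost_log))
    boost <- .stage("boost", read_boost_log(config$boost_log,
                                            temperature = config$temperature))

  report <- list(n_frames = nframes(traj),
                 frames_per_replica = as.integer(table(traj$replica)))
  report$angles <- .stage("angles", compute_fab_angles(traj, groups))
  report$shape <- .stage("shape", classify_shape(report$angles,
                                                 config$theta_threshold))
  report$dphi <- .stage("delta_phi", compute_delta_phi(report$angles))
  report$angles_table <- cbind(report$angles,
                               dphi1 = report$dphi$dphi1,
                               dphi2 = report$dphi$dphi2,
                               shape_label = as.character(report$shape$label))
  report$ch2 <- .stage("ch2", ch2_distance(traj, groups))

  analysis_frames <- seq_len(nframes(traj))
  if (config$mode == "amd") {
    report$fes <- .stage("reweight", reweight_fes(
      report$angles, boost, k_max = config$k_max,
      temperature = config$temperature))
    report$min_energy_frames <- .stage("min_energy", select_min_energy_frames(
      report$fes, config$pmf_cutoff))
    analysis_frames <- report$min_energy_frames
    report$dphi_min <- .stage("delta_phi_min", compute_delta_phi(
      report$angles[analysis_frames, , drop = FALSE]))
    sel <- sort(unique(c(groups$Fc, groups$Fab1, groups$Fab2, groups$hinge,
                         groups$CH2_A, groups$CH2_B)))
    report$ed <- .stage("essential_dynamics",
                        essential_dynamics(traj, selection = sel))
    report$filtered_dphi <- .stage("filtered_delta_phi", filtered_delta_phi(
      traj, report$ed, components = 1:2, groups = atom_groups(
        list(Fc = groups$Fc, Fab1 = groups$Fab1, Fab2 = groups$Fab2,
             hinge = groups$hinge, CH2_A = groups$CH2_A,
             CH2_B = groups$CH2_B), natoms(traj)),
      frames = analysis_frames))
    if (!is.null(groups$glycan_A) && length(groups$glycan_A)) {
      mtraj <- subset_frames(traj, analysis_frames)
      report$glycan_min <- .stage("glycan_min",
                                  glycan_min_distance(mtraj, groups))
      report$glycan_com <- .stage("glycan_com",
                                  glycan_com_displacement(mtraj, groups))
    }
    if (!is.null(groups$LC_cterm) && length(groups$LC_cterm))
      report$contacts <- .stage("contacts", residue_contacts(
        subset_frames(traj, analysis_frames), groups$LC_cterm, groups$hinge,
        cutoff = config$contact_cutoff))
    if (any(traj$top$elesy == "H"))
      report$hbonds <- .stage("hbonds", hydrogen_bonds(traj,
                                                       frames = analysis_frames))
  }

  cl_frames <- analysis_frames
  if (length(cl_frames) > config$cluster_sample)
    cl_frames <- cl_frames[unique(round(seq(1, length(cl_frames),
                                            length.out = config$cluster_sample)))]
  ctraj <- subset_frames(traj, cl_frames)
  sel_ca <- select_atoms(ctraj$top, elety = "CA")
  if (length(sel_ca) < 3L) sel_ca <- seq_len(natoms(ctraj))
  report$cluster_frames <- cl_frames
  report$clusters <- .stage("cluster", gromos_cluster(
    rmsd_matrix(ctraj, sel_ca), cutoff = config$cluster_cutoff,
    max_clusters = config$max_clusters))

  if (!is.null(config$out_dir)) {
    .write_csvs(report, config$out_dir)
    for (k in seq_along(report$clusters$sizes)) {
      mf <- cl_frames[report$clusters$medoids[k]]
      write_traj_pdb(traj, traj_file = file.path(config$out_dir,
                                                 sprintf("medoid_%02d.pdb", k)),
                     frames = mf)
    }
    .write_manifest(report, config, config$out_dir)
  }
  report
}
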
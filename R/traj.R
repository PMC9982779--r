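#' Trajectory ensemble container
#'
#' Bundles a topology table with per-frame coordinates. Coordinates are stored
#' bio3d-style as an `nframes x 3*natoms` matrix (columns x1, y1, z1, x2, ...)
#' in nanometres. `replica` records, per frame, which input replica the frame
#' came from; `time` is the frame time in ns when known.
#'
#' @param top data.frame with one row per atom and (at least) columns
#'   `elety` (atom name), `resid`, `resno`, `chain`, `elesy` (element symbol).
#' @param xyz numeric matrix, `nframes x 3*natoms`, nm.
#' @param time optional numeric vector of frame times (ns).
#' @param replica optional integer vector of per-frame replica ids.
#' @return an object of class `traj_ensemble`.
#' @export
traj_ensemble <- function(top, xyz, time = NULL, replica = NULL) {
  stopifnot(is.data.frame(top))
  xyz <- rbind(xyz)
  if (ncol(xyz) != 3L * nrow(top))
    stop("xyz has ", ncol(xyz), " columns but topology has ", nrow(top),
         " atoms (expected ", 3L * nrow(top), " columns)")
  if (!all(is.finite(xyz))) stop("non-finite coordinates in trajectory")
  nf <- nrow(xyz)
  if (is.null(time)) time <- seq_len(nf) - 1
  if (is.null(replica)) replica <- rep.int(1L, nf)
  stopifnot(length(time) == nf, length(replica) == nf)
  structure(list(top = top, xyz = unname(xyz), time = time,
                 replica = as.integer(replica)),
            class = "traj_ensemble")
}

#' @export
print.traj_ensemble <- function(x, ...) {
  cat("traj_ensemble:", nframes(x), "frames,", natoms(x), "atoms,",
      length(unique(x$replica)), "replica(s)\n")
  invisible(x)
}

#' @rdname traj_ensemble
#' @param traj a `traj_ensemble`.
#' @export
nframes <- function(traj) nrow(traj$xyz)

#' @rdname traj_ensemble
#' @export
natoms <- function(traj) nrow(traj$top)

#' Keep a subset of frames
#'
#' @param traj a `traj_ensemble`.
#' @param idx integer frame indices (1-based) to retain, in order.
#' @return a `traj_ensemble` restricted to those frames.
#' @export
subset_frames <- function(traj, idx) {
  idx <- as.integer(idx)
  if (length(idx) == 0L) stop("empty frame subset")
  if (any(idx < 1L | idx > nframes(traj))) stop("frame index out of range")
  traj_ensemble(traj$top, traj$xyz[idx, , drop = FALSE],
                time = traj$time[idx], replica = traj$replica[idx])
}

#' Atom group configuration
#'
#' Validated named atom selections used throughout the pipeline. Indices are
#' 1-based atom indices into the topology. Required groups: `Fc`, `Fab1`,
#' `Fab2`, `hinge`; the remaining groups are needed only by the operations
#' that consume them.
#'
#' @param groups named list of integer vectors.
#' @param n_atoms number of atoms in the topology the indices refer to.
#' @return the validated list, classed `atom_groups`.
#' @export
atom_groups <- function(groups, n_atoms) {
  stopifnot(is.list(groups), !is.null(names(groups)))
  groups <- lapply(groups, function(g) sort(unique(as.integer(g))))
  req <- c("Fc", "Fab1", "Fab2", "hinge")
  miss <- setdiff(req, names(groups))
  if (length(miss)) stop("missing required groups: ", paste(miss, collapse = ", "))
  for (nm in names(groups)) {
    g <- groups[[nm]]
    if (length(g) && (min(g) < 1L || max(g) > n_atoms))
      stop("group '", nm, "' has atom indices outside 1..", n_atoms)
  }
  if (length(groups$hinge) == 0L) stop("hinge group is empty")
  ov <- c(intersect(groups$Fab1, groups$Fab2),
          intersect(groups$Fab1, groups$Fc),
          intersect(groups$Fab2, groups$Fc))
  if (length(ov)) stop("Fab1/Fab2/Fc groups must be pairwise disjoint")
  structure(groups, class = "atom_groups")
}

#' Read an atom-group config file
#'
#' YAML mapping of group name to a list of atom indices. Indices in the file
#' are 0-based (the convention of the trajectory tools this pipeline mirrors)
#' and converted to 1-based internally.
#'
#' @param path YAML file path.
#' @param n_atoms number of atoms in the topology.
#' @param zero_based logical; are file indices 0-based? Default TRUE.
#' @return an `atom_groups` object.
#' @export
read_groups <- function(path, n_atoms, zero_based = TRUE) {
  raw <- yaml::read_yaml(path)
  groups <- lapply(raw, function(g) as.integer(unlist(g)) + if (zero_based) 1L else 0L)
  atom_groups(groups, n_atoms)
}

#' Select atom indices from a topology table
#'
#' Convenience programmatic selector; any argument left NULL is not filtered.
#'
#' @param top topology data.frame (see [traj_ensemble()]).
#' @param chain,resno,resid,elety optional filters.
#' @param heavy if TRUE drop hydrogens (element "H").
#' @return integer atom indices.
#' @export
select_atoms <- function(top, chain = NULL, resno = NULL, resid = NULL,
                         elety = NULL, heavy = FALSE) {
  keep <- rep(TRUE, nrow(top))
  if (!is.null(chain)) keep <- keep & top$chain %in% chain
  if (!is.null(resno)) keep <- keep & top$resno %in% resno
  if (!is.null(resid)) keep <- keep & top$resid %in% resid
  if (!is.null(elety)) keep <- keep & top$elety %in% elety
  if (heavy) keep <- keep & top$elesy != "H"
  which(keep)
}

.read_traj_file <- function(path, natoms_expected, scale) {
  ext <- tolower(tools::file_ext(path))
  xyz <- switch(ext,
    pdb = bio3d::read.pdb(path, multi = TRUE)$xyz,
    dcd = bio3d::read.dcd(path, verbose = FALSE),
    stop("unsupported trajectory format '", ext, "' for ", path,
         " (supported: pdb, dcd)"))
  xyz <- rbind(xyz)
  if (ncol(xyz) != 3L * natoms_expected)
    stop("atom-count mismatch: trajectory '", path, "' has ", ncol(xyz) / 3,
         " atoms, topology has ", natoms_expected)
  unclass(xyz) * scale
}

#' Load and merge replica trajectories
#'
#' Reads a PDB topology plus one or more trajectory files (multi-model PDB or
#' DCD), drops the leading equilibration frames of each replica, applies an
#' optional stride, and concatenates the replicas into one analysis ensemble.
#' Replica provenance is kept per frame.
#'
#' @param topology path to a PDB topology.
#' @param trajectories character vector of trajectory file paths (one per
#'   replica).
#' @param exclude_frames number of leading frames dropped from each replica
#'   (equilibration); must be shorter than every replica.
#' @param stride keep every `stride`-th frame after exclusion.
#' @param dt frame spacing in ns (for the time axis).
#' @param scale multiplicative factor applied to file coordinates to obtain
#'   nm; PDB and DCD files are conventionally in Angstrom, so default 0.1.
#' @return a `traj_ensemble`.
#' @export
load_ensemble <- function(topology, trajectories, exclude_frames = 0L,
                          stride = 1L, dt = 0.1, scale = 0.1) {
  pdb <- bio3d::read.pdb(topology)
  top <- pdb$atom[, c("elety", "resid", "chain", "resno", "elesy")]
  if (all(is.na(top$elesy)) || is.null(top$elesy))
    top$elesy <- substr(trimws(top$elety), 1L, 1L)
  nat <- nrow(top)
  xs <- list(); reps <- integer(0); times <- numeric(0)
  for (r in seq_along(trajectories)) {
    xyz <- .read_traj_file(trajectories[r], nat, scale)
    if (exclude_frames >= nrow(xyz))
      stop("equilibration exclusion (", exclude_frames,
           " frames) >= replica length (", nrow(xyz), " frames) for ",
           trajectories[r])
    keep <- seq.int(exclude_frames + 1L, nrow(xyz), by = stride)
    xs[[r]] <- xyz[keep, , drop = FALSE]
    reps <- c(reps, rep.int(r, length(keep)))
    times <- c(times, (keep - 1L) * dt)
  }
  traj_ensemble(top, do.call(rbind, xs), time = times, replica = reps)
}

#' Write topology and trajectory as PDB
#'
#' The topology goes to a single-model PDB; the trajectory to a multi-model
#' PDB. Coordinates are written in Angstrom (PDB convention).
#'
#' @param traj a `traj_ensemble`.
#' @param topology_file,traj_file output paths; either may be NULL to skip.
#' @param frames optional frame subset for the trajectory file.
#' @return invisibly, the input.
#' @export
write_traj_pdb <- function(traj, topology_file = NULL, traj_file = NULL,
                           frames = NULL) {
  top <- traj$top
  wr <- function(file, xyz) {
    bio3d::write.pdb(file = file, xyz = xyz * 10,
                     elety = top$elety, resid = top$resid,
                     chain = top$chain, resno = top$resno,
                     elesy = top$elesy)
  }
  if (!is.null(topology_file)) wr(topology_file, traj$xyz[1L, , drop = FALSE])
  if (!is.null(traj_file)) {
    xyz <- if (is.null(frames)) traj$xyz else traj$xyz[frames, , drop = FALSE]
    wr(traj_file, xyz)
  }
  invisible(traj)
}
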
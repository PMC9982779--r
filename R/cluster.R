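#' Pairwise RMSD matrix over trajectory frames
#'
#' Entry (i, j) is the minimal RMSD (nm) after optimal (Kabsch) superposition
#' of frame j onto frame i over the selection. For antibody clustering the
#' selection is C-alpha atoms; for glycans, the glycosidic oxygens.
#'
#' @param traj a `traj_ensemble` with >= 2 frames.
#' @param selection atom indices (>= 3) used for superposition and RMSD.
#' @return symmetric matrix with zero diagonal, attribute `selection`.
#' @export
rmsd_matrix <- function(traj, selection = seq_len(natoms(traj))) {
  n <- nframes(traj)
  if (n < 2L) stop("need at least two frames")
  if (length(selection) < 3L) stop("selection must have >= 3 atoms")
  inds <- xyz_inds(selection)
  m <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    rows <- (i + 1L):n
    fitted <- rbind(bio3d::fit.xyz(fixed = traj$xyz[i, ],
                                   mobile = traj$xyz[rows, , drop = FALSE],
                                   fixed.inds = inds, mobile.inds = inds))
    dev <- sweep(fitted[, inds, drop = FALSE], 2L, traj$xyz[i, inds])
    v <- sqrt(rowSums(dev^2) / length(selection))
    m[i, rows] <- v
    m[rows, i] <- v
  }
  attr(m, "selection") <- selection
  m
}

#' GROMOS conformational clustering
#'
#' Iterative neighbour counting on a pairwise RMSD matrix: the frame with the
#' most neighbours within the cutoff becomes a cluster medoid (the "central
#' member"); it and its neighbours are removed and the count repeats, until
#' the pool is empty or `max_clusters` clusters have been emitted. Remaining
#' frames are left unassigned (id -1). Ties in the neighbour count are broken
#' toward the lowest frame index, making the result deterministic.
#'
#' @param mat symmetric pairwise RMSD matrix (nm).
#' @param cutoff RMSD neighbour cutoff in nm (> 0).
#' @param max_clusters maximum number of clusters emitted (>= 1).
#' @return list (class `gromos_clusters`): `id` per frame (1, 2, ... in
#'   decreasing cluster size; -1 unassigned), `medoids` (frame indices),
#'   `sizes`, `populations` (fractions of all frames), `cutoff`,
#'   `max_clusters`.
#' @export
gromos_cluster <- function(mat, cutoff, max_clusters = 10L) {
  stopifnot(is.matrix(mat), nrow(mat) == ncol(mat))
  if (!is.finite(cutoff) || cutoff <= 0) stop("cutoff must be > 0")
  if (max_clusters < 1L) stop("max_clusters must be >= 1")
  n <- nrow(mat)
  adj <- mat <= cutoff
  id <- rep(-1L, n)
  active <- rep(TRUE, n)
  medoids <- integer(0); sizes <- integer(0)
  k <- 0L
  while (any(active) && k < max_clusters) {
    counts <- rowSums(adj[, active, drop = FALSE]) # includes self
    counts[!active] <- -1L
    med <- unname(which.max(counts))  # which.max takes the first (lowest) index on ties
    members <- which(active & adj[med, ])
    k <- k + 1L
    id[members] <- k
    medoids <- c(medoids, med)
    sizes <- c(sizes, length(members))
    active[members] <- FALSE
  }
  structure(list(id = id, medoids = medoids, sizes = sizes,
                 populations = sizes / n, cutoff = cutoff,
                 max_clusters = max_clusters),
            class = "gromos_clusters")
}

#' @export
print.gromos_clusters <- function(x, ...) {
  cat("GROMOS clustering: cutoff", x$cutoff, "nm,", length(x$sizes),
      "cluster(s),", sum(x$id == -1L), "unassigned frame(s)\n")
  for (k in seq_along(x$sizes))
    cat(sprintf("  cluster %d: %d frames (%.1f%%), medoid frame %d\n", k,
                x$sizes[k], 100 * x$populations[k], x$medoids[k] - 1L))
  invisible(x)
}
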
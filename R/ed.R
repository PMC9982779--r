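#' Essential dynamics (PCA of the coordinate covariance)
#'
#' Frames are superposed on the mean structure (fit to frame 1, recompute the
#' mean, fit to it once -- a single iteration), then the covariance matrix of
#' the 3N selected coordinates (1/N normalization) is diagonalized. No mass
#' weighting is applied (plain C-alpha coordinates); set `fit = FALSE` to
#' analyse raw coordinates.
#'
#' @param traj a `traj_ensemble` with >= 2 frames.
#' @param selection atom indices the analysis runs on.
#' @param fit superpose frames before the covariance (default TRUE).
#' @return list (class `ed_result`): `mean` (3N vector), `values`
#'   (eigenvalues, nm^2, descending), `vectors` (columns = eigenvectors),
#'   `proj` (frames x components projection matrix), `cumvar` (normalized
#'   cumulative variance), `selection`, `fitted_xyz` (superposed selection
#'   coordinates).
#' @export
essential_dynamics <- function(traj, selection = seq_len(natoms(traj)),
                               fit = TRUE) {
  if (nframes(traj) < 2L) stop("need at least two frames")
  inds <- xyz_inds(selection)
  X <- traj$xyz[, inds, drop = FALSE]
  if (fit) {
    n <- length(inds)
    fit1 <- bio3d::fit.xyz(fixed = X[1L, ], mobile = X,
                           fixed.inds = seq_len(n), mobile.inds = seq_len(n))
    m1 <- colMeans(rbind(fit1))
    X <- rbind(bio3d::fit.xyz(fixed = m1, mobile = rbind(fit1),
                              fixed.inds = seq_len(n), mobile.inds = seq_len(n)))
    X <- unclass(X)
  }
  mu <- colMeans(X)
  Xc <- sweep(X, 2L, mu)
  C <- crossprod(Xc) / nrow(Xc)
  ev <- eigen(C, symmetric = TRUE)
  vals <- pmax(ev$values, 0)
  structure(list(mean = mu, values = vals, vectors = ev$vectors,
                 proj = Xc %*% ev$vectors,
                 cumvar = cumsum(vals) / max(sum(vals), .Machine$double.eps),
                 selection = selection, fitted_xyz = X),
            class = "ed_result")
}

#' Reconstruct a trajectory filtered along chosen essential-dynamics modes
#'
#' mean + sum over the chosen components of projection x eigenvector; the
#' motion along every other mode is frozen at the mean.
#'
#' @param ed an [essential_dynamics()] result.
#' @param components integer vector of component indices.
#' @return matrix of filtered coordinates (frames x 3N of the ED selection).
#' @export
ed_filter_xyz <- function(ed, components) {
  if (any(components < 1L | components > ncol(ed$vectors)))
    stop("component index out of range (1..", ncol(ed$vectors), ")")
  rec <- ed$proj[, components, drop = FALSE] %*%
    t(ed$vectors[, components, drop = FALSE])
  sweep(rec, 2L, ed$mean, "+")
}

#' Fab longitude shifts along single essential-dynamics modes
#'
#' For each requested component, the trajectory is reconstructed keeping only
#' that mode's motion, restricted to the supplied frames (typically the
#' free-energy minimum set), and the Fab angles and delta-phi are recomputed
#' on it. Mirrors the analysis that asks whether one collective mode explains
#' the Fab rotation seen in the full ensemble.
#'
#' @param traj the `traj_ensemble` the ED was computed on.
#' @param ed an [essential_dynamics()] result over `groups`-compatible atoms.
#' @param components component indices (default 1:2).
#' @param groups an [atom_groups()] object whose indices refer to `traj`;
#'   all group atoms must be inside the ED selection.
#' @param frames optional frame subset applied before delta-phi.
#' @return named list, one data.frame per component (as from
#'   [compute_delta_phi()]), plus `full` computed from the unfiltered
#'   coordinates of the same selection and frames.
#' @export
filtered_delta_phi <- function(traj, ed, components = 1:2, groups,
                               frames = NULL) {
  sel <- ed$selection
  remap <- lapply(groups, function(g) {
    m <- match(g, sel)
    if (anyNA(m)) stop("atom group outside the ED selection")
    m
  })
  remap <- atom_groups(remap, length(sel))
  top_sel <- traj$top[sel, , drop = FALSE]
  dphi_of <- function(xyz) {
    tr <- traj_ensemble(top_sel, xyz)
    if (!is.null(frames)) tr <- subset_frames(tr, frames)
    compute_delta_phi(compute_fab_angles(tr, remap))
  }
  out <- lapply(components, function(cp) dphi_of(ed_filter_xyz(ed, cp)))
  names(out) <- paste0("component", components)
  out$full <- dphi_of(ed$fitted_xyz)
  out
}
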
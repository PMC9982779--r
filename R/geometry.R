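#' Build the Fc-anchored reference frame for one trajectory frame
#'
#' The frame is centred in the hinge and jointed to the Fc: the origin is the
#' hinge centroid; z is the dominant principal axis of the Fc atom cloud,
#' sign-fixed to point from the Fc body toward the hinge (and hence toward
#' the Fab domains, which sit beyond it) -- a rule that stays stable even
#' when both Fabs dip past the equatorial plane; x is the vector
#' joining the two CH2-domain centroids (A to B), orthogonalized against z;
#' y completes a right-handed orthonormal triad.
#'
#' @param coords N x 3 coordinate matrix (nm) for a single frame.
#' @param groups an [atom_groups()] object with `hinge`, `Fc`, `CH2_A`,
#'   `CH2_B`, `Fab1`, `Fab2`.
#' @return list with `origin` and unit axes `x`, `y`, `z`; class `fc_frame`.
#' @export
build_fc_frame <- function(coords, groups) {
  for (nm in c("hinge", "Fc", "CH2_A", "CH2_B", "Fab1", "Fab2"))
    if (is.null(groups[[nm]]) || length(groups[[nm]]) == 0L)
      stop("group '", nm, "' is empty or missing")
  origin <- group_centroid(coords, groups$hinge)

  fc <- coords[groups$Fc, , drop = FALSE]
  fc <- sweep(fc, 2L, colMeans(fc))
  ev <- eigen(crossprod(fc) / nrow(fc), symmetric = TRUE)
  z <- ev$vectors[, 1L]

  for (fg in c("Fab1", "Fab2"))
    if (vnorm(group_centroid(coords, groups[[fg]]) - origin) < 1e-6)
      stop(fg, " centroid coincides with the hinge centroid")
  d <- origin - colMeans(coords[groups$Fc, , drop = FALSE])
  if (vnorm(d) < 1e-6) stop("hinge centroid coincides with the Fc centroid")
  if (sum(d * z) < 0) z <- -z

  v <- group_centroid(coords, groups$CH2_B) - group_centroid(coords, groups$CH2_A)
  xo <- v - sum(v * z) * z
  if (vnorm(xo) < 1e-6 * vnorm(v))
    stop("degenerate geometry: CH2 A->B vector is parallel to the Fc axis")
  x <- xo / vnorm(xo)
  y <- cross3(z, x)
  structure(list(origin = origin, x = x, y = y, z = z), class = "fc_frame")
}

#' Per-frame Fab orientation angles in the Fc-anchored frame
#'
#' For each frame the Fc frame is rebuilt (it is jointed to the moving Fc),
#' and each Fab centroid direction v = centroid - origin is converted to a
#' latitude theta = acos(v.z/|v|) and a longitude phi = atan2(v.y, v.x),
#' both in degrees.
#'
#' @param traj a `traj_ensemble`.
#' @param groups an [atom_groups()] object.
#' @return data.frame (class `fab_angles`) with columns `frame` (0-based),
#'   `theta1`, `theta2` in degrees in \[0, 180\] and `phi1`, `phi2` in
#'   (-180, 180\].
#' @export
compute_fab_angles <- function(traj, groups) {
  nf <- nframes(traj)
  if (nf == 0L) stop("empty trajectory")
  out <- matrix(NA_real_, nf, 4L)
  for (f in seq_len(nf)) {
    co <- frame_coords(traj$xyz, f)
    fr <- build_fc_frame(co, groups)
    for (k in 1:2) {
      v <- group_centroid(co, groups[[paste0("Fab", k)]]) - fr$origin
      nv <- vnorm(v)
      if (nv < 1e-6) stop("Fab", k, " centroid at the frame origin in frame ", f)
      ct <- min(1, max(-1, sum(v * fr$z) / nv))
      out[f, k] <- acos(ct) * .deg
      out[f, k + 2L] <- atan2(sum(v * fr$y), sum(v * fr$x)) * .deg
    }
  }
  res <- data.frame(frame = seq_len(nf) - 1L, theta1 = out[, 1L],
                    theta2 = out[, 2L], phi1 = wrap_deg(out[, 3L]),
                    phi2 = wrap_deg(out[, 4L]))
  class(res) <- c("fab_angles", "data.frame")
  res
}

#' Classify frames as T-, Y-shaped or asymmetric
#'
#' A frame is T-shaped when both Fab latitudes are at or above the threshold,
#' Y-shaped when both are below it, and asymmetric otherwise. The default
#' 85 degrees discriminates the T-shaped crystal conformation (both theta
#' above 90 degrees) from Y-shaped ones while allowing for thermal spread.
#'
#' @param angles a `fab_angles` data.frame.
#' @param threshold latitude threshold in degrees, in (0, 180).
#' @return list (class `shape_call`) with per-frame `label` (factor with
#'   levels T, Y, asym) and `summary`: `frac_T` (both >= threshold), `frac_Y`
#'   (both < threshold), `frac_asym`, and `frac_fab` (per-Fab fraction of
#'   frames with theta >= threshold).
#' @export
classify_shape <- function(angles, threshold = 85) {
  if (!is.finite(threshold) || threshold <= 0 || threshold >= 180)
    stop("threshold must lie in (0, 180) degrees")
  if (nrow(angles) == 0L) stop("empty trajectory: no angles to classify")
  hi1 <- angles$theta1 >= threshold
  hi2 <- angles$theta2 >= threshold
  label <- factor(ifelse(hi1 & hi2, "T", ifelse(!hi1 & !hi2, "Y", "asym")),
                  levels = c("T", "Y", "asym"))
  tab <- as.numeric(table(label)) / nrow(angles)
  structure(list(
    label = label,
    threshold = threshold,
    summary = list(frac_T = tab[1L], frac_Y = tab[2L], frac_asym = tab[3L],
                   frac_fab = c(fab1 = mean(hi1), fab2 = mean(hi2)))),
    class = "shape_call")
}

#' @export
print.shape_call <- function(x, ...) {
  s <- x$summary
  cat(sprintf("shape fractions (theta threshold %g deg): T %.3f  Y %.3f  asym %.3f\n",
              x$threshold, s$frac_T, s$frac_Y, s$frac_asym))
  cat(sprintf("per-Fab fraction theta >= threshold: Fab1 %.3f  Fab2 %.3f\n",
              s$frac_fab[1L], s$frac_fab[2L]))
  invisible(x)
}

#' Longitude shift of each Fab relative to a reference frame
#'
#' delta-phi_i = phi_i - phi_ref, wrapped to (-180, 180]. The reference frame
#' itself has delta-phi exactly 0. Optionally the series can be unwrapped into
#' a cumulative (continuous) angle.
#'
#' @param angles a `fab_angles` data.frame.
#' @param ref_frame 1-based index of the reference frame (default 1, the
#'   trajectory start).
#' @param cumulative if TRUE, return the unwrapped cumulative shift instead of
#'   the wrapped one.
#' @return data.frame with columns `frame`, `dphi1`, `dphi2` (degrees).
#' @export
compute_delta_phi <- function(angles, ref_frame = 1L, cumulative = FALSE) {
  n <- nrow(angles)
  if (ref_frame < 1L || ref_frame > n) stop("reference frame index out of range")
  one <- function(phi) {
    if (cumulative) {
      step <- wrap_deg(diff(phi))
      cum <- cumsum(c(0, step))
      cum - cum[ref_frame]
    } else {
      d <- wrap_deg(phi - phi[ref_frame])
      d[ref_frame] <- 0
      d
    }
  }
  data.frame(frame = angles$frame,
             dphi1 = one(angles$phi1),
             dphi2 = one(angles$phi2))
}
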
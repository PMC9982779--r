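xyz_inds <- function(atoms) bio3d::atom2xyz(atoms)

# Superpose every frame onto a reference frame over `fit_atoms`.
superpose_frames <- function(xyz, fit_atoms, ref_frame = 1L) {
  if (length(fit_atoms) < 3L) stop("superposition needs >= 3 atoms")
  inds <- xyz_inds(fit_atoms)
  fitted <- bio3d::fit.xyz(fixed = xyz[ref_frame, ], mobile = xyz,
                           fixed.inds = inds, mobile.inds = inds)
  unclass(rbind(fitted))
}

#' RMSD, RMSF and radius of gyration
#'
#' RMSD per frame against frame 1 after least-squares superposition over the
#' selection; RMSF per selected atom about the mean superposed structure;
#' radius of gyration (unweighted) per frame over the selection. All in nm.
#'
#' @param traj a `traj_ensemble`.
#' @param selection atom indices (typically C-alpha); defaults to all atoms.
#' @return list with data.frames `rmsd` (frame, rmsd), `rmsf` (atom, rmsf)
#'   and `rg` (frame, rg).
#' @export
basic_descriptors <- function(traj, selection = seq_len(natoms(traj))) {
  if (length(selection) == 0L) stop("empty selection")
  inds <- xyz_inds(selection)
  fitted <- superpose_frames(traj$xyz, selection)[, inds, drop = FALSE]
  nf <- nrow(fitted); na <- length(selection)
  ref <- fitted[1L, ]
  rmsd <- sqrt(rowSums(sweep(fitted, 2L, ref)^2) / na)
  mstr <- colMeans(fitted)
  dev2 <- sweep(fitted, 2L, mstr)^2
  # per-atom mean squared deviation: sum x,y,z columns of each atom
  msd_atom <- sapply(seq_len(na), function(a)
    mean(rowSums(dev2[, (3 * a - 2):(3 * a), drop = FALSE])))
  rg <- apply(traj$xyz[, inds, drop = FALSE], 1L, function(row) {
    m <- matrix(row, ncol = 3L, byrow = TRUE)
    sqrt(mean(rowSums(sweep(m, 2L, colMeans(m))^2)))
  })
  list(rmsd = data.frame(frame = seq_len(nf) - 1L, rmsd = rmsd),
       rmsf = data.frame(atom = selection, rmsf = sqrt(msd_atom)),
       rg = data.frame(frame = seq_len(nf) - 1L, rg = rg))
}

distance_series <- function(values, name) {
  structure(list(name = name, values = as.numeric(values),
                 summary = stats::quantile(values, c(0.25, 0.5, 0.75),
                                           names = FALSE)),
            class = "distance_series")
}

#' @export
print.distance_series <- function(x, ...) {
  cat(sprintf("%s: n = %d, median %.3f nm (IQR %.3f-%.3f)\n", x$name,
              length(x$values), x$summary[2L], x$summary[1L], x$summary[3L]))
  invisible(x)
}

#' CH2-domain opening distance
#'
#' Per-frame distance between the C-alpha atoms of the two glycosylated Asn
#' residues (one per CH2 domain) -- the proxy for an open vs closed Fc.
#'
#' @param traj a `traj_ensemble`.
#' @param groups an [atom_groups()] object with `glyco_Asn_A`, `glyco_Asn_B`.
#' @return a `distance_series` (nm) with median/quartile summary.
#' @export
ch2_distance <- function(traj, groups) {
  for (nm in c("glyco_Asn_A", "glyco_Asn_B"))
    if (is.null(groups[[nm]]) || length(groups[[nm]]) == 0L)
      stop("group '", nm, "' is required for the CH2 distance")
  d <- vapply(seq_len(nframes(traj)), function(f) {
    co <- frame_coords(traj$xyz, f)
    vnorm(group_centroid(co, groups$glyco_Asn_A) -
          group_centroid(co, groups$glyco_Asn_B))
  }, numeric(1))
  distance_series(d, "CH2 distance")
}

#' Minimum heavy-atom distance between the two glycan chains
#'
#' @param traj a `traj_ensemble`.
#' @param groups an [atom_groups()] object with `glycan_A`, `glycan_B`.
#' @return a `distance_series` (nm).
#' @export
glycan_min_distance <- function(traj, groups) {
  ga <- groups$glycan_A; gb <- groups$glycan_B
  if (is.null(ga) || is.null(gb) || !length(ga) || !length(gb))
    stop("glycan_A and glycan_B groups must be non-empty")
  ga <- ga[traj$top$elesy[ga] != "H"]
  gb <- gb[traj$top$elesy[gb] != "H"]
  d <- vapply(seq_len(nframes(traj)), function(f) {
    co <- frame_coords(traj$xyz, f)
    a <- co[ga, , drop = FALSE]; b <- co[gb, , drop = FALSE]
    # squared distances of all pairs via the expansion |a-b|^2 = |a|^2+|b|^2-2ab
    d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
    sqrt(max(0, min(d2)))
  }, numeric(1))
  distance_series(d, "glycan min distance")
}

#' Glycan centre-of-mass displacement after Fc alignment
#'
#' Frames are superposed onto the first analyzed frame using the Fc
#' selection; the descriptor is then, per chain and frame, the distance of
#' the glycan centre of mass from its position in that reference frame. A
#' mobile glycan explores large values; one parked in the Fc cleft stays
#' near zero.
#'
#' @param traj a `traj_ensemble`.
#' @param groups an [atom_groups()] object with `glycan_A`, `glycan_B`, `Fc`.
#' @param frames optional frame subset (e.g. the minimum-energy set); frame 1
#'   of the subset is the reference.
#' @return named list of two `distance_series` (chains A and B, nm).
#' @export
glycan_com_displacement <- function(traj, groups, frames = NULL) {
  if (length(groups$Fc) < 3L) stop("Fc selection must have >= 3 atoms")
  if (!is.null(frames)) traj <- subset_frames(traj, frames)
  fitted <- superpose_frames(traj$xyz, groups$Fc)
  one <- function(g, label) {
    if (is.null(g) || !length(g)) stop("glycan group missing")
    com <- t(vapply(seq_len(nrow(fitted)), function(f)
      group_centroid(matrix(fitted[f, ], ncol = 3L, byrow = TRUE), g),
      numeric(3)))
    distance_series(sqrt(rowSums(sweep(com, 2L, com[1L, ])^2)), label)
  }
  list(A = one(groups$glycan_A, "glycan A com displacement"),
       B = one(groups$glycan_B, "glycan B com displacement"))
}

#' Heavy-atom contacts between two residue groups
#'
#' For each residue contributing atoms to `group_A`, counts per frame the
#' heavy-atom pairs (one atom in that residue, one in `group_B`) within the
#' cutoff. Default 0.4 nm (4 Angstrom). Hydrogens are excluded.
#'
#' @param traj a `traj_ensemble`.
#' @param group_A,group_B atom index vectors (e.g. LC C-terminal residues vs
#'   hinge).
#' @param cutoff contact distance in nm.
#' @return list (class `contact_table`) with `counts` (frames x residues
#'   matrix), `residues` (data.frame chain/resno), `cutoff`.
#' @export
residue_contacts <- function(traj, group_A, group_B, cutoff = 0.4) {
  if (!length(group_A) || !length(group_B)) stop("contact groups must be non-empty")
  top <- traj$top
  group_A <- group_A[top$elesy[group_A] != "H"]
  group_B <- group_B[top$elesy[group_B] != "H"]
  key <- paste(top$chain[group_A], top$resno[group_A])
  resids <- !duplicated(key)
  res_atoms <- split(group_A, factor(key, levels = key[resids]))
  nf <- nframes(traj)
  counts <- matrix(0L, nf, length(res_atoms),
                   dimnames = list(NULL, names(res_atoms)))
  for (f in seq_len(nf)) {
    co <- frame_coords(traj$xyz, f)
    b <- co[group_B, , drop = FALSE]
    for (r in seq_along(res_atoms)) {
      a <- co[res_atoms[[r]], , drop = FALSE]
      d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
      counts[f, r] <- sum(d2 <= cutoff^2 + 1e-12)
    }
  }
  structure(list(counts = counts,
                 residues = data.frame(chain = top$chain[group_A][resids],
                                       resno = top$resno[group_A][resids]),
                 cutoff = cutoff),
            class = "contact_table")
}

# covalently bonded donor-H pairs: an H within bond_cut of an N/O/S heavy atom
find_donor_pairs <- function(top, coords0, bond_cut = 0.115) {
  hyd <- which(top$elesy == "H")
  heavy <- which(top$elesy %in% c("N", "O", "S"))
  if (!length(hyd)) stop("topology contains no hydrogens; hydrogen-bond ",
                         "analysis needs explicit H atoms and elements")
  pairs <- NULL
  for (h in hyd) {
    d <- sqrt(colSums((t(coords0[heavy, , drop = FALSE]) - coords0[h, ])^2))
    j <- which.min(d)
    if (d[j] <= bond_cut) pairs <- rbind(pairs, c(heavy[j], h))
  }
  if (is.null(pairs)) stop("no donor-H pairs found within ", bond_cut, " nm")
  pairs
}

#' Geometric hydrogen-bond detection
#'
#' Donor-H pairs are inferred from the first frame (H covalently bound to
#' N/O/S); acceptors are all N/O/S heavy atoms. A bond is counted when the
#' donor-acceptor distance is at most `dist_cutoff` and the D-H...A angle is
#' at least `angle_cutoff` (Baker-Hubbard-style geometric criterion; the
#' exact thresholds are configurable). Frequencies are reported per unique
#' (donor residue, acceptor residue) pair over the analyzed frames.
#'
#' @param traj a `traj_ensemble` whose topology includes hydrogens.
#' @param frames optional frame subset (e.g. the minimum-energy set).
#' @param dist_cutoff donor-acceptor distance cutoff, nm (default 0.35).
#' @param angle_cutoff minimum D-H...A angle, degrees (default 120).
#' @return data.frame (class `hbond_table`): donor_chain, donor_res,
#'   acceptor_chain, acceptor_res, frequency in \[0, 1\], sorted by
#'   decreasing frequency.
#' @export
hydrogen_bonds <- function(traj, frames = NULL, dist_cutoff = 0.35,
                           angle_cutoff = 120) {
  if (!is.null(frames)) traj <- subset_frames(traj, frames)
  top <- traj$top
  dp <- find_donor_pairs(top, frame_coords(traj$xyz, 1L))
  acc <- which(top$elesy %in% c("N", "O", "S"))
  nf <- nframes(traj)
  hits <- new.env(parent = emptyenv())
  cosmax <- cos(angle_cutoff / .deg)
  for (f in seq_len(nf)) {
    co <- frame_coords(traj$xyz, f)
    seen <- character(0)
    for (p in seq_len(nrow(dp))) {
      dA <- dp[p, 1L]; hA <- dp[p, 2L]
      a_ok <- acc[acc != dA]
      dv <- t(co[a_ok, , drop = FALSE]) - co[dA, ]
      dist <- sqrt(colSums(dv^2))
      close <- which(dist <= dist_cutoff)
      for (ai in close) {
        a <- a_ok[ai]
        u <- co[hA, ] - co[dA, ]
        v <- co[a, ] - co[hA, ]
        # D-H...A angle: 180 deg when collinear
        cosang <- -sum(u * v) / (vnorm(u) * vnorm(v))
        if (cosang <= cosmax) {
          key <- paste(top$chain[dA], top$resno[dA],
                       top$chain[a], top$resno[a], sep = "|")
          if (!(key %in% seen)) {
            seen <- c(seen, key)
            hits[[key]] <- (if (is.null(hits[[key]])) 0L else hits[[key]]) + 1L
          }
        }
      }
    }
  }
  keys <- ls(hits)
  if (!length(keys)) {
    out <- data.frame(donor_chain = character(0), donor_res = integer(0),
                      acceptor_chain = character(0), acceptor_res = integer(0),
                      frequency = numeric(0))
  } else {
    parts <- do.call(rbind, strsplit(keys, "|", fixed = TRUE))
    out <- data.frame(donor_chain = parts[, 1L],
                      donor_res = as.integer(parts[, 2L]),
                      acceptor_chain = parts[, 3L],
                      acceptor_res = as.integer(parts[, 4L]),
                      frequency = vapply(keys, function(k) hits[[k]],
                                         integer(1)) / nf)
    out <- out[order(-out$frequency), , drop = FALSE]
    rownames(out) <- NULL
  }
  class(out) <- c("hbond_table", "data.frame")
  out
}

#' Glycosidic phi/psi torsions per linkage
#'
#' Each linkage names the four atoms of its phi torsion and the four of its
#' psi torsion (by chain, residue number and atom name). Optionally a
#' reference (allowed) range per torsion gives the fraction of frames inside
#' it, the check used to validate sampled glycan conformations against
#' experimentally derived ranges.
#'
#' @param traj a `traj_ensemble`.
#' @param linkages list of linkage specs: each a list with `name`, `phi` and
#'   `psi` (each a list of four `c(chain, resno, atom)` triplets or explicit
#'   atom indices), and optional `phi_range`, `psi_range` (length-2 degree
#'   intervals).
#' @param frames optional frame subset.
#' @return list (class `dihedral_series`) with `angles` (long data.frame:
#'   frame, linkage, phi, psi) and `fractions` (per linkage, fraction of
#'   frames with both torsions inside their reference range; NA when no
#'   range given).
#' @export
glycosidic_dihedrals <- function(traj, linkages, frames = NULL) {
  if (!is.null(frames)) traj <- subset_frames(traj, frames)
  top <- traj$top
  resolve <- function(spec, linkname) {
    vapply(spec, function(at) {
      if (is.numeric(at) && length(at) == 1L) return(as.integer(at))
      i <- which(top$chain == at[[1L]] & top$resno == as.integer(at[[2L]]) &
                 trimws(top$elety) == at[[3L]])
      if (length(i) != 1L)
        stop("linkage '", linkname, "': atom ", paste(unlist(at), collapse = " "),
             " matches ", length(i), " atoms")
      i
    }, integer(1))
  }
  nf <- nframes(traj)
  rows <- vector("list", length(linkages))
  fracs <- numeric(length(linkages))
  names(fracs) <- vapply(linkages, `[[`, "", "name")
  for (L in seq_along(linkages)) {
    lk <- linkages[[L]]
    ip <- resolve(lk$phi, lk$name); is_ <- resolve(lk$psi, lk$name)
    phi <- psi <- numeric(nf)
    for (f in seq_len(nf)) {
      co <- frame_coords(traj$xyz, f)
      phi[f] <- dihedral_deg(co[ip[1], ], co[ip[2], ], co[ip[3], ], co[ip[4], ])
      psi[f] <- dihedral_deg(co[is_[1], ], co[is_[2], ], co[is_[3], ], co[is_[4], ])
    }
    inr <- function(x, r) if (is.null(r)) rep(NA, length(x)) else
      x >= r[1L] & x <= r[2L]
    okp <- inr(phi, lk$phi_range); oks <- inr(psi, lk$psi_range)
    fracs[L] <- if (all(is.na(okp)) && all(is.na(oks))) NA_real_ else
      mean((if (all(is.na(okp))) TRUE else okp) &
           (if (all(is.na(oks))) TRUE else oks))
    rows[[L]] <- data.frame(frame = seq_len(nf) - 1L, linkage = lk$name,
                            phi = phi, psi = psi)
  }
  structure(list(angles = do.call(rbind, rows), fractions = fracs),
            class = "dihedral_series")
}
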
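#' Accelerated-MD boost parameters
#'
#' Dual-boost aMD thresholds and acceleration factors from average dihedral
#' and total potential energies of a short conventional run:
#' EthreshD = DIHED + 4 kcal/mol/residue * residues,
#' alphaD = (1/5) * 4 kcal/mol/residue * residues,
#' EthreshP = EPTOT + 0.16 kcal/mol/atom * atoms,
#' alphaP = 0.16 kcal/mol/atom * atoms.
#'
#' @param dihed average dihedral energy DIHED (kcal/mol).
#' @param eptot average total potential energy EPTOT (kcal/mol).
#' @param solute_residues number of solute residues (> 0).
#' @param n_atoms total number of atoms (> 0).
#' @return list (class `amd_params`) with the inputs and `EthreshD`,
#'   `alphaD`, `EthreshP`, `alphaP` (kcal/mol).
#' @export
compute_amd_params <- function(dihed, eptot, solute_residues, n_atoms) {
  if (!is.finite(dihed) || !is.finite(eptot))
    stop("energies must be finite")
  if (solute_residues <= 0 || n_atoms <= 0)
    stop("solute_residues and n_atoms must be positive")
  structure(list(
    DIHED = dihed, EPTOT = eptot,
    solute_residues = solute_residues, n_atoms = n_atoms,
    EthreshD = dihed + 4 * solute_residues,
    alphaD = (1 / 5) * 4 * solute_residues,
    EthreshP = eptot + 0.16 * n_atoms,
    alphaP = 0.16 * n_atoms), class = "amd_params")
}

#' Per-frame boost record
#'
#' @param dV per-frame total boost energy (kcal/mol, >= 0).
#' @param temperature simulation temperature in K (default 300).
#' @return data.frame (class `boost_record`) with `frame`, `dV`,
#'   `temperature`.
#' @export
boost_record <- function(dV, temperature = 300) {
  if (any(!is.finite(dV))) stop("non-finite boost energies")
  if (any(dV < 0)) stop("boost energies must be >= 0")
  res <- data.frame(frame = seq_along(dV) - 1L, dV = as.numeric(dV),
                    temperature = temperature)
  class(res) <- c("boost_record", "data.frame")
  res
}

#' Read a boost-energy log
#'
#' Two dialects: (i) plain two-column text `frame dV` (kcal/mol), comments
#' starting with `#`; (ii) AMBER-style aMD logs with >= 8 numeric columns,
#' whose last two columns are the potential and dihedral boost energies --
#' these are summed into the total per-frame boost, matching a dual-boost
#' run.
#'
#' @param path file path.
#' @param temperature simulation temperature in K.
#' @return a [boost_record()].
#' @export
read_boost_log <- function(path, temperature = 300) {
  tab <- utils::read.table(path, comment.char = "#")
  dV <- if (ncol(tab) >= 8L) {
    tab[[ncol(tab) - 1L]] + tab[[ncol(tab)]]
  } else if (ncol(tab) == 2L) {
    tab[[2L]]
  } else stop("unrecognised boost log layout: ", ncol(tab), " columns")
  boost_record(dV, temperature = temperature)
}

#' Maclaurin-series reweighting factors
#'
#' Truncated Maclaurin expansion of exp(beta dV): sum_{k=0..k_max}
#' (beta dV)^k / k!. Truncation tames the noise amplification of exact
#' exponential reweighting at the cost of a small, quantifiable bias.
#'
#' @param dV boost energies (kcal/mol, >= 0).
#' @param temperature temperature in K.
#' @param k_max expansion order (>= 1).
#' @return numeric weights, with attributes `max_beta_dV` and
#'   `max_rel_dev` (largest relative deviation from exp(beta dV)).
#' @export
maclaurin_weights <- function(dV, temperature = 300, k_max = 10L) {
  if (k_max < 1L) stop("k_max must be >= 1")
  x <- dV / (.kB * temperature)
  w <- rep(1, length(x))
  term <- rep(1, length(x))
  for (k in seq_len(k_max)) {
    term <- term * x / k
    w <- w + term
  }
  exact <- exp(x)
  structure(w,
            max_beta_dV = if (length(x)) max(x) else 0,
            max_rel_dev = if (length(x)) max(abs(w - exact) / exact) else 0)
}

#' Reweighted free-energy surface over (theta1, theta2)
#'
#' Histograms the per-frame Fab latitudes on a regular 2-D grid with
#' Maclaurin reweighting factors, normalizes to a probability, and converts
#' to a potential of mean force PMF = -kT ln p shifted so the occupied-bin
#' minimum is exactly 0. Empty bins carry PMF = +Inf.
#'
#' @param angles a `fab_angles` data.frame.
#' @param boost a [boost_record()] aligned frame-for-frame with `angles`,
#'   or NULL for an unbiased (all-weights-1) surface.
#' @param breaks bin edges in degrees applied to both axes (default 2.5-degree
#'   bins over \[0, 180\], fine enough to resolve the 85-degree shape
#'   threshold).
#' @param k_max Maclaurin order (default 10).
#' @param temperature temperature in K used for beta and the PMF scale; if
#'   NULL, taken from `boost` (300 K when unbiased).
#' @return list (class `fes_grid`) with `breaks`, matrices `prob`, `pmf` and
#'   `neff` (Kish effective sample count per bin, (sum w)^2 / sum w^2)
#'   (theta1 bins in rows), per-frame bin indices `bin1`/`bin2`, `k_max`,
#'   `kT`, and a `diagnostics` list (max beta dV, max relative deviation of
#'   the truncated series from the exponential, flagged when > 1%).
#' @export
reweight_fes <- function(angles, boost = NULL, breaks = seq(0, 180, by = 2.5),
                         k_max = 10L, temperature = NULL) {
  n <- nrow(angles)
  if (n == 0L) stop("no frames")
  if (is.null(boost)) {
    dV <- rep(0, n)
    if (is.null(temperature)) temperature <- 300
  } else {
    if (nrow(boost) != n)
      stop("angles (", n, ") and boost record (", nrow(boost),
           ") differ in frame count")
    dV <- boost$dV
    if (is.null(temperature)) temperature <- boost$temperature[1L]
  }
  w <- maclaurin_weights(dV, temperature = temperature, k_max = k_max)
  max_rel_dev <- attr(w, "max_rel_dev")
  if (max_rel_dev > 0.01)
    warning(sprintf(paste0("truncated Maclaurin series deviates from exp(beta dV) ",
                           "by up to %.1f%% (max beta dV = %.2f); consider a ",
                           "higher order or check the boost energies"),
                    100 * max_rel_dev, attr(w, "max_beta_dV")))
  nb <- length(breaks) - 1L
  bin_of <- function(th) {
    b <- findInterval(th, breaks, rightmost.closed = TRUE)
    if (any(b < 1L | b > nb)) stop("theta values fall outside the bin range")
    b
  }
  b1 <- bin_of(angles$theta1)
  b2 <- bin_of(angles$theta2)
  wsum <- matrix(0, nb, nb)
  w2sum <- matrix(0, nb, nb)
  for (f in seq_len(n)) {
    wsum[b1[f], b2[f]] <- wsum[b1[f], b2[f]] + w[f]
    w2sum[b1[f], b2[f]] <- w2sum[b1[f], b2[f]] + w[f]^2
  }
  prob <- wsum / sum(w)
  neff <- matrix(0, nb, nb)
  occ0 <- w2sum > 0
  neff[occ0] <- wsum[occ0]^2 / w2sum[occ0]
  kT <- .kB * temperature
  pmf <- matrix(Inf, nb, nb)
  occ <- prob > 0
  pmf[occ] <- -kT * log(prob[occ])
  pmf[occ] <- pmf[occ] - min(pmf[occ])
  structure(list(breaks = breaks, prob = prob, pmf = pmf, neff = neff,
                 bin1 = b1, bin2 = b2, weights = as.numeric(w),
                 k_max = k_max, temperature = temperature, kT = kT,
                 diagnostics = list(max_beta_dV = attr(w, "max_beta_dV"),
                                    max_rel_dev = max_rel_dev,
                                    series_ok = max_rel_dev <= 0.01)),
            class = "fes_grid")
}

#' Frames belonging to the free-energy minimum region
#'
#' Returns all frames whose (theta1, theta2) bin has PMF below the cutoff.
#' Because the surface is normalized to a zero minimum, the set is never
#' empty for a positive cutoff.
#'
#' @param grid a [reweight_fes()] result.
#' @param cutoff PMF cutoff in kcal/mol (> 0); default 0.5.
#' @return integer vector of 1-based frame indices.
#' @export
select_min_energy_frames <- function(grid, cutoff = 0.5) {
  if (!is.finite(cutoff) || cutoff <= 0) stop("cutoff must be > 0")
  sel <- grid$pmf[cbind(grid$bin1, grid$bin2)] < cutoff
  which(sel)
}
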
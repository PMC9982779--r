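#' Specification for the synthetic toy antibody
#'
#' Describes a pseudo-atomic, hinge-linked three-domain antibody (Fc slab
#' with two CH2 blobs and glycosylated Asn markers, hinge, two Fab arms, two
#' glycan chains) plus the statistical laws its per-frame geometry follows.
#' Every pipeline stage can be exercised on the resulting ensembles, with
#' ground truth emitted alongside.
#'
#' @param n_frames number of frames.
#' @param seed mandatory RNG seed; generation is fully deterministic given it.
#' @param angle_law per-frame law of the Fab latitude/longitude angles. One
#'   of: `list(type = "mixture", weights = c(T=,Y=,asym=), theta_T = c(mean=,
#'   sd=), theta_Y = c(mean=, sd=), phi = list(mean = c(,), sd =))` where
#'   T draws both latitudes from the (truncated, >= 85) high component and Y
#'   both from the low (< 85) one; `list(type = "fixed", theta1=, theta2=,
#'   phi1=, phi2=)` with scalars or per-frame vectors; or `list(type =
#'   "ramp", theta1=, theta2=, phi_start = c(,), phi_rate = c(,))` with rates
#'   in degrees/frame.
#' @param ch2 `c(mean=, sd=)` of the CH2 (glycosylated-Asn) distance, nm.
#' @param glycan list: `inside` (logical; chains parked in the Fc cleft vs
#'   outside), `jitter` (sd of the per-frame rigid displacement of each
#'   chain, nm), `fucose` (logical; add the core-fucose pseudo-atom).
#' @param fab_radius distance of each Fab centroid from the hinge, nm.
#' @param lc_sd sd of the per-frame radial breathing of the light-chain
#'   C-terminal residues toward/away from the hinge (drives contact counts).
#' @param hbond NULL, or `list(occupancy=)` to plant a donor-H/acceptor
#'   triplet hydrogen-bonded in exactly that fraction of frames.
#' @param rigid_motion apply a random global rotation + translation to every
#'   frame (all descriptors must be invariant to it).
#' @param time_step frame spacing, ns.
#' @return validated spec, class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_frames = 1000L, seed,
                           angle_law = list(type = "mixture",
                                            weights = c(T = 1/3, Y = 1/3, asym = 1/3),
                                            theta_T = c(mean = 100, sd = 5),
                                            theta_Y = c(mean = 70, sd = 5),
                                            phi = list(mean = c(90, -90), sd = 20)),
                           ch2 = c(mean = 4.0, sd = 0.3),
                           glycan = list(inside = FALSE, jitter = 0.05,
                                         fucose = FALSE),
                           fab_radius = 4.0, lc_sd = 0.15,
                           hbond = NULL, rigid_motion = FALSE,
                           time_step = 0.1) {
  if (missing(seed)) stop("a seed is mandatory for the synthetic generator")
  if (n_frames < 1L) stop("n_frames must be >= 1")
  if (ch2[["sd"]] < 0 || ch2[["mean"]] <= 0) stop("invalid CH2 law")
  if (fab_radius <= 1.5) stop("fab_radius must exceed the arm half-length")
  if (identical(angle_law$type, "mixture")) {
    w <- angle_law$weights
    if (abs(sum(w) - 1) > 1e-9 || any(w < 0))
      stop("mixture weights must be non-negative and sum to 1")
  }
  if (is.null(glycan$fucose)) glycan$fucose <- FALSE
  if (is.null(glycan$jitter)) glycan$jitter <- 0.05
  if (!is.null(hbond) && (hbond$occupancy < 0 || hbond$occupancy > 1))
    stop("hbond occupancy must be in [0, 1]")
  structure(list(n_frames = as.integer(n_frames), seed = as.integer(seed),
                 angle_law = angle_law, ch2 = ch2, glycan = glycan,
                 fab_radius = fab_radius, lc_sd = lc_sd, hbond = hbond,
                 rigid_motion = isTRUE(rigid_motion), time_step = time_step),
            class = "synthetic_spec")
}

rtrunc_norm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  lo <- stats::pnorm(lower, mean, sd); hi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(lo + stats::runif(n) * (hi - lo), mean, sd)
}

sample_angle_law <- function(law, n) {
  if (identical(law$type, "mixture")) {
    comp <- sample(c("T", "Y", "asym"), n, replace = TRUE, prob = law$weights)
    hi <- function(m) rtrunc_norm(m, law$theta_T[["mean"]], law$theta_T[["sd"]],
                                  lower = 85, upper = 180)
    lo <- function(m) rtrunc_norm(m, law$theta_Y[["mean"]], law$theta_Y[["sd"]],
                                  lower = 0, upper = 85 - 1e-9)
    th1 <- th2 <- numeric(n)
    iT <- comp == "T"; iY <- comp == "Y"; iA <- comp == "asym"
    th1[iT] <- hi(sum(iT)); th2[iT] <- hi(sum(iT))
    th1[iY] <- lo(sum(iY)); th2[iY] <- lo(sum(iY))
    th1[iA] <- hi(sum(iA)); th2[iA] <- lo(sum(iA))
    ph1 <- wrap_deg(stats::rnorm(n, law$phi$mean[1L], law$phi$sd))
    ph2 <- wrap_deg(stats::rnorm(n, law$phi$mean[2L], law$phi$sd))
    data.frame(theta1 = th1, theta2 = th2, phi1 = ph1, phi2 = ph2,
               label = comp)
  } else if (identical(law$type, "fixed")) {
    data.frame(theta1 = rep_len(law$theta1, n), theta2 = rep_len(law$theta2, n),
               phi1 = rep_len(law$phi1, n), phi2 = rep_len(law$phi2, n),
               label = "fixed")
  } else if (identical(law$type, "ramp")) {
    f <- seq_len(n) - 1
    data.frame(theta1 = rep_len(law$theta1, n), theta2 = rep_len(law$theta2, n),
               phi1 = wrap_deg(law$phi_start[1L] + law$phi_rate[1L] * f),
               phi2 = wrap_deg(law$phi_start[2L] + law$phi_rate[2L] * f),
               label = "ramp")
  } else stop("unknown angle law type: ", law$type)
}

# static topology table + per-frame coordinate builder for the toy antibody
.toy_topology <- function(spec) {
  at <- function(elety, resid, chain, resno, elesy = "C")
    data.frame(elety = elety, resid = resid, chain = chain, resno = resno,
               elesy = elesy)
  rows <- list(); groups <- list(); idx <- 0L
  add <- function(df, group = NULL) {
    rows[[length(rows) + 1L]] <<- df
    ids <- idx + seq_len(nrow(df)); idx <<- idx + nrow(df)
    for (g in group) groups[[g]] <<- c(groups[[g]], ids)
    ids
  }
  add(at("CA", "HNG", c("A", "A", "B", "B"), c(220L, 221L, 220L, 221L)), "hinge")
  add(at("CA", "FCC", rep(c("A", "B"), each = 8L), rep(230:237, 2L)), "Fc")
  add(at("CA", "CH2", "A", 260:262), "CH2_A")
  add(at("CA", "CH2", "B", 260:262), "CH2_B")
  add(at("CA", "ASN", "A", 297L), "glyco_Asn_A")
  add(at("CA", "ASN", "B", 297L), "glyco_Asn_B")
  add(at("CA", "FAB", c("A", "A", "A", "L", "L", "L"), 10:15), "Fab1")
  add(at("CA", "FAB", c("B", "B", "B", "M", "M", "M"), 10:15), "Fab2")
  add(at(rep(c("CA", "CB"), 3L), "LCC", "L", rep(212:214, each = 2L)), "LC_cterm")
  add(at(rep(c("CA", "CB"), 3L), "LCC", "M", rep(212:214, each = 2L)))
  ng <- 5L
  add(at(rep(c("C1", "O4"), ng), "SUG", "C", rep(seq_len(ng), each = 2L),
         rep(c("C", "O"), ng)), "glycan_A")
  add(at(rep(c("C1", "O4"), ng), "SUG", "D", rep(seq_len(ng), each = 2L),
         rep(c("C", "O"), ng)), "glycan_B")
  if (isTRUE(spec$glycan$fucose)) {
    add(at("C1", "FUC", "C", 6L), "glycan_A")
    add(at("C1", "FUC", "D", 6L), "glycan_B")
  }
  if (!is.null(spec$hbond)) {
    add(at(c("OD", "HD"), "DON", "C", 50L, c("O", "H")))
    add(at("OA", "ACC", "A", 250L, "O"))
  }
  top <- do.call(rbind, rows)
  rownames(top) <- NULL
  list(top = top, groups = groups)
}

.toy_frame_coords <- function(spec, top, th1, ph1, th2, ph2, d, gshift_A,
                              gshift_B, lc_scale, hbonded) {
  n <- nrow(top)
  co <- matrix(0, n, 3L)
  i <- 0L
  put <- function(m) {
    m <- rbind(m)
    co[i + seq_len(nrow(m)), ] <<- m
    i <<- i + nrow(m)
  }
  # hinge (centroid exactly at the origin)
  put(rbind(c(0.15, 0, 0.1), c(-0.15, 0, 0.1),
            c(0.15, 0, -0.1), c(-0.15, 0, -0.1)))
  # Fc column along -z
  for (sx in c(-0.35, 0.35))
    put(cbind(sx, 0, -0.7 - 0.45 * (0:7)))
  # CH2 blobs tied to the Asn positions
  off <- rbind(c(0, 0.2, 0), c(0, -0.2, 0.15), c(0, 0, -0.15))
  for (s in c(-1, 1))
    put(sweep(off, 2L, c(s * (d / 2 + 0.3), 0, -1.3), "+"))
  # glycosylated Asn C-alpha markers
  put(c(-d / 2, 0, -1.3)); put(c(d / 2, 0, -1.3))
  # Fab arms: collinear atoms along the prescribed direction from the hinge
  radii <- spec$fab_radius + c(-1, -0.6, -0.2, 0.2, 0.6, 1)
  dir_of <- function(th, ph) {
    t <- th / .deg; p <- ph / .deg
    c(sin(t) * cos(p), sin(t) * sin(p), cos(t))
  }
  put(outer(radii, dir_of(th1, ph1)))
  put(outer(radii, dir_of(th2, ph2)))
  # LC C-terminal residues breathing radially about the hinge
  lc_base <- rbind(c(-0.10, 0.42, 0.15), c(-0.10, 0.30, 0.15),
                   c(0.02, 0.45, 0.18), c(0.02, 0.33, 0.18),
                   c(0.14, 0.48, 0.21), c(0.14, 0.36, 0.21))
  put(lc_base * lc_scale)
  put(sweep(lc_base * lc_scale, 2L, c(1, -1, 1), "*"))
  # glycan chains rooted at the Asn, growing inward or outward
  gx_dir <- if (isTRUE(spec$glycan$inside)) 1 else -1
  gly <- function(side, shift) {
    root <- c(side * d / 2 - side * gx_dir * 0.4, 0.3, -1.5)
    m <- NULL
    for (su in 0:4) {
      c1 <- root + c(-side * gx_dir * 0.15 * su, 0.12 * su, -0.1 * su)
      m <- rbind(m, c1, c1 + c(0.06, 0.06, -0.06))
    }
    sweep(m, 2L, shift, "+")
  }
  put(gly(-1, gshift_A)); put(gly(1, gshift_B))
  if (isTRUE(spec$glycan$fucose)) {
    put(c(-d / 2 + gx_dir * 0.4, 0, -1.7) + gshift_A)
    put(c(d / 2 - gx_dir * 0.4, 0, -1.7) + gshift_B)
  }
  if (!is.null(spec$hbond)) {
    q <- c(0, 1.6, -0.5)
    put(rbind(q, q + c(0, 0.1, 0)))
    put(q + c(0, if (hbonded) 0.3 else 1.3, 0))
  }
  stopifnot(i == n)
  co
}

#' Generate a synthetic toy-antibody trajectory with ground truth
#'
#' Builds the pseudo-atomic topology, draws per-frame Fab angles, CH2
#' distance and glycan displacements from the laws in the spec, assembles
#' coordinates (optionally behind a random global rigid motion per frame),
#' and returns the ensemble together with the generating truth so round-trip
#' tests can compare recovered against prescribed values.
#'
#' @param spec a [synthetic_spec()].
#' @return list: `traj` (a `traj_ensemble`), `groups` ([atom_groups()]),
#'   `truth` (data.frame: frame, theta1/2, phi1/2, label, ch2, hbond) and
#'   `spec`.
#' @export
generate_toy_mab <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  n <- spec$n_frames
  ang <- sample_angle_law(spec$angle_law, n)
  d <- rtrunc_norm(n, spec$ch2[["mean"]], spec$ch2[["sd"]], lower = 1.2)
  lc <- rtrunc_norm(n, 1, spec$lc_sd, lower = 0.5)
  gj <- spec$glycan$jitter
  gA <- matrix(stats::rnorm(3 * n, 0, gj), n, 3L)
  gB <- matrix(stats::rnorm(3 * n, 0, gj), n, 3L)
  hb <- rep(FALSE, n)
  if (!is.null(spec$hbond)) {
    k <- round(spec$hbond$occupancy * n)
    hb[sample(n, k)] <- TRUE
  }
  tp <- .toy_topology(spec)
  xyz <- matrix(NA_real_, n, 3L * nrow(tp$top))
  for (f in seq_len(n)) {
    co <- .toy_frame_coords(spec, tp$top, ang$theta1[f], ang$phi1[f],
                            ang$theta2[f], ang$phi2[f], d[f],
                            gA[f, ], gB[f, ], lc[f], hb[f])
    if (spec$rigid_motion)
      co <- sweep(co %*% t(random_rotation()), 2L, stats::rnorm(3, 0, 2), "+")
    xyz[f, ] <- coords_to_row(co)
  }
  truth <- data.frame(frame = seq_len(n) - 1L, ang, ch2 = d, hbond = hb)
  list(traj = traj_ensemble(tp$top, xyz,
                            time = (seq_len(n) - 1L) * spec$time_step),
       groups = atom_groups(tp$groups, nrow(tp$top)),
       truth = truth, spec = spec)
}

#' Write a generated toy system to disk
#'
#' Emits `topology.pdb`, a multi-model `traj.pdb`, `groups.yml` (0-based
#' indices) and `truth/truth.csv` under `dir`.
#'
#' @param toy result of [generate_toy_mab()].
#' @param dir output directory (created if missing).
#' @return invisibly, the paths written.
#' @export
write_toy_mab <- function(toy, dir) {
  dir.create(file.path(dir, "truth"), recursive = TRUE, showWarnings = FALSE)
  paths <- list(topology = file.path(dir, "topology.pdb"),
                traj = file.path(dir, "traj.pdb"),
                groups = file.path(dir, "groups.yml"),
                truth = file.path(dir, "truth", "truth.csv"))
  write_traj_pdb(toy$traj, paths$topology, paths$traj)
  yaml::write_yaml(lapply(unclass(toy$groups), function(g) as.integer(g) - 1L),
                   paths$groups)
  utils::write.csv(toy$truth, paths$truth, row.names = FALSE)
  invisible(paths)
}

#' Boosted angle ensembles with an analytically known unbiased density
#'
#' Draws (theta1, theta2) from the boosted-ensemble density proportional to
#' p0 * exp(-beta dV) by rejection sampling -- the boost flattens basins, so
#' heavily boosted regions are undersampled relative to p0 and the unbiased
#' statistics are recovered by reweighting with exp(+beta dV). p0 is a mixture of
#' independent bivariate normals truncated to \[0, 180\]^2 and dV is a
#' bounded Gaussian bump (kcal/mol). Because p0 is analytic, the exact
#' unbiased per-bin probabilities (and hence the reference PMF) are available
#' in closed form via [analytic_bin_pmf()].
#'
#' @param n number of samples.
#' @param seed RNG seed.
#' @param p0 list of mixture components, each `list(w=, mean=c(,), sd=c(,))`.
#' @param dV boost model `list(A=, center=c(,), width=)`: dV(theta) =
#'   A exp(-|theta-center|^2 / (2 width^2)), so 0 <= dV <= A.
#' @param temperature temperature in K.
#' @return list: `angles` (fab_angles-style data.frame with phi set to 0),
#'   `boost` (a [boost_record()]), `p0`, `dV`, `temperature`, `efficiency`.
#' @export
generate_boosted_samples <- function(n = 50000L, seed,
                                     p0 = list(list(w = 0.65, mean = c(75, 72), sd = c(9, 9)),
                                               list(w = 0.35, mean = c(105, 102), sd = c(9, 9))),
                                     dV = list(A = 1.5, center = c(90, 90), width = 25),
                                     temperature = 300) {
  if (missing(seed)) stop("a seed is mandatory")
  stopifnot(abs(sum(vapply(p0, `[[`, 0, "w")) - 1) < 1e-9, dV$A >= 0)
  set.seed(seed)
  kT <- .kB * temperature
  dV_fun <- function(t1, t2)
    dV$A * exp(-((t1 - dV$center[1L])^2 + (t2 - dV$center[2L])^2) /
                 (2 * dV$width^2))
  th1 <- th2 <- numeric(0); tried <- 0L
  while (length(th1) < n) {
    m <- max(2L * (n - length(th1)), 1000L)
    comp <- sample(seq_along(p0), m, replace = TRUE,
                   prob = vapply(p0, `[[`, 0, "w"))
    mu1 <- vapply(p0, function(c_) c_$mean[1L], 0)[comp]
    mu2 <- vapply(p0, function(c_) c_$mean[2L], 0)[comp]
    s1 <- vapply(p0, function(c_) c_$sd[1L], 0)[comp]
    s2 <- vapply(p0, function(c_) c_$sd[2L], 0)[comp]
    x1 <- stats::rnorm(m, mu1, s1); x2 <- stats::rnorm(m, mu2, s2)
    ok <- x1 >= 0 & x1 <= 180 & x2 >= 0 & x2 <= 180
    acc <- ok & stats::runif(m) < exp(-dV_fun(x1, x2) / kT)
    tried <- tried + m
    th1 <- c(th1, x1[acc]); th2 <- c(th2, x2[acc])
    if (tried > 1000L && length(th1) / tried < 1e-3)
      stop("rejection efficiency below 1e-3; boost too strong for sampling")
  }
  efficiency <- length(th1) / tried
  th1 <- th1[seq_len(n)]; th2 <- th2[seq_len(n)]
  angles <- data.frame(frame = seq_len(n) - 1L, theta1 = th1, theta2 = th2,
                       phi1 = 0, phi2 = 0)
  class(angles) <- c("fab_angles", "data.frame")
  list(angles = angles,
       boost = boost_record(dV_fun(th1, th2), temperature = temperature),
       p0 = p0, dV = dV, dV_fun = dV_fun, temperature = temperature,
       efficiency = efficiency)
}

#' Exact unbiased per-bin PMF of the generator density
#'
#' Closed-form bin probabilities of the truncated-normal mixture `p0` on the
#' reweighting grid (products of normal CDF differences per axis,
#' renormalized over \[0, 180\]^2), converted to a PMF shifted to a zero
#' minimum -- the reference surface reweighted estimates are compared to.
#'
#' @param breaks bin edges (degrees), as in [reweight_fes()].
#' @param p0 mixture definition as in [generate_boosted_samples()].
#' @param temperature temperature in K.
#' @return list with `prob` and `pmf` matrices (theta1 bins in rows).
#' @export
analytic_bin_pmf <- function(breaks, p0, temperature = 300) {
  nb <- length(breaks) - 1L
  prob <- matrix(0, nb, nb)
  for (c_ in p0) {
    p1 <- diff(stats::pnorm(breaks, c_$mean[1L], c_$sd[1L]))
    p2 <- diff(stats::pnorm(breaks, c_$mean[2L], c_$sd[2L]))
    z1 <- diff(stats::pnorm(c(0, 180), c_$mean[1L], c_$sd[1L]))
    z2 <- diff(stats::pnorm(c(0, 180), c_$mean[2L], c_$sd[2L]))
    prob <- prob + c_$w * outer(p1, p2) / (z1 * z2)
  }
  prob <- prob / sum(prob)
  kT <- .kB * temperature
  pmf <- matrix(Inf, nb, nb)
  occ <- prob > 0
  pmf[occ] <- -kT * log(prob[occ])
  pmf[occ] <- pmf[occ] - min(pmf[occ])
  list(prob = prob, pmf = pmf)
}

#' Study-condition presets for the four antibody systems
#'
#' Mixture weights and CH2 laws emulating, at toy scale, the reported
#' conventional-MD behaviour of the four systems: fucosylated (G0F)
#' adalimumab T-preferring with a closed Fc, afucosylated (G0) adalimumab
#' strongly Y-preferring with an open Fc, and both avelumab forms
#' Y-preferring with intermediate Fc opening.
#'
#' @return named list of argument lists for [synthetic_spec()].
#' @export
toy_study_presets <- function() {
  mk <- function(wT, wY, ch2_mean, ch2_sd, fucose, inside) {
    list(angle_law = list(type = "mixture",
                          weights = c(T = wT, Y = wY, asym = 1 - wT - wY),
                          theta_T = c(mean = 100, sd = 5),
                          theta_Y = c(mean = 70, sd = 5),
                          phi = list(mean = c(90, -90), sd = 20)),
         ch2 = c(mean = ch2_mean, sd = ch2_sd),
         glycan = list(inside = inside, jitter = 0.05, fucose = fucose))
  }
  list(adalimumab_G0F = mk(0.30, 0.20, 3.1, 0.5, TRUE, TRUE),
       adalimumab_G0  = mk(0.10, 0.50, 4.8, 0.6, FALSE, FALSE),
       avelumab_G0    = mk(0.12, 0.45, 3.7, 0.6, FALSE, FALSE),
       avelumab_G0F   = mk(0.12, 0.42, 4.1, 0.6, TRUE, TRUE))
}
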
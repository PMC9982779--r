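test_that("RMSD/RMSF vanish for identical or rigidly moved frames", {
  set.seed(3)
  base <- matrix(rnorm(30, sd = 1.5), 10, 3)
  tr <- tiny_traj(list(base, base, base))
  bd <- basic_descriptors(tr)
  expect_equal(bd$rmsd$rmsd, rep(0, 3), tolerance = 1e-9)
  expect_equal(bd$rmsf$rmsf, rep(0, 10), tolerance = 1e-9)
  moved <- lapply(1:4, function(i)
    sweep(base %*% t(rand_rotation()), 2, rnorm(3, 0, 5), "+"))
  bd2 <- basic_descriptors(tiny_traj(c(list(base), moved)))
  expect_lt(max(bd2$rmsd$rmsd), 1e-7)
  # Rg of a frame is unchanged by the rigid motion
  expect_equal(sd(bd2$rg$rg), 0, tolerance = 1e-9)
})

test_that("two-frame RMSD agrees with an independent Kabsch oracle", {
  set.seed(9)
  for (i in 1:5) {
    A <- matrix(rnorm(24), 8, 3)
    B <- A + matrix(rnorm(24, sd = 0.3), 8, 3)
    bd <- basic_descriptors(tiny_traj(list(A, B)))
    expect_equal(bd$rmsd$rmsd[2], oracle_kabsch_rmsd(A, B), tolerance = 1e-8)
  }
})

test_that("CH2 distance reports the planted geometry and is rigid-motion invariant", {
  toy <- generate_toy_mab(synthetic_spec(n_frames = 300, seed = 21,
                                         ch2 = c(mean = 3.1, sd = 0)))
  d <- ch2_distance(toy$traj, toy$groups)
  expect_equal(d$values, rep(3.1, 300), tolerance = 1e-9)
  toy2 <- generate_toy_mab(synthetic_spec(n_frames = 400, seed = 22,
                                          ch2 = c(mean = 4.8, sd = 0.3),
                                          rigid_motion = TRUE))
  d2 <- ch2_distance(toy2$traj, toy2$groups)
  expect_equal(d2$values, toy2$truth$ch2, tolerance = 1e-9)
  expect_equal(d2$summary[2], 4.8, tolerance = 0.1)
  expect_error(ch2_distance(toy$traj, atom_groups(list(
    Fc = toy$groups$Fc, Fab1 = toy$groups$Fab1, Fab2 = toy$groups$Fab2,
    hinge = toy$groups$hinge), natoms(toy$traj))), "glyco_Asn")
})

test_that("glycan minimum distance equals the exhaustive pair scan", {
  two <- tiny_traj(list(rbind(c(0, 0, 0), c(1, 0, 0))))
  g <- list(glycan_A = 1L, glycan_B = 2L)
  expect_equal(glycan_min_distance(two, g)$values, 1)
  set.seed(14)
  A <- matrix(rnorm(60), 20, 3); B <- matrix(rnorm(60, mean = 1), 20, 3)
  tr <- tiny_traj(list(rbind(A, B)))
  g2 <- list(glycan_A = 1:20, glycan_B = 21:40)
  expect_equal(glycan_min_distance(tr, g2)$values, oracle_min_dist(A, B),
               tolerance = 1e-12)
  overlap <- tiny_traj(list(rbind(A, A)))
  expect_equal(glycan_min_distance(overlap, g2)$values, 0)
})

test_that("glycan com displacement is zero for static or rigidly moved systems", {
  set.seed(8)
  fc <- matrix(rnorm(30), 10, 3)
  gly <- matrix(rnorm(12, mean = 2), 4, 3)
  static <- tiny_traj(list(rbind(fc, gly), rbind(fc, gly), rbind(fc, gly)))
  g <- list(Fc = 1:10, glycan_A = 11:14, glycan_B = 11:14)
  cd <- glycan_com_displacement(static, g)
  expect_equal(cd$A$values, rep(0, 3), tolerance = 1e-9)
  # glycan translated 2 nm with a static Fc
  shifted <- rbind(fc, sweep(gly, 2, c(2, 0, 0), "+"))
  cd2 <- glycan_com_displacement(tiny_traj(list(rbind(fc, gly), shifted)), g)
  expect_equal(cd2$A$values[2], 2, tolerance = 1e-8)
  # whole-system rigid rotation is removed by the Fc alignment
  R <- rand_rotation()
  rot <- rbind(fc, gly) %*% t(R)
  cd3 <- glycan_com_displacement(tiny_traj(list(rbind(fc, gly), rot)), g)
  expect_lt(cd3$A$values[2], 1e-7)
})

test_that("residue contacts match hand-built geometry and are cutoff-monotone", {
  # residue 1 (2 atoms) vs a 3-atom hinge: exactly 3 pairs under 0.4 nm
  a <- rbind(c(0, 0, 0), c(0.38, 0, 0))
  b <- rbind(c(0.19, 0.3, 0), c(0.38, 0.3, 0), c(5, 5, 5))
  tr <- tiny_traj(list(rbind(a, b)), resno = c(1, 1, 9, 9, 9))
  ct <- residue_contacts(tr, group_A = 1:2, group_B = 3:5, cutoff = 0.4)
  expect_equal(as.integer(ct$counts), 3L)
  far <- tiny_traj(list(rbind(a, sweep(b, 2, 10, "+"))), resno = c(1, 1, 9, 9, 9))
  expect_equal(as.integer(residue_contacts(far, 1:2, 3:5)$counts), 0L)
  co <- tiny_traj(list(rbind(a, a[1, , drop = FALSE])), resno = c(1, 1, 9))
  expect_equal(as.integer(residue_contacts(co, 1:2, 3L, cutoff = 0)$counts), 1L)
  for (cut in c(0.1, 0.3, 0.5, 1)) {
    c1 <- sum(residue_contacts(tr, 1:2, 3:5, cutoff = cut)$counts)
    c2 <- sum(residue_contacts(tr, 1:2, 3:5, cutoff = cut + 0.2)$counts)
    expect_lte(c1, c2)
  }
})

test_that("hydrogen bonds follow the geometric criterion and planted occupancy", {
  # ideal linear O-H...O, H...acceptor 0.2 nm
  mk <- function(acc) tiny_traj(
    list(rbind(c(0, 0, 0), c(0.1, 0, 0), acc)),
    elety = c("OD", "HD", "OA"), elesy = c("O", "H", "O"),
    resno = c(1, 1, 2))
  hb <- hydrogen_bonds(mk(c(0.3, 0, 0)))
  expect_equal(nrow(hb), 1)
  expect_equal(hb$frequency, 1)
  # same distance but bent to a 90-degree D-H...A angle: rejected
  hb2 <- hydrogen_bonds(mk(c(0.1, 0.2, 0)))
  expect_equal(nrow(hb2), 0)
  toy <- generate_toy_mab(synthetic_spec(n_frames = 200, seed = 31,
                                         hbond = list(occupancy = 0.6)))
  hb3 <- hydrogen_bonds(toy$traj)
  expect_equal(hb3$frequency[1], 0.6)
  nohyd <- tiny_traj(list(matrix(rnorm(9), 3, 3)))
  expect_error(hydrogen_bonds(nohyd), "hydrogens")
})

test_that("glycosidic torsions agree with an explicit geometric oracle", {
  p <- rbind(c(0, 0, 0), c(0.15, 0, 0), c(0.15, 0.15, 0))
  build <- function(tors) {
    # place the fourth atom at a prescribed torsion about the 2-3 bond
    rad <- tors * pi / 180
    rbind(p, c(0.15 - 0.15 * cos(rad), 0.15, 0.15 * sin(rad)))
  }
  lk <- list(list(name = "L1", phi = as.list(1:4), psi = as.list(1:4),
                  phi_range = c(-180, 180)))
  for (tors in c(-120, -60, 0, 60, 179)) {
    tr <- tiny_traj(list(build(tors)))
    ds <- glycosidic_dihedrals(tr, lk)
    expect_equal(ds$angles$phi[1],
                 oracle_dihedral(build(tors)[1, ], build(tors)[2, ],
                                 build(tors)[3, ], build(tors)[4, ]),
                 tolerance = 1e-9)
  }
  cis <- tiny_traj(list(build(0)))
  expect_equal(glycosidic_dihedrals(cis, lk)$angles$phi[1], 0, tolerance = 1e-9)
  expect_equal(unname(glycosidic_dihedrals(cis, lk)$fractions["L1"]), 1)
  lk_bad <- list(list(name = "LX", phi = list(c("Z", 1, "CX"), 2, 3, 4),
                      psi = as.list(1:4)))
  expect_error(glycosidic_dihedrals(cis, lk_bad), "LX")
})
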
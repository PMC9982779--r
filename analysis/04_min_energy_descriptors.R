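#!/usr/bin/env Rscript
# Descriptors over the minimum-energy frames of a boosted toy ensemble:
# Fab longitude shifts (delta-phi), glycan minimum distance and
# centre-of-mass displacement, light-chain C-terminal contacts with the
# hinge, hydrogen bonds and glycosidic torsions.

suppressMessages(library(mabflex))
dir.create("results", showWarnings = FALSE)

# fucosylated, glycans parked in the Fc cleft, with a planted 60%-occupancy
# hydrogen bond -- the richer of the study conditions
toy <- generate_toy_mab(synthetic_spec(
  n_frames = 2000L, seed = 3001L,
  ch2 = c(mean = 3.1, sd = 0.4),
  glycan = list(inside = TRUE, jitter = 0.05, fucose = TRUE),
  hbond = list(occupancy = 0.6)))
ang <- compute_fab_angles(toy$traj, toy$groups)
boost <- boost_record(runif(2000, 0, 1.2))   # mild synthetic boost record
fes <- reweight_fes(ang, boost)
mf <- select_min_energy_frames(fes, cutoff = 0.5)
message(length(mf), " minimum-energy frames of ", nframes(toy$traj))

dphi <- compute_delta_phi(ang[mf, , drop = FALSE])
write.csv(dphi, "results/04_delta_phi_min_energy.csv", row.names = FALSE)
message(sprintf("delta-phi IQR: Fab1 [%.1f, %.1f] deg",
                quantile(dphi$dphi1, 0.25), quantile(dphi$dphi1, 0.75)))

mtraj <- subset_frames(toy$traj, mf)
gmin <- glycan_min_distance(mtraj, toy$groups)
gcom <- glycan_com_displacement(mtraj, toy$groups)
write.csv(data.frame(frame = mf - 1L, glycan_min_nm = gmin$values,
                     comA_nm = gcom$A$values, comB_nm = gcom$B$values),
          "results/04_glycan_descriptors.csv", row.names = FALSE)
message(sprintf("glycan min distance median %.2f nm (fucosylated chains sit in the cleft)",
                gmin$summary[2]))

ct <- residue_contacts(mtraj, toy$groups$LC_cterm, toy$groups$hinge,
                       cutoff = 0.4)
cs <- data.frame(residue = colnames(ct$counts),
                 median_contacts = apply(ct$counts, 2, median),
                 mean_contacts = colMeans(ct$counts))
write.csv(cs, "results/04_lc_hinge_contacts.csv", row.names = FALSE)

hb <- hydrogen_bonds(toy$traj, frames = mf)
write.csv(hb, "results/04_hbonds.csv", row.names = FALSE)
message(sprintf("top hydrogen bond frequency over min-energy frames: %.2f",
                hb$frequency[1]))

linkages <- list(list(
  name = "SUG1-SUG2",
  phi = list(c("C", 1, "O4"), c("C", 1, "C1"), c("C", 2, "C1"), c("C", 2, "O4")),
  psi = list(c("C", 1, "C1"), c("C", 2, "C1"), c("C", 2, "O4"), c("C", 3, "C1")),
  phi_range = c(-180, 180), psi_range = c(-180, 180)))
dih <- glycosidic_dihedrals(toy$traj, linkages, frames = mf)
write.csv(dih$angles, "results/04_glycosidic_dihedrals.csv", row.names = FALSE)
message(sprintf("fraction of frames inside the reference torsion range: %.2f",
                dih$fractions[1]))
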
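test_that("generation is deterministic given the seed and validates its spec", {
  s <- synthetic_spec(n_frames = 25, seed = 99)
  a <- generate_toy_mab(s); b <- generate_toy_mab(s)
  expect_identical(a$traj$xyz, b$traj$xyz)
  expect_identical(a$truth, b$truth)
  expect_error(synthetic_spec(n_frames = 10), "seed")
  expect_error(synthetic_spec(n_frames = 10, seed = 1,
                              angle_law = list(type = "mixture",
                                               weights = c(T = 0.5, Y = 0.7,
                                                           asym = -0.2),
                                               theta_T = c(mean = 100, sd = 5),
                                               theta_Y = c(mean = 70, sd = 5),
                                               phi = list(mean = c(0, 0), sd = 5))),
               "weights")
  expect_error(synthetic_spec(n_frames = 10, seed = 1,
                              hbond = list(occupancy = 1.4)), "occupancy")
})

test_that("written toy systems round-trip through the PDB loader", {
  toy <- generate_toy_mab(synthetic_spec(n_frames = 12, seed = 55,
                                         glycan = list(inside = TRUE,
                                                       jitter = 0.05,
                                                       fucose = TRUE)))
  d <- withr::local_tempdir()
  paths <- write_toy_mab(toy, d)
  ens <- load_ensemble(paths$topology, paths$traj)
  expect_equal(nframes(ens), 12)
  expect_equal(natoms(ens), natoms(toy$traj))
  expect_equal(ens$xyz, toy$traj$xyz, tolerance = 2e-4)  # PDB stores 0.001 A
  g <- read_groups(paths$groups, natoms(ens))
  expect_identical(unclass(g)[order(names(g))],
                   unclass(toy$groups)[order(names(toy$groups))])
  truth <- read.csv(paths$truth)
  expect_equal(truth$theta1, toy$truth$theta1)
})

test_that("mixture weights drive the planted shape composition", {
  w <- c(T = 0.3, Y = 0.5, asym = 0.2)
  toy <- generate_toy_mab(synthetic_spec(
    n_frames = 2000, seed = 77,
    angle_law = list(type = "mixture", weights = w,
                     theta_T = c(mean = 100, sd = 5),
                     theta_Y = c(mean = 70, sd = 5),
                     phi = list(mean = c(90, -90), sd = 20))))
  frac <- table(factor(toy$truth$label, levels = names(w))) / 2000
  sig <- sqrt(w * (1 - w) / 2000)
  expect_true(all(abs(as.numeric(frac) - w) <= 3 * sig))
})

test_that("an unboosted generator run reproduces the base density", {
  bs <- generate_boosted_samples(n = 4000, seed = 13,
                                 dV = list(A = 0, center = c(90, 90),
                                           width = 25))
  expect_equal(bs$boost$dV, rep(0, 4000))
  expect_equal(bs$efficiency, 1, tolerance = 0.05)
  # mixture mean recovered without any reweighting
  mu <- 0.65 * 75 + 0.35 * 105
  expect_equal(mean(bs$angles$theta1), mu, tolerance = 1)
})

test_that("two wells of known depth difference survive reweighting", {
  kT <- 0.0019872041 * 300
  # equal-sd wells whose weight ratio sets a 1 kcal/mol PMF gap
  w2 <- exp(-1 / kT) / (1 + exp(-1 / kT))
  p0 <- list(list(w = 1 - w2, mean = c(70, 70), sd = c(6, 6)),
             list(w = w2, mean = c(115, 115), sd = c(6, 6)))
  bs <- generate_boosted_samples(n = 50000, seed = 19, p0 = p0,
                                 dV = list(A = 1.5, center = c(92, 92),
                                           width = 22))
  fes <- reweight_fes(bs$angles, bs$boost)
  well_pmf <- function(t) {
    i <- findInterval(t, fes$breaks, rightmost.closed = TRUE)
    fes$pmf[i, i]
  }
  expect_equal(well_pmf(115) - well_pmf(70), 1, tolerance = 0.2)
})
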
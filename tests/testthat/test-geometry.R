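test_that("Fc frame axes are axis-aligned for an axis-aligned toy and orthonormal", {
  toy <- axis_toy()
  fr <- build_fc_frame(toy$coords, toy$groups)
  expect_equal(fr$origin, c(0, 0, 0))
  expect_equal(fr$z, c(0, 0, 1))
  expect_equal(fr$x, c(1, 0, 0))   # CH2_A -> CH2_B points along +x
  expect_equal(fr$y, c(0, 1, 0))
  M <- cbind(fr$x, fr$y, fr$z)
  expect_lt(max(abs(crossprod(M) - diag(3))), 1e-9)
  expect_equal(det(M), 1, tolerance = 1e-9)
})

test_that("Fc frame is equivariant under rigid rotation and translation", {
  toy <- axis_toy()
  fr0 <- build_fc_frame(toy$coords, toy$groups)
  set.seed(42)
  for (i in 1:5) {
    R <- rand_rotation(); t <- rnorm(3, 0, 3)
    fr <- build_fc_frame(sweep(toy$coords %*% t(R), 2, t, "+"), toy$groups)
    expect_lt(max(abs(fr$x - as.numeric(R %*% fr0$x))), 1e-9)
    expect_lt(max(abs(fr$y - as.numeric(R %*% fr0$y))), 1e-9)
    expect_lt(max(abs(fr$z - as.numeric(R %*% fr0$z))), 1e-9)
    expect_lt(max(abs(fr$origin - as.numeric(R %*% fr0$origin + t))), 1e-9)
  }
})

test_that("x axis equals Gram-Schmidt orthogonalization when CH2 vector is tilted", {
  toy <- axis_toy()
  # tilt the CH2 pair so the A->B vector is 45 degrees off the Fc axis
  toy$coords[9, ] <- c(-1, 0, -2)
  toy$coords[10, ] <- c(1, 0, 0)
  fr <- build_fc_frame(toy$coords, toy$groups)
  expect_lt(max(abs(fr$x - oracle_orthogonalize(c(2, 0, 2), fr$z))), 1e-9)
})

test_that("degenerate CH2 geometry raises an explicit error", {
  toy <- axis_toy()
  toy$coords[9, ] <- c(0, 0, -2)   # CH2 vector parallel to the Fc axis
  toy$coords[10, ] <- c(0, 0, -1)
  expect_error(build_fc_frame(toy$coords, toy$groups), "parallel")
})

test_that("fab angles hit the trivial polar and equatorial values", {
  toy <- axis_toy()
  toy$coords[11, ] <- c(0.1, 0, 2.5)   # Fab1 centroid on +z
  toy$coords[12, ] <- c(-0.1, 0, 3.5)
  toy$coords[13, ] <- c(2.5, 0, 0)     # Fab2 centroid on +x (equator)
  toy$coords[14, ] <- c(3.5, 0, 0)
  tr <- tiny_traj(list(toy$coords))
  ang <- compute_fab_angles(tr, toy$groups)
  expect_equal(ang$theta1, 0, tolerance = 1e-9)
  expect_equal(ang$theta2, 90, tolerance = 1e-9)
  expect_equal(ang$phi2, 0, tolerance = 1e-9)
})

test_that("generator-prescribed angles are recovered within 1e-6 degrees", {
  toy <- generate_toy_mab(synthetic_spec(n_frames = 100, seed = 101))
  ang <- compute_fab_angles(toy$traj, toy$groups)
  expect_lt(max(abs(ang$theta1 - toy$truth$theta1)), 1e-6)
  expect_lt(max(abs(ang$theta2 - toy$truth$theta2)), 1e-6)
  expect_lt(max(abs(wrap_deg(ang$phi1 - toy$truth$phi1))), 1e-6)
  expect_lt(max(abs(wrap_deg(ang$phi2 - toy$truth$phi2))), 1e-6)
  expect_true(all(ang$theta1 >= 0 & ang$theta1 <= 180))
  expect_true(all(ang$phi1 > -180 & ang$phi1 <= 180))
})

test_that("shape classification covers T, Y, asym and fractions sum to one", {
  mk <- function(t1, t2) {
    a <- data.frame(frame = 0:9, theta1 = rep(t1, 10), theta2 = rep(t2, 10),
                    phi1 = 0, phi2 = 0)
    class(a) <- c("fab_angles", "data.frame"); a
  }
  allT <- classify_shape(mk(90, 90))
  expect_equal(allT$summary$frac_T, 1)
  asym <- classify_shape(mk(90, 70))
  expect_true(all(asym$label == "asym"))
  expect_equal(unname(asym$summary$frac_fab), c(1, 0))
  toy <- generate_toy_mab(synthetic_spec(n_frames = 400, seed = 7))
  sc <- classify_shape(compute_fab_angles(toy$traj, toy$groups))
  s <- sc$summary
  expect_equal(s$frac_T + s$frac_Y + s$frac_asym, 1)
  expect_equal(as.character(sc$label), toy$truth$label)
  expect_error(classify_shape(mk(90, 90)[0, ]), "empty")
  expect_error(classify_shape(mk(90, 90), threshold = 200), "threshold")
})

test_that("delta-phi obeys the identity, wrap convention and ramp arithmetic", {
  mk <- function(phi) {
    a <- data.frame(frame = seq_along(phi) - 1, theta1 = 90, theta2 = 90,
                    phi1 = phi, phi2 = phi)
    class(a) <- c("fab_angles", "data.frame"); a
  }
  expect_true(all(compute_delta_phi(mk(rep(25, 5)))$dphi1 == 0))
  wrapped <- compute_delta_phi(mk(c(170, -170)))
  expect_equal(wrapped$dphi1[2], 20)
  ramp <- compute_delta_phi(mk(wrap_deg(0:150)))
  expect_equal(ramp$dphi1[101], 100)
  expect_identical(ramp$dphi1[1], 0)
  cum <- compute_delta_phi(mk(wrap_deg(0:400)), cumulative = TRUE)
  expect_equal(cum$dphi1[401], 400)
  expect_error(compute_delta_phi(mk(1:5), ref_frame = 9), "out of range")
})
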
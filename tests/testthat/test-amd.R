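test_that("boost parameters follow the dual-boost formulas", {
  p <- compute_amd_params(0, 0, 5, 1)
  expect_equal(p$EthreshD, 20)
  expect_equal(p$alphaD, 4)
  p2 <- compute_amd_params(0, -1000, 1, 1000)
  expect_equal(p2$EthreshP, -840)
  expect_equal(p2$alphaP, 160)
  set.seed(1)
  for (i in 1:20) {
    d <- rnorm(1, 0, 5000); e <- rnorm(1, 0, 5e5)
    nr <- sample(1:2000, 1); na <- sample(1:5e5, 1)
    q <- compute_amd_params(d, e, nr, na)
    expect_equal(q$EthreshD - q$DIHED, 5 * q$alphaD, tolerance = 1e-12)
    expect_equal(q$EthreshP - q$EPTOT, q$alphaP, tolerance = 1e-12)
    expect_gt(q$alphaD, 0); expect_gt(q$alphaP, 0)
  }
  expect_error(compute_amd_params(0, 0, 0, 10), "positive")
})

test_that("Maclaurin weights are monotone and converge to the exponential", {
  dV <- seq(0, 5 * 0.0019872041 * 300, length.out = 200)  # beta dV in [0, 5]
  w10 <- maclaurin_weights(dV, k_max = 10)
  expect_true(all(diff(as.numeric(w10)) > 0))
  w30 <- maclaurin_weights(dV, k_max = 30)
  expect_lt(max(abs(as.numeric(w30) - exp(dV / (0.0019872041 * 300))) /
                  exp(dV / (0.0019872041 * 300))), 1e-9)
})

test_that("unbiased and constant boosts reproduce the raw histogram exactly", {
  set.seed(5)
  a <- data.frame(frame = 0:1999, theta1 = runif(2000, 40, 140),
                  theta2 = runif(2000, 40, 140), phi1 = 0, phi2 = 0)
  class(a) <- c("fab_angles", "data.frame")
  raw <- reweight_fes(a, boost_record(rep(0, 2000)))
  expect_equal(sum(raw$prob), 1, tolerance = 1e-12)
  expect_equal(min(raw$pmf[is.finite(raw$pmf)]), 0)
  cst <- reweight_fes(a, boost_record(rep(0.7, 2000)))
  expect_equal(cst$prob, raw$prob, tolerance = 1e-12)
  h <- table(factor(raw$bin1, levels = 1:72), factor(raw$bin2, levels = 1:72))
  expect_equal(raw$prob, unclass(unname(h / 2000)), ignore_attr = TRUE)
})

test_that("a single occupied bin gives p = 1 there and +Inf elsewhere", {
  a <- data.frame(frame = 0:9, theta1 = rep(91, 10), theta2 = rep(91, 10),
                  phi1 = 0, phi2 = 0)
  class(a) <- c("fab_angles", "data.frame")
  g <- reweight_fes(a, boost_record(runif(10)))
  expect_equal(sum(g$prob > 0), 1)
  expect_equal(max(g$prob), 1)
  expect_equal(min(g$pmf), 0)
  expect_equal(sum(is.finite(g$pmf)), 1)
})

test_that("misaligned boost records and truncation breakdown are flagged", {
  a <- data.frame(frame = 0:9, theta1 = rep(91, 10), theta2 = rep(91, 10),
                  phi1 = 0, phi2 = 0)
  class(a) <- c("fab_angles", "data.frame")
  expect_error(reweight_fes(a, boost_record(rep(0, 5))), "differ")
  expect_warning(reweight_fes(a, boost_record(rep(6, 10)), k_max = 2),
                 "Maclaurin")
})

test_that("minimum-energy frame selection matches an exhaustive bin scan", {
  set.seed(11)
  a <- data.frame(frame = 0:4999,
                  theta1 = c(rnorm(2500, 70, 6), rnorm(2500, 105, 6)),
                  theta2 = c(rnorm(2500, 72, 6), rnorm(2500, 103, 6)),
                  phi1 = 0, phi2 = 0)
  class(a) <- c("fab_angles", "data.frame")
  g <- reweight_fes(a, boost_record(rep(0, 5000)))
  sel <- select_min_energy_frames(g, cutoff = 0.5)
  expect_gt(length(sel), 0)
  # brute-force: scan every bin, collect member frames under the cutoff
  expected <- integer(0)
  for (i in seq_len(nrow(g$pmf))) for (j in seq_len(ncol(g$pmf)))
    if (g$pmf[i, j] < 0.5)
      expected <- c(expected, which(g$bin1 == i & g$bin2 == j))
  expect_setequal(sel, expected)
  # two-bin toy, 90/10 split: PMF gap kT ln 9 ~ 1.3, so only the major bin
  b <- a[1:100, ]; b$theta1 <- rep(c(70, 105), c(90, 10))
  b$theta2 <- rep(c(70, 105), c(90, 10))
  class(b) <- c("fab_angles", "data.frame")
  g2 <- reweight_fes(b, boost_record(rep(0, 100)))
  expect_identical(select_min_energy_frames(g2, 0.5), 1:90)
  expect_error(select_min_energy_frames(g, cutoff = 0), "> 0")
})

test_that("boost logs are parsed in both dialects", {
  f1 <- tempfile(fileext = ".dat")
  writeLines(c("# frame dV", "0 0.5", "1 1.25", "2 0.0"), f1)
  b1 <- read_boost_log(f1)
  expect_equal(b1$dV, c(0.5, 1.25, 0))
  f2 <- tempfile(fileext = ".log")
  writeLines(c("# AMBER-style accelerated MD log",
               paste(500, 500, -1e5, 1500, 1, 1, 2.5, 0.75),
               paste(1000, 1000, -1e5, 1500, 1, 1, 1.0, 0.25)), f2)
  b2 <- read_boost_log(f2)
  expect_equal(b2$dV, c(3.25, 1.25))
  expect_error(boost_record(c(1, -0.1)), ">= 0")
})
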
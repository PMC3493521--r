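# Kabsch superposition, RMSD/Rg/B-factor statistics, distance monitors and
# convergence diagnostics.

test_that("Kabsch recovers congruence and matches a numerical optimizer", {
  pep <- build_peptide("KLVFF", conformation_spec("helix"))
  X <- pep$xyz
  self <- kabsch_superpose(X, X)
  expect_lt(self$rmsd, 1e-12)
  expect_lt(max(abs(self$transform$rotation - diag(3))), 1e-9)
  t <- transform_op(rotation_about_axis(c(2, -1, 3), 111), c(5, 6, -7))
  moved <- sweep(X %*% t(t$rotation), 2L, t$translation, "+")
  expect_lt(kabsch_superpose(moved, X)$rmsd, 1e-9)

  # 4-point asymmetric set vs perturbed copy: compare with direct numerical
  # minimisation over rotations and translations
  A <- matrix(c(0, 0, 0, 3, 0, 0, 0, 2, 0, 1, 1, 4), 4L, 3L, byrow = TRUE)
  set.seed(1)
  B <- A + matrix(rnorm(12, sd = 0.3), 4L, 3L)
  got <- kabsch_superpose(A, B)$rmsd
  obj <- function(par) {
    R <- rotation_about_axis(c(0, 0, 1), par[1]) %*%
      rotation_about_axis(c(0, 1, 0), par[2]) %*%
      rotation_about_axis(c(1, 0, 0), par[3])
    fit <- sweep(A %*% t(R), 2L, par[4:6], "+")
    sqrt(mean(rowSums((fit - B)^2)))
  }
  opt <- stats::optim(c(10, 10, 10, 0, 0, 0), obj,
                      method = "BFGS", control = list(maxit = 2000, reltol = 1e-14))
  expect_lt(abs(got - opt$value), 1e-6)
  expect_error(kabsch_superpose(A[1:2, ], B[1:2, ]), "3 points")
  line <- cbind(1:5, 0, 0)
  expect_error(kabsch_superpose(line, line), "degenerate")
})

test_that("RMSD series start at zero and ignore rigid-body motion", {
  d <- build_peptide(abeta42_sequence(), conformation_spec("extended"))
  frames <- list(d$xyz)
  for (k in 1:3) {
    t <- transform_op(rotation_about_axis(c(1, k, 0), 30 * k), c(k, -k, 2))
    frames[[k + 1]] <- sweep(d$xyz %*% t(t$rotation), 2L, t$translation, "+")
  }
  tr <- ab_trajectory(d, frames, 10)
  rs <- rmsd_series(tr, d)
  expect_equal(rs$core[1], 0, tolerance = 1e-9)
  expect_equal(rs$total[1], 0, tolerance = 1e-9)
  expect_lt(max(rs$core, rs$total), 1e-9)
})

test_that("a mobile N-terminus raises total RMSD above core RMSD", {
  d <- standard_dodecamer_fixture()
  sig <- stats::setNames(c(rep(1.2, 16), rep(0.3, 26)), 1:42)
  tr <- simulate_trajectory(d, fluctuation_spec(sig, n_frames = 15L, seed = 2L))
  rs <- rmsd_series(tr, d)
  expect_gt(mean(rs$total), mean(rs$core))
})

test_that("radius of gyration has its closed form and rigid invariance", {
  two <- toy_structure(c("C1", "C2"), c("C", "C"), c(0, 0, 0, 2, 0, 0),
                       resnums = c(1L, 2L))
  expect_equal(radius_of_gyration(two, mass_weighted = FALSE), 1)
  pep <- build_peptide("KLVFF", conformation_spec("helix"))
  t <- transform_op(rotation_about_axis(c(1, 1, 1), 60), c(10, 0, -3))
  expect_lt(abs(radius_of_gyration(pep) -
                  radius_of_gyration(apply_transform(pep, t))), 1e-9)
  # core subset is no larger than the whole particle for the fixture
  d <- standard_dodecamer_fixture()
  expect_lt(radius_of_gyration(d, region_core()), radius_of_gyration(d))
})

test_that("B-factors recover the generator sigma and vanish for static input", {
  pep <- build_peptide("AAAAA", conformation_spec("extended"))
  static <- ab_trajectory(pep, list(pep$xyz, pep$xyz, pep$xyz), 10)
  expect_lt(max(abs(bfactor_profile(static)$bfactor)), 1e-10)
  sigma <- 0.5
  tr <- simulate_trajectory(pep, fluctuation_spec(sigma, n_frames = 2000L,
                                                  seed = 8L))
  prof <- bfactor_profile(tr)
  expected <- 8 * pi^2 * sigma^2
  expect_lt(max(abs(prof$bfactor - expected) / expected), 0.05)
  expect_error(bfactor_profile(static, window = c(0, 5)), "at least 2")
})

test_that("B-factor recovery error shrinks roughly as 1/sqrt(n_frames)", {
  pep <- build_peptide("AAA", conformation_spec("extended"))
  expected <- 8 * pi^2 * 0.5^2
  err <- vapply(c(100L, 1600L), function(nf) {
    tr <- simulate_trajectory(pep, fluctuation_spec(0.5, n_frames = nf,
                                                    seed = 21L))
    mean(abs(bfactor_profile(tr)$bfactor - expected)) / expected
  }, numeric(1))
  expect_lt(err[2], err[1])
})

test_that("sidechain distance monitors report minima, means and tolerance", {
  # two ALA residues with CB atoms placed 5.8 A apart
  s <- toy_structure(rep(c("N", "CA", "C", "O", "CB"), 2),
                     rep(c("N", "C", "C", "O", "C"), 2),
                     c(0, 0, 0,  1.5, 0, 0,  2, 1.5, 0,  2, 2.7, 0,  1.5, -1.5, 0,
                       20, 0, 0, 21.5, 0, 0, 22, 1.5, 0, 22, 2.7, 0, 1.5 + 5.8, -1.5, 0),
                     resnames = "ALA", chains = "A", resnums = rep(c(1L, 5L), each = 5))
  tr <- ab_trajectory(s, list(s$xyz, s$xyz), 10)
  ds <- distance_series(tr, 1L, 5L)
  expect_equal(attr(ds, "mean"), 5.8, tolerance = 1e-9)
  expect_equal(attr(ds, "fraction_under"), 1.0)
  ds2 <- distance_series(tr, 1L, 5L, tolerance = 5.0)
  expect_equal(attr(ds2, "fraction_under"), 0.0)
  # identical sidechain positions give distance zero
  s0 <- s; s0$xyz[10, ] <- s0$xyz[5, ]
  expect_equal(attr(distance_series(s0, 1L, 5L), "mean"), 0)
  gly <- build_peptide("AGA", conformation_spec("extended"))
  expect_error(distance_series(gly, 1L, 2L), "glycine")
})

test_that("convergence statistics recover exact and statistical expectations", {
  cs <- convergence_stats(rep(3, 10), 0:9 * 10)
  expect_equal(cs$cv, 0)
  expect_equal(cs$slope, 0)
  tt <- seq(0, 1000, by = 10)
  cs2 <- convergence_stats(2 * tt / 1000, tt)
  expect_equal(cs2$slope, 2, tolerance = 1e-12)
  set.seed(5)
  noisy <- 100 + rnorm(5000, sd = 1)
  cs3 <- convergence_stats(noisy, seq_along(noisy))
  expect_lt(abs(cs3$cv - 0.01), 0.002)
  expect_error(convergence_stats(c(0, 0, 0)), "undefined|zero")
})
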
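# Peptide builder geometry, reference tripeptides, Cn assemblies and the
# Gaussian fluctuation trajectory generator.

test_that("ideal helix geometry places the i..i+4 hydrogen bond partners", {
  h <- build_peptide(strrep("A", 10), conformation_spec("helix"))
  a <- h$atoms
  for (i in 1:6) {
    O <- h$xyz[a$resnum == i & a$name == "O", ]
    N <- h$xyz[a$resnum == i + 4 & a$name == "N", ]
    d <- sqrt(sum((O - N)^2))
    expect_gte(d, 2.7); expect_lte(d, 3.3)
  }
})

test_that("extended chains have the beta-strand rise", {
  e <- build_peptide(strrep("A", 10), conformation_spec("extended"))
  ca <- function(i) e$xyz[e$atoms$resnum == i & e$atoms$name == "CA", ]
  d <- sqrt(sum((ca(1) - ca(10))^2))
  expect_gte(d, 30); expect_lte(d, 33)
})

test_that("hairpin builds paired antiparallel strands around the turn", {
  hp <- build_peptide(substr(abeta42_sequence(), 31, 42),
                      conformation_spec("hairpin", turn_center = 37L),
                      start_resnum = 31L)
  ca <- function(i) hp$xyz[hp$atoms$resnum == i & hp$atoms$name == "CA", ]
  expect_lt(sqrt(sum((ca(33) - ca(41))^2)), 6)
  expect_lt(sqrt(sum((ca(34) - ca(41))^2)), 6)
  expect_error(build_peptide("AAAA", conformation_spec("hairpin", turn_center = 4L)),
               "strictly inside")
})

test_that("built peptides satisfy structure invariants with no nonbonded clashes", {
  for (conf in list(conformation_spec("helix"), conformation_spec("extended"),
                    conformation_spec("hairpin", turn_center = 6L))) {
    s <- build_peptide("KLVFFAEDVG", conf)
    expect_s3_class(s, "ab_structure")
    hv <- which(!s$atoms$is_hydrogen)
    d <- as.matrix(dist(s$xyz[hv, ]))
    sep <- abs(outer(s$atoms$resnum[hv], s$atoms$resnum[hv], "-"))
    # pairs at least two residues apart can never be covalently bonded
    expect_gt(min(d[sep >= 2]), 1.5)
  }
  expect_error(build_peptide("AXB", conformation_spec("extended")),
               "unknown residue")
  expect_error(build_peptide("A", conformation_spec("extended")), "at least 2")
})

test_that("reference tripeptides are extended flank-x-flank with marked centre", {
  tri <- build_reference_tripeptide("K", "A")
  expect_equal(unique(tri$atoms$resname[tri$atoms$resnum == 2]), "LYS")
  expect_equal(unique(tri$atoms$resname[tri$atoms$resnum == 1]), "ALA")
  expect_equal(attr(tri, "central_resnum"), 2L)
  ggg <- build_reference_tripeptide("G", "G")
  expect_equal(unique(ggg$atoms$resname), "GLY")
})

test_that("Cn assemblies have exact symmetry and honour the clash guard", {
  sub <- build_peptide("KLVFF", conformation_spec("extended"))
  hexa <- build_cn_assembly(sub, 3L, axis = c(0, 0, 1), ring_radius = 20)
  expect_equal(n_chains(hexa), 3L)
  # superposing copy k onto copy k+1 after a 120 degree rotation: RMSD 0
  rot <- transform_op(rotation_about_axis(c(0, 0, 1), 120), c(0, 0, 0))
  ch <- chain_ids(hexa)
  x1 <- apply_transform(subset_chains(hexa, ch[1]), rot)$xyz
  x2 <- subset_chains(hexa, ch[2])$xyz
  expect_lt(max(abs(x1 - x2)), 1e-9)
  # far ring: no inter-copy contacts under 5 A
  far <- build_cn_assembly(sub, 3L, ring_radius = 60)
  d12 <- min(as.matrix(stats::dist(far$xyz))[
    far$atoms$chain == "A", far$atoms$chain == "B"])
  expect_gt(d12, 5)
  # Rg nondecreasing in ring radius
  rgs <- vapply(c(15, 25, 40), function(r)
    radius_of_gyration(build_cn_assembly(sub, 3L, ring_radius = r)),
    numeric(1))
  expect_true(all(diff(rgs) >= 0))
  # overlapping copies are rejected
  expect_error(build_cn_assembly(sub, 3L, ring_radius = 0), "clash")
})

test_that("zero-noise trajectories are static and seeds reproduce exactly", {
  s <- build_peptide("KLVFF", conformation_spec("extended"))
  t0 <- simulate_trajectory(s, fluctuation_spec(0, n_frames = 3L, seed = 7L))
  for (f in t0$frames) expect_identical(f, s$xyz)
  t1 <- simulate_trajectory(s, fluctuation_spec(0.5, n_frames = 5L, seed = 3L))
  t2 <- simulate_trajectory(s, fluctuation_spec(0.5, n_frames = 5L, seed = 3L))
  expect_identical(t1$frames, t2$frames)
  t3 <- simulate_trajectory(s, fluctuation_spec(0.5, n_frames = 5L, seed = 4L))
  expect_false(identical(t1$frames, t3$frames))
})

test_that("generator variance converges to the specified sigma", {
  s <- build_peptide("AAA", conformation_spec("extended"))
  sigma <- 0.7
  nf <- 1500L
  tr <- simulate_trajectory(s, fluctuation_spec(sigma, n_frames = nf, seed = 11L))
  x1 <- vapply(tr$frames, function(f) f[1L, 1L], numeric(1))
  v <- stats::var(x1)
  # variance of the sample variance: ~ 2 sigma^4 / (n - 1); allow 3 s.d.
  tol <- 3 * sqrt(2 / (nf - 1)) * sigma^2
  expect_lt(abs(v - sigma^2), tol)
})

test_that("helix unwinding moves the N-terminus toward an extended state", {
  d <- standard_dodecamer_fixture()
  tr <- simulate_trajectory(d, fluctuation_spec(0, n_frames = 5L,
                                                unwind_nterm = TRUE, seed = 1L))
  # first frame is the helical reference; last frame is nearly extended
  span <- function(f, ch) {
    idx <- which(d$atoms$chain == ch & d$atoms$resnum %in% c(1L, 16L) &
                   d$atoms$name == "CA")
    sqrt(sum((f[idx[1L], ] - f[idx[2L], ])^2))
  }
  expect_lt(abs(span(tr$frames[[1L]], "A") - span(d$xyz, "A")), 1e-6)
  # extended 15-residue span (~3.5 A/res) far exceeds the helical one (~1.5)
  expect_gt(span(tr$frames[[5L]], "A"), span(tr$frames[[1L]], "A") + 15)
})

test_that("the core monomer fixture honours the F19-L34 proximity constraint", {
  mono <- build_core_monomer()
  ds <- distance_series(mono, 19L, 34L)
  expect_lt(attr(ds, "mean"), 6)
  hv <- which(!mono$atoms$is_hydrogen)
  d <- as.matrix(dist(mono$xyz[hv, ]))
  sep <- abs(outer(mono$atoms$resnum[hv], mono$atoms$resnum[hv], "-"))
  expect_gt(min(d[sep >= 2]), 1.5)
})

test_that("the standard dodecamer fixture is a 12-chain particle of globulomer size", {
  d <- standard_dodecamer_fixture()
  expect_equal(n_chains(d), 12L)
  expect_equal(sort(unique(d$atoms$resnum)), 1:42)
  # diameter in the experimentally reported 40-60 A range for the core
  core <- standard_dodecamer_fixture(n_term_helices = FALSE)
  rg <- radius_of_gyration(core)
  expect_gt(2 * rg, 40); expect_lt(2 * rg, 65)
})
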
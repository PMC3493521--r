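# Atomic contact energy profiles against brute-force pair enumeration, and
# the Monte-Carlo packing density against a dense-grid integration oracle.


test_that("a single cross-chain pair contributes its energy to both residues", {
  tab <- default_ace_table()
  # LYS NZ (charged N) against LEU CD1 (aliphatic C) at 5.0 A, chains A/B
  s <- toy_structure(c("NZ", "CD1"), c("N", "C"), c(0, 0, 0, 5, 0, 0),
                     resnames = c("LYS", "LEU"), chains = c("A", "B"),
                     resnums = c(1L, 1L))
  prof <- residue_ace_profile(s, tab)
  e <- tab$energies["NPS", "CB3"]
  expect_equal(prof$ace, c(e, e))
  expect_equal(sum(prof$ace), 2 * e)
  # beyond the cutoff nothing is counted
  s2 <- s; s2$xyz[2, 1] <- 6.5
  expect_equal(residue_ace_profile(s2, tab)$ace, c(0, 0))
})

test_that("sequence-adjacent pairs are excluded within a chain but not across", {
  tab <- default_ace_table()
  xyz <- c(0, 0, 0, 4, 0, 0)
  same <- toy_structure(c("CB", "CB"), c("C", "C"), xyz, resnames = "ALA",
                        chains = "A", resnums = c(1L, 2L))
  expect_equal(residue_ace_profile(same, tab)$ace, c(0, 0))
  cross <- toy_structure(c("CB", "CB"), c("C", "C"), xyz, resnames = "ALA",
                         chains = c("A", "B"), resnums = c(1L, 2L))
  expect_equal(cross <- residue_ace_profile(cross, tab)$ace,
               rep(tab$energies["CB3", "CB3"], 2))
})

test_that("per-residue ACE equals brute-force enumeration on random toys", {
  tab <- default_ace_table()
  set.seed(42)
  pool <- data.frame(
    resname = c("LYS", "LEU", "PHE", "ASP", "SER", "MET"),
    name = c("NZ", "CD1", "CZ", "OD1", "OG", "SD"),
    element = c("N", "C", "C", "O", "O", "S"))
  for (rep in 1:4) {
    pick <- sample(nrow(pool), 20L, replace = TRUE)
    s <- toy_structure(paste0(pool$name[pick], ""),
                       pool$element[pick],
                       c(t(matrix(runif(60, 0, 12), 20L))),
                       resnames = pool$resname[pick],
                       chains = sample(c("A", "B"), 20L, replace = TRUE),
                       resnums = rep(1:20, length.out = 20L))
    # unique (chain, resnum, name): resnums 1..20 distinct, so guaranteed
    prof <- residue_ace_profile(s, tab)
    oracle <- ace_oracle(s, tab, 6.0, 1L)
    got <- setNames(prof$ace, paste(prof$chain, prof$resnum))
    expect_equal(got[names(oracle)], oracle)
    # grand total is twice the unordered-pair sum, and chain relabeling
    # leaves the profile invariant
    s2 <- s
    s2$atoms$chain <- chartr("AB", "BA", s2$atoms$chain)
    prof2 <- residue_ace_profile(s2, tab)
    expect_equal(sort(prof2$ace), sort(prof$ace))
  }
})

test_that("a hydrophobic cluster has negative ACE and untypable atoms error", {
  tab <- default_ace_table()
  # tetrahedron of LEU sidechain carbons on two chains
  s <- toy_structure(rep(c("CD1", "CD2"), 2), rep("C", 4),
                     c(0, 0, 0, 4, 0, 0, 2, 3, 0, 2, 1.5, 3),
                     resnames = "LEU", chains = c("A", "A", "B", "B"),
                     resnums = c(1L, 5L, 1L, 5L))
  prof <- residue_ace_profile(s, tab)
  expect_true(all(prof$ace < 0))
  bad <- toy_structure("XX", "C", c(0, 0, 0), resnames = "LEU")
  expect_error(residue_ace_profile(bad, tab), "LEU.*XX")
})

test_that("packing density handles the no-buried-atom case", {
  s <- one_atom()
  expect_warning(res <- packing_density(s, mc_samples = 100L), "no buried")
  expect_true(is.na(res$mean))
  expect_length(res$per_atom, 0L)
})

# Dense-grid volume integration oracle for the cell of one atom: same cell
# definition (nearest surface distance), evaluated on a regular lattice.
grid_density_oracle <- function(xyz, radii, i, R_out, h = 0.08) {
  g <- seq(-R_out, R_out, by = h)
  pts <- as.matrix(expand.grid(g, g, g))
  pts <- pts[rowSums(pts^2) <= R_out^2, , drop = FALSE]
  pts <- sweep(pts, 2L, xyz[i, ], "+")
  di <- sqrt(rowSums(sweep(pts, 2L, xyz[i, ])^2)) - radii[i]
  occupied <- di < 0
  mine <- rep(TRUE, nrow(pts))
  for (j in seq_len(nrow(xyz))) {
    if (j == i) next
    dj <- sqrt(rowSums(sweep(pts, 2L, xyz[j, ])^2)) - radii[j]
    mine <- mine & (di <= dj)
    occupied <- occupied | dj < 0
  }
  sum(occupied & mine) / sum(mine)
}

test_that("central-atom density in an FCC shell matches grid integration", {
  # FCC nearest-neighbour shell (12 atoms) plus the 6 next-nearest, carbons
  nn <- 3.2
  m <- function(...) unname(as.matrix(expand.grid(...)))
  fcc <- rbind(m(c(-1, 1), c(-1, 1), 0), m(c(-1, 1), 0, c(-1, 1)),
               cbind(0, m(c(-1, 1), c(-1, 1))))
  shell1 <- fcc * nn / sqrt(2)
  shell2 <- rbind(diag(3), -diag(3)) * nn * sqrt(2)
  pts <- rbind(c(0, 0, 0), shell1, shell2)
  s <- carbon_cloud(pts)
  res <- packing_density(s, mc_samples = 40000L, seed = 5L)
  expect_true("1" %in% names(res$per_atom))
  got <- res$per_atom[["1"]]
  oracle <- grid_density_oracle(s$xyz, rep(1.7, nrow(pts)), 1L,
                                1.7 + 2 * 1.4 + 0.2)
  expect_lt(abs(got - oracle), 0.02)
  expect_true(all(res$per_atom <= 1))
})

test_that("packing density is seed-reproducible and stable in sample count", {
  d <- standard_dodecamer_fixture(n_term_helices = FALSE)
  r1 <- packing_density(d, mc_samples = 2000L, seed = 9L)
  r2 <- packing_density(d, mc_samples = 2000L, seed = 9L)
  expect_identical(r1$per_atom, r2$per_atom)
  r4 <- packing_density(d, mc_samples = 4000L, seed = 9L)
  expect_lt(abs(r1$mean - r4$mean), 0.01)
  expect_true(all(r1$per_atom > 0 & r1$per_atom <= 1))
})
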
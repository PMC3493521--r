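# Shared fixture builders: all synthetic, generated in code at test time.

# A minimal structure from bare atom descriptions.
toy_structure <- function(names, elements, xyz, resnames = "ALA",
                          chains = "A", resnums = 1L) {
  n <- length(names)
  xyz <- if (is.matrix(xyz)) xyz else matrix(xyz, ncol = 3L, byrow = TRUE)
  atoms <- data.frame(
    serial = seq_len(n), name = names, element = elements,
    resname = rep_len(resnames, n), chain = rep_len(chains, n),
    resnum = rep_len(resnums, n), occupancy = 1, bfactor = 0,
    is_hydrogen = elements == "H", stringsAsFactors = FALSE)
  ab_structure(atoms, xyz)
}

# Single atom at a position (default carbon at origin).
one_atom <- function(x = 0, y = 0, z = 0, element = "C", name = "C1",
                     chain = "A", resnum = 1L) {
  toy_structure(name, element, c(x, y, z), chains = chain, resnums = resnum)
}

# n carbon "residues" at given coordinate rows, one atom per residue.
carbon_cloud <- function(xyz, chain = "A", name = "CA", resname = "GLY") {
  xyz <- matrix(xyz, ncol = 3L)
  toy_structure(rep(name, nrow(xyz)), rep("C", nrow(xyz)), xyz,
                resnames = resname, chains = chain,
                resnums = seq_len(nrow(xyz)))
}

# Closed-form accessible area of two intersecting spheres of (expanded)
# radii r1, r2 at centre distance d: each sphere loses a spherical cap.
two_sphere_sasa <- function(r1, r2, d) {
  if (d >= r1 + r2) return(4 * pi * (r1^2 + r2^2))
  h1 <- r1 - (d^2 + r1^2 - r2^2) / (2 * d)
  h2 <- r2 - (d^2 + r2^2 - r1^2) / (2 * d)
  4 * pi * r1^2 - 2 * pi * r1 * h1 + 4 * pi * r2^2 - 2 * pi * r2 * h2
}

# Quasi-uniform shell of carbon atoms around a centre (burial construct).
carbon_shell <- function(center, radius = 4, n = 60, chain = "Z") {
  i <- seq_len(n) - 0.5
  phi <- pi * (3 - sqrt(5)) * (seq_len(n) - 1L)
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  pts <- cbind(r * cos(phi), r * sin(phi), z) * radius
  pts <- sweep(pts, 2L, center, "+")
  carbon_cloud(pts, chain = chain, name = "C1", resname = "UNK")
}

expect_structures_close <- function(a, b, tol = 1e-6) {
  expect_equal(a$atoms$name, b$atoms$name)
  expect_equal(a$atoms$chain, b$atoms$chain)
  expect_equal(a$atoms$resnum, b$atoms$resnum)
  expect_lt(max(abs(a$xyz - b$xyz)), tol)
}
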
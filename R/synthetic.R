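# Synthetic trajectory generation: position-dependent Gaussian fluctuations
# around a reference structure, optionally with progressive unwinding of the
# N-terminal helices (residues 1-16) toward an extended conformation. Stands
# in for molecular-dynamics sampling in tests and fixtures.

#' Specify synthetic fluctuation statistics
#'
#' @param per_residue_sigma Per-coordinate Gaussian standard deviation in
#'   Angstrom: either a single value for all residues or a named numeric
#'   vector `resnum -> sigma` (uncovered residues default to 0).
#' @param n_frames Number of frames (>= 1).
#' @param frame_interval Frame spacing, ps.
#' @param unwind_nterm If `TRUE`, residues 1-16 are rebuilt each frame with
#'   backbone torsions interpolated linearly from alpha-helical to extended.
#' @param seed Integer RNG seed; a fixed seed makes the trajectory
#'   bit-reproducible.
#' @return An object of class `fluctuation_spec`.
#' @export
fluctuation_spec <- function(per_residue_sigma = 0, n_frames = 100L,
                             frame_interval = 10, unwind_nterm = FALSE,
                             seed = 1L) {
  if (any(per_residue_sigma < 0)) stop("sigma must be >= 0")
  if (n_frames < 1L) stop("n_frames must be >= 1")
  structure(list(per_residue_sigma = per_residue_sigma,
                 n_frames = as.integer(n_frames),
                 frame_interval = frame_interval,
                 unwind_nterm = isTRUE(unwind_nterm),
                 seed = as.integer(seed)),
            class = "fluctuation_spec")
}

sigma_for_atoms <- function(s, per_residue_sigma) {
  rn <- s$atoms$resnum
  if (is.null(names(per_residue_sigma))) {
    if (length(per_residue_sigma) != 1L)
      stop("per_residue_sigma must be a single value or a named vector")
    return(rep(per_residue_sigma, length(rn)))
  }
  sig <- per_residue_sigma[as.character(rn)]
  sig[is.na(sig)] <- 0
  unname(sig)
}

# Helix and extended endpoint torsions for the unwinding interpolation; the
# path runs through -180 (the shorter angular route from the helical basin).
.unwind_from <- c(phi = -57, psi = -47)
.unwind_to <- c(phi = -180, psi = -180)
.unwind_last <- 16L

# Rebuild residues 1-16 of one chain with interpolated torsions, grafted onto
# the chain by superposing the residue-17 backbone.
unwound_chain_coords <- function(topo, chain, frac) {
  a <- topo$atoms
  sel <- a$chain == chain & a$resnum <= .unwind_last + 1L
  resnums <- sort(unique(a$resnum[sel]))
  if (!all(seq_len(.unwind_last + 1L) %in% resnums))
    stop("unwind_nterm requires residues 1-", .unwind_last + 1L,
         " in chain ", chain)
  seq1 <- vapply(seq_len(.unwind_last + 1L), function(r) {
    rn <- a$resname[a$chain == chain & a$resnum == r][1L]
    .aa3to1[[rn]]
  }, character(1L))
  wrap <- function(x) ifelse(x <= -180, x + 360, x)
  phi <- wrap((1 - frac) * .unwind_from["phi"] + frac * .unwind_to["phi"])
  psi <- wrap((1 - frac) * .unwind_from["psi"] + frac * .unwind_to["psi"])
  conf <- conformation_spec("extended",
                            phi = c(rep(phi, .unwind_last), 180),
                            psi = c(rep(psi, .unwind_last), 180))
  seg <- build_peptide(paste(seq1, collapse = ""), conf, chain_id = chain)
  # superpose the built residue-(last+1) backbone onto the topology
  anchor <- .unwind_last + 1L
  seg_idx <- vapply(c("N", "CA", "C"), function(nm)
    match_atom(seg, chain, anchor, nm), integer(1L))
  top_idx <- vapply(c("N", "CA", "C"), function(nm)
    match_atom(topo, chain, anchor, nm), integer(1L))
  fit <- kabsch_superpose(seg$xyz[seg_idx, , drop = FALSE],
                          topo$xyz[top_idx, , drop = FALSE])
  seg <- apply_transform(seg, fit$transform)
  # matched replacement coordinates for residues 1..last
  out <- list()
  tgt <- which(a$chain == chain & a$resnum <= .unwind_last)
  for (i in tgt) {
    j <- match_atom(seg, chain, a$resnum[i], a$name[i])
    if (length(j) != 1L)
      stop("cannot rebuild atom ", a$name[i], " of residue ", a$resnum[i],
           " in chain ", chain, " (atom naming mismatch with the builder)")
    out[[length(out) + 1L]] <- seg$xyz[j, ]
  }
  list(indices = tgt, xyz = do.call(rbind, out))
}

#' Simulate a synthetic trajectory
#'
#' Frame coordinates are the reference coordinates plus independent Gaussian
#' noise with per-coordinate standard deviation `sigma(residue)`. With
#' `unwind_nterm`, residues 1-16 of every chain are additionally rebuilt each
#' frame with backbone torsions interpolated linearly from helical
#' (phi = -57, psi = -47) to extended over the trajectory, grafted at residue
#' 17. The closed-form B-factor of the pure-noise model is
#' `B = 8 pi^2 sigma^2` (isotropic: mean-square displacement `3 sigma^2`).
#'
#' @param s Reference `ab_structure`.
#' @param fl A [fluctuation_spec()].
#' @return An [ab_trajectory()].
#' @export
simulate_trajectory <- function(s, fl) {
  stopifnot(inherits(s, "ab_structure"), inherits(fl, "fluctuation_spec"))
  sig <- sigma_for_atoms(s, fl$per_residue_sigma)
  na <- n_atoms(s)
  set.seed(fl$seed)
  frames <- vector("list", fl$n_frames)
  unwind_cache_chains <- if (fl$unwind_nterm) chain_ids(s) else character(0)
  for (f in seq_len(fl$n_frames)) {
    base <- s$xyz
    if (fl$unwind_nterm) {
      frac <- if (fl$n_frames == 1L) 1 else (f - 1) / (fl$n_frames - 1)
      for (ch in unwind_cache_chains) {
        up <- unwound_chain_coords(s, ch, frac)
        base[up$indices, ] <- up$xyz
      }
    }
    noise <- matrix(rnorm(3L * na, sd = rep(sig, 3L)), na, 3L)
    frames[[f]] <- base + noise
  }
  ab_trajectory(s, frames, fl$frame_interval)
}

#' Build a Cn-symmetric ring assembly
#'
#' Places `n` copies of the subunit by successive rotations of `360/n`
#' degrees about `axis` (passing through the origin, the ring centre). The
#' subunit is first centred and shifted radially so its centroid lies at
#' `ring_radius` from the axis; each copy's chains are re-lettered uniquely.
#' The output has exact n-fold symmetry.
#'
#' @param subunit An `ab_structure`.
#' @param n Symmetry order (>= 2).
#' @param axis Rotation axis direction (3-vector).
#' @param ring_radius Radial centroid distance from the axis, Angstrom (>= 0).
#' @param recenter If `FALSE`, the subunit is used in place (its current
#'   position relative to the origin/axis is respected and `ring_radius` is
#'   ignored).
#' @return An `ab_structure` with attributes `symmetry_axis` and
#'   `symmetry_order`.
#' @export
build_cn_assembly <- function(subunit, n, axis = c(0, 0, 1), ring_radius = 0,
                              recenter = TRUE) {
  stopifnot(inherits(subunit, "ab_structure"))
  n <- as.integer(n)
  if (n < 2L) stop("n must be >= 2")
  if (ring_radius < 0) stop("ring_radius must be >= 0")
  u <- unitv(axis)
  s0 <- subunit
  if (recenter) {
    e <- if (abs(u[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    radial <- unitv(e - sum(e * u) * u)
    s0$xyz <- sweep(s0$xyz, 2L, centroid(s0$xyz)) +
      matrix(radial * ring_radius, n_atoms(s0), 3L, byrow = TRUE)
  }
  copies <- vector("list", n)
  copies[[1L]] <- s0
  for (k in seq_len(n - 1L)) {
    rot <- transform_op(rotation_about_axis(u, 360 * k / n), c(0, 0, 0))
    copies[[k + 1L]] <- apply_transform(s0, rot)
  }
  out <- combine_structures(copies, title = sprintf("C%d assembly", n))
  # clash guard between distinct copies (heavy atoms)
  heavy <- which(!s0$atoms$is_hydrogen)
  for (k in seq_len(n - 1L)) {
    d <- cpp_min_dist(copies[[1L]]$xyz[heavy, , drop = FALSE],
                      copies[[k + 1L]]$xyz[heavy, , drop = FALSE])
    if (d < 1.0)
      stop(sprintf(
        "inter-copy heavy-atom clash: minimum distance %.2f A < 1.0 A", d))
  }
  attr(out, "symmetry_axis") <- u
  attr(out, "symmetry_order") <- n
  out
}
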
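# Standard synthetic fixtures: the compact Abeta core monomer (residues
# 17-42, three-stranded meander with the C-terminal beta-hairpin and the
# F19-L34 sidechain contact), and the deterministic C3 hexamer / stacked
# dodecamer built from it. All numeric parameters are frozen construction
# choices of the fixture generator (see the methods vignette).

# Torsion profile of the core monomer. Strand torsions are beta (-135, 135);
# the C-terminal turn block comes from the hairpin schedule (turn at 37-38);
# the central-loop torsions (residues 23-30) were tuned once so the loop
# folds strand 17-23 against strand 30-36 with the F19/L34 sidechains in
# contact (< 6 A) and no steric clashes.
.core_loop_torsions <- list(
  psi23 = -168.5,
  phi = c(`24` = -169.0, `25` = 68.8, `26` = -44.8, `27` = -37.0,
          `28` = 39.2, `29` = 136.2),
  psi = c(`24` = -106.2, `25` = 164.9, `26` = -113.2, `27` = -109.1,
          `28` = -124.2, `29` = 40.5),
  phi30 = 92.7)

#' Build the standard Abeta core monomer (residues 17-42)
#'
#' A compact, clash-free monomer fixture: beta strands 17-23, 30-36 and
#' 39-42 in a three-stranded meander, a broad central loop over residues
#' 24-29, and the C-terminal hairpin turn at G37-G38. The F19 and L34
#' sidechains are in contact (minimum heavy-atom distance well under 6
#' Angstrom), mirroring the proximity constraint used when modelling Abeta
#' oligomers from the tetramer crystal form.
#'
#' @param chain_id Chain identifier.
#' @return An [ab_structure()] with residues numbered 17-42.
#' @export
build_core_monomer <- function(chain_id = "A") {
  resnums <- 17:42
  sched <- torsion_schedule(conformation_spec("hairpin", turn_center = 37L),
                            resnums)
  phi <- sched$phi; psi <- sched$psi
  psi[match(23L, resnums)] <- .core_loop_torsions$psi23
  for (r in 24:29) {
    phi[match(r, resnums)] <- .core_loop_torsions$phi[[as.character(r)]]
    psi[match(r, resnums)] <- .core_loop_torsions$psi[[as.character(r)]]
  }
  phi[match(30L, resnums)] <- .core_loop_torsions$phi30
  build_peptide(substr(abeta42_sequence(), 17, 42),
                conformation_spec("extended", phi = phi, psi = psi),
                chain_id = chain_id, start_resnum = 17L,
                title = "Abeta 17-42 core monomer fixture")
}

# Rotate a structure so that `from` maps onto direction `to`.
align_direction <- function(s, from, to) {
  f <- unitv(from); t2 <- unitv(to)
  v <- vcross(f, t2); c_ <- sum(f * t2)
  R <- if (vnorm(v) < 1e-12) {
    if (c_ > 0) diag(3) else rotation_about_axis(perp_basis(f)$v1, 180)
  } else rotation_about_axis(v, atan2(vnorm(v), c_) * 180 / pi)
  apply_transform(s, transform_op(R, c(0, 0, 0)))
}

# Orient the core monomer into the fixture frame: sheet normal along z,
# C-terminal (31-42) centroid direction along -x, centroid at origin.
orient_core_monomer <- function(mono) {
  mono$xyz <- sweep(mono$xyz, 2L, centroid(mono$xyz))
  ca <- select_atoms(mono, region_spec("ca", rbind(c(17L, 42L)), "calpha"))
  pc <- prcomp(mono$xyz[ca, , drop = FALSE])
  mono <- align_direction(mono, pc$rotation[, 3L], c(0, 0, 1))
  ct <- select_atoms(mono, region_cterm("heavy"))
  v <- centroid(mono$xyz[ct, , drop = FALSE]) - centroid(mono$xyz)
  v[3L] <- 0
  mono <- align_direction(mono, v, c(-1, 0, 0))
  mono$xyz <- sweep(mono$xyz, 2L, centroid(mono$xyz))
  mono
}

#' Build the standard dodecamer fixture
#'
#' Deterministic construction of the package's reference dodecamer: the core
#' monomer is stacked into a sheet-to-sheet dimer, three dimers form a C3
#' hexamer with the C-terminal hairpins oriented inward, and two hexamers are
#' stacked face-to-face about a 2-fold flip, giving 12 chains (chains A-L)
#' with a buried C-terminal core. Optionally each chain is completed with an
#' alpha-helical N-terminus (residues 1-16) radiating outward.
#'
#' @param n_term_helices Add helical residues 1-16 to every chain.
#' @param dimer_rise Sheet stacking distance inside a dimer, Angstrom. The
#'   upper copy is face-flipped (180 degrees about x) and offset laterally by
#'   `dimer_offset` so the sheet faces interdigitate without clashing.
#' @param dimer_offset Lateral (y) offset of the upper dimer copy, Angstrom.
#' @param ring_radius Centroid distance of each dimer from the 3-fold axis.
#' @param stack_gap Axial clearance between the z-extents of the two
#'   hexamers, Angstrom (negative values interdigitate the faces).
#' @param stack_twist Relative twist of the second hexamer about the 3-fold
#'   axis, degrees.
#' @return An [ab_structure()] with 12 chains; attribute `symmetry_axis` is
#'   the z axis.
#' @export
standard_dodecamer_fixture <- function(n_term_helices = TRUE,
                                       dimer_rise = 10,
                                       dimer_offset = 4,
                                       ring_radius = 16,
                                       stack_gap = -2,
                                       stack_twist = 40) {
  mono <- orient_core_monomer(build_core_monomer())
  upper <- apply_transform(mono, transform_op(
    rotation_about_axis(c(1, 0, 0), 180), c(0, 0, 0)))
  upper$xyz <- sweep(upper$xyz, 2L, c(0, dimer_offset, dimer_rise), "+")
  dimer <- combine_structures(list(mono, upper), title = "dimer fixture")
  hexamer <- build_cn_assembly(dimer, 3L, axis = c(0, 0, 1),
                               ring_radius = ring_radius)
  # second hexamer: flip about x through the origin, drop below, twist
  ext <- range(hexamer$xyz[, 3L])
  flip <- transform_op(rotation_about_axis(c(1, 0, 0), 180), c(0, 0, 0))
  lower <- apply_transform(hexamer, flip)
  lower <- apply_transform(lower, transform_op(
    rotation_about_axis(c(0, 0, 1), stack_twist), c(0, 0, 0)))
  # place: top of lower copy sits stack_gap below bottom of upper hexamer
  shift <- (ext[1L] - stack_gap) - max(lower$xyz[, 3L])
  lower$xyz[, 3L] <- lower$xyz[, 3L] + shift
  dodec <- combine_structures(list(hexamer, lower),
                              title = "dodecamer fixture")
  dodec$xyz <- sweep(dodec$xyz, 2L, centroid(dodec$xyz))
  if (n_term_helices) dodec <- prepend_nterm_helix(dodec)
  attr(dodec, "symmetry_axis") <- c(0, 0, 1)
  dodec
}

#' Complete chains with alpha-helical N-termini (residues 1-16)
#'
#' For every chain whose first residue is 17, builds residues 1-17 of the
#' Abeta sequence as an ideal alpha helix and grafts residues 1-16 onto the
#' chain by superposing the helix's residue-17 backbone (N, CA, C) onto the
#' chain's. Mirrors the modelling step of adding helical N-termini to
#' docked assemblies.
#'
#' @param s An `ab_structure` whose chains start at residue 17.
#' @param junction `c(psi16, phi17)` torsions of the helix-core junction,
#'   degrees; they set the helix direction relative to the core chain (the
#'   defaults were chosen once so the helices of the standard dodecamer
#'   radiate outward without steric overlap).
#' @return The completed `ab_structure` (residues 1-42 per chain).
#' @export
prepend_nterm_helix <- function(s, junction = c(90, -90)) {
  stopifnot(inherits(s, "ab_structure"))
  seg_seq <- substr(abeta42_sequence(), 1, 17)
  helix <- build_peptide(seg_seq,
                         conformation_spec("helix",
                                           phi = c(rep(-57, 16), junction[2L]),
                                           psi = c(rep(-47, 15), junction[1L], 135)))
  parts <- list()
  for (ch in chain_ids(s)) {
    sub <- subset_chains(s, ch)
    if (min(sub$atoms$resnum) != 17L) { parts[[ch]] <- sub; next }
    seg_idx <- vapply(c("N", "CA", "C"), function(nm)
      match_atom(helix, "A", 17L, nm), integer(1L))
    chn_idx <- vapply(c("N", "CA", "C"), function(nm)
      match_atom(sub, ch, 17L, nm), integer(1L))
    fit <- kabsch_superpose(helix$xyz[seg_idx, , drop = FALSE],
                            sub$xyz[chn_idx, , drop = FALSE])
    seg <- apply_transform(helix, fit$transform)
    keep <- seg$atoms$resnum <= 16L
    na <- seg$atoms[keep, , drop = FALSE]
    na$chain <- ch
    merged <- rbind(na, sub$atoms)
    merged$serial <- seq_len(nrow(merged))
    parts[[ch]] <- ab_structure(merged, rbind(seg$xyz[keep, , drop = FALSE],
                                              sub$xyz))
  }
  out <- combine_structures(parts, title = s$title)
  attr(out, "symmetry_axis") <- attr(s, "symmetry_axis")
  out
}
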
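# Hierarchical constrained rigid-body assembly: exhaustive-grid dimer
# docking, C3 symmetrization of dimers into hexamers, hexamer stacking into
# dodecamers, and the charged-group occlusion filter. Scoring is a
# transparent surrogate for surface-complementarity servers:
# score = contacts - 10 * clashes, with a required-contact-region constraint.

#' Docking constraint
#'
#' @param required_contact_region A [region_spec()]; a candidate must have at
#'   least `min_required_contacts` heavy-atom contact pairs with *both*
#'   partners inside this region (the C-terminus 31-42 by default, matching
#'   the restriction that interfaces involve the C-terminal segments).
#' @param contact_cutoff Heavy-atom pair distance below which a pair counts
#'   as a contact (Angstrom, default 5).
#' @param clash_cutoff Distance below which a pair counts as a steric clash
#'   (must be < `contact_cutoff`; default 2.5).
#' @param min_required_contacts Minimum region contact pairs (default 1).
#' @return An object of class `dock_constraint`.
#' @export
dock_constraint <- function(required_contact_region = region_cterm("heavy"),
                            contact_cutoff = 5.0, clash_cutoff = 2.5,
                            min_required_contacts = 1L) {
  if (clash_cutoff >= contact_cutoff)
    stop("clash_cutoff must be < contact_cutoff")
  structure(list(required_contact_region = required_contact_region,
                 contact_cutoff = contact_cutoff,
                 clash_cutoff = clash_cutoff,
                 min_required_contacts = as.integer(min_required_contacts)),
            class = "dock_constraint")
}

#' Charged-group occlusion rule
#'
#' Interfaces must not bury charged groups: a candidate fails when any listed
#' charged-group atom drops below `min_rsasa` relative accessibility in the
#' assembled complex while being at or above it in the isolated subunit.
#' C-terminal carboxylates (OXT and the terminal O) are always included.
#'
#' @param group_atoms Named list, residue name -> atom names carrying formal
#'   charge.
#' @param min_rsasa Minimum relative accessibility between 0 and 1 (default 0.10).
#' @return An object of class `charged_group_rule`.
#' @export
charged_group_rule <- function(group_atoms = list(
                                 LYS = "NZ", ARG = c("NH1", "NH2"),
                                 ASP = c("OD1", "OD2"),
                                 GLU = c("OE1", "OE2")),
                               min_rsasa = 0.10) {
  if (min_rsasa < 0 || min_rsasa > 1) stop("min_rsasa must be in [0, 1]")
  structure(list(group_atoms = group_atoms, min_rsasa = min_rsasa),
            class = "charged_group_rule")
}

heavy_info <- function(s, region) {
  idx <- which(!s$atoms$is_hydrogen)
  grp <- match(paste(s$atoms$chain[idx], s$atoms$resnum[idx]),
               unique(paste(s$atoms$chain[idx], s$atoms$resnum[idx])))
  reg <- rep(FALSE, length(idx))
  if (!is.null(region)) {
    rsel <- select_atoms(s, region_spec(region$name, region$ranges, "heavy"))
    reg <- idx %in% rsel
  }
  list(idx = idx, xyz = s$xyz[idx, , drop = FALSE], grp = as.integer(grp),
       reg = reg)
}

new_dock_candidate <- function(kind, placement, counts, grid_index, fixed,
                               mobile, extra = list()) {
  counts <- as.numeric(counts)
  structure(c(list(kind = kind, placement = placement,
                   n_contacts = counts[1L], n_clashes = counts[2L],
                   n_region_contacts = counts[3L],
                   score = counts[1L] - 10 * counts[2L],
                   grid_index = as.numeric(grid_index),
                   filter_report = c(required_region_contacts = TRUE),
                   fixed = fixed, mobile = mobile), extra),
            class = "dock_candidate")
}

#' @export
print.dock_candidate <- function(x, ...) {
  cat(sprintf("<dock_candidate:%s> score %g (%d contacts, %d clashes, %d in region), grid %d\n",
              x$kind, x$score, x$n_contacts, x$n_clashes,
              x$n_region_contacts, x$grid_index))
  invisible(x)
}

#' Assemble the structure a docking candidate describes
#'
#' @param cand A `dock_candidate` from [rigid_dock()], [symmetrize_c3()] or
#'   [stack_to_dodecamer()].
#' @return An `ab_structure` with chains re-lettered A, B, C, ...
#' @export
realize_candidate <- function(cand) {
  stopifnot(inherits(cand, "dock_candidate"))
  switch(cand$kind,
    dimer = ,
    stack = combine_structures(list(cand$fixed,
                                    apply_transform(cand$mobile,
                                                    cand$placement))),
    c3 = {
      g <- cand$placement
      s1 <- apply_transform(cand$fixed, g)
      s2 <- apply_transform(s1, g)
      out <- combine_structures(list(cand$fixed, s1, s2))
      attr(out, "symmetry_axis") <- cand$axis
      attr(out, "symmetry_order") <- 3L
      out
    },
    stop("unknown candidate kind: ", cand$kind))
}

rank_candidates <- function(cands, top_k) {
  if (length(cands) == 0L) return(structure(list(), class = "dock_candidates"))
  score <- vapply(cands, `[[`, numeric(1L), "score")
  clashes <- vapply(cands, `[[`, numeric(1L), "n_clashes")
  gi <- vapply(cands, `[[`, numeric(1L), "grid_index")
  ord <- order(-score, clashes, gi)
  structure(cands[ord[seq_len(min(top_k, length(ord)))]],
            class = "dock_candidates")
}

#' @export
print.dock_candidates <- function(x, ...) {
  cat(sprintf("<dock_candidates> %d candidate(s)\n", length(x)))
  for (c in x) print(c)
  invisible(x)
}

#' Candidate table / filter report
#'
#' @param cands A `dock_candidates` list.
#' @param file Optional TSV output path.
#' @return data.frame with one row per candidate (rank, counts, score and
#'   per-filter pass/fail columns).
#' @export
candidate_report <- function(cands, file = NULL) {
  df <- do.call(rbind, lapply(seq_along(cands), function(i) {
    c <- cands[[i]]
    fr <- as.list(c$filter_report)
    names(fr) <- paste0("filter_", names(fr))
    cbind(data.frame(rank = i, kind = c$kind, grid_index = c$grid_index,
                     n_contacts = c$n_contacts, n_clashes = c$n_clashes,
                     n_region_contacts = c$n_region_contacts,
                     score = c$score, stringsAsFactors = FALSE),
          as.data.frame(fr))
  }))
  if (!is.null(file))
    utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  df
}

#' Exhaustive-grid rigid-body docking
#'
#' Scans a full Euler rotation grid (`rot_step` degrees; alpha, gamma in
#' `[0, 360)`, beta in `[0, 180]`) crossed with a Cartesian translation grid
#' (`trans_step` Angstrom) over the bounding shell where the two surfaces can
#' touch. The mobile copy is rotated about its own centroid and its centroid
#' placed at `fixed centroid + t`. Contacts/clashes are heavy-atom pair
#' counts below the constraint cutoffs; candidates lacking
#' `min_required_contacts` pairs inside the required region (both partners)
#' are discarded; the rest are ranked by `score = contacts - 10 clashes`,
#' ties broken by fewer clashes then lexicographic grid index.
#'
#' @param fixed,mobile `ab_structure` partners.
#' @param c A [dock_constraint()].
#' @param rot_step Rotation grid step in degrees (must divide 360).
#' @param trans_step Translation grid step in Angstrom.
#' @param top_k Number of ranked candidates to return.
#' @return A `dock_candidates` list (possibly empty).
#' @export
rigid_dock <- function(fixed, mobile, c = dock_constraint(), rot_step = 30,
                       trans_step = 1.5, top_k = 10L) {
  stopifnot(inherits(fixed, "ab_structure"), inherits(mobile, "ab_structure"))
  if (360 %% rot_step != 0) stop("rot_step must divide 360")
  A <- heavy_info(fixed, c$required_contact_region)
  B <- heavy_info(mobile, c$required_contact_region)
  cf <- centroid(A$xyz); cm <- centroid(B$xyz)
  Rf <- bounding_radius(A$xyz); Rm <- bounding_radius(B$xyz)
  L <- Rf + Rm + c$contact_cutoff
  g <- seq(-floor(L / trans_step) * trans_step, L + 1e-9, by = trans_step)
  tg <- as.matrix(expand.grid(x = g, y = g, z = g,
                              KEEP.OUT.ATTRS = FALSE))[, c(1L, 2L, 3L)]
  # lexicographic order tx, ty, tz
  tg <- tg[order(tg[, 1L], tg[, 2L], tg[, 3L]), , drop = FALSE]
  keep <- sqrt(rowSums(tg^2)) <= L + 1e-9
  tg <- tg[keep, , drop = FALSE]
  alphas <- seq(0, 360 - rot_step, by = rot_step)
  betas <- seq(0, 180, by = rot_step)
  gammas <- alphas
  Bc <- sweep(B$xyz, 2L, cm)
  trans <- sweep(tg, 2L, cf, "+")
  eulers <- as.matrix(expand.grid(ga = gammas, be = betas, al = alphas,
                                  KEEP.OUT.ATTRS = FALSE))[, 3:1, drop = FALSE]
  n_tr <- nrow(tg)
  hits <- list()
  for (rot_i in seq_len(nrow(eulers))) {
    R <- euler_zyz(eulers[rot_i, 1L], eulers[rot_i, 2L], eulers[rot_i, 3L])
    counts <- cpp_dock_scan(A$xyz, Bc %*% t(R), trans, A$grp, B$grp,
                            A$reg, B$reg, c$contact_cutoff, c$clash_cutoff)
    hit <- which(counts[, 3L] >= c$min_required_contacts)
    if (length(hit) > 0L)
      hits[[length(hits) + 1L]] <- cbind(rot_i, hit, counts[hit, , drop = FALSE])
  }
  if (length(hits) == 0L) return(structure(list(), class = "dock_candidates"))
  H <- do.call(rbind, hits)
  score <- H[, 3L] - 10 * H[, 4L]
  gi <- (H[, 1L] - 1) * n_tr + H[, 2L]
  ord <- order(-score, H[, 4L], gi)[seq_len(min(top_k, nrow(H)))]
  cands <- lapply(ord, function(k) {
    R <- euler_zyz(eulers[H[k, 1L], 1L], eulers[H[k, 1L], 2L],
                   eulers[H[k, 1L], 3L])
    tau <- trans[H[k, 2L], ] - as.numeric(R %*% cm)
    new_dock_candidate("dimer", transform_op(R, tau), H[k, 3:5],
                       grid_index = gi[k], fixed = fixed, mobile = mobile)
  })
  structure(cands, class = "dock_candidates")
}

# Deterministic perpendicular basis for a unit axis.
perp_basis <- function(u) {
  e <- if (abs(u[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  v1 <- unitv(e - sum(e * u) * u)
  list(v1 = v1, v2 = vcross(u, v1))
}

#' C3 symmetrization of a dimer into hexamer candidates
#'
#' Scans candidate 3-fold axes (a grid of directions and in-plane offsets
#' from the dimer centroid); each axis generates the C3 triple of the dimer.
#' Inter-copy contacts and clashes are counted between adjacent copies (all
#' three interfaces are congruent by symmetry, so totals are three times the
#' single-interface counts); candidates whose interfaces lack the required
#' region contacts are discarded. Output hexamers are exactly 3-fold
#' symmetric by construction.
#'
#' @param dimer An `ab_structure` with >= 2 chains.
#' @param c A [dock_constraint()].
#' @param axis_search List with `n_directions` (axis directions, quasi-
#'   uniform over the hemisphere), `offset_step` (Angstrom) and optional
#'   `max_offset` (default: reaches the bounding shell).
#' @param top_k Number of ranked candidates to return.
#' @return A `dock_candidates` list of kind `"c3"`.
#' @export
symmetrize_c3 <- function(dimer, c = dock_constraint(),
                          axis_search = list(n_directions = 40L,
                                             offset_step = 2.0,
                                             max_offset = NULL),
                          top_k = 10L) {
  stopifnot(inherits(dimer, "ab_structure"))
  if (n_chains(dimer) < 2L) stop("dimer must have at least 2 chains")
  A <- heavy_info(dimer, c$required_contact_region)
  ctr <- centroid(A$xyz)
  Rb <- bounding_radius(A$xyz)
  max_off <- axis_search$max_offset
  if (is.null(max_off)) max_off <- (2 * Rb + c$contact_cutoff) / sqrt(3)
  dirs <- fibonacci_sphere(2L * axis_search$n_directions)
  dirs <- dirs[dirs[, 3L] >= 0, , drop = FALSE]
  og <- seq(-floor(max_off / axis_search$offset_step) * axis_search$offset_step,
            max_off + 1e-9, by = axis_search$offset_step)
  cands <- list()
  gi <- 0L
  for (d in seq_len(nrow(dirs))) {
    u <- unitv(dirs[d, ])
    pb <- perp_basis(u)
    for (a in og) for (b in og) {
      gi <- gi + 1L
      if (sqrt(a * a + b * b) > max_off + 1e-9) next
      p <- ctr + a * pb$v1 + b * pb$v2
      R <- rotation_about_axis(u, 120)
      tau <- p - as.numeric(R %*% p)
      B1 <- sweep(A$xyz %*% t(R), 2L, tau, "+")
      counts <- cpp_dock_scan(A$xyz, B1, matrix(0, 1L, 3L), A$grp, A$grp,
                              A$reg, A$reg, c$contact_cutoff, c$clash_cutoff)
      counts <- 3L * counts[1L, ]
      if (counts[3L] < c$min_required_contacts) next
      cands[[length(cands) + 1L]] <- new_dock_candidate(
        "c3", transform_op(R, tau), counts, grid_index = gi,
        fixed = dimer, mobile = dimer,
        extra = list(axis = u, axis_point = p))
    }
  }
  rank_candidates(cands, top_k)
}

#' Stack a hexamer into dodecamer candidates
#'
#' The second hexamer copy is placed by the C2 flip family: 180-degree
#' rotations about in-plane axes perpendicular to the hexamer's 3-fold axis
#' (through its centroid, directions every `flip_step` degrees), combined
#' with translation along the 3-fold axis. Candidates are scored and filtered
#' like [rigid_dock()]; every returned model has 12 chains when realized.
#'
#' @param hexamer An `ab_structure` with 6 chains (typically from
#'   [symmetrize_c3()], which records the symmetry axis).
#' @param c A [dock_constraint()].
#' @param axis The hexamer 3-fold axis; default the recorded
#'   `symmetry_axis` attribute, else z.
#' @param flip_step Flip-axis direction step in degrees.
#' @param trans_step Axial translation step in Angstrom.
#' @param top_k Number of ranked candidates to return.
#' @return A `dock_candidates` list of kind `"stack"`.
#' @export
stack_to_dodecamer <- function(hexamer, c = dock_constraint(), axis = NULL,
                               flip_step = 30, trans_step = 1.5, top_k = 10L) {
  stopifnot(inherits(hexamer, "ab_structure"))
  if (n_chains(hexamer) != 6L) stop("hexamer must have 6 chains")
  if (is.null(axis)) axis <- attr(hexamer, "symmetry_axis")
  if (is.null(axis)) axis <- c(0, 0, 1)
  u <- unitv(axis)
  A <- heavy_info(hexamer, c$required_contact_region)
  ctr <- centroid(A$xyz)
  ext <- max(abs((sweep(A$xyz, 2L, ctr)) %*% u))
  L <- 2 * ext + c$contact_cutoff
  zg <- seq(-floor(L / trans_step) * trans_step, L + 1e-9, by = trans_step)
  pb <- perp_basis(u)
  phis <- seq(0, 180 - flip_step, by = flip_step)
  cands <- list()
  gi <- 0L
  for (phi in phis) {
    f <- cos(phi * pi / 180) * pb$v1 + sin(phi * pi / 180) * pb$v2
    R <- rotation_about_axis(f, 180)
    tau0 <- ctr - as.numeric(R %*% ctr)
    Brot <- A$xyz %*% t(R)
    trans <- t(vapply(zg, function(z) tau0 + z * u, numeric(3L)))
    counts <- cpp_dock_scan(A$xyz, Brot, trans, A$grp, A$grp, A$reg, A$reg,
                            c$contact_cutoff, c$clash_cutoff)
    for (h in seq_along(zg)) {
      gi <- gi + 1L
      if (counts[h, 3L] < c$min_required_contacts) next
      cands[[length(cands) + 1L]] <- new_dock_candidate(
        "stack", transform_op(R, trans[h, ]), counts[h, ],
        grid_index = gi, fixed = hexamer, mobile = hexamer)
    }
  }
  rank_candidates(cands, top_k)
}

# rSASA of one atom against the appropriate tripeptide reference position
# (central residue for sidechain groups, C-terminal residue for OXT / the
# terminal carboxylate O).
charged_atom_rsasa <- function(s, idx, p, flank = "A") {
  a <- s$atoms
  vals <- unname(shrake_rupley(s, p, subset = idx)$per_atom)
  out <- numeric(length(idx))
  for (k in seq_along(idx)) {
    i <- idx[k]
    rl <- .aa3to1[[a$resname[i]]]
    terminal <- a$name[i] == "OXT" ||
      (a$name[i] == "O" && a$resnum[i] == max(a$resnum[a$chain == a$chain[i]]))
    ref <- if (terminal) {
      key <- paste("cterm", rl, a$name[i], flank, p$probe_radius, p$n_points,
                   sep = "|")
      if (is.null(.pkg_cache$ref_sasa))
        .pkg_cache$ref_sasa <- new.env(parent = emptyenv())
      hit <- .pkg_cache$ref_sasa[[key]]
      if (is.null(hit)) {
        tri <- build_peptide(paste0(flank, flank, rl),
                             conformation_spec("extended"))
        j <- match_atom(tri, "A", 3L, a$name[i])
        hit <- unname(shrake_rupley(tri, p, subset = j)$per_atom)
        .pkg_cache$ref_sasa[[key]] <- hit
      }
      hit
    } else reference_atom_sasa(rl, a$name[i], flank, p)
    out[k] <- vals[k] / ref
  }
  out
}

charged_atom_indices <- function(s, rule) {
  a <- s$atoms
  idx <- integer(0)
  for (rn in names(rule$group_atoms))
    idx <- c(idx, which(a$resname == rn & a$name %in% rule$group_atoms[[rn]]))
  for (ch in unique(a$chain)) {
    last <- max(a$resnum[a$chain == ch])
    idx <- c(idx, which(a$chain == ch & a$resnum == last &
                          a$name %in% c("OXT", "O")))
  }
  sort(unique(idx))
}

#' Filter candidates by charged-group occlusion
#'
#' A candidate fails when the assembled complex buries a charged-group atom
#' below `rule$min_rsasa` relative accessibility although the atom is
#' accessible (>= `min_rsasa`) in its isolated subunit. Passing candidates
#' are returned in their original rank order with updated filter reports.
#'
#' @param candidates A `dock_candidates` list.
#' @param rule A [charged_group_rule()].
#' @param p A [sasa_params()] used for all accessibility calculations.
#' @param max_keep Stop evaluating (in rank order) once this many candidates
#'   have passed; `NULL` evaluates every candidate. The report covers the
#'   candidates actually evaluated.
#' @return The passing `dock_candidates` (original order); the report is
#'   attached as attribute `report`.
#' @export
filter_candidates <- function(candidates, rule = charged_group_rule(),
                              p = sasa_params(), max_keep = NULL) {
  if (length(candidates) == 0L) return(candidates)
  # isolated-subunit accessibility, computed once per distinct subunit
  iso_cache <- list()
  iso_rsasa <- function(sub) {
    key <- paste(n_atoms(sub), sum(sub$xyz), collapse = "|")
    if (is.null(iso_cache[[key]])) {
      idx <- charged_atom_indices(sub, rule)
      iso_cache[[key]] <<- list(idx = idx,
                                vals = charged_atom_rsasa(sub, idx, p))
    }
    iso_cache[[key]]
  }
  keep <- logical(length(candidates))
  evaluated <- 0L
  for (ci in seq_along(candidates)) {
    if (!is.null(max_keep) && sum(keep) >= max_keep) break
    evaluated <- ci
    cand <- candidates[[ci]]
    complex <- realize_candidate(cand)
    idx_c <- charged_atom_indices(complex, rule)
    vals_c <- charged_atom_rsasa(complex, idx_c, p)
    # map complex atoms back to their source subunits by order: fixed atoms
    # first, then mobile copies (realize_candidate preserves atom order)
    parts <- switch(cand$kind,
      dimer = , stack = list(cand$fixed, cand$mobile),
      c3 = list(cand$fixed, cand$fixed, cand$fixed))
    iso_vals <- numeric(0)
    offset <- 0L
    for (pt in parts) {
      iso <- iso_rsasa(pt)
      iso_idx_global <- iso$idx + offset
      iso_vals <- c(iso_vals, setNames(iso$vals, iso_idx_global))
      offset <- offset + n_atoms(pt)
    }
    iso_for_complex <- iso_vals[as.character(idx_c)]
    occluded <- !is.na(iso_for_complex) & iso_for_complex >= rule$min_rsasa &
      vals_c < rule$min_rsasa
    ok <- !any(occluded)
    cand$filter_report <- c(cand$filter_report, charged_occlusion = ok)
    candidates[[ci]] <- cand
    keep[ci] <- ok
  }
  out <- structure(candidates[keep], class = "dock_candidates")
  attr(out, "report") <- candidate_report(
    structure(candidates[seq_len(evaluated)], class = "dock_candidates"))
  out
}
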
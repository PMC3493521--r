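# Solvent accessible surface areas (Shrake-Rupley sphere sampling), relative
# SASA against extended reference tripeptides, amide protection fractions and
# interface buried surface area.

#' SASA calculation parameters
#'
#' @param probe_radius Solvent probe radius in Angstrom (default 1.4, water).
#' @param n_points Number of sphere sample points per atom (>= 16; the
#'   default 960 gives < 1% error on an isolated sphere).
#' @param radii_set Named map element -> van der Waals radius in Angstrom;
#'   defaults to Bondi radii with H = 1.20.
#' @return An object of class `sasa_params`.
#' @export
sasa_params <- function(probe_radius = 1.4, n_points = 960L,
                        radii_set = bondi_radii()) {
  if (probe_radius <= 0) stop("probe_radius must be > 0")
  if (n_points < 16L) stop("n_points must be >= 16")
  structure(list(probe_radius = probe_radius, n_points = as.integer(n_points),
                 radii_set = radii_set),
            class = "sasa_params")
}

atom_radii <- function(s, radii_set) {
  el <- s$atoms$element
  missing_el <- setdiff(unique(el), names(radii_set))
  if (length(missing_el) > 0L)
    stop("no van der Waals radius defined for element(s): ",
         paste(missing_el, collapse = ", "))
  unname(radii_set[el])
}

#' Per-atom solvent accessible surface area (Shrake-Rupley)
#'
#' For each atom, the fraction of `n_points` quasi-uniform points on its
#' probe-expanded sphere (radius r + probe) that fall inside no neighbouring
#' expanded sphere, times `4 pi (r + probe)^2`. Hydrogens are ordinary atoms
#' with their own radius.
#'
#' @param s An `ab_structure`.
#' @param p A [sasa_params()].
#' @param subset Optional atom indices to evaluate (the whole structure still
#'   acts as occluder). Default: all atoms.
#' @return An object of class `sasa_result`: list with `per_atom` (named
#'   numeric vector, names = atom indices, Angstrom^2) and `params`.
#' @export
shrake_rupley <- function(s, p = sasa_params(), subset = NULL) {
  stopifnot(inherits(s, "ab_structure"))
  if (!all(is.finite(s$xyz))) stop("coordinates must be finite")
  radii <- atom_radii(s, p$radii_set)
  if (is.null(subset)) subset <- seq_len(n_atoms(s))
  subset <- as.integer(subset)
  sphere <- fibonacci_sphere(p$n_points)
  areas <- cpp_sasa(s$xyz, radii, p$probe_radius, sphere, subset)
  structure(list(per_atom = setNames(areas, subset), params = p),
            class = "sasa_result")
}

#' @export
print.sasa_result <- function(x, ...) {
  cat(sprintf("<sasa_result> %d atoms, total %.1f A^2 (probe %.2f, %d points)\n",
              length(x$per_atom), sum(x$per_atom), x$params$probe_radius,
              x$params$n_points))
  invisible(x)
}

match_atom <- function(s, chain, resnum, name) {
  a <- s$atoms
  which(a$chain == chain & a$resnum == resnum & a$name == name)
}

# SASA of one named atom of the central residue of a reference tripeptide,
# cached per (residue type, atom name, flank, probe, n_points).
reference_atom_sasa <- function(resletter, atom_name, flank, p) {
  key <- paste(resletter, atom_name, flank, p$probe_radius, p$n_points,
               sep = "|")
  if (is.null(.pkg_cache$ref_sasa)) .pkg_cache$ref_sasa <- new.env(parent = emptyenv())
  hit <- .pkg_cache$ref_sasa[[key]]
  if (!is.null(hit)) return(hit)
  ref <- build_reference_tripeptide(resletter, flank)
  idx <- match_atom(ref, "A", attr(ref, "central_resnum"), atom_name)
  if (length(idx) != 1L)
    stop("reference tripeptide for ", resletter, " has no atom ", atom_name)
  val <- unname(shrake_rupley(ref, p, subset = idx)$per_atom)
  .pkg_cache$ref_sasa[[key]] <- val
  val
}

.aa3to1 <- setNames(names(.aa1to3), .aa1to3)

#' Relative solvent accessibility against reference tripeptides
#'
#' rSASA of an atom is its SASA in the structure divided by the SASA of the
#' same atom in the extended reference tripeptide (AxA or GxA) for its
#' residue type. For trajectories, the per-atom SASA is averaged over frames
#' before division. Values are not clamped and may exceed 1.
#'
#' @param s An `ab_structure` or `ab_trajectory`.
#' @param targets `data.frame` with columns `resnum` and `name` (atom name),
#'   and optionally `chain`; without `chain` every chain containing the atom
#'   is evaluated.
#' @param p A [sasa_params()].
#' @param flank Reference flank residue, `"A"` (AxA) or `"G"` (GxA).
#' @return `data.frame` with columns `chain`, `resnum`, `name`, `value`,
#'   `reference_context`.
#' @export
rsasa <- function(s, targets, p = sasa_params(), flank = c("A", "G")) {
  flank <- match.arg(flank)
  topo <- if (inherits(s, "ab_trajectory")) s$topology else s
  stopifnot(inherits(topo, "ab_structure"))
  targets <- as.data.frame(targets)
  # expand targets to concrete atoms
  rows <- list()
  for (k in seq_len(nrow(targets))) {
    chains <- if ("chain" %in% names(targets)) targets$chain[k] else
      unique(topo$atoms$chain)
    for (ch in chains) {
      idx <- match_atom(topo, ch, targets$resnum[k], targets$name[k])
      if (length(idx) == 1L)
        rows[[length(rows) + 1L]] <- data.frame(
          chain = ch, resnum = targets$resnum[k], name = targets$name[k],
          idx = idx, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L)
    stop("none of the requested target atoms exist in the structure",
         if (!any(topo$atoms$is_hydrogen))
           " (structure has no hydrogens; rebuild fixtures with hydrogens)"
         else "")
  tg <- do.call(rbind, rows)
  sasa_vals <- if (inherits(s, "ab_trajectory")) {
    acc <- rep(0, nrow(tg))
    radii <- atom_radii(topo, p$radii_set)
    sphere <- fibonacci_sphere(p$n_points)
    for (f in s$frames)
      acc <- acc + cpp_sasa(f, radii, p$probe_radius, sphere, tg$idx)
    acc / length(s$frames)
  } else {
    unname(shrake_rupley(s, p, subset = tg$idx)$per_atom)
  }
  vals <- numeric(nrow(tg))
  for (k in seq_len(nrow(tg))) {
    rname <- topo$atoms$resname[tg$idx[k]]
    rl <- .aa3to1[[rname]]
    if (is.null(rl)) stop("no reference tripeptide for residue type ", rname)
    ref <- reference_atom_sasa(rl, tg$name[k], flank, p)
    if (ref <= 0)
      stop("reference SASA is zero for ", rname, " atom ", tg$name[k],
           "; rSASA undefined")
    vals[k] <- sasa_vals[k] / ref
  }
  data.frame(chain = tg$chain, resnum = tg$resnum, name = tg$name,
             value = vals,
             reference_context = paste0(flank, "x", flank),
             stringsAsFactors = FALSE)
}

#' Backbone amide protection fraction
#'
#' Fraction of backbone amide protons in a region whose rSASA is strictly
#' below `threshold` (the H/D-exchange-protection proxy: rSASA < 10% counts
#' as protected). Trajectories use frame-averaged SASA.
#'
#' @param s An `ab_structure` or `ab_trajectory`.
#' @param region A [region_spec()]; its atom filter is ignored (amide protons
#'   are always used).
#' @param p A [sasa_params()].
#' @param threshold Protection threshold on rSASA (default 0.10, strict `<`).
#' @param flank Reference flank for the rSASA denominators.
#' @return Fraction between 0 and 1.
#' @export
protection_fraction <- function(s, region, p = sasa_params(),
                                threshold = 0.10, flank = "A") {
  topo <- if (inherits(s, "ab_trajectory")) s$topology else s
  spec <- region_spec(region$name, region$ranges, "amide_proton")
  idx <- suppressWarnings(select_atoms(topo, spec))
  if (length(idx) == 0L)
    stop("region '", region$name, "' contains no backbone amide protons",
         if (!any(topo$atoms$is_hydrogen))
           "; the structure has no hydrogens (rebuild fixtures with hydrogens)"
         else "")
  tg <- topo$atoms[idx, c("chain", "resnum", "name")]
  rec <- rsasa(s, tg, p, flank)
  mean(rec$value < threshold)
}

#' Interface buried surface area
#'
#' `dSASA = SASA(A alone) + SASA(B alone) - SASA(complex)`, all three with
#' identical parameters. The chain sets must be disjoint, non-empty, and
#' together cover the complex.
#'
#' @param complex An `ab_structure`.
#' @param part_a,part_b Character vectors of chain identifiers.
#' @param p A [sasa_params()].
#' @return Buried area in Angstrom^2.
#' @export
interface_buried_sasa <- function(complex, part_a, part_b, p = sasa_params()) {
  stopifnot(inherits(complex, "ab_structure"))
  if (length(intersect(part_a, part_b)) > 0L)
    stop("part_a and part_b must be disjoint chain sets")
  if (length(part_a) == 0L || length(part_b) == 0L)
    stop("both chain sets must be non-empty")
  all_ch <- chain_ids(complex)
  if (!setequal(union(part_a, part_b), all_ch))
    stop("part_a and part_b must together cover all chains of the complex")
  sa <- sum(shrake_rupley(subset_chains(complex, part_a), p)$per_atom)
  sb <- sum(shrake_rupley(subset_chains(complex, part_b), p)$per_atom)
  sc <- sum(shrake_rupley(complex, p)$per_atom)
  sa + sb - sc
}
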
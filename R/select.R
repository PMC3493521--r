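# Residue-range / atom-class selections. The canonical regions of the Abeta42
# analyses are the N-terminus (1-17), central region (18-30), C-terminus
# (31-42) and the structured core (17-42).

.atom_filters <- c("all", "heavy", "mainchain", "calpha", "sidechain",
                   "amide_proton")
.mainchain_names <- c("N", "CA", "C", "O")

#' Define a residue-region / atom-class selection
#'
#' @param name Label for the region.
#' @param ranges Residue ranges, as a two-column matrix or a list of
#'   `c(start, end)` pairs (inclusive, 1-based). Ranges must not overlap.
#' @param atom_filter One of `"all"`, `"heavy"`, `"mainchain"` (N, CA, C, O),
#'   `"calpha"`, `"sidechain"` (non-mainchain heavy atoms) or
#'   `"amide_proton"` (backbone H bonded to N).
#' @return An object of class `region_spec`.
#' @export
region_spec <- function(name, ranges, atom_filter = "all") {
  if (is.list(ranges)) ranges <- do.call(rbind, ranges)
  ranges <- matrix(as.integer(ranges), ncol = 2L)
  atom_filter <- match.arg(atom_filter, .atom_filters)
  if (any(ranges[, 1L] > ranges[, 2L]))
    stop("each range must have start <= end")
  if (nrow(ranges) > 1L) {
    o <- order(ranges[, 1L])
    r <- ranges[o, , drop = FALSE]
    if (any(r[-1L, 1L] <= r[-nrow(r), 2L]))
      stop("ranges must be non-overlapping")
  }
  structure(list(name = name, ranges = ranges, atom_filter = atom_filter),
            class = "region_spec")
}

# Stock regions used throughout the Abeta42 analyses.
#' Standard Abeta42 analysis regions
#'
#' Convenience constructors for the conventional regions: N-terminus 1-17,
#' central 18-30, C-terminus 31-42, and the structured core 17-42.
#'
#' @param atom_filter Atom class, see [region_spec()].
#' @return A `region_spec`.
#' @export
#' @rdname standard_regions
region_nterm <- function(atom_filter = "all")
  region_spec("N-terminus", rbind(c(1L, 17L)), atom_filter)

#' @export
#' @rdname standard_regions
region_central <- function(atom_filter = "all")
  region_spec("central", rbind(c(18L, 30L)), atom_filter)

#' @export
#' @rdname standard_regions
region_cterm <- function(atom_filter = "all")
  region_spec("C-terminus", rbind(c(31L, 42L)), atom_filter)

#' @export
#' @rdname standard_regions
region_core <- function(atom_filter = "all")
  region_spec("core", rbind(c(17L, 42L)), atom_filter)

in_ranges <- function(resnum, ranges) {
  hit <- rep(FALSE, length(resnum))
  for (k in seq_len(nrow(ranges)))
    hit <- hit | (resnum >= ranges[k, 1L] & resnum <= ranges[k, 2L])
  hit
}

#' Select atoms by region and atom class
#'
#' Returns atom indices in topology order. The atom filter is applied after
#' the residue-range restriction. An empty result is allowed.
#'
#' @param s An `ab_structure`.
#' @param spec A `region_spec`.
#' @param chains Optional character vector restricting the selection to these
#'   chain identifiers.
#' @return Integer vector of atom indices (possibly empty).
#' @export
select_atoms <- function(s, spec, chains = NULL) {
  stopifnot(inherits(s, "ab_structure"), inherits(spec, "region_spec"))
  a <- s$atoms
  keep <- in_ranges(a$resnum, spec$ranges)
  if (!is.null(chains)) keep <- keep & a$chain %in% chains
  keep <- keep & switch(spec$atom_filter,
    all = TRUE,
    heavy = !a$is_hydrogen,
    mainchain = a$name %in% .mainchain_names & !a$is_hydrogen,
    calpha = a$name == "CA" & !a$is_hydrogen,
    sidechain = !(a$name %in% c(.mainchain_names, "OXT")) & !a$is_hydrogen,
    amide_proton = a$is_hydrogen & a$name == "H")
  idx <- which(keep)
  if (spec$atom_filter == "amide_proton" && length(idx) == 0L &&
      !any(a$is_hydrogen))
    warning("structure contains no hydrogens; amide_proton selection is empty")
  idx
}
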
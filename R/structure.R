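# Hierarchical structure container: chain -> residue -> atom, stored flat as
# an atom table plus an n x 3 coordinate matrix (the layout every numerical
# routine in the package consumes directly).

#' Create a molecular structure object
#'
#' The central container of the package: a flat atom table (one row per atom,
#' ordered chain -> residue -> atom) together with an `n x 3` coordinate
#' matrix in Angstrom. The hierarchical chain/residue/atom organisation is
#' encoded by the `chain`, `resnum`, `resname` columns.
#'
#' @param atoms `data.frame` with columns `serial` (integer), `name` (PDB atom
#'   name), `element` (element symbol), `resname` (3-letter residue code),
#'   `chain` (single character), `resnum` (integer, 1-based), `occupancy`,
#'   `bfactor` (Angstrom^2) and `is_hydrogen` (logical).
#' @param xyz Numeric matrix `n x 3`, Angstrom.
#' @param title Free-text title.
#' @return An object of class `ab_structure`.
#' @export
ab_structure <- function(atoms, xyz, title = "") {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  xyz <- as.matrix(xyz)
  storage.mode(xyz) <- "double"
  s <- structure(list(atoms = atoms, xyz = xyz, title = title),
                 class = "ab_structure")
  validate_structure(s)
  s
}

validate_structure <- function(s) {
  a <- s$atoms
  req <- c("serial", "name", "element", "resname", "chain", "resnum",
           "occupancy", "bfactor", "is_hydrogen")
  missing_cols <- setdiff(req, names(a))
  if (length(missing_cols) > 0L)
    stop("atom table is missing columns: ", paste(missing_cols, collapse = ", "))
  if (nrow(a) == 0L) stop("structure has no atoms")
  if (nrow(s$xyz) != nrow(a) || ncol(s$xyz) != 3L)
    stop("coordinate matrix must be n x 3 with one row per atom")
  if (!all(is.finite(s$xyz))) stop("coordinates must be finite")
  key <- paste(a$chain, a$resnum, a$name)
  if (anyDuplicated(key))
    stop("(chain, resnum, atom name) must be jointly unique; duplicated: ",
         key[duplicated(key)][1L])
  # resnum strictly increasing within each chain (checked on residue order)
  for (ch in unique(a$chain)) {
    rn <- a$resnum[a$chain == ch]
    rr <- rle(rn)$values
    if (any(diff(rr) <= 0))
      stop("residue numbers must be strictly increasing within chain ", ch)
  }
  invisible(s)
}

#' @export
print.ab_structure <- function(x, ...) {
  a <- x$atoms
  cat(sprintf("<ab_structure> %d atoms, %d residues, %d chain(s) [%s]%s\n",
              nrow(a), nrow(unique(a[, c("chain", "resnum")])),
              length(unique(a$chain)), paste(unique(a$chain), collapse = ""),
              if (nzchar(x$title)) paste0(" - ", x$title) else ""))
  invisible(x)
}

n_atoms <- function(s) nrow(s$atoms)

#' Number of chains of a structure
#' @param s An `ab_structure`.
#' @return Integer.
#' @export
n_chains <- function(s) length(unique(s$atoms$chain))

#' Chain identifiers of a structure, in atom order
#' @param s An `ab_structure`.
#' @return Character vector of unique chain identifiers.
#' @export
chain_ids <- function(s) unique(s$atoms$chain)

#' Extract chains as a new structure
#' @param s An `ab_structure`.
#' @param chains Character vector of chain identifiers to keep.
#' @return An `ab_structure` restricted to `chains`.
#' @export
subset_chains <- function(s, chains) {
  keep <- s$atoms$chain %in% chains
  if (!any(keep)) stop("no atoms in chains: ", paste(chains, collapse = ", "))
  ab_structure(s$atoms[keep, , drop = FALSE], s$xyz[keep, , drop = FALSE],
               s$title)
}

# Concatenate structures, relettering chains A, B, C, ... in order.
combine_structures <- function(parts, title = "") {
  stopifnot(length(parts) >= 1L)
  pool <- c(LETTERS, letters, as.character(0:9))
  atoms <- list(); xyz <- list(); next_chain <- 1L
  for (p in parts) {
    a <- p$atoms
    map <- setNames(pool[seq(next_chain, next_chain + length(unique(a$chain)) - 1L)],
                    unique(a$chain))
    next_chain <- next_chain + length(map)
    a$chain <- unname(map[a$chain])
    atoms[[length(atoms) + 1L]] <- a
    xyz[[length(xyz) + 1L]] <- p$xyz
  }
  a <- do.call(rbind, atoms)
  a$serial <- seq_len(nrow(a))
  ab_structure(a, do.call(rbind, xyz), title)
}

centroid <- function(xyz) colMeans(xyz)

# Maximum distance of any atom from the centroid (bounding-sphere radius).
bounding_radius <- function(xyz) {
  ctr <- colMeans(xyz)
  sqrt(max(rowSums(sweep(xyz, 2L, ctr)^2)))
}

#' Trajectory container
#'
#' An ordered set of coordinate frames sharing one topology. Frames store
#' coordinates only; atom identities come from the topology structure.
#'
#' @param topology An `ab_structure` providing atom identities.
#' @param frames List of `n x 3` coordinate matrices (Angstrom), one per frame.
#' @param frame_interval Time between frames in picoseconds (> 0).
#' @return An object of class `ab_trajectory`.
#' @export
ab_trajectory <- function(topology, frames, frame_interval = 10) {
  stopifnot(inherits(topology, "ab_structure"))
  if (!is.list(frames) || length(frames) < 1L)
    stop("frames must be a non-empty list of coordinate matrices")
  if (!is.numeric(frame_interval) || frame_interval <= 0)
    stop("frame_interval must be > 0")
  na <- n_atoms(topology)
  for (i in seq_along(frames)) {
    f <- as.matrix(frames[[i]])
    if (nrow(f) != na || ncol(f) != 3L)
      stop(sprintf("frame %d has %d coordinates; topology has %d atoms",
                   i, nrow(f), na))
    storage.mode(f) <- "double"
    frames[[i]] <- f
  }
  structure(list(topology = topology, frames = frames,
                 frame_interval = frame_interval),
            class = "ab_trajectory")
}

#' @export
print.ab_trajectory <- function(x, ...) {
  cat(sprintf("<ab_trajectory> %d frames x %d atoms, dt = %g ps\n",
              length(x$frames), n_atoms(x$topology), x$frame_interval))
  invisible(x)
}

n_frames <- function(t) length(t$frames)

frame_times <- function(t) (seq_len(n_frames(t)) - 1L) * t$frame_interval

# A single frame as a full structure (for per-frame analyses).
frame_structure <- function(t, i) {
  s <- t$topology
  s$xyz <- t$frames[[i]]
  s
}
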
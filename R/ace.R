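# Atomic contact energies: per-residue sums of atom-type pairwise contact
# pseudo-energies (proportional to desolvation free energy; negative values
# indicate a hydrophobic environment). The package ships a synthetic 18-type
# parameter table; any table in the same plain-text format can be supplied.

#' Read an atomic contact energy table
#'
#' The file format has three sections: `[types]` (label and description per
#' line), `[energies]` (symmetric pair list `type type kcal/mol`), and
#' `[assignment]` (`resname atom type`, `*` matching any residue). Energies
#' are stored symmetrically.
#'
#' @param path Path to the table file.
#' @return An object of class `ace_table`.
#' @export
read_ace_table <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  sec <- cumsum(grepl("^\\[", lines))
  hdr <- lines[grepl("^\\[", lines)]
  blocks <- split(lines[!grepl("^\\[", lines)], sec[!grepl("^\\[", lines)])
  names(blocks) <- gsub("[][]", "", hdr)
  if (!all(c("types", "energies", "assignment") %in% names(blocks)))
    stop("ACE table must contain [types], [energies] and [assignment] sections")
  types <- vapply(strsplit(blocks$types, "\t"), `[`, "", 1L)
  E <- matrix(NA_real_, length(types), length(types),
              dimnames = list(types, types))
  for (ln in blocks$energies) {
    f <- strsplit(ln, "\t")[[1L]]
    E[f[1L], f[2L]] <- E[f[2L], f[1L]] <- as.numeric(f[3L])
  }
  if (anyNA(E)) stop("energy matrix is incomplete")
  asg <- do.call(rbind, strsplit(blocks$assignment, "\t"))
  assignment <- setNames(asg[, 3L], paste(asg[, 1L], asg[, 2L]))
  bad <- setdiff(unique(assignment), types)
  if (length(bad) > 0L) stop("assignment uses unknown type(s): ",
                             paste(bad, collapse = ", "))
  structure(list(types = types, energies = E, assignment = assignment),
            class = "ace_table")
}

#' The shipped synthetic 18-type ACE table
#'
#' A synthetic parameterization (this package's own values, not a published
#' table): 18 atom types covering every heavy atom of the 20 standard
#' residues, with hydrophobic-hydrophobic contacts negative and polar
#' contacts positive.
#'
#' @return An `ace_table`.
#' @export
default_ace_table <- function() {
  if (is.null(.pkg_cache$ace_table)) {
    path <- system.file("extdata", "ace_table_synthetic18.tsv",
                        package = "globulomeR", mustWork = TRUE)
    .pkg_cache$ace_table <- read_ace_table(path)
  }
  .pkg_cache$ace_table
}

ace_atom_types <- function(s, table, idx) {
  a <- s$atoms
  key <- paste(a$resname[idx], a$name[idx])
  ty <- table$assignment[key]
  wild <- is.na(ty)
  if (any(wild)) {
    ty[wild] <- table$assignment[paste("*", a$name[idx][wild])]
  }
  if (anyNA(ty)) {
    off <- which(is.na(ty))[1L]
    stop("untypable heavy atom: residue ", a$resname[idx][off], " atom ",
         a$name[idx][off])
  }
  unname(ty)
}

#' Per-residue atomic contact energy profile
#'
#' For every heavy-atom pair closer than `cutoff` whose residues are
#' separated by more than `exclusion` in sequence (pairs across different
#' chains always count), the pair energy `e(type_i, type_j)` is added to both
#' residues' totals; hydrogens are ignored. The grand total over residues is
#' therefore twice the sum over counted unordered pairs.
#'
#' @param s An `ab_structure`.
#' @param table An [ace_table()][read_ace_table]; default the shipped
#'   synthetic table.
#' @param cutoff Contact cutoff in Angstrom (default 6).
#' @param exclusion Sequence-separation exclusion within a chain: pairs with
#'   `|resnum_i - resnum_j| <= exclusion` are skipped (default 1, excluding
#'   intra-residue and sequence-adjacent pairs).
#' @return Object of class `ace_profile`: data.frame `chain`, `resnum`,
#'   `ace` (kcal/mol), with the cutoff as an attribute.
#' @export
residue_ace_profile <- function(s, table = default_ace_table(), cutoff = 6.0,
                                exclusion = 1L) {
  stopifnot(inherits(s, "ab_structure"))
  if (cutoff <= 0) stop("cutoff must be > 0")
  idx <- which(!s$atoms$is_hydrogen)
  ty <- ace_atom_types(s, table, idx)
  a <- s$atoms
  res_key <- paste(a$chain[idx], a$resnum[idx])
  res_levels <- unique(res_key)
  res_id <- match(res_key, res_levels)
  pairs <- cpp_pairs_self(s$xyz[idx, , drop = FALSE], cutoff)
  totals <- numeric(length(res_levels))
  if (nrow(pairs) > 0L) {
    i <- pairs[, 1L]; j <- pairs[, 2L]
    same_chain <- a$chain[idx][i] == a$chain[idx][j]
    sep <- abs(a$resnum[idx][i] - a$resnum[idx][j])
    keep <- !(same_chain & sep <= exclusion)
    i <- i[keep]; j <- j[keep]
    if (length(i) > 0L) {
      e <- table$energies[cbind(ty[i], ty[j])]
      for (k in seq_along(i)) {
        totals[res_id[i[k]]] <- totals[res_id[i[k]]] + e[k]
        totals[res_id[j[k]]] <- totals[res_id[j[k]]] + e[k]
      }
    }
  }
  parts <- strsplit(res_levels, " ")
  out <- data.frame(chain = vapply(parts, `[`, "", 1L),
                    resnum = as.integer(vapply(parts, `[`, "", 2L)),
                    ace = totals, stringsAsFactors = FALSE)
  class(out) <- c("ace_profile", "data.frame")
  attr(out, "cutoff") <- cutoff
  attr(out, "exclusion") <- exclusion
  out
}
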
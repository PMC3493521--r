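# PDB reading/writing. Parsing and serialisation of the fixed-column records
# is delegated to bio3d; this layer adds the package's policies: alternate
# locations resolved to the highest-occupancy conformer, element inference
# with hydrogen flagging, rejection of insertion codes, and promotion of
# multi-MODEL files to trajectories.

infer_element <- function(name, elesy = NULL) {
  el <- toupper(trimws(ifelse(is.na(elesy), "", elesy)))
  miss <- !nzchar(el)
  if (any(miss)) {
    nm <- toupper(sub("^[0-9']*", "", trimws(name[miss])))
    first <- substr(nm, 1L, 1L)
    guess <- first
    guess[first == "H"] <- "H"
    el[miss] <- guess
  }
  el
}

scan_pdb_lines <- function(lines) {
  is_rec <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(is_rec)) stop("no ATOM/HETATM records found")
  rec_lines <- which(is_rec)
  # insertion codes (column 27) are unsupported
  icode <- substr(lines[rec_lines], 27L, 27L)
  if (any(icode != " " & icode != "")) {
    ln <- rec_lines[which(icode != " " & icode != "")[1L]]
    stop("insertion codes are not supported (line ", ln, ")")
  }
  # coordinate fields must parse
  for (cols in list(c(31L, 38L), c(39L, 46L), c(47L, 54L))) {
    fld <- substr(lines[rec_lines], cols[1L], cols[2L])
    val <- suppressWarnings(as.numeric(fld))
    if (anyNA(val)) {
      ln <- rec_lines[which(is.na(val))[1L]]
      stop("unparseable coordinate field in columns ", cols[1L], "-", cols[2L],
           " at line ", ln)
    }
  }
  model_starts <- grep("^MODEL", lines)
  n_models <- length(model_starts)
  if (n_models >= 2L) {
    # count atom records per MODEL block
    model_of <- findInterval(rec_lines, model_starts)
    if (any(model_of == 0L))
      stop("ATOM records found before the first MODEL record")
    counts <- tabulate(model_of, nbins = n_models)
    if (length(unique(counts[counts > 0L])) > 1L)
      stop("topology mismatch: MODEL blocks contain differing atom counts (",
           paste(unique(counts), collapse = ", "), ")")
  }
  n_models
}

#' Parse PDB-format text
#'
#' Returns an [ab_structure()] for single-model input, or an
#' [ab_trajectory()] when the text contains two or more MODEL blocks with
#' identical atom ordering. Alternate locations are resolved to the
#' highest-occupancy conformer (ties: first encountered); hydrogens are
#' flagged from the element column, falling back to atom-name heuristics.
#' Insertion codes are rejected.
#'
#' @param text PDB-format text (single string or character vector of lines).
#' @param frame_interval Frame spacing in ps assigned to multi-model input.
#' @return An `ab_structure` or `ab_trajectory`.
#' @export
parse_pdb <- function(text, frame_interval = 10) {
  if (length(text) == 1L && grepl("\n", text, fixed = TRUE))
    text <- strsplit(text, "\n", fixed = TRUE)[[1L]]
  n_models <- scan_pdb_lines(text)
  tf <- tempfile(fileext = ".pdb")
  on.exit(unlink(tf))
  writeLines(text, tf)
  read_pdb_file(tf, n_models, frame_interval)
}

#' Read a PDB file
#'
#' File-based counterpart of [parse_pdb()].
#'
#' @param file Path to a PDB file.
#' @inheritParams parse_pdb
#' @return An `ab_structure` or `ab_trajectory`.
#' @export
read_pdb <- function(file, frame_interval = 10) {
  lines <- readLines(file, warn = FALSE)
  n_models <- scan_pdb_lines(lines)
  read_pdb_file(file, n_models, frame_interval)
}

read_pdb_file <- function(file, n_models, frame_interval) {
  p <- bio3d::read.pdb(file, multi = n_models >= 2L, rm.alt = FALSE,
                       verbose = FALSE)
  a <- p$atom
  occ <- ifelse(is.na(a$o), 1, a$o)
  # resolve alternate locations: keep the highest-occupancy conformer,
  # ties broken by file order
  alt <- ifelse(is.na(a$alt), "", a$alt)
  keep <- rep(TRUE, nrow(a))
  if (any(nzchar(alt))) {
    key <- paste(a$chain, a$resno, a$elety)
    for (k in unique(key[nzchar(alt)])) {
      idx <- which(key == k)
      if (length(idx) > 1L) {
        best <- idx[which.max(occ[idx])]
        keep[setdiff(idx, best)] <- FALSE
      }
    }
  }
  element <- infer_element(a$elety, a$elesy)
  atoms <- data.frame(
    serial = seq_len(sum(keep)),
    name = a$elety[keep],
    element = element[keep],
    resname = a$resid[keep],
    chain = ifelse(is.na(a$chain[keep]), "A", a$chain[keep]),
    resnum = a$resno[keep],
    occupancy = occ[keep],
    bfactor = ifelse(is.na(a$b[keep]), 0, a$b[keep]),
    is_hydrogen = element[keep] == "H",
    stringsAsFactors = FALSE)
  xyz <- p$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
  col_keep <- rep(keep, each = 3L)
  if (n_models >= 2L) {
    frames <- lapply(seq_len(nrow(xyz)), function(i)
      matrix(xyz[i, col_keep], ncol = 3L, byrow = TRUE))
    topo <- ab_structure(atoms, frames[[1L]])
    ab_trajectory(topo, frames, frame_interval)
  } else {
    ab_structure(atoms, matrix(xyz[1L, col_keep], ncol = 3L, byrow = TRUE))
  }
}

#' Write a structure or trajectory as PDB
#'
#' Structures become single-model PDB files; trajectories are emitted as
#' MODEL/ENDMDL blocks (the package's trajectory interchange format).
#' Coordinates are written with three decimals in the standard fixed columns.
#'
#' @param x An `ab_structure` or `ab_trajectory`.
#' @param file Optional output path. When `NULL` the PDB text is returned.
#' @return The PDB text, invisibly when `file` is given.
#' @export
write_pdb <- function(x, file = NULL) {
  if (inherits(x, "ab_trajectory")) {
    topo <- x$topology
    xyz <- do.call(rbind, lapply(x$frames, function(f) as.numeric(t(f))))
  } else if (inherits(x, "ab_structure")) {
    validate_structure(x)
    topo <- x
    xyz <- matrix(as.numeric(t(x$xyz)), nrow = 1L)
  } else stop("x must be an ab_structure or ab_trajectory")
  a <- topo$atoms
  if (nrow(a) > 99999L)
    stop("cannot write more than 99999 atoms (serial number overflow)")
  tf <- if (is.null(file)) tempfile(fileext = ".pdb") else file
  bio3d::write.pdb(pdb = NULL, file = tf, xyz = xyz,
                   resno = a$resnum, chain = a$chain, resid = a$resname,
                   eleno = a$serial, elety = a$name, o = a$occupancy,
                   b = a$bfactor, elesy = a$element)
  txt <- paste(readLines(tf, warn = FALSE), collapse = "\n")
  if (is.null(file)) {
    unlink(tf)
    txt
  } else invisible(txt)
}
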
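# Ideal-geometry peptide construction. Backbones are grown residue by residue
# from internal coordinates (NeRF); sidechain and hydrogen positions come from
# an idealized per-residue internal-coordinate table shipped with the package
# (inst/extdata/residue_geometry.tsv), so every generated structure has
# standard stereochemistry and default rotamers.

# Ideal backbone parameters (Angstrom / degrees).
.bb <- list(
  b_n_ca = 1.458, b_ca_c = 1.525, b_c_n = 1.329,
  b_c_o = 1.231, b_c_oxt = 1.249, b_n_h = 1.010,
  a_n_ca_c = 111.0, a_ca_c_n = 116.6, a_c_n_ca = 121.7,
  a_ca_c_o = 120.5, a_ca_c_oxt = 117.0,
  omega = 180)

.aa1to3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
             Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
             L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
             S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL")

#' The amyloid-beta 1-42 sequence
#'
#' One-letter sequence of human Abeta42 (DAEFRHDSGYEVHHQKLVFFAEDVGSNKGAIIGLMVGGVVIA).
#' @return Single string of 42 residues.
#' @export
abeta42_sequence <- function() "DAEFRHDSGYEVHHQKLVFFAEDVGSNKGAIIGLMVGGVVIA"

residue_geometry_table <- function() {
  if (is.null(.pkg_cache$resgeo)) {
    path <- system.file("extdata", "residue_geometry.tsv",
                        package = "globulomeR", mustWork = TRUE)
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    .pkg_cache$resgeo <- split(tab, tab$resname)
  }
  .pkg_cache$resgeo
}

#' Specify a backbone conformation
#'
#' @param kind `"helix"` (phi = -57, psi = -47), `"extended"`
#'   (phi = psi = 180) or `"hairpin"` (two beta strands, phi = -135 /
#'   psi = 135, joined by a type-I' turn at `turn_center`).
#' @param phi,psi Optional torsion override, in degrees in (-180, 180]:
#'   either scalars or vectors with one value per residue.
#' @param turn_center Residue number of the first turn residue (hairpin only);
#'   must be strictly inside the chain.
#' @return An object of class `conformation_spec`.
#' @export
conformation_spec <- function(kind = c("extended", "helix", "hairpin"),
                              phi = NULL, psi = NULL, turn_center = NULL) {
  kind <- match.arg(kind)
  for (v in c(phi, psi))
    if (!is.null(v) && any(v <= -180 | v > 180))
      stop("torsions must lie in (-180, 180]")
  if (kind == "hairpin" && is.null(turn_center))
    stop("hairpin conformations require turn_center")
  structure(list(kind = kind, phi = phi, psi = psi,
                 turn_center = turn_center),
            class = "conformation_spec")
}

# Per-residue (phi, psi) schedule for a conformation over resnums.
torsion_schedule <- function(conf, resnums) {
  n <- length(resnums)
  sched <- switch(conf$kind,
    helix = list(phi = rep(-57, n), psi = rep(-47, n)),
    extended = list(phi = rep(180, n), psi = rep(180, n)),
    hairpin = {
      tc <- conf$turn_center
      if (tc <= resnums[1L] || tc + 1L >= resnums[n])
        stop("turn_center must be strictly inside the chain")
      phi <- rep(-135, n); psi <- rep(135, n)
      # positive-phi two-residue turn with tuned flanking torsions; the
      # values give a clash-free hairpin whose strands pair at ~5 A
      # (ideal-geometry strands with a canonical tight turn collide)
      turn <- list(
        c(NA, 131.3),        # tc - 2
        c(-171.6, 109.4),    # tc - 1
        c(85.9, -31.4),      # tc (first turn residue)
        c(150.8, 4.4),       # tc + 1 (second turn residue)
        c(-75.7, 149.4))     # tc + 2
      for (k in seq_along(turn)) {
        i <- match(tc, resnums) + k - 3L
        if (is.na(i) || i < 1L || i > n) next
        if (!is.na(turn[[k]][1L])) phi[i] <- turn[[k]][1L]
        psi[i] <- turn[[k]][2L]
      }
      list(phi = phi, psi = psi)
    })
  if (!is.null(conf$phi)) sched$phi <- rep_len(conf$phi, n)
  if (!is.null(conf$psi)) sched$psi <- rep_len(conf$psi, n)
  sched
}

# Build one residue's non-backbone atoms from the geometry table.
place_residue_extras <- function(resname, anchor) {
  rows <- residue_geometry_table()[[resname]]
  if (is.null(rows)) stop("unknown residue: ", resname)
  pos <- anchor  # named list of 3-vectors, starts with N, CA, C (+O etc.)
  out_names <- character(0); out_el <- character(0); out_xyz <- list()
  for (k in seq_len(nrow(rows))) {
    r <- rows[k, ]
    p <- pos[[r$ref1]]; g <- pos[[r$ref2]]; gg <- pos[[r$ref3]]
    if (is.null(p) || is.null(g) || is.null(gg))
      stop("geometry table references unplaced atom for ", resname, ":", r$atom)
    x <- nerf_place(gg, g, p, r$bond, r$angle, r$torsion)
    pos[[r$atom]] <- x
    out_names <- c(out_names, r$atom)
    out_el <- c(out_el, r$element)
    out_xyz[[length(out_xyz) + 1L]] <- x
  }
  list(names = out_names, element = out_el,
       xyz = do.call(rbind, out_xyz), pos = pos)
}

#' Build a peptide from ideal internal coordinates
#'
#' Grows a single chain with ideal bond lengths and angles (N-CA 1.458,
#' CA-C 1.525, C-N 1.329 Angstrom; omega fixed at 180) and backbone torsions
#' from the conformation spec. Backbone amide hydrogens are placed in-plane
#' on the N-CA / N-C(i-1) bisector (residue 1 and prolines carry no amide H);
#' sidechains and their hydrogens use idealized default rotamers. The final
#' residue carries a free (OXT) carboxylate.
#'
#' @param sequence One-letter amino-acid sequence (length >= 2).
#' @param conf A [conformation_spec()].
#' @param chain_id Chain identifier for the built chain.
#' @param start_resnum Residue number of the first residue (Abeta numbering
#'   is 1-based; fragment fixtures use e.g. 17 or 31).
#' @param title Structure title.
#' @return An [ab_structure()].
#' @export
build_peptide <- function(sequence, conf = conformation_spec("extended"),
                          chain_id = "A", start_resnum = 1L, title = "") {
  letters1 <- strsplit(toupper(sequence), "")[[1L]]
  if (length(letters1) < 2L) stop("sequence must contain at least 2 residues")
  bad <- setdiff(letters1, names(.aa1to3))
  if (length(bad) > 0L)
    stop("unknown residue letter(s): ", paste(unique(bad), collapse = ", "))
  res3 <- unname(.aa1to3[letters1])
  n <- length(res3)
  resnums <- seq.int(start_resnum, length.out = n)
  sched <- torsion_schedule(conf, resnums)

  N <- CA <- CC <- vector("list", n)
  # residue 1 in a canonical frame
  N[[1L]] <- c(0, 0, 0)
  CA[[1L]] <- c(.bb$b_n_ca, 0, 0)
  ang <- .bb$a_n_ca_c * pi / 180
  CC[[1L]] <- CA[[1L]] + .bb$b_ca_c * c(-cos(ang), sin(ang), 0)
  for (i in seq_len(n)[-1L]) {
    N[[i]] <- nerf_place(N[[i - 1L]], CA[[i - 1L]], CC[[i - 1L]],
                         .bb$b_c_n, .bb$a_ca_c_n, sched$psi[i - 1L])
    CA[[i]] <- nerf_place(CA[[i - 1L]], CC[[i - 1L]], N[[i]],
                          .bb$b_n_ca, .bb$a_c_n_ca, .bb$omega)
    CC[[i]] <- nerf_place(CC[[i - 1L]], N[[i]], CA[[i]],
                          .bb$b_ca_c, .bb$a_n_ca_c, sched$phi[i])
  }

  nm <- character(0); el <- character(0); rnm <- character(0)
  rno <- integer(0); xyz <- list()
  add <- function(name, element, coord, resname, resnum) {
    nm[length(nm) + 1L] <<- name
    el[length(el) + 1L] <<- element
    rnm[length(rnm) + 1L] <<- resname
    rno[length(rno) + 1L] <<- resnum
    xyz[[length(xyz) + 1L]] <<- coord
  }
  for (i in seq_len(n)) {
    rn <- res3[i]; num <- resnums[i]
    O <- nerf_place(N[[i]], CA[[i]], CC[[i]], .bb$b_c_o, .bb$a_ca_c_o,
                    sched$psi[i] + 180)
    add("N", "N", N[[i]], rn, num)
    add("CA", "C", CA[[i]], rn, num)
    add("C", "C", CC[[i]], rn, num)
    add("O", "O", O, rn, num)
    if (i > 1L && rn != "PRO") {
      h_dir <- unitv(unitv(N[[i]] - CC[[i - 1L]]) + unitv(N[[i]] - CA[[i]]))
      add("H", "H", N[[i]] + .bb$b_n_h * h_dir, rn, num)
    }
    extras <- place_residue_extras(rn, list(N = N[[i]], CA = CA[[i]],
                                            C = CC[[i]], O = O))
    for (k in seq_along(extras$names))
      add(extras$names[k], extras$element[k], extras$xyz[k, ], rn, num)
    if (i == n) {
      OXT <- nerf_place(N[[i]], CA[[i]], CC[[i]], .bb$b_c_oxt,
                        .bb$a_ca_c_oxt, sched$psi[i])
      add("OXT", "O", OXT, rn, num)
    }
  }
  a <- data.frame(serial = seq_along(nm), name = nm, element = el,
                  resname = rnm, chain = chain_id, resnum = rno,
                  occupancy = 1, bfactor = 0, is_hydrogen = el == "H",
                  stringsAsFactors = FALSE)
  ab_structure(a, do.call(rbind, xyz), title)
}

#' Build an extended reference tripeptide (AxA or GxA style)
#'
#' The uncapped tripeptide flank-x-flank in fully extended conformation
#' (phi = psi = 180) with hydrogens placed; the central residue (position 2)
#' is the rSASA reference context for residue type `x`.
#'
#' @param x One-letter code of the central residue.
#' @param flank `"A"` (AxA) or `"G"` (GxA).
#' @return An [ab_structure()] with attribute `central_resnum = 2`.
#' @export
build_reference_tripeptide <- function(x, flank = c("A", "G")) {
  flank <- match.arg(flank)
  s <- build_peptide(paste0(flank, x, flank),
                     conformation_spec("extended"),
                     title = sprintf("reference tripeptide %s%s%s", flank, x, flank))
  attr(s, "central_resnum") <- 2L
  s
}
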
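# Trajectory ensemble statistics: Kabsch superposition, RMSD series, radius
# of gyration, B-factor profiles, sidechain distance monitors and convergence
# diagnostics.

#' Least-squares rigid superposition (Kabsch)
#'
#' Returns the proper rotation + translation minimising the (weighted) RMSD
#' of `mobile` onto `reference`, and the post-fit RMSD.
#'
#' @param mobile,reference `m x 3` coordinate matrices, equal row counts
#'   (>= 3 non-collinear points).
#' @param weights Optional non-negative weights per point.
#' @return List with `transform` (a [transform_op()]) and `rmsd` (Angstrom).
#' @export
kabsch_superpose <- function(mobile, reference, weights = NULL) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  m <- nrow(mobile)
  if (m != nrow(reference)) stop("point counts differ")
  if (m < 3L) stop("need at least 3 points")
  w <- if (is.null(weights)) rep(1, m) else as.numeric(weights)
  if (length(w) != m || any(w < 0) || sum(w) <= 0)
    stop("weights must be non-negative with positive sum")
  w <- w / sum(w)
  cm <- colSums(mobile * w); cr <- colSums(reference * w)
  X <- sweep(mobile, 2L, cm); Y <- sweep(reference, 2L, cr)
  # collinearity check: centered reference must span >= 2 dimensions
  if (svd(sweep(Y, 1L, sqrt(w), "*"))$d[2L] < 1e-8)
    stop("degenerate (collinear or coincident) point set")
  H <- t(X * w) %*% Y
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  tr <- cr - as.numeric(R %*% cm)
  fit <- sweep(X %*% t(R), 2L, as.numeric(R %*% cm) + tr - cr, "+")
  # fitted mobile in the reference frame relative to reference centroid
  rmsd <- sqrt(sum(w * rowSums((X %*% t(R) - Y)^2)))
  list(transform = transform_op(R, tr), rmsd = rmsd)
}

#' RMSD time series against a reference structure
#'
#' Per frame, the trajectory is superposed on the selected atoms and the RMSD
#' is reported over that same selection (fit selection = report selection),
#' independently for the core and total selections.
#'
#' @param t An `ab_trajectory`.
#' @param reference An `ab_structure` with matching selections (commonly the
#'   first frame).
#' @param core Core [region_spec()] (default: C-alpha atoms of residues
#'   17-42).
#' @param total Total [region_spec()] (default: all C-alpha atoms, residues
#'   1-42).
#' @return Object of class `rmsd_series`: data.frame with columns `time`
#'   (ps), `core`, `total` (Angstrom).
#' @export
rmsd_series <- function(t, reference,
                        core = region_core("calpha"),
                        total = region_spec("total", rbind(c(1L, 42L)), "calpha")) {
  stopifnot(inherits(t, "ab_trajectory"), inherits(reference, "ab_structure"))
  res <- list()
  for (nm in c("core", "total")) {
    spec <- if (nm == "core") core else total
    it <- select_atoms(t$topology, spec)
    ir <- select_atoms(reference, spec)
    if (length(it) == 0L || length(it) != length(ir))
      stop("selection '", spec$name, "' differs between trajectory (",
           length(it), " atoms) and reference (", length(ir), " atoms)")
    ref_xyz <- reference$xyz[ir, , drop = FALSE]
    res[[nm]] <- vapply(t$frames, function(f)
      kabsch_superpose(f[it, , drop = FALSE], ref_xyz)$rmsd, numeric(1L))
  }
  out <- data.frame(time = frame_times(t), core = res$core, total = res$total)
  class(out) <- c("rmsd_series", "data.frame")
  attr(out, "core_selection") <- core
  attr(out, "total_selection") <- total
  out
}

#' Radius of gyration
#'
#' `Rg = sqrt(sum m_i |x_i - xbar|^2 / sum m_i)` over the heavy atoms of the
#' selection; `mass_weighted = FALSE` uses unit masses.
#'
#' @param s An `ab_structure` (or a bare `n x 3` frame together with a
#'   pre-selected structure is not supported; pass a structure).
#' @param selection Optional [region_spec()]; default: all residues.
#' @param mass_weighted Use atomic masses (default) or unit masses.
#' @return Rg in Angstrom.
#' @export
radius_of_gyration <- function(s, selection = NULL, mass_weighted = TRUE) {
  stopifnot(inherits(s, "ab_structure"))
  idx <- if (is.null(selection)) which(!s$atoms$is_hydrogen) else {
    sel <- region_spec(selection$name, selection$ranges, "heavy")
    select_atoms(s, sel)
  }
  if (length(idx) == 0L) stop("empty selection")
  xyz <- s$xyz[idx, , drop = FALSE]
  m <- if (mass_weighted) {
    el <- s$atoms$element[idx]
    unname(.atomic_masses[el])
  } else rep(1, length(idx))
  if (anyNA(m)) stop("no atomic mass for element(s): ",
                     paste(unique(s$atoms$element[idx][is.na(m)]), collapse = ", "))
  ctr <- colSums(xyz * m) / sum(m)
  sqrt(sum(m * rowSums(sweep(xyz, 2L, ctr)^2)) / sum(m))
}

#' Per-residue B-factor profile from a trajectory window
#'
#' Per atom, `B = (8 pi^2 / 3) <|x - <x>|^2>` over the frames in the window;
#' atom values are averaged over each residue's mainchain atoms, then over
#' chains, giving one value per residue position.
#'
#' @param t An `ab_trajectory`.
#' @param window `c(t_start, t_end)` in ps (inclusive); must contain at least
#'   2 frames.
#' @param atoms Atom-class filter within each residue (default mainchain).
#' @return Object of class `bfactor_profile`: data.frame `resnum`, `bfactor`
#'   (Angstrom^2), with the window as an attribute.
#' @export
bfactor_profile <- function(t, window = range(frame_times(t)),
                            atoms = "mainchain") {
  stopifnot(inherits(t, "ab_trajectory"))
  times <- frame_times(t)
  inw <- which(times >= window[1L] & times <= window[2L])
  if (length(inw) < 2L) stop("window must contain at least 2 frames")
  a <- t$topology$atoms
  rng <- range(a$resnum)
  spec <- region_spec("bfactor", rbind(rng), atoms)
  idx <- select_atoms(t$topology, spec)
  if (length(idx) == 0L) stop("empty atom selection for B-factors")
  # two-pass mean-square displacement (exact zero for static input)
  nf <- length(inw)
  mu <- matrix(0, length(idx), 3L)
  for (f in inw) mu <- mu + t$frames[[f]][idx, , drop = FALSE]
  mu <- mu / nf
  ssd <- matrix(0, length(idx), 3L)
  for (f in inw) ssd <- ssd + (t$frames[[f]][idx, , drop = FALSE] - mu)^2
  msd <- rowSums(ssd) / nf
  b_atom <- (8 * pi^2 / 3) * msd
  key <- paste(a$chain[idx], a$resnum[idx])
  b_res <- tapply(b_atom, key, mean)
  resnum_of <- as.integer(vapply(strsplit(names(b_res), " "), `[`, "", 2L))
  prof <- tapply(as.numeric(b_res), resnum_of, mean)
  out <- data.frame(resnum = as.integer(names(prof)),
                    bfactor = as.numeric(prof))
  out <- out[order(out$resnum), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("bfactor_profile", "data.frame")
  attr(out, "window") <- window
  out
}

sidechain_heavy_idx <- function(s, chain, resnum) {
  a <- s$atoms
  idx <- which(a$chain == chain & a$resnum == resnum & !a$is_hydrogen &
                 !(a$name %in% c(.mainchain_names, "OXT")))
  idx
}

#' Minimum sidechain heavy-atom distance series
#'
#' Per frame and chain, the minimum distance over pairs of sidechain heavy
#' atoms of residues `res_a` and `res_b` (the NOE-style proximity monitor;
#' e.g. F19-L34 with tolerance 7.5 Angstrom).
#'
#' @param t An `ab_trajectory` (a single `ab_structure` is treated as one
#'   frame).
#' @param res_a,res_b Residue numbers.
#' @param tolerance Distance tolerance in Angstrom used for the
#'   fraction-under summary (default 7.5).
#' @param chains Optional chain subset; default all chains containing both
#'   residues.
#' @return Object of class `distance_series`: data.frame `time`, `chain`,
#'   `distance`, with `mean` and `fraction_under` attributes.
#' @export
distance_series <- function(t, res_a, res_b, tolerance = 7.5, chains = NULL) {
  if (inherits(t, "ab_structure"))
    t <- ab_trajectory(t, list(t$xyz), 1)
  stopifnot(inherits(t, "ab_trajectory"))
  topo <- t$topology
  if (is.null(chains)) chains <- chain_ids(topo)
  rows <- list()
  for (ch in chains) {
    ia <- sidechain_heavy_idx(topo, ch, res_a)
    ib <- sidechain_heavy_idx(topo, ch, res_b)
    if (length(ia) == 0L && res_a %in% topo$atoms$resnum[topo$atoms$chain == ch])
      stop("residue ", res_a, " in chain ", ch,
           " has no sidechain heavy atoms (glycine?)")
    if (length(ib) == 0L && res_b %in% topo$atoms$resnum[topo$atoms$chain == ch])
      stop("residue ", res_b, " in chain ", ch,
           " has no sidechain heavy atoms (glycine?)")
    if (length(ia) == 0L || length(ib) == 0L) next
    d <- vapply(t$frames, function(f)
      cpp_min_dist(f[ia, , drop = FALSE], f[ib, , drop = FALSE]), numeric(1L))
    rows[[length(rows) + 1L]] <- data.frame(time = frame_times(t), chain = ch,
                                            distance = d,
                                            stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L)
    stop("no chain contains both residues ", res_a, " and ", res_b)
  out <- do.call(rbind, rows)
  class(out) <- c("distance_series", "data.frame")
  attr(out, "mean") <- mean(out$distance)
  attr(out, "fraction_under") <- mean(out$distance < tolerance)
  attr(out, "tolerance") <- tolerance
  out
}

#' Convergence diagnostics of a scalar time series
#'
#' Coefficient of variation (`sd / |mean|`) and the ordinary least-squares
#' slope per nanosecond over a time window.
#'
#' @param values Numeric series.
#' @param times Times in ps (defaults to 0, 1, 2, ...).
#' @param window Optional `c(t_start, t_end)` ps window (inclusive); default
#'   the full series. At least 3 points required.
#' @return Object of class `convergence_report`: list with `cv` (fraction),
#'   `slope` (series units per ns) and `window`.
#' @export
convergence_stats <- function(values, times = seq_along(values) - 1,
                              window = NULL) {
  if (length(values) != length(times)) stop("values and times differ in length")
  if (is.null(window)) window <- range(times)
  keep <- times >= window[1L] & times <= window[2L]
  if (sum(keep) < 3L) stop("window must contain at least 3 points")
  v <- values[keep]; tt <- times[keep]
  mu <- mean(v)
  if (mu == 0) stop("series mean is zero; coefficient of variation undefined")
  cv <- stats::sd(v) / abs(mu)
  slope <- unname(coef(lm(v ~ I(tt / 1000)))[2L])
  structure(list(cv = cv, slope = slope, window = window),
            class = "convergence_report")
}

#' @export
print.convergence_report <- function(x, ...) {
  cat(sprintf("<convergence_report> cv = %.4g, slope = %.4g per ns over [%g, %g] ps\n",
              x$cv, x$slope, x$window[1L], x$window[2L]))
  invisible(x)
}
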
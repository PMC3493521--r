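# End-to-end driver: fixture generation -> constrained assembly -> synthetic
# trajectory -> full analysis report (Table-1-style metrics, protection
# fractions, B-factor and rSASA profiles, ACE, packing density, convergence).

#' Build a run configuration
#'
#' Central declarative configuration of the pipeline. Defaults reproduce the
#' package's standard desk-scale study: the Abeta42 sequence, the canonical
#' regions (N 1-17, central 18-30, C 31-42, core 17-42), a C-terminal
#' docking constraint, the charged-group occlusion rule, and a synthetic
#' trajectory with a mobile N-terminus (sigma 1.2 A), stable core (sigma
#' 0.4 A) and progressive helix unwinding.
#'
#' @param mode `"build"`, `"analyze"` or `"full"`.
#' @param seed Integer seed for all stochastic stages.
#' @param out_dir Output directory (created on demand).
#' @param sasa A [sasa_params()].
#' @param dock A [dock_constraint()].
#' @param charged A [charged_group_rule()].
#' @param rot_step,trans_step,top_k Dimer docking grid (degrees / Angstrom);
#'   the coarse defaults keep the exhaustive scan desk-scale.
#' @param sigma_nterm,sigma_core Per-coordinate fluctuation s.d. (Angstrom)
#'   for residues 1-16 and 17-42.
#' @param n_frames,frame_interval Trajectory length and spacing (ps).
#' @param unwind_nterm Unwind N-terminal helices over the trajectory.
#' @param bfactor_window_ps Length of the trailing window used for B-factors
#'   (ps).
#' @param ace_range Residue range reported in the ACE profile.
#' @param mc_samples Monte-Carlo samples per atom for packing density.
#' @param n_models Number of accepted dodecamer models to keep.
#' @param add_nterm_helices Complete built models with helical N-termini.
#' @return An object of class `run_config`.
#' @export
run_config <- function(mode = c("full", "build", "analyze"),
                       seed = 1L, out_dir = tempfile("globulomer_run_"),
                       sasa = sasa_params(),
                       dock = dock_constraint(),
                       charged = charged_group_rule(),
                       rot_step = 90, trans_step = 3, top_k = 30L,
                       sigma_nterm = 1.2, sigma_core = 0.4,
                       n_frames = 20L, frame_interval = 10,
                       unwind_nterm = TRUE,
                       bfactor_window_ps = 100,
                       ace_range = c(30L, 42L),
                       mc_samples = 2000L,
                       n_models = 4L,
                       add_nterm_helices = TRUE) {
  structure(list(mode = match.arg(mode), seed = as.integer(seed),
                 out_dir = out_dir, sasa = sasa, dock = dock,
                 charged = charged, rot_step = rot_step,
                 trans_step = trans_step, top_k = as.integer(top_k),
                 sigma_nterm = sigma_nterm, sigma_core = sigma_core,
                 n_frames = as.integer(n_frames),
                 frame_interval = frame_interval,
                 unwind_nterm = isTRUE(unwind_nterm),
                 bfactor_window_ps = bfactor_window_ps,
                 ace_range = as.integer(ace_range),
                 mc_samples = as.integer(mc_samples),
                 n_models = as.integer(n_models),
                 add_nterm_helices = isTRUE(add_nterm_helices)),
            class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Any field of [run_config()] may be set; `dock`, `sasa` and `charged`
#' accept nested maps of their constructor arguments.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
load_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y
  if (!is.null(y$sasa)) args$sasa <- do.call(sasa_params, y$sasa)
  if (!is.null(y$dock)) args$dock <- do.call(dock_constraint, y$dock)
  if (!is.null(y$charged)) args$charged <- do.call(charged_group_rule, y$charged)
  do.call(run_config, args)
}

fluctuation_from_config <- function(config) {
  sig <- setNames(c(rep(config$sigma_nterm, 16L), rep(config$sigma_core, 26L)),
                  1:42)
  fluctuation_spec(per_residue_sigma = sig, n_frames = config$n_frames,
                   frame_interval = config$frame_interval,
                   unwind_nterm = config$unwind_nterm, seed = config$seed)
}

empty_stage_error <- function(stage, filter) {
  stop(structure(class = c("globulomer_empty_result", "error", "condition"),
                 list(message = sprintf(
                   "no candidates survived the %s stage (failing filter: %s)",
                   stage, filter), call = NULL)))
}

#' Run the hierarchical assembly pipeline
#'
#' Monomer -> dimer candidates (exhaustive constrained docking) -> C3
#' hexamers -> stacked dodecamers, with the required-region and charged-group
#' filters applied at every level; accepted dodecamers are optionally
#' completed with helical N-termini. Models and per-stage filter reports are
#' written under `config$out_dir`.
#'
#' @param config A [run_config()].
#' @param monomer Monomer source; default the standard core monomer fixture.
#' @return List with `models` (list of 12-chain `ab_structure`s), `reports`
#'   (per-stage candidate tables) and `paths` (written files), invisibly the
#'   same when assigned.
#' @export
run_build <- function(config = run_config(), monomer = build_core_monomer()) {
  dir.create(file.path(config$out_dir, "models"), recursive = TRUE,
             showWarnings = FALSE)
  reports <- list(); paths <- character(0)
  dimers <- rigid_dock(monomer, monomer, config$dock,
                       rot_step = config$rot_step,
                       trans_step = config$trans_step, top_k = config$top_k)
  if (length(dimers) == 0L) empty_stage_error("dimer", "required_region_contacts")
  dimers <- filter_candidates(dimers, config$charged, config$sasa,
                              max_keep = 1L)
  reports$dimer <- attr(dimers, "report")
  if (length(dimers) == 0L) empty_stage_error("dimer", "charged_occlusion")
  dimer <- realize_candidate(dimers[[1L]])

  hexes <- symmetrize_c3(dimer, config$dock, top_k = config$top_k)
  if (length(hexes) == 0L) empty_stage_error("hexamer", "required_region_contacts")
  hexes <- filter_candidates(hexes, config$charged, config$sasa,
                             max_keep = 1L)
  reports$hexamer <- attr(hexes, "report")
  if (length(hexes) == 0L) empty_stage_error("hexamer", "charged_occlusion")
  hex <- realize_candidate(hexes[[1L]])

  stacks <- stack_to_dodecamer(hex, config$dock,
                               trans_step = config$trans_step, top_k = 1000L)
  if (length(stacks) == 0L) empty_stage_error("dodecamer", "required_region_contacts")
  stacks <- filter_candidates(stacks, config$charged, config$sasa,
                              max_keep = config$n_models)
  reports$dodecamer <- attr(stacks, "report")
  if (length(stacks) == 0L) empty_stage_error("dodecamer", "charged_occlusion")

  models <- lapply(stacks, realize_candidate)
  if (config$add_nterm_helices)
    models <- lapply(models, prepend_nterm_helix)
  for (i in seq_along(models)) {
    p <- file.path(config$out_dir, "models",
                   sprintf("dodecamer_%02d.pdb", i))
    write_pdb(models[[i]], p)
    paths <- c(paths, p)
  }
  for (stage in names(reports)) {
    p <- file.path(config$out_dir, sprintf("filter_report_%s.tsv", stage))
    utils::write.table(reports[[stage]], p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths <- c(paths, p)
  }
  list(models = models, reports = reports, paths = paths)
}

window_frames <- function(t, window) {
  times <- frame_times(t)
  which(times >= window[1L] & times <= window[2L])
}

slice_trajectory <- function(t, frames) {
  ab_trajectory(t$topology, t$frames[frames], t$frame_interval)
}

#' Analyze a model / trajectory
#'
#' Computes the full analysis battery on a structure and its trajectory:
#' core/total RMSD series, radii of gyration (1-42 and 17-42), a mainchain
#' B-factor profile over the trailing window, the amide-proton rSASA profile
#' with per-region protection fractions (ensemble-averaged), the K28 NZ
#' sidechain rSASA, the F19-L34 distance monitor with its 7.5 Angstrom NOE
#' tolerance check, a per-residue ACE profile of the final frame, packing
#' density of the final frame, and convergence statistics of the Rg series.
#' Profiles and series are written as TSV, the report as JSON.
#'
#' @param config A [run_config()].
#' @param model An `ab_structure` (reference/topology). Default: the
#'   standard dodecamer fixture.
#' @param trajectory An `ab_trajectory`; by default simulated from the
#'   configuration's fluctuation settings around `model`.
#' @return An object of class `run_report` (list; see details), with the
#'   written file paths in `$paths`.
#' @export
run_analyze <- function(config = run_config(),
                        model = standard_dodecamer_fixture(),
                        trajectory = NULL) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(trajectory))
    trajectory <- simulate_trajectory(model, fluctuation_from_config(config))
  t <- trajectory
  times <- frame_times(t)
  single_frame <- n_frames(t) == 1L

  rmsd <- rmsd_series(t, model)
  rg_total <- vapply(seq_len(n_frames(t)), function(i)
    radius_of_gyration(frame_structure(t, i)), numeric(1L))
  rg_core <- vapply(seq_len(n_frames(t)), function(i)
    radius_of_gyration(frame_structure(t, i), region_core()), numeric(1L))

  bwin <- c(max(0, max(times) - config$bfactor_window_ps), max(times))
  bprof <- if (single_frame) {
    data.frame(resnum = sort(unique(t$topology$atoms$resnum)), bfactor = 0)
  } else bfactor_profile(t, bwin)

  # amide rSASA profile (ensemble-averaged SASA), reused for protection
  topo <- t$topology
  amide_idx <- suppressWarnings(select_atoms(
    topo, region_spec("all", rbind(range(topo$atoms$resnum)), "amide_proton")))
  if (length(amide_idx) == 0L)
    stop("model has no backbone amide protons; rebuild fixtures with ",
         "hydrogens (see build_peptide / standard_dodecamer_fixture)")
  amide_tg <- topo$atoms[amide_idx, c("chain", "resnum", "name")]
  am <- rsasa(t, amide_tg, config$sasa)
  prof <- do.call(rbind, lapply(split(am$value, am$resnum), function(v)
    data.frame(mean = mean(v), sd = if (length(v) > 1L) stats::sd(v) else 0)))
  rsasa_profile <- data.frame(resnum = as.integer(rownames(prof)), prof)
  rsasa_profile <- rsasa_profile[order(rsasa_profile$resnum), ]

  prot <- function(rec, lo, hi) {
    v <- rec$value[rec$resnum >= lo & rec$resnum <= hi]
    if (length(v) == 0L) NA_real_ else mean(v < 0.10)
  }
  protection <- c(nterm = prot(am, 1L, 17L), central = prot(am, 18L, 30L),
                  cterm = prot(am, 31L, 42L), total = prot(am, 1L, 42L))

  # protection drift: first-third vs last-third windows (helix unwinding)
  protection_windows <- if (single_frame) c(start = NA_real_, end = NA_real_)
  else {
    third <- max(2L, ceiling(n_frames(t) / 3))
    am_start <- rsasa(slice_trajectory(t, seq_len(third)), amide_tg, config$sasa)
    am_end <- rsasa(slice_trajectory(t, seq.int(n_frames(t) - third + 1L,
                                                n_frames(t))),
                    amide_tg, config$sasa)
    c(start = prot(am_start, 1L, 42L), end = prot(am_end, 1L, 42L))
  }

  k28 <- tryCatch(mean(rsasa(t, data.frame(resnum = 28L, name = "NZ"),
                             config$sasa)$value), error = function(e) NA_real_)
  f19l34 <- distance_series(t, 19L, 34L, tolerance = 7.5)
  final <- frame_structure(t, n_frames(t))
  ace <- residue_ace_profile(final)
  ace_sub <- ace[ace$resnum >= config$ace_range[1L] &
                   ace$resnum <= config$ace_range[2L], ]
  packing <- packing_density(final, mc_samples = config$mc_samples,
                             seed = config$seed)
  convergence <- if (single_frame) NULL else
    convergence_stats(rg_core, times)

  report <- list(
    seed = config$seed,
    n_frames = n_frames(t),
    frame_interval_ps = t$frame_interval,
    rg_total_mean = mean(rg_total),
    rg_core_mean = mean(rg_core),
    rmsd_core_mean = mean(rmsd$core),
    rmsd_total_mean = mean(rmsd$total),
    k28_nz_rsasa = k28,
    f19_l34_distance_mean = attr(f19l34, "mean"),
    f19_l34_fraction_under_tolerance = attr(f19l34, "fraction_under"),
    protection = as.list(protection),
    protection_windows = as.list(protection_windows),
    bfactor_nterm_mean = mean(bprof$bfactor[bprof$resnum <= 16L]),
    bfactor_core_mean = mean(bprof$bfactor[bprof$resnum >= 17L]),
    ace_cterm_mean = mean(ace_sub$ace),
    packing_density_mean = packing$mean,
    packing_n_buried = packing$n_buried,
    convergence = if (is.null(convergence)) NULL else
      list(cv = convergence$cv, slope_per_ns = convergence$slope))

  paths <- character(0)
  wr <- function(df, name) {
    p <- file.path(config$out_dir, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <<- c(paths, p)
  }
  wr(data.frame(time = rmsd$time, core = rmsd$core, total = rmsd$total),
     "rmsd_series.tsv")
  wr(data.frame(time = times, rg_total = rg_total, rg_core = rg_core),
     "rg_series.tsv")
  wr(bprof, "bfactor_profile.tsv")
  wr(rsasa_profile, "amide_rsasa_profile.tsv")
  wr(as.data.frame(ace), "ace_profile.tsv")
  wr(as.data.frame(f19l34), "f19_l34_distance.tsv")
  rp <- file.path(config$out_dir, "run_report.json")
  jsonlite::write_json(report, rp, auto_unbox = TRUE, digits = NA,
                       null = "null")
  paths <- c(paths, rp)
  structure(c(report, list(paths = paths,
                           tables = list(rmsd = rmsd, bfactor = bprof,
                                         rsasa_profile = rsasa_profile,
                                         ace = ace, f19_l34 = f19l34))),
            class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n")
  cat(sprintf("  Rg (1-42) %.1f A | Rg (17-42) %.1f A\n",
              x$rg_total_mean, x$rg_core_mean))
  cat(sprintf("  RMSD core %.2f A | total %.2f A\n",
              x$rmsd_core_mean, x$rmsd_total_mean))
  cat(sprintf("  K28 NZ rSASA %.2f | F19-L34 %.1f A (%.0f%% < 7.5 A)\n",
              x$k28_nz_rsasa, x$f19_l34_distance_mean,
              100 * x$f19_l34_fraction_under_tolerance))
  cat(sprintf("  protection N %.2f / central %.2f / C %.2f / total %.2f\n",
              x$protection$nterm, x$protection$central, x$protection$cterm,
              x$protection$total))
  cat(sprintf("  packing density %.2f (%d buried atoms)\n",
              x$packing_density_mean, x$packing_n_buried))
  invisible(x)
}

#' Run the full pipeline (build + analyze)
#'
#' @param config A [run_config()].
#' @return List with the build result and the `run_report` of the top model.
#' @export
run_full <- function(config = run_config()) {
  build <- run_build(config)
  report <- run_analyze(config, model = build$models[[1L]])
  list(build = build, report = report)
}
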
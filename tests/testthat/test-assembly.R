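# Rigid docking against brute-force enumeration, C3 symmetrization, hexamer
# stacking and the charged-group occlusion filter.


test_that("single-atom docking equals brute-force enumeration over the grid", {
  a <- one_atom(element = "C")
  b <- one_atom(element = "C")
  cst <- dock_constraint(region_spec("all", rbind(c(1L, 1L)), "heavy"),
                         contact_cutoff = 5, clash_cutoff = 2.5)
  got <- rigid_dock(a, b, cst, rot_step = 180, trans_step = 1, top_k = 1e6L)
  oracle <- dock_oracle(a, b, cst, 180, 1)
  expect_equal(length(got), nrow(oracle))
  for (k in seq_len(min(25L, length(got)))) {
    expect_equal(got[[k]]$n_contacts, oracle[k, 3])
    expect_equal(got[[k]]$n_clashes, oracle[k, 4])
    expect_equal(got[[k]]$grid_index, oracle[k, 6])
  }
  # the best placements put the atoms within contact but outside clash range
  best <- realize_candidate(got[[1L]])
  d <- sqrt(sum((best$xyz[1, ] - best$xyz[2, ])^2))
  expect_gt(d, 2.5); expect_lt(d, 5)
  expect_equal(got[[1L]]$score, 1)
})

test_that("multi-atom docking matches the oracle list exactly", {
  fixed <- toy_structure(c("CA", "CB"), c("C", "C"),
                         c(0, 0, 0, 0, 3, 0), resnums = c(1L, 2L))
  mobile <- toy_structure(c("CA", "CB", "CG"), c("C", "C", "C"),
                          c(0, 0, 0, 2.2, 0, 0, 0, 0, 2.2),
                          resnums = c(1L, 2L, 3L))
  cst <- dock_constraint(region_spec("all", rbind(c(1L, 3L)), "heavy"),
                         contact_cutoff = 4.5, clash_cutoff = 2.0,
                         min_required_contacts = 2L)
  got <- rigid_dock(fixed, mobile, cst, rot_step = 120, trans_step = 4,
                    top_k = 1e6L)
  oracle <- dock_oracle(fixed, mobile, cst, 120, 4)
  expect_equal(length(got), nrow(oracle))
  got_tab <- t(vapply(got, function(x)
    c(x$n_contacts, x$n_clashes, x$n_region_contacts, x$grid_index),
    numeric(4)))
  expect_equal(unname(got_tab), unname(oracle[, c(3, 4, 5, 6)]))
})

test_that("docking respects region and clash semantics", {
  a <- one_atom(element = "C")
  b <- one_atom(element = "C")
  # region without atoms -> no candidates
  empty_region <- dock_constraint(region_spec("none", rbind(c(99L, 99L)), "heavy"))
  expect_length(rigid_dock(a, b, empty_region, rot_step = 180, trans_step = 2),
                0L)
  # a 1.0 A pair is both contact and clash: score 1 - 10
  cst <- dock_constraint(region_spec("all", rbind(c(1L, 1L)), "heavy"),
                         contact_cutoff = 5, clash_cutoff = 2.5)
  got <- rigid_dock(a, b, cst, rot_step = 180, trans_step = 1, top_k = 1e6L)
  scores <- vapply(got, `[[`, numeric(1), "score")
  clashing <- vapply(got, function(x) x$n_clashes > 0, logical(1))
  expect_true(all(scores[clashing] == 1 - 10 * vapply(got[clashing], `[[`,
                                                      numeric(1), "n_clashes")))
  # determinism: identical inputs give identical candidate lists
  again <- rigid_dock(a, b, cst, rot_step = 180, trans_step = 1, top_k = 1e6L)
  expect_identical(got, again)
})

test_that("C3 symmetrization produces exactly symmetric hexamers", {
  mono <- build_peptide("ILMVGG", conformation_spec("extended"))
  partner <- mono
  partner$xyz <- partner$xyz + matrix(c(0, 0, 6), n_atoms(mono), 3, byrow = TRUE)
  dimer <- combine_structures(list(mono, partner))
  cst <- dock_constraint(region_spec("all", rbind(c(1L, 6L)), "heavy"))
  cands <- symmetrize_c3(dimer, cst,
                         axis_search = list(n_directions = 12L,
                                            offset_step = 4, max_offset = 20))
  expect_gt(length(cands), 0L)
  hex <- realize_candidate(cands[[1L]])
  expect_equal(n_chains(hex), 6L)
  rot <- transform_op(rotation_about_axis(attr(hex, "symmetry_axis"), 120),
                      c(0, 0, 0))
  # rotating about the recorded axis permutes the three dimers exactly
  p <- cands[[1L]]$axis_point
  shifted <- hex
  shifted$xyz <- sweep(shifted$xyz, 2L, p)
  ch <- chain_ids(shifted)
  x1 <- apply_transform(subset_chains(shifted, ch[1:2]), rot)$xyz
  x2 <- subset_chains(shifted, ch[3:4])$xyz
  expect_lt(max(abs(x1 - x2)), 1e-9)
})

test_that("toy symmetrization retains the axis maximizing inter-copy contacts", {
  dimer <- toy_structure(c("CA", "CA"), c("C", "C"), c(0, 0, 0, 0, 0, 4),
                         chains = c("A", "B"), resnums = c(1L, 1L))
  cst <- dock_constraint(region_spec("all", rbind(c(1L, 1L)), "heavy"),
                         contact_cutoff = 5, clash_cutoff = 1.0)
  search <- list(n_directions = 8L, offset_step = 2, max_offset = 8)
  cands <- symmetrize_c3(dimer, cst, axis_search = search, top_k = 1L)
  expect_gt(length(cands), 0L)
  # independent exhaustive re-scan of the same axis grid
  best_oracle <- -Inf
  dirs <- globulomeR:::fibonacci_sphere(16L)
  dirs <- dirs[dirs[, 3] >= 0, , drop = FALSE]
  ctr <- colMeans(dimer$xyz)
  og <- seq(-8, 8, by = 2)
  for (di in seq_len(nrow(dirs))) {
    u <- dirs[di, ] / sqrt(sum(dirs[di, ]^2))
    pb <- globulomeR:::perp_basis(u)
    for (aa in og) for (bb in og) {
      if (sqrt(aa^2 + bb^2) > 8 + 1e-9) next
      p <- ctr + aa * pb$v1 + bb * pb$v2
      R <- rotation_about_axis(u, 120)
      x2 <- sweep(sweep(dimer$xyz, 2, p) %*% t(R), 2, p, "+")
      ncon <- ncl <- 0L
      for (i in 1:2) for (j in 1:2) {
        d <- sqrt(sum((dimer$xyz[i, ] - x2[j, ])^2))
        if (d < 5) { ncon <- ncon + 1L; if (d < 1) ncl <- ncl + 1L }
      }
      best_oracle <- max(best_oracle, 3 * (ncon - 10 * ncl))
    }
  }
  expect_equal(cands[[1L]]$score, best_oracle)
})

test_that("stacked dodecamers have 12 chains, larger Rg and region contacts", {
  d <- standard_dodecamer_fixture(n_term_helices = FALSE)
  # rebuild the hexamer half directly
  hexamer <- subset_chains(d, chain_ids(d)[1:6])
  attr(hexamer, "symmetry_axis") <- c(0, 0, 1)
  cst <- dock_constraint(min_required_contacts = 1L)
  cands <- stack_to_dodecamer(hexamer, cst, trans_step = 3, top_k = 5L)
  expect_gt(length(cands), 0L)
  rg_hex <- radius_of_gyration(hexamer)
  for (cand in cands) {
    expect_gte(cand$n_region_contacts, 1L)
    model <- realize_candidate(cand)
    expect_equal(n_chains(model), 12L)
    expect_gte(radius_of_gyration(model), rg_hex)
  }
})

test_that("the charged-group filter rejects occluding interfaces", {
  tri <- build_reference_tripeptide("K", "A")
  nz <- which(tri$atoms$resnum == 2L & tri$atoms$name == "NZ")
  cage <- carbon_shell(tri$xyz[nz, ], radius = 5.5, n = 120)
  # a fake "candidate" whose mobile partner is the cage
  cand <- globulomeR:::new_dock_candidate(
    "dimer", transform_op(), c(10, 0, 10), 1L, fixed = tri, mobile = cage)
  res <- filter_candidates(structure(list(cand), class = "dock_candidates"))
  expect_length(res, 0L)
  report <- attr(res, "report")
  expect_false(report$filter_charged_occlusion[1])
  # moving the cage far away retains the candidate
  far_cage <- cage; far_cage$xyz <- far_cage$xyz + 100
  cand2 <- globulomeR:::new_dock_candidate(
    "dimer", transform_op(), c(0, 0, 0), 1L, fixed = tri, mobile = far_cage)
  res2 <- filter_candidates(structure(list(cand2), class = "dock_candidates"))
  expect_length(res2, 1L)
})

test_that("tightening the rSASA floor never admits more candidates", {
  mono <- build_core_monomer()
  cst <- dock_constraint()
  cands <- rigid_dock(mono, mono, cst, rot_step = 120, trans_step = 4,
                      top_k = 8L)
  n_pass <- vapply(c(0.02, 0.10, 0.30), function(th)
    length(filter_candidates(cands, charged_group_rule(min_rsasa = th))),
    numeric(1))
  expect_true(all(diff(n_pass) <= 0))
})
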
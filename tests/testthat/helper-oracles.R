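# Independent brute-force oracles shared by the module and acceptance tests.

# Independent brute-force docking oracle: replays the documented grid
# (Euler ZYZ rotations, lexicographic translations, centroid placement) with
# naive double loops and the same scoring definitions.
dock_oracle <- function(fixed, mobile, c, rot_step, trans_step) {
  hA <- which(!fixed$atoms$is_hydrogen); hB <- which(!mobile$atoms$is_hydrogen)
  A <- fixed$xyz[hA, , drop = FALSE]; B <- mobile$xyz[hB, , drop = FALSE]
  regA <- hA %in% select_atoms(fixed, region_spec(
    c$required_contact_region$name, c$required_contact_region$ranges, "heavy"))
  regB <- hB %in% select_atoms(mobile, region_spec(
    c$required_contact_region$name, c$required_contact_region$ranges, "heavy"))
  cf <- colMeans(A); cm <- colMeans(B)
  Rf <- sqrt(max(rowSums(sweep(A, 2, cf)^2)))
  Rm <- sqrt(max(rowSums(sweep(B, 2, cm)^2)))
  L <- Rf + Rm + c$contact_cutoff
  g <- seq(-floor(L / trans_step) * trans_step, L + 1e-9, by = trans_step)
  tg <- as.matrix(expand.grid(x = g, y = g, z = g))
  tg <- tg[order(tg[, 1], tg[, 2], tg[, 3]), , drop = FALSE]
  tg <- tg[sqrt(rowSums(tg^2)) <= L + 1e-9, , drop = FALSE]
  rows <- NULL
  rot_i <- 0L
  for (al in seq(0, 360 - rot_step, by = rot_step))
    for (be in seq(0, 180, by = rot_step))
      for (ga in seq(0, 360 - rot_step, by = rot_step)) {
        rot_i <- rot_i + 1L
        R <- rotation_about_axis(c(0, 0, 1), al) %*%
          rotation_about_axis(c(0, 1, 0), be) %*%
          rotation_about_axis(c(0, 0, 1), ga)
        Brot <- sweep(B, 2, cm) %*% t(R)
        for (h in seq_len(nrow(tg))) {
          Bp <- sweep(Brot, 2, cf + tg[h, ], "+")
          ncon <- ncl <- nreg <- 0L
          for (i in seq_len(nrow(A))) for (j in seq_len(nrow(Bp))) {
            d <- sqrt(sum((A[i, ] - Bp[j, ])^2))
            if (d < c$contact_cutoff) {
              ncon <- ncon + 1L
              if (d < c$clash_cutoff) ncl <- ncl + 1L
              if (regA[i] && regB[j]) nreg <- nreg + 1L
            }
          }
          if (nreg >= c$min_required_contacts)
            rows <- rbind(rows, c(rot_i, h, ncon, ncl, nreg,
                                  (rot_i - 1L) * nrow(tg) + h))
        }
      }
  if (is.null(rows)) return(NULL)
  score <- rows[, 3] - 10 * rows[, 4]
  rows[order(-score, rows[, 4], rows[, 6]), , drop = FALSE]
}

# Independent brute-force ACE oracle: double loop over heavy-atom pairs.
ace_oracle <- function(s, table, cutoff, exclusion) {
  a <- s$atoms
  idx <- which(!a$is_hydrogen)
  ty <- vapply(idx, function(i) {
    key <- paste(a$resname[i], a$name[i])
    t <- table$assignment[key]
    if (is.na(t)) t <- table$assignment[paste("*", a$name[i])]
    unname(t)
  }, character(1))
  res_key <- unique(paste(a$chain[idx], a$resnum[idx]))
  totals <- setNames(numeric(length(res_key)), res_key)
  for (ii in seq_along(idx)) for (jj in seq_along(idx)) {
    if (jj <= ii) next
    i <- idx[ii]; j <- idx[jj]
    if (a$chain[i] == a$chain[j] &&
        abs(a$resnum[i] - a$resnum[j]) <= exclusion) next
    if (sqrt(sum((s$xyz[i, ] - s$xyz[j, ])^2)) >= cutoff) next
    e <- table$energies[ty[ii], ty[jj]]
    ki <- paste(a$chain[i], a$resnum[i]); kj <- paste(a$chain[j], a$resnum[j])
    totals[ki] <- totals[ki] + e
    totals[kj] <- totals[kj] + e
  }
  totals
}
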
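# Rigid-body transforms (proper rotations + translations) used for symmetry
# operations and docking placements.

#' Create a rigid-body transform
#'
#' @param rotation 3x3 proper rotation matrix (orthonormal, det +1 within
#'   1e-9).
#' @param translation Numeric 3-vector, Angstrom.
#' @return An object of class `transform_op`.
#' @export
transform_op <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  if (!all(dim(rotation) == c(3L, 3L)) || length(translation) != 3L)
    stop("rotation must be 3x3 and translation length 3")
  err_orth <- max(abs(crossprod(rotation) - diag(3)))
  if (err_orth > 1e-9 || abs(det(rotation) - 1) > 1e-9)
    stop("rotation must be orthonormal with determinant +1 (tolerance 1e-9); ",
         sprintf("orthonormality error %.3g, det %.12f", err_orth, det(rotation)))
  structure(list(rotation = rotation, translation = translation),
            class = "transform_op")
}

#' @export
print.transform_op <- function(x, ...) {
  cat("<transform_op>\n rotation:\n")
  print(round(x$rotation, 6))
  cat(" translation:", paste(round(x$translation, 4), collapse = " "), "\n")
  invisible(x)
}

identity_transform <- function() transform_op()

# Compose: apply a first, then b (x -> Rb (Ra x + ta) + tb).
compose_transforms <- function(b, a) {
  transform_op(b$rotation %*% a$rotation,
               as.numeric(b$rotation %*% a$translation) + b$translation)
}

apply_transform_xyz <- function(xyz, t) {
  sweep(xyz %*% t(t$rotation), 2L, t$translation, "+")
}

#' Apply a rigid transform to a structure
#'
#' Applies `x' = R x + tau` to the selected atoms (all atoms by default).
#' Topology is unchanged.
#'
#' @param s An `ab_structure`.
#' @param t A `transform_op`.
#' @param subset Optional integer atom indices to transform.
#' @return The transformed `ab_structure`.
#' @export
apply_transform <- function(s, t, subset = NULL) {
  stopifnot(inherits(s, "ab_structure"))
  if (!inherits(t, "transform_op")) t <- do.call(transform_op, t)
  if (is.null(subset)) {
    s$xyz <- apply_transform_xyz(s$xyz, t)
  } else {
    subset <- as.integer(subset)
    stopifnot(all(subset >= 1L), all(subset <= n_atoms(s)))
    s$xyz[subset, ] <- apply_transform_xyz(s$xyz[subset, , drop = FALSE], t)
  }
  s
}
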
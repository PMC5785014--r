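#' Rigid-body transforms
#'
#' A rigid transform is a proper rotation (3x3 orthonormal matrix with
#' determinant +1) plus a translation vector in Angstrom. Transforms place a
#' ligand chain into the frame of a receptor chain and compose along the edges
#' of a spanning-tree model.
#'
#' @param rotation 3x3 rotation matrix.
#' @param translation numeric length-3 translation (Angstrom).
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  stopifnot(all(dim(rotation) == c(3L, 3L)), length(translation) == 3L,
            all(is.finite(rotation)), all(is.finite(translation)))
  err <- max(abs(crossprod(rotation) - diag(3)))
  if (err > 1e-8) {
    stop("rotation matrix is not orthonormal (max deviation ", signif(err, 3), ")")
  }
  if (det(rotation) < 0) {
    stop("rotation matrix has determinant -1 (reflection, not a rotation)")
  }
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("<rigid_transform>\n")
  cat("rotation:\n")
  print(round(x$rotation, 6))
  cat("translation:", paste(round(x$translation, 4), collapse = " "), "\n")
  invisible(x)
}

#' @rdname rigid_transform
#' @export
transform_identity <- function() rigid_transform()

#' Compose two rigid transforms
#'
#' `transform_compose(a, b)` returns the transform equivalent to applying `b`
#' first and then `a`, i.e. `x -> a(b(x))`.
#'
#' @param a,b `rigid_transform` objects.
#' @export
transform_compose <- function(a, b) {
  rigid_transform(a$rotation %*% b$rotation,
                  as.numeric(a$rotation %*% b$translation) + a$translation)
}

#' Invert a rigid transform
#' @param x A `rigid_transform`.
#' @export
transform_invert <- function(x) {
  rt <- t(x$rotation)
  rigid_transform(rt, -as.numeric(rt %*% x$translation))
}

#' Apply a rigid transform to coordinates
#'
#' @param x A `rigid_transform`.
#' @param coords Numeric matrix with 3 columns (one row per atom).
#' @return Transformed coordinate matrix of the same shape.
#' @export
transform_apply <- function(x, coords) {
  coords <- as.matrix(coords)
  stopifnot(ncol(coords) == 3L)
  sweep(coords %*% t(x$rotation), 2L, x$translation, `+`)
}

# Nearest proper rotation by polar decomposition (SVD). Errors if the input
# drifts from orthonormality by more than `max_drift` or is a reflection.
reorthonormalize <- function(m, max_drift = 1e-3) {
  m <- as.matrix(m)
  drift <- max(abs(crossprod(m) - diag(3)))
  if (drift > max_drift) {
    stop("matrix deviates from a rotation by ", signif(drift, 3),
         " (allowed drift ", max_drift, ")")
  }
  s <- svd(m)
  r <- s$u %*% t(s$v)
  if (det(r) < 0) stop("matrix is a reflection (determinant -1)")
  r
}

# Rotation about a unit axis by angle (radians), Rodrigues form.
rotation_axis_angle <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  k <- matrix(c(0, axis[3], -axis[2],
                -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3, 3)
  diag(3) + sin(angle) * k + (1 - cos(angle)) * (k %*% k)
}

# Uniform random rotation (uses the current RNG stream).
random_rotation <- function() {
  # quaternion from 4 normals, normalised
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  a <- q[1]; b <- q[2]; c <- q[3]; d <- q[4]
  matrix(c(a^2 + b^2 - c^2 - d^2, 2 * (b * c + a * d),     2 * (b * d - a * c),
           2 * (b * c - a * d),   a^2 - b^2 + c^2 - d^2,   2 * (c * d + a * b),
           2 * (b * d + a * c),   2 * (c * d - a * b),     a^2 - b^2 - c^2 + d^2),
         3, 3)
}
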
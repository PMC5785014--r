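#' Options for solvent-accessible surface area
#'
#' SASA is computed with the Shrake-Rupley method: each atom is inflated by
#' the probe radius, test points are spread quasi-uniformly on the inflated
#' sphere (golden-spiral lattice), and a point is accessible when it lies
#' outside every neighbouring inflated sphere.
#'
#' @param probe_radius Solvent probe radius in Angstrom (water: 1.4).
#' @param n_sphere_points Test points per atom (>= 60); more points, smaller
#'   quadrature error.
#' @param radii Named numeric vector of van der Waals radii by element symbol.
#' @param default_radius Radius used (with a warning) for elements missing
#'   from `radii`.
#' @return A list of class `sasa_options`.
#' @export
sasa_options <- function(probe_radius = 1.4, n_sphere_points = 960L,
                         radii = vdw_radii(), default_radius = 1.8) {
  stopifnot(probe_radius > 0, n_sphere_points >= 60L, default_radius > 0)
  structure(list(probe_radius = probe_radius,
                 n_sphere_points = as.integer(n_sphere_points),
                 radii = radii, default_radius = default_radius),
            class = "sasa_options")
}

#' Standard van der Waals radii (Angstrom) by element
#' @export
vdw_radii <- function() {
  c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80, H = 1.20,
    F = 1.47, CL = 1.75, BR = 1.85, I = 1.98, SE = 1.90,
    FE = 1.80, ZN = 1.39, MG = 1.73, CA = 1.74, MN = 1.80,
    "NA" = 2.27, K = 2.75)
}

# golden-spiral quasi-uniform points on the unit sphere
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

atom_radii <- function(elements, options) {
  r <- unname(options$radii[toupper(elements)])
  if (anyNA(r)) {
    missing <- unique(toupper(elements)[is.na(r)])
    warning("no van der Waals radius for element(s) ",
            paste(missing, collapse = ", "), "; using default ",
            options$default_radius, " A")
    r[is.na(r)] <- options$default_radius
  }
  r
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' @param atoms A `cpx_structure` or any data frame with columns `element`,
#'   `x`, `y`, `z`.
#' @param options A [sasa_options()] object.
#' @return A list with `total` (Angstrom^2) and `per_atom` (numeric vector,
#'   one entry per atom row).
#' @export
compute_sasa <- function(atoms, options = sasa_options()) {
  if (nrow(atoms) == 0L) stop("SASA of an empty atom set")
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  r <- atom_radii(atoms$element, options) + options$probe_radius
  n <- nrow(xyz)
  pts <- sphere_points(options$n_sphere_points)
  per_atom <- numeric(n)
  # neighbour lists: j is a neighbour of i when spheres can overlap
  rmax <- max(r)
  for (i in seq_len(n)) {
    d2 <- (xyz[, 1] - xyz[i, 1])^2 + (xyz[, 2] - xyz[i, 2])^2 +
      (xyz[, 3] - xyz[i, 3])^2
    nb <- which(d2 < (r[i] + r)^2 & seq_len(n) != i)
    p <- sweep(pts * r[i], 2L, xyz[i, ], `+`)
    accessible <- rep(TRUE, nrow(p))
    for (j in nb) {
      if (!any(accessible)) break
      dx <- p[accessible, 1L] - xyz[j, 1L]
      dy <- p[accessible, 2L] - xyz[j, 2L]
      dz <- p[accessible, 3L] - xyz[j, 3L]
      accessible[accessible] <- (dx * dx + dy * dy + dz * dz) >= r[j]^2
    }
    per_atom[i] <- 4 * pi * r[i]^2 * sum(accessible) / nrow(p)
  }
  list(total = sum(per_atom), per_atom = per_atom)
}
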
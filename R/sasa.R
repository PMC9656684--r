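## Deterministic golden-section spiral quadrature points on the unit sphere.
sphere_quadrature <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Numerical SASA over heavy atoms: each atom's sphere of radius
#' `r_vdw + probe_radius` is sampled with a deterministic golden-section
#' spiral; a sample point is accessible if it lies outside every
#' neighbouring atom's expanded sphere.  Van der Waals radii are the Bondi
#' radii by element.  Hydrogens are ignored both as surfaces and as
#' occluders.
#'
#' @param frame a `"Frame"`.
#' @param probe_radius solvent probe radius in Angstrom (water: 1.4).
#' @param sphere_points number of quadrature points per atom.
#' @param atoms optional integer atom indices (into the topology) to report;
#'   occlusion is always computed against all heavy atoms.  Default: all
#'   heavy atoms.
#' @return List with `per_atom` (named by atom index; `NA` for hydrogens /
#'   unrequested atoms) and `per_residue` (named by residue number, summed
#'   over each residue's requested heavy atoms), in Angstrom^2.
#' @export
sasa <- function(frame, probe_radius = 1.4, sphere_points = 960L, atoms = NULL) {
  topo <- frame$topology
  heavy <- which(topo$element != "H")
  if (length(heavy) == 0L) stop("no heavy atoms in frame")
  unknown <- setdiff(unique(topo$element[heavy]), names(.bondi_radii))
  if (length(unknown)) stop("no van der Waals radius for element(s): ",
                            paste(unknown, collapse = ", "))
  if (is.null(atoms)) atoms <- heavy
  atoms <- intersect(atoms, heavy)
  sph <- sphere_quadrature(sphere_points)
  radii <- .bondi_radii[topo$element] + probe_radius
  xyz_h <- frame$xyz[heavy, , drop = FALSE]
  rad_h <- radii[heavy]
  per_atom <- rep(NA_real_, nrow(topo))
  for (a in atoms) {
    ra <- radii[a]
    centre <- frame$xyz[a, ]
    pts <- sph * ra + matrix(centre, sphere_points, 3L, byrow = TRUE)
    # neighbours whose expanded sphere can reach this atom's surface
    dn <- sqrt(colSums((t(xyz_h) - centre)^2))
    nb <- which(dn < ra + rad_h & heavy != a)
    if (length(nb) == 0L) {
      acc <- sphere_points
    } else {
      d2 <- cross_dist(pts, xyz_h[nb, , drop = FALSE])
      buried <- rowSums(d2 < matrix(rad_h[nb], sphere_points, length(nb),
                                    byrow = TRUE) - 1e-12) > 0
      acc <- sum(!buried)
    }
    per_atom[a] <- 4 * pi * ra^2 * acc / sphere_points
  }
  res_nums <- sort(unique(topo$resno[atoms]))
  per_residue <- vapply(res_nums, function(r) {
    sum(per_atom[atoms[topo$resno[atoms] == r]])
  }, numeric(1))
  names(per_residue) <- res_nums
  list(per_atom = per_atom, per_residue = per_residue)
}
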
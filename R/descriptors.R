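#' Residue roles driving the intrinsic feature catalog
#'
#' Names the residues on which the descriptor catalog is built: the four
#' tyrosine sites, the maximally and minimally fluctuating residues, the
#' reference helix used for superposition, the chain termini and the
#' pseudo-torsion anchor.  Defaults correspond to the KIT kinase-insert
#' domain: Y703/Y721/Y730/Y747, max-fluctuating S717/K725/R739,
#' min-fluctuating V732/P754, reference helix A701-N705, termini F689/D768
#' and anchor E699.
#'
#' @param tyrosines 4 residue numbers.
#' @param max_fluct 3 residue numbers.
#' @param min_fluct 2 residue numbers.
#' @param reference_helix residue span used for normalising fits.
#' @param termini the two terminal residue numbers.
#' @param anchor residue used as pseudo-torsion anchor.
#' @return An object of class `"ResidueRoles"`.
#' @export
residue_roles <- function(tyrosines = c(703L, 721L, 730L, 747L),
                          max_fluct = c(717L, 725L, 739L),
                          min_fluct = c(732L, 754L),
                          reference_helix = 701:705,
                          termini = c(689L, 768L),
                          anchor = 699L) {
  if (length(tyrosines) != 4L) stop("exactly 4 tyrosine residues are required")
  if (length(max_fluct) != 3L) stop("exactly 3 maximally fluctuating residues are required")
  if (length(min_fluct) != 2L) stop("exactly 2 minimally fluctuating residues are required")
  if (length(termini) != 2L) stop("termini must be a pair of residue numbers")
  structure(list(tyrosines = as.integer(tyrosines),
                 max_fluct = as.integer(max_fluct),
                 min_fluct = as.integer(min_fluct),
                 reference_helix = as.integer(reference_helix),
                 termini = as.integer(termini),
                 anchor = as.integer(anchor)),
            class = "ResidueRoles")
}

check_roles <- function(roles, topology) {
  all_res <- unique(topology$resno)
  need <- c(roles$tyrosines, roles$max_fluct, roles$min_fluct,
            roles$reference_helix, roles$termini, roles$anchor)
  missing <- setdiff(need, all_res)
  if (length(missing)) {
    stop("role residues absent from topology: ", paste(missing, collapse = ", "))
  }
  invisible(TRUE)
}

#' Per-frame RMSD against a reference conformation
#'
#' For every frame, superposes the fit selection onto the reference and
#' reports the RMSD over the measure selection.  Defaults reproduce the
#' common convention of fitting and measuring on the C-alpha atoms.
#'
#' @param traj a `Trajectory`.
#' @param reference a `"Frame"` (e.g. the t = 0 conformation).
#' @param fit_selection,measure_selection atom index vectors; default all
#'   C-alpha atoms.
#' @return Numeric vector, Angstrom, one value per frame.
#' @export
rmsd_series <- function(traj, reference, fit_selection = NULL,
                        measure_selection = NULL) {
  if (is.null(fit_selection)) fit_selection <- ca_indices(traj$topology)
  if (is.null(measure_selection)) measure_selection <- ca_indices(traj$topology)
  vapply(seq_len(n_frames(traj)), function(i) {
    fr <- get_frame(traj, i)
    sp <- superpose(fr, reference, fit_selection)
    al <- sp$aligned$xyz[measure_selection, , drop = FALSE]
    rf <- reference$xyz[measure_selection, , drop = FALSE]
    sqrt(mean(rowSums((al - rf)^2)))
  }, numeric(1))
}

#' Per-residue root-mean-square fluctuation
#'
#' After fitting every frame on `fit_selection`, computes for each residue
#' the RMS deviation of its C-alpha position from its time-average position.
#'
#' @param traj a `Trajectory` with at least 2 frames.
#' @param fit_selection atom indices for the fit; default all C-alpha atoms.
#' @param measure_selection atom indices to report on; default all C-alpha
#'   atoms.
#' @return Named numeric vector (Angstrom), one value per selected atom,
#'   named by residue number.
#' @export
rmsf <- function(traj, fit_selection = NULL, measure_selection = NULL) {
  if (n_frames(traj) < 2L) stop("RMSF is undefined for a single frame")
  if (is.null(fit_selection)) fit_selection <- ca_indices(traj$topology)
  if (is.null(measure_selection)) measure_selection <- ca_indices(traj$topology)
  ref <- get_frame(traj, 1L)
  nf <- n_frames(traj)
  nm <- length(measure_selection)
  pos <- array(NA_real_, c(nf, nm, 3L))
  for (i in seq_len(nf)) {
    sp <- superpose(get_frame(traj, i), ref, fit_selection)
    pos[i, , ] <- sp$aligned$xyz[measure_selection, , drop = FALSE]
  }
  mean_pos <- apply(pos, c(2L, 3L), mean)
  dev2 <- vapply(seq_len(nm), function(j) {
    mean(rowSums((pos[, j, , drop = TRUE] -
                    matrix(mean_pos[j, ], nf, 3L, byrow = TRUE))^2))
  }, numeric(1))
  out <- sqrt(dev2)
  names(out) <- traj$topology$resno[measure_selection]
  out
}

#' Mass-weighted radius of gyration over heavy atoms
#'
#' @param frame a `"Frame"`.
#' @return Rg in Angstrom.
#' @export
radius_of_gyration <- function(frame) {
  heavy <- frame$topology$element != "H"
  if (!any(heavy)) stop("no heavy atoms in frame")
  m <- frame$topology$mass[heavy]
  x <- frame$xyz[heavy, , drop = FALSE]
  com <- colSums(x * m) / sum(m)
  d2 <- rowSums(sweep(x, 2L, com)^2)
  sqrt(sum(m * d2) / sum(m))
}

#' End-to-end distance between the terminal C-alpha atoms
#'
#' @param frame a `"Frame"`.
#' @param roles a `ResidueRoles` naming the two termini.
#' @return Distance in Angstrom.
#' @export
end_to_end_distance <- function(frame, roles) {
  idx <- atom_index(frame$topology, roles$termini, "CA")
  pdist(frame$xyz[idx[1L], ], frame$xyz[idx[2L], ])
}

#' Backbone dihedral angles phi and psi of one residue
#'
#' IUPAC sign convention, degrees in (-180, 180].  Chain-terminal residues
#' return `NA` for the dihedral that lacks a flanking peptide bond.
#'
#' @param frame a `"Frame"`.
#' @param resno residue number.
#' @return List with `phi` and `psi` (degrees or `NA`).
#' @export
backbone_dihedrals <- function(frame, resno) {
  topo <- frame$topology
  g <- function(r, a) {
    i <- which(topo$resno == r & topo$elety == a)
    if (length(i) == 0L) return(NULL)
    frame$xyz[i[1L], ]
  }
  N <- g(resno, "N"); CA <- g(resno, "CA"); C <- g(resno, "C")
  if (is.null(N) || is.null(CA) || is.null(C)) {
    stop("residue ", resno, " lacks backbone atoms for dihedral computation")
  }
  Cm <- g(resno - 1L, "C")
  Np <- g(resno + 1L, "N")
  phi <- if (is.null(Cm)) NA_real_ else torsion_points(Cm, N, CA, C)
  psi <- if (is.null(Np)) NA_real_ else torsion_points(N, CA, C, Np)
  list(phi = phi, psi = psi)
}

#' Pseudo-torsion angle over four C-alpha atoms
#'
#' The torsion of the four (generally non-consecutive) C-alpha positions:
#' the signed angle between the planes of points 1-2-3 and 2-3-4, in
#' (-180, 180] degrees.
#'
#' @param frame a `"Frame"`.
#' @param resnos 4 distinct residue numbers.
#' @return Angle in degrees.
#' @export
pseudo_torsion <- function(frame, resnos) {
  if (length(unique(resnos)) != 4L) stop("pseudo-torsion needs 4 distinct residues")
  idx <- atom_index(frame$topology, resnos, "CA")
  p <- frame$xyz[idx, , drop = FALSE]
  torsion_points(p[1L, ], p[2L, ], p[3L, ], p[4L, ])
}

#' Triangle area spanned by three C-alpha atoms
#'
#' @param frame a `"Frame"`.
#' @param resnos 3 distinct residue numbers.
#' @return Area in Angstrom^2 (0 for collinear residues).
#' @export
triangle_area <- function(frame, resnos) {
  if (length(unique(resnos)) != 3L) stop("triangle area needs 3 distinct residues")
  idx <- atom_index(frame$topology, resnos, "CA")
  p <- frame$xyz[idx, , drop = FALSE]
  0.5 * vnorm(cross3(p[2L, ] - p[1L, ], p[3L, ] - p[1L, ]))
}

#' Tetrahedron volume spanned by four C-alpha atoms
#'
#' `|det(p2-p1, p3-p1, p4-p1)| / 6`; 0 for coplanar residues.
#'
#' @param frame a `"Frame"`.
#' @param resnos 4 distinct residue numbers (e.g. the four tyrosines).
#' @return Volume in Angstrom^3.
#' @export
tetrahedron_volume <- function(frame, resnos) {
  if (length(unique(resnos)) != 4L) stop("tetrahedron volume needs 4 distinct residues")
  idx <- atom_index(frame$topology, resnos, "CA")
  p <- frame$xyz[idx, , drop = FALSE]
  M <- rbind(p[2L, ] - p[1L, ], p[3L, ] - p[1L, ], p[4L, ] - p[1L, ])
  abs(det(M)) / 6
}

#' All pairwise C-alpha distances among a residue set
#'
#' @param frame a `"Frame"`.
#' @param resnos distinct residue numbers.
#' @return `data.frame` with columns `res_i`, `res_j`, `distance` covering
#'   every unordered pair in `combn` order.
#' @export
pairwise_ca_distances <- function(frame, resnos) {
  if (anyDuplicated(resnos)) stop("duplicate residues in pairwise distance request")
  idx <- atom_index(frame$topology, resnos, "CA")
  pairs <- utils::combn(seq_along(resnos), 2L)
  d <- apply(pairs, 2L, function(pr) {
    pdist(frame$xyz[idx[pr[1L]], ], frame$xyz[idx[pr[2L]], ])
  })
  data.frame(res_i = resnos[pairs[1L, ]], res_j = resnos[pairs[2L, ]],
             distance = d)
}
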
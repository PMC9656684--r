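## Reconstruct an amide hydrogen on residue i's backbone N when absent:
## 1.01 Angstrom from N, anti (trans) to the carbonyl O of residue i-1,
## placed along the in-plane bisector direction.  For the first residue (no
## preceding carbonyl) the H is placed anti to the residue's own C.
reconstruct_amide_h <- function(N, CA, O_prev, C_prev = NULL) {
  u <- if (!is.null(O_prev) && !is.null(C_prev)) {
    # direction opposing both the N-CA bond and the C(i-1)=O direction
    d1 <- (N - CA) / vnorm(N - CA)
    d2 <- (C_prev - O_prev) / vnorm(C_prev - O_prev)   # points from O towards C
    v <- d1 + (N - C_prev) / vnorm(N - C_prev)
    v / vnorm(v)
  } else {
    d1 <- (N - CA) / vnorm(N - CA)
    d1
  }
  N + 1.01 * u
}

## Per-residue backbone coordinate table (rows: residues in order); NA rows
## where atoms are absent.
backbone_table <- function(frame) {
  topo <- frame$topology
  resn <- unique(topo$resno)
  take <- function(a) {
    t(vapply(resn, function(r) {
      i <- which(topo$resno == r & topo$elety == a)
      if (length(i) == 0L) rep(NA_real_, 3L) else frame$xyz[i[1L], ]
    }, numeric(3)))
  }
  list(resno = resn, resid = vapply(resn, function(r)
         topo$resid[which(topo$resno == r)[1L]], character(1)),
       N = take("N"), H = take("H"), CA = take("CA"),
       C = take("C"), O = take("O"))
}

#' Assign helical secondary structure (hydrogen-bond based)
#'
#' Backbone amide-to-carbonyl hydrogen bonds are detected with the
#' Kabsch-Sander electrostatic model
#' `E = 0.084 * 332 * (1/r_ON + 1/r_CH - 1/r_OH - 1/r_CN)` kcal/mol,
#' a bond being assigned when `E < -0.5`.  Two consecutive i -> i+4 turns
#' produce an alpha-helix run (`"H"`, minimum 4 residues); two consecutive
#' i -> i+3 turns a 3-10 helix run (`"G"`, minimum 3 residues); everything
#' else is coil (`"C"`).  Missing amide hydrogens are reconstructed
#' geometrically; proline (no amide H) cannot donate.
#'
#' @param frame a `"Frame"` with backbone N, CA, C, O atoms.
#' @return Character vector over residues (in residue order) with labels in
#'   `{"H", "G", "C"}`, named by residue number.
#' @export
assign_helices <- function(frame) {
  bb <- backbone_table(frame)
  n <- length(bb$resno)
  lab <- rep("C", n)
  ok <- stats::complete.cases(bb$N) & stats::complete.cases(bb$CA) &
    stats::complete.cases(bb$C) & stats::complete.cases(bb$O)
  if (any(!ok)) warning("residues with missing backbone atoms labelled 'C': ",
                        paste(bb$resno[!ok], collapse = ", "))
  # donor H per residue (reconstructed when absent); proline never donates
  H <- bb$H
  for (i in seq_len(n)) {
    if (!ok[i] || bb$resid[i] == "PRO") next
    if (anyNA(H[i, ])) {
      H[i, ] <- if (i > 1L && ok[i - 1L]) {
        reconstruct_amide_h(bb$N[i, ], bb$CA[i, ], bb$O[i - 1L, ], bb$C[i - 1L, ])
      } else {
        reconstruct_amide_h(bb$N[i, ], bb$CA[i, ], NULL, NULL)
      }
    }
  }
  hbond <- function(acc, don) {
    # acceptor C=O of residue acc, donor N-H of residue don
    if (!ok[acc] || !ok[don] || bb$resid[don] == "PRO" || anyNA(H[don, ])) return(FALSE)
    rON <- pdist(bb$O[acc, ], bb$N[don, ])
    rCH <- pdist(bb$C[acc, ], H[don, ])
    rOH <- pdist(bb$O[acc, ], H[don, ])
    rCN <- pdist(bb$C[acc, ], bb$N[don, ])
    E <- 0.084 * 332 * (1 / rON + 1 / rCH - 1 / rOH - 1 / rCN)
    E < -0.5
  }
  turn4 <- vapply(seq_len(max(0L, n - 4L)), function(i) hbond(i, i + 4L), logical(1))
  turn3 <- vapply(seq_len(max(0L, n - 3L)), function(i) hbond(i, i + 3L), logical(1))
  for (i in seq_len(max(0L, n - 5L))) {
    if (turn4[i] && turn4[i + 1L]) lab[(i + 1L):(i + 4L)] <- "H"
  }
  for (i in seq_len(max(0L, n - 4L))) {
    if (turn3[i] && turn3[i + 1L]) {
      g <- (i + 1L):(i + 3L)
      lab[g][lab[g] == "C"] <- "G"   # alpha takes precedence
    }
  }
  names(lab) <- bb$resno
  lab
}

#' Per-residue helicity occurrence over a trajectory
#'
#' Percentage of frames in which each residue is assigned a helical state
#' (`"H"` or `"G"`) by [assign_helices()].
#'
#' @param traj a `Trajectory`.
#' @return Named numeric vector in percent (0-100), named by residue number.
#' @export
helicity_occurrence <- function(traj) {
  stopifnot(n_frames(traj) >= 1L)
  nf <- n_frames(traj)
  acc <- NULL
  for (i in seq_len(nf)) {
    lab <- assign_helices(get_frame(traj, i))
    hel <- lab %in% c("H", "G")
    if (is.null(acc)) {
      acc <- as.numeric(hel)
      names(acc) <- names(lab)
    } else {
      acc <- acc + hel
    }
  }
  100 * acc / nf
}

#' Default Ramachandran region catalog
#'
#' Rectangular (phi, psi) zones, first-declared wins on overlap: alpha helix
#' centred at (-64, -41) +/- 18; 3-10 helix at (-60, -25) +/- 15; parallel
#' beta at (-119, 113) +/- (17, 15); antiparallel beta at (-139, 135)
#' +/- (18, 16); left-handed helix at (50, 60) +/- 20.
#'
#' @return `data.frame` with columns `name`, `phi`, `psi`, `phi_tol`,
#'   `psi_tol`.
#' @export
default_ramachandran_catalog <- function() {
  data.frame(
    name = c("alpha", "three_ten", "parallel_beta", "antiparallel_beta",
             "left_handed"),
    phi = c(-64, -60, -119, -139, 50),
    psi = c(-41, -25, 113, 135, 60),
    phi_tol = c(18, 15, 17, 18, 20),
    psi_tol = c(18, 15, 15, 16, 20),
    stringsAsFactors = FALSE
  )
}

#' Classify a backbone dihedral pair into a Ramachandran region
#'
#' The first catalog region containing the point wins; points outside all
#' regions are labelled `"other"`.
#'
#' @param phi,psi dihedral angles in degrees (vectorised).
#' @param catalog region catalog, see [default_ramachandran_catalog()].
#' @return Character vector of region labels.
#' @export
ramachandran_region <- function(phi, psi, catalog = default_ramachandran_catalog()) {
  stopifnot(length(phi) == length(psi))
  out <- rep("other", length(phi))
  for (i in rev(seq_len(nrow(catalog)))) {
    hit <- abs(wrap_angle(phi - catalog$phi[i])) <= catalog$phi_tol[i] &
      abs(wrap_angle(psi - catalog$psi[i])) <= catalog$psi_tol[i]
    out[which(hit)] <- catalog$name[i]
  }
  out[is.na(phi) | is.na(psi)] <- NA_character_
  out
}
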
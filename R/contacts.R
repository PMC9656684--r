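#' Geometric contact criteria
#'
#' Cut-offs for hydrogen-bond and van der Waals contact detection and the
#' occurrence filter.  Boundaries are inclusive: a donor-acceptor distance
#' of exactly 3.6 Angstrom, an angle of exactly 120 degrees and an
#' occurrence of exactly 0.40 all qualify.
#'
#' @param hbond_da_max maximum donor-acceptor heavy-atom distance (Angstrom).
#' @param hbond_angle_min minimum donor-hydrogen-acceptor angle (degrees).
#' @param vdw_cc_max maximum side-chain carbon-carbon distance (Angstrom).
#' @param occurrence_min minimum fraction of frames for a contact to be
#'   retained by [contact_occurrence()].
#' @param donor_acceptor_elements elements eligible as donors/acceptors.
#' @param min_residue_separation minimum `|i - j|` in residue numbering for
#'   a van der Waals contact (intra-residue hydrogen bonds are always
#'   excluded).
#' @return An object of class `"ContactCriteria"`.
#' @export
contact_criteria <- function(hbond_da_max = 3.6, hbond_angle_min = 120,
                             vdw_cc_max = 3.6, occurrence_min = 0.40,
                             donor_acceptor_elements = c("N", "O", "S"),
                             min_residue_separation = 2L) {
  stopifnot(hbond_da_max > 0, hbond_angle_min > 0, vdw_cc_max > 0,
            occurrence_min >= 0, occurrence_min <= 1)
  structure(list(hbond_da_max = hbond_da_max, hbond_angle_min = hbond_angle_min,
                 vdw_cc_max = vdw_cc_max, occurrence_min = occurrence_min,
                 donor_acceptor_elements = donor_acceptor_elements,
                 min_residue_separation = as.integer(min_residue_separation)),
            class = "ContactCriteria")
}

## hydrogens attached to each heavy atom: within 1.3 Angstrom
attached_hydrogens <- function(frame) {
  topo <- frame$topology
  hyd <- which(topo$element == "H")
  heavy <- which(topo$element != "H")
  if (length(hyd) == 0L) return(list(hyd = integer(0), owner = integer(0)))
  d <- cross_dist(frame$xyz[hyd, , drop = FALSE], frame$xyz[heavy, , drop = FALSE])
  owner <- heavy[apply(d, 1L, which.min)]
  keep <- d[cbind(seq_along(hyd), match(owner, heavy))] < 1.3
  list(hyd = hyd[keep], owner = owner[keep])
}

#' Detect hydrogen bonds in a frame
#'
#' A hydrogen bond is a donor heavy atom D (N/O/S bearing at least one
#' hydrogen), an acceptor heavy atom A (N/O/S in a different residue), with
#' D-A distance at most `hbond_da_max` and D-H...A angle at least
#' `hbond_angle_min`.  Each (donor, acceptor) pair is reported once with its
#' best-angle hydrogen.
#'
#' @param frame a `"Frame"` (hydrogens present; donors without hydrogens are
#'   skipped).
#' @param criteria a `ContactCriteria`.
#' @return `data.frame` with columns `donor`, `hydrogen`, `acceptor` (atom
#'   indices), `res_donor`, `res_acceptor`, `distance`, `angle`.
#' @export
find_hbonds <- function(frame, criteria = contact_criteria()) {
  topo <- frame$topology
  das <- which(topo$element %in% criteria$donor_acceptor_elements)
  att <- attached_hydrogens(frame)
  donors <- intersect(das, unique(att$owner))
  out <- list()
  if (length(donors) == 0L || length(das) < 2L) {
    return(empty_hbond_table())
  }
  dmat <- cross_dist(frame$xyz[donors, , drop = FALSE],
                     frame$xyz[das, , drop = FALSE])
  for (di in seq_along(donors)) {
    d <- donors[di]
    hs <- att$hyd[att$owner == d]
    cand <- das[dmat[di, ] <= criteria$hbond_da_max + 1e-12 &
                  topo$resno[das] != topo$resno[d]]
    cand <- setdiff(cand, d)
    for (a in cand) {
      best_ang <- -Inf
      best_h <- NA_integer_
      for (h in hs) {
        v1 <- frame$xyz[d, ] - frame$xyz[h, ]
        v2 <- frame$xyz[a, ] - frame$xyz[h, ]
        ang <- rad2deg(acos(max(-1, min(1, sum(v1 * v2) / (vnorm(v1) * vnorm(v2))))))
        if (ang > best_ang) { best_ang <- ang; best_h <- h }
      }
      if (best_ang >= criteria$hbond_angle_min - 1e-9) {
        out[[length(out) + 1L]] <- data.frame(
          donor = d, hydrogen = best_h, acceptor = a,
          res_donor = topo$resno[d], res_acceptor = topo$resno[a],
          distance = pdist(frame$xyz[d, ], frame$xyz[a, ]), angle = best_ang)
      }
    }
  }
  if (length(out) == 0L) return(empty_hbond_table())
  do.call(rbind, out)
}

empty_hbond_table <- function() {
  data.frame(donor = integer(0), hydrogen = integer(0), acceptor = integer(0),
             res_donor = integer(0), res_acceptor = integer(0),
             distance = numeric(0), angle = numeric(0))
}

#' Detect van der Waals (hydrophobic) contacts in a frame
#'
#' Residue pairs separated by at least `min_residue_separation` in sequence
#' that have at least one pair of side-chain carbon atoms within
#' `vdw_cc_max`; one record per residue pair carrying the minimal distance.
#'
#' @param frame a `"Frame"`.
#' @param criteria a `ContactCriteria`.
#' @return `data.frame` with columns `res_i`, `res_j`, `distance`.
#' @export
find_vdw_contacts <- function(frame, criteria = contact_criteria()) {
  topo <- frame$topology
  sc <- which(topo$is_sidechain & topo$element == "C")
  if (length(sc) < 2L) {
    return(data.frame(res_i = integer(0), res_j = integer(0), distance = numeric(0)))
  }
  d <- cross_dist(frame$xyz[sc, , drop = FALSE], frame$xyz[sc, , drop = FALSE])
  res <- topo$resno[sc]
  sep_ok <- abs(outer(res, res, "-")) >= criteria$min_residue_separation
  hit <- which(upper.tri(d) & d <= criteria$vdw_cc_max + 1e-12 & sep_ok,
               arr.ind = TRUE)
  if (nrow(hit) == 0L) {
    return(data.frame(res_i = integer(0), res_j = integer(0), distance = numeric(0)))
  }
  tab <- data.frame(res_i = pmin(res[hit[, 1L]], res[hit[, 2L]]),
                    res_j = pmax(res[hit[, 1L]], res[hit[, 2L]]),
                    distance = d[hit])
  agg <- stats::aggregate(distance ~ res_i + res_j, data = tab, FUN = min)
  agg[order(agg$res_i, agg$res_j), , drop = FALSE]
}

#' Per-frame hydrogen-bond and van der Waals contact counts
#'
#' @param traj a `Trajectory`.
#' @param criteria a `ContactCriteria`.
#' @return `data.frame` with one row per frame: `frame`, `n_hbonds`, `n_vdw`.
#' @export
contact_counts <- function(traj, criteria = contact_criteria()) {
  n <- n_frames(traj)
  nh <- integer(n)
  nv <- integer(n)
  for (i in seq_len(n)) {
    fr <- get_frame(traj, i)
    nh[i] <- nrow(find_hbonds(fr, criteria))
    nv[i] <- nrow(find_vdw_contacts(fr, criteria))
  }
  data.frame(frame = seq_len(n), n_hbonds = nh, n_vdw = nv)
}

#' Contact occurrence over a trajectory, with the occurrence filter
#'
#' Hydrogen bonds are identified by their (donor, acceptor) atom pair, van
#' der Waals contacts by their residue pair.  The occurrence of a contact is
#' the fraction of frames in which it is present; only contacts with
#' occurrence at least `criteria$occurrence_min` are retained.
#'
#' @param traj a `Trajectory` with at least one frame.
#' @param criteria a `ContactCriteria`.
#' @return `data.frame` with columns `kind` (`"hbond"`/`"vdw"`), `id_i`,
#'   `id_j` (atom indices for hbond, residue numbers for vdw), `res_i`,
#'   `res_j`, `occurrence`.
#' @export
contact_occurrence <- function(traj, criteria = contact_criteria()) {
  stopifnot(n_frames(traj) >= 1L)
  n <- n_frames(traj)
  topo <- traj$topology
  hb_keys <- character(0)
  vd_keys <- character(0)
  hb_tab <- new.env(parent = emptyenv())
  vd_tab <- new.env(parent = emptyenv())
  for (i in seq_len(n)) {
    fr <- get_frame(traj, i)
    hb <- find_hbonds(fr, criteria)
    if (nrow(hb)) {
      for (k in unique(paste(hb$donor, hb$acceptor, sep = "_"))) {
        hb_tab[[k]] <- (if (is.null(hb_tab[[k]])) 0L else hb_tab[[k]]) + 1L
      }
    }
    vd <- find_vdw_contacts(fr, criteria)
    if (nrow(vd)) {
      for (k in paste(vd$res_i, vd$res_j, sep = "_")) {
        vd_tab[[k]] <- (if (is.null(vd_tab[[k]])) 0L else vd_tab[[k]]) + 1L
      }
    }
  }
  rows <- list()
  for (k in ls(hb_tab)) {
    occ <- hb_tab[[k]] / n
    if (occ >= criteria$occurrence_min - 1e-12) {
      ij <- as.integer(strsplit(k, "_")[[1L]])
      rows[[length(rows) + 1L]] <- data.frame(
        kind = "hbond", id_i = ij[1L], id_j = ij[2L],
        res_i = topo$resno[ij[1L]], res_j = topo$resno[ij[2L]], occurrence = occ)
    }
  }
  for (k in ls(vd_tab)) {
    occ <- vd_tab[[k]] / n
    if (occ >= criteria$occurrence_min - 1e-12) {
      ij <- as.integer(strsplit(k, "_")[[1L]])
      rows[[length(rows) + 1L]] <- data.frame(
        kind = "vdw", id_i = ij[1L], id_j = ij[2L],
        res_i = ij[1L], res_j = ij[2L], occurrence = occ)
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(kind = character(0), id_i = integer(0), id_j = integer(0),
                      res_i = integer(0), res_j = integer(0), occurrence = numeric(0)))
  }
  out <- do.call(rbind, rows)
  out[order(out$kind, out$id_i, out$id_j), , drop = FALSE]
}
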
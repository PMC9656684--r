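## one- to three-letter amino acid codes used by the chain builder
.aa3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", E = "GLU",
          Q = "GLN", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
          M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
          Y = "TYR", V = "VAL")

# standard backbone covalent geometry (Angstrom / degrees)
.bb_geom <- list(
  b_n_ca = 1.458, b_ca_c = 1.525, b_c_n = 1.329, b_c_o = 1.231, b_n_h = 1.01,
  b_ca_cb = 1.530, b_cb_cg = 1.520, b_cg_oh = 1.430,
  a_n_ca_c = 111.2, a_ca_c_n = 116.2, a_c_n_ca = 121.7, a_ca_c_o = 120.5,
  a_c_ca_cb = 110.1, a_ca_cb_cg = 114.0, a_cb_cg_oh = 109.5,
  omega = 180
)

#' Specification of one conformational basin
#'
#' A basin is a wrapped-Gaussian mixture component in backbone dihedral
#' space: per-residue mean (phi, psi) and an angular spread sigma.  Scalar
#' means are recycled over all residues.
#'
#' @param name basin label.
#' @param weight mixture weight (fraction of frames).
#' @param phi,psi mean dihedrals in degrees (scalar or per-residue).
#' @param sigma angular standard deviation in degrees (> 0).
#' @return An object of class `"BasinSpec"`.
#' @export
basin_spec <- function(name, weight, phi, psi, sigma) {
  stopifnot(weight >= 0, sigma > 0, length(phi) == length(psi))
  structure(list(name = name, weight = weight, phi = phi, psi = psi,
                 sigma = sigma), class = "BasinSpec")
}

#' Specification of a synthetic labelled ensemble
#'
#' @param sequence one-letter amino-acid string (length >= 12).
#' @param basins list of `BasinSpec`; weights must sum to 1.
#' @param n_frames number of frames to draw.
#' @param seed integer seed (Mersenne-Twister, recorded in the output).
#' @param roles the `ResidueRoles` the ensemble is meant to exercise.
#' @param first_resno residue number of the first residue.
#' @return An object of class `"SyntheticEnsembleSpec"`.
#' @export
synthetic_ensemble_spec <- function(sequence, basins, n_frames, seed,
                                    roles = residue_roles(),
                                    first_resno = 689L) {
  aa <- strsplit(sequence, "")[[1L]]
  if (length(aa) < 12L) stop("sequence must have at least 12 residues")
  if (!all(aa %in% names(.aa3))) stop("unknown one-letter amino acid code(s)")
  w <- vapply(basins, `[[`, numeric(1), "weight")
  if (abs(sum(w) - 1) > 1e-12) stop("basin weights must sum to 1 (got ", sum(w), ")")
  resno <- first_resno + seq_along(aa) - 1L
  ty_pos <- roles$tyrosines - first_resno + 1L
  if (any(ty_pos < 1L | ty_pos > length(aa)) || any(aa[ty_pos] != "Y")) {
    stop("role tyrosine positions must carry Tyr in the sequence")
  }
  structure(list(sequence = aa, basins = basins, n_frames = as.integer(n_frames),
                 seed = as.integer(seed), roles = roles,
                 first_resno = as.integer(first_resno), resno = resno,
                 rng_kind = "Mersenne-Twister"),
            class = "SyntheticEnsembleSpec")
}

## topology of the reduced-representation peptide: per residue N, H (except
## Pro), CA, C, O; CB + CG for non-Gly; an OH ring proxy for Tyr; OXT on the
## last residue.
chain_topology <- function(sequence, first_resno = 689L) {
  elety <- character(0); resid <- character(0); resno <- integer(0)
  n <- length(sequence)
  for (i in seq_len(n)) {
    aa <- sequence[i]
    r3 <- .aa3[[aa]]
    at <- c("N", if (aa != "P") "H", "CA", "C", "O",
            if (aa != "G") c("CB", "CG"),
            if (aa == "Y") "OH",
            if (i == n) "OXT")
    elety <- c(elety, at)
    resid <- c(resid, rep(r3, length(at)))
    resno <- c(resno, rep(first_resno + i - 1L, length(at)))
  }
  topology(elety, resid, resno)
}

#' Build a peptide conformation from backbone dihedrals
#'
#' Deterministic internal-coordinate (NeRF) chain extension with standard
#' bond lengths and angles (N-CA 1.458, CA-C 1.525, C-N 1.329 Angstrom,
#' omega fixed at 180 degrees).  Each residue carries N, amide H (absent
#' for proline), CA, C, O; non-glycine residues get a two-carbon side-chain
#' proxy (CB, CG) and tyrosine additionally a terminal hydroxyl-like oxygen;
#' the last residue carries OXT.
#'
#' @param sequence character vector of one-letter codes (or a single
#'   string).
#' @param dihedrals n x 2 matrix of (phi, psi) in degrees; `phi[1]` and
#'   `psi[n]` orient the terminal atoms.
#' @param first_resno residue number of the first residue.
#' @return A `"Frame"` over the generated topology.
#' @export
build_chain <- function(sequence, dihedrals, first_resno = 689L) {
  if (length(sequence) == 1L && nchar(sequence[1L]) > 1L) {
    sequence <- strsplit(sequence, "")[[1L]]
  }
  dihedrals <- matrix(dihedrals, ncol = 2L)
  n <- length(sequence)
  if (nrow(dihedrals) != n) {
    stop("dihedral rows (", nrow(dihedrals), ") must equal sequence length (", n, ")")
  }
  g <- .bb_geom
  topo <- chain_topology(sequence, first_resno)
  xyz <- matrix(NA_real_, nrow(topo), 3L)
  N <- CA <- C <- O <- matrix(NA_real_, n, 3L)
  # seed the first three backbone atoms
  N[1L, ] <- c(0, 0, 0)
  CA[1L, ] <- c(g$b_n_ca, 0, 0)
  a <- deg2rad(g$a_n_ca_c)
  C[1L, ] <- CA[1L, ] + g$b_ca_c * c(-cos(a), sin(a), 0)
  for (i in seq_len(n)) {
    phi <- dihedrals[i, 1L]
    psi <- dihedrals[i, 2L]
    if (i > 1L) {
      # N(i) from CA(i-1), C(i-1) and psi(i-1); CA(i) from omega; C(i) from phi(i)
      N[i, ] <- place_atom(N[i - 1L, ], CA[i - 1L, ], C[i - 1L, ],
                           g$b_c_n, g$a_ca_c_n, dihedrals[i - 1L, 2L])
      CA[i, ] <- place_atom(CA[i - 1L, ], C[i - 1L, ], N[i, ],
                            g$b_n_ca, g$a_c_n_ca, g$omega)
      C[i, ] <- place_atom(C[i - 1L, ], N[i, ], CA[i, ],
                           g$b_ca_c, g$a_n_ca_c, phi)
    }
    # carbonyl O: in the peptide plane, anti to the next N
    O[i, ] <- place_atom(N[i, ], CA[i, ], C[i, ], g$b_c_o, g$a_ca_c_o, psi + 180)
  }
  for (i in seq_len(n)) {
    res_rows <- which(topo$resno == first_resno + i - 1L)
    for (r in res_rows) {
      xyz[r, ] <- switch(topo$elety[r],
        N = N[i, ], CA = CA[i, ], C = C[i, ], O = O[i, ],
        H = if (i == 1L) {
          reconstruct_amide_h(N[i, ], CA[i, ], NULL, NULL)
        } else {
          reconstruct_amide_h(N[i, ], CA[i, ], O[i - 1L, ], C[i - 1L, ])
        },
        CB = place_atom(N[i, ], C[i, ], CA[i, ], g$b_ca_cb, g$a_c_ca_cb, -122.6),
        CG = place_atom(N[i, ], CA[i, ], xyz[res_rows[topo$elety[res_rows] == "CB"][1L], ],
                        g$b_cb_cg, g$a_ca_cb_cg, -65),
        OH = place_atom(CA[i, ], xyz[res_rows[topo$elety[res_rows] == "CB"][1L], ],
                        xyz[res_rows[topo$elety[res_rows] == "CG"][1L], ],
                        g$b_cg_oh, g$a_cb_cg_oh, 180),
        OXT = place_atom(N[i, ], CA[i, ], C[i, ], g$b_c_o, g$a_ca_c_o,
                         dihedrals[i, 2L]),
        stop("unhandled atom ", topo$elety[r]))
    }
  }
  as_frame(xyz, topo)
}

## heavy-atom steric clash: any non-bonded heavy pair closer than min_dist.
## Bonded pairs are taken as all pairs within one residue plus the peptide
## C(i)-N(i+1) link.
has_clash <- function(frame, min_dist = 1.5) {
  topo <- frame$topology
  heavy <- which(topo$element != "H")
  x <- frame$xyz[heavy, , drop = FALSE]
  D <- cross_dist(x, x)
  res <- topo$resno[heavy]
  ety <- topo$elety[heavy]
  close <- D < min_dist & upper.tri(D)
  if (!any(close)) return(FALSE)
  idx <- which(close, arr.ind = TRUE)
  for (r in seq_len(nrow(idx))) {
    i <- idx[r, 1L]; j <- idx[r, 2L]
    same_res <- res[i] == res[j]
    peptide <- abs(res[i] - res[j]) == 1L &&
      ((ety[i] == "C" && ety[j] == "N") || (ety[i] == "N" && ety[j] == "C"))
    if (!same_res && !peptide) return(TRUE)
  }
  FALSE
}

#' Sample a labelled multi-basin synthetic ensemble
#'
#' For each frame a basin is drawn by weight, its per-residue mean
#' dihedrals are perturbed with wrapped-Gaussian noise of the basin's
#' sigma, and the chain is rebuilt from internal coordinates.  Frames with
#' a heavy-atom steric clash (non-bonded pair closer than 1.5 Angstrom) are
#' resampled, up to `max_retries` per frame.
#'
#' @param spec a `SyntheticEnsembleSpec`.
#' @param frame_spacing_ps time spacing attached to the trajectory (ps).
#' @param entity entity label for the trajectory.
#' @param max_retries clash-resampling cap per frame.
#' @return A `"LabeledEnsemble"`: list with `trajectory` and `true_labels`
#'   (per-frame basin names).
#' @export
sample_ensemble <- function(spec, frame_spacing_ps = 100, entity = "synthetic",
                            max_retries = 25L) {
  stopifnot(inherits(spec, "SyntheticEnsembleSpec"))
  n_res <- length(spec$sequence)
  nf <- spec$n_frames
  w <- vapply(spec$basins, `[[`, numeric(1), "weight")
  old_kind <- RNGkind(spec$rng_kind)[1L]
  on.exit(RNGkind(old_kind), add = TRUE)
  set.seed(spec$seed)
  basin_idx <- sample.int(length(spec$basins), nf, replace = TRUE, prob = w)
  topo <- chain_topology(spec$sequence, spec$first_resno)
  coords <- array(NA_real_, c(nf, nrow(topo), 3L))
  labels <- character(nf)
  for (f in seq_len(nf)) {
    b <- spec$basins[[basin_idx[f]]]
    mphi <- rep_len(b$phi, n_res)
    mpsi <- rep_len(b$psi, n_res)
    ok <- FALSE
    for (try in seq_len(max_retries)) {
      dih <- cbind(wrap_angle(mphi + stats::rnorm(n_res, 0, b$sigma)),
                   wrap_angle(mpsi + stats::rnorm(n_res, 0, b$sigma)))
      fr <- build_chain(spec$sequence, dih, spec$first_resno)
      if (!has_clash(fr)) { ok <- TRUE; break }
    }
    if (!ok) stop("frame ", f, ": steric clash persisted after ", max_retries,
                  " resampling attempts")
    coords[f, , ] <- fr$xyz
    labels[f] <- b$name
  }
  traj <- trajectory(topo, coords, entity = entity,
                     frame_spacing_ps = frame_spacing_ps)
  structure(list(trajectory = traj, true_labels = labels, spec = spec),
            class = "LabeledEnsemble")
}

#' Default three-basin ensemble specification
#'
#' An 84-residue proxy of the KIT kinase-insert domain: the 80-residue
#' F689-D768 span with tyrosines at 703/721/730/747 and the role residues
#' of the default catalog, followed by the Gly-Gly-Gly-Gly spacer.  Three
#' dihedral basins emulate the transiently helical, extended and
#' polyproline-like sub-ensembles of a disordered peptide: "helix"
#' (phi = -64, psi = -41, sigma = 8) with weight 0.5, "extended"
#' (-120, 130, sigma = 10) with weight 0.3, and "pp_like" (-75, 150,
#' sigma = 10) with weight 0.2.
#'
#' @param n_frames frames to draw (default 600).
#' @param seed integer seed (default 42).
#' @return A `SyntheticEnsembleSpec`.
#' @export
default_three_basin_spec <- function(n_frames = 600L, seed = 42L) {
  roles <- residue_roles()
  n <- 80L
  aa <- rep("A", n)
  put <- function(aa, resno, code) { aa[resno - 689L + 1L] <- code; aa }
  aa <- put(aa, 689L, "F"); aa <- put(aa, 699L, "E")
  for (r in roles$tyrosines) aa <- put(aa, r, "Y")
  aa <- put(aa, 717L, "S"); aa <- put(aa, 725L, "K"); aa <- put(aa, 739L, "R")
  aa <- put(aa, 732L, "V"); aa <- put(aa, 754L, "P")
  aa <- put(aa, 705L, "N"); aa <- put(aa, 768L, "D")
  sequence <- paste0(c(aa, rep("G", 4L)), collapse = "")
  basins <- list(
    basin_spec("helix", 0.5, -64, -41, 8),
    basin_spec("extended", 0.3, -120, 130, 10),
    basin_spec("pp_like", 0.2, -75, 150, 10)
  )
  synthetic_ensemble_spec(sequence, basins, n_frames, seed, roles = roles,
                          first_resno = 689L)
}
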
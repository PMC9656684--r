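# atomic masses (amu) for the elements that occur in peptide models
.element_masses <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06)

# Bondi van der Waals radii (Angstrom), used by the SASA quadrature
.bondi_radii <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80)

.backbone_names <- c("N", "CA", "C", "O", "OXT", "H", "H1", "H2", "H3", "HA")

#' Build a topology table
#'
#' A topology describes the atoms shared by every frame of a trajectory:
#' names, elements, residue identity, masses and backbone/side-chain flags.
#'
#' @param elety atom names (PDB atom-name column, e.g. `"CA"`).
#' @param resid three-letter residue names.
#' @param resno integer residue numbers (author numbering, non-decreasing
#'   within a chain).
#' @param chain chain identifiers (recycled).
#' @param element element symbols; inferred from `elety` where `NA`.
#' @return A `data.frame` with columns `eleno`, `elety`, `element`, `resid`,
#'   `resno`, `chain`, `mass`, `is_backbone`, `is_sidechain`.
#' @export
topology <- function(elety, resid, resno, chain = "A", element = NA_character_) {
  n <- length(elety)
  stopifnot(length(resid) == n, length(resno) == n)
  chain <- rep_len(chain, n)
  element <- rep_len(element, n)
  miss <- is.na(element) | element == ""
  element[miss] <- infer_element(elety[miss])
  bad <- !(element %in% names(.element_masses))
  if (any(bad)) {
    stop("unknown element(s): ", paste(unique(element[bad]), collapse = ", "))
  }
  for (ch in unique(chain)) {
    r <- resno[chain == ch]
    if (is.unsorted(r)) stop("residue numbers must be non-decreasing within chain ", ch)
  }
  is_bb <- elety %in% .backbone_names
  data.frame(
    eleno = seq_len(n), elety = elety, element = element,
    resid = resid, resno = as.integer(resno), chain = chain,
    mass = unname(.element_masses[element]),
    is_backbone = is_bb, is_sidechain = !is_bb,
    stringsAsFactors = FALSE
  )
}

## Infer the element from a PDB atom name: strip digits/primes, take the
## leading letter(s).  Two-letter elements are not expected in peptides, so
## the first alphabetic character decides (handles "1HB", "HG1", "CA", "OXT").
infer_element <- function(elety) {
  vapply(elety, function(a) {
    a <- gsub("[^A-Za-z]", "", a)
    if (nchar(a) == 0L) stop("cannot infer element from atom name '", a, "'")
    substr(a, 1L, 1L)
  }, character(1), USE.NAMES = FALSE)
}

#' Construct a trajectory
#'
#' A trajectory is an ordered set of frames (conformations) over one shared
#' topology, with an entity label and a time stamp per frame.
#'
#' @param topology a topology `data.frame` (see [topology()]).
#' @param coords numeric array `n_frames x n_atoms x 3` (Angstrom).
#' @param entity entity label(s); a scalar is recycled to all frames.
#' @param times frame times in ps; defaults to `0, spacing, 2*spacing, ...`.
#' @param frame_spacing_ps spacing between consecutive frames (ps).
#' @return An object of class `"Trajectory"`.
#' @export
trajectory <- function(topology, coords, entity = "ensemble", times = NULL,
                       frame_spacing_ps = 1) {
  if (length(dim(coords)) != 3L || dim(coords)[3L] != 3L) {
    stop("coords must be an n_frames x n_atoms x 3 array")
  }
  nf <- dim(coords)[1L]
  if (dim(coords)[2L] != nrow(topology)) {
    stop("coordinate count per frame (", dim(coords)[2L],
         ") does not match topology atom count (", nrow(topology), ")")
  }
  if (!all(is.finite(coords))) stop("all coordinates must be finite")
  if (is.null(times)) times <- (seq_len(nf) - 1) * frame_spacing_ps
  if (length(times) != nf) stop("times length must equal frame count")
  if (nf > 1L && any(diff(times) <= 0)) stop("frame times must be strictly increasing")
  structure(
    list(topology = topology, coords = coords,
         entity = rep_len(entity, nf), times = as.numeric(times),
         frame_spacing_ps = frame_spacing_ps),
    class = "Trajectory"
  )
}

#' @export
print.Trajectory <- function(x, ...) {
  cat("Trajectory:", n_frames(x), "frames x", nrow(x$topology), "atoms\n")
  cat("  entities:", paste(unique(x$entity), collapse = ", "), "\n")
  cat("  time span:", x$times[1L], "-", x$times[n_frames(x)], "ps\n")
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj a `Trajectory`.
#' @export
n_frames <- function(traj) dim(traj$coords)[1L]

#' Extract one frame
#'
#' @param traj a `Trajectory`.
#' @param i frame index.
#' @return A `"Frame"`: list with `xyz` (atoms x 3 matrix), `topology`,
#'   `time` (ps) and `model` (the frame index).
#' @export
get_frame <- function(traj, i) {
  stopifnot(i >= 1L, i <= n_frames(traj))
  structure(
    list(xyz = matrix(traj$coords[i, , ], ncol = 3L,
                      dimnames = list(NULL, c("x", "y", "z"))),
         topology = traj$topology, time = traj$times[i], model = i),
    class = "Frame"
  )
}

as_frame <- function(xyz, topology, time = 0, model = 1L) {
  structure(list(xyz = xyz, topology = topology, time = time, model = model),
            class = "Frame")
}

#' Read a multi-model PDB file as a trajectory
#'
#' Each `MODEL`/`ENDMDL` block becomes one frame; a file without `MODEL`
#' records is read as a single-frame trajectory.  Elements missing from the
#' element column are inferred from the atom name.  Only alternate location
#' `'A'` or blank is kept.
#'
#' @param path path to a PDB file.
#' @param entity entity label stored on every frame (e.g. `"KID_C"`).
#' @param frame_spacing_ps time spacing between models (ps).
#' @return A `Trajectory`.
#' @export
read_multimodel_pdb <- function(path, entity = "ensemble", frame_spacing_ps = 1) {
  if (!file.exists(path)) stop("file not found: ", path)
  check_pdb_atom_lines(path)
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  keep <- pdb$atom$type == "ATOM" & (is.na(pdb$atom$alt) | pdb$atom$alt %in% c("", "A"))
  atom <- pdb$atom[keep, , drop = FALSE]
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
  idx <- as.vector(t(outer(which(keep), 0:2, function(i, j) 3 * (i - 1) + 1 + j)))
  xyz <- xyz[, idx, drop = FALSE]
  topo <- topology(
    elety = atom$elety, resid = atom$resid, resno = atom$resno,
    chain = ifelse(is.na(atom$chain) | atom$chain == "", "A", atom$chain),
    element = ifelse(is.na(atom$elesy) | atom$elesy == "", NA_character_, atom$elesy)
  )
  nf <- nrow(xyz)
  na <- nrow(topo)
  coords <- array(NA_real_, c(nf, na, 3L))
  for (f in seq_len(nf)) {
    coords[f, , ] <- matrix(xyz[f, ], ncol = 3L, byrow = TRUE)
  }
  trajectory(topo, coords, entity = entity, frame_spacing_ps = frame_spacing_ps)
}

## Validate ATOM record fixed-width fields and per-model atom counts before
## handing the file to the parser, so errors can name the offending line.
check_pdb_atom_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  atom_idx <- grep("^ATOM  |^HETATM", lines)
  for (i in atom_idx) {
    ln <- lines[i]
    if (nchar(ln) < 54L) stop("malformed ATOM line ", i, ": shorter than coordinate fields")
    xyz <- suppressWarnings(as.numeric(c(substr(ln, 31, 38), substr(ln, 39, 46),
                                         substr(ln, 47, 54))))
    if (any(is.na(xyz))) stop("malformed ATOM line ", i, ": non-numeric coordinates")
  }
  model_starts <- grep("^MODEL", lines)
  if (length(model_starts) > 1L) {
    ends <- grep("^ENDMDL", lines)
    if (length(ends) >= length(model_starts)) {
      counts <- mapply(function(s, e) sum(atom_idx > s & atom_idx < e),
                       model_starts, ends[seq_along(model_starts)])
      if (length(unique(counts)) > 1L) {
        stop("topology mismatch: models contain differing atom counts (",
             paste(unique(counts), collapse = ", "), ")")
      }
    }
  }
  invisible(TRUE)
}

#' Write a trajectory as a multi-model PDB file
#'
#' @param traj a non-empty `Trajectory`.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_multimodel_pdb <- function(traj, path) {
  if (n_frames(traj) < 1L) stop("cannot write an empty trajectory")
  if (max(abs(traj$coords)) >= 10000) {
    stop("coordinate magnitude exceeds the PDB field width (|x| < 10000)")
  }
  topo <- traj$topology
  nf <- n_frames(traj)
  xyz <- matrix(NA_real_, nf, 3L * nrow(topo))
  for (f in seq_len(nf)) {
    xyz[f, ] <- as.vector(t(matrix(traj$coords[f, , ], ncol = 3L)))
  }
  bio3d::write.pdb(file = path, xyz = xyz, resno = topo$resno, resid = topo$resid,
                   eleno = topo$eleno, elety = topo$elety, chain = topo$chain)
  invisible(path)
}

#' Concatenate trajectories into one dataset
#'
#' Frames are appended in input order; every frame keeps its own entity
#' label, so a concatenated multi-entity dataset can still be decomposed.
#' Times are re-laid end to end so that the total duration is the sum of the
#' input durations (each input contributes `n_frames * spacing`).
#'
#' @param trajs list of `Trajectory` objects sharing the residue numbering of
#'   the common analysis span.
#' @return A single `Trajectory`.
#' @export
concatenate <- function(trajs) {
  stopifnot(length(trajs) >= 1L)
  if (length(trajs) == 1L) return(trajs[[1L]])
  ref <- trajs[[1L]]$topology
  for (tr in trajs[-1L]) {
    a <- tr$topology
    if (nrow(a) != nrow(ref) ||
        !all(a$elety == ref$elety & a$resno == ref$resno & a$resid == ref$resid)) {
      mism <- unique(c(setdiff(unique(a$resno), unique(ref$resno)),
                       setdiff(unique(ref$resno), unique(a$resno))))
      stop("incompatible topologies; mismatched residues: ",
           paste(utils::head(mism, 10L), collapse = ", "))
    }
  }
  coords <- do.call(function(...) {
    arrs <- list(...)
    tot <- sum(vapply(arrs, function(a) dim(a)[1L], integer(1)))
    out <- array(NA_real_, c(tot, dim(arrs[[1L]])[2L], 3L))
    at <- 0L
    for (a in arrs) {
      out[at + seq_len(dim(a)[1L]), , ] <- a
      at <- at + dim(a)[1L]
    }
    out
  }, lapply(trajs, `[[`, "coords"))
  spacing <- trajs[[1L]]$frame_spacing_ps
  entity <- unlist(lapply(trajs, `[[`, "entity"))
  nf <- dim(coords)[1L]
  trajectory(ref, coords, entity = entity,
             times = (seq_len(nf) - 1) * spacing, frame_spacing_ps = spacing)
}

#' Duration of a trajectory in ps
#'
#' Each frame represents one sampling interval, so the duration is
#' `n_frames * frame_spacing_ps`.
#' @param traj a `Trajectory`.
#' @export
duration_ps <- function(traj) n_frames(traj) * traj$frame_spacing_ps

#' Superpose a frame onto a reference
#'
#' Least-squares rigid-body fit (Kabsch SVD with proper-rotation
#' correction) of `frame` onto `reference` over the selected atoms.
#'
#' @param frame,reference `"Frame"` objects over the same topology.
#' @param selection integer atom indices used for the fit (at least 3,
#'   non-collinear).
#' @return List with `rotation` (3x3), `translation` (length 3), `rmsd`
#'   (Angstrom over the selection after the fit) and `aligned` (the whole
#'   frame after applying the transform).
#' @export
superpose <- function(frame, reference, selection) {
  stopifnot(length(selection) >= 3L)
  fit <- kabsch_fit(frame$xyz[selection, , drop = FALSE],
                    reference$xyz[selection, , drop = FALSE])
  aligned <- frame
  aligned$xyz <- apply_transform(frame$xyz, fit$rotation, fit$translation)
  list(rotation = fit$rotation, translation = fit$translation,
       rmsd = fit$rmsd, aligned = aligned)
}

#' Subsample a trajectory at a coarser time stride
#'
#' Keeps the frames whose time is a multiple of `stride_ps`; the first frame
#' (t = 0) is always included.
#'
#' @param traj a `Trajectory`.
#' @param stride_ps stride in ps; must be a positive multiple of the frame
#'   spacing.
#' @return A `Trajectory` with the retained frames.
#' @export
subsample <- function(traj, stride_ps) {
  sp <- traj$frame_spacing_ps
  if (stride_ps <= 0 || abs(stride_ps / sp - round(stride_ps / sp)) > 1e-9) {
    stop("stride (", stride_ps, " ps) must be a positive multiple of the frame spacing (",
         sp, " ps)")
  }
  keep <- which(abs(traj$times %% stride_ps) < 1e-9 |
                abs(traj$times %% stride_ps - stride_ps) < 1e-9)
  trajectory(traj$topology,
             traj$coords[keep, , , drop = FALSE],
             entity = traj$entity[keep], times = traj$times[keep],
             frame_spacing_ps = stride_ps)
}

## atom indices of a named atom for given residue numbers, in the order of
## the residue list; errors if any is missing
atom_index <- function(topology, resno, elety = "CA") {
  idx <- vapply(resno, function(r) {
    i <- which(topology$resno == r & topology$elety == elety)
    if (length(i) == 0L) {
      stop("residue ", r, " has no atom '", elety, "'")
    }
    i[1L]
  }, integer(1))
  idx
}

## Cα atom indices for all residues (in residue order)
ca_indices <- function(topology) which(topology$elety == "CA")
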
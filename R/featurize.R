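#' The 31-entry intrinsic feature catalog
#'
#' Ordered catalog of the intrinsic (reference-free) descriptors computed
#' per frame: (1) radius of gyration; (2) hydrophobic-contact count; (3)
#' hydrogen-bond count; (4-7) SASA of the four tyrosines; (8-15) phi and psi
#' of the four tyrosines; (16-21) the six tyrosine pairwise C-alpha
#' distances; (22) tyrosine tetrahedron volume; (23-25) the three pairwise
#' distances among the maximally fluctuating residues; (26-28) the three
#' pseudo-torsion angles T1-T3; (29) triangle area of the maximally
#' fluctuating residues; (30) distance between the two minimally
#' fluctuating residues; (31) pseudo-torsion of the minimally fluctuating
#' pair over the anchor pair.
#'
#' @param roles a `ResidueRoles`.
#' @return `data.frame` with columns `index`, `name`, `group`.
#' @export
feature_catalog <- function(roles = residue_roles()) {
  ty <- roles$tyrosines
  mx <- roles$max_fluct
  mn <- roles$min_fluct
  ty_pairs <- utils::combn(ty, 2L)
  mx_pairs <- utils::combn(mx, 2L)
  nm <- c(
    "rg", "n_vdw_contacts", "n_hbonds",
    paste0("sasa_tyr", ty),
    paste0(rep(c("phi_tyr", "psi_tyr"), 4L), rep(ty, each = 2L)),
    paste0("d_", ty_pairs[1L, ], "_", ty_pairs[2L, ]),
    "tyr_tetrahedron_volume",
    paste0("d_", mx_pairs[1L, ], "_", mx_pairs[2L, ]),
    paste0("T", 1:3),
    "maxfluct_triangle_area",
    paste0("d_", mn[1L], "_", mn[2L]),
    "T_minfluct"
  )
  stopifnot(length(nm) == 31L, !anyDuplicated(nm))
  data.frame(index = 1:31, name = nm,
             group = c("global", "contacts", "contacts", rep("sasa", 4L),
                       rep("dihedral", 8L), rep("distance", 6L), "volume",
                       rep("distance", 3L), rep("pseudo_torsion", 3L), "area",
                       "distance", "pseudo_torsion"),
             stringsAsFactors = FALSE)
}

## the four C-alpha points of pseudo-torsions T1, T2, T3 built from roles:
## T1 = (max2, anchor, tyr1, max1); T2 = (max3, anchor, tyr1, max2);
## T3 = (max3, anchor, tyr1, max1).  With the KID defaults these are
## T1 = K725-E699-Y703-S717, T2 = R739-E699-Y703-K725, T3 = R739-E699-Y703-S717.
pseudo_torsion_defs <- function(roles) {
  a <- roles$anchor
  y <- roles$tyrosines[1L]
  m <- roles$max_fluct
  list(T1 = c(m[2L], a, y, m[1L]),
       T2 = c(m[3L], a, y, m[2L]),
       T3 = c(m[3L], a, y, m[1L]),
       T_minfluct = c(roles$min_fluct[1L], a, y, roles$min_fluct[2L]))
}

#' Extract the 31-feature table from a trajectory
#'
#' One row per frame: the full intrinsic descriptor catalog (see
#' [feature_catalog()]) plus the metadata columns `frame`, `time_ps`,
#' `entity`.  Angular features are degrees in (-180, 180].
#'
#' @param traj a `Trajectory` (typically already subsampled to the analysis
#'   stride).
#' @param roles a `ResidueRoles` resolving in the topology.
#' @param criteria a `ContactCriteria` for the contact-count features.
#' @return A `data.frame` of class `"FeatureTable"` with attribute
#'   `state = "raw"` and attribute `features` naming the 31 feature columns.
#' @export
extract_features <- function(traj, roles = residue_roles(),
                             criteria = contact_criteria()) {
  check_roles(roles, traj$topology)
  cat31 <- feature_catalog(roles)
  tdefs <- pseudo_torsion_defs(roles)
  ty <- roles$tyrosines
  mx <- roles$max_fluct
  mn <- roles$min_fluct
  ty_atoms <- which(traj$topology$resno %in% ty & traj$topology$element != "H")
  nf <- n_frames(traj)
  M <- matrix(NA_real_, nf, 31L, dimnames = list(NULL, cat31$name))
  for (i in seq_len(nf)) {
    fr <- get_frame(traj, i)
    row <- numeric(0)
    row[1L] <- radius_of_gyration(fr)
    row[2L] <- nrow(find_vdw_contacts(fr, criteria))
    row[3L] <- nrow(find_hbonds(fr, criteria))
    s <- sasa(fr, atoms = ty_atoms)
    row[4:7] <- s$per_residue[as.character(ty)]
    for (j in 1:4) {
      di <- backbone_dihedrals(fr, ty[j])
      if (is.na(di$phi) || is.na(di$psi)) {
        stop("tyrosine ", ty[j], " is chain-terminal: phi/psi undefined")
      }
      row[8L + 2L * (j - 1L)] <- di$phi
      row[9L + 2L * (j - 1L)] <- di$psi
    }
    row[16:21] <- pairwise_ca_distances(fr, ty)$distance
    row[22L] <- tetrahedron_volume(fr, ty)
    row[23:25] <- pairwise_ca_distances(fr, mx)$distance
    row[26L] <- pseudo_torsion(fr, tdefs$T1)
    row[27L] <- pseudo_torsion(fr, tdefs$T2)
    row[28L] <- pseudo_torsion(fr, tdefs$T3)
    row[29L] <- triangle_area(fr, mx)
    row[30L] <- pdist(fr$xyz[atom_index(fr$topology, mn[1L], "CA"), ],
                      fr$xyz[atom_index(fr$topology, mn[2L], "CA"), ])
    row[31L] <- pseudo_torsion(fr, tdefs$T_minfluct)
    M[i, ] <- row
  }
  out <- data.frame(frame = seq_len(nf), time_ps = traj$times,
                    entity = traj$entity, M, check.names = FALSE)
  attr(out, "features") <- cat31$name
  attr(out, "state") <- "raw"
  class(out) <- c("FeatureTable", "data.frame")
  out
}

feature_cols <- function(table) attr(table, "features")

#' Per-entity min-max scaling of a feature table
#'
#' Each feature column is scaled to `[0, 1]` independently for every entity:
#' `x' = (x - min) / (max - min)` over that entity's frames.  A feature that
#' is constant within an entity is mapped to 0 with a warning.
#'
#' @param table a raw `FeatureTable`.
#' @return The scaled `FeatureTable` (state `"scaled"`).
#' @export
minmax_scale <- function(table) {
  feats <- feature_cols(table)
  out <- table
  for (ent in unique(table$entity)) {
    rows <- which(table$entity == ent)
    for (f in feats) {
      x <- table[[f]][rows]
      rng <- range(x)
      if (diff(rng) < .Machine$double.eps) {
        warning("feature '", f, "' constant within entity '", ent, "'; scaled to 0")
        out[[f]][rows] <- 0
      } else {
        out[[f]][rows] <- (x - rng[1L]) / diff(rng)
      }
    }
  }
  attr(out, "state") <- "scaled"
  out
}

#' Pearson correlation matrix of the feature columns
#'
#' Computed over all rows with entities pooled; a zero-variance column gets
#' correlation 0 (with a warning) off the diagonal.
#'
#' @param table a (scaled) `FeatureTable`.
#' @return Symmetric matrix with unit diagonal, named by feature.
#' @export
correlation_matrix <- function(table) {
  feats <- feature_cols(table)
  X <- as.matrix(as.data.frame(table)[, feats, drop = FALSE])
  sds <- apply(X, 2L, stats::sd)
  cm <- suppressWarnings(stats::cor(X))
  if (any(sds == 0)) {
    warning("zero-variance feature(s): ", paste(feats[sds == 0], collapse = ", "),
            "; correlations set to 0")
    cm[sds == 0, ] <- 0
    cm[, sds == 0] <- 0
  }
  diag(cm) <- 1
  cm
}

#' Remove one feature from each highly correlated pair
#'
#' Scans feature pairs in catalog order; whenever `|r| >= threshold` the
#' higher-index feature of the pair is removed (unless it already was).
#'
#' @param table a scaled `FeatureTable`.
#' @param threshold absolute Pearson correlation at or above which a pair is
#'   pruned (default 0.8, inclusive).
#' @return List with `table` (state `"pruned"`) and `removed` (character
#'   vector of dropped feature names).
#' @export
prune_correlated <- function(table, threshold = 0.8) {
  feats <- feature_cols(table)
  cm <- correlation_matrix(table)
  removed <- character(0)
  p <- length(feats)
  for (i in seq_len(p - 1L)) {
    if (feats[i] %in% removed) next
    for (j in (i + 1L):p) {
      if (feats[j] %in% removed) next
      if (abs(cm[i, j]) >= threshold - 1e-12) {
        removed <- c(removed, feats[j])
      }
    }
  }
  keep <- setdiff(feats, removed)
  out <- table[, c("frame", "time_ps", "entity", keep), drop = FALSE]
  attr(out, "features") <- keep
  attr(out, "state") <- "pruned"
  class(out) <- c("FeatureTable", "data.frame")
  list(table = out, removed = removed)
}

#' PCA reduction to a cumulative-variance target
#'
#' Centres the (scaled, pruned) feature columns, eigen-decomposes their
#' covariance and keeps the smallest number of leading components whose
#' cumulative explained variance reaches the target.
#'
#' @param table a pruned `FeatureTable` (any state is accepted; columns are
#'   centred, not re-standardised).
#' @param variance_target cumulative explained-variance fraction (default
#'   0.80).
#' @return List with `scores` (frames x k matrix), `explained` (fractions
#'   for all components), `k`, and `loadings`.
#' @export
pca_reduce <- function(table, variance_target = 0.80) {
  feats <- feature_cols(table)
  X <- as.matrix(as.data.frame(table)[, feats, drop = FALSE])
  if (nrow(X) < 2L) stop("PCA needs at least 2 rows")
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  expl <- pc$sdev^2 / sum(pc$sdev^2)
  k <- which(cumsum(expl) >= variance_target - 1e-12)[1L]
  list(scores = pc$x[, seq_len(k), drop = FALSE], explained = expl, k = k,
       loadings = pc$rotation[, seq_len(k), drop = FALSE])
}
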
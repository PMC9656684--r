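#' Boltzmann constant in kcal/mol/K
#' @export
KB_KCAL <- 1.98720425e-3

#' Relative density by the k-nearest-neighbour scheme
#'
#' For each evaluation point, the density estimate is
#' `k / (n * pi * d_k^2)` with `d_k` the distance to the k-th nearest of
#' the `n` data points.  Returned up to a common constant, which is all
#' that the `P / P_max` ratio of the free-energy landscape needs.
#'
#' @param points n x 2 matrix of data points.
#' @param k neighbour count, `1 <= k < n`.
#' @param query optional m x 2 matrix of evaluation points; default the data
#'   points themselves (each point's own zero distance is excluded there).
#' @return Numeric vector of relative densities at the query points.
#' @export
knn_density <- function(points, k, query = NULL) {
  points <- as.matrix(points)
  n <- nrow(points)
  stopifnot(k >= 1L, n > k)
  self <- is.null(query)
  if (self) query <- points
  query <- as.matrix(query)
  dk <- numeric(nrow(query))
  chunk <- max(1L, floor(2e6 / n))
  for (start in seq(1L, nrow(query), by = chunk)) {
    idx <- start:min(start + chunk - 1L, nrow(query))
    D <- cross_dist(query[idx, , drop = FALSE], points)
    kk <- if (self) k + 1L else k   # a data point is its own 0-distance neighbour
    dk[idx] <- apply(D, 1L, function(r) sort.int(r, partial = kk)[kk])
  }
  if (any(dk == 0)) {
    warning("duplicate points: k-th neighbour distance of 0 floored at machine scale")
    dk[dk == 0] <- sqrt(.Machine$double.eps)
  }
  k / (n * pi * dk^2)
}

#' Gibbs free-energy landscape over two reaction coordinates
#'
#' Estimates the probability `P` of states over a 2D grid by the
#' k-nearest-neighbour scheme and converts it to a relative Gibbs energy
#' `dG = -kB * T * log(P / P_max)` with `P_max` the density of the most
#' probable occupied bin, so the sampled mode sits at exactly `dG = 0`.
#' The k-NN density surface is defined everywhere, so every bin centre gets
#' a value; bins holding no frame are flagged in `occupied` (their `dG` is
#' a background estimate, never a stable state).  With `per_frame = TRUE`
#' the density is instead evaluated at every frame and only occupied bins
#' get values (per-bin means, `NA` elsewhere).
#'
#' @param coord1,coord2 equal-length per-frame reaction-coordinate values
#'   (e.g. PC1/PC2 scores, or a pseudo-torsion in degrees and a distance in
#'   Angstrom).
#' @param temperature temperature in K (default 310, the simulation
#'   temperature).
#' @param k neighbour count; default `ceiling(sqrt(n))`.
#' @param grid integer bin counts per axis (default 100 x 100).
#' @param padding fractional padding of the bounding box (default 5%).
#' @param per_frame evaluate the density per frame instead of at bin
#'   centres.
#' @return An object of class `"FELGrid"`: list with `axis1`, `axis2` (bin
#'   centres), `delta_g` (matrix, kcal/mol, `NA` where unoccupied),
#'   `occupied` (logical matrix), `counts`, `kBT`, `temperature`, `knn_k`,
#'   `n`.
#' @export
free_energy_landscape <- function(coord1, coord2, temperature = 310,
                                  k = NULL, grid = c(100L, 100L),
                                  padding = 0.05, per_frame = FALSE) {
  stopifnot(length(coord1) == length(coord2), temperature > 0)
  n <- length(coord1)
  if (is.null(k)) k <- ceiling(sqrt(n))
  if (n <= k) stop("need more frames (", n, ") than neighbours k (", k, ")")
  grid <- rep_len(as.integer(grid), 2L)
  pts <- cbind(coord1, coord2)
  lims <- function(x) {
    r <- range(x)
    pad <- padding * diff(r)
    if (pad == 0) pad <- max(1e-8, abs(r[1L]) * 1e-8)
    c(r[1L] - pad, r[2L] + pad)
  }
  l1 <- lims(coord1); l2 <- lims(coord2)
  br1 <- seq(l1[1L], l1[2L], length.out = grid[1L] + 1L)
  br2 <- seq(l2[1L], l2[2L], length.out = grid[2L] + 1L)
  ax1 <- (br1[-1L] + br1[-length(br1)]) / 2
  ax2 <- (br2[-1L] + br2[-length(br2)]) / 2
  b1 <- pmin(pmax(findInterval(coord1, br1, all.inside = TRUE), 1L), grid[1L])
  b2 <- pmin(pmax(findInterval(coord2, br2, all.inside = TRUE), 1L), grid[2L])
  counts <- matrix(0L, grid[1L], grid[2L])
  for (i in seq_len(n)) counts[b1[i], b2[i]] <- counts[b1[i], b2[i]] + 1L
  occupied <- counts > 0L
  occ_idx <- which(occupied, arr.ind = TRUE)
  if (per_frame) {
    dens <- matrix(NA_real_, grid[1L], grid[2L])
    dframe <- knn_density(pts, k)
    for (r in seq_len(nrow(occ_idx))) {
      sel <- b1 == occ_idx[r, 1L] & b2 == occ_idx[r, 2L]
      dens[occ_idx[r, 1L], occ_idx[r, 2L]] <- mean(dframe[sel])
    }
  } else {
    centres <- as.matrix(expand.grid(ax1, ax2))
    dens <- matrix(knn_density(pts, k, query = centres), grid[1L], grid[2L])
  }
  kBT <- KB_KCAL * temperature
  # Delta-G is anchored at the most probable *occupied* bin, so the sampled
  # mode sits at exactly 0; unoccupied bins carry the background estimate
  # of the (everywhere-defined) k-NN density surface and are flagged, never
  # treated as stable states.
  p_max <- max(dens[occupied], na.rm = TRUE)
  dg <- -kBT * log(dens / p_max)
  # background (unoccupied) bins are never reported more stable than the
  # sampled mode
  dg[!occupied & !is.na(dg) & dg < 0] <- 0
  structure(list(axis1 = ax1, axis2 = ax2, delta_g = dg, occupied = occupied,
                 counts = counts, kBT = kBT, temperature = temperature,
                 knn_k = as.integer(k), n = n),
            class = "FELGrid")
}

#' @export
print.FELGrid <- function(x, ...) {
  cat("FELGrid:", length(x$axis1), "x", length(x$axis2), "bins,",
      sum(x$occupied), "occupied\n")
  cat("  kBT =", signif(x$kBT, 5), "kcal/mol (T =", x$temperature, "K), k =",
      x$knn_k, ", n =", x$n, "\n")
  cat("  dG range:", signif(range(x$delta_g, na.rm = TRUE), 4), "kcal/mol\n")
  invisible(x)
}

#' Detect free-energy wells on a landscape
#'
#' Wells are found by sublevel-set persistence: bins are flooded in order
#' of increasing energy on the 8-connected grid graph, each local minimum
#' starting a basin; when two basins meet, the shallower one merges into
#' the deeper at the connecting saddle, and its well depth is the saddle
#' height above its own minimum (its topographic prominence).  This makes
#' the depth of a well the barrier to the nearest deeper well, insensitive
#' to small-scale roughness of the estimated surface.  The global
#' minimum's depth is the saddle of the deepest basin that merged into it,
#' or the total relief of the surface when no merged basin is itself a
#' well.  Wells shallower than
#' `depth_min` are discarded; every frame is attributed to the surviving
#' well its basin merged into below the cutoff.
#'
#' @param grid a `FELGrid`.
#' @param depth_min minimal well depth (kcal/mol).
#' @return `data.frame` with one row per well: `well`, `i`, `j` (bin
#'   indices of the minimum), `coord1`, `coord2`, `delta_g`, `depth`,
#'   `n_frames` (frames in bins draining to the well).  Zero rows for a
#'   flat landscape.
#' @export
fel_wells <- function(grid, depth_min = 1.0) {
  dg <- grid$delta_g
  ni <- nrow(dg)
  nj <- ncol(dg)
  def <- which(!is.na(dg))
  if (length(def) == 0L) return(empty_wells_table())
  ord <- def[order(dg[def])]
  comp <- integer(ni * nj)            # 0 = not yet flooded
  comp_min_bin <- integer(0)          # component -> bin index of its minimum
  parent <- integer(0)                # merge-tree parent component
  death <- numeric(0)                 # energy at which the component merged
  find_root <- function(cdx) {
    while (parent[cdx] != cdx) cdx <- parent[cdx]
    cdx
  }
  for (lin in ord) {
    i <- (lin - 1L) %% ni + 1L
    j <- (lin - 1L) %/% ni + 1L
    h <- dg[lin]
    ii <- max(1L, i - 1L):min(ni, i + 1L)
    jj <- max(1L, j - 1L):min(nj, j + 1L)
    nb <- as.vector(outer(ii, jj, function(a, b) a + (b - 1L) * ni))
    roots <- unique(vapply(nb[comp[nb] != 0L], function(l) find_root(comp[l]),
                           integer(1)))
    if (length(roots) == 0L) {
      # new local minimum
      cnew <- length(parent) + 1L
      parent[cnew] <- cnew
      comp_min_bin[cnew] <- lin
      death[cnew] <- NA_real_
      comp[lin] <- cnew
    } else if (length(roots) == 1L) {
      comp[lin] <- roots[1L]
    } else {
      # merge: survivor is the component with the lowest minimum
      mins <- dg[comp_min_bin[roots]]
      surv <- roots[which.min(mins)]
      for (rr in roots) {
        if (rr == surv) next
        parent[rr] <- surv
        death[rr] <- h
      }
      comp[lin] <- surv
    }
  }
  n_comp <- length(parent)
  top <- max(dg[def])
  prominence <- death - dg[comp_min_bin]
  # a surviving root is scored by the saddle of the deepest basin that
  # merged into it (the major barrier it is separated by); if no merged
  # basin is itself a well, by the total relief of the surface -- so a
  # featureless landscape whose relief stays under depth_min has no wells
  for (cdx in which(parent == seq_len(n_comp))) {
    kids <- which(parent == cdx)
    kids <- kids[kids != cdx & prominence[kids] >= depth_min - 1e-12]
    prominence[cdx] <- if (length(kids)) max(death[kids]) - dg[comp_min_bin[cdx]]
    else top - dg[comp_min_bin[cdx]]
  }
  is_well <- prominence >= depth_min - 1e-12
  if (!any(is_well)) return(empty_wells_table())
  # map every component to the well it belongs to: climb the merge tree
  # until a well component is reached
  well_of <- integer(n_comp)
  for (cdx in seq_len(n_comp)) {
    cur <- cdx
    while (!is_well[cur] && parent[cur] != cur) cur <- parent[cur]
    well_of[cdx] <- if (is_well[cur]) cur else 0L
  }
  wells <- which(is_well)
  rows <- lapply(wells, function(wc) {
    lin <- comp_min_bin[wc]
    i <- (lin - 1L) %% ni + 1L
    j <- (lin - 1L) %/% ni + 1L
    members <- which(comp != 0L & well_of[pmax(comp, 1L)] == wc & comp != 0L)
    data.frame(i = i, j = j, coord1 = grid$axis1[i], coord2 = grid$axis2[j],
               delta_g = dg[lin], depth = prominence[wc],
               n_frames = sum(grid$counts[members]))
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$delta_g), , drop = FALSE]
  out <- cbind(well = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  out
}

empty_wells_table <- function() {
  data.frame(well = integer(0), i = integer(0), j = integer(0),
             coord1 = numeric(0), coord2 = numeric(0),
             delta_g = numeric(0), depth = numeric(0), n_frames = integer(0))
}

#' Pseudo-torsion / distance reaction-coordinate pairs
#'
#' Returns the two per-frame series of one of the three torsion/distance
#' pairs built on the maximally fluctuating residues: `"T1"` pairs the T1
#' pseudo-torsion with the distance between max-fluctuating residues 1 and
#' 2; `"T2"` pairs T2 with the distance between residues 2 and 3; `"T3"`
#' pairs T3 with the distance between residues 1 and 3.  With the default
#' KID roles: T1/d(S717,K725), T2/d(K725,R739), T3/d(S717,R739).
#'
#' @param table a `FeatureTable` holding the raw catalog columns.
#' @param pair one of `"T1"`, `"T2"`, `"T3"`.
#' @param roles the `ResidueRoles` the table was built with.
#' @return List with `torsion` (degrees) and `distance` (Angstrom), plus
#'   `names` of the two source columns.
#' @export
td_coordinates <- function(table, pair, roles = residue_roles()) {
  mx <- roles$max_fluct
  dist_name <- switch(pair,
    T1 = paste0("d_", mx[1L], "_", mx[2L]),
    T2 = paste0("d_", mx[2L], "_", mx[3L]),
    T3 = paste0("d_", mx[1L], "_", mx[3L]),
    stop("unknown torsion/distance pair id '", pair,
         "' (expected T1, T2 or T3)"))
  for (nm in c(pair, dist_name)) {
    if (!nm %in% names(table)) stop("feature column '", nm, "' absent from table")
  }
  list(torsion = table[[pair]], distance = table[[dist_name]],
       names = c(pair, dist_name))
}
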
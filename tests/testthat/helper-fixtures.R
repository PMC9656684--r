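# Fixtures are generated in code; expensive ones are memoised for the run.
.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

## small labelled ensemble shared across test files
mini_ensemble <- function() {
  memo("mini_ensemble", sample_ensemble(default_three_basin_spec(50L, 7L)))
}

mini_features <- function() {
  memo("mini_features", extract_features(mini_ensemble()$trajectory))
}

## toy topology: n point atoms (CA carbons), residues 1..n
point_topology <- function(n, elety = "CA", element = "C") {
  topology(elety = rep(elety, n), resid = rep("ALA", n), resno = seq_len(n),
           element = rep(element, n))
}

point_frame <- function(xyz, elety = "CA", element = "C") {
  xyz <- matrix(xyz, ncol = 3L)
  idrfel:::as_frame(xyz, point_topology(nrow(xyz), elety, element))
}

random_rigid_motion <- function() {
  a <- stats::rnorm(3)
  theta <- stats::runif(1, 0, pi)
  a <- a / sqrt(sum(a^2))
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  R <- diag(3) + sin(theta) * K + (1 - cos(theta)) * K %*% K
  list(R = R, t = stats::rnorm(3, sd = 10))
}

apply_rigid <- function(xyz, motion) {
  sweep(xyz %*% motion$R, 2L, -motion$t)
}

## Independent superposition oracle: Horn's quaternion method.  Returns the
## minimal RMSD of fitting `moving` onto `fixed`.
quaternion_rmsd <- function(moving, fixed) {
  P <- sweep(moving, 2L, colMeans(moving))
  Q <- sweep(fixed, 2L, colMeans(fixed))
  M <- crossprod(P, Q)
  Sxx <- M[1, 1]; Sxy <- M[1, 2]; Sxz <- M[1, 3]
  Syx <- M[2, 1]; Syy <- M[2, 2]; Syz <- M[2, 3]
  Szx <- M[3, 1]; Szy <- M[3, 2]; Szz <- M[3, 3]
  K <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy,       Szx - Sxz,       Sxy - Syx,
    Syz - Szy,       Sxx - Syy - Szz, Sxy + Syx,       Szx + Sxz,
    Szx - Sxz,       Sxy + Syx,       -Sxx + Syy - Szz, Syz + Szy,
    Sxy - Syx,       Szx + Sxz,       Syz + Szy,       -Sxx - Syy + Szz),
    4, 4, byrow = TRUE)
  lam <- max(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  msd <- (sum(P^2) + sum(Q^2) - 2 * lam) / nrow(P)
  sqrt(max(0, msd))
}

## Cayley-Menger determinant volume of a tetrahedron from its 6 edges
cayley_menger_volume <- function(p) {
  d2 <- as.matrix(stats::dist(p))^2
  B <- rbind(c(0, 1, 1, 1, 1),
             cbind(1, d2))
  v2 <- det(B) / 288
  sqrt(max(0, v2))
}

## Heron triangle area from side lengths
heron_area <- function(p) {
  d <- as.matrix(stats::dist(p))
  a <- d[1, 2]; b <- d[1, 3]; c <- d[2, 3]
  s <- (a + b + c) / 2
  sqrt(max(0, s * (s - a) * (s - b) * (s - c)))
}

## Monte-Carlo SASA oracle for a set of spheres (centres, radii already
## probe-expanded); returns per-sphere accessible area.
mc_sasa <- function(centres, radii, n_points = 1e5, seed = 99L) {
  set.seed(seed)
  vapply(seq_len(nrow(centres)), function(i) {
    u <- matrix(stats::rnorm(3 * n_points), ncol = 3L)
    u <- u / sqrt(rowSums(u^2))
    pts <- u * radii[i] + matrix(centres[i, ], n_points, 3L, byrow = TRUE)
    buried <- rep(FALSE, n_points)
    for (j in seq_len(nrow(centres))) {
      if (j == i) next
      dj <- sqrt(rowSums(sweep(pts, 2L, centres[j, ])^2))
      buried <- buried | dj < radii[j]
    }
    4 * pi * radii[i]^2 * mean(!buried)
  }, numeric(1))
}

## brute-force hydrogen-bond enumeration, independent of the package path
brute_hbonds <- function(frame, criteria = contact_criteria()) {
  topo <- frame$topology
  xyz <- frame$xyz
  das <- which(topo$element %in% criteria$donor_acceptor_elements)
  hyd <- which(topo$element == "H")
  found <- character(0)
  for (d in das) {
    hs <- hyd[vapply(hyd, function(h) sqrt(sum((xyz[h, ] - xyz[d, ])^2)) < 1.3,
                     logical(1))]
    # hydrogen belongs to its closest heavy atom
    hs <- hs[vapply(hs, function(h) {
      dd <- vapply(which(topo$element != "H"), function(a)
        sqrt(sum((xyz[h, ] - xyz[a, ])^2)), numeric(1))
      which(topo$element != "H")[which.min(dd)] == d
    }, logical(1))]
    if (!length(hs)) next
    for (a in das) {
      if (a == d || topo$resno[a] == topo$resno[d]) next
      if (sqrt(sum((xyz[d, ] - xyz[a, ])^2)) > criteria$hbond_da_max + 1e-12) next
      angs <- vapply(hs, function(h) {
        v1 <- xyz[d, ] - xyz[h, ]
        v2 <- xyz[a, ] - xyz[h, ]
        acos(max(-1, min(1, sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))))) * 180 / pi
      }, numeric(1))
      if (max(angs) >= criteria$hbond_angle_min - 1e-9) {
        found <- c(found, paste(d, a, sep = "_"))
      }
    }
  }
  sort(found)
}

## brute-force van der Waals contact enumeration (residue pairs)
brute_vdw <- function(frame, criteria = contact_criteria()) {
  topo <- frame$topology
  xyz <- frame$xyz
  sc <- which(topo$is_sidechain & topo$element == "C")
  found <- character(0)
  for (i in sc) for (j in sc) {
    if (i >= j) next
    if (abs(topo$resno[i] - topo$resno[j]) < criteria$min_residue_separation) next
    if (sqrt(sum((xyz[i, ] - xyz[j, ])^2)) <= criteria$vdw_cc_max + 1e-12) {
      found <- c(found, paste(min(topo$resno[i], topo$resno[j]),
                              max(topo$resno[i], topo$resno[j]), sep = "_"))
    }
  }
  sort(unique(found))
}

## wrap a plain matrix as a FeatureTable (for featurize/PCA unit tests)
make_feature_table <- function(M, entity = "e1") {
  M <- as.matrix(M)
  colnames(M) <- paste0("f", seq_len(ncol(M)))
  out <- data.frame(frame = seq_len(nrow(M)), time_ps = seq_len(nrow(M)),
                    entity = rep_len(entity, nrow(M)), M)
  attr(out, "features") <- colnames(M)
  attr(out, "state") <- "raw"
  class(out) <- c("FeatureTable", "data.frame")
  out
}

## adjusted Rand index (mclust is the independent reference when present)
ari <- function(a, b) {
  if (requireNamespace("mclust", quietly = TRUE)) {
    return(mclust::adjustedRandIndex(a, b))
  }
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sij <- sum(comb2(tab))
  si <- sum(comb2(rowSums(tab)))
  sj <- sum(comb2(colSums(tab)))
  n <- comb2(sum(tab))
  (sij - si * sj / n) / ((si + sj) / 2 - si * sj / n)
}

# helper: donor N-H in residue 1 plus acceptor O in residue 2, with the
# acceptor placed at a chosen D-A distance and D-H-A angle (degrees)
hbond_probe <- function(da, angle) {
  topo <- topology(elety = c("N", "H", "O"), resid = c("GLY", "GLY", "GLY"),
                   resno = c(1L, 1L, 2L))
  Np <- c(0, 0, 0)
  h <- 1.01
  Hp <- c(h, 0, 0)
  # exact placement: |NA| = da with the requested D-H-A angle (law of cosines)
  th <- angle * pi / 180
  r <- h * cos(th) + sqrt(da^2 - h^2 * sin(th)^2)
  u <- c(cos(pi - th), sin(pi - th), 0)   # direction H -> A
  idrfel:::as_frame(rbind(Np, Hp, Hp + r * u), topo)
}
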
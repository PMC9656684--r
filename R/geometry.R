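# Low-level vector geometry shared by the descriptor and builder code.
# All coordinates are Angstrom, all angles degrees unless noted.

cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

vnorm <- function(v) sqrt(sum(v * v))

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

## Wrap an angle in degrees to (-180, 180].
wrap_angle <- function(x) {
  w <- x - 360 * floor((x + 180) / 360)
  w[w == -180] <- 180
  w
}

## Signed torsion angle (degrees) of four points given as rows.
## Angle between plane(p1,p2,p3) and plane(p2,p3,p4), IUPAC sign.
torsion_points <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  if (vnorm(n1) < 1e-10 || vnorm(n2) < 1e-10) {
    stop("degenerate torsion: three consecutive points are collinear")
  }
  m1 <- cross3(n1, b2 / vnorm(b2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  wrap_angle(rad2deg(atan2(y, x)))
}

## Optimal rigid superposition (Kabsch): rotation R and translation t such
## that moving %*% R + t best fits fixed, in least squares.  Proper rotation
## is enforced by a determinant sign correction.
kabsch_fit <- function(moving, fixed) {
  stopifnot(nrow(moving) == nrow(fixed), ncol(moving) == 3L)
  if (nrow(moving) < 3L) stop("superposition needs at least 3 atoms")
  cm <- colMeans(moving)
  cf <- colMeans(fixed)
  P <- sweep(moving, 2L, cm)
  Q <- sweep(fixed, 2L, cf)
  # collinearity check: rank of centred coordinates must exceed 1
  if (svd(P, nu = 0L, nv = 0L)$d[2L] < 1e-8 * max(1, svd(P, nu = 0L, nv = 0L)$d[1L])) {
    stop("degenerate fit: selection is collinear")
  }
  H <- crossprod(P, Q)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  R <- s$v %*% D %*% t(s$u)     # so that R %*% p aligns onto q
  R <- t(R)                     # row-vector convention: p %*% R
  tvec <- cf - cm %*% R
  aligned <- sweep(moving %*% R, 2L, -as.numeric(tvec))
  rmsd <- sqrt(mean(rowSums((aligned - fixed)^2)))
  list(rotation = R, translation = as.numeric(tvec), rmsd = rmsd)
}

apply_transform <- function(xyz, rotation, translation) {
  sweep(xyz %*% rotation, 2L, -translation)
}

## NeRF internal-coordinate placement: position atom D given the three
## preceding atoms A-B-C, the bond length C-D, the bond angle B-C-D and the
## torsion A-B-C-D (degrees).
place_atom <- function(a, b, c, bond, angle, torsion) {
  ang <- deg2rad(angle)
  tor <- deg2rad(torsion)
  bc <- c - b
  bc <- bc / vnorm(bc)
  ab <- b - a
  n <- cross3(ab, bc)
  n <- n / vnorm(n)
  m <- cross3(n, bc)
  d2 <- c(-bond * cos(ang),
          bond * sin(ang) * cos(tor),
          -bond * sin(ang) * sin(tor))
  c + d2[1L] * bc + d2[2L] * m + d2[3L] * n
}

## Euclidean distance between two points.
pdist <- function(p, q) sqrt(sum((p - q)^2))

## All pairwise distances between rows of two matrices (m x 3, n x 3).
cross_dist <- function(A, B) {
  a2 <- rowSums(A^2)
  b2 <- rowSums(B^2)
  d2 <- outer(a2, b2, "+") - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0
  sqrt(d2)
}
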
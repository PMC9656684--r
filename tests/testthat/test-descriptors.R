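test_that("radius of gyration matches closed forms and direct summation", {
  expect_equal(radius_of_gyration(point_frame(c(1, 2, 3))), 0)
  two <- point_frame(rbind(c(0, 0, 0), c(2, 0, 0)))
  expect_equal(radius_of_gyration(two), 1.0)
  # direct-sum oracle on a random 10-atom frame with mixed elements
  set.seed(4)
  topo <- topology(elety = c(rep("CA", 4), rep("N", 3), rep("O", 2), "SD"),
                   resid = rep("MET", 10), resno = rep(1L, 10))
  xyz <- matrix(rnorm(30, sd = 3), 10, 3)
  fr <- idrfel:::as_frame(xyz, topo)
  m <- topo$mass
  com <- colSums(xyz * m) / sum(m)
  expected <- sqrt(sum(m * rowSums(sweep(xyz, 2, com)^2)) / sum(m))
  expect_equal(radius_of_gyration(fr), expected, tolerance = 1e-10)
  # hydrogens are excluded
  topo_h <- topology(elety = c("CA", "H"), resid = c("ALA", "ALA"),
                     resno = c(1L, 1L))
  fr_h <- idrfel:::as_frame(rbind(c(0, 0, 0), c(50, 0, 0)), topo_h)
  expect_equal(radius_of_gyration(fr_h), 0)
})

test_that("rmsd series is zero against displaced references and matches Kabsch per frame", {
  set.seed(5)
  topo <- point_topology(8)
  base <- matrix(rnorm(24, sd = 4), 8, 3)
  coords <- array(NA_real_, c(5, 8, 3))
  coords[1, , ] <- base
  for (i in 2:5) coords[i, , ] <- base + rnorm(24, sd = 0.3)
  traj <- trajectory(topo, coords)
  ref <- get_frame(traj, 1)
  rs <- rmsd_series(traj, ref)
  expect_equal(rs[1], 0, tolerance = 1e-8)
  # reference rigidly displaced: same series
  m <- random_rigid_motion()
  ref2 <- idrfel:::as_frame(apply_rigid(ref$xyz, m), topo)
  expect_equal(rmsd_series(traj, ref2), rs, tolerance = 1e-8)
  # per-frame quaternion oracle
  expected <- vapply(1:5, function(i)
    quaternion_rmsd(coords[i, , ], base), numeric(1))
  # the quaternion eigenvalue route loses ~1e-7 to cancellation near zero
  expect_equal(rs, expected, tolerance = 1e-6)
})

test_that("rmsf recovers closed-form fluctuations and the naive oracle", {
  topo <- point_topology(5)
  # residue 5 oscillates +/- d along x, residues 1-4 fixed (fit on 1-4)
  base <- rbind(c(0, 0, 0), c(3, 0, 0), c(0, 3, 0), c(0, 0, 3), c(5, 5, 5))
  d <- 0.7
  coords <- array(NA_real_, c(2, 5, 3))
  coords[1, , ] <- base; coords[1, 5, 1] <- 5 - d
  coords[2, , ] <- base; coords[2, 5, 1] <- 5 + d
  traj <- trajectory(topo, coords)
  out <- rmsf(traj, fit_selection = 1:4)
  expect_equal(unname(out[1:4]), rep(0, 4), tolerance = 1e-10)
  expect_equal(unname(out[5]), d, tolerance = 1e-10)
  # all frames identical -> all zero
  same <- trajectory(topo, array(rep(base, each = 3), c(3, 5, 3)))
  expect_equal(max(rmsf(same)), 0, tolerance = 1e-10)
  # naive two-pass oracle on a random ensemble (fit on all CA)
  set.seed(6)
  coords <- array(rnorm(10 * 5 * 3, sd = 2), c(10, 5, 3))
  traj2 <- trajectory(topo, coords)
  got <- rmsf(traj2)
  ref <- get_frame(traj2, 1)
  pos <- array(NA_real_, c(10, 5, 3))
  for (i in 1:10) pos[i, , ] <- superpose(get_frame(traj2, i), ref, 1:5)$aligned$xyz
  mp <- apply(pos, c(2, 3), mean)
  exp_rmsf <- sqrt(vapply(1:5, function(j)
    mean(rowSums((pos[, j, ] - matrix(mp[j, ], 10, 3, byrow = TRUE))^2)),
    numeric(1)))
  expect_equal(unname(got), exp_rmsf, tolerance = 1e-10)
  # duplication idempotence
  dup <- concatenate(list(traj2, traj2))
  expect_equal(rmsf(dup), got, tolerance = 1e-8)
  expect_error(rmsf(trajectory(topo, coords[1, , , drop = FALSE])), "single")
})

test_that("distances, areas, volumes and torsions match their oracles and are rigid-motion invariant", {
  roles <- residue_roles(tyrosines = c(1, 2, 3, 4), max_fluct = c(1, 2, 3),
                         min_fluct = c(1, 2), reference_helix = 1:2,
                         termini = c(1, 2), anchor = 1)
  expect_equal(end_to_end_distance(
    point_frame(rbind(c(0, 0, 0), c(3, 4, 0))), roles), 5)
  # triangle: legs 3 and 4 at a right angle -> area 6; collinear -> 0
  tri <- point_frame(rbind(c(0, 0, 0), c(3, 0, 0), c(0, 4, 0)))
  expect_equal(triangle_area(tri, 1:3), 6)
  lin <- point_frame(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)))
  expect_equal(triangle_area(lin, 1:3), 0)
  # regular tetrahedron edge 1 -> 1/(6 sqrt 2)
  reg <- point_frame(rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, sqrt(3) / 2, 0),
                           c(0.5, sqrt(3) / 6, sqrt(2 / 3))))
  expect_equal(tetrahedron_volume(reg, 1:4), 1 / (6 * sqrt(2)),
               tolerance = 1e-10)
  flat <- point_frame(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 0)))
  expect_equal(tetrahedron_volume(flat, 1:4), 0)
  # random frames against Heron / Cayley-Menger, and rigid-motion invariance
  set.seed(7)
  for (i in 1:10) {
    p4 <- matrix(rnorm(12, sd = 5), 4, 3)
    fr <- point_frame(p4)
    expect_equal(tetrahedron_volume(fr, 1:4), cayley_menger_volume(p4),
                 tolerance = 1e-10)
    expect_equal(triangle_area(fr, 1:3), heron_area(p4[1:3, ]),
                 tolerance = 1e-10)
    m <- random_rigid_motion()
    fr2 <- point_frame(apply_rigid(p4, m))
    expect_equal(tetrahedron_volume(fr2, 1:4), tetrahedron_volume(fr, 1:4),
                 tolerance = 1e-8)
    expect_equal(pseudo_torsion(fr2, 1:4), pseudo_torsion(fr, 1:4),
                 tolerance = 1e-9)
    # Hadamard-type bound: V <= product of three concurrent edges / 6
    e <- sqrt(rowSums((p4[2:4, ] - rep(1, 3) %o% p4[1, ])^2))
    expect_lte(tetrahedron_volume(fr, 1:4), prod(e) / 6 + 1e-12)
  }
  # pairwise distances: C(4,2) pairs, symmetric
  fr <- point_frame(matrix(rnorm(12), 4, 3))
  pd <- pairwise_ca_distances(fr, 1:4)
  expect_equal(nrow(pd), 6)
  expect_equal(pd$distance[1],
               sqrt(sum((fr$xyz[1, ] - fr$xyz[2, ])^2)))
  expect_error(pairwise_ca_distances(fr, c(1, 1, 2)), "duplicate")
})

test_that("pseudo-torsion hits the planar limits and flags collinear input", {
  cis <- point_frame(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0) + c(0, 1, 0),
                           c(0, 1, 0)))
  # points 1-2-3-4 with 4 on the same side as 1: torsion 0
  p_cis <- rbind(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, 1, 0))
  expect_equal(pseudo_torsion(point_frame(p_cis), 1:4), 0)
  p_trans <- rbind(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, -1, 0))
  expect_equal(abs(pseudo_torsion(point_frame(p_trans), 1:4)), 180)
  coll <- point_frame(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 1, 0)))
  expect_error(pseudo_torsion(coll, 1:4), "collinear")
})

test_that("backbone dihedrals are recovered from chains built at known angles", {
  set.seed(8)
  dih <- cbind(runif(10, -180, 180), runif(10, -180, 180))
  fr <- build_chain(rep("A", 10), dih, first_resno = 1)
  for (r in 2:9) {
    d <- backbone_dihedrals(fr, r)
    expect_equal(d$phi, dih[r, 1], tolerance = 1e-4)
    expect_equal(d$psi, dih[r, 2], tolerance = 1e-4)
  }
  # chain termini: undefined angles are NA
  expect_true(is.na(backbone_dihedrals(fr, 1)$phi))
  expect_true(is.na(backbone_dihedrals(fr, 10)$psi))
})
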
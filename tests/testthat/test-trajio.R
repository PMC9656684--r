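test_that("multi-model PDB files round-trip through write and read", {
  set.seed(1)
  topo <- topology(elety = rep(c("N", "CA", "C", "O", "CB"), 2),
                   resid = rep(c("ALA", "SER"), each = 5),
                   resno = rep(1:2, each = 5))
  coords <- array(round(rnorm(3 * 10 * 3, sd = 5), 3), c(3, 10, 3))
  traj <- trajectory(topo, coords, entity = "toy", frame_spacing_ps = 10)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_multimodel_pdb(traj, path)
  lines <- readLines(path)
  expect_equal(sum(grepl("^MODEL", lines)), 3)
  expect_equal(sum(grepl("^ENDMDL", lines)), 3)
  back <- read_multimodel_pdb(path, entity = "toy", frame_spacing_ps = 10)
  expect_equal(n_frames(back), 3)
  expect_equal(nrow(back$topology), 10)
  expect_lt(max(abs(back$coords - traj$coords)), 1e-3 + 1e-9)
  expect_identical(back$topology$elety, topo$elety)
  expect_identical(back$topology$resno, topo$resno)
  expect_identical(back$topology$element, topo$element)

  # single unmarked model
  single <- trajectory(topo, coords[1, , , drop = FALSE], entity = "one")
  p2 <- withr::local_tempfile(fileext = ".pdb")
  write_multimodel_pdb(single, p2)
  nomodel <- readLines(p2)
  writeLines(nomodel[!grepl("^MODEL|^ENDMDL", nomodel)], p2)
  expect_equal(n_frames(read_multimodel_pdb(p2)), 1)
})

test_that("malformed or inconsistent PDB input is rejected with context", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "MODEL        1",
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00",
    "ATOM      2  CA  ALA A   2       1.000   0.000   ABC    1.00  0.00",
    "ENDMDL"), path)
  expect_error(read_multimodel_pdb(path), "line 3")
  writeLines(c(
    "MODEL        1",
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00",
    "ATOM      2  CA  ALA A   2       1.000   0.000   0.000  1.00  0.00",
    "ENDMDL",
    "MODEL        2",
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00",
    "ENDMDL"), path)
  expect_error(read_multimodel_pdb(path), "atom count")
  expect_error(read_multimodel_pdb(tempfile()), "not found")
  expect_error(write_multimodel_pdb(
    trajectory(point_topology(1), array(0, c(0, 1, 3))), path))
})

test_that("writing rejects coordinates wider than the PDB field", {
  topo <- point_topology(2)
  coords <- array(c(0, 0, 0, 12345, 0, 0), c(1, 2, 3))
  traj <- trajectory(topo, coords)
  expect_error(write_multimodel_pdb(traj, tempfile(fileext = ".pdb")),
               "field width")
})

test_that("concatenation preserves frames, entities and total duration", {
  topo <- point_topology(4)
  mk <- function(entity) {
    trajectory(topo, array(rnorm(20 * 4 * 3), c(20, 4, 3)), entity = entity,
               frame_spacing_ps = 1e5)   # 20 frames x 0.1 ns... 2 us each
  }
  set.seed(2)
  trajs <- lapply(paste0("rep", 1:7), mk)
  cc <- concatenate(trajs)
  expect_equal(n_frames(cc), 140)
  expect_equal(duration_ps(cc), 14e6)  # 14 microseconds in ps
  expect_equal(table(cc$entity), table(rep(paste0("rep", 1:7), each = 20)))
  # identity on single input
  expect_identical(concatenate(trajs[1]), trajs[[1]])
  # mismatched residue spans are refused
  other <- trajectory(point_topology(5), array(rnorm(2 * 5 * 3), c(2, 5, 3)))
  expect_error(concatenate(list(trajs[[1]], other)), "mismatched residues")
})

test_that("superposition removes rigid motions and matches the quaternion oracle", {
  set.seed(3)
  topo <- point_topology(6)
  ref_xyz <- matrix(rnorm(18, sd = 4), 6, 3)
  ref <- idrfel:::as_frame(ref_xyz, topo)
  # identity
  sp <- superpose(ref, ref, 1:6)
  expect_equal(sp$rmsd, 0, tolerance = 1e-10)
  # exact rigid motion: rotation 90 degrees about z plus translation
  Rz <- matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3, 3)
  moved <- idrfel:::as_frame(sweep(ref_xyz %*% Rz, 2L, -c(5, 5, 5)), topo)
  sp2 <- superpose(moved, ref, 1:6)
  expect_equal(sp2$rmsd, 0, tolerance = 1e-8)
  expect_lt(max(abs(sp2$aligned$xyz - ref_xyz)), 1e-8)
  # random pairs against Horn's quaternion characteristic polynomial
  for (i in 1:10) {
    A <- matrix(rnorm(18, sd = 3), 6, 3)
    B <- matrix(rnorm(18, sd = 3), 6, 3)
    got <- superpose(idrfel:::as_frame(A, topo),
                     idrfel:::as_frame(B, topo), 1:6)$rmsd
    expect_equal(got, quaternion_rmsd(A, B), tolerance = 1e-8)
  }
  # rmsd invariant under a joint rigid motion of both frames
  m <- random_rigid_motion()
  got1 <- superpose(idrfel:::as_frame(ref_xyz, topo),
                    idrfel:::as_frame(ref_xyz + 1, topo), 1:6)$rmsd
  got2 <- superpose(idrfel:::as_frame(apply_rigid(ref_xyz, m), topo),
                    idrfel:::as_frame(apply_rigid(ref_xyz + 1, m), topo), 1:6)$rmsd
  expect_equal(got1, got2, tolerance = 1e-8)
  # degenerate selections are refused
  line <- idrfel:::as_frame(cbind(1:6, 0, 0), topo)
  expect_error(superpose(line, line, 1:6), "collinear")
  expect_error(superpose(ref, ref, 1:2), "3")
})

test_that("subsampling keeps frames on the stride and validates input", {
  topo <- point_topology(2)
  traj <- trajectory(topo, array(rnorm(2000 * 2 * 3), c(2000, 2, 3)),
                     frame_spacing_ps = 10)
  sub <- subsample(traj, 100)
  expect_equal(n_frames(sub), 200)
  expect_equal(sub$times[1], 0)
  expect_true(all(sub$times %% 100 == 0))
  expect_equal(n_frames(subsample(traj, 10)), 2000)
  expect_error(subsample(traj, 25), "multiple")
})

test_that("trajectory constructor enforces its invariants", {
  topo <- point_topology(3)
  expect_error(trajectory(topo, array(0, c(1, 2, 3))), "atom count")
  bad <- array(0, c(1, 3, 3)); bad[1, 1, 1] <- NA
  expect_error(trajectory(topo, bad), "finite")
  expect_error(trajectory(topo, array(0, c(2, 3, 3)), times = c(5, 5)),
               "increasing")
  expect_error(topology(elety = c("CA", "CA"), resid = c("A", "A"),
                        resno = c(2, 1)), "non-decreasing")
})
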
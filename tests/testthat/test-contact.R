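# Grid-projected contact distance: basis, lattice, projections, separations.

test_that("orthobasis yields deterministic right-handed orthonormal triples", {
  set.seed(31)
  V <- random_units(200)
  for (v in asplit(V, 1)) {
    b <- orthobasis(as.vector(v))
    expect_lt(abs(sum(b$v_a * v)), 1e-9)
    expect_lt(abs(sum(b$v_b * v)), 1e-9)
    expect_lt(abs(sum(b$v_a * b$v_b)), 1e-9)
    expect_equal(sum(rotdock:::pracma_cross(b$v_a, b$v_b) * v), 1,
                 tolerance = 1e-9)
    b2 <- orthobasis(as.vector(v))
    expect_identical(b, b2)
    # v and -v span the same plane
    bm <- orthobasis(as.vector(-v))
    expect_lt(abs(sum(bm$v_a * v)), 1e-9)
    expect_lt(abs(sum(bm$v_b * v)), 1e-9)
  }
  expect_error(orthobasis(c(0, 0, 2)), "unit")
})

test_that("the triangular lattice is equilateral, centered and sized 17x15", {
  p <- grid_params()
  off <- lattice_points(p)
  expect_identical(nrow(off), 255L)
  expect_equal(colMeans(off), c(a = 0, b = 0), tolerance = 1e-9)
  d <- as.matrix(dist(off))
  diag(d) <- Inf
  nn <- apply(d, 1, min)
  expect_equal(max(abs(nn - p$lambda)), 0, tolerance = 1e-9)
  # footprint ~ (16.5 * lambda) x (14 * lambda * sqrt(3)/2)
  expect_equal(diff(range(off[, 1])), 16.5 * p$lambda, tolerance = 1e-9)
  expect_equal(diff(range(off[, 2])), 14 * p$lambda * sqrt(3) / 2,
               tolerance = 1e-9)
})

test_that("a single atom projects zero height into nearby cells only", {
  path <- tempfile(fileext = ".pdb")
  write_tiny_pdb(path, matrix(0, 1, 3), names = "N")
  s <- annotate(read_pdb(path))
  p <- grid_params()
  g <- project_surface(s, c(0, 0, 1), params = p)
  off <- lattice_points(p)
  lat <- sqrt(rowSums(off^2))
  h <- as.vector(t(g$heights))         # row-major, matching lattice order
  expect_true(any(!is.na(h)))
  expect_true(all(is.na(h[lat >= p$cylinder_radius])))
  expect_true(all(abs(h[lat < p$cylinder_radius]) < 1e-9))
})

test_that("a dense spherical shell projects its radius at the central cell", {
  # pole atom is farthest along the projection direction
  s <- dense_sphere_structure(9)
  g <- project_surface(s, c(0, 1, 0))
  off <- lattice_points(grid_params())
  h <- as.vector(t(g$heights))
  central <- which.min(rowSums(off^2))
  expect_equal(h[central], 9, tolerance = 0.3)
  expect_true(all(h <= 9 + 1e-9, na.rm = TRUE))
})

test_that("single-atom bodies separate by epsilon exactly", {
  path <- tempfile(fileext = ".pdb")
  write_tiny_pdb(path, matrix(0, 1, 3), names = "N")
  s <- annotate(read_pdb(path))
  p <- grid_params()
  u <- c(0, 0, 1)
  b <- orthobasis(u)
  rg <- project_surface(s, u, b, p)
  lg <- project_surface(s, -u, b, p)
  expect_equal(optimal_separation(rg, lg, p), 4.7, tolerance = 1e-9)
})

test_that("native-frame separations equal the explicit world-frame oracle", {
  fx <- small_fixture()
  decoys <- compute_separations(fx$rec, fx$lig, shared_decoys())
  ks <- seq_len(min(40L, nrow(decoys)))
  for (k in ks) {
    expect_equal(decoys$r[k], separation_worldframe(fx$rec, fx$lig, decoys, k),
                 tolerance = 1e-6)
  }
})

test_that("pseudo-atom sphere separations recover R1 + R2 + epsilon", {
  rec <- dense_sphere_structure(10, chain = "A")
  lig <- dense_sphere_structure(8, chain = "B")
  p_rec <- distribute_points(8, seed = 1)
  p_lig <- distribute_points(6, seed = 2)
  poses <- generate_poses(rec, lig, p_rec, p_lig, "RRR")
  poses <- compute_separations(rec, lig, poses)
  expect_true(all(!is.na(poses$r)))
  expect_true(all(abs(poses$r - (10 + 8 + 4.7)) <= 0.6))
})

test_that("grid separations agree with a brute-force slide oracle within lambda", {
  fx <- small_fixture()
  decoys <- compute_separations(fx$rec, fx$lig, shared_decoys())
  p <- grid_params()
  for (k in seq_len(min(25L, nrow(decoys)))) {
    rot <- pose_rotation(decoys, k)
    rl <- realize_pose(fx$rec, fx$lig, decoys, k)
    A <- coords(rl$receptor)[rl$receptor$surface_backbone, , drop = FALSE]
    B <- coords(rl$ligand)[rl$ligand$surface_backbone, , drop = FALSE]
    B <- sweep(B, 2, decoys$r[k] * rot$u)    # ligand centered at origin
    au <- A %*% rot$u; bu <- B %*% rot$u
    lat_a <- A - au %*% t(rot$u); lat_b <- B - bu %*% t(rot$u)
    d2 <- outer(rowSums(lat_a^2), rowSums(lat_b^2), "+") -
      2 * tcrossprod(lat_a, lat_b)
    shared <- d2 < p$cylinder_radius^2
    skip_if(!any(shared))
    s_touch <- max((outer(as.vector(au), as.vector(bu), "-"))[shared])
    expect_lt(abs((decoys$r[k] - p$epsilon) - s_touch), p$lambda)
  }
})

test_that("separations are invariant under a world-frame rotation", {
  fx <- small_fixture()
  decoys <- compute_separations(fx$rec, fx$lig, shared_decoys()[1:10, ])
  Q <- rot_axis(c(2, -1, 1), 1.234)
  rot_q <- function(qcols, k) {
    R <- rotdock:::matrix_from_quat(as.numeric(decoys[k, qcols]))
    rotdock:::quat_from_matrix(Q %*% R)
  }
  moved <- decoys
  for (k in seq_len(nrow(decoys))) {
    moved[k, c("qrec_w", "qrec_x", "qrec_y", "qrec_z")] <-
      as.list(rot_q(c("qrec_w", "qrec_x", "qrec_y", "qrec_z"), k))
    moved[k, c("qlig_w", "qlig_x", "qlig_y", "qlig_z")] <-
      as.list(rot_q(c("qlig_w", "qlig_x", "qlig_y", "qlig_z"), k))
    moved[k, c("ux", "uy", "uz")] <-
      as.list(as.vector(Q %*% as.numeric(decoys[k, c("ux", "uy", "uz")])))
  }
  out <- compute_separations(fx$rec, fx$lig, moved)
  expect_equal(out$r, decoys$r, tolerance = 1e-6)
})

test_that("enlarging the ligand never decreases the separation", {
  fx <- small_fixture()
  decoys <- compute_separations(fx$rec, fx$lig, shared_decoys()[1:8, ])
  big <- fx$lig
  X <- coords(big)
  Xs <- sweep(sweep(X, 2, big$center), 2, rep(1.2, 3), "*")
  Xs <- sweep(Xs, 2, big$center, "+")
  big$atoms$x <- Xs[, 1]; big$atoms$y <- Xs[, 2]; big$atoms$z <- Xs[, 3]
  big <- annotate(big, 240L)
  r_big <- compute_separations(fx$rec, big, decoys)$r
  expect_true(all(r_big >= decoys$r - 1e-9))
})

test_that("format_grid renders null cells as dots", {
  path <- tempfile(fileext = ".pdb")
  write_tiny_pdb(path, matrix(0, 1, 3), names = "N")
  s <- annotate(read_pdb(path))
  g <- project_surface(s, c(0, 0, 1))
  txt <- format_grid(g)
  expect_length(txt, 15L)
  expect_true(any(grepl(".", txt, fixed = TRUE)))
})
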
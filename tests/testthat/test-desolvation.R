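# Residue-based desolvation: tables, contact pairs, pair-sum scoring,
# filtering, and the buried-surface oracle comparison.

manual_pose <- function(u, r, R_lig = diag(3), R_rec = diag(3)) {
  poses <- rotdock:::empty_pose_set(1L)
  poses[1, c("qrec_w", "qrec_x", "qrec_y", "qrec_z")] <-
    as.list(rotdock:::quat_from_matrix(R_rec))
  poses[1, c("qlig_w", "qlig_x", "qlig_y", "qlig_z")] <-
    as.list(rotdock:::quat_from_matrix(R_lig))
  poses[1, c("ux", "uy", "uz")] <- as.list(u / sqrt(sum(u^2)))
  poses$r[1] <- r
  poses
}

test_that("residue energies partition the molecular sigma-weighted area", {
  fx <- small_fixture()
  tb <- residue_energies(fx$rec)
  sigma <- default_sigma()
  direct <- sum(rotdock:::lookup_sigma(fx$rec$atoms$element, sigma) * fx$rec$asa)
  expect_equal(sum(tb), direct, tolerance = 1e-9)
  expect_identical(length(tb),
                   length(unique(rotdock:::residue_keys(fx$rec))))
  # a fully buried residue contributes exactly zero
  buried <- tb[names(tb) %in% names(which(tapply(
    fx$rec$asa, rotdock:::residue_keys(fx$rec), sum) == 0))]
  if (length(buried) > 0) expect_true(all(buried == 0))
})

test_that("a single-atom residue energy is sigma times its area", {
  path <- tempfile(fileext = ".pdb")
  write_tiny_pdb(path, matrix(0, 1, 3), names = "N")
  s <- annotate(read_pdb(path))
  tb <- residue_energies(s, sigma = c(N = 0.01, default = 0))
  expect_equal(as.numeric(tb[1]), 0.01 * s$asa[1], tolerance = 1e-12)
  expect_error(residue_energies(s, sigma = c(C = 1)), "default")
})

test_that("contact pairs honour the 8 A cutoff boundary", {
  p1 <- tempfile(fileext = ".pdb"); p2 <- tempfile(fileext = ".pdb")
  write_tiny_pdb(p1, matrix(0, 1, 3), names = "CA", chains = "A")
  write_tiny_pdb(p2, matrix(0, 1, 3), names = "CA", chains = "B")
  a <- annotate(read_pdb(p1)); b <- annotate(read_pdb(p2))
  near <- contact_pairs(a, b, manual_pose(c(0, 0, 1), 7.9), 1)
  expect_identical(nrow(near), 1L)
  far <- contact_pairs(a, b, manual_pose(c(0, 0, 1), 8.1), 1)
  expect_identical(nrow(far), 0L)
  # 100 A away: empty
  none <- contact_pairs(a, b, manual_pose(c(0, 0, 1), 100), 1)
  expect_identical(nrow(none), 0L)
})

test_that("one receptor residue touching two ligand residues gives two pairs", {
  p1 <- tempfile(fileext = ".pdb"); p2 <- tempfile(fileext = ".pdb")
  write_tiny_pdb(p1, matrix(0, 1, 3), names = "CA", chains = "A")
  # ligand: two residues, both within 8 A of the receptor atom when posed
  write_tiny_pdb(p2, rbind(c(0, 0, -2), c(0, 0, 2)), names = c("CA", "CA"),
                 resnos = 1:2, chains = c("B", "B"))
  a <- annotate(read_pdb(p1)); b <- annotate(read_pdb(p2))
  pose <- manual_pose(c(0, 0, 1), 6)
  pairs <- contact_pairs(a, b, pose, 1)
  expect_identical(nrow(pairs), 2L)
  ta <- residue_energies(a); tb <- residue_energies(b)
  e <- pose_desolvation(ta, tb, pairs)
  expect_equal(e, 2 * ta[["A|1|"]] + tb[["B|1|"]] + tb[["B|2|"]],
               tolerance = 1e-12)
  once <- pose_desolvation(ta, tb, pairs, count_once = TRUE)
  expect_equal(once, ta[["A|1|"]] + tb[["B|1|"]] + tb[["B|2|"]],
               tolerance = 1e-12)
  expect_error(pose_desolvation(ta[0], tb, pairs), "missing")
})

test_that("accelerated contact search equals brute force on random poses", {
  fx <- small_fixture()
  decoys <- shared_decoys()
  for (k in seq_len(min(15L, nrow(decoys)))) {
    fast <- contact_pairs(fx$rec, fx$lig, decoys, k)
    brute <- brute_contact_pairs(fx$rec, fx$lig, decoys, k)
    expect_identical(
      sort(paste(fast$rec_key, fast$lig_key)),
      sort(paste(brute$rec_key, brute$lig_key)))
  }
})

test_that("score_poses matches the per-pose pair-sum computed directly", {
  fx <- small_fixture()
  decoys <- shared_decoys()[1:10, ]
  scored <- score_poses(fx$rec, fx$lig, decoys)
  ta <- residue_energies(fx$rec); tb <- residue_energies(fx$lig)
  for (k in seq_len(nrow(decoys))) {
    pairs <- contact_pairs(fx$rec, fx$lig, decoys, k)
    expect_equal(scored$desolv[k], pose_desolvation(ta, tb, pairs),
                 tolerance = 1e-9)
  }
})

test_that("pose desolvation is invariant under whole-complex rotation", {
  fx <- small_fixture()
  decoys <- shared_decoys()[1:6, ]
  scored <- score_poses(fx$rec, fx$lig, decoys)
  Q <- rot_axis(c(1, 1, -2), 0.77)
  moved <- decoys
  for (k in seq_len(nrow(decoys))) {
    Rr <- Q %*% rotdock:::matrix_from_quat(
      as.numeric(decoys[k, c("qrec_w", "qrec_x", "qrec_y", "qrec_z")]))
    Rl <- Q %*% rotdock:::matrix_from_quat(
      as.numeric(decoys[k, c("qlig_w", "qlig_x", "qlig_y", "qlig_z")]))
    moved[k, c("qrec_w", "qrec_x", "qrec_y", "qrec_z")] <-
      as.list(rotdock:::quat_from_matrix(Rr))
    moved[k, c("qlig_w", "qlig_x", "qlig_y", "qlig_z")] <-
      as.list(rotdock:::quat_from_matrix(Rl))
    moved[k, c("ux", "uy", "uz")] <-
      as.list(as.vector(Q %*% as.numeric(decoys[k, c("ux", "uy", "uz")])))
  }
  scored2 <- score_poses(fx$rec, fx$lig, moved)
  expect_equal(scored2$desolv, scored$desolv, tolerance = 1e-9)
})

test_that("filter keeps max(1, round(p*M)) best-energy poses, stable ties", {
  poses <- rotdock:::empty_pose_set(1000L)
  set.seed(17)
  poses$r <- 10
  poses$desolv <- stats::rnorm(1000)
  kept <- filter_by_desolvation(poses, 0.01)
  expect_identical(nrow(kept), 10L)
  expect_identical(kept$rank, 1:10)
  expect_lte(max(kept$desolv), min(poses$desolv[!poses$pose_id %in% kept$pose_id]))
  # all-equal energies: first k by pose_id
  poses$desolv <- 1
  kept2 <- filter_by_desolvation(poses, 0.005)
  expect_identical(kept2$pose_id, 1:5)
  # k floors at one pose
  expect_identical(nrow(filter_by_desolvation(poses, 1e-6)), 1L)
  expect_error(filter_by_desolvation(poses[0, ], 0.1), "empty")
})

test_that("a far-separated pose buries no surface", {
  fx <- small_fixture()
  far <- manual_pose(c(0, 0, 1), 200)
  e <- atom_desolvation(fx$rec, fx$lig, far, 1)
  expect_equal(e, 0, tolerance = 1e-6)
  expect_identical(e, atom_desolvation(fx$rec, fx$lig, far, 1))
})

test_that("pair over-counting tracks the buried-surface oracle better than counting once", {
  fx <- small_fixture()
  decoys <- shared_decoys()
  scored <- score_poses(fx$rec, fx$lig, decoys)
  once <- score_poses(fx$rec, fx$lig, decoys, count_once = TRUE)
  oracle <- atom_desolvation(fx$rec, fx$lig, decoys)
  c_pairs <- stats::cor(scored$desolv, oracle)
  c_once <- stats::cor(once$desolv, oracle)
  expect_gt(c_pairs, c_once)
  expect_gt(c_pairs, 0.5)
})
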
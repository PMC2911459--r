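# Pose enumeration: twist rule, pole rotations, method contracts,
# restraint restriction, table round-trips.

vec_len <- function(v) sqrt(sum(v^2))

test_that("twist count follows the square-root rule", {
  tw <- twist_angles(100)
  expect_identical(tw$count, 10L)
  expect_equal(tw$angles, 2 * pi * (0:9) / 10, tolerance = 1e-12)
  expect_equal(tw$step_deg, 36)
  expect_identical(twist_angles(1)$count, 1L)
  expect_identical(twist_angles(1)$angles, 0)
  expect_identical(twist_angles(492)$count, 22L)
})

test_that("rotation_to_point sends the north pole along the minimal arc", {
  expect_equal(rotation_to_point(c(0, 0, 1)), diag(3), tolerance = 1e-12)
  R <- rotation_to_point(c(1, 0, 0))
  expect_equal(as.vector(R %*% c(0, 0, 1)), c(1, 0, 0), tolerance = 1e-12)
  expect_equal(R, rot_axis(c(0, 1, 0), pi / 2), tolerance = 1e-12)
  expect_equal(rotation_to_point(c(0, 0, -1)), diag(c(1, -1, -1)),
               tolerance = 1e-12)
  expect_error(rotation_to_point(c(0, 0, 2)), "unit")
  set.seed(21)
  for (p in asplit(random_units(20), 1)) {
    R <- rotation_to_point(p)
    expect_equal(as.vector(R %*% c(0, 0, 1)), as.vector(p),
                 tolerance = 1e-12)
    expect_equal(det(R), 1, tolerance = 1e-9)
  }
})

test_that("pose counts equal |P_rec| x |P_lig| x round(sqrt(|P_lig|))", {
  fx <- shared_fixture()
  p_rec <- distribute_points(20, seed = 1)
  p_lig <- distribute_points(16, seed = 2)
  for (m in c("RRT", "TRR", "RRR")) {
    poses <- generate_poses(fx$rec, fx$lig, p_rec, p_lig, m)
    expect_identical(nrow(poses), 20L * 16L * 4L)
    expect_identical(poses$pose_id, seq_len(nrow(poses)))
    # enumeration order: i_rec outer, i_lig middle, i_twist inner
    expect_identical(poses$i_twist[1:4], 1:4)
    expect_identical(poses$i_lig[c(1, 5)], c(1L, 2L))
  }
})

test_that("every method poses the sampled points onto the interaction axis", {
  fx <- shared_fixture()
  p_rec <- distribute_points(12, seed = 4)
  p_lig <- distribute_points(9, seed = 5)
  set.seed(6)
  for (m in c("RRT", "TRR", "RRR")) {
    poses <- generate_poses(fx$rec, fx$lig, p_rec, p_lig, m)
    for (k in sample(nrow(poses), 34)) {
      rot <- pose_rotation(poses, k)
      # all methods: the receptor point ends on the +u axis
      expect_lt(vec_len(rot$R_rec %*% p_rec$points[poses$i_rec[k], ] - rot$u),
                1e-9)
      if (m == "RRT") {
        # twist about z, then the north pole is sent to the ligand point
        expect_lt(vec_len(rot$R_lig %*% c(0, 0, 1) -
                            p_lig$points[poses$i_lig[k], ]), 1e-9)
      } else {
        # TRR/RRR: the ligand point faces the receptor (lands on -u)
        expect_lt(vec_len(rot$R_lig %*% p_lig$points[poses$i_lig[k], ] +
                            rot$u), 1e-9)
      }
      if (m == "RRR") expect_identical(rot$u, c(0, 0, 1))
    }
  }
})

test_that("RRR with aligned points and zero twist is the identity pose", {
  fx <- shared_fixture()
  p_rec <- as_sphere_point_set(rbind(c(0, 0, 1)))
  p_lig <- as_sphere_point_set(rbind(c(0, 0, -1)))
  poses <- generate_poses(fx$rec, fx$lig, p_rec, p_lig, "RRR")
  rot <- pose_rotation(poses, 1)
  expect_equal(rot$R_rec, diag(3), tolerance = 1e-12)
  expect_lt(vec_len(rot$R_lig %*% c(0, 0, -1) - c(0, 0, -1)), 1e-12)
})

test_that("the full rotation set is Haar-uniform (KS of relative angles)", {
  fx <- shared_fixture()
  p_rec <- distribute_points(20, seed = 9)
  p_lig <- distribute_points(169, seed = 10)  # spiral branch
  poses <- generate_poses(fx$rec, fx$lig, p_rec, p_lig, "RRT")
  ang <- relative_rotation_angles(poses, n_pairs = 4000L, seed = 11L)
  expect_lt(haar_angle_ks(ang), 0.05)
})

test_that("restrict_directions picks the aligned point and its neighbours", {
  # structure whose residue 2 centroid lies along +z from the center
  path <- tempfile(fileext = ".pdb")
  xyz <- rbind(c(0, 0, -3), c(0, 0, 3), c(3, 0, 0), c(-3, 0, 0))
  write_tiny_pdb(path, xyz, names = rep("CA", 4), resnos = 1:4)
  s <- annotate(read_pdb(path))
  P <- as_sphere_point_set(octahedron_points())
  zidx <- 5L  # +z row in octahedron_points()

  r0 <- restrict_directions(P, s, data.frame(chain = "A", resno = 2),
                            n_neighbors = 0L)
  expect_identical(r0$index, zidx)
  expect_equal(r0$points, rbind(c(0, 0, 1)), ignore_attr = TRUE)
  expect_identical(r0$parent_n, 6L)

  r4 <- restrict_directions(P, s, data.frame(chain = "A", resno = 2),
                            n_neighbors = 4L)
  expect_identical(sort(r4$index), c(1L, 2L, 3L, 4L, 5L))  # +z + 4 equatorial

  # two restraints mapping to the same point stay a single selection
  rr <- data.frame(chain = c("A", "A"), resno = c(2, 2))
  r2 <- restrict_directions(P, s, rr, n_neighbors = 2L)
  expect_lte(r2$n, 3L)

  expect_error(
    restrict_directions(P, s, data.frame(chain = "B", resno = 9)),
    "B.*9")
})

test_that("restriction on both sides scales the pose count exactly", {
  fx <- shared_fixture()
  p_rec <- distribute_points(36, seed = 12)
  p_lig <- distribute_points(49, seed = 13)
  rr <- data.frame(chain = "A", resno = 5)
  rl <- data.frame(chain = "B", resno = 3)
  q_rec <- restrict_directions(p_rec, fx$rec, rr, n_neighbors = 6L)
  q_lig <- restrict_directions(p_lig, fx$lig, rl, n_neighbors = 6L)
  expect_identical(q_rec$n, 7L)
  expect_identical(q_lig$n, 7L)
  full <- generate_poses(fx$rec, fx$lig, p_rec, p_lig, "RRR")
  restr <- generate_poses(fx$rec, fx$lig, q_rec, q_lig, "RRR")
  expect_identical(nrow(restr) / nrow(full), (7 / 36) * (7 / 49))
  expect_true(all(restr$i_rec %in% q_rec$index))
})

test_that("pose tables round-trip through TSV", {
  decoys <- shared_decoys()
  path <- tempfile(fileext = ".tsv")
  write_pose_table(decoys, path)
  back <- read_pose_table(path)
  expect_identical(nrow(back), nrow(decoys))
  expect_identical(back$pose_id, decoys$pose_id)
  for (col in c("qlig_w", "qlig_x", "ux", "uz", "r"))
    expect_equal(back[[col]], decoys[[col]], tolerance = 1e-7)
  # canonical quaternions: unit norm, scalar-first w >= 0
  qn <- sqrt(back$qlig_w^2 + back$qlig_x^2 + back$qlig_y^2 + back$qlig_z^2)
  expect_equal(qn, rep(1, nrow(back)), tolerance = 1e-7)
  expect_true(all(back$qlig_w >= 0))
})
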
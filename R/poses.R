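# Pose generation: uniformly distributed rigid-body docking orientations.
#
# Three enumeration schemes over the receptor and ligand direction sets
# P_rec, P_lig and a twist grid psi:
#   RRT - ligand twisted about z, then its pole sent to p_lig; the ligand
#         center is translated along each receptor direction p_rec.
#   TRR - ligand translated along p_rec, its point p_lig rotated onto the
#         inter-center axis (facing the receptor), then twisted about it.
#   RRR - both molecules rotated so their points meet on the z axis
#         (receptor point to +z, ligand point to -z), ligand twisted about z.
# The twist count is round(sqrt(|P_lig|)), which balances the angular
# resolution of the twist with that of the point sets so the combined
# rotation set is uniform.
#
# Posed-coordinate convention used everywhere downstream: receptor center at
# the origin (rotated by R_rec), ligand center at r*u (rotated by R_lig).

#' Twist angle grid for a ligand point set
#'
#' The number of twist angles is `round(sqrt(n_lig_points))` (at least 1),
#' uniformly spaced on `[0, 2*pi)` starting at 0; this matches the angular
#' resolution of the twist to that of the point distribution.
#'
#' @param n_lig_points number of ligand sphere points (>= 1).
#' @return a `twist_set`: list with `angles` (radians), `count`, and
#'   `step_deg` (the angular step in degrees, `360 / count`).
#' @export
twist_angles <- function(n_lig_points) {
  stopifnot(n_lig_points >= 1)
  count <- max(1L, as.integer(round(sqrt(n_lig_points))))
  structure(list(angles = 2 * pi * (seq_len(count) - 1) / count,
                 count = count, step_deg = 360 / count),
            class = "twist_set")
}

method_rotations <- function(method, p_rec, p_lig, psi) {
  switch(method,
    RRT = {
      u <- p_rec
      list(R_rec = diag(3), R_lig = rotation_to_point(p_lig) %*% rot_z(psi),
           u = u)
    },
    TRR = {
      u <- p_rec
      list(R_rec = diag(3),
           R_lig = rot_axis(u, psi) %*% arc_rotation(p_lig, -u), u = u)
    },
    RRR = {
      list(R_rec = arc_rotation(p_rec, c(0, 0, 1)),
           R_lig = rot_z(psi) %*% arc_rotation(p_lig, c(0, 0, -1)),
           u = c(0, 0, 1))
    },
    stop("unknown method: ", method))
}

#' Generate the full set of rigid-body docking poses
#'
#' Enumerates all `|P_rec| x |P_lig| x twist` combinations in a fixed order
#' (receptor point outer, ligand point middle, twist inner) and records, for
#' each pose, the receptor and ligand rotations (as canonical scalar-first
#' quaternions with w >= 0) and the unit interaction direction `u` from the
#' receptor center to the ligand center in the posed frame. The separation
#' `r` is filled later by [compute_separations()], the desolvation score by
#' [score_poses()].
#'
#' The twist count is taken from the parent size of `p_lig`
#' (see [restrict_directions()]), so restricting the direction sets does not
#' change the twist resolution.
#'
#' @param receptor,ligand annotated [protein_structure]s (larger molecule as
#'   receptor). Only used for validation here; rotations depend on the point
#'   sets alone.
#' @param p_rec,p_lig `sphere_point_set`s of interaction directions.
#' @param method `"RRR"` (default), `"RRT"` or `"TRR"`.
#' @return a `pose_set` data.frame with columns pose_id, method, i_rec,
#'   i_lig, i_twist, qrec_w..qrec_z, qlig_w..qlig_z, ux, uy, uz, r, desolv,
#'   score.
#' @export
generate_poses <- function(receptor, ligand, p_rec, p_lig,
                           method = c("RRR", "RRT", "TRR")) {
  method <- match.arg(method)
  stopifnot(inherits(p_rec, "sphere_point_set"),
            inherits(p_lig, "sphere_point_set"))
  if (p_rec$n == 0L || p_lig$n == 0L) stop("empty point set")
  tw <- twist_angles(p_lig$parent_n)
  n_rec <- p_rec$n; n_lig <- p_lig$n; n_tw <- tw$count
  n_pose <- n_rec * n_lig * n_tw
  qr <- matrix(NA_real_, n_pose, 4)
  ql <- matrix(NA_real_, n_pose, 4)
  um <- matrix(NA_real_, n_pose, 3)
  i_rec <- integer(n_pose); i_lig <- integer(n_pose); i_twist <- integer(n_pose)
  row <- 0L
  for (i in seq_len(n_rec)) {
    for (j in seq_len(n_lig)) {
      for (k in seq_len(n_tw)) {
        rot <- method_rotations(method, p_rec$points[i, ], p_lig$points[j, ],
                                tw$angles[k])
        row <- row + 1L
        qr[row, ] <- quat_from_matrix(rot$R_rec)
        ql[row, ] <- quat_from_matrix(rot$R_lig)
        um[row, ] <- rot$u
        i_rec[row] <- p_rec$index[i]
        i_lig[row] <- p_lig$index[j]
        i_twist[row] <- k
      }
    }
  }
  poses <- data.frame(
    pose_id = seq_len(n_pose), method = method,
    i_rec = i_rec, i_lig = i_lig, i_twist = i_twist,
    qrec_w = qr[, 1], qrec_x = qr[, 2], qrec_y = qr[, 3], qrec_z = qr[, 4],
    qlig_w = ql[, 1], qlig_x = ql[, 2], qlig_y = ql[, 3], qlig_z = ql[, 4],
    ux = um[, 1], uy = um[, 2], uz = um[, 3],
    r = NA_real_, desolv = NA_real_, score = NA_real_,
    stringsAsFactors = FALSE)
  class(poses) <- c("pose_set", "data.frame")
  attr(poses, "twist") <- tw
  poses
}

#' Rotations and direction of one pose
#'
#' @param poses a `pose_set`.
#' @param k row index.
#' @return list with 3x3 matrices `R_rec`, `R_lig` and unit 3-vector `u`.
#' @export
pose_rotation <- function(poses, k) {
  p <- poses[k, ]
  list(R_rec = matrix_from_quat(c(p$qrec_w, p$qrec_x, p$qrec_y, p$qrec_z)),
       R_lig = matrix_from_quat(c(p$qlig_w, p$qlig_x, p$qlig_y, p$qlig_z)),
       u = c(p$ux, p$uy, p$uz))
}

#' Realize a pose as transformed structures
#'
#' Places the receptor with its center at the origin (rotated by `R_rec`) and
#' the ligand with its center at `r * u` (rotated by `R_lig`).
#'
#' @param receptor,ligand annotated [protein_structure]s.
#' @param poses a `pose_set` with `r` assigned for row `k`.
#' @param k row index.
#' @return list of the two transformed structures.
#' @export
realize_pose <- function(receptor, ligand, poses, k) {
  rot <- pose_rotation(poses, k)
  r <- poses$r[k]
  if (is.na(r)) stop("pose ", poses$pose_id[k], " has no separation r")
  rec <- transform_structure(receptor, rot$R_rec,
                             -as.vector(rot$R_rec %*% receptor$center))
  lig <- transform_structure(ligand, rot$R_lig,
                             r * rot$u - as.vector(rot$R_lig %*% ligand$center))
  list(receptor = rec, ligand = lig)
}

#' Restrict a direction set to those near expected interface residues
#'
#' For each restraint residue, the unit direction from the structure center
#' to the residue's heavy-atom centroid is computed; the point of `p` with
#' the largest dot product to it is selected, plus that point's
#' `n_neighbors` angularly nearest neighbours. The union over restraints is
#' returned with original point indices preserved (and the parent set size
#' retained, so the twist count of subsequent sampling is unchanged).
#'
#' @param p a `sphere_point_set`.
#' @param structure annotated [protein_structure] the restraints refer to.
#' @param restraint_residues data.frame with columns `chain` and `resno` (an
#'   optional `ins` column for insertion codes defaults to "").
#' @param n_neighbors how many nearest neighbour directions to add per
#'   restraint (default 6, the in-plane coordination of a hexagonal packing).
#' @return the restricted `sphere_point_set` (subset of `p`).
#' @export
restrict_directions <- function(p, structure, restraint_residues,
                                n_neighbors = 6L) {
  stopifnot(inherits(p, "sphere_point_set"),
            inherits(structure, "protein_structure"))
  if (is.null(structure$center)) stop("structure must be annotated")
  rr <- as.data.frame(restraint_residues)
  if (is.null(rr$ins)) rr$ins <- ""
  keys <- residue_keys(structure)
  sel <- integer(0)
  G <- tcrossprod(p$points)          # pairwise cosines, for neighbours
  for (q in seq_len(nrow(rr))) {
    key <- paste(rr$chain[q], rr$resno[q], rr$ins[q], sep = "|")
    idx <- which(keys == key)
    if (length(idx) == 0L)
      stop("restraint residue not found in structure: chain ", rr$chain[q],
           " residue ", rr$resno[q], rr$ins[q])
    centroid <- colMeans(coords(structure)[idx, , drop = FALSE])
    dirv <- unitize(centroid - structure$center)
    best <- which.max(p$points %*% dirv)
    nb <- order(G[best, ], decreasing = TRUE)
    nb <- setdiff(nb, best)[seq_len(min(n_neighbors, p$n - 1L))]
    sel <- union(sel, c(best, nb))
  }
  sel <- sort(sel)
  new_sphere_point_set(p$points[sel, , drop = FALSE],
                       resolution = p$resolution,
                       method_used = p$method_used, seed = p$seed,
                       index = p$index[sel], parent_n = p$parent_n)
}

quat_mul <- function(a, b) {
  cbind(a[, 1] * b[, 1] - a[, 2] * b[, 2] - a[, 3] * b[, 3] - a[, 4] * b[, 4],
        a[, 1] * b[, 2] + a[, 2] * b[, 1] + a[, 3] * b[, 4] - a[, 4] * b[, 3],
        a[, 1] * b[, 3] - a[, 2] * b[, 4] + a[, 3] * b[, 1] + a[, 4] * b[, 2],
        a[, 1] * b[, 4] + a[, 2] * b[, 3] - a[, 3] * b[, 2] + a[, 4] * b[, 1])
}

#' Sampled pairwise relative rotation angles of a pose set
#'
#' The orientation of a pose is the ligand rotation expressed in the
#' receptor frame, `R_rec^T R_lig`. For uniformly (Haar) distributed
#' orientations the angle of the relative rotation between two independent
#' poses has density `(1 - cos(theta)) / pi` on `[0, pi]`; comparing the
#' sampled angles against that law is the standard uniformity diagnostic.
#'
#' @param poses a `pose_set`.
#' @param n_pairs how many random pose pairs to draw.
#' @param seed integer seed for the pair sampling.
#' @return numeric vector of relative rotation angles in radians.
#' @export
relative_rotation_angles <- function(poses, n_pairs = 4000L, seed = 1L) {
  qr <- as.matrix(poses[, c("qrec_w", "qrec_x", "qrec_y", "qrec_z")])
  ql <- as.matrix(poses[, c("qlig_w", "qlig_x", "qlig_y", "qlig_z")])
  qrel <- quat_mul(cbind(qr[, 1], -qr[, 2], -qr[, 3], -qr[, 4]), ql)
  ij <- local_rng(as.integer(seed), {
    cbind(sample(nrow(poses), n_pairs, replace = TRUE),
          sample(nrow(poses), n_pairs, replace = TRUE))
  })
  ij <- ij[ij[, 1] != ij[, 2], , drop = FALSE]
  dq <- abs(rowSums(qrel[ij[, 1], ] * qrel[ij[, 2], ]))
  2 * acos(pmin(1, dq))
}

#' Kolmogorov-Smirnov distance to the uniform-rotation angle law
#'
#' @param angles relative rotation angles in radians, see
#'   [relative_rotation_angles()].
#' @return the KS statistic against the CDF `(theta - sin(theta)) / pi`.
#' @export
haar_angle_ks <- function(angles) {
  x <- sort(angles)
  n <- length(x)
  Fx <- (x - sin(x)) / pi
  max(pmax(seq_len(n) / n - Fx, Fx - (seq_len(n) - 1) / n))
}

POSE_COLUMNS <- c("pose_id", "method", "i_rec", "i_lig", "i_twist",
                  "qrec_w", "qrec_x", "qrec_y", "qrec_z",
                  "qlig_w", "qlig_x", "qlig_y", "qlig_z",
                  "ux", "uy", "uz", "r", "desolv", "score")

#' Write a pose table as TSV
#' @param poses a `pose_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pose_table <- function(poses, path) {
  df <- as.data.frame(poses)[, POSE_COLUMNS]
  num <- vapply(df, is.numeric, logical(1)) & names(df) != "pose_id" &
    !names(df) %in% c("i_rec", "i_lig", "i_twist")
  df[num] <- lapply(df[num], function(x) sprintf("%.9g", x))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a pose table written by [write_pose_table()]
#' @param path TSV path.
#' @return a `pose_set` data.frame.
#' @export
read_pose_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  missing_cols <- setdiff(POSE_COLUMNS, names(df))
  if (length(missing_cols) > 0)
    stop("pose table ", path, " lacks columns: ",
         paste(missing_cols, collapse = ", "))
  class(df) <- c("pose_set", "data.frame")
  df
}
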
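# Evaluation layer: superposition, ligand RMSD, near-native classification,
# success rates and ranked-set merging.

#' Least-squares rigid superposition (Kabsch)
#'
#' Proper-rotation least-squares fit of `mobile` onto `target` via the SVD of
#' the covariance matrix, with the determinant correction that forbids
#' reflections.
#'
#' @param mobile,target n x 3 coordinate matrices with matching rows, n >= 3.
#' @return list with `rotation` (3x3), `translation` (3-vector) such that
#'   `mobile %*% t(rotation) + translation` best fits `target`, and the
#'   residual `rmsd` in Angstrom.
#' @export
superpose_kabsch <- function(mobile, target) {
  mobile <- as.matrix(mobile); target <- as.matrix(target)
  if (!all(dim(mobile) == dim(target)))
    stop("mobile and target must have matching dimensions")
  if (nrow(mobile) < 3L) stop("need at least 3 points to superpose")
  cm <- colMeans(mobile); ct <- colMeans(target)
  A <- sweep(mobile, 2, cm); B <- sweep(target, 2, ct)
  H <- crossprod(A, B)                    # 3x3 covariance
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  fitted <- A %*% t(R)
  rmsd <- sqrt(mean(rowSums((fitted - B)^2)))
  list(rotation = R, translation = as.vector(ct - R %*% cm), rmsd = rmsd)
}

ca_keys_coords <- function(structure) {
  sel <- structure$atoms$name == "CA"
  list(keys = residue_keys(structure)[sel],
       xyz = coords(structure)[sel, , drop = FALSE])
}

# Match Cα atoms of `a` and `b` by residue key; unmatched residues dropped
# with a logged count.
match_ca <- function(a, b, label = "structure") {
  common <- intersect(a$keys, b$keys)
  dropped <- (length(a$keys) - length(common)) + (length(b$keys) - length(common))
  if (length(common) == 0L)
    stop("no common C-alpha atoms between posed and reference ", label)
  if (dropped > 0)
    message("ligand_rmsd: dropped ", dropped, " unmatched ", label,
            " C-alpha atoms")
  list(a = a$xyz[match(common, a$keys), , drop = FALSE],
       b = b$xyz[match(common, b$keys), , drop = FALSE])
}

#' Ligand C-alpha RMSD of poses against a reference complex
#'
#' For each pose: realize it, superpose the posed receptor C-alpha trace onto
#' the receptor part of the reference complex (matched by chain and residue
#' number), apply that transform to the posed ligand, and compute the RMSD
#' over matched ligand C-alpha atoms. A pose is near-native when this RMSD
#' is at or below 10 Angstrom.
#'
#' @param receptor,ligand annotated [protein_structure]s used to build the
#'   poses.
#' @param poses a `pose_set` with `r` assigned.
#' @param reference a [protein_structure] of the reference complex,
#'   containing the receptor and ligand chains.
#' @param k row indices to evaluate (default all).
#' @return numeric vector of RMSDs in Angstrom (NA for invalid poses).
#' @export
ligand_rmsd <- function(receptor, ligand, poses, reference,
                        k = seq_len(nrow(poses))) {
  ref <- ca_keys_coords(reference)
  rec0 <- ca_keys_coords(receptor)
  lig0 <- ca_keys_coords(ligand)
  rec_common <- intersect(rec0$keys, ref$keys)
  lig_common <- intersect(lig0$keys, ref$keys)
  if (length(rec_common) < 3L)
    stop("no usable common receptor C-alpha atoms with the reference")
  if (length(lig_common) == 0L)
    stop("no common ligand C-alpha atoms with the reference")
  dropped <- (length(rec0$keys) - length(rec_common)) +
    (length(lig0$keys) - length(lig_common))
  if (dropped > 0)
    message("ligand_rmsd: dropped ", dropped, " unmatched C-alpha atoms")
  ref_rec <- ref$xyz[match(rec_common, ref$keys), , drop = FALSE]
  ref_lig <- ref$xyz[match(lig_common, ref$keys), , drop = FALSE]
  rec_base <- sweep(rec0$xyz[match(rec_common, rec0$keys), , drop = FALSE],
                    2, receptor$center)
  lig_base <- sweep(lig0$xyz[match(lig_common, lig0$keys), , drop = FALSE],
                    2, ligand$center)
  vapply(k, function(kk) {
    if (is.na(poses$r[kk])) return(NA_real_)
    rot <- pose_rotation(poses, kk)
    posed_rec <- rec_base %*% t(rot$R_rec)
    posed_lig <- sweep(lig_base %*% t(rot$R_lig), 2,
                       poses$r[kk] * rot$u, "+")
    fit <- superpose_kabsch(posed_rec, ref_rec)
    mapped <- sweep(posed_lig %*% t(fit$rotation), 2, fit$translation, "+")
    sqrt(mean(rowSums((mapped - ref_lig)^2)))
  }, numeric(1))
}

#' Bundle one docking case's ranked results
#'
#' @param case_id identifier string.
#' @param scores per-pose scores in rank order is not required; poses are
#'   ranked here by increasing score (ties by original order).
#' @param rmsds per-pose ligand C-alpha RMSDs (same order as `scores`).
#' @param threshold near-native RMSD threshold in Angstrom (default 10).
#' @return a `docking_case`: list with `case_id`, `ranked` data.frame
#'   (rank, score, rmsd, near_native) and `near_native_rank` (best rank with
#'   RMSD at or below the threshold, or NA).
#' @export
docking_case <- function(case_id, scores, rmsds, threshold = 10) {
  stopifnot(length(scores) == length(rmsds))
  ord <- order(scores)
  ranked <- data.frame(rank = seq_along(ord), score = scores[ord],
                       rmsd = rmsds[ord],
                       near_native = rmsds[ord] <= threshold)
  nn <- which(ranked$near_native)
  structure(list(case_id = case_id, ranked = ranked,
                 near_native_rank = if (length(nn)) nn[1] else NA_integer_),
            class = "docking_case")
}

#' Success rate over a set of docking cases
#'
#' Percentage of cases with at least one near-native pose ranked within the
#' top `top_n`.
#'
#' @param cases list of [docking_case()] objects.
#' @param top_n rank cutoff (>= 1).
#' @return percentage in `[0, 100]`.
#' @export
success_rate <- function(cases, top_n) {
  if (length(cases) == 0L) stop("no docking cases")
  if (top_n < 1) stop("top_n must be >= 1")
  hits <- vapply(cases, function(cs) {
    !is.na(cs$near_native_rank) && cs$near_native_rank <= top_n
  }, logical(1))
  100 * mean(hits)
}

#' Concentration of near-native solutions in one case
#'
#' Fraction of poses with RMSD at or below the threshold; a key driver of
#' downstream scoring success.
#'
#' @param case a [docking_case()].
#' @param threshold RMSD threshold in Angstrom (default 10).
#' @return fraction in `[0, 1]`.
#' @export
nn_concentration <- function(case, threshold = 10) {
  if (nrow(case$ranked) == 0L) stop("case has no poses")
  mean(case$ranked$rmsd <= threshold, na.rm = TRUE)
}

#' FFT grid size and size class of a docking case
#'
#' `s = ceiling(2 * (max_radius_rec + max_radius_lig) / delta)`: the number
#' of grid cells an FFT docking box of spacing `delta` needs to span both
#' diameters. Cases are classed small (`s < 150`), large (`s > 250`) or
#' medium.
#'
#' @param receptor,ligand annotated [protein_structure]s.
#' @param delta FFT grid spacing in Angstrom (default 0.7).
#' @return list with integer `s` and `class` in `c("small","medium","large")`.
#' @export
fft_grid_size_class <- function(receptor, ligand, delta = 0.7) {
  if (delta <= 0) stop("delta must be positive")
  s <- as.integer(ceiling(2 * (receptor$max_radius + ligand$max_radius) / delta))
  cls <- if (s < 150) "small" else if (s > 250) "large" else "medium"
  list(s = s, class = cls)
}

#' Merge two ranked pose sets with score weighting
#'
#' Multiplies the scores of `set_a` by `weight_a`, takes the union and sorts
#' ascending by score; ties are broken stably with `set_b` first, then by
#' original rank within each set.
#'
#' @param set_a,set_b data.frames with a `score` column (rows in rank order).
#' @param weight_a multiplier applied to the scores of `set_a` (default 0.5).
#' @return merged data.frame with columns of the inputs plus `source`
#'   ("a"/"b") and a new `rank`.
#' @export
combine_ranked_sets <- function(set_a, set_b, weight_a = 0.5) {
  a <- as.data.frame(set_a); b <- as.data.frame(set_b)
  a$score <- a$score * weight_a
  a$source <- "a"; b$source <- "b"
  a$orig_rank <- seq_len(nrow(a)); b$orig_rank <- seq_len(nrow(b))
  cols <- intersect(names(a), names(b))
  m <- rbind(a[, cols, drop = FALSE], b[, cols, drop = FALSE])
  ord <- order(m$score, match(m$source, c("b", "a")), m$orig_rank)
  m <- m[ord, , drop = FALSE]
  m$rank <- seq_len(nrow(m))
  rownames(m) <- NULL
  m
}
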
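# Residue-based desolvation: fast pose scoring from precomputed per-residue
# solvation contributions.
#
# On each unbound molecule, every residue i gets a contribution
#   E_i = sum over its heavy atoms of sigma(atom) * ASA(atom),
# computed once. A pose is then scored as the sum of (E_i + E_j) over all
# intermolecular residue pairs (i, j) with at least one heavy-atom pair
# within 8 A. Residues in several pairs are counted once per pair: this
# over-counting is deliberate, since it tracks the atom-based buried-surface
# desolvation better than counting each interface residue once, while only
# distances (no ASA) are recomputed per pose.

#' Default atomic solvation parameters
#'
#' Element-keyed atomic solvation parameters (energy units per Angstrom^2)
#' with ICM-style signs: apolar carbon and sulfur favour burial (positive
#' contribution to the unbound-surface term), polar nitrogen and oxygen
#' oppose it. The table is a documented, replaceable default; any element
#' missing from it uses the `default` entry.
#'
#' @return named numeric vector with a `default` entry.
#' @export
default_sigma <- function() {
  c(C = 0.012, N = -0.060, O = -0.030, S = 0.021, default = 0)
}

lookup_sigma <- function(elements, sigma = default_sigma()) {
  s <- sigma[elements]
  miss <- is.na(s)
  if (any(miss)) {
    if (!"default" %in% names(sigma))
      stop("no solvation parameter (and no default) for atom class: ",
           paste(unique(elements[miss]), collapse = ", "))
    s[miss] <- sigma[["default"]]
  }
  unname(s)
}

#' Per-residue desolvation contributions of an unbound molecule
#'
#' `E_i = sum over the residue's heavy atoms of sigma(element) * ASA(atom)`,
#' using the unbound per-atom accessible areas from [annotate()]. Computed
#' once per molecule and reused for every pose.
#'
#' @param structure annotated [protein_structure].
#' @param sigma named per-element solvation parameter table, see
#'   [default_sigma()].
#' @return named numeric vector keyed by `chain|resno|ins` residue keys,
#'   carrying class `residue_desolvation_table`.
#' @export
residue_energies <- function(structure, sigma = default_sigma()) {
  stopifnot(inherits(structure, "protein_structure"))
  if (!isTRUE(structure$annotated)) stop("structure must be annotated")
  contrib <- lookup_sigma(structure$atoms$element, sigma) * structure$asa
  keys <- residue_keys(structure)
  e <- tapply(contrib, factor(keys, levels = unique(keys)), sum)
  out <- as.numeric(e)
  names(out) <- names(e)
  class(out) <- "residue_desolvation_table"
  out
}

# Residue centroids and enclosing radii, used to prune the pair search.
residue_geometry <- function(structure) {
  keys <- residue_keys(structure)
  f <- factor(keys, levels = unique(keys))
  X <- coords(structure)
  cx <- tapply(X[, 1], f, mean)
  cy <- tapply(X[, 2], f, mean)
  cz <- tapply(X[, 3], f, mean)
  ctr <- cbind(cx, cy, cz)
  rad <- vapply(levels(f), function(k) {
    idx <- which(keys == k)
    sqrt(max(rowSums(sweep(X[idx, , drop = FALSE], 2, ctr[k, ])^2)))
  }, numeric(1))
  list(keys = levels(f), centroids = ctr, radii = rad,
       atom_index = split(seq_len(nrow(X)), f))
}

# Exact residue contact pairs between two coordinate sets.
contact_pairs_coords <- function(Xr, gr, Xl, gl, cutoff) {
  # prune: centroid distance minus both enclosing radii must be <= cutoff
  D <- sqrt(outer(rowSums(gr$centroids^2), rowSums(gl$centroids^2), "+") -
              2 * tcrossprod(gr$centroids, gl$centroids))
  cand <- which(D - outer(gr$radii, gl$radii, "+") <= cutoff, arr.ind = TRUE)
  if (nrow(cand) == 0L)
    return(data.frame(rec_key = character(0), lig_key = character(0),
                      stringsAsFactors = FALSE))
  keep <- logical(nrow(cand))
  cut2 <- cutoff^2
  for (q in seq_len(nrow(cand))) {
    ia <- gr$atom_index[[cand[q, 1]]]
    ja <- gl$atom_index[[cand[q, 2]]]
    A <- Xr[ia, , drop = FALSE]
    B <- Xl[ja, , drop = FALSE]
    d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
    keep[q] <- min(d2) <= cut2
  }
  cand <- cand[keep, , drop = FALSE]
  ord <- order(cand[, 1], cand[, 2])
  cand <- cand[ord, , drop = FALSE]
  data.frame(rec_key = gr$keys[cand[, 1]], lig_key = gl$keys[cand[, 2]],
             stringsAsFactors = FALSE)
}

#' Intermolecular residue contact pairs of a pose
#'
#' Realizes the pose and returns every (receptor residue, ligand residue)
#' pair with at least one heavy-atom pair within `cutoff` (inclusive). The
#' search is pruned with residue centroids and enclosing radii but is exact:
#' it returns precisely the brute-force set.
#'
#' @param receptor,ligand annotated [protein_structure]s.
#' @param poses a `pose_set` with `r` assigned.
#' @param k row index.
#' @param cutoff distance cutoff in Angstrom (default 8).
#' @return data.frame with columns `rec_key`, `lig_key` (residue keys
#'   `chain|resno|ins`), no duplicate rows.
#' @export
contact_pairs <- function(receptor, ligand, poses, k, cutoff = 8.0) {
  rl <- realize_pose(receptor, ligand, poses, k)
  contact_pairs_coords(coords(rl$receptor), residue_geometry(rl$receptor),
                       coords(rl$ligand), residue_geometry(rl$ligand),
                       cutoff)
}

#' Residue-based desolvation energy of one pose
#'
#' Sum over all contact pairs (i, j) of `E_i + E_j`. A residue in k pairs
#' contributes k times its precomputed energy; set `count_once = TRUE` for
#' the variant where every interface residue contributes once regardless of
#' its pair count (used only as a comparison baseline).
#'
#' @param rec_table,lig_table [residue_energies()] tables of the two
#'   molecules.
#' @param pairs a contact pair data.frame from [contact_pairs()].
#' @param count_once logical; count each interface residue once.
#' @return desolvation energy (same units as the sigma table times A^2).
#' @export
pose_desolvation <- function(rec_table, lig_table, pairs, count_once = FALSE) {
  if (nrow(pairs) == 0L) return(0)
  missing_r <- setdiff(unique(pairs$rec_key), names(rec_table))
  missing_l <- setdiff(unique(pairs$lig_key), names(lig_table))
  if (length(missing_r) || length(missing_l))
    stop("contact pair residue missing from desolvation table: ",
         paste(c(missing_r, missing_l), collapse = ", "))
  if (count_once) {
    sum(rec_table[unique(pairs$rec_key)]) + sum(lig_table[unique(pairs$lig_key)])
  } else {
    sum(rec_table[pairs$rec_key]) + sum(lig_table[pairs$lig_key])
  }
}

#' Score every pose with the residue-based desolvation energy
#'
#' Precomputes the per-residue tables and residue geometries once, then for
#' each valid pose (finite `r`) computes the contact pairs and the pair-sum
#' energy. Invalid poses keep `desolv = NA`.
#'
#' @param receptor,ligand annotated [protein_structure]s.
#' @param poses a `pose_set` with `r` filled.
#' @param sigma solvation parameter table.
#' @param cutoff contact cutoff in Angstrom.
#' @param count_once see [pose_desolvation()].
#' @return `poses` with the `desolv` column filled.
#' @export
score_poses <- function(receptor, ligand, poses, sigma = default_sigma(),
                        cutoff = 8.0, count_once = FALSE) {
  rec_table <- residue_energies(receptor, sigma)
  lig_table <- residue_energies(ligand, sigma)
  # receptor/ligand base coordinates centered for fast per-pose transforms
  Xr0 <- sweep(coords(receptor), 2, receptor$center)
  Xl0 <- sweep(coords(ligand), 2, ligand$center)
  gr0 <- residue_geometry(receptor)
  gl0 <- residue_geometry(ligand)
  gr0$centroids <- sweep(gr0$centroids, 2, receptor$center)
  gl0$centroids <- sweep(gl0$centroids, 2, ligand$center)
  out <- rep(NA_real_, nrow(poses))
  for (k in seq_len(nrow(poses))) {
    if (is.na(poses$r[k])) next
    rot <- pose_rotation(poses, k)
    Xr <- Xr0 %*% t(rot$R_rec)         # rows are (R x)^T
    Xl <- sweep(Xl0 %*% t(rot$R_lig), 2, poses$r[k] * rot$u, "+")
    gr <- gr0; gl <- gl0
    gr$centroids <- gr0$centroids %*% t(rot$R_rec)
    gl$centroids <- sweep(gl0$centroids %*% t(rot$R_lig), 2,
                          poses$r[k] * rot$u, "+")
    pairs <- contact_pairs_coords(Xr, gr, Xl, gl, cutoff)
    out[k] <- pose_desolvation(rec_table, lig_table, pairs,
                               count_once = count_once)
  }
  poses$desolv <- out
  poses
}

#' Keep the lowest-desolvation fraction of a pose set
#'
#' Retains the `k = max(1, round(fraction * M))` poses with the most
#' favourable (lowest) desolvation energy, ties broken by enumeration order
#' (lower pose_id first). Invalid (NA) poses are never retained.
#'
#' @param poses a scored `pose_set` (desolv filled for valid poses).
#' @param fraction retained fraction, `0 < fraction <= 1`.
#' @return the retained subset with an added `rank` column (1 = best).
#' @export
filter_by_desolvation <- function(poses, fraction) {
  if (nrow(poses) == 0L) stop("empty pose set")
  stopifnot(fraction > 0, fraction <= 1)
  k <- max(1L, as.integer(round(fraction * nrow(poses))))
  ord <- order(poses$desolv, poses$pose_id, na.last = TRUE)
  keep <- ord[seq_len(min(k, sum(!is.na(poses$desolv))))]
  out <- poses[keep, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  class(out) <- c("pose_set", "data.frame")
  out
}

#' Atom-based desolvation of poses (buried-surface oracle)
#'
#' The reference atom-level desolvation: `sum over all atoms of
#' sigma(atom) * (ASA_unbound - ASA_complex)`, with the complex ASA
#' recomputed on the realized pose by Shrake-Rupley. Much slower than
#' [pose_desolvation()] (it recomputes areas per pose); used to check that
#' the fast residue pair-sum tracks the buried-surface energy.
#'
#' @param receptor,ligand annotated [protein_structure]s (their stored
#'   `asa`/`sasa_points`/`probe` define the unbound reference).
#' @param poses a `pose_set` with `r` assigned.
#' @param k row indices to score (default: all rows).
#' @param sigma solvation parameter table.
#' @return numeric vector of energies, one per requested pose.
#' @export
atom_desolvation <- function(receptor, ligand, poses, k = seq_len(nrow(poses)),
                             sigma = default_sigma()) {
  stopifnot(isTRUE(receptor$annotated), isTRUE(ligand$annotated))
  if (receptor$sasa_points != ligand$sasa_points ||
      receptor$probe != ligand$probe)
    stop("receptor and ligand must be annotated with the same probe and point count")
  np <- receptor$sasa_points
  probe <- receptor$probe
  s_all <- c(lookup_sigma(receptor$atoms$element, sigma),
             lookup_sigma(ligand$atoms$element, sigma))
  asa_unbound <- c(receptor$asa, ligand$asa)
  radii <- c(receptor$atoms$radius, ligand$atoms$radius)
  vapply(k, function(kk) {
    rl <- realize_pose(receptor, ligand, poses, kk)
    X <- rbind(coords(rl$receptor), coords(rl$ligand))
    asa_cplx <- shrake_rupley(X, radii, probe = probe, n_points = np)
    sum(s_all * (asa_unbound - asa_cplx))
  }, numeric(1))
}
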
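# Optimal center-to-center separation from grid-projected surfaces.
#
# For one interaction direction, each molecule is reduced to a 15 x 17
# triangular-lattice "distance-to-surface" matrix: at every lattice point the
# signed axial height of the farthest surface backbone atom inside a
# cylinder of radius lambda/2 is recorded (NA when the cylinder is empty).
# Summing the two matrices cell by cell (the ligand grid uses the mirrored
# in-plane basis so corresponding cells share an axis-parallel line) and
# taking the maximum over cells where both heights exist gives the
# separation at which the projected surfaces touch; a fixed margin epsilon
# is added for the side-chain volume.
#
# Grids are computed in each molecule's native frame using the pre-images of
# the interaction direction and basis under the pose rotations, so molecular
# coordinates are never transformed during sampling.

#' Grid parameters for the contact-distance computation
#'
#' Defaults: 17 x 15 cells, lattice step `lambda` = 3.5 A, side-chain margin
#' `epsilon` = 4.7 A, cylinder radius `lambda / 2`.
#'
#' @param n_cols,n_rows lattice size.
#' @param lambda lattice step in Angstrom.
#' @param epsilon additive side-chain margin in Angstrom.
#' @return a `grid_params` list.
#' @export
grid_params <- function(n_cols = 17L, n_rows = 15L, lambda = 3.5,
                        epsilon = 4.7) {
  stopifnot(n_cols >= 1, n_rows >= 1, lambda > 0, epsilon >= 0)
  structure(list(n_cols = as.integer(n_cols), n_rows = as.integer(n_rows),
                 lambda = lambda, epsilon = epsilon,
                 cylinder_radius = lambda / 2),
            class = "grid_params")
}

#' Deterministic orthonormal basis of the plane perpendicular to v
#'
#' `v_a = normalize(e x v)` where `e` is the coordinate axis least aligned
#' with `v` (ties broken x, then y, then z), and `v_b = v x v_a`, so that
#' `(v_a, v_b, v)` is a right-handed orthonormal triple.
#'
#' @param v unit 3-vector.
#' @return list with unit 3-vectors `v_a` and `v_b`.
#' @export
orthobasis <- function(v) {
  if (abs(vec_norm(v) - 1) > 1e-6) stop("orthobasis: v is not a unit vector")
  e_idx <- which.min(abs(v))[1]
  e <- c(0, 0, 0); e[e_idx] <- 1
  v_a <- unitize(pracma_cross(e, v))
  v_b <- pracma_cross(v, v_a)
  list(v_a = v_a, v_b = v_b)
}

#' In-plane offsets of the triangular lattice
#'
#' Columns are spaced `lambda` along the first basis vector, rows
#' `lambda * sqrt(3)/2` along the second, odd rows shifted by `lambda / 2`;
#' the lattice is centered so its centroid sits at the in-plane origin.
#'
#' @param params a [grid_params()] list.
#' @return (n_rows * n_cols) x 2 matrix of (a, b) offsets in Angstrom, in
#'   row-major order (row index varies slowest); rows/cols recorded in
#'   attributes `i` and `j`.
#' @export
lattice_points <- function(params = grid_params()) {
  i <- rep(seq_len(params$n_rows), each = params$n_cols)   # rows
  j <- rep(seq_len(params$n_cols), times = params$n_rows)  # cols
  oa <- (j - 1) * params$lambda + ifelse(i %% 2 == 0, params$lambda / 2, 0)
  ob <- (i - 1) * params$lambda * sqrt(3) / 2
  off <- cbind(a = oa - mean(oa), b = ob - mean(ob))
  attr(off, "i") <- i
  attr(off, "j") <- j
  off
}

new_surface_grid <- function(heights, direction, basis, origin, params) {
  structure(list(heights = heights, direction = direction, basis = basis,
                 origin = origin, params = params),
            class = "surface_grid")
}

#' Project a molecular surface onto a lattice of axial heights
#'
#' For each lattice point `g` (3-D position `center + a*v_a + b*v_b`), the
#' surface backbone atoms whose lateral distance to the line through `g`
#' along `direction` is less than the cylinder radius are collected; the
#' height of the cell is the maximum signed axial projection
#' `(atom - g) . direction` over those atoms, or NA when the cylinder is
#' empty. Negative heights are legitimate (concave faces behind the center).
#'
#' @param structure annotated [protein_structure] with at least one surface
#'   backbone atom.
#' @param direction unit 3-vector pointing toward the docking partner.
#' @param basis list with `v_a`, `v_b` spanning the perpendicular plane
#'   (defaults to [orthobasis()] of `direction`); the triple need not be
#'   right-handed with `direction` - the ligand-side grid reuses the
#'   receptor's in-plane basis while projecting along `-direction`.
#' @param params a [grid_params()] list.
#' @param center plane origin; defaults to the structure's geometric center.
#' @return a `surface_grid` with an `n_rows x n_cols` `heights` matrix.
#' @export
project_surface <- function(structure, direction, basis = NULL,
                            params = grid_params(), center = NULL) {
  stopifnot(inherits(structure, "protein_structure"))
  if (!isTRUE(structure$annotated)) stop("structure must be annotated")
  if (abs(vec_norm(direction) - 1) > 1e-6)
    stop("direction must be a unit vector")
  if (is.null(basis)) basis <- orthobasis(direction)
  ok <- abs(sum(basis$v_a * direction)) < 1e-6 &&
    abs(sum(basis$v_b * direction)) < 1e-6 &&
    abs(sum(basis$v_a * basis$v_b)) < 1e-6
  if (!ok) stop("basis is not orthogonal to the projection direction")
  if (is.null(center)) center <- structure$center
  sb <- structure$surface_backbone
  if (sum(sb) == 0L)
    stop("structure has no surface backbone atoms; cannot project")
  X <- sweep(coords(structure)[sb, , drop = FALSE], 2, center)
  a <- as.vector(X %*% basis$v_a)
  b <- as.vector(X %*% basis$v_b)
  ax <- as.vector(X %*% direction)
  off <- lattice_points(params)
  r2 <- params$cylinder_radius^2
  d2 <- outer(a, off[, 1], "-")^2 + outer(b, off[, 2], "-")^2
  hm <- matrix(ax, nrow(d2), ncol(d2))
  hm[d2 >= r2] <- -Inf
  h <- apply(hm, 2, max)
  h[!is.finite(h)] <- NA_real_
  heights <- matrix(h, params$n_rows, params$n_cols, byrow = TRUE)
  new_surface_grid(heights, direction, basis, center, params)
}

#' Optimal separation from two projected-surface grids
#'
#' `r = max over cells with both heights non-null of (h_rec + h_lig) +
#' epsilon`. Returns NA when no cell has both heights (the orientation has
#' no inter-surface column through the grid and cannot be scored).
#'
#' @param rec_grid,lig_grid `surface_grid`s with identical lattice
#'   dimensions.
#' @param params a [grid_params()] list supplying `epsilon`.
#' @return center-to-center separation in Angstrom, or `NA_real_`.
#' @export
optimal_separation <- function(rec_grid, lig_grid, params = grid_params()) {
  if (!all(dim(rec_grid$heights) == dim(lig_grid$heights)))
    stop("grids have different lattice dimensions")
  s <- rec_grid$heights + lig_grid$heights
  if (all(is.na(s))) return(NA_real_)
  max(s, na.rm = TRUE) + params$epsilon
}

# Direction and in-plane basis of each grid in the molecule's native frame.
#
# The in-plane basis is anchored in the RECEPTOR's body frame: it is the
# deterministic orthobasis of the receptor-native interaction direction
# R_rec^T u, carried into the world by R_rec. This makes the separation
# exactly invariant under a rigid motion of the whole problem (both
# rotations and u rotated together), which a basis derived from u alone
# would not be.
#
# The posed ligand is projected along -u with the SAME in-plane basis as the
# receptor, so that cell (i,j) of both height matrices samples the same
# in-plane world offset and the element-wise matrix sum pairs cells on a
# common axis-parallel line. In each molecule's native frame the direction
# and basis are the R^T pre-images of the world vectors.
native_frames <- function(rot) {
  d_rec <- as.vector(crossprod(rot$R_rec, rot$u))
  b <- orthobasis(d_rec)
  A <- crossprod(rot$R_lig, rot$R_rec)   # R_lig^T R_rec
  list(
    rec = list(direction = d_rec, basis = b),
    lig = list(direction = as.vector(crossprod(rot$R_lig, -rot$u)),
               basis = list(v_a = as.vector(A %*% b$v_a),
                            v_b = as.vector(A %*% b$v_b))))
}

# The same basis expressed in the world (posed) frame.
world_basis <- function(rot, nf) {
  list(v_a = as.vector(rot$R_rec %*% nf$rec$basis$v_a),
       v_b = as.vector(rot$R_rec %*% nf$rec$basis$v_b))
}

#' Fill the optimal separation of every pose
#'
#' Computes, for each pose, the receptor and ligand surface grids in the
#' molecules' native frames (using the pre-images of the interaction
#' direction and in-plane basis under the pose rotations) and their summed
#' maximum plus `epsilon`. Receptor grids are cached per receptor direction;
#' for the RRR method ligand grids are cached per (ligand point, twist)
#' pair, since they do not depend on the receptor direction. Poses whose
#' grids share no doubly-occupied cell are flagged invalid (`r = NA`) and
#' counted.
#'
#' @param receptor,ligand annotated [protein_structure]s.
#' @param poses a `pose_set`.
#' @param params a [grid_params()] list.
#' @return `poses` with `r` filled; the number of invalid poses is stored in
#'   `attr(poses, "n_invalid")`.
#' @export
compute_separations <- function(receptor, ligand, poses,
                                params = grid_params()) {
  n <- nrow(poses)
  r_out <- rep(NA_real_, n)
  rec_cache <- new.env(parent = emptyenv())
  lig_cache <- new.env(parent = emptyenv())
  frame_key <- function(fr) {
    paste(signif(c(fr$direction, fr$basis$v_a, fr$basis$v_b), 12),
          collapse = ",")
  }
  for (k in seq_len(n)) {
    rot <- pose_rotation(poses, k)
    nf <- native_frames(rot)
    # grids are cached by their native-frame geometry; for RRR the ligand
    # frame repeats across receptor directions, which is what makes the
    # native-frame formulation fast
    rkey <- frame_key(nf$rec)
    rg <- rec_cache[[rkey]]
    if (is.null(rg)) {
      rg <- project_surface(receptor, nf$rec$direction, nf$rec$basis, params)
      rec_cache[[rkey]] <- rg
    }
    lkey <- frame_key(nf$lig)
    lg <- lig_cache[[lkey]]
    if (is.null(lg)) {
      lg <- project_surface(ligand, nf$lig$direction, nf$lig$basis, params)
      # unbounded only for frames that actually repeat (RRR); RRT/TRR ligand
      # frames are pose-specific, so cap the cache to bound memory
      if (length(lig_cache) < 20000L) lig_cache[[lkey]] <- lg
    }
    r_out[k] <- optimal_separation(rg, lg, params)
  }
  n_invalid <- sum(is.na(r_out))
  if (n_invalid > 0)
    message("compute_separations: ", n_invalid, " of ", n,
            " poses had no overlapping surface columns and were flagged invalid")
  poses$r <- r_out
  attr(poses, "n_invalid") <- n_invalid
  poses
}

#' Optimal separation of one pose computed in the world frame
#'
#' Validation path with no native-frame optimization: the pose rotations are
#' applied to the atomic coordinates explicitly and both grids are computed
#' in the posed (world) frame along `u`. Used to cross-check
#' [compute_separations()].
#'
#' @param receptor,ligand annotated [protein_structure]s.
#' @param poses a `pose_set`.
#' @param k row index.
#' @param params a [grid_params()] list.
#' @return separation in Angstrom, or `NA_real_`.
#' @export
separation_worldframe <- function(receptor, ligand, poses, k,
                                  params = grid_params()) {
  rot <- pose_rotation(poses, k)
  basis0 <- world_basis(rot, native_frames(rot))
  rec <- transform_structure(receptor, rot$R_rec,
                             -as.vector(rot$R_rec %*% receptor$center))
  lig <- transform_structure(ligand, rot$R_lig,
                             -as.vector(rot$R_lig %*% ligand$center))
  rg <- project_surface(rec, rot$u, basis0, params, center = c(0, 0, 0))
  lg <- project_surface(lig, -rot$u, basis0, params, center = c(0, 0, 0))
  optimal_separation(rg, lg, params)
}

#' Render a surface grid as text
#'
#' One row per lattice row; null cells print as ".".
#'
#' @param grid a `surface_grid`.
#' @return character vector, one element per row.
#' @export
format_grid <- function(grid) {
  apply(grid$heights, 1, function(row) {
    paste(ifelse(is.na(row), "   .  ", sprintf("%6.1f", row)), collapse = " ")
  })
}
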
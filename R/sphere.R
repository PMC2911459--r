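# Approximately uniform point distributions on the unit sphere.
#
# Small point counts use a multi-start local minimization of the Coulomb
# (Thomson) energy sum 1/|p_i - p_j|; large counts use a deterministic
# golden-ratio generalized spiral whose offset latitude lattice avoids the
# pole crowding of the classical spiral.

# Golden-ratio spiral on the unit sphere: latitudes at the midpoints of n
# equal-area bands, longitudes advanced by the golden angle.
spiral_points <- function(n) {
  if (n == 1L) return(matrix(c(0, 0, 1), 1, 3))
  k <- seq_len(n)
  h <- -1 + (2 * k - 1) / n
  st <- sqrt(pmax(0, 1 - h^2))
  phi <- pi * (3 - sqrt(5)) * (k - 1)
  cbind(st * cos(phi), st * sin(phi), h)
}

# Coulomb energy and its projected (tangent-space) gradient for points
# parameterized as unconstrained 3n coordinates that are normalized on use.
thomson_objective <- function(x, n) {
  X <- matrix(x, n, 3)
  r <- sqrt(rowSums(X^2))
  P <- X / r
  D <- as.matrix(stats::dist(P))
  diag(D) <- Inf
  E <- sum(1 / D[upper.tri(D)])
  W <- 1 / (D^3)
  G <- matrix(0, n, 3)
  for (j in 1:3) {
    G[, j] <- -rowSums(outer(P[, j], P[, j], "-") * W)
  }
  Gt <- (G - P * rowSums(G * P)) / r
  list(value = E, gradient = as.vector(Gt))
}

thomson_points <- function(n, seed = 1L, n_starts = 4L, maxit = 2000L) {
  f <- function(x) thomson_objective(x, n)$value
  g <- function(x) thomson_objective(x, n)$gradient
  starts <- list(spiral_points(n))
  rs <- local_rng(seed, {
    lapply(seq_len(n_starts), function(i) {
      X <- matrix(stats::rnorm(3 * n), n, 3)
      X / sqrt(rowSums(X^2))
    })
  })
  starts <- c(starts, rs)
  best <- NULL
  for (X0 in starts) {
    o <- stats::optim(as.vector(X0), f, g, method = "BFGS",
                      control = list(maxit = maxit, reltol = 1e-14))
    if (is.null(best) || o$value < best$value) best <- o
  }
  X <- matrix(best$par, n, 3)
  X / sqrt(rowSums(X^2))
}

# Evaluate an expression under a temporary, seeded RNG state.
local_rng <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = .GlobalEnv)) {
    get(".Random.seed", envir = .GlobalEnv)
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = .GlobalEnv))
        rm(".Random.seed", envir = .GlobalEnv)
    } else assign(".Random.seed", old, envir = .GlobalEnv)
  })
  set.seed(seed)
  expr
}

new_sphere_point_set <- function(points, resolution = NA_real_,
                                 method_used = "geometric", seed = NA_integer_,
                                 index = seq_len(nrow(points)),
                                 parent_n = nrow(points)) {
  structure(list(points = points, n = nrow(points), resolution = resolution,
                 method_used = method_used, seed = seed,
                 index = index, parent_n = parent_n),
            class = "sphere_point_set")
}

#' Number of sampling points for a target resolution
#'
#' Converts the expanded-surface area of a molecule into the number of
#' vertices of an equilateral triangular mesh with edge length `rho` tiling
#' that area: each vertex owns an area of `(sqrt(3)/2) * rho^2`, so
#' `N = max(4, round(2 * A / (sqrt(3) * rho^2)))`.
#'
#' @param structure an annotated [protein_structure] (needs `expanded_area`).
#' @param rho sampling resolution in Angstrom (> 0); intuitively, the spacing
#'   between sampled partner-center positions on the expanded surface.
#' @return integer point count N (at least 4).
#' @export
points_for_resolution <- function(structure, rho) {
  if (!is.numeric(rho) || length(rho) != 1L || rho <= 0)
    stop("rho must be a positive number")
  stopifnot(inherits(structure, "protein_structure"))
  if (is.null(structure$expanded_area))
    stop("structure must be annotated (expanded_area missing); run annotate()")
  max(4L, as.integer(round(2 * structure$expanded_area / (sqrt(3) * rho^2))))
}

#' Distribute n points approximately uniformly on the unit sphere
#'
#' For `n <= 150` the points minimize the Coulomb energy
#' `sum_{i<j} 1/|p_i - p_j|` via a deterministic multi-start BFGS
#' (starts: golden-spiral configuration plus seeded random configurations).
#' For `n > 150` a deterministic golden-ratio generalized spiral is used
#' directly (seed-independent).
#'
#' @param n number of points (>= 1).
#' @param seed integer seed controlling the optimizer restarts.
#' @return a `sphere_point_set`: list with `points` (n x 3 matrix of unit
#'   rows), `n`, `resolution`, `method_used` ("minimized" or "geometric"),
#'   `seed`, original `index`, and `parent_n`.
#' @export
distribute_points <- function(n, seed = 1L) {
  if (!is.numeric(n) || length(n) != 1L || n < 1) stop("n must be >= 1")
  n <- as.integer(n)
  if (n <= 150L) {
    pts <- thomson_points(n, seed = seed)
    new_sphere_point_set(pts, method_used = "minimized", seed = as.integer(seed))
  } else {
    new_sphere_point_set(spiral_points(n), method_used = "geometric",
                         seed = as.integer(seed))
  }
}

#' Wrap an explicit point matrix as a sphere point set
#'
#' For user-supplied direction sets (e.g. symmetric polyhedra in tests or
#' externally computed distributions). Rows are normalized to unit length.
#'
#' @param points n x 3 matrix of directions.
#' @return a `sphere_point_set` with `method_used = "explicit"`.
#' @export
as_sphere_point_set <- function(points) {
  points <- as.matrix(points)
  stopifnot(ncol(points) == 3L, nrow(points) >= 1L)
  new_sphere_point_set(points / sqrt(rowSums(points^2)),
                       method_used = "explicit")
}

as_point_matrix <- function(points) {
  if (inherits(points, "sphere_point_set")) return(points$points)
  if (is.matrix(points) && ncol(points) == 3L) return(points)
  stop("points must be a sphere_point_set or an n x 3 matrix")
}

#' Coulomb energy of a point configuration
#'
#' `sum_{i<j} 1 / |p_i - p_j|`, the electrostatic potential energy of unit
#' charges at the points (the Thomson-problem objective).
#'
#' @param points a `sphere_point_set` or n x 3 matrix, n >= 2.
#' @return dimensionless energy.
#' @export
coulomb_energy <- function(points) {
  P <- as_point_matrix(points)
  if (nrow(P) < 2L) stop("need at least 2 points")
  d <- stats::dist(P)
  if (any(d < 1e-12)) stop("coincident points: Coulomb energy is infinite")
  sum(1 / d)
}

#' Minimum pairwise angular separation
#'
#' @param points a `sphere_point_set` or n x 3 matrix of unit vectors, n >= 2.
#' @return smallest angle between any two points, in degrees.
#' @export
min_angular_spacing <- function(points) {
  P <- as_point_matrix(points)
  if (nrow(P) < 2L) stop("need at least 2 points")
  G <- tcrossprod(P)
  diag(G) <- -2
  acos(max(-1, min(1, max(G[upper.tri(G)])))) * 180 / pi
}

#' Export a point set as plain-text xyz triples
#'
#' @param points a `sphere_point_set` or n x 3 matrix.
#' @param path output file; one whitespace-separated `x y z` triple per line.
#' @return `path`, invisibly.
#' @export
write_points_xyz <- function(points, path) {
  P <- as_point_matrix(points)
  utils::write.table(format(P, digits = 17, trim = TRUE), path,
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
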
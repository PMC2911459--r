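# Solvent-accessible surface area by the Shrake-Rupley point-counting
# method, with a fixed deterministic test-point sphere (golden spiral) so
# results are bit-reproducible without any RNG.

#' Van der Waals radii by element
#'
#' Bundled defaults (Angstrom): C 1.70, N 1.55, O 1.52, S 1.80, P 1.80;
#' anything else falls back to `default` (1.70). Only relative surface
#' geometry matters downstream, so the exact set is configurable.
#'
#' @return named numeric vector of radii, with a `default` entry.
#' @export
vdw_radii <- function() {
  c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80, default = 1.70)
}

lookup_radii <- function(elements, radii = vdw_radii()) {
  if (!"default" %in% names(radii))
    stop("radius table must contain a 'default' entry")
  r <- radii[elements]
  r[is.na(r)] <- radii[["default"]]
  unname(r)
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' For each atom, test points are placed on the sphere of radius
#' `radius + probe`; the accessible area is `4*pi*(radius+probe)^2` times the
#' fraction of points not buried inside any neighbouring atom's expanded
#' sphere. The test-point sphere is a deterministic golden spiral, rotated
#' with nothing: the same point set is reused for every atom.
#'
#' @param xyz n x 3 coordinate matrix (Angstrom).
#' @param radii per-atom van der Waals radii (Angstrom).
#' @param probe probe radius in Angstrom (1.4 = water; larger probes give a
#'   smoothed, "expanded" surface).
#' @param n_points test points per atom (default 960).
#' @return numeric vector of per-atom accessible areas, Angstrom^2.
#' @export
shrake_rupley <- function(xyz, radii, probe = 1.4, n_points = 960L) {
  n <- nrow(xyz)
  stopifnot(length(radii) == n, probe >= 0, n_points >= 12)
  S <- spiral_points(as.integer(n_points))
  re <- radii + probe          # expanded radii
  asa <- numeric(n)
  if (n == 1L) return(4 * pi * re^2)
  # neighbour candidates: centers closer than the sum of expanded radii
  D2 <- as.matrix(stats::dist(xyz))^2
  sq_s <- rowSums(S^2)         # all 1, kept for clarity of the expansion
  for (i in seq_len(n)) {
    thr <- (re[i] + re)^2
    nb <- which(D2[i, ] < thr & seq_len(n) != i)
    full <- 4 * pi * re[i]^2
    if (length(nb) == 0L) {
      asa[i] <- full
      next
    }
    nb <- nb[order(D2[i, nb])]      # closest occluders first: fast early exit
    pts <- sweep(S * re[i], 2, xyz[i, ], "+")
    alive <- seq_len(nrow(pts))
    # blocks of neighbours; points already buried are dropped, so deeply
    # buried atoms terminate after one block
    for (b0 in seq(1L, length(nb), by = 32L)) {
      blk <- nb[b0:min(b0 + 31L, length(nb))]
      nbx <- xyz[blk, , drop = FALSE]
      P <- pts[alive, , drop = FALSE]
      # squared distances test-point x neighbour via |p|^2+|a|^2-2 p.a
      d2 <- outer(rowSums(P^2), rowSums(nbx^2), "+") - 2 * tcrossprod(P, nbx)
      buried <- d2 < matrix(re[blk]^2, nrow(P), length(blk), byrow = TRUE)
      alive <- alive[rowSums(buried) == 0L]
      if (length(alive) == 0L) break
    }
    asa[i] <- full * length(alive) / nrow(pts)
  }
  asa
}
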
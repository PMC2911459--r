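# Shared fixtures and independent oracles, built once per test run.

.fx <- new.env(parent = emptyenv())

# Standard knob-and-socket pair (annotated) shared across test files.
shared_fixture <- function() {
  if (is.null(.fx$pair)) {
    dir <- file.path(tempdir(), "rotdock-shared-fixture")
    .fx$pair <- make_synthetic_pair(seed = 101, dir = dir)
    .fx$rec <- annotate(read_pdb(.fx$pair$receptor_path), 480L)
    .fx$lig <- annotate(read_pdb(.fx$pair$ligand_path), 480L)
    .fx$ref <- read_pdb(.fx$pair$complex_path)
  }
  list(pair = .fx$pair, rec = .fx$rec, lig = .fx$lig, ref = .fx$ref)
}

# Smaller pair for the per-pose ASA oracle (keeps Shrake-Rupley cheap).
small_fixture <- function() {
  if (is.null(.fx$spair)) {
    dir <- file.path(tempdir(), "rotdock-small-fixture")
    .fx$spair <- make_synthetic_pair(seed = 202, receptor_radius = 7,
                                     ligand_radius = 5.5, bead_spacing = 3,
                                     knob_radius = 4, dir = dir)
    .fx$srec <- annotate(read_pdb(.fx$spair$receptor_path), 240L)
    .fx$slig <- annotate(read_pdb(.fx$spair$ligand_path), 240L)
    .fx$sref <- read_pdb(.fx$spair$complex_path)
  }
  list(pair = .fx$spair, rec = .fx$srec, lig = .fx$slig, ref = .fx$sref)
}

shared_decoys <- function() {
  if (is.null(.fx$decoys)) {
    fx <- small_fixture()
    .fx$decoys <- make_decoy_set(fx$rec, fx$lig, fx$ref, n_decoys = 30L,
                                 seed = 7L, near_fraction = 0.2)
  }
  .fx$decoys
}

# Hand-formatted PDB ATOM records (independent of write_pdb).
write_tiny_pdb <- function(path, xyz, names = rep("CA", nrow(xyz)),
                           resnos = seq_len(nrow(xyz)),
                           chains = rep("A", nrow(xyz)),
                           resnames = rep("GLY", nrow(xyz)),
                           record = rep("ATOM  ", nrow(xyz))) {
  el <- substr(names, 1, 1)
  lines <- sprintf("%-6s%5d  %-3s %3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
                   record, seq_len(nrow(xyz)), names, resnames, chains,
                   resnos, xyz[, 1], xyz[, 2], xyz[, 3], el)
  writeLines(c(lines, "END"), path)
  path
}

# Dense single-atom (CA-only) spherical shell: every atom center exactly at
# the given radius, one pseudo-residue per atom.
dense_sphere_structure <- function(radius, spacing = 1.6, chain = "A",
                                   center = c(0, 0, 0), n_points = 240L) {
  n <- max(12L, round(4 * pi * radius^2 / spacing^2))
  xyz <- sweep(rotdock:::spiral_points(n) * radius, 2, center, "+")
  path <- tempfile(fileext = ".pdb")
  write_tiny_pdb(path, xyz, names = rep("CA", n), resnos = seq_len(n),
                 chains = rep(chain, n))
  annotate(read_pdb(path), n_points)
}

# Regular icosahedron vertices on the unit sphere.
icosahedron_points <- function() {
  phi <- (1 + sqrt(5)) / 2
  V <- rbind(c(0, 1, phi), c(0, -1, phi), c(0, 1, -phi), c(0, -1, -phi),
             c(1, phi, 0), c(-1, phi, 0), c(1, -phi, 0), c(-1, -phi, 0),
             c(phi, 0, 1), c(phi, 0, -1), c(-phi, 0, 1), c(-phi, 0, -1))
  V / sqrt(rowSums(V^2))
}

octahedron_points <- function() {
  rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
        c(0, 0, 1), c(0, 0, -1))
}

random_units <- function(n) {
  X <- matrix(stats::rnorm(3 * n), n, 3)
  X / sqrt(rowSums(X^2))
}

# Horn's closed-form quaternion absolute-orientation solution: independent
# oracle for the SVD-based Kabsch fit.
horn_superpose <- function(mobile, target) {
  cm <- colMeans(mobile); ct <- colMeans(target)
  A <- sweep(mobile, 2, cm); B <- sweep(target, 2, ct)
  S <- crossprod(A, B)
  N <- matrix(0, 4, 4)
  N[1, 1] <- S[1, 1] + S[2, 2] + S[3, 3]
  N[1, 2] <- N[2, 1] <- S[2, 3] - S[3, 2]
  N[1, 3] <- N[3, 1] <- S[3, 1] - S[1, 3]
  N[1, 4] <- N[4, 1] <- S[1, 2] - S[2, 1]
  N[2, 2] <- S[1, 1] - S[2, 2] - S[3, 3]
  N[2, 3] <- N[3, 2] <- S[1, 2] + S[2, 1]
  N[2, 4] <- N[4, 2] <- S[1, 3] + S[3, 1]
  N[3, 3] <- -S[1, 1] + S[2, 2] - S[3, 3]
  N[3, 4] <- N[4, 3] <- S[2, 3] + S[3, 2]
  N[4, 4] <- -S[1, 1] - S[2, 2] + S[3, 3]
  q <- eigen(N, symmetric = TRUE)$vectors[, 1]
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
                2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
                2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)),
              3, 3)
  fitted <- A %*% t(R)
  list(rotation = R, translation = as.vector(ct - R %*% cm),
       rmsd = sqrt(mean(rowSums((fitted - B)^2))))
}

# Brute-force residue contact pairs: full atom-atom distance matrix.
brute_contact_pairs <- function(rec, lig, poses, k, cutoff = 8) {
  rl <- realize_pose(rec, lig, poses, k)
  Xr <- coords(rl$receptor); Xl <- coords(rl$ligand)
  kr <- paste(rl$receptor$atoms$chain, rl$receptor$atoms$resno,
              rl$receptor$atoms$ins, sep = "|")
  kl <- paste(rl$ligand$atoms$chain, rl$ligand$atoms$resno,
              rl$ligand$atoms$ins, sep = "|")
  d2 <- outer(rowSums(Xr^2), rowSums(Xl^2), "+") - 2 * tcrossprod(Xr, Xl)
  hit <- which(d2 <= cutoff^2 + 1e-12, arr.ind = TRUE)
  pr <- unique(data.frame(rec_key = kr[hit[, 1]], lig_key = kl[hit[, 2]],
                          stringsAsFactors = FALSE))
  pr[order(match(pr$rec_key, unique(kr)), match(pr$lig_key, unique(kl))), ,
     drop = FALSE]
}

# Brute-force ASA oracle: random (seeded) test points, independent of the
# deterministic spiral used by the implementation.
brute_asa <- function(xyz, radii, probe = 1.4, n_points = 2000L, seed = 99L) {
  set.seed(seed)
  n <- nrow(xyz)
  out <- numeric(n)
  for (i in seq_len(n)) {
    P <- matrix(stats::rnorm(3 * n_points), ncol = 3)
    P <- P / sqrt(rowSums(P^2)) * (radii[i] + probe)
    P <- sweep(P, 2, xyz[i, ], "+")
    acc <- rep(TRUE, n_points)
    for (j in seq_len(n)[-i]) {
      d2 <- rowSums(sweep(P, 2, xyz[j, ])^2)
      acc <- acc & d2 >= (radii[j] + probe)^2
    }
    out[i] <- 4 * pi * (radii[i] + probe)^2 * mean(acc)
  }
  out
}
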
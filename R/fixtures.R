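# Synthetic rigid-body fixtures in PDB format.
#
# Bodies are built from pseudo-residues (one N/CA/C/O backbone cluster per
# bead site) covering a spherical surface plus a sparse interior, so the
# ASA, surface-backbone and residue-pair machinery runs on them unmodified.
# The knob_socket shape places a hemispherical knob on the ligand that seats
# into a matching socket on the receptor along +z, giving a complex with a
# known bound pose for end-to-end tests without any structure downloads.

# Offsets of the atoms around a bead site (all within 1 A): four backbone
# atoms plus one side-chain pseudo-atom whose element varies by residue
# type, so residues differ in their intrinsic solvation contribution the
# way real amino acids do.
BEAD_OFFSETS <- matrix(c(
   0.35,  0.00,  0.15,   # N
   0.00,  0.00,  0.00,   # CA
  -0.30,  0.25, -0.10,   # C
  -0.30, -0.25, -0.15,   # O
   0.40, -0.30,  0.35),  # side-chain pseudo-atom
  5, 3, byrow = TRUE,
  dimnames = list(c("N", "CA", "C", "O", "side"), NULL))

# residue types: apolar (ALA-like, C side atom), hydroxyl (SER-like, O),
# amide (ASN-like, N)
BEAD_TYPES <- data.frame(
  resname = c("ALA", "SER", "ASN"),
  side_name = c("CB", "OG", "ND2"),
  side_element = c("C", "O", "N"),
  stringsAsFactors = FALSE)

beads_to_structure <- function(beads, chain, jitter, types) {
  n <- nrow(beads)
  na <- nrow(BEAD_OFFSETS)
  xyz <- matrix(NA_real_, na * n, 3)
  for (b in seq_len(n)) {
    rows <- (na * (b - 1) + 1):(na * b)
    xyz[rows, ] <- sweep(BEAD_OFFSETS + jitter[rows, ], 2, beads[b, ], "+")
  }
  name <- as.vector(vapply(types, function(t) {
    c("N", "CA", "C", "O", BEAD_TYPES$side_name[t])
  }, character(na)))
  element <- as.vector(vapply(types, function(t) {
    c("N", "C", "C", "O", BEAD_TYPES$side_element[t])
  }, character(na)))
  atoms <- data.frame(
    serial = seq_len(na * n),
    name = name,
    resname = rep(BEAD_TYPES$resname[types], each = na),
    chain = chain,
    resno = rep(seq_len(n), each = na),
    ins = "",
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    element = element,
    is_backbone = name %in% BACKBONE_NAMES,
    radius = lookup_radii(element),
    stringsAsFactors = FALSE)
  new_protein_structure(atoms)
}

# Bead sites of one body centered at the origin.
fixture_beads <- function(shape, radius, spacing, knob_radius, gap, role) {
  n_surf <- max(8L, round(4 * pi * radius^2 / spacing^2))
  surf <- spiral_points(n_surf) * radius
  if (shape == "knob_socket") {
    if (role == "receptor") {
      # carve a socket: remove the surface cap around +z, add beads on the
      # inward-facing part of a sphere of knob_radius centered at the rim
      cos_rim <- 1 - knob_radius^2 / (2 * radius^2)
      surf <- surf[surf[, 3] < radius * cos_rim, , drop = FALSE]
      n_sock <- max(8L, round(4 * pi * knob_radius^2 / spacing^2))
      sock <- sweep(spiral_points(n_sock) * knob_radius, 2,
                    c(0, 0, radius), "+")
      sock <- sock[sqrt(rowSums(sock^2)) < radius - 0.3, , drop = FALSE]
      surf <- rbind(surf, sock)
    } else {
      # knob: remove the cap around -z, add the protruding part of a sphere
      # of knob_radius - gap centered on the surface point at -z
      rk <- knob_radius - gap
      cos_rim <- 1 - rk^2 / (2 * radius^2)
      surf <- surf[surf[, 3] > -radius * cos_rim, , drop = FALSE]
      n_knob <- max(8L, round(4 * pi * rk^2 / spacing^2))
      knob <- sweep(spiral_points(n_knob) * rk, 2, c(0, 0, -radius), "+")
      knob <- knob[sqrt(rowSums(knob^2)) > radius + 0.3, , drop = FALSE]
      surf <- rbind(surf, knob)
    }
  }
  inner_r <- radius * c(1 / 3, 2 / 3)
  interior <- do.call(rbind, lapply(inner_r, function(rr) {
    m <- max(4L, round(4 * pi * rr^2 / (2 * spacing)^2))
    spiral_points(m) * rr
  }))
  rbind(surf, interior, c(0, 0, 0))
}

#' Generate a synthetic receptor/ligand pair with a known bound pose
#'
#' Builds two rigid pseudo-protein bodies (receptor chain A, ligand chain B)
#' and their bound complex, written as PDB files. For `shape = "sphere"` the
#' bodies are plain spheres touching along +z at a surface gap of `gap`
#' Angstrom; for `shape = "knob_socket"` the ligand carries a hemispherical
#' knob that seats into a matching receptor socket along +z. The seed
#' controls small deterministic atom jitters, so different seeds give
#' different (byte-reproducible) structures with identical bound geometry.
#'
#' @param shape `"knob_socket"` or `"sphere"`.
#' @param receptor_radius,ligand_radius body radii in Angstrom.
#' @param bead_spacing spacing of the pseudo-residue bead lattice, Angstrom
#'   (1.5 to 4).
#' @param seed integer seed.
#' @param dir output directory for `receptor.pdb`, `ligand.pdb`,
#'   `complex.pdb`.
#' @param knob_radius socket sphere radius in Angstrom (knob_socket only).
#' @param gap bound-state surface gap in Angstrom.
#' @return list with `receptor_path`, `ligand_path`, `complex_path`, the
#'   bound ligand translation `bound_translation`, and the fixture spec.
#' @export
make_synthetic_pair <- function(shape = c("knob_socket", "sphere"),
                                receptor_radius = 10, ligand_radius = 7.5,
                                bead_spacing = 2.8, seed = 1L,
                                dir = tempdir(), knob_radius = 4.5,
                                gap = 2.6) {
  shape <- match.arg(shape)
  stopifnot(receptor_radius > 0, ligand_radius > 0,
            bead_spacing >= 1.5, bead_spacing <= 4.0)
  rec_beads <- fixture_beads(shape, receptor_radius, bead_spacing,
                             knob_radius, gap, "receptor")
  lig_beads <- fixture_beads(shape, ligand_radius, bead_spacing,
                             knob_radius, gap, "ligand")
  if (nrow(rec_beads) < 4L || nrow(lig_beads) < 4L)
    stop("fixture spec produces fewer than 4 residues")
  na <- 3L * nrow(BEAD_OFFSETS)
  jit <- local_rng(as.integer(seed), {
    list(rec = matrix(stats::runif(na * nrow(rec_beads), -0.1, 0.1),
                      ncol = 3),
         lig = matrix(stats::runif(na * nrow(lig_beads), -0.1, 0.1),
                      ncol = 3),
         rec_types = sample.int(3L, nrow(rec_beads), replace = TRUE,
                                prob = c(0.5, 0.25, 0.25)),
         lig_types = sample.int(3L, nrow(lig_beads), replace = TRUE,
                                prob = c(0.5, 0.25, 0.25)))
  })
  receptor <- beads_to_structure(rec_beads, "A", jit$rec, jit$rec_types)
  ligand <- beads_to_structure(lig_beads, "B", jit$lig, jit$lig_types)
  bound_t <- c(0, 0, receptor_radius + ligand_radius + gap)
  lig_bound <- transform_structure(ligand, diag(3), bound_t)
  cplx_atoms <- rbind(receptor$atoms, lig_bound$atoms)
  cplx_atoms$serial <- seq_len(nrow(cplx_atoms))
  cplx <- new_protein_structure(cplx_atoms)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("receptor.pdb", "ligand.pdb", "complex.pdb"))
  write_pdb(receptor, paths[1])
  write_pdb(ligand, paths[2])
  write_pdb(cplx, paths[3])
  list(receptor_path = paths[1], ligand_path = paths[2],
       complex_path = paths[3], bound_translation = bound_t,
       spec = list(shape = shape, receptor_radius = receptor_radius,
                   ligand_radius = ligand_radius,
                   bead_spacing = bead_spacing, seed = as.integer(seed),
                   knob_radius = knob_radius, gap = gap))
}

empty_pose_set <- function(n) {
  poses <- data.frame(
    pose_id = seq_len(n), method = "decoy",
    i_rec = 0L, i_lig = 0L, i_twist = 0L,
    qrec_w = 1, qrec_x = 0, qrec_y = 0, qrec_z = 0,
    qlig_w = 1, qlig_x = 0, qlig_y = 0, qlig_z = 0,
    ux = 0, uy = 0, uz = 1,
    r = NA_real_, desolv = NA_real_, score = NA_real_,
    stringsAsFactors = FALSE)
  class(poses) <- c("pose_set", "data.frame")
  poses
}

#' Decoy pose set with known ligand RMSDs
#'
#' Builds `n_decoys` poses for a fixture pair: the exact bound pose at index
#' 1, a configurable fraction of near-native perturbations (small rotation
#' plus small displacement of the bound ligand, RMSD below 10 A), and random
#' contact orientations (uniform ligand rotation, uniform interaction
#' direction, separation from the grid-projection contact distance). The
#' ground-truth ligand C-alpha RMSD of every decoy is recorded in the
#' `rmsd_true` column.
#'
#' @param receptor,ligand annotated [protein_structure]s of the unbound pair.
#' @param reference [protein_structure] of the bound complex.
#' @param n_decoys number of poses (>= 2).
#' @param seed integer seed.
#' @param near_fraction fraction of near-native decoys (including the bound
#'   pose itself).
#' @param params [grid_params()] used for the random decoys' separations.
#' @return a `pose_set` with `r` assigned and an extra `rmsd_true` column.
#' @export
make_decoy_set <- function(receptor, ligand, reference, n_decoys, seed = 1L,
                           near_fraction = 0.1, params = grid_params()) {
  if (n_decoys < 2L) stop("n_decoys must be >= 2")
  stopifnot(isTRUE(receptor$annotated), isTRUE(ligand$annotated))
  # bound ligand center in the reference frame, matched by chain
  lig_chains <- unique(ligand$atoms$chain)
  ref_lig_idx <- reference$atoms$chain %in% lig_chains
  if (!any(ref_lig_idx) || all(ref_lig_idx))
    stop("reference complex must contain the ligand chains plus the receptor")
  c_lig_ref <- colMeans(coords(reference)[ref_lig_idx, , drop = FALSE])
  ref_lig_ca <- reference$atoms$name == "CA" & ref_lig_idx
  Yref <- coords(reference)[ref_lig_ca, , drop = FALSE]
  lig_ca <- ligand$atoms$name == "CA"
  X <- coords(ligand)[lig_ca, , drop = FALSE]
  if (nrow(X) != nrow(Yref))
    stop("unbound and reference ligand C-alpha counts differ")
  n_near <- max(1L, min(n_decoys, as.integer(round(near_fraction * n_decoys))))
  poses <- empty_pose_set(n_decoys)
  rmsd_true <- numeric(n_decoys)
  place <- function(k, R_lig, p) {
    # ligand rotated by R_lig about its center, center placed at p (reference
    # frame); pose frame has the receptor center at the origin
    v <- p - receptor$center
    q <- quat_from_matrix(R_lig)
    poses[k, c("qlig_w", "qlig_x", "qlig_y", "qlig_z")] <<- as.list(q)
    poses[k, c("ux", "uy", "uz")] <<- as.list(unitize(v))
    poses$r[k] <<- vec_norm(v)
    Y <- sweep(sweep(X, 2, ligand$center) %*% t(R_lig), 2, p, "+")
    rmsd_true[k] <<- sqrt(mean(rowSums((Y - Yref)^2)))
  }
  local_rng(as.integer(seed), {
    place(1L, diag(3), c_lig_ref)
    if (n_near >= 2L) {
      for (k in 2:n_near) {
        ang <- stats::runif(1, 0, 0.6)
        R <- rot_axis(stats::rnorm(3), ang)
        t_off <- stats::rnorm(3); t_off <- t_off / vec_norm(t_off) *
          stats::runif(1, 0, 2.5)
        place(k, R, c_lig_ref + t_off)
      }
    }
    if (n_decoys > n_near) {
      for (k in (n_near + 1L):n_decoys) {
        R <- random_rotation()
        u <- unitize(stats::rnorm(3))
        q <- quat_from_matrix(R)
        poses[k, c("qlig_w", "qlig_x", "qlig_y", "qlig_z")] <- as.list(q)
        poses[k, c("ux", "uy", "uz")] <- as.list(u)
      }
    }
  })
  far <- which(is.na(poses$r))
  if (length(far) > 0L) {
    sub <- compute_separations(receptor, ligand, poses[far, , drop = FALSE],
                               params)
    poses$r[far] <- sub$r
    for (k in far) {
      if (is.na(poses$r[k])) next
      rot <- pose_rotation(poses, k)
      p <- receptor$center + poses$r[k] * rot$u
      Y <- sweep(sweep(X, 2, ligand$center) %*% t(rot$R_lig), 2, p, "+")
      rmsd_true[k] <- sqrt(mean(rowSums((Y - Yref)^2)))
    }
  }
  poses$rmsd_true <- rmsd_true
  keep <- !is.na(poses$r)
  out <- poses[keep, , drop = FALSE]
  out$pose_id <- seq_len(nrow(out))
  class(out) <- c("pose_set", "data.frame")
  out
}
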
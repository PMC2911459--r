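# PDB-backed rigid bodies: parsing, surface annotation and rigid motions.
# Reading and writing go through bio3d; the structure object keeps one
# data.frame of heavy atoms plus the derived surface/geometry quantities the
# sampling, contact-distance and desolvation layers consume.

BACKBONE_NAMES <- c("N", "CA", "C", "O")

new_protein_structure <- function(atoms) {
  structure(list(atoms = atoms, asa = NULL, expanded_area = NULL,
                 center = NULL, max_radius = NULL, surface_backbone = NULL,
                 sasa_points = NULL, probe = NULL, annotated = FALSE),
            class = "protein_structure")
}

#' Atom coordinates of a structure
#' @param structure a [protein_structure].
#' @return n x 3 numeric matrix (Angstrom).
#' @export
coords <- function(structure) {
  as.matrix(structure$atoms[, c("x", "y", "z")])
}

# Element symbol from the PDB element column when present, else from the
# first letter of the atom name (digits stripped).
infer_elements <- function(elety, elesy) {
  el <- toupper(trimws(elesy))
  miss <- is.na(el) | el == ""
  if (any(miss)) {
    nm <- gsub("[0-9' ]", "", toupper(elety[miss]))
    el[miss] <- substr(nm, 1, 1)
  }
  el
}

#' Read a protein structure from a PDB file
#'
#' Parses the ATOM records of the first model; HETATM records (including
#' waters) are skipped, hydrogens are dropped and only the first alternate
#' location is kept. Derived fields (ASA, center, ...) are left unfilled
#' until [annotate()] runs.
#'
#' @param path path to a PDB file containing at least one ATOM record.
#' @param radii named per-element van der Waals radius table, see
#'   [vdw_radii()].
#' @return a `protein_structure` (unannotated).
#' @export
read_pdb <- function(path, radii = vdw_radii()) {
  if (!file.exists(path)) stop("PDB file not found: ", path)
  pdb <- tryCatch(
    bio3d::read.pdb(path, multi = FALSE, rm.alt = TRUE, verbose = FALSE),
    error = function(e) stop("failed to parse PDB file ", path, ": ",
                             conditionMessage(e)))
  at <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0L) stop("zero ATOM records in ", path)
  bad <- which(!is.finite(at$x) | !is.finite(at$y) | !is.finite(at$z))
  if (length(bad) > 0L) {
    stop("unparseable coordinate field in ", path, " at ATOM record ",
         bad[1], " (serial ", at$eleno[bad[1]], ")")
  }
  el <- infer_elements(at$elety, at$elesy)
  keep <- el != "H"
  at <- at[keep, , drop = FALSE]
  el <- el[keep]
  if (nrow(at) == 0L) stop("zero heavy-atom ATOM records in ", path)
  name <- trimws(at$elety)
  atoms <- data.frame(
    serial = at$eleno,
    name = name,
    resname = trimws(at$resid),
    chain = ifelse(is.na(at$chain), " ", at$chain),
    resno = at$resno,
    ins = ifelse(is.na(at$insert), "", at$insert),
    x = at$x, y = at$y, z = at$z,
    element = el,
    is_backbone = name %in% BACKBONE_NAMES,
    radius = lookup_radii(el, radii),
    stringsAsFactors = FALSE)
  new_protein_structure(atoms)
}

#' Annotate a structure with surface and geometry quantities
#'
#' Fills the per-atom solvent-accessible surface area (Shrake-Rupley, probe
#' 1.4 A), the expanded-surface area (same algorithm with a 14 A probe,
#' roughly the radius of gyration of a medium-sized protein, which smooths
#' out surface detail), the geometric center (unweighted heavy-atom
#' centroid), the maximum radius, and the surface-backbone flags (backbone
#' atoms N/CA/C/O with non-zero accessible area).
#'
#' @param structure a [protein_structure].
#' @param sphere_points_per_atom Shrake-Rupley test points per atom.
#' @param probe water-probe radius in Angstrom for the per-atom ASA.
#' @param expanded_probe probe radius in Angstrom for the expanded surface.
#' @return the structure with `asa`, `expanded_area`, `center`, `max_radius`
#'   and `surface_backbone` filled and `annotated = TRUE`.
#' @export
annotate <- function(structure, sphere_points_per_atom = 960L, probe = 1.4,
                     expanded_probe = 14) {
  stopifnot(inherits(structure, "protein_structure"))
  X <- coords(structure)
  r <- structure$atoms$radius
  structure$asa <- shrake_rupley(X, r, probe = probe,
                                 n_points = sphere_points_per_atom)
  structure$expanded_area <- sum(shrake_rupley(X, r, probe = expanded_probe,
                                               n_points = sphere_points_per_atom))
  structure$center <- unname(colMeans(X))
  structure$max_radius <- sqrt(max(rowSums(sweep(X, 2, structure$center)^2)))
  structure$surface_backbone <- structure$atoms$is_backbone & structure$asa > 0
  structure$sasa_points <- as.integer(sphere_points_per_atom)
  structure$probe <- probe
  structure$annotated <- TRUE
  structure
}

#' Apply a rigid motion to a structure
#'
#' Coordinates become `rotation %*% x + translation`. ASA values are carried
#' over unchanged (rigid motions preserve accessible area); center and
#' maximum radius are updated consistently.
#'
#' @param structure a [protein_structure].
#' @param rotation 3x3 proper orthonormal matrix (det +1 within 1e-6).
#' @param translation 3-vector (Angstrom).
#' @return the transformed structure.
#' @export
transform_structure <- function(structure, rotation = diag(3),
                                translation = c(0, 0, 0)) {
  stopifnot(inherits(structure, "protein_structure"))
  if (!is_rotation_matrix(rotation))
    stop("rotation must be orthonormal with determinant +1")
  X <- coords(structure) %*% t(rotation)
  X <- sweep(X, 2, translation, "+")
  structure$atoms$x <- X[, 1]
  structure$atoms$y <- X[, 2]
  structure$atoms$z <- X[, 3]
  if (!is.null(structure$center)) {
    structure$center <- as.vector(rotation %*% structure$center) + translation
    structure$max_radius <- sqrt(max(rowSums(sweep(X, 2, structure$center)^2)))
  }
  structure
}

#' Apply a uniformly random rotation about the structure's center
#'
#' Draws one Haar-uniform rotation (from a normalized Gaussian quaternion)
#' and rotates the structure about its geometric center, emulating the
#' randomized starting orientations used when benchmarking docking runs.
#' Deterministic for a fixed seed.
#'
#' @param structure an annotated [protein_structure].
#' @param seed integer seed.
#' @return the rotated structure (center unchanged).
#' @export
randomize_orientation <- function(structure, seed) {
  stopifnot(inherits(structure, "protein_structure"))
  ctr <- if (!is.null(structure$center)) structure$center else
    colMeans(coords(structure))
  R <- local_rng(as.integer(seed), random_rotation())
  transform_structure(structure, R, as.vector(ctr - R %*% ctr))
}

#' Write a structure as a PDB file
#'
#' Standard fixed-width ATOM records, coordinates to 3 decimals.
#'
#' @param structure a [protein_structure].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(structure, path) {
  stopifnot(inherits(structure, "protein_structure"))
  a <- structure$atoms
  bio3d::write.pdb(file = path,
                   xyz = as.vector(t(coords(structure))),
                   type = rep("ATOM", nrow(a)),
                   resno = a$resno,
                   resid = a$resname,
                   eleno = a$serial,
                   elety = a$name,
                   chain = a$chain,
                   insert = ifelse(a$ins == "", NA, a$ins),
                   elesy = a$element)
  invisible(path)
}

#' @export
print.protein_structure <- function(x, ...) {
  cat("protein_structure:", nrow(x$atoms), "heavy atoms,",
      length(unique(paste(x$atoms$chain, x$atoms$resno, x$atoms$ins))),
      "residues\n")
  if (x$annotated) {
    cat(sprintf("  center (%.2f, %.2f, %.2f) A, max radius %.2f A\n",
                x$center[1], x$center[2], x$center[3], x$max_radius))
    cat(sprintf("  total ASA %.1f A^2, expanded area %.1f A^2, %d surface-backbone atoms\n",
                sum(x$asa), x$expanded_area, sum(x$surface_backbone)))
  } else cat("  (not annotated)\n")
  invisible(x)
}

# "chain|resno|ins" residue keys, the unit of the desolvation tables.
residue_keys <- function(structure) {
  a <- structure$atoms
  paste(a$chain, a$resno, a$ins, sep = "|")
}
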
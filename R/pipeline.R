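# End-to-end pipeline: sampling -> contact distance -> desolvation filter ->
# (optional plug-in scoring) -> evaluation, with per-stage logging.

#' Read an interface-restraint list
#'
#' Plain-text file, one restraint per line: `chain residue_number`
#' (whitespace separated, optional insertion code as a third field). Lines
#' starting with `#` are ignored.
#'
#' @param path file path.
#' @return data.frame with columns `chain`, `resno`, `ins`.
#' @export
read_restraints <- function(path) {
  if (!file.exists(path)) stop("restraint file not found: ", path)
  ln <- trimws(readLines(path))
  ln <- ln[ln != "" & !startsWith(ln, "#")]
  if (length(ln) == 0L) stop("restraint file is empty: ", path)
  parts <- strsplit(ln, "[[:space:]]+")
  data.frame(
    chain = vapply(parts, `[`, "", 1),
    resno = as.integer(vapply(parts, `[`, "", 2)),
    ins = vapply(parts, function(p) if (length(p) >= 3) p[3] else "", ""),
    stringsAsFactors = FALSE)
}

#' Default pipeline configuration
#'
#' @return named list of defaults; see [run_pipeline()] for the meaning of
#'   each key.
#' @export
default_config <- function() {
  list(receptor = NULL, ligand = NULL, reference = NULL,
       outdir = ".", resolution = 14, method = "RRR",
       lambda = 3.5, epsilon = 4.7, contact_cutoff = 8.0,
       keep_fraction = 0.1, neighbors = 6L,
       restraints_receptor = NULL, restraints_ligand = NULL,
       seed = 1L, threshold = 10, sasa_points = 960L)
}

load_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  cfg <- utils::modifyList(default_config(), as.list(config))
  if (is.null(cfg$receptor) || is.null(cfg$ligand))
    stop("config must name receptor and ligand PDB files")
  cfg
}

stage <- function(name, expr) {
  t0 <- Sys.time()
  out <- tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  message(sprintf("[%s] done in %.1f s", name,
                  as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  out
}

#' Run the full docking pipeline
#'
#' Reads and annotates the two structures, distributes direction points at
#' the requested resolution, optionally restricts them with interface
#' restraints, enumerates poses, computes the contact separations, scores
#' with the residue-based desolvation, keeps the best `keep_fraction`, and
#' (when a reference complex is given) evaluates ligand RMSDs. Writes
#' `poses.tsv`, `filtered.tsv` and, with a reference, `report.tsv` into
#' `outdir`; partial outputs are removed if a stage fails.
#'
#' Config keys (list or YAML file path; missing keys take
#' [default_config()] values): `receptor`, `ligand` (PDB paths, required),
#' `reference` (complex PDB, optional), `outdir`, `resolution` (Angstrom),
#' `method` (RRR/RRT/TRR), `lambda`, `epsilon`, `contact_cutoff`,
#' `keep_fraction`, `neighbors`, `restraints_receptor`/`restraints_ligand`
#' (restraint file paths), `seed`, `threshold` (near-native RMSD),
#' `sasa_points`. An optional function `scorer(receptor, ligand, poses)`
#' returning one score per pose may be supplied when calling with a config
#' list; otherwise the desolvation energy is the score.
#'
#' @param config named list or path to a YAML file.
#' @return (invisibly) list with the output `paths`, per-stage `counts`, the
#'   filtered `poses` and, with a reference, the [docking_case()].
#' @export
run_pipeline <- function(config) {
  cfg <- load_config(config)
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(cfg$outdir, c("poses.tsv", "filtered.tsv", "report.tsv"))
  names(paths) <- c("poses", "filtered", "report")
  on_fail <- function() unlink(paths[file.exists(paths)])
  withCallingHandlers({
    receptor <- stage("read+annotate receptor", {
      annotate(read_pdb(cfg$receptor),
               sphere_points_per_atom = cfg$sasa_points)
    })
    ligand <- stage("read+annotate ligand", {
      annotate(read_pdb(cfg$ligand), sphere_points_per_atom = cfg$sasa_points)
    })
    params <- grid_params(lambda = cfg$lambda, epsilon = cfg$epsilon)
    p_rec <- stage("distribute receptor directions", {
      n <- points_for_resolution(receptor, cfg$resolution)
      distribute_points(n, seed = cfg$seed)
    })
    p_lig <- stage("distribute ligand directions", {
      n <- points_for_resolution(ligand, cfg$resolution)
      distribute_points(n, seed = cfg$seed + 1L)
    })
    message("directions: ", p_rec$n, " receptor, ", p_lig$n, " ligand")
    if (!is.null(cfg$restraints_receptor)) {
      p_rec <- stage("restrict receptor directions", {
        restrict_directions(p_rec, receptor,
                            read_restraints(cfg$restraints_receptor),
                            n_neighbors = cfg$neighbors)
      })
    }
    if (!is.null(cfg$restraints_ligand)) {
      p_lig <- stage("restrict ligand directions", {
        restrict_directions(p_lig, ligand,
                            read_restraints(cfg$restraints_ligand),
                            n_neighbors = cfg$neighbors)
      })
    }
    poses <- stage("generate poses", {
      generate_poses(receptor, ligand, p_rec, p_lig, method = cfg$method)
    })
    n_generated <- nrow(poses)
    poses <- stage("contact separations", {
      compute_separations(receptor, ligand, poses, params)
    })
    n_invalid <- attr(poses, "n_invalid")
    poses <- stage("desolvation scoring", {
      score_poses(receptor, ligand, poses, cutoff = cfg$contact_cutoff)
    })
    write_pose_table(poses, paths["poses"])
    filtered <- stage("desolvation filter", {
      filter_by_desolvation(poses, cfg$keep_fraction)
    })
    if (is.function(cfg$scorer)) {
      filtered$score <- stage("plug-in scoring", {
        cfg$scorer(receptor, ligand, filtered)
      })
    } else {
      filtered$score <- filtered$desolv
    }
    write_pose_table(filtered, paths["filtered"])
    counts <- list(generated = n_generated, invalid = n_invalid,
                   retained = nrow(filtered), near_native = NA_integer_)
    case <- NULL
    if (!is.null(cfg$reference)) {
      reference <- stage("read reference complex", read_pdb(cfg$reference))
      rmsds <- stage("ligand RMSD evaluation", {
        ligand_rmsd(receptor, ligand, filtered, reference)
      })
      case <- docking_case("pipeline", filtered$score, rmsds,
                           threshold = cfg$threshold)
      counts$near_native <- sum(rmsds <= cfg$threshold, na.rm = TRUE)
      report <- data.frame(pose_id = filtered$pose_id[order(filtered$score)],
                           case$ranked)
      utils::write.table(format(report, digits = 9, trim = TRUE),
                         paths["report"], sep = "\t", quote = FALSE,
                         row.names = FALSE)
    } else {
      paths <- paths[c("poses", "filtered")]
    }
    message("counts: generated=", counts$generated,
            " invalid=", counts$invalid, " retained=", counts$retained,
            " near_native=", counts$near_native)
    invisible(list(paths = paths, counts = counts, poses = filtered,
                   case = case))
  }, error = function(e) on_fail())
}
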
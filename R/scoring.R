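# Pose re-scoring through an external CNN-scorer contract. The scorer is a
# black box invoked as `<exe> -r receptor.pdb -l poses.sdf --score_only`; its
# stdout is parsed for per-pose score fields. A bundled mock scorer keeps the
# contract testable without the real binary, and a missing scorer degrades
# gracefully to unscored records.

#' External scorer command specification
#'
#' @param command executable (searched on PATH) or path to it.
#' @param args extra arguments placed before the receptor/ligand flags.
#' @param score_field stdout field name for the pose score (probability-like).
#' @param affinity_field stdout field name for the predicted pK.
#' @return a `gk_scorer` spec.
#' @export
scorer_spec <- function(command, args = character(0),
                        score_field = "CNNscore",
                        affinity_field = "CNNaffinity") {
  structure(list(command = command, args = args, score_field = score_field,
                 affinity_field = affinity_field), class = "gk_scorer")
}

#' The bundled mock scorer (deterministic, for tests and dry runs)
#' @export
mock_scorer_spec <- function() {
  scorer_spec("Rscript",
              args = system.file("scorers", "mock_scorer.R",
                                 package = "growkit"))
}

.parse_field <- function(lines, field) {
  hits <- regmatches(lines, regexpr(paste0(field, "[: ]+[-+0-9.eE]+"), lines))
  as.numeric(sub(paste0(field, "[: ]+"), "", hits))
}

#' Score selected poses with an external scorer (score-only contract)
#'
#' Poses are written to a temporary SDF and the receptor to PDB; the scorer
#' is invoked once with the `--score_only` flag and its stdout parsed for one
#' score/affinity pair per pose. Poses are never moved. If the scorer
#' executable cannot be found, records with unset scores are returned and a
#' warning is logged, so the pipeline can continue.
#'
#' @param ligand a `gk_ligand` whose ensemble has selected poses (or any
#'   ensemble subset via `indices`).
#' @param receptor a `gk_receptor`.
#' @param scorer a [scorer_spec()] (default: the bundled mock scorer).
#' @param indices pose indices to score (default: the selection order).
#' @param temperature K, used for the pK -> free energy conversion.
#' @return data.frame: pose, cnn_pose_score, cnn_affinity, dg_pred.
#' @export
score_poses <- function(ligand, receptor, scorer = mock_scorer_spec(),
                        indices = NULL, temperature = 298.15) {
  stopifnot(inherits(ligand, "gk_ligand"))
  ens <- ligand$ensemble
  if (is.null(indices)) {
    indices <- attr(ens, "selection")
    if (is.null(indices)) indices <- which(ens$flags$selected)
  }
  empty <- data.frame(pose = integer(0), cnn_pose_score = numeric(0),
                      cnn_affinity = numeric(0), dg_pred = numeric(0))
  if (length(indices) == 0) return(empty)

  unscored <- data.frame(pose = indices, cnn_pose_score = NA_real_,
                         cnn_affinity = NA_real_, dg_pred = NA_real_)
  exe <- Sys.which(scorer$command)
  if (!nzchar(exe)) {
    warning("scorer '", scorer$command,
            "' not found; returning unscored records")
    return(unscored)
  }

  lig_sdf <- tempfile(fileext = ".sdf")
  rec_pdb <- tempfile(fileext = ".pdb")
  on.exit(unlink(c(lig_sdf, rec_pdb)))
  mol_write_sdf(ligand$mol, lig_sdf, coords_list = ens$coords[indices])
  receptor_write_pdb(receptor, rec_pdb)

  res <- suppressWarnings(system2(
    exe, c(scorer$args, "-r", rec_pdb, "-l", lig_sdf, "--score_only"),
    stdout = TRUE, stderr = TRUE))
  status <- attr(res, "status")
  if (!is.null(status) && status != 0) {
    warning("scorer exited with status ", status, "; raw output retained")
    attr(unscored, "raw_output") <- res
    return(unscored)
  }
  scores <- .parse_field(res, scorer$score_field)
  affinities <- .parse_field(res, scorer$affinity_field)
  if (length(scores) != length(indices) ||
      length(affinities) != length(indices)) {
    warning("scorer output parse error: expected ", length(indices),
            " poses, got ", length(scores), "/", length(affinities),
            " fields; raw output retained")
    attr(unscored, "raw_output") <- res
    return(unscored)
  }
  data.frame(pose = indices, cnn_pose_score = scores,
             cnn_affinity = affinities,
             dg_pred = pk_to_dg(affinities, temperature))
}

#' Score an SDF of poses against a receptor PDB on disk
#'
#' File-level variant of [score_poses()] for command-line use: invokes the
#' scorer once on the given files and parses one record per SDF pose.
#'
#' @param receptor_pdb path to the receptor PDB.
#' @param poses_sdf path to a multi-record SDF of poses.
#' @param scorer a [scorer_spec()].
#' @param temperature K.
#' @return data.frame: pose, cnn_pose_score, cnn_affinity, dg_pred.
#' @export
score_sdf_file <- function(receptor_pdb, poses_sdf,
                           scorer = mock_scorer_spec(),
                           temperature = 298.15) {
  n_poses <- length(grep("^\\$\\$\\$\\$",
                         readLines(poses_sdf, warn = FALSE)))
  if (n_poses == 0) stop("no SDF records in ", poses_sdf)
  unscored <- data.frame(pose = seq_len(n_poses), cnn_pose_score = NA_real_,
                         cnn_affinity = NA_real_, dg_pred = NA_real_)
  exe <- Sys.which(scorer$command)
  if (!nzchar(exe)) {
    warning("scorer '", scorer$command,
            "' not found; returning unscored records")
    return(unscored)
  }
  res <- suppressWarnings(system2(
    exe, c(scorer$args, "-r", receptor_pdb, "-l", poses_sdf, "--score_only"),
    stdout = TRUE, stderr = TRUE))
  status <- attr(res, "status")
  if (!is.null(status) && status != 0) {
    warning("scorer exited with status ", status)
    attr(unscored, "raw_output") <- res
    return(unscored)
  }
  scores <- .parse_field(res, scorer$score_field)
  affinities <- .parse_field(res, scorer$affinity_field)
  if (length(scores) != n_poses || length(affinities) != n_poses) {
    warning("scorer output parse error; raw output retained")
    attr(unscored, "raw_output") <- res
    return(unscored)
  }
  data.frame(pose = seq_len(n_poses), cnn_pose_score = scores,
             cnn_affinity = affinities,
             dg_pred = pk_to_dg(affinities, temperature))
}

#' Convert a predicted pK to a binding free energy
#'
#' ΔG = −RT ln(10) · pK, with R = 1.98720425e-3 kcal/(mol K).
#'
#' @param pk predicted −log10 binding constant.
#' @param temperature K (default 298.15).
#' @return kcal/mol.
#' @export
pk_to_dg <- function(pk, temperature = 298.15) {
  -.gk_rgas * temperature * log(10) * pk
}

#' Benchmark statistics against experimental affinities
#'
#' @param predicted,experimental equal-length numeric vectors (kcal/mol).
#' @return list(rmse, mue, r2); `r2` is NA when either vector has zero
#'   variance.
#' @export
benchmark_stats <- function(predicted, experimental) {
  if (length(predicted) != length(experimental)) {
    stop("predicted and experimental must have equal length")
  }
  if (length(predicted) < 2) stop("need at least 2 pairs")
  d <- predicted - experimental
  r2 <- if (stats::sd(predicted) == 0 || stats::sd(experimental) == 0) {
    NA_real_
  } else {
    stats::cor(predicted, experimental)^2
  }
  list(rmse = sqrt(mean(d^2)), mue = mean(abs(d)), r2 = r2)
}
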
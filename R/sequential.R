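# The sequential multi-ligand docking protocol: in each round a fresh ligand
# copy is docked against the protein plus all previously placed copies; the
# best-scoring pose is frozen into the receptor for the next round. Ten
# rounds by default.

#' Sequential-protocol configuration
#'
#' @param n_rounds Number of docking rounds (default 10, the protocol's
#'   standard depth: enough rounds to saturate preferred sites without
#'   accumulating noise).
#' @param docking A [docking_config()]; round `k` uses seed
#'   `docking$seed + 1000 * k` so rounds are independent and the whole run
#'   is reproducible.
#' @param weights A [scoring_weights()].
#' @return A `protocol_config` list.
#' @export
protocol_config <- function(n_rounds = 10, docking = docking_config(),
                            weights = scoring_weights()) {
  stopifnot(n_rounds >= 1)
  structure(list(n_rounds = n_rounds, docking = docking, weights = weights),
            class = "protocol_config")
}

# flat atom tibble of a complex: protein atoms + one block per ligand copy,
# with a `unit` column ("protein" or the ligand copy id)
complex_atoms <- function(cx) {
  prot <- cx$protein$atoms
  prot$unit <- "protein"
  lig <- purrr::map(cx$ligand_poses, function(lp) {
    at <- lp$atoms
    at$chain <- NA_character_
    at$resid <- NA_integer_
    at$icode <- ""
    at$resname <- lp$species
    at$unit <- lp$ligand_id
    at
  })
  dplyr::bind_rows(c(list(prot), lig))
}

#' @export
print.docked_complex <- function(x, ...) {
  cat("<docked_complex> ", x$protein$model_id, " + ",
      length(x$ligand_poses), " ligand cop",
      if (length(x$ligand_poses) == 1) "y" else "ies", "\n", sep = "")
  invisible(x)
}

# receptor atom tibble = protein + frozen ligand copies
receptor_with_ligands <- function(model, placed) {
  cols <- c("serial", "name", "element", "x", "y", "z", "class")
  prot <- model$atoms[, c(cols, "chain", "resid", "icode", "resname")]
  if (length(placed) == 0) return(prot)
  lig <- purrr::map(placed, function(lp) {
    at <- lp$atoms[, cols]
    at$chain <- NA_character_; at$resid <- NA_integer_
    at$icode <- ""; at$resname <- lp$species
    at
  })
  dplyr::bind_rows(c(list(prot), lig))
}

pose_as_placed <- function(pose, ligand_id) {
  list(ligand_id = ligand_id, species = pose$species, atoms = pose$atoms,
       n_rot = pose$n_rot, delta_g = pose$delta_g, pose = pose)
}

run_protocol <- function(model, ligand, config, initial_poses = list(),
                         retained_from = integer(0)) {
  stopifnot(inherits(model, "protein_model"), inherits(ligand, "ligand"),
            inherits(config, "protocol_config"))
  if (any(is.na(model$atoms$class))) model <- assign_interaction_classes(model)
  if (any(is.na(ligand$atoms$class))) {
    ligand <- assign_interaction_classes(ligand)
  }
  box <- default_box(model)          # fixed from the bare protein, all rounds
  placed <- initial_poses
  rounds <- vector("list", config$n_rounds)
  for (k in seq_len(config$n_rounds)) {
    receptor <- receptor_with_ligands(model, placed)
    cfg_k <- config$docking
    cfg_k$seed <- config$docking$seed + 1000L * k
    poses <- tryCatch(
      dock(receptor, ligand, box = box, weights = config$weights,
           config = cfg_k),
      error = function(e) {
        stop("sequential round ", k, " failed: ", conditionMessage(e))
      })
    # centroid separation from already placed copies (> 1.5 A)
    centroids <- purrr::map(placed, function(lp) {
      colMeans(as.matrix(lp$atoms[, c("x", "y", "z")]))
    })
    ok <- function(p) {
      ctr <- colMeans(as.matrix(p$atoms[, c("x", "y", "z")]))
      all(vapply(centroids, function(cc) sqrt(sum((ctr - cc)^2)) > 1.5,
                 logical(1)))
    }
    sel <- Filter(ok, poses)
    if (length(sel) == 0) {
      stop("sequential round ", k,
           " failed: all poses overlap previously placed ligands")
    }
    best <- sel[[1]]
    lig_id <- paste0(ligand$species, "_r", k)
    placed <- c(placed, list(pose_as_placed(best, lig_id)))
    rounds[[k]] <- list(round_index = k, ligand_id = lig_id,
                        ligand_species = ligand$species, pose = best,
                        delta_g = best$delta_g)
  }
  final_complex <- structure(
    list(protein = model,
         ligand_poses = purrr::map(placed, function(lp) {
           lp[c("ligand_id", "species", "atoms", "n_rot")]
         })),
    class = "docked_complex")
  structure(
    list(model_id = model$model_id, time_label_ns = model$time_label_ns,
         ligand_species = ligand$species, ligand = ligand, rounds = rounds,
         final_complex = final_complex, config = config,
         retained_from = retained_from,
         n_initial = length(initial_poses)),
    class = "sequential_run")
}

#' Run the sequential docking protocol
#'
#' Round `k` docks a fresh copy of the ligand against the protein plus the
#' frozen poses of rounds `< k` (previous copies are scored exactly like
#' receptor atoms and contribute no rotatable-bond penalty). The best pose
#' of each round is appended; placed poses never move, protein atoms are
#' never modified, and the docking box is derived once from the bare
#' protein. Reproducible bitwise under the seed schedule.
#'
#' @param model A `protein_model`.
#' @param ligand A `ligand`.
#' @param config A [protocol_config()].
#' @return A `sequential_run` with `rounds` (one record per round) and
#'   `final_complex` (a `docked_complex` carrying `n_rounds` ligand copies).
#' @export
run_sequential <- function(model, ligand, config = protocol_config()) {
  run_protocol(model, ligand, config)
}

#' Re-dock against a complex retaining a subset of placed ligands
#'
#' Emulates the retained-subset validation: ligands of the dropped rounds
#' are removed from the complex, and a fresh full protocol is executed
#' starting from the protein plus only the kept copies. With nothing kept
#' and the same seed, the result is identical to a from-scratch run.
#'
#' @param run A `sequential_run`.
#' @param keep_round_indices Integer round indices whose ligands stay bound.
#' @param config Protocol configuration for the rerun (defaults to the
#'   original run's).
#' @return A `sequential_run`; `retained_from` records the kept rounds.
#' @export
rerun_with_retained_subset <- function(run, keep_round_indices,
                                       config = run$config) {
  stopifnot(inherits(run, "sequential_run"))
  if (length(run$rounds) == 0) stop("empty sequential run")
  keep <- as.integer(keep_round_indices)
  if (length(keep) > 0 &&
      (any(keep < 1) || any(keep > length(run$rounds)))) {
    stop("keep_round_indices out of range 1..", length(run$rounds))
  }
  kept <- purrr::map(keep, function(k) {
    r <- run$rounds[[k]]
    pose_as_placed(r$pose, paste0("retained_", r$ligand_id))
  })
  model <- run$final_complex$protein
  run_protocol(model, run$ligand, config, initial_poses = kept,
               retained_from = keep)
}

#' @export
print.sequential_run <- function(x, ...) {
  dg <- vapply(x$rounds, function(r) r$delta_g, numeric(1))
  cat("<sequential_run> ", x$model_id, " x ", x$ligand_species, ": ",
      length(x$rounds), " rounds, best delta_g = ",
      sprintf("%.3f", min(dg)), " kcal/mol\n", sep = "")
  invisible(x)
}
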
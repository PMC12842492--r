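# End-to-end orchestration: conformer ensemble x ligand species ->
# sequential runs -> profiling -> region labels -> background statistics ->
# significance flags -> occupancy summaries -> heat-map TSV / JSON reports.

#' Build a run manifest for the end-to-end pipeline
#'
#' @param proteins Either a [toy_protein_spec()] (the ensemble and regions
#'   are generated) or a list of `protein_model` objects.
#' @param ligands A list of `ligand` objects and/or toy-ligand kind strings
#'   (see [make_toy_ligand()]).
#' @param regions Region annotation tibble; required when `proteins` is a
#'   list of models (generated automatically for a toy spec).
#' @param protocol A [protocol_config()].
#' @param out_dir Output directory for reports.
#' @param seed Global seed; every (model x species) pair derives its
#'   docking seeds from it.
#' @param protein_name Directory name used for this protein's outputs.
#' @return A `run_manifest` list; its md5 hash is recorded in all outputs.
#' @export
run_manifest <- function(proteins, ligands, regions = NULL,
                         protocol = protocol_config(), out_dir = tempfile(),
                         seed = 1, protein_name = "protein") {
  if (!is.list(ligands) || inherits(ligands, "ligand")) {
    ligands <- list(ligands)
  }
  structure(
    list(proteins = proteins, ligands = ligands, regions = regions,
         protocol = protocol, out_dir = out_dir, seed = seed,
         protein_name = protein_name),
    class = "run_manifest")
}

manifest_hash <- function(manifest) {
  desc <- list(
    proteins = if (inherits(manifest$proteins, "toy_protein_spec")) {
      unclass(manifest$proteins)
    } else {
      lapply(manifest$proteins, function(m) {
        list(id = m$model_id, t = m$time_label_ns, n = nrow(m$atoms))
      })
    },
    ligands = lapply(manifest$ligands, function(l) {
      if (is.character(l)) l else list(id = l$ligand_id, n = nrow(l$atoms))
    }),
    protocol = list(n_rounds = manifest$protocol$n_rounds,
                    docking = unclass(manifest$protocol$docking),
                    weights = unclass(manifest$protocol$weights)),
    seed = manifest$seed)
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(desc, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

resolve_ligand <- function(l) {
  if (inherits(l, "ligand")) {
    if (any(is.na(l$atoms$class))) assign_interaction_classes(l) else l
  } else if (is.character(l)) {
    make_toy_ligand(l)
  } else {
    stop("ligand entries must be ligand objects or toy kinds")
  }
}

#' Run the full pipeline described by a manifest
#'
#' For every (conformer x ligand species) pair a sequential docking run is
#' executed; rounds are region-labelled, backgrounds are pooled per species
#' across conformers, significant binders are flagged at 3 SD, linker and
#' pocket occupancies are summarised, and per-species heat-map TSVs plus a
#' JSON summary are written under `out_dir/<protein>/<species>/`. All
#' outputs record the manifest hash and the global seed. Deterministic
#' under the seed.
#'
#' @param manifest A [run_manifest()].
#' @param params [profiling_params()] used for labelling and profiling.
#' @return Invisibly, a `pipeline_result` list: `runs`, `records`
#'   (labelled rounds), `backgrounds`, `occupancy`, `profiles`, `files`,
#'   `manifest_hash`.
#' @export
run_pipeline <- function(manifest, params = profiling_params()) {
  stopifnot(inherits(manifest, "run_manifest"))
  if (inherits(manifest$proteins, "toy_protein_spec")) {
    spec <- manifest$proteins
    spec$seed <- manifest$seed
    toy <- make_toy_protein(spec)
    ensemble <- toy$ensemble
    regions <- manifest$regions %||% toy$regions
  } else {
    ensemble <- manifest$proteins
    regions <- manifest$regions
    if (is.null(regions)) stop("run_pipeline(): regions required")
  }
  ligands <- lapply(manifest$ligands, resolve_ligand)
  hash <- manifest_hash(manifest)
  dir.create(manifest$out_dir, recursive = TRUE, showWarnings = FALSE)
  runs <- list()
  records <- list()
  profiles <- list()
  files <- character(0)
  pair <- 0L
  for (lig in ligands) {
    sp_dir <- file.path(manifest$out_dir, manifest$protein_name,
                        lig$species)
    dir.create(sp_dir, recursive = TRUE, showWarnings = FALSE)
    sp_runs <- list()
    for (model in ensemble) {
      pair <- pair + 1L
      cfg <- manifest$protocol
      cfg$docking$seed <- manifest$seed + 101L * pair
      run <- tryCatch(
        run_sequential(model, lig, cfg),
        error = function(e) {
          stop("pipeline failed for pair (", model$model_id, " x ",
               lig$species, "): ", conditionMessage(e))
        })
      sp_runs[[model$model_id]] <- run
      profiles[[paste(model$model_id, lig$species, sep = "|")]] <-
        profile_complex(run$final_complex, params)
    }
    runs[[lig$species]] <- sp_runs
    recs <- label_rounds(sp_runs, regions, params)
    records[[lig$species]] <- recs
    bg <- compute_background(recs)
    hm <- heatmap_table(recs, bg)
    hm_path <- file.path(sp_dir, "heatmap.tsv")
    readr::write_tsv(hm, hm_path)
    rounds_path <- file.path(sp_dir, "rounds.tsv")
    readr::write_tsv(
      recs |>
        dplyr::mutate(
          significant = flag_significant(.data$delta_g, bg),
          regions_touched = vapply(.data$regions_touched, paste,
                                   character(1), collapse = ",")),
      rounds_path)
    summary_path <- file.path(sp_dir, "summary.json")
    occ <- dplyr::bind_rows(occupancy_summary(recs, "linker"),
                            occupancy_summary(recs, "pocket"))
    jsonlite::write_json(
      list(manifest_hash = hash, seed = manifest$seed,
           ligand_species = lig$species,
           background = list(mean = bg$mean, sd = bg$sd, n = bg$n),
           occupancy = occ,
           n_models = length(sp_runs),
           n_rounds = manifest$protocol$n_rounds),
      summary_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    files <- c(files, hm_path, rounds_path, summary_path)
  }
  all_records <- dplyr::bind_rows(records)
  backgrounds <- purrr::map(records, compute_background)
  occupancy <- purrr::imap(records, function(recs, sp) {
    dplyr::bind_rows(occupancy_summary(recs, "linker"),
                     occupancy_summary(recs, "pocket")) |>
      dplyr::mutate(ligand_species = sp)
  }) |> dplyr::bind_rows()
  manifest_path <- file.path(manifest$out_dir, "MANIFEST.json")
  jsonlite::write_json(
    list(manifest_hash = hash, seed = manifest$seed,
         files = files),
    manifest_path, auto_unbox = TRUE, pretty = TRUE)
  out <- structure(
    list(runs = runs, records = all_records, backgrounds = backgrounds,
         occupancy = occupancy, profiles = profiles,
         files = c(files, manifest_path), manifest_hash = hash),
    class = "pipeline_result")
  invisible(out)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result> ", length(x$backgrounds), " ligand species, ",
      nrow(x$records), " round records, hash ", x$manifest_hash, "\n",
      sep = "")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
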
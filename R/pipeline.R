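#' Run the full synthetic-demo pipeline
#'
#' Chains the analysis stages end-to-end on seeded synthetic specimens:
#' generate a template and population, fragment one specimen, rank the
#' references, re-assemble on the best reference, build the comparative shape
#' space and project the reconstruction, estimate cranial capacity through
#' the template endocast, slice the template into contour polylines, and run
#' the discrete-trait NJ/MP analyses on characters simulated along a known
#' tree. Every output file is written under `out_dir` beside a manifest
#' recording the package version, configuration, seed and output hashes, so
#' a re-run with the same configuration is hash-identical.
#'
#' @param config list (or path to a JSON/YAML file) with elements `seed`
#'   (integer, required), `out_dir` (required), and optionally `n` (population
#'   size, default 20), `spacing` (polyline spacing mm, default 2),
#'   `shell_thickness` (endocast shell mm, default 10).
#' @return (invisibly) the manifest list.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    config <- if (grepl("\\.ya?ml$", config)) {
      if (!requireNamespace("yaml", quietly = TRUE))
        stop("YAML configs need the yaml package; use JSON")
      yaml::read_yaml(config)
    } else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  for (key in c("seed", "out_dir"))
    if (is.null(config[[key]])) stop("config is missing required key: ", key)
  seed <- as.integer(config$seed)
  out <- config$out_dir
  n <- config$n %||% 20L
  spacing <- config$spacing %||% 2.0
  shell <- config$shell_thickness %||% 10
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  emit <- function(name) { p <- file.path(out, name); paths <<- c(paths, p); p }

  template <- generate_template(seed = seed)
  pop <- generate_population(template, n = n, seed = seed + 1L)
  write_landmarks(template$landmarks, emit("template_landmarks.csv"))
  write_mesh(template$mesh, emit("template_mesh.ply"))

  # fragment + rank + reconstruct
  fr <- fragment_specimen(pop[[1L]], seed = seed + 2L)
  refs <- lapply(pop[-1L], `[[`, "config")
  ranking <- rank_references(fr$pair, refs)
  utils::write.table(ranking, emit("reference_ranking.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  best <- refs[[match(ranking$reference_id[1L],
                      vapply(refs, `[[`, character(1), "specimen_id"))]]
  recon <- align_fragments(fr$pair, best)
  write_landmarks(recon$merged, emit("reconstruction.csv"))

  # shape space + projection (on the landmarks the reconstruction carries)
  refs_sub <- lapply(refs, subset_config, names = recon$merged$landmark_names)
  space <- shape_space(refs_sub, vapply(pop[-1L], `[[`, character(1), "group"))
  scores <- predict(space, recon$merged)
  sc <- cbind(data.frame(specimen = rownames(space$scores)),
              as.data.frame(space$scores))
  utils::write.table(sc, emit("shape_scores.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(variance_fraction = space$variance_fraction,
                            projected = as.list(scores)),
                       emit("shape_space.json"), auto_unbox = TRUE, digits = 9)

  # capacity through the template endocast
  endo <- generate_endocast(template, shell_thickness = shell)
  ref_set <- semilandmark_set(template$landmarks, template$occipital$semis)
  tgt <- pop[[2L]]
  tgt_set <- semilandmark_set(tgt$config, tps_warp(tgt$warp, template$occipital$semis))
  capacity <- estimate_capacity(endo, ref_set, tgt_set)
  jsonlite::write_json(list(capacity_cc = as.numeric(capacity),
                            reference_volume_cc = mesh_volume(endo)),
                       emit("capacity.json"), auto_unbox = TRUE, digits = 9)

  # contour polylines of the template
  frame <- define_slicing_frame(template$landmarks, spacing = spacing)
  write_polylines_json(generate_polylines(template$mesh, frame),
                       emit("polylines.json"))

  # discrete traits on a known tree
  tree <- ape::read.tree(text =
    "((MPH:1,SH:1):1,((ERN:1,ALT:1):1,(EWN1:1,EWN2:1):1):1,(MOD1:1,MOD2:1):2);")
  cm <- simulate_characters(tree, n_characters = 20L, substitution_rate = 0.4,
                            seed = seed + 3L)
  write_nexus_matrix(cm, emit("traits.nex"))
  write_newick(neighbor_joining(character_distance(cm)), emit("traits_nj.nwk"))
  mp <- exhaustive_mp(cm)
  write_newick(mp$strict_consensus, emit("traits_mp_consensus.nwk"))

  manifest <- list(tool = "virtucrania",
                   version = as.character(utils::packageVersion("virtucrania")),
                   seed = seed,
                   config = config[setdiff(names(config), "out_dir")],
                   outputs = stats::setNames(as.list(unname(tools::md5sum(paths))),
                                             basename(paths)))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
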
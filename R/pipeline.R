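#' Default pipeline configuration
#'
#' All stage parameters with their standard defaults: identity gate 0.99
#' with 200 nt minimum overlap, rarefaction to the smallest library,
#' enrichment and activity boundaries at ratio > 1, network threshold
#' |r| >= 0.7 with at most 2 zero occurrences and a total-abundance floor
#' of 1, strict (complete-core) prototrophy. Simulation parameters come
#' from [sim_params()].
#'
#' @param outdir output directory for stage files.
#' @param seed global integer seed; each stage derives its own child seed
#'   from it by stable string hashing, so adding or removing a stage does
#'   not reshuffle the others.
#' @param sim a [sim_params()] object for the simulate stage.
#' @param stages character vector of stages to run, in dependency order.
#' @return a named list of class `run_config`.
#' @export
default_config <- function(outdir = tempfile("encult_run_"), seed = 1L,
                           sim = sim_params(),
                           stages = c("simulate", "recruit", "diversity",
                                      "enrichment", "activity", "network",
                                      "trophy")) {
  structure(list(
    outdir = outdir,
    seed = as.integer(seed),
    stages = stages,
    sim = sim,
    min_identity = 0.99,
    min_overlap = 200,
    rarefy_depth = "min",
    ratio_boundary = 1,
    network_threshold = 0.7,
    max_zeros = 2,
    majority = 1,
    min_pairs = 9,
    association_rank = "family",
    pathways_file = system.file("extdata", "pathways.yaml", package = "encult"),
    presence_file = system.file("extdata", "genome_gene_presence_synthetic.tsv",
                                package = "encult"),
    lineage_file = system.file("extdata", "genome_lineage_synthetic.tsv",
                               package = "encult"),
    prototroph_min = 1.0
  ), class = "run_config")
}

#' Load a pipeline configuration from YAML
#'
#' Scalar fields override [default_config()]; a `sim` map overrides
#' [sim_params()] fields.
#'
#' @param path YAML file.
#' @return a `run_config` list.
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  cfg <- default_config()
  simover <- y$sim %||% list()
  y$sim <- NULL
  cfg[names(y)] <- y
  if (length(simover)) cfg$sim <- do.call(sim_params, simover)
  cfg$seed <- as.integer(cfg$seed)
  class(cfg) <- "run_config"
  cfg
}

#' Run the full enrichment-culture analysis pipeline
#'
#' Orchestrates simulate -> recruit -> diversity -> enrichment ->
#' activity -> network -> trophy on a synthetic community, writing each
#' stage's outputs as plain-text files under `config$outdir` and
#' returning a manifest (parameters with provenance, per-stage seeds,
#' output files with MD5 checksums). Identical config + seed reproduce
#' byte-identical outputs; no stage rewrites another stage's files.
#'
#' @param config a `run_config` from [default_config()] or
#'   [read_config()].
#' @return the manifest, invisibly also written as `manifest.json`.
#' @export
run_pipeline <- function(config = default_config()) {
  stopifnot(inherits(config, "run_config"))
  cfg <- config
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  stages <- cfg$stages
  ran <- character()
  files <- list()
  state <- new.env(parent = emptyenv())

  need <- function(stage, what) {
    if (!stage %in% ran) {
      abort(paste0("stage '", what, "' needs output of stage '", stage,
                   "', which did not run"))
    }
  }
  add_files <- function(stage, paths) files[[stage]] <<- unname(unlist(paths))

  if ("simulate" %in% stages) {
    sim <- simulate_community(cfg$sim, seed = child_seed(cfg$seed, "simulate"))
    state$sim <- sim
    dir <- file.path(cfg$outdir, "simulate")
    add_files("simulate", write_community(sim, dir))
    ran <- c(ran, "simulate")
  }

  if ("recruit" %in% stages) {
    need("simulate", "recruit")
    sim <- state$sim
    if (is.null(sim$sequences)) abort("recruit stage needs simulated sequences")
    dna_r <- rarefy(sim$counts_dna, cfg$rarefy_depth,
                    seed = child_seed(cfg$seed, "rarefy-dna"))
    state$dna_rarefied <- dna_r
    rec <- recruit(sim$sequences$isolates, sim$sequences$references, dna_r,
                   min_identity = cfg$min_identity, min_overlap = cfg$min_overlap)
    state$recruitment <- rec
    dir <- file.path(cfg$outdir, "recruit"); dir.create(dir, showWarnings = FALSE)
    readr::write_tsv(rec$counts, file.path(dir, "recruitment.tsv"))
    readr::write_tsv(rec$matches, file.path(dir, "matches.tsv"))
    add_files("recruit", file.path(dir, c("recruitment.tsv", "matches.tsv")))
    ran <- c(ran, "recruit")
  }

  if ("diversity" %in% stages) {
    need("simulate", "diversity")
    sim <- state$sim
    if (is.null(state$dna_rarefied)) {
      state$dna_rarefied <- rarefy(sim$counts_dna, cfg$rarefy_depth,
                                   seed = child_seed(cfg$seed, "rarefy-dna"))
    }
    alpha <- alpha_diversity(state$dna_rarefied)
    curves <- rarefaction_curve(state$dna_rarefied, reps = 10,
                                seed = child_seed(cfg$seed, "curves"))
    gain <- novel_otu_gain(state$dna_rarefied, sim$meta)
    dir <- file.path(cfg$outdir, "diversity"); dir.create(dir, showWarnings = FALSE)
    readr::write_tsv(alpha, file.path(dir, "alpha_diversity.tsv"))
    readr::write_tsv(curves, file.path(dir, "rarefaction_curves.tsv"))
    readr::write_tsv(gain, file.path(dir, "novel_otu_gain.tsv"))
    add_files("diversity", file.path(dir, c("alpha_diversity.tsv",
                                            "rarefaction_curves.tsv",
                                            "novel_otu_gain.tsv")))
    ran <- c(ran, "diversity")
  }

  if ("enrichment" %in% stages) {
    need("recruit", "enrichment")
    sim <- state$sim
    calls <- classify_enrichment(state$recruitment, sim$meta,
                                 sim$truth$isolate_map)
    state$enrichment <- calls
    dir <- file.path(cfg$outdir, "enrichment"); dir.create(dir, showWarnings = FALSE)
    readr::write_tsv(calls$records, file.path(dir, "enrichment_records.tsv"))
    readr::write_tsv(calls$calls, file.path(dir, "enrichment_calls.tsv"))
    jsonlite::write_json(as.list(calls$summary), file.path(dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
    add_files("enrichment", file.path(dir, c("enrichment_records.tsv",
                                             "enrichment_calls.tsv",
                                             "summary.json")))
    ran <- c(ran, "enrichment")
  }

  if ("activity" %in% stages) {
    need("simulate", "activity")
    sim <- state$sim
    rna_r <- rarefy(sim$counts_rna, cfg$rarefy_depth,
                    seed = child_seed(cfg$seed, "rarefy-rna"))
    if (is.null(state$dna_rarefied)) {
      state$dna_rarefied <- rarefy(sim$counts_dna, cfg$rarefy_depth,
                                   seed = child_seed(cfg$seed, "rarefy-dna"))
    }
    act <- aggregate_activity(rna_r, state$dna_rarefied, sim$meta,
                              taxonomy = sim$taxonomy,
                              rank = cfg$association_rank)
    prop <- proportion_active(act)
    state$activity <- act
    dir <- file.path(cfg$outdir, "activity"); dir.create(dir, showWarnings = FALSE)
    readr::write_tsv(act, file.path(dir, "activity.tsv"))
    readr::write_tsv(prop, file.path(dir, "proportion_active.tsv"))
    add_files("activity", file.path(dir, c("activity.tsv", "proportion_active.tsv")))
    ran <- c(ran, "activity")
  }

  if ("network" %in% stages) {
    need("simulate", "network")
    sim <- state$sim
    if (is.null(state$dna_rarefied)) {
      state$dna_rarefied <- rarefy(sim$counts_dna, cfg$rarefy_depth,
                                   seed = child_seed(cfg$seed, "rarefy-dna"))
    }
    filt <- filter_features(state$dna_rarefied, cfg$max_zeros, cfg$majority)
    net <- build_network(filt, threshold = cfg$network_threshold,
                         min_pairs = cfg$min_pairs)
    assoc <- group_associations(net, sim$taxonomy, rank = cfg$association_rank)
    state$network <- net
    state$associations <- assoc
    dir <- file.path(cfg$outdir, "network"); dir.create(dir, showWarnings = FALSE)
    readr::write_tsv(net$edges, file.path(dir, "edges.tsv"))
    readr::write_tsv(net$nodes, file.path(dir, "nodes.tsv"))
    readr::write_tsv(assoc, file.path(dir, "associations.tsv"))
    write_graphml(net, file.path(dir, "network.graphml"))
    add_files("network", file.path(dir, c("edges.tsv", "nodes.tsv",
                                          "associations.tsv", "network.graphml")))
    ran <- c(ran, "network")
  }

  if ("trophy" %in% stages) {
    need("network", "trophy")
    pws <- read_pathways(cfg$pathways_file)
    presence <- readr::read_tsv(cfg$presence_file, show_col_types = FALSE)
    lineage <- readr::read_tsv(cfg$lineage_file, show_col_types = FALSE)
    trophy <- purrr::map_dfr(pws, function(pw)
      classify_trophy(presence, pw, prototroph_min = cfg$prototroph_min))
    cands <- syntrophy_candidates(trophy, state$associations, lineage = lineage)
    dir <- file.path(cfg$outdir, "trophy"); dir.create(dir, showWarnings = FALSE)
    readr::write_tsv(trophy |> mutate(missing = purrr::map_chr(
      .data$missing, paste, collapse = ",")), file.path(dir, "trophy.tsv"))
    readr::write_tsv(cands, file.path(dir, "syntrophy_candidates.tsv"))
    add_files("trophy", file.path(dir, c("trophy.tsv", "syntrophy_candidates.tsv")))
    ran <- c(ran, "trophy")
  }

  defaults <- default_config(outdir = cfg$outdir, seed = cfg$seed, sim = cfg$sim,
                             stages = cfg$stages)
  scalar <- c("min_identity", "min_overlap", "rarefy_depth", "ratio_boundary",
              "network_threshold", "max_zeros", "majority", "min_pairs",
              "association_rank", "prototroph_min")
  params <- purrr::map(setNames(scalar, scalar), function(k) {
    list(value = cfg[[k]],
         provenance = if (identical(cfg[[k]], defaults[[k]])) "default" else "override")
  })
  all_files <- unlist(files, use.names = FALSE)
  manifest <- list(
    package = "encult",
    seed = cfg$seed,
    stage_seeds = setNames(lapply(ran, function(s) child_seed(cfg$seed, s)), ran),
    stages_run = ran,
    parameters = params,
    outputs = lapply(setNames(all_files, basename(all_files)), function(f)
      list(path = f, md5 = unname(tools::md5sum(f)))))
  jsonlite::write_json(manifest, file.path(cfg$outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
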
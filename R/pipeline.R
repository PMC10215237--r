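#' Assemble and validate a pipeline configuration
#'
#' A run takes exactly one input mode: either the four input file paths
#' (compound TSV, disease list, multiscale-network TSV, pathway GMT) or
#' a [SyntheticScenario-class] to generate them. All referenced files
#' must exist at validation time.
#'
#' @param inputs named list with paths `compounds`, `disease`,
#'   `network`, `pathways`, or `NULL` for a synthetic run.
#' @param scenario a [SyntheticScenario-class], or `NULL` for a
#'   file-based run.
#' @param outDir output directory for all stage artifacts.
#' @param minIngredients key-target filter threshold (default 2).
#' @param background background universe for the overlap tests:
#'   `"cpi-targets"` (union of all loaded target proteins, default) or
#'   `"network-proteins"` (all protein nodes of the multiscale network).
#' @param correction multiplicity correction for the pathway ORA
#'   (`"bh"` or `"bonferroni"`).
#' @param diffusion a [DiffusionConfig-class].
#' @param nIter iterations for the randomized fold-enrichment null.
#' @param seed integer seed for all randomized stages.
#' @param mechanismCompound compound id for mechanism extraction
#'   (default: the top-ranked compound).
#' @param diseaseLabel label used when loading the disease list.
#' @return A validated configuration (list with class
#'   `"PipelineConfig"`).
#' @export
pipelineConfig <- function(outDir, inputs = NULL, scenario = NULL,
                           minIngredients = 2L,
                           background = c("cpi-targets",
                                          "network-proteins"),
                           correction = c("bh", "bonferroni"),
                           diffusion = diffusionConfig(),
                           nIter = 1000L, seed = 1L,
                           mechanismCompound = NULL,
                           diseaseLabel = "disease") {
  background <- match.arg(background)
  correction <- match.arg(correction)
  if (is.null(inputs) == is.null(scenario))
    stop("exactly one of 'inputs' or 'scenario' must be given")
  if (!is.null(inputs)) {
    need <- c("compounds", "disease", "network", "pathways")
    missingNames <- setdiff(need, names(inputs))
    if (length(missingNames))
      stop("inputs must name paths: ", paste(missingNames, collapse = ", "))
    absent <- unlist(inputs[need])[!file.exists(unlist(inputs[need]))]
    if (length(absent))
      stop("input file(s) not found: ", paste(absent, collapse = ", "))
  }
  if (!is.null(scenario)) {
    stopifnot(is(scenario, "SyntheticScenario"))
    validObject(scenario)
  }
  stopifnot(is(diffusion, "DiffusionConfig"))
  validObject(diffusion)
  minIngredients <- assertScalarCount(minIngredients, "minIngredients")
  if (nIter < 100L) stop("nIter must be at least 100")
  structure(list(
    inputs = inputs, scenario = scenario, outDir = outDir,
    minIngredients = minIngredients, background = background,
    correction = correction, diffusion = diffusion,
    nIter = as.integer(nIter), seed = as.integer(seed),
    mechanismCompound = mechanismCompound,
    diseaseLabel = diseaseLabel), class = "PipelineConfig")
}

#' Read a pipeline configuration from YAML
#'
#' The YAML mirrors the arguments of [pipelineConfig()]; the
#' `diffusion` block maps to [diffusionConfig()] fields
#' (`continue_prob`, `edge_class_weights`, `tolerance`,
#' `max_iterations`, `k`) and a `scenario` block to
#' [syntheticScenario()] fields (snake_case names).
#'
#' @param path YAML file path.
#' @param outDir optional override of the configured output directory.
#' @return A validated configuration (see [pipelineConfig()]).
#' @export
readPipelineConfig <- function(path, outDir = NULL) {
  if (!file.exists(path)) stop("no such config file: ", path)
  y <- yaml::read_yaml(path)
  dc <- y$diffusion %||% list()
  diffusion <- diffusionConfig(
    continueProb = dc$continue_prob %||% 0.85,
    edgeClassWeights = if (!is.null(dc$edge_class_weights))
      unlist(dc$edge_class_weights),
    tolerance = dc$tolerance %||% 1e-6,
    maxIterations = dc$max_iterations %||% 1000L,
    k = dc$k %||% 20L)
  scenario <- NULL
  if (!is.null(y$scenario)) {
    sc <- y$scenario
    scenario <- syntheticScenario(
      nProteins = sc$n_proteins %||% 200L,
      nFunctions = sc$n_functions %||% 50L,
      ppiEdges = sc$ppi_edges %||% 600L,
      annotationRate = sc$annotation_rate %||% 2,
      hierarchyBranching = sc$hierarchy_branching %||% 2.3,
      nCompounds = sc$n_compounds %||% 14L,
      targetsPerCompound = unlist(sc$targets_per_compound %||% c(7L, 64L)),
      nDiseaseProteins = sc$n_disease_proteins %||% 91L,
      plantedCompounds = unlist(sc$planted_compounds %||% "C01"),
      plantedOverlapFraction = sc$planted_overlap_fraction %||% 1.0,
      nPathways = sc$n_pathways %||% 9L,
      pathwaySizeRange = unlist(sc$pathway_size_range %||% c(10L, 35L)),
      seed = sc$seed %||% (y$seed %||% 1L))
  }
  pipelineConfig(
    outDir = outDir %||% (y$out_dir %||% stop("config must set out_dir")),
    inputs = y$inputs, scenario = scenario,
    minIngredients = y$min_ingredients %||% 2L,
    background = y$background %||% "cpi-targets",
    correction = y$correction %||% "bh",
    diffusion = diffusion, nIter = y$n_iter %||% 1000L,
    seed = y$seed %||% 1L,
    mechanismCompound = y$mechanism_compound,
    diseaseLabel = y$disease_label %||% "disease")
}

runStage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

configAsList <- function(config) {
  d <- config$diffusion
  sc <- config$scenario
  list(
    inputs = config$inputs,
    scenario = if (!is.null(sc)) list(
      n_proteins = sc@nProteins, n_functions = sc@nFunctions,
      ppi_edges = sc@ppiEdges, annotation_rate = sc@annotationRate,
      hierarchy_branching = sc@hierarchyBranching,
      n_compounds = sc@nCompounds,
      targets_per_compound = sc@targetsPerCompound,
      n_disease_proteins = sc@nDiseaseProteins,
      planted_compounds = sc@plantedCompounds,
      planted_overlap_fraction = sc@plantedOverlapFraction,
      n_pathways = sc@nPathways,
      pathway_size_range = sc@pathwaySizeRange, seed = sc@seed),
    out_dir = config$outDir,
    min_ingredients = config$minIngredients,
    background = config$background,
    correction = config$correction,
    diffusion = list(continue_prob = d@continueProb,
                     edge_class_weights = as.list(d@edgeClassWeights),
                     tolerance = d@tolerance,
                     max_iterations = d@maxIterations, k = d@k),
    n_iter = config$nIter, seed = config$seed,
    mechanism_compound = config$mechanismCompound,
    disease_label = config$diseaseLabel)
}

#' Run the full network-pharmacology pipeline
#'
#' Executes, in order: input loading (or synthetic generation),
#' network summary, key-target filtering, disease-overlap statistics
#' (exact hypergeometric test plus the randomized fold-enrichment
#' null), pathway over-representation, diffusion profiles for the
#' disease and every compound, compound ranking by profile correlation,
#' and mechanism-subgraph extraction for the top-ranked (or configured)
#' compound. Every stage writes its artifact under `outDir` and the run
#' manifest is written last; any stage error aborts the run naming the
#' stage.
#'
#' @param config a configuration from [pipelineConfig()] or
#'   [readPipelineConfig()].
#' @return Invisibly, the manifest list (also written as
#'   `manifest.json`).
#' @export
runPipeline <- function(config) {
  if (!inherits(config, "PipelineConfig"))
    stop("config must come from pipelineConfig() or readPipelineConfig()")
  outDir <- config$outDir
  if (!dir.exists(outDir) &&
      !dir.create(outDir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", outDir)
  started <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")

  if (!is.null(config$scenario)) {
    bundle <- runStage("simulate", {
      b <- generateScenarioBundle(config$scenario)
      writeFixture(b, file.path(outDir, "inputs"))
      b
    })
    network <- bundle@network
    compounds <- bundle@compounds
    disease <- bundle@disease
    pathways <- bundle@pathways
  } else {
    loaded <- runStage("load-inputs", list(
      network = loadMultiscaleNetwork(config$inputs$network),
      compounds = loadCompoundTargets(config$inputs$compounds),
      disease = loadDiseaseProteins(config$inputs$disease,
                                    label = config$diseaseLabel),
      pathways = readGMT(config$inputs$pathways)))
    network <- loaded$network
    compounds <- loaded$compounds
    disease <- loaded$disease
    pathways <- loaded$pathways
  }

  rawSummary <- runStage("summarize", {
    s <- summarizeNetwork(compounds)
    writeNetworkSummary(s, file.path(outDir, "network_summary.json"))
    s
  })

  keyTable <- runStage("filter-key-targets", {
    kt <- filterKeyTargets(compounds, config$minIngredients)
    writeTsv(cpiRecords(kt), file.path(outDir, "key_targets.tsv"))
    kt
  })
  keySummary <- summarizeNetwork(keyTable)
  keyTargets <- sort(unique(cpiRecords(keyTable)$target_id))

  protNodes <- network@nodes$id[network@nodes$node_class == "protein"]
  background <- switch(config$background,
    "cpi-targets" = sort(unique(cpiRecords(compounds)$target_id)),
    "network-proteins" = protNodes)

  overlapStats <- runStage("overlap-enrichment", {
    ht <- suppressWarnings(hypergeomOverlapTest(
      keyTargets, proteinIds(disease), background,
      name = "key-targets-vs-disease"))
    mc <- monteCarloFoldEnrichment(
      intersect(keyTargets, background), proteinIds(disease), background,
      nIter = config$nIter, seed = config$seed)
    jsonlite::write_json(list(
      overlap_k = ht@overlapK, query_n = ht@queryN, set_K = ht@setK,
      background_N = ht@backgroundN, p_value = ht@pValue,
      fold_enrichment = mc$fold, empirical_p = mc$empiricalP,
      mean_random_overlap = mc$meanRandomOverlap, n_iter = mc$nIter),
      file.path(outDir, "disease_overlap.json"), auto_unbox = TRUE,
      pretty = TRUE, digits = NA)
    list(test = ht, null = mc)
  })

  ora <- runStage("pathway-ora", {
    o <- suppressWarnings(pathwayORA(keyTargets, pathways, background,
                                     correction = config$correction))
    writeEnrichmentTable(o, file.path(outDir, "pathway_enrichment.tsv"))
    o
  })

  dcfg <- config$diffusion
  profileDir <- file.path(outDir, "profiles")
  dir.create(profileDir, showWarnings = FALSE)
  diffusionOut <- runStage("diffusion", {
    tm <- buildTransitionMatrix(network, dcfg@edgeClassWeights)
    dRestart <- buildRestartVector(network, proteinIds(disease),
                                   label = disease@label)
    dProfile <- computeDiffusionProfile(network, dRestart, dcfg,
                                        transition = tm)
    writeDiffusionProfile(dProfile, network,
                          file.path(profileDir, "disease.tsv"))
    recs <- cpiRecords(compounds)
    cids <- sort(unique(recs$compound_id))
    profiles <- list()
    skipped <- character(0)
    for (cid in cids) {
      tgt <- recs$target_id[recs$compound_id == cid]
      pr <- tryCatch(
        computeDiffusionProfile(
          network,
          suppressWarnings(buildRestartVector(network, tgt, label = cid)),
          dcfg, transition = tm),
        error = function(e) NULL)
      if (is.null(pr)) {
        warning("compound ", cid, " has no network anchor; skipped",
                call. = FALSE)
        skipped <- c(skipped, cid)
        next
      }
      writeDiffusionProfile(pr, network,
                            file.path(profileDir, paste0(cid, ".tsv")))
      profiles[[cid]] <- pr
    }
    list(disease = dProfile, compounds = profiles, skipped = skipped)
  })

  ranked <- runStage("rank-compounds", {
    recs <- cpiRecords(compounds)
    overlapTab <- do.call(rbind, lapply(names(diffusionOut$compounds),
      function(cid) {
        ht <- suppressWarnings(hypergeomOverlapTest(
          recs$target_id[recs$compound_id == cid], proteinIds(disease),
          background, name = cid))
        data.frame(compound = cid, overlap_k = ht@overlapK,
                   query_n = ht@queryN, p_value = ht@pValue,
                   stringsAsFactors = FALSE)
      }))
    rk <- rankCompounds(diffusionOut$compounds, diffusionOut$disease,
                        overlap = overlapTab)
    writeRankedCompounds(rk, file.path(outDir, "ranked_compounds.tsv"))
    rk
  })

  mech <- runStage("mechanism", {
    chosen <- config$mechanismCompound %||% ranked$compound[1]
    if (!chosen %in% names(diffusionOut$compounds))
      stop("mechanism compound '", chosen, "' has no diffusion profile")
    recs <- cpiRecords(compounds)
    sg <- extractMechanismSubgraph(
      network, diffusionOut$compounds[[chosen]], diffusionOut$disease,
      compoundTargets = recs$target_id[recs$compound_id == chosen],
      diseaseProteins = proteinIds(disease), k = dcfg@k)
    exportMechanismSubgraph(
      sg, graphmlPath = file.path(outDir, "mechanism.graphml"),
      sifPath = file.path(outDir, "mechanism.sif"),
      tsvPath = file.path(outDir, "mechanism_nodes.tsv"))
    sg
  })

  manifest <- list(
    software = paste0("pharmnet ",
                      as.character(utils::packageVersion("pharmnet"))),
    config = configAsList(config),
    started = started,
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    stages = list(
      summarize = list(n_compounds = rawSummary@nCompounds,
                       n_targets = rawSummary@nTargets,
                       n_cpis = rawSummary@nCpis),
      filter_key_targets = list(
        min_ingredients = config$minIngredients,
        n_compounds = keySummary@nCompounds,
        n_key_targets = keySummary@nTargets,
        n_cpis = keySummary@nCpis),
      overlap = list(
        overlap_k = overlapStats$test@overlapK,
        query_n = overlapStats$test@queryN,
        p_value = overlapStats$test@pValue,
        fold_enrichment = overlapStats$null$fold,
        empirical_p = overlapStats$null$empiricalP),
      pathway_ora = list(n_sets = nrow(ora),
                         n_significant_005 = sum(ora$adjusted_p <= 0.05),
                         correction = config$correction),
      diffusion = list(
        n_profiles = length(diffusionOut$compounds) + 1L,
        skipped_compounds = diffusionOut$skipped,
        disease_iterations = diffusionOut$disease@iterationsUsed,
        all_converged = all(vapply(
          c(diffusionOut$compounds, list(diffusionOut$disease)),
          isConverged, TRUE))),
      rank = list(top_compound = ranked$compound[1],
                  correlations = stats::setNames(
                    as.list(ranked$correlation), ranked$compound)),
      mechanism = list(compound = mech@compound, k = mech@k,
                       n_nodes = nrow(mech@nodes),
                       n_edges = nrow(mech@edges))))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
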
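#' Define a synthetic study condition
#'
#' Constructs a [SyntheticScenario-class]. The defaults describe the
#' study condition used throughout the package's tests: a 200-protein /
#' 50-function multiscale network whose composition mirrors, at reduced
#' scale, the proportions of a real multiscale interactome (function
#' hierarchy with about 2.3 parent links per function, about 2
#' annotations per protein), a 14-compound library with target-set sizes
#' between 7 and 64, a network-localized disease cluster of 20 proteins
#' (a disease module must stay a small fraction of the network for
#' localization to be meaningful: full-scale disease sets of ~91
#' proteins are only ~0.5% of a 17,000-protein interactome), and one
#' planted "active" compound whose targets all fall in the disease
#' cluster or its direct interactors.
#'
#' @param nProteins number of protein nodes.
#' @param nFunctions number of biological-function nodes.
#' @param ppiEdges requested number of protein-protein edges.
#' @param annotationRate mean protein-function annotations per protein.
#' @param hierarchyBranching mean parent links per function.
#' @param nCompounds number of compounds in the library.
#' @param targetsPerCompound integer vector (lo, hi): range of
#'   target-set sizes.
#' @param nDiseaseProteins size of the disease protein set.
#' @param plantedCompounds ids of planted disease-proximal compounds.
#' @param plantedOverlapFraction fraction of a planted compound's targets
#'   drawn from the disease set or its 1-hop protein neighbors.
#' @param nPathways number of pathway gene sets.
#' @param pathwaySizeRange integer vector (lo, hi): pathway sizes.
#' @param seed integer seed; all generator randomness flows from it.
#' @return A validated [SyntheticScenario-class].
#' @examples
#' sc <- syntheticScenario(seed = 7)
#' sc
#' @export
syntheticScenario <- function(nProteins = 200L, nFunctions = 50L,
                              ppiEdges = 600L, annotationRate = 2,
                              hierarchyBranching = 2.3,
                              nCompounds = 14L,
                              targetsPerCompound = c(7L, 64L),
                              nDiseaseProteins = 20L,
                              plantedCompounds = "C01",
                              plantedOverlapFraction = 1.0,
                              nPathways = 9L,
                              pathwaySizeRange = c(10L, 35L),
                              seed = 1L) {
  new("SyntheticScenario",
      nProteins = as.integer(nProteins),
      nFunctions = as.integer(nFunctions),
      ppiEdges = as.integer(ppiEdges),
      annotationRate = as.numeric(annotationRate),
      hierarchyBranching = as.numeric(hierarchyBranching),
      nCompounds = as.integer(nCompounds),
      targetsPerCompound = as.integer(targetsPerCompound),
      nDiseaseProteins = as.integer(nDiseaseProteins),
      plantedCompounds = as.character(plantedCompounds),
      plantedOverlapFraction = as.numeric(plantedOverlapFraction),
      nPathways = as.integer(nPathways),
      pathwaySizeRange = as.integer(pathwaySizeRange),
      seed = as.integer(seed))
}

proteinIdsFor <- function(n) sprintf("P%0*d", max(4L, nchar(n)), seq_len(n))
functionIdsFor <- function(n) sprintf("F%0*d", max(3L, nchar(n)), seq_len(n))

#' Generate a synthetic multiscale network
#'
#' Builds a directed heterogeneous network with three biological layers:
#' a preferential-attachment (heavy-tailed) protein-protein interaction
#' graph, protein-to-function annotation edges, and a function hierarchy
#' (random DAG: a spanning tree plus extra parent links). Undirected
#' layers are stored as reciprocal directed pairs (`pp`; `pf`/`fp`) and
#' hierarchy links as `ff_up` (child to parent) with reciprocal
#' `ff_down`. Generation is a pure function of the scenario seed.
#'
#' @param scenario a [SyntheticScenario-class].
#' @return A [MultiscaleNetwork-class] in which every node has at least
#'   one incident edge.
#' @examples
#' net <- generateMultiscaleNetwork(syntheticScenario(seed = 7))
#' net
#' @export
generateMultiscaleNetwork <- function(scenario) {
  stopifnot(is(scenario, "SyntheticScenario"))
  validObject(scenario)
  nP <- scenario@nProteins
  nF <- scenario@nFunctions
  prot <- proteinIdsFor(nP)
  fun <- functionIdsFor(nF)
  withSeed(deriveSeed(scenario@seed, 1L), {
    ## protein-protein layer: scale-free-like, connected by construction
    m <- max(1L, round(scenario@ppiEdges / nP))
    g <- igraph::sample_pa(nP, m = m, directed = FALSE)
    el <- igraph::as_edgelist(g, names = FALSE)
    pp <- data.frame(source = prot[pmin(el[, 1], el[, 2])],
                     target = prot[pmax(el[, 1], el[, 2])],
                     stringsAsFactors = FALSE)
    pp <- unique(pp)

    ## annotation layer: every function annotates at least one protein
    nPf <- max(nF, round(scenario@annotationRate * nP))
    if (nPf > nP * nF)
      stop("impossible edge count: more annotations than protein-function pairs")
    coverIdx <- (seq_len(nF) - 1L) * nP + sample.int(nP, nF, replace = TRUE)
    extra <- nPf - nF
    if (extra > 0) {
      rest <- setdiff(seq_len(nP * nF), coverIdx)
      coverIdx <- c(coverIdx, sample(rest, extra))
    }
    pf <- data.frame(
      source = prot[(coverIdx - 1L) %% nP + 1L],
      target = fun[(coverIdx - 1L) %/% nP + 1L],
      stringsAsFactors = FALSE)

    ## function hierarchy: spanning tree over a random order plus extra
    ## parent links, always pointing to earlier nodes (a DAG)
    ffChild <- ffParent <- character(0)
    if (nF > 1) {
      ord <- sample.int(nF)
      parentPos <- vapply(2:nF, function(i)
        if (i == 2L) 1L else sample.int(i - 1L, 1L), 1L)
      ffChild <- fun[ord[2:nF]]
      ffParent <- fun[ord[parentPos]]
      nFf <- max(nF - 1L, round(scenario@hierarchyBranching * nF))
      extraFf <- nFf - (nF - 1L)
      if (extraFf > 0) {
        ## flatten all (later, earlier) pairs in the random order
        allPairs <- which(lower.tri(matrix(0, nF, nF)), arr.ind = TRUE)
        key <- paste(allPairs[, 1], allPairs[, 2])
        treeKey <- paste(match(ffChild, fun[ord]), parentPos)
        free <- which(!(key %in% treeKey))
        extraFf <- min(extraFf, length(free))
        pick <- allPairs[sample(free, extraFf), , drop = FALSE]
        ffChild <- c(ffChild, fun[ord[pick[, 1]]])
        ffParent <- c(ffParent, fun[ord[pick[, 2]]])
      }
    }

    edges <- rbind(
      data.frame(source = pp$source, target = pp$target,
                 edge_class = "pp", stringsAsFactors = FALSE),
      data.frame(source = pp$target, target = pp$source,
                 edge_class = "pp", stringsAsFactors = FALSE),
      data.frame(source = pf$source, target = pf$target,
                 edge_class = "pf", stringsAsFactors = FALSE),
      data.frame(source = pf$target, target = pf$source,
                 edge_class = "fp", stringsAsFactors = FALSE),
      data.frame(source = ffChild, target = ffParent,
                 edge_class = "ff_up", stringsAsFactors = FALSE),
      data.frame(source = ffParent, target = ffChild,
                 edge_class = "ff_down", stringsAsFactors = FALSE))
    nodes <- data.frame(
      id = c(prot, fun),
      node_class = rep(c("protein", "function"), c(nP, nF)),
      stringsAsFactors = FALSE)
    multiscaleNetwork(nodes, edges)
  })
}

#' Generate a network-localized synthetic disease protein set
#'
#' Samples the disease proteins as a connected-biased cluster: a random
#' seed protein plus a breadth-first ball around it on the
#' protein-protein layer, over-sampled and then uniformly thinned to the
#' requested size. Localization matters because diffusion-profile
#' correlation is only informative when the disease occupies a coherent
#' network neighborhood.
#'
#' @param network a [MultiscaleNetwork-class].
#' @param scenario a [SyntheticScenario-class]; uses `nDiseaseProteins`
#'   and the seed.
#' @return A [DiseaseProteinSet-class] of exactly `nDiseaseProteins`
#'   protein nodes.
#' @export
generateDisease <- function(network, scenario) {
  stopifnot(is(network, "MultiscaleNetwork"),
            is(scenario, "SyntheticScenario"))
  nD <- scenario@nDiseaseProteins
  g <- msnPpiIgraph(network)
  prot <- igraph::V(g)$name
  if (nD > length(prot))
    stop("nDiseaseProteins exceeds the number of protein nodes")
  withSeed(deriveSeed(scenario@seed, 2L), {
    root <- sample(prot, 1L)
    ballSize <- min(length(prot), ceiling(1.5 * nD))
    bfs <- igraph::bfs(g, root = root, order = TRUE, unreachable = TRUE)
    ball <- igraph::V(g)$name[as.integer(bfs$order)][seq_len(ballSize)]
    ids <- if (nD == 1L) root
           else c(root, sample(setdiff(ball, root), nD - 1L))
    diseaseProteinSet(ids, label = "synthetic-disease")
  })
}

#' Generate a synthetic compound library with planted active compounds
#'
#' Each compound receives a target-set size drawn uniformly from the
#' scenario range. Planted compounds draw `plantedOverlapFraction` of
#' their targets from the disease proteins or their 1-hop
#' protein-protein neighbors; decoy compounds draw targets uniformly
#' from proteins outside that pool where possible (falling back to
#' non-disease proteins, then to all proteins, only when the outside
#' pool is exhausted).
#'
#' @param network a [MultiscaleNetwork-class].
#' @param scenario a [SyntheticScenario-class].
#' @param disease a [DiseaseProteinSet-class] whose ids are protein
#'   nodes of `network`.
#' @return A [CompoundTargetTable-class].
#' @export
generateCompoundLibrary <- function(network, scenario, disease) {
  stopifnot(is(network, "MultiscaleNetwork"),
            is(scenario, "SyntheticScenario"),
            is(disease, "DiseaseProteinSet"))
  g <- msnPpiIgraph(network)
  prot <- igraph::V(g)$name
  if (!all(proteinIds(disease) %in% prot))
    stop("disease proteins must be protein nodes of the network")
  dz <- proteinIds(disease)
  nbr <- unique(unlist(lapply(
    igraph::adjacent_vertices(g, dz), function(v) igraph::V(g)$name[v])))
  pool <- sort(union(dz, nbr))
  if (!length(pool)) stop("planted pool is empty: disease set has no anchors")
  outside <- setdiff(prot, pool)
  nonDisease <- setdiff(prot, dz)
  nC <- scenario@nCompounds
  ids <- sprintf("C%0*d", max(2L, nchar(nC)), seq_len(nC))
  unknownPlanted <- setdiff(scenario@plantedCompounds, ids)
  if (length(unknownPlanted))
    stop("planted compound id(s) outside the roster: ",
         paste(unknownPlanted, collapse = ", "))
  lo <- scenario@targetsPerCompound[1]
  hi <- scenario@targetsPerCompound[2]
  withSeed(deriveSeed(scenario@seed, 3L), {
    sizes <- sample(seq.int(lo, hi), nC, replace = TRUE)
    recs <- lapply(seq_len(nC), function(i) {
      sz <- sizes[i]
      if (ids[i] %in% scenario@plantedCompounds) {
        nIn <- min(round(scenario@plantedOverlapFraction * sz), length(pool))
        tgt <- sample(pool, nIn)
        if (sz - nIn > 0) {
          left <- setdiff(outside, tgt)
          if (length(left) < sz - nIn) left <- setdiff(prot, tgt)
          tgt <- c(tgt, sample(left, sz - nIn))
        }
      } else {
        src <- if (length(outside) >= sz) outside
               else if (length(nonDisease) >= sz) nonDisease
               else prot
        tgt <- sample(src, sz)
      }
      data.frame(compound_id = ids[i],
                 compound_name = paste0("synthetic-compound-", i),
                 target_id = tgt, stringsAsFactors = FALSE)
    })
    compoundTargetTable(do.call(rbind, recs), provenance = "synthetic")
  })
}

#' Generate a synthetic pathway gene-set library
#'
#' Produces `nPathways` named protein sets with sizes drawn from the
#' scenario range. The first set is seeded to overlap the disease
#' cluster (which is regenerated deterministically from the same
#' scenario seed), so over-representation analysis has a true positive.
#'
#' @param network a [MultiscaleNetwork-class].
#' @param scenario a [SyntheticScenario-class].
#' @return A [GeneSetLibrary-class].
#' @export
generatePathwayLibrary <- function(network, scenario) {
  stopifnot(is(network, "MultiscaleNetwork"),
            is(scenario, "SyntheticScenario"))
  prot <- network@nodes$id[network@nodes$node_class == "protein"]
  lo <- scenario@pathwaySizeRange[1]
  hi <- scenario@pathwaySizeRange[2]
  if (hi > length(prot))
    stop("pathwaySizeRange max exceeds the number of protein nodes")
  dz <- proteinIds(generateDisease(network, scenario))
  nPw <- scenario@nPathways
  withSeed(deriveSeed(scenario@seed, 4L), {
    sizes <- sample(seq.int(lo, hi), nPw, replace = TRUE)
    sets <- lapply(seq_len(nPw), function(i) {
      sz <- sizes[i]
      if (i == 1L) {
        nDz <- min(ceiling(sz / 2), length(dz))
        core <- sample(dz, nDz)
        c(core, sample(setdiff(prot, core), sz - nDz))
      } else sample(prot, sz)
    })
    names(sets) <- sprintf("pathway_%0*d", max(2L, nchar(nPw)),
                           seq_len(nPw))
    geneSetLibrary(sets, source = "synthetic")
  })
}

#' Generate a full synthetic study bundle
#'
#' Runs the four generators in order (network, disease, compounds,
#' pathways) and packages the result with the planted-compound truth
#' labels.
#'
#' @param scenario a [SyntheticScenario-class].
#' @return A [ScenarioBundle-class].
#' @examples
#' bundle <- generateScenarioBundle(syntheticScenario(seed = 7))
#' bundle
#' @export
generateScenarioBundle <- function(scenario) {
  network <- generateMultiscaleNetwork(scenario)
  disease <- generateDisease(network, scenario)
  compounds <- generateCompoundLibrary(network, scenario, disease)
  pathways <- generatePathwayLibrary(network, scenario)
  new("ScenarioBundle", network = network, compounds = compounds,
      disease = disease, pathways = pathways,
      truth = sort(scenario@plantedCompounds), scenario = scenario)
}

# Collapse the expanded directed edge list to the on-disk convention:
# one row per undirected pp pair, pf rows, and hierarchy rows (class
# "ff", child -> parent).
collapseEdgesForFile <- function(network) {
  ed <- edgeTable(network)
  pp <- ed[ed$edge_class == "pp" & ed$source < ed$target, 1:2]
  pf <- ed[ed$edge_class == "pf", 1:2]
  ff <- ed[ed$edge_class == "ff_up", 1:2]
  out <- rbind(
    if (nrow(pp)) cbind(pp, edge_class = "pp"),
    if (nrow(pf)) cbind(pf, edge_class = "pf"),
    if (nrow(ff)) cbind(ff, edge_class = "ff"))
  out <- out[order(out$edge_class, out$source, out$target), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a scenario bundle to plain-text fixture files
#'
#' Writes the network edge list (TSV: `source`, `target`, `edge_class`
#' with classes `pp`/`pf`/`ff`), the compound table (TSV), the disease
#' protein list (one id per line), the pathway library (GMT), the
#' planted-compound truth labels (JSON) and a manifest (JSON). The files
#' round-trip bit-identically through [loadMultiscaleNetwork()],
#' [loadCompoundTargets()], [loadDiseaseProteins()] and [readGMT()]
#' (see [readFixture()]).
#'
#' @param bundle a [ScenarioBundle-class].
#' @param directory output directory; created if missing.
#' @return Invisibly, a named list of the written file paths.
#' @export
writeFixture <- function(bundle, directory) {
  stopifnot(is(bundle, "ScenarioBundle"))
  if (!dir.exists(directory) &&
      !dir.create(directory, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create fixture directory: ", directory)
  paths <- list(
    network = file.path(directory, "network.tsv"),
    compounds = file.path(directory, "compounds.tsv"),
    disease = file.path(directory, "disease.txt"),
    pathways = file.path(directory, "pathways.gmt"),
    truth = file.path(directory, "truth.json"),
    manifest = file.path(directory, "manifest.json"))
  ok <- tryCatch({
    writeTsv(collapseEdgesForFile(bundle@network), paths$network)
    writeTsv(cpiRecords(bundle@compounds), paths$compounds)
    writeLines(proteinIds(bundle@disease), paths$disease)
    writeGMT(bundle@pathways, paths$pathways)
    jsonlite::write_json(
      list(planted = bundle@truth,
           compounds = sort(unique(cpiRecords(bundle@compounds)$compound_id))),
      paths$truth, pretty = TRUE)
    ecl <- table(factor(edgeTable(bundle@network)$edge_class,
                        levels = EDGE_CLASSES))
    jsonlite::write_json(list(
      files = lapply(paths[1:5], basename),
      seed = bundle@scenario@seed,
      disease_label = bundle@disease@label,
      counts = list(
        proteins = sum(bundle@network@nodes$node_class == "protein"),
        functions = sum(bundle@network@nodes$node_class == "function"),
        directed_edges_by_class = as.list(
          stats::setNames(as.integer(ecl), names(ecl))),
        cpis = nrow(cpiRecords(bundle@compounds)),
        disease_proteins = length(proteinIds(bundle@disease)),
        pathways = length(geneSets(bundle@pathways)))),
      paths$manifest, pretty = TRUE, auto_unbox = TRUE)
    TRUE
  }, error = function(e)
    stop("fixture write failed under ", directory, ": ",
         conditionMessage(e), call. = FALSE))
  invisible(paths)
}

#' Reload a scenario bundle from fixture files
#'
#' Inverse of [writeFixture()]: loads the network, compound table,
#' disease list and pathway library through the package's standard
#' loaders and reattaches the truth labels.
#'
#' @param directory directory written by [writeFixture()].
#' @param scenario the originating [SyntheticScenario-class] (kept on
#'   the bundle; reloading does not rerun any generator).
#' @return A [ScenarioBundle-class].
#' @export
readFixture <- function(directory, scenario) {
  manifest <- jsonlite::read_json(file.path(directory, "manifest.json"))
  truth <- jsonlite::read_json(file.path(directory, "truth.json"),
                               simplifyVector = TRUE)
  new("ScenarioBundle",
      network = loadMultiscaleNetwork(file.path(directory, "network.tsv")),
      compounds = loadCompoundTargets(file.path(directory, "compounds.tsv"),
                                      provenance = "synthetic"),
      disease = loadDiseaseProteins(file.path(directory, "disease.txt"),
                                    label = manifest$disease_label),
      pathways = readGMT(file.path(directory, "pathways.gmt"),
                         source = "synthetic"),
      truth = sort(as.character(truth$planted)), scenario = scenario)
}
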
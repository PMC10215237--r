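#' @import methods
#' @importFrom stats phyper p.adjust cor sd
#' @importFrom utils read.delim write.table head
#' @importClassesFrom Matrix Matrix
NULL

EDGE_CLASSES <- c("pp", "pf", "fp", "ff_up", "ff_down")
FILE_EDGE_CLASSES <- c("pp", "pf", "ff")
NODE_CLASSES <- c("protein", "function")

#' MultiscaleNetwork: a directed heterogeneous biological network
#'
#' A directed graph over protein and biological-function nodes with three
#' biological edge types stored as five directed edge classes:
#' `pp` (protein-protein, stored as reciprocal directed pairs), `pf`
#' (protein to annotated function) with its reverse `fp`, and function
#' hierarchy edges `ff_up` (child to parent) with reciprocal `ff_down`.
#'
#' @slot nodes data.frame with columns `id` (character, unique) and
#'   `node_class` (`"protein"` or `"function"`), sorted lexicographically
#'   by id. The lexicographic node order is the vector order used for all
#'   profile algebra.
#' @slot edges data.frame with columns `source`, `target`, `edge_class`;
#'   endpoints must exist in `nodes`, classes must match endpoint node
#'   classes, and self-loops are forbidden.
#'
#' @seealso [multiscaleNetwork()], [loadMultiscaleNetwork()],
#'   [generateMultiscaleNetwork()]
#' @export
setClass("MultiscaleNetwork",
  representation(nodes = "data.frame", edges = "data.frame"),
  validity = function(object) {
    msg <- character()
    nd <- object@nodes
    ed <- object@edges
    if (!all(c("id", "node_class") %in% names(nd)))
      return("nodes must have columns 'id' and 'node_class'")
    if (!all(c("source", "target", "edge_class") %in% names(ed)))
      return("edges must have columns 'source', 'target' and 'edge_class'")
    if (anyDuplicated(nd$id)) msg <- c(msg, "node ids must be unique")
    if (any(!nzchar(nd$id))) msg <- c(msg, "node ids must be nonempty")
    if (!all(nd$node_class %in% NODE_CLASSES))
      msg <- c(msg, "node_class must be 'protein' or 'function'")
    if (!all(ed$edge_class %in% EDGE_CLASSES))
      msg <- c(msg, sprintf("unknown edge_class value(s): %s",
        paste(setdiff(unique(ed$edge_class), EDGE_CLASSES), collapse = ", ")))
    bad <- setdiff(unique(c(ed$source, ed$target)), nd$id)
    if (length(bad))
      msg <- c(msg, sprintf("edge endpoints not in node table: %s",
        paste(head(bad, 5L), collapse = ", ")))
    if (any(ed$source == ed$target)) msg <- c(msg, "self-loops are forbidden")
    if (!length(msg) && nrow(ed)) {
      cls <- stats::setNames(nd$node_class, nd$id)
      want <- list(
        pp = c("protein", "protein"), pf = c("protein", "function"),
        fp = c("function", "protein"), ff_up = c("function", "function"),
        ff_down = c("function", "function"))
      for (ec in unique(ed$edge_class)) {
        sel <- ed$edge_class == ec
        ok <- cls[ed$source[sel]] == want[[ec]][1] &
          cls[ed$target[sel]] == want[[ec]][2]
        if (!all(ok)) {
          off <- ed[sel, ][!ok, , drop = FALSE]
          msg <- c(msg, sprintf(
            "edge class/endpoint mismatch for class '%s': %s", ec,
            paste(sprintf("%s->%s", head(off$source, 5L),
                          head(off$target, 5L)), collapse = ", ")))
        }
      }
    }
    if (length(msg)) msg else TRUE
  })

#' Construct a MultiscaleNetwork
#'
#' Canonicalizes node and edge order (lexicographic), drops duplicate
#' edges, and validates endpoint/class consistency.
#'
#' @param nodes data.frame with columns `id`, `node_class`.
#' @param edges data.frame with columns `source`, `target`, `edge_class`
#'   (directed; reciprocal pairs must already be present).
#' @return A [MultiscaleNetwork-class] object.
#' @export
multiscaleNetwork <- function(nodes, edges) {
  nodes <- data.frame(id = as.character(nodes$id),
                      node_class = as.character(nodes$node_class),
                      stringsAsFactors = FALSE)
  nodes <- nodes[order(nodes$id), , drop = FALSE]
  rownames(nodes) <- NULL
  edges <- data.frame(source = as.character(edges$source),
                      target = as.character(edges$target),
                      edge_class = as.character(edges$edge_class),
                      stringsAsFactors = FALSE)
  edges <- unique(edges)
  edges <- edges[order(edges$source, edges$target, edges$edge_class), ,
                 drop = FALSE]
  rownames(edges) <- NULL
  new("MultiscaleNetwork", nodes = nodes, edges = edges)
}

#' CompoundTargetTable: compound-protein interaction records
#'
#' The bipartite edge set of a compound-target network: one row per
#' unique compound-protein interaction (CPI).
#'
#' @slot records data.frame with columns `compound_id`, `compound_name`,
#'   `target_id`; `(compound_id, target_id)` pairs are unique.
#' @slot provenance free-text source label.
#' @seealso [compoundTargetTable()], [loadCompoundTargets()]
#' @export
setClass("CompoundTargetTable",
  representation(records = "data.frame", provenance = "character"),
  validity = function(object) {
    r <- object@records
    need <- c("compound_id", "compound_name", "target_id")
    if (!all(need %in% names(r)))
      return(sprintf("records must have columns: %s",
                     paste(need, collapse = ", ")))
    if (nrow(r)) {
      if (any(!nzchar(r$compound_id)) || any(!nzchar(r$target_id)))
        return("compound_id and target_id must be nonempty")
      if (anyDuplicated(r[c("compound_id", "target_id")]))
        return("duplicate (compound_id, target_id) pairs")
    }
    TRUE
  })

#' Construct a CompoundTargetTable
#'
#' @param records data.frame with columns `compound_id`, `compound_name`,
#'   `target_id`.
#' @param provenance free-text source label.
#' @return A [CompoundTargetTable-class] object.
#' @export
compoundTargetTable <- function(records, provenance = "unspecified") {
  records <- data.frame(
    compound_id = as.character(records$compound_id),
    compound_name = as.character(records$compound_name),
    target_id = as.character(records$target_id),
    stringsAsFactors = FALSE)
  records <- records[order(records$compound_id, records$target_id), ,
                     drop = FALSE]
  rownames(records) <- NULL
  new("CompoundTargetTable", records = records, provenance = provenance)
}

#' DiseaseProteinSet: disease-associated protein identifiers
#'
#' @slot ids unique protein identifiers (sorted).
#' @slot label disease name.
#' @slot coOccurrenceThreshold numeric metadata recording the text-mining
#'   co-occurrence threshold used to select the proteins (NA when unknown;
#'   not used in any computation).
#' @seealso [diseaseProteinSet()]
#' @export
setClass("DiseaseProteinSet",
  representation(ids = "character", label = "character",
                 coOccurrenceThreshold = "numeric"),
  validity = function(object) {
    if (anyDuplicated(object@ids)) return("ids must be unique")
    if (any(!nzchar(object@ids))) return("ids must be nonempty strings")
    TRUE
  })

#' Construct a DiseaseProteinSet
#'
#' @param ids character vector of protein identifiers.
#' @param label disease name.
#' @param coOccurrenceThreshold optional numeric metadata.
#' @return A [DiseaseProteinSet-class] object.
#' @export
diseaseProteinSet <- function(ids, label = "disease",
                              coOccurrenceThreshold = NA_real_) {
  new("DiseaseProteinSet", ids = sort(unique(as.character(ids))),
      label = label, coOccurrenceThreshold = coOccurrenceThreshold)
}

#' GeneSetLibrary: named gene sets (GMT-style)
#'
#' @slot sets named list of character vectors of protein ids.
#' @slot source label of the library source.
#' @seealso [geneSetLibrary()], [readGMT()], [writeGMT()]
#' @export
setClass("GeneSetLibrary",
  representation(sets = "list", source = "character"),
  validity = function(object) {
    s <- object@sets
    if (length(s)) {
      if (is.null(names(s)) || any(!nzchar(names(s))))
        return("all sets must be named")
      if (anyDuplicated(names(s))) return("set names must be unique")
      if (any(vapply(s, length, 1L) == 0L))
        return("set members must be nonempty")
    }
    TRUE
  })

#' Construct a GeneSetLibrary
#'
#' @param sets named list of character vectors.
#' @param source label of the library source.
#' @return A [GeneSetLibrary-class] object.
#' @export
geneSetLibrary <- function(sets, source = "unspecified") {
  sets <- lapply(sets, function(x) sort(unique(as.character(x))))
  new("GeneSetLibrary", sets = sets, source = source)
}

#' NetworkSummary: degree statistics of a compound-target network
#'
#' @slot nCompounds number of distinct compounds.
#' @slot nTargets number of distinct protein targets.
#' @slot nCpis number of unique compound-protein interactions.
#' @slot targetDegree named integer vector: per-target distinct-compound
#'   degree; its values sum to `nCpis`.
#' @seealso [summarizeNetwork()]
#' @export
setClass("NetworkSummary",
  representation(nCompounds = "integer", nTargets = "integer",
                 nCpis = "integer", targetDegree = "integer"),
  validity = function(object) {
    if (length(object@targetDegree) != object@nTargets)
      return("nTargets must equal length(targetDegree)")
    if (sum(object@targetDegree) != object@nCpis)
      return("sum of target degrees must equal nCpis")
    TRUE
  })

#' EnrichmentResult: one overlap / over-representation test outcome
#'
#' @slot name test label (e.g. pathway name or compound id).
#' @slot overlapK observed overlap count.
#' @slot queryN query set size (within background).
#' @slot setK reference set size (within background).
#' @slot backgroundN background universe size.
#' @slot pValue exact upper-tail hypergeometric p-value, P(X >= k).
#' @slot adjustedP multiplicity-adjusted p (NA for a single test).
#' @slot zScore standardized overlap (k - nK/N) / sigma under the
#'   hypergeometric null (NA when sigma = 0).
#' @slot combinedScore -ln(p) * z (0 with `flags` noting degeneracy when
#'   z is undefined).
#' @slot foldEnrichment observed / mean random overlap (NA unless a
#'   randomized null was run; Inf with a flag when the null mean is 0).
#' @slot empiricalP (1 + #random >= observed) / (n_iter + 1) (NA unless a
#'   randomized null was run).
#' @slot overlapMembers ids in the overlap.
#' @slot flags character notes about degeneracies (dropped ids, zero
#'   variance, infinite fold).
#' @export
setClass("EnrichmentResult",
  representation(name = "character", overlapK = "integer",
                 queryN = "integer", setK = "integer",
                 backgroundN = "integer", pValue = "numeric",
                 adjustedP = "numeric", zScore = "numeric",
                 combinedScore = "numeric", foldEnrichment = "numeric",
                 empiricalP = "numeric", overlapMembers = "character",
                 flags = "character"),
  validity = function(object) {
    if (object@overlapK > min(object@queryN, object@setK))
      return("overlapK cannot exceed min(queryN, setK)")
    if (object@overlapK != length(object@overlapMembers))
      return("overlapK must equal length(overlapMembers)")
    if (!is.na(object@pValue) &&
        (object@pValue <= 0 || object@pValue > 1))
      return("pValue must be in (0, 1]")
    if (!is.na(object@adjustedP) && !is.na(object@pValue) &&
        object@adjustedP < object@pValue - 1e-12)
      return("adjustedP must be >= pValue")
    TRUE
  })

#' DiffusionConfig: random-walk-with-restart parameters
#'
#' @slot continueProb probability `c` that the walker steps along an edge
#'   rather than restarting (restart probability is `1 - c`).
#' @slot edgeClassWeights named positive weights over the five directed
#'   edge classes; step probabilities out of a node are proportional to
#'   the weight of each out-edge's class.
#' @slot tolerance L1 convergence bound for power iteration.
#' @slot maxIterations iteration cap.
#' @slot k top-k size used for mechanism extraction.
#' @seealso [diffusionConfig()]
#' @export
setClass("DiffusionConfig",
  representation(continueProb = "numeric", edgeClassWeights = "numeric",
                 tolerance = "numeric", maxIterations = "integer",
                 k = "integer"),
  validity = function(object) {
    if (object@continueProb < 0 || object@continueProb >= 1)
      return("continueProb must satisfy 0 <= c < 1")
    if (!setequal(names(object@edgeClassWeights), EDGE_CLASSES))
      return(sprintf("edgeClassWeights must name exactly: %s",
                     paste(EDGE_CLASSES, collapse = ", ")))
    if (any(object@edgeClassWeights <= 0))
      return("edge class weights must be positive")
    if (object@tolerance <= 0) return("tolerance must be positive")
    if (object@maxIterations < 1L) return("maxIterations must be >= 1")
    if (object@k < 1L) return("k must be >= 1")
    TRUE
  })

#' Construct a DiffusionConfig
#'
#' Defaults: continue probability 0.85 (a standard restart setting for
#' personalized network propagation), unit weights for all edge classes
#' (an unbiased walk), L1 tolerance 1e-6, 1000 iterations, k = 20.
#'
#' @param continueProb probability in \[0, 1) that the walk continues.
#' @param edgeClassWeights named positive numeric over
#'   `pp, pf, fp, ff_up, ff_down` (missing classes default to 1).
#' @param tolerance positive L1 convergence bound.
#' @param maxIterations positive iteration cap.
#' @param k top-k size (default 20).
#' @return A [DiffusionConfig-class] object.
#' @export
diffusionConfig <- function(continueProb = 0.85, edgeClassWeights = NULL,
                            tolerance = 1e-6, maxIterations = 1000L,
                            k = 20L) {
  w <- stats::setNames(rep(1, length(EDGE_CLASSES)), EDGE_CLASSES)
  if (!is.null(edgeClassWeights)) {
    if (is.null(names(edgeClassWeights)) ||
        !all(names(edgeClassWeights) %in% EDGE_CLASSES))
      stop("edgeClassWeights must be named with edge classes among: ",
           paste(EDGE_CLASSES, collapse = ", "))
    w[names(edgeClassWeights)] <- edgeClassWeights
  }
  new("DiffusionConfig", continueProb = continueProb, edgeClassWeights = w,
      tolerance = tolerance, maxIterations = as.integer(maxIterations),
      k = as.integer(k))
}

#' RestartVector: teleport distribution of a restarting walker
#'
#' @slot entries named nonnegative probabilities over a subset of network
#'   nodes, summing to 1.
#' @slot label entity name (compound or disease).
#' @seealso [buildRestartVector()]
#' @export
setClass("RestartVector",
  representation(entries = "numeric", label = "character"),
  validity = function(object) {
    if (is.null(names(object@entries))) return("entries must be named")
    if (any(object@entries < 0)) return("entries must be nonnegative")
    if (abs(sum(object@entries) - 1) > 1e-9)
      return("entries must sum to 1")
    TRUE
  })

#' DiffusionProfile: stationary visit frequencies of a restarting walker
#'
#' The diffusion profile of an entity encodes its propagated effect over
#' every protein and biological-function node of the multiscale network.
#'
#' @slot visitFrequency named numeric vector over every network node
#'   (lexicographic id order), nonnegative, summing to 1.
#' @slot entity entity label.
#' @slot iterationsUsed number of power iterations performed (0 for the
#'   direct solve).
#' @slot converged whether the L1 tolerance was met.
#' @slot diagnostics list of run diagnostics; power iteration records
#'   `l1Trace`, the per-iteration L1 change.
#' @seealso [computeDiffusionProfile()], [solveStationaryExact()]
#' @export
setClass("DiffusionProfile",
  representation(visitFrequency = "numeric", entity = "character",
                 iterationsUsed = "integer", converged = "logical",
                 diagnostics = "list"),
  prototype(diagnostics = list()),
  validity = function(object) {
    v <- object@visitFrequency
    if (is.null(names(v))) return("visitFrequency must be named")
    if (any(v < -1e-12)) return("visit frequencies must be nonnegative")
    if (abs(sum(v) - 1) > 1e-6) return("visit frequencies must sum to 1")
    TRUE
  })

#' TransitionModel: row-stochastic biased step structure
#'
#' @slot W sparse row-stochastic matrix (rows = source nodes in
#'   lexicographic order); rows of dangling nodes are all zero.
#' @slot nodeIds node ids in matrix order.
#' @slot dangling logical: nodes with no out-edges (their walk mass is
#'   redirected to the restart vector at each step).
#' @seealso [buildTransitionMatrix()]
#' @export
setClass("TransitionModel",
  representation(W = "Matrix", nodeIds = "character", dangling = "logical"),
  validity = function(object) {
    if (nrow(object@W) != length(object@nodeIds) ||
        ncol(object@W) != length(object@nodeIds))
      return("W must be square with dim = length(nodeIds)")
    if (length(object@dangling) != length(object@nodeIds))
      return("dangling must have one entry per node")
    TRUE
  })

#' SyntheticScenario: parameters of a synthetic study condition
#'
#' Describes a miniature multiscale interactome, a compound library with
#' planted disease-proximal ("active") compounds, a network-localized
#' disease protein set, and a pathway library. Defaults emulate, at
#' reduced scale, the composition of a real multiscale interactome and
#' the target-set sizes (7-64) and disease-set size (91) typical of
#' herbal network-pharmacology studies.
#'
#' @slot nProteins number of protein nodes.
#' @slot nFunctions number of biological-function nodes.
#' @slot ppiEdges requested protein-protein edge count.
#' @slot annotationRate mean protein-function annotations per protein.
#' @slot hierarchyBranching mean parent links per function (the function
#'   DAG gets `max(nFunctions - 1, round(hierarchyBranching * nFunctions))`
#'   edges).
#' @slot nCompounds number of compounds.
#' @slot targetsPerCompound integer range (lo, hi) of target-set sizes.
#' @slot nDiseaseProteins disease protein set size.
#' @slot plantedCompounds compound ids planted as disease-proximal.
#' @slot plantedOverlapFraction fraction in \[0,1\] of a planted
#'   compound's targets drawn from the disease set or its 1-hop protein
#'   neighborhood.
#' @slot nPathways number of pathway gene sets.
#' @slot pathwaySizeRange integer range (lo, hi) of pathway sizes.
#' @slot seed integer seed from which all randomness flows.
#' @seealso [syntheticScenario()], [generateScenarioBundle()]
#' @export
setClass("SyntheticScenario",
  representation(nProteins = "integer", nFunctions = "integer",
                 ppiEdges = "integer", annotationRate = "numeric",
                 hierarchyBranching = "numeric", nCompounds = "integer",
                 targetsPerCompound = "integer",
                 nDiseaseProteins = "integer",
                 plantedCompounds = "character",
                 plantedOverlapFraction = "numeric",
                 nPathways = "integer", pathwaySizeRange = "integer",
                 seed = "integer"),
  validity = function(object) {
    msg <- character()
    pos <- c(nProteins = object@nProteins, nFunctions = object@nFunctions,
             ppiEdges = object@ppiEdges, nCompounds = object@nCompounds,
             nDiseaseProteins = object@nDiseaseProteins,
             nPathways = object@nPathways)
    if (any(pos < 1L))
      msg <- c(msg, sprintf("counts must be positive (%s)",
        paste(names(pos)[pos < 1L], collapse = ", ")))
    if (object@plantedOverlapFraction < 0 ||
        object@plantedOverlapFraction > 1)
      msg <- c(msg, "plantedOverlapFraction must be in [0, 1]")
    if (length(object@targetsPerCompound) != 2L ||
        object@targetsPerCompound[1] > object@targetsPerCompound[2] ||
        object@targetsPerCompound[1] < 1L)
      msg <- c(msg, "targetsPerCompound must be a valid (lo, hi) range")
    else if (object@targetsPerCompound[2] > object@nProteins)
      msg <- c(msg, "targetsPerCompound max cannot exceed nProteins")
    if (object@nDiseaseProteins > object@nProteins)
      msg <- c(msg, "nDiseaseProteins cannot exceed nProteins")
    if (length(object@pathwaySizeRange) != 2L ||
        object@pathwaySizeRange[1] > object@pathwaySizeRange[2] ||
        object@pathwaySizeRange[1] < 1L)
      msg <- c(msg, "pathwaySizeRange must be a valid (lo, hi) range")
    else if (object@pathwaySizeRange[2] > object@nProteins)
      msg <- c(msg, "pathwaySizeRange max cannot exceed nProteins")
    if (object@ppiEdges > object@nProteins * (object@nProteins - 1L) / 2)
      msg <- c(msg, "ppiEdges exceeds simple-graph capacity")
    if (length(msg)) msg else TRUE
  })

#' ScenarioBundle: one generated synthetic study condition
#'
#' @slot network the generated [MultiscaleNetwork-class].
#' @slot compounds the generated [CompoundTargetTable-class].
#' @slot disease the generated [DiseaseProteinSet-class].
#' @slot pathways the generated [GeneSetLibrary-class].
#' @slot truth planted ("active") compound ids; a subset of the compound
#'   roster.
#' @slot scenario the [SyntheticScenario-class] that produced the bundle.
#' @seealso [generateScenarioBundle()], [writeFixture()]
#' @export
setClass("ScenarioBundle",
  representation(network = "MultiscaleNetwork",
                 compounds = "CompoundTargetTable",
                 disease = "DiseaseProteinSet",
                 pathways = "GeneSetLibrary", truth = "character",
                 scenario = "SyntheticScenario"),
  validity = function(object) {
    prot <- object@network@nodes$id[
      object@network@nodes$node_class == "protein"]
    msg <- character()
    if (!all(object@compounds@records$target_id %in% prot))
      msg <- c(msg, "compound targets must be protein nodes of network")
    if (!all(object@disease@ids %in% prot))
      msg <- c(msg, "disease proteins must be protein nodes of network")
    if (!all(unlist(object@pathways@sets) %in% prot))
      msg <- c(msg, "pathway members must be protein nodes of network")
    if (!all(object@truth %in% object@compounds@records$compound_id))
      msg <- c(msg, "truth labels must be a subset of compound ids")
    if (length(msg)) msg else TRUE
  })

#' MechanismSubgraph: top-k mechanism subnetwork of a compound-disease pair
#'
#' Induced subnetwork of the top-k nodes of the compound and disease
#' diffusion profiles plus anchor nodes (compound targets, disease
#' proteins), pruned so every retained compound-side node has an
#' undirected path to a disease-side node within the subgraph and vice
#' versa.
#'
#' @slot nodes data.frame: `id`, `node_class`, `rank_compound`,
#'   `rank_disease` (rank of the node in each full profile),
#'   `freq_compound`, `freq_disease`, `is_compound_target`,
#'   `is_disease_protein`, `in_top_k_compound`, `in_top_k_disease`.
#' @slot edges induced edge list (source, target, edge_class).
#' @slot compound compound label.
#' @slot disease disease label.
#' @slot k the per-profile top-k size used.
#' @seealso [extractMechanismSubgraph()], [rankMechanismNodes()]
#' @export
setClass("MechanismSubgraph",
  representation(nodes = "data.frame", edges = "data.frame",
                 compound = "character", disease = "character",
                 k = "integer"))
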
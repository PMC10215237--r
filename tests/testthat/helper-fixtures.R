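# Shared fixture builders and independent oracles.

# Expand undirected layer tables (as stored on disk) into the directed
# edge list of a MultiscaleNetwork, mirroring the loader's reciprocity
# convention but built independently of it.
msnFromLayers <- function(pp = NULL, pf = NULL, ff = NULL) {
  edges <- data.frame(source = character(0), target = character(0),
                      edge_class = character(0), stringsAsFactors = FALSE)
  addRows <- function(e, s, t, cls)
    rbind(e, data.frame(source = s, target = t, edge_class = cls,
                        stringsAsFactors = FALSE))
  proteins <- character(0)
  functions <- character(0)
  if (!is.null(pp)) {
    edges <- addRows(edges, pp[[1]], pp[[2]], "pp")
    edges <- addRows(edges, pp[[2]], pp[[1]], "pp")
    proteins <- c(proteins, pp[[1]], pp[[2]])
  }
  if (!is.null(pf)) {
    edges <- addRows(edges, pf[[1]], pf[[2]], "pf")
    edges <- addRows(edges, pf[[2]], pf[[1]], "fp")
    proteins <- c(proteins, pf[[1]])
    functions <- c(functions, pf[[2]])
  }
  if (!is.null(ff)) {
    edges <- addRows(edges, ff[[1]], ff[[2]], "ff_up")
    edges <- addRows(edges, ff[[2]], ff[[1]], "ff_down")
    functions <- c(functions, ff[[1]], ff[[2]])
  }
  nodes <- data.frame(
    id = c(unique(proteins), unique(functions)),
    node_class = rep(c("protein", "function"),
                     c(length(unique(proteins)),
                       length(unique(functions)))),
    stringsAsFactors = FALSE)
  multiscaleNetwork(nodes, edges)
}

# Small scenario for fast generator-level tests.
smallScenario <- function(seed = 1L, ...) {
  args <- list(nProteins = 60L, nFunctions = 15L, ppiEdges = 180L,
               nCompounds = 5L, targetsPerCompound = c(3L, 8L),
               nDiseaseProteins = 8L, nPathways = 4L,
               pathwaySizeRange = c(5L, 12L), seed = seed)
  override <- list(...)
  args[names(override)] <- override
  do.call(syntheticScenario, args)
}

# Exhaustive-enumeration oracle for the upper-tail hypergeometric
# probability: draw n of N items of which the first K are "reference",
# P(overlap >= k) over all C(N, n) subsets.
enumHypergeomP <- function(N, K, n, k) {
  subsets <- utils::combn(N, n)
  overlaps <- colSums(subsets <= K)
  mean(overlaps >= k)
}

# Write a compound-target TSV from a data.frame of records.
writeCompoundTsv <- function(records, path = tempfile(fileext = ".tsv")) {
  write.table(records, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  path
}

# Pearson correlation from first principles (no stats::cor).
pearsonByHand <- function(x, y) {
  dx <- x - mean(x)
  dy <- y - mean(y)
  sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
}

profileFromVector <- function(v, entity = "manual") {
  new("DiffusionProfile", visitFrequency = v, entity = entity,
      iterationsUsed = 0L, converged = TRUE)
}

# All per-compound diffusion profiles of a bundle plus the disease
# profile, sharing one transition matrix.
bundleProfiles <- function(bundle, config = diffusionConfig()) {
  net <- bundle@network
  tm <- buildTransitionMatrix(net, config@edgeClassWeights)
  disease <- computeDiffusionProfile(
    net, buildRestartVector(net, proteinIds(bundle@disease), "disease"),
    config, transition = tm)
  recs <- cpiRecords(bundle@compounds)
  compounds <- lapply(split(recs$target_id, recs$compound_id),
    function(t) computeDiffusionProfile(
      net, buildRestartVector(net, t, "compound"), config,
      transition = tm))
  list(disease = disease, compounds = compounds, transition = tm)
}
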
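test_that("top-k selection orders by frequency with lexicographic ties", {
  p <- profileFromVector(c(A = 0.5, B = 0.3, C = 0.2))
  expect_identical(topKNodes(p, 2L), c("A", "B"))
  tie <- profileFromVector(c(C = 0.3, A = 0.4, B = 0.3))
  expect_identical(topKNodes(tie, 2L), c("A", "B"))
  expect_identical(topKNodes(p, 10L), c("A", "B", "C"))
  expect_error(topKNodes(p, 0L), "positive")
  expect_identical(formals(topKNodes)$k, 20L)
})

# A hand-built network with a deliberately severable compound target:
# chain X - P1 - P2 - D1 - D2 plus an off-path node Y attached to X only.
chainNet <- function() {
  msnFromLayers(pp = data.frame(
    s = c("X", "P1", "P2", "D1", "X"),
    t = c("P1", "P2", "D1", "D2", "Y")))
}

chainProfiles <- function(net) {
  cfg <- diffusionConfig(tolerance = 1e-12)
  tm <- buildTransitionMatrix(net, cfg@edgeClassWeights)
  list(
    compound = computeDiffusionProfile(
      net, buildRestartVector(net, "X", "cmp"), cfg, transition = tm),
    disease = computeDiffusionProfile(
      net, buildRestartVector(net, c("D1", "D2"), "dz"), cfg,
      transition = tm))
}

test_that("targets disconnected from the disease side are excluded", {
  net <- chainNet()
  pr <- chainProfiles(net)
  # k = 1 keeps only the top node of each profile; target Y's only
  # neighbor X is then absent, leaving Y without a path to any
  # disease-side node
  sg <- extractMechanismSubgraph(net, pr$compound, pr$disease,
                                 compoundTargets = c("Y", "D1"),
                                 diseaseProteins = c("D1", "D2"),
                                 k = 1L)
  expect_false("Y" %in% sg@nodes$id)
  expect_true("D1" %in% sg@nodes$id)
})

test_that("anchors on both sides are never pruned", {
  net <- chainNet()
  pr <- chainProfiles(net)
  # compound targets that ARE disease proteins sit on both sides, so
  # the exclusion rule can never remove them
  sg <- extractMechanismSubgraph(net, pr$compound, pr$disease,
                                 compoundTargets = c("D1", "D2"),
                                 diseaseProteins = c("D1", "D2"),
                                 k = 2L)
  expect_true(all(c("D1", "D2") %in% sg@nodes$id))
  expect_true(all(sg@nodes$is_compound_target[
    sg@nodes$id %in% c("D1", "D2")]))
  # with a large k the whole connected chain is retained untouched
  sgAll <- extractMechanismSubgraph(net, pr$compound, pr$disease,
                                    compoundTargets = c("D1", "D2"),
                                    diseaseProteins = c("D1", "D2"),
                                    k = 10L)
  expect_setequal(sgAll@nodes$id, nodeIds(net))
})

test_that("an unlinkable pair yields an empty subgraph with a warning", {
  # two disjoint protein components
  net <- msnFromLayers(pp = data.frame(s = c("A", "C"), t = c("B", "D")))
  cfg <- diffusionConfig(tolerance = 1e-12)
  cmp <- computeDiffusionProfile(net, buildRestartVector(net, "A", "cmp"),
                                 cfg)
  dz <- computeDiffusionProfile(net, buildRestartVector(net, "C", "dz"),
                                cfg)
  expect_warning(
    sg <- extractMechanismSubgraph(net, cmp, dz, compoundTargets = "A",
                                   diseaseProteins = "C", k = 1L),
    "empty")
  expect_identical(nrow(sg@nodes), 0L)
})

test_that("planted pairs stay linked and satisfy the connectivity invariant", {
  for (seed in c(1L, 7L)) {
    bundle <- generateScenarioBundle(syntheticScenario(seed = seed))
    pr <- bundleProfiles(bundle)
    planted <- bundle@truth[1]
    recs <- cpiRecords(bundle@compounds)
    tgts <- recs$target_id[recs$compound_id == planted]
    sg <- extractMechanismSubgraph(
      bundle@network, pr$compounds[[planted]], pr$disease,
      compoundTargets = tgts,
      diseaseProteins = proteinIds(bundle@disease), k = 20L)
    expect_gt(nrow(sg@nodes), 0)
    # BFS check: every compound anchor reaches a disease-side node
    g <- igraph::graph_from_data_frame(
      unique(sg@edges[c("source", "target")]), directed = FALSE,
      vertices = data.frame(name = sg@nodes$id))
    diseaseSide <- sg@nodes$id[sg@nodes$is_disease_protein |
                                 sg@nodes$in_top_k_disease]
    for (anchor in sg@nodes$id[sg@nodes$is_compound_target]) {
      reach <- igraph::subcomponent(g, anchor)$name
      expect_gt(length(intersect(reach, diseaseSide)), 0,
                label = paste("anchor", anchor, "seed", seed))
    }
    # the symmetric check for disease anchors
    compoundSide <- sg@nodes$id[sg@nodes$is_compound_target |
                                  sg@nodes$in_top_k_compound]
    for (anchor in sg@nodes$id[sg@nodes$is_disease_protein]) {
      reach <- igraph::subcomponent(g, anchor)$name
      expect_gt(length(intersect(reach, compoundSide)), 0)
    }
    # size bound: top-k of both profiles plus anchors
    expect_lte(nrow(sg@nodes),
               2L * 20L + length(unique(c(
                 tgts, proteinIds(bundle@disease)))))
    # anchor flags mirror the input sets
    expect_setequal(sg@nodes$id[sg@nodes$is_compound_target],
                    intersect(sg@nodes$id, tgts))
    expect_setequal(sg@nodes$id[sg@nodes$is_disease_protein],
                    intersect(sg@nodes$id, proteinIds(bundle@disease)))
  }
})

test_that("subgraph extraction is deterministic", {
  bundle <- generateScenarioBundle(smallScenario(seed = 12L))
  pr <- bundleProfiles(bundle)
  recs <- cpiRecords(bundle@compounds)
  tgts <- recs$target_id[recs$compound_id == "C01"]
  run <- function() {
    sg <- extractMechanismSubgraph(
      bundle@network, pr$compounds[["C01"]], pr$disease,
      compoundTargets = tgts,
      diseaseProteins = proteinIds(bundle@disease), k = 5L)
    out <- tempfile(fileext = ".tsv")
    exportMechanismSubgraph(sg, tsvPath = out)
    readLines(out)
  }
  expect_identical(run(), run())
})

test_that("mechanism node ranking puts the most-visited node first", {
  net <- chainNet()
  pr <- chainProfiles(net)
  sg <- extractMechanismSubgraph(net, pr$compound, pr$disease,
                                 compoundTargets = "X",
                                 diseaseProteins = c("D1", "D2"),
                                 k = 3L)
  tab <- rankMechanismNodes(sg)
  expect_identical(tab$max_visit_frequency[1],
                   max(pmax(sg@nodes$freq_compound,
                            sg@nodes$freq_disease)))
  expect_true(all(diff(tab$max_visit_frequency) <= 1e-15))
  expect_identical(tab$is_compound_target, tab$id %in% "X")
  emptySg <- suppressWarnings(extractMechanismSubgraph(
    msnFromLayers(pp = data.frame(s = c("A", "C"), t = c("B", "D"))),
    profileFromVector(c(A = 0.7, B = 0.3, C = 0, D = 0), "cmp"),
    profileFromVector(c(A = 0, B = 0, C = 0.7, D = 0.3), "dz"),
    compoundTargets = "A", diseaseProteins = "C", k = 1L))
  expect_error(rankMechanismNodes(emptySg), "empty")
})

test_that("GraphML export of a subgraph carries the node attributes", {
  net <- chainNet()
  pr <- chainProfiles(net)
  sg <- extractMechanismSubgraph(net, pr$compound, pr$disease,
                                 compoundTargets = "X",
                                 diseaseProteins = c("D1", "D2"),
                                 k = 3L)
  gml <- tempfile(fileext = ".graphml")
  sif <- tempfile(fileext = ".sif")
  exportMechanismSubgraph(sg, graphmlPath = gml, sifPath = sif)
  g <- igraph::read_graph(gml, format = "graphml")
  expect_setequal(igraph::V(g)$name, sg@nodes$id)
  expect_true("rank_compound" %in%
                igraph::vertex_attr_names(g))
  expect_match(readLines(sif)[1], "\tpp\t")
})
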
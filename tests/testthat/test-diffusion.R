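test_that("loading expands undirected layers to reciprocal directed edges", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("source\ttarget\tedge_class", "P1\tP2\tpp"), path)
  net <- loadMultiscaleNetwork(path)
  expect_identical(nrow(edgeTable(net)), 2L)
  expect_setequal(paste(edgeTable(net)$source, edgeTable(net)$target),
                  c("P1 P2", "P2 P1"))
  writeLines(c("source\ttarget\tedge_class",
               "P1\tP2\tpp", "P1\tF1\tpf", "F1\tF2\tff"), path)
  net2 <- loadMultiscaleNetwork(path)
  ecl <- table(edgeTable(net2)$edge_class)
  expect_identical(as.integer(ecl[c("pp", "pf", "fp", "ff_up", "ff_down")]),
                   c(2L, 1L, 1L, 1L, 1L))
  expect_identical(unname(nodeClasses(net2)[c("P1", "F2")]),
                   c("protein", "function"))
})

test_that("class/endpoint mismatches are rejected with offenders listed", {
  path <- tempfile(fileext = ".tsv")
  # F1 is a function (pf target) but also used as a pf source
  writeLines(c("source\ttarget\tedge_class",
               "P1\tF1\tpf", "F1\tF2\tpf"), path)
  expect_error(loadMultiscaleNetwork(path), "F1")
  writeLines(c("source\ttarget\tedge_class", "P1\tP2\txx"), path)
  expect_error(loadMultiscaleNetwork(path), "unknown edge_class")
  writeLines(c("source\ttarget", "P1\tP2"), path)
  expect_error(loadMultiscaleNetwork(path), "edge_class")
})

test_that("loaded fixtures match the generator's manifest counts", {
  bundle <- generateScenarioBundle(smallScenario(seed = 10L))
  d <- tempfile("fx")
  writeFixture(bundle, d)
  net <- loadMultiscaleNetwork(file.path(d, "network.tsv"))
  manifest <- jsonlite::read_json(file.path(d, "manifest.json"),
                                  simplifyVector = TRUE)
  ecl <- table(edgeTable(net)$edge_class)
  for (cls in names(manifest$counts$directed_edges_by_class))
    expect_identical(as.integer(ecl[[cls]]),
                     manifest$counts$directed_edges_by_class[[cls]],
                     label = cls)
})

test_that("restart vectors spread uniform mass over mapped anchors", {
  net <- msnFromLayers(pp = data.frame(s = c("A", "B"), t = c("B", "C")))
  r <- buildRestartVector(net, c("A", "B"), "x")
  expect_equal(r@entries, c(A = 0.5, B = 0.5))
  expect_warning(r2 <- buildRestartVector(net, c("A", "X"), "x"),
                 "not in network")
  expect_equal(r2@entries, c(A = 1))
  expect_error(buildRestartVector(net, c("X", "Y"), "x"),
               "no network anchor")
})

test_that("step probabilities are proportional to edge-class weights", {
  net <- msnFromLayers(
    pp = data.frame(s = c("P1", "P1"), t = c("P2", "P3")),
    pf = data.frame(s = "P1", t = "F1"))
  tm <- buildTransitionMatrix(net, c(pp = 1, pf = 2))
  ids <- tm@nodeIds
  w <- as.matrix(tm@W)
  rownames(w) <- colnames(w) <- ids
  expect_equal(unname(w["P1", c("P2", "P3", "F1")]),
               c(0.25, 0.25, 0.5))
  # equal weights: uniform over out-neighbors
  tmU <- buildTransitionMatrix(net)
  wU <- as.matrix(tmU@W)
  rownames(wU) <- colnames(wU) <- ids
  expect_equal(unname(wU["P1", c("P2", "P3", "F1")]), rep(1 / 3, 3))
  expect_true(all(abs(Matrix::rowSums(tm@W)[!tm@dangling] - 1) < 1e-12))
  expect_error(buildTransitionMatrix(net, c(pp = -1)), "positive")
})

test_that("dangling nodes are flagged and teleported to the restart vector", {
  # one-way hierarchy edge leaves F2 with no out-edges
  net <- multiscaleNetwork(
    nodes = data.frame(id = c("P1", "P2", "F1", "F2"),
                       node_class = c("protein", "protein",
                                      "function", "function")),
    edges = data.frame(
      source = c("P1", "P2", "P1", "F1", "F1"),
      target = c("P2", "P1", "F1", "P1", "F2"),
      edge_class = c("pp", "pp", "pf", "fp", "ff_up")))
  expect_message(tm <- buildTransitionMatrix(net), "1 dangling")
  expect_identical(sum(tm@dangling), 1L)
  cfg <- diffusionConfig(tolerance = 1e-12)
  rs <- buildRestartVector(net, "P1", "x")
  p <- computeDiffusionProfile(net, rs, cfg, transition = tm)
  ex <- solveStationaryExact(net, rs, cfg, transition = tm)
  expect_equal(sum(visitFrequency(p)), 1, tolerance = 1e-9)
  expect_lt(max(abs(visitFrequency(p) - visitFrequency(ex))), 1e-8)
})

test_that("c = 0 returns the restart vector exactly", {
  net <- generateMultiscaleNetwork(smallScenario(seed = 2L))
  rs <- buildRestartVector(net, c("P0001", "P0002", "P0003"), "x")
  p <- computeDiffusionProfile(net, rs, diffusionConfig(continueProb = 0))
  v <- visitFrequency(p)
  expect_equal(unname(v[c("P0001", "P0002", "P0003")]), rep(1 / 3, 3))
  expect_equal(sum(v), 1)
  expect_identical(sum(v > 0), 3L)
})

test_that("the two-node closed form is reproduced", {
  net <- msnFromLayers(pp = data.frame(s = "A", t = "B"))
  rs <- buildRestartVector(net, "A", "x")
  cfg <- diffusionConfig(continueProb = 0.5, tolerance = 1e-14,
                         maxIterations = 2000L)
  p <- computeDiffusionProfile(net, rs, cfg)
  expect_equal(unname(visitFrequency(p)), c(2 / 3, 1 / 3),
               tolerance = 1e-10)
  ex <- solveStationaryExact(net, rs, cfg)
  expect_equal(unname(visitFrequency(ex)), c(2 / 3, 1 / 3),
               tolerance = 1e-12)
})

test_that("uniform restart on a degree-regular graph stays uniform", {
  # 4-cycle of proteins: every node has degree 2
  net <- msnFromLayers(pp = data.frame(
    s = c("A", "B", "C", "D"), t = c("B", "C", "D", "A")))
  rs <- buildRestartVector(net, c("A", "B", "C", "D"), "u")
  p <- computeDiffusionProfile(net, rs, diffusionConfig(tolerance = 1e-12))
  expect_equal(unname(visitFrequency(p)), rep(0.25, 4), tolerance = 1e-9)
})

test_that("power iteration agrees with the direct solve on random fixtures", {
  cfg <- diffusionConfig(tolerance = 1e-13, maxIterations = 3000L)
  for (seed in c(1L, 2L, 3L)) {
    sc <- smallScenario(seed = seed, nProteins = 50L, ppiEdges = 120L,
                        nFunctions = 12L)
    net <- generateMultiscaleNetwork(sc)
    tm <- buildTransitionMatrix(net, cfg@edgeClassWeights)
    rs <- buildRestartVector(
      net, proteinIds(generateDisease(net, sc)), "d")
    pw <- computeDiffusionProfile(net, rs, cfg, transition = tm)
    ex <- solveStationaryExact(net, rs, cfg, transition = tm)
    expect_lt(max(abs(visitFrequency(pw) - visitFrequency(ex))), 1e-8)
    expect_true(isConverged(pw))
  }
})

test_that("profiles are normalized probability vectors over all nodes", {
  net <- generateMultiscaleNetwork(smallScenario(seed = 5L))
  rs <- buildRestartVector(net, "P0010", "x")
  p <- computeDiffusionProfile(net, rs)
  v <- visitFrequency(p)
  expect_identical(names(v), nodeIds(net))
  expect_true(all(v >= 0))
  expect_equal(sum(v), 1, tolerance = 1e-9)
})

test_that("as c approaches 0 the profile approaches the restart vector", {
  net <- generateMultiscaleNetwork(smallScenario(seed = 5L))
  rs <- buildRestartVector(net, c("P0001", "P0010"), "x")
  cc <- 0.01
  p <- computeDiffusionProfile(
    net, rs, diffusionConfig(continueProb = cc, tolerance = 1e-13))
  s <- stats::setNames(numeric(length(nodeIds(net))), nodeIds(net))
  s[names(rs@entries)] <- rs@entries
  expect_lte(sum(abs(visitFrequency(p) - s)), 2 * cc / (1 - cc))
})

test_that("the L1 change contracts geometrically with ratio at most c", {
  net <- generateMultiscaleNetwork(smallScenario(seed = 9L))
  cc <- 0.85
  p <- computeDiffusionProfile(
    net, buildRestartVector(net, "P0007", "x"),
    diffusionConfig(continueProb = cc, tolerance = 1e-12))
  tr <- p@diagnostics$l1Trace
  ratios <- tr[-1] / tr[-length(tr)]
  expect_true(all(ratios <= cc + 1e-9))
})

test_that("non-convergence is reported honestly", {
  net <- generateMultiscaleNetwork(smallScenario(seed = 2L))
  expect_warning(
    p <- computeDiffusionProfile(
      net, buildRestartVector(net, "P0001", "x"),
      diffusionConfig(tolerance = 1e-14, maxIterations = 3L)),
    "did not converge")
  expect_false(isConverged(p))
  expect_identical(p@iterationsUsed, 3L)
})

test_that("a simulated restarting walker reproduces the profile", {
  sc <- smallScenario(seed = 3L)
  net <- generateMultiscaleNetwork(sc)
  cfg <- diffusionConfig(tolerance = 1e-12)
  tm <- buildTransitionMatrix(net, cfg@edgeClassWeights)
  rs <- buildRestartVector(net, proteinIds(generateDisease(net, sc)), "d")
  ex <- solveStationaryExact(net, rs, cfg, transition = tm)
  w <- simulateWalker(net, rs, cfg, nSteps = 1e6, seed = 11L,
                      transition = tm)
  z <- abs(w$freq - visitFrequency(ex)) / pmax(w$se, 1e-12)
  expect_lt(max(z), 3)
})

test_that("profile correlation matches the Pearson formula", {
  a <- profileFromVector(c(A = 0.5, B = 0.3, C = 0.2), "a")
  b <- profileFromVector(c(A = 0.2, B = 0.3, C = 0.5), "b")
  expect_equal(correlateProfiles(a, a), 1)
  expect_equal(correlateProfiles(a, b), -0.9285714, tolerance = 1e-6)
  expect_equal(correlateProfiles(a, b),
               pearsonByHand(visitFrequency(a), visitFrequency(b)),
               tolerance = 1e-12)
  u <- profileFromVector(c(A = 1 / 3, B = 1 / 3, C = 1 / 3), "uniform")
  expect_error(correlateProfiles(a, u), "zero-variance")
  d <- profileFromVector(c(A = 0.5, D = 0.5), "d")
  expect_error(correlateProfiles(a, d), "node universe")
})

test_that("compound ranking sorts by correlation with deterministic ties", {
  disease <- profileFromVector(c(A = 0.6, B = 0.3, C = 0.1), "disease")
  profs <- list(
    c2 = profileFromVector(c(A = 0.55, B = 0.35, C = 0.10), "c2"),
    c1 = profileFromVector(c(A = 0.55, B = 0.35, C = 0.10), "c1"),
    c3 = profileFromVector(c(A = 0.10, B = 0.35, C = 0.55), "c3"))
  rk <- rankCompounds(profs, disease)
  expect_identical(rk$compound, c("c1", "c2", "c3"))
  expect_true(all(diff(rk$correlation) <= 0))
  one <- rankCompounds(profs["c3"], disease)
  expect_identical(nrow(one), 1L)
  expect_error(rankCompounds(list(), disease), "at least one")
})

test_that("profile TSV output is well-formed", {
  net <- msnFromLayers(pp = data.frame(s = "A", t = "B"))
  p <- computeDiffusionProfile(
    net, buildRestartVector(net, "A", "x"),
    diffusionConfig(continueProb = 0.5, tolerance = 1e-12))
  out <- tempfile(fileext = ".tsv")
  writeDiffusionProfile(p, net, out)
  df <- read.delim(out)
  expect_identical(names(df),
                   c("node_id", "node_class", "visit_frequency"))
  expect_equal(sum(df$visit_frequency), 1, tolerance = 1e-9)
})
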
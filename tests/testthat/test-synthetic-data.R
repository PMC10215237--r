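test_that("network generation is a pure function of the seed", {
  a <- generateMultiscaleNetwork(smallScenario(seed = 7L))
  b <- generateMultiscaleNetwork(smallScenario(seed = 7L))
  c <- generateMultiscaleNetwork(smallScenario(seed = 8L))
  expect_identical(a@edges, b@edges)
  expect_identical(a@nodes, b@nodes)
  expect_false(identical(a@edges, c@edges))
})

test_that("generated networks have the requested node classes and no isolates", {
  net <- generateMultiscaleNetwork(
    syntheticScenario(nProteins = 200L, nFunctions = 50L, seed = 7L))
  cls <- nodeClasses(net)
  expect_identical(sum(cls == "protein"), 200L)
  expect_identical(sum(cls == "function"), 50L)
  touched <- unique(c(net@edges$source, net@edges$target))
  expect_setequal(touched, nodeIds(net))
  expect_true(validObject(net))
})

test_that("scaled interactome composition is realized within 10%", {
  # real multiscale interactome scaled by ~1/100:
  # 17660 proteins / 387626 pp, 34777 pf, 9798 functions / 22545 ff
  reqP <- 177L; reqF <- 64L
  reqPP <- 3876L; reqPF <- 348L; reqFF <- 225L
  sc <- syntheticScenario(
    nProteins = reqP, nFunctions = reqF, ppiEdges = reqPP,
    annotationRate = reqPF / reqP, hierarchyBranching = reqFF / reqF,
    nDiseaseProteins = 20L, seed = 11L)
  net <- generateMultiscaleNetwork(sc)
  ecl <- table(net@edges$edge_class)
  gotPP <- ecl[["pp"]] / 2
  gotPF <- ecl[["pf"]]
  gotFF <- ecl[["ff_up"]]
  expect_lt(abs(gotPP - reqPP) / reqPP, 0.10)
  expect_lt(abs(gotPF - reqPF) / reqPF, 0.10)
  expect_lt(abs(gotFF - reqFF) / reqFF, 0.10)
  expect_identical(ecl[["pf"]], ecl[["fp"]])
  expect_identical(ecl[["ff_up"]], ecl[["ff_down"]])
})

test_that("impossible edge counts are rejected", {
  expect_error(smallScenario(nProteins = 10L, ppiEdges = 100L),
               "capacity")
})

test_that("planted compounds sit in the disease neighborhood, decoys outside", {
  sc <- smallScenario(seed = 5L, plantedOverlapFraction = 1.0)
  net <- generateMultiscaleNetwork(sc)
  dz <- generateDisease(net, sc)
  tab <- generateCompoundLibrary(net, sc, dz)
  recs <- cpiRecords(tab)
  g <- igraph::graph_from_data_frame(
    unique(net@edges[net@edges$edge_class == "pp", 1:2]),
    directed = FALSE)
  pool <- union(proteinIds(dz),
                unique(unlist(lapply(
                  igraph::adjacent_vertices(g, proteinIds(dz)),
                  function(v) igraph::V(g)$name[v]))))
  planted <- recs$target_id[recs$compound_id == "C01"]
  expect_true(all(planted %in% pool))
  # decoys never touch the disease set while the outside pool suffices
  for (cid in setdiff(unique(recs$compound_id), "C01")) {
    decoy <- recs$target_id[recs$compound_id == cid]
    expect_length(intersect(decoy, proteinIds(dz)), 0)
  }
})

test_that("target-set sizes respect the scenario range", {
  sc <- syntheticScenario(seed = 13L)  # 14 compounds, sizes in [7, 64]
  net <- generateMultiscaleNetwork(sc)
  dz <- generateDisease(net, sc)
  tab <- generateCompoundLibrary(net, sc, dz)
  sizes <- table(cpiRecords(tab)$compound_id)
  expect_length(sizes, 14L)
  expect_true(all(sizes >= 7 & sizes <= 64))
})

test_that("disease generator returns the requested localized cluster", {
  sc91 <- syntheticScenario(nDiseaseProteins = 91L, seed = 3L)
  net <- generateMultiscaleNetwork(sc91)
  dz <- generateDisease(net, sc91)
  expect_length(proteinIds(dz), 91L)
  expect_true(all(nodeClasses(net)[proteinIds(dz)] == "protein"))

  sc1 <- smallScenario(nDiseaseProteins = 1L, seed = 3L)
  net1 <- generateMultiscaleNetwork(sc1)
  expect_length(proteinIds(generateDisease(net1, sc1)), 1L)

  # distinct seeds give distinct clusters nearly always
  net0 <- generateMultiscaleNetwork(smallScenario(seed = 1L))
  sets <- vapply(1:20, function(s) paste(
    proteinIds(generateDisease(net0, smallScenario(seed = s))),
    collapse = ","), "")
  expect_gte(length(unique(sets)), 18L)
})

test_that("pathway library has the requested shape and is seeded with the disease", {
  sc <- smallScenario(seed = 9L, nPathways = 9L,
                      pathwaySizeRange = c(10L, 35L))
  net <- generateMultiscaleNetwork(sc)
  lib <- generatePathwayLibrary(net, sc)
  sizes <- vapply(geneSets(lib), length, 1L)
  expect_length(sizes, 9L)
  expect_true(all(sizes >= 10 & sizes <= 35))
  dz <- proteinIds(generateDisease(net, sc))
  expect_gt(length(intersect(geneSets(lib)[[1]], dz)), 0)
})

test_that("identical scenario and seed give byte-identical fixtures", {
  sc <- smallScenario(seed = 21L)
  d1 <- file.path(tempfile("fx"), "a")
  d2 <- file.path(tempfile("fx"), "b")
  writeFixture(generateScenarioBundle(sc), d1)
  writeFixture(generateScenarioBundle(sc), d2)
  for (f in c("network.tsv", "compounds.tsv", "disease.txt",
              "pathways.gmt", "truth.json")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
})

test_that("fixtures round-trip through the loaders", {
  sc <- smallScenario(seed = 4L)
  bundle <- generateScenarioBundle(sc)
  d <- tempfile("fx")
  paths <- writeFixture(bundle, d)
  expect_true(dir.exists(d))
  back <- readFixture(d, sc)
  expect_identical(bundle@network@edges, back@network@edges)
  expect_identical(bundle@network@nodes, back@network@nodes)
  expect_identical(cpiRecords(bundle@compounds), cpiRecords(back@compounds))
  expect_identical(proteinIds(bundle@disease), proteinIds(back@disease))
  expect_identical(geneSets(bundle@pathways), geneSets(back@pathways))
  expect_identical(bundle@truth, back@truth)
})

test_that("unwritable fixture paths fail naming the path", {
  bundle <- generateScenarioBundle(smallScenario(seed = 4L))
  blocker <- tempfile("blocked")
  file.create(blocker)  # a file, so it cannot become a directory
  bad <- file.path(blocker, "sub")
  expect_error(writeFixture(bundle, bad), "blocked")
})

test_that("referential closure: all downstream ids resolve to network proteins", {
  for (seed in c(2L, 12L)) {
    bundle <- generateScenarioBundle(smallScenario(seed = seed))
    prot <- nodeIds(bundle@network)[
      nodeClasses(bundle@network) == "protein"]
    expect_true(all(cpiRecords(bundle@compounds)$target_id %in% prot))
    expect_true(all(proteinIds(bundle@disease) %in% prot))
    expect_true(all(unlist(geneSets(bundle@pathways)) %in% prot))
    expect_true(all(bundle@truth %in%
                      cpiRecords(bundle@compounds)$compound_id))
  }
})

test_that("planted compounds overlap the disease more than decoys on average", {
  plantedFrac <- numeric(0)
  decoyFrac <- numeric(0)
  for (seed in 1:20) {
    sc <- smallScenario(seed = seed, plantedOverlapFraction = 0.5)
    bundle <- generateScenarioBundle(sc)
    dz <- proteinIds(bundle@disease)
    recs <- cpiRecords(bundle@compounds)
    byCompound <- split(recs$target_id, recs$compound_id)
    frac <- vapply(byCompound, function(t)
      length(intersect(t, dz)) / length(t), 1)
    plantedFrac <- c(plantedFrac, frac[bundle@truth])
    decoyFrac <- c(decoyFrac, frac[setdiff(names(frac), bundle@truth)])
  }
  expect_gt(mean(plantedFrac), mean(decoyFrac))
})
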
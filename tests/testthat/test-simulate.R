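test_that("the generator is reproducible from its seed", {
  spec <- simSpec(nGenes = 200L, meanDegree = 8, nDiseaseSeeds = 16L,
                  nDrugs = 3L, rngSeed = 7L)
  n1 <- simulateNetwork(spec)
  n2 <- simulateNetwork(spec)
  expect_identical(edges(n1), edges(n2))
  s1 <- simulateStudy(spec)
  s2 <- simulateStudy(spec)
  expect_identical(edges(s1$network), edges(s2$network))
  expect_identical(s1$disease@records, s2$disease@records)
  expect_identical(zscores(s1$drugs[[2]]), zscores(s2$drugs[[2]]))
})

test_that("raw edge count matches the binomial moments of the ER model", {
  spec <- simSpec(nGenes = 200L, meanDegree = 8, rngSeed = 3L)
  net <- simulateNetwork(spec)
  nPairs <- choose(200, 2)
  p <- 8 / 199
  expected <- nPairs * p
  sdEdges <- sqrt(nPairs * p * (1 - p))
  expect_lte(abs(net@metadata$rawEdges - expected), 3 * sdEdges)
  # pruning only removes edges
  expect_lte(numEdges(net), net@metadata$rawEdges)
})

test_that("weights that cannot clear the pruning floor are an error", {
  spec <- simSpec(nGenes = 100L, meanDegree = 6, weightShape1 = 0.5,
                  weightShape2 = 400, rngSeed = 1L)
  expect_error(simulateNetwork(spec), "resamples")
})

test_that("the disease DEG filter recovers exactly the planted module", {
  for (seed in c(2L, 5L)) {
    spec <- simSpec(nGenes = 250L, meanDegree = 8, nDiseaseSeeds = 20L,
                    rngSeed = seed)
    net <- simulateNetwork(spec)
    dis <- simulateDisease(spec, net)
    planted <- selectDiseaseDegs(dis)
    expect_length(planted, 20L)
    # connected by construction
    sub <- igraph::induced_subgraph(net@graph, planted)
    expect_true(igraph::is_connected(sub))
  }
  # different seeds give different modules
  spec <- simSpec(nGenes = 250L, meanDegree = 8, nDiseaseSeeds = 20L)
  netA <- simulateNetwork(simSpec(nGenes = 250L, meanDegree = 8,
                                  nDiseaseSeeds = 20L, rngSeed = 2L))
  dA <- selectDiseaseDegs(simulateDisease(
    simSpec(nGenes = 250L, meanDegree = 8, nDiseaseSeeds = 20L,
            rngSeed = 2L), netA))
  dB <- selectDiseaseDegs(simulateDisease(
    simSpec(nGenes = 250L, meanDegree = 8, nDiseaseSeeds = 20L,
            rngSeed = 5L), netA))
  expect_false(setequal(dA, dB))
})

test_that("full reversal strength negates disease z exactly on shared DEGs", {
  spec <- simSpec(nGenes = 250L, meanDegree = 8, nDiseaseSeeds = 20L,
                  nDrugs = 2L, reversalStrength = 1, rngSeed = 11L)
  st <- simulateStudy(spec)
  rev <- st$drugs[[1]]
  shared <- intersect(selectDrugDegs(rev), st$truth$plantedModule)
  expect_gt(length(shared), 5L)
  sums <- zLookup(rev, shared) + zLookup(st$disease, shared)
  expect_equal(sums, rep(0, length(shared)), tolerance = 1e-12)
})

test_that("every simulated drug passes the DEG filter; decoys are matched", {
  st <- simulateStudy(simSpec(nGenes = 250L, meanDegree = 8,
                              nDiseaseSeeds = 20L, nDrugs = 6L,
                              rngSeed = 13L))
  degs <- lapply(st$drugs, selectDrugDegs)
  expect_true(all(lengths(degs) > 0))
  # decoys carry the full matched DEG set size
  expect_true(all(lengths(degs[-1]) >= 20L))
})

test_that("decoy overlap with the planted module matches the hypergeometric mean", {
  overlaps <- c()
  for (seed in 1:3) {
    st <- simulateStudy(simSpec(rngSeed = seed))  # defaults: n=500, m=40
    planted <- st$truth$plantedModule
    for (d in st$drugs[-1])
      overlaps <- c(overlaps, length(intersect(selectDrugDegs(d), planted)))
  }
  expected <- 40 * 40 / 500  # |DEG| * |module| / n
  expect_lte(abs(mean(overlaps) - expected), 1)
})

test_that("writeStudy emits the pipeline's input layout and round-trips", {
  st <- simulateStudy(simSpec(nGenes = 150L, meanDegree = 8,
                              nDiseaseSeeds = 12L, nDrugs = 2L,
                              rngSeed = 17L))
  dir <- tempfile()
  writeStudy(st, dir)
  net <- loadNetwork(file.path(dir, "fin.tsv"))
  expect_identical(edges(net), edges(st$network))
  dis <- readDiseaseSignature(file.path(dir, "disease.tsv"))
  expect_setequal(selectDiseaseDegs(dis), st$truth$plantedModule)
  drugs <- readDrugManifest(file.path(dir, "manifest.tsv"))
  expect_equal(vapply(drugs, drugId, ""),
               vapply(st$drugs, drugId, ""))
  expect_equal(zscores(drugs[[1]]), zscores(st$drugs[[1]]))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  expect_equal(truth$reversalDrug, "reversal")
})
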
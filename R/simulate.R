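# Synthetic benchmark generator: sparse weighted interactome, planted
# connected disease module, one signature-reversing drug among decoys.
#
# Every stage derives its seed from rngSeed plus a fixed offset (network
# +0, disease +1, drugs +2), so standalone calls and simulateStudy()
# produce identical data.

#' Build a simulation specification
#'
#' Defaults describe the benchmark condition used throughout the
#' package's property tests: a 500-gene interactome at mean degree 10
#' with right-skewed Beta(0.7, 5) edge weights (mimicking real
#' functional-interaction weight histograms whose mass concentrates
#' below 0.1), a planted connected disease module of 40 genes, and 25
#' drugs of which one reverses the disease signature at strength 0.9.
#'
#' @param nGenes,edgeModel,meanDegree,weightShape1,weightShape2,nDiseaseSeeds,nDrugs,reversalStrength,degZScale,rngSeed see [SimSpec-class].
#' @return a [SimSpec-class].
#' @export
simSpec <- function(nGenes = 500L, edgeModel = "erdos_renyi",
                    meanDegree = 10, weightShape1 = 0.7, weightShape2 = 5,
                    nDiseaseSeeds = 40L, nDrugs = 25L,
                    reversalStrength = 0.9, degZScale = 1.0,
                    rngSeed = 1L) {
  methods::new("SimSpec", nGenes = as.integer(nGenes), edgeModel = edgeModel,
               meanDegree = meanDegree, weightShape1 = weightShape1,
               weightShape2 = weightShape2,
               nDiseaseSeeds = as.integer(nDiseaseSeeds),
               nDrugs = as.integer(nDrugs),
               reversalStrength = reversalStrength, degZScale = degZScale,
               rngSeed = as.integer(rngSeed))
}

.geneNames <- function(n) sprintf("g%04d", seq_len(n))

# sub-threshold background draw, truncated so it can never cross the
# DEG filters by accident
.backgroundZ <- function(n) pmax(pmin(rnorm(n, 0, 0.05), 0.95), -0.95)

.supraZ <- function(n, scale) {
  sign <- sample(c(-1, 1), n, replace = TRUE)
  sign * (1 + abs(rnorm(n, 0, scale)))
}

#' Simulate a weighted functional interaction network
#'
#' Draws a random graph (Erdos-Renyi or Barabasi-Albert) at the
#' requested mean degree, assigns Beta-distributed edge weights, and
#' sends it through the standard pruning path (floor 0.1).  The result
#' must keep at least 90% of its surviving nodes in one connected
#' component; otherwise the draw is repeated (at most 100 times).
#'
#' @param spec a [SimSpec-class].
#' @return a [WeightedNetwork-class]; `metadata` records the raw edge
#'   count before pruning and the number of attempts.
#' @export
simulateNetwork <- function(spec) {
  stopifnot(methods::is(spec, "SimSpec"))
  set.seed(spec@rngSeed)
  n <- spec@nGenes
  for (attempt in seq_len(100L)) {
    g <- if (spec@edgeModel == "erdos_renyi") {
      igraph::sample_gnp(n, p = min(1, spec@meanDegree / (n - 1)))
    } else {
      igraph::sample_pa(n, m = max(1L, round(spec@meanDegree / 2)),
                        directed = FALSE)
    }
    igraph::V(g)$name <- .geneNames(n)
    edf <- igraph::as_data_frame(g, what = "edges")
    if (!nrow(edf)) next
    edf$weight <- rbeta(nrow(edf), spec@weightShape1, spec@weightShape2)
    net <- tryCatch(
      .newNetwork(edf, weightFloor = 0.1,
                  metadata = list(source = "simulated",
                                  rawEdges = nrow(edf),
                                  attempts = attempt)),
      error = function(e) NULL
    )
    if (is.null(net)) next
    comp <- igraph::components(net@graph)
    if (max(comp$csize) >= 0.9 * numNodes(net)) return(net)
  }
  stop("could not reach the 90% largest-component target in 100 resamples",
       call. = FALSE)
}

#' Simulate a disease signature with a planted connected module
#'
#' Grows a connected module of `nDiseaseSeeds` genes by breadth-first
#' search from a random root in the network's largest component.
#' Planted genes receive FDR ~ U(0, 0.009), |log2FC| >= 1 and a
#' supra-threshold signed z (|z| = 1 + half-normal of scale
#' `degZScale`, sign matching the fold-change); all other network genes
#' receive values that fail both DEG filters.  The DEG filter therefore
#' recovers exactly the planted module.
#'
#' @param spec a [SimSpec-class].
#' @param net the [WeightedNetwork-class] from [simulateNetwork()].
#' @return a [DiseaseSignature-class] over all network genes.
#' @export
simulateDisease <- function(spec, net) {
  stopifnot(methods::is(spec, "SimSpec"), methods::is(net, "WeightedNetwork"))
  set.seed(spec@rngSeed + 1L)
  g <- net@graph
  comp <- igraph::components(g)
  giant <- which(comp$membership == which.max(comp$csize))
  if (length(giant) < spec@nDiseaseSeeds)
    stop("largest component smaller than the requested disease module",
         call. = FALSE)
  root <- giant[sample.int(length(giant), 1L)]
  bfs <- igraph::bfs(g, root = root, order = TRUE, unreachable = FALSE)
  visited <- igraph::V(g)$name[as.integer(bfs$order[!is.na(bfs$order)])]
  planted <- sort(visited[seq_len(spec@nDiseaseSeeds)], method = "radix")
  genes <- nodes(net)
  isPlanted <- genes %in% planted
  nP <- sum(isPlanted)
  nB <- length(genes) - nP
  log2fc <- numeric(length(genes))
  fdr <- numeric(length(genes))
  z <- numeric(length(genes))
  fcSign <- sample(c(-1, 1), nP, replace = TRUE)
  log2fc[isPlanted] <- fcSign * (1 + abs(rnorm(nP, 0, 0.5)))
  fdr[isPlanted] <- runif(nP, 0, 0.009)
  z[isPlanted] <- fcSign * (1 + abs(rnorm(nP, 0, spec@degZScale)))
  log2fc[!isPlanted] <- runif(nB, -0.9, 0.9)
  fdr[!isPlanted] <- runif(nB, 0.02, 0.99)
  z[!isPlanted] <- .backgroundZ(nB)
  diseaseSignature("simulated-cohort",
                   data.frame(gene = genes, log2fc = log2fc, fdr = fdr,
                              z = z, stringsAsFactors = FALSE))
}

#' Simulate a drug library with one signature-reversing drug
#'
#' Every drug has a DEG set of size `nDiseaseSeeds` (matched across
#' drugs).  The reversal drug draws its DEGs from the planted disease
#' module -- except for a small off-module complement (15% of the set,
#' at least 4 genes) -- with
#' \deqn{z_{drug} = -s \cdot z_{disease} + \sqrt{1 - s^2}\, N(0, 1)}
#' (s = `reversalStrength`, so s is the anti-correlation magnitude and
#' s = 1 negates the disease z exactly); the off-module complement is
#' placed uniformly with supra-threshold random z, and genes whose
#' resulting |z| falls at or below the DEG threshold simply drop out of
#' the DEG set.  Decoy drugs place their DEGs uniformly at random.  All
#' signatures cover the same gene universe with near-zero background z
#' elsewhere (unperturbed genes are neutral under the z-adjustments, the
#' same convention as for unmeasured genes).
#'
#' An idealized all-in-module reversal drug would make its drug module a
#' subset of the disease module and the directional AUC reference set
#' degenerate (covering the whole ranked list); the off-module
#' complement is the minimal departure that keeps both AUCs defined.
#'
#' @param spec a [SimSpec-class].
#' @param net the simulated network.
#' @param disease the simulated disease signature.
#' @return list of [DrugSignature-class]; the reversal drug is named
#'   `"reversal"`, decoys `"decoy01"`, `"decoy02"`, ...
#' @export
simulateDrugs <- function(spec, net, disease) {
  stopifnot(methods::is(spec, "SimSpec"))
  set.seed(spec@rngSeed + 2L)
  genes <- nodes(net)
  planted <- selectDiseaseDegs(disease)
  zDis <- zLookup(disease, genes)
  names(zDis) <- genes
  m <- spec@nDiseaseSeeds
  s <- spec@reversalStrength

  makeBackground <- function() stats::setNames(.backgroundZ(length(genes)), genes)

  nIn <- m - max(4L, round(0.15 * m))
  inModule <- sort(sample(planted, min(nIn, length(planted))), method = "radix")
  offPool <- setdiff(genes, planted)
  offModule <- sort(sample(offPool, m - length(inModule)), method = "radix")
  zRev <- makeBackground()
  zRev[inModule] <- -s * zDis[inModule] +
    sqrt(1 - s^2) * rnorm(length(inModule))
  zRev[offModule] <- .supraZ(length(offModule), spec@degZScale)
  drugs <- list(drugSignature("reversal", zRev, cellLine = "SIM",
                              dose = "simulated"))
  for (i in seq_len(spec@nDrugs - 1L)) {
    zDec <- makeBackground()
    degSet <- sample(genes, m)
    zDec[degSet] <- .supraZ(m, spec@degZScale)
    drugs[[i + 1L]] <- drugSignature(sprintf("decoy%02d", i), zDec,
                                     cellLine = "SIM", dose = "simulated")
  }
  drugs
}

#' Simulate a complete benchmark study
#'
#' Runs [simulateNetwork()], [simulateDisease()] and [simulateDrugs()]
#' in order and returns everything plus the ground truth.
#'
#' @param spec a [SimSpec-class].
#' @return list with elements `network`, `disease`, `drugs`, and
#'   `truth` (list: `plantedModule`, `reversalDrug`).
#' @export
simulateStudy <- function(spec = simSpec()) {
  net <- simulateNetwork(spec)
  disease <- simulateDisease(spec, net)
  drugs <- simulateDrugs(spec, net, disease)
  list(network = net, disease = disease, drugs = drugs,
       truth = list(plantedModule = selectDiseaseDegs(disease),
                    reversalDrug = "reversal"))
}

#' Write a simulated study to disk
#'
#' Writes `fin.tsv` (edge list), `disease.tsv`, one
#' `drugs/<drug_id>.tsv` per signature, `manifest.tsv` and
#' `truth.json`, i.e. exactly the input layout the pipeline consumes.
#'
#' @param study result of [simulateStudy()].
#' @param dir output directory (created if needed).
#' @return invisibly, `dir`.
#' @export
writeStudy <- function(study, dir) {
  dir.create(file.path(dir, "drugs"), showWarnings = FALSE, recursive = TRUE)
  full <- function(x) sprintf("%.17g", x)  # lossless numeric round-trip
  ed <- edges(study$network)
  names(ed) <- c("gene_a", "gene_b", "weight")
  ed$weight <- full(ed$weight)
  write.table(ed, file.path(dir, "fin.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  rec <- study$disease@records
  rec[c("log2fc", "fdr", "z")] <- lapply(rec[c("log2fc", "fdr", "z")], full)
  write.table(rec, file.path(dir, "disease.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  man <- do.call(rbind, lapply(study$drugs, function(d) {
    p <- file.path("drugs", paste0(drugId(d), ".tsv"))
    write.table(data.frame(gene = names(zscores(d)),
                           zscore = full(zscores(d))),
                file.path(dir, p), sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    data.frame(drug_id = drugId(d), cell_line = d@cellLine, dose = d@dose,
               path = p, stringsAsFactors = FALSE)
  }))
  write.table(man, file.path(dir, "manifest.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  jsonlite::write_json(study$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE)
  invisible(dir)
}
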
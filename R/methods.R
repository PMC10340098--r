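#' Accessors for netDR classes
#'
#' @param x an object of the documented class.
#' @return `nodes`, `seeds`, `members`: character vectors of gene
#'   identifiers. `edges`: a data.frame (`from`, `to`, `weight`).
#'   `numNodes`, `numEdges`: integer counts. `subnetwork`: a
#'   [WeightedNetwork-class]. `scores`, `zscores`: named numeric vectors.
#'   `rocPoints`: a data.frame of (fpr, tpr). `aucValue`: a number.
#' @name accessors
NULL

#' @rdname accessors
setMethod("nodes", "WeightedNetwork", function(x) igraph::V(x@graph)$name)

#' @rdname accessors
setMethod("edges", "WeightedNetwork", function(x) {
  e <- igraph::as_data_frame(x@graph, what = "edges")
  e[, c("from", "to", "weight")]
})

#' @rdname accessors
setMethod("numNodes", "WeightedNetwork", function(x) igraph::vcount(x@graph))

#' @rdname accessors
setMethod("numEdges", "WeightedNetwork", function(x) igraph::ecount(x@graph))

#' @rdname accessors
setMethod("seeds", "GeneModule", function(x) x@seeds)

#' @rdname accessors
setMethod("members", "GeneModule", function(x) x@members)

#' @rdname accessors
setMethod("subnetwork", "GeneModule", function(x) x@subnetwork)

#' @rdname accessors
setMethod("moduleKind", "GeneModule", function(x) x@kind)

#' @rdname accessors
setMethod("drugId", "DrugSignature", function(x) x@drugId)

#' @rdname accessors
setMethod("zscores", "DrugSignature", function(x) x@zscores)

#' @rdname accessors
setMethod("zscores", "DiseaseSignature", function(x)
  stats::setNames(x@records$z, x@records$gene))

#' @rdname accessors
setMethod("scores", "ScoreTable", function(x) x@scores)

#' @rdname accessors
setMethod("rankDirection", "ScoreTable", function(x) x@rankDirection)

#' @rdname accessors
setMethod("rocPoints", "RocCurve", function(x) x@points)

#' @rdname accessors
setMethod("aucValue", "RocCurve", function(x) x@auc)

#' @describeIn zLookup on a named z-score vector
setMethod("zLookup", "numeric", function(sig, gene) {
  out <- unname(sig[gene])
  out[is.na(out)] <- 0
  out
})

#' @describeIn zLookup on a drug signature
setMethod("zLookup", "DrugSignature", function(sig, gene)
  zLookup(sig@zscores, gene))

#' @describeIn zLookup on a disease signature
setMethod("zLookup", "DiseaseSignature", function(sig, gene)
  zLookup(stats::setNames(sig@records$z, sig@records$gene), gene))

setMethod("show", "WeightedNetwork", function(object) {
  cat(sprintf("WeightedNetwork: %d genes, %d weighted interactions\n",
              numNodes(object), numEdges(object)))
  if (!is.null(object@metadata$weightFloor))
    cat(sprintf("  weight floor: %s\n", object@metadata$weightFloor))
})

setMethod("show", "GeneModule", function(object) {
  cat(sprintf("GeneModule [%s]: %d seeds, %d members, %d edges\n",
              object@kind, length(object@seeds), length(object@members),
              numEdges(object@subnetwork)))
})

setMethod("show", "DrugSignature", function(object) {
  cat(sprintf("DrugSignature '%s' (%s, %s): %d genes, |z| > %g => %d DEGs\n",
              object@drugId, object@cellLine, object@dose,
              length(object@zscores), object@degThreshold,
              sum(abs(object@zscores) > object@degThreshold)))
})

setMethod("show", "DiseaseSignature", function(object) {
  deg <- sum(object@records$fdr < object@fdrThreshold &
             2^abs(object@records$log2fc) >= object@fcThreshold)
  cat(sprintf("DiseaseSignature '%s': %d genes, FDR < %g & |FC| >= %g => %d DEGs\n",
              object@cohortId, nrow(object@records), object@fdrThreshold,
              object@fcThreshold, deg))
})

setMethod("show", "ScoreTable", function(object) {
  cat(sprintf("ScoreTable [%s, %s]: %d genes\n", object@metric,
              object@rankDirection, length(object@scores)))
})

setMethod("show", "RocCurve", function(object) {
  cat(sprintf("RocCurve: %d points, AUC = %s\n", nrow(object@points),
              format(object@auc, digits = 4)))
})

setMethod("show", "RunConfig", function(object) {
  cat("RunConfig:\n")
  cat(sprintf("  weightFloor=%g drugZThreshold=%g fdrThreshold=%g fcThreshold=%g\n",
              object@weightFloor, object@drugZThreshold, object@fdrThreshold,
              object@fcThreshold))
  cat(sprintf("  damping=%g alpha=%g epsilon=%g nThresholds=%d aucCutoff=%g\n",
              object@damping, object@alpha, object@epsilon,
              object@nThresholds, object@aucCutoff))
  cat(sprintf("  metrics: %s\n", paste(object@metrics, collapse = ", ")))
})

setMethod("show", "SimSpec", function(object) {
  cat(sprintf("SimSpec: %d genes (%s, mean degree %g), %d disease seeds, %d drugs\n",
              object@nGenes, object@edgeModel, object@meanDegree,
              object@nDiseaseSeeds, object@nDrugs))
  cat(sprintf("  reversalStrength=%g degZScale=%g weights~Beta(%g,%g) seed=%d\n",
              object@reversalStrength, object@degZScale, object@weightShape1,
              object@weightShape2, object@rngSeed))
})
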
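#' @import methods
#' @importFrom stats rnorm runif rbeta median setNames
#' @importFrom utils head write.table read.delim
NULL

setOldClass("igraph")

#' WeightedNetwork: an undirected weighted gene-gene interaction graph
#'
#' Thin S4 wrapper around an \pkg{igraph} graph holding a functional
#' interaction network (FIN) or one of its induced subgraphs.  Edges are
#' undirected, simple (no self-loops, no duplicates) and carry a
#' \code{weight} attribute in \eqn{(0, 1]} interpreted as functional
#' similarity between the two genes.
#'
#' @slot graph an undirected simple \pkg{igraph} object with numeric edge
#'   attribute \code{weight} and character vertex attribute \code{name}.
#' @slot metadata list of provenance details (source path, pruning floor,
#'   raw edge count, ...).
#'
#' @seealso [loadNetwork()], [pruneNetwork()], [buildModule()]
#' @export
setClass("WeightedNetwork",
  representation(graph = "igraph", metadata = "list"),
  prototype(metadata = list())
)

setValidity("WeightedNetwork", function(object) {
  g <- object@graph
  if (igraph::is_directed(g)) return("graph must be undirected")
  if (is.null(igraph::V(g)$name)) return("vertices must be named")
  if (igraph::ecount(g) > 0) {
    w <- igraph::E(g)$weight
    if (is.null(w)) return("edges must carry a 'weight' attribute")
    if (anyNA(w) || any(w <= 0) || any(w > 1))
      return("edge weights must lie in (0, 1]")
    if (igraph::any_loop(g)) return("self-loops are not allowed")
    if (igraph::any_multiple(g)) return("duplicate edges are not allowed")
  }
  TRUE
})

#' GeneModule: a direct-neighbor module (DAPN or DGN)
#'
#' A module is grown from a seed gene set (the mapped differentially
#' expressed genes) by adding every direct network neighbor of a seed.
#' The subnetwork is the source network induced on the member set.
#'
#' @slot seeds character, seed genes present in the source network.
#' @slot members character, seeds plus their direct neighbors.
#' @slot subnetwork [WeightedNetwork-class] induced on \code{members}.
#' @slot kind single string tag, conventionally \code{"DAPN"}
#'   (drug-affected protein network) or \code{"DGN"} (disease gene
#'   network).
#' @export
setClass("GeneModule",
  representation(seeds = "character", members = "character",
                 subnetwork = "WeightedNetwork", kind = "character")
)

setValidity("GeneModule", function(object) {
  if (length(object@kind) != 1L) return("kind must be a single string")
  if (!all(object@seeds %in% object@members))
    return("seeds must be a subset of members")
  sub <- nodes(object@subnetwork)
  if (!setequal(sub, object@members))
    return("subnetwork nodes must equal the member set")
  TRUE
})

#' DrugSignature: per-gene z-scores for one drug perturbation
#'
#' One LINCS-style differential-expression signature: the z-score of each
#' measured gene after treating a cell line with one drug at one dose.
#' Genes with \eqn{|z|} above \code{degThreshold} (strictly) are the
#' drug-affected DEG set.
#'
#' @slot drugId,cellLine,dose free-text identifiers.
#' @slot zscores named numeric vector, gene -> z.
#' @slot degThreshold absolute z cutoff (default 1).
#' @export
setClass("DrugSignature",
  representation(drugId = "character", cellLine = "character",
                 dose = "character", zscores = "numeric",
                 degThreshold = "numeric")
)

setValidity("DrugSignature", function(object) {
  if (length(object@drugId) != 1L) return("drugId must be a single string")
  z <- object@zscores
  if (length(z) && (is.null(names(z)) || anyDuplicated(names(z))))
    return("zscores must be uniquely named by gene")
  if (length(z) && !all(is.finite(z))) return("zscores must be finite")
  if (length(object@degThreshold) != 1L || object@degThreshold < 0)
    return("degThreshold must be a single non-negative number")
  TRUE
})

#' DiseaseSignature: cohort-level differential expression table
#'
#' Per-gene log2 fold-change, FDR and a signed differential-expression
#' z-score for one disease cohort.  DEGs are genes with FDR strictly
#' below \code{fdrThreshold} and absolute linear fold-change
#' (\eqn{2^{|log2FC|}}) at least \code{fcThreshold}.
#'
#' @slot cohortId single string.
#' @slot records data.frame with columns \code{gene}, \code{log2fc},
#'   \code{fdr}, \code{z}; one row per gene.
#' @slot fdrThreshold,fcThreshold the DEG filter constants
#'   (defaults 0.01 and 2.0).
#' @export
setClass("DiseaseSignature",
  representation(cohortId = "character", records = "data.frame",
                 fdrThreshold = "numeric", fcThreshold = "numeric")
)

setValidity("DiseaseSignature", function(object) {
  r <- object@records
  need <- c("gene", "log2fc", "fdr", "z")
  if (!all(need %in% names(r)))
    return(sprintf("records must have columns %s", paste(need, collapse = ", ")))
  if (nrow(r)) {
    if (anyDuplicated(r$gene)) return("duplicate genes in records")
    if (!all(is.finite(r$log2fc)) || !all(is.finite(r$z)))
      return("log2fc and z must be finite")
    if (anyNA(r$fdr) || any(r$fdr < 0 | r$fdr > 1))
      return("fdr must lie in [0, 1]")
  }
  TRUE
})

#' ScoreTable: per-gene metric scores with a ranking direction
#'
#' @slot metric one of \code{"AA1"}, \code{"AA2"}, \code{"PR1"},
#'   \code{"PR2"}, \code{"NS"}.
#' @slot scores named numeric vector, gene -> score.
#' @slot rankDirection \code{"descending"} (high score = high rank, used
#'   by the Adamic-Adar and PageRank variants) or \code{"ascending"}
#'   (low score = high rank, used by neighborhood scoring).
#' @export
setClass("ScoreTable",
  representation(metric = "character", scores = "numeric",
                 rankDirection = "character")
)

setValidity("ScoreTable", function(object) {
  if (!object@rankDirection %in% c("descending", "ascending"))
    return("rankDirection must be 'descending' or 'ascending'")
  s <- object@scores
  if (length(s) && (is.null(names(s)) || anyDuplicated(names(s))))
    return("scores must be uniquely named by gene")
  if (length(s) && !all(is.finite(s))) return("scores must be finite")
  TRUE
})

#' RocCurve: a thresholded ROC curve and its trapezoidal AUC
#'
#' @slot points data.frame with columns \code{fpr}, \code{tpr}, sorted by
#'   \code{fpr} non-decreasing, anchored at (0,0) and (1,1).
#' @slot auc trapezoidal area under the points; \code{NA} when the
#'   reference set is empty or covers the whole ranked list (degenerate
#'   confusion matrices).
#' @export
setClass("RocCurve",
  representation(points = "data.frame", auc = "numeric")
)

setValidity("RocCurve", function(object) {
  p <- object@points
  if (!all(c("fpr", "tpr") %in% names(p))) return("points needs fpr, tpr")
  if (nrow(p)) {
    if (any(p$fpr < -1e-12 | p$fpr > 1 + 1e-12) ||
        any(p$tpr < -1e-12 | p$tpr > 1 + 1e-12))
      return("fpr and tpr must lie in [0, 1]")
    if (is.unsorted(p$fpr)) return("points must be sorted by fpr")
  }
  if (!is.na(object@auc) && (object@auc < -1e-12 || object@auc > 1 + 1e-12))
    return("auc must lie in [0, 1]")
  TRUE
})

#' RunConfig: all tunable constants of the pipeline
#'
#' Defaults are the published operating point of the method: weight floor
#' 0.1, drug |z| threshold 1, disease FDR 0.01 and |FC| 2.0, PageRank
#' damping 0.75, neighborhood-scoring alpha 0.7 and epsilon 0.1, 100 ROC
#' thresholds, candidate cutoff 0.6 combined AUC.
#'
#' @slot weightFloor,drugZThreshold,fdrThreshold,fcThreshold,damping,alpha,epsilon numeric constants.
#' @slot nThresholds integer, number of percent rank cutoffs in the ROC.
#' @slot aucCutoff combined-AUC significance threshold for candidates.
#' @slot metrics character subset of AA1, AA2, PR1, PR2, NS.
#' @seealso [runConfig()]
#' @export
setClass("RunConfig",
  representation(weightFloor = "numeric", drugZThreshold = "numeric",
                 fdrThreshold = "numeric", fcThreshold = "numeric",
                 damping = "numeric", alpha = "numeric", epsilon = "numeric",
                 nThresholds = "integer", aucCutoff = "numeric",
                 metrics = "character")
)

setValidity("RunConfig", function(object) {
  chk1 <- function(x, lo, hi) length(x) == 1L && is.finite(x) && x >= lo && x <= hi
  if (!chk1(object@weightFloor, 0, 1)) return("weightFloor must be in [0, 1]")
  if (!chk1(object@drugZThreshold, 0, Inf)) return("drugZThreshold must be >= 0")
  if (!chk1(object@fdrThreshold, 0, 1)) return("fdrThreshold must be in [0, 1]")
  if (!chk1(object@fcThreshold, 1, Inf)) return("fcThreshold must be >= 1")
  if (!chk1(object@damping, 1e-6, 1 - 1e-6)) return("damping must be in (0, 1)")
  if (!chk1(object@alpha, 0, 1)) return("alpha must be in [0, 1]")
  if (!chk1(object@epsilon, 0, 1)) return("epsilon must be in [0, 1]")
  if (object@nThresholds < 1L) return("nThresholds must be >= 1")
  if (!chk1(object@aucCutoff, 0, 1)) return("aucCutoff must be in [0, 1]")
  bad <- setdiff(object@metrics, c("AA1", "AA2", "PR1", "PR2", "NS"))
  if (length(bad)) return(sprintf("unknown metrics: %s", paste(bad, collapse = ", ")))
  TRUE
})

#' SimSpec: parameters of the synthetic benchmark generator
#'
#' @slot nGenes number of genes in the simulated interactome.
#' @slot edgeModel \code{"erdos_renyi"} or \code{"barabasi_albert"}.
#' @slot meanDegree target mean degree before weight pruning.
#' @slot weightShape1,weightShape2 Beta parameters of the edge-weight
#'   distribution (right-skewed, most mass near 0, like real functional
#'   interaction weights).
#' @slot nDiseaseSeeds size of the planted connected disease module.
#' @slot nDrugs number of simulated drug signatures (one reversal drug,
#'   the rest decoys).
#' @slot reversalStrength anti-correlation magnitude in \eqn{[0,1]}
#'   between the reversal drug's z-scores and the disease z-scores on the
#'   planted module genes (1 = exact negation).
#' @slot degZScale scale of the supra-threshold |z| excess for planted
#'   DEGs.
#' @slot rngSeed integer seed; the generator is fully reproducible.
#' @seealso [simSpec()], [simulateStudy()]
#' @export
setClass("SimSpec",
  representation(nGenes = "integer", edgeModel = "character",
                 meanDegree = "numeric", weightShape1 = "numeric",
                 weightShape2 = "numeric", nDiseaseSeeds = "integer",
                 nDrugs = "integer", reversalStrength = "numeric",
                 degZScale = "numeric", rngSeed = "integer")
)

setValidity("SimSpec", function(object) {
  if (!object@edgeModel %in% c("erdos_renyi", "barabasi_albert"))
    return("edgeModel must be 'erdos_renyi' or 'barabasi_albert'")
  if (object@nDiseaseSeeds >= object@nGenes)
    return("nDiseaseSeeds must be smaller than nGenes")
  if (object@meanDegree < 2) return("meanDegree must be >= 2")
  if (object@reversalStrength < 0 || object@reversalStrength > 1)
    return("reversalStrength must be in [0, 1]")
  if (object@weightShape1 <= 0 || object@weightShape2 <= 0)
    return("Beta shapes must be positive")
  TRUE
})
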
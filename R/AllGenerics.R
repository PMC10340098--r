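# Accessor generics.  Slot access from user code is discouraged; these are
# the supported surface.

#' @rdname accessors
#' @export
setGeneric("nodes", function(x) standardGeneric("nodes"))

#' @rdname accessors
#' @export
setGeneric("edges", function(x) standardGeneric("edges"))

#' @rdname accessors
#' @export
setGeneric("numNodes", function(x) standardGeneric("numNodes"))

#' @rdname accessors
#' @export
setGeneric("numEdges", function(x) standardGeneric("numEdges"))

#' @rdname accessors
#' @export
setGeneric("seeds", function(x) standardGeneric("seeds"))

#' @rdname accessors
#' @export
setGeneric("members", function(x) standardGeneric("members"))

#' @rdname accessors
#' @export
setGeneric("subnetwork", function(x) standardGeneric("subnetwork"))

#' @rdname accessors
#' @export
setGeneric("moduleKind", function(x) standardGeneric("moduleKind"))

#' @rdname accessors
#' @export
setGeneric("drugId", function(x) standardGeneric("drugId"))

#' @rdname accessors
#' @export
setGeneric("zscores", function(x) standardGeneric("zscores"))

#' @rdname accessors
#' @export
setGeneric("scores", function(x) standardGeneric("scores"))

#' @rdname accessors
#' @export
setGeneric("rankDirection", function(x) standardGeneric("rankDirection"))

#' @rdname accessors
#' @export
setGeneric("rocPoints", function(x) standardGeneric("rocPoints"))

#' @rdname accessors
#' @export
setGeneric("aucValue", function(x) standardGeneric("aucValue"))

#' Look up a gene's z-score, defaulting to 0 for unmeasured genes
#'
#' Unmeasured genes get z = 0 so that the z-adjustment factors
#' \eqn{0.5^{|z|}} and \eqn{e^{|z|}} reduce to 1 and leave the base
#' metric score unchanged.
#'
#' @param sig a [DrugSignature-class], [DiseaseSignature-class], or named
#'   numeric vector of z-scores.
#' @param gene character vector of gene identifiers.
#' @return numeric vector of z-scores, 0 where the gene is unmeasured.
#' @examples
#' sig <- drugSignature("d1", zscores = c(TP53 = -2.3))
#' zLookup(sig, c("TP53", "EGFR"))
#' @export
setGeneric("zLookup", function(sig, gene) standardGeneric("zLookup"))
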
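# The 100-threshold ROC/AUC module-similarity statistic and the combined
# drug score.

#' Rank module genes by a score table
#'
#' Sorts genes by score in the table's ranking direction; ties are
#' broken by lexicographic (C-locale) gene identifier so the ranking is
#' deterministic.
#'
#' @param table a [ScoreTable-class].
#' @return character vector of gene identifiers, best-ranked first.
#' @examples
#' st <- scoreTable("AA1", c(a = 3, b = 1, c = 2))
#' rankGenes(st)
#' @export
rankGenes <- function(table) {
  stopifnot(methods::is(table, "ScoreTable"))
  s <- table@scores
  if (!length(s)) stop("empty score table", call. = FALSE)
  decreasing <- table@rankDirection == "descending"
  ord <- order(s, names(s), method = "radix",
               decreasing = c(decreasing, FALSE))
  names(s)[ord]
}

# round-half-up (base round() is banker's rounding)
.roundHalfUp <- function(x) floor(x + 0.5)

#' ROC curve of a ranked gene list against a reference gene set
#'
#' Builds one confusion matrix per percent rank cutoff: for
#' p = 1..`nThresholds` the cutoff is the top
#' \eqn{round(p/nThresholds \cdot n)} genes (floored at 1, duplicate
#' cutoffs collapsed).  At each cutoff, genes above the cutoff that are
#' in the reference set are true positives, above and not in the
#' reference false positives, below and in the reference false
#' negatives, and below and outside true negatives.  Each cutoff yields
#' a (FPR, TPR) point; anchors (0,0) and (1,1) are added and the AUC is
#' the trapezoidal area over the FPR-sorted unique points.
#'
#' When the reference (restricted to the ranked genes) is empty or
#' covers the whole list, one of the rate denominators is always zero
#' and the AUC is undefined: an [RocCurve-class] with `auc = NA` is
#' returned rather than an error, so batch runs can flag the drug and
#' continue.
#'
#' @param ranked character vector of genes, best-ranked first.
#' @param reference character vector; the gene set the ranking is
#'   evaluated against (membership of the opposite module).
#' @param nThresholds number of percent cutoffs (default 100).
#' @return an [RocCurve-class].
#' @examples
#' genes <- paste0("g", 1:10)
#' aucValue(rocAuc(genes, genes[1:3]))   # perfect separation: AUC 1
#' @export
rocAuc <- function(ranked, reference, nThresholds = 100L) {
  stopifnot(is.character(ranked), length(ranked) >= 2L,
            !anyDuplicated(ranked), nThresholds >= 1L)
  n <- length(ranked)
  isRef <- ranked %in% reference
  nRef <- sum(isRef)
  if (nRef == 0L || nRef == n) {
    return(methods::new("RocCurve",
                        points = data.frame(fpr = numeric(), tpr = numeric()),
                        auc = NA_real_))
  }
  ks <- unique(pmax(1L, .roundHalfUp(seq_len(nThresholds) / nThresholds * n)))
  cum <- cumsum(isRef)
  tp <- cum[ks]
  fp <- ks - tp
  fn <- nRef - tp
  tn <- n - ks - fn
  tpr <- tp / (tp + fn)
  fpr <- fp / (fp + tn)
  pts <- unique(rbind(data.frame(fpr = 0, tpr = 0),
                      data.frame(fpr = fpr, tpr = tpr),
                      data.frame(fpr = 1, tpr = 1)))
  pts <- pts[order(pts$fpr, pts$tpr, method = "radix"), , drop = FALSE]
  rownames(pts) <- NULL
  auc <- sum(diff(pts$fpr) * (head(pts$tpr, -1) + pts$tpr[-1]) / 2)
  methods::new("RocCurve", points = pts, auc = auc)
}

#' Precision, recall and F1 of the top-k cut of a ranking
#'
#' Precision = TP / k, recall = TP / |reference restricted to the
#' ranked genes|, F1 their harmonic mean (0 when both are 0).  The
#' default cutoff is the break-even point k = |reference| where
#' precision and recall share a denominator scale.
#'
#' @inheritParams rocAuc
#' @param k rank cutoff; default `length(intersect(reference, ranked))`.
#' @return named numeric vector `c(precision, recall, f1)`.
#' @export
confusionMetrics <- function(ranked, reference, k = NULL) {
  refIn <- intersect(reference, ranked)
  if (!length(refIn))
    return(c(precision = NA_real_, recall = NA_real_, f1 = NA_real_))
  if (is.null(k)) k <- length(refIn)
  stopifnot(k >= 1L, k <= length(ranked))
  tp <- sum(ranked[seq_len(k)] %in% refIn)
  precision <- tp / k
  recall <- tp / length(refIn)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  c(precision = precision, recall = recall, f1 = f1)
}

#' Combined AUC of the two module directions
#'
#' The geometric mean \eqn{\sqrt{AUC_{DAPN} \cdot AUC_{DGN}}} of the
#' drug-module-side and disease-module-side AUCs; the drug's final
#' repositioning score.  NA propagates.
#'
#' @param aucDapn,aucDgn the two directional AUCs in \[0, 1\].
#' @return a single number (or NA).
#' @examples
#' combinedAuc(0.25, 1.0)
#' @export
combinedAuc <- function(aucDapn, aucDgn) {
  if (is.na(aucDapn) || is.na(aucDgn)) return(NA_real_)
  stopifnot(aucDapn >= 0, aucDapn <= 1, aucDgn >= 0, aucDgn <= 1)
  sqrt(aucDapn * aucDgn)
}
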
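# Drug and disease signature construction, parsing, and DEG filters.

#' Construct a drug signature
#'
#' @param drugId drug identifier.
#' @param zscores named numeric vector of per-gene z-scores.
#' @param cellLine,dose free-text metadata.
#' @param degThreshold absolute z cutoff for the DEG filter (default 1;
#'   strict: a gene qualifies when |z| > threshold).
#' @return a [DrugSignature-class].
#' @export
drugSignature <- function(drugId, zscores, cellLine = "NA", dose = "NA",
                          degThreshold = 1) {
  methods::new("DrugSignature", drugId = as.character(drugId),
               cellLine = as.character(cellLine), dose = as.character(dose),
               zscores = zscores, degThreshold = degThreshold)
}

#' Construct a disease signature
#'
#' @param cohortId cohort identifier.
#' @param records data.frame with columns `gene`, `log2fc`, `fdr`, `z`.
#' @param fdrThreshold FDR cutoff (strict, default 0.01).
#' @param fcThreshold absolute linear fold-change cutoff (non-strict,
#'   default 2.0); a gene qualifies when \eqn{2^{|log2fc|} \ge}
#'   `fcThreshold`.
#' @return a [DiseaseSignature-class].
#' @export
diseaseSignature <- function(cohortId, records, fdrThreshold = 0.01,
                             fcThreshold = 2.0) {
  records$gene <- as.character(records$gene)
  methods::new("DiseaseSignature", cohortId = as.character(cohortId),
               records = records[, c("gene", "log2fc", "fdr", "z")],
               fdrThreshold = fdrThreshold, fcThreshold = fcThreshold)
}

#' Read a drug signature from a two-column TSV
#'
#' Expects columns `gene` and `zscore` (header optional, detected by a
#' non-numeric second field).
#'
#' @inheritParams drugSignature
#' @param path file path.
#' @return a [DrugSignature-class].
#' @export
readDrugSignature <- function(path, drugId = basename(path),
                              cellLine = "NA", dose = "NA",
                              degThreshold = 1) {
  tab <- read.delim(path, header = FALSE, colClasses = "character")
  if (ncol(tab) != 2L)
    stop("drug signature file must have 2 tab-separated columns: ", path,
         call. = FALSE)
  if (is.na(suppressWarnings(as.numeric(tab[1L, 2L]))))
    tab <- tab[-1L, , drop = FALSE]
  z <- suppressWarnings(as.numeric(tab[[2L]]))
  if (anyNA(z))
    stop("non-numeric z-score in drug signature file: ", path, call. = FALSE)
  drugSignature(drugId, stats::setNames(z, tab[[1L]]),
                cellLine = cellLine, dose = dose, degThreshold = degThreshold)
}

#' Read a drug manifest and its signature files
#'
#' The manifest is a TSV with header `drug_id  cell_line  dose  path`;
#' relative signature paths are resolved against the manifest's
#' directory.
#'
#' @param path manifest file path.
#' @param degThreshold absolute z cutoff applied to every signature.
#' @return a list of [DrugSignature-class] objects.
#' @export
readDrugManifest <- function(path, degThreshold = 1) {
  man <- read.delim(path, header = TRUE, colClasses = "character")
  need <- c("drug_id", "cell_line", "dose", "path")
  if (!all(need %in% names(man)))
    stop("manifest must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  base <- dirname(path)
  lapply(seq_len(nrow(man)), function(i) {
    p <- man$path[i]
    if (!file.exists(p)) p <- file.path(base, man$path[i])
    readDrugSignature(p, drugId = man$drug_id[i], cellLine = man$cell_line[i],
                      dose = man$dose[i], degThreshold = degThreshold)
  })
}

#' Read a disease differential-expression table
#'
#' Expects a TSV with header `gene  log2fc  fdr  z`.
#'
#' @inheritParams diseaseSignature
#' @param path file path.
#' @return a [DiseaseSignature-class].
#' @export
readDiseaseSignature <- function(path, cohortId = basename(path),
                                 fdrThreshold = 0.01, fcThreshold = 2.0) {
  tab <- read.delim(path, header = TRUE)
  need <- c("gene", "log2fc", "fdr", "z")
  if (!all(need %in% names(tab)))
    stop("disease table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  diseaseSignature(cohortId, tab, fdrThreshold = fdrThreshold,
                   fcThreshold = fcThreshold)
}

#' Select drug DEGs by the absolute z-score filter
#'
#' Returns the genes with |z| strictly greater than the signature's
#' threshold (default 1, the published operating point).
#'
#' @param sig a [DrugSignature-class].
#' @return character vector of DEG identifiers (sorted).
#' @examples
#' sig <- drugSignature("d", c(g1 = 0.5, g2 = -1.2, g3 = 1.0, g4 = 3.0))
#' selectDrugDegs(sig)   # g3 sits exactly at the threshold and is excluded
#' @export
selectDrugDegs <- function(sig) {
  stopifnot(methods::is(sig, "DrugSignature"))
  out <- names(sig@zscores)[abs(sig@zscores) > sig@degThreshold]
  if (!length(out))
    stop("drug '", sig@drugId, "' has no DEG at |z| > ", sig@degThreshold,
         "; signature unusable", call. = FALSE)
  sort(out, method = "radix")
}

#' Select disease DEGs by the FDR and fold-change filters
#'
#' Returns genes with FDR strictly below the FDR threshold and absolute
#' linear fold-change \eqn{2^{|log2fc|}} at or above the fold-change
#' threshold (defaults 0.01 and 2.0).
#'
#' @param sig a [DiseaseSignature-class].
#' @return character vector of DEG identifiers (sorted).
#' @export
selectDiseaseDegs <- function(sig) {
  stopifnot(methods::is(sig, "DiseaseSignature"))
  r <- sig@records
  if (!nrow(r))
    stop("disease signature '", sig@cohortId, "' has no records",
         call. = FALSE)
  keep <- r$fdr < sig@fdrThreshold & 2^abs(r$log2fc) >= sig@fcThreshold
  if (!any(keep))
    stop("disease signature '", sig@cohortId, "' has no DEG at FDR < ",
         sig@fdrThreshold, " and |FC| >= ", sig@fcThreshold, call. = FALSE)
  sort(r$gene[keep], method = "radix")
}
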
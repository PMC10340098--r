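# Pipeline orchestration: per-drug evaluation, drug ranking, batch runs.

.ALL_METRICS <- c("AA1", "AA2", "PR1", "PR2", "NS")

#' Build a run configuration
#'
#' All defaults are the published operating point of the method; see
#' [RunConfig-class].
#'
#' @param weightFloor minimum surviving FIN edge weight (0.1).
#' @param drugZThreshold absolute z cutoff for drug DEGs (1.0, strict).
#' @param fdrThreshold disease DEG FDR cutoff (0.01, strict).
#' @param fcThreshold disease DEG absolute fold-change cutoff (2.0).
#' @param damping PageRank damping factor (0.75).
#' @param alpha neighborhood-scoring blending weight (0.7).
#' @param epsilon neighborhood-scoring edge-weight threshold (0.1).
#' @param nThresholds number of percent ROC cutoffs (100).
#' @param aucCutoff combined-AUC candidate threshold (0.6; raise to 0.7
#'   to shorten a long candidate list).
#' @param metrics which metrics to run.
#' @return a [RunConfig-class].
#' @export
runConfig <- function(weightFloor = 0.1, drugZThreshold = 1.0,
                      fdrThreshold = 0.01, fcThreshold = 2.0,
                      damping = 0.75, alpha = 0.7, epsilon = 0.1,
                      nThresholds = 100L, aucCutoff = 0.6,
                      metrics = .ALL_METRICS) {
  methods::new("RunConfig", weightFloor = weightFloor,
               drugZThreshold = drugZThreshold, fdrThreshold = fdrThreshold,
               fcThreshold = fcThreshold, damping = damping, alpha = alpha,
               epsilon = epsilon, nThresholds = as.integer(nThresholds),
               aucCutoff = aucCutoff, metrics = metrics)
}

#' Read a YAML run configuration
#'
#' Field names mirror [runConfig()] arguments; unknown fields are an
#' error, absent fields keep their defaults.
#'
#' @param path YAML file path.
#' @param ... overrides applied after the file (e.g. CLI flags).
#' @return a [RunConfig-class].
#' @export
readRunConfig <- function(path, ...) {
  vals <- if (is.null(path)) list() else yaml::read_yaml(path)
  over <- list(...)
  vals[names(over)] <- over
  known <- names(formals(runConfig))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop("unknown config fields: ", paste(bad, collapse = ", "), call. = FALSE)
  do.call(runConfig, vals)
}

# Internal: base (z-independent) scores of a module for one metric
# family.  AA* share the Adamic-Adar base, PR* the PageRank base; NS has
# no drug-independent base on the DGN side beyond the module itself.
.baseScores <- function(module, cfg) {
  list(AA = adamicAdarScores(module),
       PR = pagerankScores(module, damping = cfg@damping))
}

# Internal: precompute everything about the disease side that does not
# depend on the drug: the DGN module, its AA/PR base scores, and its
# neighborhood-scoring ranking (disease z only, so fully drug-independent).
#' Precompute the disease-side state shared by all drugs
#'
#' Builds the DGN from the disease DEGs and computes its
#' drug-independent base scores once, for reuse across a drug library.
#' [runPipeline()] calls this internally; expose it when evaluating
#' drugs one at a time with [evaluateDrug()].
#'
#' @param fin the pruned FIN, a [WeightedNetwork-class].
#' @param disease a [DiseaseSignature-class].
#' @param cfg a [RunConfig-class].
#' @return an opaque list consumed by [evaluateDrug()].
#' @export
prepareDisease <- function(fin, disease, cfg = runConfig()) {
  degs <- selectDiseaseDegs(disease)
  dgn <- buildModule(fin, degs, kind = "DGN")
  base <- .baseScores(dgn, cfg)
  list(dgn = dgn, base = base, disease = disease)
}

# Internal: the three-branch combined z map used by all metrics.  A gene
# in both modules carries z_self + z_other (reversal makes this small);
# a gene in the scored module only carries z_self.
.branchZ <- function(moduleSelf, moduleOther, zSelf, zOther) {
  genes <- members(moduleSelf)
  inBoth <- genes %in% members(moduleOther)
  zs <- zLookup(zSelf, genes)
  zo <- zLookup(zOther, genes)
  stats::setNames(ifelse(inBoth, zs + zo, zs), genes)
}

# Internal: one directional AUC + confusion metrics.
.evalSide <- function(rankedTable, referenceMembers, cfg) {
  ranked <- rankGenes(rankedTable)
  roc <- rocAuc(ranked, referenceMembers, nThresholds = cfg@nThresholds)
  cm <- confusionMetrics(ranked, referenceMembers)
  list(auc = aucValue(roc), cm = cm,
       nRanked = length(ranked),
       nReference = length(intersect(referenceMembers, ranked)))
}

# Internal: geometric-mean combination of a per-side statistic,
# mirroring the combined-AUC rule.
.geoMean <- function(a, b) {
  if (is.na(a) || is.na(b)) return(NA_real_)
  sqrt(a * b)
}

#' Evaluate one drug against the disease
#'
#' Runs the full similarity computation for a single drug: builds its
#' DAPN, computes each requested metric on the DAPN and the DGN,
#' applies the matching z-score adjustment (branch membership against
#' the other module's member set; for neighborhood scoring the same
#' three-branch rule supplies the z map, and genes are ranked by |X|
#' ascending so combined-signal-neutralized genes come first), ranks
#' genes, and scores both directions -- the DAPN ranking against DGN membership
#' (`auc_dapn`) and the DGN ranking against DAPN membership
#' (`auc_dgn`) -- combining them by geometric mean.  F1, precision and
#' recall are computed per side at the break-even cutoff and combined
#' the same way.
#'
#' A degenerate reference (empty, or covering the entire ranked list)
#' yields NA AUCs for that drug-metric pair rather than an error.
#'
#' @param fin the pruned FIN, a [WeightedNetwork-class].
#' @param disease a [DiseaseSignature-class].
#' @param drug a [DrugSignature-class].
#' @param cfg a [RunConfig-class].
#' @param diseaseState optional result of [prepareDisease()]; computed
#'   on the fly when absent.
#' @return a data.frame with one row per metric and columns `drug`,
#'   `metric`, `auc_dapn`, `auc_dgn`, `combined_auc`, `f1`, `precision`,
#'   `recall`, `n_ranked`, `n_reference`.
#' @export
evaluateDrug <- function(fin, disease, drug, cfg = runConfig(),
                         diseaseState = NULL) {
  stopifnot(methods::is(drug, "DrugSignature"))
  if (is.null(diseaseState)) diseaseState <- prepareDisease(fin, disease, cfg)
  dgn <- diseaseState$dgn
  zDis <- zscores(diseaseState$disease)
  zDrug <- zscores(drug)
  if (!length(cfg@metrics)) return(.emptyResults())

  dapn <- buildModule(fin, selectDrugDegs(drug), kind = "DAPN")
  dapnBase <- .baseScores(dapn, cfg)

  rows <- lapply(cfg@metrics, function(metric) {
    if (metric == "NS") {
      dapnScores <- abs(neighborhoodScores(
        dapn, .branchZ(dapn, dgn, zDrug, zDis),
        alpha = cfg@alpha, epsilon = cfg@epsilon))
      dgnScores <- abs(neighborhoodScores(
        dgn, .branchZ(dgn, dapn, zDis, zDrug),
        alpha = cfg@alpha, epsilon = cfg@epsilon))
    } else {
      family <- substr(metric, 1, 2)        # AA or PR
      adjust <- if (substr(metric, 3, 3) == "1") adjustMultiplicative
                else adjustExponential
      dapnScores <- adjust(dapnBase[[family]], dapn, dgn, zDrug, zDis)
      dgnScores <- adjust(diseaseState$base[[family]], dgn, dapn, zDis, zDrug)
    }
    sideDapn <- .evalSide(scoreTable(metric, dapnScores), members(dgn), cfg)
    sideDgn <- .evalSide(scoreTable(metric, dgnScores), members(dapn), cfg)
    data.frame(
      drug = drugId(drug), metric = metric,
      auc_dapn = sideDapn$auc, auc_dgn = sideDgn$auc,
      combined_auc = if (is.na(sideDapn$auc) || is.na(sideDgn$auc))
        NA_real_ else combinedAuc(sideDapn$auc, sideDgn$auc),
      f1 = .geoMean(sideDapn$cm[["f1"]], sideDgn$cm[["f1"]]),
      precision = .geoMean(sideDapn$cm[["precision"]], sideDgn$cm[["precision"]]),
      recall = .geoMean(sideDapn$cm[["recall"]], sideDgn$cm[["recall"]]),
      n_ranked = sideDapn$nRanked, n_reference = sideDapn$nReference,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

.emptyResults <- function() {
  data.frame(drug = character(), metric = character(),
             auc_dapn = numeric(), auc_dgn = numeric(),
             combined_auc = numeric(), f1 = numeric(),
             precision = numeric(), recall = numeric(),
             n_ranked = integer(), n_reference = integer(),
             stringsAsFactors = FALSE)
}

#' Rank drugs by combined AUC and flag candidates
#'
#' Within each metric, drugs are sorted by combined AUC descending
#' (ties broken by drug identifier); rows at or above the configured
#' cutoff are flagged as repositioning candidates.  NA rows sort last
#' and are never candidates.
#'
#' @param results a results data.frame from [evaluateDrug()] /
#'   [runPipeline()].
#' @param cfg a [RunConfig-class] (supplies `aucCutoff`).
#' @return the results data.frame with an added logical
#'   `is_candidate` column and a per-metric `rank` column, sorted by
#'   metric then rank.
#' @export
rankDrugs <- function(results, cfg = runConfig()) {
  if (!nrow(results)) {
    out <- results
    out$rank <- integer()
    out$is_candidate <- logical()
    return(out)
  }
  if (all(is.na(results$combined_auc)))
    warning("all combined AUCs are NA; no candidates", call. = FALSE)
  parts <- lapply(split(results, results$metric), function(df) {
    ord <- order(-ifelse(is.na(df$combined_auc), -Inf, df$combined_auc),
                 df$drug, method = "radix")
    df <- df[ord, , drop = FALSE]
    df$rank <- seq_len(nrow(df))
    df$is_candidate <- !is.na(df$combined_auc) &
      df$combined_auc >= cfg@aucCutoff
    df
  })
  out <- do.call(rbind, parts[sort(names(parts), method = "radix")])
  rownames(out) <- NULL
  out
}

#' Run the full repositioning pipeline over a drug library
#'
#' Builds the DGN once, evaluates every drug against it, ranks drugs
#' per metric, and (optionally) writes `results.tsv`,
#' `candidates.tsv`, `run.log` and `config.resolved.yaml` to an output
#' directory.  A drug whose evaluation fails (e.g. no DEG survives the
#' filter, or no DEG maps to the network) is skipped and logged, not
#' fatal.
#'
#' @param fin the pruned FIN, a [WeightedNetwork-class].
#' @param disease a [DiseaseSignature-class].
#' @param drugs list of [DrugSignature-class] objects.
#' @param cfg a [RunConfig-class].
#' @param outDir optional output directory.
#' @param quiet suppress per-drug progress messages.
#' @return list with elements `results` (all drugs x metrics, ranked),
#'   `candidates` (rows at or above the AUC cutoff), and `log`
#'   (character vector of progress lines).
#' @export
runPipeline <- function(fin, disease, drugs, cfg = runConfig(),
                        outDir = NULL, quiet = TRUE) {
  stopifnot(is.list(drugs), length(drugs) > 0L)
  diseaseState <- prepareDisease(fin, disease, cfg)
  logLines <- sprintf("dgn: seeds=%d members=%d",
                      length(seeds(diseaseState$dgn)),
                      length(members(diseaseState$dgn)))
  rows <- vector("list", length(drugs))
  for (i in seq_along(drugs)) {
    d <- drugs[[i]]
    res <- tryCatch(
      evaluateDrug(fin, disease, d, cfg, diseaseState = diseaseState),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      line <- sprintf("drug=%s status=skipped reason=%s", drugId(d),
                      conditionMessage(res))
      logLines <- c(logLines, line)
      if (!quiet) message(line)
      next
    }
    line <- sprintf("drug=%s status=ok n_ranked=%d n_reference=%d",
                    drugId(d), res$n_ranked[1L], res$n_reference[1L])
    logLines <- c(logLines, line)
    if (!quiet) message(line)
    rows[[i]] <- res
  }
  results <- do.call(rbind, c(rows[!vapply(rows, is.null, TRUE)],
                              list(.emptyResults())))
  results <- rankDrugs(results, cfg)
  candidates <- results[results$is_candidate, , drop = FALSE]
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    .writeResultTable(results, file.path(outDir, "results.tsv"))
    .writeResultTable(candidates, file.path(outDir, "candidates.tsv"))
    writeLines(logLines, file.path(outDir, "run.log"))
    yaml::write_yaml(configAsList(cfg),
                     file.path(outDir, "config.resolved.yaml"))
  }
  list(results = results, candidates = candidates, log = logLines)
}

.writeResultTable <- function(df, path) {
  num <- vapply(df, is.numeric, TRUE) & names(df) != "rank" &
    !vapply(df, is.integer, TRUE)
  df[num] <- lapply(df[num], function(x) formatC(x, digits = 6, format = "g"))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Flatten a RunConfig to a plain list (for YAML export)
#' @param cfg a [RunConfig-class].
#' @return named list of configuration values.
#' @export
configAsList <- function(cfg) {
  list(weightFloor = cfg@weightFloor, drugZThreshold = cfg@drugZThreshold,
       fdrThreshold = cfg@fdrThreshold, fcThreshold = cfg@fcThreshold,
       damping = cfg@damping, alpha = cfg@alpha, epsilon = cfg@epsilon,
       nThresholds = cfg@nThresholds, aucCutoff = cfg@aucCutoff,
       metrics = cfg@metrics)
}
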
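# Network loading, pruning, and direct-neighbor module construction.

# Internal: build a WeightedNetwork from an edge data.frame
# (columns from, to, weight).  Collapses duplicate unordered pairs keeping
# the maximum weight, drops self-loops, applies the weight floor (strict:
# weights < floor are excluded, weight == floor survives), and drops
# nodes left without any surviving edge.
.newNetwork <- function(edf, weightFloor = 0, metadata = list()) {
  edf$from <- as.character(edf$from)
  edf$to <- as.character(edf$to)
  edf <- edf[edf$from != edf$to, , drop = FALSE]
  if (nrow(edf)) {
    a <- pmin(edf$from, edf$to)
    b <- pmax(edf$from, edf$to)
    key <- paste(a, b, sep = "\r")
    w <- tapply(edf$weight, key, max)
    keys <- strsplit(names(w), "\r", fixed = TRUE)
    edf <- data.frame(from = vapply(keys, `[`, "", 1L),
                      to = vapply(keys, `[`, "", 2L),
                      weight = as.numeric(w),
                      stringsAsFactors = FALSE)
    edf <- edf[edf$weight >= weightFloor, , drop = FALSE]
  }
  if (!nrow(edf))
    stop("no edges survive the weight floor of ", weightFloor,
         "; the network is empty", call. = FALSE)
  g <- igraph::graph_from_data_frame(edf, directed = FALSE)
  metadata$weightFloor <- weightFloor
  methods::new("WeightedNetwork", graph = g, metadata = metadata)
}

#' Load a weighted edge list and prune weak interactions
#'
#' Reads a 3-column tab-separated edge list (`gene_a  gene_b  weight`)
#' into a [WeightedNetwork-class], excluding edges whose weight is
#' strictly below `weightFloor` (the published floor is 0.1, chosen
#' because weights under 0.1 represent very low functional similarity).
#' A header row is detected by a non-numeric third field.  Duplicate
#' edges are collapsed keeping the maximum weight, self-loops are
#' dropped, and genes left without any surviving interaction are removed.
#'
#' @param path path to the edge-list file.
#' @param weightFloor edges with weight < `weightFloor` are excluded;
#'   default 0.1.
#' @return a [WeightedNetwork-class].
#' @examples
#' f <- tempfile()
#' writeLines(c("A\tB\t0.05", "B\tC\t0.10", "C\tD\t0.50"), f)
#' net <- loadNetwork(f)
#' nodes(net)   # A is gone: its only edge fell below the floor
#' @export
loadNetwork <- function(path, weightFloor = 0.1) {
  stopifnot(length(weightFloor) == 1L, weightFloor >= 0, weightFloor <= 1)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty edge-list file: ", path, call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  start <- 1L
  f1 <- fields[[1L]]
  if (length(f1) == 3L && is.na(suppressWarnings(as.numeric(f1[3L]))))
    start <- 2L  # header row
  if (start > length(lines))
    stop("edge-list file contains only a header: ", path, call. = FALSE)
  n <- lengths(fields)
  bad <- which(n != 3L & seq_along(fields) >= start)
  if (length(bad))
    stop(sprintf("malformed row at line %d of %s: expected 3 tab-separated columns, found %d",
                 bad[1L], path, n[bad[1L]]), call. = FALSE)
  idx <- seq.int(start, length(fields))
  from <- vapply(fields[idx], `[`, "", 1L)
  to <- vapply(fields[idx], `[`, "", 2L)
  w <- suppressWarnings(as.numeric(vapply(fields[idx], `[`, "", 3L)))
  if (anyNA(w))
    stop(sprintf("malformed row at line %d of %s: non-numeric weight",
                 idx[which(is.na(w))[1L]], path), call. = FALSE)
  if (any(w <= 0 | w > 1))
    stop(sprintf("invalid weight at line %d of %s: weights must lie in (0, 1]",
                 idx[which(w <= 0 | w > 1)[1L]], path), call. = FALSE)
  .newNetwork(data.frame(from = from, to = to, weight = w,
                         stringsAsFactors = FALSE),
              weightFloor = weightFloor,
              metadata = list(source = path))
}

#' Prune a network at a weight floor
#'
#' Removes edges with weight strictly below `weightFloor` and drops
#' genes left isolated.  Idempotent: pruning a pruned network at the same
#' floor is a no-op.
#'
#' @param net a [WeightedNetwork-class].
#' @param weightFloor minimum surviving edge weight.
#' @return a pruned [WeightedNetwork-class].
#' @export
pruneNetwork <- function(net, weightFloor = 0.1) {
  stopifnot(methods::is(net, "WeightedNetwork"))
  .newNetwork(edges(net), weightFloor = weightFloor,
              metadata = net@metadata)
}

#' Build a direct-neighbor gene module
#'
#' Maps a seed gene set (typically the DEGs of a drug signature or a
#' disease cohort) onto the network: the module members are the seeds
#' present in the network plus every gene directly adjacent to a seed,
#' and the module subnetwork is the source network induced on that
#' member set.  No additional weight filtering is applied inside the
#' module.
#'
#' @param net a [WeightedNetwork-class] (usually the pruned FIN).
#' @param seedGenes character vector of seed gene identifiers.
#' @param kind module tag, conventionally `"DAPN"` or `"DGN"`.
#' @return a [GeneModule-class].
#' @examples
#' net <- exampleNetwork()
#' mod <- buildModule(net, seedGenes = nodes(net)[1], kind = "DGN")
#' members(mod)
#' @export
buildModule <- function(net, seedGenes, kind = c("DAPN", "DGN")) {
  stopifnot(methods::is(net, "WeightedNetwork"))
  kind <- kind[1L]
  seedGenes <- unique(as.character(seedGenes))
  present <- intersect(seedGenes, nodes(net))
  if (!length(present)) {
    miss <- head(setdiff(seedGenes, nodes(net)), 10L)
    stop("no seed gene is present in the network; missing genes include: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  g <- net@graph
  ego <- igraph::ego(g, order = 1, nodes = present)
  membersSet <- union(present, unlist(lapply(ego, names), use.names = FALSE))
  # sorted for deterministic downstream ordering
  membersSet <- sort(unique(membersSet), method = "radix")
  sub <- igraph::induced_subgraph(g, membersSet)
  subnet <- methods::new("WeightedNetwork", graph = sub,
                         metadata = list(parent = "module"))
  methods::new("GeneModule", seeds = sort(present, method = "radix"),
               members = membersSet, subnetwork = subnet, kind = kind)
}

#' Small built-in example network
#'
#' A 6-gene toy network used in examples.
#' @return a [WeightedNetwork-class].
#' @export
exampleNetwork <- function() {
  edf <- data.frame(
    from = c("A", "B", "C", "C", "D", "E"),
    to = c("B", "C", "D", "E", "E", "F"),
    weight = c(0.5, 0.8, 0.3, 0.6, 0.9, 0.2),
    stringsAsFactors = FALSE
  )
  .newNetwork(edf, weightFloor = 0.1, metadata = list(source = "example"))
}

#' Export a module as node and edge tables
#'
#' Writes `<prefix>_nodes.tsv` (`gene`, `is_seed`) and
#' `<prefix>_edges.tsv` (`gene_a`, `gene_b`, `weight`) for inspection.
#'
#' @param module a [GeneModule-class].
#' @param prefix output path prefix.
#' @return invisibly, the two file paths.
#' @export
writeModule <- function(module, prefix) {
  stopifnot(methods::is(module, "GeneModule"))
  nodeFile <- paste0(prefix, "_nodes.tsv")
  edgeFile <- paste0(prefix, "_edges.tsv")
  nd <- data.frame(gene = members(module),
                   is_seed = members(module) %in% seeds(module))
  write.table(nd, nodeFile, sep = "\t", quote = FALSE, row.names = FALSE)
  ed <- edges(subnetwork(module))
  names(ed) <- c("gene_a", "gene_b", "weight")
  write.table(ed, edgeFile, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(nodes = nodeFile, edges = edgeFile))
}
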
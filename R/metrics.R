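# The three module-local gene-scoring metrics and the z-score adjustments.
#
# All metrics operate on a module's induced subnetwork: degrees,
# neighborhoods and random walks are module-local, not FIN-global.

# Internal: dense weighted adjacency of a module subnetwork, with gene
# names as dimnames.  Modules are small (10^2-10^3 genes) so dense
# algebra is both simplest and fastest here.
.moduleAdjacency <- function(module) {
  igraph::as_adjacency_matrix(subnetwork(module)@graph, attr = "weight",
                              sparse = FALSE)
}

#' Adamic-Adar similarity scores of module genes
#'
#' For every ordered gene pair (x, y) in the module subnetwork the
#' Adamic-Adar similarity is
#' \deqn{S_{xy} = \sum_{z \in \lambda_x \cap \lambda_y} 1 / \log k_z,}
#' the sum over common neighbors z of the inverse log of z's degree,
#' where \eqn{k_z} is the *weighted* degree (strength) of z in the
#' module subnetwork and the logarithm is natural.  A gene's score is
#' the sum of its similarities with every other module gene,
#' \eqn{S_x = \sum_{y \ne x} S_{xy}}.
#'
#' On a weighted graph, strengths can approach 1 from above (where
#' \eqn{1/\log k_z} explodes) or fall below it (where it turns
#' negative), so the denominator is safeguarded:
#' \eqn{\log(\max(k_z, f))} with strength floor \eqn{f = 2} by default.
#' Each common-neighbor contribution is thereby capped at
#' \eqn{1/\log 2 \approx 1.44}, the value of an unweighted degree-2
#' neighbor, and the rule is identical to the plain inverse-log for
#' \eqn{k_z \ge f}.  On realistic interactomes strengths are well above
#' 2 and the floor is inert; it matters on small induced module
#' subnetworks.
#'
#' @param module a [GeneModule-class] with at least 2 genes.
#' @param strengthFloor floor applied to the weighted degree inside the
#'   log denominator (default 2).
#' @return named numeric vector of non-negative scores, one per module
#'   gene; genes with no length-2 paths score 0.
#' @examples
#' net <- exampleNetwork()
#' mod <- buildModule(net, "C", kind = "DGN")
#' adamicAdarScores(mod)
#' @export
adamicAdarScores <- function(module, strengthFloor = 2) {
  stopifnot(methods::is(module, "GeneModule"), strengthFloor > 1)
  A <- .moduleAdjacency(module)
  n <- nrow(A)
  if (n < 2L)
    stop("Adamic-Adar needs a module subnetwork with at least 2 genes",
         call. = FALSE)
  B <- (A > 0) + 0
  k <- rowSums(A)                       # weighted degree (strength)
  contrib <- 1 / log(pmax(k, strengthFloor))
  S <- B %*% (B * contrib)              # S[x,y] = sum_z B[x,z] B[z,y] / denom[z]
  stats::setNames(rowSums(S) - diag(S), rownames(A))
}

#' Damped PageRank scores of module genes
#'
#' Edge-weight-respecting PageRank on the undirected module subnetwork:
#' each undirected edge acts as two directed edges, the transition
#' probability from a gene to a neighbor is proportional to the edge
#' weight, and teleportation is uniform.  Solved by power iteration to
#' an L1 change below `tol` (default 1e-12).
#'
#' @param module a [GeneModule-class].
#' @param damping damping factor in (0, 1); the published value is 0.75.
#' @param tol L1 convergence tolerance.
#' @param maxIter maximum power iterations before an error is raised.
#' @return named numeric vector of scores summing to 1.
#' @export
pagerankScores <- function(module, damping = 0.75, tol = 1e-12,
                           maxIter = 1000L) {
  stopifnot(methods::is(module, "GeneModule"),
            damping > 0, damping < 1)
  A <- .moduleAdjacency(module)
  n <- nrow(A)
  if (n == 0L) stop("empty module subnetwork", call. = FALSE)
  if (n == 1L) return(stats::setNames(1, rownames(A)))
  s <- rowSums(A)
  dangling <- s == 0
  P <- A / ifelse(s > 0, s, 1)          # row-stochastic where s > 0
  x <- rep(1 / n, n)
  for (it in seq_len(maxIter)) {
    xNew <- (1 - damping) / n +
      damping * (as.vector(crossprod(P, x)) + sum(x[dangling]) / n)
    delta <- sum(abs(xNew - x))
    x <- xNew
    if (delta < tol) {
      x <- x / sum(x)
      return(stats::setNames(x, rownames(A)))
    }
  }
  stop(sprintf("PageRank did not converge in %d iterations (L1 residual %.3e)",
               maxIter, delta), call. = FALSE)
}

# Internal: |z-sum| per gene under the three-branch rule.  A gene that is
# a member of both modules uses |z_self + z_other|; a gene in the scored
# module only uses |z_self|.  Branch membership is evaluated against
# module MEMBER sets (seeds plus neighbors) because the metrics score all
# module members.
.zSums <- function(genes, moduleOther, zSelf, zOther) {
  inBoth <- genes %in% members(moduleOther)
  zs <- zLookup(zSelf, genes)
  zo <- zLookup(zOther, genes)
  abs(ifelse(inBoth, zs + zo, zs))
}

#' Multiplicative z-score adjustment (the AA1 / PR1 rule)
#'
#' Scales a base metric score by \eqn{0.5^{|z|}}: for a gene in both the
#' scored module and the other module the exponent is the absolute sum
#' of its two z-scores, \eqn{|z_{self}(x) + z_{other}(x)|}; for a gene
#' in the scored module only it is \eqn{|z_{self}(x)|}.  A drug-disease
#' gene pair with opposing regulation (one up, one down) has a z-sum
#' near 0 and keeps its base score -- the desirable signature-reversal
#' configuration -- while concordant or one-sided perturbation is
#' damped.  Unmeasured genes have z = 0 and are unaffected.
#'
#' @param base named numeric vector of base scores covering the scored
#'   module's genes.
#' @param moduleSelf the module being scored (supplies the gene set).
#' @param moduleOther the opposite module (membership decides the
#'   branch).
#' @param zSelf z-score source for the scored module's signature
#'   (signature object or named vector).
#' @param zOther z-score source for the opposite signature.
#' @return named numeric vector of adjusted scores.
#' @export
adjustMultiplicative <- function(base, moduleSelf, moduleOther, zSelf, zOther) {
  genes <- names(base)
  stopifnot(!is.null(genes), all(members(moduleSelf) %in% genes))
  base * 0.5^.zSums(genes, moduleOther, zSelf, zOther)
}

#' Exponential z-score adjustment (the AA2 / PR2 rule)
#'
#' Identical branch structure to [adjustMultiplicative()] but the base
#' score is divided by \eqn{e^{|z|}} instead of multiplied by
#' \eqn{0.5^{|z|}}, a steeper damping of non-reversed perturbation.
#'
#' @inheritParams adjustMultiplicative
#' @return named numeric vector of adjusted scores.
#' @export
adjustExponential <- function(base, moduleSelf, moduleOther, zSelf, zOther) {
  genes <- names(base)
  stopifnot(!is.null(genes), all(members(moduleSelf) %in% genes))
  base / exp(.zSums(genes, moduleOther, zSelf, zOther))
}

#' Neighborhood scores of module genes
#'
#' Smooths each gene's z-score with the mean z-score of its
#' supra-threshold-weight neighbors in the module subnetwork:
#' \deqn{X_i = \alpha x_i + (1 - \alpha) \frac{\sum_{j: w_{ij} > \epsilon} x_j}{N_i},}
#' where \eqn{x_i} is gene i's z-score, the sum runs over neighbors j
#' connected by an edge of weight strictly above \eqn{\epsilon}, and
#' \eqn{N_i} counts those neighbors.  When a gene has no
#' supra-threshold neighbor, \eqn{X_i = \alpha x_i}.  The published
#' constants are \eqn{\alpha = 0.7} and \eqn{\epsilon = 0.1} (the
#' latter matching the network pruning floor).
#'
#' The returned scores are signed; the score is linear in the z map.
#' For ROC ranking the pipeline orders genes by |X| ascending: a gene
#' neutralized by its neighborhood (score near 0) is the configuration
#' the metric rewards.
#'
#' @param module a [GeneModule-class].
#' @param z z-score source (signature object or named numeric vector);
#'   unmeasured genes count as 0.
#' @param alpha blending weight in \[0, 1\].
#' @param epsilon edge-weight threshold for the neighbor set.
#' @return named numeric vector of signed scores.
#' @export
neighborhoodScores <- function(module, z, alpha = 0.7, epsilon = 0.1) {
  stopifnot(methods::is(module, "GeneModule"),
            alpha >= 0, alpha <= 1)
  A <- .moduleAdjacency(module)
  genes <- rownames(A)
  x <- zLookup(z, genes)
  mask <- (A > epsilon) + 0
  N <- rowSums(mask)
  nbrSum <- as.vector(mask %*% x)
  X <- alpha * x + (1 - alpha) * ifelse(N > 0, nbrSum / N, 0)
  stats::setNames(X, genes)
}

#' Assemble a ScoreTable
#'
#' @param metric metric tag, one of AA1, AA2, PR1, PR2, NS.
#' @param geneScores named numeric vector of scores.
#' @param rankDirection ranking direction; defaults to the metric's
#'   convention (descending for AA/PR variants, ascending for NS).
#' @return a [ScoreTable-class].
#' @export
scoreTable <- function(metric, geneScores,
                       rankDirection = if (metric == "NS") "ascending"
                                       else "descending") {
  methods::new("ScoreTable", metric = metric, scores = geneScores,
               rankDirection = rankDirection)
}
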
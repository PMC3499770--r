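#' Hierarchical clustering of conditions from the RV matrix
#'
#' Agglomerative average-linkage (UPGMA) clustering of the K conditions on
#' the distance D = 1 - RV, i.e. one minus the pairwise congruence of the
#' per-condition cross-product matrices.
#'
#' @param rv K-by-K RV coefficient matrix (symmetric, unit diagonal) or an
#'   object with an \code{\link{rvMatrix}} method.
#' @param conditionIds optional condition labels (default: rownames of the
#'   matrix).
#' @return An \code{hclust} object (merge history, heights, leaf order).
#' @export
clusterConditions <- function(rv, conditionIds = NULL) {
  if (is(rv, "StatisResult") || is(rv, "InterstructureResult"))
    rv <- rvMatrix(rv)
  rv <- as.matrix(rv)
  K <- nrow(rv)
  stopIfNot(K >= 2L, "at least two conditions are required")
  stopIfNot(ncol(rv) == K, "RV matrix must be square")
  stopIfNot(max(abs(rv - t(rv))) <= 1e-8, "RV matrix must be symmetric")
  stopIfNot(max(abs(diag(rv) - 1)) <= 1e-8, "RV matrix must have unit diagonal")
  if (is.null(conditionIds)) conditionIds <- rownames(rv)
  if (is.null(conditionIds)) conditionIds <- paste0("table_", seq_len(K))
  D <- 1 - rv
  dimnames(D) <- list(conditionIds, conditionIds)
  hclust(as.dist(D), method = "average")
}

#' Export a condition dendrogram as a Newick string
#'
#' Branch lengths follow the ultrametric convention: the root-to-leaf path
#' length below each join equals half that join's merge height, so two
#' leaves merging at height h are each assigned branch length h/2.
#'
#' @param d an \code{hclust} object from \code{\link{clusterConditions}}.
#' @return A Newick string parseable by standard readers.
#' @export
dendrogramToNewick <- function(d) {
  stopifnot(inherits(d, "hclust"))
  ape::write.tree(ape::as.phylo(d))
}
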
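#' @import methods
#' @importFrom stats eigen na.omit p.adjust phyper qnorm rnorm sd setNames
#'   as.dist hclust cophenetic
NULL

#' Condition labels of a multi-table object
#'
#' @param x an object holding per-condition data.
#' @return Character vector of condition identifiers.
#' @export
setGeneric("conditionNames", function(x) standardGeneric("conditionNames"))

#' Time grid (minutes) of a multi-table object
#'
#' @param x an object carrying a shared time grid.
#' @return Numeric vector of time points in minutes, strictly increasing;
#'   the first entry is the reference time point.
#' @export
setGeneric("timePoints", function(x) standardGeneric("timePoints"))

#' Control-condition label
#'
#' @param x an object with a designated control table.
#' @return Length-one character.
#' @export
setGeneric("controlCondition", function(x) standardGeneric("controlCondition"))

#' Scale of the stored expression values
#'
#' @param x a \code{TableCollection}.
#' @return One of \code{"linear"}, \code{"log2"}, \code{"centered"}.
#' @export
setGeneric("exprScale", function(x) standardGeneric("exprScale"))

#' Extract one condition's expression matrix
#'
#' @param x a \code{TableCollection}.
#' @param condition condition label.
#' @return Numeric gene-by-time matrix.
#' @export
setGeneric("tableMatrix", function(x, condition) standardGeneric("tableMatrix"))

#' Table weights of a STATIS analysis
#'
#' @param x an \code{InterstructureResult} or \code{StatisResult}.
#' @param norm \code{"sum1"} for weights summing to one (used to build the
#'   compromise) or \code{"l2"} for the unit-Euclidean-norm variant.
#' @return Named numeric vector of length K.
#' @export
setGeneric("tableWeights", function(x, norm = c("sum1", "l2"))
  standardGeneric("tableWeights"))

#' Pairwise RV coefficient matrix
#'
#' @param x an \code{InterstructureResult} or \code{StatisResult}.
#' @return K-by-K symmetric matrix with unit diagonal.
#' @export
setGeneric("rvMatrix", function(x) standardGeneric("rvMatrix"))

#' Compromise factor scores
#'
#' @param x a \code{CompromiseDecomposition} or \code{StatisResult}.
#' @param ... unused.
#' @return Numeric matrix of observations by retained components.
#' @export
setGeneric("factorScores", function(x, ...) standardGeneric("factorScores"))

#' Row, column or table contributions
#'
#' @param x a \code{StatisResult} or \code{ContributionSet}.
#' @param which one of \code{"rows"}, \code{"columns"}, \code{"tables"}.
#' @return Numeric matrix of contributions; each column sums to one.
#' @export
setGeneric("contributions", function(x, which = c("rows", "columns", "tables"))
  standardGeneric("contributions"))

#' Eigenvalues of the compromise decomposition
#'
#' @param x a \code{CompromiseDecomposition} or \code{StatisResult}.
#' @return Numeric vector, descending, non-negative.
#' @export
setGeneric("compromiseEigenvalues", function(x)
  standardGeneric("compromiseEigenvalues"))

#' Gene-set identifiers
#'
#' @param x a \code{GeneSetCollection}.
#' @return Character vector of set ids.
#' @export
setGeneric("geneSetIds", function(x) standardGeneric("geneSetIds"))

#' Gene-set member lists
#'
#' @param x a \code{GeneSetCollection}.
#' @return Named list of character vectors.
#' @export
setGeneric("geneSetMembers", function(x) standardGeneric("geneSetMembers"))
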
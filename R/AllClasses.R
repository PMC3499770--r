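#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#'   assayNames colData
#' @importFrom S4Vectors DataFrame metadata
NULL

.SCALES <- c("linear", "log2", "centered")

#' TableCollection: K condition tables over a shared gene list and time grid
#'
#' A \code{TableCollection} stores K gene-by-time expression matrices, one
#' per experimental condition, as assays of a
#' \linkS4class{SummarizedExperiment}.  Rows are genes (shared, identically
#' ordered across conditions), columns are time points in minutes (shared
#' grid, strictly increasing, first entry the reference), and each assay is
#' one condition's matrix.  One condition is designated the control.
#'
#' @slot controlId label of the control condition (must name an assay).
#' @slot exprScale scale of the values: \code{"linear"}, \code{"log2"}, or
#'   \code{"centered"} after preprocessing.
#'
#' @seealso \code{\link{TableCollection}} (constructor),
#'   \code{\link{readExpressionTables}}, \code{\link{generateCollection}}
#' @export
setClass("TableCollection",
  contains = "SummarizedExperiment",
  representation(controlId = "character", exprScale = "character"))

setValidity("TableCollection", function(object) {
  msg <- character()
  an <- assayNames(object)
  if (is.null(an) || anyDuplicated(an) || any(!nzchar(an)))
    msg <- c(msg, "assay (condition) names must be unique and non-empty")
  if (length(object@controlId) != 1L || !(object@controlId %in% an))
    msg <- c(msg, "'controlId' must name exactly one condition table")
  if (length(object@exprScale) != 1L || !(object@exprScale %in% .SCALES))
    msg <- c(msg, sprintf("'exprScale' must be one of %s",
                          paste(.SCALES, collapse = ", ")))
  tm <- colData(object)$time_min
  if (is.null(tm) || !is.numeric(tm))
    msg <- c(msg, "colData must carry a numeric 'time_min' column")
  else {
    if (any(tm < 0)) msg <- c(msg, "time points must be non-negative")
    if (length(tm) > 1L && any(diff(tm) <= 0))
      msg <- c(msg, "time points must be strictly increasing")
  }
  if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
    msg <- c(msg, "gene ids (rownames) must be present and unique")
  for (nm in an) {
    a <- assay(object, nm)
    if (!is.numeric(a) || anyNA(a)) {
      msg <- c(msg, sprintf("table '%s' contains missing or non-numeric values", nm))
      break
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a TableCollection
#'
#' Builds a validated \linkS4class{TableCollection} from a named list of
#' gene-by-time matrices.  Gene (row) order is canonicalized to
#' lexicographic order of the gene ids (C locale), so the result is
#' independent of the input row order.
#'
#' @param tables named list of K numeric matrices with identical dimnames
#'   (rownames = gene ids, one column per time point).
#' @param timePoints numeric vector of time points in minutes, strictly
#'   increasing; length must match the column count.
#' @param controlId condition label of the control table.
#' @param scale scale of the values, \code{"log2"} or \code{"linear"}
#'   (\code{"centered"} is reserved for preprocessed output).
#' @return A \code{TableCollection}.
#' @examples
#' m <- matrix(rnorm(12), 3, 4, dimnames = list(c("g1", "g2", "g3"), NULL))
#' tc <- TableCollection(list(ctrl = m, stress = m + 1),
#'                       timePoints = c(0, 10, 20, 40),
#'                       controlId = "ctrl", scale = "log2")
#' conditionNames(tc)
#' @export
TableCollection <- function(tables, timePoints, controlId,
                            scale = c("log2", "linear", "centered")) {
  scale <- match.arg(scale)
  if (!is.list(tables) || length(tables) < 1L)
    stop("'tables' must be a non-empty named list of matrices")
  if (is.null(names(tables)) || any(!nzchar(names(tables))))
    stop("'tables' must be named by condition")
  tables <- lapply(tables, as.matrix)
  g <- rownames(tables[[1L]])
  if (is.null(g)) stop("tables must carry gene ids as rownames")
  for (nm in names(tables)) {
    if (!identical(sort(rownames(tables[[nm]])), sort(g)))
      stop(sprintf("gene set mismatch in table '%s'", nm))
    if (ncol(tables[[nm]]) != length(timePoints))
      stop(sprintf("time grid mismatch in table '%s'", nm))
  }
  ord <- order(g, method = "radix")       # locale-independent canonical order
  canon <- g[ord]
  tables <- lapply(tables, function(m) {
    m <- m[canon, , drop = FALSE]
    colnames(m) <- as.character(timePoints)
    m
  })
  se <- SummarizedExperiment(
    assays = tables,
    colData = DataFrame(time_min = as.numeric(timePoints),
                        row.names = as.character(timePoints)))
  new("TableCollection", se, controlId = controlId, exprScale = scale)
}

#' GeneSetCollection: named gene sets for over-representation analysis
#'
#' @slot setIds character vector of unique set identifiers.
#' @slot descriptions named character vector of set descriptions.
#' @slot members named list of deduplicated member gene-id vectors.
#' @seealso \code{\link{readGeneSets}}, \code{\link{hypergeometricEnrichment}}
#' @export
setClass("GeneSetCollection",
  representation(setIds = "character", descriptions = "character",
                 members = "list"))

setValidity("GeneSetCollection", function(object) {
  msg <- character()
  if (anyDuplicated(object@setIds)) msg <- c(msg, "set ids must be unique")
  if (!identical(names(object@members), object@setIds) ||
      !identical(names(object@descriptions), object@setIds))
    msg <- c(msg, "members and descriptions must be named by the set ids")
  if (any(vapply(object@members, anyDuplicated, 0L) > 0L))
    msg <- c(msg, "member lists must be deduplicated")
  if (length(msg)) msg else TRUE
})

#' Construct a GeneSetCollection
#'
#' @param members named list of character vectors (set id -> member gene
#'   ids); members are deduplicated.
#' @param descriptions optional character vector of descriptions, recycled
#'   empty if absent.
#' @return A \code{GeneSetCollection}.
#' @export
GeneSetCollection <- function(members, descriptions = NULL) {
  ids <- names(members)
  if (is.null(ids)) stop("'members' must be a named list")
  members <- lapply(members, function(m) unique(as.character(m)))
  if (is.null(descriptions)) descriptions <- rep("", length(ids))
  new("GeneSetCollection", setIds = ids,
      descriptions = setNames(as.character(descriptions), ids),
      members = setNames(members, ids))
}

#' CrossProductSet: per-table cross-product matrices
#'
#' Holds the K square cross-product matrices S_i, either gene-by-gene
#' (\code{mode = "rows"}, S_i = X_i X_i') or time-by-time
#' (\code{mode = "columns"}, S_i = X_i' X_i), with their Frobenius norms.
#'
#' @slot mode \code{"rows"} or \code{"columns"}.
#' @slot matrices list of K symmetric positive semidefinite matrices.
#' @slot frobeniusNorms numeric vector of Frobenius norms.
#' @slot conditionIds condition labels.
#' @slot ids row/column labels of each S_i (gene ids or time labels).
#' @export
setClass("CrossProductSet",
  representation(mode = "character", matrices = "list",
                 frobeniusNorms = "numeric", conditionIds = "character",
                 ids = "character"))

setValidity("CrossProductSet", function(object) {
  msg <- character()
  if (!(object@mode %in% c("rows", "columns")))
    msg <- c(msg, "'mode' must be 'rows' or 'columns'")
  if (length(object@matrices) != length(object@frobeniusNorms) ||
      length(object@matrices) != length(object@conditionIds))
    msg <- c(msg, "matrices, norms and condition ids must have equal length")
  for (S in object@matrices) {
    if (nrow(S) != ncol(S)) { msg <- c(msg, "matrices must be square"); break }
    scl <- max(abs(S), 1e-300)
    if (max(abs(S - t(S))) > 1e-10 * scl) {
      msg <- c(msg, "matrices must be symmetric within 1e-10"); break
    }
    ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8 * max(abs(ev), 1e-300)) {
      msg <- c(msg, "matrices must be positive semidefinite"); break
    }
  }
  if (length(msg)) msg else TRUE
})

#' InterstructureResult: between-table congruence and table weights
#'
#' @slot C K-by-K matrix of Frobenius inner products between cross-product
#'   matrices.
#' @slot leadingEigenvector entrywise non-negative leading eigenvector of C.
#' @slot alphaSum1 table weights normalized to sum to one (used to build the
#'   compromise).
#' @slot alphaL2 table weights with unit Euclidean norm.
#' @slot rvMatrix pairwise RV coefficients.
#' @slot rvToCompromise RV of each table's cross-product with the
#'   compromise (NA until a compromise has been formed).
#' @slot conditionIds condition labels.
#' @export
setClass("InterstructureResult",
  representation(C = "matrix", leadingEigenvector = "numeric",
                 alphaSum1 = "numeric", alphaL2 = "numeric",
                 rvMatrix = "matrix", rvToCompromise = "numeric",
                 conditionIds = "character"))

setValidity("InterstructureResult", function(object) {
  msg <- character()
  K <- length(object@conditionIds)
  if (max(abs(object@C - t(object@C))) > 1e-8 * max(abs(object@C), 1e-300))
    msg <- c(msg, "C must be symmetric")
  if (any(object@leadingEigenvector < 0))
    msg <- c(msg, "leading eigenvector must be entrywise non-negative")
  if (abs(sum(object@alphaSum1) - 1) > 1e-8)
    msg <- c(msg, "alphaSum1 must sum to one")
  if (abs(sqrt(sum(object@alphaL2^2)) - 1) > 1e-8)
    msg <- c(msg, "alphaL2 must have unit Euclidean norm")
  rv <- object@rvMatrix
  if (nrow(rv) != K || max(abs(diag(rv) - 1)) > 1e-8 ||
      any(rv < -1e-10) || any(rv > 1 + 1e-10))
    msg <- c(msg, "rvMatrix must have unit diagonal and entries in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' CompromiseDecomposition: mass-metric eigendecomposition of the compromise
#'
#' Represents S = P Lambda P' under the constraint P' M P = I, where
#' M = diag(masses).  Computed as the standard symmetric eigendecomposition
#' of M^(1/2) S M^(1/2).
#'
#' @slot S the compromise matrix.
#' @slot eigenvalues all eigenvalues, descending, negatives within numerical
#'   noise clipped to zero.
#' @slot P eigenvector matrix, retained components only, M-orthonormal.
#' @slot Delta square roots of the retained eigenvalues.
#' @slot masses row masses (non-negative, summing to one).
#' @slot nComponents number of retained components.
#' @slot ids row labels of S.
#' @export
setClass("CompromiseDecomposition",
  representation(S = "matrix", eigenvalues = "numeric", P = "matrix",
                 Delta = "numeric", masses = "numeric",
                 nComponents = "integer", ids = "character"))

setValidity("CompromiseDecomposition", function(object) {
  msg <- character()
  if (any(object@eigenvalues < 0))
    msg <- c(msg, "eigenvalues must be non-negative")
  if (is.unsorted(rev(object@eigenvalues)))
    msg <- c(msg, "eigenvalues must be descending")
  if (abs(sum(object@masses) - 1) > 1e-12)
    msg <- c(msg, "masses must sum to one")
  r <- object@nComponents
  if (ncol(object@P) != r || length(object@Delta) != r)
    msg <- c(msg, "P and Delta must match nComponents")
  G <- crossprod(object@P, object@masses * object@P)
  if (max(abs(G - diag(r))) > 1e-8)
    msg <- c(msg, "P must satisfy P' M P = I within 1e-8")
  if (length(msg)) msg else TRUE
})

#' ScoresAndLoadings: factor scores, partial scores and loadings
#'
#' @slot F observation-by-component global factor scores.
#' @slot Fpartial list of K per-table factor score matrices.
#' @slot Q stacked loadings for all K*t columns, in table order.
#' @slot a column weights, table weight repeated over its t columns.
#' @slot variableIds labels "condition:time" for the stacked columns.
#' @export
setClass("ScoresAndLoadings",
  representation(F = "matrix", Fpartial = "list", Q = "matrix",
                 a = "numeric", variableIds = "character"))

#' ContributionSet: normalized shares of component variance
#'
#' @slot rows n-by-r contributions of observations.
#' @slot columns (K*t)-by-r contributions of columns.
#' @slot tables K-by-r contributions of tables.
#' @export
setClass("ContributionSet",
  representation(rows = "matrix", columns = "matrix", tables = "matrix"))

setValidity("ContributionSet", function(object) {
  msg <- character()
  for (nm in c("rows", "columns", "tables")) {
    m <- slot(object, nm)
    if (any(m < -1e-10) || any(m > 1 + 1e-10))
      msg <- c(msg, sprintf("%s contributions must lie in [0, 1]", nm))
    if (ncol(m) > 0 && max(abs(colSums(m) - 1)) > 1e-8)
      msg <- c(msg, sprintf("%s contributions must sum to one per component", nm))
  }
  if (length(msg)) msg else TRUE
})

#' StatisResult: full output of a STATIS or dual-STATIS run
#'
#' @slot mode \code{"rows"} (observations are genes) or \code{"columns"}
#'   (dual variant; observations are time points).
#' @slot interstructure an \code{InterstructureResult}.
#' @slot decomposition a \code{CompromiseDecomposition}.
#' @slot scores a \code{ScoresAndLoadings}.
#' @slot contributions a \code{ContributionSet}.
#' @slot conditionIds condition labels.
#' @slot observationIds labels of the observations (genes, or time points
#'   in dual mode).
#' @seealso \code{\link{runStatis}}, \code{\link{runDualStatis}}
#' @export
setClass("StatisResult",
  representation(mode = "character", interstructure = "InterstructureResult",
                 decomposition = "CompromiseDecomposition",
                 scores = "ScoresAndLoadings",
                 contributions = "ContributionSet",
                 conditionIds = "character", observationIds = "character"))

#' BootstrapResult: bootstrap-over-tables significance of observations
#'
#' @slot nBoot number of bootstrap replicates.
#' @slot ratios n-by-r bootstrap ratios (mean/sd across replicates);
#'   signed infinity marks degenerate zero-variance cases.
#' @slot meanScores,sdScores replicate means and standard deviations.
#' @slot significant logical n-by-r flags at \code{alphaLevel}.
#' @slot alphaLevel significance level.
#' @slot basis \code{"factor_scores"} (two-sided) or \code{"contributions"}
#'   (one-sided).
#' @slot seed RNG seed used.
#' @seealso \code{\link{bootstrapTables}}, \code{\link{significantGenes}}
#' @export
setClass("BootstrapResult",
  representation(nBoot = "integer", ratios = "matrix", meanScores = "matrix",
                 sdScores = "matrix", significant = "matrix",
                 alphaLevel = "numeric", basis = "character",
                 seed = "integer"))

#' SyntheticGroundTruth: generating design of a simulated collection
#'
#' @slot design data.frame with columns condition, light, temperature.
#' @slot modules named list of gene ids per response module (disjoint).
#' @slot factors named character: module id -> latent factor
#'   (\code{"diurnal"}, \code{"light"}, \code{"temperature"}).
#' @slot loadings named numeric: per module-gene signed loading.
#' @slot beta effect size (log2 units per unit latent signal).
#' @slot sigma noise standard deviation (log2 units).
#' @slot outlierCondition condition whose signals were replaced by an
#'   independent draw, or NA.
#' @slot seed generator seed.
#' @slot params list of remaining generator constants.
#' @export
setClass("SyntheticGroundTruth",
  representation(design = "data.frame", modules = "list",
                 factors = "character", loadings = "numeric",
                 beta = "numeric", sigma = "numeric",
                 outlierCondition = "character", seed = "integer",
                 params = "list"))

setValidity("SyntheticGroundTruth", function(object) {
  msg <- character()
  all_members <- unlist(object@modules, use.names = FALSE)
  if (anyDuplicated(all_members)) msg <- c(msg, "modules must be disjoint")
  if (object@beta < 0) msg <- c(msg, "beta must be non-negative")
  if (object@sigma <= 0) msg <- c(msg, "sigma must be positive")
  if (length(msg)) msg else TRUE
})
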
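#' @describeIn TableCollection condition labels (assay names).
#' @param x a \code{TableCollection}.
#' @export
setMethod("conditionNames", "TableCollection",
          function(x) assayNames(x))

#' @describeIn TableCollection shared time grid in minutes.
#' @export
setMethod("timePoints", "TableCollection",
          function(x) colData(x)$time_min)

#' @describeIn TableCollection label of the control condition.
#' @export
setMethod("controlCondition", "TableCollection", function(x) x@controlId)

#' @describeIn TableCollection scale of the stored values.
#' @export
setMethod("exprScale", "TableCollection", function(x) x@exprScale)

#' @describeIn TableCollection one condition's gene-by-time matrix.
#' @param condition condition label.
#' @export
setMethod("tableMatrix", "TableCollection", function(x, condition) {
  if (!(condition %in% assayNames(x)))
    stop(sprintf("unknown condition '%s'", condition))
  assay(x, condition)
})

setMethod("show", "TableCollection", function(object) {
  cat(sprintf(
    "TableCollection: %d conditions x %d genes x %d time points [%s scale]\n",
    length(assayNames(object)), nrow(object), ncol(object),
    object@exprScale))
  cat("  conditions:", paste(assayNames(object), collapse = ", "), "\n")
  cat("  control:   ", object@controlId, "\n")
  tm <- colData(object)$time_min
  cat(sprintf("  time grid:  %g .. %g min\n", tm[1L], tm[length(tm)]))
})

#' Convert a TableCollection to a plain list of matrices
#'
#' @param x a \code{TableCollection}.
#' @return Named list of K gene-by-time matrices.
#' @export
tableList <- function(x) {
  stopifnot(is(x, "TableCollection"))
  setNames(lapply(assayNames(x), function(nm) assay(x, nm)), assayNames(x))
}

setMethod("show", "GeneSetCollection", function(object) {
  sz <- lengths(object@members)
  cat(sprintf("GeneSetCollection: %d sets (sizes %s)\n", length(object@setIds),
              if (length(sz)) paste0(min(sz), "-", max(sz)) else "-"))
})

#' @describeIn GeneSetCollection set identifiers.
#' @param x a \code{GeneSetCollection}.
#' @export
setMethod("geneSetIds", "GeneSetCollection", function(x) x@setIds)

#' @describeIn GeneSetCollection named list of member gene ids.
#' @export
setMethod("geneSetMembers", "GeneSetCollection", function(x) x@members)

setMethod("show", "StatisResult", function(object) {
  lam <- object@decomposition@eigenvalues
  r <- object@decomposition@nComponents
  prop <- if (sum(lam) > 0) lam[seq_len(r)] / sum(lam) else rep(NA_real_, r)
  cat(sprintf("StatisResult (%s mode): %d tables, %d observations, %d components\n",
              if (object@mode == "rows") "STATIS" else "dual-STATIS",
              length(object@conditionIds), length(object@observationIds), r))
  cat("  variance explained:",
      paste(sprintf("%.1f%%", 100 * prop), collapse = ", "), "\n")
  w <- object@interstructure@alphaSum1
  cat("  table weights (sum-to-one):",
      paste(sprintf("%s=%.3f", object@conditionIds, w), collapse = " "), "\n")
})

setMethod("show", "BootstrapResult", function(object) {
  cat(sprintf("BootstrapResult: B=%d, basis=%s, alpha=%g; %d/%d observations significant on >=1 component\n",
              object@nBoot, object@basis, object@alphaLevel,
              sum(rowSums(object@significant) > 0), nrow(object@ratios)))
})

#' @describeIn StatisResult table weights of the analysis.
#' @param norm \code{"sum1"} or \code{"l2"}.
#' @export
setMethod("tableWeights", "StatisResult", function(x, norm = c("sum1", "l2"))
  tableWeights(x@interstructure, norm))

#' @describeIn StatisResult pairwise RV matrix.
#' @export
setMethod("rvMatrix", "StatisResult", function(x) x@interstructure@rvMatrix)

setMethod("tableWeights", "InterstructureResult",
  function(x, norm = c("sum1", "l2")) {
    norm <- match.arg(norm)
    w <- if (norm == "sum1") x@alphaSum1 else x@alphaL2
    setNames(w, x@conditionIds)
  })

setMethod("rvMatrix", "InterstructureResult", function(x) x@rvMatrix)

#' @describeIn StatisResult global factor scores.
#' @param ... unused.
#' @export
setMethod("factorScores", "StatisResult", function(x, ...) x@scores@F)

#' @describeIn StatisResult contributions of rows, columns or tables.
#' @param which one of \code{"rows"}, \code{"columns"}, \code{"tables"}.
#' @export
setMethod("contributions", "StatisResult",
  function(x, which = c("rows", "columns", "tables")) {
    which <- match.arg(which)
    slot(x@contributions, which)
  })

setMethod("contributions", "ContributionSet",
  function(x, which = c("rows", "columns", "tables")) {
    which <- match.arg(which)
    slot(x, which)
  })

#' @describeIn StatisResult eigenvalues of the compromise.
#' @export
setMethod("compromiseEigenvalues", "StatisResult",
          function(x) x@decomposition@eigenvalues)

setMethod("compromiseEigenvalues", "CompromiseDecomposition",
          function(x) x@eigenvalues)
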
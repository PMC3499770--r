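#' Filter for informative genes by fold-change and coefficient of variation
#'
#' Reproduces the two-criterion filter used to select responsive genes from
#' single-replicate time courses.  Both criteria are evaluated on the
#' linear intensity scale (log2 input is exponentiated for filtering only):
#' a gene is kept iff (A) in at least one condition the fold-change
#' relative to the first (reference) time point, counting induction and
#' repression alike as \code{max(x/x0, x0/x)}, reaches
#' \code{fcThreshold} in at least \code{minFcTimepoints} time points, and
#' (B) in at least one condition (default) or pooled over all conditions,
#' the coefficient of variation (sample sd / mean over the time domain)
#' reaches \code{cvThreshold}.
#'
#' @param collection a \code{\link{TableCollection}} on linear or log2
#'   scale.
#' @param fcThreshold fold-change threshold (default 2).
#' @param minFcTimepoints minimum number of time points at or above the
#'   fold-change threshold (default 2).
#' @param cvThreshold coefficient-of-variation threshold (default 1).
#' @param cvScope \code{"per_condition"} (a gene passes if any single
#'   condition reaches the CV threshold, the default) or \code{"pooled"}
#'   (CV over all K*t values).
#' @return A list with elements \code{collection} (the kept genes, in
#'   canonical order) and \code{report}, a data.frame with one row per
#'   input gene: \code{gene_id}, \code{max_fc_timepoints} (best condition's
#'   count), \code{max_cv}, \code{kept}, and \code{reason} (\code{pass},
#'   \code{fc_fail} or \code{cv_fail}).
#' @export
filterInformativeGenes <- function(collection, fcThreshold = 2,
                                   minFcTimepoints = 2L, cvThreshold = 1,
                                   cvScope = c("per_condition", "pooled")) {
  cvScope <- match.arg(cvScope)
  stopifnot(is(collection, "TableCollection"))
  stopIfNot(exprScale(collection) %in% c("linear", "log2"),
            "filtering requires linear or log2 scale, not '%s'",
            exprScale(collection))
  tabs <- tableList(collection)
  if (exprScale(collection) == "log2") tabs <- lapply(tabs, function(m) 2^m)
  genes <- rownames(collection)
  n <- length(genes); t <- ncol(collection)
  stopIfNot(t >= 2L, "at least two time points are required")

  fc_count <- matrix(0L, n, length(tabs))
  cv <- matrix(NA_real_, n, length(tabs))
  for (k in seq_along(tabs)) {
    m <- tabs[[k]]
    x0 <- m[, 1L]
    bad <- which(x0 <= 0)
    if (length(bad))
      stop(sprintf("non-positive reference value for gene '%s' in condition '%s'",
                   genes[bad[1L]], names(tabs)[k]))
    fc <- pmax(m[, -1L, drop = FALSE] / x0, x0 / m[, -1L, drop = FALSE])
    fc_count[, k] <- rowSums(fc >= fcThreshold)
    mu <- rowMeans(m)
    badm <- which(mu <= 0)
    if (length(badm))
      stop(sprintf("non-positive mean for gene '%s' in condition '%s'",
                   genes[badm[1L]], names(tabs)[k]))
    s2 <- rowSums((m - mu)^2) / (t - 1L)
    cv[, k] <- sqrt(s2) / mu
  }
  max_fc <- apply(fc_count, 1L, max)
  max_cv <- if (cvScope == "per_condition") {
    apply(cv, 1L, max)
  } else {
    all_m <- do.call(cbind, tabs)
    mu <- rowMeans(all_m)
    sqrt(rowSums((all_m - mu)^2) / (ncol(all_m) - 1L)) / mu
  }
  fc_ok <- max_fc >= minFcTimepoints
  cv_ok <- max_cv >= cvThreshold
  kept <- fc_ok & cv_ok
  reason <- ifelse(kept, "pass", ifelse(!fc_ok, "fc_fail", "cv_fail"))
  report <- data.frame(gene_id = genes, max_fc_timepoints = max_fc,
                       max_cv = max_cv, kept = kept, reason = reason,
                       stringsAsFactors = FALSE)
  sub <- collection[kept, ]
  list(collection = sub, report = report)
}

#' Center and scale one expression matrix for multi-table analysis
#'
#' Column-centers the matrix and rescales it so that its total sum of
#' squares equals one (\code{method = "table"}); this puts every table on
#' the same footing so that no single table dominates the between-table
#' congruence by sheer scale, and makes cross-product inner products
#' directly comparable to RV numerators.  With \code{method = "column_z"}
#' each column is additionally divided by its sample standard deviation
#' before the table-level rescaling (all-constant columns become all-zero
#' and are retained).
#'
#' @param m numeric matrix, at least two rows.
#' @param method \code{"table"} (default) or \code{"column_z"}.
#' @return The preprocessed matrix: column means 0, total sum of squares 1.
#' @export
centerScaleMatrix <- function(m, method = c("table", "column_z")) {
  method <- match.arg(method)
  stopIfNot(nrow(m) >= 2L, "at least two rows are required")
  m <- sweep(m, 2L, colMeans(m), "-")
  if (method == "column_z") {
    s <- apply(m, 2L, sd)
    s[s < 1e-12] <- 1           # constant column stays all-zero
    m <- sweep(m, 2L, s, "/")
  }
  ss <- sum(m^2)
  if (ss < 1e-300) stop("degenerate table: zero total sum of squares after centering")
  m / sqrt(ss)
}

#' Preprocess every table of a collection
#'
#' Applies \code{\link{centerScaleMatrix}} to each condition table.
#'
#' @param collection a \code{\link{TableCollection}}.
#' @param method passed to \code{\link{centerScaleMatrix}}.
#' @return A \code{TableCollection} on \code{"centered"} scale.
#' @export
preprocessTables <- function(collection, method = c("table", "column_z")) {
  method <- match.arg(method)
  tabs <- lapply(tableList(collection), centerScaleMatrix, method = method)
  TableCollection(tabs, timePoints = timePoints(collection),
                  controlId = controlCondition(collection),
                  scale = "centered")
}

#' Normalize every condition against the control time course
#'
#' On the log2 scale, subtracts the control condition's value at the same
#' gene and time point from every non-control table, i.e. replaces
#' absolute expression by the log2 fold-change relative to the control time
#' course.  This removes temporal structure shared with the control --
#' notably circadian/diurnal dynamics -- so that condition-specific
#' responses stand out.  The control table itself is returned unchanged.
#'
#' @param collection a \code{\link{TableCollection}} on log2 scale.
#' @return A \code{TableCollection} on log2 scale.
#' @export
controlNormalize <- function(collection) {
  stopifnot(is(collection, "TableCollection"))
  stopIfNot(exprScale(collection) == "log2",
            "control normalization requires log2 scale, not '%s'",
            exprScale(collection))
  ctrl_id <- controlCondition(collection)
  tabs <- tableList(collection)
  stopIfNot(ctrl_id %in% names(tabs), "missing control table '%s'", ctrl_id)
  ctrl <- tabs[[ctrl_id]]
  out <- lapply(names(tabs), function(nm)
    if (nm == ctrl_id) tabs[[nm]] else tabs[[nm]] - ctrl)
  names(out) <- names(tabs)
  TableCollection(out, timePoints = timePoints(collection),
                  controlId = ctrl_id, scale = "log2")
}

#' Uniform row masses
#'
#' @param n number of rows (observations).
#' @return Numeric vector of length n, all entries 1/n, summing to one.
#' @export
uniformMasses <- function(n) {
  stopIfNot(is.numeric(n) && length(n) == 1L && n >= 1L,
            "'n' must be a positive integer")
  rep(1 / n, n)
}
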
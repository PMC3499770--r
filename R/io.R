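#' Read per-condition expression tables from TSV files
#'
#' Each file holds one condition's gene-by-time matrix: first column header
#' \code{gene_id}, remaining headers the numeric time points in minutes.
#' All files must share the same gene set and time grid.  Rows are
#' canonicalized to lexicographic gene-id order, so the result does not
#' depend on the row order of the input files.  Missing cells (empty or
#' \code{"."}) and non-numeric cells are rejected with the offending
#' location; duplicated gene ids are rejected.
#'
#' @param paths character vector of file paths; if named, the names are the
#'   condition labels, otherwise labels are the file base names without
#'   extension.
#' @param controlId condition label of the control table.
#' @param scale scale of the stored values, \code{"log2"} or
#'   \code{"linear"}.
#' @return A validated \code{\link{TableCollection}}.
#' @export
readExpressionTables <- function(paths, controlId,
                                 scale = c("log2", "linear")) {
  scale <- match.arg(scale)
  stopIfNot(length(paths) >= 1L, "at least one expression table is required")
  ids <- names(paths)
  if (is.null(ids) || any(!nzchar(ids)))
    ids <- sub("\\.[^.]*$", "", basename(paths))
  stopIfNot(!anyDuplicated(ids), "condition labels must be unique")

  tables <- vector("list", length(paths))
  tp_ref <- NULL
  for (k in seq_along(paths)) {
    parsed <- .readOneTable(paths[[k]])
    if (is.null(tp_ref)) tp_ref <- parsed$time
    else if (!isTRUE(all.equal(tp_ref, parsed$time)))
      stop(sprintf("time grid mismatch in file '%s'", paths[[k]]))
    tables[[k]] <- parsed$values
  }
  names(tables) <- ids
  genes0 <- sort(rownames(tables[[1L]]), method = "radix")
  for (k in seq_along(tables)) {
    if (!identical(sort(rownames(tables[[k]]), method = "radix"), genes0))
      stop(sprintf("gene set mismatch in file '%s'", paths[[k]]))
  }
  TableCollection(tables, timePoints = tp_ref, controlId = controlId,
                  scale = scale)
}

.readOneTable <- function(path) {
  stopIfNot(file.exists(path), "file not found: '%s'", path)
  raw <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                           colClasses = "character",
                           stringsAsFactors = FALSE)
  stopIfNot(ncol(raw) >= 2L, "file '%s' must have gene_id plus time columns", path)
  stopIfNot(identical(colnames(raw)[1L], "gene_id"),
            "file '%s': first column header must be 'gene_id'", path)
  tp <- suppressWarnings(as.numeric(colnames(raw)[-1L]))
  stopIfNot(!anyNA(tp), "file '%s': time-point headers must be numeric", path)
  genes <- raw[[1L]]
  if (anyDuplicated(genes))
    stop(sprintf("duplicate gene_id '%s' in file '%s'",
                 genes[duplicated(genes)][1L], path))
  vals <- as.matrix(raw[, -1L, drop = FALSE])
  miss <- vals == "" | vals == "."
  num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals)))
  bad <- which(miss | is.na(num), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf("file '%s': missing or non-numeric cell at row %d (gene '%s'), column '%s'",
                 path, bad[1L, 1L], genes[bad[1L, 1L]],
                 colnames(raw)[bad[1L, 2L] + 1L]))
  rownames(num) <- genes
  list(values = num, time = tp)
}

#' Read gene sets from a GMT file
#'
#' Broad-dialect GMT: one set per line, tab-separated fields set id,
#' description, then member gene ids.  Members are deduplicated; sets with
#' fewer than \code{minSize} members after deduplication are dropped (the
#' number dropped is reported via \code{message}).
#'
#' @param path path to a GMT file.
#' @param minSize minimum member count for a set to be retained.
#' @return A \code{\link{GeneSetCollection}}.
#' @export
readGeneSets <- function(path, minSize = 3L) {
  stopIfNot(file.exists(path), "file not found: '%s'", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  members <- list(); desc <- character()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 2L)
      stop(sprintf("GMT line %d has fewer than 2 fields", i))
    id <- f[[1L]]
    if (id %in% names(members))
      stop(sprintf("duplicate set id '%s' at GMT line %d", id, i))
    members[[id]] <- unique(f[-(1:2)])
    desc[[id]] <- f[[2L]]
  }
  keep <- lengths(members) >= minSize
  if (any(!keep))
    message(sprintf("readGeneSets: dropped %d set(s) below minSize=%d",
                    sum(!keep), minSize))
  GeneSetCollection(members[keep], desc[keep])
}

#' Write gene sets to a GMT file
#'
#' @param sets a \code{GeneSetCollection}.
#' @param path output path.
#' @return Invisibly, the path.
#' @export
writeGeneSets <- function(sets, path) {
  stopifnot(is(sets, "GeneSetCollection"))
  lines <- vapply(sets@setIds, function(id) {
    paste(c(id, sets@descriptions[[id]], sets@members[[id]]), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Write analysis results as a set of TSV files
#'
#' Exports every result component as tab-separated text with 12 significant
#' digits and deterministic row order: \code{table_weights.tsv},
#' \code{rv_matrix.tsv}, \code{eigenvalues.tsv}, \code{factor_scores.tsv},
#' \code{partial_factor_scores.tsv}, \code{loadings.tsv},
#' \code{contributions_rows.tsv}, \code{contributions_columns.tsv},
#' \code{contributions_tables.tsv}, plus \code{bootstrap_ratios.tsv},
#' \code{enrichment.tsv}, \code{dendrogram.nwk} and
#' \code{filter_report.tsv} when the corresponding results are supplied.
#'
#' @param statis a \code{\link{StatisResult}}.
#' @param outDir output directory (created if absent).
#' @param bootstrap optional \code{BootstrapResult}.
#' @param enrichment optional enrichment data.frame
#'   (\code{\link{hypergeometricEnrichment}}); an empty result yields a
#'   header-only file.
#' @param dendrogram optional \code{hclust} from
#'   \code{\link{clusterConditions}}.
#' @param filterReport optional filter report data.frame.
#' @return Invisibly, the character vector of files written.
#' @export
writeResults <- function(statis, outDir, bootstrap = NULL, enrichment = NULL,
                         dendrogram = NULL, filterReport = NULL) {
  stopifnot(is(statis, "StatisResult"))
  ok <- dir.exists(outDir) || dir.create(outDir, recursive = TRUE,
                                         showWarnings = FALSE)
  stopIfNot(ok && file.access(outDir, 2L) == 0L,
            "output directory '%s' is not writable", outDir)
  files <- character()
  put <- function(df, name) {
    p <- file.path(outDir, name)
    writeTsv(df, p)
    files <<- c(files, p)
  }
  inter <- statis@interstructure
  dec <- statis@decomposition
  sc <- statis@scores
  r <- dec@nComponents
  comp_cols <- paste0("comp_", seq_len(r))

  put(data.frame(condition = inter@conditionIds,
                 alpha_sum1 = inter@alphaSum1,
                 alpha_l2 = inter@alphaL2,
                 rv_to_compromise = inter@rvToCompromise,
                 rv2_to_compromise = inter@rvToCompromise^2,
                 stringsAsFactors = FALSE), "table_weights.tsv")

  rv <- as.data.frame(inter@rvMatrix)
  colnames(rv) <- inter@conditionIds
  put(cbind(data.frame(condition = inter@conditionIds,
                       stringsAsFactors = FALSE), rv), "rv_matrix.tsv")

  lam <- dec@eigenvalues
  put(data.frame(component = seq_along(lam), eigenvalue = lam,
                 proportion = if (sum(lam) > 0) lam / sum(lam) else lam),
      "eigenvalues.tsv")

  fs <- as.data.frame(sc@F); colnames(fs) <- comp_cols
  put(cbind(data.frame(id = statis@observationIds,
                       stringsAsFactors = FALSE), fs), "factor_scores.tsv")

  pf <- do.call(rbind, lapply(seq_along(sc@Fpartial), function(k) {
    m <- as.data.frame(sc@Fpartial[[k]]); colnames(m) <- comp_cols
    cbind(data.frame(condition = statis@conditionIds[[k]],
                     id = statis@observationIds,
                     stringsAsFactors = FALSE), m)
  }))
  put(pf, "partial_factor_scores.tsv")

  q <- as.data.frame(sc@Q); colnames(q) <- comp_cols
  put(cbind(data.frame(variable = sc@variableIds,
                       column_weight = sc@a, stringsAsFactors = FALSE), q),
      "loadings.tsv")

  ctr <- statis@contributions
  mk <- function(m, idcol, ids) {
    d <- as.data.frame(m); colnames(d) <- comp_cols
    cbind(setNames(data.frame(ids, stringsAsFactors = FALSE), idcol), d)
  }
  put(mk(ctr@rows, "id", statis@observationIds), "contributions_rows.tsv")
  put(mk(ctr@columns, "variable", sc@variableIds), "contributions_columns.tsv")
  put(mk(ctr@tables, "condition", statis@conditionIds), "contributions_tables.tsv")

  if (!is.null(bootstrap)) {
    stopifnot(is(bootstrap, "BootstrapResult"))
    rb <- as.data.frame(bootstrap@ratios)
    colnames(rb) <- paste0("ratio_", seq_len(ncol(rb)))
    fl <- as.data.frame(bootstrap@significant)
    colnames(fl) <- paste0("significant_", seq_len(ncol(fl)))
    put(cbind(data.frame(id = rownames(bootstrap@ratios),
                         stringsAsFactors = FALSE), rb, fl),
        "bootstrap_ratios.tsv")
  }
  if (!is.null(enrichment)) put(enrichment, "enrichment.tsv")
  if (!is.null(dendrogram)) {
    p <- file.path(outDir, "dendrogram.nwk")
    writeLines(dendrogramToNewick(dendrogram), p)
    files <- c(files, p)
  }
  if (!is.null(filterReport)) put(filterReport, "filter_report.tsv")
  invisible(files)
}
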
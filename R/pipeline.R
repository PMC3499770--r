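.PIPELINE_KEYS <- c("io", "simulate", "filter", "table_norm", "statis",
                    "bootstrap", "enrichment", "cluster",
                    "alt_normalization", "out_dir")

.checkKeys <- function(block, allowed, where) {
  bad <- setdiff(names(block), allowed)
  if (length(bad))
    stop(sprintf("unknown key(s) in '%s' config block: %s", where,
                 paste(bad, collapse = ", ")))
}

.getOr <- function(block, key, default) {
  if (is.null(block[[key]])) default else block[[key]]
}

#' Run the full multi-table analysis pipeline
#'
#' Orchestrates the complete analysis from a structured configuration:
#' load (or simulate) the condition tables, filter informative genes, run
#' STATIS and dual-STATIS, bootstrap significance, gene-set
#' over-representation, RV-based condition clustering, and write all
#' outputs as TSV/Newick under the output directory.  When
#' \code{alt_normalization} is true the whole analysis is repeated on the
#' control-normalized data in a second subdirectory
#' (\code{control_normalized/} next to \code{standard/}).  A
#' \code{manifest.json} records the configuration, package and R versions
#' and all seeds, so every analysis choice is auditable from the outputs.
#' Results are a pure function of (inputs, config): reruns produce
#' byte-identical tables.
#'
#' Configuration blocks (unknown keys are rejected): \code{io} (paths,
#' control_id, scale) or \code{simulate} (arguments of
#' \code{\link{generateCollection}}, seed mandatory); \code{filter}
#' (fc_threshold, min_fc_timepoints, cv_threshold, cv_scope, enabled);
#' \code{table_norm} ("table" or "column_z"); \code{statis}
#' (n_components, weight_norm, dual); \code{bootstrap} (B, seed, basis,
#' alpha_level, components_for_union, enabled); \code{enrichment}
#' (gmt, fdr_cutoff, min_set_size, ground_truth_sets, n_decoys, seed);
#' \code{cluster} (logical); \code{alt_normalization} (logical).
#'
#' @param config path to a YAML or JSON configuration file, or an
#'   equivalent named list.
#' @param outDir output directory; overrides \code{out_dir} in the config.
#' @param verbose log per-stage progress to stderr.
#' @return Invisibly, a named list of per-strategy results (each with
#'   elements statis, dual, bootstrap, significant, enrichment,
#'   dendrogram, filterReport).
#' @export
runPipeline <- function(config, outDir = NULL, verbose = FALSE) {
  if (is.character(config)) {
    stopIfNot(file.exists(config), "config file not found: '%s'", config)
    config <- if (grepl("\\.json$", config, ignore.case = TRUE))
      jsonlite::read_json(config, simplifyVector = TRUE)
    else yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  .checkKeys(config, .PIPELINE_KEYS, "top-level")
  if (is.null(outDir)) outDir <- config$out_dir
  stopIfNot(!is.null(outDir), "an output directory is required")
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  log <- function(fmt, ...) {
    if (verbose) message(sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                                 sprintf(fmt, ...)))
  }
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    log("stage %-18s %.2fs", name, proc.time()[["elapsed"]] - t0)
    out
  }

  truth <- NULL
  data <- stage("load", {
    if (!is.null(config$simulate)) {
      sb <- config$simulate
      .checkKeys(sb, c("n_genes", "time_points", "module_sizes", "beta",
                       "sigma", "seed", "outlier_condition", "scale",
                       "control_id"), "simulate")
      stopIfNot(!is.null(sb$seed), "simulate block requires a seed")
      args <- list(seed = sb$seed)
      if (!is.null(sb$n_genes)) args$nGenes <- sb$n_genes
      if (!is.null(sb$time_points)) args$timePoints <- as.numeric(sb$time_points)
      if (!is.null(sb$module_sizes)) args$moduleSizes <- unlist(sb$module_sizes)
      if (!is.null(sb$beta)) args$beta <- sb$beta
      if (!is.null(sb$sigma)) args$sigma <- sb$sigma
      if (!is.null(sb$outlier_condition)) args$outlierCondition <- sb$outlier_condition
      if (!is.null(sb$scale)) args$scale <- sb$scale
      if (!is.null(sb$control_id)) args$controlId <- sb$control_id
      sim <- do.call(generateCollection, args)
      truth <- sim$truth
      jsonlite::write_json(
        list(seed = sim$truth@seed, beta = sim$truth@beta,
             sigma = sim$truth@sigma,
             outlier_condition = sim$truth@outlierCondition,
             modules = sim$truth@modules,
             factors = as.list(sim$truth@factors),
             design = sim$truth@design),
        file.path(outDir, "ground_truth.json"), auto_unbox = TRUE,
        digits = NA)
      sim$collection
    } else {
      io <- config$io
      stopIfNot(!is.null(io), "either an 'io' or a 'simulate' block is required")
      .checkKeys(io, c("paths", "control_id", "scale"), "io")
      paths <- unlist(io$paths)
      readExpressionTables(paths, controlId = io$control_id,
                           scale = .getOr(io, "scale", "log2"))
    }
  })

  fb <- .getOr(config, "filter", list())
  .checkKeys(fb, c("fc_threshold", "min_fc_timepoints", "cv_threshold",
                   "cv_scope", "enabled"), "filter")

  # each strategy transforms the raw data, then re-runs the gene filter,
  # so the informative-gene universe is normalization-specific
  strategies <- list(standard = data)
  if (isTRUE(config$alt_normalization))
    strategies$control_normalized <- stage("control_normalize",
                                           controlNormalize(data))
  filterReports <- list()
  for (strat in names(strategies)) {
    if (.getOr(fb, "enabled", TRUE)) {
      flt <- stage(paste0(strat, "/filter"), filterInformativeGenes(
        strategies[[strat]], fcThreshold = .getOr(fb, "fc_threshold", 2),
        minFcTimepoints = .getOr(fb, "min_fc_timepoints", 2L),
        cvThreshold = .getOr(fb, "cv_threshold", 1),
        cvScope = .getOr(fb, "cv_scope", "per_condition")))
      strategies[[strat]] <- flt$collection
      filterReports[[strat]] <- flt$report
      log("%s: filter kept %d/%d genes", strat, sum(flt$report$kept),
          nrow(flt$report))
    }
  }

  sblock <- .getOr(config, "statis", list())
  .checkKeys(sblock, c("n_components", "weight_norm", "dual"), "statis")
  bblock <- .getOr(config, "bootstrap", list())
  .checkKeys(bblock, c("B", "seed", "basis", "alpha_level",
                       "components_for_union", "enabled"), "bootstrap")
  eblock <- .getOr(config, "enrichment", list())
  .checkKeys(eblock, c("gmt", "fdr_cutoff", "min_set_size",
                       "ground_truth_sets", "n_decoys", "seed"), "enrichment")
  tableNorm <- .getOr(config, "table_norm", "table")

  results <- list()
  for (strat in names(strategies)) {
    sdir <- file.path(outDir, strat)
    coll <- strategies[[strat]]
    res <- list(filterReport = filterReports[[strat]])

    res$statis <- stage(paste0(strat, "/statis"), runStatis(
      coll, nComponents = .getOr(sblock, "n_components", 3L),
      tableNorm = tableNorm,
      weightNorm = .getOr(sblock, "weight_norm", "sum1")))
    if (.getOr(sblock, "dual", TRUE))
      res$dual <- stage(paste0(strat, "/dual-statis"), runDualStatis(
        coll, nComponents = .getOr(sblock, "n_components", 3L),
        tableNorm = tableNorm,
        weightNorm = .getOr(sblock, "weight_norm", 'sum1')))

    if (.getOr(bblock, "enabled", TRUE)) {
      stopIfNot(!is.null(bblock$seed), "bootstrap block requires a seed")
      res$bootstrap <- stage(paste0(strat, "/bootstrap"), bootstrapTables(
        res$statis, B = .getOr(bblock, "B", 1000L), seed = bblock$seed,
        basis = .getOr(bblock, "basis", "factor_scores"),
        alphaLevel = .getOr(bblock, "alpha_level", 0.01)))
      res$significant <- significantGenes(
        res$bootstrap, alphaLevel = .getOr(bblock, "alpha_level", 0.01),
        components = .getOr(bblock, "components_for_union", 1:2))
    }

    sets <- NULL
    if (!is.null(eblock$gmt)) {
      sets <- readGeneSets(eblock$gmt,
                           minSize = .getOr(eblock, "min_set_size", 3L))
    } else if (isTRUE(eblock$ground_truth_sets) && !is.null(truth)) {
      stopIfNot(!is.null(eblock$seed),
                "enrichment with ground-truth sets requires a seed")
      sets <- groundTruthGeneSets(truth,
                                  nDecoys = .getOr(eblock, "n_decoys", 5L),
                                  seed = eblock$seed,
                                  allGenes = rownames(coll))
    }
    if (!is.null(sets) && !is.null(res$significant)) {
      res$enrichment <- stage(paste0(strat, "/enrichment"),
        hypergeometricEnrichment(
          res$significant$union, background = rownames(coll), sets = sets,
          fdrCutoff = .getOr(eblock, "fdr_cutoff", 0.01),
          minSetSize = .getOr(eblock, "min_set_size", 3L)))
    }

    if (.getOr(config, "cluster", TRUE))
      res$dendrogram <- stage(paste0(strat, "/cluster"),
                              clusterConditions(res$statis))

    stage(paste0(strat, "/write"), {
      writeResults(res$statis, sdir, bootstrap = res$bootstrap,
                   enrichment = res$enrichment, dendrogram = res$dendrogram,
                   filterReport = res$filterReport)
      if (!is.null(res$dual))
        writeResults(res$dual, file.path(sdir, "dual"))
    })
    results[[strat]] <- res
  }

  manifest <- list(
    package = "statisOmics",
    package_version = as.character(utils::packageVersion("statisOmics")),
    r_version = R.version.string,
    config = config,
    seeds = list(simulate = config$simulate$seed,
                 bootstrap = bblock$seed, enrichment = eblock$seed))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(results)
}
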
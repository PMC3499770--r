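#' Default condition design: a light-by-temperature grid
#'
#' Eight conditions spanning darkness to high light (0-300 uE) and cold to
#' heat (4-32 C), with "21-L" (150 uE, 21 C) as the control.
#'
#' @return data.frame with columns \code{condition}, \code{light} (uE),
#'   \code{temperature} (C).
#' @export
defaultConditionDesign <- function() {
  data.frame(
    condition = c("21-L", "21-LL", "21-HL", "21-D",
                  "4-D", "32-D", "4-L", "32-L"),
    light = c(150, 75, 300, 0, 0, 0, 85, 150),
    temperature = c(21, 21, 21, 21, 4, 32, 4, 32),
    stringsAsFactors = FALSE)
}

#' Default sampling grid: dense early coverage plus late samples
#'
#' 0, 5, 10 min, then every 20 min up to 360 min, plus 640 and 1280 min
#' (23 time points covering both a linear and a logarithmic scale).
#'
#' @return Numeric vector of 23 time points in minutes.
#' @export
defaultTimeGrid <- function() c(0, 5, 10, seq(20, 360, by = 20), 640, 1280)

.latentSignal <- function(fac, tp, light, temp, ctrl_light, ctrl_temp, par) {
  # all response programs ride on a condition-shared oscillation (diurnal
  # regulation is pervasive; even the control shows strong changes), with
  # the condition-driven modulation added on top
  osc <- sin(2 * pi * tp / par$period)
  step <- 1 - exp(-tp / par$tau0)
  switch(fac,
    # circadian: self-sustained at a baseline amplitude even in darkness
    # (temperature-compensated), amplitude growing with light
    diurnal = (par$diurnalBase + light / par$diurnalScale) * osc,
    light = par$sharedBase * osc +
      ((light - ctrl_light) / par$lightScale) * step,
    temperature = par$sharedBase * osc +
      ((temp - ctrl_temp) / par$tempScale) * step)
}

#' Generate a synthetic multi-condition time-course collection
#'
#' Simulates K log2-scale expression tables over a shared gene list and
#' time grid with known ground truth.  Each gene g in condition c follows
#' \deqn{x(g, \tau, c) = \mu_g + \beta L_g s(\tau, c) + \epsilon,\quad
#'   \epsilon \sim N(0, \sigma^2),}
#' where \eqn{\mu_g \sim N(8, 1)} is a per-gene baseline drawn once,
#' \eqn{L_g \in \{-1, +1\}} is a signed module loading (zero for
#' background genes), and the latent signal s depends on the gene's
#' module: a diurnal sinusoid \eqn{\sin(2\pi\tau/T)} scaled by the
#' condition's light level, a saturating light-step response
#' \eqn{\Delta_{light} (1 - e^{-\tau/\tau_0})}, or the analogous
#' temperature-step response.  If \code{outlierCondition} is set, that
#' condition's latent signals are replaced by an independent random draw,
#' giving it a deviant covariance structure while leaving its marginal
#' signal magnitude comparable.  Output is bitwise reproducible for a
#' given seed.
#'
#' @param nGenes total number of genes (must cover the module sizes).
#' @param timePoints time grid in minutes (at least 4 points).
#' @param design condition design data.frame
#'   (\code{\link{defaultConditionDesign}}).
#' @param moduleSizes named integer vector: genes per response module; the
#'   names select the latent factor of each module and must be drawn from
#'   \code{"diurnal"}, \code{"light"}, \code{"temperature"}.
#' @param beta effect size in log2 units per unit latent signal
#'   (default 2).
#' @param sigma noise standard deviation in log2 units (default 0.5).
#' @param seed RNG seed (mandatory).
#' @param outlierCondition optional condition label whose signals are
#'   replaced by an independent draw.
#' @param scale return scale: \code{"log2"} (default) or \code{"linear"}
#'   (values exponentiated).
#' @param controlId control condition label (default "21-L").
#' @param period diurnal period T in minutes (default 1440).
#' @param tau0 step-response time constant in minutes (default 60).
#' @param lightScale light normalization constant for the step response,
#'   in uE (default 75).
#' @param tempScale temperature normalization constant in C (default 6).
#' @param diurnalBase baseline (darkness) diurnal amplitude in latent
#'   units (default 2); the light-dependent gain adds
#'   \code{light/diurnalScale} to it.
#' @param diurnalScale light normalization constant for the diurnal
#'   amplitude, in uE (default 150).
#' @param sharedBase amplitude of the condition-shared oscillatory
#'   baseline carried by the light and temperature programs (default 2).
#' @return List with elements \code{collection}
#'   (a \code{\link{TableCollection}}) and \code{truth}
#'   (a \code{\link{SyntheticGroundTruth}}).
#' @export
generateCollection <- function(nGenes = 500L,
                               timePoints = defaultTimeGrid(),
                               design = defaultConditionDesign(),
                               moduleSizes = c(diurnal = 40L, light = 40L,
                                               temperature = 40L),
                               beta = 2, sigma = 0.5, seed,
                               outlierCondition = NULL,
                               scale = c("log2", "linear"),
                               controlId = "21-L",
                               period = 1440, tau0 = 60,
                               lightScale = 75, tempScale = 6,
                               diurnalBase = 2, diurnalScale = 150,
                               sharedBase = 2) {
  scale <- match.arg(scale)
  if (missing(seed)) stop("'seed' is required")
  nGenes <- as.integer(nGenes)
  stopIfNot(length(timePoints) >= 4L, "at least 4 time points are required")
  stopIfNot(all(names(moduleSizes) %in% c("diurnal", "light", "temperature")),
            "module names must be diurnal, light or temperature")
  stopIfNot(!anyDuplicated(names(moduleSizes)), "module names must be unique")
  stopIfNot(sum(moduleSizes) <= nGenes,
            "nGenes must cover the module genes (%d needed)", sum(moduleSizes))
  stopIfNot(controlId %in% design$condition,
            "control '%s' missing from design", controlId)
  if (!is.null(outlierCondition))
    stopIfNot(outlierCondition %in% design$condition,
              "outlier condition '%s' missing from design", outlierCondition)
  par <- list(period = period, tau0 = tau0, lightScale = lightScale,
              tempScale = tempScale, diurnalBase = diurnalBase,
              diurnalScale = diurnalScale, sharedBase = sharedBase)
  nt <- length(timePoints)
  width <- max(4L, nchar(as.character(nGenes)))
  genes <- sprintf(paste0("g%0", width, "d"), seq_len(nGenes))
  modules <- list(); offset <- 0L
  for (mn in names(moduleSizes)) {
    modules[[paste0("module_", mn)]] <-
      genes[seq_len(moduleSizes[[mn]]) + offset]
    offset <- offset + moduleSizes[[mn]]
  }
  factors <- setNames(sub("^module_", "", names(modules)), names(modules))
  module_genes <- unlist(modules, use.names = FALSE)
  gene_factor <- setNames(rep(NA_character_, nGenes), genes)
  for (mid in names(modules)) gene_factor[modules[[mid]]] <- factors[[mid]]

  ctrl_light <- design$light[design$condition == controlId]
  ctrl_temp <- design$temperature[design$condition == controlId]

  withSeed(seed, {
    mu <- rnorm(nGenes, mean = 8, sd = 1)
    loadings <- setNames(sample(c(-1, 1), length(module_genes),
                                replace = TRUE), module_genes)
    # per-condition, per-factor latent signals (t x 3)
    signal <- lapply(seq_len(nrow(design)), function(k) {
      sapply(c("diurnal", "light", "temperature"), function(fac)
        .latentSignal(fac, timePoints, design$light[k],
                      design$temperature[k], ctrl_light, ctrl_temp, par))
    })
    names(signal) <- design$condition
    # the outlier's whole signal matrix is an independent draw: fresh
    # random time profiles AND fresh random gene loadings, so its
    # covariance structure is deviant in gene space, not just in time
    outlier_loadings <- loadings
    if (!is.null(outlierCondition)) {
      signal[[outlierCondition]] <- matrix(
        rnorm(nt * 3L), nt, 3L,
        dimnames = list(NULL, c("diurnal", "light", "temperature")))
      outlier_loadings <- setNames(
        sample(c(-1, 1), length(module_genes), replace = TRUE), module_genes)
    }
    tabs <- lapply(design$condition, function(cond) {
      sg <- signal[[cond]]
      ld <- if (!is.null(outlierCondition) && cond == outlierCondition)
        outlier_loadings else loadings
      L <- setNames(rep(0, nGenes), genes)
      L[module_genes] <- ld
      m <- matrix(rep(mu, nt), nGenes, nt)
      for (fac in c("diurnal", "light", "temperature")) {
        in_fac <- which(!is.na(gene_factor) & gene_factor == fac)
        if (length(in_fac))
          m[in_fac, ] <- m[in_fac, ] +
            beta * outer(L[in_fac], sg[, fac])
      }
      m <- m + matrix(rnorm(nGenes * nt, 0, sigma), nGenes, nt)
      rownames(m) <- genes
      m
    })
    names(tabs) <- design$condition
  })
  if (scale == "linear") tabs <- lapply(tabs, function(m) 2^m)
  collection <- TableCollection(tabs, timePoints = timePoints,
                                controlId = controlId, scale = scale)
  truth <- new("SyntheticGroundTruth", design = design, modules = modules,
               factors = factors, loadings = loadings, beta = beta,
               sigma = sigma,
               outlierCondition = if (is.null(outlierCondition))
                 NA_character_ else outlierCondition,
               seed = as.integer(seed), params = par)
  list(collection = collection, truth = truth)
}

#' Gene sets from the generator's ground truth
#'
#' One gene set per true response module, plus \code{nDecoys} random sets
#' of matching sizes drawn from the background (non-module) genes, for
#' end-to-end validation of the over-representation step.
#'
#' @param truth a \code{\link{SyntheticGroundTruth}}.
#' @param nDecoys number of decoy sets (default 5).
#' @param seed RNG seed (mandatory).
#' @param backgroundGenes character vector of genes to draw decoys from;
#'   defaults to all generated genes outside any module.
#' @param allGenes full gene universe of the generated collection; only
#'   needed when \code{backgroundGenes} is not supplied.
#' @return A \code{\link{GeneSetCollection}}.
#' @export
groundTruthGeneSets <- function(truth, nDecoys = 5L, seed,
                                backgroundGenes = NULL, allGenes = NULL) {
  stopifnot(is(truth, "SyntheticGroundTruth"))
  if (missing(seed)) stop("'seed' is required")
  module_genes <- unlist(truth@modules, use.names = FALSE)
  if (is.null(backgroundGenes)) {
    if (is.null(allGenes))
      stop("supply 'backgroundGenes' or 'allGenes'")
    backgroundGenes <- setdiff(allGenes, module_genes)
  }
  sizes <- lengths(truth@modules)
  members <- truth@modules
  desc <- setNames(paste("true", truth@factors, "response module"),
                   names(truth@modules))
  withSeed(seed, {
    for (d in seq_len(nDecoys)) {
      sz <- sizes[[((d - 1L) %% length(sizes)) + 1L]]
      nm <- sprintf("decoy_%02d", d)
      members[[nm]] <- sample(backgroundGenes, min(sz, length(backgroundGenes)))
      desc[[nm]] <- "random background set"
    }
  })
  GeneSetCollection(members, desc)
}
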
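#' Bootstrap-over-tables significance ratios
#'
#' Assesses how stably each observation (gene, or time point in dual mode)
#' drives each compromise component by resampling the set of K tables
#' uniformly with replacement.  For every replicate the table weights are
#' recomputed on the resampled congruence matrix and the resampled
#' compromise is projected onto the FIXED component space of the original
#' decomposition (F* = S* M P Delta^-1); recomputing a full decomposition
#' per replicate would misalign components across replicates through
#' rotation and sign indeterminacy.  The bootstrap ratio mean/sd across
#' replicates is interpreted like a t statistic.
#'
#' With \code{basis = "factor_scores"} (default) ratios are computed on the
#' signed projected scores and tested two-sided; with
#' \code{basis = "contributions"} they are computed on the non-negative
#' projected contributions m_i f*^2 / lambda_b and tested one-sided.
#' Replicates whose resampled congruence matrix is all zero are redrawn
#' (with a message).  When the replicate standard deviation collapses below
#' 1e-12 the ratio is reported as signed infinity and the observation is
#' significant iff |mean| > 1e-12.
#'
#' @param result a \code{\link{StatisResult}} from the full data.
#' @param B number of bootstrap replicates (>= 50; default 1000).
#' @param seed RNG seed (mandatory, for reproducibility).
#' @param basis \code{"factor_scores"} or \code{"contributions"}.
#' @param alphaLevel significance level (default 0.01).
#' @return A \code{\link{BootstrapResult}}.
#' @export
bootstrapTables <- function(result, B = 1000L, seed,
                            basis = c("factor_scores", "contributions"),
                            alphaLevel = 0.01) {
  basis <- match.arg(basis)
  stopifnot(is(result, "StatisResult"))
  B <- as.integer(B)
  stopIfNot(B >= 50L, "B must be at least 50")
  if (missing(seed)) stop("'seed' is required")
  stopIfNot(alphaLevel > 0 && alphaLevel < 1, "alphaLevel must be in (0,1)")

  Fp <- result@scores@Fpartial
  K <- length(Fp)
  C <- result@interstructure@C
  r <- result@decomposition@nComponents
  lam <- result@decomposition@eigenvalues[seq_len(r)]
  masses <- result@decomposition@masses
  n <- nrow(Fp[[1L]])
  # accumulate deviations from the full-data statistic: numerically stable
  # when replicates are (near-)identical
  F0 <- result@scores@F
  stat0 <- if (basis == "factor_scores") F0
           else sweep(masses * F0^2, 2L, lam, "/")
  acc <- matrix(0, n, r); acc2 <- matrix(0, n, r)
  n_redrawn <- 0L

  withSeed(seed, {
    for (b in seq_len(B)) {
      repeat {
        idx <- sample.int(K, K, replace = TRUE)
        Cs <- C[idx, idx, drop = FALSE]
        if (any(Cs != 0)) break
        n_redrawn <- n_redrawn + 1L
      }
      u <- eigen(Cs, symmetric = TRUE)$vectors[, 1L]
      if (sum(u) < 0) u <- -u
      u[u < 0] <- 0
      alpha <- u / sum(u)
      Fstar <- matrix(0, n, r)
      for (k in seq_len(K)) Fstar <- Fstar + alpha[k] * Fp[[idx[k]]]
      stat <- if (basis == "factor_scores") Fstar
              else sweep(masses * Fstar^2, 2L, lam, "/")
      dev <- stat - stat0
      acc <- acc + dev
      acc2 <- acc2 + dev^2
    }
  })
  if (n_redrawn > 0L)
    message(sprintf("bootstrapTables: redrew %d all-zero replicate(s)", n_redrawn))

  dev_mean <- acc / B
  mean_s <- stat0 + dev_mean
  var_s <- pmax((acc2 - B * dev_mean^2) / (B - 1L), 0)
  sd_s <- sqrt(var_s)
  deg <- sd_s < 1e-12
  ratios <- mean_s / sd_s
  ratios[deg] <- ifelse(abs(mean_s[deg]) > 1e-12, sign(mean_s[deg]) * Inf, 0)
  sig <- if (basis == "factor_scores")
    abs(ratios) >= qnorm(1 - alphaLevel / 2)
  else
    ratios >= qnorm(1 - alphaLevel)
  dn <- list(result@observationIds, paste0("comp_", seq_len(r)))
  dimnames(ratios) <- dimnames(mean_s) <- dimnames(sd_s) <- dimnames(sig) <- dn
  new("BootstrapResult", nBoot = B, ratios = ratios, meanScores = mean_s,
      sdScores = sd_s, significant = sig, alphaLevel = alphaLevel,
      basis = basis, seed = as.integer(seed))
}

#' Select significantly contributing observations
#'
#' Thresholds the bootstrap ratios at the requested significance level
#' (two-sided on the factor-score basis, one-sided on the contribution
#' basis) and returns per-component gene lists plus their union over a
#' configurable component set (default components 1-2, mirroring selection
#' on either of the two leading components).
#'
#' @param result a \code{\link{BootstrapResult}}.
#' @param alphaLevel significance level (default 0.01).
#' @param components components pooled into the union (default 1:2).
#' @return List with \code{perComponent} (named list of id vectors) and
#'   \code{union} (ids significant on at least one pooled component).
#' @export
significantGenes <- function(result, alphaLevel = 0.01, components = 1:2) {
  stopifnot(is(result, "BootstrapResult"))
  r <- ncol(result@ratios)
  components <- intersect(as.integer(components), seq_len(r))
  thr <- if (result@basis == "factor_scores") qnorm(1 - alphaLevel / 2)
         else qnorm(1 - alphaLevel)
  flags <- if (result@basis == "factor_scores") abs(result@ratios) >= thr
           else result@ratios >= thr
  ids <- rownames(result@ratios)
  perComponent <- lapply(seq_len(r), function(b) ids[flags[, b]])
  names(perComponent) <- colnames(result@ratios)
  union_ids <- ids[rowSums(flags[, components, drop = FALSE]) > 0]
  list(perComponent = perComponent, union = union_ids)
}
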
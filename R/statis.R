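#' Per-table cross-product matrices
#'
#' For each condition table X_i computes the cross-product S_i = X_i X_i'
#' (gene-by-gene, \code{mode = "rows"}) or S_i = X_i' X_i (time-by-time,
#' \code{mode = "columns"}, the dual variant).  Each S_i captures the
#' within-table similarity structure of the observations as seen by that
#' table.  Exact symmetry is enforced by (S + S')/2.
#'
#' @param collection a preprocessed (centered) \code{\link{TableCollection}};
#'   uncentered input is accepted but a warning is issued.
#' @param mode \code{"rows"} (STATIS) or \code{"columns"} (dual-STATIS).
#' @return A \code{\link{CrossProductSet}}.
#' @export
crossProducts <- function(collection, mode = c("rows", "columns")) {
  mode <- match.arg(mode)
  stopifnot(is(collection, "TableCollection"))
  if (exprScale(collection) != "centered")
    warning("cross-products computed on non-centered tables")
  tabs <- tableList(collection)
  mats <- lapply(tabs, function(x) {
    S <- if (mode == "rows") tcrossprod(x) else crossprod(x)
    (S + t(S)) / 2
  })
  ids <- if (mode == "rows") rownames(collection)
         else as.character(timePoints(collection))
  mats <- lapply(mats, function(S) { dimnames(S) <- list(ids, ids); S })
  new("CrossProductSet", mode = mode, matrices = mats,
      frobeniusNorms = vapply(mats, function(S) sqrt(sum(S^2)), 0),
      conditionIds = names(tabs), ids = ids)
}

#' RV coefficient of two cross-product matrices
#'
#' The RV coefficient is the cosine similarity of two positive
#' semidefinite matrices under the Frobenius inner product,
#' \eqn{R_V = \langle S_1, S_2\rangle_F / (\|S_1\|_F \|S_2\|_F)}; it lies
#' in [0, 1], with 1 for identical similarity structure and 0 for
#' orthogonal structure.
#'
#' @param S1,S2 square symmetric positive semidefinite matrices of equal
#'   dimension with positive Frobenius norms.
#' @return A number in [0, 1].
#' @export
rvCoefficient <- function(S1, S2) {
  stopIfNot(all(dim(S1) == dim(S2)), "matrices must have equal dimensions")
  n1 <- sqrt(sum(S1^2)); n2 <- sqrt(sum(S2^2))
  stopIfNot(n1 > 0 && n2 > 0, "RV coefficient undefined for a zero matrix")
  min(max(sum(S1 * S2) / (n1 * n2), 0), 1)
}

#' Interstructure: between-table congruence and optimal table weights
#'
#' Builds the K-by-K congruence matrix C whose entry (i, j) is the
#' Frobenius inner product of the cross-products S_i and S_j, takes its
#' leading eigenvector u1 (sign-flipped entrywise non-negative, which is
#' always possible since C is entrywise non-negative), and derives the
#' table weights in the two normalizations: \code{alphaSum1 = u1/sum(u1)}
#' (used to form the compromise as a weighted average) and
#' \code{alphaL2 = u1/||u1||} (unit Euclidean norm).  Also computes the
#' pairwise RV coefficient matrix.
#'
#' @param cps a \code{\link{CrossProductSet}}.
#' @return An \code{\link{InterstructureResult}};
#'   \code{rvToCompromise} is NA until filled by \code{\link{runStatis}}.
#' @export
interstructure <- function(cps) {
  stopifnot(is(cps, "CrossProductSet"))
  K <- length(cps@matrices)
  if (all(cps@frobeniusNorms == 0)) stop("all tables are zero")
  C <- matrix(0, K, K, dimnames = list(cps@conditionIds, cps@conditionIds))
  for (i in seq_len(K)) for (j in i:K) {
    C[i, j] <- C[j, i] <- sum(cps@matrices[[i]] * cps@matrices[[j]])
  }
  e <- eigen(C, symmetric = TRUE)
  u1 <- e$vectors[, 1L]
  if (sum(u1) < 0) u1 <- -u1
  u1[u1 < 0 & u1 > -1e-10] <- 0
  if (any(u1 < 0))
    stop("leading eigenvector of C is not entrywise non-negative")
  rv <- C / outer(cps@frobeniusNorms, cps@frobeniusNorms)
  diag(rv) <- 1
  rv[] <- pmin(pmax(rv, 0), 1)
  new(Class = "InterstructureResult", C = C, leadingEigenvector = u1,
      alphaSum1 = u1 / sum(u1), alphaL2 = u1 / sqrt(sum(u1^2)),
      rvMatrix = rv, rvToCompromise = rep(NA_real_, K),
      conditionIds = cps@conditionIds)
}

#' Compromise matrix: optimally weighted average of cross-products
#'
#' @param cps a \code{\link{CrossProductSet}}.
#' @param weights non-negative weights of length K (normally
#'   \code{alphaSum1} from \code{\link{interstructure}}).
#' @return The square compromise matrix S = sum(weights_i * S_i).
#' @export
compromiseMatrix <- function(cps, weights) {
  stopifnot(is(cps, "CrossProductSet"))
  stopIfNot(length(weights) == length(cps@matrices),
            "expected %d weights, got %d", length(cps@matrices),
            length(weights))
  stopIfNot(all(weights >= 0), "weights must be non-negative")
  Reduce(`+`, Map(`*`, as.list(weights), cps@matrices))
}

#' Mass-metric eigendecomposition of the compromise
#'
#' Solves S = P Lambda P' under the constraint P' M P = I with
#' M = diag(masses), via the standard symmetric eigendecomposition of
#' M^(1/2) S M^(1/2) = V Lambda V', setting P = M^(-1/2) V.  Eigenvalues
#' within -1e-10 of zero are clipped to zero; an eigenvalue below
#' -1e-6 times the largest raises an error.  Each retained eigenvector is
#' sign-fixed so that its largest-magnitude coordinate is positive (ties
#' broken by lowest index), giving reproducible output orientations.
#'
#' @param S square symmetric matrix (the compromise).
#' @param masses non-negative row masses summing to one.
#' @param nComponents number of components to retain (default 3).
#' @return A \code{\link{CompromiseDecomposition}}.
#' @export
decomposeCompromise <- function(S, masses, nComponents = 3L) {
  n <- nrow(S)
  stopIfNot(ncol(S) == n, "S must be square")
  stopIfNot(max(abs(S - t(S))) <= 1e-8 * max(abs(S), 1e-300),
            "S must be symmetric")
  stopIfNot(length(masses) == n, "masses must have length nrow(S)")
  stopIfNot(all(masses >= 0) && abs(sum(masses) - 1) <= 1e-12,
            "masses must be non-negative and sum to one")
  nComponents <- as.integer(nComponents)
  stopIfNot(nComponents >= 1L && nComponents <= n,
            "nComponents must be in [1, %d]", n)
  sm <- sqrt(masses)
  W <- S * outer(sm, sm)
  e <- eigen(W, symmetric = TRUE)
  lam <- e$values
  if (any(lam < -1e-6 * max(lam[1L], 1e-300)))
    stop("compromise not PSD")
  lam[lam < 0] <- 0
  V <- e$vectors[, seq_len(nComponents), drop = FALSE]
  P <- V / sm
  for (b in seq_len(nComponents)) {
    jmax <- which.max(abs(P[, b]))    # ties resolved to lowest index
    if (P[jmax, b] < 0) P[, b] <- -P[, b]
  }
  ids <- rownames(S)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  rownames(P) <- ids
  new("CompromiseDecomposition", S = S, eigenvalues = lam, P = P,
      Delta = sqrt(lam[seq_len(nComponents)]), masses = masses,
      nComponents = nComponents, ids = ids)
}

#' @describeIn decomposeCompromise global factor scores
#'   F = S M P Delta^-1 of a decomposition; algebraically F = P Delta, and
#'   the two routes are checked against each other internally.
#' @param x a \code{CompromiseDecomposition}.
#' @param ... unused.
#' @export
setMethod("factorScores", "CompromiseDecomposition", function(x, ...) {
  if (any(x@Delta <= 0)) stop("rank deficient: reduce n_components")
  FF <- x@S %*% (x@masses * x@P) %*% diag(1 / x@Delta, x@nComponents)
  PD <- sweep(x@P, 2L, x@Delta, "*")
  if (max(abs(FF - PD)) > 1e-8 * max(1, max(abs(PD))))
    warning("factor-score identity F = P Delta violated beyond tolerance")
  dimnames(FF) <- list(x@ids, paste0("comp_", seq_len(x@nComponents)))
  FF
})

#' Per-table (partial) factor scores
#'
#' Projects each table's own cross-product onto the fixed compromise
#' space: F_i = S_i M P Delta^-1.  The weighted average of the partial
#' scores under the sum-to-one table weights equals the global scores.
#'
#' @param cps a \code{\link{CrossProductSet}}.
#' @param decomposition a \code{\link{CompromiseDecomposition}}.
#' @return List of K observation-by-component matrices.
#' @export
partialFactorScores <- function(cps, decomposition) {
  stopifnot(is(cps, "CrossProductSet"),
            is(decomposition, "CompromiseDecomposition"))
  if (any(decomposition@Delta <= 0))
    stop("rank deficient: reduce n_components")
  proj <- (decomposition@masses * decomposition@P) %*%
    diag(1 / decomposition@Delta, decomposition@nComponents)
  out <- lapply(cps@matrices, function(S) {
    FF <- S %*% proj
    dimnames(FF) <- list(cps@ids,
                         paste0("comp_", seq_len(decomposition@nComponents)))
    FF
  })
  names(out) <- cps@conditionIds
  out
}

#' Loadings of the original columns on the compromise components
#'
#' Computes Q = X' M P Delta^-1 for the stacked matrix
#' X = [X_1 | ... | X_K] (per-table slices correspond to the per-table
#' formula Q_i = X_i' M P Delta^-1), together with the column-weight
#' vector a that repeats each table's weight over its t columns.  Under
#' the weights used to build the compromise, Q' A Q = I with A = diag(a).
#'
#' @param tables named list of K observation-by-variable matrices, already
#'   oriented so that rows are the observations of the analysis.
#' @param decomposition a \code{\link{CompromiseDecomposition}}.
#' @param weights the table weights used to build the compromise.
#' @return List with elements \code{Q} ((K*t)-by-r matrix), \code{a}
#'   (length K*t), and \code{variableIds}.
#' @export
statisLoadings <- function(tables, decomposition, weights) {
  stopifnot(is(decomposition, "CompromiseDecomposition"))
  stopIfNot(length(weights) == length(tables),
            "expected %d weights, got %d", length(tables), length(weights))
  if (any(decomposition@Delta <= 0))
    stop("rank deficient: reduce n_components")
  proj <- (decomposition@masses * decomposition@P) %*%
    diag(1 / decomposition@Delta, decomposition@nComponents)
  Q <- do.call(rbind, lapply(tables, function(X) crossprod(X, proj)))
  a <- rep(weights, times = vapply(tables, ncol, 0L))
  variableIds <- unlist(lapply(names(tables), function(nm) {
    cn <- colnames(tables[[nm]])
    if (is.null(cn)) cn <- seq_len(ncol(tables[[nm]]))
    paste0(nm, ":", cn)
  }), use.names = FALSE)
  rownames(Q) <- variableIds
  colnames(Q) <- paste0("comp_", seq_len(decomposition@nComponents))
  list(Q = Q, a = a, variableIds = variableIds)
}

#' Contributions of rows, columns and tables to the components
#'
#' Row contributions are m_i f_ib^2 / lambda_b; column contributions are
#' a_j q_jb^2; a table's contribution is the sum over its columns.  Within
#' each component every one of the three families sums to one.
#'
#' @param decomposition a \code{\link{CompromiseDecomposition}}.
#' @param F global factor scores.
#' @param Q stacked loadings.
#' @param a column weights.
#' @param tableIndex factor/character of length nrow(Q) mapping each
#'   column to its table, in table order.
#' @return A \code{\link{ContributionSet}}.
#' @export
statisContributions <- function(decomposition, F, Q, a, tableIndex) {
  r <- decomposition@nComponents
  lam <- decomposition@eigenvalues[seq_len(r)]
  if (any(lam <= 0)) stop("rank deficient: reduce n_components")
  rows <- sweep(decomposition@masses * F^2, 2L, lam, "/")
  cols <- a * Q^2
  tabs <- rowsum(cols, group = factor(tableIndex, levels = unique(tableIndex)))
  tabs <- as.matrix(tabs)
  dimnames(rows) <- dimnames(F)
  colnames(tabs) <- colnames(F)
  new("ContributionSet", rows = rows, columns = cols, tables = tabs)
}

.runStatisInternal <- function(collection, mode, masses = NULL,
                               nComponents = 3L, tableNorm = "table",
                               weightNorm = c("sum1", "l2")) {
  weightNorm <- match.arg(weightNorm)
  stopifnot(is(collection, "TableCollection"))
  prep <- if (exprScale(collection) == "centered") collection
          else preprocessTables(collection, method = tableNorm)
  cps <- crossProducts(prep, mode = mode)
  inter <- interstructure(cps)
  w <- if (weightNorm == "sum1") inter@alphaSum1 else inter@alphaL2
  S <- compromiseMatrix(cps, w)
  nobs <- nrow(cps@matrices[[1L]])
  if (is.null(masses)) masses <- uniformMasses(nobs)
  stopIfNot(length(masses) == nobs, "masses must have length %d", nobs)
  dec <- decomposeCompromise(S, masses, nComponents = nComponents)
  FF <- factorScores(dec)
  Fp <- partialFactorScores(cps, dec)
  oriented <- lapply(tableList(prep),
                     function(x) if (mode == "rows") x else t(x))
  ld <- statisLoadings(oriented, dec, w)
  tix <- rep(names(oriented), times = vapply(oriented, ncol, 0L))
  ctr <- statisContributions(dec, FF, ld$Q, ld$a, tix)
  inter@rvToCompromise <- vapply(cps@matrices, rvCoefficient, 0, S2 = S)
  sc <- new("ScoresAndLoadings", F = FF, Fpartial = Fp, Q = ld$Q, a = ld$a,
            variableIds = ld$variableIds)
  new("StatisResult", mode = mode, interstructure = inter,
      decomposition = dec, scores = sc, contributions = ctr,
      conditionIds = cps@conditionIds, observationIds = cps@ids)
}

#' Run a full STATIS analysis
#'
#' Orchestrates the complete analysis on a collection of condition tables:
#' per-table cross-products (gene-by-gene), interstructure and table
#' weights, the weighted compromise, its mass-metric eigendecomposition,
#' global and per-table factor scores, loadings, contributions, and the RV
#' coefficient of each table with the compromise.  Input on linear/log2
#' scale is centered and table-normalized first; pass an already-centered
#' collection to control preprocessing yourself.
#'
#' @param collection a \code{\link{TableCollection}}.
#' @param masses optional row masses (default uniform 1/n).
#' @param nComponents retained components (default 3).
#' @param tableNorm preprocessing variant, see
#'   \code{\link{centerScaleMatrix}}.
#' @param weightNorm which weight normalization builds the compromise:
#'   \code{"sum1"} (default; the compromise is a weighted average) or
#'   \code{"l2"}.
#' @return A \code{\link{StatisResult}} with \code{mode = "rows"}.
#' @examples
#' sim <- generateCollection(nGenes = 60, seed = 1)
#' res <- runStatis(sim$collection)
#' tableWeights(res)
#' @export
runStatis <- function(collection, masses = NULL, nComponents = 3L,
                      tableNorm = "table", weightNorm = "sum1") {
  .runStatisInternal(collection, mode = "rows", masses = masses,
                     nComponents = nComponents, tableNorm = tableNorm,
                     weightNorm = weightNorm)
}

#' Run a dual-STATIS analysis
#'
#' Identical pipeline on the transposed tables: cross-products are
#' time-by-time (S_i = X_i' X_i), observations are the time points (with
#' uniform masses 1/t), and the compromise describes the temporal
#' covariance structure shared across conditions.
#'
#' @inheritParams runStatis
#' @return A \code{\link{StatisResult}} with \code{mode = "columns"}.
#' @export
runDualStatis <- function(collection, masses = NULL, nComponents = 3L,
                          tableNorm = "table", weightNorm = "sum1") {
  .runStatisInternal(collection, mode = "columns", masses = masses,
                     nComponents = nComponents, tableNorm = tableNorm,
                     weightNorm = weightNorm)
}
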
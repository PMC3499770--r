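# Independent brute-force oracles and small fixture builders.
# These deliberately avoid the package's own linear-algebra paths.

# random small collection with named genes/conditions
randomCollection <- function(K = 3, n = 6, t = 4, seed = 1,
                             scale = "log2") {
  set.seed(seed)
  genes <- sprintf("g%02d", seq_len(n))
  tabs <- lapply(seq_len(K), function(k) {
    m <- matrix(rnorm(n * t, mean = 8), n, t)
    rownames(m) <- genes
    m
  })
  names(tabs) <- paste0("cond", seq_len(K))
  TableCollection(tabs, timePoints = seq(0, by = 10, length.out = t),
                  controlId = "cond1", scale = scale)
}

# entry-by-entry triple-loop cross-product
crossProductLoop <- function(X, mode = "rows") {
  if (mode == "columns") X <- t(X)
  n <- nrow(X); t <- ncol(X)
  S <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    acc <- 0
    for (l in seq_len(t)) acc <- acc + X[i, l] * X[j, l]
    S[i, j] <- acc
  }
  S
}

# double-loop Frobenius inner product / RV
rvLoop <- function(S1, S2) {
  num <- 0; n1 <- 0; n2 <- 0
  for (i in seq_len(nrow(S1))) for (j in seq_len(ncol(S1))) {
    num <- num + S1[i, j] * S2[i, j]
    n1 <- n1 + S1[i, j]^2
    n2 <- n2 + S2[i, j]^2
  }
  num / sqrt(n1 * n2)
}

# SVD route for the compromise: eigenvalues and factor scores from the
# generalized SVD of the weighted stacked matrix M^(1/2) [sqrt(a_i) X_i]
svdRouteOracle <- function(tabs, weights, masses) {
  Xw <- do.call(cbind, Map(function(X, a) sqrt(a) * X, tabs,
                           as.list(weights)))
  Y <- sqrt(masses) * Xw
  sv <- svd(Y)
  lambda <- sv$d^2
  Fm <- (1 / sqrt(masses)) * sv$u %*% diag(sv$d, length(sv$d))
  list(eigenvalues = lambda, F = Fm)
}

# exhaustive UPGMA: cluster-average distances recomputed from the original
# matrix at every merge
upgmaOracle <- function(D) {
  K <- nrow(D)
  clusters <- as.list(seq_len(K))
  heights <- numeric(0)
  coph <- matrix(0, K, K)
  while (length(clusters) > 1L) {
    best <- c(NA, NA); bestd <- Inf
    for (a in seq_along(clusters)) for (b in seq_along(clusters)) {
      if (a >= b) next
      dd <- mean(D[clusters[[a]], clusters[[b]]])
      if (dd < bestd - 1e-12) { bestd <- dd; best <- c(a, b) }
    }
    ia <- clusters[[best[1]]]; ib <- clusters[[best[2]]]
    coph[ia, ib] <- bestd; coph[ib, ia] <- bestd
    heights <- c(heights, bestd)
    clusters[[best[1]]] <- c(ia, ib)
    clusters[[best[2]]] <- NULL
  }
  list(heights = heights, cophenetic = coph)
}

# exact hypergeometric upper-tail by enumeration of the combinatorial sum
hyperTailOracle <- function(k, m, N, n) {
  upper <- min(m, n)
  if (k > upper) return(0)
  sum(vapply(k:upper, function(j)
    choose(m, j) * choose(N - m, n - j), 0)) / choose(N, n)
}

# direct single-gene evaluation of the informative-gene filter
filterOracleGene <- function(cond_values, x0_index = 1, fc = 2,
                             min_tp = 2, cv = 1) {
  fc_ok <- any(vapply(cond_values, function(x) {
    x0 <- x[x0_index]
    sum(pmax(x[-x0_index] / x0, x0 / x[-x0_index]) >= fc) >= min_tp
  }, TRUE))
  cv_ok <- any(vapply(cond_values, function(x) sd(x) / mean(x) >= cv, TRUE))
  fc_ok && cv_ok
}

# write a TableCollection's tables as TSV files, returns named paths
writeCollectionTsv <- function(collection, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tabs <- tableList(collection)
  tp <- timePoints(collection)
  paths <- vapply(names(tabs), function(nm) {
    p <- file.path(dir, paste0(nm, ".tsv"))
    df <- data.frame(gene_id = rownames(tabs[[nm]]), tabs[[nm]],
                     check.names = FALSE)
    colnames(df) <- c("gene_id", as.character(tp))
    write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }, character(1))
  paths
}
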
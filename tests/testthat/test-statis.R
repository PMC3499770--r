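prepCollection <- function(K = 3, n = 6, t = 4, seed = 1) {
  preprocessTables(randomCollection(K, n, t, seed))
}

test_that("cross-products match the triple-loop oracle and PSD identities", {
  prep <- prepCollection(K = 2, n = 3, t = 2, seed = 2)
  cps <- crossProducts(prep, mode = "rows")
  for (k in 1:2) {
    X <- tableMatrix(prep, conditionNames(prep)[k])
    expect_equal(unname(cps@matrices[[k]]), crossProductLoop(X),
                 tolerance = 1e-12)
  }
  # dual mode equals loop on the transpose
  cpt <- crossProducts(prep, mode = "columns")
  X <- tableMatrix(prep, "cond1")
  expect_equal(unname(cpt@matrices[[1]]), crossProductLoop(X, "columns"),
               tolerance = 1e-12)

  # nonzero eigenvalues of XX' and X'X agree
  er <- eigen(cps@matrices[[1]], symmetric = TRUE, only.values = TRUE)$values
  ec <- eigen(cpt@matrices[[1]], symmetric = TRUE, only.values = TRUE)$values
  m <- min(length(er), length(ec))
  expect_equal(er[1:m], ec[1:m], tolerance = 1e-8)

  # identity matrix in, identity cross-product out
  I2 <- diag(2); rownames(I2) <- c("a", "b")
  idc <- TableCollection(list(one = I2), timePoints = c(0, 10),
                         controlId = "one", scale = "centered")
  expect_equal(unname(crossProducts(idc)@matrices[[1]]), diag(2))
})

test_that("RV coefficient is a cosine: self-similarity 1, orthogonality 0", {
  set.seed(5)
  A <- crossprod(matrix(rnorm(16), 4, 4))
  B <- crossprod(matrix(rnorm(16), 4, 4))
  expect_equal(rvCoefficient(A, A), 1, tolerance = 1e-12)
  expect_equal(rvCoefficient(diag(c(1, 0)), diag(c(0, 1))), 0)
  expect_equal(rvCoefficient(A, B), rvLoop(A, B), tolerance = 1e-12)
  expect_error(rvCoefficient(A, matrix(0, 4, 4)), "zero matrix")

  # invariance to orthogonal rotation of a table's columns
  X <- matrix(rnorm(24), 6, 4)
  Q <- qr.Q(qr(matrix(rnorm(16), 4, 4)))
  S1 <- tcrossprod(X); S2 <- tcrossprod(X %*% Q)
  expect_equal(rvCoefficient(S1, S2), 1, tolerance = 1e-10)
})

test_that("interstructure weights: symmetry, normalizations, K=1", {
  # identical tables share the weight equally in both normalizations
  X <- centerScaleMatrix(matrix(rnorm(24, 8), 6, 4))
  rownames(X) <- sprintf("g%d", 1:6)
  K <- 4
  tabs <- setNames(rep(list(X), K), paste0("c", 1:K))
  coll <- TableCollection(tabs, timePoints = c(0, 5, 10, 20),
                          controlId = "c1", scale = "centered")
  inter <- interstructure(crossProducts(coll))
  expect_equal(unname(inter@alphaSum1), rep(1 / K, K), tolerance = 1e-10)
  expect_equal(unname(inter@alphaL2), rep(1 / sqrt(K), K), tolerance = 1e-10)
  expect_equal(unname(inter@rvMatrix), matrix(1, K, K), tolerance = 1e-10)

  one <- TableCollection(list(only = X), timePoints = c(0, 5, 10, 20),
                         controlId = "only", scale = "centered")
  i1 <- interstructure(crossProducts(one))
  expect_equal(unname(i1@alphaSum1), 1)

  # eight near-identical tables: unit-norm weights near 1/sqrt(8) ~ 0.354
  set.seed(6)
  tabs8 <- lapply(1:8, function(k)
    centerScaleMatrix(X + matrix(rnorm(24, 0, 0.01), 6, 4)))
  names(tabs8) <- paste0("c", 1:8)
  coll8 <- TableCollection(tabs8, timePoints = c(0, 5, 10, 20),
                           controlId = "c1", scale = "centered")
  i8 <- interstructure(crossProducts(coll8))
  expect_true(all(abs(i8@alphaL2 - 1 / sqrt(8)) < 0.02))
})

test_that("compromise is the weighted average of cross-products", {
  prep <- prepCollection(K = 3, n = 5, t = 4, seed = 9)
  cps <- crossProducts(prep)
  w <- c(0.5, 0.3, 0.2)
  S <- compromiseMatrix(cps, w)
  expect_equal(S, 0.5 * cps@matrices[[1]] + 0.3 * cps@matrices[[2]] +
                 0.2 * cps@matrices[[3]], tolerance = 1e-12)
  expect_equal(compromiseMatrix(cps, c(1, 0, 0)), cps@matrices[[1]])
  expect_error(compromiseMatrix(cps, c(1, 0)), "3 weights")
})

test_that("mass-metric eigendecomposition: hand-forced case and constraints", {
  S <- diag(c(4, 1))
  dec <- decomposeCompromise(S, masses = c(0.5, 0.5), nComponents = 2L)
  expect_equal(dec@eigenvalues, c(2, 0.5))
  expect_equal(unname(dec@P), sqrt(2) * diag(2), tolerance = 1e-12)
  FF <- factorScores(dec)
  expect_equal(unname(FF), diag(c(2, 1)), tolerance = 1e-12)

  # P'MP = I and reconstruction at full rank on a random instance
  set.seed(10)
  X <- matrix(rnorm(36), 6, 6)
  S <- crossprod(X)
  m <- runif(6); m <- m / sum(m)
  dec <- decomposeCompromise(S, m, nComponents = 6L)
  G <- crossprod(dec@P, m * dec@P)
  expect_equal(G, diag(6), tolerance = 1e-8)
  # full-rank reconstruction S = P Lambda P'
  expect_equal(dec@P %*% diag(dec@eigenvalues) %*% t(dec@P), S,
               tolerance = 1e-8, ignore_attr = TRUE)
  expect_error(decomposeCompromise(S, m, nComponents = 7L))
  expect_error(decomposeCompromise(-S, m, 2L), "not PSD")
})

test_that("eigen route matches the SVD route on random instances", {
  for (seed in 1:25) {
    set.seed(seed)
    K <- sample(1:4, 1); n <- sample(4:12, 1); t <- sample(2:6, 1)
    prep <- prepCollection(K, n, t, seed)
    tabs <- tableList(prep)
    cps <- crossProducts(prep)
    inter <- interstructure(cps)
    S <- compromiseMatrix(cps, inter@alphaSum1)
    masses <- uniformMasses(n)
    r <- max(1L, min(n - 1L, K * t, 3L))
    dec <- decomposeCompromise(S, masses, nComponents = r)
    oracle <- svdRouteOracle(tabs, inter@alphaSum1, masses)
    expect_equal(dec@eigenvalues[1:r], oracle$eigenvalues[1:r],
                 tolerance = 1e-8, label = sprintf("seed %d", seed))
    FF <- factorScores(dec)
    for (b in seq_len(r)) {
      expect_lt(min(max(abs(FF[, b] - oracle$F[, b])),
                    max(abs(FF[, b] + oracle$F[, b]))), 1e-8)
    }
  }
})

test_that("scores, loadings and contributions satisfy the conservation laws", {
  sim <- generateCollection(nGenes = 80, seed = 12,
                            moduleSizes = c(diurnal = 20L, light = 20L))
  res <- runStatis(sim$collection, nComponents = 3L)
  dec <- res@decomposition
  r <- dec@nComponents
  lam <- dec@eigenvalues[seq_len(r)]

  # F = P Delta
  expect_equal(res@scores@F, sweep(dec@P, 2, dec@Delta, "*"),
               tolerance = 1e-8, ignore_attr = TRUE)
  # lambda_b = sum_i m_i f_ib^2
  expect_equal(colSums(dec@masses * res@scores@F^2), lam,
               tolerance = 1e-8, ignore_attr = TRUE)
  # P'MP = I
  expect_equal(crossprod(dec@P, dec@masses * dec@P), diag(r),
               tolerance = 1e-8, ignore_attr = TRUE)
  # Q'AQ = I
  expect_equal(crossprod(res@scores@Q, res@scores@a * res@scores@Q),
               diag(r), tolerance = 1e-8, ignore_attr = TRUE)
  # contribution conservation and bounds
  for (wh in c("rows", "columns", "tables")) {
    ctr <- contributions(res, wh)
    expect_equal(unname(colSums(ctr)), rep(1, r), tolerance = 1e-8)
    expect_true(all(ctr >= -1e-10 & ctr <= 1 + 1e-10))
  }
  # alpha-weighted average of partial scores equals global scores
  w <- res@interstructure@alphaSum1
  Favg <- Reduce(`+`, Map(`*`, as.list(w), res@scores@Fpartial))
  expect_equal(Favg, res@scores@F, tolerance = 1e-8)
  # rows with zero factor score contribute zero
  expect_equal(unname(contributions(res, "rows")[res@scores@F == 0]),
               rep(0, sum(res@scores@F == 0)))
})

test_that("K=1 STATIS reduces to PCA of the single table", {
  set.seed(13)
  n <- 8; t <- 5
  X <- centerScaleMatrix(matrix(rnorm(n * t, 8), n, t))
  rownames(X) <- sprintf("g%d", 1:n)
  coll <- TableCollection(list(only = X), timePoints = seq(0, 40, 10),
                          controlId = "only", scale = "centered")
  r <- 3L
  res <- runStatis(coll, nComponents = r)
  # PCA via SVD of M^(1/2) X
  sv <- svd(sqrt(1 / n) * X)
  expect_equal(res@decomposition@eigenvalues[1:r], sv$d[1:r]^2,
               tolerance = 1e-8, ignore_attr = TRUE)
  pca_scores <- sqrt(n) * sv$u %*% diag(sv$d, length(sv$d))
  FF <- factorScores(res)
  for (b in 1:r) {
    expect_lt(min(max(abs(FF[, b] - pca_scores[, b])),
                  max(abs(FF[, b] + pca_scores[, b]))), 1e-8)
  }
  expect_equal(unname(tableWeights(res)), 1)
})

test_that("table order permutation permutes weights and leaves the compromise invariant", {
  sim <- generateCollection(nGenes = 50, seed = 14,
                            moduleSizes = c(diurnal = 15L, light = 15L))
  res <- runStatis(sim$collection, nComponents = 2L)
  tabs <- tableList(sim$collection)
  perm <- c(4, 1, 8, 2, 6, 3, 7, 5)
  permc <- TableCollection(tabs[perm], timePoints = timePoints(sim$collection),
                           controlId = controlCondition(sim$collection),
                           scale = "log2")
  resp <- runStatis(permc, nComponents = 2L)
  expect_equal(unname(tableWeights(resp)[conditionNames(sim$collection)]),
               unname(tableWeights(res)), tolerance = 1e-10)
  expect_equal(resp@decomposition@eigenvalues,
               res@decomposition@eigenvalues, tolerance = 1e-10)
  expect_equal(factorScores(resp), factorScores(res), tolerance = 1e-8)
  expect_equal(contributions(resp, "tables")[conditionNames(sim$collection), ],
               contributions(res, "tables"), tolerance = 1e-8)
})

test_that("duplicating a table increases its share of the weight mass", {
  prep <- prepCollection(K = 3, n = 8, t = 5, seed = 15)
  tabs <- tableList(prep)
  inter <- interstructure(crossProducts(prep))
  base_share <- inter@alphaSum1[1]
  tabs$dup <- tabs[[1]]
  dupc <- TableCollection(tabs, timePoints = timePoints(prep),
                          controlId = "cond1", scale = "centered")
  inter2 <- interstructure(crossProducts(dupc))
  expect_gt(inter2@alphaSum1[1] + inter2@alphaSum1[4], base_share)
})

test_that("dual-STATIS equals STATIS on the transposed collection", {
  sim <- generateCollection(nGenes = 40, seed = 16,
                            moduleSizes = c(diurnal = 10L, light = 10L),
                            timePoints = c(0, 5, 10, 20, 40, 80, 160, 320))
  prep <- preprocessTables(sim$collection)
  dual <- runDualStatis(prep, nComponents = 3L)

  # transposed collection fed through the rows-mode pipeline
  tabs_t <- lapply(tableList(prep), t)
  tabs_t <- lapply(tabs_t, function(m) {
    rownames(m) <- sprintf("t%03d", seq_len(nrow(m))); m
  })
  collt <- TableCollection(tabs_t, timePoints = seq_len(ncol(tabs_t[[1]])),
                           controlId = controlCondition(prep),
                           scale = "centered")
  straight <- runStatis(collt, nComponents = 3L)
  expect_equal(unname(tableWeights(dual)), unname(tableWeights(straight)),
               tolerance = 1e-10)
  expect_equal(dual@decomposition@eigenvalues,
               straight@decomposition@eigenvalues, tolerance = 1e-10)
  expect_equal(unname(factorScores(dual)), unname(factorScores(straight)),
               tolerance = 1e-8)

  # K identical tables: dual compromise equals the single table's t x t
  # cross-product
  X <- tableMatrix(prep, "21-L")
  tabsK <- setNames(rep(list(X), 4), paste0("c", 1:4))
  collK <- TableCollection(tabsK, timePoints = timePoints(prep),
                           controlId = "c1", scale = "centered")
  cpsK <- crossProducts(collK, mode = "columns")
  SK <- compromiseMatrix(cpsK, interstructure(cpsK)@alphaSum1)
  expect_equal(SK, crossprod(X), tolerance = 1e-10, ignore_attr = TRUE)
})
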
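makeFilterCollection <- function(gene_cond_values, timePoints = c(0, 10, 20, 30)) {
  # gene_cond_values: list gene -> list cond -> numeric vector
  genes <- names(gene_cond_values)
  conds <- names(gene_cond_values[[1]])
  tabs <- lapply(conds, function(cd) {
    m <- do.call(rbind, lapply(genes, function(g) gene_cond_values[[g]][[cd]]))
    rownames(m) <- genes
    m
  })
  names(tabs) <- conds
  TableCollection(tabs, timePoints = timePoints, controlId = conds[1],
                  scale = "linear")
}

test_that("fold-change/CV filter matches the direct per-gene evaluation", {
  flat <- list(ctrl = c(2, 2, 2, 2), stress = c(2, 2, 2, 2))
  spike <- list(ctrl = c(3, 3, 3, 3), stress = c(0.5, 9, 9, 0.5))
  onehit <- list(ctrl = c(3, 3, 3, 3), stress = c(1, 9, 1, 1))
  coll <- makeFilterCollection(list(gFlat = flat, gSpike = spike,
                                    gOne = onehit))
  out <- filterInformativeGenes(coll)
  rep <- out$report
  rownames(rep) <- rep$gene_id

  # constant gene: FC = 1 everywhere and CV = 0
  expect_false(rep["gFlat", "kept"])
  expect_equal(rep["gFlat", "reason"], "fc_fail")

  # spike gene: FC = 18 at two time points; CV = 4.907/4.75 ~ 1.033
  expect_true(rep["gSpike", "kept"])
  expect_equal(rep["gSpike", "max_fc_timepoints"], 2)
  expect_equal(rep["gSpike", "max_cv"], sd(c(0.5, 9, 9, 0.5)) / 4.75,
               tolerance = 1e-12)
  expect_gte(rep["gSpike", "max_cv"], 1)

  # single FC hit is not enough
  expect_false(rep["gOne", "kept"])
  expect_equal(rep["gOne", "reason"], "fc_fail")

  # kept collection contains exactly the kept genes
  expect_equal(rownames(out$collection), "gSpike")

  # agreement with the independent oracle
  for (g in rep$gene_id) {
    vals <- list(gFlat = flat, gSpike = spike, gOne = onehit)[[g]]
    expect_equal(rep[g, "kept"], filterOracleGene(vals), label = g)
  }
})

test_that("filter handles log2 input, errors and cv scope", {
  spike <- list(ctrl = c(3, 3, 3, 3), stress = c(0.5, 9, 9, 0.5))
  coll <- makeFilterCollection(list(gSpike = spike, gFlat = list(
    ctrl = c(2, 2, 2, 2), stress = c(2, 2, 2, 2))))
  log2coll <- TableCollection(lapply(tableList(coll), log2),
                              timePoints = timePoints(coll),
                              controlId = "ctrl", scale = "log2")
  out_lin <- filterInformativeGenes(coll)
  out_log <- filterInformativeGenes(log2coll)
  expect_equal(out_lin$report$kept, out_log$report$kept)
  expect_equal(out_lin$report$max_cv, out_log$report$max_cv,
               tolerance = 1e-12)

  # non-positive reference rejected with gene and condition named
  bad <- makeFilterCollection(list(gBad = list(ctrl = c(0, 1, 1, 1),
                                               stress = c(1, 1, 1, 1))))
  expect_error(filterInformativeGenes(bad), "gBad.*ctrl")

  # pooled CV differs from per-condition and is accepted
  pooled <- filterInformativeGenes(coll, cvScope = "pooled")
  expect_true(is.finite(pooled$report$max_cv[1]))
})

test_that("filter is monotone in both thresholds", {
  sim <- generateCollection(nGenes = 80, seed = 3,
                            moduleSizes = c(diurnal = 20L, light = 20L))
  base <- sum(filterInformativeGenes(sim$collection)$report$kept)
  for (fc in c(3, 5)) {
    expect_lte(sum(filterInformativeGenes(sim$collection,
                                          fcThreshold = fc)$report$kept),
               base)
  }
  for (cv in c(1.5, 3)) {
    expect_lte(sum(filterInformativeGenes(sim$collection,
                                          cvThreshold = cv)$report$kept),
               base)
  }
})

test_that("centering and scaling meet their postconditions", {
  X <- matrix(c(1, 0, 0, 1), 2, 2)
  Z <- centerScaleMatrix(X)
  expect_equal(Z, matrix(c(0.5, -0.5, -0.5, 0.5), 2, 2))

  set.seed(4)
  Y <- matrix(rnorm(35), 7, 5)
  Y[, 3] <- 2                      # constant column survives as zeros
  Z <- centerScaleMatrix(Y)
  expect_equal(colMeans(Z), rep(0, 5), tolerance = 1e-12)
  expect_equal(sum(Z^2), 1, tolerance = 1e-12)
  expect_equal(Z[, 3], rep(0, 7))

  Zz <- centerScaleMatrix(Y, method = "column_z")
  expect_equal(colMeans(Zz), rep(0, 5), tolerance = 1e-12)
  expect_equal(sum(Zz^2), 1, tolerance = 1e-12)

  # identical rows -> degenerate
  expect_error(centerScaleMatrix(matrix(1:4, 2, 2, byrow = TRUE)[c(1, 1), ]),
               "degenerate table")
})

test_that("control normalization subtracts the control time course only", {
  coll <- randomCollection(K = 3, n = 5, t = 4, seed = 11)
  out <- controlNormalize(coll)
  ctrl <- tableMatrix(coll, "cond1")
  expect_identical(tableMatrix(out, "cond1"), ctrl)
  expect_equal(tableMatrix(out, "cond2"),
               tableMatrix(coll, "cond2") - ctrl)
  expect_equal(exprScale(out), "log2")

  # a condition equal to the control becomes all zeros
  tabs <- tableList(coll)
  tabs$cond2 <- tabs$cond1
  same <- TableCollection(tabs, timePoints = timePoints(coll),
                          controlId = "cond1", scale = "log2")
  outs <- controlNormalize(same)
  expect_true(all(tableMatrix(outs, "cond2") == 0))

  # idempotent on the control table, linear in inputs
  out2 <- controlNormalize(out)
  expect_identical(tableMatrix(out2, "cond1"), ctrl)
  expect_error(controlNormalize(preprocessTables(coll)), "log2")
})

test_that("uniform masses sum to one for any n", {
  expect_equal(uniformMasses(4), rep(0.25, 4))
  expect_equal(uniformMasses(1), 1)
  for (n in c(2, 17, 501)) expect_equal(sum(uniformMasses(n)), 1,
                                        tolerance = 1e-12)
  expect_error(uniformMasses(0))
})
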
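# The PLS2 core: oracle equivalences (SVD, least squares, an established
# reference implementation), prediction arithmetic, explained variance,
# structural invariants and beta back-projection.

test_that("an exactly linear response is reproduced at full rank", {
  set.seed(1)
  X <- matrix(rnorm(10 * 6), 10, 6)
  B <- matrix(rnorm(6 * 2), 6, 2)
  Y <- X %*% B + rep(c(2, -1), each = 10)
  colnames(Y) <- c("disease", "age")
  fit <- fitPLS(X, Y, nComponents = 6)
  pred <- predict(fit, X)
  expect_lt(max(abs(pred - Y)), 1e-8)
  ev <- explainedVariance(fit)
  expect_equal(ev$cum_var_y[6], 1, tolerance = 1e-10)
})

test_that("the first weight is the leading singular vector of X'Y", {
  for (seed in 1:5) {
    pr <- randomPLSProblem(n = 15, p = 20, m = 3, seed = seed)
    fit <- fitPLS(pr$X, pr$Y, nComponents = 3)
    Xc <- scale(pr$X, scale = FALSE); Yc <- scale(pr$Y, scale = FALSE)
    sv <- svd(crossprod(Xc, Yc))
    cosine <- abs(sum(fit@xWeights[, 1] * sv$u[, 1]))
    expect_gt(cosine, 1 - 1e-8)
  }
})

test_that("full-component beta equals the least-squares solution", {
  for (seed in 1:5) {
    pr <- randomPLSProblem(n = 30, p = 5, m = 2, seed = seed)
    fit <- fitPLS(pr$X, pr$Y, nComponents = 5)
    Xc <- scale(pr$X, scale = FALSE); Yc <- scale(pr$Y, scale = FALSE)
    bls <- solve(crossprod(Xc), crossprod(Xc, Yc))
    expect_lt(max(abs(fit@beta - bls)), 1e-6)
  }
})

test_that("prediction is the documented centering arithmetic", {
  pr <- randomPLSProblem(n = 18, p = 12, m = 3, seed = 7)
  fit <- fitPLS(pr$X, pr$Y, nComponents = 4)
  # the training mean predicts the response mean
  expect_equal(drop(predict(fit, fit@xMean)), fit@yMean,
               tolerance = 1e-10, ignore_attr = TRUE)
  # random new data against explicit matrix arithmetic
  set.seed(99)
  xnew <- matrix(rnorm(2 * 12), 2, 12)
  manual <- sweep(xnew, 2, fit@xMean) %*% fit@beta +
    rep(1, 2) %o% fit@yMean
  expect_equal(predict(fit, xnew), manual, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(diseaseScore(fit, xnew), unname(manual[, 1]),
               tolerance = 1e-12)
  expect_error(predict(fit, xnew[, 1:5]), "predictors")
})

test_that("explained variance is a cumulative residual-SS decomposition", {
  pr <- randomPLSProblem(n = 25, p = 10, m = 3, seed = 3)
  fit <- fitPLS(pr$X, pr$Y, nComponents = 6)
  ev <- explainedVariance(fit)
  expect_false(is.unsorted(ev$cum_var_y))
  expect_false(is.unsorted(ev$cum_var_x))
  expect_lte(max(ev$cum_var_y), 1 + 1e-12)
  # independent recomputation: regress centered Y on the first k scores
  Yc <- scale(pr$Y, scale = FALSE)
  ssY <- sum(Yc^2)
  for (k in c(1, 3, 6)) {
    fitK <- lm.fit(fit@xScores[, 1:k, drop = FALSE], Yc)
    expect_equal(ev$cum_var_y[k], 1 - sum(fitK$residuals^2) / ssY,
                 tolerance = 1e-10)
  }
})

test_that("responses orthogonal to the predictors yield no components", {
  set.seed(12)
  X <- matrix(rnorm(20 * 6), 20, 6)
  Xc <- scale(X, scale = FALSE)
  y <- rnorm(20)
  y <- y - Xc %*% solve(crossprod(Xc), crossprod(Xc, y - mean(y)))
  Y <- cbind(disease = drop(y))
  expect_warning(fit <- fitPLS(X, Y, nComponents = 3), "covariance")
  expect_equal(nComponents(fit), 0L)
  # a zero-component model predicts the training mean
  expect_equal(drop(predict(fit, X[3, ])), fit@yMean, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("scores are orthogonal and predictions are shift invariant", {
  for (seed in 1:4) {
    pr <- randomPLSProblem(n = 16, p = 30, m = 4, seed = seed)
    fit <- fitPLS(pr$X, pr$Y, nComponents = 5)
    G <- crossprod(fit@xScores)
    offDiag <- G - diag(diag(G))
    expect_lt(max(abs(offDiag)) / max(diag(G)), 1e-8)
    # shifting a predictor column only moves the centering vector
    X2 <- pr$X; X2[, 3] <- X2[, 3] + 100
    fit2 <- fitPLS(X2, pr$Y, nComponents = 5)
    xnew <- pr$X[2, ]; xnew2 <- X2[2, ]
    expect_equal(predict(fit, xnew), predict(fit2, xnew2),
                 tolerance = 1e-6)
  }
})

test_that("one-component single-response PLS is the covariance projection", {
  for (seed in 1:4) {
    set.seed(seed)
    X <- matrix(rnorm(12 * 8), 12, 8)
    y <- cbind(disease = rnorm(12) + X[, 1])
    fit <- fitPLS(X, y, nComponents = 1)
    Xc <- scale(X, scale = FALSE); yc <- drop(scale(y, scale = FALSE))
    w <- drop(crossprod(Xc, yc)); w <- w / sqrt(sum(w^2))
    t1 <- drop(Xc %*% w)
    beta1 <- w * sum(yc * t1) / sum(t1^2)
    expect_equal(drop(fit@beta), beta1, tolerance = 1e-10,
                 ignore_attr = TRUE)
  }
})

test_that("fits agree with an established reference implementation", {
  skip_if_not_installed("mixOmics")
  for (seed in 1:3) {
    pr <- randomPLSProblem(n = 20, p = 25, m = 3, seed = seed)
    k <- 5
    fit <- fitPLS(pr$X, pr$Y, nComponents = k)
    ref <- mixOmics::pls(pr$X, pr$Y, ncomp = k, scale = FALSE,
                         mode = "regression")
    set.seed(seed + 100)
    xnew <- matrix(rnorm(4 * 25), 4, 25,
                   dimnames = list(NULL, colnames(pr$X)))
    ours <- predict(fit, xnew)
    theirs <- predict(ref, xnew)$predict[, , k]
    expect_equal(unname(ours), unname(theirs), tolerance = 1e-6)
  }
})

test_that("the Gram-space fit equals the direct fit", {
  for (seed in 1:3) {
    pr <- randomPLSProblem(n = 14, p = 40, m = 3, seed = seed)
    k <- 4
    fit <- fitPLS(pr$X, pr$Y, nComponents = k)
    Xc <- scale(pr$X, scale = FALSE)
    Yc <- scale(pr$Y, scale = FALSE)
    gf <- suvrPLS:::.plsGramFit(tcrossprod(Xc), Yc, k)
    set.seed(seed)
    xnew <- rnorm(40)
    g <- drop(Xc %*% (xnew - fit@xMean))
    expect_equal(drop(g %*% gf$C) + fit@yMean,
                 drop(predict(fit, xnew)), tolerance = 1e-8,
                 ignore_attr = TRUE)
    # scores match too
    expect_equal(abs(gf$T), abs(fit@xScores), tolerance = 1e-8,
                 ignore_attr = TRUE)
  }
})

test_that("component counts outside the rank bound are rejected", {
  pr <- randomPLSProblem(n = 8, p = 5, m = 2, seed = 2)
  expect_error(fitPLS(pr$X, pr$Y, nComponents = 6), "nComponents")
  expect_error(fitPLS(pr$X, pr$Y, nComponents = 0), "nComponents")
  expect_error(fitPLS(pr$X[1:5, ], pr$Y, nComponents = 2), "aligned")
})

test_that("the response block carries diagnosis plus one-hot covariates", {
  coh <- generateCohort(tinyConfig(seed = 4))
  Y <- buildResponseBlock(coh$subjects)
  expect_true("disease" %in% colnames(Y))
  siteCols <- grep("^site\\.", colnames(Y))
  expect_equal(unname(rowSums(Y[, siteCols, drop = FALSE])),
               rep(1, nrow(Y)))
  expect_equal(unname(Y[, "disease"]), coh$subjects$diagnosis)
  Yd <- buildResponseBlock(coh$subjects, withDOI = TRUE)
  expect_true("doi" %in% colnames(Yd))
  bad <- coh$subjects; bad$duration_of_illness[2] <- NA
  expect_error(buildResponseBlock(bad, withDOI = TRUE),
               bad$subject_id[2])
})

test_that("beta maps back-project coefficients to their voxels", {
  vd <- randomVoxelData(nSubjects = 12, dim = c(4, 4, 4), seed = 8)
  Y <- buildResponseBlock(subjectTable(vd))
  fit <- fitPLS(vd, Y, nComponents = 3)
  bm <- betaMap(fit, vd, "disease")
  vals <- gridValues(bm)
  expect_equal(sum(!is.na(vals)), nrow(vd))
  rd <- SummarizedExperiment::rowData(vd)
  for (j in c(1, 17, 64))
    expect_equal(vals[rd$i[j], rd$j[j], rd$k[j]],
                 unname(fit@beta[j, "disease"]))
  expect_error(betaMap(fit, vd, "nope"), "unknown response")
})

test_that("seeded effects imprint the expected beta-coefficient signs", {
  hits <- 0; total <- 0
  for (seed in 1:3) {
    cfg <- tinyConfig(seed = seed, nBD = 10, nMDD = 12, delta = 0.15,
                      gridShape = c(14, 14, 14))
    coh <- generateCohort(cfg)
    mask <- buildSignalMask(coh$volumes)
    vd <- stackMatrix(coh$volumes, mask, coh$subjects)
    fit <- fitPLS(vd, buildResponseBlock(coh$subjects), nComponents = 8)
    bm <- gridValues(betaMap(fit, vd, "disease"))
    for (e in coh$groundTruth) {
      ind <- suvrPLS:::.effectIndicator(e, cfg@gridShape,
                                        brainMask(coh$volumes[[1]]))$indicator
      inMask <- ind & !is.na(bm)
      if (!any(inMask)) next
      total <- total + 1
      hits <- hits + (sign(mean(bm[inMask])) == e@sign)
    }
  }
  expect_gte(total, 4)
  expect_gte(hits / total, 0.9)
})
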
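# Leave-one-pair-out enumeration, fold-faithful CV, ROC/AUC, DeLong
# intervals, Youden thresholds and confusion metrics.

test_that("pair splits enumerate the Cartesian product without leakage", {
  sp <- looPairSplits(c("b1", "b2"), c("m1", "m2", "m3"))
  expect_length(sp, 6)
  for (s in sp) {
    expect_false(s$testBD %in% s$trainIds)
    expect_false(s$testMDD %in% s$trainIds)
    expect_length(s$trainIds, 3)
  }
  # deterministic lexicographic order
  expect_equal(sp[[1]]$testBD, "b1"); expect_equal(sp[[1]]$testMDD, "m1")
  expect_equal(sp[[6]]$testBD, "b2"); expect_equal(sp[[6]]$testMDD, "m3")

  one <- looPairSplits("b", "m")
  expect_length(one, 1)
  expect_length(one[[1]]$trainIds, 0)

  expect_error(looPairSplits(c("a", "a"), "m"), "duplicate")
  expect_error(looPairSplits(character(0), "m"), "nonempty")
})

test_that("cross-validation predictions match fold-by-fold refits", {
  vd <- randomVoxelData(nSubjects = 9, dim = c(4, 4, 4), seed = 14,
                        diagnosis = rep(c(1L, 0L), c(4, 5)))
  Y <- buildResponseBlock(subjectTable(vd))
  cv <- runCV(vd, Y, nComponents = 3)
  fp <- foldPredictions(cv)
  ss <- subjectScores(cv)
  # each BD subject is predicted once per MDD subject and vice versa
  expect_equal(unname(ss$n_folds[ss$diagnosis == 1]), rep(5, 4))
  expect_equal(unname(ss$n_folds[ss$diagnosis == 0]), rep(4, 5))
  expect_equal(nrow(fp), 2 * 20)
  # refit two folds independently through the public fit/predict path
  X <- voxelMatrix(vd)
  splits <- looPairSplits(rownames(X)[1:4], rownames(X)[5:9])
  for (s in c(3, 17)) {
    sp <- splits[[s]]
    fit <- fitPLS(X[sp$trainIds, ], Y[sp$trainIds, ], nComponents = 3)
    manual <- diseaseScore(fit, X[c(sp$testBD, sp$testMDD), ])
    expect_equal(fp$score[fp$fold == s], unname(manual), tolerance = 1e-8)
  }
  # per-subject means are the arithmetic means of the fold scores
  for (id in ss$subject_id)
    expect_equal(ss$mean_score[ss$subject_id == id],
                 mean(fp$score[fp$subject_id == id]))
})

test_that("the fold model never sees the held-out pair", {
  vd <- randomVoxelData(nSubjects = 8, dim = c(4, 4, 4), seed = 4)
  Y <- buildResponseBlock(subjectTable(vd))
  X <- voxelMatrix(vd)
  ids <- rownames(X)
  d <- subjectTable(vd)$diagnosis
  sp <- looPairSplits(ids[d == 1], ids[d == 0])[[1]]
  test <- c(sp$testBD, sp$testMDD)
  # corrupting the held-out rows leaves the fold model untouched
  X2 <- X
  X2[test, ] <- X2[test, ] * 1000 + 7
  f1 <- fitPLS(X[sp$trainIds, ], Y[sp$trainIds, ], nComponents = 2)
  f2 <- fitPLS(X2[sp$trainIds, ], Y[sp$trainIds, ], nComponents = 2)
  expect_identical(f1@beta, f2@beta)
  cv1 <- runCV(X, Y, splits = list(sp), nComponents = 2)
  cv2 <- runCV(X2, Y, splits = list(sp), nComponents = 2)
  # same model, different test inputs: other folds would be unchanged
  expect_equal(foldPredictions(cv1)$subject_id,
               foldPredictions(cv2)$subject_id)
})

test_that("uninformative predictors give the training disease mean and chance AUC", {
  n <- 10
  X <- matrix(5, n, 30)
  rownames(X) <- sprintf("S%02d", 1:n)
  subjects <- data.frame(subject_id = rownames(X),
                         diagnosis = rep(c(1L, 0L), each = 5),
                         age = 40, sex = 0L, site = "a",
                         duration_of_illness = 5, madrs = 15L, ymrs = 2L)
  Y <- buildResponseBlock(subjects)
  cv <- runCV(X, Y, nComponents = 2)
  ss <- subjectScores(cv)
  # every training set holds 4 BD of 8 subjects
  expect_equal(unname(ss$mean_score), rep(0.5, n), tolerance = 1e-12)
  expect_equal(rocAuc(ss$mean_score, ss$diagnosis)$auc, 0.5)
})

test_that("AUC is the Mann-Whitney pair probability with half ties", {
  expect_equal(rocAuc(c(1, 2, 3, 4), c(0, 0, 1, 1))$auc, 1)
  expect_equal(rocAuc(rep(2, 6), rep(c(0, 1), 3))$auc, 0.5)
  set.seed(20)
  for (rep in 1:5) {
    scores <- round(rnorm(12), 1)  # rounding forces some ties
    labels <- rep(c(1, 0), c(5, 7))
    pos <- scores[labels == 1]; neg <- scores[labels == 0]
    brute <- 0
    for (a in pos) for (b in neg)
      brute <- brute + (a > b) + 0.5 * (a == b)
    expect_equal(rocAuc(scores, labels)$auc, brute / (5 * 7))
  }
  expect_error(rocAuc(1:3, c(1, 1, 1)), "nonempty")
})

test_that("AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(33)
  scores <- rnorm(30)
  labels <- rep(c(1, 0), c(12, 18))
  ours <- rocAuc(scores, labels)$auc
  ref <- pROC::roc(labels, scores, levels = c(0, 1), direction = "<",
                   quiet = TRUE)
  expect_equal(ours, as.numeric(pROC::auc(ref)), tolerance = 1e-12)
  ci <- aucCI(scores, labels)
  refCI <- as.numeric(pROC::ci.auc(ref, method = "delong"))
  expect_equal(unname(ci), refCI[c(1, 3)], tolerance = 1e-10)
})

test_that("the DeLong interval matches the structural-components formula", {
  pos <- c(0.9, 0.8, 0.55, 0.4)
  neg <- c(0.7, 0.5, 0.3, 0.2, 0.1)
  scores <- c(pos, neg); labels <- rep(c(1, 0), c(4, 5))
  # hand computation
  psi <- matrix(0, 4, 5)
  for (i in 1:4) for (j in 1:5)
    psi[i, j] <- (pos[i] > neg[j]) + 0.5 * (pos[i] == neg[j])
  auc <- mean(psi)
  v10 <- rowMeans(psi); v01 <- colMeans(psi)
  vr <- var(v10) / 4 + var(v01) / 5
  want <- auc + c(-1, 1) * qnorm(0.975) * sqrt(vr)
  got <- aucCI(scores, labels)
  expect_equal(unname(got), pmin(pmax(want, 0), 1), tolerance = 1e-12)

  # clipping and degenerate variance
  sep <- c(rep(1, 5), rep(0, 5)); lab <- rep(c(1, 0), each = 5)
  expect_warning(ciSep <- aucCI(sep, lab), "degenerate")
  expect_equal(unname(ciSep), c(1, 1))

  # seeded bootstrap is reproducible
  set.seed(50); s2 <- rnorm(20); l2 <- rep(c(1, 0), 10)
  b1 <- aucCI(s2, l2, method = "bootstrap", nBoot = 200, seed = 9)
  b2 <- aucCI(s2, l2, method = "bootstrap", nBoot = 200, seed = 9)
  expect_identical(b1, b2)
  expect_true(b1[1] >= 0 && b1[2] <= 1)
})

test_that("the Youden threshold maximizes J with smallest-threshold ties", {
  yd <- youdenThreshold(c(0.1, 0.2, 0.3, 0.4), c(0, 0, 1, 1))
  expect_equal(yd$threshold, 0.3)
  expect_equal(yd$J, 1)
  expect_equal(youdenThreshold(rep(1, 6), rep(c(0, 1), 3))$J, 0)
  set.seed(41)
  for (rep in 1:5) {
    scores <- round(rnorm(14), 1)
    labels <- rep(c(1, 0), 7)
    pos <- scores[labels == 1]; neg <- scores[labels == 0]
    cand <- sort(unique(scores))
    J <- vapply(cand, function(th) mean(pos >= th) + mean(neg < th) - 1,
                numeric(1))
    best <- min(cand[J == max(J)])
    got <- youdenThreshold(scores, labels)
    expect_equal(got$threshold, best)
    expect_equal(got$J, max(J))
  }
})

test_that("confusion metrics follow the percentage formulas", {
  expect_equal(unname(confusionMetrics(5, 0, 7, 0)), rep(100, 4))
  set.seed(2)
  for (rep in 1:5) {
    cnt <- rpois(4, 10) + 1
    got <- confusionMetrics(cnt[1], cnt[2], cnt[3], cnt[4])
    expect_equal(unname(got),
                 round(100 * c(cnt[1] / (cnt[1] + cnt[2]),
                               cnt[3] / (cnt[3] + cnt[4]),
                               cnt[1] / (cnt[1] + cnt[4]),
                               cnt[3] / (cnt[3] + cnt[2])), 1))
  }
  expect_true(is.na(confusionMetrics(0, 3, 5, 0)[["ppv"]]))
  expect_error(confusionMetrics(0, 0, 3, 1), "positives")
})

test_that("evaluateCV ties the Youden threshold to its confusion counts", {
  vd <- randomVoxelData(nSubjects = 10, dim = c(4, 4, 4), seed = 23,
                        diagnosis = rep(c(1L, 0L), c(4, 6)))
  Y <- buildResponseBlock(subjectTable(vd))
  cv <- runCV(vd, Y, nComponents = 3)
  ev <- evaluateCV(cv)
  ss <- subjectScores(cv)
  pred <- as.integer(ss$mean_score >= ev$youden_threshold)
  expect_equal(unname(ev$confusion["TP"]), sum(pred & ss$diagnosis))
  expect_equal(unname(ev$confusion["TN"]), sum(!pred & !ss$diagnosis))
  expect_equal(sum(ev$confusion[c("TP", "FN")]), 4)
  expect_equal(sum(ev$confusion[c("TN", "FP")]), 6)
  # the sweep row at the chosen threshold reports the same counts
  row <- ev$curve[ev$curve$threshold == ev$youden_threshold, ]
  expect_equal(unname(unlist(row[c("TP", "FN", "TN", "FP")])),
               unname(ev$confusion[c("TP", "FN", "TN", "FP")]))
  expect_equal(ev$J, row$sensitivity + row$specificity - 1)
})

test_that("a constant DOI column leaves the classification unchanged", {
  vd <- randomVoxelData(nSubjects = 8, dim = c(4, 4, 4), seed = 31)
  subjects <- subjectTable(vd)
  subjects$duration_of_illness <- 7.5
  res <- doiSensitivity(voxelMatrix(vd), subjects, nComponents = 3)
  expect_lt(abs(res$auc_difference), 1e-10)
  expect_named(res, c("auc_without", "auc_with", "auc_difference",
                      "cv_without", "cv_with"))
  expect_equal(
    subjectScores(res$cv_without)$mean_score,
    subjectScores(res$cv_with)$mean_score, tolerance = 1e-10)
})
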
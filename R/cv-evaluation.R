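# Leave-one-pair-out cross-validation and threshold-free / thresholded
# performance evaluation. One BD and one MDD subject are held out per
# fold (the full Cartesian product of pairs), each subject's held-out
# predictions are averaged, and the per-subject mean scores feed the ROC.

#' Enumerate leave-one-pair-out splits
#'
#' The full Cartesian product of (BD, MDD) subject pairs, in
#' lexicographic order of ids: for 16 BD and 27 MDD subjects this yields
#' 432 splits, so every BD subject is held out 27 times and every MDD
#' subject 16 times.
#'
#' @param bdIds,mddIds character vectors of subject ids (disjoint, no
#'   duplicates).
#' @return list of splits, each a list with `testBD`, `testMDD`,
#'   `trainIds`.
#' @export
looPairSplits <- function(bdIds, mddIds) {
  bdIds <- as.character(bdIds); mddIds <- as.character(mddIds)
  if (length(bdIds) == 0L || length(mddIds) == 0L)
    .stopf("both id lists must be nonempty")
  all <- c(bdIds, mddIds)
  if (anyDuplicated(all))
    .stopf("duplicate subject id(s): %s",
           paste(unique(all[duplicated(all)]), collapse = ", "))
  bdIds <- sort(bdIds); mddIds <- sort(mddIds)
  splits <- vector("list", length(bdIds) * length(mddIds))
  s <- 0L
  for (b in bdIds) for (m in mddIds) {
    s <- s + 1L
    splits[[s]] <- list(testBD = b, testMDD = m,
                        trainIds = setdiff(all, c(b, m)))
  }
  splits
}

#' Run leave-one-pair-out cross-validation of the PLS classifier
#'
#' Per split, the PLS model is fitted on the training rows only --
#' centering (and scaling, if enabled) is recomputed from the training
#' set, so no information from the held-out pair leaks into the fit --
#' and the continuous disease score is predicted for the two held-out
#' subjects. Each subject's held-out scores are then averaged.
#'
#' @param X a [VoxelData-class] or subjects x voxels matrix with subject
#'   ids as rownames.
#' @param responses response block from [buildResponseBlock()], rows
#'   aligned with `X`.
#' @param splits list from [looPairSplits()]; defaults to the full
#'   enumeration from the `disease` column.
#' @param nComponents latent components per fold, default 10.
#' @param scale scale predictors to unit variance within each fold.
#' @return A [CVResult-class].
#' @export
runCV <- function(X, responses, splits = NULL, nComponents = 10,
                  scale = FALSE) {
  if (is(X, "VoxelData")) X <- voxelMatrix(X)
  X <- as.matrix(X)
  if (is.null(rownames(X))) rownames(X) <- rownames(responses)
  if (is.null(rownames(X)))
    .stopf("subject ids are required as rownames of X or responses")
  if (!identical(sort(rownames(X)), sort(rownames(responses))))
    .stopf("X and responses must cover the same subjects")
  responses <- responses[rownames(X), , drop = FALSE]
  disease <- responses[, "disease"]
  if (is.null(splits))
    splits <- looPairSplits(rownames(X)[disease == 1],
                            rownames(X)[disease == 0])
  nf <- length(splits)
  fold <- integer(2L * nf); sid <- character(2L * nf)
  score <- numeric(2L * nf)
  ncomp <- as.integer(nComponents)
  kmax <- min(length(disease) - 2L - 1L, ncol(X))
  if (ncomp < 1L || ncomp > kmax)
    .stopf("'nComponents' must be in [1, %d] for these training sets, got %d",
           kmax, ncomp)
  # All per-fold quantities (centered Gram, held-out Gram rows) derive
  # from the one full Gram matrix; see .plsGramFit.
  G0 <- if (!scale) tcrossprod(X) else NULL
  dcol <- match("disease", colnames(responses))
  for (s in seq_len(nf)) {
    sp <- splits[[s]]
    tr <- sp$trainIds
    test <- c(sp$testBD, sp$testMDD)
    if (any(test %in% tr))
      .stopf("split %d: test subjects appear in the training set", s)
    if (length(unique(disease[tr])) < 2L)
      .stopf("split %d: training set lacks one of the classes", s)
    if (scale) {
      fit <- .plsFit(X[tr, , drop = FALSE], responses[tr, , drop = FALSE],
                     ncomp, scale = TRUE)
      Xc <- sweep(sweep(X[test, , drop = FALSE], 2L, fit$xm, "-"),
                  2L, fit$xs, "/")
      pred <- drop(Xc %*% fit$beta[, dcol]) + fit$ym[[dcol]]
    } else {
      ti <- match(tr, rownames(X)); te <- match(test, rownames(X))
      Gtt <- G0[ti, ti]
      rm_ <- rowMeans(Gtt); mm <- mean(Gtt)
      K0 <- Gtt - outer(rm_, rep(1, length(ti))) -
        outer(rep(1, length(ti)), rm_) + mm
      Ytr <- responses[ti, , drop = FALSE]
      ym <- colMeans(Ytr)
      fit <- .plsGramFit(K0, sweep(Ytr, 2L, ym, "-"), ncomp)
      gte <- G0[te, ti, drop = FALSE] - rowMeans(G0[te, ti, drop = FALSE]) -
        outer(rep(1, 2L), rm_) + mm
      pred <- drop(gte %*% fit$C[, dcol]) + ym[[dcol]]
    }
    ii <- (2L * s - 1L):(2L * s)
    fold[ii] <- s; sid[ii] <- test; score[ii] <- pred
  }
  fp <- data.frame(fold = fold, subject_id = sid,
                   diagnosis = as.integer(disease[sid]), score = score,
                   stringsAsFactors = FALSE)
  agg <- split(fp$score, fp$subject_id)
  ids <- rownames(X)[rownames(X) %in% names(agg)]
  ss <- data.frame(subject_id = ids,
                   diagnosis = as.integer(disease[ids]),
                   n_folds = vapply(agg[ids], length, integer(1)),
                   mean_score = vapply(agg[ids], mean, numeric(1)),
                   stringsAsFactors = FALSE)
  rownames(ss) <- NULL
  new("CVResult", foldPredictions = fp, subjectScores = ss)
}

#' ROC curve and AUC from scores of two classes
#'
#' The AUC is the Mann-Whitney probability that a random BD score exceeds
#' a random MDD score, ties counted 1/2. The threshold sweep runs over
#' the observed scores, classifying BD iff `score >= threshold`.
#'
#' @param scores numeric prediction scores (higher = more BD-like).
#' @param labels 0/1 class labels aligned with `scores` (1 = BD).
#' @return list with `auc`, and `curve` (data.frame: `threshold`,
#'   `sensitivity`, `specificity`, and the confusion counts `TP`, `FN`,
#'   `TN`, `FP` at each threshold).
#' @export
rocAuc <- function(scores, labels) {
  labels <- as.integer(labels)
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  if (length(pos) == 0L || length(neg) == 0L)
    .stopf("both classes must be nonempty")
  cmp <- outer(pos, neg, FUN = function(a, b) (a > b) + 0.5 * (a == b))
  auc <- mean(cmp)
  thr <- sort(unique(scores))
  sens <- vapply(thr, function(th) mean(pos >= th), numeric(1))
  spec <- vapply(thr, function(th) mean(neg < th), numeric(1))
  curve <- data.frame(threshold = thr, sensitivity = sens,
                      specificity = spec,
                      TP = as.integer(round(sens * length(pos))),
                      FN = as.integer(round((1 - sens) * length(pos))),
                      TN = as.integer(round(spec * length(neg))),
                      FP = as.integer(round((1 - spec) * length(neg))))
  list(auc = auc, curve = curve)
}

# DeLong structural components: V10[i] = mean_j psi(pos_i, neg_j),
# V01[j] = mean_i psi(pos_i, neg_j), psi = 1, 1/2, 0.
.delongVariance <- function(pos, neg) {
  psi <- outer(pos, neg, FUN = function(a, b) (a > b) + 0.5 * (a == b))
  v10 <- rowMeans(psi)
  v01 <- colMeans(psi)
  var(v10) / length(pos) + var(v01) / length(neg)
}

#' Confidence interval for an AUC
#'
#' Default is the DeLong variance-based normal-approximation interval
#' (deterministic), clipped to \[0, 1\]; alternatively a seeded stratified
#' bootstrap percentile interval.
#'
#' @param scores,labels as in [rocAuc()].
#' @param level confidence level, default 0.95.
#' @param method `"delong"` or `"bootstrap"`.
#' @param nBoot bootstrap replicates (bootstrap method only).
#' @param seed RNG seed (bootstrap method only).
#' @return numeric vector `c(low, high)`.
#' @export
aucCI <- function(scores, labels, level = 0.95,
                  method = c("delong", "bootstrap"), nBoot = 2000,
                  seed = 1L) {
  method <- match.arg(method)
  labels <- as.integer(labels)
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  if (length(pos) < 2L || length(neg) < 2L)
    .stopf("both classes need >= 2 scores for a confidence interval")
  auc <- rocAuc(scores, labels)$auc
  if (method == "delong") {
    v <- .delongVariance(pos, neg)
    if (v <= 0) {
      warning("degenerate DeLong variance: interval collapses to the AUC")
      return(c(low = auc, high = auc))
    }
    z <- qnorm(1 - (1 - level) / 2)
    ci <- auc + c(-1, 1) * z * sqrt(v)
  } else {
    ci <- withSeed(seed, {
      reps <- vapply(seq_len(nBoot), function(b) {
        bp <- sample(pos, replace = TRUE)
        bn <- sample(neg, replace = TRUE)
        rocAuc(c(bp, bn), rep(c(1L, 0L), c(length(bp), length(bn))))$auc
      }, numeric(1))
      unname(quantile(reps, c((1 - level) / 2, 1 - (1 - level) / 2)))
    })
  }
  c(low = max(0, ci[1]), high = min(1, ci[2]))
}

#' Youden-index optimal threshold
#'
#' Sweeps the observed scores as candidate thresholds (classify BD iff
#' `score >= threshold`) and maximizes `J = sensitivity + specificity -
#' 1`; ties are broken by the smallest qualifying threshold.
#'
#' @param scores,labels as in [rocAuc()].
#' @return list with `threshold` and `J`.
#' @export
youdenThreshold <- function(scores, labels) {
  roc <- rocAuc(scores, labels)
  j <- roc$curve$sensitivity + roc$curve$specificity - 1
  best <- which(j == max(j))[1]  # thresholds are sorted ascending
  list(threshold = roc$curve$threshold[best], J = max(j))
}

#' Confusion-matrix metrics as percentages
#'
#' Sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`, positive and
#' negative predictive values `TP/(TP+FP)` and `TN/(TN+FN)`, each times
#' 100 and rounded to one decimal. A zero predicted-positive (or
#' -negative) margin makes the PPV (or NPV) undefined and it is returned
#' as `NA`.
#'
#' @param TP,FN,TN,FP confusion counts (positives = BD).
#' @return named numeric vector `sens`, `spec`, `ppv`, `npv` (percent).
#' @examples
#' confusionMetrics(12, 4, 21, 6)  # 75.0, 77.8, 66.7, 84.0
#' @export
confusionMetrics <- function(TP, FN, TN, FP) {
  if (any(c(TP, FN, TN, FP) < 0)) .stopf("counts must be >= 0")
  if (TP + FN == 0) .stopf("no actual positives: sensitivity undefined")
  if (TN + FP == 0) .stopf("no actual negatives: specificity undefined")
  pct <- function(num, den) if (den == 0) NA_real_ else
    round(100 * num / den, 1)
  c(sens = pct(TP, TP + FN), spec = pct(TN, TN + FP),
    ppv = pct(TP, TP + FP), npv = pct(TN, TN + FN))
}

#' Full ROC summary of a cross-validation result
#'
#' Combines the per-subject mean scores into ROC/AUC, the DeLong (or
#' bootstrap) confidence interval, the Youden threshold and the
#' confusion metrics at that threshold.
#'
#' @param cv a [CVResult-class].
#' @param level confidence level for the AUC interval.
#' @param ciMethod `"delong"` or `"bootstrap"`.
#' @param seed seed for the bootstrap interval.
#' @param perFold use the per-fold predictions (two rows per fold)
#'   instead of the per-subject means.
#' @return list with `auc`, `auc_ci`, `youden_threshold`, `J`,
#'   `confusion` (TP, FN, TN, FP), `metrics` (percent), and `curve`.
#' @export
evaluateCV <- function(cv, level = 0.95, ciMethod = "delong", seed = 1L,
                       perFold = FALSE) {
  stopifnot(is(cv, "CVResult"))
  d <- if (perFold) cv@foldPredictions else cv@subjectScores
  scores <- if (perFold) d$score else d$mean_score
  labels <- d$diagnosis
  roc <- rocAuc(scores, labels)
  yd <- youdenThreshold(scores, labels)
  pred <- as.integer(scores >= yd$threshold)
  TP <- sum(pred == 1 & labels == 1); FN <- sum(pred == 0 & labels == 1)
  TN <- sum(pred == 0 & labels == 0); FP <- sum(pred == 1 & labels == 0)
  list(auc = roc$auc,
       auc_ci = aucCI(scores, labels, level = level, method = ciMethod,
                      seed = seed),
       youden_threshold = yd$threshold, J = yd$J,
       confusion = c(TP = TP, FN = FN, TN = TN, FP = FP),
       metrics = confusionMetrics(TP, FN, TN, FP),
       curve = roc$curve)
}

#' Sensitivity analysis: add duration of illness to the response block
#'
#' Re-runs the leave-one-pair-out cross-validation with duration of
#' illness (DOI) appended to the response block and reports both AUCs
#' and their signed difference, to check that illness-duration
#' imbalance does not drive the classification.
#'
#' @param X a [VoxelData-class] or subjects x voxels matrix.
#' @param subjects subject table (needs `duration_of_illness` without
#'   missing values).
#' @param splits optional split list; defaults to the full enumeration.
#' @param nComponents latent components, default 10.
#' @param scale scale predictors within folds.
#' @return list with `auc_without`, `auc_with`, `auc_difference`
#'   (with minus without), and the two [CVResult-class] objects.
#' @export
doiSensitivity <- function(X, subjects, splits = NULL, nComponents = 10,
                           scale = FALSE) {
  y0 <- buildResponseBlock(subjects, withDOI = FALSE)
  y1 <- buildResponseBlock(subjects, withDOI = TRUE)
  cv0 <- runCV(X, y0, splits = splits, nComponents = nComponents,
               scale = scale)
  cv1 <- runCV(X, y1, splits = splits, nComponents = nComponents,
               scale = scale)
  a0 <- rocAuc(cv0@subjectScores$mean_score, cv0@subjectScores$diagnosis)$auc
  a1 <- rocAuc(cv1@subjectScores$mean_score, cv1@subjectScores$diagnosis)$auc
  list(auc_without = a0, auc_with = a1, auc_difference = a1 - a0,
       cv_without = cv0, cv_with = cv1)
}

#' Violin/box plot of per-subject mean predicted scores by diagnosis
#'
#' @param cv a [CVResult-class].
#' @return a ggplot object.
#' @export
plotPredictedScores <- function(cv) {
  ss <- cv@subjectScores
  ss$group <- factor(ifelse(ss$diagnosis == 1, "BD", "MDD"),
                     levels = c("MDD", "BD"))
  ggplot2::ggplot(ss, ggplot2::aes(x = .data$group, y = .data$mean_score,
                                   fill = .data$group)) +
    ggplot2::geom_violin(alpha = 0.4, show.legend = FALSE) +
    ggplot2::geom_boxplot(width = 0.15, outlier.shape = NA,
                          show.legend = FALSE) +
    ggplot2::geom_point(show.legend = FALSE) +
    ggplot2::labs(x = NULL, y = "mean predicted disease score") +
    ggplot2::theme_minimal()
}

#' ROC curve plot
#'
#' @param rocSummary output of [evaluateCV()].
#' @return a ggplot object.
#' @export
plotROC <- function(rocSummary) {
  cu <- rocSummary$curve[order(1 - rocSummary$curve$specificity,
                               rocSummary$curve$sensitivity), ]
  df <- rbind(data.frame(fpr = 1, tpr = 1),
              data.frame(fpr = 1 - cu$specificity, tpr = cu$sensitivity),
              data.frame(fpr = 0, tpr = 0))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_step(direction = "vh") +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "1 - specificity", y = "sensitivity",
                  title = sprintf("AUC = %.2f (95%% CI %.2f-%.2f)",
                                  rocSummary$auc, rocSummary$auc_ci[1],
                                  rocSummary$auc_ci[2])) +
    ggplot2::theme_minimal()
}
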
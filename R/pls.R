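# Multi-response partial least squares (PLS2) regression, written from
# scratch. Per component the X-weight vector maximizes the covariance
# between the X score and a Y score; X is deflated by the score-loading
# outer product and Y by the score-yloading outer product, as in textbook
# NIPALS. The inner loop is solved exactly: the Y-side direction is the
# dominant eigenvector of the small (responses x responses) matrix
# Z'Z with Z = X_a' Y_a, which is the fixed point the NIPALS power
# iteration converges to -- so the fit is deterministic with no
# convergence tolerance. Deflation is carried lazily through the stored
# scores/loadings (X_a = X - T P'), avoiding repeated copies of the wide
# voxel matrix.

#' Build the multi-column response block for PLS
#'
#' Assembles disease status (0 = MDD, 1 = BD) together with the nuisance
#' covariates age, sex and site (one-hot, all levels retained -- centering
#' absorbs the redundancy) and optionally duration of illness, so the
#' latent components can separate diagnosis from confound structure.
#'
#' @param subjects subject table with columns `diagnosis`, `age`, `sex`,
#'   `site` (and `duration_of_illness` if `withDOI`).
#' @param withDOI include duration of illness as an extra response.
#' @param siteLevels site levels defining the one-hot columns; defaults
#'   to the sorted unique sites present.
#' @return numeric matrix with named columns `disease`, `age`, `sex`,
#'   `site.<label>`..., and optionally `doi`; rownames are subject ids.
#' @export
buildResponseBlock <- function(subjects, withDOI = FALSE, siteLevels = NULL) {
  need <- c("diagnosis", "age", "sex", "site")
  miss <- setdiff(need, names(subjects))
  if (length(miss))
    .stopf("subject table lacks column(s): %s", paste(miss, collapse = ", "))
  if (is.null(siteLevels)) siteLevels <- sort(unique(subjects$site))
  siteMat <- vapply(siteLevels, function(s) as.numeric(subjects$site == s),
                    numeric(nrow(subjects)))
  colnames(siteMat) <- paste0("site.", siteLevels)
  Y <- cbind(disease = as.numeric(subjects$diagnosis),
             age = as.numeric(subjects$age),
             sex = as.numeric(subjects$sex), siteMat)
  if (withDOI) {
    doi <- subjects$duration_of_illness
    if (is.null(doi) || anyNA(doi))
      .stopf("duration of illness missing for subject(s): %s",
             paste(subjects$subject_id[is.na(doi)], collapse = ", "))
    Y <- cbind(Y, doi = as.numeric(doi))
  }
  rownames(Y) <- subjects$subject_id
  Y
}

# Core fit on plain matrices: X subjects x predictors, Y subjects x
# responses, both numeric.
.plsFit <- function(X, Y, ncomp, scale = FALSE) {
  n <- nrow(X); p <- ncol(X); m <- ncol(Y)
  kmax <- min(n - 1L, p)
  if (ncomp < 1L || ncomp > kmax)
    .stopf("'nComponents' must be in [1, %d] (min(n - 1, predictors)), got %d",
           kmax, ncomp)
  xm <- colMeans(X); ym <- colMeans(Y)
  Xc <- sweep(X, 2L, xm, "-")
  xs <- rep(1, p)
  if (scale) {
    xs <- apply(Xc, 2L, sd)
    xs[xs == 0] <- 1
    Xc <- sweep(Xc, 2L, xs, "/")
  }
  Yc <- sweep(Y, 2L, ym, "-")
  ssX <- sum(Xc^2); ssY <- sum(Yc^2)
  # sign anchor: highest-variance original response column, ties -> lowest
  j0 <- which.max(apply(Yc, 2L, function(y) sum(y^2)))

  W <- matrix(0, p, ncomp); P <- matrix(0, p, ncomp)
  Q <- matrix(0, m, ncomp); Tm <- matrix(0, n, ncomp)
  tt <- numeric(ncomp)
  Ydef <- Yc
  covFloor <- 1e-10 * sqrt(ssX * ssY)
  k <- 0L
  for (a in seq_len(ncomp)) {
    Z <- crossprod(Xc, Ydef)                       # X_a' Y_a, lazily deflated
    if (k > 0L)
      Z <- Z - P[, 1:k, drop = FALSE] %*%
        crossprod(Tm[, 1:k, drop = FALSE], Ydef)
    M <- crossprod(Z)
    eg <- eigen(M, symmetric = TRUE)
    lam <- eg$values[1]
    if (!is.finite(lam) || sqrt(max(lam, 0)) <= covFloor) {
      warning("stopping after ", k, " component(s): remaining X-Y covariance",
              " is numerically zero")
      break
    }
    qdir <- eg$vectors[, 1]
    if (qdir[j0] < 0 || (qdir[j0] == 0 && qdir[which(qdir != 0)[1]] < 0))
      qdir <- -qdir
    w <- Z %*% qdir
    w <- w / sqrt(sum(w^2))
    t <- Xc %*% w
    if (k > 0L)
      t <- t - Tm[, 1:k, drop = FALSE] %*%
        crossprod(P[, 1:k, drop = FALSE], w)
    tta <- sum(t^2)
    if (tta <= .Machine$double.eps * ssX) {
      warning("stopping after ", k, " component(s): degenerate score")
      break
    }
    pa <- crossprod(Xc, t)
    if (k > 0L)
      pa <- pa - P[, 1:k, drop = FALSE] %*%
        crossprod(Tm[, 1:k, drop = FALSE], t)
    pa <- pa / tta
    qa <- crossprod(Ydef, t) / tta
    Ydef <- Ydef - t %*% t(qa)
    k <- a
    W[, a] <- w; P[, a] <- pa; Q[, a] <- qa; Tm[, a] <- t; tt[a] <- tta
  }
  if (k == 0L) {
    return(list(k = 0L, xm = xm, ym = ym, xs = xs,
                W = W[, 0, drop = FALSE], P = P[, 0, drop = FALSE],
                Q = Q[, 0, drop = FALSE], T = Tm[, 0, drop = FALSE],
                beta = matrix(0, p, m, dimnames = list(colnames(X),
                                                       colnames(Y))),
                cumVarX = numeric(0), cumVarY = numeric(0)))
  }
  W <- W[, 1:k, drop = FALSE]; P <- P[, 1:k, drop = FALSE]
  Q <- Q[, 1:k, drop = FALSE]; Tm <- Tm[, 1:k, drop = FALSE]
  tt <- tt[1:k]
  beta <- W %*% solve(crossprod(P, W), t(Q))
  # scores are orthogonal, so per-component captured sums of squares add
  cumVarX <- cumsum(tt * colSums(P^2)) / ssX
  cumVarY <- if (ssY > 0) cumsum(tt * colSums(Q^2)) / ssY
             else rep(0, k)
  dimnames(beta) <- list(colnames(X), colnames(Y))
  list(k = k, xm = xm, ym = ym, xs = xs, W = W, P = P, Q = Q, T = Tm,
       beta = beta, cumVarX = cumVarX, cumVarY = cumVarY)
}

# Gram-space formulation of the same fit, for n << p. Works entirely
# with the centered training Gram matrix K = Xc Xc' (subjects space):
# per component the Y-side direction comes from the dominant eigenvector
# of Ydef' K_a Ydef (= Z'Z above), scores are t = K_a u / ||X_a'u|| with
# ||X_a'u||^2 = u' K_a u, and K is deflated by the score projector.
# Predictions for a new subject need only its centered Gram row
# g_i = (x_new - xm)'(x_i - xm):  y_hat = y_mean + g' C  with
# C = Unorm (P'W)^{-1} Q' and P'W = diag(1/tt) T' K0 Unorm. Identical
# (up to floating point) to .plsFit; asserted against it in the tests.
.plsGramFit <- function(K0, Yc, ncomp, ssY = sum(Yc^2)) {
  n <- nrow(K0); m <- ncol(Yc)
  ssX <- sum(diag(K0))
  j0 <- which.max(colSums(Yc^2))
  Un <- matrix(0, n, ncomp); Tm <- matrix(0, n, ncomp)
  Q <- matrix(0, m, ncomp); tt <- numeric(ncomp)
  K <- K0; Ydef <- Yc
  covFloor <- 1e-10 * sqrt(ssX * ssY)
  k <- 0L
  for (a in seq_len(ncomp)) {
    KY <- K %*% Ydef
    G <- crossprod(Ydef, KY)
    eg <- eigen(G, symmetric = TRUE)
    lam <- eg$values[1]
    if (!is.finite(lam) || sqrt(max(lam, 0)) <= covFloor) break
    qdir <- eg$vectors[, 1]
    if (qdir[j0] < 0 || (qdir[j0] == 0 && qdir[which(qdir != 0)[1]] < 0))
      qdir <- -qdir
    u <- Ydef %*% qdir
    v2 <- drop(crossprod(u, K %*% u))
    if (v2 <= .Machine$double.eps * ssX) break
    t <- (K %*% u) / sqrt(v2)
    tta <- sum(t^2)
    if (tta <= .Machine$double.eps * ssX) break
    qa <- crossprod(Ydef, t) / tta
    Ydef <- Ydef - t %*% t(qa)
    # weight column in subjects space: project u off earlier scores
    ut <- u
    if (k > 0L) for (i in 1:k)
      ut <- ut - Tm[, i] * (sum(Tm[, i] * ut) / tt[i])
    k <- a
    Un[, a] <- ut / sqrt(v2); Tm[, a] <- t; Q[, a] <- qa; tt[a] <- tta
    # deflate K by the score projector on both sides
    Kt <- K %*% t
    K <- K - (tcrossprod(t, Kt) + tcrossprod(Kt, t)) / tta +
      (drop(crossprod(t, Kt)) / tta^2) * tcrossprod(t)
  }
  if (k == 0L)
    return(list(k = 0L, C = matrix(0, n, m), T = Tm[, 0, drop = FALSE]))
  Un <- Un[, 1:k, drop = FALSE]; Tm <- Tm[, 1:k, drop = FALSE]
  Q <- Q[, 1:k, drop = FALSE]; tt <- tt[1:k]
  PW <- (crossprod(Tm, K0 %*% Un)) / tt  # rows scaled by 1/tt
  C <- Un %*% solve(PW, t(Q))
  list(k = k, C = C, T = Tm)
}

#' Fit a multi-response PLS regression
#'
#' Columns of X and Y are centered (no unit-variance scaling of X by
#' default: SUVR voxels share a physical scale); per component the weight
#' vector maximizing the X-score/Y-score covariance is extracted and X is
#' deflated. The regression coefficients `beta` map centered predictors
#' to centered responses. The fit is fully deterministic.
#'
#' @param X a [VoxelData-class] or a subjects x predictors numeric
#'   matrix.
#' @param Y response block from [buildResponseBlock()] (subjects x
#'   responses, must include a `disease` column for classification use).
#' @param nComponents number of latent components, default 10 (the
#'   explained-variance plateau for cohorts of this size). If the
#'   X-Y covariance degenerates earlier, fewer components are returned
#'   with a warning.
#' @param scale also scale predictor columns to unit variance.
#' @return A [PLSModel-class].
#' @export
fitPLS <- function(X, Y, nComponents = 10, scale = FALSE) {
  if (is(X, "VoxelData")) X <- voxelMatrix(X)
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y))
    .stopf("X has %d rows but Y has %d: rows must be aligned subjects",
           nrow(X), nrow(Y))
  if (!is.null(rownames(X)) && !is.null(rownames(Y)) &&
      !identical(rownames(X), rownames(Y)))
    .stopf("X and Y rownames disagree: rows must be aligned subjects")
  f <- .plsFit(X, Y, as.integer(nComponents), scale = scale)
  new("PLSModel", nComponents = f$k, xMean = f$xm, yMean = f$ym,
      xScale = f$xs, xWeights = f$W, xLoadings = f$P, yLoadings = f$Q,
      xScores = f$T, beta = f$beta, cumVarX = f$cumVarX,
      cumVarY = f$cumVarY,
      responseNames = colnames(Y))
}

#' Predict the response block for new subjects
#'
#' `y_hat = y_mean + (x_new - x_mean) beta` (with the training centering
#' and, if used, scaling).
#'
#' @param object a [PLSModel-class].
#' @param newdata predictor matrix (subjects x voxels) or a single
#'   predictor vector.
#' @param ... ignored.
#' @return matrix of predicted responses (subjects x responses).
#' @export
setMethod("predict", "PLSModel", function(object, newdata, ...) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1L)
  if (ncol(newdata) != length(object@xMean))
    .stopf("newdata has %d predictors, model expects %d", ncol(newdata),
           length(object@xMean))
  Xc <- sweep(sweep(newdata, 2L, object@xMean, "-"), 2L, object@xScale, "/")
  out <- Xc %*% object@beta
  out <- sweep(out, 2L, object@yMean, "+")
  colnames(out) <- object@responseNames
  out
})

#' @rdname diseaseScore
setMethod("diseaseScore", "PLSModel", function(object, newdata) {
  if (!"disease" %in% object@responseNames)
    .stopf("model has no 'disease' response")
  drop(predict(object, newdata)[, "disease"])
})

#' Regression coefficients of a fitted PLS model
#'
#' @param object a [PLSModel-class].
#' @param ... ignored.
#' @return predictors x responses beta matrix (on centered scales).
#' @export
setMethod("coef", "PLSModel", function(object, ...) object@beta)

#' @rdname explainedVariance
setMethod("explainedVariance", "PLSModel", function(object) {
  data.frame(component = seq_len(object@nComponents),
             cum_var_x = object@cumVarX, cum_var_y = object@cumVarY)
})

#' Smallest component count at the explained-variance plateau
#'
#' Automatic alternative to the fixed default: the smallest k whose
#' marginal gain in cumulative explained Y variance drops below
#' `tolGain` (default 1%).
#'
#' @param model a [PLSModel-class].
#' @param tolGain marginal-gain cutoff as a fraction, default 0.01.
#' @return integer component count.
#' @export
plateauComponents <- function(model, tolGain = 0.01) {
  cv <- model@cumVarY
  if (length(cv) <= 1L) return(length(cv))
  gain <- diff(c(0, cv))
  idx <- which(gain < tolGain)
  if (length(idx) == 0L) length(cv) else max(1L, idx[1] - 1L)
}

#' @rdname betaMap
setMethod("betaMap", "PLSModel", function(object, voxelData,
                                          response = "disease") {
  if (!response %in% object@responseNames)
    .stopf("unknown response '%s'; model has: %s", response,
           paste(object@responseNames, collapse = ", "))
  if (nrow(voxelData) != nrow(object@beta))
    .stopf("model has %d voxel coefficients but VoxelData has %d voxels",
           nrow(object@beta), nrow(voxelData))
  backProject(voxelData, object@beta[, response])
})
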
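# Voxel-wise two-sample group statistics with permutation-calibrated
# cluster-level FDR, plus the scalar summary-statistic tests used for
# demographic tables.

#' Pooled-variance Student's t from group summaries
#'
#' Computes the two-sample Student t statistic for (group2 - group1) from
#' means, standard deviations and sizes, with `df = n1 + n2 - 2`. This is
#' the statistic reported in demographic comparison tables.
#'
#' @param mean1,sd1,n1 summary statistics of group 1.
#' @param mean2,sd2,n2 summary statistics of group 2.
#' @return The t statistic (a single number). Zero pooled variance with
#'   equal means gives `t = 0`; with unequal means it is an error.
#' @examples
#' # illness-duration contrast of a 27-vs-16 cohort
#' tFromSummary(8.8, 8.1, 27, 16.6, 8.6, 16)  # about 3.0
#' @export
tFromSummary <- function(mean1, sd1, n1, mean2, sd2, n2) {
  if (n1 < 2 || n2 < 2) .stopf("both groups need n >= 2")
  if (sd1 < 0 || sd2 < 0) .stopf("standard deviations must be >= 0")
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
  diff <- mean2 - mean1
  if (sp2 == 0) {
    if (diff == 0) return(0)
    .stopf("zero pooled variance with unequal means: t is infinite")
  }
  diff / sqrt(sp2 * (1 / n1 + 1 / n2))
}

#' Pearson's chi-squared statistic for a 2x2 table
#'
#' `N (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))`, without continuity
#' correction.
#'
#' @param a,b,c,d cell counts (row-wise: `a b / c d`).
#' @return The chi-squared statistic.
#' @export
pearsonChi2 <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (any(counts < 0)) .stopf("counts must be >= 0")
  n <- sum(counts)
  if (n == 0) .stopf("empty table")
  margins <- c(a + b, c + d, a + c, b + d)
  if (any(margins == 0))
    .stopf("undefined statistic: a table margin is zero")
  n * (a * d - b * c)^2 / prod(margins)
}

#' One-tailed or two-tailed critical Student t threshold
#'
#' @param df degrees of freedom (>= 1).
#' @param alpha significance level in (0, 1), default 0.05.
#' @param tails `"one"` or `"two"`.
#' @return The upper-tail quantile `qt(1 - alpha, df)` (one-tailed) or
#'   `qt(1 - alpha/2, df)` (two-tailed).
#' @examples
#' criticalT(41, 0.05, "one")  # 1.68, the cluster-forming threshold at n = 43
#' @export
criticalT <- function(df, alpha = 0.05, tails = c("one", "two")) {
  tails <- match.arg(tails)
  if (df < 1) .stopf("'df' must be >= 1")
  if (alpha <= 0 || alpha >= 1) .stopf("'alpha' must be in (0, 1)")
  qt(1 - if (tails == "one") alpha else alpha / 2, df)
}

# Vectorized pooled t over the columns of a subjects x voxels matrix.
# Returns list(t, df). Zero-variance columns: t = 0 if group means agree,
# NA (with optional warning) otherwise.
.tColumns <- function(X, labels, warnDegenerate = TRUE) {
  g1 <- labels == 1
  n1 <- sum(g1); n2 <- sum(!g1)
  if (n1 < 2 || n2 < 2) .stopf("both groups need at least 2 subjects")
  df <- n1 + n2 - 2
  s1 <- colSums(X[g1, , drop = FALSE])
  s2 <- colSums(X[!g1, , drop = FALSE])
  q1 <- colSums(X[g1, , drop = FALSE]^2)
  q2 <- colSums(X[!g1, , drop = FALSE]^2)
  m1 <- s1 / n1; m2 <- s2 / n2
  sp2 <- (q1 - n1 * m1^2 + q2 - n2 * m2^2) / df
  sp2[sp2 < 0] <- 0  # guard rounding
  diff <- m1 - m2    # BD minus MDD
  tv <- diff / sqrt(sp2 * (1 / n1 + 1 / n2))
  zero <- sp2 == 0
  if (any(zero)) {
    tv[zero & diff == 0] <- 0
    bad <- zero & diff != 0
    if (any(bad)) {
      tv[bad] <- NA_real_
      if (warnDegenerate)
        warning(sum(bad), " zero-variance voxel(s) with unequal means excluded")
    }
  }
  list(t = tv, df = as.integer(df))
}

#' Voxel-wise pooled two-sample t map (BD minus MDD)
#'
#' Applies the pooled-variance Student t test independently at every
#' masked voxel; the degrees of freedom are constant across voxels.
#'
#' @param voxelData a [VoxelData-class] (subjects in columns).
#' @param labels diagnosis labels (1 = BD, 0 = MDD); defaults to the
#'   `diagnosis` column of the subject table.
#' @param direction tail annotation carried on the result, default
#'   `"two_sided"`.
#' @return A [TStatMap-class].
#' @export
voxelwiseTTest <- function(voxelData, labels = NULL,
                           direction = "two_sided") {
  stopifnot(is(voxelData, "VoxelData"))
  if (is.null(labels)) labels <- subjectTable(voxelData)$diagnosis
  X <- voxelMatrix(voxelData)
  res <- .tColumns(X, labels)
  md <- S4Vectors::metadata(voxelData)
  arr <- array(NA_real_, md$gridShape)
  arr[SummarizedExperiment::rowData(voxelData)$index] <- res$t
  new("TStatMap", tValues = arr, df = res$df, direction = direction)
}

# Connected components of a set of voxels under 26-connectivity, by
# iterative minimum-label propagation (converges in at most the cluster
# diameter). `coords`: k x 3 integer matrix; `dims`: grid shape.
# Returns integer component labels 1..ncomp (renumbered, order of first
# appearance) of length k.
.labelComponents <- function(coords, dims) {
  k <- nrow(coords)
  if (k == 0L) return(integer(0))
  if (k == 1L) return(1L)
  d12 <- dims[1] * dims[2]
  key <- (coords[, 3] - 1L) * d12 + (coords[, 2] - 1L) * dims[1] + coords[, 1]
  id <- integer(prod(dims))
  id[key] <- seq_len(k)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  # neighbor compact ids, k x 26 (0 = none)
  nbr <- matrix(0L, k, nrow(offs))
  for (o in seq_len(nrow(offs))) {
    nx <- coords[, 1] + offs[o, 1]
    ny <- coords[, 2] + offs[o, 2]
    nz <- coords[, 3] + offs[o, 3]
    ok <- nx >= 1L & nx <= dims[1] & ny >= 1L & ny <= dims[2] &
      nz >= 1L & nz <= dims[3]
    nk <- (nz[ok] - 1L) * d12 + (ny[ok] - 1L) * dims[1] + nx[ok]
    nbr[ok, o] <- id[nk]
  }
  # keep only realized edges; propagate minimum labels to convergence
  src <- rep(seq_len(k), ncol(nbr))
  dst <- as.vector(nbr)
  keep <- dst > 0L
  src <- src[keep]; dst <- dst[keep]
  lab <- seq_len(k)
  repeat {
    sel <- lab[dst] < lab[src]
    if (!any(sel)) break
    # duplicate targets resolve over iterations; labels only decrease
    lab[src[sel]] <- lab[dst[sel]]
  }
  match(lab, unique(lab))
}

# Precomputed 26-neighbor table over all mask voxels: row v holds the
# compact ids of v's in-mask neighbors (0 = none), so per-permutation
# component labeling reduces to subsetting plus label propagation.
.neighborTable <- function(coords, dims) {
  k <- nrow(coords)
  d12 <- dims[1] * dims[2]
  key <- (coords[, 3] - 1L) * d12 + (coords[, 2] - 1L) * dims[1] + coords[, 1]
  id <- integer(prod(dims))
  id[key] <- seq_len(k)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  nbr <- matrix(0L, k, nrow(offs))
  for (o in seq_len(nrow(offs))) {
    nx <- coords[, 1] + offs[o, 1]
    ny <- coords[, 2] + offs[o, 2]
    nz <- coords[, 3] + offs[o, 3]
    ok <- nx >= 1L & nx <= dims[1] & ny >= 1L & ny <= dims[2] &
      nz >= 1L & nz <= dims[3]
    nbr[ok, o] <- id[(nz[ok] - 1L) * d12 + (ny[ok] - 1L) * dims[1] + nx[ok]]
  }
  nbr
}

# One-slot cache: simulation studies call clusterFDR repeatedly on the
# same grid and mask, for which the neighbor table is identical.
.nbrCache <- new.env(parent = emptyenv())
.neighborTableCached <- function(coords, dims) {
  if (!is.null(.nbrCache$dims) && identical(.nbrCache$dims, dims) &&
      identical(.nbrCache$coords, coords))
    return(.nbrCache$nbr)
  nbr <- .neighborTable(coords, dims)
  .nbrCache$dims <- dims; .nbrCache$coords <- coords; .nbrCache$nbr <- nbr
  nbr
}

# Max component size among a suprathreshold subset (compact voxel ids).
.maxClusterSizeFast <- function(supraIdx, nbrAll) {
  k <- length(supraIdx)
  if (k == 0L) return(0L)
  if (k == 1L) return(1L)
  local <- integer(nrow(nbrAll))
  local[supraIdx] <- seq_len(k)
  nb <- nbrAll[supraIdx, , drop = FALSE]
  pos <- which(nb > 0L)
  nbl <- matrix(0L, k, ncol(nb))
  nbl[pos] <- local[nb[pos]]
  keep <- nbl > 0L
  src <- row(nbl)[keep]; dst <- nbl[keep]
  if (length(src) == 0L) return(1L)
  lab <- seq_len(k)
  repeat {
    sel <- lab[dst] < lab[src]
    if (!any(sel)) break
    lab[src[sel]] <- lab[dst[sel]]
  }
  max(tabulate(lab))
}

#' Cluster-level FDR on a one-tailed voxel-wise t map
#'
#' Thresholds the voxel-wise t map at the one-tailed critical value,
#' labels suprathreshold voxels into 26-connected clusters, assigns each
#' cluster a permutation p-value (the tail probability of the maximum
#' cluster size under diagnosis-label shuffling), and applies
#' Benjamini-Hochberg across clusters at level `q`. Clusters whose
#' adjusted p-value is at most `q` are kept.
#'
#' @param voxelData a [VoxelData-class] restricted to the analysis mask
#'   (e.g. the gray-matter stand-in intersected with the signal mask).
#' @param direction `"BD_gt_MDD"` (threshold `t > critical`) or
#'   `"BD_lt_MDD"` (`t < -critical`).
#' @param labels diagnosis labels; defaults to the subject table.
#' @param clusterAlpha one-tailed cluster-forming alpha, default 0.05.
#' @param q FDR level across clusters, default 0.05.
#' @param nPermutations number of label permutations, default 1000.
#' @param seed RNG seed for the permutations.
#' @return list with `table` (data.frame: `label`, `size`, `peak_t`,
#'   `p_cluster`, `q_value`, `kept`), `labels` (integer array: cluster id
#'   per voxel, 0 elsewhere), `threshold` (the critical t used),
#'   `direction`, and `nPermutations`. An empty table (zero rows) means
#'   no suprathreshold voxels.
#' @export
clusterFDR <- function(voxelData, direction = c("BD_gt_MDD", "BD_lt_MDD"),
                       labels = NULL, clusterAlpha = 0.05, q = 0.05,
                       nPermutations = 1000, seed = 1L) {
  direction <- match.arg(direction)
  sc <- .clusterScaffold(voxelData, labels, clusterAlpha, nPermutations,
                         seed)
  .clusterOneDirection(sc, direction, q)
}

#' @rdname clusterFDR
#' @details `clusterFDRBoth()` runs both one-tailed analyses on a shared
#'   set of label permutations and returns a named list
#'   (`up` = BD > MDD, `down` = BD < MDD).
#' @export
clusterFDRBoth <- function(voxelData, labels = NULL, clusterAlpha = 0.05,
                           q = 0.05, nPermutations = 1000, seed = 1L) {
  sc <- .clusterScaffold(voxelData, labels, clusterAlpha, nPermutations,
                         seed)
  list(up = .clusterOneDirection(sc, "BD_gt_MDD", q),
       down = .clusterOneDirection(sc, "BD_lt_MDD", q))
}

# Shared machinery: observed t map, critical threshold, neighbor table
# and the voxels x permutations matrix of permuted t statistics.
.clusterScaffold <- function(voxelData, labels, clusterAlpha,
                             nPermutations, seed) {
  stopifnot(is(voxelData, "VoxelData"))
  if (is.null(labels)) labels <- subjectTable(voxelData)$diagnosis
  X <- voxelMatrix(voxelData)
  md <- S4Vectors::metadata(voxelData)
  dims <- md$gridShape
  rd <- SummarizedExperiment::rowData(voxelData)
  coords <- cbind(rd$i, rd$j, rd$k)
  obs <- .tColumns(X, labels)
  thr <- criticalT(obs$df, clusterAlpha, "one")
  n1 <- sum(labels == 1)
  n <- length(labels)
  n2 <- n - n1
  X2 <- X^2
  S <- colSums(X); S2 <- colSums(X2)
  seFac <- sqrt(1 / n1 + 1 / n2)
  TVt <- withSeed(seed, {
    P <- matrix(0, n, nPermutations)
    for (b in seq_len(nPermutations))
      P[sample.int(n, n1), b] <- 1
    S1 <- crossprod(X, P)               # voxels x permutations
    Q1 <- crossprod(X2, P)
    M1 <- S1 / n1
    M2 <- (S - S1) / n2                 # S recycles down columns
    SP2 <- ((Q1 - n1 * M1^2) + (S2 - Q1 - n2 * M2^2)) / obs$df
    SP2[SP2 < 0] <- 0
    TV <- (M1 - M2) / (sqrt(SP2) * seFac)
    TV[SP2 == 0] <- 0
    TV
  })
  list(obs = obs, thr = thr, dims = dims, coords = coords,
       index = rd$index, nbrAll = .neighborTableCached(coords, dims),
       TVt = TVt, nPermutations = nPermutations)
}

.clusterOneDirection <- function(sc, direction, q) {
  up <- direction == "BD_gt_MDD"
  thr <- sc$thr
  labArr <- array(0L, sc$dims)
  supra <- if (up) !is.na(sc$obs$t) & sc$obs$t > thr
           else !is.na(sc$obs$t) & sc$obs$t < -thr
  empty <- list(table = data.frame(label = integer(0), size = integer(0),
                                   peak_t = numeric(0), p_cluster = numeric(0),
                                   q_value = numeric(0), kept = logical(0)),
                labels = labArr, threshold = thr, direction = direction,
                nPermutations = sc$nPermutations)
  if (!any(supra)) return(empty)
  lab <- .labelComponents(sc$coords[supra, , drop = FALSE], sc$dims)
  sizes <- tabulate(lab)
  peak <- vapply(seq_along(sizes), function(cl) {
    tv <- sc$obs$t[supra][lab == cl]
    if (up) max(tv) else min(tv)
  }, numeric(1))
  labArr[sc$index[supra]] <- lab
  permMax <- vapply(seq_len(sc$nPermutations), function(b) {
    tv <- sc$TVt[, b]
    .maxClusterSizeFast(if (up) which(tv > thr) else which(tv < -thr),
                        sc$nbrAll)
  }, integer(1))
  pClust <- vapply(sizes, function(s) (1 + sum(permMax >= s)) /
                     (sc$nPermutations + 1), numeric(1))
  qVal <- p.adjust(pClust, method = "BH")
  kept <- .fdrKeep(pClust, q)
  list(table = data.frame(label = seq_along(sizes), size = sizes,
                          peak_t = peak, p_cluster = pClust, q_value = qVal,
                          kept = kept),
       labels = labArr, threshold = thr, direction = direction,
       nPermutations = sc$nPermutations)
}

# Benjamini-Hochberg step-up decision: reject i iff adjusted p <= q.
.fdrKeep <- function(p, q) p.adjust(p, method = "BH") <= q

#' Per-subject mean SUVR inside (region x significance mask)
#'
#' For each labelled region, averages every subject's SUVR over the
#' voxels the region shares with the significance mask; regions with an
#' empty intersection are omitted.
#'
#' @param volumes list of SUVR [VolumeGrid-class] objects.
#' @param significanceMask a [VoxelMask-class] (e.g. the kept-cluster
#'   mask).
#' @param regionLabels a [VolumeGrid-class] of integer region labels
#'   (0 = background), aligned with the data.
#' @param subjectIds optional subject identifiers, defaults to `S001`...
#' @return data.frame with columns `subject_id`, `region`, `mean_suvr`
#'   (long format). Empty (with a warning) if no region overlaps the
#'   mask.
#' @export
roiSummarize <- function(volumes, significanceMask, regionLabels,
                         subjectIds = NULL) {
  stopifnot(is(significanceMask, "VoxelMask"), is(regionLabels, "VolumeGrid"))
  labs <- regionLabels@values
  if (!identical(dim(labs), dim(significanceMask@indicator)))
    .stopf("region labels and mask must share the grid")
  if (is.null(subjectIds))
    subjectIds <- sprintf("S%03d", seq_along(volumes))
  regions <- sort(unique(labs[labs > 0 & significanceMask@indicator]))
  if (length(regions) == 0L) {
    warning("no region overlaps the significance mask")
    return(data.frame(subject_id = character(0), region = integer(0),
                      mean_suvr = numeric(0)))
  }
  out <- do.call(rbind, lapply(regions, function(r) {
    idx <- which(labs == r & significanceMask@indicator)
    data.frame(subject_id = subjectIds,
               region = as.integer(r),
               mean_suvr = vapply(volumes, function(v) mean(v@values[idx]),
                                  numeric(1)))
  }))
  rownames(out) <- NULL
  out
}
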
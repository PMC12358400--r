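# Shared fixture builders. Everything is generated in code at test time;
# sizes are kept at desk scale so single tests run in seconds.

# A small cohort configuration for fast end-to-end tests.
tinyConfig <- function(seed = 1, nBD = 6, nMDD = 8, delta = 0.1,
                       noiseSd = 0.5, gridShape = c(12, 12, 12), ...) {
  effects <- if (delta > 0) {
    c0 <- (gridShape + 1) / 2
    list(effectSpec(1L, -1, delta, "sphere", center = c0 + c(0, 2, 0),
                    size = 2),
         effectSpec(2L, +1, delta, "sphere", center = c0 - c(0, 3, 0),
                    size = 2))
  } else list()
  cohortConfig(nBD = nBD, nMDD = nMDD, gridShape = gridShape,
               voxelSize = 4, noiseSd = noiseSd, effects = effects,
               siteLabels = c("siteA", "siteB"), seed = seed, ...)
}

# A random VolumeGrid on a small grid.
randomVolume <- function(dim = c(5, 5, 5), seed = 1, voxelSize = 2,
                         positive = TRUE) {
  set.seed(seed)
  v <- array(rnorm(prod(dim), mean = if (positive) 5 else 0), dim)
  VolumeGrid(v, voxelSize)
}

# Stack a list of random volumes into a VoxelData over the full grid.
randomVoxelData <- function(nSubjects = 8, dim = c(4, 4, 4), seed = 1,
                            diagnosis = NULL) {
  set.seed(seed)
  vols <- lapply(seq_len(nSubjects), function(s)
    VolumeGrid(array(rnorm(prod(dim), mean = 2), dim), 2))
  if (is.null(diagnosis))
    diagnosis <- rep(c(1L, 0L), length.out = nSubjects)
  subjects <- data.frame(
    subject_id = sprintf("S%02d", seq_len(nSubjects)),
    diagnosis = diagnosis,
    age = 40 + seq_len(nSubjects), sex = rep(0:1, length.out = nSubjects),
    site = rep(c("a", "b"), length.out = nSubjects),
    duration_of_illness = seq_len(nSubjects), madrs = 10 + seq_len(nSubjects),
    ymrs = rep(2L, nSubjects))
  stackMatrix(vols, brainVoxelMask(vols[[1]]), subjects)
}

# Random PLS problem (tall or wide); Y has m responses correlated with X.
randomPLSProblem <- function(n = 20, p = 15, m = 3, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  B <- matrix(rnorm(p * m), p, m)
  Y <- X %*% B * 0.5 + matrix(rnorm(n * m), n, m)
  colnames(Y) <- c("disease", paste0("y", seq_len(m - 1)))[seq_len(m)]
  colnames(X) <- paste0("x", seq_len(p))
  list(X = X, Y = Y)
}
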
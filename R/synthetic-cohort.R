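# Synthetic PET-like SUVR cohorts with known ground truth. The generator
# is the test bed for every downstream stage: group effects, site gain
# offsets, covariates and noise are all embedded under a fixed seed, so
# recovery can be asserted exactly or statistically.

.defaultEffects <- function(gridShape) {
  # Two opposite-signed contiguous regions inside the ellipsoidal brain
  # mask: an anterior/"frontal" BD-lower sphere and a posterior
  # "parieto-occipital" BD-higher sphere, 0.1 SUVR each (the scale of
  # reported between-group SUVR differences).
  c0 <- (gridShape + 1) / 2
  r <- max(2, round(min(gridShape) / 8))
  list(
    effectSpec(1L, -1, 0.1, "sphere",
               center = c0 + c(0, round(gridShape[2] * 0.22), 0), size = r),
    effectSpec(2L, +1, 0.1, "sphere",
               center = c0 + c(0, -round(gridShape[2] * 0.22),
                               round(gridShape[3] * 0.08)), size = r))
}

#' Configure a synthetic SUVR cohort
#'
#' Defaults describe the cohort the package's validation suite simulates:
#' 16 BD and 27 MDD subjects scanned at four sites on a 24x24x24 grid of
#' 4 mm voxels, smoothed with an 8 mm FWHM kernel. The voxel noise SD of
#' 0.5 (pre-smoothing, on a baseline near 1) leaves roughly 0.1 SUVR of
#' between-subject variability after smoothing, matching the magnitude
#' seen in real SUVR maps.
#'
#' @param nBD,nMDD group sizes (defaults 16 and 27).
#' @param gridShape voxels per axis (each >= 8).
#' @param voxelSize voxel edge length in mm.
#' @param noiseSd SD of additive Gaussian voxel noise, SUVR units,
#'   applied before smoothing.
#' @param effects list of [EffectSpec-class]; `NULL` gives the two default
#'   opposite-signed regions. Use `list()` for a null cohort.
#' @param siteLabels site names.
#' @param siteOffsetSd SD of the per-site multiplicative gain offset.
#' @param smoothFwhm generator smoothing FWHM, mm.
#' @param sexProb probability that `sex == 1`.
#' @param doiDependent draw duration of illness from
#'   diagnosis-dependent distributions (default) or independently.
#' @param seed integer RNG seed.
#' @return A validated [CohortConfig-class].
#' @examples
#' cfg <- cohortConfig(seed = 1)
#' cfg
#' @export
cohortConfig <- function(nBD = 16, nMDD = 27, gridShape = c(24, 24, 24),
                         voxelSize = 4, noiseSd = 0.5, effects = NULL,
                         siteLabels = c("siteA", "siteB", "siteC", "siteD"),
                         siteOffsetSd = 0.02, smoothFwhm = 8,
                         sexProb = 0.45, doiDependent = TRUE, seed = 1L) {
  gridShape <- rep_len(as.integer(gridShape), 3L)
  if (is.null(effects))
    effects <- .defaultEffects(gridShape)
  new("CohortConfig", nBD = as.integer(nBD), nMDD = as.integer(nMDD),
      gridShape = gridShape, voxelSize = rep_len(as.numeric(voxelSize), 3L),
      noiseSd = as.numeric(noiseSd), effects = effects,
      siteLabels = as.character(siteLabels),
      siteOffsetSd = as.numeric(siteOffsetSd),
      smoothFwhm = as.numeric(smoothFwhm), sexProb = as.numeric(sexProb),
      doiDependent = isTRUE(doiDependent), seed = as.integer(seed))
}

# Inscribed-ellipsoid brain mask.
.ellipsoidMask <- function(gridShape) {
  c0 <- (gridShape + 1) / 2
  r <- gridShape / 2 - 0.5
  i <- slice.index(array(0, gridShape), 1)
  j <- slice.index(array(0, gridShape), 2)
  k <- slice.index(array(0, gridShape), 3)
  ((i - c0[1]) / r[1])^2 + ((j - c0[2]) / r[2])^2 +
    ((k - c0[3]) / r[3])^2 <= 1
}

# Smooth low-frequency baseline uptake: a constant plus three broad
# Gaussian bumps, so SUVR is spatially non-uniform and the > 0.9 signal
# mask bites.
.baselineField <- function(gridShape) {
  i <- slice.index(array(0, gridShape), 1)
  j <- slice.index(array(0, gridShape), 2)
  k <- slice.index(array(0, gridShape), 3)
  bump <- function(c, s, a) {
    a * exp(-(((i - c[1])^2 + (j - c[2])^2 + (k - c[3])^2) / (2 * s^2)))
  }
  d <- gridShape
  1 +
    bump(d * c(0.50, 0.50, 0.50), min(d) / 2.0,  0.90) +
    bump(d * c(0.35, 0.22, 0.35), min(d) / 5.0, -0.25) +
    bump(d * c(0.62, 0.72, 0.40), min(d) / 5.0,  0.15)
}

# Logical indicator of one effect region, restricted to the brain mask.
.effectIndicator <- function(effect, gridShape, mask) {
  i <- slice.index(array(0, gridShape), 1)
  j <- slice.index(array(0, gridShape), 2)
  k <- slice.index(array(0, gridShape), 3)
  c0 <- effect@center
  ind <- if (effect@shape == "sphere") {
    (i - c0[1])^2 + (j - c0[2])^2 + (k - c0[3])^2 <= effect@size[1]^2
  } else {
    hw <- rep_len(effect@size, 3L)
    abs(i - c0[1]) <= hw[1] & abs(j - c0[2]) <= hw[2] & abs(k - c0[3]) <= hw[3]
  }
  list(indicator = ind & mask, insideMask = all(!ind | mask))
}

#' Generate a synthetic SUVR cohort
#'
#' Each subject's volume is built as
#' `smooth(baseline * (1 + site offset) + noise) + diagnosis * effects`,
#' then (optionally) SUVR-normalized to in-brain mean 1. Effects are added
#' after smoothing so that, with zero noise and zero site offsets, the
#' group-mean difference inside every effect region equals
#' `sign * delta` exactly (the ground truth the test suite asserts);
#' smoothing still shapes the baseline and the noise, as the scanner's
#' point-spread function would.
#'
#' @param config a [CohortConfig-class].
#' @param normalize SUVR-normalize the volumes (default `TRUE`); set
#'   `FALSE` to obtain the pre-normalization uptake volumes.
#' @return list with elements `subjects` (data.frame: `subject_id`,
#'   `diagnosis` (1 = BD, 0 = MDD), `age`, `sex`, `site`,
#'   `duration_of_illness`, `madrs`, `ymrs`), `volumes` (list of
#'   [VolumeGrid-class], same order), and `groundTruth` (the effect list).
#' @examples
#' coh <- generateCohort(cohortConfig(nBD = 2, nMDD = 3,
#'                                    gridShape = c(12, 12, 12), seed = 7))
#' table(coh$subjects$diagnosis)
#' @export
generateCohort <- function(config, normalize = TRUE) {
  stopifnot(is(config, "CohortConfig"))
  validObject(config)
  d <- config@gridShape
  mask <- .ellipsoidMask(d)
  effInd <- lapply(config@effects, .effectIndicator, gridShape = d,
                   mask = mask)
  for (e in seq_along(effInd)) {
    if (!effInd[[e]]$insideMask)
      .stopf("effects: region %d extends outside the brain mask",
             config@effects[[e]]@regionId)
  }
  if (length(effInd) > 1L) {
    tot <- Reduce(`+`, lapply(effInd, function(x) x$indicator * 1L))
    if (any(tot > 1L))
      .stopf("effects: regions must be pairwise disjoint")
  }
  effectField <- array(0, d)
  for (e in seq_along(effInd))
    effectField <- effectField + config@effects[[e]]@sign *
      config@effects[[e]]@delta * effInd[[e]]$indicator

  baseline <- .baselineField(d)
  n <- config@nBD + config@nMDD

  withSeed(config@seed, {
    siteOffsets <- setNames(rnorm(length(config@siteLabels), 0,
                                  config@siteOffsetSd), config@siteLabels)
    subjects <- .drawSubjects(config)
    volumes <- vector("list", n)
    proto <- VolumeGrid(baseline, config@voxelSize, mask)
    for (s in seq_len(n)) {
      raw <- baseline * (1 + siteOffsets[[subjects$site[s]]]) +
        array(rnorm(prod(d), 0, config@noiseSd), d)
      sm <- gaussianSmooth(VolumeGrid(raw, config@voxelSize, mask),
                           config@smoothFwhm)
      vals <- sm@values + subjects$diagnosis[s] * effectField
      vol <- VolumeGrid(vals, config@voxelSize, mask)
      volumes[[s]] <- if (normalize) computeSUVR(vol) else vol
    }
  })
  list(subjects = subjects, volumes = volumes, groundTruth = config@effects)
}

# Covariates mirror the clinical table of the cohort being emulated:
# comparable ages, depressive-range MADRS in both groups, low YMRS
# (depressive state), and a roughly doubled illness duration in BD when
# doiDependent is TRUE.
.drawSubjects <- function(config) {
  nBD <- config@nBD; nMDD <- config@nMDD
  n <- nBD + nMDD
  diagnosis <- c(rep(1L, nBD), rep(0L, nMDD))
  subject_id <- c(sprintf("BD%03d", seq_len(nBD)),
                  sprintf("MDD%03d", seq_len(nMDD)))
  age <- round(.rtruncnorm(n, mean = 42, sd = 8, lower = 20, upper = 59), 1)
  sex <- as.integer(runif(n) < config@sexProb)
  site <- sample(config@siteLabels, n, replace = TRUE)
  doi <- if (config@doiDependent) {
    round(c(.rtruncnorm(nBD, 16.6, 8.6, lower = 0.5),
            .rtruncnorm(nMDD, 8.8, 8.1, lower = 0.5)), 1)
  } else {
    round(.rtruncnorm(n, 12, 8, lower = 0.5), 1)
  }
  madrs <- as.integer(round(c(.rtruncnorm(nBD, 16.6, 5.7, lower = 8),
                              .rtruncnorm(nMDD, 20.6, 8.8, lower = 8))))
  ymrs <- as.integer(round(.rtruncnorm(n, 2.6, 2.5, lower = 0, upper = 7)))
  data.frame(subject_id = subject_id, diagnosis = diagnosis, age = age,
             sex = sex, site = site, duration_of_illness = doi,
             madrs = madrs, ymrs = ymrs, stringsAsFactors = FALSE)
}

#' Write a cohort to disk (NIfTI volumes + subject table)
#'
#' @param subjects subject table as returned by [generateCohort()].
#' @param volumes list of [VolumeGrid-class], same order as `subjects`.
#' @param outDir output directory (created if needed).
#' @return (invisibly) list with `volumePaths` (one `.nii.gz` per subject)
#'   and `tablePath` (`subjects.csv`).
#' @export
writeCohort <- function(subjects, volumes, outDir) {
  if (length(volumes) != nrow(subjects))
    .stopf("'subjects' (%d rows) and 'volumes' (%d) must have equal length",
           nrow(subjects), length(volumes))
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outDir)) .stopf("cannot create output directory '%s'", outDir)
  paths <- character(length(volumes))
  for (s in seq_along(volumes)) {
    paths[s] <- file.path(outDir, paste0(subjects$subject_id[s], ".nii.gz"))
    writeVolume(volumes[[s]], paths[s])
  }
  tablePath <- file.path(outDir, "subjects.csv")
  write.csv(subjects, tablePath, row.names = FALSE)
  invisible(list(volumePaths = paths, tablePath = tablePath))
}

#' Read a cohort written by [writeCohort()]
#'
#' @param dir directory containing `subjects.csv` and one NIfTI volume per
#'   subject.
#' @return list with `subjects` and `volumes` (brain mask reconstructed as
#'   the all-finite, nonzero support is not stored in NIfTI, so the mask
#'   defaults to all `TRUE`; re-derive analysis masks downstream).
#' @export
readCohort <- function(dir) {
  subjects <- readSubjectTable(file.path(dir, "subjects.csv"))
  volumes <- lapply(subjects$subject_id, function(id)
    readVolume(file.path(dir, paste0(id, ".nii.gz"))))
  list(subjects = subjects, volumes = volumes)
}
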
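#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom stats var sd qt pt rnorm runif p.adjust setNames quantile
#'   qnorm pnorm predict coef
#' @importFrom utils read.csv write.csv head
NULL

#' VolumeGrid: a 3D scalar image with voxel-size metadata and a brain mask
#'
#' The basic volumetric container of the package. `values` holds one scalar
#' per voxel (e.g. summed tracer uptake or SUVR), `voxelSize` the physical
#' edge length of a voxel in millimetres per axis, and `brainMask` a logical
#' array of the same shape marking in-brain voxels. All spatial operations
#' (smoothing, SUVR normalization, masking) act on this class.
#'
#' @slot values 3D numeric array.
#' @slot voxelSize numeric(3), mm per axis, all > 0.
#' @slot brainMask 3D logical array, same shape as `values`, at least one
#'   `TRUE` voxel.
#' @export
setClass("VolumeGrid",
  representation(values = "array", voxelSize = "numeric", brainMask = "array"))

setValidity("VolumeGrid", function(object) {
  msg <- NULL
  if (length(dim(object@values)) != 3L)
    msg <- c(msg, "'values' must be a 3D array")
  if (length(object@voxelSize) != 3L || any(!is.finite(object@voxelSize)) ||
      any(object@voxelSize <= 0))
    msg <- c(msg, "'voxelSize' must be three positive finite numbers (mm)")
  if (!is.logical(object@brainMask))
    msg <- c(msg, "'brainMask' must be logical")
  if (!identical(dim(object@values), dim(object@brainMask)))
    msg <- c(msg, "'values' and 'brainMask' must share dimensions")
  if (is.logical(object@brainMask) && !any(object@brainMask))
    msg <- c(msg, "'brainMask' must contain at least one TRUE voxel")
  if (is.null(msg)) TRUE else msg
})

#' Construct a VolumeGrid
#'
#' @param values 3D numeric array of voxel values.
#' @param voxelSize voxel edge length in mm, recycled to length 3.
#' @param brainMask logical array of the same shape; defaults to all `TRUE`.
#' @return A [VolumeGrid-class] object.
#' @examples
#' v <- VolumeGrid(array(1, c(8, 8, 8)), voxelSize = 4)
#' @export
VolumeGrid <- function(values, voxelSize = c(1, 1, 1), brainMask = NULL) {
  values <- as.array(values)
  storage.mode(values) <- "double"
  if (is.null(brainMask))
    brainMask <- array(TRUE, dim(values))
  new("VolumeGrid", values = values,
      voxelSize = rep_len(as.numeric(voxelSize), 3L),
      brainMask = brainMask)
}

#' VoxelMask: an analysis mask over a VolumeGrid
#'
#' @slot indicator 3D logical array of included voxels.
#' @slot nVoxels number of `TRUE` voxels.
#' @slot origin one of `"signal_mask"`, `"gray_matter"`, `"intersection"`,
#'   `"brain"`.
#' @export
setClass("VoxelMask",
  representation(indicator = "array", nVoxels = "integer", origin = "character"))

setValidity("VoxelMask", function(object) {
  msg <- NULL
  if (!is.logical(object@indicator) || length(dim(object@indicator)) != 3L)
    msg <- c(msg, "'indicator' must be a 3D logical array")
  if (object@nVoxels != sum(object@indicator))
    msg <- c(msg, "'nVoxels' must equal the number of TRUE voxels")
  if (!object@origin %in% c("signal_mask", "gray_matter", "intersection", "brain"))
    msg <- c(msg, "unknown mask 'origin'")
  if (is.null(msg)) TRUE else msg
})

.VoxelMask <- function(indicator, origin) {
  new("VoxelMask", indicator = indicator, nVoxels = sum(indicator),
      origin = origin)
}

#' EffectSpec: a signed ground-truth group effect region
#'
#' Describes one spatially contiguous region where the synthetic cohort
#' embeds an additive group-mean SUVR difference (BD minus MDD) of
#' `sign * delta`.
#'
#' @slot regionId integer label, unique within a configuration.
#' @slot sign +1 (BD higher) or -1 (BD lower).
#' @slot delta magnitude of the additive group-mean difference, SUVR units.
#' @slot shape `"box"` or `"sphere"` in voxel coordinates.
#' @slot center region center, voxel coordinates (length 3).
#' @slot size half-width per axis (box) or radius (sphere), voxels.
#' @export
setClass("EffectSpec",
  representation(regionId = "integer", sign = "numeric", delta = "numeric",
                 shape = "character", center = "numeric", size = "numeric"))

setValidity("EffectSpec", function(object) {
  msg <- NULL
  if (!object@sign %in% c(-1, 1)) msg <- c(msg, "'sign' must be +1 or -1")
  if (object@delta < 0) msg <- c(msg, "'delta' must be >= 0")
  if (!object@shape %in% c("box", "sphere"))
    msg <- c(msg, "'shape' must be 'box' or 'sphere'")
  if (length(object@center) != 3L) msg <- c(msg, "'center' must be length 3")
  if (any(object@size <= 0)) msg <- c(msg, "'size' must be positive")
  if (is.null(msg)) TRUE else msg
})

#' Construct an EffectSpec
#'
#' @param regionId integer label.
#' @param sign +1 or -1 (direction of the BD-minus-MDD difference).
#' @param delta effect magnitude in SUVR units.
#' @param shape `"box"` or `"sphere"`.
#' @param center voxel coordinates of the region center.
#' @param size half-width (box, recycled per axis) or radius (sphere),
#'   in voxels.
#' @return An [EffectSpec-class] object.
#' @export
effectSpec <- function(regionId, sign, delta, shape = c("sphere", "box"),
                       center, size) {
  shape <- match.arg(shape)
  new("EffectSpec", regionId = as.integer(regionId), sign = as.numeric(sign),
      delta = as.numeric(delta), shape = shape,
      center = as.numeric(center), size = as.numeric(size))
}

#' CohortConfig: parameters of the synthetic PET cohort generator
#'
#' Defaults emulate the study conditions of the source cohort this package
#' was designed around: 16 bipolar (BD) and 27 unipolar (MDD) depressed
#' subjects recruited at four sites, with two opposite-signed contiguous
#' effect regions (a "frontal/cerebellar" BD-lower region and a
#' "parieto-occipital" BD-higher region).
#'
#' @slot nBD,nMDD group sizes.
#' @slot gridShape voxels per axis (each >= 8).
#' @slot voxelSize mm per axis.
#' @slot noiseSd SD of additive Gaussian voxel noise (SUVR units,
#'   pre-smoothing).
#' @slot effects list of [EffectSpec-class] ground-truth regions.
#' @slot siteLabels site names; subjects are assigned at random.
#' @slot siteOffsetSd SD of the per-site multiplicative gain offset.
#' @slot smoothFwhm Gaussian smoothing FWHM in mm applied by the generator.
#' @slot sexProb probability of sex == 1.
#' @slot doiDependent if `TRUE`, duration of illness differs by diagnosis
#'   (BD about twice MDD, as observed clinically); if `FALSE` it is drawn
#'   independently of diagnosis.
#' @slot seed integer RNG seed; identical configs give bit-identical cohorts.
#' @export
setClass("CohortConfig",
  representation(nBD = "integer", nMDD = "integer", gridShape = "integer",
                 voxelSize = "numeric", noiseSd = "numeric", effects = "list",
                 siteLabels = "character", siteOffsetSd = "numeric",
                 smoothFwhm = "numeric", sexProb = "numeric",
                 doiDependent = "logical", seed = "integer"))

setValidity("CohortConfig", function(object) {
  msg <- NULL
  if (object@nBD < 1L) msg <- c(msg, "'nBD' must be >= 1")
  if (object@nMDD < 1L) msg <- c(msg, "'nMDD' must be >= 1")
  if (length(object@gridShape) != 3L || any(object@gridShape < 8L))
    msg <- c(msg, "'gridShape' must have three axes, each >= 8 voxels")
  if (any(object@voxelSize <= 0)) msg <- c(msg, "'voxelSize' must be positive")
  if (object@noiseSd < 0) msg <- c(msg, "'noiseSd' must be >= 0")
  if (object@siteOffsetSd < 0) msg <- c(msg, "'siteOffsetSd' must be >= 0")
  if (object@smoothFwhm < 0) msg <- c(msg, "'smoothFwhm' must be >= 0")
  if (object@sexProb < 0 || object@sexProb > 1)
    msg <- c(msg, "'sexProb' must be in [0, 1]")
  if (length(object@siteLabels) < 1L || anyDuplicated(object@siteLabels))
    msg <- c(msg, "'siteLabels' must be nonempty and unique")
  if (!all(vapply(object@effects, is, logical(1), class2 = "EffectSpec")))
    msg <- c(msg, "'effects' must be a list of EffectSpec objects")
  if (is.null(msg)) TRUE else msg
})

#' TStatMap: a voxel-wise two-sample t map
#'
#' @slot tValues 3D array, populated on the analysis mask, `NA` elsewhere.
#' @slot df pooled-t degrees of freedom (n1 + n2 - 2).
#' @slot direction `"BD_gt_MDD"`, `"BD_lt_MDD"` or `"two_sided"` (the tail
#'   the map is intended to be thresholded with; the statistic itself is
#'   always signed BD minus MDD).
#' @export
setClass("TStatMap",
  representation(tValues = "array", df = "integer", direction = "character"))

setValidity("TStatMap", function(object) {
  msg <- NULL
  if (object@df <= 0L) msg <- c(msg, "'df' must be positive")
  if (!object@direction %in% c("BD_gt_MDD", "BD_lt_MDD", "two_sided"))
    msg <- c(msg, "unknown 'direction'")
  if (is.null(msg)) TRUE else msg
})

#' PLSModel: a fitted multi-response partial least squares regression
#'
#' Stores the NIPALS-style PLS2 decomposition of a centered predictor block
#' (voxels) against a centered multi-column response block, together with
#' the implied regression coefficients mapping centered predictors to
#' centered responses.
#'
#' @slot nComponents number of latent components retained.
#' @slot xMean,yMean centering vectors.
#' @slot xScale predictor scale divisors (all 1 unless `scale = TRUE`).
#' @slot xWeights,xLoadings predictors x components matrices.
#' @slot yLoadings responses x components matrix.
#' @slot xScores training-subjects x components score matrix (columns
#'   mutually orthogonal).
#' @slot beta predictors x responses coefficient matrix.
#' @slot cumVarX,cumVarY cumulative fractions of centered X / Y sum of
#'   squares captured by the first k components.
#' @slot responseNames response column names (includes `"disease"`).
#' @export
setClass("PLSModel",
  representation(nComponents = "integer", xMean = "numeric", yMean = "numeric",
                 xScale = "numeric", xWeights = "matrix", xLoadings = "matrix",
                 yLoadings = "matrix", xScores = "matrix", beta = "matrix",
                 cumVarX = "numeric", cumVarY = "numeric",
                 responseNames = "character"))

setValidity("PLSModel", function(object) {
  msg <- NULL
  k <- object@nComponents
  if (k < 0L) msg <- c(msg, "'nComponents' must be >= 0")
  if (k > 0L && ncol(object@xWeights) != k)
    msg <- c(msg, "'xWeights' must have one column per component")
  if (k > 0L && is.unsorted(object@cumVarY + 1e-12))
    msg <- c(msg, "'cumVarY' must be non-decreasing")
  if (is.null(msg)) TRUE else msg
})

#' CVResult: leave-one-pair-out cross-validation predictions
#'
#' @slot foldPredictions data.frame with one row per (fold, test subject):
#'   columns `fold`, `subject_id`, `diagnosis`, `score`.
#' @slot subjectScores data.frame with one row per subject: columns
#'   `subject_id`, `diagnosis`, `n_folds`, `mean_score`.
#' @export
setClass("CVResult",
  representation(foldPredictions = "data.frame", subjectScores = "data.frame"))

setValidity("CVResult", function(object) {
  msg <- NULL
  need <- c("subject_id", "diagnosis", "n_folds", "mean_score")
  if (!all(need %in% names(object@subjectScores)))
    msg <- c(msg, "'subjectScores' missing required columns")
  if (is.null(msg)) TRUE else msg
})

#' VoxelData: subjects-by-voxels SUVR matrix as a SummarizedExperiment
#'
#' Rows are masked voxels (with their grid coordinates in `rowData`),
#' columns are subjects (with the subject table in `colData`); the single
#' assay `"suvr"` holds the masked SUVR values. The grid shape, voxel size
#' and mask origin travel in `metadata` so voxel vectors can be
#' back-projected to [VolumeGrid-class] space.
#'
#' @export
setClass("VoxelData", contains = "SummarizedExperiment")

setValidity("VoxelData", function(object) {
  msg <- NULL
  if (!"suvr" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'suvr' is required")
  if (!all(c("i", "j", "k") %in%
           colnames(SummarizedExperiment::rowData(object))))
    msg <- c(msg, "rowData must carry voxel coordinates i, j, k")
  md <- S4Vectors::metadata(object)
  if (is.null(md$gridShape) || is.null(md$voxelSize))
    msg <- c(msg, "metadata must carry gridShape and voxelSize")
  if (is.null(msg)) TRUE else msg
})
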
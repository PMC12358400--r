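#' @rdname VolumeGrid-class
setMethod("gridValues", "VolumeGrid", function(x) x@values)

#' @rdname VolumeGrid-class
setMethod("voxelSize", "VolumeGrid", function(x) x@voxelSize)

#' @rdname VolumeGrid-class
setMethod("brainMask", "VolumeGrid", function(x) x@brainMask)

#' @rdname VoxelMask-class
setMethod("maskIndicator", "VoxelMask", function(x) x@indicator)

#' @rdname VoxelMask-class
setMethod("nVoxels", "VoxelMask", function(x) x@nVoxels)

#' @rdname PLSModel-class
setMethod("nComponents", "PLSModel", function(x) x@nComponents)

#' @rdname TStatMap-class
setMethod("tValues", "TStatMap", function(x) x@tValues)

#' @rdname CVResult-class
setMethod("subjectScores", "CVResult", function(x) x@subjectScores)

#' @rdname CVResult-class
setMethod("foldPredictions", "CVResult", function(x) x@foldPredictions)

#' Subjects-by-voxels matrix of a VoxelData object
#'
#' @rdname VoxelData-class
setMethod("voxelMatrix", "VoxelData", function(x)
  t(SummarizedExperiment::assay(x, "suvr")))

#' @rdname VoxelData-class
setMethod("subjectTable", "VoxelData", function(x)
  as.data.frame(SummarizedExperiment::colData(x)))

setMethod("show", "VolumeGrid", function(object) {
  d <- dim(object@values)
  cat(sprintf("VolumeGrid %d x %d x %d voxels (%g x %g x %g mm), %d in brain mask\n",
              d[1], d[2], d[3], object@voxelSize[1], object@voxelSize[2],
              object@voxelSize[3], sum(object@brainMask)))
  v <- object@values[object@brainMask]
  cat(sprintf("  in-mask values: mean %.4g, range [%.4g, %.4g]\n",
              mean(v), min(v), max(v)))
})

setMethod("show", "VoxelMask", function(object) {
  d <- dim(object@indicator)
  cat(sprintf("VoxelMask (%s): %d of %d voxels on a %d x %d x %d grid\n",
              object@origin, object@nVoxels, prod(d), d[1], d[2], d[3]))
})

setMethod("show", "TStatMap", function(object) {
  tv <- object@tValues[!is.na(object@tValues)]
  cat(sprintf("TStatMap (%s), df = %d, %d voxels, t range [%.3f, %.3f]\n",
              object@direction, object@df, length(tv), min(tv), max(tv)))
})

setMethod("show", "PLSModel", function(object) {
  cat(sprintf("PLSModel: %d components, %d predictors, responses: %s\n",
              object@nComponents, nrow(object@beta),
              paste(object@responseNames, collapse = ", ")))
  if (object@nComponents > 0L)
    cat(sprintf("  cumulative explained variance: X %.1f%%, Y %.1f%%\n",
                100 * object@cumVarX[object@nComponents],
                100 * object@cumVarY[object@nComponents]))
})

setMethod("show", "CVResult", function(object) {
  ss <- object@subjectScores
  cat(sprintf("CVResult: %d folds, %d subjects (%d BD / %d MDD)\n",
              length(unique(object@foldPredictions$fold)), nrow(ss),
              sum(ss$diagnosis == 1), sum(ss$diagnosis == 0)))
})

setMethod("show", "EffectSpec", function(object) {
  cat(sprintf("EffectSpec %d: %s%g SUVR in a %s at (%s), size %s voxels\n",
              object@regionId, ifelse(object@sign > 0, "+", "-"),
              object@delta, object@shape,
              paste(object@center, collapse = ", "),
              paste(object@size, collapse = "x")))
})

setMethod("show", "CohortConfig", function(object) {
  cat(sprintf(paste0("CohortConfig: %d BD / %d MDD on a %s grid ",
                     "(%g mm voxels), %d sites, seed %d\n"),
              object@nBD, object@nMDD,
              paste(object@gridShape, collapse = "x"),
              object@voxelSize[1], length(object@siteLabels), object@seed))
  cat(sprintf("  noise sd %g, site offset sd %g, smoothing %g mm FWHM, %d effect region(s)\n",
              object@noiseSd, object@siteOffsetSd, object@smoothFwhm,
              length(object@effects)))
})
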
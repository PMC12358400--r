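#' @rdname VolumeGrid-class
#' @param x,object an object of the documented class.
#' @export
setGeneric("gridValues", function(x) standardGeneric("gridValues"))

#' @rdname VolumeGrid-class
#' @export
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))

#' @rdname VolumeGrid-class
#' @export
setGeneric("brainMask", function(x) standardGeneric("brainMask"))

#' @rdname VoxelMask-class
#' @param x a `VoxelMask`.
#' @export
setGeneric("maskIndicator", function(x) standardGeneric("maskIndicator"))

#' @rdname VoxelMask-class
#' @export
setGeneric("nVoxels", function(x) standardGeneric("nVoxels"))

#' @rdname VoxelData-class
#' @param x a `VoxelData`.
#' @export
setGeneric("voxelMatrix", function(x) standardGeneric("voxelMatrix"))

#' @rdname VoxelData-class
#' @export
setGeneric("subjectTable", function(x) standardGeneric("subjectTable"))

#' @rdname PLSModel-class
#' @export
setGeneric("nComponents", function(x) standardGeneric("nComponents"))

#' @rdname TStatMap-class
#' @param x a `TStatMap`.
#' @export
setGeneric("tValues", function(x) standardGeneric("tValues"))

#' @rdname CVResult-class
#' @param x a `CVResult`.
#' @export
setGeneric("subjectScores", function(x) standardGeneric("subjectScores"))

#' @rdname CVResult-class
#' @export
setGeneric("foldPredictions", function(x) standardGeneric("foldPredictions"))

#' Per-subject disease score from a fitted PLS model
#'
#' @param object a [PLSModel-class].
#' @param newdata predictor matrix (subjects x voxels) or a single
#'   predictor vector.
#' @return numeric vector: the continuous disease column of the predicted
#'   response block (not thresholded).
#' @export
setGeneric("diseaseScore", function(object, newdata)
  standardGeneric("diseaseScore"))

#' Cumulative explained-variance curves of a PLS model
#'
#' @param object a [PLSModel-class].
#' @return data.frame with one row per component and the cumulative
#'   fractions of centered predictor (`cum_var_x`) and response
#'   (`cum_var_y`) sum of squares captured.
#' @export
setGeneric("explainedVariance", function(object)
  standardGeneric("explainedVariance"))

#' Back-project one response's beta coefficients to voxel space
#'
#' @param object a [PLSModel-class] fitted on a [VoxelData-class] matrix.
#' @param voxelData the `VoxelData` the model was fitted on (provides the
#'   voxel-index mapping and grid geometry).
#' @param response response column name, default `"disease"`.
#' @return A [VolumeGrid-class] whose masked voxels hold the beta
#'   coefficients and whose off-mask voxels are `NA`.
#' @export
setGeneric("betaMap", function(object, voxelData, response = "disease")
  standardGeneric("betaMap"))
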
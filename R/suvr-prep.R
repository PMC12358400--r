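#' Normalize a volume to whole-brain uptake (SUVR)
#'
#' Divides every voxel by the mean value over the brain mask, so that the
#' in-mask mean of the result is exactly 1. This is the standard SUVR
#' definition with the whole brain as reference region; it is idempotent.
#'
#' @param uptake a [VolumeGrid-class] of non-negative uptake values.
#' @return A [VolumeGrid-class] of SUVR values (in-mask mean 1).
#' @examples
#' v <- VolumeGrid(array(5, c(8, 8, 8)))
#' range(gridValues(computeSUVR(v)))  # all 1
#' @export
computeSUVR <- function(uptake) {
  stopifnot(is(uptake, "VolumeGrid"))
  m <- mean(uptake@values[uptake@brainMask])
  if (!is.finite(m) || m <= 0)
    .stopf("degenerate input: whole-brain mean uptake is %g (must be > 0)", m)
  VolumeGrid(uptake@values / m, uptake@voxelSize, uptake@brainMask)
}

#' Convert a Gaussian FWHM to its standard deviation
#'
#' `sigma = fwhm / (2 * sqrt(2 * log(2)))`, both in mm.
#'
#' @param fwhm full width at half maximum, mm (> 0).
#' @return sigma in mm.
#' @examples
#' fwhmToSigma(8)  # 3.3973, the usual 8 mm PET smoothing kernel
#' @export
fwhmToSigma <- function(fwhm) {
  .assertScalarNumeric(fwhm, "fwhm")
  if (fwhm <= 0) .stopf("'fwhm' must be > 0, got %g", fwhm)
  fwhm / (2 * sqrt(2 * log(2)))
}

# Normalized sampled Gaussian kernel for a sigma given in voxels.
.gaussKernel1d <- function(sigmaVox) {
  r <- max(1L, as.integer(ceiling(4 * sigmaVox)))
  k <- exp(-((-r:r)^2) / (2 * sigmaVox^2))
  k / sum(k)
}

# Map out-of-range indices back in by half-sample symmetric reflection.
.reflectIndex <- function(s, n) {
  while (any(s < 1L | s > n)) {
    s <- ifelse(s < 1L, 1L - s, s)
    s <- ifelse(s > n, 2L * n + 1L - s, s)
  }
  s
}

# Dense 1D convolution operator with reflected boundaries. Rows sum to 1
# (constants are preserved); for a symmetric kernel columns also sum to 1,
# so the total in-volume sum is conserved.
.convMatrix1d <- function(n, kernel) {
  r <- (length(kernel) - 1L) %/% 2L
  C <- matrix(0, n, n)
  idx <- seq_len(n)
  for (d in -r:r) {
    src <- .reflectIndex(idx + d, n)
    pos <- cbind(idx, src)
    C[pos] <- C[pos] + kernel[d + r + 1L]
  }
  C
}

#' Smooth a volume with an FWHM-parameterized Gaussian kernel
#'
#' Separable 3D Gaussian convolution. The per-axis kernel standard
#' deviation in voxel units is `fwhmToSigma(fwhm) / voxelSize[axis]`;
#' boundaries are handled by symmetric reflection, which preserves
#' constants and conserves the total in-volume sum. `fwhm = 0` is the
#' identity.
#'
#' @param volume a [VolumeGrid-class].
#' @param fwhm kernel full width at half maximum, mm (>= 0).
#' @return The smoothed [VolumeGrid-class] (mask and voxel size unchanged).
#' @export
gaussianSmooth <- function(volume, fwhm) {
  stopifnot(is(volume, "VolumeGrid"))
  .assertScalarNumeric(fwhm, "fwhm")
  if (fwhm < 0) .stopf("'fwhm' must be >= 0, got %g", fwhm)
  if (fwhm == 0) return(volume)
  sigma <- fwhmToSigma(fwhm)
  vals <- volume@values
  d <- dim(vals)
  for (ax in 1:3) {
    sigVox <- sigma / volume@voxelSize[ax]
    C <- .convMatrix1d(d[ax], .gaussKernel1d(sigVox))
    perm <- c(ax, setdiff(1:3, ax))
    A <- aperm(vals, perm)
    dims <- dim(A)
    dim(A) <- c(dims[1], dims[2] * dims[3])
    A <- C %*% A
    dim(A) <- dims
    vals <- aperm(A, order(perm))
  }
  VolumeGrid(vals, volume@voxelSize, volume@brainMask)
}

#' Harmonize the resolution of one site's volumes
#'
#' Applies the site-specific Gaussian filter (e.g. 5 mm FWHM for a scanner
#' with higher intrinsic resolution) before the common smoothing step, so
#' that all sites enter the analysis at a matched effective resolution.
#' Sites absent from the filter map pass through unchanged.
#'
#' @param volume a [VolumeGrid-class].
#' @param site the subject's site label.
#' @param siteFilterMap named numeric vector mapping site labels to filter
#'   FWHMs in mm; may be `NULL` (no-op).
#' @return A [VolumeGrid-class].
#' @export
harmonizeSite <- function(volume, site, siteFilterMap = NULL) {
  if (is.null(siteFilterMap) || !site %in% names(siteFilterMap))
    return(volume)
  gaussianSmooth(volume, siteFilterMap[[site]])
}

#' Build the high-signal analysis mask
#'
#' A voxel is included iff its SUVR exceeds `threshold` in every subject
#' (a conjunction across participants), intersected with the brain mask.
#' The default threshold of 0.9 excludes low-signal voxels and is slightly
#' more restrictive than a typical gray-matter probability mask.
#'
#' @param volumes list of SUVR [VolumeGrid-class] objects sharing shape
#'   and brain mask.
#' @param threshold SUVR cutoff, default 0.9.
#' @return A [VoxelMask-class] with origin `"signal_mask"`. If no voxel
#'   qualifies, an empty mask is returned with a warning.
#' @export
buildSignalMask <- function(volumes, threshold = 0.9) {
  stopifnot(length(volumes) >= 1L, all(vapply(volumes, is, logical(1),
                                              class2 = "VolumeGrid")))
  d <- dim(volumes[[1]]@values)
  low <- volumes[[1]]@values
  for (v in volumes[-1]) {
    if (!identical(dim(v@values), d))
      .stopf("volumes must share grid shape")
    low <- pmin(low, v@values)
  }
  ind <- (low > threshold) & volumes[[1]]@brainMask
  if (!any(ind))
    warning("signal mask is empty at threshold ", threshold)
  .VoxelMask(ind, "signal_mask")
}

#' Threshold a tissue-probability volume into a mask
#'
#' Stand-in for a gray-matter mask: voxels whose probability exceeds the
#' threshold (default 10%), intersected with the brain mask.
#'
#' @param probability a [VolumeGrid-class] of probabilities in \[0, 1\].
#' @param threshold inclusion cutoff, default 0.1.
#' @return A [VoxelMask-class] with origin `"gray_matter"`.
#' @export
probabilityMask <- function(probability, threshold = 0.1) {
  stopifnot(is(probability, "VolumeGrid"))
  .VoxelMask((probability@values > threshold) & probability@brainMask,
             "gray_matter")
}

#' @rdname probabilityMask
#' @param volume a [VolumeGrid-class] whose brain mask becomes the mask.
#' @export
brainVoxelMask <- function(volume) {
  stopifnot(is(volume, "VolumeGrid"))
  .VoxelMask(volume@brainMask, "brain")
}

#' Intersect two analysis masks
#'
#' @param a,b [VoxelMask-class] objects on the same grid.
#' @return A [VoxelMask-class] with origin `"intersection"`.
#' @export
intersectMasks <- function(a, b) {
  stopifnot(is(a, "VoxelMask"), is(b, "VoxelMask"),
            identical(dim(a@indicator), dim(b@indicator)))
  .VoxelMask(a@indicator & b@indicator, "intersection")
}

#' Stack masked volumes into a VoxelData matrix
#'
#' Extracts the masked voxels of every subject in a fixed linear order
#' (column-major grid order) and assembles them into a
#' [VoxelData-class] container, keeping the voxel-to-grid index mapping
#' for later back-projection of statistics or coefficients.
#'
#' @param volumes list of [VolumeGrid-class] objects, one per subject,
#'   sharing grid shape.
#' @param mask a [VoxelMask-class] selecting the analysis voxels.
#' @param subjects optional subject table (data.frame with at least
#'   `subject_id`); row order must match `volumes`.
#' @return A [VoxelData-class] with assay `"suvr"` (voxels x subjects).
#' @export
stackMatrix <- function(volumes, mask, subjects = NULL) {
  stopifnot(is(mask, "VoxelMask"), length(volumes) >= 1L)
  d <- dim(mask@indicator)
  if (!all(vapply(volumes, function(v) identical(dim(v@values), d),
                  logical(1))))
    .stopf("volume shapes do not match the mask grid")
  idx <- which(mask@indicator)
  coords <- arrayInd(idx, d)
  mat <- vapply(volumes, function(v) v@values[idx], numeric(length(idx)))
  if (is.null(subjects))
    subjects <- data.frame(subject_id = sprintf("S%03d", seq_along(volumes)))
  if (nrow(subjects) != length(volumes))
    .stopf("subject table has %d rows but there are %d volumes",
           nrow(subjects), length(volumes))
  colnames(mat) <- subjects$subject_id
  rownames(mat) <- sprintf("v%06d", idx)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(suvr = mat),
    rowData = S4Vectors::DataFrame(i = coords[, 1], j = coords[, 2],
                                   k = coords[, 3], index = idx),
    colData = S4Vectors::DataFrame(subjects, row.names = subjects$subject_id))
  md <- list(gridShape = d, voxelSize = volumes[[1]]@voxelSize,
             maskOrigin = mask@origin)
  S4Vectors::metadata(se) <- md
  new("VoxelData", se)
}

#' Back-project a voxel vector onto the volume grid
#'
#' Inverse of the stacking step: places one value per masked voxel back at
#' its grid coordinate; off-mask voxels are `NA`.
#'
#' @param voxelData a [VoxelData-class].
#' @param values numeric vector, one value per masked voxel (row of
#'   `voxelData`).
#' @return A [VolumeGrid-class] whose brain mask is the analysis mask.
#' @export
backProject <- function(voxelData, values) {
  stopifnot(is(voxelData, "VoxelData"))
  if (length(values) != nrow(voxelData))
    .stopf("expected %d voxel values, got %d", nrow(voxelData),
           length(values))
  md <- S4Vectors::metadata(voxelData)
  arr <- array(NA_real_, md$gridShape)
  idx <- SummarizedExperiment::rowData(voxelData)$index
  arr[idx] <- values
  ind <- array(FALSE, md$gridShape)
  ind[idx] <- TRUE
  VolumeGrid(arr, md$voxelSize, ind)
}

# Rebuild the VoxelMask underlying a VoxelData object.
.maskOf <- function(voxelData) {
  md <- S4Vectors::metadata(voxelData)
  ind <- array(FALSE, md$gridShape)
  ind[SummarizedExperiment::rowData(voxelData)$index] <- TRUE
  .VoxelMask(ind, md$maskOrigin)
}
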
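# End-to-end orchestration: simulate (or load) -> prep -> voxel stats ->
# classify -> evaluate, with every intermediate artifact written to the
# output directory and a plain-text log carrying one JSON summary line
# per stage.

.subjectColumns <- c("subject_id", "diagnosis", "age", "sex", "site",
                     "duration_of_illness", "madrs", "ymrs")

#' Read and validate a subject table
#'
#' @param path CSV file with exactly the columns `subject_id`,
#'   `diagnosis`, `age`, `sex`, `site`, `duration_of_illness`, `madrs`,
#'   `ymrs`.
#' @return data.frame of validated subject records.
#' @export
readSubjectTable <- function(path) {
  if (!file.exists(path)) .stopf("subject table not found: '%s'", path)
  tab <- read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(.subjectColumns, names(tab))
  if (length(miss))
    .stopf("subject table is missing column(s): %s",
           paste(miss, collapse = ", "))
  bad <- which(!tab$diagnosis %in% c(0, 1))
  if (length(bad))
    .stopf("'diagnosis' must be 0 (MDD) or 1 (BD); offending row(s): %s",
           paste(bad, collapse = ", "))
  for (col in c("age", "duration_of_illness", "madrs", "ymrs")) {
    if (!is.numeric(tab[[col]]))
      .stopf("column '%s' must be numeric", col)
  }
  if (any(tab$age <= 0)) .stopf("'age' must be positive")
  if (any(tab$madrs < 0) || any(tab$ymrs < 0))
    .stopf("'madrs' and 'ymrs' must be >= 0")
  if (!all(tab$sex %in% c(0, 1))) .stopf("'sex' must be 0 or 1")
  if (anyDuplicated(tab$subject_id))
    .stopf("duplicate subject_id values")
  tab
}

#' Read a NIfTI volume into a VolumeGrid
#'
#' @param path NIfTI-1 file (`.nii` or `.nii.gz`).
#' @param brainMask optional logical array; defaults to all `TRUE`.
#' @return A [VolumeGrid-class] with the voxel size taken from the NIfTI
#'   header.
#' @export
readVolume <- function(path, brainMask = NULL) {
  if (!file.exists(path)) .stopf("volume not found: '%s'", path)
  img <- RNifti::readNifti(path)
  vals <- array(as.numeric(img), dim(img))
  if (length(dim(vals)) != 3L)
    .stopf("'%s' is not a 3D volume", path)
  VolumeGrid(vals, RNifti::pixdim(img)[1:3], brainMask)
}

#' Write a VolumeGrid as NIfTI-1
#'
#' Voxel values and voxel size survive a round trip to within storage
#' precision; the brain mask is not stored (NIfTI has no mask slot) and
#' must be re-derived on read.
#'
#' @param volume a [VolumeGrid-class].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return (invisibly) the path.
#' @export
writeVolume <- function(volume, path) {
  stopifnot(is(volume, "VolumeGrid"))
  img <- RNifti::asNifti(volume@values)
  RNifti::pixdim(img) <- volume@voxelSize
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Configure an end-to-end pipeline run
#'
#' @param outDir output directory for all artifacts.
#' @param cohort a [CohortConfig-class] to simulate from, or `NULL` when
#'   reading real data from `volumePaths`/`subjectTablePath`.
#' @param volumePaths,subjectTablePath inputs for real-data mode
#'   (ignored when `cohort` is given).
#' @param fwhm common smoothing FWHM in mm applied in real-data mode
#'   (simulated volumes are already smoothed by the generator).
#' @param siteFilterMap named FWHMs for site harmonization, or `NULL`.
#' @param signalThreshold SUVR cutoff of the signal mask, default 0.9.
#' @param clusterAlpha,q,nPermutations cluster-FDR parameters.
#' @param nComponents PLS components, default 10.
#' @param withDOI add duration of illness to the response block.
#' @param scale scale predictors to unit variance.
#' @param ciMethod `"delong"` or `"bootstrap"` AUC interval.
#' @param makePlots write score and ROC plots (PDF).
#' @param seed master seed; stage seeds are derived at fixed offsets.
#' @return validated config (list with class `"pipelineConfig"`).
#' @export
pipelineConfig <- function(outDir, cohort = NULL, volumePaths = NULL,
                           subjectTablePath = NULL, fwhm = 8,
                           siteFilterMap = NULL, signalThreshold = 0.9,
                           clusterAlpha = 0.05, q = 0.05,
                           nPermutations = 1000, nComponents = 10,
                           withDOI = FALSE, scale = FALSE,
                           ciMethod = "delong", makePlots = FALSE,
                           seed = 1L) {
  if (is.null(cohort)) {
    if (is.null(volumePaths) || is.null(subjectTablePath))
      .stopf("either 'cohort' or both 'volumePaths' and 'subjectTablePath' are required")
    if (!all(file.exists(volumePaths)))
      .stopf("missing input volume(s): %s",
             paste(volumePaths[!file.exists(volumePaths)], collapse = ", "))
    if (!file.exists(subjectTablePath))
      .stopf("subject table not found: '%s'", subjectTablePath)
  } else {
    stopifnot(is(cohort, "CohortConfig"))
  }
  for (nm in c("fwhm", "signalThreshold", "clusterAlpha", "q"))
    .assertScalarNumeric(get(nm), nm)
  if (clusterAlpha <= 0 || clusterAlpha >= 1)
    .stopf("'clusterAlpha' must be in (0, 1)")
  if (q <= 0 || q >= 1) .stopf("'q' must be in (0, 1)")
  if (nPermutations < 10) .stopf("'nPermutations' must be >= 10")
  if (nComponents < 1) .stopf("'nComponents' must be >= 1")
  if (!ciMethod %in% c("delong", "bootstrap"))
    .stopf("'ciMethod' must be 'delong' or 'bootstrap'")
  structure(list(outDir = outDir, cohort = cohort,
                 volumePaths = volumePaths,
                 subjectTablePath = subjectTablePath, fwhm = fwhm,
                 siteFilterMap = siteFilterMap,
                 signalThreshold = signalThreshold,
                 clusterAlpha = clusterAlpha, q = q,
                 nPermutations = as.integer(nPermutations),
                 nComponents = as.integer(nComponents),
                 withDOI = isTRUE(withDOI), scale = isTRUE(scale),
                 ciMethod = ciMethod, makePlots = isTRUE(makePlots),
                 seed = as.integer(seed)),
            class = "pipelineConfig")
}

.logStage <- function(con, stage, summary) {
  line <- jsonlite::toJSON(c(list(stage = stage), summary),
                           auto_unbox = TRUE, digits = NA)
  writeLines(as.character(line), con)
}

#' Run the full pipeline
#'
#' Stages: simulate (or load), prep (harmonize/smooth/SUVR + signal
#' mask + stacking), voxelstats (both one-tailed cluster-FDR maps +
#' ROI table), classify (all-subject PLS fit + beta map), evaluate
#' (leave-one-pair-out CV, ROC/AUC with CI, Youden threshold,
#' confusion metrics). Every artifact lands under `config$outDir`;
#' re-running with an identical config reproduces identical outputs.
#'
#' @param config from [pipelineConfig()].
#' @return (invisibly) the report bundle: a list with the cohort,
#'   `voxelData`, cluster results, the full-data model, the CV result,
#'   the ROC summary, and `paths` of the written artifacts.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "pipelineConfig"))
  dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
  logPath <- file.path(config$outDir, "run.log")
  con <- file(logPath, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("suvrPLS %s | R %s | seed %d",
                     as.character(utils::packageVersion("suvrPLS")),
                     getRversion(), config$seed), con)
  paths <- list(log = logPath)
  stage <- "simulate"
  result <- tryCatch({
    # -- simulate / load ---------------------------------------------
    if (!is.null(config$cohort)) {
      coh <- generateCohort(config$cohort)
      subjects <- coh$subjects
      suvr <- coh$volumes  # generator output is smoothed + normalized
      groundTruth <- coh$groundTruth
    } else {
      subjects <- readSubjectTable(config$subjectTablePath)
      if (length(config$volumePaths) != nrow(subjects))
        .stopf("%d volumes for %d subjects", length(config$volumePaths),
               nrow(subjects))
      raw <- lapply(config$volumePaths, readVolume)
      suvr <- lapply(seq_along(raw), function(s) {
        v <- harmonizeSite(raw[[s]], subjects$site[s], config$siteFilterMap)
        computeSUVR(gaussianSmooth(v, config$fwhm))
      })
      groundTruth <- NULL
    }
    .logStage(con, "simulate",
              list(n_bd = sum(subjects$diagnosis == 1),
                   n_mdd = sum(subjects$diagnosis == 0)))

    # -- prep --------------------------------------------------------
    stage <- "prep"
    # voxel statistics run on the gray-matter stand-in (brain mask);
    # classification on the stricter SUVR > threshold signal mask
    sigMask <- buildSignalMask(suvr, config$signalThreshold)
    gmMask <- brainVoxelMask(suvr[[1]])
    mask <- intersectMasks(sigMask, gmMask)
    n <- nrow(subjects)
    kmax <- min(n - 2L - 1L, nVoxels(mask))  # smallest CV training set
    if (config$nComponents > kmax)
      .stopf("nComponents = %d exceeds the rank bound %d for %d subjects",
             config$nComponents, kmax, n)
    vd <- stackMatrix(suvr, mask, subjects)
    vdStats <- stackMatrix(suvr, gmMask, subjects)
    .logStage(con, "prep", list(n_voxels = nVoxels(mask),
                                n_voxels_stats = nVoxels(gmMask),
                                signal_threshold = config$signalThreshold))

    # -- voxelstats --------------------------------------------------
    stage <- "voxelstats"
    tmap <- voxelwiseTTest(vdStats)
    paths$tmap <- file.path(config$outDir, "tmap.nii.gz")
    writeVolume(VolumeGrid(ifelse(is.na(tmap@tValues), 0, tmap@tValues),
                           voxelSize(suvr[[1]]), brainMask(suvr[[1]])),
                paths$tmap)
    clusters <- clusterFDRBoth(vdStats, clusterAlpha = config$clusterAlpha,
                               q = config$q,
                               nPermutations = config$nPermutations,
                               seed = config$seed + 1000L)
    clusterTab <- do.call(rbind, lapply(names(clusters), function(nm) {
      tb <- clusters[[nm]]$table
      if (nrow(tb)) cbind(direction = clusters[[nm]]$direction, tb)
      else cbind(direction = character(0), tb)
    }))
    paths$clusters <- file.path(config$outDir, "clusters.csv")
    write.csv(clusterTab, paths$clusters, row.names = FALSE)
    keptArr <- (clusters$up$labels > 0 &
                  clusters$up$labels %in%
                    clusters$up$table$label[clusters$up$table$kept]) |
               (clusters$down$labels > 0 &
                  clusters$down$labels %in%
                    clusters$down$table$label[clusters$down$table$kept])
    if (any(keptArr) && !is.null(groundTruth)) {
      regions <- array(0L, dim(keptArr))
      for (e in groundTruth) {
        ind <- .effectIndicator(e, S4Vectors::metadata(vd)$gridShape,
                                brainMask(suvr[[1]]))$indicator
        regions[ind] <- e@regionId
      }
      roi <- roiSummarize(suvr, .VoxelMask(keptArr, "intersection"),
                          VolumeGrid(regions + 0.0, voxelSize(suvr[[1]]),
                                     brainMask(suvr[[1]])),
                          subjectIds = subjects$subject_id)
      paths$roi <- file.path(config$outDir, "roi_means.csv")
      write.csv(roi, paths$roi, row.names = FALSE)
    }
    .logStage(con, "voxelstats",
              list(n_clusters = nrow(clusterTab),
                   n_kept = sum(clusterTab$kept),
                   threshold = clusters$up$threshold))

    # -- classify ----------------------------------------------------
    stage <- "classify"
    responses <- buildResponseBlock(subjects, withDOI = config$withDOI)
    model <- fitPLS(vd, responses, nComponents = config$nComponents,
                    scale = config$scale)
    bmap <- betaMap(model, vd, "disease")
    paths$betaMap <- file.path(config$outDir, "beta_disease.nii.gz")
    writeVolume(VolumeGrid(ifelse(is.na(bmap@values), 0, bmap@values),
                           bmap@voxelSize, bmap@brainMask), paths$betaMap)
    .logStage(con, "classify",
              list(n_components = nComponents(model),
                   cum_var_y = model@cumVarY[nComponents(model)]))

    # -- evaluate ----------------------------------------------------
    stage <- "evaluate"
    cv <- runCV(vd, responses, nComponents = config$nComponents,
                scale = config$scale)
    rocSummary <- evaluateCV(cv, ciMethod = config$ciMethod,
                             seed = config$seed + 2000L)
    paths$predictions <- file.path(config$outDir, "predictions.csv")
    write.csv(cv@subjectScores, paths$predictions, row.names = FALSE)
    paths$roc <- file.path(config$outDir, "roc_summary.json")
    jsonlite::write_json(
      list(auc = rocSummary$auc, auc_ci = as.list(rocSummary$auc_ci),
           youden_threshold = rocSummary$youden_threshold, J = rocSummary$J,
           confusion = as.list(rocSummary$confusion),
           metrics = as.list(rocSummary$metrics)),
      paths$roc, auto_unbox = TRUE, digits = NA)
    if (config$makePlots) {
      paths$scorePlot <- file.path(config$outDir, "predicted_scores.pdf")
      paths$rocPlot <- file.path(config$outDir, "roc_curve.pdf")
      ggplot2::ggsave(paths$scorePlot, plotPredictedScores(cv),
                      width = 4, height = 4, device = grDevices::pdf)
      ggplot2::ggsave(paths$rocPlot, plotROC(rocSummary),
                      width = 4, height = 4, device = grDevices::pdf)
    }
    .logStage(con, "evaluate",
              list(auc = rocSummary$auc,
                   youden_threshold = rocSummary$youden_threshold))

    list(subjects = subjects, volumes = suvr, mask = mask, voxelData = vd,
         tmap = tmap, clusters = clusters, model = model, cv = cv,
         rocSummary = rocSummary, paths = paths)
  }, error = function(e) {
    .logStage(con, stage, list(error = conditionMessage(e)))
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  invisible(result)
}
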
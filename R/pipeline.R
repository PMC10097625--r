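#' @include AllClasses.R
#' @importFrom jsonlite write_json toJSON
#' @importFrom tools md5sum
#' @importFrom utils packageVersion read.csv write.csv read.table
#' @importFrom stats approx cor rnorm runif sd setNames
NULL

## Resolve one defining ROI: look up by name, union extras, dilate,
## validate against the reference grid.
resolveROI <- function(name, extras, dilate, rois, grid) {
  lookup <- function(nm) {
    if (is.null(rois[[nm]]))
      stop("ROI '", nm, "' not found among the supplied ROIs")
    rois[[nm]]
  }
  roi <- lookup(name)
  if (length(extras))
    roi <- combineROIs(c(list(roi), lapply(extras, lookup)))
  if (dilate > 0L)
    roi <- dilateROI(roi, dilate)
  validateROI(roi, grid)
}

#' Run the tractometry pipeline for a set of tracts
#'
#' Executes, per tractparams row: ROI resolution (combine, dilate,
#' validate) -> ROI-crossing selection from the whole-brain tractogram ->
#' SD-based cleaning -> optional clip-to-ROI -> core-fiber estimation ->
#' Gaussian-weighted 100-node profile per requested metric. A failure in
#' one tract is recorded in the manifest and does not abort the others;
#' an empty selection is an outcome, not an error. The stage order is
#' fixed and the run is single-threaded and deterministic: identical
#' inputs and parameters reproduce every output byte-for-byte (only the
#' manifest timestamp differs).
#'
#' When `outDir` is given the file set of a full run is written:
#' `<tract>.tck` and `<tract>_SF.tck` (tract and super fiber),
#' `<tract>_fa_bin.nii.gz` and `<tract>_fbcnt.nii.gz` (binary and
#' fiber-count masks), one `<metric>_profiles.csv` per metric (100 rows,
#' one column per tract), and `manifest.json`.
#'
#' @param wbt the whole-brain \linkS4class{Tractogram}.
#' @param rois named list of \linkS4class{BinaryROI}s.
#' @param tractparams result of [parseTractparams()] (or something
#'   coercible by it).
#' @param metricMaps named list of \linkS4class{ScalarMap}s (names must
#'   cover every metric requested in tractparams).
#' @param grid reference \linkS4class{VolumeGrid} for masks; defaults to
#'   the first metric map's grid.
#' @param outDir optional output directory (created if missing).
#' @param inputPaths optional named character vector of input file paths;
#'   their md5 digests are recorded in the manifest.
#' @return a list with `tracts` (named list of final
#'   \linkS4class{Tract}s), `cores` (named list of
#'   \linkS4class{CoreFiber}s), `profiles` (named list, one entry per
#'   metric, each a list of \linkS4class{TractProfile}s), `cleaning`
#'   (named list of \linkS4class{CleaningReport}s) and `manifest` (named
#'   list).
#' @export
runPipeline <- function(wbt, rois, tractparams, metricMaps,
                        grid = NULL, outDir = NULL, inputPaths = NULL) {
  if (!is.list(tractparams) || is.data.frame(tractparams))
    tractparams <- parseTractparams(tractparams)
  if (is.null(names(metricMaps)) || any(!nzchar(names(metricMaps))))
    stop("metricMaps must be a named list")
  if (is.null(grid))
    grid <- volumeGrid(metricMaps[[1]])
  if (!is.null(outDir) && !dir.exists(outDir))
    dir.create(outDir, recursive = TRUE)

  tracts <- list(); cores <- list(); cleaning <- list()
  profiles <- list()
  perTract <- list()

  runOneTract <- function(tp) {
    nm <- tp$tract_name
    rec <- list(params = tp, status = "ok", n_wbt = nStreamlines(wbt))
    roi1 <- resolveROI(tp$roi1, tp$roi1_combine, tp$roi1_dilate,
                       rois, grid)
    roi2 <- resolveROI(tp$roi2, tp$roi2_combine, tp$roi2_dilate,
                       rois, grid)
    tract <- selectByROIs(wbt, list(roi1, roi2), mode = tp$select_mode,
                          name = nm)
    rec$n_selected <- nStreamlines(tract)
    if (isEmptyTract(tract)) {
      rec$status <- "empty_selection"
      return(list(rec = rec, tract = tract))
    }
    report <- NULL
    if (tp$clean && nStreamlines(tract) >= 3L) {
      cl <- cleanTract(tract, maxLenSD = tp$max_len_sd,
                       maxDistSD = tp$max_dist_sd, maxIter = tp$max_iter)
      tract <- cl$tract
      report <- cl$report
      rec$n_after_cleaning <- nStreamlines(tract)
    }
    if (tp$c2roi) {
      tract <- clipToROI(tract, roi1, roi2)
      rec$n_after_clip <- nStreamlines(tract)
      if (isEmptyTract(tract)) {
        rec$status <- "empty_after_clip"
        return(list(rec = rec, tract = tract, cleaning = report))
      }
    }
    core <- coreFiber(tract)
    prs <- list()
    for (met in tp$metrics) {
      if (is.null(metricMaps[[met]]))
        stop("metric map '", met, "' not supplied")
      prs[[met]] <- tractProfile(tract, metricMaps[[met]])
    }
    if (!is.null(outDir)) {
      writeTck(tract, file.path(outDir, paste0(nm, ".tck")))
      writeSuperFiber(core, file.path(outDir, paste0(nm, "_SF.tck")))
      writeVolume(tractToBinaryMask(tract, grid),
                  file.path(outDir, paste0(nm, "_fa_bin.nii.gz")))
      writeVolume(tractToCountMask(tract, grid),
                  file.path(outDir, paste0(nm, "_fbcnt.nii.gz")))
    }
    list(rec = rec, tract = tract, cleaning = report, core = core,
         profiles = prs)
  }

  for (tp in tractparams) {
    nm <- tp$tract_name
    res <- tryCatch(runOneTract(tp), error = function(e) {
      list(rec = list(params = tp, status = "failed",
                      error = conditionMessage(e)))
    })
    perTract[[nm]] <- res$rec
    if (!is.null(res$tract)) tracts[[nm]] <- res$tract
    if (!is.null(res$cleaning)) cleaning[[nm]] <- res$cleaning
    if (!is.null(res$core)) cores[[nm]] <- res$core
    if (!is.null(res$profiles))
      for (met in names(res$profiles))
        profiles[[met]] <- c(profiles[[met]], list(res$profiles[[met]]))
  }

  if (!is.null(outDir)) {
    for (met in names(profiles))
      profilesToCSV(profiles[[met]],
                    file = file.path(outDir,
                                     paste0(met, "_profiles.csv")))
  }

  manifest <- list(
    software = "tractoprof",
    version = as.character(utils::packageVersion("tractoprof")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    reference_grid = list(shape = gridShape(grid),
                          affine = affine(grid)),
    input_digests = if (!is.null(inputPaths))
      as.list(tools::md5sum(inputPaths)) else NULL,
    tracts = perTract)
  if (!is.null(outDir))
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         matrix = "rowmajor", null = "null")

  list(tracts = tracts, cores = cores, profiles = profiles,
       cleaning = cleaning, manifest = manifest)
}
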
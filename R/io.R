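# Serialization. Cohorts, volumes and heatmaps are stored as RDS containers
# plus plain-text CSV metadata tables; 3d heatmaps can be exported to NIfTI
# for visualization when the RNifti package is available.

#' Write / read a cohort container
#'
#' Stores the [SourceCohort-class] (surface, generator parameters, seed) as
#' an RDS file and its per-subject metadata table (subject id, group,
#' ground-truth amplitude, scores, seed) as a CSV next to it.
#'
#' @param cohort a [SourceCohort-class].
#' @param path RDS file path; the metadata CSV takes the same path with a
#'   `.csv` extension.
#' @return `path`, invisibly (`writeCohort`); the cohort (`readCohort`).
#' @export
writeCohort <- function(cohort, path) {
  saveRDS(cohort, path)
  meta <- cohortMeta(cohort)
  meta$seed <- cohort@seed
  write.csv(meta, sub("\\.rds$", ".csv", path, ignore.case = TRUE),
            row.names = FALSE)
  invisible(path)
}

#' @rdname writeCohort
#' @export
readCohort <- function(path) {
  obj <- readRDS(path)
  stopIfNot(is(obj, "SourceCohort"), "file does not contain a SourceCohort")
  obj
}

#' Export a 3d heatmap to NIfTI
#'
#' Writes an H x W x nBins heatmap as a NIfTI volume (requires the RNifti
#' package).
#'
#' @param heatmap 3d numeric array.
#' @param path output `.nii` / `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
writeHeatmapNifti <- function(heatmap, path) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("NIfTI export requires the RNifti package", call. = FALSE)
  RNifti::writeNifti(RNifti::asNifti(heatmap), path)
  invisible(path)
}
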
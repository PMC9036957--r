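#' Read a multi-b-value DWI series
#'
#' Reads a 4D NIfTI-1 volume together with its FSL-style b-value sidecar (a
#' single line of whitespace-separated b-values, aligned with the 4th
#' dimension).  Images are assumed co-registered across b-values; masks must
#' live on the same grid.
#'
#' @param path NIfTI file of the 4D series.
#' @param bvalPath plain-text sidecar with one b-value per volume.
#' @param deltaSmall,deltaBig gradient timing in ms to attach to the scheme
#'   (not stored in either file).
#' @return A list with elements \code{volume} (4D array) and \code{scheme}
#'   (an [AcquisitionScheme-class]).
#' @export
readDwiSeries <- function(path, bvalPath, deltaSmall = 20, deltaBig = 40) {
  vol <- RNifti::readNifti(path)
  vol <- array(as.numeric(vol), dim = dim(vol))
  bvals <- readBvalFile(bvalPath)
  if (length(dim(vol)) != 4L || dim(vol)[4L] != length(bvals)) {
    stop(sprintf("DWI series has %s volumes but sidecar lists %d b-values",
                 if (length(dim(vol)) == 4L) dim(vol)[4L] else "no",
                 length(bvals)))
  }
  list(volume = vol,
       scheme = acquisitionScheme(bvals, deltaSmall = deltaSmall,
                                  deltaBig = deltaBig))
}

#' @rdname readDwiSeries
#' @param x 4D array to write.
#' @param scheme the [AcquisitionScheme-class] whose b-values go to the
#'   sidecar.
#' @export
writeDwiSeries <- function(x, path, bvalPath, scheme) {
  stopifnot(length(dim(x)) == 4L,
            dim(x)[4L] == length(scheme@bValues))
  RNifti::writeNifti(RNifti::asNifti(x), path)
  writeLines(paste(format(scheme@bValues, trim = TRUE, scientific = FALSE),
                   collapse = " "), bvalPath)
  invisible(path)
}

#' @rdname readDwiSeries
#' @export
readBvalFile <- function(bvalPath) {
  txt <- readLines(bvalPath, warn = FALSE)
  txt <- txt[nzchar(trimws(txt))]
  if (!length(txt)) stop("empty b-value sidecar: ", bvalPath)
  bvals <- as.numeric(strsplit(trimws(txt[1L]), "[[:space:],]+")[[1L]])
  if (anyNA(bvals)) stop("unparseable b-value sidecar: ", bvalPath)
  bvals
}

#' Read or write a binary mask volume
#'
#' @param path NIfTI file.
#' @return 3D logical array.
#' @export
readMask <- function(path) {
  m <- RNifti::readNifti(path)
  array(as.numeric(m) != 0, dim = dim(m))
}

#' @rdname readMask
#' @param mask 3D logical/0-1 array to write.
#' @export
writeMask <- function(mask, path) {
  RNifti::writeNifti(RNifti::asNifti(array(as.integer(mask != 0), dim = dim(mask))),
                     path)
  invisible(path)
}

#' VOI summary of a parameter map set
#'
#' Arithmetic mean of each parameter map over the intersection of the VOI
#' mask with the converged voxels, mirroring the per-lesion means recorded
#' in a VOI-based DWI analysis.
#'
#' @param maps a [ParameterMapSet-class].
#' @param mask 3D VOI mask on the same grid (defaults to the fitted mask).
#' @param subjectId identifier used in the output and in error messages.
#' @return A one-row data.frame: subject_id, mean_adc, mean_beta, mean_d,
#'   mean_mu, n_voxels.
#' @export
voiSummary <- function(maps, mask = NULL, subjectId = "subject") {
  stopifnot(is(maps, "ParameterMapSet"))
  if (is.null(mask)) mask <- maps@mask
  if (!all(dim(mask) == dim(maps@adc))) {
    stop("VOI mask shape does not match the maps")
  }
  sel <- array(as.logical(mask), dim = dim(mask)) & maps@converged
  n <- sum(sel)
  if (n < 1L) {
    stop(sprintf("subject %s: VOI has no overlap with converged voxels",
                 subjectId))
  }
  data.frame(subject_id = as.character(subjectId),
             mean_adc = mean(maps@adc[sel]),
             mean_beta = mean(maps@beta[sel]),
             mean_d = mean(maps@d[sel]),
             mean_mu = mean(maps@mu[sel]),
             n_voxels = n,
             stringsAsFactors = FALSE)
}

#' Read and write cohort tables
#'
#' Comma-separated text with a header row.  A cohort table holds one row per
#' subject: \code{subject_id}, one or more group-label columns (e.g.
#' \code{subtype} with levels SCC/ACA or \code{grade} with levels low/high),
#' and the VOI-mean parameters \code{mean_adc}, \code{mean_beta},
#' \code{mean_d}, \code{mean_mu} (plus \code{n_voxels} when derived from
#' images).
#'
#' @param path CSV file path.
#' @return A data.frame.
#' @export
readCohortTable <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "mean_adc", "mean_beta", "mean_d", "mean_mu")
  miss <- setdiff(need, names(x))
  if (length(miss)) {
    stop("cohort table lacks required columns: ", paste(miss, collapse = ", "))
  }
  x
}

#' @rdname readCohortTable
#' @param cohort data.frame to write.
#' @export
writeCohortTable <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
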
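#' Write a multi-echo series to NIfTI with a JSON sidecar
#'
#' The 4D stack (x, y, echo, frame) is stored as a NIfTI volume; echo times,
#' frame interval and paradigm timings go into a JSON sidecar next to it.
#'
#' @param series A [multi_echo_series()].
#' @param path Output path without extension (writes `<path>.nii.gz` and
#'   `<path>.json`).
#' @param paradigm Optional [cuff_paradigm()] recorded in the sidecar.
#' @return Invisibly, the two file paths.
#' @export
write_series <- function(series, path, paradigm = NULL) {
  stopifnot(inherits(series, "multi_echo_series"))
  nii <- paste0(path, ".nii.gz")
  RNifti::writeNifti(RNifti::asNifti(series$data), nii)
  side <- list(echo_times_ms = series$echo_times_ms, dt_s = series$dt_s)
  if (!is.null(paradigm))
    side$paradigm <- paradigm[c("baseline_s", "occlusion_s", "post_s", "dt_s")]
  json <- paste0(path, ".json")
  jsonlite::write_json(side, json, auto_unbox = TRUE, digits = NA)
  invisible(c(nii, json))
}

#' Read a multi-echo series written by [write_series()]
#'
#' @param path Path without extension.
#' @return List with `series` and, when present in the sidecar, `paradigm`.
#' @export
read_series <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  data <- array(as.numeric(RNifti::readNifti(paste0(path, ".nii.gz"))),
                dim = dim(RNifti::readNifti(paste0(path, ".nii.gz"))))
  out <- list(series = multi_echo_series(data, side$echo_times_ms, side$dt_s))
  if (!is.null(side$paradigm))
    out$paradigm <- do.call(cuff_paradigm, as.list(side$paradigm))
  out
}

#' Write / read a ROI label mask as NIfTI
#' @param mask A [roi_mask()].
#' @param path File path (`.nii.gz` appended if absent).
#' @return Invisibly, the file path.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "roi_mask"))
  if (!grepl("\\.nii(\\.gz)?$", path)) path <- paste0(path, ".nii.gz")
  RNifti::writeNifti(RNifti::asNifti(mask$labels), path)
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  img <- RNifti::readNifti(path)
  roi_mask(matrix(as.integer(round(as.numeric(img))), nrow = dim(img)[1]))
}

#' Write T2* maps and their validity mask as NIfTI
#' @param t2series A `t2star_series`.
#' @param path Output path prefix (writes `<path>_t2star.nii.gz` and
#'   `<path>_valid.nii.gz`).
#' @return Invisibly, the file paths.
#' @export
write_t2star <- function(t2series, path) {
  stopifnot(inherits(t2series, "t2star_series"))
  t2 <- t2series$t2star_ms
  t2[!is.finite(t2)] <- 0
  f1 <- paste0(path, "_t2star.nii.gz")
  f2 <- paste0(path, "_valid.nii.gz")
  RNifti::writeNifti(RNifti::asNifti(t2), f1)
  RNifti::writeNifti(RNifti::asNifti(t2series$valid_mask * 1), f2)
  invisible(c(f1, f2))
}

#' Serialise a ground-truth record to JSON
#' @param truth Ground-truth record from [render_series()].
#' @param path Output `.json` path.
#' @return Invisibly, the path.
#' @export
write_truth <- function(truth, path) {
  enc <- truth
  enc$t2init_map <- NULL                      # voxel map not round-tripped
  enc$tissues <- lapply(truth$tissues, function(ts) {
    ts$params <- unclass(ts$params)
    ts$bold <- unclass(ts$bold)
    ts
  })
  enc$paradigm <- enc$paradigm[c("baseline_s", "occlusion_s", "post_s", "dt_s")]
  jsonlite::write_json(enc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
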
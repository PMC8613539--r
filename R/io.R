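#' Write / read a cine series as NIfTI
#'
#' The series is stored as an `H x W x T` NIfTI volume (pixel size in mm
#' on the spatial axes, frame duration in seconds on the third) with a
#' JSON sidecar holding the metadata that NIfTI cannot carry (view label,
#' subject id, TR).
#'
#' @param series A `cine_series`.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return The path, invisibly.
#' @export
write_cine_nifti <- function(series, path) {
  stopifnot(inherits(series, "cine_series"))
  img <- RNifti::asNifti(series$frames,
                         pixdim = c(series$pixel_mm, series$pixel_mm,
                                    series$tr_ms / 1000))
  RNifti::writeNifti(img, path)
  jsonlite::write_json(list(pixel_mm = series$pixel_mm, tr_ms = series$tr_ms,
                            view = series$view, subject = series$subject),
                       paste0(path, ".json"), auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_cine_nifti
#' @export
read_cine_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  meta_path <- paste0(path, ".json")
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path)
          else list(pixel_mm = 1.67, tr_ms = 3.2, view = NA, subject = NA)
  cine_series(array(as.numeric(img), dim = dim(img)),
              pixel_mm = as.numeric(meta$pixel_mm),
              tr_ms = as.numeric(meta$tr_ms),
              view = if (is.null(meta$view)) NA_character_ else as.character(meta$view),
              subject = if (is.null(meta$subject)) NA_character_ else as.character(meta$subject))
}

#' Write a dataset manifest as JSON
#'
#' Records per-sample provenance (view, seed, split, acceleration) so a
#' dataset can be regenerated exactly.
#'
#' @param dataset List of `paired_sample`s.
#' @param path Output JSON path.
#' @return The path, invisibly.
#' @export
write_manifest <- function(dataset, path) {
  entries <- lapply(dataset, function(s)
    list(view = s$view, seed = s$seed, split = s$split,
         spokes_per_frame = s$accel$spokes_per_frame,
         r_factor = s$accel$r_factor, frame_ms = s$accel$frame_ms,
         n_frames = n_frames(s$target)))
  jsonlite::write_json(entries, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
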
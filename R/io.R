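#' Save an RF stack to disk
#'
#' Writes the sample array as a single-precision NIfTI-1 volume with a JSON
#' sidecar (`<path>.json`) carrying the acquisition metadata (geometry
#' fields, frame interval, provenance), following the imaging-community
#' convention of pairing a standard binary volume with a plain-text metadata
#' sidecar. Both files are written to temporaries and renamed into place so
#' an interrupted write never leaves a truncated container.
#'
#' @param stack An [rf_stack()].
#' @param path Output path; conventionally ending in `.nii`.
#' @return Invisibly, `path`.
#' @seealso [load_rf()]
#' @export
save_rf <- function(stack, path) {
  stopifnot(is_rf_stack(stack))
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("directory does not exist: ", dir)
  if (file.access(dir, 2) != 0) stop("directory not writable: ", dir)
  meta <- c(stack$geometry[rf_meta_fields()[["geometry"]]],
            list(frame_interval = stack$frame_interval,
                 provenance = stack$provenance))
  tmp_nii <- tempfile(tmpdir = dir, fileext = ".nii")
  tmp_json <- tempfile(tmpdir = dir, fileext = ".json")
  on.exit(unlink(c(tmp_nii, tmp_json)), add = TRUE)
  RNifti::writeNifti(RNifti::asNifti(stack$samples, datatype = "float"),
                     tmp_nii)
  jsonlite::write_json(meta, tmp_json, auto_unbox = TRUE, digits = NA)
  if (!file.rename(tmp_nii, path) ||
      !file.rename(tmp_json, paste0(path, ".json"))) {
    stop("failed to move container into place at ", path)
  }
  invisible(path)
}

rf_meta_fields <- function() {
  list(geometry = c("n_elements", "pitch", "center_frequency",
                    "fractional_bandwidth", "sampling_rate", "sound_speed"),
       scalar = c("frame_interval"))
}

#' Load an RF stack from disk
#'
#' Reads a container written by [save_rf()]. Every metadata field must be
#' present in the sidecar; a missing field raises an error naming it.
#'
#' @param path Path to the `.nii` volume (the `<path>.json` sidecar must sit
#'   next to it).
#' @return An [rf_stack()].
#' @export
load_rf <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar)) stop("missing metadata sidecar: ", sidecar)
  vol <- RNifti::readNifti(path)
  samples <- array(as.numeric(vol), dim = dim(vol))
  if (length(dim(samples)) != 3L) {
    stop("container must hold a 3-D sample array, got ",
         length(dim(samples)), " dimensions")
  }
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  fields <- rf_meta_fields()
  for (f in c(fields$geometry, fields$scalar)) {
    if (is.null(meta[[f]])) stop("metadata sidecar lacks field \"", f, "\"")
  }
  geom <- array_geometry(n_elements = meta$n_elements,
                         pitch = meta$pitch,
                         center_frequency = meta$center_frequency,
                         fractional_bandwidth = meta$fractional_bandwidth,
                         sampling_rate = meta$sampling_rate,
                         sound_speed = meta$sound_speed)
  if (dim(samples)[1] != geom$n_elements) {
    stop("sample array first dimension (", dim(samples)[1],
         ") does not match metadata field \"n_elements\" (",
         geom$n_elements, ")")
  }
  rf_stack(samples, geom, meta$frame_interval,
           if (is.null(meta$provenance)) "unspecified" else meta$provenance)
}

#' Export a reconstructed image as a 32-bit float TIFF
#'
#' For visual inspection in external viewers. TIFF writers clamp values to
#' [0, 1], so the image is rescaled by its maximum absolute value before
#' writing; the scale factor is returned so quantitative work can stay with
#' the in-memory [pa_image()].
#'
#' @param image A [pa_image()] or plain matrix.
#' @param path Output TIFF path.
#' @return Invisibly, the scale factor that was divided out.
#' @export
write_pa_tiff <- function(image, path) {
  px <- if (inherits(image, "pa_image")) image$pixels else as.matrix(image)
  m <- max(abs(px))
  scale <- if (m > 0) m else 1
  tiff::writeTIFF(pmin(pmax(px / scale, 0), 1), path, bits.per.sample = 32L)
  invisible(scale)
}
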
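#' Linear-array acquisition geometry
#'
#' Describes the ultrasound detection array and sampling used to record
#' photoacoustic RF data. The default corresponds to a 128-element, 0.3 mm
#' pitch (38.4 mm aperture) linear array with 7 MHz center frequency and an
#' 80.9% -6 dB fractional bandwidth, sampled at 40 MHz with an assumed sound
#' speed of 1500 m/s.
#'
#' @param n_elements Number of transducer elements (>= 1).
#' @param pitch Element pitch in mm.
#' @param center_frequency Element center frequency in MHz.
#' @param fractional_bandwidth -6 dB fractional bandwidth in percent of the
#'   center frequency.
#' @param sampling_rate RF sampling rate in MHz; must exceed twice the center
#'   frequency (Nyquist).
#' @param sound_speed Speed of sound in m/s.
#'
#' @return An object of class `array_geometry`.
#' @examples
#' geom <- array_geometry()
#' aperture_mm(geom) # 38.4
#' @export
array_geometry <- function(n_elements = 128L,
                           pitch = 0.3,
                           center_frequency = 7,
                           fractional_bandwidth = 80.9,
                           sampling_rate = 40,
                           sound_speed = 1500) {
  n_elements <- as.integer(n_elements)
  stopifnot(length(n_elements) == 1L, n_elements >= 1L)
  stopifnot(is.numeric(pitch), length(pitch) == 1L, pitch > 0)
  stopifnot(center_frequency > 0, sound_speed > 0)
  if (!(sampling_rate > 2 * center_frequency)) {
    stop("sampling_rate (", sampling_rate, " MHz) must exceed twice the ",
         "center frequency (Nyquist: > ", 2 * center_frequency, " MHz)")
  }
  structure(
    list(n_elements = n_elements,
         pitch = as.numeric(pitch),
         center_frequency = as.numeric(center_frequency),
         fractional_bandwidth = as.numeric(fractional_bandwidth),
         sampling_rate = as.numeric(sampling_rate),
         sound_speed = as.numeric(sound_speed)),
    class = "array_geometry"
  )
}

#' @export
print.array_geometry <- function(x, ...) {
  cat("Linear array geometry\n")
  cat(sprintf("  %d elements, pitch %.3g mm (aperture %.4g mm)\n",
              x$n_elements, x$pitch, aperture_mm(x)))
  cat(sprintf("  fc %.3g MHz (-6 dB BW %.3g%%), fs %.3g MHz, c %.4g m/s\n",
              x$center_frequency, x$fractional_bandwidth,
              x$sampling_rate, x$sound_speed))
  invisible(x)
}

#' Aperture length of a linear array
#'
#' @param geom An [array_geometry()].
#' @return Aperture `n_elements * pitch` in mm.
#' @export
aperture_mm <- function(geom) {
  stopifnot(inherits(geom, "array_geometry"))
  geom$n_elements * geom$pitch
}

#' Lateral element center positions
#'
#' Element centers in mm, symmetric about 0 (the array midpoint).
#'
#' @param geom An [array_geometry()].
#' @return Numeric vector of length `n_elements`.
#' @export
element_positions_mm <- function(geom) {
  stopifnot(inherits(geom, "array_geometry"))
  (seq_len(geom$n_elements) - (geom$n_elements + 1) / 2) * geom$pitch
}
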
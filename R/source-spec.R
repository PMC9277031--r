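#' Optical source and spectrometer specification
#'
#' Describes the SD-OCT light source and detection spectrometer: a broadband
#' source centred at `center_wavelength` with FWHM bandwidth `bandwidth_fwhm`,
#' sampled by a spectrometer of resolution `spectrometer_resolution` over
#' `n_spectral_pixels` detector pixels. These four numbers fix the axial
#' resolution and the maximum imaging depth of the instrument.
#'
#' @param center_wavelength Centre wavelength \eqn{\lambda_0} in nm.
#' @param bandwidth_fwhm Source FWHM bandwidth \eqn{\Delta\lambda} in nm.
#' @param spectrometer_resolution Spectrometer sampling interval
#'   \eqn{\delta\lambda} in nm.
#' @param n_spectral_pixels Number of spectrometer pixels.
#' @return An object of class `source_spec`.
#' @examples
#' src <- source_spec()
#' axial_resolution(src)
#' max_imaging_depth(src)
#' @export
source_spec <- function(center_wavelength = 840,
                        bandwidth_fwhm = 50,
                        spectrometer_resolution = 0.09,
                        n_spectral_pixels = 1024) {
  stopifnot(
    center_wavelength > 0, bandwidth_fwhm > 0,
    spectrometer_resolution > 0, n_spectral_pixels >= 8
  )
  if (spectrometer_resolution > bandwidth_fwhm) {
    abort("Spectrometer resolution must not exceed the source bandwidth.")
  }
  structure(
    list(
      center_wavelength = center_wavelength,
      bandwidth_fwhm = bandwidth_fwhm,
      spectrometer_resolution = spectrometer_resolution,
      n_spectral_pixels = as.integer(n_spectral_pixels)
    ),
    class = "source_spec"
  )
}

#' @export
print.source_spec <- function(x, ...) {
  cat(sprintf(
    "<source_spec> λ0 = %g nm, Δλ = %g nm (FWHM), δλ = %g nm, %d px\n",
    x$center_wavelength, x$bandwidth_fwhm, x$spectrometer_resolution,
    x$n_spectral_pixels
  ))
  cat(sprintf(
    "  axial resolution (n = 1): %.2f um; max imaging depth: %.3f mm\n",
    axial_resolution(x), max_imaging_depth(x)
  ))
  invisible(x)
}

# uniform wavelength grid centred on lambda0
wavelength_grid <- function(source) {
  n <- source$n_spectral_pixels
  source$center_wavelength +
    (seq_len(n) - (n + 1) / 2) * source$spectrometer_resolution
}

#' Theoretical axial resolution of an SD-OCT source
#'
#' Coherence-length axial resolution of a Gaussian source,
#' \eqn{(2\ln 2/\pi)\,\lambda_0^2/\Delta\lambda}, divided by the tissue
#' refractive index (the resolution improves inside a medium).
#'
#' @param source A [source_spec()].
#' @param refractive_index Group refractive index of the medium (>= 1).
#' @return Axial resolution in micrometres.
#' @export
axial_resolution <- function(source, refractive_index = 1) {
  stopifnot(inherits(source, "source_spec"), refractive_index >= 1)
  lc_nm <- (2 * log(2) / pi) *
    source$center_wavelength^2 / source$bandwidth_fwhm
  lc_nm / 1000 / refractive_index
}

#' Maximum imaging depth set by the spectrometer resolution
#'
#' Nyquist depth of spectral sampling, \eqn{\lambda_0^2/(4\,\delta\lambda)}.
#' Reflectors beyond this optical depth alias back into the image.
#'
#' @param source A [source_spec()].
#' @return Maximum optical imaging depth in millimetres.
#' @export
max_imaging_depth <- function(source) {
  stopifnot(inherits(source, "source_spec"))
  source$center_wavelength^2 / (4 * source$spectrometer_resolution) / 1e6
}
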
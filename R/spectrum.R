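#' Specify a transform-limited Gaussian pulse
#'
#' @param centerWavelength vacuum centre wavelength, nm
#' @param durationFwhm intensity FWHM of the transform-limited pulse, fs
#' @param nSamples number of spectral samples (1 = monochromatic / CW limit)
#' @return a \linkS4class{PulseSpec}
#' @examples
#' pulseSpec(780, 20, 33)
#' @export
pulseSpec <- function(centerWavelength, durationFwhm, nSamples = 33L) {
  if (!is.numeric(durationFwhm) || durationFwhm <= 0)
    stop("durationFwhm must be a positive duration in fs")
  if (nSamples < 1) stop("nSamples must be >= 1")
  new("PulseSpec", centerWavelength = as.numeric(centerWavelength),
      durationFwhm = as.numeric(durationFwhm), nSamples = as.integer(nSamples))
}

#' Sample the Gaussian spectrum of a transform-limited pulse
#'
#' The spectral intensity is Gaussian in optical frequency with FWHM
#' Delta nu = 2 ln 2 / (pi tau) (the transform-limited time-bandwidth
#' product Delta nu * tau = 0.441 for Gaussian pulses), sampled uniformly in
#' frequency over +/- 3 intensity standard deviations. Amplitudes are the
#' square roots of the spectral intensities with zero spectral phase.
#'
#' @param pulse a \linkS4class{PulseSpec}
#' @return a \linkS4class{Spectrum}; for nSamples = 1 a single line at the
#'   centre wavelength with unit amplitude
#' @examples
#' sp <- makePulseSpectrum(pulseSpec(780, 20, 65))
#' @export
makePulseSpectrum <- function(pulse) {
  stopifnot(is(pulse, "PulseSpec"))
  nu0 <- .C_NM_FS / pulse@centerWavelength * 1000  # THz (1/fs * 1000)
  if (pulse@nSamples == 1L)
    return(new("Spectrum", wavelengths = pulse@centerWavelength,
               amplitudes = 1, centerWavelength = pulse@centerWavelength))
  dnuFwhm <- 2 * log(2) / (pi * pulse@durationFwhm) * 1000  # THz
  sigma <- dnuFwhm / (2 * sqrt(2 * log(2)))                 # intensity std, THz
  nu <- nu0 + seq(-3, 3, length.out = pulse@nSamples) * sigma
  nu <- nu[nu > 0]
  intensity <- exp(-(nu - nu0)^2 / (2 * sigma^2))
  lambda <- .C_NM_FS * 1000 / nu  # nm
  ord <- order(lambda)
  new("Spectrum", wavelengths = lambda[ord], amplitudes = sqrt(intensity)[ord],
      centerWavelength = pulse@centerWavelength)
}

# Optical frequencies (THz) of a Spectrum, in storage (wavelength) order.
.spectrumFrequencies <- function(spectrum) {
  .C_NM_FS * 1000 / spectrum@wavelengths
}
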
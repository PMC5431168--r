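#' Specify a refractive cubic (Airy) phase mask
#'
#' @param alpha cubic modulation depth: centre-to-edge phase difference in
#'   full wave cycles at the reference wavelength
#' @param referenceWavelength nm, default 532
#' @param apertureRadius mm, default 3.5
#' @param substrate \linkS4class{DispersionModel} of the substrate,
#'   default fused silica
#' @return a \linkS4class{CubicMaskSpec}
#' @examples
#' cubicMask(7)
#' @export
cubicMask <- function(alpha, referenceWavelength = 532, apertureRadius = 3.5,
                      substrate = dispersionModel("fused_silica")) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0)
    stop("alpha must be a single positive number")
  new("CubicMaskSpec", alpha = as.numeric(alpha),
      referenceWavelength = as.numeric(referenceWavelength),
      apertureRadius = as.numeric(apertureRadius), substrate = substrate)
}

#' The manufactured four-region mask
#'
#' The reference mask is divided into four regions with cubic modulation
#' depths alpha = 3.5, 7, 14 and 21 (full wave cycles at 532 nm over a
#' 3.5 mm aperture radius).
#'
#' @return named list of four \linkS4class{CubicMaskSpec} objects
#' @export
airyMaskSet <- function() {
  a <- c(3.5, 7, 14, 21)
  stats::setNames(lapply(a, cubicMask), paste0("alpha_", sub("\\.", "p", a)))
}

#' Phase of the cubic mask at a normalized mask coordinate
#'
#' phi(u, lambda) = 2 pi alpha u^3 (lambda_ref / lambda) *
#' (n_sub(lambda) - 1) / (n_sub(lambda_ref) - 1): the phase a refractive
#' cubic surface imparts, scaled from the reference-wavelength calibration by
#' the wavenumber and the substrate dispersion. At lambda = lambda_ref the
#' centre-to-edge difference is exactly 2 pi alpha. The pure-wavenumber
#' approximation (phase proportional to 1/lambda, dispersion ignored) is
#' available with \code{dispersive = FALSE}.
#'
#' @param mask a \linkS4class{CubicMaskSpec}
#' @param u normalized mask coordinate(s) in [-1, 1] (u = 1 is the aperture
#'   edge, radius \code{apertureRadius})
#' @param wavelength vacuum wavelength, nm
#' @param dispersive include substrate dispersion in the wavelength scaling
#' @return phase in radians, vectorized over u
#' @examples
#' cubicMaskPhase(cubicMask(7), 1, 532) / (2 * pi)  # 7 wave cycles
#' @export
cubicMaskPhase <- function(mask, u, wavelength, dispersive = TRUE) {
  stopifnot(is(mask, "CubicMaskSpec"))
  if (any(abs(u) > 1 + 1e-12)) stop("mask coordinate |u| must not exceed 1")
  scale <- mask@referenceWavelength / wavelength
  if (dispersive && mask@substrate@name != "vacuum") {
    nRef <- refractiveIndex(mask@substrate, mask@referenceWavelength)
    nLam <- refractiveIndex(mask@substrate, wavelength)
    scale <- scale * (nLam - 1) / (nRef - 1)
  }
  2 * pi * mask@alpha * u^3 * scale
}

#' Surface height profile of the cubic mask
#'
#' h(u) = alpha lambda_ref u^3 / (n_sub(lambda_ref) - 1), the physical
#' surface relief that produces \code{\link{cubicMaskPhase}} through
#' (2 pi / lambda) (n_sub(lambda) - 1) h(u).
#'
#' @inheritParams cubicMaskPhase
#' @return surface height in um, vectorized over u
#' @export
maskHeightProfile <- function(mask, u) {
  stopifnot(is(mask, "CubicMaskSpec"))
  if (any(abs(u) > 1 + 1e-12)) stop("mask coordinate |u| must not exceed 1")
  nRef <- refractiveIndex(mask@substrate, mask@referenceWavelength)
  mask@alpha * (mask@referenceWavelength / 1000) * u^3 / (nRef - 1)
}
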
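#' Excitation-path configuration
#'
#' Defaults describe the reference instrument: Olympus 10x/0.3 water-dipping
#' excitation objective (effective focal length 18 mm with a 180 mm tube
#' lens), a 2x relay telescope imaging the 3.5 mm phase mask onto the back
#' aperture, water immersion. The Gaussian pupil amplitude is
#' A(u) = exp(-(u / fillFactor)^2) on the normalized pupil coordinate
#' u in [-1, 1], i.e. fillFactor is the beam radius (amplitude 1/e,
#' intensity 1/e^2) in units of the pupil aperture radius.
#'
#' @param naExcitation excitation numerical aperture
#' @param fillFactor Gaussian pupil fill (see above); 1.0 is the best-case
#'   default, \code{\link{calibrateFillFactor}} yields the measured-match fill
#' @param immersion immersion \linkS4class{DispersionModel}
#' @param objectiveFocal effective focal length of the objective, mm
#' @param relayMagnification mask-to-pupil relay magnification
#' @param nPupil pupil quadrature samples
#' @return an \linkS4class{IlluminationConfig}
#' @export
illuminationConfig <- function(naExcitation = 0.3, fillFactor = 1.0,
                               immersion = dispersionModel("water"),
                               objectiveFocal = 18, relayMagnification = 2,
                               nPupil = 1025L) {
  new("IlluminationConfig", naExcitation = naExcitation,
      fillFactor = fillFactor, immersion = immersion,
      objectiveFocal = objectiveFocal,
      relayMagnification = relayMagnification, nPupil = as.integer(nPupil))
}

#' Sampling grid for sheet fields
#'
#' @param x propagation-axis positions, um (uniform)
#' @param z thickness-axis positions, um (uniform)
#' @return a \linkS4class{SheetGrid}
#' @export
sheetGrid <- function(x, z) new("SheetGrid", x = as.numeric(x), z = as.numeric(z))

# Diffraction-limited single-photon axial FWHM used for the sampling guard
# (uniformly filled line pupil: 0.443 lambda / NA).
.diffractionFwhm <- function(naExcitation, wavelengthNm) {
  0.443 * (wavelengthNm / 1000) / naExcitation
}

.checkAxialSampling <- function(config, grid, wavelengthNm) {
  dz <- grid@z[2] - grid@z[1]
  fw <- .diffractionFwhm(config@naExcitation, wavelengthNm)
  if (dz > fw / 8)
    stop(sprintf(paste0("configuration error: z spacing %.4g um too coarse; ",
                        "need >= 8 samples across the diffraction-limited ",
                        "FWHM (%.4g um), i.e. dz <= %.4g um"),
                 dz, fw, fw / 8))
  invisible(TRUE)
}

#' Monochromatic light-sheet field from the pupil function
#'
#' Evaluates the scalar line-focus field
#' E(x, z) = integral A(u) exp(i phi_mask) exp(i k n_w x sqrt(1 - (NA u / n_w)^2))
#' exp(i k NA u z) du over the normalized pupil coordinate u in [-1, 1] by
#' trapezoidal quadrature, with A(u) the Gaussian pupil amplitude, k the
#' vacuum wavenumber and n_w the immersion index. The exact (non-paraxial)
#' defocus phase is used. The cubic mask phase is evaluated at the mask-plane
#' coordinate obtained by demagnifying the pupil coordinate through the relay
#' (pupil radius NA x f_objective, mask image radius relayMagnification x
#' apertureRadius); pupil zones beyond the mask edge are blocked.
#'
#' @param config an \linkS4class{IlluminationConfig}
#' @param mask a \linkS4class{CubicMaskSpec} or NULL for the plain Gaussian sheet
#' @param wavelength vacuum wavelength, nm
#' @param grid a \linkS4class{SheetGrid} (um)
#' @return complex matrix length(x) by length(z) with attributes "x", "z",
#'   "wavelength"
#' @export
monochromaticSheetField <- function(config, mask, wavelength, grid) {
  stopifnot(is(config, "IlluminationConfig"), is(grid, "SheetGrid"))
  .checkAxialSampling(config, grid, wavelength)
  nw <- refractiveIndex(config@immersion, wavelength)
  if (config@naExcitation >= nw)
    stop("naExcitation must be smaller than the immersion index")
  k <- 2 * pi / (wavelength / 1000)  # rad / um
  u <- seq(-1, 1, length.out = config@nPupil)
  du <- u[2] - u[1]
  w <- rep(du, config@nPupil); w[c(1, config@nPupil)] <- du / 2
  A <- exp(-(u / config@fillFactor)^2)
  phiMask <- 0
  if (!is.null(mask)) {
    stopifnot(is(mask, "CubicMaskSpec"))
    pupilRadius <- config@naExcitation * config@objectiveFocal  # mm
    uMask <- u * pupilRadius / (config@relayMagnification * mask@apertureRadius)
    blocked <- abs(uMask) > 1
    A[blocked] <- 0
    uMask[blocked] <- 0
    phiMask <- cubicMaskPhase(mask, uMask, wavelength)
  }
  defoc <- k * nw * outer(sqrt(pmax(0, 1 - (config@naExcitation * u / nw)^2)),
                          grid@x)                       # nPupil x nx
  P <- (w * A * exp(1i * phiMask)) * exp(1i * defoc)    # nPupil x nx
  Z <- exp(1i * k * config@naExcitation * outer(u, grid@z))  # nPupil x nz
  E <- cmatmul(t(P), Z)
  attr(E, "x") <- grid@x; attr(E, "z") <- grid@z
  attr(E, "wavelength") <- wavelength
  E
}

#' Two-photon excitation response of a (pulsed) light sheet
#'
#' For each spectral sample the monochromatic field is propagated with its
#' own wavelength-dependent mask phase, immersion index and defocus phase.
#' The constant and group-delay parts of the common spectral phase are
#' referenced out at the grid point nearest (x = 0, z = 0), emulating the
#' experimental dispersion-compensation optimization; higher-order residual
#' dispersion is retained. The fields are transformed to time on a window of
#' 1 / (frequency spacing) and the two-photon response
#' S(x, z) = integral |E(t)|^4 dt is returned, normalized to peak 1. With
#' nSamples = 1 this reduces exactly to the squared monochromatic intensity.
#'
#' Spectral samples falling outside the joint validity band of the dispersion
#' models (water: 182--1129 nm) are dropped with a warning; this only affects
#' pulses shorter than about 5 fs, whose extreme spectral wings would not be
#' transmitted by a water-immersed system in any case.
#'
#' @param config an \linkS4class{IlluminationConfig}
#' @param mask a \linkS4class{CubicMaskSpec} or NULL
#' @param pulse a \linkS4class{PulseSpec}
#' @param grid a \linkS4class{SheetGrid}
#' @param nTime number of time samples (default 4 x number of spectral samples,
#'   at least 128)
#' @return a \linkS4class{SheetField}
#' @export
twoPhotonSheet <- function(config, mask, pulse, grid, nTime = NULL) {
  stopifnot(is(config, "IlluminationConfig"), is(pulse, "PulseSpec"),
            is(grid, "SheetGrid"))
  spec <- makePulseSpectrum(pulse)
  models <- list(config@immersion)
  if (!is.null(mask)) models <- c(models, list(mask@substrate))
  band <- .jointValidRange(models)
  keep <- spec@wavelengths >= band[1] & spec@wavelengths <= band[2]
  if (!all(keep)) {
    warning(sprintf(paste0("%d of %d spectral samples outside the dispersion-",
                           "model validity band [%g, %g] nm were dropped"),
                    sum(!keep), length(keep), band[1], band[2]))
    if (!any(keep)) stop("no spectral samples inside the dispersion validity band")
    spec <- new("Spectrum", wavelengths = spec@wavelengths[keep],
                amplitudes = spec@amplitudes[keep],
                centerWavelength = spec@centerWavelength)
  }
  nL <- length(spec@wavelengths)
  meta <- list(alpha = if (is.null(mask)) NA_real_ else mask@alpha,
               pulse = list(centerWavelength = pulse@centerWavelength,
                            durationFwhm = pulse@durationFwhm,
                            nSamples = pulse@nSamples),
               naExcitation = config@naExcitation,
               fillFactor = config@fillFactor)
  if (nL == 1L) {
    E <- monochromaticSheetField(config, mask, spec@wavelengths[1], grid)
    S <- (Mod(E)^2)^2
    meta$normalization <- max(S)
    return(new("SheetField", grid = grid, values = S / max(S), meta = meta))
  }
  nu <- .spectrumFrequencies(spec) / 1000           # 1 / fs, decreasing order? no:
  ord <- order(nu)                                  # ensure increasing frequency
  nu <- nu[ord]
  lams <- spec@wavelengths[ord]
  amps <- spec@amplitudes[ord]
  nx <- length(grid@x); nz <- length(grid@z)
  i0x <- which.min(abs(grid@x)); i0z <- which.min(abs(grid@z))
  G <- matrix(0 + 0i, nx * nz, nL)
  ref <- complex(nL)
  for (j in seq_len(nL)) {
    E <- monochromaticSheetField(config, mask, lams[j], grid)
    ref[j] <- E[i0x, i0z]
    G[, j] <- as.vector(E)
  }
  # reference out constant + group-delay spectral phase at (x0, z0),
  # emulating the experimental dispersion-compensation optimization
  phi <- .unwrapPhase(Arg(ref))
  fit <- stats::lsfit(nu, phi)
  phiLin <- fit$coefficients[1] + fit$coefficients[2] * nu
  G <- G * matrix(amps * exp(-1i * phiLin), nx * nz, nL, byrow = TRUE)
  dnu <- nu[2] - nu[1]
  if (max(abs(diff(nu) - dnu)) > 1e-9 * dnu)
    stop("spectral samples must be uniform in frequency")
  if (is.null(nTime)) nTime <- max(128L, 4L * nL)
  Twin <- 1 / dnu                                    # fs
  t <- seq(-Twin / 2, Twin / 2, length.out = nTime + 1L)[seq_len(nTime)]
  dt <- t[2] - t[1]
  # carrier removed: envelope frequencies relative to band centre
  nuRel <- nu - mean(nu)
  Texp <- exp(-2i * pi * outer(nuRel, t))            # nL x nTime
  Et <- cmatmul(G, Texp)                             # (nx nz) x nTime
  P4 <- Mod(Et)^4
  # The reconstruction is periodic with period 1 / dnu, and the time
  # integral of |E(t)|^4 over one full period is invariant under the
  # circular shift produced by any residual group delay (e.g. the pulse
  # front arriving later far from the waist). Aliasing therefore only
  # occurs when the stretched pulse fills a substantial fraction of the
  # window: flag points whose |E(t)|^4 stays above 1e-6 of its local peak
  # over more than half the period.
  rowMax <- P4[, 1L]
  for (j in 2:nTime) rowMax <- pmax(rowMax, P4[, j])
  significant <- rowMax > 1e-9 * max(rowMax)
  occupancy <- rowSums(P4 > 1e-6 * rowMax) / nTime
  if (any(occupancy[significant] > 0.5))
    stop(paste0("sampling error: the pulse fills more than half of the ",
                "reconstruction time window; increase the number of ",
                "spectral samples (finer frequency spacing widens the ",
                "window)"))
  S <- matrix(rowSums(P4) * dt, nx, nz)
  meta$normalization <- max(S)
  new("SheetField", grid = grid, values = S / max(S), meta = meta)
}

.unwrapPhase <- function(p) {
  d <- diff(p)
  jumps <- round(d / (2 * pi))
  p - c(0, cumsum(jumps)) * 2 * pi
}

#' Effective cubic depth and parabolic trajectory of an Airy sheet
#'
#' \code{effectiveCubicDepth} is the cubic modulation depth seen at the
#' objective pupil edge: the mask's alpha scaled to the working wavelength
#' (wavenumber times substrate dispersion) and by the cube of the
#' pupil-to-mask aperture ratio of the relay.
#' \code{airyTrajectoryApex} evaluates the stationary-phase prediction for
#' the main-lobe deflection z(x) = x^2 NA^3 / (12 alpha_eff lambda n_w^2),
#' used to size simulation grids and to cross-check the parabolic
#' acceleration of the beam.
#'
#' @param config an \linkS4class{IlluminationConfig}
#' @param mask a \linkS4class{CubicMaskSpec}
#' @param wavelength nm
#' @param x propagation distance(s) from the waist, um
#' @return \code{effectiveCubicDepth}: wave cycles (dimensionless);
#'   \code{airyTrajectoryApex}: deflection in um
#' @export
effectiveCubicDepth <- function(config, mask, wavelength) {
  pupilRadius <- config@naExcitation * config@objectiveFocal
  trunc <- min(1, pupilRadius / (config@relayMagnification * mask@apertureRadius))
  cubicMaskPhase(mask, 1, wavelength) / (2 * pi) * trunc^3
}

#' @rdname effectiveCubicDepth
#' @export
airyTrajectoryApex <- function(config, mask, wavelength, x) {
  aEff <- effectiveCubicDepth(config, mask, wavelength)
  nw <- refractiveIndex(config@immersion, wavelength)
  x^2 * config@naExcitation^3 / (12 * aEff * (wavelength / 1000) * nw^2)
}

#' Calibrate the Gaussian pupil fill against a measured waist resolution
#'
#' Root-solves the fill factor so that the simulated two-photon axial FWHM of
#' the Gaussian sheet at the waist equals \code{targetFwhm}. Used to
#' reconcile best-case simulations (fill 1.0) with the measured Gaussian
#' axial resolution (1.4 um at 780 nm in the reference system).
#'
#' @param targetFwhm target two-photon axial FWHM at the waist, um
#' @param wavelength nm
#' @param config template \linkS4class{IlluminationConfig}; its fillFactor is
#'   ignored
#' @param interval search interval for the fill factor
#' @return the calibrated fill factor
#' @export
calibrateFillFactor <- function(targetFwhm = 1.4, wavelength = 780,
                                config = illuminationConfig(),
                                interval = c(0.15, 1.5)) {
  z <- seq(-4 * targetFwhm, 4 * targetFwhm, by = targetFwhm / 40)
  grid <- sheetGrid(c(-1e-9, 0, 1e-9), z)
  waistFwhm <- function(f) {
    cfg <- config; cfg@fillFactor <- f
    E <- monochromaticSheetField(cfg, NULL, wavelength, grid)
    mainLobeFwhm(z, Mod(E[2, ])^4)$fwhm
  }
  stats::uniroot(function(f) waistFwhm(f) - targetFwhm,
                 interval = interval, tol = 1e-4)$root
}
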
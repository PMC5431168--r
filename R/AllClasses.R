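#' @import methods
NULL

#' Sellmeier dispersion model for an optical material
#'
#' Holds the coefficients of a published Sellmeier equation
#' n^2(lambda) - 1 = sum_i A_i lambda^2 / (lambda^2 - L_i), with lambda in
#' micrometres, together with the wavelength range over which the source
#' tabulation is valid.
#'
#' @slot name material identifier ("vacuum", "fused_silica" or "water")
#' @slot coefA numeric, Sellmeier numerators A_i (dimensionless)
#' @slot coefL numeric, Sellmeier denominators L_i (um^2)
#' @slot validRange numeric(2), validity range of the source fit in nm
#' @slot source character, literature reference for the coefficients
#' @export
setClass("DispersionModel",
  representation(name = "character", coefA = "numeric", coefL = "numeric",
                 validRange = "numeric", source = "character"))

setValidity("DispersionModel", function(object) {
  if (length(object@coefA) != length(object@coefL))
    return("coefA and coefL must have equal length")
  if (length(object@validRange) != 2L || diff(object@validRange) <= 0)
    return("validRange must be c(min, max) in nm with min < max")
  TRUE
})

#' Transform-limited Gaussian pulse specification
#'
#' @slot centerWavelength vacuum centre wavelength in nm
#' @slot durationFwhm intensity full width at half maximum of the
#'   transform-limited pulse in fs
#' @slot nSamples number of spectral samples; 1 means the monochromatic
#'   (continuous-wave) limit
#' @export
setClass("PulseSpec",
  representation(centerWavelength = "numeric", durationFwhm = "numeric",
                 nSamples = "integer"))

setValidity("PulseSpec", function(object) {
  if (object@durationFwhm <= 0) return("durationFwhm must be positive (fs)")
  if (object@nSamples < 1L) return("nSamples must be >= 1")
  if (object@centerWavelength <= 0) return("centerWavelength must be positive (nm)")
  TRUE
})

#' Sampled complex spectral amplitudes of an excitation pulse
#'
#' Wavelengths are vacuum wavelengths in nm, strictly increasing; amplitudes
#' are non-negative spectral field amplitudes (square roots of spectral
#' intensity, zero spectral phase, i.e. a transform-limited pulse).
#'
#' @slot wavelengths numeric, nm, strictly increasing
#' @slot amplitudes numeric, arbitrary units, not all zero
#' @slot centerWavelength numeric, nm
#' @export
setClass("Spectrum",
  representation(wavelengths = "numeric", amplitudes = "numeric",
                 centerWavelength = "numeric"))

setValidity("Spectrum", function(object) {
  if (length(object@wavelengths) < 1L) return("at least one spectral sample")
  if (length(object@wavelengths) != length(object@amplitudes))
    return("wavelengths and amplitudes must have equal length")
  if (any(diff(object@wavelengths) <= 0))
    return("wavelengths must be strictly increasing")
  if (all(object@amplitudes == 0)) return("amplitudes must not all be zero")
  if (any(object@amplitudes < 0)) return("amplitudes must be non-negative")
  TRUE
})

#' Refractive cubic (Airy) phase mask specification
#'
#' The cubic modulation depth alpha is the centre-to-edge phase difference of
#' the mask in full wave cycles at the reference wavelength (532 nm for the
#' manufactured four-region mask, whose regions carry alpha = 3.5, 7, 14, 21
#' over a 3.5 mm aperture radius).
#'
#' @slot alpha cubic modulation depth in full wave cycles at referenceWavelength
#' @slot referenceWavelength nm (532 for the manufactured mask)
#' @slot apertureRadius mm (3.5 for the manufactured mask)
#' @slot substrate a \linkS4class{DispersionModel} (fused silica)
#' @export
setClass("CubicMaskSpec",
  representation(alpha = "numeric", referenceWavelength = "numeric",
                 apertureRadius = "numeric", substrate = "DispersionModel"))

setValidity("CubicMaskSpec", function(object) {
  if (object@alpha <= 0) return("alpha must be positive")
  if (object@apertureRadius <= 0) return("apertureRadius must be positive (mm)")
  if (object@referenceWavelength <= 0) return("referenceWavelength must be positive (nm)")
  TRUE
})

#' Excitation-path configuration
#'
#' Describes the excitation objective, the Gaussian pupil fill and the relay
#' that images the phase mask onto the objective back aperture. The pupil
#' radius is naExcitation * objectiveFocal; the mask plane is magnified by
#' relayMagnification before the back aperture, so pupil coordinate u = 1
#' maps to mask radius pupilRadius / relayMagnification.
#'
#' @slot naExcitation numerical aperture of the excitation objective
#' @slot fillFactor ratio of the Gaussian pupil beam radius (amplitude 1/e,
#'   i.e. intensity 1/e^2 radius) to the pupil aperture radius
#' @slot immersion \linkS4class{DispersionModel} of the immersion medium (water)
#' @slot objectiveFocal effective focal length of the excitation objective, mm
#' @slot relayMagnification magnification of the mask-to-pupil relay telescope
#' @slot nPupil number of pupil quadrature samples
#' @export
setClass("IlluminationConfig",
  representation(naExcitation = "numeric", fillFactor = "numeric",
                 immersion = "DispersionModel", objectiveFocal = "numeric",
                 relayMagnification = "numeric", nPupil = "integer"))

setValidity("IlluminationConfig", function(object) {
  if (object@naExcitation <= 0) return("naExcitation must be positive")
  if (object@fillFactor <= 0) return("fillFactor must be positive")
  if (object@objectiveFocal <= 0) return("objectiveFocal must be positive (mm)")
  if (object@relayMagnification <= 0) return("relayMagnification must be positive")
  if (object@nPupil < 64L) return("nPupil must be at least 64")
  TRUE
})

#' Sampling grid for a light-sheet field
#'
#' x is the propagation axis of the sheet and z the sheet-thickness axis
#' (the detection optical axis), both in micrometres and uniformly spaced.
#'
#' @slot x numeric, propagation-axis sample positions (um)
#' @slot z numeric, thickness-axis sample positions (um)
#' @export
setClass("SheetGrid", representation(x = "numeric", z = "numeric"))

setValidity("SheetGrid", function(object) {
  for (ax in c("x", "z")) {
    v <- slot(object, ax)
    if (length(v) < 2L) return(sprintf("axis %s needs at least 2 samples", ax))
    d <- diff(v)
    if (any(d <= 0)) return(sprintf("axis %s must be strictly increasing", ax))
    if (max(d) - min(d) > 1e-9 * max(abs(d)))
      return(sprintf("axis %s must be uniformly spaced", ax))
  }
  TRUE
})

#' Sampled light-sheet excitation response
#'
#' values[i, j] holds the (single- or two-photon) excitation response at
#' (x[i], z[j]), normalized to peak 1 and non-negative. For two-photon
#' fields this is the time-integrated squared intensity S(x, z).
#'
#' @slot grid a \linkS4class{SheetGrid}
#' @slot values numeric matrix, length(x) by length(z), >= 0, max 1
#' @slot meta list describing how the field was computed (alpha, pulse,
#'   configuration, normalization constant)
#' @export
setClass("SheetField",
  representation(grid = "SheetGrid", values = "matrix", meta = "list"))

setValidity("SheetField", function(object) {
  if (!all(dim(object@values) == c(length(object@grid@x), length(object@grid@z))))
    return("values must be length(x) by length(z)")
  if (any(object@values < 0)) return("values must be non-negative")
  if (abs(max(object@values) - 1) > 1e-8) return("values must be normalized to peak 1")
  TRUE
})

#' Modulation transfer function along the sheet-thickness axis
#'
#' @slot nuNormalized spatial frequency nu_z divided by 2 NA / lambda
#' @slot magnitude MTF values in [0, 1], 1 at nu = 0
#' @export
setClass("MTFCurve",
  representation(nuNormalized = "numeric", magnitude = "numeric"))

setValidity("MTFCurve", function(object) {
  if (length(object@nuNormalized) != length(object@magnitude))
    return("frequency and magnitude must have equal length")
  if (abs(object@magnitude[which.min(abs(object@nuNormalized))] - 1) > 1e-8)
    return("magnitude at nu = 0 must be 1")
  if (any(object@magnitude < -1e-12 | object@magnitude > 1 + 1e-8))
    return("magnitude must lie in [0, 1]")
  TRUE
})

#' Synthetic fluorescent-bead phantom
#'
#' Bead centres live in the detection-objective coordinate frame: x along the
#' sheet propagation axis, y the in-focal-plane axis along which the scan
#' drifts, z the detection optical axis (z = 0 is the detection focal plane,
#' where the static sheet is centred).
#'
#' @slot positions numeric matrix n x 3 (columns x, y, z in um)
#' @slot diameters numeric, bead diameters in um
#' @slot brightnesses numeric, expected photon counts at focus
#' @slot box numeric matrix 2 x 3, lower/upper extents of the volume (um)
#' @export
setClass("BeadPhantom",
  representation(positions = "matrix", diameters = "numeric",
                 brightnesses = "numeric", box = "matrix"))

setValidity("BeadPhantom", function(object) {
  n <- nrow(object@positions)
  if (ncol(object@positions) != 3L) return("positions must be n x 3")
  if (length(object@diameters) != n || length(object@brightnesses) != n)
    return("diameters and brightnesses must match the number of beads")
  if (n > 0 && any(object@diameters <= 0)) return("diameters must be positive")
  if (!all(dim(object@box) == c(2L, 3L))) return("box must be 2 x 3")
  if (n > 0) {
    inside <- all(t(object@positions) >= object@box[1, ] - 1e-9) &&
      all(t(object@positions) <= object@box[2, ] + 1e-9)
    if (!inside) return("all bead positions must lie inside the box")
  }
  TRUE
})

#' Detection-path configuration
#'
#' @slot naDetection numerical aperture of the detection objective (0.5)
#' @slot magnification total magnification onto the camera (20)
#' @slot cameraPixel physical camera pixel pitch at the sensor, um (6.5)
#' @slot emissionWavelength nm
#' @slot immersionIndex refractive index of the detection immersion medium
#' @export
setClass("DetectionConfig",
  representation(naDetection = "numeric", magnification = "numeric",
                 cameraPixel = "numeric", emissionWavelength = "numeric",
                 immersionIndex = "numeric"))

setValidity("DetectionConfig", function(object) {
  if (object@naDetection <= 0) return("naDetection must be positive")
  if (object@naDetection >= object@immersionIndex)
    return("naDetection must be smaller than the immersion index")
  if (object@magnification <= 0 || object@cameraPixel <= 0)
    return("magnification and cameraPixel must be positive")
  if (object@emissionWavelength <= 0) return("emissionWavelength must be positive (nm)")
  TRUE
})

#' iSPIM scan geometry
#'
#' The sample is translated along the t-axis at angle angleDeg to the
#' detection optical axis; each frame advances the sample by step um along t.
#' The lateral component (step * sin(theta)) drifts beads along the camera
#' row axis, the axial component (step * cos(theta)) along the detection axis.
#'
#' @slot angleDeg angle between translation axis and detection axis, degrees
#' @slot step translation per frame Delta t, um (0.092 in the reference setup)
#' @slot nFrames number of frames in a stack
#' @export
setClass("ScanGeometry",
  representation(angleDeg = "numeric", step = "numeric", nFrames = "integer"))

setValidity("ScanGeometry", function(object) {
  if (object@angleDeg <= 0 || object@angleDeg >= 90)
    return("angleDeg must lie strictly between 0 and 90")
  if (object@step <= 0) return("step must be positive (um)")
  if (object@nFrames < 1L) return("nFrames must be >= 1")
  TRUE
})

#' Raw iSPIM camera stack with scan metadata
#'
#' @slot frames numeric array nrow x ncol x nFrames of camera counts (>= 0)
#' @slot scan a \linkS4class{ScanGeometry}
#' @slot pixel sample-plane pixel size, um (cameraPixel / magnification)
#' @slot meta list: noise parameters, RNG seed, provenance
#' @export
setClass("ImageStack",
  representation(frames = "array", scan = "ScanGeometry", pixel = "numeric",
                 meta = "list"))

setValidity("ImageStack", function(object) {
  if (length(dim(object@frames)) != 3L) return("frames must be a 3-D array")
  if (dim(object@frames)[3] != object@scan@nFrames)
    return("third dimension of frames must equal scan nFrames")
  if (any(object@frames < 0)) return("counts must be non-negative")
  if (object@pixel <= 0) return("pixel must be positive (um)")
  TRUE
})

#' Aggregated resolution report for one beam type
#'
#' @slot beamLabel character label ("gaussian", "airy_a7", ...)
#' @slot meanFwhmZ mean axial FWHM, um
#' @slot ciFwhmZ 95 percent Student-t confidence half-width, um (NA if n < 2)
#' @slot meanFwhmLateral mean lateral FWHM, um
#' @slot ciFwhmLateral 95 percent confidence half-width, um
#' @slot fov field of view from the sqrt(2)-FWHM criterion, um
#' @slot fovCensored TRUE if the FOV interval touched the measured range
#' @slot n number of uncensored measurements
#' @slot figureOfMerit (depth of field x sheet width) / axial resolution^2
#' @export
setClass("ResolutionSummary",
  representation(beamLabel = "character", meanFwhmZ = "numeric",
                 ciFwhmZ = "numeric", meanFwhmLateral = "numeric",
                 ciFwhmLateral = "numeric", fov = "numeric",
                 fovCensored = "logical", n = "integer",
                 figureOfMerit = "numeric"))
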
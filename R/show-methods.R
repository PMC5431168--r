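#' @describeIn dispersionModel show method
#' @param object a DispersionModel
#' @export
setMethod("show", "DispersionModel", function(object) {
  cat(sprintf("DispersionModel '%s' (%s), valid %g-%g nm\n", object@name,
              object@source, object@validRange[1],
              min(object@validRange[2], 1e6)))
})

setMethod("show", "PulseSpec", function(object) {
  cat(sprintf("PulseSpec: %g nm, %g fs FWHM, %d spectral sample(s)%s\n",
              object@centerWavelength, object@durationFwhm, object@nSamples,
              if (object@nSamples == 1L) " [CW limit]" else ""))
})

setMethod("show", "Spectrum", function(object) {
  cat(sprintf("Spectrum: %d sample(s), %g-%g nm (centre %g nm)\n",
              length(object@wavelengths), min(object@wavelengths),
              max(object@wavelengths), object@centerWavelength))
})

setMethod("show", "CubicMaskSpec", function(object) {
  cat(sprintf(
    "CubicMaskSpec: alpha = %g wave cycles @ %g nm, aperture %g mm, %s\n",
    object@alpha, object@referenceWavelength, object@apertureRadius,
    object@substrate@name))
})

setMethod("show", "IlluminationConfig", function(object) {
  cat(sprintf(
    "IlluminationConfig: NA %g, fill %g, %s immersion, f = %g mm, relay %gx\n",
    object@naExcitation, object@fillFactor, object@immersion@name,
    object@objectiveFocal, object@relayMagnification))
})

setMethod("show", "SheetField", function(object) {
  g <- object@grid
  cat(sprintf(
    "SheetField: %d x %d samples, x [%g, %g] um, z [%g, %g] um%s\n",
    length(g@x), length(g@z), min(g@x), max(g@x), min(g@z), max(g@z),
    if (is.na(object@meta$alpha %||% NA)) " (Gaussian)"
    else sprintf(" (Airy alpha = %g)", object@meta$alpha)))
})

setMethod("show", "BeadPhantom", function(object) {
  cat(sprintf("BeadPhantom: %d bead(s) in [%g x %g x %g] um box\n",
              nrow(object@positions), diff(object@box[, 1]),
              diff(object@box[, 2]), diff(object@box[, 3])))
})

setMethod("show", "ImageStack", function(object) {
  n <- dim(object@frames)
  cat(sprintf(
    "ImageStack: %d frame(s) of %d x %d px (%g um/px), theta = %g deg, dt = %g um\n",
    n[3], n[1], n[2], object@pixel, object@scan@angleDeg, object@scan@step))
})

setMethod("show", "ResolutionSummary", function(object) {
  cat(sprintf("ResolutionSummary [%s]: n = %d\n", object@beamLabel, object@n))
  cat(sprintf("  axial FWHM   %.2f +/- %.2f um (95%% CI)\n",
              object@meanFwhmZ, object@ciFwhmZ))
  cat(sprintf("  lateral FWHM %.2f +/- %.2f um (95%% CI)\n",
              object@meanFwhmLateral, object@ciFwhmLateral))
  cat(sprintf("  FOV          %.0f um%s\n", object@fov,
              if (object@fovCensored) " (censored: lower bound)" else ""))
  if (is.finite(object@figureOfMerit))
    cat(sprintf("  figure of merit %.0f\n", object@figureOfMerit))
})

#' Accessors for sheet fields and stacks
#'
#' @param sheet a \linkS4class{SheetField}
#' @return \code{sheetValues}: the response matrix; \code{sheetX},
#'   \code{sheetZ}: grid axes in um
#' @export
sheetValues <- function(sheet) sheet@values

#' @rdname sheetValues
#' @export
sheetX <- function(sheet) sheet@grid@x

#' @rdname sheetValues
#' @export
sheetZ <- function(sheet) sheet@grid@z

#' @rdname sheetValues
#' @param stack an \linkS4class{ImageStack}
#' @export
stackFrames <- function(stack) stack@frames

#' @rdname sheetValues
#' @export
stackPixel <- function(stack) stack@pixel

#' @rdname sheetValues
#' @export
scanOf <- function(stack) stack@scan

#' @rdname sheetValues
#' @param phantom a \linkS4class{BeadPhantom}
#' @export
beadPositions <- function(phantom) phantom@positions
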
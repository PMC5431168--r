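#' Modulation transfer function of the sheet along the thickness axis
#'
#' Magnitude of the 1-D discrete Fourier transform of S(x0, z) along z,
#' normalized so that MTF(0) = 1, with the frequency axis divided by the
#' maximum transmitted spatial frequency 2 NA / lambda.
#'
#' @param sheet a \linkS4class{SheetField}
#' @param xPosition propagation position at which to take the profile, um
#'   (snapped to the nearest grid sample)
#' @param na numerical aperture used for the frequency normalization
#' @param wavelength wavelength used for the frequency normalization, nm
#' @return an \linkS4class{MTFCurve} (non-negative frequencies)
#' @export
mtfProfile <- function(sheet, xPosition, na, wavelength) {
  stopifnot(is(sheet, "SheetField"))
  x <- sheet@grid@x
  if (xPosition < min(x) - 1e-9 || xPosition > max(x) + 1e-9)
    stop("xPosition outside the sheet grid")
  profile <- sheet@values[which.min(abs(x - xPosition)), ]
  nz <- length(profile)
  dz <- sheet@grid@z[2] - sheet@grid@z[1]
  ft <- Mod(stats::fft(profile))
  nKeep <- floor(nz / 2) + 1L
  freq <- (seq_len(nKeep) - 1L) / (nz * dz)       # cycles / um
  mag <- ft[seq_len(nKeep)] / ft[1]
  nuMax <- 2 * na / (wavelength / 1000)           # cycles / um
  new("MTFCurve", nuNormalized = freq / nuMax, magnitude = pmin(mag, 1))
}

#' Axial resolution versus propagation distance
#'
#' For each x the main lobe is the contiguous region of S(x, z) above half of
#' its global maximum; its FWHM is measured by linear interpolation of the
#' half-maximum crossings. Measurements whose main lobe touches the z grid
#' edge are flagged censored.
#'
#' @param sheet a \linkS4class{SheetField}
#' @return data.frame with columns x (um), fwhm (um), zPeak (um),
#'   censored (logical)
#' @export
axialResolutionCurve <- function(sheet) {
  stopifnot(is(sheet, "SheetField"))
  z <- sheet@grid@z
  res <- lapply(seq_along(sheet@grid@x), function(i) {
    m <- mainLobeFwhm(z, sheet@values[i, ])
    data.frame(x = sheet@grid@x[i], fwhm = m$fwhm, zPeak = m$peak,
               censored = m$censored)
  })
  do.call(rbind, res)
}

#' Usable field of view of a light sheet
#'
#' Length of the maximal contiguous x-interval, containing the minimum of
#' the axial-FWHM curve, over which the FWHM stays below sqrt(2) times its
#' minimum (the confocal-parameter convention; for an ideal Gaussian beam
#' this is twice the Rayleigh range). Interval endpoints are refined by
#' linear interpolation of the threshold crossing. If the criterion is still
#' satisfied at the curve edge the returned length is a lower bound and the
#' result is flagged censored.
#'
#' @param curve data.frame with columns x and fwhm (as from
#'   \code{\link{axialResolutionCurve}}); rows with non-finite fwhm are
#'   ignored
#' @return list with elements fov (um), censored (logical), interval
#'   (numeric(2), um), minFwhm (um), xAtMin (um)
#' @export
estimateFov <- function(curve) {
  stopifnot(is.data.frame(curve), all(c("x", "fwhm") %in% names(curve)))
  curve <- curve[is.finite(curve$fwhm), , drop = FALSE]
  if (nrow(curve) < 8L) stop("FOV estimation needs at least 8 curve points")
  x <- curve$x; fw <- curve$fwhm
  imin <- which.min(fw)
  thr <- sqrt(2) * fw[imin]
  l <- imin
  while (l > 1L && fw[l - 1L] <= thr) l <- l - 1L
  r <- imin
  while (r < length(fw) && fw[r + 1L] <= thr) r <- r + 1L
  censoredL <- l == 1L
  censoredR <- r == length(fw)
  left <- if (censoredL) x[1L] else .crossing(x, fw, l - 1L, thr)
  right <- if (censoredR) x[length(x)] else .crossing(x, fw, r, thr)
  list(fov = right - left, censored = censoredL || censoredR,
       interval = c(left, right), minFwhm = fw[imin], xAtMin = x[imin])
}
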
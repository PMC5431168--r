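#' Extract per-bead PSF measurements from a deskewed volume
#'
#' For each bead a background-subtracted sub-volume centred on its (static)
#' lateral position is taken; the background is the median of the lateral
#' ROI perimeter ring per slice. The axial (z) profile is by default the
#' laterally integrated flux per slice, which is invariant to the
#' defocus-dependent lateral blur; \code{profile = "centroid"} instead uses
#' the interpolated amplitude at the lateral centroid. The FWHM is measured
#' on the contiguous above-half-maximum region by linear interpolation; the
#' lateral FWHM is the mean of the row/col marginal FWHMs at the peak slice.
#' Measurements are labelled by subregion of a configurable grid over the
#' field of view for per-region averaging.
#'
#' @param deskewed list from \code{\link{deskewStack}}
#' @param positions data.frame with columns row, col (0-based px, as from
#'   linked tracks after deskewing) and optionally beadId
#' @param roiRadiusPx lateral ROI half-size, px
#' @param subregionGrid c(nRow, nCol) subregion grid, default 3 x 3
#' @param profile "integrated" (default) or "centroid"
#' @param origin um position of pixel (0, 0) as c(x, y), used to report bead
#'   x positions
#' @return data.frame: beadId, x, y (um), zPeak (um), fwhmZ, fwhmLateral
#'   (um), subregion, censored
#' @export
extractPsf <- function(deskewed, positions, roiRadiusPx = 6L,
                       subregionGrid = c(3L, 3L),
                       profile = c("integrated", "centroid"),
                       origin = c(0, 0)) {
  profile <- match.arg(profile)
  vol <- deskewed$volume
  n <- dim(vol)
  dz <- deskewed$dz; pixel <- deskewed$pixel
  if (is.null(positions$beadId)) positions$beadId <- seq_len(nrow(positions))
  subRow <- function(r) pmin(subregionGrid[1],
                             1L + floor(r / n[1] * subregionGrid[1]))
  subCol <- function(c) pmin(subregionGrid[2],
                             1L + floor(c / n[2] * subregionGrid[2]))
  out <- lapply(seq_len(nrow(positions)), function(i) {
    r0 <- round(positions$row[i]) + 1L   # to 1-based index
    c0 <- round(positions$col[i]) + 1L
    rs <- (r0 - roiRadiusPx):(r0 + roiRadiusPx)
    cs <- (c0 - roiRadiusPx):(c0 + roiRadiusPx)
    clipped <- min(rs) < 1L || max(rs) > n[1] || min(cs) < 1L || max(cs) > n[2]
    rs <- rs[rs >= 1L & rs <= n[1]]; cs <- cs[cs >= 1L & cs <= n[2]]
    sub <- vol[rs, cs, , drop = FALSE]
    zOk <- which(apply(sub, 3, function(m) !anyNA(m)))
    rec <- data.frame(beadId = positions$beadId[i],
                      x = origin[1] + positions$col[i] * pixel,
                      y = origin[2] + positions$row[i] * pixel,
                      zPeak = NA_real_, fwhmZ = NA_real_,
                      fwhmLateral = NA_real_,
                      subregion = (subRow(positions$row[i]) - 1L) *
                        subregionGrid[2] + subCol(positions$col[i]),
                      censored = TRUE)
    if (length(zOk) < 5L || clipped) return(rec)
    prof <- vapply(zOk, function(k) {
      m <- sub[, , k]
      bg <- stats::median(c(m[1, ], m[nrow(m), ], m[, 1], m[, ncol(m)]))
      # flux sums stay unclipped: rectifying the read noise would add a
      # positive pedestal that biases the axial FWHM wide
      if (profile == "integrated") sum(m - bg) else {
      sig <- pmax(m - bg, 0)
        ms <- sum(sig)
        if (ms <= 0) return(0)
        rc <- sum(sig * seq_len(nrow(sig))) / ms
        cc <- sum(t(sig) * seq_len(ncol(sig))) / ms
        # bilinear amplitude at the centroid
        ri <- min(max(floor(rc), 1L), nrow(sig) - 1L)
        ci <- min(max(floor(cc), 1L), ncol(sig) - 1L)
        fr <- rc - ri; fc <- cc - ci
        (1 - fr) * ((1 - fc) * sig[ri, ci] + fc * sig[ri, ci + 1]) +
          fr * ((1 - fc) * sig[ri + 1, ci] + fc * sig[ri + 1, ci + 1])
      }
    }, numeric(1))
    if (max(prof) <= 0) return(rec)
    zUm <- (zOk - 1L) * dz
    mz <- mainLobeFwhm(zUm, prof)
    kPeak <- zOk[which.max(prof)]
    m <- sub[, , kPeak]
    bg <- stats::median(c(m[1, ], m[nrow(m), ], m[, 1], m[, ncol(m)]))
    sig <- m - bg
    latR <- mainLobeFwhm(seq_len(nrow(sig)) * pixel, rowSums(sig))
    latC <- mainLobeFwhm(seq_len(ncol(sig)) * pixel, colSums(sig))
    rec$zPeak <- mz$peak
    rec$fwhmZ <- mz$fwhm
    rec$fwhmLateral <- mean(c(latR$fwhm, latC$fwhm))
    rec$censored <- mz$censored || latR$censored || latC$censored
    rec
  })
  do.call(rbind, out)
}

#' Summarize PSF measurements into a resolution report
#'
#' Mean and Student-t 95 percent confidence interval of the axial and
#' lateral FWHMs over uncensored measurements, plus the measured field of
#' view: the per-x FWHM curve is binned along the propagation axis (default
#' 20 um bins) and passed to \code{\link{estimateFov}}. With fewer than 8
#' occupied bins the FOV is reported as the measured x span, censored.
#'
#' @param measurements data.frame from \code{\link{extractPsf}}
#' @param beamLabel character label for the beam type
#' @param binWidth x bin width for the FOV curve, um
#' @param depthOfField,sheetWidth optional um values; when both are given the
#'   figure of merit (depthOfField x sheetWidth / meanFwhmZ^2) is filled in
#' @return a \linkS4class{ResolutionSummary}
#' @export
summarizeResolution <- function(measurements, beamLabel = "", binWidth = 20,
                                depthOfField = NA_real_,
                                sheetWidth = NA_real_) {
  ok <- measurements[!measurements$censored & is.finite(measurements$fwhmZ), ,
                     drop = FALSE]
  n <- nrow(ok)
  if (n < 2L)
    stop("summarizeResolution needs at least 2 uncensored measurements")
  ciHalf <- function(v) {
    if (length(v) < 2L || stats::sd(v) == 0) return(0)
    stats::qt(0.975, length(v) - 1L) * stats::sd(v) / sqrt(length(v))
  }
  bins <- floor(ok$x / binWidth)
  curve <- do.call(rbind, lapply(split(ok, bins), function(d)
    data.frame(x = mean(d$x), fwhm = mean(d$fwhmZ))))
  curve <- curve[order(curve$x), ]
  if (nrow(curve) >= 8L) {
    fov <- estimateFov(curve)
    fovUm <- fov$fov; fovCens <- fov$censored
  } else {
    fovUm <- diff(range(ok$x)); fovCens <- TRUE
  }
  fom <- if (is.finite(depthOfField) && is.finite(sheetWidth))
    figureOfMerit(depthOfField, sheetWidth, mean(ok$fwhmZ)) else NA_real_
  new("ResolutionSummary", beamLabel = beamLabel,
      meanFwhmZ = mean(ok$fwhmZ), ciFwhmZ = ciHalf(ok$fwhmZ),
      meanFwhmLateral = mean(ok$fwhmLateral),
      ciFwhmLateral = ciHalf(ok$fwhmLateral),
      fov = fovUm, fovCensored = fovCens, n = n, figureOfMerit = fom)
}

#' Dimensionless light-sheet figure of merit
#'
#' (depth of field x width of light sheet) / axial resolution^2 -- a
#' dimensionless metric for comparing light-sheet systems; the reference
#' Airy system (300 um x 300 um at 3 um axial resolution) yields 10,000.
#'
#' @param depthOfField um
#' @param sheetWidth um
#' @param axialResolution um
#' @return dimensionless figure of merit
#' @examples
#' figureOfMerit(300, 300, 3)  # 10000
#' @export
figureOfMerit <- function(depthOfField, sheetWidth, axialResolution) {
  if (any(c(depthOfField, sheetWidth, axialResolution) <= 0) ||
      any(!is.finite(c(depthOfField, sheetWidth, axialResolution))))
    stop("all figure-of-merit inputs must be positive and finite")
  depthOfField * sheetWidth / axialResolution^2
}

#' Nyquist sampling rate of a widefield detection path
#'
#' lambda / (4 NA): the sample-plane pixel pitch required to critically
#' sample the incoherent diffraction limit (cutoff 2 NA / lambda).
#'
#' @param na detection numerical aperture
#' @param emissionWavelength nm
#' @return Nyquist pixel pitch in nm
#' @examples
#' nyquistSampling(0.5, 500)  # 250 nm
#' @export
nyquistSampling <- function(na, emissionWavelength = 500) {
  stopifnot(na > 0, na < 1.5, emissionWavelength > 0)
  emissionWavelength / (4 * na)
}

#' Effective sample-plane pixel size
#'
#' @param cameraPixel camera pixel pitch at the sensor, um
#' @param magnification total magnification
#' @return sample-plane pixel in nm
#' @examples
#' effectiveSamplePixel(6.5, 20)  # 325 nm
#' @export
effectiveSamplePixel <- function(cameraPixel, magnification) {
  stopifnot(cameraPixel > 0, magnification > 0)
  cameraPixel / magnification * 1000
}
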
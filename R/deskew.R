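#' Deskew an iSPIM stack into detection coordinates
#'
#' Frame i (1-based) is translated by -(i - 1) * step * sin(theta) / pixel
#' along the row (drift) axis using linear interpolation; samples shifted in
#' from outside the frame are set to NA (a sentinel excluded from later
#' statistics). After deskewing, a static bead appears as a straight column
#' along the stack dimension, whose spacing is step * cos(theta).
#'
#' @param stack an \linkS4class{ImageStack}
#' @param thetaDeg scan angle, degrees (from \code{\link{estimateScanAngle}}
#'   or metadata); theta = 0 returns the input frames with z spacing = step
#' @return list: volume (nrow x ncol x nFrames array, NA outside the sheared
#'   support), dz (um), pixel (um), thetaDeg
#' @export
deskewStack <- function(stack, thetaDeg = stack@scan@angleDeg) {
  stopifnot(is(stack, "ImageStack"))
  theta <- thetaDeg * pi / 180
  shiftPx <- stack@scan@step * sin(theta) / stack@pixel  # px per frame
  n <- dim(stack@frames)
  if (abs(shiftPx) * (n[3] - 1L) > n[1])
    stop("total deskew shift exceeds the frame height")
  vol <- array(NA_real_, n)
  for (i in seq_len(n[3])) {
    s <- (i - 1L) * shiftPx
    if (s == 0) { vol[, , i] <- stack@frames[, , i]; next }
    # output row r samples input at r + s (rows drift towards larger r)
    src <- seq_len(n[1]) + floor(s)
    f <- s - floor(s)
    lo <- src; hi <- src + 1L
    ok <- lo >= 1L & hi <= n[1]
    okLoOnly <- lo >= 1L & lo <= n[1] & !ok & f == 0
    frame <- stack@frames[, , i]
    out <- matrix(NA_real_, n[1], n[2])
    if (any(ok))
      out[ok, ] <- (1 - f) * frame[lo[ok], , drop = FALSE] +
                   f * frame[hi[ok], , drop = FALSE]
    if (any(okLoOnly)) out[okLoOnly, ] <- frame[lo[okLoOnly], , drop = FALSE]
    vol[, , i] <- out
  }
  list(volume = vol, dz = stack@scan@step * cos(theta), pixel = stack@pixel,
       thetaDeg = thetaDeg)
}
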
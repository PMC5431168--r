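# Shared fixtures, built once per test run and cached.

.fx <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fx[[name]])) .fx[[name]] <- builder()
  .fx[[name]]
}

# Fill factor calibrated so the Gaussian two-photon waist FWHM at 780 nm
# is 1.4 um (the measured Gaussian axial resolution).
calibratedFill <- function() fixture("fill", function() calibrateFillFactor())

# Calibrated Gaussian two-photon sheet (CW limit) over the Gaussian FOV.
calibGaussSheet <- function() fixture("calibGaussSheet", function() {
  cfg <- illuminationConfig(fillFactor = calibratedFill())
  grid <- sheetGrid(seq(-32, 32, by = 0.5), seq(-3.5, 3.5, by = 0.05))
  twoPhotonSheet(cfg, NULL, pulseSpec(780, 20, 1), grid)
})

# Deterministic well-separated bead row for end-to-end pipeline tests.
e2ePhantom <- function(nFrames = 100L, step = 0.092) {
  zMid <- -nFrames * step * cos(pi / 4) / 2
  xs <- seq(-24, 24, by = 8)
  pos <- cbind(x = xs, y = seq(5, 20, length.out = length(xs)), z = zMid)
  beadPhantom(pos, diameter = 0.2, brightness = 6000,
              box = list(x = c(-25, 25), y = c(3, 22), z = c(zMid - 1, 0)))
}

renderE2eStack <- function(noiseFree = FALSE, seed = 11L, nFrames = 100L) {
  scan <- scanGeometry(45, 0.092, nFrames)
  noise <- if (noiseFree)
    list(readSigma = 0, background = 10, poisson = FALSE)
  else list(photonScale = 1, readSigma = 1.5, background = 10, poisson = TRUE)
  renderStack(e2ePhantom(nFrames), calibGaussSheet(), detectionConfig(),
              scan, noise = noise, origin = c(-25, 3), seed = seed)
}

# Single centred bead stack (used by detection/linking tests).
oneBeadStack <- function(noiseFree = TRUE, nFrames = 40L) {
  zMid <- -nFrames * 0.092 * cos(pi / 4) / 2
  ph <- beadPhantom(cbind(0, 8, zMid), diameter = 0.2, brightness = 5000,
                    box = list(x = c(-8, 8), y = c(2, 14), z = c(zMid - 1, 0)))
  noise <- if (noiseFree) list(readSigma = 0, background = 5, poisson = FALSE)
  else list(readSigma = 1.5, background = 5, poisson = TRUE)
  renderStack(ph, calibGaussSheet(), detectionConfig(),
              scanGeometry(45, 0.092, nFrames), noise = noise,
              origin = c(-8, 2), seed = 3L)
}

expect_rel <- function(actual, expected, tol) {
  expect_lt(abs(actual / expected - 1), tol)
}
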
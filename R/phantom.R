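#' Detection-path configuration
#'
#' Defaults describe the reference instrument: Olympus 20x/0.5 water-dipping
#' detection objective with a 180 mm achromatic tube lens and an sCMOS
#' camera with 6.5 um pixel pitch, giving a 325 nm sample-plane pixel.
#'
#' @param naDetection detection numerical aperture
#' @param magnification total magnification onto the camera
#' @param cameraPixel camera pixel pitch at the sensor, um
#' @param emissionWavelength nm
#' @param immersionIndex refractive index of the detection immersion medium
#' @return a \linkS4class{DetectionConfig}
#' @export
detectionConfig <- function(naDetection = 0.5, magnification = 20,
                            cameraPixel = 6.5, emissionWavelength = 520,
                            immersionIndex = 1.333) {
  new("DetectionConfig", naDetection = naDetection,
      magnification = magnification, cameraPixel = cameraPixel,
      emissionWavelength = emissionWavelength, immersionIndex = immersionIndex)
}

#' iSPIM scan geometry
#'
#' @param angleDeg angle between translation and detection axes, degrees
#' @param step translation per frame Delta t, um
#' @param nFrames number of frames
#' @return a \linkS4class{ScanGeometry}
#' @export
scanGeometry <- function(angleDeg = 45, step = 0.092, nFrames) {
  new("ScanGeometry", angleDeg = angleDeg, step = step,
      nFrames = as.integer(nFrames))
}

#' Sample-plane pixel size of a detection configuration
#'
#' @param det a \linkS4class{DetectionConfig}
#' @return pixel size in um
#' @export
samplePixel <- function(det) det@cameraPixel / det@magnification

#' Defocus-dependent lateral detection blur
#'
#' Parametric Gaussian defocus model: sigma(z) = sqrt(sigma0^2 + (c z)^2)
#' with sigma0 = 0.21 lambda_em / NA the diffraction-limited in-focus width
#' and c = NA / (2 n) the geometric defocus growth rate.
#'
#' @param zDefocus defocus from the detection focal plane, um (vectorized)
#' @param det a \linkS4class{DetectionConfig}
#' @return Gaussian sigma in um
#' @export
detectionLateralSigma <- function(zDefocus, det) {
  stopifnot(is(det, "DetectionConfig"))
  sigma0 <- 0.21 * (det@emissionWavelength / 1000) / det@naDetection
  cc <- det@naDetection / (2 * det@immersionIndex)
  sqrt(sigma0^2 + (cc * zDefocus)^2)
}

#' Construct a bead phantom from explicit positions
#'
#' @param positions n x 3 matrix of bead centres (x, y, z), um
#' @param diameter bead diameter(s), um
#' @param brightness expected photon count(s) at focus
#' @param box optional 2 x 3 extent matrix; default the position bounding box
#' @return a \linkS4class{BeadPhantom}
#' @export
beadPhantom <- function(positions, diameter = 0.2, brightness = 2000,
                        box = NULL) {
  positions <- as.matrix(positions)
  colnames(positions) <- c("x", "y", "z")
  if (is.null(box)) box <- apply(positions, 2, range)
  if (is.list(box)) box <- cbind(x = box$x, y = box$y, z = box$z)
  n <- nrow(positions)
  new("BeadPhantom", positions = positions,
      diameters = rep_len(diameter, n),
      brightnesses = rep_len(brightness, n), box = box)
}

#' Generate a random bead phantom
#'
#' Bead centres are drawn uniformly inside the box from a seeded generator;
#' the result is deterministic for a fixed seed.
#'
#' @param box 2 x 3 numeric matrix (rows lower/upper, columns x, y, z) or a
#'   list with elements x, y, z each c(lo, hi), um
#' @param nBeads number of beads (>= 0)
#' @param diameter bead diameter(s), um
#' @param brightness expected photon count(s) at focus
#' @param seed integer RNG seed
#' @return a \linkS4class{BeadPhantom}
#' @export
generateBeadPhantom <- function(box, nBeads, diameter = 0.2,
                                brightness = 2000, seed = 1L) {
  if (is.list(box)) box <- cbind(x = box$x, y = box$y, z = box$z)
  stopifnot(all(dim(box) == c(2, 3)), nBeads >= 0)
  pos <- withSeed(seed, {
    matrix(stats::runif(3 * nBeads,
                        rep(box[1, ], each = nBeads),
                        rep(box[2, ], each = nBeads)),
           ncol = 3, dimnames = list(NULL, c("x", "y", "z")))
  })
  if (nBeads == 0) pos <- matrix(numeric(0), 0, 3,
                                 dimnames = list(NULL, c("x", "y", "z")))
  new("BeadPhantom", positions = pos,
      diameters = rep_len(diameter, nBeads),
      brightnesses = rep_len(brightness, nBeads), box = box)
}

# Gaussian smoothing of the sheet response along z (bead-size broadening).
.smoothSheetAxial <- function(values, dz, sigma) {
  if (sigma <= 0) return(values)
  half <- max(1L, ceiling(4 * sigma / dz))
  kz <- stats::dnorm(seq(-half, half) * dz, sd = sigma)
  kz <- kz / sum(kz)
  nz <- ncol(values)
  pad <- cbind(values[, rep(1L, half), drop = FALSE], values,
               values[, rep(nz, half), drop = FALSE])
  out <- values
  for (j in seq_len(nz))
    out[, j] <- pad[, j:(j + 2L * half), drop = FALSE] %*% kz
  out
}

# Bilinear lookup of sheet response at (x, z); 0 outside the grid.
.sheetLookup <- function(sheet, values, x, z) {
  gx <- sheet@grid@x; gz <- sheet@grid@z
  if (x < gx[1] || x > gx[length(gx)] || z < gz[1] || z > gz[length(gz)])
    return(0)
  ix <- findInterval(x, gx, all.inside = TRUE)
  iz <- findInterval(z, gz, all.inside = TRUE)
  fx <- (x - gx[ix]) / (gx[ix + 1L] - gx[ix])
  fz <- (z - gz[iz]) / (gz[iz + 1L] - gz[iz])
  (1 - fx) * ((1 - fz) * values[ix, iz] + fz * values[ix, iz + 1L]) +
    fx * ((1 - fz) * values[ix + 1L, iz] + fz * values[ix + 1L, iz + 1L])
}

#' Render a synthetic iSPIM bead stack
#'
#' For frame i (1-based) each bead is displaced by (i - 1) * step along the
#' t-axis, decomposed as step * sin(theta) along the camera row axis (lateral
#' drift within the detection focal plane) and step * cos(theta) along the
#' detection axis z. The bead signal is brightness x S(x_bead, z_bead)
#' (sheet response, pre-smoothed along z by the bead size) rendered as a
#' pixel-integrated 2-D Gaussian of width sigma(z_bead) from the defocus
#' model, combined in quadrature with the bead radius. Poisson noise is
#' applied to photonScale x (signal + background), then Gaussian read noise;
#' the result is deterministic for a fixed seed. Beads outside the sheet
#' grid contribute zero.
#'
#' Camera coordinates are 0-based pixel centres; column c maps to
#' x = origin[1] + c * pixel and row r to y = origin[2] + r * pixel.
#'
#' @param phantom a \linkS4class{BeadPhantom}
#' @param sheet a \linkS4class{SheetField} covering the illuminated region
#' @param det a \linkS4class{DetectionConfig}
#' @param scan a \linkS4class{ScanGeometry}
#' @param noise list(photonScale, readSigma, background, poisson); set
#'   poisson = FALSE and readSigma = 0 for noise-free rendering
#' @param dims frame dimensions c(nrow, ncol); default sized to the box plus
#'   the scan drift
#' @param origin um position of pixel (row 0, col 0) as c(x, y); default the
#'   lower box corner
#' @param seed integer RNG seed
#' @return an \linkS4class{ImageStack}
#' @export
renderStack <- function(phantom, sheet, det, scan,
                        noise = list(photonScale = 1, readSigma = 1.5,
                                     background = 10, poisson = TRUE),
                        dims = NULL, origin = NULL, seed = 1L) {
  stopifnot(is(phantom, "BeadPhantom"), is(sheet, "SheetField"),
            is(det, "DetectionConfig"), is(scan, "ScanGeometry"))
  noise <- utils::modifyList(
    list(photonScale = 1, readSigma = 1.5, background = 10, poisson = TRUE),
    noise)
  pixel <- samplePixel(det)
  theta <- scan@angleDeg * pi / 180
  driftRowUm <- scan@step * sin(theta)
  driftZ <- scan@step * cos(theta)
  if (is.null(origin)) origin <- c(phantom@box[1, 1], phantom@box[1, 2])
  if (is.null(dims)) {
    ncol <- ceiling(diff(phantom@box[, 1]) / pixel) + 9L
    nrow <- ceiling((diff(phantom@box[, 2]) +
                     scan@nFrames * driftRowUm) / pixel) + 9L
    dims <- c(nrow, ncol)
  }
  dz <- sheet@grid@z[2] - sheet@grid@z[1]
  nBeads <- nrow(phantom@positions)
  # per-bead z-smoothed sheets (beads of equal diameter share one)
  smoothCache <- new.env()
  sheetFor <- function(d) {
    key <- sprintf("%.6f", d)
    if (is.null(smoothCache[[key]]))
      smoothCache[[key]] <- .smoothSheetAxial(sheet@values, dz, d / 4)
    smoothCache[[key]]
  }
  frames <- array(0, c(dims[1], dims[2], scan@nFrames))
  rowEdges <- seq(0, dims[1]) - 0.5   # pixel edges in pixel units
  colEdges <- seq(0, dims[2]) - 0.5
  for (i in seq_len(scan@nFrames)) {
    img <- matrix(0, dims[1], dims[2])
    for (b in seq_len(nBeads)) {
      p <- phantom@positions[b, ]
      yB <- p[2] + (i - 1L) * driftRowUm
      zB <- p[3] + (i - 1L) * driftZ
      S <- .sheetLookup(sheet, sheetFor(phantom@diameters[b]), p[1], zB)
      if (S <= 0) next
      flux <- phantom@brightnesses[b] * S
      sigma <- sqrt(detectionLateralSigma(zB, det)^2 +
                    (phantom@diameters[b] / 4)^2) / pixel  # in pixels
      rowC <- (yB - origin[2]) / pixel
      colC <- (p[1] - origin[1]) / pixel
      rLo <- max(1L, floor(rowC - 5 * sigma) + 1L)
      rHi <- min(dims[1], ceiling(rowC + 5 * sigma) + 1L)
      cLo <- max(1L, floor(colC - 5 * sigma) + 1L)
      cHi <- min(dims[2], ceiling(colC + 5 * sigma) + 1L)
      if (rLo > rHi || cLo > cHi) next
      fr <- diff(stats::pnorm(rowEdges[rLo:(rHi + 1L)], rowC, sigma))
      fc <- diff(stats::pnorm(colEdges[cLo:(cHi + 1L)], colC, sigma))
      img[rLo:rHi, cLo:cHi] <- img[rLo:rHi, cLo:cHi] + flux * outer(fr, fc)
    }
    frames[, , i] <- img + noise$background
  }
  if (isTRUE(noise$poisson) || noise$readSigma > 0) {
    frames <- withSeed(seed, {
      f <- frames
      if (isTRUE(noise$poisson))
        f <- array(stats::rpois(length(f), noise$photonScale * f) /
                     noise$photonScale, dim(f))
      if (noise$readSigma > 0)
        f <- f + array(stats::rnorm(length(f), 0, noise$readSigma), dim(f))
      f
    })
  }
  frames <- pmax(frames, 0)
  new("ImageStack", frames = frames, scan = scan, pixel = pixel,
      meta = list(noise = noise, seed = seed, origin = origin))
}
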
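test_that("the pipeline recovers the sheet FWHM and scan angle (noise-free)", {
  stack <- renderE2eStack(noiseFree = TRUE)
  res <- characterizeStack(stack, detectParams = list(threshold = 3))
  expect_lt(abs(res$thetaDeg - 45), 0.3)
  curve <- axialResolutionCurve(calibGaussSheet())
  m <- res$measurements
  m <- m[!m$censored, ]
  expect_gte(nrow(m), 5)
  truth <- vapply(m$x, function(x)
    curve$fwhm[which.min(abs(curve$x - x))], numeric(1))
  expect_true(all(abs(m$fwhmZ / truth - 1) < 0.1))
})

test_that("recovery holds under realistic noise at SNR >= 20", {
  stack <- renderE2eStack(noiseFree = FALSE, seed = 11)
  res <- characterizeStack(stack, detectParams = list(threshold = 8))
  expect_lt(abs(res$thetaDeg - 45), 0.3)
  curve <- axialResolutionCurve(calibGaussSheet())
  m <- res$measurements[!res$measurements$censored, ]
  truth <- vapply(m$x, function(x)
    curve$fwhm[which.min(abs(curve$x - x))], numeric(1))
  # mean recovery within 10 percent
  expect_lt(abs(mean(m$fwhmZ / truth) - 1), 0.1)
})

test_that("measurements are deterministic across repeated extraction", {
  stack <- renderE2eStack(noiseFree = TRUE)
  r1 <- characterizeStack(stack, detectParams = list(threshold = 3))
  r2 <- characterizeStack(stack, detectParams = list(threshold = 3))
  expect_equal(r1$measurements$fwhmZ, r2$measurements$fwhmZ, tolerance = 1e-12)
})

test_that("larger beads measure broader than smaller beads", {
  measure <- function(diam) {
    nFrames <- 80L
    zMid <- -nFrames * 0.092 * cos(pi / 4) / 2
    ph <- beadPhantom(cbind(0, 8, zMid), diameter = diam, brightness = 6000,
                      box = list(x = c(-8, 8), y = c(2, 14), z = c(zMid - 1, 0)))
    stack <- renderStack(ph, calibGaussSheet(), detectionConfig(),
                         scanGeometry(45, 0.092, nFrames),
                         noise = list(readSigma = 0, background = 5,
                                      poisson = FALSE), origin = c(-8, 2))
    res <- characterizeStack(stack, detectParams = list(threshold = 3))
    mean(res$measurements$fwhmZ, na.rm = TRUE)
  }
  expect_gt(measure(0.4), measure(0.2))
})

test_that("measured axial FWHM increases with the cubic modulation depth", {
  cfg <- illuminationConfig(fillFactor = calibratedFill())
  grid <- sheetGrid(seq(-9, 9, by = 0.5), seq(-4, 5, by = 0.05))
  alphas <- c(NA, 3.5, 7, 14, 21)
  fwhms <- vapply(alphas, function(a) {
    mask <- if (is.na(a)) NULL else cubicMask(a)
    sheet <- twoPhotonSheet(cfg, mask, pulseSpec(780, 20, 1), grid)
    # the Airy main lobe sits below the focal axis (further down for larger
    # alpha), so start the crossing deep enough to bracket every lobe
    nFrames <- 120L
    zMid <- -nFrames * 0.092 * cos(pi / 4) / 2
    ph <- beadPhantom(cbind(c(-4, 4), c(5, 11), zMid), diameter = 0.2,
                      brightness = 6000,
                      box = list(x = c(-8, 8), y = c(2, 16), z = c(zMid - 1, 0)))
    stack <- renderStack(ph, sheet, detectionConfig(),
                         scanGeometry(45, 0.092, nFrames),
                         noise = list(readSigma = 0, background = 5,
                                      poisson = FALSE), origin = c(-8, 2))
    res <- characterizeStack(stack, detectParams = list(threshold = 3))
    mean(res$measurements$fwhmZ, na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(fwhms) > 0))
})

test_that("summary statistics use the Student-t confidence interval", {
  vals <- c(1.32, 1.45, 1.38, 1.51, 1.42, 1.36, 1.48, 1.40, 1.44, 1.39)
  meas <- data.frame(beadId = 1:10, x = seq(0, 45, by = 5), y = 5,
                     zPeak = 0, fwhmZ = vals, fwhmLateral = 0.9,
                     subregion = 1, censored = FALSE)
  s <- summarizeResolution(meas, "gaussian")
  expect_equal(s@meanFwhmZ, mean(vals))
  expect_equal(s@ciFwhmZ, qt(0.975, 9) * sd(vals) / sqrt(10))
  expect_equal(s@n, 10L)
  # identical measurements: zero CI half-width
  meas$fwhmZ <- 1.4
  expect_equal(summarizeResolution(meas, "g")@ciFwhmZ, 0)
  expect_error(summarizeResolution(meas[1, , drop = FALSE]), "at least 2")
})

test_that("figure of merit matches printed arithmetic and is scale-free", {
  expect_equal(figureOfMerit(300, 300, 3), 10000)
  expect_equal(figureOfMerit(1, 1, 1), 1)
  expect_equal(figureOfMerit(47, 300, 1.42), 6992.66, tolerance = 1e-5)
  for (k in c(0.1, 2, 17)) {
    expect_equal(figureOfMerit(k * 47, k * 300, k * 1.42),
                 figureOfMerit(47, 300, 1.42))
  }
  expect_error(figureOfMerit(-1, 300, 3), "positive")
  expect_error(figureOfMerit(300, 300, 0), "positive")
})

test_that("sampling-rate helpers reproduce the system constants", {
  expect_equal(nyquistSampling(0.5, 500), 250)
  expect_equal(nyquistSampling(0.25, 500), 500)
  expect_equal(nyquistSampling(0.5, 650), 325)
  expect_equal(effectiveSamplePixel(6.5, 20), 325)
  expect_equal(effectiveSamplePixel(6.5, 10), 650)
  expect_equal(effectiveSamplePixel(11, 20), 550)
})
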
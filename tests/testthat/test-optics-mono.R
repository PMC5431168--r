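test_that("paraxial Gaussian waist matches the closed-form beam expression", {
  # At small effective NA the line focus is an untruncated Gaussian beam:
  # single-photon waist intensity FWHM = sqrt(2 ln 2) lambda / (pi NA_eff)
  # with NA_eff = fillFactor * NA (amplitude 1/e far-field half-angle times
  # the immersion index).
  for (fill in c(0.3, 0.5)) {
    cfg <- illuminationConfig(fillFactor = fill)
    naEff <- fill * 0.3
    expected <- sqrt(2 * log(2)) * 0.78 / (pi * naEff)
    grid <- sheetGrid(c(-1, 0, 1), seq(-4 * expected, 4 * expected,
                                       by = expected / 50))
    E <- monochromaticSheetField(cfg, NULL, 780, grid)
    fw <- AirySheet:::mainLobeFwhm(sheetZ <- attr(E, "z"), Mod(E[2, ])^2)$fwhm
    expect_rel(fw, expected, 0.02)
  }
})

test_that("axial FWHM follows the Gaussian divergence law over x", {
  fill <- 0.4
  cfg <- illuminationConfig(fillFactor = fill)
  naEff <- fill * 0.3
  w0 <- 0.78 / (pi * naEff)
  nw <- refractiveIndex(dispersionModel("water"), 780)
  xR <- pi * w0^2 * nw / 0.78
  grid <- sheetGrid(seq(-30, 30, by = 3), seq(-12, 12, by = 0.1))
  E <- monochromaticSheetField(cfg, NULL, 780, grid)
  z <- attr(E, "z")
  for (i in seq_along(grid@x)) {
    fw <- AirySheet:::mainLobeFwhm(z, Mod(E[i, ])^2)$fwhm
    expected <- sqrt(2 * log(2)) * w0 * sqrt(1 + (grid@x[i] / xR)^2)
    expect_rel(fw, expected, 0.02)
  }
})

test_that("propagation conserves energy across x", {
  cfg <- illuminationConfig(fillFactor = 0.5)
  grid <- sheetGrid(seq(-30, 30, by = 5), seq(-14, 14, by = 0.1))
  E <- monochromaticSheetField(cfg, NULL, 780, grid)
  energy <- rowSums(Mod(E)^2)
  expect_lt(max(energy) / min(energy) - 1, 0.01)
})

test_that("doubling pupil quadrature changes reported FWHMs by < 0.5 %", {
  grid <- sheetGrid(seq(-50, 50, by = 10), seq(-6, 10, by = 0.05))
  mask <- cubicMask(7)
  fw <- function(nPupil) {
    cfg <- illuminationConfig(nPupil = nPupil)
    sheet <- twoPhotonSheet(cfg, mask, pulseSpec(780, 20, 1), grid)
    axialResolutionCurve(sheet)$fwhm
  }
  expect_lt(max(abs(fw(2049L) / fw(1025L) - 1)), 0.005)
})

test_that("too coarse axial sampling is a configuration error", {
  cfg <- illuminationConfig()
  grid <- sheetGrid(c(-1, 0, 1), seq(-4, 4, by = 0.5))
  expect_error(monochromaticSheetField(cfg, NULL, 780, grid), "8 samples")
})

test_that("Airy main lobe follows a shared parabolic trajectory", {
  cfg <- illuminationConfig()
  mask <- cubicMask(7)
  # stay inside the propagation-invariant range of the alpha = 7 region
  grid <- sheetGrid(seq(-80, 80, by = 8), seq(-3, 8, by = 0.05))
  zPeak <- function(lambda) {
    E <- monochromaticSheetField(cfg, mask, lambda, grid)
    vapply(seq_along(grid@x), function(i)
      AirySheet:::mainLobeFwhm(grid@z, Mod(E[i, ])^2)$peak, numeric(1))
  }
  zp <- zPeak(780)
  fit <- lm(zp ~ I(grid@x^2))
  # the Gaussian pupil envelope leaves a smooth ~0.2 um residual around the
  # vertex, so the fit explains 99.5+ percent of the trajectory variance
  expect_gt(summary(fit)$r.squared, 0.995)
  # quadratic coefficient against the independent stationary-phase result
  expect_rel(coef(fit)[[2]], airyTrajectoryApex(cfg, mask, 780, 1), 0.05)
  # wavelength constituents share the trajectory: deflection shift between
  # 700 and 900 nm far smaller than the main-lobe width (~1.8 um)
  i150 <- which.max(grid@x)
  shift <- abs(zPeak(700)[i150] - zPeak(900)[i150])
  E <- monochromaticSheetField(cfg, mask, 780, grid)
  width <- AirySheet:::mainLobeFwhm(grid@z, Mod(E[i150, ])^2)$fwhm
  expect_lt(shift, 0.1 * width)
})
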
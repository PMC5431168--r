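test_that("phantom generation is seeded and deterministic", {
  box <- list(x = c(0, 300), y = c(0, 300), z = c(0, 300))
  a <- generateBeadPhantom(box, 50, seed = 42)
  b <- generateBeadPhantom(box, 50, seed = 42)
  expect_identical(beadPositions(a), beadPositions(b))
  c <- generateBeadPhantom(box, 50, seed = 43)
  expect_false(identical(beadPositions(a), beadPositions(c)))
  expect_equal(nrow(beadPositions(generateBeadPhantom(box, 0))), 0)
})

test_that("bead positions follow uniform spatial statistics", {
  # Monte-Carlo oracle: mean nearest-neighbour distance of plain runif
  # points in the same box, computed independently of the generator.
  box <- list(x = c(0, 300), y = c(0, 300), z = c(0, 300))
  meanNN <- function(p) {
    d <- as.matrix(dist(p)); diag(d) <- Inf
    mean(apply(d, 1, min))
  }
  got <- mean(vapply(1:20, function(s)
    meanNN(beadPositions(generateBeadPhantom(box, 100, seed = s))),
    numeric(1)))
  oracle <- mean(vapply(1:20, function(s) {
    set.seed(1000 + s)
    meanNN(matrix(runif(300, 0, 300), ncol = 3))
  }, numeric(1)))
  expect_rel(got, oracle, 0.05)
})

test_that("defocus blur model has the stated in-focus width and symmetry", {
  det <- detectionConfig(emissionWavelength = 520)
  expect_equal(detectionLateralSigma(0, det), 0.21 * 0.52 / 0.5)
  expect_equal(detectionLateralSigma(0, det), 0.2184)
  expect_equal(detectionLateralSigma(-3, det), detectionLateralSigma(3, det))
  expect_true(all(diff(detectionLateralSigma(seq(0, 5, 0.5), det)) > 0))
})

test_that("noise-free empty phantom renders pure background", {
  ph <- beadPhantom(matrix(numeric(0), 0, 3),
                    box = list(x = c(-5, 5), y = c(0, 10), z = c(-2, 0)))
  stack <- renderStack(ph, calibGaussSheet(), detectionConfig(),
                       scanGeometry(45, 0.092, 5L),
                       noise = list(readSigma = 0, background = 7,
                                    poisson = FALSE))
  expect_true(all(stackFrames(stack) == 7))
})

test_that("a bead at the waist peaks at the predicted pixel and frame", {
  nFrames <- 41L
  # bead crosses z = 0 exactly at the middle frame
  z0 <- -(nFrames - 1) / 2 * 0.092 * cos(pi / 4)
  ph <- beadPhantom(cbind(2, 6, z0), diameter = 0.2, brightness = 5000,
                    box = list(x = c(-8, 8), y = c(2, 12), z = c(z0 - 1, 0)))
  stack <- renderStack(ph, calibGaussSheet(), detectionConfig(),
                       scanGeometry(45, 0.092, nFrames),
                       noise = list(readSigma = 0, background = 0,
                                    poisson = FALSE), origin = c(-8, 2))
  fr <- stackFrames(stack)
  # integrated flux tracks the sheet response; the brightest single pixel
  # additionally jitters with the sub-pixel phase of the drifting bead
  peakFrame <- which.max(apply(fr, 3, sum))
  expect_equal(peakFrame, (nFrames + 1) / 2)
  idx <- which(fr[, , peakFrame] == max(fr[, , peakFrame]), arr.ind = TRUE)
  pixel <- stackPixel(stack)
  drift <- (peakFrame - 1) * 0.092 * sin(pi / 4)
  expectCol <- (2 - (-8)) / pixel + 1      # x = 2 um
  expectRow <- (6 + drift - 2) / pixel + 1 # y drifted by the scan
  expect_lt(abs(idx[1] - expectRow), 1.1)
  expect_lt(abs(idx[2] - expectCol), 1.1)
})

test_that("Poisson noise gives variance close to the mean", {
  ph <- beadPhantom(matrix(numeric(0), 0, 3),
                    box = list(x = c(-5, 5), y = c(0, 10), z = c(-2, 0)))
  stack <- renderStack(ph, calibGaussSheet(), detectionConfig(),
                       scanGeometry(45, 0.092, 20L),
                       noise = list(readSigma = 0, background = 50,
                                    poisson = TRUE), seed = 9)
  counts <- as.vector(stackFrames(stack))
  expect_rel(mean(counts), 50, 0.02)
  expect_rel(var(counts), 50, 0.05)
  # deterministic per seed
  again <- renderStack(ph, calibGaussSheet(), detectionConfig(),
                       scanGeometry(45, 0.092, 20L),
                       noise = list(readSigma = 0, background = 50,
                                    poisson = TRUE), seed = 9)
  expect_identical(stackFrames(stack), stackFrames(again))
})
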
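test_that("the 45 degree scan geometry implies a 0.2002 px/frame drift", {
  expect_equal(0.092 * sin(45 * pi / 180) / 0.325, 0.2002, tolerance = 1e-3)
})

test_that("scan angle is recovered within 0.3 degrees from phantoms", {
  for (theta in c(45, 30)) {
    nFrames <- 90L
    zMid <- -nFrames * 0.092 * cos(theta * pi / 180) / 2
    ph <- beadPhantom(cbind(c(-6, 0, 6), c(5, 10, 15), zMid),
                      diameter = 0.2, brightness = 8000,
                      box = list(x = c(-8, 8), y = c(2, 20),
                                 z = c(zMid - 1, 0)))
    stack <- renderStack(ph, calibGaussSheet(), detectionConfig(),
                         scanGeometry(theta, 0.092, nFrames),
                         noise = list(readSigma = 1, background = 5,
                                      poisson = TRUE),
                         origin = c(-8, 2), seed = 5)
    det <- detectSpotsStack(stack, list(threshold = 8))
    drift <- 0.092 * sin(theta * pi / 180) / stackPixel(stack)
    tracks <- linkTracks(det, c(drift, 0))
    est <- estimateScanAngle(tracks, 0.092, stackPixel(stack))
    expect_lt(abs(est - theta), 0.3)
  }
})

test_that("zero drift yields a zero scan angle", {
  tracks <- data.frame(frame = rep(1:10, 2),
                       row = rep(c(10, 30), each = 10),
                       col = rep(c(10, 30), each = 10),
                       mass = 1, beadId = rep(1:2, each = 10))
  expect_equal(estimateScanAngle(tracks, 0.092, 0.325), 0)
})

test_that("impossible drift raises a geometry error", {
  tracks <- data.frame(frame = 1:10, row = (1:10) * 2, col = 5, mass = 1,
                       beadId = 1)
  expect_error(estimateScanAngle(tracks, 0.092, 0.325), "geometry error")
})

test_that("theta = 0 deskew is the identity with z spacing = step", {
  stack <- oneBeadStack(noiseFree = TRUE)
  d <- deskewStack(stack, 0)
  expect_identical(d$volume, stackFrames(stack))
  expect_equal(d$dz, 0.092)
})

test_that("deskew applies the expected per-frame shift", {
  # delta-row stack: frame i has a bright row at r0 + round(drift)
  nFrames <- 5L
  drift <- 0.092 * sin(pi / 4) / 0.325  # 0.2002 px/frame
  expect_equal(drift * 100, 20.02, tolerance = 0.01)  # 100-frame total
  frames <- array(0, c(40, 10, nFrames))
  for (i in seq_len(nFrames)) {
    r <- 20 + (i - 1) * drift
    lo <- floor(r); f <- r - lo
    frames[lo + 1, , i] <- 1 - f   # 0-based row r rendered bilinearly
    frames[lo + 2, , i] <- f
  }
  stack <- new("ImageStack", frames = frames,
               scan = scanGeometry(45, 0.092, nFrames), pixel = 0.325,
               meta = list())
  vol <- deskewStack(stack, 45)$volume
  for (i in seq_len(nFrames)) {
    prof <- vol[, 5, i]
    com <- sum(prof * seq_along(prof), na.rm = TRUE) /
      sum(prof, na.rm = TRUE) - 1
    expect_lt(abs(com - 20), 0.05)
  }
})

test_that("shear round trip on a band-limited volume is below 1 % error", {
  # smooth blob, sheared by deskew(theta) then deskew(-theta)
  n <- c(60, 12, 30)
  rr <- outer((1:60 - 30)^2 / 64, rep(0, 12), "+")
  frames <- array(0, n)
  for (k in 1:30) frames[, , k] <- exp(-rr / 2) * exp(-(k - 15)^2 / 40)
  stack <- new("ImageStack", frames = frames,
               scan = scanGeometry(45, 0.4, 30L), pixel = 0.325,
               meta = list())
  once <- deskewStack(stack, 45)
  stack2 <- new("ImageStack", frames = ifelse(is.na(once$volume), 0,
                                              once$volume),
                scan = scanGeometry(45, 0.4, 30L), pixel = 0.325,
                meta = list())
  back <- deskewStack(stack2, -45)$volume
  core <- 18:34  # rows untouched by NA edges in either direction
  err <- abs(back[core, , ] - frames[core, , ])
  expect_lt(max(err, na.rm = TRUE), 0.01 * max(frames))
})

test_that("excessive total shift is rejected", {
  frames <- array(0, c(10, 5, 100))
  stack <- new("ImageStack", frames = frames,
               scan = scanGeometry(45, 0.4, 100L), pixel = 0.325,
               meta = list())
  expect_error(deskewStack(stack, 45), "exceeds")
})
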
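blob3d <- function(n = c(32, 32, 24), ctr = n / 2, sigma = 2.5) {
  g1 <- function(m, c) exp(-((1:m) - c)^2 / (2 * sigma^2))
  outer(outer(g1(n[1], ctr[1]), g1(n[2], ctr[2])), g1(n[3], ctr[3])) * 100
}

psfFrom <- function(profile) {
  # separable 3-D PSF with the given axial profile
  lat <- dnorm(-3:3, sd = 1.2)
  p <- outer(outer(lat, lat), profile)
  p / sum(p)
}

convolve3d <- function(vol, psf) {
  # independent direct (space-domain) convolution oracle, same centring
  d <- dim(psf); ctr <- (d + 1) %/% 2
  out <- array(0, dim(vol))
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    w <- psf[i, j, k]
    if (w < 1e-12) next
    sh <- c(i, j, k) - ctr
    src <- list(pmin(pmax(seq_len(dim(vol)[1]) - sh[1], 1), dim(vol)[1]),
                pmin(pmax(seq_len(dim(vol)[2]) - sh[2], 1), dim(vol)[2]),
                pmin(pmax(seq_len(dim(vol)[3]) - sh[3], 1), dim(vol)[3]))
    out <- out + w * vol[src[[1]], src[[2]], src[[3]]]
  }
  out
}

test_that("a delta PSF is the identity for any iteration count", {
  vol <- blob3d()
  psf <- array(0, c(5, 5, 5)); psf[3, 3, 3] <- 1
  expect_equal(richardsonLucy(vol, psf, 1), vol, tolerance = 1e-10)
  expect_equal(richardsonLucy(vol, psf, 7), vol, tolerance = 1e-10)
})

test_that("iterations conserve flux and non-negativity", {
  vol <- blob3d()
  psf <- psfFrom(dnorm(seq(-3, 3), sd = 1.5))
  blurred <- convolve3d(vol, psf)
  prev <- sum(blurred)
  for (it in c(1, 3, 5, 10)) {
    out <- richardsonLucy(blurred, psf, it)
    expect_true(all(out >= 0))
    expect_lt(abs(sum(out) / sum(blurred) - 1), 1e-6)
  }
})

test_that("zero-sum and negative PSFs are rejected", {
  vol <- blob3d()
  expect_error(richardsonLucy(vol, array(0, c(3, 3, 3))), "positive sum")
  bad <- array(1, c(3, 3, 3)); bad[1] <- -1
  expect_error(richardsonLucy(vol, bad), "non-negative")
})

test_that("deconvolving an Airy-like blur raises the peak-to-sidelobe ratio", {
  # asymmetric axial PSF with a secondary lobe, like a single-photon Airy sheet
  prof <- dnorm(seq(-4, 8), sd = 1)
  prof <- prof + 0.45 * dnorm(seq(-4, 8), mean = 4, sd = 1.2)
  psf <- psfFrom(prof / sum(prof))
  truth <- blob3d(sigma = 1.5)
  blurred <- convolve3d(truth, psf)
  psr <- function(v) {
    ax <- v[16, 16, ]
    pk <- which.max(ax)
    side <- max(ax[-(max(1, pk - 3):min(length(ax), pk + 3))])
    ax[pk] / side
  }
  ratios <- vapply(1:10, function(it)
    psr(richardsonLucy(blurred, psf, it)), numeric(1))
  expect_true(all(diff(ratios) > 0))
})

test_that("the blurred-reblurred residual is non-increasing over iterations", {
  psf <- psfFrom(dnorm(seq(-3, 3), sd = 1.5))
  blurred <- convolve3d(blob3d(), psf)
  resid <- vapply(c(1, 2, 4, 8, 16), function(it) {
    est <- richardsonLucy(blurred, psf, it)
    sum((convolve3d(est, psf) - blurred)^2)
  }, numeric(1))
  # strictly decreasing until the small floor set by the difference between
  # the oracle's clamped-edge convolution and the reflective RL model
  expect_true(all(diff(resid) <= 1e-4 * resid[1]))
  expect_lt(resid[4], 1e-3 * resid[1])
})

test_that("per-subregion deconvolution blends blocks smoothly", {
  vol <- blob3d(n = c(24, 48, 20), ctr = c(12, 24, 10))
  psf <- psfFrom(dnorm(seq(-3, 3), sd = 1.2))
  single <- richardsonLucy(vol, psf, 4)
  blocked <- richardsonLucy(vol, list(psf, psf), 4)
  # identical PSFs per block: blocked result close to shift-invariant result
  expect_lt(max(abs(blocked - single)) / max(single), 0.02)
})
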
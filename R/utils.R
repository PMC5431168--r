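# Internal numerical helpers shared across modules.

# Complex matrix product via four real BLAS products (R's native complex
# %*% does not dispatch to zgemm).
cmatmul <- function(a, b) {
  ar <- Re(a); ai <- Im(a); br <- Re(b); bi <- Im(b)
  re <- ar %*% br - ai %*% bi
  matrix(complex(real = re, imaginary = ar %*% bi + ai %*% br),
         nrow(re), ncol(re))
}

# FWHM of the main lobe of a sampled non-negative profile: the contiguous
# region above half of the global maximum, with half-maximum crossings
# located by linear interpolation. Returns the width and a censored flag
# (TRUE when the above-half region touches either end of the grid).
mainLobeFwhm <- function(pos, values) {
  stopifnot(length(pos) == length(values), length(pos) >= 3L)
  i <- which.max(values)
  half <- values[i] / 2
  l <- i
  while (l > 1L && values[l - 1L] > half) l <- l - 1L
  r <- i
  while (r < length(values) && values[r + 1L] > half) r <- r + 1L
  censored <- (l == 1L) || (r == length(values))
  left <- if (l == 1L) pos[1L] else {
    # interpolate between (l-1, l): values[l-1] <= half < values[l]
    pos[l - 1L] + (half - values[l - 1L]) / (values[l] - values[l - 1L]) *
      (pos[l] - pos[l - 1L])
  }
  right <- if (r == length(values)) pos[length(pos)] else {
    pos[r] + (values[r] - half) / (values[r] - values[r + 1L]) *
      (pos[r + 1L] - pos[r])
  }
  # sub-sample peak position by 3-point parabolic interpolation
  peak <- pos[i]
  if (i > 1L && i < length(values)) {
    den <- values[i - 1L] - 2 * values[i] + values[i + 1L]
    if (den < 0) {
      delta <- 0.5 * (values[i - 1L] - values[i + 1L]) / den
      peak <- pos[i] + max(-0.5, min(0.5, delta)) * (pos[i + 1L] - pos[i])
    }
  }
  list(fwhm = right - left, left = left, right = right,
       peak = peak, peakValue = values[i], censored = censored)
}

# Linear-interpolated crossing of `threshold` on the segment between
# indices i and i+1 of (pos, values).
.crossing <- function(pos, values, i, threshold) {
  pos[i] + (threshold - values[i]) / (values[i + 1L] - values[i]) *
    (pos[i + 1L] - pos[i])
}

# Seeded evaluation that restores the caller's RNG state.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

# Speed of light in vacuum, nm / fs (= um / ps = 299.792458).
.C_NM_FS <- 299.792458
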
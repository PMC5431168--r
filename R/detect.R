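# Spot detection and tracking (a compact re-implementation of the
# band-pass + centroid-refinement scheme of common particle-tracking
# toolkits, sized for sparse bead fields).

# Separable Gaussian blur with edge replication; sigma in pixels.
.gaussBlur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  half <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(seq(-half, half), sd = sigma)
  k <- k / sum(k)
  blur1 <- function(m) {  # along rows (dim 1)
    n <- nrow(m)
    idx <- pmin(pmax(outer(seq_len(n), seq(-half, half), `+`), 1L), n)
    out <- matrix(0, n, ncol(m))
    for (j in seq_len(2L * half + 1L))
      out <- out + k[j] * m[idx[, j], , drop = FALSE]
    out
  }
  t(blur1(t(blur1(img))))
}

#' Detect bead images in a single frame
#'
#' Difference-of-Gaussians band-pass, local maxima above a threshold with a
#' minimum mutual separation, then sub-pixel refinement by intensity-weighted
#' centroid of the background-subtracted signal in a window around each
#' maximum. Positions are 0-based pixel-centre coordinates.
#'
#' @param frame 2-D non-negative numeric matrix
#' @param params list: dogSmall, dogLarge (Gaussian sigmas, px), minSeparation
#'   (px), threshold (DoG amplitude)
#' @return data.frame with columns row, col (sub-pixel, 0-based) and mass
#'   (background-subtracted integrated intensity)
#' @export
detectSpots <- function(frame, params = list(dogSmall = 1, dogLarge = 3,
                                             minSeparation = 5,
                                             threshold = 5)) {
  stopifnot(is.matrix(frame), all(frame >= 0))
  p <- utils::modifyList(list(dogSmall = 1, dogLarge = 3, minSeparation = 5,
                              threshold = 5), params)
  empty <- data.frame(row = numeric(0), col = numeric(0), mass = numeric(0))
  if (length(frame) == 0) return(empty)
  dog <- .gaussBlur(frame, p$dogSmall) - .gaussBlur(frame, p$dogLarge)
  nr <- nrow(dog); nc <- ncol(dog)
  if (nr < 3L || nc < 3L) return(empty)
  inner <- dog[2:(nr - 1), 2:(nc - 1)]
  isMax <- inner > p$threshold
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    isMax <- isMax & (inner >= dog[2:(nr - 1) + dr, 2:(nc - 1) + dc])
  }
  idx <- which(isMax, arr.ind = TRUE)
  if (nrow(idx) == 0) return(empty)
  cand <- data.frame(r = idx[, 1] + 1L, c = idx[, 2] + 1L,
                     v = inner[idx])
  cand <- cand[order(-cand$v), ]
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (i == 1L) { keep[1] <- TRUE; next }
    prev <- cand[keep, , drop = FALSE]
    d2 <- (prev$r - cand$r[i])^2 + (prev$c - cand$c[i])^2
    keep[i] <- all(d2 > p$minSeparation^2)
  }
  cand <- cand[keep, , drop = FALSE]
  wr <- max(2L, ceiling(p$minSeparation / 2))
  out <- lapply(seq_len(nrow(cand)), function(i) {
    r0 <- cand$r[i]; c0 <- cand$c[i]
    rs <- max(1L, r0 - wr):min(nr, r0 + wr)
    cs <- max(1L, c0 - wr):min(nc, c0 + wr)
    win <- frame[rs, cs, drop = FALSE]
    ring <- c(win[1, ], win[nrow(win), ], win[, 1], win[, ncol(win)])
    sig <- pmax(win - stats::median(ring), 0)
    mass <- sum(sig)
    if (mass <= 0) return(NULL)
    data.frame(row = sum(sig * (rs - 1L)) / mass,  # 0-based rows
               col = sum(t(sig) * (cs - 1L)) / mass,
               mass = mass)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) empty else out
}

#' Detect spots in every frame of a stack
#'
#' @param stack an \linkS4class{ImageStack}
#' @param params detection parameters, see \code{\link{detectSpots}}
#' @return data.frame with columns frame (1-based), row, col, mass
#' @export
detectSpotsStack <- function(stack, params = list()) {
  stopifnot(is(stack, "ImageStack"))
  res <- lapply(seq_len(dim(stack@frames)[3]), function(i) {
    d <- detectSpots(stack@frames[, , i], params)
    if (nrow(d)) cbind(frame = i, d) else NULL
  })
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(frame = integer(0), row = numeric(0),
                      col = numeric(0), mass = numeric(0))
  out
}

#' Link per-frame detections into bead tracks
#'
#' Nearest-neighbour linking after subtracting the expected constant drift;
#' candidate pairs beyond maxDisp pixels are not linked. Ambiguities are
#' resolved greedily by smallest residual. Tracks with fewer than 3
#' detections are dropped.
#'
#' @param detections data.frame from \code{\link{detectSpotsStack}}
#' @param expectedDriftPxPerFrame c(drow, dcol) expected drift in px/frame
#' @param maxDisp maximum residual displacement for a link, px
#' @return data.frame with an additional beadId column, ordered by beadId
#'   then frame
#' @export
linkTracks <- function(detections, expectedDriftPxPerFrame = c(0, 0),
                       maxDisp = 3) {
  empty <- cbind(detections[0, , drop = FALSE], beadId = integer(0))
  if (nrow(detections) == 0) return(empty)
  drift <- expectedDriftPxPerFrame
  frames <- sort(unique(detections$frame))
  detections$beadId <- NA_integer_
  nextId <- 1L
  active <- NULL  # data.frame beadId, row, col, frame
  for (f in frames) {
    cur <- which(detections$frame == f)
    assigned <- rep(FALSE, length(cur))
    if (!is.null(active) && nrow(active)) {
      # predict active tracks forward
      pr <- active$row + drift[1] * (f - active$frame)
      pc <- active$col + drift[2] * (f - active$frame)
      pairs <- expand.grid(a = seq_len(nrow(active)), d = seq_along(cur))
      pairs$d2 <- (pr[pairs$a] - detections$row[cur[pairs$d]])^2 +
                  (pc[pairs$a] - detections$col[cur[pairs$d]])^2
      pairs <- pairs[pairs$d2 <= maxDisp^2, , drop = FALSE]
      pairs <- pairs[order(pairs$d2), , drop = FALSE]
      usedA <- logical(nrow(active))
      for (i in seq_len(nrow(pairs))) {
        a <- pairs$a[i]; d <- pairs$d[i]
        if (usedA[a] || assigned[d]) next
        usedA[a] <- TRUE; assigned[d] <- TRUE
        detections$beadId[cur[d]] <- active$beadId[a]
        active$row[a] <- detections$row[cur[d]]
        active$col[a] <- detections$col[cur[d]]
        active$frame[a] <- f
      }
    }
    for (d in which(!assigned)) {
      detections$beadId[cur[d]] <- nextId
      active <- rbind(active,
                      data.frame(beadId = nextId,
                                 row = detections$row[cur[d]],
                                 col = detections$col[cur[d]], frame = f))
      nextId <- nextId + 1L
    }
  }
  counts <- table(detections$beadId)
  keep <- detections$beadId %in% as.integer(names(counts)[counts >= 3])
  out <- detections[keep, , drop = FALSE]
  out[order(out$beadId, out$frame), , drop = FALSE]
}

#' Estimate the scan angle from bead tracks
#'
#' Each track's mean lateral (row-axis) displacement per frame d (um) is
#' taken from a least-squares line fit of row position versus frame index;
#' theta = arcsin(d / step). The per-track angles are aggregated by the
#' median.
#'
#' @param tracks data.frame from \code{\link{linkTracks}}
#' @param step translation per frame Delta t, um
#' @param pixel sample-plane pixel size, um
#' @return estimated angle in degrees
#' @export
estimateScanAngle <- function(tracks, step, pixel) {
  stopifnot(nrow(tracks) > 0)
  ids <- unique(tracks$beadId)
  drifts <- vapply(ids, function(id) {
    tr <- tracks[tracks$beadId == id, ]
    if (nrow(tr) < 3L) return(NA_real_)
    stats::coef(stats::lm(row ~ frame, data = tr))[["frame"]] * pixel
  }, numeric(1))
  drifts <- drifts[is.finite(drifts)]
  if (!length(drifts)) stop("no track with >= 3 detections")
  d <- stats::median(drifts)
  if (abs(d) > step)
    stop(sprintf(paste0("geometry error: lateral drift %.4g um/frame exceeds ",
                        "the scan step %.4g um (impossible angle)"), d, step))
  asin(abs(d) / step) * 180 / pi
}
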
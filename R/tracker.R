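#' @include hungarian.R
NULL

#' Pre-processing configuration
#'
#' Flat-field division (pixel-wise temporal median, the iSCAT convention for
#' removing static background scattering), temporal-mean background
#' subtraction and min-max normalisation.
#'
#' @param medianWindow number of frames for the temporal-median flat field
#'   (default 1000; capped at the stack length).
#' @param enableFlatfield divide by the temporal-median flat field.
#' @param enableBackgroundSubtract subtract the temporal-mean background.
#' @param normalize min-max normalise intensities to [0, 1].
#' @return a validated config list.
#' @export
preprocessConfig <- function(medianWindow = 1000L, enableFlatfield = TRUE,
                             enableBackgroundSubtract = TRUE,
                             normalize = TRUE) {
  if (medianWindow < 1L) stop("medianWindow must be >= 1")
  list(medianWindow = as.integer(medianWindow),
       enableFlatfield = isTRUE(enableFlatfield),
       enableBackgroundSubtract = isTRUE(enableBackgroundSubtract),
       normalize = isTRUE(normalize))
}

#' Detection configuration
#'
#' @param sigma scale of the Laplacian-of-Gaussian spot-enhancing kernel,
#'   pixels; match to the spot radius.
#' @param c threshold weight: the global threshold on the filtered image is
#'   T = mean + c * sd (default c = 3).
#' @param roiSize odd window size (>= 3) for radial-symmetry sub-pixel
#'   refinement.
#' @param peakSizeLimits c(min, max) allowed footprint diameter in pixels of
#'   the above-threshold region around a peak.
#' @param darkSpots detect dark spots (image negated first); iSCAT contrast
#'   can be negative.
#' @return a validated config list.
#' @export
detectionConfig <- function(sigma = 2, c = 3, roiSize = 7L,
                            peakSizeLimits = c(1, 20), darkSpots = FALSE) {
  if (sigma <= 0) stop("sigma must be positive")
  roiSize <- as.integer(roiSize)
  if (roiSize < 3L || roiSize %% 2L == 0L)
    stop("roiSize must be an odd integer >= 3")
  if (length(peakSizeLimits) != 2L || peakSizeLimits[1L] > peakSizeLimits[2L])
    stop("peakSizeLimits must be c(min, max) with min <= max")
  list(sigma = sigma, c = c, roiSize = roiSize,
       peakSizeLimits = peakSizeLimits, darkSpots = isTRUE(darkSpots))
}

#' Linking configuration
#'
#' @param maxDistance maximum spatial distance (pixels) for linking two
#'   detections in neighbouring frames.
#' @param maxGap maximum number of consecutive frames a track may miss a
#'   detection; gap positions are filled by linear interpolation.
#' @param minTrackLength minimum track length in frames (>= 2); shorter
#'   tracks are discarded.
#' @return a validated config list.
#' @export
linkConfig <- function(maxDistance = 5, maxGap = 2L, minTrackLength = 10L) {
  if (maxDistance < 0 || maxGap < 0) stop("maxDistance and maxGap must be >= 0")
  if (minTrackLength < 2L) stop("minTrackLength must be >= 2")
  list(maxDistance = maxDistance, maxGap = as.integer(maxGap),
       minTrackLength = as.integer(minTrackLength))
}

#' Pre-process an image stack
#'
#' Stages (each switchable in the config): division by the flat field (the
#' pixel-wise temporal median over the first \code{medianWindow} frames;
#' near-zero flat-field pixels are floored at 1e-6 of its global median to
#' guard the division), subtraction of the temporal-mean background, and
#' min-max normalisation to [0, 1].
#'
#' @param stack numeric array (height, width, frames).
#' @param config from \code{\link{preprocessConfig}}.
#' @return processed array of the same shape.
#' @export
preprocessStack <- function(stack, config = preprocessConfig()) {
  d <- dim(stack)
  if (length(d) != 3L) stop("stack must be a (height, width, frames) array")
  out <- stack
  if (config$enableFlatfield) {
    k <- min(config$medianWindow, d[3L])
    flat <- apply(out[, , seq_len(k), drop = FALSE], c(1L, 2L),
                  stats::median)
    gm <- stats::median(flat)
    if (!is.finite(gm) || gm == 0)
      stop("preprocessing error: flat field is all zero")
    flat[flat < 1e-6 * gm] <- gm
    out <- sweep(out, c(1L, 2L), flat, "/")
  }
  if (config$enableBackgroundSubtract) {
    bg <- apply(out, c(1L, 2L), mean)
    out <- sweep(out, c(1L, 2L), bg, "-")
  }
  if (config$normalize) {
    rng <- range(out)
    out <- if (rng[2L] > rng[1L]) (out - rng[1L]) / (rng[2L] - rng[1L])
           else out * 0
  }
  out
}

# negated zero-sum Laplacian-of-Gaussian kernel: positive response on bright
# blobs of radius ~ sigma
.logKernel <- function(sigma) {
  half <- max(1L, ceiling(3 * sigma))
  ax <- -half:half
  g <- outer(ax, ax, function(x, y) {
    r2 <- x^2 + y^2
    -((r2 - 2 * sigma^2) / sigma^4) * exp(-r2 / (2 * sigma^2))
  })
  g - mean(g)  # enforce zero sum: flat regions give exactly zero response
}

#' Radial-symmetry centre of an image patch
#'
#' Non-iterative sub-pixel localisation for radially symmetric spots: the
#' centre is the least-squares point minimising the distance to the lines
#' through each half-pixel gradient. Gradients are computed on the
#' half-pixel grid via diagonal differences and smoothed with a 3x3 boxcar;
#' each line is weighted by squared gradient magnitude divided by its
#' distance from the gradient-magnitude centroid.
#'
#' @param window numeric matrix patch, odd-sized, >= 3x3; rows = y, cols = x.
#' @return c(x, y) centre in 0-based pixel coordinates within the patch
#'   (the patch midpoint is ((ncol-1)/2, (nrow-1)/2)).
#' @export
radialSymmetryCenter <- function(window) {
  I <- as.matrix(window)
  ny <- nrow(I); nx <- ncol(I)
  if (ny < 3L || nx < 3L) stop("patch must be at least 3x3")
  # midpoint grid, centred on the patch centre
  xm <- matrix(rep(seq(-(nx - 1) / 2 + 0.5, (nx - 1) / 2 - 0.5), each = ny - 1L),
               nrow = ny - 1L)
  ym <- matrix(rep(seq(-(ny - 1) / 2 + 0.5, (ny - 1) / 2 - 0.5), nx - 1L),
               nrow = ny - 1L)
  # diagonal derivatives on the half-pixel grid (u, v at 45 degrees)
  dIdu <- I[1:(ny - 1), 2:nx] - I[2:ny, 1:(nx - 1)]
  dIdv <- I[1:(ny - 1), 1:(nx - 1)] - I[2:ny, 2:nx]
  fdu <- .box3(dIdu)
  fdv <- .box3(dIdv)
  mag2 <- fdu^2 + fdv^2
  if (sum(mag2) == 0)
    stop("undefined centre: the patch has no intensity gradient")
  # slope of the gradient line through each midpoint (image x/y frame)
  m <- -(fdv + fdu) / (fdu - fdv)
  ok <- is.finite(m)
  b <- ym - m * xm
  sdI2 <- sum(mag2)
  xc0 <- sum(mag2 * xm) / sdI2
  yc0 <- sum(mag2 * ym) / sdI2
  w <- mag2 / sqrt((xm - xc0)^2 + (ym - yc0)^2 + 1e-12)
  w[!ok] <- 0
  m[!ok] <- 0; b[!ok] <- 0
  wm2p1 <- w / (m^2 + 1)
  sw <- sum(wm2p1)
  smmw <- sum(m^2 * wm2p1)
  smw <- sum(m * wm2p1)
  smbw <- sum(m * b * wm2p1)
  sbw <- sum(b * wm2p1)
  det <- smw^2 - smmw * sw
  if (!is.finite(det) || det == 0)
    stop("undefined centre: degenerate gradient geometry")
  xc <- (smbw * sw - smw * sbw) / det
  yc <- (smbw * smw - smmw * sbw) / det
  c(x = xc + (nx - 1) / 2, y = yc + (ny - 1) / 2)
}

# 3x3 boxcar smoothing with zero padding
.box3 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  p <- matrix(0, nr + 2L, nc + 2L)
  p[2:(nr + 1L), 2:(nc + 1L)] <- m
  out <- matrix(0, nr, nc)
  for (dr in 0:2) for (dc in 0:2)
    out <- out + p[(1L + dr):(nr + dr), (1L + dc):(nc + dc)]
  out / 9
}

#' Detect particles in a single frame
#'
#' Spot-enhancing filter: the frame is convolved with a zero-sum
#' (negated) Laplacian-of-Gaussian kernel of scale sigma; a global threshold
#' T = mean + c * sd is computed on the filtered image; local maxima above T
#' whose above-threshold footprint diameter lies within
#' \code{peakSizeLimits} are kept and refined to sub-pixel precision by the
#' radial-symmetry centre within a \code{roiSize} window on the
#' (polarity-corrected) intensity image. Windows falling off the image edge
#' are dropped.
#'
#' @param frame numeric matrix (rows = y, cols = x).
#' @param config from \code{\link{detectionConfig}}.
#' @return data.frame with columns x, y (0-based sub-pixel pixel
#'   coordinates) and response (filtered peak value); zero rows when nothing
#'   is detected.
#' @export
detectSpots <- function(frame, config = detectionConfig()) {
  img <- as.matrix(frame)
  empty <- data.frame(x = numeric(0), y = numeric(0), response = numeric(0))
  if (diff(range(img)) == 0) return(empty)  # no structure at all
  if (config$darkSpots) img <- -img
  resp <- EBImage::filter2(img, .logKernel(config$sigma),
                           boundary = "replicate")
  resp <- as.matrix(resp)
  thr <- mean(resp) + config$c * stats::sd(resp)
  mask <- resp > thr
  if (!any(mask)) return(empty)
  # local maxima over the 8-neighbourhood; exact ties are broken so that a
  # flat two-pixel plateau yields one detection, not two
  nr <- nrow(resp); nc <- ncol(resp)
  pad <- matrix(-Inf, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- resp
  isMax <- mask
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    shifted <- pad[(2L + dr):(nr + 1L + dr), (2L + dc):(nc + 1L + dc)]
    isMax <- isMax & if (dr > 0L || (dr == 0L && dc > 0L))
      resp > shifted else resp >= shifted
  }
  peaks <- which(isMax, arr.ind = TRUE)
  if (!nrow(peaks)) return(empty)
  # footprint diameter of the above-threshold blob containing each peak
  labels <- EBImage::bwlabel(matrix(as.numeric(mask), nr, nc))
  keep <- logical(nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    lab <- labels[peaks[i, 1L], peaks[i, 2L]]
    px <- which(labels == lab, arr.ind = TRUE)
    diam <- max(diff(range(px[, 1L])), diff(range(px[, 2L]))) + 1L
    keep[i] <- diam >= config$peakSizeLimits[1L] &&
      diam <= config$peakSizeLimits[2L]
  }
  peaks <- peaks[keep, , drop = FALSE]
  if (!nrow(peaks)) return(empty)
  half <- (config$roiSize - 1L) %/% 2L
  dets <- lapply(seq_len(nrow(peaks)), function(i) {
    r <- peaks[i, 1L]; cc <- peaks[i, 2L]
    if (r - half < 1L || r + half > nr || cc - half < 1L || cc + half > nc) {
      message("detection at (", cc - 1L, ", ", r - 1L,
              ") dropped: refinement window off the image edge")
      return(NULL)
    }
    patch <- img[(r - half):(r + half), (cc - half):(cc + half)]
    ctr <- try(radialSymmetryCenter(patch), silent = TRUE)
    if (inherits(ctr, "try-error")) return(NULL)
    data.frame(x = (cc - 1L) - half + ctr[["x"]],
               y = (r - 1L) - half + ctr[["y"]],
               response = resp[r, cc])
  })
  dets <- do.call(rbind, dets)
  if (is.null(dets)) empty else dets
}

#' Link per-frame detections into tracks
#'
#' For every frame, open tracks (those with a detection within the last
#' \code{maxGap + 1} frames) are matched one-to-one against the frame's
#' detections by the Hungarian algorithm on Euclidean distance; matches
#' beyond \code{maxDistance} are forbidden. Unmatched detections start new
#' tracks; tracks silent for more than \code{maxGap} frames are closed.
#' Missed frames inside a track are filled by linear interpolation between
#' the flanking detections. Tracks shorter than \code{minTrackLength}
#' frames are discarded.
#'
#' @param detections data.frame with columns frame (integer), x, y (pixels);
#'   e.g. \code{\link{detectSpots}} output augmented with a frame column.
#' @param config from \code{\link{linkConfig}}.
#' @return a \linkS4class{TrackSet} in pixel/frame units (t = frame index).
#' @export
linkDetections <- function(detections, config = linkConfig()) {
  if (!nrow(detections)) return(TrackSet())
  frames <- sort(unique(detections$frame))
  active <- list()   # each: list(frames, x, y, lastFrame)
  done <- list()
  nextId <- 1L
  for (f in seq(min(frames), max(frames))) {
    dets <- detections[detections$frame == f, , drop = FALSE]
    # retire tracks that exceeded the gap tolerance
    if (length(active)) {
      expired <- vapply(active, function(a) f - a$lastFrame > config$maxGap + 1L,
                        logical(1))
      done <- c(done, active[expired])
      active <- active[!expired]
    }
    if (!nrow(dets)) next
    assigned <- rep(NA_integer_, length(active))
    if (length(active)) {
      cost <- vapply(seq_len(nrow(dets)), function(j) {
        vapply(active, function(a)
          sqrt((a$x[length(a$x)] - dets$x[j])^2 +
               (a$y[length(a$y)] - dets$y[j])^2), numeric(1))
      }, numeric(length(active)))
      cost <- matrix(cost, nrow = length(active))
      assigned <- solveAssignment(cost, maxCost = config$maxDistance)
    }
    usedDet <- logical(nrow(dets))
    for (i in seq_along(active)) {
      j <- assigned[i]
      if (is.na(j)) next
      usedDet[j] <- TRUE
      a <- active[[i]]
      gap <- f - a$lastFrame - 1L
      if (gap > 0L) {  # linear interpolation across the gap
        frac <- seq_len(gap) / (gap + 1L)
        a$frames <- c(a$frames, a$lastFrame + seq_len(gap))
        a$x <- c(a$x, a$x[length(a$x)] + frac * (dets$x[j] - a$x[length(a$x)]))
        a$y <- c(a$y, a$y[length(a$y)] + frac * (dets$y[j] - a$y[length(a$y)]))
      }
      a$frames <- c(a$frames, f)
      a$x <- c(a$x, dets$x[j]); a$y <- c(a$y, dets$y[j])
      a$lastFrame <- f
      active[[i]] <- a
    }
    for (j in which(!usedDet)) {
      active[[length(active) + 1L]] <-
        list(frames = f, x = dets$x[j], y = dets$y[j], lastFrame = f)
    }
  }
  done <- c(done, active)
  done <- Filter(function(a) length(a$frames) >= config$minTrackLength, done)
  tracks <- lapply(seq_along(done), function(i) {
    a <- done[[i]]
    Track(t = as.numeric(a$frames), x = a$x, y = a$y, id = i)
  })
  TrackSet(tracks)
}

#' Track particles through a movie
#'
#' Full pipeline: pre-process the stack, detect spots in every frame, link
#' detections into tracks, and convert to physical units (metres, seconds).
#'
#' @param stack numeric array (height, width, frames), e.g. from
#'   \code{\link{readTIFFStack}}.
#' @param pre from \code{\link{preprocessConfig}}.
#' @param det from \code{\link{detectionConfig}}.
#' @param link from \code{\link{linkConfig}}.
#' @param pixelSize metres per pixel.
#' @param frameInterval seconds per frame.
#' @return a \linkS4class{TrackSet} in metres/seconds (empty when nothing
#'   was tracked).
#' @export
trackMovie <- function(stack, pre = preprocessConfig(),
                       det = detectionConfig(), link = linkConfig(),
                       pixelSize = 1, frameInterval = 1) {
  proc <- tryCatch(preprocessStack(stack, pre),
                   error = function(e) stop("preprocess: ", e$message))
  nf <- dim(proc)[3L]
  detList <- lapply(seq_len(nf), function(k) {
    d <- tryCatch(detectSpots(proc[, , k], det),
                  error = function(e) stop("detect (frame ", k, "): ",
                                           e$message))
    if (nrow(d)) cbind(frame = k - 1L, d) else NULL
  })
  detections <- do.call(rbind, detList)
  if (is.null(detections)) return(TrackSet())
  pxTracks <- tryCatch(linkDetections(detections, link),
                       error = function(e) stop("link: ", e$message))
  tracks <- lapply(pxTracks@tracks, function(tr)
    Track(t = trackTimes(tr) * frameInterval,
          x = trackX(tr) * pixelSize,
          y = trackY(tr) * pixelSize, id = tr@id))
  TrackSet(tracks)
}
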
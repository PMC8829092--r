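#' @include simulate.R
NULL

#' Construct a movie generator configuration
#'
#' @param rXY spatial resolution, metres per pixel.
#' @param rT temporal resolution, seconds per frame.
#' @param contrast spot contrast C = I_p - mu_bg (negative values allowed,
#'   for absorption/iSCAT-like contrast).
#' @param muBg background mean intensity.
#' @param sigma2Bg background Gaussian variance.
#' @param psf optional 2D matrix or 3D array; a 3D stack contributes its
#'   central slice (the focus position).
#' @param squareGrid force a square spatial grid (enclosing square of the
#'   track extents).
#' @param normalizePSF rescale the PSF to unit sum before convolution
#'   (default TRUE), so total spot intensity is conserved away from edges.
#' @param poisson apply the final pixelwise Poisson noise stage (default TRUE).
#' @param padPx spatial margin in pixels added on every side of the grid
#'   (default 0: the grid spans exactly the track extents). A margin keeps
#'   spots away from the borders so PSF convolution and sub-pixel
#'   refinement windows stay inside the frame.
#' @return a validated \linkS4class{MovieConfig}.
#' @export
movieConfig <- function(rXY, rT, contrast = 10, muBg = 100, sigma2Bg = 0,
                        psf = NULL, squareGrid = FALSE, normalizePSF = TRUE,
                        poisson = TRUE, padPx = 0L) {
  cfg <- new("MovieConfig", rXY = rXY, rT = rT, contrast = contrast,
             muBg = muBg, sigma2Bg = sigma2Bg, psf = psf,
             squareGrid = squareGrid, normalizePSF = normalizePSF,
             poisson = poisson)
  attr(cfg, "padPx") <- as.integer(padPx)
  cfg
}

#' Discretise a physical coordinate onto the simulation grid
#'
#' m = round((x - minimum) / resolution); rounding is R's round-half-to-even.
#'
#' @param position physical coordinate(s) (metres or seconds).
#' @param minimum grid origin in the same unit.
#' @param resolution grid pitch (> 0) in the same unit.
#' @return integer grid index/indices (0-based).
#' @export
discretize <- function(position, minimum, resolution) {
  if (resolution <= 0) stop("resolution must be positive")
  as.integer(round((position - minimum) / resolution))
}

# spatio-temporal extents over all tracks
.trackExtents <- function(tracks) {
  xs <- unlist(lapply(tracks@tracks, trackX))
  ys <- unlist(lapply(tracks@tracks, trackY))
  ts <- unlist(lapply(tracks@tracks, trackTimes))
  list(x = range(xs), y = range(ys), t = range(ts))
}

#' Initialise an empty movie grid from track extents
#'
#' The grid spans the min/max positions and times over all tracks, with
#' side = round(extent / resolution) + 1 pixels (frames). With
#' \code{squareGrid} the enclosing square is taken: both spatial axes span
#' [min(x_min, y_min), max(x_max, y_max)].
#'
#' @param tracks a non-empty \linkS4class{TrackSet}.
#' @param config a \linkS4class{MovieConfig}.
#' @return a \linkS4class{MovieScene} with all-zero frames.
#' @examples
#' tr <- Track(t = 0:10, x = c(0, rep(5, 9), 10), y = c(0, rep(5, 9), 10))
#' scene <- buildGrid(TrackSet(list(tr)), movieConfig(rXY = 1, rT = 1))
#' dim(sceneFrames(scene))  # (11, 11, 11)
#' @export
buildGrid <- function(tracks, config) {
  if (!length(tracks@tracks)) stop("need at least one track")
  ext <- .trackExtents(tracks)
  if (config@squareGrid) {
    lo <- min(ext$x[1L], ext$y[1L]); hi <- max(ext$x[2L], ext$y[2L])
    ext$x <- c(lo, hi); ext$y <- c(lo, hi)
  }
  pad <- attr(config, "padPx")
  if (is.null(pad)) pad <- 0L
  ext$x <- ext$x + c(-1, 1) * pad * config@rXY
  ext$y <- ext$y + c(-1, 1) * pad * config@rXY
  w <- discretize(ext$x[2L], ext$x[1L], config@rXY) + 1L
  h <- discretize(ext$y[2L], ext$y[1L], config@rXY) + 1L
  nf <- discretize(ext$t[2L], ext$t[1L], config@rT) + 1L
  new("MovieScene", frames = array(0, dim = c(h, w, nf)),
      origin = c(ext$x[1L], ext$y[1L], ext$t[1L]),
      rXY = config@rXY, rT = config@rT)
}

# central 2D slice of a PSF, normalised to unit sum if requested
.preparePSF <- function(config, frameDim) {
  psf <- config@psf
  if (is.null(psf)) return(NULL)
  if (length(dim(psf)) == 3L)
    psf <- psf[, , floor(dim(psf)[3L] / 2) + 1L]
  psf <- as.matrix(psf)
  if (any(dim(psf) > frameDim))
    stop("PSF (", paste(dim(psf), collapse = "x"),
         ") is larger than the frame (", paste(frameDim, collapse = "x"), ")")
  if (config@normalizePSF) {
    s <- sum(psf)
    if (s == 0) stop("PSF sums to zero; cannot normalise")
    psf <- psf / s
  }
  psf
}

#' Render tracks into a synthetic movie
#'
#' Pipeline: (1) i.i.d. Gaussian background B ~ N(mu_bg, sigma2_bg) at every
#' pixel of every frame; (2) each track point is discretised onto the grid
#' and adds intensity C at its pixel (a delta spot; shape comes only from
#' the PSF); (3) if a PSF is configured, the spot field of each frame is
#' convolved with it (zero padding at the borders) before the background is
#' added; (4) pixelwise Poisson noise with lambda = the pre-noise intensity
#' (negative pre-noise values are clipped to zero first, with a warning).
#' A fixed \code{noiseSeed} gives a bitwise-identical movie.
#'
#' @param tracks a non-empty \linkS4class{TrackSet} (metres/seconds).
#' @param config a \linkS4class{MovieConfig}.
#' @param noiseSeed integer seed for both noise stages.
#' @return a \linkS4class{MovieScene}.
#' @export
renderMovie <- function(tracks, config, noiseSeed = 0L) {
  scene <- buildGrid(tracks, config)
  d <- dim(scene@frames)
  spots <- array(0, dim = d)
  for (tr in tracks@tracks) {
    mx <- discretize(trackX(tr), scene@origin[1L], scene@rXY)
    my <- discretize(trackY(tr), scene@origin[2L], scene@rXY)
    mt <- discretize(trackTimes(tr), scene@origin[3L], scene@rT)
    for (i in seq_along(mx))
      spots[my[i] + 1L, mx[i] + 1L, mt[i] + 1L] <-
        spots[my[i] + 1L, mx[i] + 1L, mt[i] + 1L] + config@contrast
  }
  psf <- .preparePSF(config, d[1:2])
  if (!is.null(psf))
    for (k in seq_len(d[3L]))
      spots[, , k] <- EBImage::filter2(spots[, , k], psf, boundary = 0)

  frames <- .withSeed(noiseSeed, {
    bg <- array(stats::rnorm(prod(d), mean = config@muBg,
                             sd = sqrt(config@sigma2Bg)), dim = d)
    m <- spots + bg
    if (config@poisson) {
      if (any(m < 0)) {
        warning("clipping ", sum(m < 0),
                " negative pre-noise intensities to 0 for the Poisson stage")
        m[m < 0] <- 0
      }
      m <- array(stats::rpois(prod(d), lambda = m), dim = d)
    }
    m
  })
  scene@frames <- frames
  validObject(scene)
  scene
}

setMethod("sceneFrames", "MovieScene", function(x) x@frames)

#' MovieScene accessors
#' @param x a \linkS4class{MovieScene}.
#' @name MovieScene-accessors
NULL

#' @rdname exportTIFF
setMethod("exportTIFF", "MovieScene",
  function(scene, path, bitDepth = c("16", "8", "float32")) {
    bitDepth <- match.arg(bitDepth)
    bits <- switch(bitDepth, "8" = 8L, "16" = 16L, "float32" = 32L)
    fr <- scene@frames
    mn <- min(fr); mx <- max(fr)
    scale <- if (mx > mn) mx - mn else 1
    pages <- lapply(seq_len(dim(fr)[3L]),
                    function(k) (fr[, , k] - mn) / scale)
    ok <- try(tiff::writeTIFF(pages, path, bits.per.sample = bits),
              silent = TRUE)
    if (inherits(ok, "try-error"))
      stop("I/O error writing ", path, ": ", attr(ok, "condition")$message)
    sidecar <- list(offset = mn, scale = scale, bitDepth = bitDepth,
                    rXY = scene@rXY, rT = scene@rT, origin = scene@origin)
    jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
    invisible(NULL)
  })

#' Read a multi-page grayscale TIFF into a (height, width, frames) array
#'
#' If a JSON sidecar written by \code{\link{exportTIFF}} is present next to
#' the file, the stored intensities are rescaled back to absolute values
#' (\code{applySidecar = FALSE} keeps the raw stored range).
#'
#' @param path TIFF file path.
#' @param applySidecar apply sidecar scaling when available (default TRUE).
#' @return numeric array (height, width, frames).
#' @export
readTIFFStack <- function(path, applySidecar = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1L]  # first channel of RGB(A) input
    p
  })
  arr <- array(unlist(pages), dim = c(dim(pages[[1L]]), length(pages)))
  sidecarPath <- paste0(path, ".json")
  if (applySidecar && file.exists(sidecarPath)) {
    sc <- jsonlite::read_json(sidecarPath, simplifyVector = TRUE)
    arr <- arr * sc$scale + sc$offset
  }
  arr
}

setMethod("show", "MovieScene", function(object) {
  d <- dim(object@frames)
  cat(sprintf(
    "MovieScene: %d x %d px, %d frame(s); rXY = %.3g m/px, rT = %.3g s\n",
    d[1L], d[2L], d[3L], object@rXY, object@rT))
})
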
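test_that("pre-processing neutralises constant stacks and static artefacts", {
  # temporally constant stack: flat-field division gives 1 everywhere,
  # background subtraction then zeroes it
  stack <- array(5, dim = c(8, 8, 6))
  out <- preprocessStack(stack, preprocessConfig(normalize = FALSE))
  expect_true(all(out == 0))
  # a static bright pixel is removed by the flat field (ratio 1)
  stack2 <- array(10, dim = c(8, 8, 6))
  stack2[4, 4, ] <- 200
  out2 <- preprocessStack(stack2, preprocessConfig(normalize = FALSE))
  expect_equal(max(abs(out2)), 0)
  # all-zero stacks are a preprocessing error
  expect_error(preprocessStack(array(0, dim = c(4, 4, 3))), "flat field")
})

test_that("pre-processing improves spot contrast on a structured background", {
  # static gradient background times a moving bright spot
  set.seed(4)
  h <- 32; nf <- 20
  grad <- outer(seq(1, 3, length.out = h), seq(1, 2, length.out = h))
  stack <- array(0, dim = c(h, h, nf))
  pos <- cbind(8 + (1:nf), 10 + rep(0:1, 10))
  for (k in 1:nf) {
    fr <- grad * 50 + matrix(rnorm(h * h, 0, 1), h, h)
    fr[pos[k, 1], pos[k, 2]] <- fr[pos[k, 1], pos[k, 2]] + 40
    stack[, , k] <- fr
  }
  rawContrast <- (stack[pos[1, 1], pos[1, 2], 1] - mean(stack[, , 1])) /
    sd(stack[, , 1])
  proc <- preprocessStack(stack)
  procContrast <- (proc[pos[1, 1], pos[1, 2], 1] - mean(proc[, , 1])) /
    sd(proc[, , 1])
  expect_gt(procContrast, rawContrast)
})

test_that("blank frames yield zero detections", {
  expect_equal(nrow(detectSpots(matrix(3, 32, 32))), 0L)
  set.seed(2)
  noise <- matrix(rnorm(32 * 32), 32, 32)
  # pure noise may fire occasionally at c = 3; at c = 6 it must not
  expect_equal(nrow(detectSpots(noise, detectionConfig(sigma = 2, c = 6))), 0L)
})

test_that("a pixel-centred symmetric spot is localised exactly", {
  img <- gaussSpotImage(33, cx = 16, cy = 16, sigma = 2, A = 10)
  det <- detectSpots(img, detectionConfig(sigma = 2, c = 3, roiSize = 9))
  expect_equal(nrow(det), 1L)
  expect_equal(det$x, 16, tolerance = 1e-6)
  expect_equal(det$y, 16, tolerance = 1e-6)
})

test_that("detection count never increases with the threshold weight", {
  set.seed(14)
  img <- matrix(rnorm(64 * 64, 10, 1), 64, 64)
  for (p in list(c(20, 20), c(40, 45), c(25, 50)))
    img <- img + gaussSpotImage(64, p[1], p[2], sigma = 2, A = 12)
  counts <- vapply(c(1, 2, 3, 5, 8), function(cw)
    nrow(detectSpots(img, detectionConfig(sigma = 2, c = cw, roiSize = 9))),
    integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("radial symmetry centre is exact on symmetric patches", {
  p <- gaussSpotImage(9, 4, 4, sigma = 1.5)
  ctr <- radialSymmetryCenter(p)
  expect_equal(unname(ctr), c(4, 4), tolerance = 1e-9)
  # mirrored patch: x reflects about the midpoint, y unchanged
  po <- gaussSpotImage(9, 4.3, 4, sigma = 1.5)
  a <- radialSymmetryCenter(po)
  b <- radialSymmetryCenter(po[, ncol(po):1])
  expect_equal(b[["x"]], 8 - a[["x"]], tolerance = 1e-9)
  expect_equal(b[["y"]], a[["y"]], tolerance = 1e-9)
  # constant patch has no centre
  expect_error(radialSymmetryCenter(matrix(1, 5, 5)), "undefined centre")
  expect_error(radialSymmetryCenter(matrix(1, 2, 2)), "at least 3x3")
})

test_that("noiseless sub-pixel offsets are recovered within 0.02 px", {
  for (off in list(c(0.3, -0.2), c(-0.45, 0.1), c(0.05, 0.4))) {
    p <- gaussSpotImage(11, 5 + off[1], 5 + off[2], sigma = 2)
    ctr <- radialSymmetryCenter(p)
    err <- sqrt((ctr[["x"]] - 5 - off[1])^2 + (ctr[["y"]] - 5 - off[2])^2)
    expect_lt(err, 0.02)
  }
})

test_that("well-separated particles link into clean tracks", {
  # two particles 20 px apart, drifting < 1 px/frame, 10 frames
  set.seed(8)
  det <- do.call(rbind, lapply(0:9, function(f)
    data.frame(frame = f,
               x = c(5 + 0.3 * f, 25 - 0.2 * f),
               y = c(5 + 0.1 * f, 5 + 0.3 * f))))
  ts <- linkDetections(det, linkConfig(maxDistance = 5, maxGap = 0,
                                       minTrackLength = 2))
  expect_equal(length(ts), 2L)
  lens <- vapply(ts@tracks, function(t) length(trackTimes(t)), integer(1))
  expect_equal(lens, c(10L, 10L))
  # no identity swap: each track is monotone in its own x direction
  xs <- lapply(ts@tracks, trackX)
  expect_true(all(diff(xs[[which.min(vapply(xs, min, numeric(1)))]]) > 0))
})

test_that("gaps are filled by linear interpolation", {
  det <- data.frame(frame = c(0, 1, 3, 4),
                    x = c(0, 1, 3, 4), y = c(0, 2, 6, 8))
  ts <- linkDetections(det, linkConfig(maxDistance = 5, maxGap = 1,
                                       minTrackLength = 2))
  expect_equal(length(ts), 1L)
  tr <- ts[[1]]
  expect_equal(length(trackTimes(tr)), 5L)
  # filled frame 2 is the midpoint of frames 1 and 3
  expect_equal(trackX(tr)[3], 2)
  expect_equal(trackY(tr)[3], 4)
})

test_that("short tracks are filtered and empty input is not an error", {
  det <- data.frame(frame = 0:2, x = c(0, 0.5, 1), y = c(0, 0, 0))
  ts <- linkDetections(det, linkConfig(maxDistance = 2, maxGap = 0,
                                       minTrackLength = 5))
  expect_equal(length(ts), 0L)
  empty <- data.frame(frame = integer(0), x = numeric(0), y = numeric(0))
  expect_equal(length(linkDetections(empty)), 0L)
})

test_that("a rendered movie round-trips through the full tracker", {
  tr <- simulateBrownian(Tmax = 0.02, dt = 1e-4, D = 1e-12, L = 1e-5,
                         seed = 3)
  cfg <- movieConfig(rXY = 3e-8, rT = 1e-4, contrast = 150, muBg = 50,
                     sigma2Bg = 25, psf = gaussPSF(sigma = 1.5, half = 5),
                     normalizePSF = FALSE, padPx = 8)
  scene <- renderMovie(TrackSet(list(tr)), cfg, noiseSeed = 77)
  # the movie has a spatially uniform background, so the temporal
  # flat-field/background stages are disabled: with a slowly diffusing
  # particle they would subtract a smeared ghost of the spot itself and
  # distort the sub-pixel localisation
  rec <- suppressMessages(trackMovie(
    sceneFrames(scene),
    pre = preprocessConfig(enableFlatfield = FALSE,
                           enableBackgroundSubtract = FALSE),
    det = detectionConfig(sigma = 1.5, c = 5, roiSize = 9,
                          peakSizeLimits = c(1, 30)),
    link = linkConfig(maxDistance = 4, maxGap = 5, minTrackLength = 50),
    pixelSize = 3e-8, frameInterval = 1e-4))
  expect_equal(length(rec), 1L)
  got <- rec[[1]]
  expect_gt(length(trackTimes(got)), 190)  # within a few frames of 201
  # mean deviation from ground truth < 0.5 px after aligning the origin
  nT <- length(trackTimes(got))
  offX <- mean(trackX(got) - trackX(tr)[1:nT])
  offY <- mean(trackY(got) - trackY(tr)[1:nT])
  devPx <- sqrt((trackX(got) - trackX(tr)[1:nT] - offX)^2 +
                (trackY(got) - trackY(tr)[1:nT] - offY)^2) / 3e-8
  expect_lt(mean(devPx), 0.5)
})

test_that("a blank movie produces an empty TrackSet", {
  stack <- array(100, dim = c(16, 16, 5))
  rec <- trackMovie(stack)
  expect_equal(length(rec), 0L)
})
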
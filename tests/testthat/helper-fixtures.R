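# shared fixture builders for the test suite (everything generated in code)

# symmetric Gaussian spot on an n x n pixel grid; centre in 0-based pixel
# coordinates, amplitude A, width sigma
gaussSpotImage <- function(n, cx, cy, sigma = 2, A = 1) {
  ax <- 0:(n - 1)
  outer(ax, ax, function(y, x) A * exp(-((x - cx)^2 + (y - cy)^2) /
                                         (2 * sigma^2)))
}

# peak-normalised Gaussian PSF kernel (odd side 2*half+1)
gaussPSF <- function(sigma = 1.5, half = 5) {
  ax <- -half:half
  outer(ax, ax, function(x, y) exp(-(x^2 + y^2) / (2 * sigma^2)))
}

# straight-line track: x = a*i, y = 0, dt = 1
linearTrack <- function(n, a = 1, id = 0L) {
  Track(t = 0:(n - 1), x = a * (0:(n - 1)), y = numeric(n), id = id)
}

# brute-force time-averaged MSD: explicit double loop over all (i, i+n) pairs
bruteForceMSD <- function(x, y, dt) {
  n <- length(x)
  vals <- numeric(n - 1)
  for (lag in 1:(n - 1)) {
    acc <- 0
    for (i in 1:(n - lag))
      acc <- acc + (x[i + lag] - x[i])^2 + (y[i + lag] - y[i])^2
    vals[lag] <- acc / (n - lag)
  }
  list(lags = dt * (1:(n - 1)), values = vals)
}

# brute-force optimal assignment by exhaustive permutation search (n <= m);
# returns minimal total cost over all one-to-one assignments of rows to
# columns (forbidden = Inf entries allowed, pairs skipped)
bruteForceAssignmentCost <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  stopifnot(n <= m, n <= 5)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    out
  }
  best <- Inf
  for (cols in utils::combn(m, n, simplify = FALSE))
    for (p in perms(cols)) {
      tot <- sum(cost[cbind(1:n, p)])
      if (tot < best) best <- tot
    }
  best
}

# total cost realised by a solveAssignment() result (unassigned rows cost 0)
assignmentCost <- function(cost, assignment) {
  idx <- which(!is.na(assignment))
  sum(cost[cbind(idx, assignment[idx])])
}

# MSD curve generated exactly from the linear blur model
modelMsdCurve <- function(D, delta2, dt, nLags, R = 0, alpha = 1) {
  tn <- dt * (1:nLags)
  vals <- 4 * D * tn^alpha + 2 * delta2 - 8 * D * R * dt
  new("MsdCurve", lags = tn, values = vals,
      nTrackPoints = as.integer(nLags + 1))
}
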
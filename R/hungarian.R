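#' @include movie.R
NULL

# Hungarian algorithm (Kuhn-Munkres, potentials + shortest augmenting path,
# O(n^2 m)) for rectangular cost matrices with nrow <= ncol. Indices: rows
# 1..n, columns 1..m, plus a virtual column 0 stored at R index m + 1.
# Returns for each row the assigned column.
.hungarianCore <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  stopifnot(n <= m)
  J0 <- m + 1L                      # R index of virtual column 0
  u <- numeric(n)                   # row potentials
  v <- numeric(m + 1L)              # column potentials (incl. virtual)
  p <- integer(m + 1L)              # p[j]: row matched to column j (0 = none)
  way <- integer(m + 1L)
  for (i in seq_len(n)) {
    p[J0] <- i
    j0 <- J0
    minv <- rep(Inf, m)
    used <- logical(m + 1L)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      # column reduced costs against the current potentials
      cur <- cost[i0, ] - u[i0] - v[seq_len(m)]
      upd <- !used[seq_len(m)] & cur < minv
      minv[upd] <- cur[upd]
      way[upd] <- j0
      free <- which(!used[seq_len(m)])
      j1 <- free[which.min(minv[free])]
      delta <- minv[j1]
      usedCols <- which(used)
      u[p[usedCols]] <- u[p[usedCols]] + delta
      v[usedCols] <- v[usedCols] - delta
      minv[!used[seq_len(m)]] <- minv[!used[seq_len(m)]] - delta
      j0 <- j1
      if (p[j0] == 0L) break
    }
    # augment along the alternating path
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == J0) break
    }
  }
  assignment <- integer(n)
  for (j in seq_len(m)) if (p[j] > 0L) assignment[p[j]] <- j
  assignment
}

#' Optimal one-to-one assignment minimising total cost
#'
#' Solves the linear assignment problem (Hungarian algorithm) for an
#' arbitrary rectangular cost matrix. Entries that are \code{Inf} or exceed
#' \code{maxCost} are forbidden: a row forced onto a forbidden column is
#' reported unassigned (NA). Surplus rows/columns remain unassigned.
#'
#' @param cost numeric matrix, cost of assigning row i to column j.
#' @param maxCost assignments with cost > maxCost are forbidden
#'   (default Inf = no limit).
#' @return integer vector of length nrow(cost): assigned column per row, or
#'   NA when unassigned.
#' @examples
#' solveAssignment(rbind(c(4, 1, 3), c(2, 0, 5), c(3, 2, 2)))
#' @export
solveAssignment <- function(cost, maxCost = Inf) {
  cost <- as.matrix(cost)
  if (!length(cost)) return(integer(0))
  n <- nrow(cost); m <- ncol(cost)
  forbidden <- !is.finite(cost) | cost > maxCost
  work <- cost
  finiteVals <- work[!forbidden]
  big <- if (length(finiteVals))
    (max(abs(finiteVals)) + 1) * (n + m + 1) else 1
  work[forbidden] <- big
  if (n <= m) {
    assignment <- .hungarianCore(work)
  } else {
    colOfRow <- integer(n)
    byCol <- .hungarianCore(t(work))
    colOfRow[] <- NA_integer_
    colOfRow[byCol] <- seq_len(m)
    assignment <- colOfRow
  }
  bad <- !is.na(assignment) &
    forbidden[cbind(seq_len(n), ifelse(is.na(assignment), 1L, assignment))]
  assignment[bad] <- NA_integer_
  assignment
}
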
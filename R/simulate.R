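#' @include adc.R
NULL

# run expr with a locally seeded RNG, restoring the caller's RNG state
.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

# fold a coordinate back into [0, L] (reflecting boundary)
.reflect <- function(p, L) {
  p <- p %% (2 * L)
  ifelse(p > L, 2 * L - p, p)
}

#' Simulate a free Brownian trajectory
#'
#' Random walk on a square domain of side L with reflecting boundaries. The
#' particle starts at the domain centre; each axis is updated independently
#' per step by sqrt(2 D dt) times a standard normal deviate. The trajectory
#' has floor(Tmax/dt) + 1 points including the origin and is bitwise
#' reproducible for a fixed seed.
#'
#' @param Tmax total simulated time, seconds.
#' @param dt time step, seconds (0 < dt < Tmax).
#' @param D diffusion coefficient, m^2/s.
#' @param L side of the square domain, metres.
#' @param dL optional spatial grid pitch, metres (used when quantize = TRUE).
#' @param seed integer RNG seed.
#' @param quantize round positions to the dL grid (default FALSE).
#' @param id track id for the returned \linkS4class{Track}.
#' @return a \linkS4class{Track} in metres/seconds.
#' @examples
#' tr <- simulateBrownian(Tmax = 0.01, dt = 1e-4, D = 1e-12, L = 1e-5, seed = 42)
#' tr
#' @export
simulateBrownian <- function(Tmax, dt, D, L, dL = NULL, seed = 0L,
                             quantize = FALSE, id = 0L) {
  if (!(Tmax > dt) || dt <= 0) stop("need Tmax > dt > 0")
  if (D < 0) stop("D must be non-negative")
  if (L <= 0) stop("L must be positive")
  step <- sqrt(2 * D * dt)
  if (step >= L)
    warning("step scale sqrt(2 D dt) >= L: the particle exits the domain ",
            "at the first step; boundaries will dominate")
  nSteps <- floor(Tmax / dt)
  .withSeed(seed, {
    dx <- step * stats::rnorm(nSteps)
    dy <- step * stats::rnorm(nSteps)
    x <- .reflect(L / 2 + cumsum(c(0, dx)), L)
    y <- .reflect(L / 2 + cumsum(c(0, dy)), L)
    if (quantize) {
      if (is.null(dL) || dL <= 0) stop("quantize = TRUE needs a positive dL")
      x <- round(x / dL) * dL
      y <- round(y / dL) * dL
    }
    Track(t = dt * (0:nSteps), x = x, y = y, id = id)
  })
}

#' Build a compartment map from uniformly placed Voronoi seeds
#'
#' @param nCompartments number of compartments (>= 1).
#' @param L domain side, metres.
#' @param voronoiSeed RNG seed for the seed-point placement.
#' @return a \linkS4class{CompartmentMap}.
#' @export
compartmentMap <- function(nCompartments, L, voronoiSeed = 0L) {
  if (nCompartments < 1L) stop("need at least one compartment")
  seeds <- .withSeed(voronoiSeed,
    matrix(stats::runif(2L * nCompartments, 0, L), ncol = 2L))
  new("CompartmentMap", seeds = seeds, L = L)
}

#' @rdname assignCompartment
setMethod("assignCompartment", "CompartmentMap", function(map, point) {
  pts <- if (is.matrix(point)) point else matrix(point, ncol = 2L)
  if (!all(is.finite(pts))) stop("query points must be finite")
  sx <- map@seeds[, 1L]; sy <- map@seeds[, 2L]
  vapply(seq_len(nrow(pts)), function(i) {
    d2 <- (sx - pts[i, 1L])^2 + (sy - pts[i, 2L])^2
    which.min(d2)  # which.min takes the first (lowest id) on ties
  }, integer(1))
})

#' Simulate hop diffusion on a Voronoi-compartmentalised membrane
#'
#' The domain is split into compartments as the Voronoi diagram of random
#' seed points (realised by nearest-seed assignment). The particle starts at
#' the domain centre and performs the same Brownian stepping as
#' \code{\link{simulateBrownian}}, except that a proposed step landing in a
#' different compartment is accepted only with hopping probability HP;
#' otherwise the step is redrawn (up to \code{maxRetries} times) so the
#' particle stays in its compartment. With HP = 0 the particle never changes
#' compartment (confined diffusion); with HP = 1 the statistics are those of
#' free Brownian motion. When every retry would hop, the particle stays in
#' place for that step (counted in attribute "rejectedSteps").
#'
#' @inheritParams simulateBrownian
#' @param nCompartments number of Voronoi compartments.
#' @param HP hopping probability in [0, 1].
#' @param voronoiSeed RNG seed for compartment geometry.
#' @param maxRetries bounded redraws per step (default 100).
#' @return list with elements \code{track} (a \linkS4class{Track}),
#'   \code{map} (a \linkS4class{CompartmentMap}) and \code{compartments}
#'   (integer compartment id at every track point).
#' @export
simulateHop <- function(Tmax, dt, D, L, nCompartments, HP,
                        seed = 0L, voronoiSeed = 1L, maxRetries = 100L,
                        id = 0L) {
  if (!(Tmax > dt) || dt <= 0) stop("need Tmax > dt > 0")
  if (HP < 0 || HP > 1) stop("HP must lie in [0, 1]")
  map <- compartmentMap(nCompartments, L, voronoiSeed)
  if (nCompartments == 1L) {
    # no boundaries to cross: exactly the free Brownian walk
    track <- simulateBrownian(Tmax = Tmax, dt = dt, D = D, L = L,
                              seed = seed, id = id)
    return(list(track = track, map = map,
                compartments = rep(1L, length(trackTimes(track)))))
  }
  step <- sqrt(2 * D * dt)
  nSteps <- floor(Tmax / dt)
  x <- numeric(nSteps + 1L); y <- numeric(nSteps + 1L)
  comp <- integer(nSteps + 1L)
  x[1L] <- L / 2; y[1L] <- L / 2
  comp[1L] <- assignCompartment(map, c(x[1L], y[1L]))
  rejected <- 0L
  .withSeed(seed, {
    for (i in seq_len(nSteps)) {
      accepted <- FALSE
      for (try in seq_len(maxRetries)) {
        nx <- .reflect(x[i] + step * stats::rnorm(1L), L)
        ny <- .reflect(y[i] + step * stats::rnorm(1L), L)
        newComp <- assignCompartment(map, c(nx, ny))
        if (newComp == comp[i] || stats::runif(1L) < HP) {
          x[i + 1L] <- nx; y[i + 1L] <- ny; comp[i + 1L] <- newComp
          accepted <- TRUE
          break
        }
      }
      if (!accepted) {  # retry budget exhausted: stay in place
        x[i + 1L] <- x[i]; y[i + 1L] <- y[i]; comp[i + 1L] <- comp[i]
        rejected <- rejected + 1L
      }
    }
  })
  track <- Track(t = dt * (0:nSteps), x = x, y = y, id = id)
  attr(track, "rejectedSteps") <- rejected
  list(track = track, map = map, compartments = comp)
}

#' Mean equivalent compartment diameter of a map
#'
#' Diameter of the circle with the mean cell area L^2 / n; a convenient
#' scalar scale for comparing against the confinement size
#' L = sqrt(12 D tau) fitted by the confined ADC model.
#'
#' @param map a \linkS4class{CompartmentMap}.
#' @return mean equivalent diameter in metres.
#' @export
meanCompartmentDiameter <- function(map) {
  meanArea <- map@L^2 / nrow(map@seeds)
  2 * sqrt(meanArea / pi)
}

setMethod("show", "CompartmentMap", function(object) {
  cat(sprintf("CompartmentMap: %d Voronoi seeds on a %.3g m square domain\n",
              nrow(object@seeds), object@L))
})
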
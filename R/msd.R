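#' @include trackio.R
NULL

#' @rdname computeMSD
setMethod("computeMSD", "Track", function(track) {
  n <- length(track@t)
  if (n < 2L) stop("MSD needs at least 2 track points")
  dt <- timeStep(track)
  vals <- numeric(n - 1L)
  x <- track@x; y <- track@y
  for (lag in seq_len(n - 1L)) {
    dx <- x[(1L + lag):n] - x[1L:(n - lag)]
    dy <- y[(1L + lag):n] - y[1L:(n - lag)]
    vals[lag] <- sum(dx * dx + dy * dy) / (n - lag)
  }
  new("MsdCurve", lags = dt * seq_len(n - 1L), values = vals,
      nTrackPoints = as.integer(n))
})

# resolve the fit range shared by MSD and ADC fitting: indices of lags used
.fitRange <- function(lags, fitMaxTime, fractionFitPoints) {
  if (!is.null(fitMaxTime) && !is.null(fractionFitPoints))
    stop("give exactly one of fitMaxTime and fractionFitPoints")
  if (is.null(fitMaxTime) && is.null(fractionFitPoints))
    fractionFitPoints <- 0.25
  if (!is.null(fitMaxTime)) {
    if (fitMaxTime <= 0) stop("fitMaxTime must be positive")
    sel <- which(lags <= fitMaxTime)
  } else {
    if (fractionFitPoints <= 0 || fractionFitPoints > 1)
      stop("fractionFitPoints must lie in (0, 1]")
    sel <- seq_len(max(1L, ceiling(fractionFitPoints * length(lags))))
  }
  if (!length(sel)) stop("fit range contains no lag points")
  sel
}

.checkR <- function(R) {
  if (length(R) != 1L || !is.finite(R) || R < 0 || R > 0.25)
    stop("blur coefficient R must lie in [0, 1/4], got ", R)
  R
}

# Levenberg-Marquardt bounded least squares; returns list(par, errors, rss,
# converged, message). Errors are sqrt of the diagonal of
# RSS/(n-k) * (J'J)^{-1}; NA when the system is degenerate (e.g. exact data).
.lmFit <- function(resid, par, lower, upper) {
  fit <- try(minpack.lm::nls.lm(
    par = par, lower = lower, upper = upper, fn = resid,
    control = minpack.lm::nls.lm.control(
      maxfev = 1000L, maxiter = 500L,
      ftol = 1e-12, ptol = 1e-12, gtol = 1e-12)), silent = TRUE)
  if (inherits(fit, "try-error"))
    return(list(par = par, errors = rep(NA_real_, length(par)),
                rss = Inf, converged = FALSE,
                message = attr(fit, "condition")$message))
  rss <- fit$deviance
  nres <- length(fit$fvec)
  k <- length(par)
  errors <- rep(NA_real_, k)
  if (nres > k && rss > 0) {
    covm <- try(solve(fit$hessian) * rss / (nres - k), silent = TRUE)
    if (!inherits(covm, "try-error")) {
      d <- diag(covm)
      errors <- ifelse(d >= 0, sqrt(pmax(d, 0)), NA_real_)
    }
  }
  conv <- fit$info %in% c(1L, 2L, 3L, 4L) && is.finite(rss)
  list(par = stats::setNames(as.numeric(fit$par), names(par)),
       errors = stats::setNames(errors, names(par)),
       rss = rss, converged = conv, message = fit$message)
}

#' Fit a blur-aware diffusion model to an MSD curve
#'
#' Nonlinear least squares of
#' \deqn{MSD(t_n) = 4 D t_n + 2\delta^2 - 8 D R t_0}{MSD(t_n) = 4 D t_n + 2 delta^2 - 8 D R t_0}
#' (model "linear_blur") or \eqn{4 D t_n^\alpha + 2\delta^2 - 8 D R t_0}
#' (model "anomalous_blur") over lags up to the chosen cutoff, with
#' \eqn{t_0} the track time step. D and \eqn{\delta^2} are constrained
#' non-negative; the blur coefficient R (set by the illumination mode) is a
#' supplied constant in [0, 1/4], never fitted. The fit range "must be chosen
#' with care": too long a range mixes in poorly averaged long-lag points.
#'
#' @param curve an \linkS4class{MsdCurve}.
#' @param model "linear_blur" (default) or "anomalous_blur".
#' @param fitMaxTime,fractionFitPoints fit-range cutoff: give at most one;
#'   defaults to the first 25\% of available lags.
#' @param R blur coefficient in [0, 1/4]; default 0 (no blur correction).
#' @param fixDelta optional localisation error in metres; when given,
#'   delta^2 is fixed at fixDelta^2 instead of floating.
#' @return an \linkS4class{MsdFit}.
#' @export
fitMSD <- function(curve, model = c("linear_blur", "anomalous_blur"),
                   fitMaxTime = NULL, fractionFitPoints = NULL,
                   R = 0, fixDelta = NULL) {
  model <- match.arg(model)
  .checkR(R)
  if (!length(curve@lags)) stop("empty MSD curve")
  sel <- .fitRange(curve@lags, fitMaxTime, fractionFitPoints)
  tn <- curve@lags[sel]
  yv <- curve@values[sel]
  t0 <- curve@lags[1L]
  anomalous <- model == "anomalous_blur"
  freeDelta <- is.null(fixDelta)
  fixedDelta2 <- if (freeDelta) 0 else fixDelta^2

  k <- 1L + as.integer(freeDelta) + as.integer(anomalous)
  if (length(sel) < k)
    stop("fitting error: ", length(sel), " fit point(s) for ", k,
         " free parameter(s)")

  # slope-based initial D from the first two lags
  D0 <- if (length(tn) >= 2L) (yv[2L] - yv[1L]) / (4 * (tn[2L] - tn[1L])) else
    yv[1L] / (4 * tn[1L])
  if (!is.finite(D0) || D0 <= 0) D0 <- max(yv[1L] / (4 * tn[1L]), 1e-30)

  par <- c(D = D0)
  lower <- c(D = 0); upper <- c(D = Inf)
  if (freeDelta) {
    par <- c(par, delta2 = 0)
    lower <- c(lower, delta2 = 0); upper <- c(upper, delta2 = Inf)
  }
  if (anomalous) {
    par <- c(par, alpha = 1)
    lower <- c(lower, alpha = 1e-6); upper <- c(upper, alpha = Inf)
  }

  modelFun <- function(p) {
    d2 <- if (freeDelta) p[["delta2"]] else fixedDelta2
    a <- if (anomalous) p[["alpha"]] else 1
    4 * p[["D"]] * tn^a + 2 * d2 - 8 * p[["D"]] * R * t0
  }
  fit <- .lmFit(function(p) yv - modelFun(p), par, lower, upper)
  if (!fit$converged)
    stop("fitting error (", model, "): ", fit$message)

  new("MsdFit", model = model,
      D = fit$par[["D"]],
      delta2 = if (freeDelta) fit$par[["delta2"]] else fixedDelta2,
      alpha = if (anomalous) fit$par[["alpha"]] else NA_real_,
      R = R,
      paramErrors = fit$errors,
      rss = fit$rss, nFitPoints = length(sel))
}

setMethod("msdLags", "MsdCurve", function(x) x@lags)
setMethod("msdValues", "MsdCurve", function(x) x@values)
setMethod("msdLags", "AdcCurve", function(x) x@lags)
setMethod("msdValues", "AdcCurve", function(x) x@values)

#' MsdCurve accessors
#' @param x an \linkS4class{MsdCurve} or \linkS4class{AdcCurve}.
#' @name MsdCurve-accessors
NULL

setMethod("show", "MsdCurve", function(object) {
  cat(sprintf("MsdCurve: %d lags (%.3g .. %.3g s) from a %d-point track\n",
              length(object@lags), object@lags[1],
              object@lags[length(object@lags)], object@nTrackPoints))
})

setMethod("show", "MsdFit", function(object) {
  cat(sprintf("MsdFit [%s]: D = %.4g m^2/s, delta^2 = %.4g m^2",
              object@model, object@D, object@delta2))
  if (!is.na(object@alpha)) cat(sprintf(", alpha = %.4g", object@alpha))
  cat(sprintf("\n  R = %.3g, RSS = %.4g m^4 over %d lags\n",
              object@R, object@rss, object@nFitPoints))
})
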
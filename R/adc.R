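#' @include models.R
NULL

#' @rdname computeADC
setMethod("computeADC", "MsdCurve", function(curve, R = 0) {
  .checkR(R)
  if (!length(curve@lags)) stop("empty MSD curve")
  nIdx <- seq_along(curve@lags)
  denom <- 1 - 2 * R / nIdx
  if (any(denom <= 0))
    stop("ADC denominator non-positive; R must be below n/2 for every lag")
  vals <- curve@values / (4 * curve@lags * denom)
  new("AdcCurve", lags = curve@lags, values = vals,
      nIndex = as.integer(nIdx))
})

#' Bayesian information criterion for a least-squares fit
#'
#' BIC = k ln(n) + n ln(RSS/n) with n the number of fitted points and k the
#' number of free parameters.
#'
#' @param rss residual sum of squares.
#' @param n number of fitted points.
#' @param k number of free parameters.
#' @return the BIC value (finite; an exactly zero RSS is floored at the
#'   smallest positive double to avoid -Inf).
#' @export
bicScore <- function(rss, n, k) {
  k * log(n) + n * log(max(rss, .Machine$double.xmin) / n)
}

# fit a single DiffusionModel to ADC data over preselected lags
.fitAdcModel <- function(model, tn, yv, R, dt) {
  par <- stats::setNames(model@initial, model@paramNames)
  resid <- function(p) yv - model@fun(tn, as.list(p), R, dt)
  fit <- .lmFit(resid, par, model@lower, model@upper)
  n <- length(tn)
  k <- length(par)
  out <- fit
  if (fit$converged && n > k) {
    out$bic <- bicScore(fit$rss, n, k)
    fitted <- model@fun(tn, as.list(fit$par), R, dt)
    ks <- suppressWarnings(stats::ks.test(yv, fitted))
    out$ksStat <- unname(ks$statistic)
    out$ksP <- ks$p.value
  } else {
    out$converged <- FALSE
    out$rss <- Inf
    out$bic <- Inf
    out$ksStat <- NA_real_
    out$ksP <- NA_real_
    if (n <= k) out$message <- sprintf(
      "%d fit point(s) for %d free parameter(s)", n, k)
  }
  out[c("par", "errors", "rss", "bic", "ksStat", "ksP", "converged",
        "message")]
}

#' @rdname adcAnalysis
setMethod("adcAnalysis", "Track",
  function(object, registry = builtinModels(), fitMaxTime = NULL,
           fractionFitPoints = NULL, R = 0) {
    .checkR(R)
    if (!length(registry@models)) stop("the model registry is empty")
    curve <- computeMSD(object)
    adc <- computeADC(curve, R)
    sel <- .fitRange(adc@lags, fitMaxTime, fractionFitPoints)
    tn <- adc@lags[sel]
    yv <- adc@values[sel]
    dt <- timeStep(object)

    fits <- lapply(registry@models, .fitAdcModel, tn = tn, yv = yv,
                   R = R, dt = dt)
    names(fits) <- names(registry@models)
    fits <- lapply(fits, function(f) {
      list(params = f$par, errors = f$errors, rss = f$rss, bic = f$bic,
           ksStat = f$ksStat, ksP = f$ksP, converged = f$converged,
           message = f$message)
    })

    conv <- vapply(fits, function(f) isTRUE(f$converged), logical(1))
    if (!any(conv)) {
      msgs <- vapply(fits, function(f) paste0(f$message, ""), character(1))
      stop("analysis error: no model converged for track ", object@id, ": ",
           paste(sprintf("[%s] %s", names(fits), msgs), collapse = "; "))
    }
    bics <- vapply(fits, function(f)
      if (isTRUE(f$converged)) f$bic else Inf, numeric(1))
    # ties (< 1e-9 apart): first-registered model wins, flagged
    bestIdx <- which(bics <= min(bics) + 1e-9)
    tie <- length(bestIdx) > 1L
    best <- names(fits)[bestIdx[1L]]

    report <- new("FitReport", trackId = object@id, fits = fits,
                  bestModel = best, tie = tie,
                  nFitPoints = length(sel), R = R, dt = dt, adc = adc)
    object@results$adc <- report
    object
  })

#' @rdname adcAnalysis
setMethod("adcAnalysis", "TrackSet",
  function(object, registry = builtinModels(), fitMaxTime = NULL,
           fractionFitPoints = NULL, R = 0) {
    object@tracks <- lapply(object@tracks, adcAnalysis, registry = registry,
                            fitMaxTime = fitMaxTime,
                            fractionFitPoints = fractionFitPoints, R = R)
    object
  })

#' Retrieve the ADC fit report attached to a track
#'
#' @param track a \linkS4class{Track} previously analysed with
#'   \code{\link{adcAnalysis}}.
#' @return the \linkS4class{FitReport}.
#' @export
adcReport <- function(track) {
  rep <- track@results$adc
  if (is.null(rep))
    stop("track ", track@id, " has not been analysed; run adcAnalysis first")
  rep
}

#' @rdname adcSummary
setMethod("adcSummary", "TrackSet", function(tracks) {
  if (!length(tracks@tracks)) stop("empty TrackSet")
  reports <- lapply(tracks@tracks, adcReport)
  best <- vapply(reports, function(r) r@bestModel, character(1))
  ids <- trackIds(tracks)
  counts <- table(best)
  fractions <- counts / length(best)
  perTrack <- data.frame(
    id = ids, bestModel = best,
    bic = vapply(reports, function(r) r@fits[[r@bestModel]]$bic, numeric(1)),
    row.names = NULL)
  # average D_app over the lag range common to all tracks
  nmin <- min(vapply(reports, function(r) length(r@adc@lags), integer(1)))
  mat <- vapply(reports, function(r) r@adc@values[seq_len(nmin)],
                numeric(nmin))
  meanAdc <- new("AdcCurve", lags = reports[[1L]]@adc@lags[seq_len(nmin)],
                 values = rowMeans(as.matrix(mat)),
                 nIndex = reports[[1L]]@adc@nIndex[seq_len(nmin)])
  list(counts = counts, fractions = fractions, perTrack = perTrack,
       meanAdc = meanAdc)
})

setMethod("bestModel", "FitReport", function(x) x@bestModel)
setMethod("modelFits", "FitReport", function(x) x@fits)

#' FitReport accessors
#' @param x a \linkS4class{FitReport}.
#' @name FitReport-accessors
NULL

setMethod("show", "FitReport", function(object) {
  cat(sprintf("FitReport for track %d (%d fit points, R = %.3g):\n",
              object@trackId, object@nFitPoints, object@R))
  for (nm in names(object@fits)) {
    f <- object@fits[[nm]]
    flag <- if (nm == object@bestModel) " *best*" else ""
    if (isTRUE(f$converged))
      cat(sprintf("  %-10s BIC = %.2f, RSS = %.3g, KS = %.3f%s\n",
                  nm, f$bic, f$rss, f$ksStat, flag))
    else
      cat(sprintf("  %-10s did not converge (%s)\n", nm, f$message))
  }
  if (object@tie) cat("  (BIC tie broken by registration order)\n")
})
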
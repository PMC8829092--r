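#' @import methods
NULL

.REL_DT_TOL <- 1e-6

#' Track: a single 2D particle trajectory
#'
#' Holds one trajectory sampled at a uniform time interval: time stamps
#' \code{t} (seconds), positions \code{x}, \code{y} (metres) and an integer
#' track label. Analysis pipelines assume a constant interval between
#' localisations; this is enforced at construction with a relative tolerance
#' of 1e-6 on the spacing. Analysis results (MSD, ADC fit reports) are
#' attached to the \code{results} slot by the corresponding pipeline
#' functions so they can be retrieved later.
#'
#' @slot t numeric, strictly increasing time stamps in seconds, uniform spacing.
#' @slot x,y numeric particle coordinates in metres.
#' @slot id integer track label.
#' @slot lengthUnit character, length unit of the source file ("m", "um", "nm").
#' @slot results list of analysis results keyed by pipeline name.
#' @exportClass Track
setClass("Track",
  representation(t = "numeric", x = "numeric", y = "numeric",
                 id = "integer", lengthUnit = "character", results = "list"),
  prototype(lengthUnit = "m", results = list()))

setValidity("Track", function(object) {
  n <- length(object@t)
  if (n < 2L)
    return("a track needs at least 2 points (MSD is undefined otherwise)")
  if (length(object@x) != n || length(object@y) != n)
    return("t, x and y must have equal length")
  if (!all(is.finite(object@t)) || !all(is.finite(object@x)) ||
      !all(is.finite(object@y)))
    return("all coordinates and times must be finite")
  dts <- diff(object@t)
  if (any(dts <= 0))
    return("time stamps must be strictly increasing")
  dt <- stats::median(dts)
  worst <- max(abs(dts - dt))
  if (worst > .REL_DT_TOL * dt)
    return(sprintf(
      "non-uniform time spacing: worst gap deviates by %.3g s from dt = %.3g s (relative %.3g > %.0e)",
      worst, dt, worst / dt, .REL_DT_TOL))
  if (length(object@id) != 1L || is.na(object@id))
    return("id must be a single non-missing integer")
  TRUE
})

#' TrackSet: an ordered pool of tracks
#'
#' Ordered collection of \linkS4class{Track} objects with unique ids,
#' supporting bulk analysis (\code{\link{adcAnalysis}}) and summary
#' (\code{\link{adcSummary}}).
#'
#' @slot tracks list of \linkS4class{Track}.
#' @exportClass TrackSet
setClass("TrackSet", representation(tracks = "list"))

setValidity("TrackSet", function(object) {
  if (!all(vapply(object@tracks, is, logical(1), "Track")))
    return("all elements must be Track objects")
  ids <- vapply(object@tracks, function(tr) tr@id, integer(1))
  if (anyDuplicated(ids))
    return(sprintf("track ids must be unique; duplicated: %s",
                   paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  TRUE
})

#' MsdCurve: time-averaged mean squared displacement
#'
#' MSD values (metres squared) against lag times t_n = n * dt for
#' n = 1 .. N-1, computed with overlapping windows (divisor N - n).
#'
#' @slot lags numeric lag times in seconds, strictly increasing.
#' @slot values numeric MSD values in metres squared, non-negative.
#' @slot nTrackPoints integer, number of points N in the source track.
#' @exportClass MsdCurve
setClass("MsdCurve",
  representation(lags = "numeric", values = "numeric",
                 nTrackPoints = "integer"))

setValidity("MsdCurve", function(object) {
  if (length(object@lags) != length(object@values))
    return("lags and values must have equal length")
  if (any(diff(object@lags) <= 0))
    return("lags must be strictly increasing")
  if (any(object@values < 0))
    return("MSD values must be non-negative")
  TRUE
})

#' MsdFit: blur-aware MSD model fit
#'
#' Result of fitting MSD(t_n) = 4 D t_n + 2 delta^2 - 8 D R t_0 (linear)
#' or 4 D t_n^alpha + 2 delta^2 - 8 D R t_0 (anomalous) to an
#' \linkS4class{MsdCurve}. \code{alpha} is NA for the linear model. R is the
#' motion-blur coefficient in [0, 1/4] set by the illumination mode; it is a
#' supplied constant, never fitted.
#'
#' @slot model character, "linear_blur" or "anomalous_blur".
#' @slot D numeric diffusion coefficient, m^2/s.
#' @slot delta2 numeric localisation-error variance term, m^2.
#' @slot alpha numeric anomalous exponent (NA for linear model).
#' @slot R numeric blur coefficient in [0, 1/4].
#' @slot paramErrors named numeric, 1-sigma errors (sqrt of covariance diagonal).
#' @slot rss numeric residual sum of squares, m^4.
#' @slot nFitPoints integer number of lags used in the fit.
#' @exportClass MsdFit
setClass("MsdFit",
  representation(model = "character", D = "numeric", delta2 = "numeric",
                 alpha = "numeric", R = "numeric", paramErrors = "numeric",
                 rss = "numeric", nFitPoints = "integer"))

setValidity("MsdFit", function(object) {
  if (!object@model %in% c("linear_blur", "anomalous_blur"))
    return("model must be 'linear_blur' or 'anomalous_blur'")
  if (object@D < 0) return("D must be non-negative")
  if (object@R < 0 || object@R > 0.25) return("R must lie in [0, 1/4]")
  if (!is.na(object@alpha) && object@alpha <= 0)
    return("alpha must be positive")
  if (any(object@paramErrors < 0, na.rm = TRUE))
    return("parameter errors must be non-negative")
  TRUE
})

#' AdcCurve: apparent diffusion coefficient against lag time
#'
#' D_app(t_n) = MSD(t_n) / (4 t_n (1 - 2R/n)) with n the integer lag index.
#' "Apparent" because the values still contain the localisation-error
#' contribution.
#'
#' @slot lags numeric lag times, seconds.
#' @slot values numeric D_app values, m^2/s.
#' @slot nIndex integer lag indices n (t_n = n * dt).
#' @exportClass AdcCurve
setClass("AdcCurve",
  representation(lags = "numeric", values = "numeric", nIndex = "integer"))

setValidity("AdcCurve", function(object) {
  if (length(object@lags) != length(object@values) ||
      length(object@lags) != length(object@nIndex))
    return("lags, values and nIndex must have equal length")
  if (any(diff(object@lags) <= 0))
    return("lags must be strictly increasing")
  TRUE
})

#' DiffusionModel: a named parametric D_app(t) curve
#'
#' A diffusion model for ADC fitting: a curve function D_app(t; params, R, dt)
#' together with parameter names, box bounds and initial values. The blur
#' coefficient R and the track time step dt are injected by the analysis
#' pipeline at fit time, mirroring how such models carry the acquisition
#' constants of the data they are fitted to.
#'
#' @slot name character model name, unique within a registry.
#' @slot paramNames character vector of free-parameter names.
#' @slot lower,upper,initial numeric vectors aligned with paramNames.
#' @slot fun function(t, params, R, dt) returning D_app values.
#' @exportClass DiffusionModel
setClass("DiffusionModel",
  representation(name = "character", paramNames = "character",
                 lower = "numeric", upper = "numeric", initial = "numeric",
                 fun = "function"))

setValidity("DiffusionModel", function(object) {
  k <- length(object@paramNames)
  if (length(object@lower) != k || length(object@upper) != k ||
      length(object@initial) != k)
    return("lower, upper and initial must match the number of parameters")
  if (any(object@lower > object@initial) || any(object@initial > object@upper))
    return("initial values must satisfy lower <= initial <= upper")
  TRUE
})

#' ModelRegistry: ordered set of diffusion models
#'
#' Ordered registry of \linkS4class{DiffusionModel} objects with unique
#' names. \code{\link{builtinModels}} returns a registry holding the three
#' built-in models (brownian, confined, hop); \code{\link{registerModel}}
#' adds user-defined models.
#'
#' @slot models named list of \linkS4class{DiffusionModel}, fit order = registration order.
#' @exportClass ModelRegistry
setClass("ModelRegistry", representation(models = "list"))

setValidity("ModelRegistry", function(object) {
  if (!all(vapply(object@models, is, logical(1), "DiffusionModel")))
    return("all registry entries must be DiffusionModel objects")
  nms <- vapply(object@models, function(m) m@name, character(1))
  if (anyDuplicated(nms)) return("model names must be unique")
  if (length(nms) && !identical(unname(nms), names(object@models)))
    return("list names must equal model names")
  TRUE
})

#' FitReport: per-model ADC fit results for one track
#'
#' For each fitted model: parameters, parameter errors, RSS, BIC and the
#' Kolmogorov-Smirnov statistic/p-value between the ADC data and the fitted
#' curve over the fit range. \code{bestModel} is the converged model with the
#' lowest BIC (ties broken by registration order and flagged).
#'
#' @slot trackId integer id of the analysed track.
#' @slot fits named list, one entry per model with elements
#'   params, errors, rss, bic, ksStat, ksP, converged, message.
#' @slot bestModel character name of the BIC-minimising model.
#' @slot tie logical, TRUE when the BIC minimum was tied (< 1e-9 apart).
#' @slot nFitPoints integer number of ADC points fitted.
#' @slot R,dt numeric blur coefficient and time step used.
#' @slot adc the \linkS4class{AdcCurve} that was fitted.
#' @exportClass FitReport
setClass("FitReport",
  representation(trackId = "integer", fits = "list", bestModel = "character",
                 tie = "logical", nFitPoints = "integer",
                 R = "numeric", dt = "numeric", adc = "AdcCurve"))

setValidity("FitReport", function(object) {
  conv <- Filter(function(f) isTRUE(f$converged), object@fits)
  if (!length(conv)) return("at least one model fit must have converged")
  bics <- vapply(conv, function(f) f$bic, numeric(1))
  if (!all(is.finite(bics)))
    return("BIC must be finite for every converged fit")
  if (!object@bestModel %in% names(conv))
    return("bestModel must be a converged model")
  if (bics[[object@bestModel]] > min(bics) + 1e-9)
    return("bestModel must attain the minimum BIC")
  TRUE
})

#' MovieConfig: parameters of the synthetic movie generator
#'
#' @slot rXY numeric spatial resolution, metres per pixel.
#' @slot rT numeric temporal resolution, seconds per frame.
#' @slot contrast numeric spot contrast C = I_p - mu_bg (may be negative for
#'   absorption/iSCAT-like imaging).
#' @slot muBg numeric background mean intensity.
#' @slot sigma2Bg numeric background Gaussian variance (intensity squared).
#' @slot psf optional 2D matrix or 3D array point spread function (NULL for a
#'   single-pixel delta spot); a 3D stack contributes its central slice.
#' @slot squareGrid logical, force a square spatial grid.
#' @slot normalizePSF logical, rescale the PSF to unit sum before convolution.
#' @slot poisson logical, apply the pixelwise Poisson noise stage.
#' @exportClass MovieConfig
setClass("MovieConfig",
  representation(rXY = "numeric", rT = "numeric", contrast = "numeric",
                 muBg = "numeric", sigma2Bg = "numeric", psf = "ANY",
                 squareGrid = "logical", normalizePSF = "logical",
                 poisson = "logical"))

setValidity("MovieConfig", function(object) {
  if (object@rXY <= 0 || object@rT <= 0)
    return("rXY and rT must be positive")
  if (object@sigma2Bg < 0) return("sigma2Bg must be non-negative")
  if (!is.null(object@psf)) {
    d <- dim(object@psf)
    if (is.null(d) || !length(d) %in% c(2L, 3L))
      return("psf must be a 2D matrix or a 3D array")
  }
  TRUE
})

#' MovieScene: discretised spatio-temporal intensity grid
#'
#' @slot frames numeric array (height, width, frames) of pixel intensities.
#' @slot origin numeric length-3 (x_min, y_min, t_min) of the grid.
#' @slot rXY,rT numeric grid resolutions (m/px, s/frame).
#' @exportClass MovieScene
setClass("MovieScene",
  representation(frames = "array", origin = "numeric",
                 rXY = "numeric", rT = "numeric"))

setValidity("MovieScene", function(object) {
  if (length(dim(object@frames)) != 3L)
    return("frames must be a 3D array (height, width, time)")
  if (!all(is.finite(object@frames)))
    return("all intensities must be finite")
  if (length(object@origin) != 3L)
    return("origin must be (x_min, y_min, t_min)")
  TRUE
})

#' CompartmentMap: Voronoi compartments for hop-diffusion simulation
#'
#' Compartments are realised by nearest-seed assignment (equivalent to the
#' Voronoi diagram of the seed points); no explicit polygon construction.
#' Compartment ids are 1-based (R convention).
#'
#' @slot seeds numeric matrix (n x 2) of seed coordinates in metres.
#' @slot L numeric side of the square domain, metres.
#' @exportClass CompartmentMap
setClass("CompartmentMap", representation(seeds = "matrix", L = "numeric"))

setValidity("CompartmentMap", function(object) {
  if (ncol(object@seeds) != 2L || nrow(object@seeds) < 1L)
    return("seeds must be an n x 2 matrix with n >= 1")
  if (!all(is.finite(object@seeds))) return("seeds must be finite")
  TRUE
})
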
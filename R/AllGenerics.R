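#' @include AllClasses.R
NULL

#' Compute the time-averaged MSD of a track
#'
#' For each lag n = 1 .. N-1 the MSD is the mean over all start indices i of
#' |r(t_{i+n}) - r(t_i)|^2 (overlapping windows, divisor N - n).
#'
#' @param track a \linkS4class{Track}.
#' @return an \linkS4class{MsdCurve}.
#' @examples
#' tr <- simulateBrownian(Tmax = 0.01, dt = 1e-4, D = 1e-12, L = 1e-5, seed = 1)
#' msd <- computeMSD(tr)
#' head(msdValues(msd))
#' @export
setGeneric("computeMSD", function(track) standardGeneric("computeMSD"))

#' Transform an MSD curve into apparent diffusion coefficients
#'
#' D_app(t_n) = MSD(t_n) / (4 t_n (1 - 2R/n)) where n is the integer lag
#' index and R the motion-blur coefficient in [0, 1/4].
#'
#' @param curve an \linkS4class{MsdCurve}.
#' @param R blur coefficient, dimensionless, in [0, 1/4]. Default 0.
#' @return an \linkS4class{AdcCurve}.
#' @export
setGeneric("computeADC", function(curve, R = 0) standardGeneric("computeADC"))

#' ADC analysis: fit diffusion models and select the best by BIC
#'
#' Computes the ADC transform of the track's MSD, fits every model in the
#' registry by bounded nonlinear least squares over the chosen fit range,
#' scores each with BIC = k ln(n) + n ln(RSS/n), and picks the model with
#' the lowest BIC. A two-sample Kolmogorov-Smirnov statistic between the ADC
#' data and the fitted curve is recorded per model as a goodness check (it
#' never overrides BIC). Results are attached to the track (slot
#' \code{results$adc}) for later retrieval.
#'
#' @param object a \linkS4class{Track} or \linkS4class{TrackSet}.
#' @param registry a \linkS4class{ModelRegistry}; default \code{builtinModels()}.
#' @param fitMaxTime fit lags with t_n <= this time (seconds); give exactly
#'   one of \code{fitMaxTime} / \code{fractionFitPoints}.
#' @param fractionFitPoints fit the first fraction of available lags
#'   (default 0.25 when neither argument is given).
#' @param R blur coefficient in [0, 1/4], default 0.
#' @return for a Track, the Track with a \linkS4class{FitReport} attached;
#'   for a TrackSet, the TrackSet with every track analysed.
#' @export
setGeneric("adcAnalysis",
  function(object, registry = builtinModels(), fitMaxTime = NULL,
           fractionFitPoints = NULL, R = 0)
    standardGeneric("adcAnalysis"))

#' Summarise ADC analyses over a pool of tracks
#'
#' @param tracks a \linkS4class{TrackSet} whose tracks were analysed with
#'   \code{\link{adcAnalysis}}.
#' @return a list with elements \code{counts} (best-model track counts),
#'   \code{fractions}, \code{perTrack} (data.frame id/best model/BIC) and
#'   \code{meanAdc} (average D_app curve over the common lag range).
#' @export
setGeneric("adcSummary", function(tracks) standardGeneric("adcSummary"))

#' Write a TrackSet to CSV
#'
#' Writes columns id,t,x,y (seconds/metres) such that
#' \code{readTracks()} reproduces the set to 1e-12 relative.
#'
#' @param tracks a non-empty \linkS4class{TrackSet}.
#' @param path output file path.
#' @export
setGeneric("writeTracks", function(tracks, path) standardGeneric("writeTracks"))

#' Assign points to compartments by nearest Voronoi seed
#'
#' @param map a \linkS4class{CompartmentMap}.
#' @param point numeric vector c(x, y) or an n x 2 matrix of points (metres).
#' @return integer compartment id(s), 1-based; ties broken by lowest id.
#' @export
setGeneric("assignCompartment",
  function(map, point) standardGeneric("assignCompartment"))

#' Export a movie scene as a multi-page TIFF
#'
#' One page per frame. Intensities are min-max scaled into [0, 1] for
#' storage at the requested bit depth; the scaling constants are written to
#' a JSON sidecar (\code{<path>.json}) so absolute intensities can be
#' recovered on read (see \code{\link{readTIFFStack}}).
#'
#' @param scene a \linkS4class{MovieScene}.
#' @param path output TIFF path.
#' @param bitDepth "16" (default), "8" or "float32".
#' @export
setGeneric("exportTIFF",
  function(scene, path, bitDepth = c("16", "8", "float32"))
    standardGeneric("exportTIFF"))

# ---- simple accessors ----

#' @describeIn Track-accessors time stamps in seconds
#' @export
setGeneric("trackTimes", function(x) standardGeneric("trackTimes"))
#' @describeIn Track-accessors x coordinates in metres
#' @export
setGeneric("trackX", function(x) standardGeneric("trackX"))
#' @describeIn Track-accessors y coordinates in metres
#' @export
setGeneric("trackY", function(x) standardGeneric("trackY"))
#' @describeIn Track-accessors integer track label
#' @export
setGeneric("trackId", function(x) standardGeneric("trackId"))
#' @describeIn Track-accessors uniform time step dt in seconds
#' @export
setGeneric("timeStep", function(x) standardGeneric("timeStep"))
#' @describeIn Track-accessors attached analysis results (list)
#' @export
setGeneric("analysisResults", function(x) standardGeneric("analysisResults"))

#' @describeIn MsdCurve-accessors lag times (seconds)
#' @export
setGeneric("msdLags", function(x) standardGeneric("msdLags"))
#' @describeIn MsdCurve-accessors MSD or D_app values
#' @export
setGeneric("msdValues", function(x) standardGeneric("msdValues"))

#' @describeIn TrackSet-accessors ids of the contained tracks
#' @export
setGeneric("trackIds", function(x) standardGeneric("trackIds"))
#' @describeIn TrackSet-accessors retrieve one track by id
#' @export
setGeneric("getTrack", function(x, id) standardGeneric("getTrack"))

#' @describeIn FitReport-accessors name of the BIC-selected model
#' @export
setGeneric("bestModel", function(x) standardGeneric("bestModel"))
#' @describeIn FitReport-accessors per-model fit list
#' @export
setGeneric("modelFits", function(x) standardGeneric("modelFits"))

#' @describeIn ModelRegistry-accessors names of registered models
#' @export
setGeneric("modelNames", function(x) standardGeneric("modelNames"))

#' @describeIn MovieScene-accessors the (height, width, frames) array
#' @export
setGeneric("sceneFrames", function(x) standardGeneric("sceneFrames"))
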
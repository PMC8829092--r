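#' @include AllGenerics.R
NULL

.UNIT_FACTORS <- c(m = 1, um = 1e-6, nm = 1e-9)

.unitFactor <- function(lengthUnit) {
  # accept the micro sign spelling as well
  if (lengthUnit %in% c("µm", "μm", "micrometres", "micrometers"))
    lengthUnit <- "um"
  if (!lengthUnit %in% names(.UNIT_FACTORS))
    stop("unknown length unit '", lengthUnit,
         "'; expected one of: ", paste(names(.UNIT_FACTORS), collapse = ", "))
  .UNIT_FACTORS[[lengthUnit]]
}

#' Construct a Track
#'
#' @param t time stamps in seconds, strictly increasing, uniform spacing.
#' @param x,y coordinates in metres.
#' @param id integer track label (default 0).
#' @param lengthUnit unit of the source data, for bookkeeping only; the
#'   stored coordinates are always metres.
#' @return a validated \linkS4class{Track}.
#' @export
Track <- function(t, x, y, id = 0L, lengthUnit = "m") {
  new("Track", t = as.numeric(t), x = as.numeric(x), y = as.numeric(y),
      id = as.integer(id), lengthUnit = lengthUnit)
}

#' Construct a TrackSet
#'
#' @param tracks list of \linkS4class{Track} objects with unique ids. The
#'   empty set is allowed (for construction) but cannot be written out.
#' @return a validated \linkS4class{TrackSet}.
#' @export
TrackSet <- function(tracks = list()) new("TrackSet", tracks = tracks)

#' Read tracks from a CSV file
#'
#' The file must contain columns \code{t}, \code{x}, \code{y} (any order)
#' and, when it holds more than one track, an \code{id} column matching each
#' localisation to a track. Column names can be remapped with
#' \code{columnMap}. Times are taken as seconds; coordinates are converted
#' from \code{lengthUnit} to metres.
#'
#' @param path CSV file path (UTF-8, comma separated, header row).
#' @param columnMap optional named character vector mapping canonical names
#'   to file columns, e.g. \code{c(t = "time", x = "pos_x")}.
#' @param lengthUnit "m", "um" (micrometres) or "nm". Default "m".
#' @return a \linkS4class{TrackSet}, one track per distinct id
#'   (single-track files get id 0).
#' @export
readTracks <- function(path, columnMap = NULL, lengthUnit = "m") {
  if (!file.exists(path)) stop("file not found: ", path)
  fac <- .unitFactor(lengthUnit)
  df <- utils::read.csv(path, check.names = FALSE)
  for (canon in names(columnMap)) {
    src <- columnMap[[canon]]
    if (!src %in% names(df))
      stop("format error: mapped column '", src, "' (for '", canon,
           "') not found in ", path)
    names(df)[names(df) == src] <- canon
  }
  for (col in c("t", "x", "y"))
    if (!col %in% names(df))
      stop("format error: required column '", col, "' missing in ", path)
  hasId <- "id" %in% names(df)
  ids <- if (hasId) df$id else rep(0L, nrow(df))
  uids <- unique(ids)
  if (!hasId && length(uids) == 1L) uids <- 0L
  tracks <- lapply(uids, function(u) {
    sub <- df[ids == u, , drop = FALSE]
    if (anyDuplicated(sub$t))
      stop("format error: duplicate (id, t) rows for id ", u, " in ", path)
    sub <- sub[order(sub$t), , drop = FALSE]
    tr <- try(Track(sub$t, sub$x * fac, sub$y * fac, id = as.integer(u),
                    lengthUnit = lengthUnit), silent = TRUE)
    if (inherits(tr, "try-error"))
      stop("validation error for track id ", u, ": ",
           attr(tr, "condition")$message)
    tr
  })
  TrackSet(tracks)
}

#' @rdname writeTracks
setMethod("writeTracks", "TrackSet", function(tracks, path) {
  if (length(tracks@tracks) == 0L)
    stop("cannot write an empty TrackSet")
  rows <- lapply(tracks@tracks, function(tr)
    data.frame(id = tr@id, t = tr@t, x = tr@x, y = tr@y))
  df <- do.call(rbind, rows)
  ok <- try(utils::write.csv(df, path, row.names = FALSE, quote = FALSE),
            silent = TRUE)
  if (inherits(ok, "try-error"))
    stop("I/O error writing ", path, ": ", attr(ok, "condition")$message)
  invisible(NULL)
})

# ---- accessors & methods ----

#' Track accessors
#'
#' @param x a \linkS4class{Track}.
#' @name Track-accessors
NULL

setMethod("trackTimes", "Track", function(x) x@t)
setMethod("trackX", "Track", function(x) x@x)
setMethod("trackY", "Track", function(x) x@y)
setMethod("trackId", "Track", function(x) x@id)
setMethod("timeStep", "Track", function(x) stats::median(diff(x@t)))
setMethod("analysisResults", "Track", function(x) x@results)

#' TrackSet accessors
#'
#' @param x a \linkS4class{TrackSet}.
#' @param id integer track id.
#' @name TrackSet-accessors
NULL

setMethod("trackIds", "TrackSet",
  function(x) vapply(x@tracks, function(tr) tr@id, integer(1)))

setMethod("getTrack", "TrackSet", function(x, id) {
  idx <- which(trackIds(x) == id)
  if (!length(idx)) stop("no track with id ", id)
  x@tracks[[idx[1L]]]
})

#' @export
setMethod("length", "TrackSet", function(x) length(x@tracks))

#' @export
setMethod("[[", "TrackSet", function(x, i) x@tracks[[i]])

setMethod("show", "Track", function(object) {
  cat(sprintf("Track id %d: %d points, dt = %.4g s, duration %.4g s\n",
              object@id, length(object@t), timeStep(object),
              object@t[length(object@t)] - object@t[1]))
  if (length(object@results))
    cat("  attached results:", paste(names(object@results), collapse = ", "),
        "\n")
})

setMethod("show", "TrackSet", function(object) {
  cat(sprintf("TrackSet with %d track(s)", length(object@tracks)))
  if (length(object@tracks))
    cat("; ids:", paste(utils::head(trackIds(object), 10), collapse = ", "),
        if (length(object@tracks) > 10) "..." else "")
  cat("\n")
})
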
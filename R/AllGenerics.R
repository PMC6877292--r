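#' Accessors for bbbflux classes
#'
#' `voxels()` returns the raw 4D array of a [Hyperstack-class];
#' `frameTimes()` its per-frame session times in minutes; `segments()` and
#' `labelVolume()` the geometry table and label array of a
#' [VesselTree-class]; `roiPixels()` the linear pixel indices covered by a
#' [RoiSet-class] on its grid.
#'
#' @param object a bbbflux object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("voxels", function(object) standardGeneric("voxels"))
#' @rdname accessors
#' @export
setGeneric("frameTimes", function(object) standardGeneric("frameTimes"))
#' @rdname accessors
#' @export
setGeneric("segments", function(object) standardGeneric("segments"))
#' @rdname accessors
#' @export
setGeneric("labelVolume", function(object) standardGeneric("labelVolume"))
#' @rdname accessors
#' @export
setGeneric("roiPixels", function(object) standardGeneric("roiPixels"))

#' @rdname accessors
#' @export
setMethod("voxels", "Hyperstack", function(object) object@voxels)

#' @rdname accessors
#' @export
setMethod("frameTimes", "Hyperstack", function(object)
  object@t0Min + (seq_len(dim(object@voxels)[1]) - 1L) * object@frameIntervalMin)

#' @rdname accessors
#' @export
setMethod("segments", "VesselTree", function(object) object@segments)

#' @rdname accessors
#' @export
setMethod("labelVolume", "VesselTree", function(object) object@labels)

#' @rdname accessors
#' @export
setMethod("roiPixels", "RoiSet", function(object) {
  ny <- object@gridDim[1]
  idx <- unlist(lapply(seq_len(nrow(object@rois)), function(i) {
    r <- object@rois[i, ]
    rows <- r$row:(r$row + r$height - 1L)
    cols <- r$col:(r$col + r$width - 1L)
    as.vector(outer(rows, (cols - 1L) * ny, `+`))
  }))
  sort(unique(idx))
})

setMethod("show", "Hyperstack", function(object) {
  d <- dim(object@voxels)
  cat(sprintf(
    "Hyperstack: %d frames x %d planes x %d x %d px\n", d[1], d[2], d[3], d[4]))
  cat(sprintf("  pixel %.3g um, z-step %.3g um, frame interval %.3g min, t0 %.3g min\n",
              object@pixelSizeUm, object@zStepUm, object@frameIntervalMin,
              object@t0Min))
})

setMethod("show", "IntensityTrace", function(object) {
  cat(sprintf("IntensityTrace (%s, %s): %d timepoints, t = [%.3g, %.3g] min\n",
              object@compartment, object@units, length(object@values),
              min(object@timesMin), max(object@timesMin)))
})

setMethod("show", "VesselTree", function(object) {
  s <- object@segments
  cat(sprintf("VesselTree: %d segments, label volume %s\n", nrow(s),
              paste(dim(object@labels), collapse = " x ")))
  if (nrow(s) > 0) print(table(s$category))
})

setMethod("show", "ExponentialFit", function(object) {
  cat(sprintf("ExponentialFit [%s%s]: a = %.4g, b = %.4g, c = %.4g /min, rmse = %.3g\n",
              object@model, if (object@fallback) ", linear fallback" else "",
              object@a, object@b, object@c, object@rmse))
})

setMethod("show", "PermeabilityResult", function(object) {
  cat(sprintf("PermeabilityResult '%s': AUC = %.4g min (%d correction fit%s)\n",
              object@tracer, object@aucMin, length(object@correctionFits),
              if (length(object@correctionFits) == 1) "" else "s"))
})

setMethod("show", "GroupComparisonResult", function(object) {
  cat(sprintf("GroupComparisonResult [%s]: statistic = %.4g, p = %.4g\n",
              object@testName, object@statistic, object@pValue))
})

#' @rdname accessors
#' @param x an `IntensityTrace`.
#' @export
setMethod("length", "IntensityTrace", function(x) length(x@values))

#' Coerce an IntensityTrace to a data.frame
#' @param x an `IntensityTrace`.
#' @param ... ignored.
#' @export
setMethod("as.data.frame", "IntensityTrace", function(x, ...)
  data.frame(time_min = x@timesMin, value = x@values, units = x@units,
             compartment = x@compartment))
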
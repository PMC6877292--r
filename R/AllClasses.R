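#' @import methods
NULL

VESSEL_CATEGORIES <- c("pial_arteriole", "penetrating_arteriole", "capillary",
                       "post_capillary_venule", "ascending_venule",
                       "pial_venule")

TRACE_UNITS <- c("raw_au", "relative", "fraction_of_baseline")
COMPARTMENTS <- c("parenchyma", "blood")

#' Hyperstack: a 4D two-photon image series
#'
#' Container for a time-lapse volumetric recording, ordered
#' (time, depth, row, col), together with the acquisition metadata needed to
#' convert voxel indices to physical units.  Intensities are arbitrary
#' detector units (16-bit range on disk); in memory they may be non-integer
#' (e.g. noiseless simulated expectations).
#'
#' @slot voxels 4D numeric array, dimensions (T, Z, Y, X), all values >= 0.
#' @slot pixelSizeUm lateral pixel size in micrometres.
#' @slot zStepUm axial plane spacing in micrometres.
#' @slot frameIntervalMin time between consecutive Z-stacks, minutes.
#' @slot t0Min session time of the first frame, minutes.
#' @export
setClass("Hyperstack",
  representation(voxels = "array", pixelSizeUm = "numeric",
                 zStepUm = "numeric", frameIntervalMin = "numeric",
                 t0Min = "numeric"))

setValidity("Hyperstack", function(object) {
  v <- object@voxels
  if (length(dim(v)) != 4L) return("voxels must be a 4D (T,Z,Y,X) array")
  if (any(!is.finite(v))) return("voxel intensities must be finite")
  if (any(v < 0)) return("voxel intensities must be >= 0")
  for (s in c("pixelSizeUm", "zStepUm", "frameIntervalMin")) {
    x <- slot(object, s)
    if (length(x) != 1L || !is.finite(x) || x <= 0)
      return(paste0(s, " must be a positive scalar"))
  }
  if (length(object@t0Min) != 1L || !is.finite(object@t0Min))
    return("t0Min must be a finite scalar")
  TRUE
})

#' Construct a Hyperstack
#'
#' @param voxels 4D array ordered (time, depth, row, col).
#' @param pixelSizeUm,zStepUm,frameIntervalMin acquisition metadata
#'   (micrometres, micrometres, minutes); all strictly positive.
#' @param t0Min session time of the first frame in minutes.
#' @return A [Hyperstack-class] object.
#' @export
Hyperstack <- function(voxels, pixelSizeUm, zStepUm, frameIntervalMin,
                       t0Min = 0) {
  new("Hyperstack", voxels = voxels, pixelSizeUm = pixelSizeUm,
      zStepUm = zStepUm, frameIntervalMin = frameIntervalMin, t0Min = t0Min)
}

#' IntensityTrace: a time-stamped compartment signal
#'
#' One-dimensional fluorescence signal extracted from a compartment
#' (parenchyma or blood).  Units are `"raw_au"` (detector units),
#' `"relative"` (\eqn{(F_t - F_0)/F_0}; first value is 0 by construction) or
#' `"fraction_of_baseline"` (\eqn{F_t/F_0}; first value 1).
#'
#' @slot timesMin strictly increasing time vector, minutes.
#' @slot values numeric vector, same length as `timesMin`.
#' @slot units one of `"raw_au"`, `"relative"`, `"fraction_of_baseline"`.
#' @slot compartment `"parenchyma"` or `"blood"`.
#' @export
setClass("IntensityTrace",
  representation(timesMin = "numeric", values = "numeric",
                 units = "character", compartment = "character"))

setValidity("IntensityTrace", function(object) {
  t <- object@timesMin; v <- object@values
  if (length(t) != length(v)) return("times and values lengths differ")
  if (length(t) == 0L) return("trace must be non-empty")
  if (any(!is.finite(t)) || any(diff(t) <= 0))
    return("timesMin must be finite and strictly increasing")
  if (any(!is.finite(v))) return("values must be finite")
  if (!object@units %in% TRACE_UNITS)
    return(paste("units must be one of:", paste(TRACE_UNITS, collapse = ", ")))
  if (!object@compartment %in% COMPARTMENTS)
    return("compartment must be 'parenchyma' or 'blood'")
  if (object@units == "relative" && abs(v[1]) > 1e-9)
    return("relative traces must be 0 at the baseline timepoint")
  TRUE
})

#' Construct an IntensityTrace
#' @param timesMin strictly increasing times in minutes.
#' @param values signal values, same length.
#' @param units `"raw_au"`, `"relative"` or `"fraction_of_baseline"`.
#' @param compartment `"parenchyma"` or `"blood"`.
#' @export
IntensityTrace <- function(timesMin, values, units = "raw_au",
                           compartment = "parenchyma") {
  new("IntensityTrace", timesMin = as.numeric(timesMin),
      values = as.numeric(values), units = units, compartment = compartment)
}

#' RoiSet: square regions of interest on the projected grid
#'
#' @slot rois data.frame with columns `row`, `col` (1-based top-left corner),
#'   `height`, `width` in pixels.
#' @slot compartment `"parenchyma"` or `"blood"`.
#' @slot gridDim integer vector (nrow, ncol) of the projected frame.
#' @export
setClass("RoiSet",
  representation(rois = "data.frame", compartment = "character",
                 gridDim = "integer"))

setValidity("RoiSet", function(object) {
  r <- object@rois
  need <- c("row", "col", "height", "width")
  if (!all(need %in% names(r))) return("rois needs row/col/height/width")
  if (nrow(r) == 0L) return("RoiSet must contain at least one ROI")
  if (any(r$height < 1 | r$width < 1)) return("every ROI must be non-empty")
  if (length(object@gridDim) != 2L) return("gridDim must be length 2")
  if (any(r$row < 1 | r$col < 1 | r$row + r$height - 1 > object@gridDim[1] |
          r$col + r$width - 1 > object@gridDim[2]))
    return("ROIs must lie inside the grid")
  if (!object@compartment %in% COMPARTMENTS)
    return("compartment must be 'parenchyma' or 'blood'")
  TRUE
})

#' ExponentialFit: a fitted exponential trend on a trace window
#'
#' Saturating growth evaluates as \eqn{a + b(1 - e^{-c(t - t_s)})}, decay as
#' \eqn{a + b e^{-c(t - t_s)}}, where \eqn{t_s} is the start of the fit
#' window.  A degenerate rate estimate falls back to a linear fit, reported
#' with `c = 0` and `b` equal to the fitted slope times the window length
#' (the \eqn{c \to 0} limit); such fits carry `fallback = TRUE` and a growth
#' model then evaluates as \eqn{a + b (t - t_s)/L} with \eqn{L} the window
#' length.
#'
#' @slot model `"saturating_growth"` or `"decay"`.
#' @slot a,b,c offset, amplitude and rate (per minute, `c >= 0`).
#' @slot rmse root-mean-square residual of the fit on its window.
#' @slot window numeric length-2, the time window the fit was computed on.
#' @slot fallback logical; `TRUE` if the linear fallback was used.
#' @export
setClass("ExponentialFit",
  representation(model = "character", a = "numeric", b = "numeric",
                 c = "numeric", rmse = "numeric", window = "numeric",
                 fallback = "logical"))

setValidity("ExponentialFit", function(object) {
  if (!object@model %in% c("saturating_growth", "decay"))
    return("model must be 'saturating_growth' or 'decay'")
  for (s in c("a", "b", "c", "rmse"))
    if (length(slot(object, s)) != 1L || !is.finite(slot(object, s)))
      return(paste0(s, " must be a finite scalar"))
  if (object@c < 0) return("rate c must be >= 0")
  if (object@rmse < 0) return("rmse must be >= 0")
  if (length(object@window) != 2L || diff(object@window) <= 0)
    return("window must be an increasing length-2 vector")
  TRUE
})

#' VesselTree: simulated vessel geometry with a voxel label volume
#'
#' @slot segments data.frame with columns `id`, `category`, `diameter_um`,
#'   `length_um`, `orientation` (`"in_plane"`/`"through_plane"`), `arterial`
#'   (logical; `NA` for capillaries).
#' @slot labels 3D integer array (Z, Y, X); voxel value = segment id, 0 =
#'   background.  Masks of distinct segments are disjoint by construction.
#' @slot pixelSizeUm,zStepUm voxel geometry in micrometres.
#' @export
setClass("VesselTree",
  representation(segments = "data.frame", labels = "array",
                 pixelSizeUm = "numeric", zStepUm = "numeric"))

setValidity("VesselTree", function(object) {
  s <- object@segments
  need <- c("id", "category", "diameter_um", "length_um", "orientation",
            "arterial")
  if (!all(need %in% names(s))) return("segments missing required columns")
  if (length(dim(object@labels)) != 3L) return("labels must be 3D (Z,Y,X)")
  if (nrow(s) > 0) {
    if (any(!s$category %in% c(VESSEL_CATEGORIES, "unclassified")))
      return("unknown vessel category")
    if (any(s$diameter_um <= 0) || any(s$length_um <= 0))
      return("diameters and lengths must be > 0")
    lab <- unique(as.vector(object@labels))
    if (!all(setdiff(lab, 0L) %in% s$id))
      return("label volume contains ids absent from segments")
  } else if (any(object@labels != 0L)) {
    return("empty tree must have an all-zero label volume")
  }
  TRUE
})

#' PermeabilityResult: per-tracer paracellular leak score
#'
#' @slot tracer tracer name.
#' @slot correctedTrace corrected relative parenchymal trace over the
#'   tracer's imaging window.
#' @slot aucMin area under the corrected relative trace, dimensionless
#'   fluorescence integrated over minutes (reported in "min").
#' @slot correctionFits list of [ExponentialFit-class] subtracted from this
#'   tracer (empty for the first tracer of a session).
#' @slot bloodFit exponential decay fit to the tracer's blood window (or
#'   `NULL`).
#' @export
setClass("PermeabilityResult",
  representation(tracer = "character", correctedTrace = "IntensityTrace",
                 aucMin = "numeric", correctionFits = "list",
                 bloodFit = "ANY"))

#' GroupComparisonResult: outcome of a study-style group test
#'
#' @slot testName `"welch_t"`, `"mann_whitney"` or `"anova_log_tukey"`.
#' @slot statistic test statistic.
#' @slot pValue p-value in `[0, 1]`.
#' @slot groupSummaries data.frame with `group`, `n`, `mean`, `sem`.
#' @slot normalityP per-group normality p-values (`NA` where not computed).
#' @slot tukey data.frame of Tukey-adjusted pairwise contrasts, or `NULL`.
#' @export
setClass("GroupComparisonResult",
  representation(testName = "character", statistic = "numeric",
                 pValue = "numeric", groupSummaries = "data.frame",
                 normalityP = "numeric", tukey = "ANY"))

setValidity("GroupComparisonResult", function(object) {
  if (!object@testName %in% c("welch_t", "mann_whitney", "anova_log_tukey"))
    return("unknown testName")
  if (object@pValue < 0 || object@pValue > 1) return("pValue outside [0,1]")
  if (any(object@groupSummaries$n < 2)) return("need n >= 2 per group")
  TRUE
})
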
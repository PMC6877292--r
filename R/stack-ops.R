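#' Maximum intensity projection along depth
#'
#' Collapses each Z-stack to a single frame: `out[t, y, x] = max_z
#' stack[t, z, y, x]`.  Projection of a single-plane stack is the identity.
#'
#' @param stack a [Hyperstack-class].
#' @return 3D array (T, Y, X).
#' @export
maxProject <- function(stack) {
  v <- voxels(stack)
  d <- dim(v)
  out <- v[, 1, , , drop = TRUE]
  if (d[1] == 1L) out <- array(out, dim = d[c(1, 3, 4)])
  if (d[2] > 1L) for (z in 2:d[2]) out <- pmax(out, array(v[, z, , ], dim = d[c(1, 3, 4)]))
  out
}

## EBImage dilation on a plain logical matrix
ebDilate <- function(mask, size) {
  EBImage::imageData(EBImage::dilate(mask * 1, EBImage::makeBrush(size, "disc"))) > 0
}

#' Segment the vasculature on a baseline projected frame
#'
#' Global Otsu threshold (computed on 256 bins between the frame minimum and
#' maximum, hence exactly invariant to adding a constant offset), followed
#' by morphological closing and removal of small components.  The input
#' should be the first projected timepoint at which intravascular tracer is
#' present.
#'
#' @param frame 2D numeric matrix.
#' @param closingSizePx diameter of the closing structuring element.
#' @param minComponentPx components smaller than this are discarded.
#' @return logical matrix (TRUE = vessel).
#' @export
segmentVasculature <- function(frame, closingSizePx = 3L, minComponentPx = 20L) {
  th <- otsuThreshold(frame)   # errors on a constant frame
  mask <- frame > th
  if (!any(mask) || all(mask))
    stop("segmentation failure: thresholding yields no foreground/background split")
  mask <- EBImage::imageData(EBImage::closing(
    mask * 1, EBImage::makeBrush(closingSizePx, "disc"))) > 0
  lab <- EBImage::bwlabel(mask * 1)
  sizes <- tabulate(as.integer(lab))
  keep <- which(sizes >= minComponentPx)
  mask <- matrix(as.integer(lab) %in% keep, nrow(frame), ncol(frame))
  if (!any(mask))
    stop("segmentation failure: no vessel component of at least ",
         minComponentPx, " px")
  mask
}

## top-left positions (ny' x nx' logical) whose sizePx x sizePx window
## contains no TRUE pixel of `bad` -- via a summed-area table
validTopLefts <- function(bad, sizePx) {
  ny <- nrow(bad); nx <- ncol(bad)
  if (ny < sizePx || nx < sizePx)
    return(matrix(FALSE, 0, 0))
  cs <- apply(bad * 1, 2, cumsum)            # cumulate down rows
  cs <- t(apply(cs, 1, cumsum))              # then across columns
  S <- rbind(0, cbind(0, cs))                # (ny+1) x (nx+1) integral image
  r0 <- 1:(ny - sizePx + 1L); c0 <- 1:(nx - sizePx + 1L)
  win <- S[r0 + sizePx, c0 + sizePx, drop = FALSE] -
    S[r0, c0 + sizePx, drop = FALSE] -
    S[r0 + sizePx, c0, drop = FALSE] + S[r0, c0, drop = FALSE]
  win == 0
}

## greedy seeded placement of n non-overlapping sizePx ROIs on valid
## top-left positions; returns data.frame or the achieved subset
placeSquares <- function(valid, sizePx, n, seed) {
  pos <- which(valid, arr.ind = TRUE)
  if (nrow(pos) == 0L) return(pos <- data.frame(row = integer(), col = integer()))
  ord <- withSeed(seed, sample.int(nrow(pos)))
  chosen <- matrix(0L, 0, 2)
  for (i in ord) {
    p <- pos[i, ]
    if (nrow(chosen) > 0 &&
        any(abs(chosen[, 1] - p[1]) < sizePx & abs(chosen[, 2] - p[2]) < sizePx))
      next
    chosen <- rbind(chosen, p)
    if (nrow(chosen) == n) break
  }
  data.frame(row = chosen[, 1], col = chosen[, 2])
}

#' Place parenchymal ROIs clear of the vasculature
#'
#' Uniform-random rejection placement of `nRois` square ROIs that do not
#' intersect the vessel mask dilated by `dilationMarginPx` (keeping the
#' perivascular halo out of parenchymal measurements) and do not overlap
#' each other.  Deterministic under `seed`; fails informatively when fewer
#' than `nRois` placements exist.
#'
#' @param mask logical vessel mask from [segmentVasculature()].
#' @param roiSizePx ROI side length, pixels.
#' @param nRois number of ROIs (pooled downstream into one trace).
#' @param seed RNG seed.
#' @param dilationMarginPx exclusion margin around the mask, pixels.
#' @return a [RoiSet-class] (compartment `"parenchyma"`).
#' @export
placeParenchymalRois <- function(mask, roiSizePx = 8L, nRois = 10L, seed = 1L,
                                 dilationMarginPx = 3L) {
  bad <- if (any(mask)) ebDilate(mask, 2L * dilationMarginPx + 1L) else mask
  valid <- validTopLefts(bad, roiSizePx)
  df <- placeSquares(valid, roiSizePx, nRois, seed)
  if (nrow(df) < nRois)
    stop("placement failure: only ", nrow(df), " of ", nRois,
         " parenchymal ROIs fit outside the dilated vessel mask")
  df$height <- df$width <- as.integer(roiSizePx)
  new("RoiSet", rois = df, compartment = "parenchyma",
      gridDim = dim(mask))
}

#' Place blood ROIs inside vessel lumina
#'
#' Like [placeParenchymalRois()] but each ROI must lie entirely inside the
#' vessel mask.
#'
#' @inheritParams placeParenchymalRois
#' @return a [RoiSet-class] (compartment `"blood"`).
#' @export
placeBloodRois <- function(mask, roiSizePx = 2L, nRois = 3L, seed = 1L) {
  valid <- validTopLefts(!mask, roiSizePx)
  df <- placeSquares(valid, roiSizePx, nRois, seed)
  if (nrow(df) < nRois)
    stop("placement failure: only ", nrow(df), " of ", nRois,
         " blood ROIs fit inside the vessel mask")
  df$height <- df$width <- as.integer(roiSizePx)
  new("RoiSet", rois = df, compartment = "blood", gridDim = dim(mask))
}

#' Extract a pooled intensity trace from projected frames
#'
#' The value at each timepoint is the mean intensity over the union of all
#' ROI pixels (so the pooled mean of two disjoint ROIs is their
#' pixel-weighted mean).
#'
#' @param frames 3D array (T, Y, X) from [maxProject()].
#' @param roiset a [RoiSet-class] on the same grid.
#' @param timesMin per-frame times in minutes (see [frameTimes()]).
#' @return an [IntensityTrace-class] in raw units.
#' @export
extractTrace <- function(frames, roiset, timesMin) {
  stopifnot(length(dim(frames)) == 3L,
            all(dim(frames)[2:3] == roiset@gridDim),
            length(timesMin) == dim(frames)[1])
  px <- roiPixels(roiset)
  if (length(px) == 0L) stop("empty ROI union")
  nyx <- prod(roiset@gridDim)
  vals <- vapply(seq_len(dim(frames)[1]), function(t) {
    f <- frames[t, , ]
    mean(f[px])
  }, numeric(1))
  IntensityTrace(timesMin, vals, units = "raw_au",
                 compartment = roiset@compartment)
}

#' Relative change over the baseline timepoint
#'
#' Converts a raw trace to \eqn{(F_t - F_0)/F_0}, where \eqn{F_0} is the
#' value at the first timepoint.  The first value of the result is exactly
#' 0.  Errors if the baseline is not positive (a symptom of background
#' over-subtraction upstream).
#'
#' @param trace an [IntensityTrace-class] in raw units.
#' @return an [IntensityTrace-class] with units `"relative"`.
#' @export
relativeChange <- function(trace) {
  f0 <- trace@values[1]
  if (f0 <= 0)
    stop("baseline value must be > 0 (background subtraction overshoot?)")
  v <- (trace@values - f0) / f0
  v[1] <- 0
  IntensityTrace(trace@timesMin, v, units = "relative",
                 compartment = trace@compartment)
}
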
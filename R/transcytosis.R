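#' Classify a vessel segment into the microvascular taxonomy
#'
#' Deterministic decision table on diameter, orientation and the
#' arterial/venous flag: capillary (d < 6 um, any orientation);
#' post-capillary venule (6 <= d < 10, venous); penetrating arteriole
#' (10 <= d < 25, through-plane, arterial); ascending venule (10 <= d < 25,
#' through-plane, venous); pial arteriole (25 <= d < 60, in-plane,
#' arterial); pial venule (25 <= d < 100, in-plane, venous).  Feature
#' combinations outside the table return `"unclassified"`, never dropped.
#' The arterial flag must be supplied (from synthetic ground truth or user
#' annotation); morphology alone cannot decide it.
#'
#' @param diameterUm vessel diameter(s), micrometres.
#' @param orientation `"in_plane"` or `"through_plane"` (recycled).
#' @param arterial logical (recycled); `NA` allowed for capillaries.
#' @return character vector of categories.
#' @export
classifyVessel <- function(diameterUm, orientation = "in_plane",
                           arterial = NA) {
  n <- length(diameterUm)
  orientation <- rep_len(orientation, n)
  arterial <- rep_len(arterial, n)
  vapply(seq_len(n), function(i) {
    d <- diameterUm[i]; o <- orientation[i]; a <- arterial[i]
    if (!is.finite(d) || d <= 0) return("unclassified")
    if (d < 6) return("capillary")
    if (d < 10) return(if (isFALSE(a)) "post_capillary_venule" else "unclassified")
    if (d < 25) {
      if (o != "through_plane" || is.na(a)) return("unclassified")
      return(if (a) "penetrating_arteriole" else "ascending_venule")
    }
    if (o != "in_plane" || is.na(a)) return("unclassified")
    if (a && d < 60) return("pial_arteriole")
    if (!a && d < 100) return("pial_venule")
    "unclassified"
  }, character(1))
}

#' Vessel surface area
#'
#' The lateral surface of a cylinder, `pi * d * L`, the normalization
#' surface for vesicle densities.
#'
#' @param diameterUm,lengthUm diameter and length in micrometres, > 0.
#' @return surface area in square micrometres.
#' @export
vesselSurfaceArea <- function(diameterUm, lengthUm) {
  if (any(diameterUm <= 0) || any(lengthUm <= 0))
    stop("diameter and length must be > 0")
  pi * diameterUm * lengthUm
}

#' Detection parameters for wall puncta
#'
#' @param bandMarginPx half-width of the wall band around the vessel mask
#'   boundary (pixels); luminal interior and distant parenchyma are
#'   excluded from counting.
#' @param madMultiplier `m` in the robust intensity threshold
#'   `median + m * MAD` over wall-band pixels.
#' @param radiusRangeUm accepted punctum radius band, micrometres.
#' @param smoothSigmaPx Gaussian pre-smoothing of the change image.
#' @param minProminence absolute floor (detector counts) on the detection
#'   threshold and the watershed split tolerance; changes below one
#'   quantization step are never treated as signal.
#' @param maxAssignDistPx max distance for assigning a detection to a
#'   vessel.
#' @param linkRadiusUm nearest-neighbour linking radius for punctum
#'   identity across timepoints; unlinked reappearances count as new
#'   puncta.
#' @param minPersistFrames frames a linked punctum must be seen in before
#'   it is counted (suppresses one-off noise blips; persistent puncta are
#'   unaffected).
#' @export
vesicleDetectionParams <- function(bandMarginPx = 2L, madMultiplier = 3,
                                   radiusRangeUm = c(0.25, 1.5),
                                   smoothSigmaPx = 0.5,
                                   minProminence = 1,
                                   maxAssignDistPx = 4L,
                                   linkRadiusUm = 1, minPersistFrames = 2L) {
  list(bandMarginPx = bandMarginPx, madMultiplier = madMultiplier,
       radiusRangeUm = radiusRangeUm, smoothSigmaPx = smoothSigmaPx,
       minProminence = minProminence,
       maxAssignDistPx = maxAssignDistPx, linkRadiusUm = linkRadiusUm,
       minPersistFrames = minPersistFrames)
}

## small Gaussian smoothing kernel for filter2
gaussKernel <- function(sigma) {
  ext <- max(1L, ceiling(3 * sigma))
  g <- outer(-ext:ext, -ext:ext,
             function(y, x) exp(-(y^2 + x^2) / (2 * sigma^2)))
  g / sum(g)
}

#' Detect vesicle puncta on vessel walls
#'
#' Blob detection restricted to the wall band (mask boundary dilated by
#' `bandMarginPx` on both sides).  Each frame is compared against the
#' session's first (pre-accumulation) frame; the change image is Gaussian
#' smoothed, thresholded at `median + m * MAD` of its wall-band pixels
#' (robust to global gain changes), and connected components inside the
#' band whose equivalent radius falls in `radiusRangeUm` become detections.
#'
#' @param frames 3D array (T, Y, X) of projected frames.
#' @param mask logical vessel mask on the same grid.
#' @param timesMin per-frame times, minutes.
#' @param pixelSizeUm pixel size, micrometres.
#' @param params from [vesicleDetectionParams()].
#' @return data.frame with `time_min`, `row`, `col` (centroid, may be
#'   fractional), `peak_intensity`, `radius_um`, `vessel_id` (`NA` until
#'   assigned).
#' @export
detectVesicles <- function(frames, mask, timesMin, pixelSizeUm,
                           params = vesicleDetectionParams()) {
  stopifnot(length(dim(frames)) == 3L, dim(frames)[1] == length(timesMin))
  bsz <- 2L * params$bandMarginPx + 1L
  ## the wall band: the projected vessel silhouette (onto which the whole
  ## cylindrical wall projects) plus a margin beyond the boundary; distant
  ## parenchyma (e.g. macrophage uptake) stays excluded from counting
  band <- ebDilate(mask, bsz)
  if (!any(band)) stop("empty wall band")
  kern <- gaussKernel(params$smoothSigmaPx)
  base <- frames[1, , ]
  out <- list()
  for (t in 2:dim(frames)[1]) {
    diffImg <- frames[t, , ] - base
    ## remove the global blood-pool drift (tracer clearance) so the
    ## no-change level inside vessels sits at 0 like the parenchyma
    diffImg[mask] <- diffImg[mask] - median(diffImg[mask])
    sm <- EBImage::imageData(EBImage::filter2(diffImg, kern))
    ## threshold statistics come from the vascular portion of the band,
    ## whose shot noise dominates (the parenchymal margin is much quieter
    ## and would drag the robust scale estimate down)
    bandVals <- sm[band & mask]
    if (length(bandVals) == 0) bandVals <- sm[band]
    med <- median(bandVals)
    ## robust threshold with a one-detector-count prominence floor
    ## (sub-quantization changes are not signal)
    prom <- max(params$madMultiplier * mad(bandVals), params$minProminence)
    thr <- med + prom
    cand <- band & (sm > thr)
    if (!any(cand)) next
    ## watershed separates puncta that merge at threshold level; the
    ## tolerance (valley depth needed to split) scales with the robust
    ## noise estimate, so splitting is gain-invariant too
    relief <- (sm - med) * cand
    lab <- EBImage::imageData(EBImage::watershed(relief, tolerance = prom))
    labv <- as.integer(lab)
    comp <- which(labv > 0)
    if (length(comp) == 0) next
    ids <- labv[comp]
    rows <- (comp - 1L) %% nrow(mask) + 1L
    cols <- (comp - 1L) %/% nrow(mask) + 1L
    vals <- relief[comp]
    ## smoothed current frame, for the local-prominence veto below
    smCur <- EBImage::imageData(EBImage::filter2(frames[t, , ], kern))
    ny <- nrow(mask); nx <- ncol(mask)
    det <- do.call(rbind, lapply(unique(ids), function(id) {
      sel <- ids == id
      pk <- max(vals[sel])
      ## half-max footprint: threshold-independent size; intensity-weighted
      ## centroid for sub-pixel, noise-stable localization
      half <- sel & vals >= pk / 2
      w <- vals[half]
      ## a real punctum is a local blob in the current frame as well, not
      ## merely a deficit in the baseline frame
      ipk <- comp[sel][which.max(vals[sel])]
      r0 <- (ipk - 1L) %% ny + 1L; c0 <- (ipk - 1L) %/% ny + 1L
      rw <- max(1, r0 - 4):min(ny, r0 + 4)
      cw <- max(1, c0 - 4):min(nx, c0 + 4)
      win <- smCur[rw, cw]
      ## reference level from vessel pixels of the window where possible:
      ## on a thin vessel the raw window median would sit at parenchyma
      ## level and a baseline-frame deficit would masquerade as a blob
      inMask <- mask[rw, cw]
      ref <- if (sum(inMask) >= 5) median(win[inMask]) else median(win)
      prominent <- smCur[r0, c0] - ref >= 3 * prom
      data.frame(row = sum(rows[half] * w) / sum(w),
                 col = sum(cols[half] * w) / sum(w),
                 peak_intensity = pk,
                 radius_um = pixelSizeUm * sqrt(sum(half) / pi),
                 prominent = prominent)
    }))
    det <- det[det$prominent, , drop = FALSE]
    det$prominent <- NULL
    if (nrow(det) == 0) next
    keep <- det$radius_um >= params$radiusRangeUm[1] &
      det$radius_um <= params$radiusRangeUm[2]
    if (!any(keep)) next
    det <- det[keep, , drop = FALSE]
    det$time_min <- timesMin[t]
    det$vessel_id <- NA_integer_
    out[[length(out) + 1L]] <- det[, c("time_min", "row", "col",
                                       "peak_intensity", "radius_um",
                                       "vessel_id")]
  }
  if (length(out)) do.call(rbind, out)
  else data.frame(time_min = numeric(), row = numeric(), col = numeric(),
                  peak_intensity = numeric(), radius_um = numeric(),
                  vessel_id = integer())
}

#' Assign detections to vessel segments
#'
#' Each detection takes the id of the nearest labelled pixel of the
#' projected vessel label map within `maxAssignDistPx`; detections farther
#' from any vessel stay unassigned (`NA`).
#'
#' @param detections from [detectVesicles()].
#' @param tree a [VesselTree-class].
#' @param maxAssignDistPx search radius in pixels.
#' @return the detections data.frame with `vessel_id` filled in.
#' @export
assignDetections <- function(detections, tree, maxAssignDistPx = 4L) {
  if (nrow(detections) == 0) return(detections)
  labels <- labelVolume(tree)
  proj <- apply(labels, c(2, 3), max)
  ny <- nrow(proj); nx <- ncol(proj)
  m <- maxAssignDistPx
  for (i in seq_len(nrow(detections))) {
    r0 <- round(detections$row[i]); c0 <- round(detections$col[i])
    rs <- max(1, r0 - m):min(ny, r0 + m)
    cs <- max(1, c0 - m):min(nx, c0 + m)
    sub <- proj[rs, cs, drop = FALSE]
    hit <- which(sub > 0, arr.ind = TRUE)
    if (nrow(hit) == 0) next
    d2 <- (rs[hit[, 1]] - detections$row[i])^2 +
      (cs[hit[, 2]] - detections$col[i])^2
    detections$vessel_id[i] <- sub[hit[which.min(d2), , drop = FALSE]]
  }
  detections
}

#' Link detections into distinct puncta across timepoints
#'
#' Within each vessel, a detection is linked to an existing punctum track
#' when it falls within `linkRadiusUm` of the track position
#' (nearest-neighbour); otherwise it starts a new track (unlinked
#' reappearances count as new puncta).  Tracks seen in fewer than
#' `minPersistFrames` frames are discarded as noise.
#'
#' @param detections assigned detections (see [assignDetections()]).
#' @param pixelSizeUm pixel size, micrometres.
#' @param params from [vesicleDetectionParams()].
#' @return data.frame of tracks: `vessel_id`, `first_time_min`, `row`,
#'   `col`, `n_seen`.
#' @export
linkDetections <- function(detections, pixelSizeUm,
                           params = vesicleDetectionParams()) {
  det <- detections[!is.na(detections$vessel_id), , drop = FALSE]
  tracks <- data.frame(vessel_id = integer(), first_time_min = numeric(),
                       row = numeric(), col = numeric(), n_seen = integer())
  if (nrow(det) == 0) return(tracks)
  rad <- params$linkRadiusUm / pixelSizeUm
  det <- det[order(det$time_min), , drop = FALSE]
  for (i in seq_len(nrow(det))) {
    cand <- which(tracks$vessel_id == det$vessel_id[i])
    linked <- FALSE
    if (length(cand)) {
      d2 <- (tracks$row[cand] - det$row[i])^2 +
        (tracks$col[cand] - det$col[i])^2
      j <- cand[which.min(d2)]
      if (min(d2) <= rad^2) {
        tracks$n_seen[j] <- tracks$n_seen[j] + 1L
        linked <- TRUE
      }
    }
    if (!linked)
      tracks <- rbind(tracks, data.frame(
        vessel_id = det$vessel_id[i], first_time_min = det$time_min[i],
        row = det$row[i], col = det$col[i], n_seen = 1L))
  }
  tracks[tracks$n_seen >= params$minPersistFrames, , drop = FALSE]
}

#' Vesicle surface-density kinetics per vessel
#'
#' For every vessel and timepoint, the cumulative count of distinct puncta
#' first seen at or before that time, normalized by the vessel's surface
#' area (`pi * d * L`) and expressed per 100 square micrometres.  With
#' cumulative counting the per-vessel density is non-decreasing in time.
#'
#' @param tracks from [linkDetections()] (or a ground-truth event list with
#'   columns `vessel_id` and `first_time_min`/`time_min`).
#' @param segs segments data.frame (see [segments()]).
#' @param timepoints times (minutes) at which to evaluate the density.
#' @return data.frame with `vessel_id`, `category`, `time_min`, `count`,
#'   `surface_area_um2`, `density_per_100um2`.
#' @export
densityKinetics <- function(tracks, segs, timepoints) {
  tcol <- if ("first_time_min" %in% names(tracks)) "first_time_min" else "time_min"
  res <- expand.grid(vessel_id = segs$id, time_min = timepoints)
  res <- merge(res, segs[, c("id", "category", "diameter_um", "length_um")],
               by.x = "vessel_id", by.y = "id")
  res$surface_area_um2 <- vesselSurfaceArea(res$diameter_um, res$length_um)
  res$count <- vapply(seq_len(nrow(res)), function(i)
    sum(tracks$vessel_id == res$vessel_id[i] &
          tracks[[tcol]] <= res$time_min[i]), integer(1))
  res$density_per_100um2 <- 100 * res$count / res$surface_area_um2
  res <- res[order(res$vessel_id, res$time_min),
             c("vessel_id", "category", "time_min", "count",
               "surface_area_um2", "density_per_100um2")]
  rownames(res) <- NULL
  res
}

#' Aggregate density kinetics by vessel category
#'
#' @param records from [densityKinetics()].
#' @return data.frame with per category and timepoint the mean density,
#'   SEM and number of vessels.
#' @export
aggregateDensity <- function(records) {
  agg <- aggregate(density_per_100um2 ~ category + time_min, records,
                   function(x) c(mean = mean(x), sem = sem(x), n = length(x)))
  out <- data.frame(category = agg$category, time_min = agg$time_min,
                    mean_density = agg$density_per_100um2[, "mean"],
                    sem = agg$density_per_100um2[, "sem"],
                    n = agg$density_per_100um2[, "n"])
  out[order(out$category, out$time_min), ]
}

#' Recover per-category vesicle event rates from density kinetics
#'
#' Least-squares slope (through the origin, since density starts at 0) of
#' density versus time, pooled over the vessels of each category.  Under
#' the Poisson event model the expected density is `rate * t` regardless of
#' vessel size, so the slope estimates the configured per-100-um2 event
#' rate.
#'
#' @param records from [densityKinetics()].
#' @return data.frame with `category` and `slope_per_100um2_per_min`.
#' @export
rateRecovery <- function(records) {
  if (length(unique(records$time_min)) < 2)
    stop("need at least 2 timepoints to estimate a rate")
  cats <- unique(records$category)
  slope <- vapply(cats, function(cat) {
    r <- records[records$category == cat, ]
    sum(r$density_per_100um2 * r$time_min) / sum(r$time_min^2)
  }, numeric(1))
  data.frame(category = cats, slope_per_100um2_per_min = slope,
             row.names = NULL)
}
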
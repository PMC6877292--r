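#' Tree configuration for vesicle (albumin-conjugate) sessions
#'
#' Conjugate sessions are acquired at higher magnification than the
#' paracellular sessions, so the default grid uses a sub-micrometre pixel
#' and a smaller field of view; pial diameter ranges are narrowed so the
#' large surface vessels still fit the field.
#'
#' @inheritParams vesselTreeConfig
#' @export
vesicleTreeConfig <- function(shape = c(8, 256, 256), pixelSizeUm = 0.755,
                              zStepUm = 6,
                              counts = c(pial_arteriole = 1,
                                         penetrating_arteriole = 3,
                                         capillary = 4,
                                         post_capillary_venule = 2,
                                         ascending_venule = 3,
                                         pial_venule = 1),
                              lengthRangeUm = c(40, 100)) {
  rng <- defaultDiameterRanges()
  rng$pial_arteriole <- c(25, 40)
  rng$pial_venule <- c(25, 40)
  ## generous inter-vessel clearance (~3 um) so wall puncta are always
  ## attributable to a unique segment, as in hand-selected imaging fields
  vesselTreeConfig(shape = shape, pixelSizeUm = pixelSizeUm,
                   zStepUm = zStepUm, counts = counts,
                   diameterRanges = rng, lengthRangeUm = lengthRangeUm,
                   marginPx = 4L, maxTries = 500L)
}

## z-planes in which the segment exists
segmentZ <- function(labels, id) which(apply(labels == id, 1, any))

#' Simulate an albumin-conjugate transcytosis session
#'
#' Renders a time-lapse hyperstack of vessels carrying a slowly clearing
#' blood-pool conjugate, on whose walls bright vesicle puncta accumulate as
#' a Poisson process: for each segment the cumulative event count at time
#' `t` is Poisson with mean `rate * (surface_area/100) * t`, where the
#' per-category rates come from `truth$vesicleRatePer100um2PerMin` and the
#' surface area is `pi * d * L`.  Events persist once created (vesicle
#' density does not saturate over the session) and are rendered as compact
#' Gaussian puncta on the projected vessel wall.  The ground-truth event
#' list is returned alongside.
#'
#' @param tree a [VesselTree-class] (see [vesicleTreeConfig()]).
#' @param truth from [groundTruth()].
#' @param durationMin session length, minutes.
#' @param frameIntervalMin frame spacing, minutes.
#' @param conjugateAmplitude blood-pool intensity of the conjugate (au).
#' @param conjugateClearancePerMin its (slow) blood clearance rate.
#' @param punctumAmplitude peak punctum intensity above background (au).
#' @param punctumSigmaUm Gaussian radius of a rendered punctum.
#' @param noise logical; apply the Poisson + Gaussian noise model.
#' @param seed RNG seed.
#' @return list with `stack` ([Hyperstack-class]) and `events` (data.frame
#'   `vessel_id`, `time_min`, `row`, `col`).
#' @export
simulateVesicleSession <- function(tree, truth = groundTruth(),
                                   durationMin = 120, frameIntervalMin = 7.5,
                                   conjugateAmplitude = 300,
                                   conjugateClearancePerMin = 0.002,
                                   punctumAmplitude = 2000,
                                   punctumSigmaUm = 0.3,
                                   noise = TRUE, seed = 1L) {
  assertScalar(durationMin, "durationMin", positive = TRUE)
  seg <- segments(tree)
  labels <- labelVolume(tree)
  d3 <- dim(labels)
  times <- seq(0, durationMin, by = frameIntervalMin)
  rates <- truth$vesicleRatePer100um2PerMin
  events <- withSeed(seed, {
    ev <- list()
    for (i in seq_len(nrow(seg))) {
      rate <- rates[[seg$category[i]]]
      if (is.null(rate)) stop("no vesicle rate configured for category '",
                              seg$category[i], "'")
      area <- vesselSurfaceArea(seg$diameter_um[i], seg$length_um[i])
      n <- rpois(1, rate * area / 100 * durationMin)
      if (n == 0) next
      ## the cylindrical wall projects onto the full vessel silhouette, so
      ## puncta are placed uniformly over the projected footprint
      fp <- apply(labels == seg$id[i], c(2, 3), any)
      pix <- which(fp, arr.ind = TRUE)
      if (nrow(pix) == 0) next
      pick <- sample.int(nrow(pix), n, replace = TRUE)
      zs <- segmentZ(labels, seg$id[i])
      ev[[length(ev) + 1L]] <- data.frame(
        vessel_id = seg$id[i],
        time_min = sort(runif(n, 0, durationMin)),
        row = pix[pick, 1], col = pix[pick, 2],
        z = sample(zs, n, replace = TRUE))
    }
    if (length(ev)) do.call(rbind, ev)
    else data.frame(vessel_id = integer(), time_min = numeric(),
                    row = integer(), col = integer(), z = integer())
  })
  ## static punctum kernel
  sigPx <- punctumSigmaUm / tree@pixelSizeUm
  ext <- max(1L, ceiling(2.5 * sigPx))
  off <- expand.grid(dy = -ext:ext, dx = -ext:ext)
  kern <- punctumAmplitude * exp(-(off$dy^2 + off$dx^2) / (2 * sigPx^2))
  offFrame <- truth$autofluorescenceOffset
  vessel <- labels > 0L
  vox <- array(0, dim = c(length(times), d3))
  for (t in seq_along(times)) {
    frame3 <- array(offFrame, dim = d3)
    frame3[vessel] <- offFrame +
      conjugateAmplitude * exp(-conjugateClearancePerMin * times[t])
    live <- events[events$time_min <= times[t], , drop = FALSE]
    if (nrow(live)) for (e in seq_len(nrow(live))) {
      ys <- live$row[e] + off$dy; xs <- live$col[e] + off$dx
      ok <- ys >= 1 & ys <= d3[2] & xs >= 1 & xs <= d3[3]
      idx <- cbind(live$z[e], ys[ok], xs[ok])
      frame3[idx] <- frame3[idx] + kern[ok]
    }
    vox[t, , , ] <- frame3
  }
  if (noise) vox <- withSeed(seed + 1L, applyNoise(vox, truth$noise))
  stack <- Hyperstack(pmin(vox, 65535), pixelSizeUm = tree@pixelSizeUm,
                      zStepUm = tree@zStepUm,
                      frameIntervalMin = frameIntervalMin, t0Min = 0)
  list(stack = stack, events = events[, c("vessel_id", "time_min", "row", "col")],
       eventsFull = events, truth = truth)
}
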
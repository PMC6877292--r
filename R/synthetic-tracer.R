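#' Tracer injection schedules
#'
#' A schedule is a data.frame with one row per tracer, columns `name`,
#' `mw_kda`, `injection_time_min`, `window_start_min`, `window_end_min` and
#' `leak_class` (`"paracellular"` or `"conjugate"`).  Each bolus is injected
#' 1 min before its first recorded frame; paracellular tracers are imaged
#' for 30 min, the albumin conjugate for 120 min (both configurable).
#' `tracerSchedule()` builds the default three-tracer session: consecutive
#' injections of FITC-dextran (10 kDa), Alexa Fluor 488 (0.643 kDa) and
#' sodium fluorescein (0.365 kDa), sharing one detection channel, separated
#' by 30-min time-lapse windows.
#'
#' @param names tracer names, in injection order.
#' @param mwKda molecular masses, kDa.
#' @param windowMin imaging window length per tracer, minutes.
#' @param injectionOffsetMin minutes between injection and first frame.
#' @param leakClass per-tracer leak class.
#' @return schedule data.frame.
#' @export
tracerSchedule <- function(names = c("FITC-dx", "AF488", "NaFluo"),
                           mwKda = c(10, 0.643, 0.365),
                           windowMin = 30, injectionOffsetMin = 1,
                           leakClass = "paracellular") {
  n <- length(names)
  windowMin <- rep_len(windowMin, n)
  leakClass <- rep_len(leakClass, n)
  ## windows tile the session contiguously; injection precedes each window
  inj <- c(0, cumsum(windowMin + injectionOffsetMin))[seq_len(n)]
  df <- data.frame(name = names, mw_kda = rep_len(mwKda, n),
                   injection_time_min = inj,
                   window_start_min = inj + injectionOffsetMin,
                   window_end_min = inj + injectionOffsetMin + windowMin,
                   leak_class = leakClass,
                   stringsAsFactors = FALSE)
  validateSchedule(df)
}

#' @rdname tracerSchedule
#' @param schedule a schedule data.frame to validate.
#' @export
validateSchedule <- function(schedule) {
  need <- c("name", "mw_kda", "injection_time_min", "window_start_min",
            "window_end_min", "leak_class")
  if (!all(need %in% names(schedule)))
    stop("schedule missing columns: ",
         paste(setdiff(need, names(schedule)), collapse = ", "))
  if (is.unsorted(schedule$injection_time_min, strictly = TRUE))
    stop("schedule must be ordered by injection time")
  if (any(schedule$window_start_min <= schedule$injection_time_min))
    stop("each injection must precede its window start")
  if (any(schedule$window_end_min <= schedule$window_start_min))
    stop("imaging windows must have positive length")
  ## windows must not overlap (shared decoupling channel)
  if (nrow(schedule) > 1) {
    for (i in seq_len(nrow(schedule) - 1))
      if (schedule$window_start_min[i + 1] < schedule$window_end_min[i])
        stop("imaging windows must not overlap")
  }
  schedule
}

#' Simulation ground truth
#'
#' Holds the two-compartment kinetic parameters, vesicle event rates and
#' noise model that the synthetic sessions are generated from (and against
#' which recovery is tested).  Per-tracer vectors are matched to the
#' schedule by name, or recycled.
#'
#' Default kinetic parameters are order-of-magnitude choices (the blood
#' half-lives of the individual dyes are not tabulated anywhere
#' authoritative): small free dyes clear faster than the 10 kDa dextran, and
#' leak rates are calibrated so a wild-type-like 30-min session yields AUC
#' scores of a few minutes for the small tracers and essentially zero for
#' the dextran.
#'
#' @param leakRatePerMin named per-tracer paracellular leak rate k (>= 0, /min).
#' @param bloodClearancePerMin named per-tracer mono-exponential blood
#'   clearance rate lambda (>= 0, /min).
#' @param bloodAmplitude named per-tracer initial blood amplitude C0 (> 0, au).
#' @param autofluorescenceOffset constant background added everywhere (au).
#' @param vesicleRatePer100um2PerMin named per-category Poisson vesicle
#'   event rate (events per 100 um^2 of wall per minute).
#' @param poissonGain,readSigma noise model: intensities are Poisson at
#'   `gain * expectation` rescaled by `1/gain`, then Gaussian read noise of
#'   sd `readSigma` is added (last).
#' @return classed list of ground-truth parameters.
#' @export
groundTruth <- function(leakRatePerMin = c("FITC-dx" = 1e-05,
                                           "AF488" = 6e-04,
                                           "NaFluo" = 3.4e-03),
                        bloodClearancePerMin = c("FITC-dx" = 0.02,
                                                 "AF488" = 0.04,
                                                 "NaFluo" = 0.05),
                        bloodAmplitude = c("FITC-dx" = 100, "AF488" = 100,
                                           "NaFluo" = 100),
                        autofluorescenceOffset = 20,
                        vesicleRatePer100um2PerMin = c(
                          pial_arteriole = 0.003, penetrating_arteriole = 0.003,
                          capillary = 0.004, post_capillary_venule = 0.0035,
                          ascending_venule = 0.003, pial_venule = 0.0025),
                        poissonGain = 1, readSigma = 2) {
  stopifnot(all(leakRatePerMin >= 0), all(bloodClearancePerMin >= 0),
            all(bloodAmplitude > 0), all(is.finite(leakRatePerMin)),
            all(is.finite(bloodClearancePerMin)))
  assertScalar(autofluorescenceOffset, "autofluorescenceOffset", nonneg = TRUE)
  assertScalar(poissonGain, "poissonGain", positive = TRUE)
  assertScalar(readSigma, "readSigma", nonneg = TRUE)
  stopifnot(all(vesicleRatePer100um2PerMin >= 0))
  structure(list(leakRatePerMin = leakRatePerMin,
                 bloodClearancePerMin = bloodClearancePerMin,
                 bloodAmplitude = bloodAmplitude,
                 autofluorescenceOffset = autofluorescenceOffset,
                 vesicleRatePer100um2PerMin = vesicleRatePer100um2PerMin,
                 noise = list(poissonGain = poissonGain,
                              readSigma = readSigma)),
            class = "bbbGroundTruth")
}

## look up a per-tracer parameter by tracer name, with recycling
truthParam <- function(truth, field, tracerNames) {
  v <- truth[[field]]
  if (!is.null(names(v)) && all(tracerNames %in% names(v))) return(v[tracerNames])
  rep_len(v, length(tracerNames))
}

#' Noiseless two-compartment tracer expectations
#'
#' For each tracer `i` injected at `t_inj`, the blood expectation at
#' `t > t_inj` is `C0 * exp(-lambda * (t - t_inj))` and the parenchymal
#' expectation is its leak integral, `(k*C0/lambda) * (1 - exp(-lambda *
#' (t - t_inj)))` (or `k*C0*(t - t_inj)` in the `lambda = 0` limit).
#' Tracers sharing the channel sum; the autofluorescence offset is **not**
#' included here.
#'
#' @param schedule tracer schedule (see [tracerSchedule()]).
#' @param truth from [groundTruth()].
#' @param timesMin times at which to evaluate, minutes.
#' @return list with `blood`, `parenchyma` (summed expectation vectors) and
#'   `components` (per-tracer matrices, tracers in columns).
#' @export
tracerKinetics <- function(schedule, truth, timesMin) {
  nm <- schedule$name
  k <- truthParam(truth, "leakRatePerMin", nm)
  lam <- truthParam(truth, "bloodClearancePerMin", nm)
  C0 <- truthParam(truth, "bloodAmplitude", nm)
  B <- P <- matrix(0, length(timesMin), nrow(schedule),
                   dimnames = list(NULL, nm))
  for (i in seq_len(nrow(schedule))) {
    dt <- timesMin - schedule$injection_time_min[i]
    on <- dt > 0
    B[on, i] <- C0[i] * exp(-lam[i] * dt[on])
    P[on, i] <- if (lam[i] > 0)
      (k[i] * C0[i] / lam[i]) * (1 - exp(-lam[i] * dt[on]))
    else k[i] * C0[i] * dt[on]
  }
  list(blood = rowSums(B), parenchyma = rowSums(P),
       components = list(blood = B, parenchyma = P))
}

## Poisson shot + Gaussian read noise, applied to an expectation array
applyNoise <- function(E, noise) {
  g <- noise$poissonGain
  v <- rpois(length(E), lambda = as.vector(E) * g) / g
  if (noise$readSigma > 0) v <- v + rnorm(length(v), sd = noise$readSigma)
  v <- pmin(pmax(v, 0), 65535)
  array(v, dim = dim(E))
}

#' Simulate a sequential-tracer imaging session
#'
#' Renders a 4D hyperstack of a session in which the scheduled tracers are
#' consecutively injected into the blood stream and imaged in a shared
#' detection channel.  Vessel voxels carry the summed blood expectation,
#' all other voxels the summed parenchymal leak expectation; the constant
#' autofluorescence offset is added everywhere, and noise (if enabled) is
#' applied last.  Frames are uniform in time from
#' `min(window_start) - baselineFrames * frameInterval` to
#' `max(window_end)`; pre-injection baseline frames contain offset only and
#' can be used to estimate the background.
#'
#' @param tree a [VesselTree-class].
#' @param schedule tracer schedule; injections ordered in time.
#' @param truth from [groundTruth()].
#' @param frameIntervalMin frame spacing, minutes.
#' @param baselineFrames number of pre-injection frames to prepend.
#' @param noise logical; `FALSE` renders the noiseless expectations.
#' @param seed RNG seed (noise only).
#' @return list with `stack` ([Hyperstack-class]), `reference` (noiseless
#'   [IntensityTrace-class]s: `parenchyma`, `blood`, plus per-tracer
#'   `components`), `schedule` and `truth`.
#' @export
simulateTracerSession <- function(tree, schedule, truth = groundTruth(),
                                  frameIntervalMin = 1, baselineFrames = 0L,
                                  noise = TRUE, seed = 1L) {
  schedule <- validateSchedule(schedule)
  times <- seq(min(schedule$window_start_min) -
                 baselineFrames * frameIntervalMin,
               max(schedule$window_end_min), by = frameIntervalMin)
  kin <- tracerKinetics(schedule, truth, times)
  off <- truth$autofluorescenceOffset
  labels <- labelVolume(tree)
  vessel <- labels > 0L
  d <- dim(labels)
  stopifnot(all(kin$blood >= 0), all(kin$parenchyma >= 0))
  vox <- array(0, dim = c(length(times), d))
  for (t in seq_along(times)) {
    frame <- array(off + kin$parenchyma[t], dim = d)
    frame[vessel] <- off + kin$blood[t]
    vox[t, , , ] <- frame
  }
  if (noise) vox <- withSeed(seed, applyNoise(vox, truth$noise))
  stack <- Hyperstack(vox, pixelSizeUm = tree@pixelSizeUm,
                      zStepUm = tree@zStepUm,
                      frameIntervalMin = frameIntervalMin, t0Min = times[1])
  reference <- list(
    parenchyma = IntensityTrace(times, off + kin$parenchyma, "raw_au",
                                "parenchyma"),
    blood = IntensityTrace(times, off + kin$blood, "raw_au", "blood"),
    components = kin$components)
  list(stack = stack, reference = reference, schedule = schedule,
       truth = truth)
}
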
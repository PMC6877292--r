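#' Tree configuration for paracellular (free-tracer) sessions
#'
#' A compact field of view with a handful of small vessels: enough vascular
#' signal to segment and place blood ROIs, while leaving most of the frame
#' as parenchyma for ROI placement.
#'
#' @inheritParams vesselTreeConfig
#' @export
paracellularTreeConfig <- function(shape = c(4, 96, 96), pixelSizeUm = 3,
                                   zStepUm = 5,
                                   counts = c(penetrating_arteriole = 1,
                                              ascending_venule = 1,
                                              capillary = 4,
                                              post_capillary_venule = 1)) {
  ## every vessel must be resolvable at this pixel size and survive the
  ## small-component filter of the segmentation (>= 20 px footprint)
  rng <- defaultDiameterRanges()
  rng$penetrating_arteriole <- c(15, 25)
  rng$ascending_venule <- c(15, 25)
  vesselTreeConfig(shape = shape, pixelSizeUm = pixelSizeUm,
                   zStepUm = zStepUm, counts = counts,
                   diameterRanges = rng, lengthRangeUm = c(60, 120))
}

## estimate the constant background from pre-injection frames, if any
estimateBackground <- function(trace, schedule) {
  pre <- trace@timesMin < min(schedule$injection_time_min)
  if (!any(pre)) return(NULL)
  mean(trace@values[pre])
}

windowTrace <- function(trace, w0, w1) {
  sel <- trace@timesMin >= w0 - 1e-9 & trace@timesMin <= w1 + 1e-9
  new("IntensityTrace", timesMin = trace@timesMin[sel],
      values = trace@values[sel], units = trace@units,
      compartment = trace@compartment)
}

#' Paracellular-permeability scoring of a tracer session
#'
#' The full analysis chain for a sequential-tracer hyperstack: maximum
#' intensity projection; vessel segmentation on the first frame of the
#' first tracer window; pooled parenchymal ROIs clear of the (dilated)
#' vessel mask and blood ROIs inside it; trace extraction; constant
#' background subtraction (estimated from pre-injection frames when
#' present, else `background` must be supplied); sequential-tracer
#' decoupling (saturating-growth fits for parenchyma, decay fits for
#' blood); conversion of each corrected window to relative change over its
#' baseline frame; and the 30-min AUC per tracer.
#'
#' The relative denominator is the window's measured baseline fluorescence
#' (corrected signal plus the constant background), i.e. the fluorescence
#' an observer reads off the baseline frame; this keeps the normalization
#' stable and comparable across tracers.  Setting `relativeFirst = TRUE`
#' instead converts raw windows to relative before any correction (the
#' alternative ordering; exposed without endorsement).
#'
#' @param stack a [Hyperstack-class].
#' @param schedule tracer schedule (see [tracerSchedule()]).
#' @param background constant autofluorescence background; `NULL` to
#'   estimate from pre-injection frames.
#' @param nRois,roiSizePx parenchymal ROI count and size.
#' @param nBloodRois,bloodRoiSizePx blood ROI count and size.
#' @param seed seed for ROI placement.
#' @param relativeFirst alternative ordering (relative before correction).
#' @return list with `results` (per-tracer [PermeabilityResult-class]),
#'   `mask`, `parenchymaRois`, `bloodRois`, `background`, and the raw
#'   pooled `traces`.
#' @export
analyzeParacellular <- function(stack, schedule, background = NULL,
                                nRois = 10L, roiSizePx = 8L,
                                nBloodRois = 3L, bloodRoiSizePx = 2L,
                                seed = 1L, relativeFirst = FALSE) {
  schedule <- validateSchedule(schedule)
  frames <- maxProject(stack)
  times <- frameTimes(stack)
  baseIdx <- which(times >= min(schedule$window_start_min) - 1e-9)[1]
  mask <- segmentVasculature(frames[baseIdx, , ])
  parRois <- placeParenchymalRois(mask, roiSizePx = roiSizePx,
                                  nRois = nRois, seed = seed)
  bloodRois <- placeBloodRois(mask, roiSizePx = bloodRoiSizePx,
                              nRois = nBloodRois, seed = seed)
  rawPar <- extractTrace(frames, parRois, times)
  rawBlood <- extractTrace(frames, bloodRois, times)
  if (is.null(background)) background <- estimateBackground(rawPar, schedule)
  if (is.null(background))
    stop("no pre-injection frames to estimate the background from; ",
         "supply 'background'")
  parBS <- suppressMessages(subtractBackground(rawPar, background))
  bloodBS <- suppressMessages(subtractBackground(rawBlood, background))
  n <- nrow(schedule)
  parWin <- bloodWin <- vector("list", n)
  for (i in seq_len(n)) {
    parWin[[i]] <- windowTrace(if (relativeFirst) rawPar else parBS,
                               schedule$window_start_min[i],
                               schedule$window_end_min[i])
    if (relativeFirst) parWin[[i]] <- relativeChange(parWin[[i]])
    bloodWin[[i]] <- windowTrace(bloodBS, schedule$window_start_min[i],
                                 schedule$window_end_min[i])
  }
  names(parWin) <- names(bloodWin) <- schedule$name
  dec <- decoupleSequential(parWin, model = "saturating_growth")
  decBlood <- decoupleSequential(bloodWin, model = "decay")
  results <- vector("list", n)
  for (i in seq_len(n)) {
    corr <- dec$corrected[[i]]
    rel <- if (relativeFirst) corr
    else {
      restored <- new("IntensityTrace", timesMin = corr@timesMin,
                      values = corr@values + background, units = "raw_au",
                      compartment = "parenchyma")
      relativeChange(restored)
    }
    bf <- suppressWarnings(
      fitExponential(decBlood$corrected[[i]], model = "decay"))
    results[[i]] <- new("PermeabilityResult", tracer = schedule$name[i],
                        correctedTrace = rel,
                        aucMin = computeAuc(rel),
                        correctionFits = dec$correctionFits[[i]],
                        bloodFit = bf)
  }
  names(results) <- schedule$name
  list(results = results, mask = mask, parenchymaRois = parRois,
       bloodRois = bloodRois, background = background,
       traces = list(parenchyma = rawPar, blood = rawBlood,
                     parenchymaCorrected = dec$corrected,
                     bloodCorrected = decBlood$corrected))
}

#' Simulate and analyze one paracellular session end to end
#'
#' Convenience wrapper: generates a vessel tree, simulates the scheduled
#' tracer session (with two pre-injection baseline frames used for
#' background estimation) and runs [analyzeParacellular()].
#'
#' @param truth from [groundTruth()].
#' @param schedule tracer schedule.
#' @param treeConfig from [paracellularTreeConfig()].
#' @param seed RNG seed (tree, noise and ROI placement).
#' @param noise logical.
#' @param baselineFrames pre-injection frames to simulate.
#' @param ... passed to [analyzeParacellular()].
#' @return list with `sim` (see [simulateTracerSession()]) and `analysis`
#'   (see [analyzeParacellular()]).
#' @export
runParacellularSession <- function(truth = groundTruth(),
                                   schedule = tracerSchedule(),
                                   treeConfig = paracellularTreeConfig(),
                                   seed = 1L, noise = TRUE,
                                   baselineFrames = 2L, ...) {
  tree <- generateVesselTree(treeConfig, seed = seed)
  sim <- simulateTracerSession(tree, schedule, truth,
                               baselineFrames = baselineFrames,
                               noise = noise, seed = seed)
  analysis <- analyzeParacellular(sim$stack, schedule, seed = seed, ...)
  list(sim = sim, analysis = analysis, tree = tree)
}

#' Vesicle-density quantification of a conjugate session
#'
#' Projects the stack, derives the vessel mask from the supplied geometry,
#' detects wall puncta, assigns them to vessels, links punctum identity
#' across timepoints and computes per-vessel cumulative surface-density
#' kinetics.
#'
#' @param stack a [Hyperstack-class].
#' @param tree the vessel geometry ([VesselTree-class]).
#' @param params from [vesicleDetectionParams()].
#' @return list with `detections`, `tracks` and `records` (see
#'   [densityKinetics()]).
#' @export
analyzeTranscytosis <- function(stack, tree,
                                params = vesicleDetectionParams()) {
  frames <- maxProject(stack)
  labels <- labelVolume(tree)
  mask <- apply(labels > 0, c(2, 3), any)
  det <- detectVesicles(frames, mask, frameTimes(stack), stack@pixelSizeUm,
                        params)
  det <- assignDetections(det, tree, params$maxAssignDistPx)
  tracks <- linkDetections(det, stack@pixelSizeUm, params)
  records <- densityKinetics(tracks, segments(tree), frameTimes(stack))
  list(detections = det, tracks = tracks, records = records)
}

#' Simulate and analyze one vesicle session end to end
#'
#' @param truth from [groundTruth()].
#' @param treeConfig from [vesicleTreeConfig()].
#' @param seed RNG seed.
#' @param noise logical.
#' @param ... passed to [simulateVesicleSession()].
#' @return list with `sim`, `tree` and `analysis`
#'   (see [analyzeTranscytosis()]).
#' @export
runVesicleSession <- function(truth = groundTruth(),
                              treeConfig = vesicleTreeConfig(), seed = 1L,
                              noise = TRUE, ...) {
  tree <- generateVesselTree(treeConfig, seed = seed)
  sim <- simulateVesicleSession(tree, truth, noise = noise, seed = seed, ...)
  analysis <- analyzeTranscytosis(sim$stack, tree)
  list(sim = sim, tree = tree, analysis = analysis)
}
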
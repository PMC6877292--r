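## shared fixtures for the test suite -- everything is generated in code

## a tiny single-tracer schedule
singleSchedule <- function(name = "T") tracerSchedule(names = name, mwKda = 0.365)

## ground truth for a single tracer
singleTruth <- function(k = 0.01, lambda = 0.1, C0 = 100, offset = 20,
                        name = "T", ...) {
  groundTruth(leakRatePerMin = setNames(k, name),
              bloodClearancePerMin = setNames(lambda, name),
              bloodAmplitude = setNames(C0, name),
              autofluorescenceOffset = offset, ...)
}

## small vessel tree for trace-level tests
smallTreeConfig <- function(nz = 4) paracellularTreeConfig(shape = c(nz, 96, 96))

## uniform vesicle rates across categories
uniformRates <- function(r)
  setNames(rep(r, 6), c("pial_arteriole", "penetrating_arteriole",
                        "capillary", "post_capillary_venule",
                        "ascending_venule", "pial_venule"))

## greedy matching of detections to ground-truth events; returns per-frame
## mean recall and precision
detectionMatchStats <- function(det, ev, times, tolPx = 1.5) {
  rec <- prec <- c()
  for (tm in times[-1]) {
    d <- det[abs(det$time_min - tm) < 1e-9, ]
    e <- ev[ev$time_min <= tm, ]
    if (nrow(e) == 0) next
    used <- rep(FALSE, nrow(d))
    n <- 0
    for (i in seq_len(nrow(e))) {
      d2 <- (d$row - e$row[i])^2 + (d$col - e$col[i])^2
      d2[used] <- Inf
      j <- which.min(d2)
      if (length(j) && is.finite(d2[j]) && d2[j] <= tolPx^2) {
        used[j] <- TRUE
        n <- n + 1
      }
    }
    rec <- c(rec, n / nrow(e))
    prec <- c(prec, if (nrow(d)) n / nrow(d) else 1)
  }
  c(recall = mean(rec), precision = mean(prec))
}
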
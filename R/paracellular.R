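#' Subtract the constant autofluorescence background from a trace
#'
#' Values are reduced by a constant; negative results are clipped at 0 and
#' the number of clipped points is recorded in the `"nClipped"` attribute of
#' the returned trace (and reported via `message()`).  A background larger
#' than the trace minimum by more than half the trace's dynamic range
#' triggers a warning, as it was likely mis-estimated.
#'
#' @param trace an [IntensityTrace-class] in raw units.
#' @param backgroundLevel constant background, >= 0.
#' @return background-subtracted [IntensityTrace-class].
#' @export
subtractBackground <- function(trace, backgroundLevel) {
  assertScalar(backgroundLevel, "backgroundLevel", nonneg = TRUE)
  v <- trace@values
  rng <- diff(range(v))
  if (rng > 0 && backgroundLevel > min(v) + 0.5 * rng)
    warning("background (", signif(backgroundLevel, 4),
            ") exceeds the trace minimum by more than half the dynamic range;",
            " it may be mis-estimated")
  out <- v - backgroundLevel
  nClipped <- sum(out < 0)
  if (nClipped > 0) {
    message(nClipped, " point", if (nClipped > 1) "s" else "",
            " clipped at 0 during background subtraction")
    out[out < 0] <- 0
  }
  res <- IntensityTrace(trace@timesMin, out, units = trace@units,
                        compartment = trace@compartment)
  attr(res, "nClipped") <- nClipped
  res
}

#' Fit an exponential model to a trace window
#'
#' Nonlinear least squares (Levenberg-Marquardt) fit of a saturating-growth
#' model \eqn{a + b(1 - e^{-c(t - t_s)})} or a decay model
#' \eqn{a + b e^{-c(t - t_s)}}, with \eqn{t_s} the window start.
#' Initialization: `a` = first value, `b` = last - first (growth) or
#' first - last (decay), `c` = 1/window length; `c` is bounded to
#' `[0, 10]` per minute.  Constant data return the degenerate fit
#' `a = value, b = 0, c = 0`.  If the optimizer fails, a linear fallback is
#' fitted and reported with `c = 0`, `b = slope * window length` and
#' `fallback = TRUE` (see [ExponentialFit-class] for the evaluation
#' semantics).
#'
#' @param trace an [IntensityTrace-class].
#' @param model `"saturating_growth"` or `"decay"`.
#' @param window optional `c(start, end)` fit window in minutes; defaults to
#'   the full trace extent.
#' @return an [ExponentialFit-class].
#' @export
fitExponential <- function(trace, model = c("saturating_growth", "decay"),
                           window = NULL) {
  model <- match.arg(model)
  t <- trace@timesMin; y <- trace@values
  if (!is.null(window)) {
    sel <- t >= window[1] & t <= window[2]
    t <- t[sel]; y <- y[sel]
  }
  if (length(t) < 5L) stop("need at least 5 timepoints in the fit window")
  w0 <- t[1]; L <- t[length(t)] - w0
  tt <- t - w0
  mkFit <- function(a, b, c, rmse, fallback = FALSE)
    new("ExponentialFit", model = model, a = a, b = b, c = c, rmse = rmse,
        window = c(w0, w0 + L), fallback = fallback)
  if (diff(range(y)) == 0)
    return(mkFit(a = y[1], b = 0, c = 0, rmse = 0))
  form <- if (model == "saturating_growth")
    y ~ a + b * (1 - exp(-c * tt)) else y ~ a + b * exp(-c * tt)
  b0 <- if (model == "saturating_growth") y[length(y)] - y[1] else y[1] - y[length(y)]
  start <- list(a = y[1], b = b0, c = 1 / L)
  fit <- tryCatch(
    minpack.lm::nlsLM(form, data = data.frame(y = y, tt = tt), start = start,
                      lower = c(-Inf, -Inf, 0), upper = c(Inf, Inf, 10),
                      control = minpack.lm::nls.lm.control(
                        maxiter = 500, ftol = 1e-14, ptol = 1e-14)),
    error = function(e) NULL)
  if (!is.null(fit)) {
    p <- coef(fit)
    rmse <- sqrt(mean(residuals(fit)^2))
    return(mkFit(a = unname(p["a"]), b = unname(p["b"]), c = unname(p["c"]),
                 rmse = rmse))
  }
  ## linear fallback: the c -> 0 limit, with b = slope * window length
  lf <- lm(y ~ tt)
  rmse <- sqrt(mean(residuals(lf)^2))
  mkFit(a = unname(coef(lf)[1]), b = unname(coef(lf)[2]) * L, c = 0,
        rmse = rmse, fallback = TRUE)
}

#' Evaluate an exponential fit at arbitrary times
#'
#' Evaluates the closed form of the fit at the requested times, which may
#' lie outside the fit window (extrapolation).  A saturating-growth fit
#' approaches `a + b` as `t` grows; a decay fit with `c = 0` is the
#' constant `a + b`.  Linear-fallback growth fits evaluate as
#' `a + b * (t - t_s)/L`.
#'
#' @param fit an [ExponentialFit-class].
#' @param times times in minutes.
#' @return numeric vector of fitted values.
#' @export
extrapolateFit <- function(fit, times) {
  dt <- times - fit@window[1]
  if (fit@model == "saturating_growth") {
    if (fit@fallback) fit@a + fit@b * dt / diff(fit@window)
    else fit@a + fit@b * (1 - exp(-fit@c * dt))
  } else {
    if (fit@fallback) fit@a + fit@b * dt / diff(fit@window)
    else fit@a + fit@b * exp(-fit@c * dt)
  }
}

#' Decouple consecutively injected tracers sharing a detection channel
#'
#' Fluorescence in a shared channel is additive, so the signal measured in a
#' later tracer's window still contains the earlier tracers' contributions.
#' The correction fits an exponential trend to each tracer's (corrected)
#' trace on its own window and subtracts the extrapolated fit from all later
#' tracers' traces, in injection order: the first trace is returned
#' unchanged; trace `i` has the fits of corrected traces `1..i-1`
#' subtracted.  Negative corrected values are retained, so systematic
#' over-correction stays visible.  The correction is asymmetric by
#' construction: earlier tracers are never corrected by later ones.
#'
#' @param traces named list of [IntensityTrace-class], in injection order,
#'   each spanning its own (non-overlapping) imaging window; background
#'   should already be subtracted.
#' @param model fit model: `"saturating_growth"` for parenchymal traces
#'   (extrapolation is bounded and non-decreasing, a conservative estimate
#'   of the largest contribution a preceding tracer can make), `"decay"`
#'   for blood traces.
#' @return list with `corrected` (list of traces) and `correctionFits`
#'   (per-trace list of the [ExponentialFit-class]s subtracted from it;
#'   empty for the first).
#' @export
decoupleSequential <- function(traces, model = "saturating_growth") {
  n <- length(traces)
  if (n == 0L) return(list(corrected = traces,
                           correctionFits = list()))
  starts <- vapply(traces, function(tr) tr@timesMin[1], numeric(1))
  ends <- vapply(traces, function(tr) max(tr@timesMin), numeric(1))
  if (n > 1 && any(starts[-1] < ends[-n]))
    stop("tracer windows must be non-overlapping and in injection order")
  corrected <- traces
  applied <- rep(list(list()), n)
  names(applied) <- names(traces)
  if (n > 1) for (i in seq_len(n - 1)) {
    fit <- tryCatch(fitExponential(corrected[[i]], model = model),
                    error = function(e)
                      stop("decoupling failed: exponential fit for tracer '",
                           names(traces)[i], "': ", conditionMessage(e),
                           call. = FALSE))
    for (j in (i + 1):n) {
      tr <- corrected[[j]]
      corr <- tr@values - extrapolateFit(fit, tr@timesMin)
      corrected[[j]] <- new("IntensityTrace", timesMin = tr@timesMin,
                            values = corr, units = tr@units,
                            compartment = tr@compartment)
      applied[[j]] <- c(applied[[j]], fit)
    }
  }
  list(corrected = corrected, correctionFits = applied)
}

#' Fit blood clearance and normalize the blood trace
#'
#' Fits an exponential decay to the blood trace (accounting for baseline
#' fluorescence changes in the bloodstream) and returns the trace
#' normalized to its first value (fraction of baseline, invariant to gain
#' rescaling).  Warns when the blood signal increases over the full window,
#' which suggests suspect injection timing.
#'
#' @param bloodTrace an [IntensityTrace-class] from an in-lumen ROI.
#' @param window optional fit window `c(start, end)`.
#' @return list with `fit` ([ExponentialFit-class]) and `normalized`
#'   ([IntensityTrace-class], units `"fraction_of_baseline"`).
#' @export
bloodClearanceFit <- function(bloodTrace, window = NULL) {
  v <- bloodTrace@values
  if (v[length(v)] > v[1] && diff(range(v)) > 0)
    warning("blood signal increases over the window; injection timing suspect")
  fit <- fitExponential(bloodTrace, model = "decay", window = window)
  if (v[1] == 0) stop("blood trace starts at 0; cannot normalize")
  normalized <- IntensityTrace(bloodTrace@timesMin, v / v[1],
                               units = "fraction_of_baseline",
                               compartment = "blood")
  list(fit = fit, normalized = normalized)
}

#' Area under the curve of a relative trace
#'
#' Trapezoidal integral of the trace values over the requested time window
#' (minutes), on the native time grid without resampling.  For a corrected
#' relative parenchymal trace this is the paracellular leak score, in
#' dimensionless-fluorescence x minutes (reported as "min").
#'
#' @param trace an [IntensityTrace-class] (typically relative units).
#' @param window `c(start, end)` in minutes; must be covered by the trace.
#' @return the AUC (scalar).
#' @export
computeAuc <- function(trace, window = range(trace@timesMin)) {
  t <- trace@timesMin
  tol <- 1e-9
  if (window[1] < t[1] - tol || window[2] > t[length(t)] + tol)
    stop("AUC window [", window[1], ", ", window[2],
         "] not covered by the trace")
  sel <- t >= window[1] - tol & t <= window[2] + tol
  pracma::trapz(t[sel], trace@values[sel])
}

#' Estimate the leak rate from paired parenchymal and blood traces
#'
#' Under the two-compartment model the parenchymal signal is
#' \eqn{P(t) = k \int_0^t B(s) ds}; this returns the least-squares
#' \eqn{\hat k} minimizing \eqn{\|P(t) - k \int B\|} on the common time
#' grid.  Both traces must be background-subtracted and on identical time
#' grids.  If `injectionTimeMin` precedes the first sample, the unobserved
#' head of the blood integral is reconstructed from an exponential decay
#' fit to the blood trace.
#'
#' @param parTrace background-subtracted parenchymal [IntensityTrace-class].
#' @param bloodTrace background-subtracted blood [IntensityTrace-class].
#' @param injectionTimeMin optional injection time (minutes).
#' @return estimated leak rate per minute.
#' @export
estimateLeakRate <- function(parTrace, bloodTrace, injectionTimeMin = NULL) {
  t <- parTrace@timesMin
  if (!isTRUE(all.equal(t, bloodTrace@timesMin)))
    stop("parenchymal and blood traces must share one time grid")
  B <- bloodTrace@values
  if (all(B == 0)) stop("blood trace is all zero; leak rate is unidentifiable")
  I <- as.vector(pracma::cumtrapz(t, B))
  if (!is.null(injectionTimeMin) && injectionTimeMin < t[1]) {
    fit <- fitExponential(bloodTrace, model = "decay")
    dt <- t[1] - injectionTimeMin
    head <- if (fit@c > 0)
      fit@a * dt + fit@b * (exp(fit@c * dt) - 1) / fit@c
    else (fit@a + fit@b) * dt
    I <- I + head
  }
  sum(parTrace@values * I) / sum(I^2)
}
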
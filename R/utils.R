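#' @importFrom pracma trapz cumtrapz
#' @importFrom stats rpois rnorm rlnorm runif sd median mad aov TukeyHSD
#'   t.test wilcox.test pchisq lm coef residuals aggregate cor setNames
#' @importFrom utils write.csv read.csv
NULL

## Evaluate `code` under a fixed RNG seed without disturbing the caller's
## RNG state.  All stochastic generators in the package funnel through this.
withSeed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

## scalar checks used by constructors
assertScalar <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop("'", name, "' must be a finite numeric scalar", call. = FALSE)
  if (positive && x <= 0) stop("'", name, "' must be > 0", call. = FALSE)
  if (nonneg && x < 0) stop("'", name, "' must be >= 0", call. = FALSE)
  invisible(x)
}

## Otsu threshold on 256 bins spanned between min and max of the data, so the
## returned class boundary is exactly invariant to adding a constant offset.
otsuThreshold <- function(x, nbins = 256L) {
  r <- range(x)
  if (diff(r) == 0) stop("segmentation failure: frame has no contrast")
  h <- tabulate(pmin(nbins, 1L + floor((x - r[1]) / diff(r) * nbins)), nbins)
  p <- h / sum(h)
  omega <- cumsum(p)
  mids <- r[1] + (seq_len(nbins) - 0.5) / nbins * diff(r)
  mu <- cumsum(p * mids)
  muT <- mu[nbins]
  sigma2 <- (muT * omega - mu)^2 / (omega * (1 - omega))
  sigma2[!is.finite(sigma2)] <- -Inf
  mids[which.max(sigma2)]
}

## standard error of the mean
sem <- function(x) stats::sd(x) / sqrt(length(x))
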
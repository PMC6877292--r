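#' Omnibus (skewness + kurtosis) normality test
#'
#' The D'Agostino-Pearson omnibus statistic: the sample skewness and
#' kurtosis are separately transformed to approximate standard normal
#' deviates and \eqn{K^2 = Z_{skew}^2 + Z_{kurt}^2} is referred to a
#' chi-squared distribution with 2 df.  Requires `n >= 8`.
#'
#' @param x numeric sample.
#' @return list with `statistic` (K2) and `p.value`.
#' @export
omnibusNormalityTest <- function(x) {
  n <- length(x)
  if (n < 8) stop("omnibus normality test requires n >= 8")
  if (diff(range(x)) == 0) stop("constant sample")
  m <- mean(x)
  m2 <- mean((x - m)^2); m3 <- mean((x - m)^3); m4 <- mean((x - m)^4)
  ## skewness transform (D'Agostino)
  g1 <- m3 / m2^1.5
  Y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  W2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(log(sqrt(W2)))
  alpha <- sqrt(2 / (W2 - 1))
  Zs <- delta * log(Y / alpha + sqrt((Y / alpha)^2 + 1))
  ## kurtosis transform (Anscombe-Glynn)
  b2 <- m4 / m2^2
  Eb2 <- 3 * (n - 1) / (n + 1)
  Vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xk <- (b2 - Eb2) / sqrt(Vb2)
  sqB1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  A <- 6 + 8 / sqB1 * (2 / sqB1 + sqrt(1 + 4 / sqB1^2))
  Zk <- ((1 - 2 / (9 * A)) -
           ((1 - 2 / A) / (1 + xk * sqrt(2 / (A - 4))))^(1 / 3)) /
    sqrt(2 / (9 * A))
  K2 <- Zs^2 + Zk^2
  list(statistic = K2, p.value = pchisq(K2, df = 2, lower.tail = FALSE))
}

#' Normality gate for group comparisons
#'
#' Applies the omnibus normality test per group; the data are treated as
#' normal only if every group passes at level `alpha`.  Groups with fewer
#' than 8 observations default to non-normal with a note; constant groups
#' are non-normal with a warning.
#'
#' @param groups named list of numeric samples.
#' @param alpha gate level.
#' @return list with `normal` (overall logical), `perGroup` (logical
#'   vector), `pValues` (NA where not computed) and `notes`.
#' @export
normalityGate <- function(groups, alpha = 0.05) {
  p <- setNames(rep(NA_real_, length(groups)), names(groups))
  pass <- setNames(logical(length(groups)), names(groups))
  notes <- character()
  for (g in seq_along(groups)) {
    x <- groups[[g]]
    nm <- if (!is.null(names(groups))) names(groups)[g] else as.character(g)
    if (length(x) < 8) {
      pass[g] <- FALSE
      notes <- c(notes, paste0("group '", nm,
                               "': n < 8, defaulting to non-normal"))
      next
    }
    if (diff(range(x)) == 0) {
      pass[g] <- FALSE
      warning("group '", nm, "' is constant; treated as non-normal")
      next
    }
    res <- omnibusNormalityTest(x)
    p[g] <- res$p.value
    pass[g] <- res$p.value >= alpha
  }
  if (length(notes)) message(paste(notes, collapse = "\n"))
  list(normal = all(pass), perGroup = pass, pValues = p, notes = notes)
}

groupSummaries <- function(groups) {
  data.frame(group = names(groups),
             n = vapply(groups, length, integer(1)),
             mean = vapply(groups, mean, numeric(1)),
             sem = vapply(groups, sem, numeric(1)),
             row.names = NULL)
}

#' Two-group comparison with a normality gate
#'
#' Welch's unpaired two-tailed t-test when both groups pass the omnibus
#' normality gate at `alpha`, otherwise the (two-tailed) Mann-Whitney test
#' with the midrank convention for ties.
#'
#' @param a,b numeric samples (n >= 2 each).
#' @param alpha level of the normality gate.
#' @return a [GroupComparisonResult-class].
#' @export
compareTwoGroups <- function(a, b, alpha = 0.05) {
  if (length(a) < 2 || length(b) < 2) stop("need n >= 2 per group")
  groups <- list(a = a, b = b)
  gate <- suppressMessages(withCallingHandlers(
    normalityGate(groups, alpha),
    warning = function(w) invokeRestart("muffleWarning")))
  if (gate$normal) {
    tt <- t.test(a, b, var.equal = FALSE)
    testName <- "welch_t"; statistic <- unname(tt$statistic); p <- tt$p.value
  } else {
    wt <- suppressWarnings(wilcox.test(a, b, exact = FALSE, correct = TRUE))
    testName <- "mann_whitney"; statistic <- unname(wt$statistic)
    p <- wt$p.value
    if (is.na(p)) p <- 1   # fully tied identical samples
  }
  new("GroupComparisonResult", testName = testName, statistic = statistic,
      pValue = p, groupSummaries = groupSummaries(groups),
      normalityP = gate$pValues, tukey = NULL)
}

#' Morphometry comparison: log-transformed one-way ANOVA with Tukey HSD
#'
#' The positive-valued samples undergo logarithmic transformation (making
#' the test invariant to multiplicative rescaling) and are evaluated with
#' one-way analysis of variance followed by Tukey's multiple-comparison
#' test.
#'
#' @param groups named list of >= 2 positive numeric samples.
#' @return a [GroupComparisonResult-class]; `tukey` holds the adjusted
#'   pairwise contrasts.
#' @export
compareMorphometry <- function(groups) {
  stopifnot(length(groups) >= 2)
  for (g in names(groups))
    if (any(groups[[g]] <= 0)) {
      i <- which(groups[[g]] <= 0)[1]
      stop("non-positive value in group '", g, "' (record ", i,
           "); log transform undefined")
    }
  df <- data.frame(
    value = unlist(groups, use.names = FALSE),
    group = factor(rep(names(groups), vapply(groups, length, integer(1)))))
  fit <- aov(log(value) ~ group, data = df)
  an <- summary(fit)[[1]]
  tk <- TukeyHSD(fit)$group
  tukey <- data.frame(contrast = rownames(tk), diff_log = tk[, "diff"],
                      p_adj = tk[, "p adj"], row.names = NULL)
  new("GroupComparisonResult", testName = "anova_log_tukey",
      statistic = an[["F value"]][1], pValue = an[["Pr(>F)"]][1],
      groupSummaries = groupSummaries(groups),
      normalityP = setNames(rep(NA_real_, length(groups)), names(groups)),
      tukey = tukey)
}

#' Percent difference of a test mean over a reference mean
#'
#' `100 * (meanTest - meanRef) / meanRef`.
#'
#' @param meanTest,meanRef group means; `meanRef > 0`.
#' @export
percentDifference <- function(meanTest, meanRef) {
  if (meanRef <= 0) stop("reference mean must be > 0")
  100 * (meanTest - meanRef) / meanRef
}

#' Fold ratio of two group means
#'
#' @param meanA,meanB group means; `meanB > 0`.
#' @export
foldRatio <- function(meanA, meanB) {
  if (meanB <= 0) stop("denominator mean must be > 0")
  meanA / meanB
}
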
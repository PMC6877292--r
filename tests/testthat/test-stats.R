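## Reference values for the omnibus test computed with an independent
## implementation (scipy.stats.normaltest) on the frozen samples below.
gaussSample <- c(
  10.609434, 7.920032, 11.500902, 11.881129, 6.097930, 7.395641, 10.255681,
  9.367515, 9.966398, 8.293912, 11.758796, 11.555584, 10.132061, 12.254482,
  10.935019, 8.281415, 10.737502, 8.082235, 11.756901, 9.900148, 9.630275,
  8.638141, 12.445083, 9.690941, 9.143344, 9.295733, 11.064618, 10.730888,
  10.825465, 10.861642, 14.283295, 9.187170, 8.975515, 8.372455, 11.231959,
  12.257945, 9.772105, 8.319687, 8.351038, 11.301186)
lognormSample <- c(
  2.102767, 1.721428, 0.514011, 1.261323, 1.123766, 1.244444, 2.390324,
  1.250565, 1.971734, 1.069915, 1.335251, 1.880031, 0.232898, 0.726388,
  0.624769, 0.527884, 0.759464, 4.459075, 0.420702, 2.633407, 0.185840,
  0.715420, 1.176746, 1.797186, 2.036488, 2.210784, 0.705587, 0.629801,
  2.358382, 0.825881, 0.279239, 0.321973, 0.398737, 1.644047, 1.153067,
  1.994683, 0.652299, 1.171798, 1.869349, 0.733926)

test_that("the omnibus normality statistic matches an independent reference
           implementation", {
  r1 <- omnibusNormalityTest(gaussSample)
  expect_equal(r1$statistic, 0.1154816272, tolerance = 1e-8)
  expect_equal(r1$p.value, 0.9438945604, tolerance = 1e-8)
  r2 <- omnibusNormalityTest(lognormSample)
  expect_equal(r2$statistic, 17.8534268865, tolerance = 1e-8)
  expect_equal(r2$p.value, 0.0001327937, tolerance = 1e-6)
  expect_error(omnibusNormalityTest(rnorm(5)), "n >= 8")
})

test_that("the normality gate is calibrated: Gaussian samples pass and
           heavy-tailed samples fail", {
  passG <- passL <- logical(100)
  for (i in 1:100) {
    set.seed(i)
    passG[i] <- omnibusNormalityTest(rnorm(500))$p.value >= 0.05
    passL[i] <- omnibusNormalityTest(rlnorm(500, 0, 1))$p.value >= 0.05
  }
  expect_gte(mean(passG), 0.9)
  expect_gte(mean(!passL), 0.95)
})

test_that("small and constant groups are routed to non-normal", {
  suppressMessages({
    gate <- normalityGate(list(a = rnorm(5), b = rnorm(20)))
  })
  expect_false(gate$perGroup[["a"]])
  expect_true(any(grepl("n < 8", gate$notes)))
  expect_warning(normalityGate(list(a = rep(1, 20))), "constant")
})

test_that("two-group comparisons gate to Welch or Mann-Whitney and behave
           at the null and under a large effect", {
  ## identical, clearly non-Gaussian samples: gated to Mann-Whitney with
  ## midranks, p = 1, no difference
  same <- rep(c(1, 1, 1, 1, 10), 8)
  res <- compareTwoGroups(same, same)
  expect_equal(res@pValue, 1, tolerance = 1e-9)
  expect_equal(res@testName, "mann_whitney")
  ## clear separation: p < 0.001 with the parametric branch
  set.seed(5)
  a <- rnorm(50, 0, 1); b <- rnorm(50, 2, 1)
  r2 <- compareTwoGroups(a, b)
  expect_equal(r2@testName, "welch_t")
  expect_lt(r2@pValue, 0.001)
  ## swap symmetry: sign flips, p unchanged
  r3 <- compareTwoGroups(b, a)
  expect_equal(r3@pValue, r2@pValue)
  expect_equal(r3@statistic, -r2@statistic)
  expect_error(compareTwoGroups(1, 1:5), "n >= 2")
})

test_that("morphometry ANOVA on log values is null-calibrated, powered for
           the reported thickness effect, and scale-invariant", {
  set.seed(11)
  g <- list(WT = rlnorm(50, 0, 0.2), KO = rlnorm(50, 0, 0.2),
            RES = rlnorm(50, 0, 0.2))
  null <- compareMorphometry(g)
  expect_gt(null@pValue, 0.05)
  expect_true(all(null@tukey$p_adj > 0.05))
  ## power: means 0.071 / 0.078 / 0.070 um at cv 5%, n = 100
  hits <- 0
  for (s in 1:50) {
    params <- defaultMorphometryParams()
    for (gname in names(params))
      params[[gname]]$endothelial_thickness_um["cv"] <- 0.05
    tab <- generateMorphometryTable(params, nPerGroup = 100, seed = s)
    th <- tab[tab$measure == "endothelial_thickness_um", ]
    res <- compareMorphometry(split(th$value, th$group))
    p <- res@tukey$p_adj[grepl("WT", res@tukey$contrast) &
                           grepl("ApoM_KO($|-)", res@tukey$contrast) &
                           !grepl("SEW", res@tukey$contrast)]
    if (length(p) && p < 0.05) hits <- hits + 1
  }
  expect_gte(hits / 50, 0.8)
  ## multiplicative rescaling leaves the log-ANOVA invariant
  sc <- lapply(g, function(x) 1000 * x)
  expect_equal(compareMorphometry(sc)@pValue, null@pValue, tolerance = 1e-9)
  expect_error(compareMorphometry(list(a = c(1, -1, 2), b = c(1, 2, 3))),
               "non-positive")
})

test_that("percent difference and fold ratio reproduce simple arithmetic", {
  ## endothelial thickness: (0.078 - 0.071)/0.071 -> ~10% increase
  expect_equal(percentDifference(0.078, 0.071), 9.859155, tolerance = 1e-6)
  expect_equal(percentDifference(5, 5), 0)
  expect_equal(percentDifference(2, 1), 100)
  expect_error(percentDifference(1, 0), "> 0")
  ## penetrating vs pial density ratio: 0.30 / 0.099 -> ~3x
  expect_equal(foldRatio(0.30, 0.099), 3.030303, tolerance = 1e-6)
  expect_equal(foldRatio(4, 4), 1)
  expect_equal(foldRatio(3, 7) * foldRatio(7, 3), 1)
  expect_error(foldRatio(1, 0), "> 0")
})
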
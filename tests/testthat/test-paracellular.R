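test_that("background subtraction is exact, clips at zero with a count, and
           warns on implausible levels", {
  tr <- IntensityTrace(1:3, c(5, 8, 11))
  expect_equal(subtractBackground(tr, 0)@values, tr@values)
  expect_equal(subtractBackground(IntensityTrace(1:3, rep(10, 3)), 10)@values,
               rep(0, 3))
  res <- suppressMessages(subtractBackground(IntensityTrace(1:2, c(5, 8)), 6))
  expect_equal(res@values, c(0, 2))
  expect_equal(attr(res, "nClipped"), 1L)
  expect_warning(subtractBackground(IntensityTrace(1:3, c(5, 6, 105)), 60),
                 "dynamic range")
})

test_that("exponential fits recover generating parameters to 1e-4 and handle
           the degenerate constant case", {
  t <- seq(0, 30, by = 1)
  y <- 0 + 2 * (1 - exp(-0.05 * t))
  fit <- fitExponential(IntensityTrace(t, y), "saturating_growth")
  expect_lt(abs(fit@a - 0) , 1e-4)
  expect_lt(abs(fit@b - 2) / 2, 1e-4)
  expect_lt(abs(fit@c - 0.05) / 0.05, 1e-4)
  expect_lt(fit@rmse, 1e-8)
  ## decay: a=1, b=5, c=0.1; extrapolated value at t=60 is 1 + 5 e^-6
  yd <- 1 + 5 * exp(-0.1 * t)
  fd <- fitExponential(IntensityTrace(t, yd), "decay")
  expect_lt(abs(fd@c - 0.1) / 0.1, 1e-4)
  expect_equal(extrapolateFit(fd, 60), 1 + 5 * exp(-6), tolerance = 1e-4)
  expect_equal(1 + 5 * exp(-6), 1.012394, tolerance = 1e-6)
  ## constant data: a = value, b = 0, fit evaluates to the constant
  fc <- fitExponential(IntensityTrace(t, rep(3.5, length(t))), "decay")
  expect_equal(fc@a, 3.5)
  expect_equal(fc@b, 0)
  expect_equal(extrapolateFit(fc, c(0, 100)), c(3.5, 3.5))
  expect_error(fitExponential(IntensityTrace(1:4, 1:4)), "5 timepoints")
})

test_that("extrapolation honors the closed forms and their limits", {
  fg <- new("ExponentialFit", model = "saturating_growth", a = 1, b = 2,
            c = 0.5, rmse = 0, window = c(0, 30), fallback = FALSE)
  ## matches fitted values inside the window
  expect_equal(extrapolateFit(fg, c(0, 10)), 1 + 2 * (1 - exp(-0.5 * c(0, 10))))
  ## asymptote a + b
  expect_equal(extrapolateFit(fg, 1e6), 3, tolerance = 1e-12)
  fd0 <- new("ExponentialFit", model = "decay", a = 1.5, b = 2.5, c = 0,
             rmse = 0, window = c(0, 30), fallback = FALSE)
  expect_equal(extrapolateFit(fd0, c(5, 500)), c(4, 4))
})

test_that("sequential decoupling leaves a single tracer unchanged and
           cancels a constructed pure-continuation trace", {
  t1 <- seq(1, 31)
  y1 <- 3 * (1 - exp(-0.08 * (t1 - 1)))
  tr1 <- IntensityTrace(t1, y1)
  one <- decoupleSequential(list(A = tr1))
  expect_identical(one$corrected$A@values, y1)
  expect_length(one$correctionFits$A, 0)
  ## tracer 2 with zero own leak: exactly the continuation of tracer 1
  t2 <- seq(33, 63)
  y2 <- 3 * (1 - exp(-0.08 * (t2 - 1)))
  dec <- decoupleSequential(list(A = tr1, B = IntensityTrace(t2, y2)))
  plateau <- 3
  expect_lt(abs(mean(dec$corrected$B@values)), 0.02 * plateau)
  expect_length(dec$correctionFits$B, 1)
  ## overlapping windows are rejected
  expect_error(decoupleSequential(list(A = tr1,
                                       B = IntensityTrace(t1 + 5, y1))),
               "non-overlapping")
})

test_that("blood clearance fits recover the decay rate and normalization is
           gain-invariant", {
  t <- seq(1, 31)
  blood <- IntensityTrace(t, 100 * exp(-0.02 * (t - 1)), compartment = "blood")
  res <- bloodClearanceFit(blood)
  expect_lt(abs(res$fit@c - 0.02) / 0.02, 0.01)
  expect_equal(res$normalized@values[1], 1)
  ## constant blood: normalized all ones, c = 0
  cres <- bloodClearanceFit(IntensityTrace(t, rep(40, 31), compartment = "blood"))
  expect_equal(cres$normalized@values, rep(1, 31))
  expect_equal(cres$fit@c, 0)
  ## gain invariance
  g <- bloodClearanceFit(IntensityTrace(t, 7 * blood@values, compartment = "blood"))
  expect_equal(g$normalized@values, res$normalized@values, tolerance = 1e-12)
  expect_warning(
    bloodClearanceFit(IntensityTrace(t, seq(10, 40, length.out = 31),
                                     compartment = "blood")),
    "increases")
})

test_that("AUC integrates trapezoidally over the requested window and is
           linear", {
  t <- seq(0, 30)
  expect_equal(computeAuc(IntensityTrace(t, rep(0, 31)), c(0, 30)), 0)
  expect_equal(computeAuc(IntensityTrace(t, rep(0.5, 31)), c(0, 30)), 15)
  ## linear ramp 0 -> 1: trapezoid is exact
  ramp <- IntensityTrace(t, t / 30)
  expect_equal(computeAuc(ramp, c(0, 30)), 15)
  expect_error(computeAuc(ramp, c(0, 45)), "not covered")
  ## linearity on a shared grid
  set.seed(3)
  x <- runif(31); y <- runif(31)
  expect_equal(computeAuc(IntensityTrace(t, 2 * x + 3 * y), c(0, 30)),
               2 * computeAuc(IntensityTrace(t, x), c(0, 30)) +
                 3 * computeAuc(IntensityTrace(t, y), c(0, 30)))
})

test_that("the leak-rate estimator is exact on noiseless data, zero for
           zero leak, and linear in the parenchymal signal", {
  t <- seq(1, 31)
  lam <- 0.1; C0 <- 100; k <- 0.01
  B <- C0 * exp(-lam * t)
  P <- k * C0 / lam * (1 - exp(-lam * t))
  pt <- IntensityTrace(t, P)
  bt <- IntensityTrace(t, B, compartment = "blood")
  khat <- estimateLeakRate(pt, bt, injectionTimeMin = 0)
  expect_lt(abs(khat - k) / k, 0.01)
  k0 <- estimateLeakRate(IntensityTrace(t, rep(0, 31)), bt,
                         injectionTimeMin = 0)
  expect_lt(abs(k0), 1e-6)
  k2 <- estimateLeakRate(IntensityTrace(t, 2 * P), bt, injectionTimeMin = 0)
  expect_equal(k2, 2 * khat, tolerance = 1e-9)
  expect_error(estimateLeakRate(pt, IntensityTrace(t, rep(0, 31),
                                                   compartment = "blood")),
               "all zero")
})

test_that("noiseless AUC increases strictly with the leak rate", {
  ks <- c(0.002, 0.005, 0.01, 0.02)
  aucs <- vapply(ks, function(k) {
    rs <- runParacellularSession(singleTruth(k = k), singleSchedule(),
                                 treeConfig = smallTreeConfig(nz = 1),
                                 seed = 6, noise = FALSE)
    rs$analysis$results[[1]]@aucMin
  }, numeric(1))
  expect_true(all(diff(aucs) > 0))
})
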
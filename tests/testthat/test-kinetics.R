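test_that("RIA statistics follow the chemistry-specific definitions", {
  expect_equal(riaAA(c("0" = 55, "6" = 45)), 0.45)
  expect_equal(riaAA(c("0" = 100, "6" = 0)), 0)
  expect_equal(riaAA(c("0" = 0, "6" = 100)), 1)
  expect_warning(expect_true(is.na(riaAA(c("0" = 0, "6" = 0)))))

  expect_equal(riaHW(setNames(c(100, 0, 0, 0, 0, 0), 0:5)), 1)
  expect_equal(riaHW(setNames(c(50, 25, 15, 5, 3, 2), 0:5)), 0.5)
  expect_equal(riaHW(setNames(rep(7, 6), 0:5)), 1 / 6)
  expect_warning(expect_true(is.na(riaHW(setNames(rep(0, 6), 0:5)))))
})

test_that("one-compartment curve hits its boundary values and half-rise", {
  expect_equal(oneCompartmentA(0, 0.1, 0.2, 0.8), 0.2)
  expect_equal(oneCompartmentA(log(2) / 0.1, 0.1, 0, 0.45), 0.225)
  expect_lt(abs(oneCompartmentA(20 / 0.1, 0.1, 0, 0.45) - 0.45),
            1e-8 * 0.45)
  ## decreasing (heavy water) direction
  expect_equal(oneCompartmentA(log(2) / 0.3, 0.3, 0.5, 0.3), 0.4)
})

test_that("two-compartment curve handles limits and the k = kp singularity", {
  expect_equal(twoCompartmentA(0, 0.7, 0.3, 0.1, 0.9), 0.1)
  ## near-instantaneous precursor: equals one-compartment within 1e-3 at
  ## every sampling day (the sub-day transient is below the first sample)
  t <- 0:31
  for (k in c(0.01, 0.1, 1)) {
    rel <- max(abs(twoCompartmentA(t, k, 600, 0, 0.45) -
                     oneCompartmentA(t, k, 0, 0.45))) / 0.45
    expect_lt(rel, 1e-3)
  }
  ## removable singularity: limit value and epsilon cross-check
  lim <- twoCompartmentA(2, 0.5, 0.5, 0, 1)
  expect_equal(lim, 1 - 2 * exp(-1), tolerance = 1e-12)
  expect_equal(twoCompartmentA(2, 0.5, 0.5 * (1 + 1e-7), 0, 1), lim,
               tolerance = 1e-6)
  expect_equal(twoCompartmentA(2, 0.5, 0.5 * (1 - 1e-7), 0, 1), lim,
               tolerance = 1e-6)
})

test_that("two-compartment converges uniformly to one-compartment as kp grows", {
  ## closed form of the gap: two - one = D * k/(kp-k) * (e^{-kp t} - e^{-kt}),
  ## whose sup over t is D * k/(kp-k) * (e^{-k t*} - e^{-kp t*}) at
  ## t* = log(kp/k)/(kp - k); so the sup-norm shrinks as ~D/ratio
  t <- seq(0, 30, by = 0.01)
  D <- 0.45
  for (k in c(0.002, 0.05, 1)) {
    for (ratio in c(6000, 60000)) {
      kp <- ratio * k
      supDiff <- max(abs(twoCompartmentA(t, k, kp, 0, D) -
                           oneCompartmentA(t, k, 0, D)))
      tStar <- log(kp / k) / (kp - k)
      oracle <- D * k / (kp - k) * (exp(-k * tStar) - exp(-kp * tStar))
      expect_equal(supDiff, oracle, tolerance = 1e-3)
      expect_lte(supDiff, D * k / (kp - k) * (1 + 1e-12))
    }
    ## uniform convergence: one decade in kp is one decade in the gap
    sup1 <- max(abs(twoCompartmentA(t, k, 6000 * k, 0, D) -
                      oneCompartmentA(t, k, 0, D)))
    sup2 <- max(abs(twoCompartmentA(t, k, 60000 * k, 0, D) -
                      oneCompartmentA(t, k, 0, D)))
    expect_lt(sup2, sup1 / 9)
    expect_lt(sup2, 2e-5 * D)
  }
})

test_that("convolution model reduces to closed forms and matches quadrature", {
  t <- seq(0, 30, by = 0.5)
  ## single-exponential precursor: identical to the two-compartment curve
  for (kp in c(0.1, 0.5, 6)) {
    pf <- precursorFunction("single_exponential", kp = kp, plateau = 1)
    expect_lt(max(abs(convolutionA(t, 0.7, pf, 0, 1) -
                        twoCompartmentA(t, 0.7, kp, 0, 1))), 1e-12)
  }
  ## bi-exponential with both rates equal degenerates to a single rate:
  ## r -> infinity collapses the model to rate b
  pfBig <- precursorFunction("two_exponential", a = 0.12, b = 0.84,
                             r = 1e9, plateau = 1)
  expect_lt(max(abs(convolutionA(t, 0.3, pfBig, 0, 1) -
                      twoCompartmentA(t, 0.3, 0.84, 0, 1))), 1e-6)
  ## adaptive quadrature oracle for the bi-exponential precursor
  pf2 <- precursorFunction("two_exponential", a = 0.12, b = 0.84, r = 9.08,
                           plateau = 1)
  for (tt in c(1, 7, 20)) {
    num <- 0.3 * stats::integrate(function(tau)
      evalPrecursor(pf2, tau) * exp(-0.3 * (tt - tau)), 0, tt,
      rel.tol = 1e-12)$value
    expect_equal(convolutionA(tt, 0.3, pf2, 0, 1), num, tolerance = 1e-8)
  }
  ## instantaneous precursor: the one-compartment curve
  pfi <- precursorFunction("instantaneous", plateau = 1)
  expect_equal(convolutionA(t, 0.2, pfi, 0, 0.45),
               oneCompartmentA(t, 0.2, 0, 0.45), tolerance = 1e-12)
})

test_that("model curves are monotone between A0 and Ainf", {
  t <- seq(0, 40, by = 0.1)
  pf <- precursorFunction("single_exponential", kp = 0.4, plateau = 1)
  for (bounds in list(c(0, 0.45), c(0.55, 0.31))) {
    for (curve in list(
      oneCompartmentA(t, 0.3, bounds[1], bounds[2]),
      twoCompartmentA(t, 0.3, 0.4, bounds[1], bounds[2]),
      convolutionA(t, 0.3, pf, bounds[1], bounds[2]))) {
      fs <- fractionalSynthesis(curve, bounds[1], bounds[2])
      expect_true(all(diff(fs) >= -1e-12))
      expect_true(all(fs >= -1e-12 & fs <= 1 + 1e-12))
    }
  }
})

test_that("kdeg is recovered to 4 significant figures on noise-free series", {
  for (k in c(0.002, 0.02, 0.29, 1, 2)) {
    f1 <- fitKdeg(makeAaSeries(k))
    expect_lt(abs(kdeg(f1) - k) / k, 1e-4)
    expect_equal(rSquared(f1), 1, tolerance = 1e-9)
    f2 <- fitKdeg(makeAaSeries(k, kp = 0.5), "two_compartment", kp = 0.5)
    expect_lt(abs(kdeg(f2) - k) / k, 1e-4)
  }
  ## heavy-water direction (decreasing A)
  days <- hwDays
  A <- oneCompartmentA(days, 0.15, 0.52, 0.33)
  s <- riaTimeSeries(days, A, 0.52, 0.33, chemistry = "HW")
  expect_lt(abs(kdeg(fitKdeg(s)) - 0.15) / 0.15, 1e-4)
})

test_that("ignoring precursor delay underestimates kdeg, worse at lower kp", {
  for (k in c(0.01, 0.1, 1)) {
    fitted <- vapply(c(600, 6, 0.5, 0.1), function(kp)
      kdeg(fitKdeg(makeAaSeries(k, kp = kp), "one_compartment")), numeric(1))
    expect_true(all(fitted[-1] < k))       # delayed precursor: biased low
    expect_true(all(diff(fitted) < 0))     # bias grows as kp decreases
  }
})

test_that("degenerate constant series is flagged with no signal", {
  s <- riaTimeSeries(aaDays, rep(0, length(aaDays)), 0, 0.45)
  f <- fitKdeg(s)
  expect_lte(kdeg(f), 1e-4)
  expect_match(f@flag, "no_signal|at_bound")
  expect_true(is.na(rSquared(f)))
})

test_that("fitting error follows first-order propagation at t = 1/k", {
  s <- makeAaSeries(0.1)
  f <- fitKdeg(s)
  f@sigmaA <- 0.01
  expect_equal(fitErrorDk(f), 0.1 * exp(1) * 0.01 / 0.45,
               tolerance = 1e-10)
  ## zero residual: zero error
  f@sigmaA <- 0
  expect_equal(fitErrorDk(f), 0)
  ## two-compartment dk converges to the one-compartment dk as kp grows
  f2 <- fitKdeg(makeAaSeries(0.1, kp = 1e6 * 0.1), "two_compartment",
                kp = 1e6 * 0.1)
  f2@sigmaA <- 0.01
  expect_equal(fitErrorDk(f2), 0.1 * exp(1) * 0.01 / 0.45,
               tolerance = 1e-4)
})

test_that("R-squared equals 1 - SSE/SST and is floored at zero", {
  ## perfect fit
  expect_equal(rSquared(fitKdeg(makeAaSeries(0.2))), 1, tolerance = 1e-9)
  ## noisy series: recompute 1 - SSE/SST by hand
  set.seed(42)
  A <- oneCompartmentA(aaDays, 0.2, 0, 0.45) + rnorm(length(aaDays), 0, 0.02)
  s <- riaTimeSeries(aaDays, pmin(pmax(A, 0), 1), 0, 0.45)
  f <- fitKdeg(s)
  pred <- oneCompartmentA(s@t, kdeg(f), 0, 0.45)
  sse <- sum((s@A - pred)^2)
  sst <- sum((s@A - mean(s@A))^2)
  expect_equal(rSquared(f), 1 - sse / sst, tolerance = 1e-8)
  expect_equal(f@sse, sse, tolerance = 1e-10)
  expect_equal(sigmaA(f), sqrt(sse / (length(s@t) - 1)), tolerance = 1e-10)
})

test_that("Akaike weights normalize relative model likelihoods", {
  mkFit <- function(aicv) new("KineticFit", kdeg = 0.1, dk = 0,
    sigmaA = 0.01, r2 = 0.9, r2raw = 0.9, sse = 1, nPoints = 10L,
    modelId = "one_compartment", kp = NA_real_, precursor = NULL, A0 = 0,
    Ainf = 0.45, logL = 0, aic = aicv, converged = TRUE, flag = "")
  expect_equal(aicWeights(list(mkFit(12), mkFit(12))), c(0.5, 0.5))
  w <- aicWeights(list(mkFit(0), mkFit(20)))
  expect_equal(w[2], exp(-10) / (1 + exp(-10)), tolerance = 1e-10)
  expect_equal(w[1], 0.99995, tolerance = 1e-4)
  expect_equal(aicWeights(list(mkFit(5))), 1)
  badN <- mkFit(5); badN@nPoints <- 9L
  expect_error(aicWeights(list(mkFit(5), badN)), "different numbers")
})

test_that("fractional synthesis rescales both chemistries to [0, 1]", {
  expect_equal(fractionalSynthesis(0, 0, 0.45), 0)
  expect_equal(fractionalSynthesis(0.45, 0, 0.45), 1)
  expect_equal(fractionalSynthesis(0.4, 0.5, 0.3), 0.5)  # HW direction
  expect_error(fractionalSynthesis(0.4, 0.3, 0.3), "A0 == Ainf")
})

test_that("half-life and measurable-range conversions are correct", {
  expect_equal(signif(halfLife(c(0.01, 0.1, 1)), 2), c(69, 6.9, 0.69))
  rng <- measurableKdegRange(c(1, 2, 3, 4, 8, 10, 13, 16, 20, 32))
  expect_equal(signif(rng[["upper"]], 1), 1)
  expect_equal(rng[["upper"]], log(20) / 3, tolerance = 1e-12)
  expect_equal(rng[["lower"]], log(1 / 0.95) / 32, tolerance = 1e-12)
})
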
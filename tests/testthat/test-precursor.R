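test_that("MIDA inverts the binomial forward map exactly", {
  expect_equal(midaPrecursorRia(100, 0), 0)
  expect_equal(midaPrecursorRia(100, 25), 1 / 3)
  expect_equal(midaPrecursorRia(50, 50), 2 / 3)
  expect_equal(midaPrecursorRia(100, 50), 0.5)
  expect_true(is.na(midaPrecursorRia(0, 10)))
  expect_true(is.na(midaPrecursorRia(0, 0)))
  ## forward binomial at p: m6 : m12 = 2p(1-p) : p^2, inverted exactly,
  ## invariant to abundance scaling
  for (p in seq(0.05, 0.95, by = 0.05)) {
    for (scale in c(1, 3e7)) {
      expect_equal(midaPrecursorRia(scale * 2 * p * (1 - p), scale * p^2),
                   p, tolerance = 1e-12)
    }
  }
})

test_that("one-pass weighted fit recovers precursor kinetics", {
  ## noise-free points on the exponential rise, 12 dilysine peptides
  mkObs <- function(kp, riap, nPep = 12, noise = 0) {
    set.seed(17)
    do.call(rbind, lapply(seq_len(nPep), function(i) {
      p <- riap * (1 - exp(-kp * aaDays[-1])) +
        if (noise > 0) rnorm(length(aaDays) - 1, 0, noise) else 0
      data.frame(sequence = sprintf("PEPKTIDEK%02d", i), charge = 2L,
                 tissue = "liver", day = aaDays[-1], p = pmax(p, 0),
                 intensity = 10^runif(length(aaDays) - 1, 5, 7))
    }))
  }
  obs <- mkObs(0.5, 0.45)
  est <- kkOnePassFit(obs)
  expect_equal(unname(precursorFn(est)@parameters["kp"]), 0.5,
               tolerance = 1e-3)
  expect_equal(precursorFn(est)@plateau, 0.45, tolerance = 1e-3)

  ## equal weights reduce to the unweighted fit
  obsEq <- obs; obsEq$intensity <- 1
  estEq <- kkOnePassFit(obsEq)
  fitU <- minpack.lm::nlsLM(p ~ RIAp * (1 - exp(-kp * day)), data = obsEq,
                            start = list(kp = 0.5, RIAp = 0.4))
  expect_equal(unname(precursorFn(estEq)@parameters["kp"]),
               coef(fitU)[["kp"]], tolerance = 1e-6)

  ## out-of-range RIA points are excluded and counted
  obsHi <- obs; obsHi$p[1:5] <- 0.75
  estHi <- kkOnePassFit(obsHi)
  expect_equal(unname(estHi@details$excluded["ria_out_of_range"]), 5)
  expect_error(kkOnePassFit(obs[obs$day == 1, ]), "2 distinct")
})

test_that("KDE mode locates the dominant precursor RIA population", {
  expect_equal(kkKdeMode(rep(0.4, 10)), 0.4)
  set.seed(5)
  v <- c(rnorm(80, 0.40, 0.01), rnorm(20, 0.10, 0.01))
  expect_lt(abs(kkKdeMode(v) - 0.40), 0.02)
  ## symmetric unimodal sample: mode near the median, within a bandwidth
  set.seed(6)
  u <- rnorm(200, 0.3, 0.02)
  bw <- sd(u) * length(u)^(-1 / 5)
  expect_lt(abs(kkKdeMode(u) - median(u)), bw)
})

test_that("median per-peptide kp summarizes dilysine series", {
  mkSeries <- function(kp, seqc) data.frame(
    sequence = seqc, charge = 2L, tissue = "heart", day = aaDays[-1],
    p = 0.4 * (1 - exp(-kp * aaDays[-1])), intensity = 1e6)
  obs <- rbind(mkSeries(0.1, "AAKBBKAAA"), mkSeries(0.3, "CCKDDKCCC"),
               mkSeries(0.5, "EEKFFKEEE"))
  est <- kkMedianKp(obs)
  expect_equal(unname(precursorFn(est)@parameters["kp"]), 0.3,
               tolerance = 1e-4)
  ## identical truths: the median is that truth
  obsSame <- rbind(mkSeries(0.3, "A1"), mkSeries(0.3, "A2"),
                   mkSeries(0.3, "A3"))
  obsSame$sequence <- rep(c("AAKBBK", "CCKDDK", "EEKFFK"), each = 10)
  expect_equal(unname(precursorFn(kkMedianKp(obsSame))@parameters["kp"]),
               0.3, tolerance = 1e-4)
  ## seeded noisy recovery within 15%
  set.seed(23)
  obsN <- do.call(rbind, lapply(1:15, function(i) {
    d <- mkSeries(0.3, sprintf("AAK%02dBBK", i))
    d$p <- pmax(d$p + rnorm(nrow(d), 0, 0.02), 0)
    d
  }))
  estN <- kkMedianKp(obsN)
  expect_lt(abs(precursorFn(estN)@parameters[["kp"]] - 0.3) / 0.3, 0.15)
})

test_that("two-exponent precursor model is recovered and preferred on
           reutilization-shaped data", {
  pf <- precursorFunction("two_exponential", a = 0.12, b = 0.84, r = 9.08,
                          plateau = 0.5)
  tt <- rep(c(0.5, 1, 2, 3, 4, 6, 9, 12, 17, 22, 30), each = 3)
  obs <- data.frame(day = tt, p = precursorEnrichment(pf, tt),
                    intensity = 1, tissue = "heart")
  est <- twoExponentPrecursorFit(obs)
  pars <- precursorFn(est)@parameters
  expect_equal(unname(pars["a"]), 0.12, tolerance = 0.01)
  expect_equal(unname(pars["b"]), 0.84, tolerance = 0.01)
  expect_equal(unname(pars["r"]), 9.08, tolerance = 0.01)
  ## model comparison on bi-exponential truth: near-unit Akaike weight
  expect_gt(est@details$aicWeights[["two_exponent"]], 0.99)

  ## r -> infinity (no reutilization): single exponential at rate b
  pf1 <- precursorFunction("single_exponential", kp = 0.8, plateau = 0.5)
  obs1 <- data.frame(day = tt, p = precursorEnrichment(pf1, tt),
                     intensity = 1)
  est1 <- twoExponentPrecursorFit(obs1)
  expect_equal(est1@details$kpSingle, 0.8, tolerance = 1e-3)
  mx <- twoExponentRates(precursorFn(est1)@parameters["a"],
                         precursorFn(est1)@parameters["b"],
                         precursorFn(est1)@parameters["r"])
  ## fitted bi-exponential collapses onto the generating single curve
  curveFit <- 0.5 * (1 - mx$c[1] * exp(-mx$mu[1] * aaDays) -
                       mx$c[2] * exp(-mx$mu[2] * aaDays))
  expect_lt(max(abs(curveFit - precursorEnrichment(pf1, aaDays))), 1e-3)
  expect_error(twoExponentPrecursorFit(obs[obs$day < 2, ]), "4 distinct")
})

test_that("nested kp optimization finds slow-equilibration precursor rates
           and degrades honestly on fast tissues", {
  set.seed(2)
  mkser <- function(k, kp) riaTimeSeries(
    aaDays, twoCompartmentA(aaDays, k, kp, 0, 0.45), 0, 0.45)
  ## slow tissue: kdeg spread below the true kp = 0.3
  slow <- lapply(exp(runif(25, log(0.01), log(0.3))), mkser, kp = 0.3)
  resSlow <- nestedKpOptimization(slow, seq(0.05, 1, 0.05))
  expect_equal(resSlow$kp, 0.3, tolerance = 1e-9)
  expect_lt(resSlow$objective$medianSSE[resSlow$objective$kp == 0.3],
            resSlow$baseline)
  ## noise-free objective is minimized exactly at a grid point on the truth
  expect_equal(resSlow$objective$kp[which.min(resSlow$objective$medianSSE)],
               0.3)
  expect_error(nestedKpOptimization(slow, numeric(0)), "empty")

  ## fast-equilibration tissue (precursor effectively instantaneous
  ## relative to turnover) with noise: the kp objective loses its interior
  ## minimum and flattens out at high kp -- the identifiability failure
  set.seed(3)
  kdFast <- exp(runif(25, log(0.01), log(0.05)))
  fast <- lapply(kdFast, function(k) {
    A <- oneCompartmentA(aaDays, k, 0, 0.45) +
      rnorm(length(aaDays), 0, 0.009)
    riaTimeSeriesClamped <- pmin(pmax(A, 0), 1)
    riaTimeSeries(aaDays, riaTimeSeriesClamped, 0, 0.45)
  })
  grid <- c(seq(0.1, 1, 0.3), seq(2, 10, 1))
  resFast <- nestedKpOptimization(fast, grid)
  o <- resFast$objective
  ## no meaningful improvement over the one-compartment baseline
  gain <- (resFast$baseline - min(o$medianSSE)) / resFast$baseline
  expect_lt(gain, 0.05)
  ## the objective collapses onto the baseline at high kp: the top of the
  ## grid is two orders of magnitude flatter than the full range
  regionHi <- o$kp > 100 * max(kdFast)
  relHi <- diff(range(o$medianSSE[regionHi])) / mean(o$medianSSE[regionHi])
  relAll <- diff(range(o$medianSSE)) / mean(o$medianSSE)
  expect_lt(relHi, 0.05)
  expect_lt(relHi, relAll / 20)
  ## and the high-kp plateau sits at the baseline level
  expect_lt(abs(mean(o$medianSSE[regionHi]) - resFast$baseline) /
              resFast$baseline, 0.05)
})

test_that("heavy-water reference calibration locates the generating cell", {
  set.seed(4)
  nPep <- 40
  kd <- exp(runif(nPep, log(0.05), log(1)))
  pool <- setdiff(names(commerfordSites()), c("K", "R"))
  seqs <- vapply(seq_len(nPep), function(i)
    paste(c(sample(pool, 9, TRUE), "K"), collapse = ""), character(1))
  aaIso <- do.call(rbind, lapply(seq_len(nPep), function(i) {
    A <- twoCompartmentA(aaDays, kd[i], 0.5, 0, 0.45)
    do.call(rbind, lapply(seq_along(aaDays), function(j) data.frame(
      sequence = seqs[i], charge = 2L, tissue = "liver", day = aaDays[j],
      iso = c(0L, 6L), auc = c(1 - A[j], A[j]) * 1e6,
      proteins = sprintf("P%02d", i), nProteins = 1L)))
  }))
  aaBuilt <- buildRiaSeries(aaIso, labelingConfig("AA"))
  hwRef <- data.frame(sequence = seqs, charge = 2L, kdeg = kd)
  cal <- hwReferenceCalibration(aaBuilt, hwRef,
                                riaGrid = seq(0.35, 0.55, 0.05),
                                kpGrid = seq(0.3, 0.7, 0.1))
  expect_equal(unname(cal$argmin["riap"]), 0.45)
  expect_equal(unname(cal$argmin["kp"]), 0.5)
  ## identical kdeg sets: zero difference at the generating cell
  expect_lt(cal$diff["0.45", "0.5"], 1e-6)
  ## log-log slope at the argmin within 0.05 of unity
  expect_lt(abs(cal$slope["0.45", "0.5"] - 1), 0.05)
  expect_error(hwReferenceCalibration(aaBuilt, hwRef[1:5, ],
                                      seq(0.4, 0.5, 0.05),
                                      seq(0.4, 0.6, 0.1)),
               "shared")
})

test_that("secreted reporters estimate precursor kinetics from pooled
           fractional synthesis", {
  set.seed(6)
  mkFs <- function(kp, noise = 0.02) do.call(rbind, lapply(1:6, function(i)
    data.frame(sequence = sprintf("MUPPEPT%dK", i), charge = 2L,
               tissue = "liver", t = aaDays,
               fs = pmin(pmax(1 - exp(-kp * aaDays) +
                                rnorm(length(aaDays), 0, noise), 0), 1))))
  est <- secretedProteinKp(mkFs(0.49), minTimepoints = 10)
  kpHat <- precursorFn(est)@parameters[["kp"]]
  expect_lt(abs(kpHat - 0.49) / 0.49, 0.05)
  expect_false(est@details$lowerBoundOnly)

  ## labeling faster than the sampling grid: flagged as lower bound only
  estFast <- secretedProteinKp(mkFs(2, noise = 0.01), minTimepoints = 10)
  expect_true(estFast@details$lowerBoundOnly)

  ## single peptide: identical to fitting its own FS series
  one <- mkFs(0.49)[1:length(aaDays), ]
  estOne <- secretedProteinKp(one, minTimepoints = 10)
  direct <- fitRatePoints(one$t, one$fs, 0, 1, "one_compartment")
  expect_equal(precursorFn(estOne)@parameters[["kp"]], kdeg(direct),
               tolerance = 1e-9)
  expect_error(secretedProteinKp(mkFs(0.49)[1:3, ], minTimepoints = 10),
               "no qualifying")
})
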
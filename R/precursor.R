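## Precursor enrichment kinetics: evaluation and the estimation strategies
## (dilysine mass-isotopomer analysis, nested optimization, heavy-water
## reference calibration, secreted-reporter fitting).

#' Evaluate a precursor function
#'
#' `evalPrecursor` returns the normalized rise `f(t)` in `[0, 1]`;
#' `precursorEnrichment` the absolute enrichment `plateau * f(t)`. The
#' instantaneous kind returns 0 at `t = 0` and 1 (resp. the plateau) for
#' `t > 0`.
#'
#' @param pf A [PrecursorFunction-class].
#' @param t Time in days (vectorized).
#' @return Numeric vector.
#' @export
evalPrecursor <- function(pf, t) {
  switch(pf@kind,
    instantaneous = as.numeric(t > 0),
    single_exponential = 1 - exp(-unname(pf@parameters["kp"]) * t),
    two_exponential = {
      mx <- twoExponentRates(pf@parameters["a"], pf@parameters["b"],
                             pf@parameters["r"])
      1 - mx$c[1] * exp(-mx$mu[1] * t) - mx$c[2] * exp(-mx$mu[2] * t)
    })
}

#' @rdname evalPrecursor
#' @export
precursorEnrichment <- function(pf, t) pf@plateau * evalPrecursor(pf, t)

#' Precursor RIA from dilysine mass isotopomer analysis
#'
#' Among newly synthesized peptides with two lysines, the number of heavy
#' lysines is binomial(2, p) in the precursor RIA p, so the doubly to singly
#' labeled intensity ratio is `m12/m6 = p / (2 (1 - p))`. Inverting,
#' `p = 2 q / (1 + 2 q)` with `q = m12/m6`.
#'
#' @param m6 Area of the single heavy-lysine (heavy-light) isotopomer.
#' @param m12 Area of the double heavy-lysine (heavy-heavy) isotopomer.
#' @return Estimated precursor RIA p; `NA` when `m6` is 0.
#' @export
#' @examples
#' midaPrecursorRia(100, 25)  # 1/3
midaPrecursorRia <- function(m6, m12) {
  p <- rep(NA_real_, length(m6))
  ok <- m6 > 0 & m12 >= 0
  q <- m12[ok] / m6[ok]
  p[ok] <- 2 * q / (1 + 2 * q)
  if (length(p) == 1) p[[1]] else p
}

#' Dilysine observations from a tidy isotopomer table
#'
#' Selects peptide-charge series whose sequence carries exactly two lysines
#' and computes the MIDA precursor RIA at each time point.
#'
#' @param isoTable Tidy isotopomer table (needs iso indices 6 and 12).
#' @return data.frame with columns `sequence`, `charge`, `tissue`, `day`,
#'   `m6`, `m12`, `p`, `intensity` (total isotopomer area at that time
#'   point). Rows with undefined p are kept as `NA` for bookkeeping.
#' @export
dilysineObservations <- function(isoTable) {
  nK <- vapply(strsplit(isoTable$sequence, ""), function(x) sum(x == "K"),
               numeric(1))
  tab <- isoTable[nK == 2, , drop = FALSE]
  if (nrow(tab) == 0)
    return(data.frame(sequence = character(0), charge = integer(0),
                      tissue = character(0), day = numeric(0),
                      m6 = numeric(0), m12 = numeric(0), p = numeric(0),
                      intensity = numeric(0)))
  key <- interaction(tab$sequence, tab$charge, tab$tissue, tab$day,
                     drop = TRUE)
  rows <- lapply(split(tab, key), function(sub) {
    areas <- stats::setNames(sub$auc, sub$iso)
    m6 <- unname(.area(areas, 6)); m12 <- unname(.area(areas, 12))
    data.frame(sequence = sub$sequence[1], charge = sub$charge[1],
               tissue = sub$tissue[1], day = sub$day[1], m6 = m6, m12 = m12,
               p = midaPrecursorRia(m6, m12), intensity = sum(sub$auc),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$sequence, out$charge, out$day), ]
}

.filterDilysine <- function(obs, minTimepoints, riaRange) {
  ok <- is.finite(obs$p)
  key <- paste(obs$sequence, obs$charge)
  counts <- tapply(obs$day[ok], key[ok], function(d) length(unique(d)))
  qualif <- names(counts)[counts >= minTimepoints]
  excludedPeptides <- length(unique(key)) - length(qualif)
  obs <- obs[key %in% qualif & ok, , drop = FALSE]
  inRange <- obs$p >= riaRange[1] & obs$p <= riaRange[2]
  list(obs = obs[inRange, , drop = FALSE],
       excluded = c(peptides_min_timepoints = excludedPeptides,
                    ria_out_of_range = sum(!inRange)))
}

#' One-pass weighted exponential fit of dilysine precursor RIA
#'
#' Pools all qualifying dilysine RIA values of a tissue (peptides with at
#' least `minTimepoints` quantified time points; RIA within `riaRange`) and
#' fits a single exponential rise `p(t) = RIA_p (1 - exp(-kp t))` by
#' weighted nonlinear least squares, each point weighted by the square of
#' its normalized isotopomer intensity.
#'
#' @param obs data.frame from [dilysineObservations()] (one tissue).
#' @param minTimepoints Minimum quantified time points per peptide
#'   (default 9).
#' @param riaRange Admissible RIA range (default `c(0, 0.6)`).
#' @param start Starting values for `kp` and `RIAp`.
#' @return A [PrecursorEstimate-class] (method `"kk_one_pass"`); details
#'   carry the exclusion counts.
#' @export
kkOnePassFit <- function(obs, minTimepoints = 9, riaRange = c(0, 0.6),
                         start = c(kp = 0.5, RIAp = 0.4)) {
  fl <- .filterDilysine(obs, minTimepoints, riaRange)
  dat <- fl$obs
  if (length(unique(dat$day)) < 2)
    stop("fewer than 2 distinct time points after filtering")
  w <- (dat$intensity / max(dat$intensity))^2
  fit <- minpack.lm::nlsLM(
    p ~ RIAp * (1 - exp(-kp * day)), data = dat,
    start = as.list(start), weights = w,
    lower = c(kp = 1e-4, RIAp = 1e-3), upper = c(kp = 50, RIAp = 1),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- stats::coef(fit)
  new("PrecursorEstimate", method = "kk_one_pass",
      tissue = if (nrow(dat)) dat$tissue[1] else NA_character_,
      fn = precursorFunction("single_exponential", kp = cf[["kp"]],
                             plateau = cf[["RIAp"]]),
      sse = sum(stats::residuals(fit)^2), n = nrow(dat),
      details = list(excluded = fl$excluded, weighted = TRUE))
}

#' Mode of precursor RIA estimates by Gaussian kernel density
#'
#' Estimates the representative tissue precursor RIA at one time point as
#' the mode of a Gaussian kernel density over the per-peptide estimates,
#' with Scott's bandwidth rule (`sd(x) n^{-1/5}`), evaluated on a 512-point
#' grid over the admissible range.
#'
#' @param values Per-peptide RIA estimates at one time point.
#' @param from,to Grid range (default 0 to 0.6).
#' @param n Grid size (default 512).
#' @return The mode RIA.
#' @export
kkKdeMode <- function(values, from = 0, to = 0.6, n = 512) {
  values <- values[is.finite(values)]
  if (length(values) == 0) stop("no finite values")
  if (length(unique(values)) == 1) return(values[1])
  bw <- stats::sd(values) * length(values)^(-1 / 5)
  d <- stats::density(values, bw = bw, from = from, to = to, n = n)
  d$x[which.max(d$y)]
}

#' Median per-peptide precursor rate constant
#'
#' Fits each dilysine peptide's RIA time series to an exponential rise
#' curve and returns the median of the best-fit `kp` values.
#'
#' @param obs data.frame from [dilysineObservations()] (one tissue).
#' @param minPoints Minimum points per series (default 3).
#' @return A [PrecursorEstimate-class] (method `"kk_median"`); the fitted
#'   plateau is the median per-peptide plateau, details carry all
#'   per-peptide estimates.
#' @export
kkMedianKp <- function(obs, minPoints = 3) {
  obs <- obs[is.finite(obs$p), , drop = FALSE]
  key <- interaction(obs$sequence, obs$charge, drop = TRUE)
  ests <- lapply(split(obs, key), function(sub) {
    if (length(unique(sub$day)) < minPoints) return(NULL)
    fit <- tryCatch(minpack.lm::nlsLM(
      p ~ RIAp * (1 - exp(-kp * day)), data = sub,
      start = list(kp = 0.5, RIAp = 0.4),
      lower = c(kp = 1e-4, RIAp = 1e-3), upper = c(kp = 50, RIAp = 1),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) return(NULL)
    stats::coef(fit)
  })
  ests <- ests[!vapply(ests, is.null, logical(1))]
  if (length(ests) == 0) stop("no dilysine series could be fitted")
  kps <- vapply(ests, `[[`, numeric(1), "kp")
  plateaus <- vapply(ests, `[[`, numeric(1), "RIAp")
  new("PrecursorEstimate", method = "kk_median",
      tissue = obs$tissue[1],
      fn = precursorFunction("single_exponential",
                             kp = stats::median(kps),
                             plateau = stats::median(plateaus)),
      sse = NA_real_, n = length(kps),
      details = list(kp = kps, plateau = plateaus))
}

#' Two-exponent reutilization precursor fit
#'
#' Fits the bi-exponential precursor model of [twoExponentRates()] to
#' dilysine RIA observations, scaled to a fixed plateau (50% heavy lysine
#' by default). Also fits the single-exponential rise to the same points
#' and reports AIC-based Akaike weights for the model comparison.
#'
#' @param obs data.frame with columns `day`, `p`, `intensity` (one tissue),
#'   e.g. filtered output of [dilysineObservations()].
#' @param scale Fixed plateau of the scaled model (default 0.5).
#' @param minTimepoints Minimum distinct time points (default 4).
#' @param start Starting values for `a`, `b`, `r`.
#' @return A [PrecursorEstimate-class] (method `"kk_two_exponent"`);
#'   details carry the single-exponential comparison (`kpSingle`,
#'   `aicWeights` with elements `two_exponent`, `single_exponent`) and a
#'   `converged` flag.
#' @export
twoExponentPrecursorFit <- function(obs, scale = 0.5, minTimepoints = 4,
                                    start = c(a = 0.1, b = 1, r = 8)) {
  obs <- obs[is.finite(obs$p), , drop = FALSE]
  if (length(unique(obs$day)) < minTimepoints)
    stop("need at least ", minTimepoints, " distinct time points")
  tt <- obs$day; y <- obs$p
  w <- if (!is.null(obs$intensity) && any(obs$intensity > 0))
    (obs$intensity / max(obs$intensity))^2 else rep(1, length(y))

  rise <- function(tt, a, b, r) {
    mx <- twoExponentRates(a, b, r)
    1 - mx$c[1] * exp(-mx$mu[1] * tt) - mx$c[2] * exp(-mx$mu[2] * tt)
  }
  objective <- function(theta) {
    pr <- exp(theta)
    sum(w * (y - scale * rise(tt, pr[1], pr[2], pr[3]))^2)
  }
  opt <- stats::optim(log(start), objective, method = "BFGS",
                      control = list(maxit = 2000, reltol = 1e-15))
  ## polish with a second pass from the first optimum
  opt2 <- stats::optim(opt$par, objective, method = "BFGS",
                       control = list(maxit = 2000, reltol = 1e-15))
  if (opt2$value < opt$value) opt <- opt2
  pr <- exp(opt$par)
  names(pr) <- c("a", "b", "r")
  sse2 <- opt$value
  n <- length(y)

  singleFit <- tryCatch(minpack.lm::nlsLM(
    p ~ scale * (1 - exp(-kp * day)), data = data.frame(p = y, day = tt),
    start = list(kp = 0.5), weights = w, lower = c(kp = 1e-4),
    upper = c(kp = 50)), error = function(e) NULL)
  sse1 <- if (is.null(singleFit)) NA_real_ else
    sum(w * stats::residuals(singleFit)^2)
  aicOf <- function(sse, npar) {
    2 * (npar + 1) + n * (log(2 * pi * sse / n) + 1)
  }
  aics <- c(two_exponent = aicOf(sse2, 3),
            single_exponent = if (is.na(sse1)) NA else aicOf(sse1, 1))
  wts <- if (any(is.na(aics))) c(two_exponent = 1, single_exponent = 0)
  else {
    d <- aics - min(aics); ww <- exp(-d / 2); ww / sum(ww)
  }
  new("PrecursorEstimate", method = "kk_two_exponent",
      tissue = if ("tissue" %in% names(obs) && nrow(obs))
        obs$tissue[1] else NA_character_,
      fn = precursorFunction("two_exponential", a = pr[["a"]], b = pr[["b"]],
                             r = pr[["r"]], plateau = scale),
      sse = sse2, n = as.integer(n),
      details = list(kpSingle = if (is.null(singleFit)) NA_real_ else
        stats::coef(singleFit)[["kp"]],
        aic = aics, aicWeights = wts, converged = opt$convergence == 0))
}

#' Nested proteome-wide optimization of the precursor rate constant
#'
#' For each candidate `kp`, refits every peptide's `kdeg` under the
#' two-compartment model and records the median SSE across peptides; the
#' one-compartment median SSE serves as the baseline. Returns the `kp`
#' minimizing the median SSE among candidates that beat the baseline, or no
#' estimate when none does (the identifiability failure expected when
#' `kdeg << kp` throughout a tissue). A flat objective (relative range
#' below 1% across improving candidates) is flagged.
#'
#' @param seriesList List of [RIATimeSeries-class] (one tissue).
#' @param kpGrid Candidate `kp` values (1/d).
#' @return List with `kp` (chosen value or `NA`), `objective` (data.frame
#'   of `kp`, `medianSSE`), `baseline` (one-compartment median SSE),
#'   `improved` (logical per candidate), and `flat` (logical).
#' @export
nestedKpOptimization <- function(seriesList, kpGrid) {
  if (length(kpGrid) == 0) stop("empty kp grid")
  kpGrid <- sort(kpGrid)
  sseOne <- vapply(seriesList, function(s)
    fitKdeg(s, "one_compartment")@sse, numeric(1))
  baseline <- stats::median(sseOne)
  med <- vapply(kpGrid, function(kp) {
    stats::median(vapply(seriesList, function(s)
      fitKdeg(s, "two_compartment", kp = kp)@sse, numeric(1)))
  }, numeric(1))
  improved <- med < baseline
  kpBest <- if (any(improved)) {
    cand <- which(improved)
    cand[which.min(med[cand])]
  } else NA_integer_
  rng <- diff(range(med))
  flat <- is.finite(rng) &&
    (rng <= 0.01 * max(stats::median(med), .Machine$double.eps) ||
     rng < 1e-12)
  list(kp = if (is.na(kpBest)) NA_real_ else kpGrid[kpBest],
       objective = data.frame(kp = kpGrid, medianSSE = med),
       baseline = baseline, improved = improved, flat = flat)
}

#' Calibrate amino-acid precursor kinetics against a heavy-water reference
#'
#' Scans a grid of plateau RIA_p and `kp` values; in each cell the
#' amino-acid series are refitted under the two-compartment model with that
#' cell's boundary values, and the resulting `kdeg` are compared with the
#' heavy-water reference values for the shared peptides: (i) the median
#' absolute pairwise difference of log `kdeg`, (ii) the deviation from 1 of
#' the robust log-log regression slope. The `kp` minimizing the difference
#' surface is reported for every RIA_p.
#'
#' @param aaBuilt Output of [buildRiaSeries()] for the amino-acid table
#'   (series must have `A0 = 0`).
#' @param hwKdeg data.frame with columns `sequence`, `charge`, `kdeg`: the
#'   heavy-water reference rate constants.
#' @param riaGrid,kpGrid Grid of plateau RIA_p and `kp` values.
#' @param minShared Minimum number of shared peptides (default 10).
#' @return List with matrices `diff` and `slope` (rows = RIA_p, cols = kp),
#'   `best` (data.frame per RIA_p: `riap`, `kp`, `medianAbsDiff`, `slope`),
#'   and `argmin` (named vector `riap`, `kp` of the global difference
#'   minimum).
#' @export
hwReferenceCalibration <- function(aaBuilt, hwKdeg, riaGrid, kpGrid,
                                   minShared = 10) {
  keyAA <- paste(aaBuilt$meta$sequence, aaBuilt$meta$charge)
  keyHW <- paste(hwKdeg$sequence, hwKdeg$charge)
  shared <- intersect(keyAA, keyHW)
  if (length(shared) < minShared)
    stop("fewer than ", minShared, " shared peptides between the tables")
  idx <- match(shared, keyAA)
  refK <- hwKdeg$kdeg[match(shared, keyHW)]
  serList <- aaBuilt$series[idx]

  diffM <- matrix(NA_real_, length(riaGrid), length(kpGrid),
                  dimnames = list(riaGrid, kpGrid))
  slopeM <- diffM
  for (i in seq_along(riaGrid)) {
    for (j in seq_along(kpGrid)) {
      kAA <- vapply(serList, function(s) {
        s@Ainf <- riaGrid[i]
        fitKdeg(s, "two_compartment", kp = kpGrid[j])@kdeg
      }, numeric(1))
      lr <- log(refK); la <- log(kAA)
      diffM[i, j] <- stats::median(abs(lr - la))
      sl <- tryCatch(unname(stats::coef(MASS::rlm(la ~ lr, maxit = 50))[2]),
                     error = function(e)
                       unname(stats::coef(stats::lm(la ~ lr))[2]))
      slopeM[i, j] <- sl
    }
  }
  best <- data.frame(
    riap = riaGrid,
    kp = kpGrid[apply(diffM, 1, which.min)],
    medianAbsDiff = apply(diffM, 1, min),
    slope = slopeM[cbind(seq_along(riaGrid), apply(diffM, 1, which.min))])
  am <- arrayInd(which.min(diffM), dim(diffM))
  list(diff = diffM, slope = slopeM, best = best,
       argmin = c(riap = riaGrid[am[1]], kp = kpGrid[am[2]]))
}

#' Precursor rate constant from secreted reporter proteins
#'
#' Secreted reporter proteins (e.g. the liver's major urinary proteins)
#' leave the tissue as soon as they are made, so their labeling trajectory
#' tracks precursor availability. Each qualifying peptide series is
#' converted to fractional synthesis, all points are pooled, and a single
#' exponential rise `FS(t) = 1 - exp(-kp t)` is fitted.
#'
#' @param fsObs data.frame of fractional-synthesis observations (columns
#'   `sequence`, `charge`, `t`, `fs`), e.g. from [fsObservations()].
#' @param r2Min Per-peptide R^2 threshold for inclusion (default 0.6).
#' @param minTimepoints Minimum time points per peptide (default 10).
#' @return A [PrecursorEstimate-class] (method `"mup_secretion"`); details
#'   carry `dk`, `r2` of the pooled fit, the number of peptides pooled, and
#'   `lowerBoundOnly` (TRUE when labeling is too fast for the schedule to
#'   resolve the rate, i.e. the first sampled point is already near
#'   plateau).
#' @export
secretedProteinKp <- function(fsObs, r2Min = 0.6, minTimepoints = 10) {
  key <- interaction(fsObs$sequence, fsObs$charge, drop = TRUE)
  keep <- unlist(lapply(split(fsObs, key), function(sub) {
    if (length(unique(sub$t)) < minTimepoints) return(character(0))
    fit <- tryCatch(fitRatePoints(sub$t, sub$fs, 0, 1, "one_compartment"),
                    error = function(e) NULL)
    if (is.null(fit) || is.na(fit@r2) || fit@r2 < r2Min) return(character(0))
    as.character(sub$sequence[1])
  }))
  dat <- fsObs[fsObs$sequence %in% keep, , drop = FALSE]
  if (nrow(dat) == 0) stop("no qualifying reporter peptides")
  fit <- fitRatePoints(dat$t, dat$fs, 0, 1, "one_compartment")
  tpos <- min(dat$t[dat$t > 0])
  lowerBound <- (1 - exp(-fit@kdeg * tpos)) > 0.8
  new("PrecursorEstimate", method = "mup_secretion",
      tissue = if ("tissue" %in% names(dat)) dat$tissue[1] else
        NA_character_,
      fn = precursorFunction("single_exponential", kp = fit@kdeg,
                             plateau = 1),
      sse = fit@sse, n = fit@nPoints,
      details = list(dk = fit@dk, r2 = fit@r2,
                     nPeptides = length(unique(keep)),
                     lowerBoundOnly = lowerBound))
}
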
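## Relative isotope abundance statistics and kinetic models.

.area <- function(areas, i) {
  v <- areas[as.character(i)]
  ifelse(is.na(v), 0, v)
}

#' RIA for amino-acid labeling: m6 / (m0 + m6)
#'
#' @param areas Named numeric vector of isotopomer areas; names are the
#'   isotopomer indices (`"0"`, `"6"`, ...).
#' @return RIA fraction, or `NA` (with a warning) when m0 + m6 = 0.
#' @export
#' @examples
#' riaAA(c("0" = 55, "6" = 45))  # 0.45
riaAA <- function(areas) {
  m0 <- .area(areas, 0); m6 <- .area(areas, 6)
  if (m0 + m6 <= 0) {
    warning("undefined AA RIA: m0 + m6 = 0")
    return(NA_real_)
  }
  unname(m6 / (m0 + m6))
}

#' RIA for heavy-water labeling: m0 / sum(m0..m5)
#'
#' @inheritParams riaAA
#' @return RIA fraction, or `NA` (with a warning) when the envelope sums
#'   to zero.
#' @export
#' @examples
#' riaHW(setNames(c(50, 25, 15, 5, 3, 2), 0:5))  # 0.5
riaHW <- function(areas) {
  m <- vapply(0:5, function(i) .area(areas, i), numeric(1))
  s <- sum(m)
  if (s <= 0) {
    warning("undefined HW RIA: sum(m0..m5) = 0")
    return(NA_real_)
  }
  unname(m[1] / s)
}

#' Heavy-water labeling plateau of the monoisotopic fraction
#'
#' The asymptotic RIA under heavy-water labeling: the fully light isotopomer
#' requires all N accessible deuterium sites of the peptide to remain
#' unlabeled, so the natural monoisotopic fraction is depleted binomially:
#' `Ainf = A0 * (1 - p)^N` with `N` the summed per-residue accessible sites.
#'
#' @param sequence Peptide sequence.
#' @param p Plateau body-water deuterium enrichment (fraction).
#' @param A0 Prelabeling RIA (natural monoisotopic fraction,
#'   [naturalM0Fraction()]).
#' @param siteTable Accessible sites per residue; default [commerfordSites()].
#' @return Asymptotic RIA (< A0 for p > 0).
#' @export
#' @examples
#' hwPlateau("GAK", p = 0.046, A0 = 0.5)
hwPlateau <- function(sequence, p, A0, siteTable = commerfordSites()) {
  res <- strsplit(sequence, "")[[1]]
  miss <- setdiff(res, names(siteTable))
  if (length(miss))
    stop("residue(s) missing from site table: ",
         paste(unique(miss), collapse = ", "))
  N <- sum(siteTable[res])
  A0 * (1 - p)^N
}

#' Accessible labeling sites of a peptide
#'
#' @inheritParams hwPlateau
#' @return Summed accessible deuterium site count N.
#' @export
accessibleSites <- function(sequence, siteTable = commerfordSites()) {
  res <- strsplit(sequence, "")[[1]]
  sum(siteTable[res])
}

#' One-compartment exponential labeling curve
#'
#' `A(t) = A0 + (Ainf - A0) * (1 - exp(-k t))`: first-order replacement of
#' the protein pool under instantaneous precursor equilibration. The sign of
#' `Ainf - A0` sets the direction of change, covering both chemistries.
#'
#' @param t Time (days); vectorized.
#' @param k Degradation rate constant (1/d).
#' @param A0,Ainf Initial and asymptotic RIA.
#' @return RIA at each `t`.
#' @export
oneCompartmentA <- function(t, k, A0, Ainf) {
  A0 + (Ainf - A0) * (1 - exp(-k * t))
}

#' Two-compartment labeling curve with exponential precursor rise
#'
#' `A(t) = A0 + (Ainf - A0) * [1 - (kp e^{-kt} - k e^{-kp t})/(kp - k)]`:
#' protein labeling driven by a precursor pool that itself equilibrates with
#' first-order rate `kp`. At `k = kp` the removable singularity is evaluated
#' by its limit `1 - (1 + k t) e^{-k t}`.
#'
#' @inheritParams oneCompartmentA
#' @param kp Precursor equilibration rate constant (1/d).
#' @export
twoCompartmentA <- function(t, k, kp, A0, Ainf) {
  if (abs(kp - k) < 1e-9 * max(k, kp)) {
    rise <- 1 - (1 + k * t) * exp(-k * t)
  } else {
    rise <- 1 - (kp * exp(-k * t) - k * exp(-kp * t)) / (kp - k)
  }
  A0 + (Ainf - A0) * rise
}

## exponential-sum representation of a normalized precursor rise:
## f(t) = sum(alpha_j * exp(-beta_j * t)); returns list(alpha, beta)
.precursorExpsum <- function(pf) {
  switch(pf@kind,
    instantaneous = list(alpha = 1, beta = 0),
    single_exponential = {
      kp <- unname(pf@parameters["kp"])
      list(alpha = c(1, -1), beta = c(0, kp))
    },
    two_exponential = {
      mx <- twoExponentRates(pf@parameters["a"], pf@parameters["b"],
                             pf@parameters["r"])
      list(alpha = c(1, -mx$c), beta = c(0, mx$mu))
    })
}

#' Rates and weights of the two-exponential precursor model
#'
#' Closed-form solution of the coupled linear exchange system: dietary label
#' enters the soluble pool at rate `b`; the protein-bound pool turns over at
#' rate `a`, returning (partially labeled) residues to the soluble pool
#' scaled by the pool-size ratio `r`. The soluble enrichment is
#' `s(t) = 1 - c1 e^{-mu1 t} - c2 e^{-mu2 t}` with `mu1, mu2` the roots of
#' `mu^2 - S mu + a b` for `S = a + b + a/r`, and weights fixed by
#' `s(0) = 0`, `s'(0) = b`.
#'
#' @param a Global protein degradation rate constant (1/d).
#' @param b Soluble precursor exchange rate constant (1/d).
#' @param r Pool-size ratio coupling the return flux (dimensionless).
#' @return List with `mu` (two decay rates, fast first) and `c` (their
#'   mixture weights summing to 1).
#' @export
twoExponentRates <- function(a, b, r) {
  a <- unname(a); b <- unname(b); r <- unname(r)
  S <- a + b + a / r
  disc <- S^2 - 4 * a * b
  rt <- sqrt(max(disc, 0))
  mu1 <- (S + rt) / 2
  mu2 <- (S - rt) / 2
  if (abs(mu1 - mu2) < 1e-12 * mu1) mu2 <- mu1 * (1 - 1e-9)
  c1 <- (b - mu2) / (mu1 - mu2)
  list(mu = c(mu1, mu2), c = c(c1, 1 - c1))
}

## k * integral_0^t exp(-beta tau) exp(-k (t - tau)) dtau, vectorized over t
.convExp <- function(beta, k, t) {
  if (abs(k - beta) < 1e-9 * max(k, beta, 1e-300)) {
    k * t * exp(-k * t)
  } else {
    k * (exp(-beta * t) - exp(-k * t)) / (k - beta)
  }
}

#' Precursor-convolution labeling curve
#'
#' `A(t) = A0 + (Ainf - A0) * k * int_0^t f_p(tau) e^{-k(t-tau)} d tau`
#' with `f_p` the normalized precursor rise (0 to 1). Evaluated in closed
#' form for instantaneous, single-exponential and bi-exponential precursor
#' functions; with a single-exponential precursor this is algebraically
#' identical to [twoCompartmentA()].
#'
#' @inheritParams oneCompartmentA
#' @param precursor A [PrecursorFunction-class].
#' @export
convolutionA <- function(t, k, precursor, A0, Ainf) {
  es <- .precursorExpsum(precursor)
  rise <- 0
  for (j in seq_along(es$alpha))
    rise <- rise + es$alpha[j] * .convExp(es$beta[j], k, t)
  A0 + (Ainf - A0) * rise
}

#' Evaluate a kinetic model curve
#'
#' @inheritParams oneCompartmentA
#' @param model `"one_compartment"`, `"two_compartment"` or `"convolution"`.
#' @param kp Fixed precursor rate (two-compartment).
#' @param precursor Fixed [PrecursorFunction-class] (convolution).
#' @return RIA at each `t`.
#' @export
modelRia <- function(t, k, model, A0, Ainf, kp = NULL, precursor = NULL) {
  switch(model,
    one_compartment = oneCompartmentA(t, k, A0, Ainf),
    two_compartment = twoCompartmentA(t, k, kp, A0, Ainf),
    convolution = convolutionA(t, k, precursor, A0, Ainf),
    stop("unknown model: ", model))
}

#' Fit the turnover rate constant of one RIA time series
#'
#' Minimizes the sum of squared RIA residuals over `kdeg`, the only free
#' kinetic parameter (`A0`, `Ainf` and any precursor parameters are fixed
#' from the labeling configuration). Optimization runs over `log kdeg` with
#' the BFGS quasi-Newton method from a starting value of 0.29 1/d, which
#' enforces positivity; fitted values are clamped to `[1e-5, 50]` 1/d and
#' flagged when they hit a bound.
#'
#' @param series An [RIATimeSeries-class].
#' @param model `"one_compartment"`, `"two_compartment"` or `"convolution"`.
#' @param kp Fixed precursor rate constant (1/d; two-compartment model).
#' @param precursor Fixed [PrecursorFunction-class] (convolution model).
#' @param start Starting value for `kdeg` (default 0.29 1/d).
#' @param bounds Allowed `kdeg` range (default `c(1e-5, 50)`).
#' @param weights Optional per-observation weights (normalized to mean 1
#'   internally); default unweighted.
#' @return A [KineticFit-class] with `kdeg`, `dk`, `sigmaA`, `r2`, SSE,
#'   log-likelihood and AIC.
#' @export
#' @examples
#' t <- c(0, 1, 2, 3, 4, 6, 9, 12, 17, 22, 30)
#' s <- riaTimeSeries(t, oneCompartmentA(t, 0.2, 0, 0.45), A0 = 0, Ainf = 0.45)
#' fitKdeg(s)
fitKdeg <- function(series, model = c("one_compartment", "two_compartment",
                                      "convolution"),
                    kp = NULL, precursor = NULL, start = 0.29,
                    bounds = c(1e-5, 50), weights = NULL) {
  model <- match.arg(model)
  fitRatePoints(series@t, series@A, series@A0, series@Ainf, model = model,
                kp = kp, precursor = precursor, start = start,
                bounds = bounds, weights = weights)
}

#' Fit a rate constant to arbitrary (t, A) observations
#'
#' Workhorse behind [fitKdeg()], also used for pooled fits (protein-level
#' refitting, secreted-reporter precursor estimation) where time points may
#' repeat.
#'
#' @inheritParams fitKdeg
#' @param t,A Observations (days; RIA or fractional-synthesis values).
#' @param A0,Ainf Fixed boundary values of the curve.
#' @return A [KineticFit-class].
#' @export
fitRatePoints <- function(t, A, A0, Ainf,
                          model = c("one_compartment", "two_compartment",
                                    "convolution"),
                          kp = NULL, precursor = NULL, start = 0.29,
                          bounds = c(1e-5, 50), weights = NULL) {
  model <- match.arg(model)
  ok <- is.finite(A) & is.finite(t)
  if (!is.null(weights)) weights <- weights[ok]
  t <- t[ok]; A <- A[ok]
  n <- length(t)
  if (n < 2) stop("need at least 2 observations to fit kdeg")
  if (model == "two_compartment" && (is.null(kp) || kp <= 0))
    stop("two_compartment model requires fixed kp > 0")
  if (model == "convolution" && is.null(precursor))
    stop("convolution model requires a fixed precursor function")
  w <- if (is.null(weights)) rep(1, n) else weights / mean(weights)

  obj <- function(theta) {
    k <- exp(theta)
    pred <- modelRia(t, k, model, A0, Ainf, kp, precursor)
    sum(w * (A - pred)^2)
  }
  grad <- function(theta) {
    k <- exp(theta)
    pred <- modelRia(t, k, model, A0, Ainf, kp, precursor)
    -2 * k * sum(w * (A - pred) * .modelDAdk(t, k, model, A0, Ainf, kp,
                                             precursor))
  }
  opt <- stats::optim(log(start), obj, gr = grad, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-14))
  ## 1-D golden-section polish guards against quasi-Newton overshoot into
  ## the flat low-k region of the SSE surface
  pol <- stats::optimize(obj, c(log(bounds[1]), log(bounds[2])),
                         tol = 1e-10)
  if (pol$objective < opt$value)
    opt <- list(par = pol$minimum, value = pol$objective, convergence = 0L)
  k <- exp(opt$par)
  flag <- ""
  if (k <= bounds[1]) { k <- bounds[1]; flag <- "at_bound" }
  if (k >= bounds[2]) { k <- bounds[2]; flag <- "at_bound" }

  pred <- modelRia(t, k, model, A0, Ainf, kp, precursor)
  sse <- sum(w * (A - pred)^2)
  sigA <- sqrt(sse / max(n - 1, 1))
  mA <- sum(w * A) / sum(w)
  sst <- sum(w * (A - mA)^2)
  if (sst <= 0) {
    r2raw <- NA_real_; r2 <- NA_real_
    flag <- paste0(flag, if (nzchar(flag)) ";", "no_signal")
  } else {
    r2raw <- 1 - sse / sst
    r2 <- max(r2raw, 0)
  }
  sigma2 <- sse / n
  logL <- if (sigma2 > 0) -n / 2 * (log(2 * pi * sigma2) + 1) else Inf
  p <- 2  # kdeg + noise variance (kp / precursor parameters are fixed)
  aicv <- 2 * p - 2 * logL

  fit <- new("KineticFit", kdeg = k, dk = NA_real_, sigmaA = sigA,
             r2 = r2, r2raw = r2raw, sse = sse, nPoints = as.integer(n),
             modelId = model, kp = if (is.null(kp)) NA_real_ else kp,
             precursor = precursor, A0 = A0, Ainf = Ainf, logL = logL,
             aic = aicv, converged = opt$convergence == 0, flag = flag)
  fit@dk <- fitErrorDk(fit)
  fit
}

#' First-order fitting error of the rate constant
#'
#' Propagates the residual RIA error through the model sensitivity:
#' `dk = sigmaA / |dA/dk|` evaluated at `t = 1/k`. For the one-compartment
#' model this collapses to `dk = k e sigmaA / |Ainf - A0|`; for the
#' two-compartment model the analytic derivative
#' `dA/dk = D kp [(t(kp-k)-1) e^{-kt} + e^{-kp t}]/(kp-k)^2` is used, and
#' for the general convolution model a central finite difference.
#'
#' @param fit A [KineticFit-class].
#' @return Fitting error `dk` (1/d); `NA` when the fit sits at a bound, 0
#'   when `sigmaA` is 0.
#' @export
fitErrorDk <- function(fit) {
  if (grepl("at_bound", fit@flag)) return(NA_real_)
  k <- fit@kdeg; sA <- fit@sigmaA
  if (sA == 0) return(0)
  dAdk <- .modelDAdk(1 / k, k, fit@modelId, fit@A0, fit@Ainf, fit@kp,
                     fit@precursor)
  sA / abs(dAdk)
}

## dA/dk of the model curve, vectorized over t
.modelDAdk <- function(t, k, model, A0, Ainf, kp = NULL, precursor = NULL) {
  D <- Ainf - A0
  switch(model,
    one_compartment = D * t * exp(-k * t),
    two_compartment = {
      if (abs(kp - k) < 1e-6 * max(k, kp)) {
        vapply(t, function(tt) .numDeriv(
          function(kk) twoCompartmentA(tt, kk, kp, A0, Ainf), k), numeric(1))
      } else {
        D * kp * ((t * (kp - k) - 1) * exp(-k * t) + exp(-kp * t)) /
          (kp - k)^2
      }
    },
    convolution = vapply(t, function(tt) .numDeriv(
      function(kk) convolutionA(tt, kk, precursor, A0, Ainf), k),
      numeric(1)))
}

.numDeriv <- function(f, x, h = 1e-6) {
  hh <- h * max(abs(x), 1)
  (f(x + hh) - f(x - hh)) / (2 * hh)
}

#' Akaike weights across competing fits of the same series
#'
#' @param fits List of [KineticFit-class] objects fitted to the same
#'   observations.
#' @return Numeric vector of Akaike weights summing to 1.
#' @export
#' @examples
#' ## two models with equal AIC share weight 0.5 each
aicWeights <- function(fits) {
  n <- vapply(fits, function(f) f@nPoints, integer(1))
  if (length(unique(n)) != 1)
    stop("fits compare different numbers of observations")
  a <- vapply(fits, function(f) f@aic, numeric(1))
  d <- a - min(a)
  w <- exp(-d / 2)
  w / sum(w)
}

#' Fractional synthesis
#'
#' Linearly rescales an RIA value to the fraction of the protein pool
#' replaced since label start: 0 before labeling, 1 at plateau. Valid for
#' both chemistries (heavy-water RIA decreases; FS still rises 0 to 1).
#'
#' @param A Observed RIA (vectorized).
#' @param A0,Ainf Initial and asymptotic RIA (must differ).
#' @return Fractional synthesis.
#' @export
#' @examples
#' fractionalSynthesis(0.4, A0 = 0.5, Ainf = 0.3)  # 0.5
fractionalSynthesis <- function(A, A0, Ainf) {
  if (A0 == Ainf) stop("fractional synthesis undefined: A0 == Ainf")
  (A - A0) / (Ainf - A0)
}

#' Half-life of a first-order rate constant
#'
#' @param k Rate constant (1/d).
#' @return Half-life `ln(2)/k` in days.
#' @export
#' @examples
#' halfLife(c(0.01, 0.1, 1))  # 69.3, 6.93, 0.693 d
halfLife <- function(k) log(2) / k

#' Measurable turnover-rate range of a sampling schedule
#'
#' A labeling curve is only informative where the minor species (labeled or
#' unlabeled) is detectable. Requiring at least `nPoints` early samples with
#' an unlabeled fraction above the detectability threshold bounds the
#' fastest measurable rate: `k_max = ln(1/d) / t_(nPoints)` with
#' `t_(nPoints)` the nPoints-th earliest sampling day. Requiring a labeled
#' fraction above the threshold by the end of sampling bounds the slowest:
#' `k_min = ln(1/(1-d)) / max(t)`.
#'
#' @param schedule Sampling days (t > 0).
#' @param detectable Detectability threshold as a fraction of total
#'   intensity (default 0.05).
#' @param nPoints Number of early time points that must remain informative
#'   (default 3).
#' @return Named vector `c(lower, upper)` in 1/d.
#' @export
#' @examples
#' measurableKdegRange(c(1, 2, 3, 4, 8, 10, 13, 16, 20, 32))
measurableKdegRange <- function(schedule, detectable = 0.05, nPoints = 3) {
  ts <- sort(schedule[schedule > 0])
  if (length(ts) < nPoints) stop("schedule shorter than nPoints")
  upper <- log(1 / detectable) / ts[nPoints]
  lower <- log(1 / (1 - detectable)) / max(ts)
  c(lower = lower, upper = upper)
}
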
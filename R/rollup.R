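## Peptide quality filters, protein-level aggregation and precision
## diagnostics.

#' Filter a peptide fit table by quality criteria
#'
#' Applies the conservative peptide admission rules: minimum quantified
#' time points, minimum R^2 of the kinetic fit, maximum lysine count (for
#' AA-comparable sets), and unique protein mapping. Returns the qualifying
#' subset together with an exclusion ledger counting, for each criterion,
#' how many rows fail it.
#'
#' @param fitTable Peptide fit table from [fitPeptides()] (columns
#'   `nPoints`, `r2`, `nLysine`, `nProteins`).
#' @param minTimepoints Minimum time points (default 9).
#' @param r2Min Minimum R^2 (default 0.9).
#' @param maxLysines Maximum lysine count (default `Inf`; use 1 for sets
#'   comparable with amino-acid labeling).
#' @param requireUnique Drop peptides mapping to more than one accession
#'   (default TRUE).
#' @return List with `retained` (qualifying rows) and `ledger` (named
#'   integer vector of exclusion counts per criterion).
#' @export
#' @examples
#' tab <- data.frame(nPoints = c(10, 8, 11, 12, 9),
#'                   r2 = c(0.95, 0.99, 0.85, 0.91, 0.90),
#'                   nLysine = 1, nProteins = 1)
#' filterPeptides(tab)$retained  # 3 rows
filterPeptides <- function(fitTable, minTimepoints = 9, r2Min = 0.9,
                           maxLysines = Inf, requireUnique = TRUE) {
  failTime <- fitTable$nPoints < minTimepoints
  failR2 <- is.na(fitTable$r2) | fitTable$r2 < r2Min
  failLys <- if ("nLysine" %in% names(fitTable))
    fitTable$nLysine > maxLysines else rep(FALSE, nrow(fitTable))
  failUniq <- if (requireUnique && "nProteins" %in% names(fitTable))
    fitTable$nProteins != 1 else rep(FALSE, nrow(fitTable))
  keep <- !(failTime | failR2 | failLys | failUniq)
  list(retained = fitTable[keep, , drop = FALSE],
       ledger = c(min_timepoints = sum(failTime), r2_min = sum(failR2),
                  lysine_count = sum(failLys),
                  non_unique_protein = sum(failUniq),
                  retained = sum(keep)))
}

#' Geometric coefficient of variation
#'
#' `CV_geo = sqrt(exp(sd(log k)^2) - 1)` with the sample standard
#' deviation; the intraprotein precision metric across peptides of one
#' protein. Scale invariant.
#'
#' @param k Positive rate constants (length >= 2).
#' @return Geometric CV.
#' @export
#' @examples
#' geometricCv(c(0.1, 0.1 * exp(1)))  # 0.8050
geometricCv <- function(k) {
  if (length(k) < 2) stop("need at least 2 values")
  if (any(k <= 0)) stop("geometric CV requires positive values")
  sqrt(exp(stats::sd(log(k))^2) - 1)
}

.harmonicMean <- function(k) length(k) / sum(1 / k)

## delta-method SD of the harmonic mean via the reciprocal scale
.harmonicMeanSd <- function(k) {
  n <- length(k)
  if (n < 2) return(NA_real_)
  m <- mean(1 / k)
  sdm <- stats::sd(1 / k) / sqrt(n)
  sdm / m^2
}

#' Aggregate peptide turnover rates to the protein level
#'
#' Four aggregation methods: `"median"` (median peptide `kdeg`, spread =
#' median absolute deviation), `"harmonic_mean"` (harmonic mean, spread by
#' the delta method), `"refit"` (pool all peptide observations in
#' fractional-synthesis space and fit a single curve; spread = fitting
#' error `dk`), and `"weighted_refit"` (as refit, with per-point weights
#' given by the peptide's normalized log10 total intensity).
#'
#' @param fitTable Qualifying peptide fit table (after [filterPeptides()]);
#'   needs columns `proteins`, `kdeg`, and for the refit methods matching
#'   observations in `obs`.
#' @param method Aggregation method.
#' @param obs Fractional-synthesis observations from [fsObservations()]
#'   (required for the refit methods).
#' @param model,kp,precursor Kinetic model used for refitting (default
#'   one-compartment in FS space).
#' @return data.frame: one row per protein with `protein`, `tissue`,
#'   `method`, `kdeg`, `spread`, `nPeptides`, `r2` (refit methods only).
#' @export
rollupProtein <- function(fitTable,
                          method = c("median", "harmonic_mean", "refit",
                                     "weighted_refit"),
                          obs = NULL, model = "one_compartment", kp = NULL,
                          precursor = NULL) {
  method <- match.arg(method)
  if (method %in% c("refit", "weighted_refit") && is.null(obs))
    stop("refit methods require fractional-synthesis observations")
  groups <- split(fitTable, fitTable$proteins)
  rows <- lapply(groups, function(sub) {
    prot <- sub$proteins[1]
    tis <- if ("tissue" %in% names(sub)) sub$tissue[1] else NA_character_
    base <- data.frame(protein = prot, tissue = tis, method = method,
                       stringsAsFactors = FALSE)
    if (method == "median") {
      base$kdeg <- stats::median(sub$kdeg)
      base$spread <- stats::mad(sub$kdeg, constant = 1)
      base$nPeptides <- nrow(sub); base$r2 <- NA_real_
    } else if (method == "harmonic_mean") {
      base$kdeg <- .harmonicMean(sub$kdeg)
      base$spread <- .harmonicMeanSd(sub$kdeg)
      base$nPeptides <- nrow(sub); base$r2 <- NA_real_
    } else {
      key <- paste(sub$sequence, sub$charge)
      po <- obs[paste(obs$sequence, obs$charge) %in% key, , drop = FALSE]
      if (nrow(po) < 2) return(NULL)
      w <- if (method == "weighted_refit") {
        lw <- log10(pmax(po$totalIntensity, 1))
        lw / max(lw)
      } else NULL
      fit <- tryCatch(
        fitRatePoints(po$t, po$fs, 0, 1, model, kp = kp,
                      precursor = precursor, weights = w),
        error = function(e) NULL)
      if (is.null(fit)) {
        base$kdeg <- NA_real_; base$spread <- NA_real_
        base$nPeptides <- nrow(sub); base$r2 <- NA_real_
        base$flag <- "refit_failed"
        return(base)
      }
      base$kdeg <- fit@kdeg; base$spread <- fit@dk
      base$nPeptides <- nrow(sub); base$r2 <- fit@r2
    }
    base
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Peptide count and intraprotein variance across filter thresholds
#'
#' Evaluates, for every combination of R^2 threshold and minimum-timepoint
#' threshold, the number of retained peptides and the median intraprotein
#' geometric CV of `kdeg` (over proteins with at least `minPeptides`
#' uniquely mapped peptides). Supports choosing operating thresholds.
#'
#' @param fitTable Peptide fit table.
#' @param r2Grid R^2 thresholds to scan.
#' @param timepointGrid Minimum-timepoint thresholds to scan.
#' @param minPeptides Minimum peptides per protein entering the CV
#'   (default 3).
#' @return data.frame with columns `r2Min`, `minTimepoints`, `nPeptides`,
#'   `medianGeomCv`.
#' @export
varianceVsFilterSweep <- function(fitTable, r2Grid = seq(0.5, 0.95, 0.05),
                                  timepointGrid = c(4, 6, 9),
                                  minPeptides = 3) {
  grid <- expand.grid(r2Min = r2Grid, minTimepoints = timepointGrid)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    fl <- filterPeptides(fitTable, minTimepoints = grid$minTimepoints[i],
                         r2Min = grid$r2Min[i])
    ret <- fl$retained
    cvs <- unlist(lapply(split(ret$kdeg, ret$proteins), function(k)
      if (length(k) >= minPeptides) geometricCv(k) else NULL))
    data.frame(r2Min = grid$r2Min[i], minTimepoints = grid$minTimepoints[i],
               nPeptides = nrow(ret),
               medianGeomCv = if (length(cvs)) stats::median(cvs) else
                 NA_real_)
  })
  do.call(rbind, res)
}

#' Day-0 fractional-synthesis diagnostic
#'
#' Before labeling starts the true fractional synthesis is 0; the spread of
#' the empirically derived day-0 values therefore measures quantitative
#' error at the isotopomer level. Returns per-peptide day-0 FS values with
#' quantile summaries stratified by fit R^2 bin and intensity bin.
#'
#' @param obs Fractional-synthesis observations ([fsObservations()]).
#' @param fitTable Optional peptide fit table supplying `r2` per peptide.
#' @param r2Breaks,intensityQuantiles Stratification bins.
#' @return List with `values` (data.frame of day-0 FS per peptide, with
#'   bins) and `summary` (quantiles per stratum).
#' @export
day0FsDiagnostic <- function(obs, fitTable = NULL,
                             r2Breaks = c(0, 0.5, 0.9, 1),
                             intensityQuantiles = c(0, 1 / 3, 2 / 3, 1)) {
  d0 <- obs[obs$t == 0, , drop = FALSE]
  if (nrow(d0) == 0) stop("no day-0 observations present")
  if (!is.null(fitTable)) {
    key <- paste(d0$sequence, d0$charge)
    keyF <- paste(fitTable$sequence, fitTable$charge)
    d0$r2 <- fitTable$r2[match(key, keyF)]
    d0$r2Bin <- cut(d0$r2, breaks = r2Breaks, include.lowest = TRUE)
  } else {
    d0$r2Bin <- factor("all")
  }
  qs <- stats::quantile(d0$totalIntensity,
                        probs = intensityQuantiles, names = FALSE)
  d0$intensityBin <- cut(d0$totalIntensity, breaks = unique(qs),
                         include.lowest = TRUE)
  summ <- do.call(rbind, lapply(
    split(d0, list(d0$r2Bin, d0$intensityBin), drop = TRUE),
    function(sub) data.frame(
      r2Bin = as.character(sub$r2Bin[1]),
      intensityBin = as.character(sub$intensityBin[1]),
      n = nrow(sub),
      q25 = stats::quantile(sub$fs, 0.25, names = FALSE),
      median = stats::median(sub$fs),
      q75 = stats::quantile(sub$fs, 0.75, names = FALSE),
      iqr = stats::IQR(sub$fs))))
  rownames(summ) <- NULL
  list(values = d0, summary = summ)
}
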
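## From tidy isotopomer tables to RIA series and peptide-level fit tables.

#' Build RIA time series from a tidy isotopomer table
#'
#' Groups the table by peptide-charge within each tissue, computes the
#' chemistry-specific RIA at each time point (m6/(m0+m6) for AA;
#' m0/sum(m0..m5) for HW), and attaches the fixed boundary values: for AA
#' labeling `A0 = 0` and `Ainf` = plateau precursor RIA; for HW labeling
#' `A0` is the natural monoisotopic fraction of the sequence and `Ainf` its
#' binomial depletion at the plateau enrichment. Time points with an
#' undefined RIA (zero denominator) are dropped with a warning count.
#' Charge states are kept separate throughout.
#'
#' @param isoTable Tidy table with columns `sequence`, `charge`, `tissue`,
#'   `day`, `iso`, `auc` (as produced by [integrateRun()] or
#'   [simulateExperiment()]).
#' @param config A [LabelingConfig-class].
#' @return List with `series` (list of [RIATimeSeries-class]) and `meta`
#'   (data.frame of per-series identity: sequence, charge, tissue, proteins,
#'   nProteins, nLysine, totalIntensity).
#' @export
buildRiaSeries <- function(isoTable, config) {
  chem <- config@chemistry
  key <- interaction(isoTable$sequence, isoTable$charge, isoTable$tissue,
                     drop = TRUE)
  groups <- split(isoTable, key)
  series <- vector("list", length(groups))
  meta <- vector("list", length(groups))
  dropped <- 0L
  for (g in seq_along(groups)) {
    tab <- groups[[g]]
    seqc <- tab$sequence[1]; z <- tab$charge[1]; tis <- tab$tissue[1]
    days <- sort(unique(tab$day))
    Avals <- numeric(length(days)); wts <- numeric(length(days))
    for (d in seq_along(days)) {
      sub <- tab[tab$day == days[d], ]
      areas <- stats::setNames(sub$auc, sub$iso)
      Avals[d] <- suppressWarnings(
        if (chem == "AA") riaAA(areas) else riaHW(areas))
      wts[d] <- sum(sub$auc)
    }
    keep <- is.finite(Avals)
    dropped <- dropped + sum(!keep)
    if (chem == "AA") {
      A0 <- 0; Ainf <- config@plateau
    } else {
      A0 <- naturalM0Fraction(seqc, config@abundances)
      Ainf <- hwPlateau(seqc, config@plateau, A0, config@siteTable)
    }
    series[[g]] <- riaTimeSeries(days[keep], Avals[keep], A0, Ainf,
                                 sequence = seqc, charge = z, tissue = tis,
                                 chemistry = chem, weight = wts[keep])
    meta[[g]] <- data.frame(
      sequence = seqc, charge = z, tissue = tis,
      proteins = if ("proteins" %in% names(tab)) tab$proteins[1] else
        NA_character_,
      nProteins = if ("nProteins" %in% names(tab)) tab$nProteins[1] else
        NA_integer_,
      nLysine = sum(strsplit(seqc, "")[[1]] == "K"),
      totalIntensity = sum(tab$auc), stringsAsFactors = FALSE)
  }
  if (dropped > 0)
    warning(dropped, " observation(s) with undefined RIA dropped")
  list(series = series, meta = do.call(rbind, meta))
}

#' Fit turnover rate constants for every peptide-charge series
#'
#' Runs [fitKdeg()] on each series built by [buildRiaSeries()] and returns
#' a tidy peptide-level fit table.
#'
#' @inheritParams buildRiaSeries
#' @param model,kp,precursor Passed to [fitKdeg()].
#' @param minTimepoints Series with fewer observations are skipped.
#' @return data.frame with one row per peptide-charge series: identity
#'   columns plus `model`, `kdeg`, `dk`, `sigmaA`, `r2`, `nPoints`, `sse`,
#'   `aic`, `flag`.
#' @export
fitPeptides <- function(isoTable, config,
                        model = c("one_compartment", "two_compartment",
                                  "convolution"),
                        kp = NULL, precursor = NULL, minTimepoints = 2) {
  model <- match.arg(model)
  built <- buildRiaSeries(isoTable, config)
  rows <- vector("list", length(built$series))
  for (i in seq_along(built$series)) {
    s <- built$series[[i]]
    if (length(s@t) < minTimepoints) next
    fit <- tryCatch(fitKdeg(s, model, kp = kp, precursor = precursor),
                    error = function(e) NULL)
    if (is.null(fit)) next
    rows[[i]] <- cbind(built$meta[i, , drop = FALSE],
      data.frame(model = model, kdeg = fit@kdeg, dk = fit@dk,
                 sigmaA = fit@sigmaA, r2 = fit@r2, nPoints = fit@nPoints,
                 sse = fit@sse, aic = fit@aic, flag = fit@flag,
                 A0 = fit@A0, Ainf = fit@Ainf, stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  rownames(out) <- NULL
  out
}

#' Fractional-synthesis observations for a set of series
#'
#' Converts every (t, RIA) observation to fractional synthesis for pooled
#' (protein-level or reporter-protein) refitting.
#'
#' @param built Output of [buildRiaSeries()].
#' @return data.frame with columns `sequence`, `charge`, `tissue`,
#'   `proteins`, `t`, `fs`, `weight` (total isotopomer intensity of the
#'   observation) and `totalIntensity` of the series.
#' @export
fsObservations <- function(built) {
  rows <- lapply(seq_along(built$series), function(i) {
    s <- built$series[[i]]
    if (s@A0 == s@Ainf || length(s@t) == 0) return(NULL)
    data.frame(sequence = s@sequence, charge = s@charge, tissue = s@tissue,
               proteins = built$meta$proteins[i], t = s@t,
               fs = fractionalSynthesis(s@A, s@A0, s@Ainf),
               weight = s@weight,
               totalIntensity = built$meta$totalIntensity[i],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  rownames(out) <- NULL
  out
}
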
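## Synthetic labeling experiments with known ground truth.

#' SimulationConfig: parameters of a synthetic labeling experiment
#'
#' @slot chemistry `"HW"` or `"AA"`.
#' @slot tissues data.frame with columns `tissue`, `kp` (1/d) and `plateau`
#'   (precursor plateau enrichment) per simulated tissue.
#' @slot nProteins Number of proteins per tissue.
#' @slot peptidesPerProtein Integer range `c(lo, hi)`.
#' @slot fractionDilysine Fraction of peptides carrying two lysines.
#' @slot timePoints Sampling days.
#' @slot noiseCv Multiplicative log-normal CV on each isotopomer area.
#' @slot missingness Dropout probability, a scalar or one value per time
#'   point.
#' @slot detectionFloor Absolute intensity below which an isotopomer area
#'   is reported as 0 (emulates under-reporting of minor peaks in
#'   low-abundance peptides; default 0 = off).
#' @slot additiveSd Standard deviation of additive (intensity-independent)
#'   area noise, making relative errors larger for low-abundance peptides
#'   (default 0 = off).
#' @slot kdegRange Log-uniform bounds for the true `kdeg` draw (1/d).
#' @slot dilysineMode `"integrated"` (label probability taken at each
#'   molecule's synthesis time, integrated over the synthesis-time
#'   distribution) or `"current"` (instantaneous precursor RIA at sampling
#'   time).
#' @slot seed Integer seed; all outputs are deterministic given the config.
#' @export
setClass("SimulationConfig",
  representation(chemistry = "character", tissues = "data.frame",
                 nProteins = "integer", peptidesPerProtein = "integer",
                 fractionDilysine = "numeric", timePoints = "numeric",
                 noiseCv = "numeric", missingness = "numeric",
                 detectionFloor = "numeric", additiveSd = "numeric",
                 kdegRange = "numeric", dilysineMode = "character",
                 seed = "integer"),
  validity = function(object) {
    msg <- NULL
    if (!object@chemistry %in% c("HW", "AA"))
      msg <- c(msg, "chemistry must be 'HW' or 'AA'")
    if (any(object@tissues$kp <= 0) || any(object@tissues$plateau <= 0) ||
        any(object@tissues$plateau >= 1))
      msg <- c(msg, "tissue kp must be > 0 and plateau in (0, 1)")
    if (any(object@timePoints < 0) || is.unsorted(object@timePoints))
      msg <- c(msg, "time points must be nonnegative and sorted")
    if (!length(object@missingness) %in% c(1, length(object@timePoints)))
      msg <- c(msg, "missingness must be scalar or one value per time point")
    if (any(object@missingness < 0) || any(object@missingness > 1) ||
        object@fractionDilysine < 0 || object@fractionDilysine > 1)
      msg <- c(msg, "probabilities must lie in [0, 1]")
    if (any(object@kdegRange <= 0) || object@kdegRange[1] > object@kdegRange[2])
      msg <- c(msg, "kdegRange must be positive and ordered")
    if (is.null(msg)) TRUE else msg
  })

#' Construct a simulation configuration
#'
#' Defaults follow the study design this simulator emulates: an 11-point
#' 0-30 d schedule and plateau 0.45 for amino-acid labeling, a 12-point
#' 0-31 d schedule and plateau 0.046 for heavy-water labeling, and true
#' `kdeg` drawn log-uniformly over the measurable range 0.002-2 1/d.
#'
#' @param chemistry `"HW"` or `"AA"`.
#' @param tissues data.frame(`tissue`, `kp`, `plateau`); default a single
#'   tissue with `kp = 0.5` and the chemistry's default plateau.
#' @param nProteins,peptidesPerProtein,fractionDilysine Cohort shape.
#' @param timePoints Sampling days; chemistry-specific default.
#' @param noiseCv Multiplicative CV on isotopomer areas (default 0.02).
#' @param missingness Dropout probability: scalar or one value per time
#'   point (default 0).
#' @param detectionFloor Absolute intensity below which areas report as 0
#'   (default 0).
#' @param additiveSd Additive area noise SD (default 0).
#' @param kdegRange Log-uniform `kdeg` bounds (default `c(0.002, 2)`).
#' @param dilysineMode See [SimulationConfig-class].
#' @param seed Integer seed.
#' @return A [SimulationConfig-class].
#' @export
simulationConfig <- function(chemistry = c("AA", "HW"), tissues = NULL,
                             nProteins = 20, peptidesPerProtein = c(2, 4),
                             fractionDilysine = 0.2, timePoints = NULL,
                             noiseCv = 0.02, missingness = 0,
                             detectionFloor = 0, additiveSd = 0,
                             kdegRange = c(0.002, 2),
                             dilysineMode = c("integrated", "current"),
                             seed = 1L) {
  chemistry <- match.arg(chemistry)
  dilysineMode <- match.arg(dilysineMode)
  if (is.null(timePoints))
    timePoints <- if (chemistry == "AA")
      c(0, 1, 2, 3, 4, 6, 9, 12, 17, 22, 30)
    else c(0, 1, 2, 3, 6, 7, 9, 13, 16, 21, 24, 31)
  if (is.null(tissues))
    tissues <- data.frame(tissue = "tissue1", kp = 0.5,
                          plateau = if (chemistry == "AA") 0.45 else 0.046)
  new("SimulationConfig", chemistry = chemistry, tissues = tissues,
      nProteins = as.integer(nProteins),
      peptidesPerProtein = as.integer(peptidesPerProtein),
      fractionDilysine = fractionDilysine, timePoints = timePoints,
      noiseCv = noiseCv, missingness = missingness,
      detectionFloor = detectionFloor, additiveSd = additiveSd,
      kdegRange = kdegRange,
      dilysineMode = dilysineMode, seed = as.integer(seed))
}

setMethod("show", "SimulationConfig", function(object) {
  cat(sprintf(
    "SimulationConfig [%s]: %d tissue(s), %d proteins, %d time points, noise CV %.3g, seed %d\n",
    object@chemistry, nrow(object@tissues), object@nProteins,
    length(object@timePoints), object@noiseCv, object@seed))
})

#' Precursor enrichment trajectory of a simulation
#'
#' @param t Time (days).
#' @param precursor A [PrecursorFunction-class].
#' @return Absolute precursor enrichment at `t` (0 at `t = 0`; the plateau
#'   for `t > 0` under the instantaneous kind).
#' @export
simulatePrecursor <- function(t, precursor) precursorEnrichment(precursor, t)

## expsum algebra: f(t) = sum(alpha * exp(-beta t))
.expsumScale <- function(es, s) list(alpha = es$alpha * s, beta = es$beta)
.expsumSquare <- function(es) {
  a <- outer(es$alpha, es$alpha)
  b <- outer(es$beta, es$beta, `+`)
  list(alpha = as.vector(a), beta = as.vector(b))
}
## integral_0^t f(tau) k exp(-k (t - tau)) dtau for an expsum f
.expsumConvK <- function(es, k, t) {
  out <- 0
  for (j in seq_along(es$alpha))
    out <- out + es$alpha[j] * .convExp(es$beta[j], k, t)
  out
}

#' Simulate an isotopomer envelope at one time point
#'
#' Generates the noise-free isotopomer areas of one peptide-charge species
#' at labeling time `t`, consistent with the kinetic models fitted
#' downstream. For amino-acid labeling the labeled fraction of the pool is
#' the precursor-convolution integral, split binomially over one or two
#' lysine sites (dilysine peptides use the precursor RIA at each molecule's
#' synthesis time by default). For heavy-water labeling the monoisotopic
#' fraction follows the convolution model between the natural value and the
#' binomial depletion plateau, with the m1-m5 intensities shaped by the
#' binomial-convolved labeled envelope.
#'
#' @param sequence Peptide sequence.
#' @param chemistry `"HW"` or `"AA"`.
#' @param precursor A [PrecursorFunction-class] (plateau = absolute
#'   enrichment).
#' @param kdeg True degradation rate constant (1/d).
#' @param t Labeling time (days, scalar).
#' @param config A [LabelingConfig-class] supplying site table and natural
#'   abundances (defaults to the chemistry's defaults).
#' @param abundance Total intensity scale factor.
#' @param isoList Isotopomer indices to emit.
#' @param dilysineMode `"integrated"` or `"current"` (see
#'   [SimulationConfig-class]).
#' @return Named numeric vector of areas over `isoList`.
#' @export
simulateEnvelope <- function(sequence, chemistry, precursor, kdeg, t,
                             config = labelingConfig(chemistry,
                                                     precursor@plateau),
                             abundance = 1, isoList = c(0:6, 12),
                             dilysineMode = c("integrated", "current")) {
  dilysineMode <- match.arg(dilysineMode)
  stopifnot(kdeg > 0, length(t) == 1)
  nat <- naturalEnvelope(sequence, nIso = 6, abundances = config@abundances)
  natn <- nat / sum(nat)  # normalized over the first six isotopomers
  m <- stats::setNames(numeric(length(isoList)), isoList)
  es <- .precursorExpsum(precursor)  # normalized rise

  if (chemistry == "AA") {
    nK <- sum(strsplit(sequence, "")[[1]] == "K")
    pAbs <- .expsumScale(es, precursor@plateau)
    if (nK <= 1) {
      L <- if (nK == 1) .expsumConvK(pAbs, kdeg, t) else 0
      for (i in 0:5) if (as.character(i) %in% names(m))
        m[as.character(i)] <- (1 - L) * natn[i + 1]
      if ("6" %in% names(m)) m["6"] <- L * natn[1]
    } else if (nK == 2) {
      if (dilysineMode == "integrated") {
        p2 <- .expsumSquare(pAbs)
        w2 <- .expsumConvK(p2, kdeg, t)
        w1 <- 2 * (.expsumConvK(pAbs, kdeg, t) - w2)
      } else {
        Fnew <- 1 - exp(-kdeg * t)
        p <- precursorEnrichment(precursor, t)
        w2 <- Fnew * p^2
        w1 <- Fnew * 2 * p * (1 - p)
      }
      w0 <- 1 - w1 - w2
      for (i in 0:5) if (as.character(i) %in% names(m))
        m[as.character(i)] <- w0 * natn[i + 1]
      if ("6" %in% names(m)) m["6"] <- w1 * natn[1]
      if ("12" %in% names(m)) m["12"] <- w2 * natn[1]
    } else {
      stop("AA simulation supports peptides with at most 2 lysines")
    }
  } else {
    A0 <- natn[1]
    Ainf <- hwPlateau(sequence, precursor@plateau, A0, config@siteTable)
    rise <- .expsumConvK(es, kdeg, t)
    A <- A0 + (Ainf - A0) * rise
    ## shape m1..m5 as a mixture of the natural tail and the labeled tail
    lab <- .labeledHwShape(sequence, precursor@plateau, config)
    shape <- (1 - rise) * natn[2:6] + rise * lab
    shape <- shape / sum(shape)
    m["0"] <- A
    for (i in 1:5) if (as.character(i) %in% names(m))
      m[as.character(i)] <- (1 - A) * shape[i]
  }
  m * abundance
}

## heavy-water labeled-molecule envelope tail (m1..m5 shape): natural
## envelope convolved with a generalized binomial over the accessible sites
.labeledHwShape <- function(sequence, p, config) {
  N <- accessibleSites(sequence, config@siteTable)
  kmax <- 5
  lw <- lgamma(N + 1) - lgamma(0:kmax + 1) - lgamma(N - 0:kmax + 1)
  w <- exp(lw) * p^(0:kmax) * (1 - p)^(N - 0:kmax)
  w[!is.finite(w) | w < 0] <- 0
  nat <- naturalEnvelope(sequence, nIso = 6, abundances = config@abundances)
  env <- numeric(6)
  for (i in 0:5) for (k in 0:i)
    env[i + 1] <- env[i + 1] + nat[i - k + 1] * w[k + 1]
  tail <- env[2:6]
  tail / sum(tail)
}

.randomPeptide <- function(len, nLysine) {
  pool <- setdiff(names(RESIDUE_MASS), c("K", "R"))
  body <- sample(pool, len - nLysine, replace = TRUE)
  if (nLysine == 0) return(paste(c(body, "R"), collapse = ""))
  if (nLysine == 1) return(paste(c(body, "K"), collapse = ""))
  cut <- sample(seq_len(length(body) - 1), 1)
  paste(c(body[seq_len(cut)], "K", body[-seq_len(cut)], "K"), collapse = "")
}

#' Simulate a full labeling experiment
#'
#' Draws a cohort of proteins and peptides, simulates noise-free isotopomer
#' envelopes at every configured time point, applies multiplicative
#' log-normal intensity noise and dropout, and emits a tidy isotopomer
#' table (same schema as [integrateRun()]) together with a truth ledger.
#' Deterministic given the config's seed.
#'
#' @param config A [SimulationConfig-class].
#' @return List with `isoTable` (tidy isotopomer table), `truth`
#'   (data.frame: `sequence`, `charge`, `protein`, `tissue`, `kdegTrue`,
#'   `nLysine`, `abundance`, plus per-tissue `kp`/`plateau` columns) and
#'   `config`.
#' @export
simulateExperiment <- function(config) {
  oldSeed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(oldSeed)) assign(".Random.seed", oldSeed, .GlobalEnv))
  set.seed(config@seed)

  chem <- config@chemistry
  isoList <- c(0:6, 12)
  sdlog <- if (config@noiseCv > 0) sqrt(log(1 + config@noiseCv^2)) else 0
  rowsIso <- list(); rowsTruth <- list()
  usedSeq <- character(0)
  for (ti in seq_len(nrow(config@tissues))) {
    tis <- config@tissues$tissue[ti]
    pf <- precursorFunction("single_exponential",
                            kp = config@tissues$kp[ti],
                            plateau = config@tissues$plateau[ti])
    lc <- labelingConfig(chem, plateau = config@tissues$plateau[ti])
    for (pr in seq_len(config@nProteins)) {
      acc <- sprintf("%s_P%03d", toupper(substr(tis, 1, 3)), pr)
      kdTrue <- exp(stats::runif(1, log(config@kdegRange[1]),
                                 log(config@kdegRange[2])))
      nPep <- config@peptidesPerProtein[1] +
        sample.int(diff(config@peptidesPerProtein) + 1L, 1) - 1L
      for (pep in seq_len(nPep)) {
        nK <- if (stats::runif(1) < config@fractionDilysine) 2L else 1L
        repeat {
          seqc <- .randomPeptide(sample(8:16, 1), nK)
          if (!seqc %in% usedSeq) break
        }
        usedSeq <- c(usedSeq, seqc)
        z <- sample(2:3, 1)
        abund <- 10^stats::rnorm(1, 0, 1) * 1e6
        miss <- rep(config@missingness, length.out =
                      length(config@timePoints))
        for (di in seq_along(config@timePoints)) {
          day <- config@timePoints[di]
          if (miss[di] > 0 && stats::runif(1) < miss[di]) next
          areas <- simulateEnvelope(seqc, chem, pf, kdTrue, day, lc,
                                    abundance = abund, isoList = isoList,
                                    dilysineMode = config@dilysineMode)
          if (sdlog > 0)
            areas <- areas * stats::rlnorm(length(areas),
                                           -sdlog^2 / 2, sdlog)
          if (config@additiveSd > 0)
            areas <- pmax(areas + stats::rnorm(length(areas), 0,
                                               config@additiveSd), 0)
          if (config@detectionFloor > 0)
            areas[areas < config@detectionFloor] <- 0
          rowsIso[[length(rowsIso) + 1]] <- data.frame(
            sequence = seqc, charge = z, tissue = tis, day = day,
            iso = as.integer(names(areas)), auc = unname(areas),
            nScans = NA_integer_, proteins = acc, nProteins = 1L,
            nLysine = nK, stringsAsFactors = FALSE)
        }
        rowsTruth[[length(rowsTruth) + 1]] <- data.frame(
          sequence = seqc, charge = z, protein = acc, tissue = tis,
          kdegTrue = kdTrue, nLysine = nK, abundance = abund,
          kp = config@tissues$kp[ti], plateau = config@tissues$plateau[ti],
          stringsAsFactors = FALSE)
      }
    }
  }
  isoTable <- do.call(rbind, rowsIso)
  truth <- do.call(rbind, rowsTruth)
  rownames(isoTable) <- rownames(truth) <- NULL
  list(isoTable = isoTable, truth = truth, config = config)
}

#' Write mzML and PSM fixtures for a simulated isotopomer table
#'
#' Builds valid centroided-MS1 mzML files (one per tissue/day) in which
#' each peptide-charge elutes as a Gaussian peak whose trapezoid area
#' reproduces the table's isotopomer areas, plus matching Percolator-style
#' PSM tables and a run manifest. Intended for small peptide sets.
#'
#' @param isoTable Tidy isotopomer table (e.g. from
#'   [simulateExperiment()]).
#' @param dir Output directory (created if needed).
#' @param chemistry `"HW"` or `"AA"` (isotopomer m/z layout).
#' @param peakSd Gaussian elution SD in minutes (default 0.08).
#' @param scanInterval MS1 scan spacing in minutes (default 0.02).
#' @param rtSpacing Retention-time spacing between peptides (default
#'   1.5 min).
#' @param ppmOffset Shift applied to every peak's m/z in ppm (default 0;
#'   use e.g. 30 for a negative-control fixture outside the 25 ppm
#'   tolerance).
#' @return The run manifest data.frame (`mzml`, `psm`, `tissue`, `day`)
#'   with an `rtMap` attribute giving each peptide's elution apex.
#' @export
writeFixtureMzml <- function(isoTable, dir, chemistry = c("HW", "AA"),
                             peakSd = 0.08, scanInterval = 0.02,
                             rtSpacing = 1.5, ppmOffset = 0) {
  chemistry <- match.arg(chemistry)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (nrow(isoTable) == 0)
    return(data.frame(mzml = character(0), psm = character(0),
                      tissue = character(0), day = numeric(0)))
  peps <- unique(isoTable[, c("sequence", "charge")])
  peps$rt <- 5 + (seq_len(nrow(peps)) - 1) * rtSpacing
  peps$proteins <- isoTable$proteins[
    match(paste(peps$sequence, peps$charge),
          paste(isoTable$sequence, isoTable$charge))]
  runs <- unique(isoTable[, c("tissue", "day")])
  manifest <- vector("list", nrow(runs))

  rtGrid <- seq(5 - 0.6, max(peps$rt) + 0.6, by = scanInterval)
  nsc <- length(rtGrid)
  for (rr in seq_len(nrow(runs))) {
    tis <- runs$tissue[rr]; day <- runs$day[rr]
    sub <- isoTable[isoTable$tissue == tis & isoTable$day == day, ]
    ## per-scan peak lists
    pkMz <- vector("list", nsc); pkInt <- vector("list", nsc)
    psmRows <- list()
    for (pp in seq_len(nrow(peps))) {
      pepSub <- sub[sub$sequence == peps$sequence[pp] &
                    sub$charge == peps$charge[pp], ]
      if (nrow(pepSub) == 0) next
      mass <- peptideMonoisotopicMass(peps$sequence[pp])
      rtC <- peps$rt[pp]
      amp <- 1 / (peakSd * sqrt(2 * pi))
      gau <- amp * exp(-(rtGrid - rtC)^2 / (2 * peakSd^2))
      inWin <- which(abs(rtGrid - rtC) <= 0.55)
      for (ii in seq_len(nrow(pepSub))) {
        if (pepSub$auc[ii] <= 0) next
        mz <- isotopomerMz(mass, peps$charge[pp], pepSub$iso[ii], chemistry)
        mz <- mz * (1 + ppmOffset * 1e-6)
        for (s in inWin) {
          pkMz[[s]] <- c(pkMz[[s]], mz)
          pkInt[[s]] <- c(pkInt[[s]], gau[s] * pepSub$auc[ii])
        }
      }
      apex <- which.min(abs(rtGrid - rtC))
      psmRows[[length(psmRows) + 1]] <- data.frame(
        PSMId = sprintf("run%d_%d_%d_1", rr, apex, peps$charge[pp]),
        sequence = peps$sequence[pp], charge = peps$charge[pp],
        scan = apex, retention_time = rtGrid[apex], `q-value` = 0.001,
        proteinIds = peps$proteins[pp], check.names = FALSE,
        stringsAsFactors = FALSE)
    }
    peaks <- lapply(seq_len(nsc), function(s) {
      if (is.null(pkMz[[s]]))
        return(matrix(numeric(0), 0, 2,
                      dimnames = list(NULL, c("mz", "intensity"))))
      ord <- order(pkMz[[s]])
      cbind(mz = pkMz[[s]][ord], intensity = pkInt[[s]][ord])
    })
    npk <- vapply(peaks, nrow, integer(1))
    hdr <- data.frame(
      seqNum = seq_len(nsc), acquisitionNum = seq_len(nsc),
      msLevel = 1L, polarity = 1L, peaksCount = npk,
      totIonCurrent = vapply(peaks, function(p)
        if (nrow(p)) sum(p[, 2]) else 0, numeric(1)),
      retentionTime = rtGrid * 60,
      basePeakMZ = 0, basePeakIntensity = 0, collisionEnergy = 0,
      ionisationEnergy = 0, lowMZ = 0, highMZ = 2000,
      precursorScanNum = 0L, precursorMZ = 0, precursorCharge = 0L,
      precursorIntensity = 0, mergedScan = 0L, mergedResultScanNum = 0L,
      mergedResultStartScanNum = 0L, mergedResultEndScanNum = 0L,
      injectionTime = 0, filterString = NA_character_,
      spectrumId = paste0("scan=", seq_len(nsc)), centroided = TRUE,
      ionMobilityDriftTime = NA_real_,
      isolationWindowTargetMZ = NA_real_,
      isolationWindowLowerOffset = NA_real_,
      isolationWindowUpperOffset = NA_real_,
      scanWindowLowerLimit = 0, scanWindowUpperLimit = 2000)
    stem <- sprintf("%s_day%g", tis, day)
    mzmlPath <- file.path(dir, paste0(stem, ".mzML"))
    psmPath <- file.path(dir, paste0(stem, "_psms.tsv"))
    mzR::writeMSData(peaks, mzmlPath, header = hdr, outformat = "mzml")
    psmTab <- do.call(rbind, psmRows)
    utils::write.table(psmTab, psmPath, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    manifest[[rr]] <- data.frame(mzml = mzmlPath, psm = psmPath,
                                 tissue = tis, day = day,
                                 stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, manifest)
  attr(out, "rtMap") <- peps
  out
}
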
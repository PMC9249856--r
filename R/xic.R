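## MS1 chromatogram extraction and integration (the peak-integration stage).

#' Read centroided MS1 spectra from an mzML file
#'
#' Loads all MS-level-1 spectra into memory through Bioconductor's mzR.
#' Retention times are converted to minutes.
#'
#' @param path Path to a centroided mzML file.
#' @return A list of class `Ms1Spectra` with elements `rt` (minutes,
#'   ascending), `scan` (acquisition numbers) and `peaks` (list of
#'   two-column mz/intensity matrices).
#' @export
readMs1 <- function(path) {
  ms <- mzR::openMSfile(path)
  on.exit(mzR::close(ms))
  hdr <- mzR::header(ms)
  ms1 <- which(hdr$msLevel == 1L)
  pk <- mzR::peaks(ms)
  if (!is.list(pk)) pk <- list(pk)
  out <- list(rt = hdr$retentionTime[ms1] / 60,
              scan = hdr$acquisitionNum[ms1],
              peaks = pk[ms1])
  ord <- order(out$rt)
  out$rt <- out$rt[ord]; out$scan <- out$scan[ord]
  out$peaks <- out$peaks[ord]
  class(out) <- "Ms1Spectra"
  out
}

#' Extract an isotopomer ion chromatogram
#'
#' For every MS1 scan with retention time inside the window, sums the
#' intensity of centroid peaks within the ppm tolerance of the target m/z.
#' Scans with no matching centroid contribute zero intensity, preserving the
#' trapezoid geometry across gaps.
#'
#' @param ms1 An `Ms1Spectra` object from [readMs1()].
#' @param mzTarget Target m/z (Th).
#' @param rtCenter Window center (minutes), typically the identification
#'   scan's retention time.
#' @param rtHalfWindow Window half-width in minutes (default 0.5).
#' @param ppm Mass tolerance in parts per million (default 25).
#' @return data.frame of class `XicTrace` with columns `rt` (minutes,
#'   strictly increasing) and `intensity`; empty when no MS1 scan falls in
#'   the window.
#' @export
extractXic <- function(ms1, mzTarget, rtCenter, rtHalfWindow = 0.5,
                       ppm = 25) {
  sel <- which(ms1$rt >= rtCenter - rtHalfWindow &
               ms1$rt <= rtCenter + rtHalfWindow)
  tol <- mzTarget * ppm * 1e-6
  inten <- vapply(sel, function(j) {
    p <- ms1$peaks[[j]]
    if (length(p) == 0 || nrow(p) == 0) return(0)
    hit <- abs(p[, 1] - mzTarget) <= tol
    if (any(hit)) sum(p[hit, 2]) else 0
  }, numeric(1))
  out <- data.frame(rt = ms1$rt[sel], intensity = inten)
  class(out) <- c("XicTrace", "data.frame")
  out
}

#' Trapezoidal area under a chromatogram
#'
#' @param trace An `XicTrace` (or any data.frame with `rt` and `intensity`).
#' @return Area under the curve (intensity x minutes); 0 for traces with
#'   fewer than two points.
#' @export
#' @examples
#' integrateTrapezoid(data.frame(rt = c(0, 1, 2), intensity = c(0, 10, 0)))
integrateTrapezoid <- function(trace) {
  n <- nrow(trace)
  if (is.null(n) || n < 2) return(0)
  rt <- trace$rt; y <- trace$intensity
  sum(diff(rt) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' Integrate isotopomer chromatograms for one run
#'
#' For every unique peptide-charge among the PSMs, computes the theoretical
#' m/z of each configured isotopomer from the stripped (unlabeled) sequence
#' plus retained non-label modifications, extracts the chromatogram around
#' the identification retention time, and integrates it by the trapezoid
#' rule. All configured isotopomers are integrated regardless of whether the
#' heavy form was itself identified. When a peptide-charge has several PSMs
#' in the run, the retention time of the lowest-q PSM anchors the window.
#'
#' @param psms PSM data.frame from [parsePsmTable()]; rows with missing `rt`
#'   get their retention time from the scan number via the spectra header.
#' @param ms1 `Ms1Spectra` object (or mzML path, read on the fly).
#' @param tissue,day Labeling context recorded in the output.
#' @param isoList Isotopomer indices to integrate (default 0:6 and 12).
#' @param rtHalfWindow,ppm Extraction parameters (defaults 0.5 min, 25 ppm).
#' @param chemistry `"HW"` or `"AA"` (meaning of isotopomer indices 6/12).
#' @return Tidy data.frame: one row per peptide/charge/isotopomer with
#'   columns `sequence`, `charge`, `tissue`, `day`, `iso`, `auc`, `nScans`,
#'   `proteins`, `nProteins`, `nLysine`.
#' @export
integrateRun <- function(psms, ms1, tissue, day, isoList = c(0:6, 12),
                         rtHalfWindow = 0.5, ppm = 25,
                         chemistry = c("HW", "AA")) {
  chemistry <- match.arg(chemistry)
  if (is.character(ms1)) ms1 <- readMs1(ms1)
  if (nrow(psms) == 0)
    return(data.frame(sequence = character(0), charge = integer(0),
                      tissue = character(0), day = numeric(0),
                      iso = integer(0), auc = numeric(0),
                      nScans = integer(0), proteins = character(0),
                      nProteins = integer(0), nLysine = integer(0)))
  ## one window per peptide-charge: anchor at the best (lowest q) PSM
  ord <- order(psms$qValue)
  best <- psms[ord, ][!duplicated(psms[ord, c("sequence", "charge")]), ]
  out <- vector("list", nrow(best))
  for (r in seq_len(nrow(best))) {
    p <- best[r, ]
    rt <- p$rt
    if (is.na(rt)) {
      hit <- match(p$scan, ms1$scan)
      if (is.na(hit))
        stop("PSM scan ", p$scan, " not found in MS1 spectra and no ",
             "retention time given")
      rt <- ms1$rt[hit]
    }
    mass <- peptideMonoisotopicMass(p$sequence) + p$modMassShift
    areas <- numeric(length(isoList))
    nsc <- integer(length(isoList))
    for (k in seq_along(isoList)) {
      mz <- isotopomerMz(mass, p$charge, isoList[k], chemistry)
      tr <- extractXic(ms1, mz, rt, rtHalfWindow, ppm)
      areas[k] <- integrateTrapezoid(tr)
      nsc[k] <- nrow(tr)
    }
    out[[r]] <- data.frame(
      sequence = p$sequence, charge = p$charge, tissue = tissue, day = day,
      iso = as.integer(isoList), auc = areas, nScans = nsc,
      proteins = p$proteins, nProteins = p$nProteins, nLysine = p$nLysine,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Integrate a whole labeled experiment from a run manifest
#'
#' @param manifest data.frame with columns `mzml`, `psm`, `tissue`, `day`
#'   mapping each mzML file (and its PSM table) to a labeling time point.
#' @param qThreshold q-value threshold passed to [parsePsmTable()].
#' @inheritParams integrateRun
#' @return Row-bound tidy isotopomer table over all runs.
#' @export
integrateManifest <- function(manifest, isoList = c(0:6, 12),
                              rtHalfWindow = 0.5, ppm = 25,
                              chemistry = c("HW", "AA"), qThreshold = 0.01) {
  chemistry <- match.arg(chemistry)
  need <- c("mzml", "psm", "tissue", "day")
  miss <- setdiff(need, names(manifest))
  if (length(miss))
    stop("manifest is missing column(s): ", paste(miss, collapse = ", "))
  gone <- manifest$mzml[!file.exists(manifest$mzml)]
  if (length(gone))
    stop("manifest lists missing mzML file(s): ", paste(gone, collapse = ", "))
  res <- lapply(seq_len(nrow(manifest)), function(r) {
    psms <- parsePsmTable(manifest$psm[r], qThreshold = qThreshold)
    integrateRun(psms, manifest$mzml[r], manifest$tissue[r], manifest$day[r],
                 isoList, rtHalfWindow, ppm, chemistry)
  })
  do.call(rbind, res)
}
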
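#' Monoisotopic mass of a peptide
#'
#' Sum of residue monoisotopic masses plus one water, plus any additional
#' mass shifts (e.g. retained non-label modifications such as +15.9949
#' methionine oxidation).
#'
#' @param sequence Peptide sequence using the 20 standard residue letters.
#' @param extraShifts Numeric vector of additional mass shifts in Da.
#' @return Neutral monoisotopic mass in Da.
#' @export
#' @examples
#' peptideMonoisotopicMass("G")        # 75.03203
#' peptideMonoisotopicMass("PEPTIDE")  # 799.35996
peptideMonoisotopicMass <- function(sequence, extraShifts = numeric(0)) {
  res <- strsplit(sequence, "")[[1]]
  unknown <- setdiff(res, names(RESIDUE_MASS))
  if (length(unknown))
    stop("unknown residue letter(s): ", paste(unique(unknown), collapse = ", "))
  sum(RESIDUE_MASS[res]) + WATER_MASS + sum(extraShifts)
}

#' Theoretical m/z of an isotopomer peak
#'
#' For isotopomer indices 0-5 the spacing is the 13C-12C mass difference
#' (1.003355 Da) per index. Under amino-acid labeling, index 6 is the
#' monoisotopic peak of the single heavy-lysine form (+6.0201 Da) and index
#' 12 the double heavy-lysine form (+12.0402 Da).
#'
#' @param neutralMass Neutral monoisotopic mass of the unlabeled peptide (Da).
#' @param charge Positive integer charge.
#' @param i Isotopomer index, one of 0-6 or 12.
#' @param chemistry `"HW"` or `"AA"`; decides the meaning of indices 6/12.
#' @return m/z in Thomson.
#' @export
#' @examples
#' isotopomerMz(1000, 2, 0)                     # 501.00728
#' isotopomerMz(1000, 1, 6, chemistry = "AA")   # 1007.0274
isotopomerMz <- function(neutralMass, charge, i, chemistry = c("HW", "AA")) {
  chemistry <- match.arg(chemistry)
  if (charge < 1) stop("charge must be >= 1")
  if (!i %in% c(0:6, 12L)) stop("isotopomer index must be one of 0-6, 12")
  shift <-
    if (chemistry == "AA" && i == 6) HEAVY_K_SHIFT
    else if (chemistry == "AA" && i == 12) 2 * HEAVY_K_SHIFT
    else i * ISO_SPACING
  (neutralMass + shift + charge * PROTON_MASS) / charge
}

#' Elemental composition of a peptide
#'
#' @param sequence Peptide sequence.
#' @return Named integer vector of C, H, N, O, S atom counts (residues plus
#'   one water).
#' @export
peptideComposition <- function(sequence) {
  res <- strsplit(sequence, "")[[1]]
  unknown <- setdiff(res, rownames(RESIDUE_COMPOSITION))
  if (length(unknown))
    stop("unknown residue letter(s): ", paste(unique(unknown), collapse = ", "))
  comp <- colSums(RESIDUE_COMPOSITION[res, , drop = FALSE])
  comp["H"] <- comp["H"] + 2
  comp["O"] <- comp["O"] + 1
  comp
}

#' Natural isotopomer envelope of a peptide
#'
#' Convolves the per-element natural isotope distributions (by nominal mass
#' offset) over the peptide's elemental composition.
#'
#' @param sequence Peptide sequence.
#' @param nIso Number of isotopomers to return (offsets 0 .. nIso-1).
#' @param abundances Per-element abundance tables; default
#'   [naturalAbundances()].
#' @return Numeric vector of relative abundances summing to <= 1 (the full
#'   distribution over all offsets sums to 1).
#' @export
naturalEnvelope <- function(sequence, nIso = 6,
                            abundances = naturalAbundances()) {
  comp <- peptideComposition(sequence)
  env <- 1
  for (el in names(comp)) {
    n <- comp[[el]]
    if (n == 0) next
    d <- abundances[[el]]
    for (j in seq_len(n)) {
      env <- convolve(env, rev(d), type = "open")
      if (length(env) > nIso + 4) env <- env[seq_len(nIso + 4)]
    }
  }
  env <- pmax(env, 0)
  out <- numeric(nIso)
  take <- seq_len(min(nIso, length(env)))
  out[take] <- env[take]
  out
}

#' Natural monoisotopic fraction over the first six isotopomers
#'
#' The prelabeling RIA `A0` for heavy-water labeling: the natural abundance
#' of the monoisotopic peak divided by the summed abundance of isotopomers
#' m0..m5.
#'
#' @inheritParams naturalEnvelope
#' @return Fraction in (0, 1].
#' @export
#' @examples
#' naturalM0Fraction("PEPTIDEK")
naturalM0Fraction <- function(sequence, abundances = naturalAbundances()) {
  env <- naturalEnvelope(sequence, nIso = 6, abundances = abundances)
  env[1] / sum(env)
}
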
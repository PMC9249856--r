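## Physical constants and reference tables used throughout the package.

## Monoisotopic mass of a proton (Da); used to convert neutral mass to m/z.
PROTON_MASS <- 1.00727646

## Monoisotopic mass of water (Da); added once per peptide chain.
WATER_MASS <- 18.0105646

## Nominal isotopomer spacing (Da): the 13C-12C mass difference. At 25 ppm
## extraction tolerance the 2H/13C spacing difference stays inside the window
## for tryptic peptides, so a single constant keeps extraction deterministic.
ISO_SPACING <- 1.003355

## Mass shift of one 13C6-lysine (Da), as annotated by the search engine.
HEAVY_K_SHIFT <- 6.0201

## Monoisotopic residue masses (Da) for the 20 standard amino acids.
RESIDUE_MASS <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)

## Elemental composition (C, H, N, O, S) of each residue (amino acid - H2O).
RESIDUE_COMPOSITION <- rbind(
  G = c(2,  3, 1, 1, 0), A = c(3,  5, 1, 1, 0), S = c(3,  5, 1, 2, 0),
  P = c(5,  7, 1, 1, 0), V = c(5,  9, 1, 1, 0), T = c(4,  7, 1, 2, 0),
  C = c(3,  5, 1, 1, 1), L = c(6, 11, 1, 1, 0), I = c(6, 11, 1, 1, 0),
  N = c(4,  6, 2, 2, 0), D = c(4,  5, 1, 3, 0), Q = c(5,  8, 2, 2, 0),
  K = c(6, 12, 2, 1, 0), E = c(5,  7, 1, 3, 0), M = c(5,  9, 1, 1, 1),
  H = c(6,  7, 3, 1, 0), F = c(9,  9, 1, 1, 0), R = c(6, 12, 4, 1, 0),
  Y = c(9,  9, 1, 2, 0), W = c(11, 10, 2, 1, 0)
)
colnames(RESIDUE_COMPOSITION) <- c("C", "H", "N", "O", "S")

## Representative natural isotope abundances (fractions per element, indexed
## by neutron-number offset 0, 1, 2, ...), after Berglund & Wieser.
NATURAL_ABUNDANCE <- list(
  C = c(0.9893, 0.0107),
  H = c(0.999885, 0.000115),
  N = c(0.99636, 0.00364),
  O = c(0.99757, 0.00038, 0.00205),
  S = c(0.9499, 0.0075, 0.0425, 0, 0.0001)
)

## Accessible deuterium labeling sites per residue under heavy-water labeling
## (tritiated-water accessibility data; the table conventionally used by
## heavy-water turnover software). Values are effective site counts and may
## be fractional.
COMMERFORD_SITES <- c(
  A = 4.00, R = 3.43, N = 1.89, D = 1.89, C = 1.62, E = 3.95, Q = 3.95,
  G = 2.06, H = 2.88, I = 1.00, L = 0.60, K = 0.54, M = 1.12, F = 0.32,
  P = 2.59, S = 2.61, T = 0.20, W = 0.08, Y = 0.42, V = 0.56
)

#' Accessible heavy-water labeling sites per residue
#'
#' Returns the per-residue counts of hydrogen positions that stably exchange
#' with body-water deuterium during biosynthesis. The sum over a peptide
#' sequence sets the heavy-water labeling plateau (see [hwPlateau()]).
#'
#' @return Named numeric vector over the 20 standard residues.
#' @export
#' @examples
#' commerfordSites()[c("A", "K")]
commerfordSites <- function() COMMERFORD_SITES

#' Natural isotope abundance tables
#'
#' Per-element isotope abundance fractions, indexed by neutron-number offset
#' (position 1 = lightest isotope), used to compute natural peptide
#' isotopomer envelopes.
#'
#' @return Named list of numeric vectors for C, H, N, O, S.
#' @export
naturalAbundances <- function() NATURAL_ABUNDANCE
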
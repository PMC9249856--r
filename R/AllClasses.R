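#' @import methods
NULL

#' LabelingConfig: label chemistry and precursor context
#'
#' Bundles everything needed to turn integrated isotopomer areas into
#' relative isotope abundance (RIA) observations and model boundary values:
#' the label chemistry, the plateau precursor enrichment, the per-residue
#' accessible-site table (heavy water), and natural isotope abundances.
#'
#' @slot chemistry `"HW"` (heavy water) or `"AA"` (amino acid, 13C6-lysine).
#' @slot plateau Plateau precursor enrichment: body-water deuterium fraction
#'   for HW (default 0.046) or dietary heavy-lysine RIA for AA (default 0.45).
#' @slot siteTable Named numeric vector of accessible deuterium sites per
#'   residue (HW only; see [commerfordSites()]).
#' @slot abundances Per-element natural isotope abundance list.
#'
#' @export
setClass("LabelingConfig",
  representation(chemistry = "character", plateau = "numeric",
                 siteTable = "numeric", abundances = "list"),
  validity = function(object) {
    msg <- NULL
    if (!object@chemistry %in% c("HW", "AA"))
      msg <- c(msg, "chemistry must be 'HW' or 'AA'")
    if (length(object@plateau) != 1 || is.na(object@plateau) ||
        object@plateau <= 0 || object@plateau >= 1)
      msg <- c(msg, "plateau must be a single value in (0, 1)")
    if (object@chemistry == "HW" &&
        !all(names(RESIDUE_MASS) %in% names(object@siteTable)))
      msg <- c(msg, "siteTable must cover all 20 standard residues")
    if (is.null(msg)) TRUE else msg
  })

#' Construct a labeling configuration
#'
#' @param chemistry `"HW"` or `"AA"`.
#' @param plateau Plateau precursor enrichment; defaults to 0.046 for HW
#'   (8% drinking water protocol) and 0.45 for AA (heavy-lysine diet).
#' @param siteTable Accessible-site table (HW); default [commerfordSites()].
#' @param abundances Natural abundance tables; default [naturalAbundances()].
#' @return A [LabelingConfig-class] object.
#' @export
#' @examples
#' labelingConfig("AA")
#' labelingConfig("HW", plateau = 0.046)
labelingConfig <- function(chemistry = c("HW", "AA"), plateau = NULL,
                           siteTable = commerfordSites(),
                           abundances = naturalAbundances()) {
  chemistry <- match.arg(chemistry)
  if (is.null(plateau)) plateau <- if (chemistry == "HW") 0.046 else 0.45
  new("LabelingConfig", chemistry = chemistry, plateau = plateau,
      siteTable = siteTable, abundances = abundances)
}

setMethod("show", "LabelingConfig", function(object) {
  cat("LabelingConfig:", object@chemistry,
      "| plateau precursor enrichment:", object@plateau, "\n")
})

#' PrecursorFunction: normalized precursor enrichment kinetics
#'
#' Describes the rise of precursor enrichment from 0 toward its plateau.
#' The normalized form `f(t)` rises from 0 to 1; absolute enrichment is
#' `plateau * f(t)`.
#'
#' Kinds: `"instantaneous"` (f = 1 for t > 0), `"single_exponential"`
#' (f = 1 - exp(-k_p t), parameter `kp`), and `"two_exponential"` (the
#' reutilization model with parameters `a`, `b`, `r`: soluble-pool exchange
#' rate `b`, global protein degradation rate `a`, pool-size ratio `r`,
#' yielding a bi-exponential rise).
#'
#' @slot kind Character; one of the three kinds above.
#' @slot parameters Named numeric vector (`kp`, or `a`, `b`, `r`).
#' @slot plateau Plateau enrichment (fraction).
#' @export
setClass("PrecursorFunction",
  representation(kind = "character", parameters = "numeric",
                 plateau = "numeric"),
  validity = function(object) {
    msg <- NULL
    kinds <- c("instantaneous", "single_exponential", "two_exponential")
    if (!object@kind %in% kinds)
      msg <- c(msg, paste("kind must be one of:", paste(kinds, collapse = ", ")))
    if (object@kind == "single_exponential" &&
        (is.na(object@parameters["kp"]) || object@parameters["kp"] <= 0))
      msg <- c(msg, "single_exponential requires parameter kp > 0")
    if (object@kind == "two_exponential") {
      p <- object@parameters
      if (any(is.na(p[c("a", "b", "r")])) || any(p[c("a", "b", "r")] <= 0))
        msg <- c(msg, "two_exponential requires parameters a, b, r > 0")
    }
    if (length(object@plateau) != 1 || object@plateau <= 0 || object@plateau > 1)
      msg <- c(msg, "plateau must be in (0, 1]")
    if (is.null(msg)) TRUE else msg
  })

#' Construct a precursor enrichment function
#'
#' @param kind `"instantaneous"`, `"single_exponential"` or
#'   `"two_exponential"`.
#' @param kp Rate constant (1/d) for the single-exponential rise.
#' @param a,b,r Parameters of the two-exponential reutilization model.
#' @param plateau Plateau enrichment (fraction).
#' @return A [PrecursorFunction-class] object.
#' @export
#' @examples
#' precursorFunction("single_exponential", kp = 0.5, plateau = 0.45)
precursorFunction <- function(kind = c("single_exponential", "instantaneous",
                                       "two_exponential"),
                              kp = NULL, a = NULL, b = NULL, r = NULL,
                              plateau = 1) {
  kind <- match.arg(kind)
  pars <- switch(kind,
    instantaneous = numeric(0),
    single_exponential = c(kp = as.numeric(kp)),
    two_exponential = c(a = as.numeric(a), b = as.numeric(b),
                        r = as.numeric(r)))
  new("PrecursorFunction", kind = kind, parameters = pars, plateau = plateau)
}

setMethod("show", "PrecursorFunction", function(object) {
  cat("PrecursorFunction:", object@kind, "| plateau:", object@plateau)
  if (length(object@parameters))
    cat(" |", paste(names(object@parameters),
                    signif(object@parameters, 4), sep = "=", collapse = " "))
  cat("\n")
})

#' RIATimeSeries: one peptide-charge labeling time course
#'
#' Holds the (time, RIA) observations of a single peptide-charge series in
#' one tissue, together with the boundary values needed for kinetic fitting:
#' the prelabeling RIA `A0` and the asymptotic RIA `Ainf`. For heavy-water
#' labeling A decreases from the natural monoisotopic fraction toward the
#' plateau; for amino-acid labeling A rises from 0 toward the precursor RIA.
#'
#' @slot sequence Peptide sequence (plain residues).
#' @slot charge Positive integer charge state.
#' @slot tissue Tissue label.
#' @slot chemistry `"HW"` or `"AA"`.
#' @slot t Time points (days), strictly increasing.
#' @slot A Observed RIA at each time point, in `[0, 1]`.
#' @slot weight Per-observation weight (typically total isotopomer intensity).
#' @slot A0 Initial (prelabeling) RIA.
#' @slot Ainf Asymptotic RIA.
#' @export
setClass("RIATimeSeries",
  representation(sequence = "character", charge = "integer",
                 tissue = "character", chemistry = "character",
                 t = "numeric", A = "numeric", weight = "numeric",
                 A0 = "numeric", Ainf = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (length(object@t) != length(object@A))
      msg <- c(msg, "t and A must have equal length")
    if (any(object@t < 0)) msg <- c(msg, "time points must be >= 0")
    if (is.unsorted(object@t, strictly = TRUE))
      msg <- c(msg, "time points must be strictly increasing")
    if (any(object@A < -1e-9 | object@A > 1 + 1e-9, na.rm = TRUE))
      msg <- c(msg, "RIA observations must lie in [0, 1]")
    if (is.null(msg)) TRUE else msg
  })

#' Construct an RIA time series
#'
#' @param sequence,charge,tissue,chemistry Series identity.
#' @param t,A Observations (days; RIA fractions). Sorted by `t` on input.
#' @param weight Optional per-observation weights (default 1).
#' @param A0,Ainf Boundary RIA values fixed from the labeling configuration.
#' @return An [RIATimeSeries-class] object.
#' @export
riaTimeSeries <- function(t, A, A0, Ainf, sequence = "PEPTIDE", charge = 2L,
                          tissue = "tissue", chemistry = "AA", weight = NULL) {
  ord <- order(t)
  t <- as.numeric(t)[ord]; A <- as.numeric(A)[ord]
  if (is.null(weight)) weight <- rep(1, length(t)) else weight <- weight[ord]
  new("RIATimeSeries", sequence = sequence, charge = as.integer(charge),
      tissue = tissue, chemistry = chemistry, t = t, A = pmin(pmax(A, 0), 1),
      weight = as.numeric(weight), A0 = A0, Ainf = Ainf)
}

setMethod("show", "RIATimeSeries", function(object) {
  cat(sprintf("RIATimeSeries %s/%d [%s, %s]: %d points, A0=%.4g, Ainf=%.4g\n",
              object@sequence, object@charge, object@tissue,
              object@chemistry, length(object@t), object@A0, object@Ainf))
})

#' KineticFit: a fitted turnover rate constant
#'
#' Result of fitting a kinetic model to one RIA time series. The only free
#' kinetic parameter is `kdeg`; `kp` (or a full precursor function) is fixed
#' during the fit.
#'
#' @slot kdeg Best-fit degradation rate constant (1/d).
#' @slot dk First-order fitting error of `kdeg` (1/d).
#' @slot sigmaA Residual RIA error, sqrt(SSE/(n-1)).
#' @slot r2 Coefficient of determination, floored at 0 for filtering.
#' @slot r2raw Unfloored R^2 (may be negative).
#' @slot sse Residual sum of squares.
#' @slot nPoints Number of observations fitted.
#' @slot modelId `"one_compartment"`, `"two_compartment"` or `"convolution"`.
#' @slot kp Fixed precursor rate constant (NA for one-compartment).
#' @slot precursor Fixed precursor function (convolution model) or NULL.
#' @slot A0,Ainf Boundary RIA values used.
#' @slot logL Gaussian log-likelihood at the optimum.
#' @slot aic Akaike information criterion (free kinetic parameters + noise
#'   variance).
#' @slot converged Logical; optimizer convergence.
#' @slot flag Character diagnostic (`""` when clean; e.g. `"at_bound"`,
#'   `"no_signal"`).
#' @export
setClass("KineticFit",
  representation(kdeg = "numeric", dk = "numeric", sigmaA = "numeric",
                 r2 = "numeric", r2raw = "numeric", sse = "numeric",
                 nPoints = "integer", modelId = "character", kp = "numeric",
                 precursor = "ANY", A0 = "numeric", Ainf = "numeric",
                 logL = "numeric", aic = "numeric", converged = "logical",
                 flag = "character"),
  validity = function(object) {
    msg <- NULL
    if (!is.na(object@kdeg) && object@kdeg <= 0)
      msg <- c(msg, "kdeg must be > 0")
    if (!is.na(object@r2) && (object@r2 < 0 || object@r2 > 1))
      msg <- c(msg, "reported r2 must lie in [0, 1]")
    if (is.null(msg)) TRUE else msg
  })

setMethod("show", "KineticFit", function(object) {
  cat(sprintf(
    "KineticFit [%s]: kdeg=%.5g 1/d (dk=%.3g), R2=%.3f, sigmaA=%.3g, n=%d%s\n",
    object@modelId, object@kdeg, object@dk, object@r2, object@sigmaA,
    object@nPoints,
    if (nzchar(object@flag)) paste0(" [", object@flag, "]") else ""))
})

#' @rdname KineticFit-class
#' @param object A `KineticFit`.
#' @export
setGeneric("kdeg", function(object) standardGeneric("kdeg"))
#' @rdname KineticFit-class
#' @export
setMethod("kdeg", "KineticFit", function(object) object@kdeg)

#' @rdname KineticFit-class
#' @export
setGeneric("fitError", function(object) standardGeneric("fitError"))
#' @rdname KineticFit-class
#' @export
setMethod("fitError", "KineticFit", function(object) object@dk)

#' @rdname KineticFit-class
#' @export
setGeneric("sigmaA", function(object) standardGeneric("sigmaA"))
#' @rdname KineticFit-class
#' @export
setMethod("sigmaA", "KineticFit", function(object) object@sigmaA)

#' @rdname KineticFit-class
#' @export
setGeneric("rSquared", function(object, ...) standardGeneric("rSquared"))
#' @rdname KineticFit-class
#' @export
setMethod("rSquared", "KineticFit", function(object) object@r2)

#' @rdname KineticFit-class
#' @export
setGeneric("aic", function(object) standardGeneric("aic"))
#' @rdname KineticFit-class
#' @export
setMethod("aic", "KineticFit", function(object) object@aic)

#' PrecursorEstimate: an estimated precursor kinetics model
#'
#' Result of one of the precursor-estimation strategies: the method name,
#' the tissue, the estimated [PrecursorFunction-class], and fit diagnostics.
#'
#' @slot method Estimation method identifier.
#' @slot tissue Tissue label.
#' @slot fn The estimated precursor function.
#' @slot sse Residual sum of squares of the precursor fit.
#' @slot n Number of observations used.
#' @slot details List of method-specific extras (e.g. excluded counts, AIC).
#' @export
setClass("PrecursorEstimate",
  representation(method = "character", tissue = "character",
                 fn = "PrecursorFunction", sse = "numeric", n = "integer",
                 details = "list"))

setMethod("show", "PrecursorEstimate", function(object) {
  cat(sprintf("PrecursorEstimate [%s, %s]: ", object@method, object@tissue))
  show(object@fn)
})

#' @rdname PrecursorEstimate-class
#' @param object A `PrecursorEstimate`.
#' @export
setGeneric("precursorFn", function(object) standardGeneric("precursorFn"))
#' @rdname PrecursorEstimate-class
#' @export
setMethod("precursorFn", "PrecursorEstimate", function(object) object@fn)
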
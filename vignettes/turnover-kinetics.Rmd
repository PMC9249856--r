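---
title: "Measuring protein turnover from stable-isotope labeling time courses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring protein turnover from stable-isotope labeling time courses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isoturn)
```

## The measurement problem

At steady state a protein pool is constantly replaced: synthesis feeds
molecules in, first-order degradation removes them at rate $k_{deg}$
(1/d). Because the pool size does not change, replacement can only be
observed by feeding a stable-isotope tracer and watching labeled molecules
displace unlabeled ones. In intact animals two tracers dominate:

* **Amino-acid (AA) labeling**: a heavy essential amino acid
  ($^{13}$C$_6$-lysine) in the diet. A labeled peptide appears +6.0201 Da
  above its light form; the relative isotope abundance (RIA) tracked over
  time is $A_t = m_6/(m_0 + m_6)$, rising from 0 toward the dietary
  plateau RIA$_p$ (0.45 here).
* **Heavy-water (HW) labeling**: deuterated drinking water. Deuterium
  enters many residue positions during biosynthesis, gradually shifting
  the whole isotopomer envelope; the statistic is
  $A_t = m_0/\sum_{i=0}^{5} m_i$, *decreasing* from the natural
  monoisotopic fraction toward a sequence-specific plateau.

`isoturn` implements the full chain: MS1 isotopomer integration from mzML,
RIA series construction, kinetic fitting with precursor-delay correction,
precursor-kinetics estimation, protein-level aggregation, and a
ground-truth simulator that exercises every stage.

## Kinetic models

With instantaneous precursor equilibration the labeling curve is
one-compartment:

$$A_t = A_0 + (A_\infty - A_0)(1 - e^{-k t}).$$

Dietary amino acids equilibrate slowly through body pools. When the
precursor itself rises as $1 - e^{-k_p t}$, the protein curve becomes the
two-compartment form

$$A_t = A_0 + (A_\infty - A_0)
\left[1 - \frac{k_p e^{-kt} - k e^{-k_p t}}{k_p - k}\right],$$

with the removable singularity at $k = k_p$ evaluated as
$1 - (1 + kt)e^{-kt}$. The general form is a convolution
$A_t = A_0 + (A_\infty - A_0)\, k \int_0^t f_p(\tau) e^{-k(t-\tau)}
d\tau$ over any normalized precursor rise $f_p$; `convolutionA()`
evaluates it in closed form for instantaneous, single-exponential and
bi-exponential precursors (every precursor here is a sum of exponentials,
so the convolution is, too). With a single-exponential $f_p$ the
convolution reproduces the two-compartment curve to machine precision —
a standing identity test in the suite.

Ignoring a genuine delay biases rates low: fitting one-compartment curves
to delayed-precursor data underestimates $k_{deg}$, and the bias grows as
$k_p$ falls. The gap between the two models has the closed form
$(A_\infty - A_0)\,\tfrac{k}{k_p - k}(e^{-k_p t} - e^{-kt})$, maximal at
$t^\ast = \ln(k_p/k)/(k_p - k)$. Two consequences documented by the
tests: the sup-norm gap decays exactly one decade per decade of $k_p$,
and at $k_p = 600$/d the transient peaks around 15 minutes — below the
first sampling day — so on the daily sampling grid the models agree
within $10^{-3}$ relative for $k \le 1$/d, which is the sense in which
such a precursor is "instantaneous".

### Boundary values

* AA: $A_0 = 0$, $A_\infty =$ RIA$_p$ (default 0.45).
* HW: $A_0$ is computed from the peptide's elemental composition by
  convolving per-element natural isotope abundances;
  $A_\infty = A_0 (1-p)^N$, the binomial depletion of the fully light
  isotopomer across the $N$ accessible deuterium sites of the sequence
  (per-residue site counts from tritiated-water accessibility data,
  shipped as `commerfordSites()`; $p$ is the body-water plateau, default
  0.046). The binomial-depletion form is our choice where the exact
  published form is not printed; it is exact for the $m_0$ statistic the
  pipeline actually fits.

### Fitting and errors

`fitKdeg()` minimizes the residual sum of squares over $k_{deg}$ — the
only free kinetic parameter; boundary values and precursor parameters
are fixed by configuration. Optimization runs over $\log k$ (positivity)
with BFGS from a start of 0.29/d, followed by a golden-section polish on
$\log k \in [\log 10^{-5}, \log 50]$ that guards against quasi-Newton
overshoot into the flat low-$k$ region; fits at a bound are flagged.
Reported per fit: $\sigma_A = \sqrt{SSE/(n-1)}$ (residual RIA scale),
$R^2 = 1 - SSE/SST$ floored at 0 for filtering (undefined and flagged
for constant series), a Gaussian log-likelihood, and AIC with two free
parameters (rate + noise variance). The fitting error is first-order
propagation through the model sensitivity,
$dk = \sigma_A / |\partial A/\partial k|$ evaluated at $t = 1/k$: for
the one-compartment model this collapses to
$k\,e\,\sigma_A/|A_\infty - A_0|$, for the two-compartment model the
analytic derivative is used, and the general convolution model falls
back to a central difference. The evaluation point $t = 1/k$ is our
inference; it makes the two-compartment error collapse onto the
one-compartment form in the $k_p \to \infty$ limit, which the tests
check.

## Precursor kinetics estimation

Knowing $k_p$ (and RIA$_p$) is the crux of AA labeling. The package
implements the strategies compared in this workflow:

* **Secreted reporters** (`secretedProteinKp()`): liver proteins secreted
  as soon as they are made track precursor availability directly.
  Qualifying peptide series ($R^2 \ge 0.6$, $\ge 10$ time points) are
  pooled in fractional-synthesis space and fitted to
  $1 - e^{-k_p t}$. When the first sampled day is already near plateau
  the estimate is flagged as a lower bound only.
* **Dilysine MIDA** (`midaPrecursorRia()`): in a newly made two-lysine
  peptide the heavy-site count is binomial$(2, p)$, so
  $m_{12}/m_6 = p/(2(1-p))$ and $p = 2q/(1+2q)$, $q = m_{12}/m_6$. The
  inversion is exact and abundance-invariant. The ratio form is our
  derivation from the stated peak semantics; the forward-binomial oracle
  in the tests confirms it.
* **One-pass weighted fit** (`kkOnePassFit()`): all qualifying dilysine
  RIA points of a tissue ($\ge 9$ time points per peptide,
  $0 \le p \le 0.6$) fitted to a single exponential rise, weighted by
  squared normalized intensity.
* **KDE mode** (`kkKdeMode()`): the per-time-point mode of a Gaussian
  kernel density over peptide-level $p$ estimates, Scott's bandwidth
  ($\hat\sigma n^{-1/5}$), 512-point grid on $[0, 0.6]$.
* **Per-peptide median** (`kkMedianKp()`): exponential fit per dilysine
  series, median of the rates.
* **Two-exponent reutilization model** (`twoExponentPrecursorFit()`):
  label dilution by proteome-wide degradation makes the precursor rise
  biphasic. We model the coupled linear exchange (diet to soluble pool at
  rate $b$; protein-bound pool turning over at rate $a$; pool-size ratio
  $r$ scaling the return flux as $a/r$), whose solution is
  $s(t) = 1 - c_1 e^{-\mu_1 t} - c_2 e^{-\mu_2 t}$ with
  $\mu_{1,2} = (S \pm \sqrt{S^2 - 4ab})/2$, $S = a + b + a/r$, and
  weights set by $s(0)=0$, $s'(0)=b$. As $r \to \infty$ this collapses to
  a single exponential at rate $b$ (a tested limit). The direction of
  $r$ (soluble vs protein-bound) is left as a labeled parameter; only the
  product structure matters for the fitted curve. Fits are scaled to a
  50% heavy-lysine plateau and compared against the single-exponential
  rise by Akaike weights.
* **Nested optimization** (`nestedKpOptimization()`): scan a $k_p$ grid,
  refit every peptide's $k_{deg}$ under the two-compartment model at each
  candidate, and track the median SSE against the one-compartment
  baseline. In slow-equilibration regimes the objective has a clean
  interior minimum at the true $k_p$. When turnover is much slower than
  equilibration, delay and rate trade off freely: no candidate improves
  on the baseline, and the objective flattens onto it at high $k_p$. At
  realistic noise the flattening is gradual — the relative range is still
  tens of percent at $k_p \approx 10 \times \max k_{deg}$ and only
  collapses below a few percent around $100\times$ — so the failure is
  reported via the improvement test and a flatness flag rather than a
  hard threshold.
* **Heavy-water reference** (`hwReferenceCalibration()`): with both
  chemistries measured on shared peptides, scan (RIA$_p$, $k_p$) cells,
  refit the AA arm in each, and map the median absolute log-$k_{deg}$
  difference to the HW reference and the robust log–log slope. The
  difference argmin and a slope of 1 coincide at the generating cell on
  synthetic dual-chemistry data.

## Peptide filters and protein rollup

`filterPeptides()` applies the admission rules (defaults: $\ge 9$ time
points, $R^2 \ge 0.9$, unique protein mapping, optional lysine-count cap
for AA-comparable sets) and returns an exclusion ledger.
`rollupProtein()` aggregates peptide rates four ways: median (+ MAD),
harmonic mean (+ delta-method SD on the reciprocal scale — the named but
undefined spread statistic is our choice), refit (all peptide
observations pooled in fractional-synthesis space, one curve), and
weighted refit (weights = log10 total peptide intensity normalized to the
within-protein maximum, bounded in (0, 1]). Equal weights reduce the
weighted refit to the plain refit exactly. Precision diagnostics:
`geometricCv()` ($\sqrt{e^{sd(\ln k)^2} - 1}$, scale-invariant),
`varianceVsFilterSweep()` (retained peptides and median intraprotein
geometric CV across threshold grids, proteins with $\ge 3$ peptides), and
`day0FsDiagnostic()` (day-0 fractional synthesis should be 0; its spread,
stratified by $R^2$ and intensity, measures isotopomer-level error).

## The simulator: what it emulates, and what it does not

`simulateExperiment()` draws a cohort (proteins sharing a true $k_{deg}$
drawn log-uniform on 0.002–2/d, the measurable range of a ~30-day design;
peptides with one or two lysines; log-normal abundances spanning two
decades), evaluates noise-free envelopes at the study schedules (11
points, 0–30 d for AA; 12 points, 0–31 d for HW), then applies
multiplicative log-normal area noise (configurable CV), optional additive
noise (making relative error intensity-dependent), an optional detection
floor (zeroing sub-threshold minor peaks, which reproduces the negative
day-0 fractional-synthesis bias of low-abundance HW peptides), and
per-time-point dropout. Everything is reproducible from the seed, and a
truth ledger traces every observation.

Envelope construction is *model-consistent by design*: the AA labeled
fraction is the exact precursor convolution (so simulated RIA equals the
two-compartment curve to $10^{-9}$), and the HW $m_0$ fraction follows
the convolution model between the natural value and the binomial
plateau, with $m_1$–$m_5$ shaped by the binomial-convolved labeled
envelope. A strictly molecule-level binomial bookkeeping would disagree
with the fitted model at the $10^{-3}$ level (envelope mass leaking past
$m_5$, and $(1-p)^N$ being nonlinear in $p$ during the precursor rise);
we deliberately keep ground truth exact and treat those real-data effects
as what the day-0 diagnostic and the noise options emulate. Passing
recovery tests therefore demonstrates correctness of the estimation
chain, not robustness to every envelope distortion of real spectra.

Dilysine peptides label with the precursor RIA at each molecule's
synthesis time, integrated over the synthesis-time distribution — so
MIDA-derived $p(t)$ lags the instantaneous precursor during the rise, as
observed in practice; a `current` mode (instantaneous $p$) is available
and is what exact-inversion tests use.

`writeFixtureMzml()` renders a table as centroided MS1 mzML (through
Bioconductor's mzR): each peptide elutes as a Gaussian whose trapezoid
area reproduces the table, peptides are spaced in retention time so
extraction windows never overlap, and a configurable ppm offset provides
negative controls outside the 25 ppm tolerance.

## Numerical choices and degenerate inputs

* Isotopomer spacing is fixed at 1.003355 Da ($^{13}$C–$^{12}$C) for
  indices 1–5; at 25 ppm tolerance the $^2$H/$^{13}$C spacing difference
  stays inside the window for tryptic peptides. AA indices 6/12 use the
  exact printed shifts 6.0201/12.0402. Proton mass 1.007276 Da; retention
  times in minutes.
* Scans with no matching centroid contribute zero intensity, preserving
  trapezoid geometry across gaps; empty and single-point traces integrate
  to 0.
* Repeated identifications of a peptide-charge in one run are collapsed
  to the window of the lowest-q PSM; charge states are never merged.
* Undefined RIA observations (zero denominators) are dropped with a
  warning count; series shorter than two points are not fitted; constant
  series are flagged (`no_signal`) with undefined $R^2$.
* Decoy/contaminant accessions are excluded by configurable prefixes
  (`DECOY_`, `CONTAM_`).
* Day-0 observations are included in fits; dilysine day-0 points enter
  the one-pass fit whenever their ratio is defined.

## Problem sizes

The test-suite and acceptance computations run at desk scale, chosen to
make every statistical check decisive while staying quick: 200-peptide
cohorts for recovery, 50 shared peptides with a 5 × 7
(RIA$_p$ × $k_p$) grid for the calibration surface, and ~10-peptide
fixtures for mzML round trips. All scale linearly if larger runs are
wanted.

## Known limitations

* No retention-time alignment, MS2 processing, profile-mode peak picking,
  or database search: identifications are consumed, not produced.
* The HW plateau uses binomial depletion of $m_0$; envelope statistics
  beyond $m_0/\Sigma$ and $m_6/(m_0+m_6)$ are out of scope.
* The two-exponent precursor parameterization follows our exchange-system
  derivation; comparisons of its $a$, $b$, $r$ values against other
  software should verify the same parameterization is in use.
* Non-steady-state (growing or shrinking pool) models and Bayesian
  fitting are not provided.
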
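---
title: "Mutation-rate kinetics and Chargaff's second parity rule"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mutation-rate kinetics and Chargaff's second parity rule}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pr2sim)
```

## The problem

Chargaff's second parity rule (PR-2) states that within a *single* strand of
double-stranded DNA the complementary base contents match: C~A~ ≈ C~T~ and
C~G~ ≈ C~C~. Almost every nuclear dsDNA genome obeys it, quantified here by
the skews (G − C)/(G + C) and (A − T)/(A + T), which are both ≈ 0 under
PR-2. `pr2sim` implements a kinetic account of the rule: base contents
evolve deterministically under the twelve directed mutation rate constants
k~s→u~, and the question is which rate combinations drive the skews into the
empirically observed tolerance regions within the age of life on Earth
(4.28 byr).

The model is a mean-field linear ODE: contents are fractions of an
effectively infinite genome, so no sampling noise enters the dynamics. This
is a deliberate idealisation — finite-genome stochasticity, selection,
indels and regional rate heterogeneity are out of scope; what passing tests
show is therefore a property of the averaged kinetics, not of any individual
finite sequence.

## The singleton model

With the composition vector C = (C~A~, C~C~, C~G~, C~T~), the kinetics are
dC/dt = M·C with the generator convention *columns index the source base*:
`M[u, s] = k_{s→u}` off the diagonal and each column sums to zero
(`build_rate_matrix()`). Column sums being zero makes ΣC invariant, and
every trajectory conserves total content to solver tolerance.

Two propagation routes exist and are cross-checked in the tests:

* `evolve()` integrates with a stiff-capable solver (deSolve `lsoda`,
  rtol 1e-9 / atol 1e-12 by default). The defaults are deliberately tight:
  rate spreads up to ~8 per byr over 4.28 byr are mild, but ensemble runs
  must not accumulate visible drift.
* `final_compositions()` / the batch backend propagate with the matrix
  exponential C(t) = e^{Mt}·C(0), exact for a linear system, compiled with
  RcppArmadillo for Monte Carlo ensembles.

Under the no-strand-bias (NSB) assumption the twelve rates collapse to six
(i, j, k, l, m, n; `nsb_reduce()` / `nsb_expand()`), and the stationary
state is closed-form (`nsb_equilibrium()`): C~A~ = C~T~ = (i+m)/2(i+j+m+n),
C~G~ = C~C~ = (j+n)/2(i+j+m+n). PR-2 is exact at the NSB equilibrium, and
the equilibrium G+C content depends only on (n+j)/(i+m)
(`gc_equilibrium()`); the k and l rates cancel. A dedicated integrator for
the reduced six-rate equations (`evolve_nsb()`) exists purely as a
cross-check that the two formulations are trajectory-identical.

`stationary_composition()` is the independent oracle for long-time limits:
the normalised null-space vector of M. Reducible networks (multi-dimensional
null space, e.g. a single nonzero rate) have no unique stationary state and
raise an error; the long-time limit then depends on the start and must be
obtained by integration.

## The dyad model

The 16 dyads (5′→3′ dinucleotides, keyed "AC" for ApC) form a tesseract
graph with 96 directed single-position substitution edges
(`dyad_edges()`). NSB pairs each edge with the mutation between the
reverse-complement dyads (ApC→ApT with GpT→ApT) — an involution without
fixed points, giving 48 rate classes. Any NSB-paired network equilibrates
into ten reverse-complement content classes; with context-independent rates
(each edge carrying the singleton rate of its mutating position,
`context_independent_network()`) only three distinct values survive — the
outer square of the singleton equilibrium, as independence of the two
positions dictates. The class detector (`equilibrium_classes()`) merges
stationary contents within an absolute tolerance, default 1e-6: the class
structure is exact algebra, but numerical null spaces need a threshold.
Higher-order k-mers are not implemented.

## Sampling protocols

Three rate-sampling modes (`sample_rates()`), all centred on the packaged
human reference rates (`reference_rates()`, per site per byr, derived from
genome-wide LINE-1-based rate estimation):

* `uniform_unconstrained` — 12 independent draws from U(0, U~m~), where
  U~m~ = 1.109 + m × 0.690 from the largest symmetry-averaged reference
  rate (CT/GA); m = 1 gives 1.799. This is the assumption-free protocol.
* `truncnorm_individual` — 12 draws from normals truncated at zero, centred
  at the per-mutation reference means with sd scaled by m.
* `truncnorm_symmetric` — six draws centred at the symmetry-averaged block,
  expanded to exact NSB pairs.

The zero-truncated normal is drawn by the exact inverse-CDF transform
(`qnorm` over a rescaled uniform), which is distribution-identical to
rejection sampling from a left-truncated normal and consumes exactly one
uniform per draw. Truncation at zero gives the draws a positive mean bias
relative to their centres — an artefact of the truncation, asserted in the
tests, not a biological effect. No upper truncation is applied.

Initial compositions (`sample_initial()`): the fixed uniform quarter
(0.25 each); `random_constrained`, where two randomly chosen bases are drawn
inside a plausible per-base window (default 0.1–0.4 — a configurable
package choice covering the base-content range seen across eukaryotic and
prokaryotic genomes) and the remaining two split 1 − remainder so the four
sum to exactly 1; and the four extreme-skew corners (±1, ±1), using the
symmetric split between the two nonzero bases since the corners are
otherwise underdetermined.

All draws come sequentially from one seeded RNG stream, so any
(seed, scheme, n) triple is bit-reproducible regardless of hardware
parallelism.

## PR-2 metrics and the timing analysis

Compliance is membership in a closed mean ± 1 sd tolerance box per kingdom
(`tolerance_boxes()`): eukaryote GC 7.780e-5 ± 1.908e-3 /
AT 1.096e-5 ± 1.178e-3; prokaryote GC 1.425e-4 ± 1.907e-2 /
AT −1.386e-5 ± 9.401e-3; virus GC 2.262e-2 ± 9.666e-2 /
AT 3.668e-2 ± 1.041e-1. A composition with a vanishing G+C or A+T total has
no defined skew; it is reported as 0 with a degeneracy flag, since such
states never arise from positive-rate kinetics.

`time_to_pr2()` takes the first recorded compliance crossing and refines it
by bisection with the exact propagator to 1e-3 byr. Skew trajectories of
linear systems need not be monotone, so an optional persistence window can
require compliance to hold for a stretch of records; the default is the
plain first crossing.

Equilibration (`time_to_equilibrium()`) has two documented interpretations,
because the calibration recipe it follows is ambiguous as printed in its
source description:

* **oracle_threshold** — equilibrated when
  max~b~ |C~b~(t) − C~b~(∞)| ≤ EQtolerance (default 1e-4), with C(∞) from
  the null-space oracle. Unambiguous, used for invariants (equilibration
  time is 0 when starting at stationarity; PR-2 always precedes or
  coincides with equilibration).
* **fluctuation_calibrated** — the per-replicate fluctuation between
  consecutive records is Σ~b~|ΔC~b~|/4; EQtolerance is 1% of the
  ensemble-mean fluctuation over 25 evenly spaced reference records; a
  replicate is equilibrated at the first record where the range
  (max − min) across bases of |ΔC~b~| falls to EQtolerance or below.

`timing_study()` wires the pieces together: sampled rates and initial
compositions, batch propagation on a uniform recording grid (default 250
intervals — the per-step quantities of the calibrated mode are defined on
this grid), bisected PR-2 crossings, and a tidy per-replicate table with
`tidy()`/`glance()` accessors.

Under the package defaults (truncnorm_symmetric rates at multiplier 1,
range-constrained random starts, prokaryote box, 42.8 byr horizon), the
mean time to PR-2 compliance is ≈ 3.2 byr — comfortably within the 4.28 byr
age of life — and precedes mean equilibration at every multiplier, both
times shrinking monotonically as the sampling multiplier grows (wider rate
draws make forward/backward rate differences larger and relaxation faster).
The *size* of the compliance-before-equilibration gap, however, depends
entirely on how the ambiguous calibration sentence is read: under the
interpretation implemented here the mean gap is ≈ 3 byr, while the source
analysis reports ≈ 1 byr, and the alternative parse ("1% of 25× the mean
fluctuation") drives the gap to ≈ 0. The tests therefore assert the
ordering and monotonicity claims strictly but bound the gap only loosely
(positive and below 4.28 byr).

## Ratio diagnostics and the generalized constraints

For an unconstrained uniform ensemble, each reverse-complement rate-pair
ratio follows the closed-form uniform-ratio law (density 1/2 below 1,
1/(2r²) above — `uniform_ratio_density()`). Conditioning on PR-2 compliance
reshapes the ratios to concentrate around 1, echoing the NSB equalities
without imposing them. `nsb_ratio_diagnostics()` histograms the ratios per
pair and compliance subset; its default bins are equal-width on the
*log-ratio* scale with one bin (e^−0.25, e^0.25] containing 1. The
log-symmetric binning is a deliberate choice: a ratio and its reciprocal
describe the same physical asymmetry, and linear-scale bins tilt the
apparent peak below 1 purely through the reciprocal (Jacobian) asymmetry —
at desk-scale ensembles (2×10⁵ systems, prokaryote box) the linear-binned
mode of the most asymmetric pair sits just below 1 even though the
distribution is symmetric around equality on the log scale.

The twelve generalized constraint relations (`predict_rates()`) each
express one rate as a fixed linear combination of the other eleven plus an
intercept; the coefficients are packaged verbatim and covered by a
literal-transcription fixture test. They are strictly linear, so
predictions interpolate exactly. The packaged coefficients are printed to
1–2 significant figures at source, so every consequence derived from them
is checked with tolerances, never exact equality. On compliant ensembles
the actual-versus-predicted correlation is strongly positive for all twelve
relations (Pearson r ≈ 0.8–0.95 at 2×10⁵-system scale), and the aggregate
residual norm (`constraint_residuals()`) separates compliant from
non-compliant rate sets distributionally. `species_vs_gc_curve()` compares
user-supplied per-species symmetric rates and observed G+C fractions
against the NSB equilibrium curve; no species data are packaged.

## Genome content counting

`count_genome()` counts bases and dyads on the forward strand of FASTA
records (Biostrings), case-insensitively — soft-masked lowercase letters are
counted identically to uppercase by construction, a documented divergence
from mask-aware counting that matters little for genome-wide skews.
Ambiguity codes are skipped and tallied; dyads never span a skipped symbol
(contiguous-segment rule). Sliding (all overlapping dimers) and
segmentation (non-overlapping from position 1) modes agree in expectation
for i.i.d. sequences. Multi-record files are pooled into a whole-genome row
by default, with per-record rows always available.

## Synthetic data

`make_genome()` draws i.i.d. sequences whose expected base fractions solve
the (G+C content, GC skew, AT skew) system exactly; a first-order Markov
option adds controllable neighbour correlation (for dyad-count tests)
without changing the stationary composition. Repeat structure and isochores
are not emulated, so conclusions about real genomes rest on the counting
machinery, not the generator. `make_rate_ensemble()` provides labelled
ensembles: exactly symmetric sets, ε-perturbed pairs with a provable ratio
envelope, sets solved to satisfy chosen constraint relations exactly
(rejection-sampled into the non-negative orthant), and adversarial
strand-asymmetric sets.

## Numerical choices and test problem sizes

* Generator columns = source base; asserted once in the tests.
* Class-detection tolerance 1e-6 absolute on contents; stationary
  compositions from SVD null spaces with a 1e-10 relative singular-value
  threshold.
* "Large t" for convergence checks: 100 / min(positive rate), capped at
  1000 byr (`convergence_horizon()`).
* Crossing-time bisection resolution 1e-3 byr.
* Ensemble sizes in the shipped tests: 2×10⁵ systems for the
  compliance-conditioned ratio and constraint analyses; 10⁴ replicates per
  multiplier for the timing study; 20 seeded networks for the dyad class
  census; 100 seeded rate sets for the closed-form-versus-numerical
  equilibrium sweep. These are the package's documented study conditions;
  the qualitative results are stable under enlargement.

## Known limitations

Deterministic mean-field kinetics only; no selection, context-dependent
singleton rates, or k > 2 oligomer networks. The equilibration-tolerance
calibration implements one documented reading of an ambiguous recipe (see
above). Packaged tolerance boxes and reference rates are constants; cohort
re-estimation from genome collections is supported
(`kingdom_tolerance()`) but no genome downloads are performed.
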
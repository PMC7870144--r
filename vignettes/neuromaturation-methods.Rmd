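---
title: "Methods: quantifying the maturation of induced neurons"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying the maturation of induced neurons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neuromaturation)
```

## The analysis problem

Induced neurons (iNs) are generated by forced expression of the proneural
transcription factor NGN2 in pluripotent stem cells and mature over several
weeks in culture. Comparing the *pace* of that maturation between groups
(e.g. ape versus human cell lines) requires the same quantities to be
extracted reproducibly from three very different kinds of raw data:

1. **Traced reconstructions** of single GFP-labelled cells (SWC or
   Imaris-style HOC): total neurite length, the length of the axon
   (operationally, the longest neurite), the remaining dendritic length,
   polarity class, and Sholl intersection profiles.
2. **Whole-cell patch-clamp recordings**: resting membrane potential
   (Vrmp), input resistance (Rcell), whole-cell capacitance (Ccell), the
   membrane time constant tau = Rcell·Ccell, maximal action-potential (AP)
   counts over a current-step family, and spontaneous EPSC frequencies from
   60-s voltage-clamp traces at -80 mV.
3. **Single-cell RNA-seq count matrices**: cell and gene quality control,
   Wilcoxon differential expression between neurons and progenitor-like
   cells, and gene-set enrichment (exact binomial against a background, or
   one-sided Fisher with FDR control), plus Pearson correlation of
   enrichment profiles across cell groups.

Group contrasts use the Mann-Whitney U test (morphometry), Welch's t test
(AP and EPSC measures), a Shapiro-Wilk screen, and two-way ANOVA
(day x species, or batch effects). Every stage has a ground-truthed
synthetic generator, so the full pipeline is testable with no recorded data.

## Morphometry

A reconstruction is a soma centroid plus rooted neurite trees; the first
segment of each neurite runs from the soma centroid to its first traced
point, so somatic attachment length is counted. All lengths are micrometres
and the file readers perform no unit conversion.

* **Axon rule.** The axon is the neurite of maximal total path length
  (validated in sparse-labelling experiments by axonal-marker staining).
  Length ties are broken deterministically toward the lowest neurite index.
* **Polarity.** The literature defines uni/bi/multipolar visually; we count
  *primary* neurites, those of total length at least `min_primary_length`
  (default 5 µm — longer than a filopodium, much shorter than any genuine
  process), and map 1/2/>=3 to unipolar/bipolar/multipolar. Unipolar cells
  are classified but flagged so downstream statistics can exclude them, as
  they may be unhealthy.
* **Sholl analysis.** Reconstructions come from 3-D confocal stacks, so we
  intersect the arbor with concentric *spheres* (not planar circles) around
  the soma centroid; the radius step defaults to 10 µm (tracing software
  rarely documents its internal increment; the step is configurable). A
  segment's distance to the centre is a convex quadratic along the segment,
  so crossings are counted exactly as the sign-changing roots of
  d²(t) − r² in (0, 1] — a segment that enters and leaves a shell counts
  twice at that radius. `sholl_profile_dense()` is a brute-force
  reference (0.01 µm resampling, sign-change counting) kept as the
  independent check.
* **HOC dialect.** Only `create`, `connect` and `pt3dadd` statements are
  honoured; anything else is ignored with a warning, since tracing-software
  exports vary. Cross-format tests require SWC and HOC serializations of
  the same cell to give identical morphometry records.
* **Batch normalization.** Arbor growth is strongly batch dependent (a
  batch = one differentiation experiment). Axon lengths are therefore
  divided by the per-batch mean of the reference ("ape") group, which makes
  the reference group's per-batch normalized mean exactly 1 and removes the
  batch scale from between-group contrasts.
* **Dendrite length** is total length minus the single longest neurite,
  matching the convention of reporting "other neurites (excluding the
  longest ones)".

## Passive membrane properties

The forward model — and the estimator's assumption — is the standard
whole-cell circuit: pipette series resistance Rs in series with the
membrane (Rcell parallel Ccell) resting at Vrmp.

* **Step protocol** (20 kHz): four uncompensated voltage steps from -80 mV
  to -95/-85/-75/-65 mV. The plateau current (mean over 10 ms starting
  20 ms after onset) is linear in the command voltage with slope
  1/(Rs + Rcell); Rcell is the fitted slope minus Rs (Rs is read from the
  amplifier metadata; 50% compensation is assumed applied upstream and not
  modelled).
* **Capacitance.** The fast transient after a step decays with
  tau_fast = Ccell·(Rs·Rcell/(Rs+Rcell)). We fit a single exponential with
  offset over the first 500 µs after onset, skipping the first 2 samples
  (anti-alias filter artifacts; acquisition is typically Bessel-filtered at
  2.5 kHz). Two numerical choices matter: (i) when the plateau has been
  measured, the steady-state term Iss is *fixed* at the plateau value,
  which conditions the three-parameter fit dramatically better on a window
  that covers less than one time constant for large cells; (ii) Ccell is
  recovered as tau_fast·(Rs+Rcell)/(Rs·Rcell) when an Rcell estimate is
  available, and as the large-Rcell limit tau_fast/Rs otherwise. (The
  relation is sometimes quoted as "C = Rs/tau", which is dimensionally
  inconsistent; the implemented forms are the circuit solutions.) Fits with
  tau outside (10 µs, 10 ms) raise a failure flag.
* **Ramp protocol**: hold at -90 mV for 200 ms, ramp to +60 mV in 800 ms.
  During the ramp the capacitance adds a constant pedestal
  C_eff·dV/dt to the current, which shifts the apparent zero-current
  crossing by roughly tau_m·dV/dt — about 3 mV at typical parameters, so
  it cannot be ignored if Vrmp is to be recovered to 1 mV. The pedestal is
  estimated as the jump between the pre-ramp holding current and the
  quasi-steady ramp current extrapolated back to ramp onset, and
  subtracted. Rcell is the inverse current slope over the -75 to -65 mV
  window (window configurable); Vrmp is the zero crossing of the corrected
  current, located on a 15-ms smoothed trace and refined by a local linear
  fit (+/-3 mV). When the corrected current is non-monotonic just above the
  window — the signature of a subthreshold voltage-gated inward current
  distorting the crossing — Vrmp falls back to the zero crossing of the
  window's linear fit, which stays below the contaminated range.
* **Consolidation.** Independent estimates of Rcell (steps, ramp, optional
  amplifier value) and Ccell (per-sweep fits, optional amplifier value) are
  averaged when their maximal pairwise relative deviation (relative to the
  larger value) is below 10%, otherwise the median is taken and a
  disagreement flag raised. tau is reported as Rcell·Ccell in ms.
* **Recording QC.** A recording is excluded when Rs exceeds 25 MOhm, when
  Rs rose by more than 5 MOhm, or when Rcell, Ccell or Vrmp drifted more
  than 20% from their initial values. These are pure threshold functions
  and are property-tested at their boundaries.

## Action potentials and spontaneous EPSCs

* **AP counting.** An AP is an upward crossing of -20 mV in current clamp;
  crossings closer than a 1 ms refractory window (not a biological claim —
  a guard against noise double-counts; configurable) count once. The
  per-cell statistic is the maximal count over the 20-step family (500 ms
  steps, two hyperpolarizing, eighteen depolarizing).
* **EPSC detection** is scaled-template matching in the Clements-Bekkers
  family: a triangular kernel (linear rise over 1.5 ms, linear decay over
  6 ms, unit peak) slides along the inward-rectified trace; at each
  position a least-squares fit with free scale and offset is computed in
  O(1) per position via running sums. The detection statistic is the
  fitted scale divided by its standard error. Accepted events must reach
  the detection criterion, exceed the 14 pA noise floor, and not exceed the
  500 pA amplitude cap. Suprathreshold runs closer than one template length
  merge to their local statistic maximum (an event's decay tail re-triggers
  the statistic); the amplitude cap acts as artifact rejection — any
  detection within three template lengths of a sample above the cap is
  discarded, so the tail of an oversized deflection cannot re-enter below
  the cap.

  The **detection criterion defaults to 5**. This is a calibration, chosen
  before freezing the defaults by simulating the stated operating regime:
  at 14 pA Gaussian noise, a threshold of 3 on the scale/SE statistic fires
  on noise alone at several events per second (the statistic is t-like, and
  a 60-s trace offers thousands of effectively independent positions),
  while thresholding the scale against the residual SD instead would need
  amplitudes above roughly 3x the noise SD and miss a third of 30-100 pA
  events. Criterion 5 holds the false-event rate on pure 14 pA noise below
  0.02 Hz while keeping recall above 0.94 and precision above 0.96 on
  30-100 pA lognormal events at 0.5 Hz (pooled over 20 simulations).
* **Frequency transform.** Event counts over 60 s are converted to Hz and
  log10-transformed for group statistics (their distribution is heavily
  right-skewed). Zero-event cells have no defined log frequency; they are
  flagged and excluded from the transformed series rather than imputed.

## Count-matrix QC, differential expression, enrichment

* **Cell QC** keeps cells with 500-6000 detected genes (count > 0) and a
  mitochondrial transcript fraction of at most 5% (mitochondrial genes:
  symbols starting with "MT-", overridable per annotation).
* **Gene QC** keeps genes whose mean count exceeds 0.1 in at least one
  batch (sum of counts over a batch's cells divided by cells in the batch).
  Both filters are idempotent.
* **Differential expression**: counts-per-10k + log1p normalization, then a
  two-sided Wilcoxon rank-sum per gene and Benjamini-Hochberg adjustment.
  The rank test is insensitive to the monotone normalization; CP10K/log1p
  is used in place of model-based normalization (the named pipeline step is
  out of scope here) and is sufficient for a rank-based test. log2 fold
  change is log2(mean_a + eps) − log2(mean_b + eps) on the CP10K scale with
  eps = 1e-9 (configurable). A gene is flagged when the adjusted p is below
  0.05 *and* the log2 fold change exceeds 0.25, direction "higher in group
  a" — both cutoffs configurable, defaults as in the study design.
* **Enrichment**: for flat term lists (no ontology-graph propagation), the
  exact binomial upper tail P(X >= k), X ~ Bin(n, K/N), flags terms at raw
  p < 0.05 (the GO-screen convention); the one-sided Fisher exact test (the
  hypergeometric upper tail) with BH control flags terms at FDR < 0.05 (the
  SynGO-style convention). Both p-values are exact tail sums and are tested
  against brute-force summation to 1e-12.
* **Correlation of enrichment profiles** defaults to Pearson r on
  -log10 p (raw-p mode available: the scale used in the original figure is
  not documented), with the conventional r > 0.7 mask. Zero-variance
  profiles yield NA with a warning rather than a spurious +/-1.

## Group statistics

The exact Mann-Whitney path and the significance-star mapping are
implemented in-repo so oracle tests bind to this code; other standard tests
delegate to the platform (`shapiro.test`, `car::Anova` over `lm`). The
Mann-Whitney test enumerates all group assignments when both groups have at
most 8 observations (valid under ties; p = 2·min(tails), capped at 1) and
uses the tie-corrected normal approximation with continuity correction
otherwise. Welch's t is computed from its closed form with Satterthwaite
degrees of freedom; two degenerate zero-variance groups give p = 1 for
equal means. Two-way ANOVA uses type-II sums of squares, appropriate for
the unbalanced day-by-species designs (type I/II/III coincide on balanced
designs, which the tests verify). Stars: p < 0.05 *, p < 0.01 **,
p < 0.001 ***.

## Synthetic data: what it does and does not establish

Each generator records ground truth at construction time:

* **Morphology**: stochastic branching trees; 1-5 primary neurites with
  default class weights giving ~6% unipolar / 30% bipolar / 64% multipolar
  cells (the proportions reported for iN cultures); segment lengths scale
  multiplicatively with day (default 1.05/day after d7), species and batch.
  Truth records per-neurite lengths, node and branch counts.
* **Membrane**: the single-compartment circuit is integrated with the exact
  exponential (zero-order-hold) update, or RK4 sub-stepping when the
  optional Boltzmann subthreshold conductance is enabled; 5 pA RMS current
  noise in the recovery studies. Stylized APs (2 ms, peak +20 mV) are
  inserted at known times, since the analysis only counts threshold
  crossings — waveform realism adds nothing to that check; the passive
  depolarization is soft-capped at -35 mV so planted counts are exact truth.
* **EPSC trains**: homogeneous Poisson times; biexponential kernels
  (rise 0.5 ms, decay 4 ms — comfortably inside the 1.5/6 ms template
  caps); lognormal amplitudes with meanlog = log(sqrt(30·100)) and
  sdlog = log(100/30)/(2·1.96), i.e. 95% of mass in 30-100 pA; 14 pA
  Gaussian noise; 60 s duration.
* **Counts**: negative-binomial (size 2) with lognormal base means; planted
  DEGs at a common fold change are drawn from genes with base mean >= 0.2
  so that "planted DEG" does not secretly mean "gene the QC removes";
  per-cell mitochondrial fractions and planted QC violations are
  constructed with decisive margins so the expected retained-cell set is
  exact truth.

Passing tests on these fixtures establishes *estimator correctness under
the stated model*: unbiased recovery of circuit parameters, exact AP
counts, calibrated detection and DEG error rates. They do not establish
robustness to what the generators do not model: electrode drift and seal
instability, correlated (filtered) noise, overlapping synaptic bursts,
space-clamp error in extended arbors, ambient RNA/doublets, or
batch-by-gene interactions. Those caveats are inherent to any desk-scale
validation and are why the recording-QC thresholds exist.

## Problem sizes and determinism

The bundled checks use the sizes the properties are stated at: 100
simulated cells for passive recovery (median absolute relative error < 5%
for Rcell and Ccell, Vrmp within 1 mV), 100 twenty-step families for exact
AP counting, 20 sixty-second traces each for EPSC recall/precision and the
noise-only false-positive rate, 50 random trees for Sholl-oracle and
SWC/HOC equivalence, a 2000-gene / 400-cell matrix (100 planted DEGs at
4-fold) for DEG recovery plus twenty 1000-gene null matrices, and
exhaustive Mann-Whitney enumeration for all group sizes up to 8. The demo
study in `run_study()` uses reduced cohort sizes chosen to exercise every
stage while keeping a full run in the tens of seconds; all generators take
explicit seeds and `run_study()` is byte-identical under a fixed
configuration.

## Known limitations

* The HOC reader covers the geometry-exporting subset of the dialect only;
  it is not a NEURON interpreter.
* The EPSC detector estimates rise/fall descriptively from the raw trace
  around each event; it does not fit kinetic models, and overlapping events
  within one template length resolve to a single detection.
* The exact Mann-Whitney path enumerates C(n1+n2, n1) assignments and is
  restricted to groups of at most 8 by default.
* Binomial/Fisher enrichment treats term lists as flat sets; no
  parent-term propagation is performed.
* Zero-EPSC cells are excluded from log-frequency statistics (flagged),
  which conditions those contrasts on activity being present.
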
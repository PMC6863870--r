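---
title: "From progenitor pool to cortical circuit: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From progenitor pool to cortical circuit: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lineagecircuits)
```

# The analysis this package implements

Whether the embryonic progenitor a cortical neuron comes from leaves a
trace in the neuron's adult identity is a question that joins three very
different kinds of data: single-cell RNA-seq of lineage-labelled
(Patch-seq) neurons, simultaneous multi-electrode patch-clamp tests of
monosynaptic connectivity, and optogenetically evoked synaptic responses
in downstream targets. `lineagecircuits` implements the statistical
chain for all three, together with synthetic generators that emulate
each input so the whole chain can be exercised and validated end to end
without access to raw recordings.

Cells come from two lineage pools: **aIP**-derived neurons (apical
intermediate progenitors, labelled through a Tα1-promoter reporter) and
**OP**-derived neurons (all other concurrently dividing progenitors).

# Single-cell QC and normalization

Per-cell metrics are the library size, the number of detected genes,
and the fractions of counts in mitochondrial genes and ERCC spike-ins.
Outliers are flagged with median-absolute-deviation thresholds, the MAD
scaled by 1.4826 so that it estimates an SD under normality:

* library size and detected genes: more than 3 MADs **below** the
  log-transformed median (we use log10(x + 1); whether the original
  convention was natural log or log10 is immaterial, since scaling the
  log base rescales median and MAD identically);
* mitochondrial fraction: more than 5 MADs **above** the median;
* ERCC fraction: more than 4 MADs **above** the median.

Thresholds are computed jointly over the whole plate, not per pool —
pools are processed on shared plates, and pool-wise thresholds would
let a systematically degraded pool re-normalize itself.

Because MAD thresholds are scale-free, the *fraction* of a clean,
homogeneous plate falling beyond 3 MADs does not shrink as the plate
gets tighter; roughly 0.1–0.5% of genuinely fine cells will always sit
past the cutoffs. This is inherent to robust outlier rules and is why
we quote "removes essentially all injected low-quality cells and ≲1% of
clean cells" rather than an absolute guarantee.

Classifier input is `log2(CPM + 1)` where CPM uses only
endogenous-flagged genes in the denominator; ERCC and reporter rows are
dropped from the output (mitochondrial rows are kept, for
traceability, but never enter the denominator). We deliberately feed
the classifier plain log2-CPM rather than pooled-factor or
batch-corrected expression: the correlation-based mapping below is
invariant to per-cell scaling, and batch correction is out of scope
here.

# Reference atlas and bootstrap classification

The reference atlas summarizes each labelled class by its **median**
log2-CPM profile. Markers are chosen per ordered pair of classes
(i, j): genes are ranked by `median_i − median_j` (descending), kept
only if the difference is positive and class i detects the gene in at
least 30% of its cells, and the top K = 50 per pair are pooled into the
marker set. Ranking each direction separately guarantees both classes
of a pair contribute their own up-regulated genes; a single ranking of
absolute differences would let one class's markers crowd out the
other's.

A query cell is classified by Pearson correlation (configurable to
Spearman) between its log2-CPM values and each class median, over a
random 80% of the markers, repeated for 100 bootstrap iterations. The
**certainty** is the vote fraction of the modal class; a cell is
classified only when certainty strictly exceeds 0.5 and the winning
class is not flagged low quality. Ties at the argmax go to the
lexicographically smallest class name and are counted
(`attr(res, "n_ties")`).

Two properties of vote-fraction certainty are worth knowing. With two
classes the certainty can never fall below 0.5 (it is the *modal* vote
fraction), so a perfectly ambiguous cell has expected certainty ≈ 0.54
and is rejected only on an exact 50/50 split; ambiguity is better read
from the margin between the two largest mean correlations. And as the
marker fraction approaches 1 every iteration uses the same genes, so
certainty collapses to 0 or 1.

Pool compositions among classified cells are compared with Pearson
chi-square tests, available both as goodness-of-fit against reference
proportions and as a contingency test of two count vectors (without
continuity correction); the construction used for any given published
comparison is ambiguous, so both are exposed.

# Connectivity statistics

Each tested directed pair contributes one Bernoulli outcome to its
pre→post pool category. The **out-of-class bias** of a pre-synaptic
pool is

\[ B = \frac{p_{\text{out}}}{p_{\text{out}} + p_{\text{in}}} \]

where \(p_{\text{out}}\) and \(p_{\text{in}}\) are the connection
probabilities onto the other pool and the own pool; 0.5 means no
preference and satisfies \(B(x, y) + B(y, x) = 1\).

`fisher_exact_2x2()` computes the two-sided p as the sum of
hypergeometric probabilities of all tables sharing the observed margins
whose probability does not exceed the observed one (with a 1e-12
relative guard for floating-point ties) — the standard "probability
mass" convention for two-sided exactness. A zero margin returns p = 1
with a warning.

`wilcoxon_signed_rank()` drops zero differences (Wilcoxon's
convention; Pratt's is available), assigns midranks to ties, and for up
to 25 nonzero differences computes the exact two-sided p from the full
\(2^n\) sign-assignment distribution via subset-sum convolution (twice
the smaller tail, capped at 1). Beyond 25 it switches to the normal
approximation with the exact rank-based variance
\(\sum r_i^2 / 4\) (which absorbs tie corrections) and a 0.5 continuity
correction.

The **output bias** of a simultaneously recorded L5a/L5b pair is
`amp_L5a / (amp_L5a + amp_L5b)`; the summary is its mean ± SEM (sample
SD / √n), tested against 0.5 with the signed-rank test. The ratio form
is pinned down by the convention that 0.5 represents equal drive.

# EPSP features

Features are extracted from the pointwise mean of 10–20 sweeps.
Baseline mean and SD come from a 50 ms window ending 2 ms before the
stimulus; the response window is 50 ms after it (both configurable —
no canonical values exist). An EPSP is **detected** when the response
amplitude exceeds twice the baseline SD.

The amplitude is measured on a 2 ms boxcar-smoothed copy of the trace.
This matters: the raw maximum of \(N\) noisy samples sits
\(\approx \sigma\sqrt{2\ln N}\) above the baseline (over 3σ for a 50 ms
window at 20 kHz), so a raw-max amplitude would cross the 2-SD
criterion on pure noise nearly always. Smoothing restores the intended
meaning of the threshold; the baseline SD itself stays unsmoothed so
"2 SD above baseline" keeps its literal sense.

**Synaptic delay** is the time from the presynaptic action potential to
the first (linearly interpolated) crossing of 20% of the EPSP maximum,
computed on the raw trace so that the noiseless double-exponential
kernel reproduces the closed-form crossing to within one sample. On
noisy single traces an early noise excursion can cross first; in
practice the delay is taken from averaged sweeps where this is
negligible. **Input resistance** is Ohm's law on the steady-state
deflection of a −300 pA step (window: last 20% of the step), in
MΩ = mV/nA.

The adaptation ratio during spike trains is deliberately not
implemented: no operational definition is available to us, and
guessing one would manufacture irreproducibility.

# The synthetic generators

The generators produce every input the chain consumes, as pure
functions of explicit parameters and a seed (bit-identical outputs,
caller's RNG untouched).

**Counts.** Genes × cells negative-binomial counts with a shared
dispersion (`var = μ + φμ²`, φ = 0.4 — a typical scRNA-seq value), a
per-cell log-normal library factor (σ = 0.35), planted marker blocks
(50 genes per class at +3 log2 fold-change), 20 mitochondrial genes at
a 5% expected fraction, 30 ERCC species at 3%, one reporter gene.
Defaults: 3 classes named after the upper-layer transcriptomic types
(Agmat, Adamts2, Rrad), 2000 endogenous genes, baseline mean 1.5
counts/gene — about 3,000 counts and ~1,400 detected genes per cell, a
deliberate scale-down (by ~1000×) of real Patch-seq libraries that
preserves detection fractions rather than absolute depth. Two baseline
regimes fail subtly and are avoided: at high baseline means nearly
every gene is detected, the detected-genes MAD collapses, and clean
cells start failing QC; at baseline 1 the NB median sits on its 0/1
knife edge and sampling flips of class medians fabricate huge spurious
log2 differences that displace true markers.

**Query pools** draw each cell's class from its pool mixture — defaults
aIP = (0.94, 0.06, 0) and OP = (0.65, 0.32, 0.03), the composition
regime of the study — and inject a 10% low-quality population with
library × 0.1 and mitochondrial/ERCC fractions tripled, which places
them decisively past all default MAD cutoffs.

**Pair tests** are Bernoulli per directed category (default
probabilities 3.1 / 12.2 / 14.6 / 14.7%, the L4 regime), with
log-normal delays and amplitudes for connected pairs. **Paired
responses** split a log-normal total drive `bias : 1 − bias` and apply
independent unit-mean log-normal noise of CV 0.3 to each amplitude;
because the per-pair ratio is nonlinear in the noise, the mean
recovered bias is shrunk toward 0.5 by about 0.007 at bias 0.67 —
second-order and far inside every tolerance used. **EPSP traces** are
a peak-normalized double exponential
(`exp(−t/τ_d) − exp(−t/τ_r)`, defaults τ_r = 2 ms, τ_d = 20 ms) plus
Gaussian noise.

What the generators do *not* emulate: batch and plate effects,
gene–gene correlation beyond the class structure, zero inflation beyond
NB sampling, distance-dependent connectivity, polysynaptic
contamination, or action-potential waveforms. Passing tests therefore
demonstrate the correctness and calibration of the *statistics*, not
that the classifier would reach any particular accuracy on real
libraries.

# Problem sizes and validation design

The validation suite checks, among others:

* exact arithmetic of every tally and bias against the printed
  probabilities (51/434 → 11.8%, bias(0.122, 0.031) → 0.8, …);
* `fisher_exact_2x2` against exhaustive hypergeometric enumeration
  (200 random tables, 1e-10 relative) and `stats::fisher.test`;
  `wilcoxon_signed_rank` against full 2^n sign enumeration (n ≤ 12)
  and `stats::wilcox.test`; `log2_cpm` and class correlations against
  independently coded references;
* mixture recovery on plates of 1000 cells per pool (QC → atlas →
  classification → composition) within 99% binomial intervals, with
  ≥95% agreement to ground truth;
* Fisher's size under the null on 2000 simulated pair-test tables of
  1000 tests per category — the size where exact-test conservatism has
  worn off (measured 0.042 at 500/category, ~0.05 at 1000);
* output-bias recovery at n = 500 pairs and signed-rank power against
  0.5;
* the analytic 20%-crossing of the noiseless EPSP kernel and detection
  behavior over 500 seeded traces.

These sizes keep the full suite around half a minute on one core while
leaving each stochastic check comfortable statistical margin.

# Limitations

* The classifier assumes the reference classes are exhaustive; there is
  no novel-class detection, and a cell from an unrepresented type will
  be forced toward its nearest class or rejected only via certainty.
* Vote-fraction certainty is coarse (grid 1/n_boot) and, for two
  classes, bounded below by 0.5.
* The exact category denominators behind the published per-category
  connection probabilities are not available, so Fisher p-values on
  real category tables are not reproduction targets; only the
  probabilities and biases themselves are.
* Batch correction, differential expression, dimensionality reduction
  and morphology are all out of scope.
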
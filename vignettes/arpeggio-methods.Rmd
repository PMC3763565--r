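---
title: "Spectral compression and deconvolution of ChIP-seq signals: methods"
author: "arpeggio package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spectral compression and deconvolution of ChIP-seq signals: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(arpeggio)
```

## The representation

A ChIP-seq experiment, reduced to the deduplicated 5' ends of its aligned
single-end reads, is a pair of 0/1 indicator signals per chromosome —
$D^+(t)$ and $D^-(t)$. `arpeggio` compresses an experiment into the
pair-count autocorrelation of these signals:

$$R(\tau) \;=\; \#\{(r_i, r_j) : r_j - r_i = \tau,\ \text{same strand,
same chromosome}\}, \qquad 0 \le \tau < W,$$

with $W = 8192$ bp by default. This is the *DSP* autocorrelation — raw
pair counts, with no mean-centering and no variance normalization, because
read-count data have no agreed-upon normalization and any multiplicative
constant cancels in the spectral ratios below. $R(0)$ equals the number of
occupied positions (each position pairs with itself). The discrete Fourier
transform of $R$ is the experiment's **spectral density**, a fixed-length
(8192-element) feature vector in which the magnitude at frequency bin $k$
describes signal recurring at genomic length scale $W/k$ bp.

The window $W$ is chosen because protein–chromatin interaction geometry —
fragment-scale pile-ups, nucleosome repeat spacing, polymerase gene-body
spread — lives at scales from tens of bp to a few kb; beyond that lag the
pair histogram is uninformative background. $W$ must be a power of two
only for FFT convenience; it is configurable.

Computationally, `autocorrelation()` and `cross_correlation()` never
allocate genome-length arrays: positions are kept sorted per chromosome
and counted with a sliding window (compiled code), $O(Nk)$ where $k$ is
the mean number of neighbours within $W$. 200,000 reads take a few
seconds.

## Deconvolution: the Arpeggio profile

The measured ChIP signal $Y$ is modelled as the convolution of the true
IP signal $Z$ with technical variability $X$ (accessibility, shearing and
library biases, stochastic sampling). Autocorrelation turns convolution
into multiplication of spectra, so given a control experiment measuring
$X$ alone,

$$\tilde R_Z \;=\; \mathcal{F}^{-1}\!\left[\frac{\mathcal{F}(R_Y)}
{\mathcal{F}(R_X)}\right]$$

recovers the autocorrelation of the true IP signal. This is the
**Arpeggio profile** (`deconvolve()`). Its shape classifies the
interaction: an isolated factor gives a sharp pulse with decaying tails, a
phased nucleosome array a damped oscillation at the repeat length, a
polymerase a pulse with slow shoulders, and a control deconvolved against
a matched control a pure impulse — no recurrent structure survives the
ratio. $Z$ itself is not recoverable (phase is lost in autocorrelation);
the profile is the invariant the method works with.

Numerical choices:

* **Regularization.** Bins where the control spectrum magnitude falls
  below `epsilon_rel` (default $10^{-6}$) of its maximum are inflated to
  that threshold magnitude, preserving phase. This leaves
  well-conditioned spectra untouched (the convolution-recovery identity
  holds to $10^{-6}$ relative error in the tests) and bounds the ratio
  otherwise; the number of guarded bins is recorded in the result.
* **Windowing.** The plain DFT of the $W$-windowed profile is used
  (implicit circularity); no taper by default, a Hann option exists.
  Both numerator and denominator are windowed identically, so window
  effects largely cancel in the ratio.
* **Display conventions.** The lag-0 value only reflects the read-count
  difference between experiment and control, and moving-average smoothing
  helps the eye; both are display-time operations
  (`smooth_profile()`) and never touch stored values.

### Control matching

When several candidate controls exist, `match_control()` filters them to
the sample's organism and shearing technique and picks the candidate with
the highest Pearson correlation between low-passed spectral magnitude
vectors (DC excluded — it only reflects depth), requiring $\rho > 0.85$.
Two points deserve emphasis. Correlation is computed in the frequency
domain: two experiments can match spectrally while being uncorrelated
position-by-position, and that is intended — the match captures shared
*statistics* of technical structure. For the same reason the
autocorrelation cannot see *where* accessible regions are, only their
length-scale and contrast statistics; simulated controls sharing the
identical accessibility landscape are spectrally indistinguishable from
independent layouts with the same statistics, and the package's tests
distinguish controls by differing statistics, not positions.

## Fragment-length recovery from single-end reads

A fragment of length $f$ sequenced from the minus strand places its read
5' end $f-1$ bp downstream of where a plus-strand read of the same
fragment would start. If fragment start $W$ and length $F$ are
independent, the minus-strand read-start intensity is the plus-strand one
convolved with the length distribution, so the opposing-strand
cross-correlation $C(\tau)$ satisfies
$\mathcal{F}(C) = \mathcal{F}(R^+)\cdot\mathcal{F}(q)$ with $q$ the
length pmf, and the ratio recovers the full distribution — not just its
mean — from single-end reads (`fragment_length_distribution()`).

Implementation notes, each of which matters in practice:

* **Even extension.** The stored autocorrelation is one-sided in lag; as
  an autocorrelation it is an even function, and it is mirrored to its
  circular even extension before the transform. The cross-correlation
  peak carries both flanks of the pair-distance distribution, so omitting
  the mirror step deconvolves a two-sided function by a one-sided one and
  is structurally wrong.
* **Single-strand denominator.** The minus-strand autocorrelation equals
  $|\mathcal{F}(W)|^2 |\mathcal{F}(q)|^2$ — it already contains the
  length distribution. Using the plus+minus sum as denominator therefore
  multiplies the recovered spectrum by a $1/(1+|\hat q|^2)$ envelope and
  distorts the shape. The recommended denominator is the plus-strand-only
  autocorrelation (`autocorrelation(x, strands = "plus")`), which is what
  the package's own pipelines use.
* **Identifiability.** For a *point source* that every fragment must
  cover, the fragment's start is uniform over the $f$ positions covering
  the event — start and length are dependent. In that geometry the
  cross/auto ratio reduces algebraically to a pure phase factor: the
  *mean* length is recovered sharply (the estimate approaches an impulse
  at the mean), but the distribution's shape is not identifiable. Shape
  recovery requires a geometry where starts are independent of lengths —
  digestion-boundary-anchored libraries (`fragment_placement =
  "anchored"` in the simulator) or broad distributed sources. This is a
  property of the estimator's information content, not of the
  implementation, and it is why the package's shape-fidelity validation
  uses the anchored geometry while the fixed-length mode validation uses
  point sources.
* **Denoising.** At desk-scale depths the bin-wise ratio is correct in
  expectation but noisy, and broadband bin noise integrates over the
  8192-lag support into substantial spurious mass. The default estimator
  therefore applies standard spectral cleaning: a Wiener-style shrinkage
  of each bin by $m^2/(1+m^2)$, where $m$ is the cross-correlation
  spectrum's magnitude in units of its own noise floor (estimated from
  the lower decile of the high-frequency tail, calibrated for Rayleigh
  noise so that persistent high-frequency signal — a discrete length
  mixture — does not inflate the floor); a light moving average of the
  ratio after demodulating by the cross-correlation peak lag (so
  smoothing does not damp components away from the peak); a cosine taper
  beyond the last reliable frequency band; truncation of the support at
  1024 bp (size-selected ChIP libraries live well below this); and
  zeroing of pmf bins below 2% of the peak. Each step leaves a noise-free
  ratio essentially untouched; `denoise = FALSE` gives the raw guarded
  ratio. Negative values are clipped and the result renormalized to sum
  one.
* **Axis convention.** Deconvolution lag $\tau$ corresponds to fragment
  length $\tau + 1$ (0-based coordinates put the minus-strand 5' end at
  fragment end $-\,1$); the returned pmf is indexed on the shifted axis
  so mode and mean align with true fragment length.
* **Read-length artifact.** Real single-end data often show a spurious
  spike at the sequencing read length, caused by mappability and
  duplication structure. The simulator deliberately models neither, so
  simulated data do not reproduce the spike; the estimator annotates the
  read-length bin (`read_length_spike`) so real-data users can inspect
  it.

`compare_to_paired_end()` scores an estimate against known fragment
lengths by Kolmogorov–Smirnov distance and mode offset. Under the
anchored geometry at 50,000 fragments the package recovers a
lognormal(250, 30) distribution with KS $\le 0.05$ and mean within 2%;
under point-source cover geometry a fixed 250-bp length is recovered as
the pmf mode within $\pm 2$ bp from 20,000 fragments.

## Nucleosome-spacing ratio

`alpha_ratio()` summarizes periodicity as the spectral magnitude at the
nucleosome repeat period (default 190 bp) divided by the median magnitude
at off-period scales within a 100–300 bp band (excluding ±30 bp around
the period). The ratio is scale-invariant; values near 1 indicate
isolated or flexibly spaced events, values clearly above 1 strict
spacing. The exact numerator/denominator bands are configurable and
recorded; the defaults are a declared surrogate for "magnitude at the
repeat length relative to its neighbourhood".

## The embedding and collection analytics

`arpeggio_mds()` low-pass filters each spectral density (scales below
40 bp zeroed — below that, spikey sampling noise dominates), takes the
real part (the transform of a true autocorrelation is real; the numerical
imaginary residue is discarded), and runs PCA on the sample × frequency
matrix, keeping six components by default — enough to capture the bulk of
variance in heterogeneous collections.

On top of the embedding (or of `1 - Pearson` distances between spectra,
`spectral_correlation_distance()`):

* `davies_bouldin()` — cluster-separation index over class labels on the
  six leading components, with a label-permutation bootstrap (n = 1000)
  that preserves cluster sizes (the null is unspecified in the source
  method; size-preserving permutation is this package's choice).
* `knn_classify()` — leave-one-out 1-nearest-neighbour balanced accuracy;
  one replicate per replicate group is retained at random per repetition
  to prevent leakage; permutation p-values (n = 100).
* `auc_aggregation()` — per-anchor AUC of ranking same-label samples
  closer than others (anchor's replicates excluded, midrank tie credit),
  100 replicate-resampled repetitions, averaged within label, median
  across labels.
* `jaccard_peak_distance()` — peak-based similarity for comparison:
  peaks overlap if they share ≥ 1 bp; the overlap count is symmetrized as
  the average of the two directed hit counts (a deliberate resolution of
  the many-to-many ambiguity; it reduces to the obvious count in
  one-to-one cases), total = $|a| + |b| - o$, distance $1 - o/\text{total}$.

## The simulator: what it emulates, and what it does not

`simulate_experiment()` generates stranded single-end reads with full
ground truth (fragments, events, accessibility blocks) for four regimes:
isolated factor binding, phased nucleosome arrays (repeat length 190 bp,
tunable positional jitter), polymerase-like gene-body spread with a 5'
anchor, and background-only controls. Background fragments are drawn from
piecewise-constant accessibility blocks that `simulate_matched_pair()`
shares between ChIP and control, emulating the common technical component
the deconvolution removes. Every fragment emits one read, plus-strand at
the fragment start or minus-strand at the end − 1 with probability ½, and
read starts are deduplicated exactly as real input would be.

Fragment placement is regime-aware. Point sources use the cover geometry
(start uniform over positions covering the event — random shearing).
Phased arrays default to nucleosome-protected fragments (midpoint at the
nucleosome): enzymatic digestion tracks particle boundaries, and this is
also what makes the repeat detectable — under cover placement the ±250-bp
uniform smear attenuates the 190-bp fundamental roughly twenty-five-fold,
burying it at any realistic depth. The anchored placement (5' end at the
event) models digestion-boundary libraries and is the geometry in which
fragment-length shape recovery is identifiable (above).

Default study conditions (chosen once, on realism grounds): genome 2 Mb;
background fraction 0.7 for factors (a fraction of reads in peaks near
0.3 is strong enrichment), 0.3 for broad histone-mark arrays (domains
capture most of the library), 0.5 for polymerase, 1.0 for controls;
lognormal(250, 30) fragments (sonication size-selection target; use ~150
for MNase-style libraries); read length 36.

What the simulator does *not* model: sequence content, mappability,
PCR duplication beyond position collisions, inter-chromosomal structure,
copy-number variation. Consequently, passing tests demonstrate the
estimators' correctness under the stated geometries and noise from
finite sampling and accessibility bias — they do not certify behaviour
under alignment artifacts or duplication-heavy real libraries, where the
read-length spike and mappability holes add structure the tests never
see.

## Problem sizes used in the validation suite

The test suite and acceptance script run these study conditions
(each a deliberate balance of signal detectability and runtime):

* Periodicity: 200 arrays × 10 nucleosomes, 190-bp repeat, 5-bp jitter,
  200,000 reads, deconvolved against a matched control; the first
  positive-lag maximum lands within ±5 bp of 190.
* Fragment mode: 20,000 fixed-250 fragments over 500 events.
* Fragment shape: 50,000 lognormal(250, 30) fragments anchored at 2,500
  boundaries.
* Spacing discrimination: 50 seeded repetitions at 80,000 reads per
  experiment — the depth needed because 60-bp jitter attenuates the
  190-bp comb to ~14% of its strict-array amplitude, leaving a small
  margin over the isolated-event baseline at shallower depth.
* Collection analytics: a 4-class × 10-sample panel (factor, histone
  array, input-like and IgG-like controls) at 30,000 reads per sample.

## Known limitations

* Fragment-length *shape* recovery is information-limited for pure point
  sources (mean only); the package recovers shape where the geometry
  permits and documents the distinction rather than hiding it.
* The α surrogate compares one period against a single band; multi-scale
  periodicity (e.g., mixed repeat lengths) needs the full spectrum.
* Spectral control matching cannot distinguish controls that differ only
  in the *location* of accessible regions.
* The Davies–Bouldin bootstrap and kNN p-values are permutation-based
  and inherit the usual granularity of small permutation counts.
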
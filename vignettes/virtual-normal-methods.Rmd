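---
title: "Virtual-normal copy-number estimation: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Virtual-normal copy-number estimation: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vncn)
```

## The problem and the model

Raw copy number from a SNP array is a per-marker log2 ratio of a sample's
total intensity to a reference intensity.  Its noise has two very different
components: *private* noise, independent across samples (hybridization,
scanner, tissue heterogeneity), and a *shared* probe-effect track — a
high-frequency, marker-indexed pattern common to every sample processed
under one protocol and batch.  A reference built from normals processed
elsewhere (public repositories, a different preservation protocol such as
frozen vs FFPE) carries a *different* shared track, so the log2 ratio picks
up both tracks at full strength.

The virtual-normal construction replaces the reference with a corrected
average of the test samples themselves:

* `I_t_avg(p)`, `I_r_avg(p)` — per-marker medians (or means) of the test
  and template sets;
* `CNavg(p) = log2(I_t_avg / I_r_avg)` — locates aberrations common to the
  test set, with the template used *only* as a baseline;
* `S(p)` — a piecewise-constant (or smoothed) estimate of the non-zero
  structure in `CNavg`;
* `I_vn(p) = I_t_avg(p) * 2^(-S(p))` — the test average with its common
  aberrations shifted back to baseline;
* `rawCN_i(p) = log2(I_i(p) / I_vn(p))`.

Two properties make `I_vn` a good reference.  (a) Its high-frequency
component is the test batch's own shared track, so the ratio cancels it —
the package asserts this as a correlation test between the reference's
high-frequency residual and the generative shared track.  (b) The shift by
`2^(-S)` removes the common aberrations, so they reappear in each
individual sample's `rawCN` instead of being divided away.  The exact
algebraic identity `log2(I_t_avg / I_vn) = S(p)` holds at machine precision
by construction and is used as a wiring regression test.

The assumptions are the usual ones for total-copy-number array work: the
intensities arrive already preprocessed (allelic crosstalk, probe-sequence
and fragment-length effects handled upstream), positive, on a common marker
scaffold; noise is roughly stationary in the log2 domain; and aberrations
are piecewise-constant in genomic position.  Allele-specific copy number is
out of scope.

## Averaging statistic: median vs mean

The set averages default to the **median**, which is what makes the
construction robust: an event carried by a minority of test samples does
not enter `I_t_avg` at all, so nothing needs to be corrected.  With the
**mean** (also available via `vn_config(statistic = "mean")`), a minority
event enters the average attenuated by its carrier fraction `f`; if the
baseline-shift estimator then misses it (a narrow event under the filter
variant), a carrier's recovered amplitude loses up to that same fraction
`f`.  The classical description of this trade-off predicts suppression
proportional to the event frequency — about 25–30% for events carried by
25–30% of samples, and under 20% for very small regions — which is
mean-like arithmetic.  Both statistics are exposed so either behaviour is
available; the suppression bound is asserted in the test suite for both.

## Baseline-shift estimation

Two interchangeable estimators of `S(p)`:

* **Segmentation variant** (`variant = "segmentation"`): recursive binary
  splitting per chromosome.  At each step the candidate breakpoint
  maximizing `z = |m_L - m_R| / (sigma * sqrt(1/n_L + 1/n_R))` is accepted
  when `z >= z_min`; ties go to the leftmost candidate so results are
  deterministic.  The noise scale `sigma` is estimated once per chromosome
  from the median absolute successive difference divided by
  `sqrt(2) * qnorm(0.75)`, which is insensitive to step changes as long as
  breakpoints are sparse.  Every final segment's level is the arithmetic
  mean of the data inside it — *mean preservation*, the property the
  reference correction actually requires, holds exactly by construction
  rather than approximately.  Defaults: `z_min = 4` (roughly a per-split
  false-positive rate far below one call per chromosome at desk scales;
  the noise-only Monte-Carlo in the test suite confirms < 0.05 spurious
  calls per 500-marker chromosome), `min_seg = 5` markers, maximum
  recursion depth 30.
* **Filter variant** (`variant = "filter"`): per-marker Gaussian-window
  smoothing, `sigma = w/4`, truncated at `±w/2` and renormalized at
  chromosome edges so weights always sum to one; windows never cross
  chromosome boundaries.  Default `w = 20` markers, the middle of the
  10–30-point range customary for pre-segmentation smoothing of raw CN.
  The result is stored as one degenerate single-marker segment per marker,
  so both estimators expose the same piecewise interface.

The recursive splitter was chosen over sparse-Bayesian or CBS-style
machinery for transparency and testability: an exhaustive single-breakpoint
search and a dynamic-programming minimum-RSS oracle (with the same
acceptance rule) pin its behaviour on small instances in the test suite,
where it agrees with the oracle in at least 95% of seeded replicates.  Its
known weakness is deliberate: a short event embedded in a very long
chromosome can fail the *first* chromosome-wide split even though a local
test would find it, because the flank-mean statistic dilutes with flank
length.  In that regime — which coincides with noisy averages — the filter
variant is the intended tool, exactly the trade-off that motivates having
both.

## GC-wave correction

Slow intensity waves correlated with local GC content are fitted on the
log2-ratio profile as per-bin medians over `nbins = 50` equal-width bins of
the observed GC range; bins holding fewer than 10 unmasked markers merge
into their neighbour, and at least two usable bins are required (constant
GC degenerates to a zero model).  The levels are mean-centred with
marker-count weights, so correction never moves the genome-wide mean.
Using the *median* per bin is the aberration-tolerance mechanism: amplified
and deleted regions are deliberately left in the fit — no aberration
pre-masking, which would have to be circular — yet cannot drag a bin's
level unless they own more than half of it.  Sex chromosomes are excluded
from fitting by default (their copy state differs) but are corrected on
application.  No parametric form is imposed because none is established;
binned medians need no tuning and are idempotent to within bin-median
sampling error (asserted in the tests).

Correction is applied at both places it matters: to `CNavg` before `S(p)`
is estimated, and to each sample's `rawCN` before its final segmentation.
The per-sample model is refitted per sample rather than reusing the
`CNavg` model: waves are partly sample-specific, and the median fit is
cheap and robust.  One desk-scale caveat: on small simulated scaffolds
(a few thousand markers) a concentrated aberration can constitute a third
or more of some GC bins — far above anything seen on a 250K-marker array —
and then biases bin medians by a fraction of the local noise scale.
Simulations that inject no GC wave are therefore analysed with
`gc_correct = FALSE`, matching the generative condition; on wave-bearing
input the correction removes the wave to below 0.05 log2 while preserving
a 1.0-log2 aberration within 5% (asserted in the tests).

## The synthetic-data generator

`simulate_cn_study()` draws, per marker and sample,
`intensity = base * 2^(shared + private + gcwave + cna)`: lognormal
intensities, i.e. Gaussian noise in the log2 domain, chosen so closed-form
SD predictions are available for validation (no distributional claim is
made about real arrays).  Its defaults are the study conditions the method
targets: 20 test samples vs 10 template normals, shared probe-effect SD
0.3 per set with *independent* tracks (the FFPE-vs-frozen protocol
mismatch), private noise SD 0.1, base intensity 2000.
`template_shares_test_track = TRUE` gives the paired/same-batch scenario.
GC content follows a smooth positional oscillation plus jitter (regional
autocorrelation, as with ~1 Mb GC windows); the GC wave is linear in GC
with configurable amplitude.  CNA events specify chromosome, start,
length, log2 amplitude and carrier fraction; carriers are drawn without
replacement with the count rounded to the nearest integer.  Test, template
and carrier draws use independent substreams of one seed, so changing the
template count never perturbs the test set (asserted).

What the generator does **not** emulate: probe-sequence and
fragment-length artefacts (handled upstream in real pipelines), allelic
intensities, tumour purity/ploidy mixtures, spatially correlated noise, or
waves unrelated to GC.  Passing tests on this generator therefore show
that the algorithm does what it claims under its own noise model — shared
track cancellation, common-event restoration, bounded minority-event
suppression — not that it is robust to every FFPE pathology.

## Numerical and interface choices

* Coordinates are 1-based inclusive throughout; the BED writer converts to
  0-based half-open explicitly, the SEG writer keeps 1-based.
* Markers with a non-positive or non-finite intensity in *any* sample of a
  set are masked set-wide (the averages and every per-sample ratio need
  the marker everywhere); masks propagate monotonically and are recorded.
* Chromosome order is first appearance in the marker map.
* GC values outside every fitted bin take the nearest bin's level.
* Chromosomes shorter than `2 * min_seg` markers form a single segment;
  chromosomes shorter than 3 markers pass through smoothing unchanged;
  fully masked chromosomes yield no segments.
* Tab-separated outputs print doubles with the shortest representation
  that round-trips bit-exactly, and the readers re-parse through `strtod`,
  so write-then-read is the identity — this keeps reruns byte-identical
  (provenance headers carry no timestamps).
* The segmented-region SD averages within-segment SDs *unweighted* across
  segments (single-marker segments excluded); a length-weighted variant is
  provided.  The CN=3 signal-to-noise uses the theoretical numerator
  `log2(3/2) = 0.585` by default; a measured-levels variant
  (`snr_cn3_measured()`) accepts observed CN3/CN2 segment means, which is
  how published S/N figures that disagree with `0.585/SD` arithmetic
  typically arise.

## Problem sizes

The test-suite simulations use 0.5–20k markers and 3–20 samples per set,
sized so the full suite runs in about a minute while keeping Monte-Carlo
margins comfortable; the reproduction script uses 10k markers, 20 test and
10 template samples and averages 20 seeds per quantity.  These are the
package's validation scales; the algorithm itself is linear in markers ×
samples and runs comfortably at array scale.

## Known limitations

* Binary-split segmentation can miss short embedded events on very long,
  noisy chromosomes (see above); use the filter variant there.
* The GC model is piecewise-constant in GC; a genuinely non-monotone wave
  narrower than a bin is not representable.
* No allele-specific output, no purity/ploidy correction, no significance
  calibration of SD differences between pipelines.
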
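---
title: "Sizing circular DNA from single-molecule fluorescence intensities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sizing circular DNA from single-molecule fluorescence intensities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The measurement principle

Circular DNA species that are rare in a heterogeneous sample — episomal
viral vectors, plasmids, eccDNA — are hard to quantify in bulk. The
approach implemented here works one molecule at a time: DNA is stained
with the bis-intercalating dye YOYO-1, deposited on functionalized glass,
and imaged by fluorescence microscopy. Each surface-bound molecule of a
few kilobases appears as a diffraction-limited punctum, and the number of
intercalated fluorophores — hence the background-adjusted *integrated*
intensity of the punctum — is, to good approximation, proportional to the
molecule's length in base pairs. A mixture of reference plasmids of known
sizes therefore calibrates a linear map from intensity to base pairs, and
any other molecule imaged under the same staining and buffer condition
can be sized by inverting that map.

Sequence identity is supplied by a second channel: catalytically dead
Cas9 loaded with a fluorescently tagged guide RNA binds its target
sequence without cutting. A punctum whose pixels correlate strongly
between the DNA channel and the dCas9 channel (Pearson correlation above
0.25 with one-sided p < 0.05) is classified as carrying the target.

`punctasizer` implements the full chain — quality control, shading
correction, segmentation, population fitting, calibration, colocalization
gating, background histogram subtraction, and population calling — plus a
synthetic image generator with per-molecule ground truth, so that every
stage can be validated without any physical sample.

## Pipeline stages and their assumptions

### Field QC and shading correction

Field selection is automated: a variance-of-Laplacian focus score
(normalised by the squared mean, so it is exposure-invariant) and a
saturated-pixel fraction are thresholded, with permissive defaults and a
manual `exclude` override. Illumination flatness is estimated
retrospectively from the data: puncta are sparse, so the per-pixel median
across fields is dominated by background; a heavy Gaussian smooth
(`smooth_sigma = 25` px) of that median, rescaled to mean 1, is the
multiplicative shading field. Division by a *mean-one* field removes
relative unevenness but keeps an arbitrary global factor (the mean
illumination); this factor cancels between calibration and analysis as
long as both are processed the same way, which is why calibration curves
are keyed to a condition tag and never transferred across conditions.

### Segmentation

Two masks are combined by union: an edge-based mask (Sobel gradient
magnitude, Otsu threshold on the gradient, morphological closing, hole
filling) and a local adaptive mask. The local threshold uses *robust*
moving-window statistics — window median plus `k = 3` times
1.4826 x the window MAD (a 31 px window) — rather than Niblack's
mean/SD: bright puncta inside the window inflate the window SD enough to
mask out nearby dim molecules, while the median/MAD pair stays anchored
to the local background. Components smaller than 4 px and components
touching the image border (truncated flux) are removed.

Measurement apertures are larger than the detection masks: each record
is seeded from a smoothed intensity maximum inside the mask (maxima
closer than ~5 px collapse to one seed) and grown into a 3 px dilation
of the mask by nearest-seed assignment. The dilation captures the PSF
tails (> 99.9% of the flux of a 1.3 px-sigma spot), and the seeded
growth keeps molecules a few PSF widths apart from merging into one
record. Molecules closer than about 6 PSF sigma still merge — there is
deliberately no declumping or watershed splitting, matching the
measurement's own convention that overlapping molecules appear as single
bright records; the synthetic truth flags them (`overlapped`).

The local background per pixel is the median of an annulus around each
record (2 px gap, 4 px wide, excluding all labelled foreground), and

    adjusted_intensity = raw_integrated - area * background.

This is offset-invariant and linear in the underlying molecule intensity
(both are tested properties) — the foundation of the sizing regression.

### Population fitting and calibration

Molecule intensities are histogrammed with a square-root rule (about
`2 * sqrt(n)` bins): variance-based rules (Freedman-Diaconis, Scott) key
the bin width to the *overall* spread, which for a multimodal mixture is
far too coarse to resolve individual populations. Peaks are local maxima
whose prominence exceeds `max(3, 0.05 * max, 2 * sqrt(max))`; the
`2 sqrt(max)` term keeps Poisson bin-to-bin fluctuations from
registering as populations. Each peak seeds a Gaussian through its full
width at half maximum (`sigma0 = FWHM / 2.355`), and a Gaussian is
least-squares fitted to the binned counts restricted to
`mu0 +/- 2 sigma0`. The windowing keeps neighbouring populations from
biasing each fit, at the price of a mild truncation bias that is
negligible for well-separated peaks. Fitting binned counts rather than
maximising a sample likelihood matches the histogram-level definition of
the populations and is equivalent on clean data (tested).

Calibration regresses known size (bp) on fitted population mean (a.u.)
by ordinary least squares. R-squared is always computed about the mean
of the sizes — including for the through-origin variant — so the two
variants are comparable and coercion through the origin can only lower
R-squared. (The no-intercept convention of computing R-squared about
zero would make the through-origin fit look spuriously better, inverting
the comparison the method relies on.)

Per-molecule size error is reported as the half-width of the regression
*prediction* interval at `ci_level = 0.99`, which widens away from the
calibration centroid. Note that with only three calibration points the
prediction interval has one residual degree of freedom and is extremely
conservative; pooling population means from replicate experiments as
additional calibration points tightens it substantially.

### Colocalization

The Pearson correlation between the two channels is computed over each
record's pixels plus a 1 px dilation (tolerating sub-pixel channel
offsets and PSF bleed; switchable to the exact mask). The p-value uses
the one-sided t transform `t = r sqrt((n-2)/(1-r^2))`; a permutation
oracle in the test suite confirms the parametric choice to within 0.02
at the decision threshold. An undefined correlation (a flat dCas9 patch,
i.e. no signal at all) is classified non-colocalized, since absence of
signal is the biologically negative case. Thresholds (PCC > 0.25,
p < 0.05) live in one configuration object and nowhere else.

### Background subtraction and population calling

A background sample (e.g. a mock-transduced control) is assumed to
contain everything uninteresting. Its histogram — on bins shared with
the target — is rescaled so both samples represent equal analyzed
molecules per imaged field (fields are the sampling unit; total-count
and fixed-factor normalisations are available), subtracted binwise, and
negative residuals are clipped to zero. Pure counting noise would
otherwise leak a few percent of spurious positive mass through the
clipping, so a per-bin significance gate is applied by default: a
residual bin is kept only if it exceeds `2 sqrt(target + scale^2 * bg)`,
the shot-noise SD of the difference. Clipped and gated mass is logged.

The residual is realized as bin-centre values and clustered by an
**exact** 1-D k-means: in one dimension the optimal clusters are
contiguous in sorted order, so dynamic programming over weighted unique
values finds the global optimum — no seeding, no restarts, bit-identical
results. `k` is a user decision (the number of expected species, e.g.
monomer/dimer), informed by an advisory elbow report; clusters below 1%
abundance are flagged as unsupported rather than suppressed. Cluster
means map to base pairs through the calibration curve.

## The synthetic generator

`gen_field()` renders each molecule as a pixel-integrated isotropic 2-D
Gaussian (PSF sigma 1.3 px) whose integral equals the molecule's drawn
intensity; per-population intensities are Normal with mean
`size_bp * intensity_per_bp` and CV as configured, truncated at zero.
Channel 2 receives spots where molecules carry a dCas9, plus a Poisson
number of unattached spots modelling transient binding. The field is
modulated by a smooth radial vignette, then degraded by gain-scaled
Poisson shot noise and Gaussian read noise — a pragmatic EMCCD
approximation.

Default study conditions: 512 x 512 px fields covering 1.5e4 um^2. The
field area is *inferred*, not stated: it is the area implied by a
deposition regime of one molecule per 15 um^2 yielding about 1000
molecules per field; the per-pixel area follows from it and is
configurable. The default 100 molecules per field keeps overlap rare;
the maximal deposition regime (1000 per field) is available by setting
`molecules_per_field`.

Two fixture designs recur in the tests and the acceptance script, chosen
once as follows:

* **Calibration ladder** — three equal populations of 2686, 5562 and
  12920 bp at 5% intensity CV; six fields of ~150 molecules give about
  300 molecules per population.
* **Transduction analogue** — a genomic-background smear (two broad
  populations at 1.5 and 4.5 kb with CV 0.5-0.6, emulating fragmented
  chromosomal DNA whose bulk lies below the monomer intensity) carrying
  a 7% spike of vector molecules split 98:2 between monomer (2684 bp)
  and dimer (5368 bp). For colocalization contrasts the vector molecules
  have 90% dCas9 occupancy and the false-spot density is set so the
  negative control shows a few percent apparent colocalization, the
  background level the real measurement exhibits.

What the generator does **not** emulate: DNA conformation (all molecules
are ideal points; real large circles are slightly extended), camera
pixel-response non-uniformity, chromatic offset between channels (the
channels are co-registered by construction), focus drift, and intensity
variation from staining-ratio gradients. Passing tests therefore
demonstrate the correctness and calibration of the *analysis*, not the
physics of a particular microscope.

## Numerical choices and degenerate inputs

* Histograms: values outside the range are counted and logged, never
  silently dropped. Negative adjusted intensities are retained in
  records and excluded by histogram range, to avoid biasing the dim tail.
* `init_gaussian()` reports a peak whose half-height crossing runs off
  the histogram edge as *unresolved*; drivers turn that into a named
  error listing the affected reference size.
* `kmeans_1d()` collapses duplicate values to weights first; ties in
  the dynamic program resolve to the earliest split, deterministically.
* Constant images yield empty masks and a zero focus score with a
  `constant` flag — degraded inputs produce flagged results, not crashes.
* All randomness flows through one seed per entry point; identical seed
  and configuration reproduce images byte-for-byte.

## Problem sizes

The test suite and the acceptance script size their simulations to run
on a single CPU in a few minutes: the image-based calibration uses six
512 x 512 fields (~900 molecules), subtraction experiments use 2e4
molecules per sample at the table level, and colocalization contrasts
use eight 256 x 256 fields per arm. These sizes put sampling error well
inside the tolerances being asserted; larger experiments only narrow
the error bars.

## Known limitations

* No declumping: at one molecule per 15 um^2 (the maximal deposition
  regime) roughly a quarter of molecules have a neighbour within the
  merge radius and are reported as single brighter records, inflating
  the apparent concatemer tail. Deposit more dilutely when composition
  matters.
* Sub-populations below the per-bin noise gate of the difference
  histogram (a fraction of a percent of molecules over a strong
  background) are not recoverable without pooling more data; the gate
  trades that sensitivity for false-discovery control.
* The colocalization gate's false-positive rate rises with unattached
  dCas9 density; the negative-control degree should always be reported
  alongside the positive.
* A calibration curve is valid only for its own staining/buffer
  condition; the package warns, but cannot correct, cross-condition use.
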
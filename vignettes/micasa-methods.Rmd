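---
title: "Quantifying tissue organization with multitaper radial spectra"
author: "micasa"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying tissue organization with multitaper radial spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(micasa)
```

## The problem

Histology can tell you *what* cells a tissue contains; it is much harder to
quantify *how* they are arranged. Two thymus sections can have identical
marker composition while one has crisp cortical/medullary compartments and
the other a disorganized mixture — a difference the eye sees but a cell
count cannot. This package measures organization directly: given
two-channel fluorescence images of tissue sections (two markers per
section, several sections per biological condition), it estimates how much
spatial structure each marker has at every length scale, how strongly the
two markers are associated scale by scale, and how consistent those
properties are across sections. Conditions are then compared band-by-band
on a physical length-scale axis.

## The estimator

For each section the two channels are mean-subtracted, multiplied by each
of $M$ orthonormal two-dimensional Slepian (DPSS) tapers, and Fourier
transformed, giving tapered coefficients $J^{(i,m)}_c(\mathbf{k})$ for
image $i$, taper $m$, channel $c$. Three frequency-domain summaries follow:

* **log-spectrum** per channel: $\log |J|^2$, one 2D map per
  (image, taper) estimate;
* **atanh-coherence**: the magnitude coherence pooled over all $NM$
  estimates,
  $C(\mathbf{k}) = |\sum J_a J_b^*| \big/ \sqrt{\sum|J_a|^2 \sum|J_b|^2}$,
  transformed by $\mathrm{atanh}$ (variance-stabilizing; capped at
  $1-10^{-6}$ because a self-coherent bin would diverge). Coherence from a
  *single* tapered estimate is identically 1, which is why pooling across
  the estimate set is not optional but constitutive;
* **variance curves**: the spread of the per-estimate curves, separating
  "organized differently" (mean shifts) from "disorganized" (spread
  rises).

Each 2D map is circularly averaged — the unweighted mean over all 2D
frequencies whose radius falls in each of 60 log-spaced bins between the
image's fundamental frequency and the Nyquist frequency $1/(2\,\Delta x)$
— and reported against length scale $1/f$ in micrometres. Sections of
different pixel dimensions get their own taper sets and native radial
grids; curves are then linearly interpolated in log-frequency onto the
intersection grid (never extrapolated), and the pooled coherence is formed
per shape group and combined with estimate-count weights.

Slepian tapers are used because they maximize spectral concentration in a
band $|f| \le W$: with the default per-axis time-bandwidth product
$NW = 2$, each axis contributes $K = 3$ concentrated sequences, the 2D
tapers are their outer products ranked by concentration-eigenvalue
product, and the top $M = 7$ are kept. The 1D sequences are computed from
the standard tridiagonal commuting matrix (numerically stable) with
concentrations recovered as sinc-kernel quadratic forms; the tests verify
both against a direct eigendecomposition of the concentration kernel.

## Confidence intervals and the choice of resampling unit

Intervals come from delete-one jackknife resampling with a
$t_{\nu,(1+\gamma)/2}$ quantile at the configured level $\gamma$
(default 99%); variance curves get the textbook $\chi^2$ interval.
The one genuinely open design question is the resampling *unit*, and the
package's default is the result of a measurement, not a convention.

The classical multitaper argument treats all $NM$ (image, taper)
estimates as exchangeable, giving $NM$ degrees of freedom. That argument
is exact at a *fixed* frequency, where orthogonal tapers give
uncorrelated coefficients. It fails after circular averaging: a wide
radial bin pools thousands of 2D cells, the per-taper estimation noise
averages away, and what remains in every taper's ring average is the same
quantity — the realization's energy in that annulus. The $M$ taper curves
of one image therefore become positively correlated copies. Measured on
white-noise images (128×128 px, 60-bin grid), the cross-taper correlation
of ring-averaged log-spectra rises from about 0.10 in sparse bins to
about 0.34 in the widest bins, and the nominal-99% estimate-level
interval covers the true curve only ~93% of the time (down to ~90% at
fine scales). The same miscalibration produced frequent false
"significant bands" when comparing two conditions drawn from one process.

The default is therefore `jackknife_unit = "image"`: delete one whole
image (its $M$ tapers together), $t_{N-1}$ intervals. Images are
genuinely independent, so this is calibrated by construction; measured
coverage at the same setup is 98.9–99.0%. The cost is power: with
$N \le 5$ sections, $t_{N-1}$ quantiles are large, and modest
between-condition effects that the $NM$-dof intervals would flag are no
longer separable — some of those flags were, precisely, the
miscalibration. The estimate-level unit remains available as
`analysis_config(jackknife_unit = "estimate")` for comparison with the
classical construction; results still record $NM$ as the total estimate
count. For a single-section dataset ($N = 1$) the image unit is
impossible and the estimate unit is used automatically — intervals there
inherit the caveat above.

The coherence variance curve uses jackknife pseudo-values of the deleted
units (a direct single-estimate coherence does not exist); log-spectrum
variance uses the per-estimate curves directly. Variance $\chi^2$
intervals use $N-1$ degrees of freedom under the image unit, $NM-1$ under
the estimate unit.

## Comparing conditions

`compare_conditions()` reports maximal runs of consecutive bins where the
two conditions' confidence bands are disjoint, with the higher condition
and the band's length-scale extent. Non-overlap of two independent
level-$\gamma$ intervals implies at least level-$\gamma$ confidence in a
difference — "statistics by eye" made explicit. Masked bins (empty radial
bins, out-of-range after interpolation) are dropped, never significant.
No multiplicity correction is applied across bins; a band spanning one
bin at 99% should be read accordingly.

## Synthetic study conditions

All tests run on seeded generators rather than tissue:

* **White noise** — flat expected spectrum; calibration runs use
  128×128 px at 2 μm/px, $N = 3$, matching the smallest realistic study.
* **Blob lattices** — Gaussian blobs (radius spacing/6, truncated at 3
  radii) on a square lattice with positional jitter of sd spacing/10.
  The jitter matters: a perfectly periodic, noise-free lattice has zero
  off-comb power, so its log-spectrum between comb lines is pure taper
  side-lobe structure; jitter supplies the broadband floor that real
  cellular images always have. Peak-recovery runs use 1024×1024 px
  (2,048 μm — whole-section scale), where the taper bandwidth
  $W = NW/(n\,\Delta x)$ is narrow enough that the lattice fundamental
  lands within one radial bin of $1/\text{spacing}$.
* **Compartment pairs** — a Gaussian random field smoothed to a stated
  correlation length (kernel sd = scale/2, periodic FFT convolution;
  wrap-around is immaterial at the sizes used) is thresholded at the
  quantile giving the stated fill fraction; channel A lives inside the
  mask, channel B outside, on disjoint supports. Within its compartment
  each channel's intensity is an independent pixel-scale texture (the
  pre-smoothing noise, rescaled to [0, 1]) — stains are granular, and a
  smooth intensity would make fine-scale spectra realization-locked in a
  way real images are not. `replicate_variability` rescales the
  compartment scale per replicate by $e^{\rho z}$, $z \sim N(0,1)$,
  emulating section-to-section inconsistency. Null and phenotype runs use
  fill fraction 0.35 (a medulla-like share) and extents ≥ 8× the
  compartment scale, the self-averaging regime whole sections provide.
  Replicate seeds derive as $(\text{base} + i\cdot 1000003) \bmod
  (2^{31}-1)$, so datasets are reproducible element-wise.

What these generators do *not* emulate: optics (PSF, vignetting), stain
bleed-through between channels, anisotropy, and tissue boundaries —
passing tests say the estimator and its statistics behave as designed on
stationary textures, not that any particular tissue result is correct.

Two synthetic findings deserve explicit caveats. First, for exactly
complementary compartment channels the large-scale coherence saturates
near 1, where atanh amplifies tiny coherence differences into large
value swings; variance comparisons are therefore read on organization
scales (tests use 20–300 μm) rather than at the organ scale. Second, a
compartment-scale shift of 200 → 320 μm moves the coherence curve by
less than the between-section variability at $N = 5$, so calibrated
99% intervals do not separate the two conditions — detecting effects of
that size at such small $N$ requires either more sections or accepting
the undercoverage of the estimate-level unit.

## Numerical choices

* Log floor: $\log(|J|^2 + \epsilon)$ with $\epsilon$ the smallest
  normalized double; only exactly-zero bins feel it.
* atanh cap $1 - 10^{-6}$; DC excluded everywhere (the mean is removed);
  Nyquist row/column included; corner frequencies beyond the Nyquist
  radius excluded from radial bins.
* Radial bins: 60 log-spaced, geometric-midpoint centres, unweighted bin
  means; empty bins masked. Ties at bin edges resolve to the lower bin;
  the Nyquist edge is closed.
* Taper candidate ties (equal eigenvalue products) break
  lexicographically on the 1D index pair. Taper sets are cached per image
  shape within a session.
* Interpolation is linear in log-frequency, only within the source range.
* "Interior" bins in calibration runs: pooled cell count ≥ 16, excluding
  the outermost unmasked bins — sparse bins average too few exponential
  variates for a $t$ reference to be meaningful.

## Region-based density quantification

Independent of the spectral pipeline, `medulla_mask()`,
`partition_regions()` and `cell_density()` reimplement region-specific
cell-density quantification: the medullary marker channel is smoothed and
thresholded (Otsu by default; speckles below 400 μm² removed), the
cortico-medullary junction is the 100 μm band outside the medulla, the
subcapsular region the 100 μm band inside the tissue perimeter, and the
cortex the remainder — distance transforms define both bands, and where
they would overlap in thin tissue the CMJ wins (medulla > CMJ >
subcapsular > cortex). Marker-positive objects are threshold + connected
components with a minimum area, assigned to regions by centroid, so
counts are conserved; densities are objects per μm². The object detector
is deliberately simple — a stand-in for purpose-built cell segmentation,
adequate for the partition logic it feeds.

## Reference problem sizes

Test and validation runs use: calibration, 200 replicates of
$N=3$ 128×128 white-noise pairs against a 10,000-estimate oracle mean;
null comparisons, 12 replicate pairs of $N=3$ 512×512 compartment
conditions; peak recovery, $N=3$ at 1024×1024 for spacings 20/40/80 μm;
phenotype runs, $N=5$ at 1024×1024. These sizes put the generators in the
regime the method targets (sections much larger than their features)
while keeping a full validation run in minutes on one core.
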
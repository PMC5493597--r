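# micasa

Multitaper circularly averaged spectral analysis of two-channel
fluorescence tissue images.

## What it measures, and for whom

Most image-quantification tools count cells; this package quantifies how
cells are *arranged*. It is written for biologists comparing tissue
organization between conditions — mutant vs control thymus sections,
developmental stages, treatment groups — from whole-section two-channel
fluorescence images (two markers per section, N sections per condition).

Each image pair is windowed by a family of M orthonormal 2D Slepian
(DPSS) tapers and Fourier transformed, giving tapered coefficients
J⁽ⁱ'ᵐ⁾(**k**) per image i, taper m and channel. From the N·M estimates
the package computes, as functions of radial spatial frequency
f = |**k**| (cycles/μm, labelled by length scale 1/f in μm):

- the **log-spectrum** of each channel, log |J|², circularly averaged —
  large values at frequency f mean that cells of that type recur with a
  characteristic separation 1/f;
- the **atanh-coherence** atanh C(f), with
  C = |Σ Jₐ J_b\*| / √(Σ|Jₐ|² Σ|J_b|²) pooled over estimates — the
  scale-resolved association between the two markers (compartmentalized
  tissue shows strong coherence at the compartment scale);
- the **variances** of all three curves across estimates — distinguishing
  a tissue that is organized *differently* from one that is
  *disorganized* (inconsistent from section to section).

Every curve carries jackknife confidence intervals (t-based, default
99%; χ² for variances). Two conditions differ significantly in a
frequency band when their confidence bands are disjoint there —
statistics you can read off the plot. `compare_conditions()` extracts
those bands automatically with their length-scale extents.

The package also includes seeded synthetic-image generators (noise
fields, blob lattices with a known spacing, anticorrelated compartment
patterns with controllable scale and replicate variability) used by the
test suite as ground truth, and a region-density module that partitions a
section into medulla, cortico-medullary junction, subcapsular band and
cortex and reports marker-positive object densities per region.

## Worked example

Two synthetic conditions with the same 60 μm compartment organization,
one perfectly consistent across sections, one with replicate-to-replicate
scale variability (a "disorganization" phenotype):

```r
library(micasa)

spec <- generator_spec("compartments", shape = c(256, 256),
                       pixel_size_um = 2, seed = 1,
                       compartment_scale_um = 60, fill_fraction = 0.35)
wt  <- make_condition(4, spec, base_seed = 101, label = "wildtype")
spec_mut <- spec; spec_mut$replicate_variability <- 0.5
mut <- make_condition(4, spec_mut, base_seed = 202, label = "mutant")

res_wt  <- micasa_analyze(wt)
res_mut <- micasa_analyze(mut)
res_wt
#> <micasa_result> 'wildtype': N = 4, M = 7, NM = 28 dof, 99% CIs
#>   51 radial bins spanning 0.002034-0.2401 cycles/um (4.17-492 um)

i <- which.min(abs(res_wt$grid$frequencies - 1/60))
res_wt$atanh_coherence$estimate[i]
#> 2.87  (99% CI [2.64, 3.10])
```

The atanh-coherence near the 60 μm scale is high (2.87 ≈ coherence 0.99):
the two markers occupy complementary compartments of that size. The
variance curves separate the conditions — the mutant's coherence is about
three times more variable across sections at organization scales:

```r
sc <- 1 / res_wt$grid$frequencies
band <- sc >= 20 & sc <= 120 & !res_wt$var_atanh_coherence$mask
median(res_wt$var_atanh_coherence$estimate[band])
#> 0.00735
median(res_mut$var_atanh_coherence$estimate[band])
#> 0.0229

plot_result(res_wt, "curves.pdf", compare = res_mut)  # overlaid 99% bands
compare_conditions(res_wt, res_mut)                   # disjoint-CI bands
```

## Command line

A thin driver over the same functions is installed at
`exec/micasa` inside the package:

```sh
micasa=$(Rscript -e 'cat(file.path(find.package("micasa"), "exec", "micasa"))')
Rscript $micasa simulate --pattern compartments --rows 256 --cols 256 \
        --scale 60 --n-images 4 --seed 4 --out condA
Rscript $micasa analyze --dir condA --mode paired --pixel-size 2 --out outA
Rscript $micasa compare outA outB --out report
Rscript $micasa regions --dir condA --mode paired --pixel-size 2 --out reg
```

`analyze` accepts RGB images (red/green planes are the two markers) or
paired single-channel files matched by a name token; it writes one CSV
per output curve (frequency, length scale, estimate, CI bounds), a JSON
run manifest and a PDF figure. Flags mirror a YAML config file
(`--config`); explicit flags win.

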
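---
title: "Mapping fatty-acid chain length and saturation from NIR hyperspectral images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping fatty-acid chain length and saturation from NIR hyperspectral images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nirlipidmap)
```

## The problem

Liver lipid composition is usually characterized destructively: total lipid
by solvent extraction, fatty-acid profiles by gas chromatography (GC) of the
methyl esters. Near-infrared hyperspectral imaging (NIR-HSI) offers a
label-free alternative: the second overtones of aliphatic C–H stretches
absorb in the 1000–1400 nm window, with the CH~2~ band near 1170–1180 nm,
the CH~3~ band near 1150 nm and the olefinic CH band near 1185–1195 nm, so
the shape of a tissue spectrum in this window encodes how much lipid there
is and what kind of hydrocarbon chains it carries.

`nirlipidmap` implements the full analysis chain: chemical descriptors of
fatty-acid composition, radiometric and chemometric preprocessing of
hyperspectral cubes, kernel-regression calibration against per-sample
reference values, and per-pixel mapping. A synthetic scene generator with
diet-structured liver compositions makes every stage runnable and testable
without instrument data.

## Chain length and saturation as functional-group statistics

For a straight-chain fatty acid with `C` carbons and `d` double bonds,
counting functional groups gives one CH~3~, one COOH, `2d` olefinic CH
carbons and `C - 2 - 2d` CH~2~ carbons. Two statistics summarize the chain:

- **HCL** (hydrocarbon chain length):
  `(CH3 + CH2 + CH + COOH) / CH3`, which equals `C` exactly for straight
  chains. Phrasing the carbon count in group terms is what ties it to NIR
  band intensities — CH~3~ occurs once per molecule, so total group counts
  per methyl measure chain length.
- **DS** (degree of saturation): `CH2 / (CH + CH2) = (C - 2 - 2d)/(C - 2)`,
  equal to 1 for saturated chains and strictly decreasing in `d`.

```{r}
vapply(0:3, function(d) fatty_acid_ds(fatty_acid(18, d)), 1)
```

At tissue level a composition is a set of molar fractions. Two conventions
for the tissue DS are provided. The **pooled** ratio (default) forms total
CH~2~ over total CH + CH~2~ across all molecules — the literal group-count
ratio of the tissue. The **weighted** mean averages per-acid DS values with
the molar fractions — the picture in which each tissue point on the HCL/DS
plane is a convex ("vector") combination of the per-acid vertices. The two
agree for HCL (every straight chain has exactly one methyl) but differ
slightly for DS, because the pooled ratio weights longer chains more. Both
are exposed so the discrepancy is testable; the hull-containment guarantee
on the HCL/DS scatter holds for the weighted reading, while pooled points
can sit marginally below a hull edge.

Rounding of reported two-decimal DS values uses half-away-from-zero
(`round_half_away()`), matching how such tables are conventionally printed
(0.625 is reported as 0.63).

## Preprocessing model

The instrument records raw counts `I_raw`, a dark-current frame `I_dark`
(shutter closed) and a white reference `I_white` (standard reflector).
Relative reflectance is `R = (I_raw - I_dark) / (I_white - I_dark)`; pixels
whose denominator falls below 1e-12 of the white-frame scale are masked out
rather than divided. Downstream steps only ever shrink the mask.

The chain, in order: reflectance → spike removal → pixel averaging (for
calibration; per-pixel for mapping) → absorbance → wavelength crop → SNV.

- **Spike removal.** The acquisition occasionally produces isolated
  single-band outliers. Detection runs along the spectral axis per pixel: a
  running median (window 7 bands) gives residuals, and bands whose residual
  exceeds 6 robust SDs (1.4826 × median absolute residual) are replaced by
  the local median. On noise-free spectra the median absolute residual is
  exactly zero (running medians reproduce monotone stretches), so the scale
  falls back to the 98th-percentile residual; smooth-curvature residuals
  then set the scale and only far-out isolated bands are touched. Whether a
  spectral or spatial neighborhood is the right reference is an open
  choice; the spectral axis is used here because spikes are single-band
  events while genuine absorption features span many 2.2 nm bands.
- **Absorbance** is decadic, `A = log10(1/R)` — the spectroscopic
  convention when "log" is unqualified.
- **Crop** keeps the closed interval [1000, 1400] nm: below 1000 nm the
  InGaAs camera loses sensitivity, above 1400 nm water absorption
  dominates. On the instrument's 760–1885 nm, 2.2 nm grid this keeps 181
  bands.
- **SNV** standardizes each spectrum over its bands,
  `z = (x - mean(x)) / sd(x)`, removing additive baseline offsets and
  multiplicative scatter factors. The sample (n−1) SD is used, matching
  common chemometrics implementations; the population SD is one argument
  away. SNV is applied to absorbance spectra (the domain in which corrected
  spectra are interpreted and plotted); applying it to reflectance instead
  is available as a configuration switch.

## Calibration and validation

Per-sample mean SNV spectra are paired with the sample's reference total
lipid (mg/g), HCL and DS, and one independent epsilon-SVR model per target
is fitted (`e1071`/libsvm under the hood). Defaults, chosen here since
no standard values exist for this instrument/feature combination:
radial-basis kernel with width from the median-heuristic
(`gamma` = 1 / median pairwise squared distance between training spectra),
`cost = 10`, `epsilon = 0.05` on the internally standardized target. All
resolved hyperparameters are stored in the model object, so runs are
reproducible. Calibration uses per-sample mean spectra; deployment applies
the same model to every pixel spectrum.

Validation is leave-one-out: each sample is predicted by a model refitted
from scratch (including the kernel-width heuristic) on the remaining n−1.
Accuracy is the conventional cross-validated coefficient of determination,
`R² = 1 - Σ(ŷᵢ - yᵢ)² / Σ(yᵢ - ȳ)²` with residuals predicted-vs-measured
and the total sum of squares about the measured mean.

## What the synthetic generator emulates

Five diet groups (normal diet, high-fat, high-cholesterol, and high-fat
with 2% or 12% linoleic acid) are modeled as `diet_profile` objects over a
16-acid liver panel. Each group's mean composition is solved, not tuned:
thirteen minor acids carry fixed small fractions (totalling 0.20) and the
three dominant liver acids — palmitic 16:0, linoleic 18:2, α-linolenic
18:3 — are solved from a 3×3 linear system so the pooled tissue HCL/DS of
the mean composition equal the group's target values exactly. The targets
are the group-level statistics of a diet-modified mouse-liver study: HCL
rising 17.22 → 17.54 → 17.56 → 17.72 → 17.83 and DS falling 0.83 → 0.81 →
0.79 → 0.77 → 0.75 across 2% LA, 12% LA, HFD, ND, HCD, with group lipid
means from 65 to 174 mg/g. Lobe-to-lobe scatter is Dirichlet with
concentration 300, which reproduces group SDs of about 0.07 on HCL and
0.01 on DS; total lipid is normal truncated at zero with the group SDs.

Spectra follow a Beer–Lambert construction: Gaussian bands at 1150 (CH~3~),
1175 (CH~2~) and 1190 nm (CH), all 12 nm wide, with amplitudes
proportional to lipid content × pooled group count × band weight, plus a
logistic water edge centered at 1400 nm (so the crop is exercised) and a
per-pixel affine scatter baseline (which SNV must remove). Raw frames are
`signal × 10^(-A) + dark current`; the stored white reference is signal
plus dark current, as an instrument records it, so reflectance correction
recovers `10^(-A)` exactly at zero noise — the basis of the pipeline's
1e-6 round-trip oracle. Noise is shot-like (∝ √signal) plus Gaussian
readout; spikes are single-band positive outliers of at least 10 local
noise SDs at a configurable rate.

The generator deliberately omits radiative transfer, scattering physics,
instrument point-spread, temperature effects and any absorption by
non-lipid constituents other than the water edge. Band weights are free
parameters — nothing in the tests asserts absolute spectral shapes, only
that composition statistics are *recoverable* from them. Passing recovery
tests therefore demonstrates that the analysis chain is correct and
self-consistent, not that it would achieve the same accuracy on real
tissue, where confounding absorbers and scattering structure are present.

## Problem sizes and numerical choices

Rendered calibration lobes are 12×12-pixel scenes (~110 tissue pixels)
rather than the 1500–3000-pixel regions of interest a line-scan instrument
yields; pixel averaging shrinks noise either way, and the small scenes keep
the full synthetic study (100 lobes, three LOOCV analyses) at around ten
seconds. The recovery study uses 20 lobes per diet group; a calibration of
more than 70 samples is the regime in which such NIR estimation stabilizes.
Under these conditions the cross-validated R² is about 0.98 for total
lipid, 0.98 for DS and 0.83 for HCL — HCL is hardest because the CH~3~
count is one per molecule regardless of chain length, so its band varies
only weakly; the same ordering of difficulty is seen on real data.

Other conventions: wavelength crop bounds are inclusive on both ends;
degenerate inputs error early and loudly (empty masks, zero-variance
spectra, all-identical training spectra, white ≈ dark references); LOOCV
reports are keyed by sample identifier and invariant to sample order;
tie-breaking in nearest-band lookup is `which.min` (lower band wins at
exact midpoints).

## Known limitations

- The 16-acid panel and the per-group mean fractions are package defaults
  standing in for study-specific GC tables; both are configurable.
- Branched, hydroxy or otherwise modified fatty acids are outside the
  straight-chain counting model; the C17:0 internal standard is treated as
  an ordinary straight chain.
- Double-bond position and cis/trans geometry are invisible to
  CH/CH~2~/CH~3~ counting and are not modeled.
- SVR hyperparameters are sensible defaults, not the result of a nested
  search; an inner grid search can be layered on via the `cost`/`epsilon`/
  `gamma` arguments.
- Tumor/normal regions are user-supplied masks; no segmentation is
  attempted.
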
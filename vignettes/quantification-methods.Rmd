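---
title: "Quantifying McSC epidermal migration from two-channel skin images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying McSC epidermal migration from two-channel skin images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement problem

After UVB irradiation, melanocyte stem cells (McSCs) leave the hair-follicle
bulge and repopulate the interfollicular epidermis. In whole-mount imaging of
flattened dorsal skin, the limited optical depth of a widefield microscope
means that only surface (epidermal) signal is captured: nuclear H2B-GFP
reporter expression marks migrated melanocyte nuclei as point-like spots in
the green channel, while hair follicles autofluoresce strongly in the red
channel. The quantity of interest is the **migration rate**

$$\text{migration rate} \;=\;
  \frac{\#\,\text{McSCs}}{\#\,\text{hair follicles}}$$

pooled over all fields of a mouse (typically 20–25 fields with roughly 320
follicles each, i.e. 6400–8000 follicles per animal). Two complications make
the naive "count green dots" approach fail:

1. **Bleed-through.** Follicle autofluorescence is broad-band: a fraction
   $\alpha$ of the red-channel signal also appears in the green channel.
   Uncorrected, every follicle looks like a cluster of green signal.
2. **Scale.** Thousands of follicles and tens of spots per mouse rule out
   manual counting; thresholds must be chosen by criteria that transfer
   across fields and acquisition sessions.

`mcscquant` implements the full chain — follicle detection, bleed estimation
and removal, spot detection, per-mouse aggregation, normalization and group
statistics — together with a synthetic image generator whose ground truth
makes every stage testable.

## Signal model and the synthetic generator

`generate_wholemount()` draws one field from an explicit generative model:

* **Red channel.** Constant background $b$ plus one radially decaying blob
  per follicle, $I(r) = p\,\max(0, 1 - (r/R)^2)$, with radius
  $R \sim U(12, 20)$ px and peak $p \sim U(500, 1000)$ at centres laid on a
  jittered hexagonal grid (minimum separation $2.5 R_\max$). Murine follicles
  are quasi-regular; the separation guarantees blobs never merge, which is
  what the real images show.
* **Green channel.** $b + \alpha \cdot \text{red}_\text{clean} + \text{spots}$,
  where each spot is an isotropic Gaussian of sd 2 px (a diffraction-blurred
  nucleus at ~1 µm/px) with peak $\sim U(800, 1200)$, and the per-field spot
  count is Poisson($n_\text{follicles} \times \text{rate}$) with uniform
  positions. Bleed is applied to the *noise-free* red channel because
  crosstalk is optical and precedes detector noise.
* **Noise.** Independent additive Gaussian noise (sd 10) on each channel,
  clipped at zero.

Defaults are 2048×2048 px at 1 µm/px with 320 follicles and
$\alpha = 0.30$; 20 fields per mouse reproduce the 6400-follicle per-mouse
quantification basis. Field size and signal-to-noise are the package's own
choices (chosen once so that follicle density matches the published field
geometry and a field quantifies in seconds on one CPU); rates, field counts
and follicles-per-field follow the study design. Every stochastic operation
takes an explicit seed and restores the caller's RNG state; identical
parameters and seed give bit-identical images — a hard invariant of the test
suite.

What the generator deliberately does **not** emulate: hair-shaft
autofluorescence streaks, spatially varying illumination, epidermal texture,
and depth structure (no z-stacks). Passing tests therefore demonstrate
correctness of the *computational* chain under the stated model, not
robustness to every artefact of real whole-mount acquisitions; on real data
the QC overlays (`write_qc_overlay()`) are the audit mechanism.

Section-style images (`generate_section_pair()`) paint DAPI and stain masks
with *exact* pixel areas (the stain region nested inside the DAPI region, or
disjoint cell-sized discs in cell mode), making area-ratio recovery an exact
identity in the noise-free case. `generate_coloc_pair()` places reference
spots and partner spots so the true colocalized fraction is exact by
construction.

## Detection choices

**Follicles** (`detect_follicles`): median background subtraction, Gaussian
smoothing at follicle scale (sd 4 px), Otsu threshold, binary opening
(radius 2 px) and 4-connected components with an area gate of
100–8000 px². Otsu is the default because it is parameter-free and the red
channel is strongly bimodal; a quantile or absolute threshold is a config
override. Components count when their centroid lies in the field — fields
tile a larger specimen, so this border policy is unbiased. A constant image
returns zero with a `low_contrast` flag instead of erroring, so batch runs
complete.

**Bleed coefficient** (`estimate_bleed`): over the dilated follicle
footprints (3 px dilation), green intensity is linear in red with slope
$\alpha$ and intercept equal to the green background. The slope is fitted
with Theil–Sen (median of pairwise slopes over a deterministic subsample of
at most 1500 mask pixels), so the occasional GFP spot inside the mask —
a gross outlier of the linear relation — cannot bias the fit. Least squares
is available via config. The corrected image is
$\max(\text{green} - \hat\alpha\,\text{red} - \hat c,\, 0)$.

**Spots** (`detect_mcsc_spots`): scale-normalised negative
Laplacian-of-Gaussian response maximised over scales $\sigma \in \{1.5, 2,
3\}$ px; 8-neighbourhood local maxima with positive response qualify when
their corrected intensity exceeds `median + 5 × scale`, where the robust
scale is the larger of the MAD and the upper-quantile spread
$(q_{0.975}-\text{median})/1.96$. The fallback matters: after unmixing,
about half the pixels are clipped at zero and the plain MAD collapses.
At the default 5-sigma criterion a 2048² field contributes on the order of
one false positive — the dominant (small, positive) bias of rate recovery.
Non-maximum suppression keeps the strongest maximum within 6 px
(2 × the largest scale); ties break lexicographically on (y, x), so
detection is fully deterministic. Two nuclei closer than the suppression
radius merge into one detection by design.

**Sections** (`area_ratio`, `count_cells`, `colocalization_fraction`):
per-channel Otsu (overridable), foreground pixel counts, and the ratio
positive-area / DAPI-area. An empty DAPI foreground is an *error*, not a
zero — the ratio is undefined and silent zeros would bias group means.
Colocalization is object-based (centroid proximity, default radius 3 px ≈
one nuclear radius) rather than pixel-overlap, because both signals are
nuclear and point-like; matching is one-to-many since duplicates are
removed upstream by non-maximum suppression. An empty reference set returns
fraction 0 with an `empty_reference` flag.

## Aggregation, normalization and statistics

`aggregate_mouse()` pools counts: rate = Σ spots / Σ follicles, which equals
the follicle-weighted mean of per-field rates (an asserted identity). The
unweighted per-field mean is a config alternative. Mice below 6000 pooled
follicles are flagged, matching the usual per-mouse quantification floor.

`normalize_migration()` implements the two normalization schemes of
littermate-paired designs: dividing by the animal's own Cox-2 expression
level (by default the Cox-2 immunofluorescence area ratio from matched
sections — the measured definition is not standardised, so any positive
per-mouse scalar is accepted) or by the matched control littermate's rate,
making the control exactly 1.

`compare_groups()` wraps the three tests used for such designs — two-sided
Welch t, paired t, Mann–Whitney U (exact for groups ≤ 8 without ties,
otherwise normal approximation with tie correction) — and reports group
means with SEMs. Degenerate inputs (zero variance of paired differences,
two constant groups) yield a `degenerate_variance` flag with NA statistic
rather than a fabricated p-value. No multiple-testing correction is applied
by default, matching the pairwise-comparison convention of these designs;
`p.adjust` can be applied downstream.

## Numerical and design notes

* Coordinates are 0-based, x = column, y = row, pixel centres at integers.
* Images are real-valued matrices internally; TIFF I/O rounds to 16-bit
  (page 0 = green/stain, page 1 = red/DAPI unless remapped), so a write/read
  round trip changes intensities by at most 0.5.
* Convolution uses mirrored boundaries; kernels truncate at 4 sigma.
* Connected components are 4-connected, and the suite cross-checks counts
  against an independent flood-fill oracle.
* A fitted bleed coefficient above 1 is physically impossible for crosstalk
  and raises `suspect_channel_order` — the typical signature of a swapped
  channel map.
* Manual ("by eye") curation of counts is deliberately out of scope;
  QC overlays let a human audit detections without editing them.

## Validation scales

The test suite validates at desk scale, chosen so the full run completes in
minutes on one CPU while every tolerance stays statistically meaningful:
exactness tests on noise-free 512² fields (counts and residuals are exact
identities there); bleed recovery within ±0.02 for α ∈ {0.1, 0.3, 0.5} over
20 noisy 512² fields each; migration-rate recovery within ±0.01 of
configured rates {0.02, 0.05, 0.1} on the mean of 10 replicate mice
(10 fields of 1024² px, 80 follicles per field — the default density);
Welch p-values against the closed form to 1e-10 and exact Mann–Whitney
against full enumeration for n ≤ 6; and type-I error 0.05 ± 0.02 over 2000
same-population replicates of the count-level Poisson model. The full-scale
geometry (one 2048² field with 320 follicles; a 20-field mouse with 6400
follicles) is exercised by the acceptance checks and by
`scripts/acceptance.R`.

## Known limitations

* Rate recovery carries a small positive bias (≈ +0.004 at 1024²-field
  density) from the ~5-sigma false-positive floor; raising `threshold_k`
  trades it against misses.
* The bleed model is a single global coefficient per field; spatially
  varying crosstalk would need a local fit.
* Dense melanocyte fields (rate ≫ 0.2) violate the separation assumptions
  of non-maximum suppression and will undercount merged nuclei.
* `run_pipeline()` drives simulated inputs; on-disk TIFF directories are
  quantified via `read_field()` + `quantify_dataset()`.
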
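# mcscquant

Quantification of UVB-induced melanocyte stem cell (McSC) epidermal
migration from two-channel fluorescence images of whole-mount mouse skin,
plus the section-based staining measures and group statistics that go with
such experiments.

After UVB exposure, McSCs migrate from the hair-follicle bulge into the
interfollicular epidermis. In whole-mount images, hair follicles
autofluoresce in the red channel and nuclear H2B-GFP labels migrated
melanocytes as point signals in the green channel — contaminated by a
fraction α of the red signal (bleed-through). The package measures, per
field and per mouse,

    migration rate = number of McSCs / number of hair follicles

via: follicle blob detection in red → robust estimation of α (Theil–Sen
over follicle pixels) → green-channel unmixing
`max(green − α·red − c, 0)` → Laplacian-of-Gaussian spot detection →
pooled per-mouse rates → normalization (per-mouse Cox-2 level, or matched
littermate control) → Welch t / paired t / Mann–Whitney comparisons with
SEM reporting.

Because no image data are public for this design, the package ships a
synthetic two-channel generator with complete ground truth (follicle
centres/radii, melanocyte coordinates, the true α) emulating the study
geometry — ~320 follicles per 2048×2048 field, 20–25 fields per mouse,
6400+ follicles per animal — so that every stage is verifiable: exact
counts on noise-free input, parameter recovery under noise, and
statistical calibration. Section-style stain/DAPI pairs (exact painted
areas) and two-channel spot patterns (exact colocalized fraction) cover
the sectioned-tissue measures.

## Worked example

```r
library(mcscquant)

# one synthetic field at the default whole-mount geometry
sim <- generate_wholemount(field_params(seed = 1))
q <- quantify_field(sim$field)
q$record
#>   field_id mouse_id n_follicles n_mcsc     alpha intercept flags
#> 1  field01  mouse01         320     20 0.2996648  100.0283

# a full mouse: 20 fields, pooled rate
ds  <- generate_mouse_dataset(field_params(), n_fields = 20, base_seed = 1)
rec <- quantify_dataset(ds)
aggregate_mouse(rec[, c("mouse_id", "n_follicles", "n_mcsc")])
#> MouseMigration [mouse01]: 331 McSCs / 6400 follicles = 0.0517 (20 fields)
```

All 320 follicles of the field are found; the bleed coefficient is
recovered to 0.2997 against a true 0.30; the pooled 20-field rate 0.0517
recovers the generator's true rate 0.05 (the small excess is the ~5σ
false-positive floor, about one spurious spot per 4-megapixel field). The
truth is available for direct comparison, e.g.
`nrow(sim$truth$mcsc_positions)` is 19 for this seed against 20 detections.

Group comparison on per-mouse rates:

```r
a <- simulate_migration_rates(5, rate = 0.05, seed = 101)
b <- simulate_migration_rates(5, rate = 0.15, seed = 102)
compare_groups(a, b, "welch_t")
#> GroupComparison (welch_t): statistic -42.56, p 8.436e-08;
#>   means 0.05053 vs 0.1503 (SEM 0.000851, 0.00218; n 5, 5)
```

Section measures: `area_ratio()` (positive-stain area over DAPI area),
`count_cells()` (cells per image), `colocalization_fraction()`
(object-based EdU–reporter colocalization). See the vignette
(`vignettes/quantification-methods.Rmd`) for the model, parameter
defaults, and validation scales; `scripts/mcscquant-cli.R` is a thin
command-line front end for simulation and end-to-end runs.

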
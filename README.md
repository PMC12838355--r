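# nucyto

Per-compartment quantification of single-cell confocal fluorescence, with a
synthetic phantom generator and cohort-level statistics.

## The problem

Markers of genomic instability and senescence — HMGB1, which translocates
from nucleus to cytoplasm under stress, and γH2AX, which accumulates at
nuclear DNA double-strand breaks — are read out by immunofluorescence on
sorted immune cells. Comparing donor groups (e.g. young vs elderly) needs a
quantitative, per-cell, per-compartment intensity measure from 3D confocal
z-stacks, plus the statistics to contrast cohorts.

`nucyto` implements that pipeline. A two-channel stack (nuclear stain +
marker) is reduced and quantified as:

1. **z-sum projection** — `P(y,x) = Σ_z V(z,y,x)` per channel, preserving
   total fluorophore content per pixel column;
2. **8-bit rescale** — linear stretch of `P` to `[0, 255]`;
3. **segmentation** — Otsu's global threshold, then the largest 8-connected
   object is the cell; Otsu on the DAPI pixels within the cell gives the
   nucleus (all components kept: lobed nuclei are non-contiguous), and
   cytoplasm = cell ∖ nucleus — an exact partition;
4. **metrics per compartment** of the marker image: the histogram
   `H(k) = #{(y,x) : I(y,x) = k}, k ∈ [1, 255]`; `N = Σ_k H(k)` (non-zero
   pixels); `S = Σ_k k·H(k)` (integrated intensity); `MFI = S / N` (the
   image-based analog of flow cytometry's mean fluorescence intensity); and
   the histogram's half-width at half-maximum (**HWHM**), a measure of
   fluorophore dispersion;
5. **statistics** — one-way ANOVA + Tukey HSD across conditions, or the
   two-sided Mann–Whitney U test for two-group contrasts, reported with the
   usual significance stars at α = 0.05.

Because such clinical images are rarely public, the package includes a
first-class synthetic generator: ellipsoidal (or slab-extruded, i.e.
compressed mounted) cells with round, kidney (monocyte) or multilobed
(granulocyte) nuclei, configurable nuclear:cytoplasmic marker ratio,
Gaussian/Poisson noise, Gaussian optical blur, and voxel-level ground-truth
masks — so segmentation and metrics are validated against known truth, and
whole cohort experiments (2 groups × 8 donors × 30 cells per cell type and
marker = 480 cells per panel) can be simulated end to end.

## Worked example

```r
library(nucyto)
library(dplyr)

# one synthetic granulocyte at analysis-scale sampling
acq <- acquisition_geometry(field_pixels = c(64, 64), n_slices = 9,
                            dx = 0.28, dz = 0.655)
g <- generate_cell_stack(cell_geometry(nucleus_shape = "multilobed"),
                         intensity_model(), acq, seed = 42)
g$stack
#> <image_stack> 64 x 64 x 9, channels: dapi, marker

quantify_cell(g$stack, cell_id = "demo") %>%
  select(cell_id, cell_px, nuclear_n, nuclear_mfi, nuclear_hwhm,
         cyto_n, cyto_mfi, cyto_hwhm)
#>   cell_id cell_px nuclear_n nuclear_mfi nuclear_hwhm cyto_n cyto_mfi cyto_hwhm
#> 1    demo    1447       347       245.9        1.951   1100      123     2.132
```

The cell mask found 1447 pixels; the marker's mean pixel intensity (MFI) is
245.9 in the nucleus versus 123.0 in the cytoplasm — recovering the 2×
nuclear enrichment of the default intensity model — and the narrow HWHM
values (≈2 intensity units) say each compartment is internally homogeneous.

A cohort run contrasts two donor groups. With identical generator
parameters in both groups (a true null), the junior/senior report is
non-significant; planting a 2× cytoplasmic translocation of HMGB1 in the
senior group is detected exactly where planted:

```r
run_replication(replication_config(
  seed = 1, design = cohort_design(n_donors_per_group = 2,
                                   cells_per_donor = 10, seed = 1)))$report
#>   marker compartment n1 n2 median1 median2 p.value stars
#> 1  HMGB1 cytoplasmic 20 20   123.1   123.1  0.9680    ns
#> 2  HMGB1     nuclear 20 20   245.7   245.5  0.9467    ns

run_replication(replication_config(
  seed = 1,
  design = cohort_design(n_donors_per_group = 2, cells_per_donor = 10,
                         markers = c("HMGB1", "gH2AX"), seed = 1),
  planted_effect = list(marker = "HMGB1", factor = 2)))$report
#>   marker compartment median1 median2   p.value stars
#> 1  HMGB1 cytoplasmic   123.1   245.3 1.451e-11  ****
#> 2  HMGB1     nuclear   245.6   250.0 1.451e-11  ****
#> 3  gH2AX cytoplasmic   123.1   123.0 6.980e-01    ns
#> 4  gH2AX     nuclear   245.6   245.7 4.450e-01    ns
```

(The planted marker's *nuclear* stratum also shifts: z-sum columns through
the nucleus traverse cytoplasm above and below it, so cytoplasmic signal
leaks into nuclear 2D metrics — an inherent property of sum-projection,
discussed in the vignette.)

`compare_groups()` gives broom-style `tidy()`/`glance()` access and
`autoplot()` figures for any single contrast; `write_stack()`/
`read_stack()` handle multi-page TIFF IO; `make_fixtures()` writes a small
ground-truthed test corpus. A thin CLI wraps the same functions:

```sh
Rscript inst/cli/nucyto replicate --seed 7 --out out/
Rscript inst/cli/nucyto quantify --in stacks/ --labels stacks/labels.csv --out records.csv
```

## Package layout

- `R/` — phantom generator (`generate_cell_stack()`, `cohort_design()`),
  projection/segmentation primitives (`sum_project()`, `rescale_8bit()`,
  `otsu_threshold()`, `largest_component()`, `nucleus_mask()`,
  `compartments()`), metrics (`intensity_histogram()`, `hwhm()`,
  `compartment_metrics()`, `quantify_cell()`, `quantify_cohort()`),
  statistics (`compare_groups()`, `compartment_report()`) and the
  replication harness (`run_replication()`, `make_fixtures()`).
- `vignettes/quantification-methods.Rmd` — the methods vignette: model
  assumptions, parameter choices, numerical conventions, limitations.
- `tests/testthat/` — unit, property and end-to-end validation suites with
  independent brute-force oracles.
- `inst/cli/nucyto` — command-line wrapper
  (`simulate | quantify | compare | replicate | fixtures`).
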
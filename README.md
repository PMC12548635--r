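# ctspacing

Slice-spacing audit and measurement validation for single-frame DICOM CT
series.

## The problem

The through-plane geometry of a CT volume is governed by the **slice
spacing** — the distance between the centers of consecutive slices — not by
whatever the metadata tags claim. In archival scan collections a series is
sometimes secretly split into many small acquisition blocks ("sub-volumes")
with one gap inside a block and a different gap between blocks. A volume
importer confronted with such a stack *regularizes* it: it assigns the
uniform spacing that preserves total extent,

    ŝ = (z_last − z_first) / (n − 1)

which for V sub-volumes of m slices (within-gap w, between-gap b) equals

    ŝ = (V(m−1)w + (V−1)b) / (Vm − 1).

For the canonical case of V = 51, m = 6, w = 0.60 mm, b = 0.50 mm that is
178/305 = **0.58360656 mm**, not the 0.60 mm the metadata claims. Every
distance measured along the slice axis scales with the assigned spacing, so
the wrong choice biases anterior–posterior measurements by
s_wrong/s_true − 1 ≈ 2.8% — millimetres on a cranium, and inconsistently
across a collection where only some specimens are affected.

`ctspacing` provides, for anatomists, morphometricians and imaging-core
staff working with repository CT data:

- **Geometry reconstruction** (`load_series()`, `write_series()`): ordered
  slice stacks from single-frame DICOM files, sorted along the slice
  normal.
- **Spacing audit** (`profile_gaps()`, `detect_subvolumes()`,
  `regularized_spacing()`, `audit()`): gap clustering, sub-volume recovery,
  the regularized spacing, and reconciliation against the metadata claim.
- **Bias model** (`distance_under_spacing()`, `rescale_distance()`,
  `relative_bias()`): the landmark-distance error a misassigned spacing
  induces, parameterized by the axial fraction of the measurement.
- **Validation statistics** (`paired_t()`, `prediction_interval()`,
  `inclusion_audit()`, `run_validation()`): paired t-tests with Bonferroni
  adjustment, 99% prediction intervals for a single future observation, and
  inclusion audits of one-shot digitizer measurements — the machinery for
  deciding which spacing faithfully represents the physical specimen.
- **Synthetic generators** (`make_series()`, `make_measurement_table()`):
  phantom series with injected sub-volume structure and measurement tables
  with the study's statistical design, so everything is testable offline.
- **A CLI** (`inst/cli/ctspacing.R`): `audit`, `correct`,
  `simulate-series`, `simulate-measurements`, `validate`, with triage exit
  codes (0 clean / 2 flagged / 1 read errors).

## Worked example

Write the canonical inconsistent series to disk, re-load it, and audit:

```r
library(ctspacing)

spec <- w584_series_spec()           # V = 51, m = 6, w = 0.60, b = 0.50
dir <- file.path(tempdir(), "W584")
write_series(spec, dir)
geom <- load_series(dir)
geom
#> <series_geometry> W584: 306 slices, extent 178 mm, stated spacing 0.6 mm
#>   gaps (rounded to 1e-3): 0.5 mm x50, 0.6 mm x255

audit(geom)
#> <audit_result> W584: INCONSISTENT
#>   slices: 306, sub-volumes: 51
#>   stated spacing:      0.6 mm
#>   regularized spacing: 0.58360656 mm
#>   metadata match: FALSE (relative discrepancy -0.0273)
```

The series claims 0.60 mm but its 305 gaps split into 255 × 0.60 mm and
50 × 0.50 mm; the importer's regularized spacing is 0.58360656 mm, a −2.7%
discrepancy against the metadata. What does measuring under the wrong value
do to a cranial length? Re-reading a 173.3 mm axial distance under 0.60 mm
instead:

```r
rescale_distance(173.3, axial_fraction = 1,
                 spacing_old = 0.58360656, spacing_new = 0.60)
#> [1] 178.168
```

178.2 mm at 0.1 mm rounding — 4.9 mm (2.83%) of pure geometry error.

The validation side: simulate the repeated-measurement design (three
specimen groups, one misassigned CT modality in each of groups 2 and 3)
and run the full pipeline:

```r
tab <- make_measurement_table(synthetic_measurement_spec(seed = 1))
run <- run_validation(tab, m = 40)
subset(run$comparisons, group == "G3",
       c(specimen_id, modality_1, modality_2, statistic, p_adj, significance))[1:3, ]
#>    specimen_id modality_1 modality_2 statistic        p_adj significance
#> 26      SYN016    CT_0.58    CT_0.60 -22.49693 1.283813e-07         ****
#> 27      SYN016    CT_0.58   Original   1.08972 1.000000e+00           ns
#> 28      SYN016    CT_0.60   Original  27.47915 2.171946e-08         ****
```

In group 3 (true spacing 0.58360656 mm) the CT model read under the
*correct* spacing is statistically indistinguishable from the calipers
(`ns`), while the misassigned 0.60 mm model differs overwhelmingly — the
signature that identifies the true spacing of each scan group.

The package also ships the published per-specimen prediction intervals as
a plain-text fixture; `audit_printed_intervals()` re-runs the inclusion
audit on them and reproduces every published verdict, including 17/20
caliper-interval inclusions.

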
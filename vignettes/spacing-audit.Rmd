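---
title: "Auditing CT slice spacing and validating measurements against physical specimens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing CT slice spacing and validating measurements against physical specimens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctspacing)
```

## The problem

A single-frame DICOM CT series encodes its through-plane geometry
implicitly: each slice file carries a patient-space origin, and the volume
is reconstructed by sorting slices along the normal to their shared image
plane. The metadata *claims* a slice spacing (the Spacing Between Slices or
Slice Thickness tag), but nothing forces the actual inter-slice gaps to
match it. In archival collections a particularly insidious failure mode
appears: the scanner or the DICOM conversion splits a scan into many small
acquisition blocks ("sub-volumes") with one gap *within* a block and a
different gap *between* blocks. The stack is then not uniform at all, and a
volume importer has to choose: refuse the series, or *regularize* it —
assign the uniform spacing that preserves total extent,

$$\hat s \;=\; \frac{z_{\text{last}} - z_{\text{first}}}{n - 1},$$

the mean gap. For a series of $V$ sub-volumes of $m$ slices, with
within-gap $w$ and between-gap $b$,

$$\hat s \;=\; \frac{V(m-1)\,w + (V-1)\,b}{Vm - 1}.$$

With $V = 51$, $m = 6$, $w = 0.60$ mm, $b = 0.50$ mm this gives
$178/305 = 0.58360656$ mm — noticeably smaller than the claimed 0.60 mm.
Every distance measured along the slice axis scales with the assigned
spacing, so choosing the wrong value biases anterior–posterior measurements
by $s_{\text{wrong}}/s_{\text{true}} - 1 \approx 2.8\%$ — several
millimetres on a cranium. In collections where only a subset of specimens
is affected, such a bias is inconsistent across the sample and poisons any
downstream quantitative analysis.

This package implements the audit that detects the condition, the
regularization arithmetic, the bias model that predicts its measurement
consequences, and the repeated-measures statistics used to decide — from
physical-specimen measurements — which spacing is the true one.

## Series geometry and the audit

`load_series()` reduces a directory of slice files to a `series_geometry`:
slices sorted by the scalar projection of their origin onto the slice
normal (the cross product of the first slice's in-plane direction cosines),
ties broken by instance number. Ordering is geometric rather than by
instance number because the spacing problem *is* geometric: instance
numbers survive arbitrary renumbering, positions do not lie.

The audit proper has three steps:

1. **Gap profiling** (`profile_gaps()`). The $n-1$ consecutive gaps are
   clustered with an absolute tolerance of $10^{-3}$ mm (sorted gaps are
   split where neighbours differ by more). The tolerance sits three orders
   of magnitude below the 0.1 mm scale of real sub-volume discrepancies
   and comfortably above the $\sim 10^{-9}$ mm noise that decimal-string
   round-tripping of positions introduces.
2. **Sub-volume recovery** (`detect_subvolumes()`). When the
   acquisition-number tag varies it is authoritative: runs are maximal
   blocks of constant acquisition number. Without tags, runs are maximal
   stretches whose gaps stay in the dominant cluster. The tag-free route
   recovers the structure whenever $|w - b|$ exceeds the gap tolerance;
   the audit makes no assumption about which of $w, b$ is larger.
3. **Verdict** (`audit()`). A series is `INCONSISTENT` as soon as the
   profile holds more than one cluster — a single deviant gap flags it,
   because that is exactly when a real importer interrupts the user, and a
   QC tool should not be more forgiving than the importer it emulates. The
   regularized spacing is always computed, and compared with the metadata
   claim at a default relative tolerance of 0.5%: scanner rounding is far
   below that, a genuine sub-volume mix-up (≈2.7% here) far above. The
   audit never consults the collection's reference table
   (`expected_group()`), so the geometric evidence and the archival
   expectation remain independent lines of evidence that can be compared.

Correction (`regularize_geometry()`, `cmd_correct()`) is metadata-level
only: offsets are replaced by the arithmetic sequence with step $\hat s$,
pixel data are never resampled. That mirrors what importers actually do,
and it is idempotent.

## The bias model

A landmark distance measured on a voxel grid under assigned spacing
$s_a$ relates to the same distance under reference spacing $s_t$ through
the **axial fraction** $f$, the share of the squared distance lying along
the slice axis:

$$d_{a} \;=\; d_{t}\,\sqrt{(1 - f) + f\,(s_a/s_t)^2}.$$

With $f = 1$ this is the pure ratio $d_t \, s_a/s_t$; with $f = 0$ the
distance is immune to the spacing. Cranial-length measurements on
coronally acquired stacks are nearly axial, so the headline prediction
uses $f = 1$ by default while the formula stays general. The worked
example: a 173.3 mm axial distance re-read under 0.60 mm instead of the
regularized 0.58360656 mm becomes

```{r}
rescale_distance(173.3, axial_fraction = 1,
                 spacing_old = 0.58360656, spacing_new = 0.60)
```

i.e. 178.2 mm at 0.1 mm rounding — a 4.9 mm inflation, 2.83% of the
measurement (the quoted percentage is the ratio of the two *rounded*
distances, $178.2/173.3 - 1$; the unrounded axial-limit bias is
$0.60/0.58360656 - 1 = 2.81\%$ — both are reported side by side by
`relative_bias()` and the worked example, since at 0.1 mm print precision
they are the same statement).

## Validation statistics

Deciding which spacing is *true* requires an external anchor: repeated
measurements of the same landmark distance on the physical specimen. The
pipeline (`run_validation()`) takes a long-format table of replicates per
specimen × modality (calipers, CT models under each candidate spacing, and
a one-shot articulated-arm digitizer) and runs:

- **Paired t-tests** between every within-specimen pair of repeated
  modalities, replicates paired by index. The published comparison tables
  report paired statistics even though the replicates have no stated
  physical pairing; this implementation follows the computed artifact and
  documents the choice. Identical samples raise a degenerate-pairing
  error that is caught and recorded per comparison; a zero-variance,
  nonzero-mean difference reports a signed infinite statistic with
  $p = 0$.
- **Bonferroni adjustment** over the comparison family. The published
  tables do not name their adjustment method, but Bonferroni with
  $m = 40$ (the study's 10 + 15 + 15 comparisons) reproduces every
  printed p/p.adj pair (0.002→0.08, 0.018→0.72, 0.005→0.20), so that is
  the default; $m$ is configurable and defaults to the number of
  comparisons actually run.
- **99% prediction intervals** for a single future observation,
  $\bar x \pm t_{0.995,\,n-1}\, s \sqrt{1 + 1/n}$ — the interval from an
  intercept-only normal fit, wider than the mean's confidence interval by
  $\sqrt{1+1/n}$. This is the right container for the digitizer probe,
  which is a *single* new measurement, not a mean.
- **Inclusion audits**: closed-interval membership of the probe, with a
  signed exceedance (positive above the upper limit, negative below the
  lower) that is zero when included. Closed membership makes the boundary
  decision deterministic and errs toward agreement.

The logic of the design: on specimens whose spacing is correctly assigned,
CT-derived distances agree with calipers (non-significant paired tests)
and contain the digitizer probe; under a misassigned spacing the CT
distances shift by the bias-model prediction — two to four millimetres at
cranial scale, an order of magnitude beyond measurement noise — and every
test flags it.

## The synthetic generators

`make_series()` realizes a `synthetic_series_spec` exactly: offsets follow
the $V/m/w/b$ pattern, acquisition numbers increment per block, and the
stated-spacing tags carry whatever the spec claims, so metadata mismatches
are injected deliberately. The optional phantom is a bright ellipsoid plus
two single-voxel fiducials at known physical positions, which lets an
end-to-end test write a series to disk, re-load it, detect the fiducials,
and check that measuring under the true spacing recovers ground truth
within half a voxel diagonal while the stated (wrong) spacing reproduces
the bias prediction. The phantom is geometric only — no noise texture,
partial-volume or beam-hardening physics — so passing tests certify the
geometry pipeline, not robustness to real CT image quality.

`make_measurement_table()` emulates the validation study's design: three
groups of 10/5/5 specimens with true spacings 0.75, 0.60 and
0.58360656 mm, the latter two each carrying a correctly-assigned and a
misassigned CT modality; 10 replicates per repeated modality; true
distances drawn uniformly on 110–155 mm (spanning the published
per-specimen means of 113–153 mm); a fully axial measurement ($f = 1$).
The noise model is Gaussian and additive — caliper sd 0.4 mm, CT sd
0.3 mm, digitizer sd 0.3 mm with a +0.5 mm systematic offset. The source
study publishes no variance components, so these are this package's
modelling choices, made once: they reproduce the published
prediction-interval widths (≈1–3 mm) and the observation that the
digitizer tends to read slightly high, and they are all configurable
fields of the spec. A master seed drives per-specimen substreams derived
deterministically from the specimen index, so enlarging a later group
never perturbs earlier specimens.

What the generator does *not* emulate: inter-observer effects, distance
heteroscedasticity, non-Gaussian error tails, or any correlation between
replicates. Conclusions from synthetic runs therefore speak to the
pipeline's correctness under its stated model, not to the error structure
of any particular instrument.

## Numerical and reporting choices

- Regularized spacing is reported to 8 decimal places, matching importer
  display precision; distances to 0.1 mm and percentages to 2 decimals in
  reports.
- Gap equality: $10^{-3}$ mm absolute. Metadata agreement: 0.5% relative.
  Both are package choices — importers do not document their exact
  thresholds — and both are exposed as arguments.
- Dominant-gap ties break toward the smaller value, so batch reports are
  deterministic.
- DICOM decimal-string tags are written with 10 significant digits
  (within the format's 16-byte limit); geometry round-trips to
  $\sim 10^{-9}$ mm.
- Degenerate inputs: fewer than two slices is an error; a zero-variance
  sample collapses its prediction interval to a point with a warning
  flag; a missing digitizer value excludes that specimen from the
  inclusion audit with a warning, never an abort.

## Problem sizes used by the test suite

The suite generates everything it needs at run time: the canonical 51×6
series (306 slices), batches of a handful of written series for the CLI
triage tests, 100 random sub-volume specs for the estimator properties,
10,000 simulations for the prediction-interval coverage check, and
measurement tables at the study's 20-specimen design. The full-collection
triage count (182 of 985 flagged, 18.5%) is computed from the reference
table directly, which is exact at any scale. These sizes are the package's
own choice of a thorough-but-quick regime; every generator scales up by
changing spec fields.

## Reproducing the published tables

The inclusion audit over the *printed* prediction intervals ships with the
package (`audit_printed_intervals()`): it reproduces every published
TRUE/FALSE verdict, the 17/20 caliper inclusions, and the exceedance
ranges. Recomputing the t statistics and the interval limits themselves
requires the study's raw replicate table, which is supplementary data not
redistributable here; `reproduce_supplementary()` runs the full pipeline
on a user-supplied copy (long-format CSV: `specimen_id`, `group`,
`modality`, `replicate`, `distance_mm`).

## Known limitations

- Single-frame, uncompressed, Explicit-VR-little-endian DICOM only; no
  multi-frame objects, compressed transfer syntaxes, or gantry-tilt
  geometry. Non-parallel slices are an error, not a rescue case.
- The audit assumes gaps are strictly positive after sorting (duplicate
  slice positions are rejected rather than de-duplicated).
- The sub-volume detector's tag-free route cannot separate blocks whose
  between-gap differs from the within-gap by less than the gap tolerance
  — by construction, since such a series is geometrically uniform at the
  tolerance.
- The bias model treats the grid as rigid; it does not model partial
  volume effects near landmarks, which is why the end-to-end phantom test
  budgets half a voxel diagonal.
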
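---
title: "Dose/volume-point extraction and cohort statistics for plan review"
author: "dvhpoints"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dose/volume-point extraction and cohort statistics for plan review}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dvhpoints)
```

## The problem

Dosimetry compliance review in radiotherapy clinical trials checks whether a
submitted treatment plan's dose--volume histogram (DVH) meets the dose/volume
limits a protocol states: typically more than ten points per case (the dose
covering 95% of the target, the lung volume receiving at least 20 Gy, the
spinal-cord near-maximum, and so on), across cohorts of a hundred or more
enrolled patients. Reading these values off a DVH viewer and typing them into
a spreadsheet is slow and error-prone. `dvhpoints` automates the loop: it
parses a plain-text review request written in a compact expression syntax,
evaluates every requested point against each case's exported cumulative DVH,
and tabulates values plus cohort quantile statistics into per-structure and
overview spreadsheet reports.

## The data model

A **cumulative DVH** for a structure is the function $V(d)$: the absolute
volume (cc) receiving at least dose $d$ (Gy). A planning-system export holds
one case per CSV file: the patient/site ID in cell A1, an optional
case-specific prescription dose in cell C1 (`"Rx = 60 Gy"` or just `"60"`),
an optional per-case global maximum dose in cell D1 (`"Dmax = 80 Gy"` or
`"80"`), structure names in row 2, and from row 3 a shared dose column
followed by one absolute-volume column per structure. `readDVH()` maps this
onto the S4 classes `DVHCase` and `StructureDVH`, validating that the dose
grid is strictly increasing and every cumulative-volume column is
non-increasing and non-negative.

Only cumulative DVHs are supported; differential exports are out of scope.
The dose column is taken as Gy (cGy exports are not auto-detected -- a
documented limitation), values use `.` as the decimal separator regardless of
locale, and a UTF-8 byte-order mark is tolerated.

## The expression syntax

A dose/volume point is written as

```
expr   := base suffix?
base   := ('D' | 'V') '(' unit ')' number '(' unit ')' | 'Dmax' | 'Dmin' | 'Dmean'
suffix := '/Rx' (('x'|'X'|'*'|'×') '100')?
```

`D(Gy)40(cc)` is the dose covering 40 cc; `V(%)20(Gy)` the percent of the
structure receiving at least 20 Gy. `D` outputs Gy or % and takes a cc or %
argument; `V` outputs cc or % and takes a Gy or % argument -- exactly eight
D/V unit pairings plus the three named metrics. `Dmax` and `Dmin` are the
RTOG near-extremes read 0.03 cc from the hot and cold ends of the curve
(`Dmax` is by definition `D(Gy)0.03(cc)`, and the package keeps that identity
bitwise). The `/Rx` suffix divides an absolute-dose result by the
prescription dose; with `x 100` the ratio becomes a percent.

Design choices where the syntax left room:

* **`/Rx` scope.** It is accepted after any metric whose value is an absolute
  dose (`D(Gy)...`, `Dmax`, `Dmin`, `Dmean`) and rejected after volumes and
  percent doses -- the minimal consistent generalization of the documented
  `Dmean/Rx`, and a guard against double normalization.
* **Strict case.** `Gy`, `cc`, `%`, `Rx` and the metric names are
  case-sensitive; a lenient mode is deliberately not provided, keeping the
  DSL unambiguous for audit trails.
* **Multiplication sign.** The canonical form prints `×`, but `x`, `X` and
  `*` are accepted so request files can stay ASCII.
* **Numbers** are positive plain decimals; scientific notation is not part of
  the syntax.

Parse errors are classed conditions carrying the 1-based character position;
`validateRequestSyntax()` collects failures over a whole request instead of
stopping at the first.

## Evaluation semantics

The exported curve is treated as exactly piecewise linear, so linear
interpolation is used in both query directions with no smoothing:

* `volumeAtDose(s, d)`: interpolate $V$ at $d$; below the grid start return
  the total volume, beyond the end the last tabulated value.
* `doseAtVolume(s, v)`: the *largest* dose whose covered volume is still
  $\ge v$ (supremum convention). On a flat segment this returns the
  segment's far end, matching "dose that covers" semantics and keeping the
  RTOG extremes well defined near the tail.
* `meanDose(s)`: the trapezoidal integral of $V$ over the grid divided by the
  total volume -- exact under the piecewise-linear assumption and equal to
  the mean of the implied differential DVH; the differential route is never
  taken. (The integral runs over the exported grid; grids that start above
  0 Gy would ignore the plateau below the first point, a convention noted
  here because every generated grid starts at 0.)

Degenerate and boundary inputs are handled as data, not crashes: a volume
query above the total volume yields 0 Gy flagged `out_of_range`; a curve
whose last volume is positive (truncated export) is treated as dropping to
zero immediately after the last grid dose and queries reaching that tail are
flagged `structure_truncated`; structures smaller than 0.03 cc refuse the
RTOG metrics with a degenerate-structure error.

Percent conversions use a **reference dose**: either the prescription dose
(global run setting, overridden by a case-specific C1 value) or the per-case
maximum dose from D1 -- plans do not share one global maximum, so mode
`"maximum"` requires D1 per case. `/Rx` always divides by the prescription
dose even under maximum mode; the reference mode governs percent units only.

## Batch runs and reports

`runBatch()` iterates cases, request rows, and points in input order,
resolving the reference once per case. Every (case, structure, expression)
triple becomes exactly one cell; failures are recorded in the cell
(`structure_missing`, or `evaluation_error` with the message) and never abort
the batch -- a QA run must complete and report everything it could compute.
Structure matching is exact after whitespace trimming, with a case-insensitive
fallback that raises a naming-deviation warning, since protocols expect
standard structure names.

`buildReport()` lays out one sheet per requested structure plus an overview
sheet, each in three regions: the echoed request, the value block, and a
statistics block holding per column the count of contributing cases and the
1, 2, 5, 10, 15, 85, 90, 95, 98, 99% quantiles. The quantile is the
order-statistic rule with linear interpolation, $h = (n-1)p/100 + 1$ on
1-based sorted ranks -- stated as a formula so any implementation reproduces
it exactly (it coincides with R's type-7 default, which the tests use as an
independent cross-check). Cases missing a value are excluded from the
statistics and the count column says so; imputation would fabricate plan
quality.

`writeReport()` emits RFC 4180 CSV, one file per sheet with sanitized names,
values rendered with 2 decimals (a full-precision sidecar is available off
by default), LF line endings and UTF-8 -- regeneration from the same result
table is byte-identical, which matters for diffable audit trails. Each value
column is followed by a `note` column carrying the absence reason or quality
flags. A single-workbook xlsx writer is not implemented in this package; CSV
is the supported audit format.

## The synthetic generator

Because clinical DVHs cannot ship with the package, every test runs on
synthetic cases with known ground truth. Three curve families cover the
shapes that matter:

* `uniform(d0)`: a flat curve dropping over one grid interval -- an ideally
  covered target;
* `linear(D0)`: $V(d) = V_0(1 - d/D_0)_+$ -- closed forms for every metric;
* `sigmoid(d50, slope)`: a logistic fall-off -- a realistic organ-at-risk
  curve that is *not* exactly representable on the grid.

The default grid is 0.1 Gy steps up to 1.2 times the largest characteristic
dose. Uniform/linear dose parameters are snapped to the grid so their truth
maps are exact closed forms of the discretized curve (tested at 1e-6
relative); sigmoid truths come from a dense (step/100) numeric oracle that
applies the same supremum/truncation conventions but shares no code with the
evaluator, and are tested at 1e-3 relative with a 0.01 Gy absolute floor --
inverting the near-flat top of a logistic is dose-resolution limited, so a
purely relative bound is not meaningful for truths of order 0.001 Gy.

`generateCohort()` jitters each structure's volume and characteristic dose by
independent lognormal factors $e^{N(0,\sigma)}$ (default $\sigma = 0.1$,
about 10% case-to-case spread -- a realistic cohort variation), keeping all
quantities positive with the base value as the cohort median; a seed is a
mandatory argument, there is no hidden global randomness. The built-in
`exampleSpec()`/`exampleRequest()` pair emulates a thoracic trial review:
6 structures, 14 points, a 60 Gy prescription.

What passing these tests does *not* show: real exports have scatter from dose
recalculation, coarser or non-uniform grids, cGy units, and naming drift
across institutions. The generator covers the geometric behaviour of the
query primitives, not planning-system idiosyncrasies beyond the documented
CSV dialect.

## Problem sizes and numerical choices

The test suite and the acceptance script use cohorts of 20 cases (the scale
of a typical per-trial rehearsal), 50--100 random piecewise-linear structures
for the oracle and identity properties, and a 1e5-point dense resample for
the brute-force oracle; the dense grid additionally includes the original
kink doses, making the oracle exact for piecewise-linear curves instead of
resolution-limited. All interpolation-based comparisons on exactly
representable curves are asserted at 1e-9 relative or tighter; round trips
through CSV formatting at 1e-6 relative (15 significant digits are written).
Ties in `doseAtVolume` are broken by the supremum rule; `v = 0` maps to the
last grid dose and `v` equal to the total volume to the start of the curve's
strictly decreasing part.

## Limitations

* No DICOM-RT parsing and no DVH computation from dose grids: the CSV export
  is the interface.
* No arithmetic between points (sums, conformity indices), no gEUD/NTCP/TCP
  models.
* Protocol pass/fail adjudication is out of scope: the tool extracts and
  tabulates; the reviewer judges against the protocol text.
* Per-arm analyses are run as separate invocations with per-arm request
  files; there is no arm logic inside the tool.
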
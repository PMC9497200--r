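---
title: "Enumerating CTCs and tdEVs in cartridge images: models, gates and validation"
author: "ctcscope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Enumerating CTCs and tdEVs in cartridge images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctcscope)
```

## The measurement problem

Circulating tumor cells (CTCs) and large tumor-derived extracellular
vesicles (tdEVs) are enumerated from blood after EpCAM-based immunomagnetic
enrichment: the enriched, fluorescently stained cell fraction sits in a
cartridge that a semi-automated microscope scans as a series of frames
(175 on the production instrument), each acquired through four filter
cubes — DAPI (DNA), PE (cytokeratin, CK), APC (CD45) and FITC (a free
marker position). A CTC is an object with a nucleus, cytokeratin and no
CD45; a tdEV is a CK-positive particle of 1–12 µm with no nucleus and no
CD45. Counting is done by segmenting *every* fluorescent object
("full detection"), measuring a fixed panel of intensity and shape
features per object, and applying linear gates — conjunctions of one-sided
thresholds — to the feature vectors. Gated CTCs are further sorted into
six morphological subclasses (clusters; intact "pretty" cells;
heterogeneous CK; cleaved CK; fragmented DNA/CK; cleaved CK with
fragmented DNA), which carry biological signal of their own: cluster and
heterogeneous-CK counts differ between castration-naive (CNPC) and
castration-resistant (CRPC) disease stages.

`ctcscope` implements this pipeline end to end, together with a synthetic
cartridge generator whose planted ground truth makes every stage testable,
and the cohort-level statistical battery used to compare patient groups.

## Data model

A `CartridgeStack` holds co-registered frames as `H × W × 4` arrays in the
12-bit intensity range (0–4095 AU) with a pixel pitch in µm (default
0.64 µm/px; the instrument's optics fix the magnification but not a
published pixel pitch, so the value is configuration, never hard-coded in
the mathematics). Detection yields per-event channel masks; morphometry
reduces them to a feature row per event; `GateSet` objects apply the
enumeration gates; the cohort layer consumes per-patient count tables.

Table-style gates address five logical channels while the instrument
acquires four layers. The mapping is CK ← PE, CD45 ← APC, marker 2 ← FITC;
marker 1 is a virtual constant-zero channel, so its exclusion predicates
(`mean ≤ 5 AU`) pass vacuously unless a fifth physical channel is supplied.
This mirrors the ambiguity that the acquisition names only four layers
while the printed gate table lists both "CK" and a PE-conjugated
"marker 1"; the virtual channel keeps the printed predicate count without
inventing data.

## Segmentation and merging

Each channel of each frame is thresholded adaptively — a triangle
threshold on the intensity histogram (a geometric criterion suited to
sparse bright objects over a dark background; Otsu is available as an
option), floored at `background + 3·noise SD` estimated by median and
MAD — and connected components below 4 px are discarded. Components from
different channels are merged transitively into *events* when they overlap
or touch within a 1-px dilation: a component dilated by *r* touches a
neighbor across an *r*-pixel background gap, i.e. at Chebyshev distance
`r + 1`. This is what joins a DAPI nucleus to its surrounding CK ring even
when thresholding leaves a one-pixel moat. CD45 and FITC components never
seed an event of their own — they only contribute measurements — because
the gates use them purely as exclusion channels; CK and DAPI both seed by
default (configurable).

## Morphometry conventions

All conventions are fixed and shared between the measured and the
analytic (render-free) feature paths:

* **area / size** — mask pixel count × pixel size² (µm²); "size" is an
  alias of area, and both predicates of the printed gate table are applied
  as printed.
* **perimeter** — count of mask boundary pixels (a mask pixel with at
  least one 4-neighbour outside the mask), in pixels; the printed
  perimeter threshold is stated in pixels, implying a pixel-count
  convention rather than a Crofton-style length estimate.
* **eccentricity** — from the central second moments of the mask
  (0 = circle).
* **overlay** — |CK ∩ DAPI| / |CK|: the fraction of the CK footprint
  covered by nucleus. The denominator is configurable
  (`ck`, `dapi`, `union`); `ck` is the default.
* **intensities** — mean/max over the channel's own mask,
  background-inclusive (no background subtraction), because the absolute
  `≤ 5 AU` exclusion thresholds only make sense against a known flat
  background (default 2 AU). Marker channels are measured over the whole
  event footprint.
* empty masks give 0 for every feature plus an emptiness flag; strict `>`
  predicates on a flagged-empty channel therefore fail, inclusive `≤`
  predicates pass.

## The gates

`defaultGateSet()` encodes the shipped enumeration gates bit-exactly
(also available as YAML under `inst/extdata/gates/table1.yaml`): the CTC
gate has 8 predicates (CD45-negative, DAPI-positive, CK-positive, CK size
in (16, 400] µm², CK–DAPI overlay > 0.2, both markers negative), the tdEV
gate 11 (DAPI-negative instead of positive, CK mean > 60 and max > 90 AU,
area/size ≤ 150 µm², eccentricity ≤ 0.8, perimeter > 5 px,
perimeter-to-area ≤ 1). `>` is strict and `≤` inclusive, exactly as
printed. The two default gates are mutually exclusive (DAPI mean cannot be
both > 45 and ≤ 5); for custom gate sets the CTC gate is applied first, a
fixed order chosen for stable semantics. Review is an annotation layer
(CSV of object id and label), not a GUI: excluded artifacts reduce the
corrected CTC count only, since review in practice corrects CTC calls and
leaves tdEV counts untouched.

## Subclassification

Human reviewers assign the six subclasses by eye; the package
operationalizes their verbal criteria with measurable evidence and
explicit thresholds, all surfaced in `subclassParams()`:

| evidence | meaning | default threshold |
|---|---|---|
| `nuclei_in_ck` | intact DAPI components (area ≥ 20 µm²) with centroid inside CK | — |
| `ck_cv` | SD/mean of CK intensities in the CK mask | 0.25 |
| `shape_irregularity` | 1 − solidity of the CK mask | 0.15 |
| `speckle_flag` | ≥ 3 CK components, each ≤ 16 µm² and eccentricity ≤ 0.8 | — |
| `dna_fragment_count` | all DAPI components of the event | — |

The first-match cascade — clusters, then cleaved + fragmented, cleaved,
fragmented, heterogeneous, pretty — is part of the contract: permuting the
apoptotic rules changes labels on events that carry both speckling and
fragmentation evidence. The minimum-nucleus-area criterion is a deliberate
addition: without a size floor, a nucleus broken into two pieces whose
centroids both lie in CK is indistinguishable from a genuine two-nucleus
cluster, and the two classes could not be separated by any cascade order.
A dedicated protrusion metric for the "protruding nuclei" phrasing of the
heterogeneous class is out of scope; shape irregularity stands in for it.
These thresholds capture the verbal class definitions, not the inter-rater
behavior of any particular reviewer panel — no agreement statistics exist
to calibrate against.

## The synthetic cartridge generator

Because the patient image data are available only on request, validation
rests on synthetic cartridges with planted ground truth. Each archetype is
built from disc footprints (radius = 2σ) on the pixel grid:

* DAPI/CD45/FITC blobs carry a clipped Gaussian profile
  `peak · exp(−r²/2σ²)`.
* CK blobs are *smooth discs*: a blend of a uniform disc and the Gaussian
  cap, with the blend weight solved from the requested coefficient of
  variation. A pure clipped Gaussian has an intrinsic CV of 0.56 over its
  footprint, which would make every rendered cell "heterogeneous"; the
  blend makes homogeneous CK (CV ≈ 0.05) renderable at all. Strongly
  heterogeneous CK additionally receives multiplicative sinusoidal
  modulation (amplitude 2·CV target).
* Cluster nuclei are packed inside a CK envelope sized from the nuclei so
  that the overlay fraction stays clear of its gate threshold; cleaved
  cells scatter 3–5 round CK speckles (≤ 4 µm) over an intact nucleus;
  fragmented cells split the nucleus into 2 sub-nuclear pieces inside an
  intact CK disc; the combined class is a connected chain of three nuclear
  fragments bridged by CK speckles; tdEVs are bare CK discs of 4–10 µm;
  leukocytes are DAPI + CD45 discs; debris is a dim CK fleck with FITC
  signal, exercising the exclusion channel.

Rendering is additive over a flat background (default 2 AU), optionally
with Gaussian noise, clipped to the 12-bit range and rounded to integer
counts. Objects are placed with center-to-center spacing of at least the
sum of extents plus 6 px (so distinct objects can never fall within the
merge radius, even diagonally) and generation is bit-reproducible for a
fixed seed.

Ground-truth labels are produced by computing each planted object's
*idealized* feature vector — shape features from the exact footprint
rasterized on the pixel grid, intensity means from the closed-form profile
averages — and passing it through the same `GateSet` used downstream.
There is no independent labeling path. The generator additionally re-draws
any object whose idealized features sit within a safety margin of a gate
threshold (e.g. 10 AU on means, 15 % on areas, 0.1 on overlay), so that
noise-free rendering and rasterization differences cannot flip a planted
label; borderline objects are a property of real data that these study
conditions deliberately exclude.

What passing tests on this generator do **not** show: robustness to
optical artifacts (PSF blur, chromatic shift, uneven illumination),
touching or overlapping cells beyond threshold-level separation, and
reviewer-grade judgment on borderline morphology. The generator's
archetypes are separable by construction; real cartridges are not.

## The cohort model

Per patient, one latent log-burden `L ~ N(µ, σ)` drives both markers:
`CTC = round(exp(L + ε₁))`, zeroed with a small inflation probability, and
`tdEV = round(M · exp(L + ε₂))` with a log-normal multiplier `M` roughly
an order of magnitude above 1. The shared burden induces the strong
CTC–tdEV rank correlation seen in patients; the printed summaries
(medians, ranges, SDs) do not identify a distributional family, so the
zero-inflated log-normal is a modeling choice. Defaults are calibrated to
the two stages' published summaries: median CTC/tdEV 1/11 (CNPC,
µ = log 1, σ = 2.2) and 3.5/49.5 (CRPC, µ = log 3.5), CTC-zero fractions
near 46 %/27 %, Spearman ρ ≈ 0.85/0.90. For the paired pre/post-treatment
analysis, baselines are conditioned on CTC ≥ 3 — the screening criterion
the contributing studies imposed before leukapheresis — and a per-patient
decline factor U(0.05, 0.4) multiplies both markers, reflecting that
essentially all treated patients decline.

```{r cohort-example}
d <- simulateCohort(nPerStage = 200, seed = 1)
aggregate(cbind(ctc, tdev) ~ stage, d, median)
```

## The statistical battery

* `mannWhitneyU()` — midranks over the pooled sample, U from rank sums,
  mean ranks reported (the convention used when cohort comparisons are
  published). Two-sided p from the tie-corrected normal approximation
  without continuity correction; exact enumeration of the permutation
  distribution switches on automatically when both groups have ≤ 8
  observations. The uncorrected normal approximation deviates from the
  exact two-sided p by up to ≈ 0.07 at groups of 6–7 (mean ≈ 0.02) — an
  inherent property of approximating a discrete null, documented rather
  than hidden by a continuity correction the variant does not use.
* `spearmanRho()` — Pearson correlation of midranks, p via the
  t approximation; degenerate (zero rank variance) inputs are flagged,
  not silently dropped.
* `chiSquare2x2()` — Pearson Σ(O−E)²/E *without* Yates continuity
  correction, 1 df. The uncorrected statistic is the variant consistent
  with the published presence-by-stage comparison (p = 0.014 on the
  printed table; the corrected statistic would give ≈ 0.02).
* `pairedTTest()` — standard paired t on raw count differences (a
  log-scale option exists, off by default, since counts were compared on
  the raw scale).
* `binCounts()` — the published reporting bins: CTC {0}, [1, 5), [5, ∞)
  and tdEV ≤ 50 / > 50, with inclusive boundaries exactly as printed
  (CTC = 5 falls in "≥ 5", tdEV = 50 in "≤ 50").

`cohortReport()` assembles per-stage descriptives, the between-stage
tests, per-stage CTC–tdEV correlations and the paired tests into a tidy
results table plus a markdown report; p-values are rounded to 3 decimals
in reports and kept at full precision in CSV output.

## Numerical choices and problem sizes

Validation uses scaled-down cartridges — a handful of 200–256 px frames
with up to ~160 objects — chosen so the full suite exercises every stage
(including 1 200 rendered archetypes for subclass recovery and 20
simulated cohorts of 500 patients per stage) in a few minutes on one core;
all sizes are configuration, and the frame count scales to the
instrument's 175 without code changes. Thresholding falls back to a
background floor on constant frames (empty mask, not an error); infeasible
object packings abort with the offending frame named after bounded
retries; duplicate object ids, unknown review annotations and malformed
gate predicates are hard errors naming the offender. Determinism is a
contract everywhere: fixed seeds give bit-identical stacks, tables and
thumbnails.

## Known limitations

* The subclass thresholds are operationalizations; their agreement with
  human reviewer consensus on real images is untested and untestable from
  published material.
* The absolute AU gate thresholds presuppose a calibrated, flat
  background; the package neither models nor corrects illumination, and
  gates are applied to background-inclusive intensities by design.
* Frames are processed independently; no mosaic stitching, no declumping
  of touching cells beyond threshold separation.
* The cohort model reproduces published summary statistics, not
  patient-level data; heavy-tail behavior beyond the log-normal family
  (the published SDs suggest occasional extreme counts) is only partially
  captured.
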
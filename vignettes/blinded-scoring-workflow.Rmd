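---
title: "Blinded multi-observer image scoring: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Blinded multi-observer image scoring: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(blindscore)
```

## The workflow model

`blindscore` treats a grading study as four stages with hard contracts
between them.

**Ingestion.** An upload is identified by content signature alone (PNG/JPEG
magic bytes, the `DICM` marker at offset 128, the zip and `ftyp` signatures);
the declared filename never decides the kind. Zip archives become ordered
frame stacks (natural sort, so `img2` precedes `img10`). Every image receives
a fresh random id from the OS CSPRNG — never derived from the name, content,
or upload order — so no observable identifier can be inverted. The
observer-facing copy of the bytes is stripped of identifying metadata:
for DICOM, a configurable denylist (patient demographics,
study/series/acquisition/content timestamps, institution and personnel
names, accession and study ids) plus *all* private tags; for PNG, every
text-capable chunk; for JPEG, all APP1–APP15 and comment segments. Stripping
operates at the container level — `IDAT` and `PixelData` bytes are copied
verbatim — so pixel fidelity is exact by construction, not by re-encoding.
The original file and name are retained master-side. We chose to *strip*
metadata for the observer view rather than merely hide it at render time:
hiding leaves the values one HTTP request away, stripping makes the leak
impossible at the transport layer, and the tests assert it by grepping full
wire transcripts for planted values.

**Blinded sessions.** A session is one observer's single pass. Its
presentation order is drawn uniformly over all permutations by a
Fisher–Yates shuffle; a per-query "pick a random image" strategy would not
guarantee each image exactly once, which is why the permutation is drawn
up front and stored. The shuffle runs under a per-session seed drawn from
the CSPRNG and persisted, so any ordering can be re-derived for audit. The
seed is 31-bit — the widest integer R's RNG can be seeded with — which is
ample for audit purposes since unguessability rests on the share token and
session id, not the shuffle seed. Navigation is forward-only: one current
item, `submit_and_advance` is the only transition, the cursor never
decreases, and no operation accepts an image selector. Sessions are
resumable by session id (a browser reload must not lose work) and never
re-randomize. An observer may run several sessions under the same label;
they are reported separately, which is exactly what an intra-observer
reliability study needs.

**Share tokens.** 32 characters from a 64-symbol URL-safe alphabet, drawn
from the CSPRNG (192 bits, comfortably above a 128-bit non-guessability
floor), constant for the project's lifetime. "Temporarily valid" is
implemented as the master's enable/disable toggle plus an optional expiry
timestamp (default none) — a fixed validity duration would be arbitrary.
Unknown and disabled tokens fail with distinguishable conditions for the
master's logs but identical responses for observers.

**Aggregation.** Means are computed on the numeric encoding of answers:
numeric questions directly, single-choice questions through a per-label
numeric value declared at project creation (e.g. `"Grade 0.5"` → 0.5).
Labels may omit the encoding, in which case the question is tally-only and
summary requests signal accordingly. The displayed dispersion is the
*sample* standard deviation (n−1), undefined (absent) for n < 2; the
convention is documented rather than guessed at, since either would be
defensible for a result display. Responses from unfinished sessions are
flagged in the merged table and excluded from summaries by default — a
partial pass covers a random subset of images, and folding it into group
means would bias them.

## Grading scale

The demonstration project offers grades 0–6 in half steps (13 choices).
Half grades are included because merged result displays of such studies
show them in use; a master who wants the strict integer scale simply defines
seven choices instead.

## Measurement geometry

All tools work in image coordinates: origin at the top-left pixel center,
x rightward, y downward, sub-pixel positions allowed. This is the canvas
convention of browser viewers; it is documented prominently because DICOM
indexes pixels (row, column) = (y, x). Zoom and pan are presentation state
and never touch stored values.

- **Length** is the Euclidean distance; with a calibration it converts as
  `px × scale`. Under anisotropic DICOM spacing the per-axis displacements
  are scaled separately (`Δx·col_spacing`, `Δy·row_spacing`) and combined
  in quadrature.
- **Angle** is the interior angle at the vertex, `acos` of the normalized
  dot product clamped to [−1, 1], reported in [0, 180]°. It is invariant
  under any similarity transform and no calibration ever applies.
- **Freehand area** is `|shoelace sum| / 2` over the implicitly closed
  polygon; with calibration it converts as `px² × row_spacing ×
  col_spacing`. For a self-intersecting outline, oppositely wound regions
  cancel under this convention — the simplest well-defined choice, and the
  one documented to users.
- **Count** counts placed markers, optionally restricted to a
  boundary-inclusive rectangular region of interest.
- **Probe** reports the nearest integer pixel's value (RGB triple or
  grayscale); DICOM stored values pass through rescale slope/intercept when
  present, so CT probes read in output units.

Calibration provenance is recorded (`dicom_metadata`, `manual_scale`,
`known_object`); the known-object path is `scale = known_mm / measured_px`.

## Statistics

`spearman_cor` is Pearson's product-moment correlation applied to
average-rank transforms — the definition under ties — written out
explicitly; `stats::cor(method = "spearman")` serves as an independent
cross-check in the tests, never as the implementation. Constant inputs
signal an undefined correlation rather than returning `NA` silently.
Study summaries can be correlated either per image on observer-averaged
scores or on all observer-image pairs; both are one `summarize_responses`
call away, and the package deliberately does not privilege one.

`mann_whitney` reports U for the first sample (ties count ½) and a
two-sided p-value. For pooled sizes up to 12 the null distribution is built
by enumerating all `choose(n, n_a)` labelings of the pooled data — exact
under ties, where the classical exact tables do not apply — and
`p = P(|U − n_a n_b/2| ≥ |U_obs − n_a n_b/2|)`. Beyond that, the normal
approximation with tie-corrected variance and a continuity correction is
used; the two branches agree within 0.02 at the boundary in the tests. The
enumeration limit of 12 keeps the worst case at 924 labelings —
instantaneous — while covering the sample sizes typical of observer-timing
comparisons.

## The synthetic-data generator

`make_synthetic_png` / `make_synthetic_dicom` draw disjoint filled discs
(rejection sampling, 1000 retries per disc before a clean generation error)
and a horizontal calibration bar whose ground-truth endpoints are exactly
`bar_px` apart, returning all ground truth beside the bytes. Disc radii
scale with the image (2–5% of the short side) so both small test rasters
and realistic sizes are placeable. DICOM output is a 16-bit grayscale
secondary-capture file with arbitrary planted string elements and optional
`PixelSpacing`, written by the package's own explicit-VR little-endian
codec (cross-validated against pydicom in the test suite).

`simulate_observers` models a rater as `true score + Gaussian noise`,
discretized to the nearest grade with midpoint ties going to the lower
grade. This is a stand-in, not a claim about real raters: it has no
per-observer bias, no drift, no image-difficulty interaction, and its noise
is homoscedastic. Passing tests therefore demonstrate that the *pipeline*
recovers planted signal under honest noise — not that real observers
behave this way.

`build_demo_project` fixes the study shape: 24 images, four data groups
("2", "4", "8", "12", six images each), per-group true mean grades 1, 2,
3.5, 5 (a monotone progression across timepoints, as cartilage degeneration
scores would rise), per-image jitter SD 0.3 clipped to [0, 6], four
observers, noise SD 0.5 grades. The rising group means give recovery tests
a known signal; 0.5 grades of observer noise is chosen as a realistic
half-step disagreement level on an ordinal scale.

## Numerical and degenerate-input choices

- Angle: the dot-product ratio is clamped before `acos`, so collinear rays
  return exactly 0° or 180° instead of `NaN`; rays of zero length are a
  validation error.
- Exact Mann–Whitney comparisons use an epsilon of `sqrt(.Machine$double.eps)`
  when comparing U distances, so ties in the null distribution are counted
  inclusively regardless of floating-point noise.
- CSV export writes the numeric encoding with 15 significant digits;
  re-importing and re-aggregating reproduces the in-memory summaries to
  machine precision in the round-trip tests.
- Empty grouping (`group_by = character()`) yields the single grand row;
  empty response sets yield empty, correctly typed tables.
- A zip stack with zero decodable images is an error; undecodable entries
  inside an otherwise valid stack are skipped with a warning.

## HTTP layer

The router is a pure function from request records to response records;
`serve()` mounts it on httpuv. This keeps the entire wire contract —
including the blinding guarantees — testable in-process, with one
end-to-end test driving a real socket server through the full demo study.
Master routes sit behind a single shared admin secret (a deliberate
simplification: multi-tenant user management is out of scope). Frames are
served only through per-session HMAC-SHA256-signed URLs bound to the
session's *current* item, so a frame URL cannot be replayed in another
session or after advancing. Observer-facing error bodies carry a generic
code only. Client-side rendering (zoom, pan, window/level) is a viewer
concern: measurement points are always submitted in image coordinates, and
any client-computed values are advisory.

## Problem sizes in the test suite

The suite validates randomization uniformity with 10,000 sessions on a
5-image project (all 120 orderings observed; per-position chi-square),
geometry with 100 seeded polygons against a fan-triangulation oracle and
1000 similarity-transform trials, aggregation with 1000-response fuzz sets,
and the statistics against brute-force enumeration on all splits of pooled
samples up to n = 8. These sizes give the property checks comfortable
statistical power while keeping a full run fast on a single CPU.

## Known limitations

- DICOM support is explicit-VR little-endian, uncompressed, without
  sequence recursion — sufficient for the secondary-capture and plain
  radiography files the workflow targets; encapsulated transfer syntaxes
  are rejected up front with a clear error. The denylist approach is
  pragmatic de-identification, not full standards-conformant
  de-identification.
- MP4 is stored and served, not decoded; video frames cannot be measured.
- The observer noise model is intentionally simple (see above).
- One shared admin secret; no per-user accounts or roles beyond
  master-vs-observer.
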
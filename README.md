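# blindscore

Collaborative, **blinded, randomized image scoring** for multi-observer
studies — as a self-hostable R service with a fully testable computation
core.

## The problem

When several experts grade the same set of images — histopathology sections,
radiographs, micrographs — the standard e-mail-and-spreadsheet workflow
leaks bias at every step: filenames reveal the treatment arm, DICOM headers
carry patient names and acquisition dates, observers can flip back and forth
between images and calibrate their scores against each other, and merging
hand-kept spreadsheets is slow and error-prone.

`blindscore` implements the alternative workflow end to end:

1. **Anonymized ingestion** — uploads (JPG/PNG, MP4, DICOM, zip stacks) are
   identified by content sniffing, stripped of identifying metadata
   (denylisted DICOM elements and all private tags; PNG text chunks; JPEG
   EXIF/comment segments) without re-encoding a single pixel, and filed
   under opaque random ids. Original names stay master-side only.
2. **Token-gated, randomized, forward-only sessions** — observers reach a
   project through a non-guessable share URL. Each session draws a fresh
   uniform permutation of the images (Fisher–Yates under a stored audit
   seed); there is exactly one current item, the *Next* action stores the
   answers and advances, and nothing can be revisited or fetched by id.
3. **In-window measurement** — count, length, angle, freehand (shoelace)
   area, and pixel probe, in image coordinates (origin at the top-left pixel
   center, y down). Calibration from DICOM `PixelSpacing` (anisotropic
   spacing handled per axis), a typed-in factor, or an object of known size
   (e.g. a 25 mm ball marker): `scale = known_mm / measured_px`, lengths
   convert as `px × scale`, areas as `px² × scale²`.
4. **Immediate merging** — combined and per-observer/per-group means ± SD
   (sample SD, n−1), per-image answer tallies, RFC 4180 CSV export, and the
   method-comparison statistics used in validation studies: Spearman rank
   correlation (average ranks under ties) and a Mann–Whitney U test whose
   two-sided p-value is exact by full enumeration for pooled n ≤ 12, ties
   included.

A synthetic-data module generates images with known ground truth
(disc counts, calibration-bar lengths, planted DICOM tags) and simulated
observer cohorts (true grade + Gaussian noise, discretized to the nearest
grade), so the entire workflow is testable offline.

## Worked example

A complete simulated study — 24 synthetic images in four data groups
("2", "4", "8", "12", emulating weeks after intervention) with rising true
OARSI-style grades, scored 0–6 in half steps by four simulated observers in
independent randomized sessions:

```r
library(blindscore)
st <- store_open(":memory:")
demo <- build_demo_project(st, seed = 1)

summ <- summarize_responses(st, demo$project$project_id, demo$question_id,
                            group_by = "data_group")
summ[match(c("2", "4", "8", "12"), summ$data_group), ]
#>  data_group  n     mean        sd
#>           2 24 1.020833 0.6338147
#>           4 24 2.125000 0.6796738
#>           8 24 3.312500 0.5863020
#>          12 24 5.104167 0.5311834

round(demo$group_true_means, 3)   # the planted per-group truth
#>     2     4     8    12
#> 0.991 2.170 3.459 5.060
```

Each group mean is recovered from 24 responses (6 images × 4 observers);
the recovered means track the planted truth well within the observer noise
(SD ≈ 0.5–0.7 grades) and rise monotonically across the groups.

Measurement and statistics:

```r
measure_length(c(0, 0), c(300, 400), calibrate_known_object(250, 25))
#> <measurement:length> 500 px = 50 mm

measure_area(rbind(c(0,0), c(40,0), c(40,30), c(0,30)), calibration(0.1))
#> <measurement:area> 1200 px^2 = 12 mm^2

mw <- mann_whitney(c(84.3, 120, 60.1, 49), c(15.3, 8.2, 22.5, 11))
#> U = 16, p = 0.0286 (exact_enumeration)
```

## Running a server

```r
blindscore::serve("study.sqlite", port = 8080, admin_secret = "change-me")
```

Master routes (`x-admin-secret` header): `POST /api/projects`,
`POST /api/projects/<id>/images`, `POST /api/projects/<id>/share`,
`GET /api/projects/<id>/results?view=combined|per_observer|per_group|per_image`,
`GET /api/projects/<id>/export.csv`. Observer routes (share token only):
`POST /api/observe/<token>/sessions`, then `GET .../current`,
`POST .../submit`, with frames served solely through per-session
HMAC-signed URLs.

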
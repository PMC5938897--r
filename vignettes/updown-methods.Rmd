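---
title: "Methods: reading and scoring up-down von Frey sheets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: reading and scoring up-down von Frey sheets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(updown)
```

This vignette documents the models, numerical choices and design
decisions behind `updown`, and what its synthetic tests do and do not
establish.

## The up-down protocol and its recording grammar

Testing starts at the mid-range filament of the assay's ladder. After a
positive response (X) the next weaker filament is tested; after a
negative (O), the next stronger. Row 1 of a scoring table holds the
initial run of identical responses *up to and including* the first
response that differs; the next four trials are recorded one per row in
rows 2–5, after which the test is complete. If a subject fails to
respond to the strongest filament — or, symmetrically, responds to the
weakest — testing concludes "out of range" in whichever row that
happens, and the remaining rows stay empty.

`table_to_sequence()` inverts this grammar exactly, and
`enumerate_valid_tables()` expands it exhaustively into the lexicon of
every legal table (122 for the mouse and rat ladders, 106 for human MDT,
121 for human MPT). Two facts the test suite verifies follow from the
grammar: the lexicon equals the image of the protocol simulator over all
possible outcome vectors, and no legal table ever has more than 12
marks, so the 12-box invalidation gate (below) can never reject a
genuine recording.

## Filament ladders

The source material prints force *ranges* and start filaments per assay,
not the individual filaments. We bundle the standard commercial von Frey
set restricted to those ranges:

| assay | forces (g) | start | δ printed | δ ladder mean |
|---|---|---|---|---|
| mouse | 0.04 0.07 0.16 0.4 **0.6** 1.0 1.4 2.0 4.0 | 0.6 | 0.25 | 0.250 |
| rat | 0.6 1.0 1.4 2.0 **4.0** 6.0 8.0 10 15 | 4 | 0.17 | 0.175 |
| human MDT | 0.02 0.04 0.07 0.16 **0.4** 0.6 1.0 1.4 | 0.4 | 0.25 | 0.264 |
| human MPT | 4 6 **8** 10 15 26 60 100 180 | 8 | 0.21 | 0.207 |

Both δ values are stored on every ladder; the Dixon formula uses the
printed constant. For human MDT the printed 0.25 and the ladder mean
(≈0.26) disagree slightly; we follow the printed constant and record the
discrepancy. Log units follow the filament handle-marking convention,
`Xf = log10(10000 × grams)`, under which κ = 0 returns exactly the final
filament force — an identity the tests assert for every filament of
every ladder. Conversions to mN use standard gravity (1 gf = 9.80665
mN), reproducing the printed 39.2 / 147 / 5.88 mN endpoints.

## The κ table

κ corrects the final filament force for the response pattern near
threshold. We index it by the last six responses: the trial before the
first change, the change trial, and the four post-change trials — 32
patterns in all (the first two characters always differ). The published
transcription of the classical table was not available to this package,
so the bundled resource (`inst/extdata/kappa_table_synthetic.txt`,
marked synthetic) is *derived*: assuming a cumulative-normal response
curve in log force with scale equal to the step δ — the design
assumption behind the classical small-sample up-down tables — the six
trial positions relative to the final filament are fixed by the up-down
rule, and κ is the maximum-likelihood location measured from the final
filament in step units. Values are computed on the X-leading half of the
pattern space and negated for complements, so the antisymmetry
κ(complement) = −κ(p) is exact by construction; the loader re-validates
it, and a test re-derives every entry independently. One anchor is
closed-form: the alternating pattern `XOXOXO` has three positives one
step above three negatives, a likelihood symmetric about the midpoint,
hence κ = 1/2 exactly.

Out-of-range runs have no κ; we report the extreme filament force capped
and flagged (`OOR_HIGH`/`OOR_LOW`) so the CSV column stays numeric, with
the flag carrying the censoring information. Empty table slots and
crossed-out tables are `INVALID` with the literal `N/A` threshold.

## Optical mark reading

Pages are 8-bit grayscale rasters (default 300 dpi for printable
templates, 150 dpi for the synthetic scan fixtures — at 150 dpi a mouse
cell is ≈28×54 px, ample for the 20×20 canonical glyph, and the full
200-table acceptance round trip stays inside its time budget).

**Frame location.** The template's 2 mm solid border is found by Otsu
binarization, block-downsampled largest connected component, and
diagonal-extreme corners, refined to sub-pixel precision by
least-squares line fits through the border's outer edge pixels (the
extreme ink pixel centres sit half a pixel inside the edge; the fit
corrects for this). A 4-point homography maps layout millimetres to scan
pixels and the page is deskewed by inverse-mapped bilinear sampling.
Degenerate pages are rejected before component analysis: a blank page
under Otsu would classify sensor noise as "ink" covering half the page,
so pages with class-mean separation < 40 gray levels or ink fraction
outside (0.0001, 0.3) raise frame-not-found, as does any fiducial
quadrilateral covering less than 30% of the page.

**Cell extraction and classification.** Each cell box is cropped with a
12% inner margin (removing printed grid lines) and binarized against its
own mean minus 40 gray levels (floored at 60 so fully struck-through
cells still register). Cells with ink fraction below 0.02 are EMPTY —
this decision precedes and is independent of the classifier. Inked
patches are cropped to their ink bounding box and area-resized to 20×20
(aspect-normalizing, as usual in glyph OCR). Three k-NN members vote:
raw 400-d binary pixels (k = 3), 4×4 zone densities (k = 5), and an
8-bin gradient-orientation histogram on a blurred patch (k = 3);
Euclidean distance throughout. The k-NN is implemented in-package with
include-all-ties neighbourhoods and a deterministic vote tie-break
(smaller summed distance, then label order), which makes predictions
exactly invariant to training-set order — a property the random
tie-breaking in `class::knn` would violate.

**Repair.** Recognized tables are flattened row-major into strings over
`{X, O, .}`. Strings absent from the lexicon are replaced by the entry
at minimal Levenshtein distance (unit costs; the fixed-length encoding
makes substitutions dominate, but insertions/deletions remain supported).
Ties prefer the candidate changing the fewest high-confidence cells
(confidence = ensemble vote agreement), then the lexicographically
smallest; ties are also flagged. Repairs at distance > 3 are rejected as
unrepairable — the cutoff keeps one- and two-glyph errors repairable
while refusing to hallucinate a table from garbage; it is exposed in the
configuration because the source tool does not state one.

**The 12-box gate.** Tables with more than 12 marked cells are treated
as deliberately crossed out and reported `N/A`. 12 marks exactly is
valid (the rule is "over 12"), and the enumeration shows legal tables
never exceed 11 marks, so the gate is safe.

## The synthetic world

The generator exists so the pipeline can be tested end to end with
known ground truth; its defaults are fixed once:

* **Subjects** respond through a cumulative Gaussian in log10 force,
  P(X at f) = Φ((log10 f − log10 t)/σ); σ = 0 is the deterministic step
  responder (respond iff f ≥ t, positive at exactly t). σ = 0.1 log
  units is the default stochastic slope — a realistic
  animal-to-animal trial variability that still converges within a
  filament step. One Bernoulli draw per filament presentation
  (labs differ in how many applications they aggregate; the simulation
  abstracts that to one draw).
* **Glyphs**: X = two slightly bowed strokes with 2%-of-cell endpoint
  jitter; O = a perturbed rotated ellipse with occasional gaps; stroke
  width ≈ 10–16% of cell size. A jitter level scales all perturbations
  and adds stray-pixel flips quadratically; level 1 is "legible
  handwriting", level 5 is scrawl — classifier accuracy degrades
  monotonically across levels by construction of the scale, which the
  tests assert.
* **Scan noise presets**: `none` (geometric identity), `nominal`
  (rotation ≤ 3°, translation ≤ 2 mm, scale ±2%, Gaussian gray noise
  σ = 8), `envelope` (5°, ±5%). The scan canvas is padded 8% per side
  like a scanner bed slightly larger than the page — without the pad, a
  +5% scale would push an 8 mm-margin border off the canvas and no
  reader could succeed.
* All randomness flows from explicit seeds through a save/restore
  helper; nothing touches the caller's RNG state.

What a green end-to-end test establishes: the full chain (render →
scan-noise → rasterize → frame → cells → k-NN → repair → Dixon) recovers
exact thresholds from sheets *printed by this package and filled with
its glyph model* at the stated noise. What it does not establish:
performance on real ink, real handwriting idiosyncrasies, JPEG scanner
compression, or sheets not printed from these templates. The original
tool's benchmark on real scanned sheets (98.8% vs 96.3% human accuracy)
is not reproducible without those scans; the synthetic round trip
(100% at zero noise, ≥95% required at nominal noise on 200 tables) is
its desk-scale analog, not a replication.

## Numerical and design choices

* Coordinates: millimetres, origin top-left, y down; cell boxes
  half-open; pixel (i, j) has continuous centre (j − 0.5, i − 0.5).
  Tables are indexed row-major from 1.
* Homography: exact 4-point DLT (8×8 solve); the residual reported is
  the corner reprojection RMS.
* Otsu threshold maximizes between-class variance on a 256-bin
  histogram; binarization uses ≤ so clean black-and-white renders
  (threshold 0) keep their ink.
* Area-average resizing uses exact interval-overlap weight matrices
  (BLAS-friendly `L %*% X %*% R`), binarized at 0.3 after resize so thin
  strokes survive downscaling.
* Levenshtein: full DP for `edit_distance()`; the lexicon scan uses an
  early-abandoning bounded DP whose cap shrinks to the running minimum,
  so the minimum and all ties at it are exact.
* The ML optimization for κ is a 1-d `optimize()` on a log-concave
  likelihood over [−8, 8], tolerance 1e-10.
* PDF I/O is a minimal deterministic raster container (one FlateDecode
  grayscale XObject per page, zlib via `memCompress`) — no timestamps,
  so template generation is byte-stable. Vector-PDF input is out of
  scope offline; PGM and PNG pages are accepted directly.
* Empty tables are `INVALID/empty` (distinct from `overmarked`);
  tables whose repaired distance exceeds the cutoff are
  `INVALID/unrepairable`; unusable pages yield one flagged row per
  table slot so row counts are always pages × capacity.

## Known limitations

* Ladders are fixed per assay (as in the source tool); sheets must use
  the printed forces.
* The κ resource is a numerical reconstruction, not a transcription of
  the published appendix; values agree with the classical anchors we
  can check (antisymmetry, the ±1/2 alternating patterns) but have not
  been compared entry-by-entry against the printed table.
* Human MDT's printed δ (0.25) and the 8-filament commercial ladder's
  mean spacing (0.264) cannot both be right; we use the printed value
  in the formula.
* The reader assumes one template sheet per page, upright within ±~40°;
  it performs no general document layout analysis.
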
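---
title: "Digitizing printed 12-lead ECG pages: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Digitizing printed 12-lead ECG pages: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecgtrace)
```

## The problem and the model

A printed 12-lead ECG page is a highly structured image: four columns of
lead traces separated by drawn vertical lines, three rows of short lead
segments plus a long rhythm strip across the bottom, dark thin ink on light
paper. `ecgtrace` treats digitization as three deterministic sub-problems —
binarization, layout detection, and per-lead centerline tracking — followed
by a reconstruction-based fidelity score. Nothing is learned from data;
every stage is a transparent image-processing rule with a handful of pixel
-unit parameters.

**Binarization.** After optional cropping and Gaussian smoothing, the page
is thresholded globally with Otsu's rule: the threshold maximizes the
between-class variance of the intensity distribution, and pixels strictly
darker than it become foreground. We evaluate candidates at every distinct
intensity in the image (not a fixed bin grid), so the search is exhaustive
on the data; ties take the lowest threshold. The smoothing kernel is
truncated at radius `ceil(3 sigma)` and uses edge-repeating reflection
padding, so constant images are fixed points and the global mean is
conserved away from borders.

**Layout.** In a binary page the three separator lines dominate the
per-column foreground counts and the four isoelectric baselines dominate
the per-row counts. Raw "take the k largest bins" fails on any line thicker
than one pixel — the top bins would all belong to one line — so peaks are
selected greedily with a suppression radius: take the highest remaining
count (ties toward the lower index), disable every position strictly
within `min_sep` pixels, repeat. `min_sep` defaults to one eighth of the
page width (separators) and height (baselines), wide enough for the
4-column x 4-row grid and configurable for other spacings. Patch column
spans apply a 5 px guard band on each side of every separator — the band
also swallows the separator ink and any lead-name lettering printed next to
it. Baselines are re-estimated inside each patch rather than once globally:
per-patch estimates tolerate slightly tilted scans at no extra cost.

**Tracking.** Each lead is extracted as signed pixel offsets from its
baseline (positive above, the display convention). The seed point is found
in the first column holding ink within an `alpha`-pixel window centered on
the baseline; the trace is then followed rightward, each column's candidate
being the median foreground row within a `beta`-pixel window centered on
the previous point. The median (lower-middle element on even counts, so
rows stay integers) is what makes tracking robust to trace thickness. Two
failure rules keep the trace full-width: an empty window (a print gap)
carries the previous offset forward, and a candidate whose offset differs
from the previous one by more than `gamma` pixels is rejected as an outlier
and also carried forward. The stepwise procedure's failure branch is
deliberately resolved as "carry forward *and advance one column*": a rule
that neither appends nor advances would never terminate. Columns left of
the seed are filled with the seed offset, so the output length always
equals the patch width exactly. A lead whose seed search finds nothing
becomes a *missing* trace rather than a page failure — real pages can lack
the rhythm row.

## Parameters

| parameter | meaning | unit | default |
|---|---|---|---|
| `sigma` | Gaussian smoothing SD | px | 0.7 |
| `alpha` | seed-search window height around the baseline | px | 150 |
| `beta` | tracking window height around the previous point | px | 75 |
| `gamma` | validation margin on successive-offset jumps | px | 15 |
| `margin` | guard band beside each separator | px | 5 |
| `K1`, `K2`, `L` | SSIM stabilizers, dynamic range | — | 0.01, 0.03, 1 |

Window sizes are full heights: a window of `w` around row `r` spans
`[r - floor(w/2), r + floor(w/2)]`, clipped to the patch. `alpha` must
exceed the largest trace excursion at the patch's left edge; `beta` bounds
the steepest slope the tracker can follow (`beta/2` per column);
`gamma` trades outlier rejection against the ability to follow genuine
steep QRS flanks. The defaults are the tuned operating point for
full-page scans of the common printout format and are exposed through
`ecg_config()` / `tracking_params()`.

## Evaluation conventions

Reconstruction draws each trace as an 8-connected polyline: rows strictly
between consecutive points are split evenly between the two columns (the
odd row goes to the earlier column), which keeps each column's ink centered
on its point; thickness dilates the line vertically and symmetrically.

SSIM is computed with a *single global window* — means, variances and the
covariance over all compared pixels, population (1/N) normalization —
rather than the common sliding-window mean SSIM; windowed variants are out
of scope. `L = 1` for binary masks, 255 for 8-bit images; `K1 = 0.01`,
`K2 = 0.03` are the conventional stabilizers. MSE on 0/1 masks equals the
mismatched-pixel fraction exactly, which makes the two metrics easy to
sanity-check against each other.

`evaluate_page()` compares original and reconstruction over the union of
the four margin-trimmed patch column spans (full row extent), not the whole
page. The separator lines and guard bands are layout furniture that traces
never encode; including them would penalize every reconstruction by a
constant artifact term. With this convention, rendering the *ground-truth*
offsets of a clean thickness-1 synthetic page and scoring it against that
page's binarization gives SSIM = 1 and MSE = 0 exactly — the test suite
asserts this bit-exactly.

## The synthetic page generator

`page_spec()` + `render_synthetic_page()` draw pages that emulate the
printout format: dark traces over four isoelectric baselines, three
full-height separator lines, a rhythm waveform crossing all four patches,
variable trace thickness, short gap erasures, label clutter near column
starts, an optional faint grid, and salt-and-pepper noise. The waveform is
a sum of Gaussian bumps (P, Q, R, S, T) repeated with a fixed period plus
seeded per-beat timing jitter — a *geometric* model of how a printed trace
looks, chosen because it exercises exactly what the tracker must survive
(steep flanks bounded by `gamma`, thick lines, gaps, clutter), not a
physiological simulator.

Default geometry is a 600 x 1000 page with baselines at rows
110/255/400/530, separators at columns 250/500/750, an R amplitude of 40 px
and a beat period of 180 px — a scaled-down stand-in for ~1240 x 2000
cropped scans that preserves the ratios that matter (amplitude vs baseline
spacing, period vs patch width, slope vs `gamma`). Gap erasures default to
flat (isoelectric) segments, modeling print dropouts of the isoelectric
line; explicit `gap_spans` can be placed anywhere for stress tests. The
faint grid's gray level sits above the trace/paper Otsu split so default
binarization removes it, with a "hard grid" level available to make it
survive. Equal specs (including the seed) give bit-identical pages.

What passing the synthetic suite does *not* show: robustness to skewed or
rotated scans, colored grids requiring hue-based removal, interlaced or
overlapping leads, or pathology-realistic morphologies. Those are outside
the generator's model and the pipeline's scope.

## Numerical choices and degenerate inputs

- All indexing is 1-based with inclusive spans, row 1 at top — idiomatic R.
  Patch spans translate the slice rule "5 px inside each separator"
  literally: `[margin+1, s1-margin-1]`, `[s1+margin, s2-margin-1]`, …,
  `[s3+margin, width]`.
- Medians use the lower-middle element on even counts: rows stay integers
  and the choice is deterministic.
- Otsu requires at least two distinct intensities; single-valued images
  raise a typed error (`ecgtrace_degenerate_image`). Peak selection raises
  `ecgtrace_insufficient_peaks` when fewer than `k` positive-count
  positions survive suppression; collapsed patch spans raise
  `ecgtrace_empty_patch`.
- Color images are converted with luminance weights 0.299/0.587/0.114.

## Known limitations

- **Median bias on steep slopes.** A connected polyline must place
  connecting ink in some column; the per-column median of that ink sits up
  to a pixel off the true point on steep flanks. Extraction of a rendered
  page is therefore exact on flat traces but not bit-exact on curved ones,
  and the render–extract loop is only *approximately* idempotent (about
  0.1% of page pixels, confined to slope columns, change in one pass). The
  balanced fill rule above halves this bias relative to naive
  trailing-edge fill.
- **Thickness tie-breaks.** A line of even effective thickness has no
  central row; the lower-index tie-break shifts detected baselines by up to
  `(thickness-1)/2` px, which appears as a constant offset in per-lead
  error (well inside the `thickness/2 + 1` px recovery bound the tests
  assert).
- **SSIM is thickness-sensitive.** With one global window over sparse ink,
  every mismatched pixel is a large fraction of the foreground: a clean
  1 px-trace page scores ~0.95 while 3–5 px traces score 0.98–0.99, and a
  deliberate thickness mismatch between page and rendering lowers SSIM
  further. Reported SSIM values are therefore only comparable at matched
  thickness and matched conventions (global window, population variance).

## Problem sizes used by the test and benchmark suites

Unit tests run on 200 x 400 pages with proportionally scaled beats; the
acceptance-style suites and `scripts/acceptance.R` use the default
600 x 1000 geometry: 50 clean pages for layout recovery, 50 pages with
thickness 1/3/5 px and two 10 px gaps per trace for trace recovery and
corpus-level SSIM/MSE, 100 random images for the Otsu brute-force
cross-check and 200 random patches for the tracker-transcription
cross-check. These sizes give stable aggregate statistics while keeping a
full run in tens of seconds on one CPU.

```{r example}
gt  <- render_synthetic_page(page_spec(seed = 42, thickness = 3L))
res <- segment_page(gt$page, ecg_config(sigma = NULL, thickness = 3L))
glance(res$eval)
trace_errors(gt$traces, res$traces)
```
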
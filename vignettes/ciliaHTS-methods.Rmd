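---
title: "ciliaHTS: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ciliaHTS: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the model behind `ciliaHTS`, the parameters that
matter, the numerical conventions, and the choices made where the design was
genuinely open. It is the companion to the package reference: the reference
says *what* each function does, this document says *why*.

## The measurement problem

A ciliogenesis screen asks, per well, what fraction of cells carry a primary
cilium. The axoneme stains for acetylated α-tubulin, but that marker is not
specific: cytoplasmic microtubule bundles and the bright tubulin cloud of
mitotic-organizing centers (MTOCs) produce abundant false positives. The
dual-label strategy resolves this by requiring every putative axoneme to be
anchored at a basal body (pericentrin punctum). The basal body, not the
nucleus, is therefore the countable "cell" unit for ciliation: each basal
body contributes a Boolean (1 if an accepted cilium links to it), and the
well readout is 100 × the mean Boolean, pooled over the well's fields.
Nucleus counts are used only for the toxicity filter, where they measure
survival; a >20% nucleus/basal-body count discrepancy is reported per well.

## Per-field pipeline

1. **Background subtraction** (`subtract_background`). Rolling-ball =
   grayscale opening with a Euclidean disc (default radius 25 px), i.e. the
   background is the largest signal a disc "rolled" under the surface can
   explain. The field is edge-replicated by the radius before the opening
   and cropped afterwards, so border pixels are estimated from real edge
   values instead of implicit zeros. The alternative `mode` method subtracts
   the modal pixel value (the "black space" level): exact tabulation for
   quantized data, a 256-bin histogram midpoint otherwise. Output is clipped
   at zero.
2. **Nuclei** (`segment_nuclei`). Gaussian smoothing (σ = 2 px), Otsu
   threshold, hole filling, watershed on the distance transform to split
   touching nuclei, minimum-area filter (60 px²). Touching nuclei may merge
   or oversplit by one; nuclei only feed the cell count, so single-count
   errors are tolerable.
3. **Basal bodies** (`segment_basal_bodies`). Gaussian smoothing (σ = 1 px),
   Otsu threshold, connected components, closed-interval area filter
   (default [4, 200] px² at 0.33 µm/px) to drop specks and aggregates. The
   smoothing step matters: puncta occupy <1% of the field, and Otsu applied
   to the raw channel splits the (zero-clipped) noise mode instead — with
   smoothing the threshold lands cleanly between noise and puncta at
   realistic densities (≳50 cells per 512² field). Below that density the
   threshold can collapse into the noise floor; in a real screen such sparse
   wells are toxicity-excluded anyway, and this limitation is documented
   rather than patched. Each basal body carries a circular **local
   neighborhood** (default radius 50 px). One deliberate simplification:
   this single region serves as the normalization mask, the local-background
   region, and the local centrosome mask — one consistent definition that
   makes every downstream statistic well-defined.
4. **Cilium-channel conditioning** (`enhance_contrast`,
   `local_background_normalize`). The contrast stretch is linear with the
   top `contrast_low_pct` = 1% of pixels saturated at 1 and the
   (100 − `contrast_high_pct`) = 2nd percentile floored at 0 — an aggressive
   stretch whose two governing numbers are exposed as parameters; both
   percentiles are computed per field (enhancement is a per-field
   operation). A constant field degenerates to all zeros with a warning.
   Normalization then zeroes everything outside the union of basal-body
   neighborhoods and, within each neighborhood, keeps only pixels strictly
   above that neighborhood's 80th intensity percentile. The strict rule is
   deliberate: with a heavily tied intensity multiset, "remove below the
   80th percentile" must remove values equal to the percentile for the cut
   to retain at most the top 20%. A pixel covered by overlapping
   neighborhoods survives if any one of them keeps it.
5. **Three-class clustering** (`cluster_segment_cilia`). 1-D k-means on the
   nonzero conditioned intensities into high / medium / background; only the
   high class becomes candidates (8-connected components — axonemes are thin
   and often diagonal). Three classes, not a binary cut, because the
   percentile cut's survivors include the upper tail of the noise: the
   medium class absorbs it. Determinism: centers initialize at the 10th /
   50th / 90th percentiles, assignment ties go to the lower class, iteration
   caps at 100 with tolerance 1e-6. Fields with fewer than three distinct
   nonzero values fall back to "all nonzero pixels are high" with a warning.
6. **Filter cascade** (`run_filter_cascade`). Acceptance is conjunctive; the
   order (touching → size → ratio → snr → SD) only determines which stage a
   failing candidate is attributed to in the flag table. All boundary
   comparisons are inclusive. Each stage can be ablated (`skip=`) to
   demonstrate its necessity.
   - *Touching*: pass iff the minimum Chebyshev pixel distance to a basal
     body is ≤ `touch_max_gap_px` + 1 (adjacent pixels are distance 1 = gap
     0; the default gap of 1 tolerates one eroded pixel at the axoneme
     base). Links go to the nearest basal body, ties to the lower label.
   - *Size*: closed interval [5, 4000] px². The wide ceiling is intentional:
     MTOC cores must reach the ratio filter, whose rejection is specific and
     interpretable, rather than be silently size-capped.
   - *Mask-area ratio*: candidate area over its neighborhood area, default
     maximum 0.1. Because the percentile cut retains at most 20% of any
     neighborhood, no candidate can exceed ~0.2; 0.1 sits halfway to that
     bound, fails MTOC cores (which are exactly the surviving top-20% disc)
     and passes axonemes by more than an order of magnitude.
   - *Signal-to-background*: mean raw (background-subtracted,
     pre-enhancement) candidate intensity over the mean of the neighborhood
     minus all candidate and basal-body pixels; zero-mean background gives
     +Inf (pass). Default minimum 2.
   - *Centrosome SD distance*: the candidate mean must sit ≥ 2 SD above the
     mean of the local centrosome mask, computed over the neighborhood
     excluding all candidate pixels. Excluding the candidate itself is
     essential: a bright object dominating its own reference region would
     otherwise always "pass within" its own statistics and the filter would
     reject exactly the objects it should measure. "Outside 2 SD" is read
     one-sided above — cilia are brighter than local background, and a
     signal 2 SD *below* it has no biological reading here.

## Plate statistics

`z_prime` uses sample (n−1) SDs — control-well counts are small.
`toxicity_filter` is strict at the boundary: a well at exactly 80% of the
positive-control mean survives ("lower than 80%"). Z-scores standardize
against the negative-reference wells and are left undefined (NA) for toxic
wells; `call_hits` is one-sided above by default (`two_sided = TRUE` is
available) and `screen_stats` restricts hit calls to compound wells —
controls trivially sit many SDs from the reference mean and are not
discoveries. Z′ and Z-scores are computed per plate. No multiple-testing
correction is applied: the 3-SD rule is used as-is, by design.

## The synthetic generator

`generate_field` emulates what the assay measures, not optics: nuclei are
soft-edged super-Gaussian discs (radius 8 px), basal bodies Gaussian puncta
(FWHM 4 px), axonemes anti-aliased quadratic Bézier strokes (width 2 px,
length 12–30 px) originating at their basal body's centroid. Confounders are
generated with the geometry that should trip exactly one filter: cytoplasmic
streaks are axoneme-shaped strokes kept ≥ ~4 px clear of every basal body
(touching filter), MTOCs are bright blobs (radius 25 px) centered on a
non-ciliated cell's basal body (ratio filter). Ciliation is Bernoulli per
cell; background = offset 80 + smooth gradient (amplitude 60) + Gaussian
noise, with per-channel amplitude/noise defaults of 1000–1200 / 100–120
(SNR 10); an optional Poisson stage adds photon noise. Intensities clip at
zero; pixel size defaults to 0.33 µm (20× class).

Placement is collision-free per channel: nuclei keep ≥ 3 px apart, axonemes
avoid each other and other cells' basal-body base zones (so every base stays
reachable), with bounded retries, a deterministic angle sweep at minimum
length, and — as a last resort — relocation of the cell's own basal body
around its nucleus. Cells whose basal body falls under an MTOC blob are
forced non-ciliated (recorded in the truth table) since no clear axoneme can
exist there. If placement still fails the generator errors and suggests
lowering `n_cells`. Wells are independently reproducible via counter-based
seeds (`seed + 7919·well + 131·field`, mod 2³¹−1).

What the generator does **not** emulate — and hence what passing tests do
not show about real data: no point-spread function or optical blur, no
z-stack light physics, no illumination-field inhomogeneity beyond a linear
gradient, no cell-shape variation or clustered (colony-like) spatial
statistics, no marker-specific staining variability, no partial or branching
axonemes. Ground-truth recovery on these fields demonstrates that the
algorithm is correct and its thresholds mutually consistent, not that the
defaults are tuned for any particular microscope.

`simulate_plate_values` is the value-level companion (per-well readouts
drawn as Normal(100·f, cv·100·f), default cv = 0.05, cell counts
Normal(450, cv·450)) for studying the plate statistics at 384-well scale
without rendering images.

## Numerical conventions

- Pixel coordinates are 0-based (row, col), origin top-left, in all object
  tables; R matrices are 1-based internally.
- Quantiles are type-7 (R default) everywhere.
- All thresholds are relative (percentiles, Otsu on a max-normalized
  histogram, SD ratios), so every mask and the accepted-cilium set are
  invariant under global positive rescaling of intensities; the test suite
  checks this with power-of-2 factors, which are exact in floating point and
  so isolate algorithmic covariance from representation rounding.
- TIFF output is 16-bit with intensities stored as value/65535; readers
  restore the 0..65535 scale. Reports are RFC-4180 CSVs written through a
  binary connection (byte-stable across platforms and reruns).
- Z-stacks collapse by maximum-intensity projection by default (cilia are
  thin, bright, and may span planes); mean projection is available. The
  multi-page order is z-major: page = (z−1)·n_channels + channel index.

## Problem sizes used by tests and the acceptance script

Chosen as the package's own validation design: oracle-equivalence checks run
on twenty 192² fields of 12 cells; ground-truth recovery on fifty (tests)
or twenty (acceptance script) 512² fields of 100 cells with 15 streaks and
5 MTOCs; the image-based plate is 10 wells × 2 fields at 60 cells; screen-
level behavior uses value-level simulation of a full 384-well plate (16
positive controls, one spiked rescue compound at fraction 0.65 against
references at 0.20) across 100–500 seeded replicates.

## Known limitations

- Basal-body thresholding needs ≳50 cells per 512² field at SNR 10; sparser
  fields under-threshold (such wells are toxicity-excluded in real screens).
- Heavily overlapping axonemes (not generated by default) would merge into
  one candidate and undercount ciliation; the generator's collision-free
  placement matches the sub-confluent plating the assay itself requires.
- No B-score/spatial plate-effect normalization, no dose–response fitting,
  no cilium length measurement: out of scope by design.
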
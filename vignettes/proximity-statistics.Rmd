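---
title: "Quantifying punctum-organelle association with trajectory randomization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying punctum-organelle association with trajectory randomization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(punctaprox)
```

## The problem

A protein that clusters into diffraction-limited puncta may look
"associated" with the ER or with mitochondria simply because those
organelles are everywhere: in a cultured cell the 100 nm neighbourhood of
the ER web can cover half of the cytoplasm. Any honest association claim
therefore needs a null model that answers: *how often would a punctum with
exactly this trajectory be within 100 nm of the organelle if it had been
placed anywhere in the cytoplasm at random?* `punctaprox` builds that null
by rigid trajectory randomization and tests the observed excess with a
paired design across cells.

## The model and its assumptions

Per cell, the pipeline produces one distance sample per detection of every
tracked punctum (a long-lived punctum contributes many samples — the
statistic deliberately describes occupancy *over time*, not a per-punctum
average; per-track averaging is available by aggregating the sample table
yourself). The distance is the exact Euclidean distance from the subpixel
centroid to the nearest organelle-positive pixel center, and exactly 0
when the centroid's own pixel is organelle-positive. This
centroid-to-mask-pixel convention keeps an exact brute-force oracle
available: it is evaluated by ring search over pixel centers, never by
interpolating a distance map.

The null repositions each trajectory by a rigid motion: a translation
drawn uniformly over the cytoplasm (rejection-sampled until every point of
the moved trajectory is inside the mask) plus, by default, a uniform
rotation about the trajectory centroid. Randomizing whole trajectories
rather than individual points preserves the temporal autocorrelation of
the motion; including rotation removes orientation bias in elongated
cells (`mode = "translate"` is available for sensitivity analysis). The
per-cell null fraction is the mean over `n_replicates` (default 100)
replicates. Observed-minus-null differences are tested across cells with
a two-sided paired t-test; pairing is essential because cells share no
common chance level — a cell with a denser ER has a higher null.

Assumptions worth stating: distances are 2-D (a single optical section);
the cytoplasm mask is the placement domain, so if the nucleus should be
excluded it must be excluded from the mask the caller provides; and the
test treats cells as exchangeable units, so n is the number of cells, not
of puncta.

## Key parameters

| parameter | default | units | why |
|---|---|---|---|
| `threshold_nm` | 100 | nm | association cutoff, inclusive (`<=`) |
| `pixel_size_nm` | 80 | nm/px | typical confocal sampling with a 63x/1.4 NA objective; all distance logic is in nm so the choice is isolated |
| `n_replicates` | 100 | – | stabilizes the per-cell null mean |
| `mode` | translate_rotate | – | see above |
| `max_attempts` | 200 | – | placement draws before keeping the original position (warned) |
| `log_sigma_px` | 1.6 | px | LoG scale matching a ~200 nm spot at 80 nm/px |
| `min_response` | 30 | intensity | frozen after measuring rendered-spot responses across generator seeds (~20% of the default spot amplitude) |
| `max_disp_px`, `max_gap` | 5, 1 | px, frames | modest punctum mobility; gap-closed links get a per-gap budget `max_disp_px * gap` |
| `min_track_length` | 3 | frames | randomization statistics need trajectories, not flickers |
| `assoc_distance_um` (immunogold) | 0.03 | µm | silver-enhanced gold sits tens of nm from its epitope; 30 nm acknowledges that while remaining strict |

## What the synthetic generator emulates — and what it does not

`generate_cell_geometry()` draws a star-convex cytoplasm blob, an ER web
(minimum spanning tree over nodes scattered in the cytoplasm, edges drawn
2–4 px wide, a few loop-closing chords added) and 2–6:1 elliptical
mitochondria. With the default ER node density (25 nodes per 1000
cytoplasm pixels, frozen after measuring across seeds) the 100 nm ER
neighbourhood covers ≈47% of the cytoplasm — a deliberately high chance
level, because that is exactly the regime in which naive colocalization
overstates association. `simulate_puncta_tracks()` seeds each punctum
organelle-associated with probability `p_assoc` (within `assoc_radius_nm`,
verified on the exact distance) or uniformly; free puncta diffuse with
isotropic Gaussian steps reflected at the cytoplasm boundary (reflection
avoids the re-sampling bias of rejection), associated puncta ride their
organelle's per-frame rigid jitter plus a mean-reverting AR(1) tether
residual (coefficient 0.7, SD one quarter of the free step SD) so they
track the organelle instead of diffusing off it. `render_timelapse()`
renders Gaussian-PSF spots and mask channels with Poisson-then-Gaussian
noise.

Deliberately not modeled: 3-D structure and z-stacks, photobleaching, ER
fission/fusion and mitochondrial fragmentation dynamics, non-Gaussian PSFs,
punctum merging/splitting, and organelle rotation (organelle motion is
translation-only rigid jitter — the simplest motion that still forces
per-frame mask recomputation). Consequently, green tests certify the
*statistics* — null calibration, effect recovery, exactness of distances —
on data whose realism is qualitative, not that the defaults are optimal
for any particular microscope.

## Numerical choices

- **Coordinates** are `(row, col)`, 1-based, pixel centers at integer
  coordinates — matrix indexing order, stated once and used everywhere.
- **Step-length exactness.** Rigid motions preserve step lengths by
  definition, so randomized trajectories are rebuilt from the original
  step lengths and headings (polar form: rotation only adds to the
  heading) and the parent's step lengths are carried on the replicate.
  The shape-preservation invariant therefore holds bit-for-bit, not
  merely to floating-point rounding.
- **Otsu** is an exhaustive search over 256 quantized levels maximizing
  between-class variance (ties resolve to the lowest cut); constant
  images are an error, as is a membrane frame with no closed contour.
- **Detection** takes strict local maxima of a negated LoG response
  (kernel zero-meaned so flat background responds 0, scaled so a matched
  spot of amplitude A responds ≈A/2) and refines them by intensity-weighted
  centroid over a (2⌈2σ⌉+1)² window of the background-subtracted frame.
- **Linking** is greedy mutual-nearest (candidate links accepted in order
  of increasing displacement): at the sparse densities simulated it
  attains the enumerated optimum — the suite checks this against a
  brute-force assignment oracle on small well-separated cases — without a
  full assignment solver. Within-frame processing order is canonicalized
  so linking is invariant to detection order.
- **Degenerate inputs** error loudly rather than silently: empty organelle
  masks, zero-variance paired differences, constant correlation profiles,
  zero-denominator Manders coefficients, cells with no distance samples.
- **Fraction profiles** mix a shared latent `z` with marker noise,
  `x = a z + e`, `a = noise_sd * sqrt(|r|/(1−|r|))`, so the population
  correlation equals the target; `noise_sd = 0` is only meaningful with
  `|r| = 1` and is rejected otherwise.
- The **n = 12** used for the cofractionation correlation p-values is an
  inference (24 gradient fractions paired two-by-two onto 12 lanes),
  confirmed because the same t-transform at n = 12 simultaneously
  reproduces all three reported (r, p) pairs to their printed precision.

## Validation strategy and problem sizes

The suite validates each stage against an independent oracle: exact
brute-force nearest-pixel search for all distances (50 random masks × 20
subpixel queries at 1e-9 nm), exhaustive 256-level search for Otsu,
enumerated optimal assignment for linking, quadrature of the dilated
organelle footprint for the randomization null (10,000 single-point
placements, mean within 3 SE of the area fraction, χ² occupancy-grid
uniformity at α = 0.01), and closed-form textbook formulas for the t-tests.
Calibration and power use simulation at sizes chosen for tight-enough
Monte-Carlo error: 400 repeats of a 13-cell null experiment (25 puncta and
25 randomization replicates per cell, single-frame trajectories, geometry
reused across repeats) for the 5% rejection-rate check, and 100 repeats of
the fraction-level effect model for power. The effect model's defaults —
chance level 46.95% with 20-point between-cell SD, excess 23.87 points
with 5.1-point SD — encode the reported group means, SEMs and paired-test
statistic of a 13-cell ER-association experiment; the full imaging
pipeline (render → segment → detect → link → randomize) is additionally
checked to recover the ordering of `p_assoc` ∈ {0, 0.5, 1} and ≥90%
association at `p_assoc = 1`.

## Known limitations

Real ER networks are denser and more reticulated than an MST web, and a
trajectory that leaves the focal plane simply ends here. The greedy linker
has no motion model and will mis-link at densities far above those
simulated. The cytoplasm mask may include the nucleus unless the caller
excludes it; whether that matters depends on whether puncta can actually
enter the nuclear region. Rotation of randomized trajectories is about the
trajectory centroid only; strongly curved cells near the boundary can make
valid placements rare, in which case the affected track keeps its original
position and a warning reports the count — inspect it before trusting the
null for cells with extreme geometry.
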
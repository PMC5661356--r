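---
title: "Activity-based level-set segmentation of calcium imaging videos"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Activity-based level-set segmentation of calcium imaging videos}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Two-photon calcium imaging records the activity of neuronal populations as
a `T x H x W` fluorescence video. Before any spike inference or population
analysis, the regions of interest (ROIs) -- somata, dendrites, or mixtures
-- must be located. Cells vary in shape, size and baseline brightness;
genetically encoded indicators excluded from the nucleus produce annular
("donut") intensity profiles; and the low axial resolution of two-photon
microscopy makes cells in nearby z-planes *overlap* in the image plane, so
single pixels can carry the summed signal of two cells. `caimseg`
implements a segmentation model built for exactly these conditions.

## The model

Each candidate ROI `i` carries a level set function `phi_i(x)`: positive
inside the cell interior `in_i = {phi_i > 0}`, negative outside, zero on
the active contour. The exterior is restricted to a *narrowband*, the
annulus of pixels within `2r` of the interior (with `r` the expected cell
radius), so each contour only ever looks at a local patch of the video.

The model assumes that the local patch splits into two temporally coherent
regions. Writing `I(x)` for the time course of pixel `x`, `f_in` for the
average time course of pixels exclusively in the interior, and `f_out` for
the average over narrowband pixels outside every interior, the external
(data) energy of a single cell is

    E_ext = sum_{x in interior} D(I(x), f_in) +
            sum_{x in narrowband} D(I(x), f_out)

with a dissimilarity `D`. With `M` cells the interior term becomes
`D(I(x), sum_{j in C(x)} f_in_j)` where `C(x)` lists the cells whose
interior contains `x`: a pixel shared by several cells is explained by the
*sum* of their time courses. Overlap is never penalized -- this is what
lets the model demix cells that genuinely overlap in the optics.

Two metrics are provided:

* **Euclidean** `D(a, b) = ||a - b||_2` -- uses pattern *and* magnitude;
  the default, suited to synthetic dyes with fairly uniform brightness.
* **Correlation** `D(a, b) = 1 - cor(a, b)` -- scale- and offset-free;
  suited to donut cells and uneven indicator expression, where pixels of
  one cell share a temporal pattern at different amplitudes.

The total cost `lambda * E_ext + mu * R` adds the double-well
distance-regularization energy `R`, minimized when `|grad phi| = 1` near
the contour and `0` far away. Its gradient flow keeps `phi` close to a
signed distance function throughout, so no periodic re-initialization is
needed; `phi` is re-initialized only when two contours merge.

Each sweep updates every active contour in ascending index order by the
discretized descent

    phi <- phi - delta_tau * (lambda * dirac_eps(phi) * V + mu * dR/dphi)

where the smoothed Dirac `dirac_eps` (cosine bump, half-width `epsilon`)
confines the data force to the contour band, and the external velocity `V`
compares each band pixel with the interior and background features (two
branches: plain pixels use `D(I, f_in) - D(I, f_out)`; pixels inside
neighbouring cells compare the summed explanations with and without this
cell). A pixel that looks like the interior -- or, in an overlap, whose
time course is better fit once this cell's feature is added to its
neighbours' sum -- pulls the contour outward; otherwise it pushes it back.

## Parameters

| parameter | default | meaning |
|---|---|---|
| `radius` | (required) | expected cell radius, pixels |
| `lambda` | (required) | weight of the data term |
| `metric` | `"euclidean"` | dissimilarity (see above) |
| `delta_tau` | 10 | evolution step |
| `mu` | `0.2/delta_tau` | regularizer weight; `mu*delta_tau < 0.25` (CFL) is asserted |
| `epsilon` | 2 px | Dirac band half-width |
| `alpha` | 0.5 | seeding selectivity, SD units (0.2–0.8 recommended) |
| `n_max`, `n_con`, `rho` | 100, 40, 2 | stop after `n_max` sweeps, or when fewer than `rho` interior pixels change for `n_con` consecutive sweeps |
| `min_area`, `max_area` | 3, `3*pi*r^2` px | pruning bounds |
| `merge_threshold` | 0.8 | interior-correlation gate for merging |
| `narrowband_width` | `2*radius` | exterior annulus width |

Only `radius` and `lambda` need choosing per dataset. `lambda` must beat
the regularizer's smoothing bias without destabilizing the update; because
the correlation metric bounds `D` in `[0, 2]`, useful values are of order
1 (we use `lambda = 2` throughout the synthetic studies below), whereas
the unnormalized Euclidean metric calls for dataset-specific tuning on a
small crop, typically on the order of tens to hundreds.

The merge threshold has a closed-form link to trace quality: two pixel
sets from the *same* cell, observed with independent noise at
signal-to-noise ratio `SNR_dB`, have expected trace correlation
`1/(1 + 10^(-SNR_dB/10))` (`merge_threshold_from_snr()`). The 0.8 default
corresponds to an assumed 5 dB; `estimate_trace_snr()` measures the SNR at
the seeding scale if a data-derived threshold is wanted
(`snr_db = "auto"`). Note the trade-off: raising the threshold toward the
correlation of genuine same-cell duplicates (about 0.95 and higher on
clean data) stops redundant seeds from being absorbed, so thresholds far
above the default are counterproductive.

## Initialization, merging, pruning

Automatic seeding takes the extended maxima (h-maxima with
`h = alpha * SD`, then regional maxima) of both the correlation image and
the mean image; bright-but-silent structures must be seeded too, or their
pixels would contaminate the narrowband of neighbouring ROIs. Mean-image
seeds whose centroid duplicates a correlation-image seed (within `r`) are
collapsed onto the latter. A fixed-grid initialization (`init = "grid"`)
is also provided: discs on a lattice covering the field. For the grid to
guarantee a seed well inside every cell, the spacing must satisfy
`spacing * sqrt(2) / 2 + disc_radius < r`; we use spacing `1.5 r` with
discs of `r / 2`.

During evolution:

* contours outside `[min_area, max_area]` are **pruned** (background
  seeds shrink or wander; merged background blobs overshoot the maximum);
* nearby contours (minimum boundary distance at most `r`) whose interior
  time courses correlate at or above `merge_threshold` are **merged**,
  greedily in descending correlation, the pair being replaced by one
  signed-distance level set of the union of interiors;
* with `prune_undifferentiated = TRUE`, a contour whose converged
  interior correlates with its own narrowband at or above
  `undiff_threshold` (default 0.8) is dropped: it is indistinguishable
  from local background. This is the natural companion of grid seeding,
  where most seeds start on background;
* at the end of the run, redundant survivors are resolved explicitly,
  smallest-first: a contour with fewer than `min_area` pixels *exclusive*
  to itself (wholly contained in other interiors), and a contour with two
  or more neighbours within one radius whose interior trace correlates
  with the **sum** of those neighbours' interior features at or above the
  merge threshold. The second rule closes a genuine degeneracy of the
  cost: the partitions "A and B overlapping" and "A-minus-overlap,
  B-minus-overlap, overlap-as-its-own-region" fit the data equally well,
  so a seed landing exactly on an overlap zone can survive there; its
  signature -- a trace equal to the sum of its neighbours' -- is exactly
  the quantity the overlap model already computes. Under the correlation
  metric both kinds of impostor are velocity-neutral, so no force removes
  them during evolution.

Two scheduling choices are deliberate. Merging and pruning run every
sweep, but merge decisions start only at sweep `merge_start` (default 1).
With dense grid seeding we set `merge_start = 10`: a freshly seeded disc
still straddles cell fringes and background, its interior trace is an
arbitrary mixture, and correlations between such immature traces are
inflated -- merging on them can weld two overlapping cells into one
contour before their own seeds have claimed them. Ten sweeps is roughly
one cell radius of contour travel at the observed front speed, after
which interior features are dominated by the cell each contour has locked
onto. Converged contours are frozen but keep contributing to their
neighbours' overlap maps, feature sums and merge tests: the coupling must
outlive individual convergence.

## Numerical choices

Spatial derivatives are central differences with replicate (Neumann)
boundaries. The Dirac approximation is the cosine bump
`(1 + cos(pi phi / epsilon)) / (2 epsilon)` on `|phi| <= epsilon`. The
double-well potential has minima at gradient magnitudes 0 and 1 with
`d_p(s) = p'(s)/s` continued by its limit 1 at `s = 0`. Interior and
narrowband are recomputed from `phi` and an exact Euclidean distance
transform after every update, so the narrowband never drifts from its
definition even when `phi` deviates from a perfect signed distance.
Region features are recomputed once per cell per sweep (sequentially, so
each update sees its neighbours' latest features). Zero-variance time
courses contribute correlation 0 everywhere (correlation image,
correlation metric): a flat trace is treated as uninformative rather than
similar or dissimilar, which keeps dead pixels from seeding or steering
contours. Degenerate candidates (empty masks, all-background videos) fail
fast with informative errors; an interior emptied by evolution is caught
by the minimum-area prune on the same sweep.

## The synthetic generator

`simulate_video()` emulates the structure of real recordings that the
model relies on, with every parameter in `synth_spec()`:

* independent homogeneous Poisson spike trains per cell (default 0.5 Hz
  for 30 s at 10 Hz sampling: every cell is expected to fire ~15 times,
  enough for temporal signatures to be distinguishable);
* a stereotyped transient: causal exponential, amplitude 100 a.u., decay
  1 s -- a generic indicator response; the segmentation itself assumes no
  waveform, so the exact shape is immaterial downstream;
* donut cells: disc masks (radius jittered ±15%) whose pixel weights fall
  linearly from 1 at the boundary to 0.3 at the centre, plus a uniform
  baseline drawn from U(20, 50);
* overlap: cells flagged to overlap are laid out as pairs at centre
  distance `1.5 r` (plus one open 3-chain when the count is odd, bent so
  its end cells stay clear of each other). Every overlap pixel therefore
  has exactly two contributors, and its value is the sum of both cells'
  contributions;
* background in non-cell pixels, generated independently of the cells: a
  static smooth inhomogeneous offset plus a smooth spatial gain field (in
  [0.5, 1], correlation scale `4r`) times a slow unit-SD temporal
  modulation (~2 s correlation), amplitude 40 a.u. -- standing in for
  neuropil and slow global fluctuations;
* white Gaussian noise of configurable SD everywhere.

The `demix25_spec()` preset fixes the 25-cell benchmark: 128 x 128 field,
25 cells of radius 6, 17 of them overlapping a neighbour, noise SD 60
against transient amplitude 100 -- a regime where single-pixel traces are
noise-dominated but region averages are workable.

What the generator does *not* emulate: motion artefacts, photobleaching,
slow drift correlated with cellular activity, indicator nonlinearity and
saturation, and anisotropic cell shapes. Passing the synthetic benchmarks
therefore demonstrates correct demixing and robustness to noise and
background structure, not robustness to registration errors or exotic
morphologies.

## Benchmark problem sizes

The validation suite runs, per realization, a 128 x 128 x 300 video
downsampled by 3 before segmentation (downsampling by averaging is part
of the recommended pipeline: the model is agnostic to temporal waveforms,
and a factor `k` raises trace SNR by `sqrt(k)`). The demixing benchmark
uses 10 noise realizations with grid initialization (spacing 9, disc
radius 3, 196 seeds), correlation metric, `lambda = 2`,
`prune_undifferentiated = TRUE`, `merge_start = 10`; scored by one-to-one
optimal centre matching within 5 px and the harmonic-mean success rate.
The single-cell recovery study uses a 48 x 48 field with noise calibrated
to a mean per-pixel SNR of 10 dB over the cell; the crowding study
compares sweeps-to-convergence of a seeded cell with 0 vs 4 neighbours
placed at 13 px on a 72 x 72 field, five realizations each.

## Known limitations

* One contour per seed: a cell with no seed is never found, and a seed
  spanning two cells can only be rescued by the coupling and merging
  machinery, not split explicitly.
* The correlation metric cannot distinguish a pixel containing `a + b`
  from one containing `k (a + b)`; demixing relies on neighbours'
  features, and pathological geometries (e.g. a region lying in three
  cells at once) admit degenerate explanations.
* Dense clusters with smooth correlation images can under-seed under
  automatic initialization; the grid initializer is the fallback.
* Runtime grows linearly with the number of active contours and is
  insensitive to video length after downsampling, but the per-sweep cost
  is dominated by distance transforms and feature extraction on the full
  field; very large fields would want windowed updates.
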